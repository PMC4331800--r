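consensus_training <- function(n = 20L) {
  tibble::tibble(minus35 = rep("TTGACA", n), spacer_len = rep(17L, n),
                 minus10 = rep("TATAAT", n))
}

test_that("the consensus configuration scores exactly zero", {
  model <- build_promoter_model(consensus_training())
  set.seed(91)
  for (i in 1:5) {
    spacer_seq <- random_dna(17)
    expect_identical(score_window(paste0("TTGACA", spacer_seq, "TATAAT"),
                                  17L, model), 0)
  }
})

test_that("every perturbation of the consensus scores below zero", {
  model <- build_promoter_model(consensus_training())
  spacer_seq <- strrep("A", 17)
  consensus <- paste0("TTGACA", spacer_seq, "TATAAT")
  for (pos in c(1:6, 24:29)) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(consensus, pos, pos))) {
      mut <- consensus
      substr(mut, pos, pos) <- b
      expect_lt(score_window(mut, 17L, model), 0)
    }
  }
})

test_that("matrix entries equal hand-computed log-odds on a toy set", {
  toy <- tibble::tibble(
    minus35 = c("TTGACA", "TTGACA", "TTGACA", "CTGACA"),
    spacer_len = c(17L, 17L, 17L, 17L),
    minus10 = rep("TATAAT", 4)
  )
  model <- build_promoter_model(toy, pseudocount = 0.5)
  # column 1 of the -35: counts T=3, C=1; log-odds vs 0.25 background with
  # pseudocount 0.5, then shifted so the column max is zero
  lo <- log((c(A = 0.5, C = 1.5, G = 0.5, T = 3.5) / 6) / 0.25)
  expect_equal(unname(model$pwm35[, 1]), unname(lo - max(lo)),
               tolerance = 1e-12)
})

test_that("spacer scores are shifted empirical log-frequencies", {
  tr <- tibble::tibble(
    minus35 = rep("TTGACA", 4), spacer_len = c(16L, 17L, 17L, 18L),
    minus10 = rep("TATAAT", 4)
  )
  model <- build_promoter_model(tr)
  expect_equal(unname(model$spacer_score[["17"]]), 0)
  expect_equal(unname(model$spacer_score[["16"]]), log(1 / 2))
  expect_equal(unname(model$spacer_score[["18"]]), log(1 / 2))
  expect_identical(unname(model$spacer_score[["19"]]), -Inf)
  # spacer contribution is additive on top of element scores
  sp <- strrep("G", 18)
  expect_equal(score_window(paste0("TTGACA", sp, "TATAAT"), 18L, model),
               log(1 / 2))
})

test_that("training violations are rejected", {
  bad_spacer <- tibble::tibble(minus35 = "TTGACA", spacer_len = 25L,
                               minus10 = "TATAAT")
  expect_error(build_promoter_model(bad_spacer), "support")
  no_17 <- tibble::tibble(minus35 = rep("TTGACA", 3),
                          spacer_len = c(16L, 16L, 18L),
                          minus10 = rep("TATAAT", 3))
  expect_error(build_promoter_model(no_17), "17")
})

test_that("the worst window matches brute-force enumeration at reduced width", {
  # 2 bp elements make the full 4^4 = 256 element space enumerable
  set.seed(101)
  tr <- tibble::tibble(
    minus35 = sample(c("TT", "TA", "TG"), 30, replace = TRUE,
                     prob = c(0.6, 0.2, 0.2)),
    spacer_len = sample(c(16L, 17L, 18L), 30, replace = TRUE,
                        prob = c(0.2, 0.6, 0.2)),
    minus10 = sample(c("CA", "CG", "AA"), 30, replace = TRUE,
                     prob = c(0.6, 0.2, 0.2))
  )
  model <- build_promoter_model(tr)
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(a = bases, b = bases, c = bases, d = bases,
                        stringsAsFactors = FALSE)
  spacer_seq <- strrep("A", 17)
  scores <- apply(combos, 1, function(r) {
    score_window(paste0(r["a"], r["b"], spacer_seq, r["c"], r["d"]),
                 17L, model)
  })
  expect_equal(max(scores), 0)
  got_min <- min(scores)
  # independent brute-force: worst column entries summed
  worst <- sum(apply(model$pwm35, 2, min)) + sum(apply(model$pwm10, 2, min))
  expect_equal(got_min, worst, tolerance = 1e-12)
})

test_that("scan finds a planted consensus promoter once, at score zero", {
  set.seed(111)
  model <- build_promoter_model(consensus_training())
  g_seq <- random_dna(600)
  promoter <- paste0("TTGACA", random_dna(17), "TATAAT")
  substr(g_seq, 101, 129) <- promoter
  g <- genome_record(g_seq, topology = "linear")
  preds <- scan_genome(g, model, threshold = -1)
  expect_equal(nrow(preds), 1L)
  expect_equal(preds$score, 0)
  expect_equal(preds$start, 101L)
  expect_equal(preds$end, 129L)
  expect_identical(preds$strand, "+")
  expect_error(scan_genome(g, model, threshold = -Inf), "finite")
})

test_that("lower thresholds give supersets of predictions", {
  set.seed(121)
  tr <- simulate_training_promoters(n = 300, seed = 5)
  model <- build_promoter_model(tr)
  g <- genome_record(random_dna(4000), topology = "linear")
  strict <- scan_genome(g, model, threshold = -3)
  loose <- scan_genome(g, model, threshold = -6)
  key <- function(p) paste(p$start, p$strand)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("strand-bias threshold selection follows the order statistics", {
  preds <- tibble::tibble(
    start = 1:4, end = 30:33,
    strand = c("-", "-", "-", "+"),
    minus35 = "x", spacer_length = 17L, minus10 = "y",
    score = c(-1, -2, -3, -4)
  )
  thr <- threshold_by_strand_bias(preds, required_minus = 3)
  expect_equal(thr$threshold, -3)
  expect_equal(thr$n_minus, 3L)
  expect_equal(thr$n_plus, 0L)
  expect_true(thr$achieved)
})

test_that("an all-plus top list triggers the warning path", {
  preds <- tibble::tibble(
    start = 1:2, end = 30:31, strand = c("+", "-"),
    minus35 = "x", spacer_length = 17L, minus10 = "y",
    score = c(-1, -5)
  )
  warns <- testthat::capture_warnings(
    thr <- threshold_by_strand_bias(preds, required_minus = 1)
  )
  expect_gte(length(warns), 1L)
  expect_match(warns, "threshold|predictions", all = FALSE)
  expect_false(thr$achieved)
})

test_that("matrices rebuilt from 500 sampled promoters recover the model", {
  freq35 <- phagetx:::default_sigma70_freq("TTGACA",
                                           c(0.7, 0.65, 0.55, 0.45, 0.4, 0.5))
  freq10 <- phagetx:::default_sigma70_freq("TATAAT",
                                           c(0.7, 0.72, 0.45, 0.42, 0.45, 0.75))
  n <- 500L
  tr <- simulate_training_promoters(n = n, freq35 = freq35,
                                    freq10 = freq10, seed = 9)
  model <- build_promoter_model(tr, pseudocount = 0.5)
  expect_identical(model$consensus35, "TTGACA")
  expect_identical(model$consensus10, "TATAAT")
  shift0 <- function(m) sweep(m, 2, apply(m, 2, max))
  check <- function(pwm, freq) {
    err <- abs(pwm - shift0(log(freq / 0.25)))
    se_log <- sqrt(freq * (1 - freq) / n) / freq
    tol <- 4 * sweep(se_log, 2, apply(se_log, 2, min), "+") + 0.02
    expect_true(all(err < tol))
  }
  check(model$pwm35, freq35)
  check(model$pwm10, freq10)
})
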