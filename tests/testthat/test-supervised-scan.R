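region_row <- function(sequence, strand = "+", g5 = 1L, gene = 1L) {
  tibble::tibble(
    region_id = 1L, downstream_gene = gene, upstream_gene = NA_integer_,
    strand = strand, gap_start = g5, gap_end = g5 + nchar(sequence) - 1L,
    gap_len = nchar(sequence), fused_offset = 0L, g5 = g5,
    sequence = sequence
  )
}

test_that("core_scan slides a 2+core+4 window over the direct strand", {
  g <- genome_record(strrep("A", 100), topology = "linear")
  w <- core_scan(region_row("AAAGTGATGTGTAAAA"), g)
  expect_equal(nrow(w), 1L)
  expect_identical(w$sequence, "AGTGATGTGTAA")
  expect_equal(w$offset, 3L)
  expect_equal(w$coord_window, 3L)
  expect_equal(w$coord_core, 5L)

  none <- core_scan(region_row("AAAACCCCGGGGTTTT"), g)
  expect_equal(nrow(none), 0L)
})

test_that("edge-truncated and ambiguous windows are skipped", {
  g <- genome_record(strrep("A", 100), topology = "linear")
  # core starts at position 2: no room for the left flank
  w <- core_scan(region_row("ATGATGTAAAAAA"), g)
  expect_equal(nrow(w), 0L)
  amb <- core_scan(region_row("AANGTGATGTGTAAAA"), g)
  expect_equal(nrow(amb), 0L)
  expect_gte(attr(amb, "n_skipped"), 1L)
})

test_that("windows on '-' regions get genomic coordinates on that strand", {
  g <- genome_record(strrep("A", 200), topology = "linear")
  r <- region_row("AAAGTGATGTGTAAAA", strand = "-", g5 = 116L)
  w <- core_scan(r, g)
  # offset 3 on the oriented strand: genomic coordinate counts downwards
  expect_equal(w$coord_window, 116L - 3L + 1L)
  expect_equal(w$coord_core, 116L - 5L + 1L)
})

test_that("long/short classification follows the TG + TATA rule", {
  g <- genome_record(strrep("A", 100), topology = "linear")
  mk <- function(seq) {
    # one core mismatch allowed: alignment-discovered long motifs can
    # carry one (the classification rule must still see them)
    w <- core_scan(region_row(paste0("AA", seq, "AA")), g,
                   max_core_mismatch = 1L)
    classify_long_short(w[w$offset == 3L, ])
  }
  expect_identical(mk("TGTGATGTTATA")$promoter_class, "late_long")
  expect_identical(mk("GGGGATGTTATA")$promoter_class, "late_long")
  expect_identical(mk("AGTGATGTGTAA")$promoter_class, "middle_short")
  # two mismatches in the TG segment: not long even with TATA
  expect_identical(mk("CATGATGTTATA")$promoter_class, "middle_short")

  # anchors: window 5' end for long, core 5' end for short
  long <- mk("TGTGATGTTATA")
  short <- mk("AGTGATGTGTAA")
  expect_equal(long$genomic_coordinate, long$coord_window)
  expect_equal(short$genomic_coordinate, short$coord_core)
})

test_that("every window gets exactly one class", {
  set.seed(61)
  g <- genome_record(strrep("A", 100), topology = "linear")
  seqs <- vapply(1:30, function(i) {
    paste0(random_dna(2), "TGATGT", random_dna(4))
  }, character(1))
  w <- core_scan(region_row(paste(paste0("CC", seqs, "CC"), collapse = "")), g)
  cls <- classify_long_short(w)
  expect_true(all(cls$promoter_class %in% c("late_long", "middle_short")))
  expect_equal(nrow(cls), nrow(w))
})

test_that("information content matches hand-computed entropies", {
  expect_equal(information_content(c("T", "T"))$ic, 2)
  expect_equal(information_content(c("A", "C", "G", "T"))$ic, 0)
  got <- information_content(c("T", "T", "T", "G"))$ic
  expect_equal(got, 2 + 0.75 * log2(0.75) + 0.25 * log2(0.25),
               tolerance = 1e-12)
  expect_error(information_content(c("AC", "ACG")), "equal lengths")
  logo <- information_content(c("ACGT", "ACGA"))
  expect_true(all(abs(colSums(logo$freq) - 1) < 1e-12))
  expect_true(all(logo$ic >= 0 & logo$ic <= 2))
})

test_that("window p-values are exact score tails", {
  profile <- information_content(rep("TGTGATGTTATA", 20), pseudocount = 0.5)
  # the consensus window is the unique maximum-score word
  p_best <- window_pvalue("TGTGATGTTATA", profile)
  expect_equal(p_best, 0.25^12, tolerance = 1e-15)

  uniform <- structure(
    list(freq = matrix(0.25, 4, 12, dimnames = list(c("A", "C", "G", "T"))),
         ic = rep(0, 12), n = 4),
    class = "logo_matrix"
  )
  expect_equal(window_pvalue("ACGTACGTACGT", uniform), 1)

  raw <- information_content(rep("TGTGATGTTATA", 20))
  expect_error(window_pvalue("TGTGATGTTATA", raw), "degenerate")
})

test_that("p-values decrease with score and match Monte-Carlo draws", {
  profile <- information_content(
    c("TGTGATGTTATA", "TGTGATGTTATA", "TGTAATGTTATA", "GGGGATGTTATA"),
    pseudocount = 0.5
  )
  set.seed(71)
  lo <- log(profile$freq / 0.25)
  windows <- vapply(1:40, function(i) random_dna(12), character(1))
  score_of <- function(w) {
    codes <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    sum(lo[cbind(codes, 1:12)])
  }
  scores <- vapply(windows, score_of, numeric(1))
  pvals <- vapply(windows, window_pvalue, numeric(1), profile = profile)
  # monotone non-increasing in score; scores closer than the lattice
  # resolution times the window width can tie either way
  ord <- order(scores)
  sep <- diff(scores[ord]) > 12 * 1e-3
  expect_true(all(diff(pvals[ord])[sep] <= 1e-12))

  # Monte-Carlo agreement on a mid-range window
  w <- windows[which.min(abs(pvals - 0.05))]
  n_mc <- 2e5
  draws <- matrix(sample.int(4L, 12 * n_mc, replace = TRUE), nrow = 12)
  mc_scores <- colSums(matrix(lo[cbind(as.vector(draws),
                                       rep(1:12, n_mc))], nrow = 12))
  p_hat <- mean(mc_scores >= score_of(w) - 1e-9)
  p_exact <- window_pvalue(w, profile)
  se <- sqrt(p_exact * (1 - p_exact) / n_mc)
  expect_lt(abs(p_hat - p_exact), 4 * se + 1e-4)
})

test_that("track_promoters finds planted middle motifs at p < 0.05", {
  sim <- simulate_phage_genome(seed = 42)
  regions <- extract_upstream_regions(sim$genome, sim$genes)
  prom <- track_promoters(regions, sim$genome,
                          seed_motifs = rep("TGTGATGTTATA", 4))
  expect_equal(sum(prom$promoter_class == "late_long"), 4L)
  expect_equal(sum(prom$promoter_class == "middle_short"), 6L)
  expect_true(all(prom$pvalue < 0.05))
})

test_that("specificity logos align with zero offset when identical", {
  set.seed(81)
  seqs <- c("TAATGTATA", "TAATGTATA", "TACTGTATA", "TAATGAATA")
  logo <- information_content(seqs)
  res <- compare_specificities(logo, logo)
  expect_equal(res$offset, 0)
  expect_identical(res$gap_in, "none")
})

test_that("a single deleted column is recovered as a gap", {
  freq <- phagetx:::default_sigma70_freq("ACGTACGT", rep(0.85, 8))
  logo_a <- structure(list(freq = freq, ic = rep(1, 8), n = 10),
                      class = "logo_matrix")
  logo_b <- structure(list(freq = freq[, -4], ic = rep(1, 7), n = 10),
                      class = "logo_matrix")
  res <- compare_specificities(logo_a, logo_b)
  expect_identical(res$gap_in, "b")
  expect_equal(res$gap_pos, 4L)
  expect_equal(res$offset, 0)
})
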