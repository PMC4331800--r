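test_that("scoring schemes are validated", {
  expect_error(align_scoring(match = 0), "match")
  expect_error(align_scoring(mismatch = 1))
  expect_error(align_scoring(min_hit_len = 3))
})

test_that("local alignment finds the shared core of two diverged motifs", {
  h <- local_align("TGTGATGTTATA", "GGGGATGTTATA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$length, 9L)
  expect_equal(h$identities, 9L)
  # the hit is the common suffix GATGTTATA
  expect_identical(substr("TGTGATGTTATA", h$start_a, h$end_a), "GATGTTATA")
})

test_that("self-alignment excludes the main diagonal", {
  h <- local_align("ACGTACGT", self = TRUE,
                   scoring = align_scoring(min_hit_len = 4))
  expect_equal(nrow(h), 1L)
  expect_identical(substr("ACGTACGT", h$start_a, h$end_a), "ACGT")
  expect_true(h$start_a != h$start_b)
})

test_that("empty sequences give an empty hit list", {
  expect_equal(nrow(local_align("", "ACGT")), 0L)
  expect_equal(nrow(local_align("ACGT", "")), 0L)
})

test_that("hits never share positions and stay within bounds", {
  set.seed(21)
  for (rep in 1:20) {
    a <- random_dna(80)
    b <- random_dna(80)
    h <- local_align(a, b, align_scoring(min_hit_len = 4))
    if (nrow(h) < 2) next
    expect_true(all(h$start_a >= 1 & h$end_a <= nchar(a)))
    expect_true(all(h$start_b >= 1 & h$end_b <= nchar(b)))
    for (i in seq_len(nrow(h) - 1)) {
      for (j in (i + 1):nrow(h)) {
        expect_true(h$start_a[i] > h$end_a[j] || h$start_a[j] > h$end_a[i])
        expect_true(h$start_b[i] > h$end_b[j] || h$start_b[j] > h$end_b[i])
      }
    }
  }
})

test_that("top hit scores agree with Biostrings local alignment", {
  set.seed(31)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  for (rep in 1:50) {
    a <- random_dna(40)
    b <- random_dna(40)
    ours <- local_align(a, b, align_scoring(min_hit_len = 4))
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE
    )
    # any alignment scoring >= 4 has >= 4 match columns, so it is
    # reportable under min_hit_len = 4 and the top scores must agree
    if (ref >= 4) {
      expect_equal(max(ours$score), ref)
    } else if (nrow(ours) > 0) {
      expect_lte(max(ours$score), ref)
    }
  }
})

test_that("repeat_search builds the right comparison sets", {
  sim <- simulate_phage_genome(seed = 13)
  regions <- extract_upstream_regions(sim$genome, sim$genes)
  one <- regions[regions$strand == "+", ][1, ]
  h1 <- repeat_search(one, mode = "anchor", anchor_id = one$region_id)
  expect_true(all(h1$region_a == one$region_id &
                    h1$region_b == one$region_id))
  expect_equal(attr(h1, "search_bp"), nchar(one$sequence))

  four <- regions[1:4, ]
  h4 <- repeat_search(four, mode = "all_pairs")
  # 4 self + 6 cross comparisons were run; hits only where similarity exists
  expect_true(all(h4$region_a <= h4$region_b))
  expect_error(repeat_search(four, mode = "anchor"), "anchor")
})

test_that("word-Poisson E-values match closed forms and are monotone", {
  expect_equal(repeat_evalue(1, 1, 4), 4 * (1 - exp(-1)), tolerance = 1e-12)
  e_paper <- repeat_evalue(4, 12, 4400)
  expect_lt(e_paper, 1e-8)
  expect_gt(e_paper, 1e-10)

  expect_lt(repeat_evalue(5, 12, 4400), repeat_evalue(4, 12, 4400))
  expect_lt(repeat_evalue(4, 13, 4400), repeat_evalue(4, 12, 4400))
  expect_lt(repeat_evalue(4, 12, 4400), repeat_evalue(4, 12, 8800))
  expect_error(repeat_evalue(0, 12, 4400))
})

test_that("E-value matches a Monte-Carlo word-count simulation", {
  # count 6-mers occurring >= 2 times in 2 kb of uniform sequence
  k <- 2L; L <- 6L; n <- 2000L
  set.seed(17)
  n_rep <- 400L
  counts <- vapply(seq_len(n_rep), function(r) {
    s <- sample.int(4L, n, replace = TRUE)
    words <- vapply(seq_len(n - L + 1L), function(i) {
      sum((s[i:(i + L - 1L)] - 1L) * 4L^(0:(L - 1L)))
    }, numeric(1))
    sum(table(words) >= k)
  }, numeric(1))
  mc <- mean(counts)
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(repeat_evalue(k, L, n) - mc), 3 * se + 1e-9)
})

test_that("consolidation recovers planted repeats with consensus and E-value", {
  sim <- simulate_phage_genome(seed = 42)
  regions <- extract_upstream_regions(sim$genome, sim$genes)
  anchor <- regions[regions$strand == "+", ]
  hits <- repeat_search(anchor, mode = "anchor",
                        anchor_id = anchor$region_id[1])
  motifs <- consolidate_motifs(hits, anchor, sim$genome)
  top <- motifs[1, ]
  expect_lt(top$evalue, 1e-8)
  expect_gte(top$k, 4L)
  # every planted copy lies inside one recovered instance (instances may
  # be ragged-extended by chance flank matches, so containment is the
  # right check, honouring origin wrap)
  planted <- sim$truth$coordinate[sim$truth$type == "late_promoter"]
  inst <- top$instances[[1]]
  glen <- sim$genome$length
  covered <- unlist(lapply(seq_len(nrow(inst)), function(i) {
    len <- nchar(inst$sequence[i])
    ((inst$genomic_coord[i] - 1L + seq_len(len) - 1L) %% glen) + 1L
  }))
  expect_true(all(planted %in% covered))
  seed_set <- motif_window_from_instances(inst$sequence)
  expect_identical(seed_set$consensus, "TGTGATGTTATA")
  expect_identical(seed_set$core, "TGATGT")
  expect_gte(length(seed_set$windows), 4L)
})

test_that("two unrelated planted repeats come out as disjoint motif sets", {
  set.seed(55)
  bg <- function() random_dna(140)
  m1 <- "TGTGATGTTATA"
  m2 <- "CCAAGGTTCCAA"
  r1 <- paste0(bg(), m1, bg(), m1, bg())
  r2 <- paste0(bg(), m2, bg(), m2, bg())
  regions <- tibble::tibble(
    region_id = 1:2, downstream_gene = 1:2, upstream_gene = 2:1,
    strand = "+", gap_start = c(1L, 1000L),
    gap_end = c(nchar(r1), 1000L + nchar(r2) - 1L),
    gap_len = nchar(c(r1, r2)), fused_offset = 0L,
    g5 = c(1L, 1000L), sequence = c(r1, r2)
  )
  genome <- genome_record(paste0(r1, strrep("A", 1000 - nchar(r1) - 1), r2),
                          topology = "linear")
  hits <- repeat_search(regions, mode = "all_pairs")
  motifs <- consolidate_motifs(hits, regions, genome)
  cons <- motifs$consensus[motifs$k >= 2]
  expect_true(any(grepl("TGATGT", cons)))
  expect_true(any(grepl("AGGTTCC", cons)))
  # the two repeats are never merged into one set
  expect_false(any(grepl("TGATGT", cons) & grepl("AGGTTCC", cons)))
})
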