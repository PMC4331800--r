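# Shared fixture builders. Everything is generated in code; no data files.

random_dna <- function(len, freq = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = freq),
        collapse = "")
}

# n sequences of length len with `motif` planted once in each sequence
# listed in plant_in (uniform random position).
plant_motif_seqs <- function(n, len, motif, plant_in = seq_len(n), seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (i %in% plant_in) {
      p <- sample(len - nchar(motif) + 1L, 1L)
      s[p:(p + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))
}

# Exhaustive ungapped local-alignment oracle: best score over all pairs of
# equal-length substrings with at least min_len columns. For sequences of
# length <= 15 under the default scoring (match +1, mismatch -3, gap
# open -5 / extend -2) a gapped alignment can never beat the best ungapped
# one (two segments flanking a gap would need 8+ matches each, exceeding
# the length budget), so this is a valid full local-alignment oracle there.
brute_force_local_score <- function(a, b, match = 1, mismatch = -3,
                                    min_len = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- 0
  for (ia in seq_along(ca)) {
    for (ib in seq_along(cb)) {
      max_l <- min(length(ca) - ia, length(cb) - ib) + 1L
      if (max_l < min_len) next
      v <- ifelse(ca[ia:(ia + max_l - 1L)] == cb[ib:(ib + max_l - 1L)],
                  match, mismatch)
      cs <- cumsum(v)
      best <- max(best, cs[min_len:max_l])
    }
  }
  best
}

# Best-hit score from the DP engine with no length constraint (the raw
# Smith-Waterman optimum, comparable to the brute-force oracle above).
sw_best_score <- function(a, b) {
  enc <- function(x) {
    c <- match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T"))
    c[is.na(c)] <- 0L
    c
  }
  h <- phagetx:::cpp_local_align(enc(a), enc(b), 1L, -3L, -5L, -2L,
                                 1L, FALSE, 1L)
  if (nrow(h) == 0) 0L else max(h$score)
}

# A hand-written circular GenBank record: 120 bp, three CDS features
# including a complement and an origin-spanning join.
write_test_genbank <- function(path) {
  set.seed(7)
  seq <- tolower(random_dna(120))
  rows <- substring(seq, seq(1, 120, 60), pmin(seq(60, 180, 60), 120))
  fmt_row <- function(s, start) {
    chunks <- substring(s, seq(1, nchar(s), 10), pmin(seq(10, nchar(s) + 9, 10), nchar(s)))
    sprintf("%9d %s", start, paste(chunks, collapse = " "))
  }
  lines <- c(
    "LOCUS       TESTPHG                  120 bp    DNA     circular PHG 01-JAN-2020",
    "DEFINITION  synthetic test phage record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             10..30",
    '                     /gene="gp1"',
    '                     /product="test protein one"',
    "     CDS             complement(40..60)",
    '                     /locus_tag="gp2"',
    "     CDS             join(100..120,1..9)",
    '                     /gene="gp3"',
    "ORIGIN",
    fmt_row(rows[1], 1),
    fmt_row(rows[2], 61),
    "//"
  )
  writeLines(lines, path)
  invisible(seq)
}

write_test_gff3 <- function(path, seqid = "chr") {
  writeLines(c(
    "##gff-version 3",
    paste(seqid, "test", "CDS", "10", "90", ".", "+", "0", "ID=cds1",
          sep = "\t"),
    paste(seqid, "test", "CDS", "150", "260", ".", "-", "0", "ID=cds2",
          sep = "\t")
  ), path)
}

# Small annotated linear/circular test genomes built directly.
toy_genes <- function(starts, ends, strands) {
  tibble::tibble(
    gene_number = seq_along(starts), start = starts, end = ends,
    strand = strands, label = sprintf("g%d", seq_along(starts))
  )
}
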