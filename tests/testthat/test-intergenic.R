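make_linear_genome <- function(len = 300L) {
  set.seed(11)
  genome_record(random_dna(len), topology = "linear")
}

test_that("gaps at or below the length cutoff yield no region", {
  g <- make_linear_genome(300L)
  genes <- toy_genes(c(1L, 141L), c(100L, 300L), c("+", "+"))
  regions <- extract_upstream_regions(g, genes, group = "plus")
  expect_equal(nrow(regions), 0L)  # 40 bp gap <= 50
})

test_that("a qualifying '+' gap yields one fused forward-strand region", {
  g <- make_linear_genome(300L)
  genes <- toy_genes(c(1L, 161L), c(100L, 290L), c("+", "+"))
  regions <- extract_upstream_regions(g, genes, group = "plus")
  expect_equal(nrow(regions), 1L)
  r <- regions[1, ]
  expect_equal(r$gap_len, 60L)
  expect_equal(nchar(r$sequence), 90L)  # 60 + 30 fused
  expect_identical(r$sequence, substr(g$sequence, 71, 160))
  expect_equal(r$downstream_gene, 2L)
  expect_identical(r$strand, "+")
  expect_equal(r$fused_offset, 30L)
})

test_that("a '-' gene's region is the reverse complement of its slice", {
  g <- make_linear_genome(300L)
  genes <- toy_genes(c(1L, 151L), c(50L, 250L), c("-", "-"))
  regions <- extract_upstream_regions(g, genes, group = "minus")
  expect_equal(nrow(regions), 1L)
  r <- regions[1, ]
  expect_equal(r$downstream_gene, 1L)
  expect_identical(r$sequence, revcomp(substr(g$sequence, 51, 180)))
})

test_that("divergent gaps yield two regions, convergent gaps none", {
  g <- make_linear_genome(400L)
  div <- toy_genes(c(1L, 201L), c(100L, 400L), c("-", "+"))
  r_div <- extract_upstream_regions(g, div, group = "all")
  expect_equal(nrow(r_div), 2L)
  expect_setequal(r_div$strand, c("+", "-"))
  expect_setequal(r_div$downstream_gene, c(1L, 2L))

  conv <- toy_genes(c(1L, 201L), c(100L, 400L), c("+", "-"))
  r_conv <- extract_upstream_regions(g, conv, group = "all")
  expect_equal(nrow(r_conv), 0L)
})

test_that("region count is monotone non-increasing in min_len", {
  sim <- simulate_phage_genome(seed = 5)
  counts <- vapply(c(30L, 50L, 80L, 120L), function(ml) {
    nrow(extract_upstream_regions(sim$genome, sim$genes, min_len = ml))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("local offsets map back to the genomic sequence on both strands", {
  sim <- simulate_phage_genome(seed = 8)
  regions <- extract_upstream_regions(sim$genome, sim$genes)
  chars <- strsplit(sim$genome$sequence, "")[[1]]
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    offs <- seq_len(nchar(r$sequence))
    coords <- region_to_genomic(r, offs, sim$genome$length)
    got <- chars[coords]
    want <- strsplit(r$sequence, "")[[1]]
    if (r$strand == "-") want <- chartr("ACGT", "TGCA", want)
    expect_identical(got, want)
  }
})

test_that("the origin-spanning region joins the genome ends", {
  set.seed(3)
  g <- genome_record(random_dna(1000L), topology = "circular")
  genes <- toy_genes(c(151L, 501L), c(400L, 900L), c("+", "+"))
  r <- origin_spanning_region(g, genes)
  expect_equal(r$gap_start, 901L)
  expect_equal(r$gap_end, 150L)
  expect_equal(r$gap_len, 250L)
  expect_equal(nchar(r$sequence), 250L)
  expect_identical(r$sequence,
                   paste0(substr(g$sequence, 901, 1000),
                          substr(g$sequence, 1, 150)))
  expect_true(r$anchor)
})

test_that("degenerate and linear origin regions are rejected", {
  set.seed(4)
  g <- genome_record(random_dna(500L), topology = "circular")
  genes <- toy_genes(1L, 500L, "+")
  expect_error(origin_spanning_region(g, genes), "no intergenic")
  g_lin <- genome_record(random_dna(500L), topology = "linear")
  expect_error(origin_spanning_region(g_lin, toy_genes(100L, 400L, "+")),
               "circular")
})

test_that("the anchor is the upstream-most '+'-cluster region", {
  sim <- simulate_phage_genome(seed = 42)
  regions <- extract_upstream_regions(sim$genome, sim$genes)
  anchor <- phagetx:::find_anchor_region(regions, sim$genes, "circular")
  expect_identical(anchor$strand, "+")
  expect_equal(anchor$downstream_gene, 1L)
  expect_equal(anchor$gap_len, 1200L)  # the origin-spanning gap
})
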