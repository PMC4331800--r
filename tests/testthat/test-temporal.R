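# A linear toy genome: three "-" genes transcribed right-to-left with a
# sigma70 promoter upstream (rightmost) and optionally a middle motif
# mid-cluster.
toy_minus_setup <- function() {
  genes <- toy_genes(c(100L, 400L, 700L), c(300L, 600L, 900L),
                     c("-", "-", "-"))
  genome <- genome_record(strrep("ACGT", 300), topology = "linear")
  sigma70 <- tibble::tibble(
    start = 950L, end = 978L, strand = "-", minus35 = "TTGACA",
    spacer_length = 17L, minus10 = "TATAAT", score = 0
  )
  list(genes = genes, genome = genome, sigma70 = sigma70)
}

empty_motifs <- function() {
  tibble::tibble(downstream_gene = integer(), promoter_class = character(),
                 genomic_coordinate = integer(), strand = character())
}

test_that("a sigma70 promoter propagates 'early' down its cluster", {
  s <- toy_minus_setup()
  out <- classify_genes_temporal(s$genes, s$sigma70, empty_motifs(),
                                 s$genome)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$temporal_class == "early"))
})

test_that("a middle motif mid-cluster flips downstream genes to middle", {
  s <- toy_minus_setup()
  motifs <- tibble::tibble(
    downstream_gene = 2L, promoter_class = "middle_short",
    genomic_coordinate = 650L, strand = "-"
  )
  out <- classify_genes_temporal(s$genes, s$sigma70, motifs, s$genome)
  # transcription order is gene 3, 2, 1; the motif sits upstream of gene 2
  expect_identical(out$temporal_class[out$gene_number == 3L], "early")
  expect_identical(out$temporal_class[out$gene_number == 2L], "middle")
  expect_identical(out$temporal_class[out$gene_number == 1L], "middle")
  dual <- out[out$gene_number == 2L, ]
  expect_match(dual$rationale, "dual")
})

test_that("genes with no upstream promoter in-cluster are unassigned", {
  s <- toy_minus_setup()
  out <- classify_genes_temporal(s$genes, s$sigma70[0, ], empty_motifs(),
                                 s$genome)
  expect_true(all(out$temporal_class == "unassigned"))
})

test_that("removing middle motifs reverts middle genes to early", {
  s <- toy_minus_setup()
  motifs <- tibble::tibble(
    downstream_gene = 2L, promoter_class = "middle_short",
    genomic_coordinate = 650L, strand = "-"
  )
  with_mid <- classify_genes_temporal(s$genes, s$sigma70, motifs, s$genome)
  without <- classify_genes_temporal(s$genes, s$sigma70, empty_motifs(),
                                     s$genome)
  was_middle <- with_mid$gene_number[with_mid$temporal_class == "middle"]
  expect_true(all(without$temporal_class[without$gene_number %in%
                                           was_middle] %in%
                    c("early", "unassigned")))
})

test_that("assignment is total and deterministic", {
  sim <- simulate_phage_genome(seed = 42)
  st <- infer_strategy(sim$genome, sim$genes, seed = 7)
  a1 <- st$assignments
  a2 <- classify_genes_temporal(sim$genes, st$sigma70_promoters,
                                st$phage_promoters, sim$genome)
  expect_identical(a1, a2)
  expect_setequal(a1$gene_number, sim$genes$gene_number)
  expect_equal(nrow(a1), nrow(sim$genes))
})

test_that("late promoters across the origin classify the '+' cluster late", {
  sim <- simulate_phage_genome(seed = 42)
  st <- infer_strategy(sim$genome, sim$genes, seed = 7)
  plus_genes <- sim$genes$gene_number[sim$genes$strand == "+"]
  cls <- st$assignments$temporal_class[st$assignments$gene_number %in%
                                         plus_genes]
  expect_true(all(cls == "late"))
})

test_that("an empty promoter set produces a flagged failure report", {
  s <- toy_minus_setup()
  ass <- classify_genes_temporal(s$genes, s$sigma70[0, ], empty_motifs(),
                                 s$genome)
  rep <- strategy_report(s$genome, ass,
                         tibble::tibble(coordinate = integer(),
                                        strand = character(),
                                        class = character()))
  expect_true(rep$failed)
  expect_match(rep$narrative[1], "No promoters")
  expect_equal(rep$counts$n_genes[rep$counts$temporal_class == "unassigned"],
               3L)
})

test_that("report layout is ordered and serialisable", {
  sim <- simulate_phage_genome(seed = 42)
  st <- infer_strategy(sim$genome, sim$genes, seed = 7)
  rep <- st$report
  expect_false(rep$failed)
  expect_true(!is.unsorted(rep$layout$coordinate))
  counts <- setNames(rep$counts$n_genes, rep$counts$temporal_class)
  expect_equal(sum(counts), nrow(sim$genes))

  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed, c("genome", "counts", "layout", "blocks",
                         "narrative", "failed"), ignore.order = TRUE)

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_temporal_gff3(sim$genes, st$assignments, sim$genome, gff)
  back <- rtracklayer::import(gff)
  expect_equal(length(back), nrow(sim$genes))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_promoters_bed(st$promoter_layout, sim$genome, bed)
  bed_df <- utils::read.table(bed, sep = "\t")
  expect_equal(nrow(bed_df), nrow(st$promoter_layout))
  # BED is 0-based half-open: chromStart is the 1-based coordinate minus 1
  expect_setequal(bed_df$V2, st$promoter_layout$coordinate - 1L)
})
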