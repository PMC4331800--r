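#' Infer a phage's transcription strategy from genome and annotations
#'
#' End-to-end pipeline: extract oriented intergenic regions; discover
#' low-copy conserved phage promoters by pairwise local alignment of the
#' "+"-cluster regions anchored at the upstream-most one; track additional
#' core-motif copies in all regions with the supervised scan and classify
#' them late (long) vs middle (short); fit the composite sigma70 model
#' (from supplied training promoters, or a simulated training set) and
#' scan the regions, choosing the reporting threshold by strand bias; then
#' propagate promoter classes to genes and assemble the strategy report.
#'
#' @param genome A [genome_record()].
#' @param genes Gene tibble from [read_annotations()].
#' @param sigma70_training Training tibble for [build_promoter_model()];
#'   `NULL` simulates a default training set (seeded from `seed`).
#' @param seed Seed for the simulated training set and any sampling.
#' @param scoring Alignment scoring ([align_scoring()]).
#' @param min_len,fuse_len Intergenic extraction parameters.
#' @param p_threshold Supervised-scan significance threshold.
#' @param permissive_threshold Initial sigma70 scan threshold before
#'   strand-bias selection.
#' @param required_minus Requested number of "-"-strand sigma70 promoters.
#' @return A `phage_strategy` list: `regions`, `hits`, `motif_sets`,
#'   `phage_promoters`, `sigma70_model`, `sigma70_scan` (permissive),
#'   `sigma70_threshold`, `sigma70_promoters`, `assignments`, `report`.
#' @export
infer_strategy <- function(genome, genes, sigma70_training = NULL,
                           seed = 1L, scoring = align_scoring(),
                           min_len = 50L, fuse_len = 30L,
                           p_threshold = 0.05,
                           permissive_threshold = -8,
                           required_minus = 1L) {
  regions <- extract_upstream_regions(genome, genes, group = "all",
                                      min_len = min_len,
                                      fuse_len = fuse_len)
  plus_regions <- regions[regions$strand == "+", ]
  anchor <- find_anchor_region(regions, genes, genome$topology)
  search_regions <- dplyr::distinct(
    dplyr::bind_rows(plus_regions, anchor), .data$region_id,
    .keep_all = TRUE
  )
  hits <- repeat_search(search_regions, mode = "anchor", scoring = scoring,
                        anchor_id = anchor$region_id)
  motif_sets <- consolidate_motifs(hits, search_regions, genome)
  if (nrow(motif_sets) == 0L) {
    stop("no repeated motifs found in the '+'-cluster intergenic regions; ",
         "try `repeat_search(mode = \"all_pairs\")` as a backup")
  }
  top <- motif_sets[1, ]
  seed_set <- motif_window_from_instances(top$instances[[1]]$sequence)
  seed_windows <- seed_instance_windows(top$instances[[1]], regions, genome)

  phage_promoters <- track_promoters(regions, genome, seed_set$windows,
                                     core = seed_set$core,
                                     p_threshold = p_threshold,
                                     extra_windows = seed_windows)

  if (is.null(sigma70_training)) {
    sigma70_training <- simulate_training_promoters(n = 500L, seed = seed)
  }
  model <- build_promoter_model(sigma70_training)
  scan <- scan_genome(genome, model, threshold = permissive_threshold,
                      regions = regions)
  thr <- threshold_by_strand_bias(scan, required_minus = required_minus,
                                  max_plus = 0L)
  sigma70 <- scan[scan$score >= thr$threshold, ]

  assignments <- classify_genes_temporal(genes, sigma70, phage_promoters,
                                         genome)
  layout <- dplyr::bind_rows(
    if (nrow(sigma70) > 0) {
      tibble(coordinate = as.integer(ifelse(sigma70$strand == "+",
                                            sigma70$start, sigma70$end)),
             strand = sigma70$strand, class = "early",
             score = sigma70$score)
    },
    if (nrow(phage_promoters) > 0) {
      tibble(coordinate = as.integer(phage_promoters$genomic_coordinate),
             strand = phage_promoters$strand,
             class = ifelse(phage_promoters$promoter_class == "late_long",
                            "late", "middle"),
             score = NA_real_)
    }
  )
  report <- strategy_report(genome, assignments, layout)

  structure(
    list(genes = genes, regions = regions, hits = hits,
         motif_sets = motif_sets,
         phage_promoters = phage_promoters, sigma70_model = model,
         sigma70_scan = scan, sigma70_threshold = thr,
         sigma70_promoters = sigma70, promoter_layout = layout,
         assignments = assignments, report = report),
    class = "phage_strategy"
  )
}

#' @export
print.phage_strategy <- function(x, ...) {
  cat("<phage_strategy>\n")
  cat(sprintf("  %d intergenic regions; top motif set: %s (k=%d, E=%.2g)\n",
              nrow(x$regions), x$motif_sets$consensus[1],
              x$motif_sets$k[1], x$motif_sets$evalue[1]))
  cat(sprintf("  phage promoters: %d late, %d middle\n",
              sum(x$phage_promoters$promoter_class == "late_long"),
              sum(x$phage_promoters$promoter_class == "middle_short")))
  cat(sprintf("  sigma70: %d on '-', %d on '+' at threshold %.3f\n",
              x$sigma70_threshold$n_minus, x$sigma70_threshold$n_plus,
              x$sigma70_threshold$threshold))
  print(x$report)
  invisible(x)
}
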