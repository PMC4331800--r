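#' Assign genes to early/middle/late temporal classes
#'
#' Integrates the two promoter searches into the infection timeline: host
#' sigma70 promoters drive *early* transcription (before the anti-sigma
#' factor shuts the host polymerase off), short core-only phage motifs
#' drive *middle* genes, and the TATA-bearing long motifs drive the *late*
#' structural genes. Each gene inherits the class of the nearest upstream
#' same-strand promoter within its strand cluster (operon propagation to
#' the cluster end; cluster boundaries are the only stop signal used).
#' Genes reachable from both a sigma70 and a middle promoter — typically
#' the phage sigma-factor gene itself — are labelled middle with a
#' dual-promoter rationale. Genes with no upstream promoter in their
#' cluster are `unassigned`.
#'
#' @param genes Gene tibble from [read_annotations()].
#' @param sigma70_predictions Prediction tibble from [scan_genome()]
#'   (columns `start`, `end`, `strand`).
#' @param phage_motifs Classified motif tibble from
#'   [classify_long_short()]/[track_promoters()] (columns
#'   `downstream_gene`, `promoter_class`, `genomic_coordinate`, `strand`).
#' @param genome A [genome_record()] (topology drives cluster merging and
#'   promoter-to-gene assignment across the origin).
#' @return Tibble with one row per gene: `gene_number`, `temporal_class`,
#'   `n_promoters` (supporting promoters at that gene), `rationale`.
#' @export
classify_genes_temporal <- function(genes, sigma70_predictions,
                                    phage_motifs, genome) {
  genes <- dplyr::arrange(genes, .data$start)
  clusters <- strand_clusters(genes, genome$topology)

  promoters <- dplyr::bind_rows(
    tibble(downstream_gene = integer(), class = character(),
           strand = character(), coordinate = integer()),
    if (nrow(sigma70_predictions) > 0) {
      tibble(
        downstream_gene = purrr::map2_int(
          ifelse(sigma70_predictions$strand == "+",
                 sigma70_predictions$start, sigma70_predictions$end),
          sigma70_predictions$strand,
          assign_downstream_gene, genes = genes, genome = genome
        ),
        class = "early", strand = sigma70_predictions$strand,
        coordinate = as.integer(ifelse(sigma70_predictions$strand == "+",
                                       sigma70_predictions$start,
                                       sigma70_predictions$end))
      )
    },
    if (nrow(phage_motifs) > 0) {
      tibble(
        downstream_gene = phage_motifs$downstream_gene,
        class = ifelse(phage_motifs$promoter_class == "late_long",
                       "late", "middle"),
        strand = phage_motifs$strand,
        coordinate = as.integer(phage_motifs$genomic_coordinate)
      )
    }
  )

  purrr::map_dfr(seq_len(nrow(clusters)), function(ci) {
    cl <- clusters[ci, ]
    members <- cl$members[[1]]
    sub <- genes[match(members, genes$gene_number), ]
    # transcription order within the cluster
    ord <- if (cl$strand == "+") order(sub$start) else order(-sub$start)
    sub <- sub[ord, ]
    current <- NA_character_
    seen <- character(0)
    purrr::map_dfr(seq_len(nrow(sub)), function(k) {
      g <- sub$gene_number[k]
      here <- promoters[promoters$downstream_gene %in% g &
                          promoters$strand == cl$strand, ]
      if (nrow(here) > 0) {
        # promoters in this gene's upstream gap; the closest (last in
        # transcription order) wins, i.e. max coordinate for "+" genes
        ord_p <- if (cl$strand == "+") order(here$coordinate) else
          order(-here$coordinate)
        current <<- here$class[ord_p[nrow(here)]]
        seen <<- union(seen, here$class)
      }
      cls <- current
      rationale <- if (is.na(cls)) {
        "no upstream promoter within cluster"
      } else if (cls %in% c("early", "middle") &&
                 all(c("early", "middle") %in% seen)) {
        cls <- "middle"
        "dual promoters: sigma70 (early) and phage middle upstream"
      } else {
        paste0("nearest upstream promoter class: ", cls)
      }
      tibble(gene_number = g,
             temporal_class = ifelse(is.na(cls), "unassigned", cls),
             n_promoters = nrow(here), rationale = rationale)
    })
  }) |>
    dplyr::arrange(.data$gene_number)
}

# The gene whose upstream gap contains a promoter at `coordinate` on
# `strand`: the first gene downstream of the coordinate in transcription
# direction, wrapping the origin on circular genomes.
assign_downstream_gene <- function(coordinate, strand, genes, genome) {
  genes <- dplyr::arrange(genes, .data$start)
  if (strand == "+") {
    after <- genes[genes$start > coordinate, ]
    if (nrow(after) > 0) return(after$gene_number[1])
    if (genome$topology == "circular") return(genes$gene_number[1])
  } else {
    before <- genes[genes$end < coordinate, ]
    if (nrow(before) > 0) return(before$gene_number[nrow(before)])
    if (genome$topology == "circular") {
      return(genes$gene_number[nrow(genes)])
    }
  }
  NA_integer_
}

#' Build the infection-strategy report
#'
#' Deterministic, machine-readable summary of the inferred transcription
#' strategy: the promoter layout ordered along the genome, contiguous
#' temporal class blocks, per-class gene counts, and a short narrative
#' skeleton. When no promoters were found the report flags the failure.
#'
#' @param genome A [genome_record()].
#' @param assignments Tibble from [classify_genes_temporal()].
#' @param promoters Combined promoter tibble: needs `coordinate`, `strand`
#'   and `class` columns (any of "early", "middle", "late").
#' @return A `strategy_report` list: `genome`, `counts`, `layout`,
#'   `blocks`, `narrative`, `failed`.
#' @export
strategy_report <- function(genome, assignments, promoters) {
  counts <- assignments |>
    dplyr::count(.data$temporal_class, name = "n_genes") |>
    tidyr::complete(
      temporal_class = c("early", "middle", "late", "unassigned"),
      fill = list(n_genes = 0L)
    )
  layout <- if (nrow(promoters) > 0) {
    dplyr::arrange(promoters, .data$coordinate)
  } else {
    tibble(coordinate = integer(), strand = character(), class = character())
  }
  blocks <- assignments |>
    dplyr::mutate(block = cumsum(
      .data$temporal_class != dplyr::lag(.data$temporal_class,
                                         default = "<none>")
    )) |>
    dplyr::group_by(.data$block, .data$temporal_class) |>
    dplyr::summarise(first_gene = min(.data$gene_number),
                     last_gene = max(.data$gene_number),
                     n_genes = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"block")
  failed <- nrow(promoters) == 0L
  narrative <- if (failed) {
    "No promoters supplied: no temporal classes could be inferred."
  } else {
    c(
      sprintf("Genome %s (%d bp, %s).", genome$identifier, genome$length,
              genome$topology),
      sprintf("%d promoters: %s.", nrow(layout),
              paste(sprintf("%d %s", table(layout$class)[unique(layout$class)],
                            unique(layout$class)), collapse = ", ")),
      sprintf("Gene classes: %s.",
              paste(sprintf("%d %s", counts$n_genes, counts$temporal_class),
                    collapse = ", ")),
      paste("Inferred strategy: host RNAP transcribes the early genes from",
            "sigma70 promoters; once the anti-sigma factor shuts host",
            "transcription off, the phage sigma factor takes over at the",
            "middle (core-motif) and then late (TATA-bearing) promoters,",
            "producing the structural proteins last.")
    )
  }
  structure(
    list(genome = genome$identifier, counts = counts, layout = layout,
         blocks = blocks, narrative = narrative, failed = failed),
    class = "strategy_report"
  )
}

#' @export
print.strategy_report <- function(x, ...) {
  cat("<strategy_report>", x$genome, "\n")
  cat(paste0("  ", x$narrative, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a strategy report as JSON
#'
#' @param report A [strategy_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export temporal assignments as GFF3
#'
#' One `gene` feature per gene with the temporal class as attribute.
#'
#' @param genes Gene tibble.
#' @param assignments Tibble from [classify_genes_temporal()].
#' @param genome A [genome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_temporal_gff3 <- function(genes, assignments, genome, path) {
  merged <- dplyr::inner_join(genes, assignments, by = "gene_number")
  # origin-spanning genes cannot be represented in one GFF3 range
  merged <- merged[merged$end >= merged$start, ]
  gr <- GenomicRanges::GRanges(
    seqnames = genome$identifier,
    ranges = IRanges::IRanges(start = merged$start, end = merged$end),
    strand = merged$strand
  )
  gr$type <- "gene"
  gr$ID <- sprintf("gene_%d", merged$gene_number)
  gr$temporal_class <- merged$temporal_class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export promoter predictions as BED6
#'
#' @param promoters Tibble with `coordinate` (or `start`/`end`), `strand`,
#'   `class` and optionally `score` columns.
#' @param genome A [genome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_bed <- function(promoters, genome, path) {
  start <- promoters[["start"]] %||% promoters$coordinate
  end <- promoters[["end"]] %||% promoters$coordinate
  df <- data.frame(
    chrom = genome$identifier,
    chromStart = pmin(start, end) - 1L,  # BED is 0-based half-open
    chromEnd = pmax(start, end),
    name = promoters$class,
    score = round(promoters[["score"]] %||% rep(0, nrow(promoters)), 3),
    strand = promoters$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
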