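#' Extract oriented upstream intergenic regions
#'
#' For each gene whose upstream gap is longer than `min_len` bp, extracts
#' the intergenic sequence oriented in the gene's transcription direction
#' (reverse-complemented for "-" genes), so downstream motif searches scan
#' only the direct strand. Because promoter elements can overlap the 3' end
#' of the upstream gene, `fuse_len` bp of sequence immediately 5' of the gap
#' (in the oriented frame) are prepended.
#'
#' A gap between divergently transcribed genes is upstream of both flanking
#' genes and yields two regions, one per orientation; a gap between
#' convergent genes yields none. On a circular genome the gap joining the
#' genome's 3' and 5' ends is included.
#'
#' @param genome A [genome_record()].
#' @param genes Gene tibble from [read_annotations()].
#' @param group Restrict to regions upstream of `"plus"` genes, `"minus"`
#'   genes, or `"all"` (default).
#' @param min_len Minimum unfused gap length in bp; strictly greater-than.
#' @param fuse_len bp of upstream flank prepended to the oriented region.
#' @return Tibble with one row per region: `region_id`, `downstream_gene`,
#'   `upstream_gene`, `strand`, `gap_start`, `gap_end` (genomic, 1-based,
#'   `gap_start > gap_end` when the region wraps the origin), `gap_len`,
#'   `fused_offset`, `g5` (genomic coordinate of the fused region's 5'
#'   base), `sequence`.
#' @export
extract_upstream_regions <- function(genome, genes,
                                     group = c("all", "plus", "minus"),
                                     min_len = 50L, fuse_len = 30L) {
  group <- match.arg(group)
  stopifnot(nrow(genes) > 0)
  validate_genes(genes, genome)
  genes <- dplyr::arrange(genes, .data$start)
  len <- genome$length
  circular <- genome$topology == "circular"

  gaps <- adjacent_gaps(genes, len, circular)
  regions <- purrr::pmap_dfr(gaps, function(left_gene, right_gene,
                                            gap_start, gap_end, gap_len) {
    if (gap_len <= min_len) return(NULL)
    out <- list()
    lg <- genes[match(left_gene, genes$gene_number), ]
    rg <- genes[match(right_gene, genes$gene_number), ]
    if (!is.na(right_gene) && rg$strand == "+") {
      out <- c(out, list(make_region(
        genome, downstream = right_gene, upstream = left_gene, strand = "+",
        gap_start = gap_start, gap_end = gap_end, gap_len = gap_len,
        fuse_len = fuse_len, circular = circular
      )))
    }
    if (!is.na(left_gene) && lg$strand == "-") {
      out <- c(out, list(make_region(
        genome, downstream = left_gene, upstream = right_gene, strand = "-",
        gap_start = gap_start, gap_end = gap_end, gap_len = gap_len,
        fuse_len = fuse_len, circular = circular
      )))
    }
    dplyr::bind_rows(out)
  })
  if (nrow(regions) == 0L) {
    return(empty_regions())
  }
  regions <- switch(group,
    all = regions,
    plus = regions[regions$strand == "+", ],
    minus = regions[regions$strand == "-", ]
  )
  regions$region_id <- seq_len(nrow(regions))
  regions[, c("region_id", names(regions)[names(regions) != "region_id"])]
}

empty_regions <- function() {
  tibble(
    region_id = integer(), downstream_gene = integer(),
    upstream_gene = integer(), strand = character(),
    gap_start = integer(), gap_end = integer(), gap_len = integer(),
    fused_offset = integer(), g5 = integer(), sequence = character()
  )
}

# Gaps between genes adjacent in genomic order, plus the origin-wrapping
# gap on circular genomes. Overlapping/nested genes give gap_len <= 0 and
# are dropped by the caller's min_len filter.
adjacent_gaps <- function(genes, len, circular) {
  n <- nrow(genes)
  rows <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      rows[[length(rows) + 1L]] <- tibble(
        left_gene = genes$gene_number[i],
        right_gene = genes$gene_number[i + 1L],
        gap_start = genes$end[i] + 1L,
        gap_end = genes$start[i + 1L] - 1L,
        gap_len = genes$start[i + 1L] - genes$end[i] - 1L
      )
    }
  }
  if (circular) {
    gap_len <- len - genes$end[n] + genes$start[1] - 1L
    if (n == 1L) gap_len <- len - (genes$end[1] - genes$start[1] + 1L)
    rows[[length(rows) + 1L]] <- tibble(
      left_gene = genes$gene_number[n],
      right_gene = genes$gene_number[1],
      gap_start = (genes$end[n] %% len) + 1L,
      gap_end = ((genes$start[1] - 2L) %% len) + 1L,
      gap_len = as.integer(gap_len)
    )
  } else {
    if (genes$start[1] > 1L) {
      rows[[length(rows) + 1L]] <- tibble(
        left_gene = NA_integer_, right_gene = genes$gene_number[1],
        gap_start = 1L, gap_end = genes$start[1] - 1L,
        gap_len = genes$start[1] - 1L
      )
    }
    if (genes$end[n] < len) {
      rows[[length(rows) + 1L]] <- tibble(
        left_gene = genes$gene_number[n], right_gene = NA_integer_,
        gap_start = genes$end[n] + 1L, gap_end = len,
        gap_len = len - genes$end[n]
      )
    }
  }
  dplyr::bind_rows(rows)
}

make_region <- function(genome, downstream, upstream, strand,
                        gap_start, gap_end, gap_len, fuse_len, circular) {
  len <- genome$length
  wrap <- function(p) ((p - 1L) %% len) + 1L
  if (strand == "+") {
    f5 <- gap_start - fuse_len
    if (!circular) f5 <- max(1L, f5)
    fused <- gap_start - f5
    if (circular) fused <- fuse_len
    g5 <- if (circular) wrap(f5) else f5
    sequence <- circ_slice(genome$sequence, g5, gap_end, circular)
  } else {
    f5 <- gap_end + fuse_len
    if (!circular) f5 <- min(len, f5)
    fused <- f5 - gap_end
    if (circular) fused <- fuse_len
    g5 <- if (circular) wrap(f5) else f5
    sequence <- revcomp(circ_slice(genome$sequence, gap_start, g5, circular))
  }
  tibble(
    downstream_gene = downstream, upstream_gene = upstream, strand = strand,
    gap_start = as.integer(gap_start), gap_end = as.integer(gap_end),
    gap_len = as.integer(gap_len), fused_offset = as.integer(fused),
    g5 = as.integer(g5), sequence = sequence
  )
}

#' Map a region-local offset to a genomic coordinate
#'
#' Offsets are 1-based positions in the oriented (fused) region sequence;
#' the result is the 1-based genomic coordinate of that base, honouring
#' strand and origin wrap.
#'
#' @param region One row of the regions tibble.
#' @param offset Integer vector of local positions.
#' @param genome_length Genome length in bp.
#' @return Integer vector of genomic coordinates.
#' @export
region_to_genomic <- function(region, offset, genome_length) {
  wrap <- function(p) ((p - 1L) %% genome_length) + 1L
  if (region$strand == "+") {
    wrap(region$g5 + offset - 1L)
  } else {
    wrap(region$g5 - offset + 1L)
  }
}

#' The origin-spanning intergenic region
#'
#' On a circular phage genome the 5' and 3' genome ends join, creating a
#' long intergenic region that separates the two divergent gene clusters
#' and is the prime candidate for hosting phage-specific promoters (the
#' genes downstream of it would otherwise not be transcribed). Returns that
#' region oriented for its "+"-strand downstream gene when one exists,
#' otherwise for the "-" flank.
#'
#' @inheritParams extract_upstream_regions
#' @param fuse_len bp of upstream flank prepended (default 0: the bare gap).
#' @return One-row region tibble (see [extract_upstream_regions()]).
#' @export
origin_spanning_region <- function(genome, genes, fuse_len = 0L) {
  if (genome$topology != "circular") {
    stop("origin-spanning region requires circular topology; ",
         "supply strand clusters manually for linear genomes")
  }
  genes <- dplyr::arrange(genes, .data$start)
  n <- nrow(genes)
  len <- genome$length
  gap_len <- len - genes$end[n] + genes$start[1] - 1L
  if (gap_len <= 0L) {
    stop("no intergenic sequence between the genome ends ",
         "(last gene ends at genome end and/or first gene starts at 1)")
  }
  gap_start <- (genes$end[n] %% len) + 1L
  gap_end <- ((genes$start[1] - 2L) %% len) + 1L
  strand <- if (genes$strand[1] == "+") "+" else "-"
  downstream <- if (strand == "+") genes$gene_number[1] else genes$gene_number[n]
  upstream <- if (strand == "+") genes$gene_number[n] else genes$gene_number[1]
  if (strand == "-" && genes$strand[n] != "-") {
    stop("origin gap is downstream of both flanking genes (convergent)")
  }
  region <- make_region(genome, downstream, upstream, strand,
                        gap_start, gap_end, as.integer(gap_len),
                        fuse_len, circular = TRUE)
  region$region_id <- 1L
  region$anchor <- TRUE
  region
}

# The anchor region for repeat discovery: the upstream-most intergenic
# region of the "+" (structural/late) gene cluster. Falls back to the
# longest "+" region with a warning when that gene has no qualifying gap.
find_anchor_region <- function(regions, genes,
                               topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  plus <- regions[regions$strand == "+", ]
  if (nrow(plus) == 0L) stop("no '+'-strand intergenic regions")
  clusters <- strand_clusters(genes, topology)
  plus_cl <- clusters[clusters$strand == "+", ]
  if (nrow(plus_cl) > 0L) {
    plus_cl <- plus_cl[which.max(plus_cl$n_genes), ]
    members <- plus_cl$members[[1]]
    first_gene <- members[which.min(genes$start[match(members, genes$gene_number)])]
    hit <- plus[plus$downstream_gene == first_gene, ]
    if (nrow(hit) == 1L) return(hit)
  }
  warning("first '+'-cluster gene has no qualifying upstream region; ",
          "using the longest '+' region as anchor")
  plus[which.max(plus$gap_len), ]
}

#' Write regions as multi-FASTA with provenance headers
#'
#' @param regions Regions tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_fasta <- function(regions, path) {
  set <- Biostrings::DNAStringSet(regions$sequence)
  names(set) <- sprintf(
    "region_%d gene=%d interval=%d..%d strand=%s fused=%d",
    regions$region_id, regions$downstream_gene, regions$gap_start,
    regions$gap_end, regions$strand, regions$fused_offset
  )
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
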