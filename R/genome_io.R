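#' Create a genome record
#'
#' A `genome_record` holds one (possibly circular) DNA sequence. Phage
#' genomes typically circularise on cell entry, so `topology` defaults to
#' `"circular"`; the origin-spanning intergenic region between the two
#' divergent gene clusters only exists under that topology.
#'
#' @param sequence DNA string over IUPAC codes; normalised to upper case.
#' @param identifier Record identifier.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `genome_record` with fields `identifier`,
#'   `sequence`, `topology` and `length`.
#' @export
genome_record <- function(sequence, identifier = "genome",
                          topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  # validates the alphabet (IUPAC DNA) as a side effect
  Biostrings::DNAString(sequence)
  structure(
    list(
      identifier = identifier,
      sequence = sequence,
      topology = topology,
      length = nchar(sequence)
    ),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf(
    "<genome_record> %s: %s bp, %s\n", x$identifier,
    format(x$length, big.mark = ","), x$topology
  ))
  invisible(x)
}

#' Read a genome sequence
#'
#' Reads a single-record FASTA or GenBank flat file. Multi-record files are
#' rejected: the pipeline operates on one phage genome at a time.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"fasta"` or `"genbank"`.
#' @param topology Override the topology; `NULL` keeps the file's LOCUS
#'   topology for GenBank and defaults to circular for FASTA.
#' @return A [genome_record()].
#' @export
read_genome <- function(path, format = c("auto", "fasta", "genbank"),
                        topology = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "genbank") {
    gb <- parse_genbank(path)
    topo <- topology %||% gb$topology
    return(genome_record(gb$sequence, identifier = gb$locus, topology = topo))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record, found ", length(set))
  }
  genome_record(as.character(set[[1]]),
    identifier = sub("\\s.*$", "", names(set)[1]),
    topology = topology %||% "circular"
  )
}

#' Write a genome record as FASTA
#'
#' @param genome A [genome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$identifier
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    fa = , fna = , fasta = "fasta",
    gb = , gbk = , genbank = "genbank",
    gff = , gff3 = "gff3",
    stop("cannot guess format from extension '.", ext, "'; pass `format`")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene annotations
#'
#' Reads gene coordinates from a GFF3 file or from the FEATURES table of a
#' GenBank flat file. Genes are returned sorted by start coordinate and
#' numbered in genomic order (the ordinal `gene_number` used throughout the
#' package) unless the file itself provides numbering.
#'
#' On a circular genome an origin-spanning gene is represented with
#' `end < start`; that representation is rejected for linear genomes.
#'
#' @param path Path to a GFF3 or GenBank file.
#' @param format `"auto"`, `"gff3"` or `"genbank"`.
#' @param genome Optional [genome_record()]; when supplied, coordinates are
#'   validated against its length and topology.
#' @return A tibble with columns `gene_number`, `start`, `end`, `strand`,
#'   `label` (1-based inclusive coordinates).
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "genbank"),
                             genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  genes <- switch(format,
    gff3 = {
      gr <- rtracklayer::import(path, format = "gff3")
      gr <- gr[gr$type %in% c("gene", "CDS")]
      # prefer gene features when both layers are annotated
      if (any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
      tibble(
        start = BiocGenerics::start(gr),
        end = BiocGenerics::end(gr),
        strand = as.character(BiocGenerics::strand(gr)),
        label = as.character(gr$ID %||% gr$Name %||% NA_character_)
      )
    },
    genbank = {
      gb <- parse_genbank(path)
      feats <- gb$features
      keep <- if (any(feats$key == "CDS")) "CDS" else "gene"
      feats <- feats[feats$key == keep, , drop = FALSE]
      tibble(
        start = feats$start, end = feats$end, strand = feats$strand,
        label = feats$label
      )
    },
    stop("unsupported annotation format: ", format)
  )
  if (nrow(genes) == 0L) stop("no gene features found in ", path)
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene strands must be '+' or '-'")
  }
  genes <- dplyr::arrange(genes, .data$start, .data$end)
  genes$gene_number <- seq_len(nrow(genes))
  genes <- genes[, c("gene_number", "start", "end", "strand", "label")]
  if (!is.null(genome)) validate_genes(genes, genome)
  genes
}

validate_genes <- function(genes, genome) {
  len <- genome$length
  bad <- genes$start < 1 | genes$end < 1 | genes$start > len | genes$end > len
  if (any(bad)) {
    stop("gene coordinates out of range 1..", len, " for gene(s) ",
         paste(genes$gene_number[bad], collapse = ", "))
  }
  wraps <- genes$end < genes$start
  if (any(wraps) && genome$topology != "circular") {
    stop("origin-spanning gene(s) (end < start) require circular topology")
  }
  if (anyDuplicated(genes$gene_number)) stop("gene_numbers must be unique")
  invisible(genes)
}

# Physical span of a gene in bp, honouring origin wrap.
gene_length <- function(genes, genome) {
  interval_length(genes$start, genes$end, genome$length)
}

#' Group genes into strand clusters
#'
#' Maximal runs of consecutive same-strand genes, in genomic order. Phage
#' genomes of the kind analysed here fall into two divergent clusters: a
#' "+" cluster of structural/packaging genes and a "-" cluster of
#' functional genes. On a circular genome the first and last run are merged
#' when same-stranded across the origin.
#'
#' @param genes Gene tibble from [read_annotations()].
#' @param topology `"circular"` or `"linear"`.
#' @return A tibble with one row per cluster: `cluster_id`, `strand`,
#'   `n_genes`, `members` (list column of gene numbers), `span_start`,
#'   `span_end`.
#' @export
strand_clusters <- function(genes, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(nrow(genes) > 0)
  genes <- dplyr::arrange(genes, .data$start)
  r <- rle(genes$strand)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  clusters <- purrr::map(seq_along(r$values), function(i) {
    members <- genes$gene_number[idx_start[i]:idx_end[i]]
    list(strand = r$values[i], members = members)
  })
  if (topology == "circular" && length(clusters) > 1L &&
      clusters[[1]]$strand == clusters[[length(clusters)]]$strand) {
    last <- clusters[[length(clusters)]]
    clusters[[1]]$members <- c(last$members, clusters[[1]]$members)
    clusters <- clusters[-length(clusters)]
  }
  purrr::imap_dfr(clusters, function(cl, i) {
    sub <- genes[genes$gene_number %in% cl$members, ]
    tibble(
      cluster_id = i,
      strand = cl$strand,
      n_genes = length(cl$members),
      members = list(cl$members),
      span_start = min(sub$start),
      span_end = max(sub$end)
    )
  })
}
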