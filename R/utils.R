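DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (IUPAC codes allowed).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode a DNA string as integers 1..4 (A,C,G,T); anything else becomes NA.
encode_dna <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
}

decode_dna <- function(codes) {
  paste(DNA_BASES[codes], collapse = "")
}

# Slice a (possibly circular) genome sequence, 1-based inclusive.
# On a circular genome start may exceed end, meaning the slice wraps the
# origin; positions outside 1..len are reduced modulo the genome length.
circ_slice <- function(sequence, start, end, circular = TRUE) {
  len <- nchar(sequence)
  if (!circular) {
    stopifnot(start >= 1, end <= len, start <= end)
    return(substr(sequence, start, end))
  }
  wrap <- function(p) ((p - 1L) %% len) + 1L
  start <- wrap(start)
  end <- wrap(end)
  if (start <= end) {
    substr(sequence, start, end)
  } else {
    paste0(substr(sequence, start, len), substr(sequence, 1, end))
  }
}

# Length of a 1-based inclusive interval on a genome of length `len`,
# wrapping the origin when start > end.
interval_length <- function(start, end, len) {
  ifelse(start <= end, end - start + 1L, len - start + 1L + end)
}

# Base composition of a sequence (named frequency vector over A,C,G,T).
base_composition <- function(sequence) {
  codes <- encode_dna(sequence)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) {
    return(setNames(rep(0.25, 4), DNA_BASES))
  }
  counts <- tabulate(codes, nbins = 4L)
  setNames(counts / sum(counts), DNA_BASES)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Majority-rule consensus of equal-length sequences (ties broken by
# alphabetical base order, for determinism).
majority_consensus <- function(sequences) {
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = DNA_BASES))
    DNA_BASES[which.max(tab)]
  }) |> paste(collapse = "")
}
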