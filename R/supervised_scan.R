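#' Per-position frequency and information-content matrix
#'
#' Builds the matrix underlying a sequence logo from aligned equal-length
#' sequences: per-position base frequencies and information content
#' `IC = 2 - H` bits (Shannon entropy H, no small-sample correction).
#'
#' @param sequences Character vector of equal-length DNA sequences.
#' @param pseudocount Added per base per position before normalising
#'   (default 0: raw frequencies, as drawn in a logo).
#' @return A `logo_matrix`: list with `freq` (4 x L matrix, rows A,C,G,T),
#'   `ic` (bits per position), `n` (number of sequences).
#' @export
information_content <- function(sequences, pseudocount = 0) {
  stopifnot(length(sequences) >= 1)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences must have equal lengths")
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  freq <- apply(mat, 2, function(col) {
    counts <- table(factor(col, levels = DNA_BASES)) + pseudocount
    as.numeric(counts / sum(counts))
  })
  rownames(freq) <- DNA_BASES
  ic <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(freq = freq, ic = ic, n = length(sequences)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("<logo_matrix> %d positions from %d sequences, total IC %.2f bits\n",
              ncol(x$freq), x$n, sum(x$ic)))
  cat("consensus:", logo_consensus(x), "\n")
  invisible(x)
}

logo_consensus <- function(logo) {
  paste(DNA_BASES[apply(logo$freq, 2, which.max)], collapse = "")
}

#' Supervised scan for core-motif windows
#'
#' Slides over the direct strand of each oriented intergenic region and
#' reports every 12 bp window whose positions 3-8 match the given core
#' (default the discovered phage-promoter core "TGATGT") within
#' `max_core_mismatch` mismatches: 2 bp left flank (the "TG" segment
#' position) and 4 bp right flank (the "TATA" position). This recovers
#' promoter copies that pairwise alignment misses because their conserved
#' stretch is shorter.
#'
#' Windows truncated by a region edge, or containing ambiguous bases, are
#' skipped; the skipped count is returned as attribute `n_skipped`.
#'
#' @param regions Regions tibble from [extract_upstream_regions()].
#' @param genome A [genome_record()] for coordinate mapping.
#' @param core Core motif (length >= 4).
#' @param max_core_mismatch Allowed mismatches to the core (default 0).
#' @param flank_left,flank_right Flank widths around the core (2 and 4 give
#'   the canonical 12 bp window).
#' @return Tibble of candidate windows: `region_id`, `downstream_gene`,
#'   `strand`, `offset` (local 1-based window start), `coord_window`
#'   (genomic coordinate of window position 1), `coord_core` (of the core's
#'   5' base), `sequence`.
#' @export
core_scan <- function(regions, genome, core = "TGATGT",
                      max_core_mismatch = 0L, flank_left = 2L,
                      flank_right = 4L) {
  stopifnot(nchar(core) >= 4)
  core_chars <- strsplit(toupper(core), "", fixed = TRUE)[[1]]
  win_len <- flank_left + nchar(core) + flank_right
  skipped <- 0L
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    region <- regions[i, ]
    s <- region$sequence
    n <- nchar(s)
    if (n < win_len) return(NULL)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hits <- list()
    for (w in seq_len(n - win_len + 1L)) {
      core_at <- w + flank_left
      window <- chars[w:(w + win_len - 1L)]
      if (any(!window %in% DNA_BASES)) {
        skipped <<- skipped + 1L
        next
      }
      mm <- sum(chars[core_at:(core_at + length(core_chars) - 1L)] != core_chars)
      if (mm > max_core_mismatch) next
      hits[[length(hits) + 1L]] <- tibble(
        region_id = region$region_id,
        downstream_gene = region$downstream_gene,
        strand = region$strand,
        offset = w,
        coord_window = region_to_genomic(region, w, genome$length),
        coord_core = region_to_genomic(region, core_at, genome$length),
        sequence = paste(window, collapse = "")
      )
    }
    dplyr::bind_rows(hits)
  })
  if (nrow(out) == 0L) {
    out <- tibble(region_id = integer(), downstream_gene = integer(),
                  strand = character(), offset = integer(),
                  coord_window = integer(), coord_core = integer(),
                  sequence = character())
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Exact score-tail p-value of a window under a profile
#'
#' Scores the window by its log-likelihood ratio against the profile
#' (frequency matrix with pseudocounts) versus the background, then
#' computes the exact probability that an i.i.d. background 12-mer scores
#' at least as high, by dynamic programming over the per-position score
#' distribution (scores discretised to a fine lattice).
#'
#' @param window DNA string matching the profile width.
#' @param profile A `logo_matrix` (use `pseudocount > 0` when built from
#'   few sequences) or a 4 x L frequency matrix.
#' @param background Base-frequency vector (A,C,G,T); default uniform.
#' @param resolution Lattice width in score units (natural-log scale).
#' @return The p-value.
#' @export
window_pvalue <- function(window, profile, background = rep(0.25, 4),
                          resolution = 1e-3) {
  freq <- if (inherits(profile, "logo_matrix")) profile$freq else profile
  L <- ncol(freq)
  stopifnot(nchar(window) == L)
  if (any(freq == 0)) {
    stop("degenerate profile (zero frequencies); rebuild with a pseudocount")
  }
  background <- background / sum(background)
  s <- log(freq / background)  # 4 x L log-likelihood-ratio scores
  # integer lattice, per position shifted to non-negative
  r <- round(sweep(s, 2, apply(s, 2, min)) / resolution)
  codes <- encode_dna(window)
  if (anyNA(codes)) stop("window contains non-ACGT characters")
  obs <- sum(r[cbind(codes, seq_len(L))])
  # DP over positions: distribution of the lattice score under background
  dist <- 1
  for (j in seq_len(L)) {
    width <- max(r[, j])
    new <- numeric(length(dist) + width)
    for (b in 1:4) {
      shift <- r[b, j]
      new[(shift + 1):(shift + length(dist))] <-
        new[(shift + 1):(shift + length(dist))] + dist * background[b]
    }
    dist <- new
  }
  sum(dist[(obs + 1):length(dist)])
}

#' Classify candidate windows into long (late) and short (middle) motifs
#'
#' The two phage-promoter classes differ in conserved length: late
#' promoters are full 12 bp motifs — a "TG" segment (at most one mismatch),
#' the "TGATGT" core, and an extra "TATA" element — while middle promoters
#' conserve only the core. A window is `late_long` iff its first two bases
#' match "TG" with <= 1 mismatch AND positions 9-12 equal "TATA";
#' otherwise it is `middle_short`. The reported anchor coordinate is the 5'
#' end of the "TG" segment for long motifs and of the core for short ones.
#'
#' @param windows Window tibble from [core_scan()] (optionally carrying a
#'   `pvalue` column).
#' @return The windows with `promoter_class` and `genomic_coordinate`
#'   columns added.
#' @export
classify_long_short <- function(windows) {
  if (nrow(windows) == 0L) {
    return(dplyr::mutate(windows, promoter_class = character(),
                         genomic_coordinate = integer()))
  }
  stopifnot(all(nchar(windows$sequence) == 12L))
  is_long <- purrr::map_lgl(windows$sequence, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    tg_mm <- sum(chars[1:2] != c("T", "G"))
    tg_mm <= 1L && identical(chars[9:12], c("T", "A", "T", "A"))
  })
  dplyr::mutate(
    windows,
    promoter_class = ifelse(is_long, "late_long", "middle_short"),
    genomic_coordinate = ifelse(is_long, .data$coord_window, .data$coord_core)
  )
}

#' Supervised promoter tracking
#'
#' Full supervised stage: scan all regions for the core, score each window
#' against a profile built from the seed (alignment-discovered) motif
#' instances, keep windows significant at `p_threshold`, and classify them
#' long/late vs short/middle. Seed windows rediscovered by the scan are
#' retained regardless of p-value.
#'
#' @param regions,genome As in [core_scan()].
#' @param seed_motifs Character vector of the alignment-discovered motif
#'   instances (equal length, typically 12 bp).
#' @param core Core to scan for; default the central 6-mer of the seed
#'   consensus.
#' @param p_threshold Reporting threshold for additional windows.
#' @param pseudocount Pseudocount per base when building the profile.
#' @param background Base frequencies for the p-value.
#' @param max_core_mismatch Allowed core mismatches in the scan.
#' @param extra_windows Optional window tibble (shape of [core_scan()]
#'   output) appended to the scan results — used for alignment-discovered
#'   instances whose core carries a mismatch and would escape an exact
#'   scan. Extra and seed windows are kept regardless of p-value: they
#'   were already validated by the alignment's E-value.
#' @return Classified promoter tibble (see [classify_long_short()]) with a
#'   `pvalue` column, sorted by genomic coordinate.
#' @export
track_promoters <- function(regions, genome, seed_motifs,
                            core = NULL, p_threshold = 0.05,
                            pseudocount = 0.5, background = rep(0.25, 4),
                            max_core_mismatch = 0L, extra_windows = NULL) {
  stopifnot(length(seed_motifs) >= 2)
  if (is.null(core)) {
    cons <- majority_consensus(seed_motifs)
    core <- substr(cons, 3, 8)
  }
  profile <- information_content(seed_motifs, pseudocount = pseudocount)
  windows <- core_scan(regions, genome, core = core,
                       max_core_mismatch = max_core_mismatch)
  protected <- character(0)
  if (!is.null(extra_windows) && nrow(extra_windows) > 0L) {
    extra <- dplyr::anti_join(extra_windows, windows,
                              by = c("region_id", "offset"))
    windows <- dplyr::bind_rows(windows, extra)
    protected <- extra_windows$sequence
  }
  if (nrow(windows) == 0L) return(classify_long_short(windows))
  windows$pvalue <- purrr::map_dbl(windows$sequence, window_pvalue,
                                   profile = profile, background = background)
  keep <- windows$pvalue < p_threshold |
    toupper(windows$sequence) %in% toupper(c(seed_motifs, protected))
  classify_long_short(windows[keep, ]) |>
    dplyr::arrange(.data$genomic_coordinate)
}

#' Align two specificity logos allowing at most one gap
#'
#' Compares two promoter specificities (e.g. a newly inferred phage-sigma
#' logo against an experimentally established consensus from a related
#' phage) by finding the relative offset — optionally with a single gap
#' column inserted in either logo — that maximises the summed per-position
#' dot product of base-frequency vectors.
#'
#' @param logo_a,logo_b `logo_matrix` objects (see [information_content()]).
#' @param max_gap 0 or 1 gap columns allowed.
#' @return List with `offset` (columns of B shifted right relative to A),
#'   `gap_in` ("none", "a", "b"), `gap_pos` (column index before which the
#'   gap sits, NA if none), `score`, and `n_overlap` (aligned columns).
#' @export
compare_specificities <- function(logo_a, logo_b, max_gap = 1L) {
  A <- logo_a$freq
  B <- logo_b$freq
  stopifnot(ncol(A) > 0, ncol(B) > 0, max_gap %in% c(0L, 1L))
  gap_col <- matrix(0, nrow = 4)
  variants <- list(list(A = A, B = B, gap_in = "none", gap_pos = NA_integer_))
  if (max_gap >= 1L) {
    for (g in seq_len(ncol(A) + 1L)) {
      Ag <- cbind(A[, seq_len(g - 1L), drop = FALSE], gap_col,
                  A[, seq_len(ncol(A)) >= g, drop = FALSE])
      variants[[length(variants) + 1L]] <-
        list(A = Ag, B = B, gap_in = "a", gap_pos = g)
    }
    for (g in seq_len(ncol(B) + 1L)) {
      Bg <- cbind(B[, seq_len(g - 1L), drop = FALSE], gap_col,
                  B[, seq_len(ncol(B)) >= g, drop = FALSE])
      variants[[length(variants) + 1L]] <-
        list(A = A, B = Bg, gap_in = "b", gap_pos = g)
    }
  }
  best <- NULL
  for (v in variants) {
    la <- ncol(v$A); lb <- ncol(v$B)
    for (o in seq(-(lb - 1L), la - 1L)) {
      ia <- seq_len(la); ib <- ia - o
      keep <- ib >= 1L & ib <= lb
      if (!any(keep)) next
      sc <- sum(v$A[, ia[keep], drop = FALSE] * v$B[, ib[keep], drop = FALSE])
      cand <- list(offset = o, gap_in = v$gap_in, gap_pos = v$gap_pos,
                   score = sc, n_overlap = sum(keep))
      if (is.null(best) || sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 && v$gap_in == "none" &&
           best$gap_in != "none")) {
        best <- cand
      }
    }
  }
  best
}
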