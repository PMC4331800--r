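#' Simulate a circular phage-like genome with planted promoters
#'
#' Generates the genome architecture characteristic of lytic phages that
#' encode their own sigma factor: a circular genome with two divergent
#' gene clusters — a "+" cluster of (structural) genes and a "-" cluster
#' of (functional) genes — separated on one side by a long origin-spanning
#' intergenic region and on the other by a short convergent gap. Late
#' promoter motifs are planted in the origin-spanning region (upstream of
#' the "+" cluster), middle core motifs in intergenic gaps of the
#' downstream part of the "-" cluster, and sigma70 promoters upstream of /
#' within the upstream part of the "-" cluster, on its strand.
#'
#' Defaults mirror the architecture the pipeline targets at a desk-scale
#' size: 20 kb, 5 "+" and 15 "-" genes with log-normal lengths around a
#' few hundred bp, 4 late copies of the 12 bp template "TGTGATGTTATA",
#' 6 middle copies of its core, 8 sigma70 promoters, uniform background,
#' and no mutation of the planted copies (they are well-conserved repeats).
#'
#' @param genome_length Upper bound on genome size used to check packing
#'   feasibility; the realised length is the gene content plus gaps plus
#'   `origin_gap` (about 12-13 kb at the defaults).
#' @param n_plus,n_minus Gene counts for the two clusters.
#' @param late_template Late (long) motif template; its positions 3-8 are
#'   the core used for middle motifs.
#' @param n_late,n_middle,n_sigma70 Planted copy numbers.
#' @param mutation_rate Per-position substitution probability applied
#'   independently to every planted copy.
#' @param sigma70_minus35,sigma70_minus10 Consensus hexamers for planted
#'   host promoters (planted as consensus, spacer 17, so they score 0
#'   under a model trained on matching data).
#' @param background Base-frequency vector for the random backbone.
#' @param gene_meanlog,gene_sdlog Log-normal gene-length parameters.
#' @param origin_gap Length of the origin-spanning intergenic region (bp).
#' @param seed Mandatory random seed.
#' @return List with `genome` (a [genome_record()]), `genes` (annotation
#'   tibble) and `truth` (tibble: `type`, `coordinate`, `strand`,
#'   `sequence`, `temporal_class`; coordinates follow the reporting
#'   anchors: motif 5' base for late/middle, -35..-10 footprint 5' end for
#'   sigma70).
#' @export
simulate_phage_genome <- function(genome_length = 20000L,
                                  n_plus = 5L, n_minus = 15L,
                                  late_template = "TGTGATGTTATA",
                                  n_late = 4L, n_middle = 6L,
                                  n_sigma70 = 8L,
                                  mutation_rate = 0,
                                  sigma70_minus35 = "TTGACA",
                                  sigma70_minus10 = "TATAAT",
                                  background = rep(0.25, 4),
                                  gene_meanlog = log(400), gene_sdlog = 0.4,
                                  origin_gap = 1200L, seed) {
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  background <- background / sum(background)

  # --- gene layout -------------------------------------------------------
  # [origin gap (wraps)] [+ cluster] [convergent gap] [- cluster] [origin..
  n_genes <- n_plus + n_minus
  gene_lens <- pmax(90L, round(stats::rlnorm(n_genes, gene_meanlog,
                                             gene_sdlog)))
  # "+"-cluster gaps stay below the 50 bp extraction cutoff (the late
  # promoters all sit in the origin region); "-"-cluster gaps are large
  # enough to be searchable and to host planted promoters
  plus_gaps <- sample(15:45, n_plus, replace = TRUE)
  minus_gaps <- sample(90:140, n_minus, replace = TRUE)
  convergent_gap <- 40L
  body <- sum(gene_lens) + sum(plus_gaps[-1]) + sum(minus_gaps[-1]) +
    convergent_gap
  if (body + origin_gap + 200L > genome_length) {
    stop("infeasible packing: genes + gaps exceed genome_length")
  }
  # genome coordinate 1 sits inside the origin gap, `upstream_pad` bp
  # before the first "+" gene, so the origin gap wraps the origin
  upstream_pad <- round(origin_gap / 2)

  starts <- integer(n_genes)
  ends <- integer(n_genes)
  strands <- c(rep("+", n_plus), rep("-", n_minus))
  pos <- upstream_pad + 1L
  for (i in seq_len(n_plus)) {
    if (i > 1L) pos <- pos + plus_gaps[i]
    starts[i] <- pos
    ends[i] <- pos + gene_lens[i] - 1L
    pos <- ends[i] + 1L
  }
  pos <- pos + convergent_gap
  for (k in seq_len(n_minus)) {
    i <- n_plus + k
    if (k > 1L) pos <- pos + minus_gaps[k]
    starts[i] <- pos
    ends[i] <- pos + gene_lens[i] - 1L
    pos <- ends[i] + 1L
  }
  last_end <- ends[n_genes]
  # stretch the genome so the wrap gap is exactly origin_gap
  genome_length <- as.integer(last_end + (origin_gap - upstream_pad))
  genes <- tibble(
    gene_number = seq_len(n_genes), start = starts, end = ends,
    strand = strands,
    label = c(sprintf("structural_%d", seq_len(n_plus)),
              sprintf("functional_%d", seq_len(n_minus)))
  )

  # --- backbone sequence -------------------------------------------------
  seq_chars <- sample(DNA_BASES, genome_length, replace = TRUE,
                      prob = background)

  truth <- list()
  plant <- function(oriented_seq, coord5, strand, type, temporal,
                    anchor_offset = 0L) {
    # place `oriented_seq` so its 5' base lands on genomic `coord5`,
    # reading rightwards for "+" and leftwards for "-"
    chars <- strsplit(oriented_seq, "", fixed = TRUE)[[1]]
    if (mutation_rate > 0) {
      mut <- runif(length(chars)) < mutation_rate
      chars[mut] <- vapply(chars[mut], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
    }
    mutated <- paste(chars, collapse = "")
    genomic <- if (strand == "+") chars else rev(chartr("ACGT", "TGCA", chars))
    pos0 <- if (strand == "+") coord5 else coord5 - length(chars) + 1L
    idx <- ((pos0 + seq_along(chars) - 2L) %% genome_length) + 1L
    seq_chars[idx] <<- genomic
    anchor <- if (strand == "+") coord5 + anchor_offset else
      coord5 - anchor_offset
    truth[[length(truth) + 1L]] <<- tibble(
      type = type, coordinate = ((anchor - 1L) %% genome_length) + 1L,
      strand = strand, sequence = mutated, temporal_class = temporal
    )
  }

  # Late motifs go in the right half of the origin-spanning region (the
  # side nearest the "+" cluster it transcribes), oriented "+".
  Lm <- nchar(late_template)
  origin_lo <- last_end + 1L  # wraps through genome_length to upstream_pad
  slots <- round(seq(ceiling(origin_gap / 2), origin_gap - Lm - 10L,
                     length.out = max(n_late, 1L)))
  for (s in slots[seq_len(n_late)]) {
    plant(late_template, ((origin_lo + s - 2L) %% genome_length) + 1L,
          "+", "late_promoter", "late")
  }

  # Middle motifs (core embedded in a 12 bp window whose flanks break the
  # TG/TATA long-motif rule) go in the gaps of the DOWNSTREAM part of the
  # "-" cluster: transcription runs right-to-left, so downstream gaps are
  # the low-coordinate ones. The gap left of "-" gene i is upstream of
  # gene i - 1.
  # flanks weakly resemble the long template (so the windows stay
  # significant under the long-motif profile) but fail the TG+TATA rule
  core <- substr(late_template, 3L, 8L)
  middle_window <- paste0("AG", core, "GTAA")
  big_ks <- 2L:n_minus
  stopifnot(n_middle + min(n_sigma70, length(big_ks) - n_middle) <=
              length(big_ks))
  middle_ks <- head(big_ks, n_middle)
  for (k in middle_ks) {
    i <- n_plus + k
    gap_start <- ends[i - 1L] + 1L
    gap_end <- starts[i] - 1L
    mid <- gap_start + floor((gap_end - gap_start) / 2)
    # oriented "-": 5' base at the higher coordinate; anchor = core 5' base
    plant(middle_window, mid, "-", "middle_promoter", "middle",
          anchor_offset = 2L)
  }

  # Sigma70 promoters (consensus -35 + random 17 bp spacer + consensus
  # -10, "-" strand) go in the UPSTREAM part of the "-" cluster, with any
  # remainder in the left (cluster-proximal) half of the origin gap.
  sig_ks <- setdiff(big_ks, middle_ks)
  promoter_len <- 12L + 17L
  sig_slots <- integer(0)
  for (k in rev(sig_ks)) {
    if (length(sig_slots) >= n_sigma70) break
    i <- n_plus + k
    gap_start <- ends[i - 1L] + 1L
    gap_end <- starts[i] - 1L
    if (gap_end - gap_start + 1L < promoter_len + 8L) next
    sig_slots <- c(sig_slots, gap_end - 4L)
  }
  n_extra <- n_sigma70 - length(sig_slots)
  if (n_extra > 0L) {
    lo_half_end <- floor(origin_gap / 2) - Lm - 10L
    stopifnot(lo_half_end - 40L >= promoter_len)
    extra <- round(seq(40L, lo_half_end, length.out = n_extra))
    sig_slots <- c(sig_slots,
                   ((origin_lo + extra - 2L) %% genome_length) + 1L)
  }
  for (s in sig_slots) {
    spacer_seq <- paste(sample(DNA_BASES, 17L, replace = TRUE),
                        collapse = "")
    plant(paste0(sigma70_minus35, spacer_seq, sigma70_minus10), s, "-",
          "sigma70_promoter", "early")
  }

  genome <- genome_record(paste(seq_chars, collapse = ""),
                          identifier = sprintf("sim_phage_seed%d", seed),
                          topology = "circular")
  truth <- dplyr::bind_rows(truth)
  list(genome = genome, genes = genes, truth = truth)
}

#' Simulate a sigma70 promoter training set
#'
#' Samples aligned training promoters from per-position base frequencies
#' for the -35 and -10 hexamers and a spacer-length distribution. The
#' default frequency profile is a synthetic stand-in for a large-scale
#' E. coli sigma70 promoter alignment: consensus TTGACA / TATAAT with
#' position-dependent conservation (strong at the invariant positions,
#' weaker elsewhere) and a 17 bp-modal spacer distribution.
#'
#' @param n Number of promoters (>= 10).
#' @param freq35,freq10 4 x 6 base-frequency matrices (rows A,C,G,T);
#'   `NULL` uses the built-in synthetic profile.
#' @param spacer_probs Named numeric vector of spacer-length
#'   probabilities.
#' @param seed Mandatory random seed.
#' @return Training tibble with `minus35`, `spacer_len`, `minus10`.
#' @export
simulate_training_promoters <- function(n = 500L, freq35 = NULL,
                                        freq10 = NULL,
                                        spacer_probs = c(
                                          "15" = 0.02, "16" = 0.18,
                                          "17" = 0.45, "18" = 0.25,
                                          "19" = 0.08, "20" = 0.02
                                        ),
                                        seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(n >= 10)
  set.seed(seed)
  freq35 <- freq35 %||% default_sigma70_freq("TTGACA",
                                             c(0.82, 0.80, 0.65, 0.55, 0.50, 0.60))
  freq10 <- freq10 %||% default_sigma70_freq("TATAAT",
                                             c(0.85, 0.88, 0.55, 0.52, 0.55, 0.90))
  sample_element <- function(freq) {
    vapply(seq_len(n), function(i) {
      paste(vapply(seq_len(ncol(freq)), function(j) {
        sample(DNA_BASES, 1L, prob = freq[, j])
      }, character(1)), collapse = "")
    }, character(1))
  }
  spacer_lens <- as.integer(names(spacer_probs))
  tibble(
    minus35 = sample_element(freq35),
    spacer_len = if (length(spacer_lens) == 1L) rep(spacer_lens, n) else
      sample(spacer_lens, n, replace = TRUE, prob = spacer_probs),
    minus10 = sample_element(freq10)
  )
}

# Frequency matrix with `conservation[j]` mass on the consensus base and
# the remainder spread evenly over the other three bases.
default_sigma70_freq <- function(consensus, conservation) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  freq <- vapply(seq_along(chars), function(j) {
    f <- rep((1 - conservation[j]) / 3, 4)
    f[match(chars[j], DNA_BASES)] <- conservation[j]
    f
  }, numeric(4))
  rownames(freq) <- DNA_BASES
  freq
}

#' Precision and recall against a planted truth set
#'
#' A prediction is a true positive when a truth feature of matching class
#' exists within `tolerance` bp of its anchor coordinate (each truth
#' feature can be matched at most once). With no predictions, recall is 0
#' and precision is reported as 0 with `undefined_precision = TRUE`.
#'
#' @param predictions Tibble with `coordinate` and `class` columns (class
#'   values comparable to truth `type` or `temporal_class`; pass truth
#'   `type` values such as "late_promoter").
#' @param truth Truth tibble from [simulate_phage_genome()].
#' @param tolerance Coordinate tolerance in bp.
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `undefined_precision`.
#' @export
evaluate_against_truth <- function(predictions, truth, tolerance = 3L) {
  if (nrow(predictions) == 0L) {
    return(list(precision = 0, recall = 0, tp = 0L, fp = 0L,
                fn = nrow(truth), undefined_precision = TRUE))
  }
  matched <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(predictions))) {
    cand <- which(!matched &
                    truth$type == predictions$class[i] &
                    abs(truth$coordinate - predictions$coordinate[i]) <=
                      tolerance)
    if (length(cand)) {
      matched[cand[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(predictions) - tp
  fn <- sum(!matched & truth$type %in% predictions$class)
  list(precision = tp / nrow(predictions),
       recall = if (any(truth$type %in% predictions$class)) {
         tp / sum(truth$type %in% predictions$class)
       } else 0,
       tp = tp, fp = fp, fn = fn, undefined_precision = FALSE)
}

#' Write a truth set as TSV
#'
#' @param truth Truth tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
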