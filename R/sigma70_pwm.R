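#' Build the composite sigma70 promoter model
#'
#' Trains the host-promoter scoring model from an aligned promoter set:
#' log-odds weight matrices for the -35 and -10 hexamers (and optionally a
#' -15 element immediately upstream of the -10), plus a spacer-length score
#' from the empirical spacer distribution. All components are normalised so
#' that the consensus -35, optimal 17 bp spacer and consensus -10 score
#' exactly zero, and every other configuration scores below zero — the
#' closer to zero, the better the promoter.
#'
#' The spacer score is `log(freq(l) / freq(17))` with no pseudocount:
#' spacer lengths unseen in training (within the support) score `-Inf`,
#' i.e. are excluded, and lengths outside the support are rejected.
#'
#' @param training Tibble with columns `minus35`, `spacer_len`, `minus10`
#'   and optionally `minus15` (aligned fixed-width sequences; see
#'   [read_training_promoters()]). Ten or more promoters are recommended
#'   for stable matrices.
#' @param pseudocount Per-base pseudocount for the element matrices.
#' @param background Base-frequency vector (A,C,G,T).
#' @param spacer_support Allowed spacer lengths (bp).
#' @return An object of class `promoter_model`.
#' @export
build_promoter_model <- function(training, pseudocount = 0.5,
                                 background = rep(0.25, 4),
                                 spacer_support = 15:20) {
  stopifnot(nrow(training) >= 1,
            all(c("minus35", "spacer_len", "minus10") %in% names(training)))
  if (!all(training$spacer_len %in% spacer_support)) {
    stop("training spacer lengths outside support ",
         paste(range(spacer_support), collapse = ".."))
  }
  if (!17L %in% spacer_support) stop("spacer support must include 17")
  background <- setNames(background / sum(background), DNA_BASES)

  pwm35 <- element_pwm(training$minus35, pseudocount, background)
  pwm10 <- element_pwm(training$minus10, pseudocount, background)
  pwm15 <- if ("minus15" %in% names(training) &&
               !all(is.na(training$minus15))) {
    element_pwm(training$minus15[!is.na(training$minus15)], pseudocount,
                background)
  }

  counts <- table(factor(training$spacer_len, levels = spacer_support))
  if (counts[["17"]] == 0L) {
    stop("training set contains no 17 bp spacers; ",
         "the consensus-zero normalisation is anchored at 17")
  }
  spacer_score <- log(as.numeric(counts) / counts[["17"]])
  names(spacer_score) <- as.character(spacer_support)
  if (max(spacer_score) > 0) {
    warning("17 bp is not the modal training spacer; the consensus ",
            "configuration is not the unique score maximum")
  }

  structure(
    list(
      pwm35 = pwm35$shifted, pwm10 = pwm10$shifted,
      pwm15 = if (!is.null(pwm15)) pwm15$shifted,
      spacer_score = spacer_score,
      spacer_support = spacer_support,
      consensus35 = pwm35$consensus, consensus10 = pwm10$consensus,
      background = background,
      normalization = pwm35$colmax_sum + pwm10$colmax_sum +
        (if (!is.null(pwm15)) pwm15$colmax_sum else 0),
      n_training = nrow(training), pseudocount = pseudocount
    ),
    class = "promoter_model"
  )
}

element_pwm <- function(sequences, pseudocount, background) {
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("element sequences must have equal width")
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  lo <- apply(mat, 2, function(col) {
    counts <- table(factor(col, levels = DNA_BASES)) + pseudocount
    log(as.numeric(counts / sum(counts)) / background)
  })
  rownames(lo) <- DNA_BASES
  colmax <- apply(lo, 2, max)
  list(
    shifted = sweep(lo, 2, colmax),
    colmax_sum = sum(colmax),
    consensus = paste(DNA_BASES[apply(lo, 2, which.max)], collapse = "")
  )
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf(
    "<promoter_model> %s ..%s.. %s (trained on %d promoters%s)\n",
    tolower(x$consensus35), "17bp", tolower(x$consensus10), x$n_training,
    if (is.null(x$pwm15)) "" else ", with -15 element"
  ))
  cat("spacer support:", paste(x$spacer_support, collapse = ","),
      " consensus score: 0 (maximum)\n")
  invisible(x)
}

#' Score one promoter window
#'
#' Scores a candidate window decomposed as 6 bp (-35) + spacer + 6 bp
#' (-10). The -15 contribution, when the model carries one, is scored on
#' the spacer bases immediately upstream of the -10 hexamer. The score is
#' <= 0; 0 is attained exactly by the consensus configuration with a 17 bp
#' spacer.
#'
#' @param window DNA string of length `width(-35) + spacer + width(-10)`
#'   (12 + spacer for the standard hexamer model).
#' @param spacer Spacer length in bp (must be in the model's support).
#' @param model A [build_promoter_model()] fit.
#' @return The score, or `NA` if the window contains non-ACGT characters.
#' @export
score_window <- function(window, spacer, model) {
  stopifnot(inherits(model, "promoter_model"))
  if (!spacer %in% model$spacer_support) {
    stop("spacer ", spacer, " outside model support")
  }
  w35 <- ncol(model$pwm35)
  w10 <- ncol(model$pwm10)
  if (nchar(window) != w35 + w10 + spacer) {
    stop("window must be ", w35, " + spacer + ", w10, " bp")
  }
  codes <- encode_dna(window)
  if (anyNA(codes)) return(NA_real_)
  s35 <- sum(model$pwm35[cbind(codes[seq_len(w35)], seq_len(w35))])
  s10 <- sum(model$pwm10[cbind(codes[(w35 + spacer + 1L):(w35 + spacer + w10)],
                               seq_len(w10))])
  s15 <- 0
  if (!is.null(model$pwm15)) {
    w <- ncol(model$pwm15)
    if (spacer >= w) {
      i15 <- (w35 + spacer - w + 1L):(w35 + spacer)
      s15 <- sum(model$pwm15[cbind(codes[i15], seq_len(w))])
    }
  }
  s35 + s10 + s15 + model$spacer_score[[as.character(spacer)]]
}

# Vectorised element scores at every start of a coded sequence.
pwm_scan_scores <- function(codes, pwm) {
  w <- ncol(pwm)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + pwm[cbind(codes[j:(j + n - 1L)], j)]
  }
  sc
}

#' Scan a genome (or its intergenic regions) for sigma70 promoters
#'
#' Slides the composite model over the sequence, reporting every window
#' scoring at least `threshold` with its best spacer decomposition.
#' Overlapping same-strand predictions (sharing more than half of the
#' shorter interval) are merged to the best-scoring one. Windows containing
#' ambiguous bases are skipped.
#'
#' @param genome A [genome_record()].
#' @param model A [build_promoter_model()] fit.
#' @param threshold Finite score threshold (<= 0).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param regions Optional regions tibble; when supplied only those
#'   oriented intergenic sequences are scanned (direct strand), as in the
#'   intergenic promoter search.
#' @return Tibble of predictions: `start`, `end` (1-based genomic interval
#'   of the -35..-10 footprint), `strand`, `minus35`, `spacer_length`,
#'   `minus10`, `score`, sorted by score.
#' @export
scan_genome <- function(genome, model, threshold, strands = "both",
                        regions = NULL) {
  stopifnot(is.finite(threshold), threshold <= 0)
  preds <- if (is.null(regions)) {
    scan_tracks <- list()
    if (strands %in% c("both", "+")) {
      scan_tracks$plus <- scan_one_strand(genome$sequence, model, "+",
                                          genome$length)
    }
    if (strands %in% c("both", "-")) {
      scan_tracks$minus <- scan_one_strand(revcomp(genome$sequence), model,
                                           "-", genome$length)
    }
    dplyr::bind_rows(scan_tracks)
  } else {
    purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      region <- regions[i, ]
      p <- scan_one_strand(region$sequence, model, region$strand,
                           genome$length, region = region)
      p
    })
  }
  if (nrow(preds) == 0L) return(preds)
  preds <- preds[preds$score >= threshold, ]
  preds <- merge_overlapping_predictions(preds)
  dplyr::arrange(preds, dplyr::desc(.data$score))
}

scan_one_strand <- function(sequence, model, strand, genome_length,
                            region = NULL) {
  codes <- encode_dna(sequence)
  codes[is.na(codes)] <- 5L  # sentinel row of -Inf would break lookups:
  # pad the matrices with a 5th all -Inf row instead
  pad <- function(m) rbind(m, rep(-Inf, ncol(m)))
  p35 <- pad(model$pwm35); p10 <- pad(model$pwm10)
  p15 <- if (!is.null(model$pwm15)) pad(model$pwm15)
  s35 <- pwm_scan_scores(codes, p35)
  s10 <- pwm_scan_scores(codes, p10)
  s15 <- if (!is.null(p15)) pwm_scan_scores(codes, p15)
  n <- length(codes)
  w35 <- ncol(model$pwm35)
  w10 <- ncol(model$pwm10)
  out <- list()
  for (sp in model$spacer_support) {
    sp_score <- model$spacer_score[[as.character(sp)]]
    if (!is.finite(sp_score)) next
    width <- w35 + w10 + sp
    n_start <- n - width + 1L
    if (n_start < 1L) next
    i <- seq_len(n_start)
    total <- s35[i] + sp_score + s10[i + w35 + sp]
    if (!is.null(s15)) {
      w15 <- ncol(model$pwm15)
      if (sp >= w15) total <- total + s15[i + w35 + sp - w15]
    }
    ok <- which(is.finite(total))
    if (!length(ok)) next
    out[[length(out) + 1L]] <- tibble(
      local_start = ok, spacer_length = sp, score = total[ok]
    )
  }
  preds <- dplyr::bind_rows(out)
  if (is.null(preds) || nrow(preds) == 0L) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  minus35 = character(), spacer_length = integer(),
                  minus10 = character(), score = double()))
  }
  # best spacer decomposition per start
  preds <- preds |>
    dplyr::group_by(.data$local_start) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  width <- w35 + w10 + preds$spacer_length
  m35 <- substring(sequence, preds$local_start, preds$local_start + w35 - 1L)
  m10 <- substring(sequence,
                   preds$local_start + w35 + preds$spacer_length,
                   preds$local_start + width - 1L)
  if (is.null(region)) {
    if (strand == "+") {
      g_start <- preds$local_start
      g_end <- preds$local_start + width - 1L
    } else {
      g_end <- genome_length - preds$local_start + 1L
      g_start <- g_end - width + 1L
    }
  } else {
    a <- region_to_genomic(region, preds$local_start, genome_length)
    b <- region_to_genomic(region, preds$local_start + width - 1L,
                           genome_length)
    g_start <- pmin(a, b)
    g_end <- pmax(a, b)
  }
  tibble(
    start = as.integer(g_start), end = as.integer(g_end), strand = strand,
    minus35 = m35, spacer_length = preds$spacer_length, minus10 = m10,
    score = preds$score
  )
}

merge_overlapping_predictions <- function(preds, min_frac = 0.5) {
  preds <- dplyr::arrange(preds, dplyr::desc(.data$score))
  keep <- rep(TRUE, nrow(preds))
  for (i in seq_len(nrow(preds))[-1]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || preds$strand[i] != preds$strand[j]) next
      ov <- min(preds$end[i], preds$end[j]) -
        max(preds$start[i], preds$start[j]) + 1L
      shorter <- min(preds$end[i] - preds$start[i],
                     preds$end[j] - preds$start[j]) + 1L
      if (ov > min_frac * shorter) {
        keep[i] <- FALSE
        break
      }
    }
  }
  preds[keep, ]
}

#' Choose a reporting threshold by strand positional bias
#'
#' The score threshold for promoter reporting is in principle arbitrary;
#' what lends confidence is positional bias: early (host-transcribed)
#' promoters should sit on the strand of the functional gene cluster, with
#' none on the structural cluster's strand. This picks the most permissive
#' threshold such that at most `max_plus` "+"-strand predictions remain,
#' and reports the resulting "-"-strand count.
#'
#' @param predictions Prediction tibble from [scan_genome()] run at a
#'   permissive threshold.
#' @param required_minus Desired number of "-"-strand predictions; a
#'   warning is issued when unattainable.
#' @param max_plus Maximum tolerated "+"-strand predictions (default 0).
#' @return List with `threshold`, `n_minus`, `n_plus`, `achieved`.
#' @export
threshold_by_strand_bias <- function(predictions, required_minus = 1L,
                                     max_plus = 0L) {
  stopifnot(nrow(predictions) > 0)
  cand <- sort(unique(predictions$score))
  plus <- predictions$score[predictions$strand == "+"]
  minus <- predictions$score[predictions$strand == "-"]
  ok <- cand[vapply(cand, function(t) sum(plus >= t) <= max_plus, logical(1))]
  if (length(ok) == 0L) {
    warning("no threshold satisfies the '+'-strand constraint")
    thr <- max(cand)
  } else {
    thr <- min(ok)
  }
  n_minus <- sum(minus >= thr)
  n_plus <- sum(plus >= thr)
  if (n_minus < required_minus) {
    warning("only ", n_minus, " '-'-strand predictions at the selected ",
            "threshold (", required_minus, " requested)")
  }
  list(threshold = thr, n_minus = n_minus, n_plus = n_plus,
       achieved = n_minus >= required_minus && n_plus <= max_plus)
}

#' Read a sigma70 training alignment
#'
#' Tab-separated columns `minus35`, `spacer_len`, `minus10` and optionally
#' `minus15`.
#'
#' @param path TSV path.
#' @return Training tibble for [build_promoter_model()].
#' @export
read_training_promoters <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("minus35", "spacer_len", "minus10")
  if (!all(need %in% names(df))) {
    stop("training file must have columns ", paste(need, collapse = ", "))
  }
  as_tibble(df)
}
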