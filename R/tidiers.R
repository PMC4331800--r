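#' Tidy a sigma70 promoter model
#'
#' One row per element, position and base, with the normalised log-odds
#' score (0 for the consensus base of each column).
#'
#' @param x A `promoter_model`.
#' @param ... Unused.
#' @return A tibble with columns `element`, `position`, `base`, `score`.
#' @method tidy promoter_model
#' @export
tidy.promoter_model <- function(x, ...) {
  mat_rows <- function(mat, element) {
    tibble(
      element = element,
      position = rep(seq_len(ncol(mat)), each = 4L),
      base = rep(DNA_BASES, ncol(mat)),
      score = as.vector(mat)
    )
  }
  out <- dplyr::bind_rows(
    mat_rows(x$pwm35, "minus35"),
    if (!is.null(x$pwm15)) mat_rows(x$pwm15, "minus15"),
    mat_rows(x$pwm10, "minus10"),
    tibble(element = "spacer",
           position = as.integer(names(x$spacer_score)),
           base = NA_character_, score = unname(x$spacer_score))
  )
  out
}

#' One-row summary of a sigma70 promoter model
#'
#' @param x A `promoter_model`.
#' @param ... Unused.
#' @return A one-row tibble: consensus elements, training size, spacer
#'   support, normalisation constant.
#' @method glance promoter_model
#' @export
glance.promoter_model <- function(x, ...) {
  tibble(
    consensus35 = x$consensus35, consensus10 = x$consensus10,
    has_minus15 = !is.null(x$pwm15),
    n_training = x$n_training,
    spacer_min = min(x$spacer_support), spacer_max = max(x$spacer_support),
    normalization = x$normalization
  )
}

#' Tidy a Gibbs sampler result
#'
#' @param x A `sampler_result`.
#' @param ... Unused.
#' @return The site tibble (`seq`, `pos`, `sequence`, `score` in bits).
#' @method tidy sampler_result
#' @export
tidy.sampler_result <- function(x, ...) x$sites

#' One-row summary of a Gibbs sampler result
#'
#' @param x A `sampler_result`.
#' @param ... Unused.
#' @return A one-row tibble: consensus, site count, total information
#'   content (bits), motif length, seed.
#' @method glance sampler_result
#' @export
glance.sampler_result <- function(x, ...) {
  tibble(
    consensus = x$consensus, n_sites = nrow(x$sites),
    total_ic = sum(x$ic), motif_len = x$motif_len, seed = x$seed
  )
}

#' Tidy a logo matrix
#'
#' @param x A `logo_matrix`.
#' @param ... Unused.
#' @return A tibble with `position`, `base`, `freq` and per-position
#'   `bits`.
#' @method tidy logo_matrix
#' @export
tidy.logo_matrix <- function(x, ...) {
  tibble(
    position = rep(seq_len(ncol(x$freq)), each = 4L),
    base = rep(DNA_BASES, ncol(x$freq)),
    freq = as.vector(x$freq),
    bits = rep(x$ic, each = 4L)
  )
}
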