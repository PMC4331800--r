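#' Gibbs site sampler for motif discovery (MLSA baseline)
#'
#' Classic multiple-local-sequence-alignment motif finder: each sequence
#' holds one candidate site; sweeps hold one sequence out, rebuild the
#' motif frequency matrix from the remaining sites, and resample the
#' held-out site proportionally to its profile-vs-background likelihood
#' ratio. A final add/subtract cycle then removes sites that score below
#' background and adds extra non-overlapping sites that score above the
#' current site average, so the final alignment can hold fewer or more
#' than one site per sequence.
#'
#' This sampler is the baseline the pairwise-repeat method is compared
#' against: it excels when an (ambiguous) motif is present in most input
#' sequences, and is expected to be non-robust when a well-conserved motif
#' occurs in only a few of many sequences.
#'
#' @param sequences Character vector of DNA sequences (>= 2). Sequences
#'   shorter than `motif_len` are excluded with a message.
#' @param motif_len Motif width in bp (9 for sigma-factor phage searches,
#'   18 for single-subunit-RNAP promoters).
#' @param iterations Full sweeps of the site sampler.
#' @param restarts Independent chains; the best by total site score is
#'   returned.
#' @param seed Random seed (mandatory: results are deterministic given it).
#' @param pseudocount Per-base pseudocount in the profile.
#' @param background Base frequencies; default the 0-order composition of
#'   the input.
#' @return A `sampler_result`: `sites` tibble (`seq`, `pos`, `sequence`,
#'   `score` in log2 likelihood-ratio units), `pfm` (4 x L frequency
#'   matrix), `consensus`, `ic` (bits per position), `seed`, `motif_len`.
#' @export
gibbs_motif_sampler <- function(sequences, motif_len = 9L,
                                iterations = 500L, restarts = 1L,
                                seed, pseudocount = 0.5,
                                background = NULL) {
  stopifnot(length(sequences) >= 2, motif_len >= 4, restarts >= 1)
  if (missing(seed)) stop("`seed` is required")
  too_short <- nchar(sequences) < motif_len
  if (any(too_short)) {
    message(sum(too_short), " sequence(s) shorter than the motif excluded")
    sequences <- sequences[!too_short]
  }
  stopifnot(length(sequences) >= 2)
  set.seed(seed)

  if (is.null(background)) {
    background <- base_composition(paste(sequences, collapse = ""))
  }
  lbg <- c(log(background), -Inf)  # 5th entry: ambiguous base sentinel

  n_seq <- length(sequences)
  win <- purrr::map(sequences, function(s) {
    codes <- encode_dna(s)
    codes[is.na(codes)] <- 5L
    W <- length(codes) - motif_len + 1L
    matrix(codes[outer(seq_len(motif_len), seq_len(W) - 1L, `+`)],
           nrow = motif_len)
  })
  # background log-probability of every window (constant across sweeps)
  bg_w <- purrr::map(win, function(m) colSums(matrix(lbg[m], nrow = motif_len)))

  best <- NULL
  for (r in seq_len(restarts)) {
    res <- gibbs_chain(win, bg_w, sequences, motif_len, iterations,
                       pseudocount, background)
    if (is.null(best) || res$total_score > best$total_score) best <- res
  }
  structure(
    c(best, list(seed = seed, motif_len = motif_len,
                 iterations = iterations, background = background)),
    class = "sampler_result"
  )
}

gibbs_chain <- function(win, bg_w, sequences, L, iterations,
                        pseudocount, background) {
  n_seq <- length(win)
  n_win <- vapply(win, ncol, integer(1))
  sites <- vapply(n_win, function(w) sample.int(w, 1L), integer(1))

  site_counts <- function(sites) {
    C <- matrix(0, nrow = 5, ncol = L)
    for (i in seq_len(n_seq)) {
      if (is.na(sites[i])) next
      col <- win[[i]][, sites[i]]
      C[cbind(col, seq_len(L))] <- C[cbind(col, seq_len(L))] + 1
    }
    C
  }
  C <- site_counts(sites)

  profile_logp <- function(C, n_sites) {
    # ambiguous-base row never enters the profile
    p <- sweep(C[1:4, , drop = FALSE] + pseudocount, 2,
               n_sites + 4 * pseudocount, "/")
    rbind(log(p), rep(-Inf, L))
  }

  total_sites_score <- function(sites) {
    Cs <- site_counts(sites)
    lp <- profile_logp(Cs, n_seq)
    sum(vapply(seq_len(n_seq), function(i) {
      colSums(matrix(lp[cbind(win[[i]][, sites[i]], seq_len(L))],
                     nrow = L)) - bg_w[[i]][sites[i]]
    }, numeric(1)))
  }

  for (it in seq_len(iterations)) {
    for (i in seq_len(n_seq)) {
      col <- win[[i]][, sites[i]]
      C[cbind(col, seq_len(L))] <- C[cbind(col, seq_len(L))] - 1
      lp <- profile_logp(C, n_seq - 1L)
      sc <- colSums(matrix(lp[cbind(as.vector(win[[i]]),
                                    rep(seq_len(L), n_win[i]))],
                           nrow = L)) - bg_w[[i]]
      w <- exp(sc - max(sc[is.finite(sc)]))
      w[!is.finite(w)] <- 0
      sites[i] <- sample.int(n_win[i], 1L, prob = w)
      col <- win[[i]][, sites[i]]
      C[cbind(col, seq_len(L))] <- C[cbind(col, seq_len(L))] + 1
    }
    # phase-shift move: slide the whole alignment a few bp if that
    # improves the total site score (avoids shifted-registration traps)
    if (it %% 5L == 0L || it == iterations) {
      cur <- total_sites_score(sites)
      for (d in c(-2L, -1L, 1L, 2L)) {
        cand <- sites + d
        if (any(cand < 1L | cand > n_win)) next
        sc_d <- total_sites_score(cand)
        if (sc_d > cur) {
          sites <- cand
          cur <- sc_d
        }
      }
      C <- site_counts(sites)
    }
  }

  # add/subtract cycle: score every current site under the final profile;
  # drop sites scoring below background, then add non-overlapping extra
  # sites scoring above the mean retained-site score
  lp <- profile_logp(C, n_seq)
  window_scores <- function(i) {
    colSums(matrix(lp[cbind(as.vector(win[[i]]), rep(seq_len(L), n_win[i]))],
                   nrow = L)) - bg_w[[i]]
  }
  site_list <- purrr::map(seq_len(n_seq), function(i) {
    sc <- window_scores(i)
    keep <- if (sc[sites[i]] > 0) sites[i] else integer(0)
    list(scores = sc, sites = keep)
  })
  kept_scores <- unlist(purrr::map2(site_list, seq_len(n_seq),
                                    function(s, i) s$scores[s$sites]))
  add_thr <- if (length(kept_scores)) mean(kept_scores) else Inf
  site_list <- purrr::map(site_list, function(s) {
    for (p in order(s$scores, decreasing = TRUE)) {
      if (s$scores[p] <= add_thr) break
      if (length(s$sites) && any(abs(p - s$sites) < L)) next
      s$sites <- c(s$sites, p)
    }
    s
  })

  sites_tbl <- purrr::imap_dfr(site_list, function(s, i) {
    if (length(s$sites) == 0L) return(NULL)
    tibble(seq = i, pos = sort(s$sites),
           sequence = substring(sequences[i], sort(s$sites),
                                  sort(s$sites) + L - 1L),
           score = s$scores[sort(s$sites)] / log(2))
  })
  if (is.null(sites_tbl) || nrow(sites_tbl) == 0L) {
    # degenerate: keep the sampled sites even if weak
    sites_tbl <- purrr::imap_dfr(seq_len(n_seq), function(i, ...) {
      tibble(seq = i, pos = sites[i],
             sequence = substr(sequences[i], sites[i], sites[i] + L - 1L),
             score = window_scores(i)[sites[i]] / log(2))
    })
  }
  logo <- information_content(sites_tbl$sequence)
  pfm <- information_content(sites_tbl$sequence,
                             pseudocount = pseudocount)$freq
  list(sites = sites_tbl, pfm = pfm, consensus = logo_consensus(logo),
       ic = logo$ic, total_score = sum(sites_tbl$score))
}

#' @export
print.sampler_result <- function(x, ...) {
  cat(sprintf(
    "<sampler_result> %d bp motif, %d sites, total IC %.2f bits (seed %s)\n",
    x$motif_len, nrow(x$sites), sum(x$ic), format(x$seed)
  ))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Robustness of repeated motif-sampler runs
#'
#' Motif-sampler predictions carry no usable significance estimate, so
#' reliability is judged by robustness: independent runs on identical
#' input should converge to the same motif. The score is the mean, over
#' all result pairs, of the best-offset identity between their consensus
#' strings (matching positions divided by the motif length); 1 means
#' perfectly reproducible, while unrelated random consensus strings give
#' about 0.25.
#'
#' @param results List of `sampler_result` objects from runs on the same
#'   input with different seeds.
#' @return Robustness fraction in `[0, 1]`.
#' @export
robustness_score <- function(results) {
  stopifnot(length(results) >= 2)
  cons <- purrr::map_chr(results, "consensus")
  L <- max(nchar(cons))
  pairs <- utils::combn(length(cons), 2)
  sims <- apply(pairs, 2, function(p) {
    consensus_similarity(cons[p[1]], cons[p[2]]) / L
  })
  mean(sims)
}

# Max matches between two strings over all relative offsets.
consensus_similarity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- 0L
  for (o in seq(-length(cb) + 1L, length(ca) - 1L)) {
    ia <- seq_along(ca)
    ib <- ia - o
    keep <- ib >= 1L & ib <= length(cb)
    if (!any(keep)) next
    best <- max(best, sum(ca[keep] == cb[ib[keep]]))
  }
  best
}
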