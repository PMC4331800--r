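#' Alignment scoring scheme
#'
#' Scoring for pairwise local alignment of intergenic regions. Defaults
#' mirror common short-sequence nucleotide alignment settings (match +1,
#' mismatch -3, affine gaps), with a 7 bp minimum reported hit length so
#' that short but perfectly conserved promoter repeats are not missed.
#'
#' @param match Positive match reward.
#' @param mismatch Mismatch penalty (<= 0).
#' @param gap_open,gap_extend Affine gap penalties (<= 0); a gap of length
#'   g costs `gap_open + g * gap_extend`.
#' @param min_hit_len Minimum reported alignment length in bp (>= 4).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1L, mismatch = -3L, gap_open = -5L,
                          gap_extend = -2L, min_hit_len = 7L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0,
            min_hit_len >= 4)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         min_hit_len = as.integer(min_hit_len)),
    class = "align_scoring"
  )
}

#' Local alignment of two DNA sequences
#'
#' Dynamic-programming local alignment (Smith-Waterman with affine gaps)
#' returning all locally optimal, position-disjoint hits of length at least
#' `scoring$min_hit_len`, found by iterative masking of already-aligned
#' positions. Only the given (direct) strands are compared: the promoter
#' motifs targeted here are not palindromic, so each orientation is
#' searched separately by orienting the regions first.
#'
#' In self-comparison mode (`self = TRUE`, `b` missing) the trivial main
#' diagonal is excluded and each repeat instance is reported once per role,
#' so k copies of a repeat surface as a chain of pairwise hits.
#'
#' @param a,b DNA strings. Ambiguous bases score as mismatches.
#' @param scoring An [align_scoring()] scheme.
#' @param self Compare `a` against itself, excluding the main diagonal.
#' @param max_hits Cap on reported hits per pair.
#' @return Tibble with columns `start_a`, `end_a`, `start_b`, `end_b`
#'   (1-based inclusive local offsets), `length` (alignment columns),
#'   `identities`, `score`. Ties among equal scores are broken by smallest
#'   `start_a`, then `start_b`.
#' @export
local_align <- function(a, b = NULL, scoring = align_scoring(),
                        self = FALSE, max_hits = 50L) {
  if (self) b <- a
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) {
    return(as_tibble(cpp_local_align(integer(), integer(), 1L, -1L, 0L, 0L,
                                     4L, FALSE, 0L)))
  }
  ca <- encode_dna(a); ca[is.na(ca)] <- 0L
  cb <- encode_dna(b); cb[is.na(cb)] <- 0L
  hits <- cpp_local_align(ca, cb, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend,
                          scoring$min_hit_len, self, as.integer(max_hits))
  hits <- as_tibble(hits)
  dplyr::arrange(hits, dplyr::desc(.data$score), .data$start_a, .data$start_b)
}

#' Pairwise repeat search over intergenic regions
#'
#' Discovers candidate phage promoters as low-copy, well-conserved repeats.
#' In `"anchor"` mode the upstream-most intergenic region of the "+"
#' (structural) gene cluster — on a circular genome usually the long
#' origin-spanning region — is aligned against itself and against every
#' other region: the genes downstream of that region could not be
#' transcribed unless it carried at least one promoter copy. `"all_pairs"`
#' mode (the backup) aligns every region pair plus each self-comparison.
#'
#' @param regions Regions tibble from [extract_upstream_regions()].
#' @param mode `"anchor"` or `"all_pairs"`.
#' @param scoring An [align_scoring()] scheme.
#' @param anchor_id `region_id` of the anchor; when `NULL` it is located
#'   from `genes` (first "+"-cluster gene's upstream region).
#' @param genes Gene tibble, needed only to auto-locate the anchor.
#' @param topology Genome topology for anchor location.
#' @return Tibble of hits with `region_a`, `region_b` (region ids) plus the
#'   columns of [local_align()]; attribute `search_bp` records the total
#'   searched sequence length.
#' @export
repeat_search <- function(regions, mode = c("anchor", "all_pairs"),
                          scoring = align_scoring(), anchor_id = NULL,
                          genes = NULL, topology = "circular") {
  mode <- match.arg(mode)
  stopifnot(nrow(regions) >= 1)
  ids <- regions$region_id
  if (mode == "anchor") {
    if (is.null(anchor_id)) {
      if (!is.null(regions[["anchor"]]) && any(regions$anchor)) {
        anchor_id <- ids[which(regions$anchor)[1]]
      } else if (!is.null(genes)) {
        anchor_id <- find_anchor_region(regions, genes, topology)$region_id
      } else {
        stop("anchor mode needs `anchor_id`, an `anchor` column, or `genes`")
      }
    }
    others <- setdiff(ids, anchor_id)
    pairs <- tibble(
      a = c(anchor_id, rep(anchor_id, length(others))),
      b = c(anchor_id, others)
    )
  } else {
    grid <- which(upper.tri(diag(length(ids)), diag = TRUE), arr.ind = TRUE)
    pairs <- tibble(a = ids[grid[, "row"]], b = ids[grid[, "col"]])
  }
  seq_of <- setNames(regions$sequence, as.character(ids))
  hits <- purrr::pmap_dfr(pairs, function(a, b) {
    h <- local_align(seq_of[[as.character(a)]], seq_of[[as.character(b)]],
                     scoring = scoring, self = a == b)
    if (nrow(h) == 0L) return(NULL)
    dplyr::mutate(h, region_a = a, region_b = b, .before = 1)
  })
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- tibble(
      region_a = integer(), region_b = integer(), start_a = integer(),
      end_a = integer(), start_b = integer(), end_b = integer(),
      length = integer(), identities = integer(), score = integer()
    )
  }
  attr(hits, "search_bp") <- sum(nchar(regions$sequence))
  attr(hits, "mode") <- mode
  hits
}

#' Expected count of repeated words (E-value)
#'
#' Significance of observing an L bp word k times in n bp of background
#' sequence: the expected number of L-words that occur at least k times,
#' `E(k, L, n) = W * P[Poisson(n / W) >= k]` with `W = 4^L` word types
#' under the uniform i.i.d. background. A composition-matched variant
#' replaces the per-position match probability 1/4 by `sum(f^2)` for base
#' frequencies f (a homogeneous approximation over word types).
#'
#' E is monotone decreasing in k and L and increasing in n; four exact
#' copies of a 12 bp word in ~4.4 kb of intergenic sequence come out around
#' 3e-9 — far below 1, i.e. essentially impossible by chance.
#'
#' @param k Observed copy number (>= 1).
#' @param L Word length in bp (>= 1).
#' @param n Search-space size in bp (>= L).
#' @param background Optional base-frequency vector (A,C,G,T) for the
#'   composition-matched variant; `NULL` = uniform.
#' @return Expected number of L-words occurring >= k times.
#' @export
repeat_evalue <- function(k, L, n, background = NULL) {
  stopifnot(k >= 1, L >= 1, n >= L)
  q <- if (is.null(background)) 0.25 else sum(background^2)
  words <- (1 / q)^L
  lambda <- n * q^L
  words * ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Consolidate alignment hits into candidate motif sets
#'
#' Hit intervals that overlap within a region, or that are linked by an
#' alignment, are merged transitively (graph components) into sets of
#' repeat instances. Each set gets a majority consensus, its instance list
#' with genomic coordinates, and an E-value from [repeat_evalue()] with n =
#' total searched bp.
#'
#' @param hits Hit tibble from [repeat_search()].
#' @param regions The regions tibble the search ran on.
#' @param genome A [genome_record()] (for genomic coordinates).
#' @param max_mismatch_frac Hits whose identity fraction falls below
#'   `1 - max_mismatch_frac` are dropped before consolidation.
#' @param background Optional base frequencies for the E-value.
#' @return Tibble with one row per motif set: `motif_id`, `consensus`,
#'   `k` (copy number), `n_bp` (search space), `evalue`, and `instances`
#'   (list column: `region_id`, `downstream_gene`, `start`, `end`,
#'   `genomic_coord`, `sequence`).
#' @export
consolidate_motifs <- function(hits, regions, genome,
                               max_mismatch_frac = 0.25,
                               background = NULL) {
  search_bp <- attr(hits, "search_bp") %||% sum(nchar(regions$sequence))
  hits <- hits[hits$identities >= (1 - max_mismatch_frac) * hits$length, ]
  if (nrow(hits) == 0L) {
    return(tibble(motif_id = integer(), consensus = character(),
                  k = integer(), n_bp = integer(), evalue = double(),
                  instances = list()))
  }
  iv <- dplyr::bind_rows(
    tibble(region = hits$region_a, start = hits$start_a, end = hits$end_a,
           hit = seq_len(nrow(hits))),
    tibble(region = hits$region_b, start = hits$start_b, end = hits$end_b,
           hit = seq_len(nrow(hits)))
  )
  ni <- nrow(iv)
  edges <- matrix(integer(), ncol = 2)
  # link the two sides of each hit
  edges <- rbind(edges, cbind(seq_len(nrow(hits)), nrow(hits) + seq_len(nrow(hits))))
  # link intervals within a region that share at least half the shorter
  # interval (a marginal 1-2 bp brush with an unrelated hit must not
  # bridge two distinct repeat families)
  for (r in unique(iv$region)) {
    ix <- which(iv$region == r)
    if (length(ix) < 2L) next
    for (p in seq_along(ix)) {
      for (q in seq_len(p - 1L)) {
        i <- ix[p]; j <- ix[q]
        if (intervals_share_half(iv$start[i], iv$end[i],
                                 iv$start[j], iv$end[j])) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, ni - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(ni)]

  sets <- purrr::map(split(seq_len(ni), comp), function(members) {
    merge_instance_intervals(iv[members, ], regions, genome)
  })
  # a k-copy repeat surfaces as several disjoint pairwise components (each
  # instance aligns in one hit); merge sets whose consensi agree
  sets <- merge_similar_sets(sets, min_identity = 0.8)

  out <- purrr::map_dfr(sets, function(inst) {
    inst <- full_length_instances(inst)
    consensus <- instance_consensus(inst$sequence)
    # transitive linking can chain unrelated short hits; only instances
    # that actually resemble the set consensus count as copies of it
    ok <- vapply(inst$sequence, function(s) {
      consensus_similarity(s, consensus) >=
        (1 - max_mismatch_frac) * nchar(consensus)
    }, logical(1))
    inst <- inst[ok, , drop = FALSE]
    if (nrow(inst) < 2L) return(NULL)
    consensus <- instance_consensus(inst$sequence)
    ev <- repeat_evalue(nrow(inst), nchar(consensus), search_bp, background)
    tibble(consensus = consensus, k = nrow(inst),
           n_bp = as.integer(search_bp), evalue = ev,
           instances = list(inst))
  })
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(motif_id = integer(), consensus = character(),
                  k = integer(), n_bp = integer(), evalue = double(),
                  instances = list()))
  }
  out |>
    dplyr::arrange(.data$evalue) |>
    dplyr::mutate(motif_id = dplyr::row_number(), .before = 1)
}

# Short partial echoes (chance hits covering a fraction of the repeat)
# legitimately join a component but would corrupt the majority consensus
# and inflate the copy number; keep instances within 70% of the median
# length (the median, unlike the maximum, is robust to one instance
# ragged-extended by chance flank matches).
full_length_instances <- function(inst) {
  inst[nchar(inst$sequence) >= 0.7 * stats::median(nchar(inst$sequence)), ,
       drop = FALSE]
}

merge_similar_sets <- function(sets, min_identity = 0.8) {
  set_consensus <- function(s) {
    instance_consensus(full_length_instances(s)$sequence)
  }
  cons <- purrr::map_chr(sets, set_consensus)
  repeat {
    merged_any <- FALSE
    n <- length(sets)
    if (n < 2L) break
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        shorter <- min(nchar(cons[i]), nchar(cons[j]))
        sim <- consensus_similarity(cons[i], cons[j]) / shorter
        if (sim >= min_identity) {
          both <- dplyr::bind_rows(sets[[i]], sets[[j]])
          both <- dplyr::distinct(both)
          sets[[i]] <- dplyr::arrange(both, .data$region_id, .data$start)
          cons[i] <- set_consensus(sets[[i]])
          sets <- sets[-j]
          cons <- cons[-j]
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  sets
}

intervals_share_half <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  ov >= 0.5 * min(e1 - s1 + 1L, e2 - s2 + 1L)
}

# Union substantially overlapping intervals within each region (same 50%
# rule as the component linking); each merged interval is one instance.
merge_instance_intervals <- function(iv, regions, genome) {
  purrr::map_dfr(split(iv, iv$region), function(sub) {
    sub <- sub[order(sub$start), ]
    merged <- list(c(sub$start[1], sub$end[1]))
    for (i in seq_len(nrow(sub))[-1]) {
      last <- merged[[length(merged)]]
      if (intervals_share_half(last[1], last[2], sub$start[i], sub$end[i])) {
        merged[[length(merged)]][2] <- max(last[2], sub$end[i])
        merged[[length(merged)]][1] <- min(last[1], sub$start[i])
      } else {
        merged[[length(merged) + 1L]] <- c(sub$start[i], sub$end[i])
      }
    }
    region <- regions[match(sub$region[1], regions$region_id), ]
    purrr::map_dfr(merged, function(m) {
      tibble(
        region_id = region$region_id,
        downstream_gene = region$downstream_gene,
        start = m[1], end = m[2],
        genomic_coord = region_to_genomic(region, m[1], genome$length),
        sequence = substr(region$sequence, m[1], m[2])
      )
    })
  })
}

# Align instances to the longest instance at each instance's best
# ungapped offset, allowing overhangs on either side (ragged chance
# extensions would otherwise force misalignment). Returns the character
# matrix over the padded column frame; attr "offsets" gives each
# instance's start column minus one.
instance_columns <- function(sequences) {
  ref_i <- which.max(nchar(sequences))
  rr <- strsplit(sequences[ref_i], "", fixed = TRUE)[[1]]
  L <- length(rr)
  rel <- integer(length(sequences))  # offset of instance start vs ref start
  for (i in seq_along(sequences)) {
    s <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
    best <- c(-1L, -1L, -.Machine$integer.max)
    for (o in seq(-(length(s) - 1L), L - 1L)) {
      idx <- seq_along(s) + o
      keep <- idx >= 1L & idx <= L
      if (!any(keep)) next
      cand <- c(sum(s[keep] == rr[idx[keep]]), sum(keep), -abs(o))
      # lexicographic: most matches, then largest overlap, then smallest
      # absolute offset (determinism)
      better <- cand[1] > best[1] ||
        (cand[1] == best[1] && cand[2] > best[2]) ||
        (cand[1] == best[1] && cand[2] == best[2] && cand[3] > best[3])
      if (better) {
        best <- cand
        rel[i] <- o
      }
    }
  }
  left_pad <- max(0L, -min(rel))
  width <- max(rel + nchar(sequences)) + left_pad
  cols <- matrix(NA_character_, nrow = length(sequences), ncol = width)
  offsets <- rel + left_pad
  for (i in seq_along(sequences)) {
    s <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
    cols[i, offsets[i] + seq_along(s)] <- s
  }
  attr(cols, "offsets") <- offsets
  cols
}

# Majority consensus over the columns covered by at least half the
# instances.
instance_consensus <- function(sequences) {
  cols <- instance_columns(sequences)
  covered <- colSums(!is.na(cols)) >= length(sequences) / 2
  apply(cols[, covered, drop = FALSE], 2, function(col) {
    tab <- table(factor(col[!is.na(col)], levels = DNA_BASES))
    DNA_BASES[which.max(tab)]
  }) |> paste(collapse = "")
}

#' Fixed-width seed windows from repeat instances
#'
#' Repeat instances recovered by alignment may carry ragged flank
#' extensions. This aligns them (ungapped, 5'-anchored to the longest),
#' picks the `width` consecutive columns with the highest instance
#' coverage — the repeat proper — and returns the complete windows, their
#' consensus, and the central core hexamer used for supervised scanning.
#'
#' @param sequences Instance sequences of one motif set.
#' @param width Motif window width (12 for this promoter family: 2 bp
#'   "TG" segment + 6 bp core + 4 bp "TATA" position).
#' @param core_at Positions of the core within the window (default 3:8).
#' @return List with `windows` (complete `width`-mers), `consensus`,
#'   `core`, plus `instance_index` and `start_in_instance` locating each
#'   window inside its source instance (1-based).
#' @export
motif_window_from_instances <- function(sequences, width = 12L,
                                        core_at = 3:8) {
  cols <- instance_columns(sequences)
  if (ncol(cols) < width) {
    stop("instances shorter than the requested window width")
  }
  # per-column majority agreement: chance flank extensions are covered
  # but not conserved, so the true motif frame maximises this
  agreement <- apply(cols, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) 0L else max(table(col))
  })
  win_score <- vapply(seq_len(ncol(cols) - width + 1L), function(s) {
    sum(agreement[s:(s + width - 1L)])
  }, numeric(1))
  s <- which.max(win_score)
  sub <- cols[, s:(s + width - 1L), drop = FALSE]
  complete <- which(!apply(is.na(sub), 1, any))
  windows <- apply(sub[complete, , drop = FALSE], 1, paste, collapse = "")
  if (length(windows) < 2L) {
    stop("fewer than two complete instances at the selected window")
  }
  consensus <- majority_consensus(windows)
  list(windows = unname(windows), consensus = consensus,
       core = substr(consensus, min(core_at), max(core_at)),
       instance_index = complete,
       start_in_instance = s - attr(cols, "offsets")[complete])
}

# Windows from alignment-discovered instances with genomic coordinates,
# shaped like core_scan() output so the supervised stage can carry them.
seed_instance_windows <- function(instances, regions, genome, width = 12L) {
  meta <- motif_window_from_instances(instances$sequence, width = width)
  purrr::map_dfr(seq_along(meta$instance_index), function(j) {
    inst <- instances[meta$instance_index[j], ]
    region <- regions[match(inst$region_id, regions$region_id), ]
    local <- inst$start + meta$start_in_instance[j] - 1L
    tibble(
      region_id = region$region_id,
      downstream_gene = region$downstream_gene,
      strand = region$strand,
      offset = as.integer(local),
      coord_window = region_to_genomic(region, local, genome$length),
      coord_core = region_to_genomic(region, local + 2L, genome$length),
      sequence = meta$windows[j]
    )
  })
}

#' Export motif instances as a Table-1-style TSV
#'
#' One row per instance: downstream gene, instance sequence, 1-based
#' genomic coordinate of the 5' anchor, plus the set's consensus and
#' E-value.
#'
#' @param motifs Tibble from [consolidate_motifs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  flat <- tidyr::unnest(motifs, "instances")
  out <- flat[, c("downstream_gene", "sequence", "genomic_coord",
                  "motif_id", "consensus", "evalue")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
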