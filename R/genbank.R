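# Minimal GenBank flat-file parser: LOCUS line, FEATURES table (gene/CDS
# locations including complement() and origin-spanning join()), ORIGIN
# sequence block. Enough to carry an annotated phage genome; not a general
# GenBank implementation.

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^LOCUS", lines)) != 1L) {
    stop("expected exactly one GenBank record (one LOCUS line) in ", path)
  }
  locus_line <- lines[grepl("^LOCUS", lines)][1]
  locus_fields <- strsplit(trimws(locus_line), "\\s+")[[1]]
  locus <- locus_fields[2]
  topology <- if (any(tolower(locus_fields) == "circular")) "circular" else "linear"

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) != 1L) stop("no ORIGIN block in ", path)
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  features <- if (length(feat_at) == 1L) {
    parse_genbank_features(lines[(feat_at + 1L):(origin_at - 1L)])
  } else {
    tibble(key = character(), start = integer(), end = integer(),
           strand = character(), label = character())
  }
  list(locus = locus, topology = topology, sequence = sequence,
       features = features)
}

parse_genbank_features <- function(lines) {
  # feature keys start at column 6; qualifiers/continuations at column 22
  is_key <- grepl("^ {5}\\S", lines)
  starts <- which(is_key)
  if (length(starts) == 0L) {
    return(tibble(key = character(), start = integer(), end = integer(),
                  strand = character(), label = character()))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2_dfr(starts, ends, function(s, e) {
    block <- lines[s:e]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    if (!key %in% c("gene", "CDS")) return(NULL)
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s+/", block)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
    loc <- paste(trimws(sub("^\\s*\\S+\\s*", "", block[1])),
                 paste(trimws(block[seq_len(loc_end)[-1]]), collapse = ""),
                 sep = "")
    loc <- gsub("\\s", "", loc)
    parsed <- parse_gb_location(loc)
    label <- NA_character_
    for (q in c("gene", "locus_tag", "product")) {
      m <- grep(sprintf('^\\s+/%s="?', q), block, value = TRUE)
      if (length(m)) {
        label <- gsub('"', "", sub(sprintf('^\\s+/%s=', q), "", m[1]))
        break
      }
    }
    tibble(key = key, start = parsed$start, end = parsed$end,
           strand = parsed$strand, label = label)
  })
}

parse_gb_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    ranges <- purrr::map(parts, parse_gb_range)
    # origin-spanning join: start of first segment, end of last (end < start)
    list(start = ranges[[1]]$start, end = ranges[[length(ranges)]]$end,
         strand = strand)
  } else {
    r <- parse_gb_range(loc)
    list(start = r$start, end = r$end, strand = strand)
  }
}

parse_gb_range <- function(x) {
  x <- gsub("[<>]", "", x)
  nums <- as.integer(strsplit(x, "\\.\\.")[[1]])
  if (length(nums) == 1L) nums <- c(nums, nums)
  list(start = nums[1], end = nums[2])
}
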