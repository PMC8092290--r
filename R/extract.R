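#' Extraction configuration
#'
#' Quality-trimming and spacer-extraction parameters. Trimming applies the
#' trailing-quality cut first, then a 5'-to-3' sliding-window scan, then a
#' minimum-length filter; extraction takes the 27-32 bp window between an
#' intact first repeat and the first `repeat_anchor_len` bases of the next
#' repeat.
#'
#' @param window_size Sliding window width (bases).
#' @param window_mean_quality Minimum mean Phred quality per window.
#' @param trailing_quality Minimum Phred quality for 3'-end bases.
#' @param min_read_length Reads shorter than this after trimming are
#'   dropped.
#' @param min_spacer_len,max_spacer_len Accepted spacer lengths.
#' @param repeat_anchor_len Bases of the next repeat required downstream
#'   of the spacer.
#' @param max_repeat_mismatches Mismatches tolerated in the full first
#'   repeat (0 = intact repeat required).
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(window_size = 3L, window_mean_quality = 21,
                              trailing_quality = 23, min_read_length = 100L,
                              min_spacer_len = 27L, max_spacer_len = 32L,
                              repeat_anchor_len = 4L,
                              max_repeat_mismatches = 0L) {
  if (min_spacer_len <= 0 || min_spacer_len > max_spacer_len)
    abort_param("need 0 < min_spacer_len <= max_spacer_len")
  if (repeat_anchor_len < 1) abort_param("repeat_anchor_len must be >= 1")
  structure(list(window_size = as.integer(window_size),
                 window_mean_quality = window_mean_quality,
                 trailing_quality = trailing_quality,
                 min_read_length = as.integer(min_read_length),
                 min_spacer_len = as.integer(min_spacer_len),
                 max_spacer_len = as.integer(max_spacer_len),
                 repeat_anchor_len = as.integer(repeat_anchor_len),
                 max_repeat_mismatches = as.integer(max_repeat_mismatches)),
            class = "extraction_config")
}

#' Quality-trim a single read
#'
#' Trailing bases below `trailing_quality` are removed from the 3' end;
#' the remaining read is scanned 5'-to-3' in windows of `window_size` and
#' cut before the first window whose mean quality falls below
#' `window_mean_quality`; reads ending shorter than `min_read_length` are
#' dropped.
#'
#' @param sequence Read sequence.
#' @param quality Integer Phred scores (same length) or a Phred+33 string.
#' @param cfg [extraction_config()].
#' @return List with `sequence`, `quality` (integer vector) and `dropped`;
#'   when dropped, sequence is `NA`.
#' @export
trim_read <- function(sequence, quality, cfg = extraction_config()) {
  if (is.character(quality)) quality <- phred_scores(quality)[[1]]
  if (nchar(sequence) != length(quality))
    abort_format("sequence/quality length mismatch")
  keep <- length(quality)
  while (keep > 0 && quality[keep] < cfg$trailing_quality) keep <- keep - 1L
  if (keep >= cfg$window_size) {
    q <- quality[seq_len(keep)]
    cs <- cumsum(c(0, q))
    w <- cfg$window_size
    means <- (cs[(w + 1):(keep + 1)] - cs[1:(keep - w + 1)]) / w
    bad <- which(means < cfg$window_mean_quality)
    if (length(bad)) keep <- bad[1] - 1L
  }
  if (keep < cfg$min_read_length)
    return(list(sequence = NA_character_, quality = NULL, dropped = TRUE))
  list(sequence = substr(sequence, 1, keep), quality = quality[seq_len(keep)],
       dropped = FALSE)
}

# positions (0-based) where `pattern` occurs in `x` with <= max_mm mismatches
find_approx <- function(x, pattern, max_mm) {
  if (max_mm == 0)
    return(Biostrings::start(Biostrings::matchPattern(pattern, x)) - 1L)
  Biostrings::start(Biostrings::matchPattern(pattern, x,
                                             max.mismatch = max_mm)) - 1L
}

#' Extract the new spacer from a trimmed read
#'
#' Finds a full-length occurrence of the locus repeat (at most
#' `max_repeat_mismatches` mismatches), then searches for the
#' `repeat_anchor_len`-base prefix of the next repeat at every offset from
#' `min_spacer_len` to `max_spacer_len` downstream; the intervening bases
#' are the spacer. When the locus's reads are the reverse complement of
#' the crRNA the read is reverse-complemented first, so the returned
#' spacer is always crRNA-oriented. At most one spacer (the first valid
#' one) is returned per read.
#'
#' @param sequence Trimmed read sequence.
#' @param locus [locus_model()].
#' @param cfg [extraction_config()].
#' @return Spacer string, or `NA_character_` when no valid extraction
#'   exists.
#' @export
extract_spacer <- function(sequence, locus, cfg = extraction_config()) {
  if (is.na(sequence)) return(NA_character_)
  work <- if (locus$read_orientation == "reverse_complement_of_crRNA")
    revcomp(sequence) else sequence
  if (grepl("[^ACGTN]", work)) return(NA_character_)
  rep_seq <- locus$repeat_seq
  anchor <- substr(rep_seq, 1, cfg$repeat_anchor_len)
  subj <- Biostrings::DNAString(work)
  starts <- find_approx(subj, Biostrings::DNAString(rep_seq),
                        cfg$max_repeat_mismatches)
  for (s in starts) {
    sp_start <- s + nchar(rep_seq)  # 0-based start of candidate spacer
    # longest-first (greedy) anchor search: a true spacer whose own suffix
    # happens to end with a prefix of the anchor would otherwise be
    # truncated, while false extensions would require the anchor to recur
    # inside the repeat itself
    for (L in cfg$max_spacer_len:cfg$min_spacer_len) {
      a0 <- sp_start + L
      cand <- substr(work, a0 + 1L, a0 + cfg$repeat_anchor_len)
      if (nchar(cand) == cfg$repeat_anchor_len && cand == anchor) {
        spacer <- substr(work, sp_start + 1L, sp_start + L)
        if (!grepl("N", spacer, fixed = TRUE)) return(spacer)
      }
    }
  }
  NA_character_
}

#' Trim all reads and extract spacers
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` and
#'   optionally `replicate`.
#' @param locus [locus_model()].
#' @param cfg [extraction_config()].
#' @return Tibble of spacer observations (`sequence`, `locus_id`,
#'   `replicate`, `read_id`), with an `extraction_summary` attribute
#'   (tibble: `reads_in`, `trimmed_out`, `no_spacer`, `extracted`);
#'   retrieve it with [extraction_summary()].
#' @export
extract_spacers <- function(reads, locus, cfg = extraction_config()) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  replicate <- if ("replicate" %in% names(reads)) reads$replicate
               else rep(NA_character_, nrow(reads))
  quals <- phred_scores(reads$quality)
  trimmed <- purrr::map2(reads$sequence, quals,
                         function(s, q) trim_read(s, q, cfg))
  dropped <- vapply(trimmed, `[[`, TRUE, "dropped")
  spacers <- rep(NA_character_, nrow(reads))
  idx <- which(!dropped)
  spacers[idx] <- vapply(trimmed[idx], function(tr)
    extract_spacer(tr$sequence, locus, cfg), "")
  ok <- !is.na(spacers)
  out <- tibble(sequence = spacers[ok], locus_id = locus$locus_id,
                replicate = replicate[ok], read_id = reads$read_id[ok])
  attr(out, "extraction_summary") <- tibble(
    locus_id = locus$locus_id, reads_in = nrow(reads),
    trimmed_out = sum(dropped), no_spacer = sum(!dropped & !ok),
    extracted = sum(ok))
  out
}

#' @rdname extract_spacers
#' @param x Result of [extract_spacers()].
#' @export
extraction_summary <- function(x) attr(x, "extraction_summary")
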