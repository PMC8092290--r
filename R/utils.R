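#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `A/C/G/T/N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTAA"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(cpp_revcomp(x))
}

abort_format <- function(msg, ...) {
  abort(msg, class = "spaceracq_format_error", ...)
}

abort_param <- function(msg, ...) {
  abort(msg, class = "spaceracq_parameter_error", ...)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort_param(sprintf("`%s` must be a single probability in [0, 1]", name))
  x
}

check_dna <- function(x, name = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad))
    abort_param(sprintf("`%s` contains non-DNA characters (first offender: %s)",
                        name, x[which(bad)[1]]))
  invisible(x)
}

#' Extract a subsequence honouring genome topology
#'
#' Returns the forward-strand bases of `[start, end)` (0-based half-open).
#' Circular genomes wrap around the origin; on linear genomes an
#' out-of-bounds request is truncated and flagged.
#'
#' @param genome A [genome_record()].
#' @param start,end 0-based half-open interval (may exceed bounds).
#' @return List with `sequence` and logical `truncated`.
#' @keywords internal
genome_subseq <- function(genome, start, end) {
  len <- nchar(genome$sequence)
  if (end <= start) return(list(sequence = "", truncated = FALSE))
  if (start >= 0 && end <= len)
    return(list(sequence = substr(genome$sequence, start + 1L, end),
                truncated = FALSE))
  if (identical(genome$topology, "circular")) {
    idx <- ((seq.int(start, end - 1L)) %% len) + 1L
    pieces <- substring(genome$sequence, idx, idx)
    return(list(sequence = paste(pieces, collapse = ""), truncated = FALSE))
  }
  s <- max(start, 0L)
  e <- min(end, len)
  trunc <- (s != start) || (e != end)
  seq <- if (e > s) substr(genome$sequence, s + 1L, e) else ""
  list(sequence = seq, truncated = trunc)
}

# stable short hash of a configuration (provenance stamping)
config_hash <- function(x) rlang::hash(x)

pkg_version_string <- function() {
  as.character(utils::packageVersion("spaceracq"))
}

# derive a stream-specific 32-bit seed from a master seed (double
# arithmetic: products stay far below 2^53, so the modulus is exact)
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 7919) %%
               2147483647)
}
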