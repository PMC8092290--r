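#' Extract guide-oriented protospacer flanks
#'
#' For every hit, returns the 15-base regions upstream and downstream of
#' the protospacer read 5'-to-3' on the hit's crRNA-matching strand (the
#' nontarget strand): for a `+` hit these are the forward-strand bases
#' before and after the interval; for a `-` hit they are the reverse
#' complements of the opposite genomic sides. On a linear genome a flank
#' running off an end is truncated and flagged (and excluded from
#' matrices); a circular genome wraps.
#'
#' @param hits Hit tibble from [hierarchical_map()] (any tibble with
#'   `genome_id`, `start`, `end`, `strand`).
#' @param genome [genome_record()] the hits refer to.
#' @param flank_len Flank length (default 15).
#' @return `hits` with added columns `upstream`, `downstream`,
#'   `upstream_truncated`, `downstream_truncated`.
#' @export
extract_flanks <- function(hits, genome, flank_len = 15L) {
  n <- nrow(hits)
  up <- dn <- character(n)
  up_tr <- dn_tr <- logical(n)
  for (i in seq_len(n)) {
    s <- hits$start[i]; e <- hits$end[i]
    left <- genome_subseq(genome, s - flank_len, s)
    right <- genome_subseq(genome, e, e + flank_len)
    if (hits$strand[i] == "+") {
      up[i] <- left$sequence; up_tr[i] <- left$truncated ||
        nchar(left$sequence) < flank_len
      dn[i] <- right$sequence; dn_tr[i] <- right$truncated ||
        nchar(right$sequence) < flank_len
    } else {
      up[i] <- revcomp(right$sequence); up_tr[i] <- right$truncated ||
        nchar(right$sequence) < flank_len
      dn[i] <- revcomp(left$sequence); dn_tr[i] <- left$truncated ||
        nchar(left$sequence) < flank_len
    }
  }
  mutate(hits, upstream = up, downstream = dn,
         upstream_truncated = up_tr, downstream_truncated = dn_tr)
}

#' Detect the canonical spacer acquisition motif next to each hit
#'
#' Array-to-leader loci (subtype II-C style) carry the SAM as `NNNNNTAAA`
#' downstream of the guide: the test is `TAAA` at downstream flank
#' positions 6-9 (1-based). Leader-to-array loci (subtype VI-B style) see
#' the reverse-complement placement `TTTANNNNN` upstream: `TTTA` at
#' upstream positions 7-10. The relevant side follows from the locus's
#' transcription direction; both tests are exact reverse complements of
#' each other, so the same genomic protospacer assigned the opposite
#' crRNA strand flips between them.
#'
#' @param flanks Tibble from [extract_flanks()].
#' @param locus [locus_model()] supplying the convention.
#' @return `flanks` with a logical `sam` column (`NA` when the relevant
#'   flank is truncated).
#' @export
detect_sam <- function(flanks, locus) {
  conv <- sam_convention(locus)
  if (conv == "downstream_taaa") {
    sam <- ifelse(flanks$downstream_truncated, NA,
                  substr(flanks$downstream, 6, 9) == "TAAA")
  } else {
    sam <- ifelse(flanks$upstream_truncated, NA,
                  substr(flanks$upstream, 7, 10) == "TTTA")
  }
  mutate(flanks, sam = sam)
}

#' Position frequency matrix of flank sequences
#'
#' @param flanks Tibble from [extract_flanks()].
#' @param side `"upstream"` or `"downstream"`.
#' @param flank_len Expected flank length.
#' @return A `spacer_pfm`: list with `counts` (4 x flank_len matrix over
#'   A/C/G/T), `n_sequences`, `information` (bits per column,
#'   `2 - Shannon entropy`) and `side`. Truncated flanks are excluded.
#' @export
build_pfm <- function(flanks, side = c("downstream", "upstream"),
                      flank_len = 15L) {
  side <- match.arg(side)
  trunc_col <- paste0(side, "_truncated")
  seqs <- flanks[[side]][!flanks[[trunc_col]]]
  seqs <- seqs[nchar(seqs) == flank_len & !grepl("N", seqs, fixed = TRUE)]
  if (!length(seqs)) abort_param("no usable (untruncated) flank sequences")
  mat <- matrix(0L, nrow = 4, ncol = flank_len,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (cs in chars)
    for (j in seq_len(flank_len))
      mat[cs[j], j] <- mat[cs[j], j] + 1L
  freq <- sweep(mat, 2, colSums(mat), "/")
  ent <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(counts = mat, n_sequences = length(seqs),
                 information = 2 - ent, side = side),
            class = "spacer_pfm")
}

#' @export
print.spacer_pfm <- function(x, ...) {
  cat(sprintf("<spacer_pfm> %s flank, %d sequences\n", x$side,
              x$n_sequences))
  cons <- rownames(x$counts)[apply(x$counts, 2, which.max)]
  cat("consensus:", paste(cons, collapse = ""), "\n")
  cat("IC (bits):", paste(sprintf("%.2f", x$information), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
tidy.spacer_pfm <- function(x, ...) {
  freq <- sweep(x$counts, 2, colSums(x$counts), "/")
  tibble(position = rep(seq_len(ncol(x$counts)), each = 4),
         base = rep(rownames(x$counts), ncol(x$counts)),
         count = as.vector(x$counts), frequency = as.vector(freq),
         information = rep(x$information, each = 4))
}

#' Count motif occurrences on a genome
#'
#' Occurrences of an IUPAC motif on both strands (a `-` strand occurrence
#' is the reverse-complement motif on the forward strand); overlapping
#' occurrences all count. With scope `cds_only`, occurrences are
#' restricted to those fully inside an ORF feature and strand labels
#' follow each feature's orientation (`coding` = the feature strand);
#' with `whole_genome` the forward strand is labelled `coding` by
#' reporting convention.
#'
#' @param genome [genome_record()].
#' @param motif IUPAC motif string (e.g. `"TAAA"`).
#' @param scope `"whole_genome"` or `"cds_only"`.
#' @param features Feature tibble (defaults to the genome's own).
#' @return One-row tibble: `motif`, `scope`, `count_total`,
#'   `count_coding_strand`, `count_template_strand`, `prop_coding`,
#'   `prop_template`.
#' @export
count_motif <- function(genome, motif,
                        scope = c("whole_genome", "cds_only"),
                        features = NULL) {
  scope <- match.arg(scope)
  motif <- toupper(motif)
  if (grepl("[^ACGTRYSWKMBDHVN]", motif))
    abort_param("motif contains non-IUPAC symbols")
  features <- features %||% genome$features
  subj <- Biostrings::DNAString(genome$sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(motif), subj, fixed = "subject")) - 1L
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)), subj,
    fixed = "subject")) - 1L
  k <- nchar(motif)
  if (scope == "whole_genome") {
    coding <- length(fwd)
    template <- length(rev)
  } else {
    # occurrence strand: '+' for fwd matches, '-' for rev matches; coding
    # when it equals the containing feature's strand
    coding <- 0L
    template <- 0L
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      fwd_in <- sum(fwd >= f$start & (fwd + k) <= f$end)
      rev_in <- sum(rev >= f$start & (rev + k) <= f$end)
      if (f$strand == "+") {
        coding <- coding + fwd_in
        template <- template + rev_in
      } else {
        coding <- coding + rev_in
        template <- template + fwd_in
      }
    }
  }
  total <- coding + template
  tibble(motif = motif, scope = scope, count_total = total,
         count_coding_strand = coding, count_template_strand = template,
         prop_coding = if (total > 0) coding / total else NA_real_,
         prop_template = if (total > 0) template / total else NA_real_)
}

#' Histogram of core-motif offsets in downstream flanks
#'
#' Position-resolved occurrence counts of the SAM core (default `TAAA`)
#' across untruncated downstream flanks: variants with shortened or
#' extended N regions show up as off-canonical offsets rather than being
#' folded into the canonical SAM call.
#'
#' @param flanks Tibble from [extract_flanks()].
#' @param core Core motif.
#' @param side Flank side to scan.
#' @return Tibble `offset` (1-based flank position of the core start),
#'   `count`.
#' @export
sam_offset_histogram <- function(flanks, core = "TAAA",
                                 side = c("downstream", "upstream")) {
  side <- match.arg(side)
  trunc_col <- paste0(side, "_truncated")
  seqs <- flanks[[side]][!flanks[[trunc_col]]]
  k <- nchar(core)
  offs <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    which(vapply(seq_len(n - k + 1),
                 function(i) substr(s, i, i + k - 1) == core, TRUE))
  }))
  if (!length(offs)) return(tibble(offset = integer(), count = integer()))
  tb <- table(offs)
  tibble(offset = as.integer(names(tb)), count = as.integer(tb))
}
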