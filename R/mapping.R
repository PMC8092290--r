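#' Alignment configuration
#'
#' Ungapped local alignment scored as `2*matches - 6*mismatches` with a
#' length-dependent acceptance threshold
#' `score_min_intercept + score_min_slope * ln(L)` (the natural-log score
#' floor used for sensitive local short-read mapping; 10 + 8*ln(30) is
#' about 37.2 for a 30-bp spacer).
#'
#' @param match_bonus Per-match score (> 0).
#' @param mismatch_penalty Per-mismatch penalty (subtracted).
#' @param score_min_intercept,score_min_slope Threshold coefficients.
#' @return An object of class `align_config`.
#' @export
align_config <- function(match_bonus = 2, mismatch_penalty = 6,
                         score_min_intercept = 10, score_min_slope = 8) {
  if (match_bonus <= 0) abort_param("match_bonus must be > 0")
  structure(list(match_bonus = match_bonus,
                 mismatch_penalty = mismatch_penalty,
                 score_min_intercept = score_min_intercept,
                 score_min_slope = score_min_slope),
            class = "align_config")
}

#' Minimum acceptable alignment score for a spacer length
#'
#' @param length Spacer length.
#' @param cfg [align_config()].
#' @return Numeric threshold.
#' @export
score_threshold <- function(length, cfg = align_config()) {
  cfg$score_min_intercept + cfg$score_min_slope * log(length)
}

#' Best ungapped local hit of a spacer on a genome
#'
#' Scans both strands for the contiguous sub-span of the (soft-clipped)
#' spacer maximising `match_bonus*matches - mismatch_penalty*mismatches`.
#' Ties are broken by fewer mismatches, then smaller genome start, then
#' `+` strand before `-`. The hit strand is the genome strand whose
#' forward sequence equals the crRNA over the aligned span.
#'
#' @param spacer Spacer sequence (crRNA orientation).
#' @param genome [genome_record()].
#' @param cfg [align_config()].
#' @return One-row tibble (`start`, `end` 0-based half-open, `strand`,
#'   `score`, `mismatches`), or `NULL` when no sub-span reaches the score
#'   threshold.
#' @export
best_local_hit <- function(spacer, genome, cfg = align_config()) {
  spacer <- toupper(spacer)
  hit <- cpp_best_local_hit(spacer, genome$sequence, cfg$match_bonus,
                            cfg$mismatch_penalty)
  if (!hit$found || hit$score < score_threshold(nchar(spacer), cfg))
    return(NULL)
  tibble(genome_id = genome$id, start = hit$start, end = hit$end,
         strand = hit$strand, score = hit$score,
         mismatches = hit$mismatches)
}

#' Hierarchically map a spacer pool to phage then host
#'
#' Every unique spacer is first aligned to the phage genome; only spacers
#' failing the phage score threshold attempt the host genome; the rest
#' are discarded. The partition `n_phage + n_self + n_discarded =
#' n_input` always holds.
#'
#' @param pool A `spacer_pool` (unique view is mapped; absolute counts
#'   are carried as weights).
#' @param phage,host [genome_record()]s.
#' @param cfg [align_config()].
#' @return List with `hits` (tibble: `spacer`, `genome_id`, `start`,
#'   `end`, `strand`, `score`, `mismatches`, `target_class`,
#'   `unique_count`, `absolute_count`, `replicate_counts`) and `summary`
#'   (tibble: `n_input`, `n_phage`, `n_self`, `n_discarded`,
#'   `discard_fraction`).
#' @export
hierarchical_map <- function(pool, phage, host, cfg = align_config()) {
  clusters <- pool$clusters
  rows <- vector("list", nrow(clusters))
  n_phage <- n_self <- n_disc <- 0L
  for (i in seq_len(nrow(clusters))) {
    sp <- clusters$representative[i]
    hit <- best_local_hit(sp, phage, cfg)
    cls <- "phage"
    if (is.null(hit)) {
      hit <- best_local_hit(sp, host, cfg)
      cls <- "self"
    }
    if (is.null(hit)) {
      n_disc <- n_disc + 1L
      next
    }
    if (cls == "phage") n_phage <- n_phage + 1L else n_self <- n_self + 1L
    rows[[i]] <- mutate(hit, spacer = sp, target_class = cls,
                        unique_count = 1L,
                        absolute_count = clusters$total_count[i],
                        replicate_counts = clusters$replicate_counts[i],
                        locus_id = pool$locus_id, .before = 1)
  }
  hits <- bind_rows(rows)
  if (nrow(hits) == 0)
    hits <- tibble(spacer = character(), target_class = character(),
                   unique_count = integer(), absolute_count = integer(),
                   replicate_counts = list(), locus_id = character(),
                   genome_id = character(), start = integer(),
                   end = integer(), strand = character(), score = double(),
                   mismatches = integer())
  n_in <- nrow(clusters)
  list(hits = hits,
       summary = tibble(locus_id = pool$locus_id, n_input = n_in,
                        n_phage = n_phage, n_self = n_self,
                        n_discarded = n_disc,
                        discard_fraction = if (n_in > 0) n_disc / n_in else NA_real_))
}
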