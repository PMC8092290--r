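#' Clustering configuration
#'
#' @param within_pool_identity Greedy clustering threshold for collapsing
#'   a locus's observations into unique spacers (default 0.8).
#' @param cross_pool_identity Threshold for counting a match between two
#'   unique pools (default 0.9).
#' @param word_size Exact word length a member must share with its
#'   representative (default 5).
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(within_pool_identity = 0.8,
                           cross_pool_identity = 0.9, word_size = 5L) {
  for (x in c(within_pool_identity, cross_pool_identity))
    if (x <= 0 || x > 1) abort_param("identity thresholds must lie in (0, 1]")
  if (word_size < 3) abort_param("word_size must be >= 3")
  structure(list(within_pool_identity = within_pool_identity,
                 cross_pool_identity = cross_pool_identity,
                 word_size = as.integer(word_size)),
            class = "cluster_config")
}

#' Pairwise sequence identity (best ungapped offset)
#'
#' Identity is the number of matching bases in the best ungapped alignment
#' over all relative offsets, divided by the length of the shorter
#' sequence; it is symmetric in its arguments. `N` matches nothing.
#'
#' @param a,b DNA strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' sequence_identity("ACGTACGT", "ACGTACGT")
#' sequence_identity("ACGT", "TTACGTTT") # exact substring: 1
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort_param("sequences must be non-empty")
  cpp_identity(toupper(a), toupper(b))
}

#' Collapse spacer observations into a unique pool
#'
#' Greedy CD-HIT-style clustering: observations are first aggregated into
#' distinct sequences with read counts, ordered deterministically by
#' (count desc, length desc, lexicographic), and each sequence joins the
#' first existing representative with identity at or above
#' `within_pool_identity` that shares at least one exact word of
#' `word_size`, or founds a new cluster. Spacers are assumed to be already
#' crRNA-orientation-canonicalised, so the two strands are deliberately
#' not compared.
#'
#' @param observations Tibble from [extract_spacers()] (columns
#'   `sequence`, optionally `replicate`), or a character vector of
#'   spacer sequences.
#' @param cfg [cluster_config()].
#' @param locus_id Pool label (taken from the observations when absent).
#' @return A `spacer_pool`: list with `clusters` (tibble: `cluster_id`,
#'   `representative`, `n_members`, `total_count`, `replicate_counts`
#'   list-column), `locus_id` and the config echo. The unique view is one
#'   row per cluster; the absolute view weights each cluster by
#'   `total_count`.
#' @export
cluster_spacers <- function(observations, cfg = cluster_config(),
                            locus_id = NULL) {
  if (is.character(observations))
    observations <- tibble(sequence = observations,
                           replicate = NA_character_)
  if (!"replicate" %in% names(observations))
    observations$replicate <- NA_character_
  locus_id <- locus_id %||%
    (if ("locus_id" %in% names(observations) && nrow(observations))
       observations$locus_id[1] else "pool")
  agg <- observations |>
    group_by(.data$sequence) |>
    summarise(total_count = n(), .groups = "drop")
  rep_counts <- observations |>
    group_by(.data$sequence, .data$replicate) |>
    summarise(count = n(), .groups = "drop")
  agg <- agg |>
    arrange(desc(.data$total_count), desc(nchar(.data$sequence)),
            .data$sequence)
  if (nrow(agg) == 0) {
    clusters <- tibble(cluster_id = integer(), representative = character(),
                       n_members = integer(), total_count = integer(),
                       replicate_counts = list())
  } else {
    assignment <- cpp_greedy_cluster(agg$sequence, cfg$within_pool_identity,
                                     cfg$word_size)
    agg$rep_seq <- agg$sequence[assignment]
    members <- agg |>
      group_by(.data$rep_seq) |>
      summarise(n_members = n(), total_count = sum(.data$total_count),
                member_seqs = list(.data$sequence), .groups = "drop")
    # preserve founding order (first occurrence among sorted input)
    members <- members[order(match(members$rep_seq, agg$rep_seq)), ]
    rc <- lapply(members$member_seqs, function(seqs) {
      rep_counts |>
        filter(.data$sequence %in% seqs) |>
        group_by(.data$replicate) |>
        summarise(count = sum(.data$count), .groups = "drop")
    })
    clusters <- tibble(cluster_id = seq_len(nrow(members)),
                       representative = members$rep_seq,
                       n_members = members$n_members,
                       total_count = as.integer(members$total_count),
                       replicate_counts = rc)
  }
  structure(list(clusters = clusters, locus_id = locus_id, config = cfg),
            class = "spacer_pool")
}

#' @export
print.spacer_pool <- function(x, ...) {
  cat(sprintf("<spacer_pool> %s: %d unique spacers, %d observations\n",
              x$locus_id, nrow(x$clusters), sum(x$clusters$total_count)))
  invisible(x)
}

#' Number of spacers in a pool under a counting view
#'
#' @param pool A `spacer_pool`.
#' @param view `"unique"` (each cluster once) or `"absolute"` (clusters
#'   weighted by read-supported size).
#' @return Integer count.
#' @export
pool_size <- function(pool, view = c("unique", "absolute")) {
  view <- match.arg(view)
  if (view == "unique") nrow(pool$clusters) else
    sum(pool$clusters$total_count)
}

#' Representative sequences of a pool (unique view)
#'
#' @param pool A `spacer_pool`.
#' @return Character vector of cluster representatives.
#' @export
pool_sequences <- function(pool) pool$clusters$representative

#' Fraction of a query pool matched in a reference pool
#'
#' A query representative counts as matched when at least one reference
#' representative reaches `cross_pool_identity` (best ungapped offset,
#' shorter-sequence denominator). Both pools are compared in their unique
#' views.
#'
#' @param query,reference `spacer_pool`s, or character vectors of unique
#'   sequences.
#' @param cfg [cluster_config()].
#' @return List with `fraction` and `matches` (tibble: `query`,
#'   `matched`, `reference` of the first matching representative or
#'   `NA`).
#' @export
cross_pool_fraction <- function(query, reference, cfg = cluster_config()) {
  q <- if (inherits(query, "spacer_pool")) pool_sequences(query) else query
  r <- if (inherits(reference, "spacer_pool")) pool_sequences(reference)
       else reference
  if (length(q) == 0) abort_param("query pool is empty: fraction undefined")
  hit <- cpp_cross_match(q, r, cfg$cross_pool_identity)
  matches <- tibble(query = q, matched = !is.na(hit),
                    reference = ifelse(is.na(hit), NA_character_, r[hit]))
  list(fraction = mean(matches$matched), matches = matches)
}

#' @export
tidy.spacer_pool <- function(x, ...) {
  select(x$clusters, -"replicate_counts")
}

#' @export
glance.spacer_pool <- function(x, ...) {
  tibble(locus_id = x$locus_id, n_clusters = nrow(x$clusters),
         n_observations = sum(x$clusters$total_count),
         identity_threshold = x$config$within_pool_identity,
         word_size = x$config$word_size)
}
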