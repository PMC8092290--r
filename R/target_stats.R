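#' Classify hits by mRNA-targeting ability
#'
#' A spacer's crRNA can anneal to a transcript only if (i) the crRNA is
#' complementary to the coding strand — i.e. the hit's crRNA-matching
#' strand is opposite the ORF strand — and (ii) the protospacer lies fully
#' within the ORF. Hits fully inside an ORF on the same strand are
#' `non_mRNA`; hits not fully contained in any ORF (including
#' boundary-straddling ones) are `intergenic_excluded`.
#'
#' @param hits Hit tibble with `start`, `end`, `strand`.
#' @param features Feature tibble (`start`, `end`, `strand`, 0-based
#'   half-open).
#' @return `hits` with an added `mrna_class` column.
#' @export
classify_mrna <- function(hits, features) {
  cls <- rep("intergenic_excluded", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    contained <- features$start <= hits$start[i] &
      features$end >= hits$end[i]
    if (!any(contained)) next
    orf_strand <- features$strand[which(contained)[1]]
    cls[i] <- if (hits$strand[i] != orf_strand) "mRNA_targeting"
              else "non_mRNA"
  }
  mutate(hits, mrna_class = cls)
}

#' One-tailed exact binomial bias test at p = 0.5
#'
#' The null assumes an equal chance of a spacer targeting either strand.
#' The one-tailed p-value is `P(X >= k)` (direction `"above"`) or
#' `P(X <= k)` (direction `"below"`) for `X ~ Binomial(n, 0.5)`, computed
#' by exact summation of the probability mass in log space. The expected
#' 95% interval of `k/n` under the null comes from the exact binomial
#' quantiles.
#'
#' @param k Observed count (e.g. mRNA-targeting spacers).
#' @param n Pool size (ORF-contained spacers; must be >= 1).
#' @param direction `"above"`, `"below"`, or `"auto"` (side of the
#'   observed proportion relative to 0.5; the chosen side is recorded in
#'   the result, never silent).
#' @return An object of class `binom_bias` with fields `k`, `n`,
#'   `proportion`, `direction`, `p_value`, `null_lower`, `null_upper`.
#' @export
#' @examples
#' binomial_bias_test(19, 19, "above") # p = 0.5^19 ~ 1.9e-6
binomial_bias_test <- function(k, n, direction = c("auto", "above", "below")) {
  direction <- match.arg(direction)
  if (n < 1) abort_param("n must be >= 1")
  if (k < 0 || k > n) abort_param("k must lie in [0, n]")
  if (direction == "auto")
    direction <- if (k / n >= 0.5) "above" else "below"
  ks <- if (direction == "above") k:n else 0:k
  # exact tail: sum_{i in ks} C(n, i) / 2^n, accumulated in log space
  logs <- lchoose(n, ks) - n * log(2)
  m <- max(logs)
  p <- exp(m + log(sum(exp(logs - m))))
  p <- min(p, 1)
  structure(list(k = as.integer(k), n = as.integer(n), proportion = k / n,
                 direction = direction, p_value = p,
                 null_lower = qbinom(0.025, n, 0.5) / n,
                 null_upper = qbinom(0.975, n, 0.5) / n),
            class = "binom_bias")
}

#' @export
print.binom_bias <- function(x, ...) {
  cat(sprintf(
    "<binom_bias> k = %d / n = %d (%.3f); one-tailed (%s) p = %.3g; null 95%% [%.3f, %.3f]\n",
    x$k, x$n, x$proportion, x$direction, x$p_value, x$null_lower,
    x$null_upper))
  invisible(x)
}

#' @export
tidy.binom_bias <- function(x, ...) {
  tibble(k = x$k, n = x$n, proportion = x$proportion,
         direction = x$direction, p_value = x$p_value,
         null_lower = x$null_lower, null_upper = x$null_upper)
}

#' @export
glance.binom_bias <- function(x, ...) tidy(x)

#' mRNA-targeting proportions with pool-size-matched binomial tests
#'
#' Splits classified hits into pools by locus and target genome, under
#' unique and/or absolute counting views, optionally per replicate, and
#' tests each pool's mRNA-targeting proportion against the equal-strand
#' binomial null. Intergenic hits are excluded before testing.
#'
#' @param hits Classified hit tibble ([classify_mrna()] output carrying
#'   `locus_id`, `target_class`, `unique_count`, `absolute_count`,
#'   `replicate_counts`).
#' @param views Counting views to report.
#' @param grouping `"pooled"` (all replicates together) and/or
#'   `"per_replicate"`.
#' @param direction Passed to [binomial_bias_test()] (default `"auto"`,
#'   recorded per pool).
#' @return Tibble with one row per (locus, genome, view, replicate) pool:
#'   `n`, `k`, `proportion`, `direction`, `p_value`, `null_lower`,
#'   `null_upper` (NA rows for empty pools).
#' @export
mrna_proportions <- function(hits, views = c("unique", "absolute"),
                             grouping = "pooled", direction = "auto") {
  hits <- filter(hits, .data$mrna_class != "intergenic_excluded")
  combos <- expand.grid(view = views, group = grouping,
                        stringsAsFactors = FALSE)
  out <- list()
  for (ci in seq_len(nrow(combos))) {
    view <- combos$view[ci]
    per_rep <- combos$group[ci] == "per_replicate"
    if (per_rep) {
      long <- tidyr::unnest(
        select(hits, "locus_id", "target_class", "mrna_class",
               "replicate_counts"),
        "replicate_counts")
      long$w <- if (view == "unique") 1L else long$count
      grp <- group_by(long, .data$locus_id, .data$target_class,
                      .data$replicate)
    } else {
      hits$w <- if (view == "unique") hits$unique_count else
        hits$absolute_count
      grp <- group_by(mutate(hits, replicate = "pooled"), .data$locus_id,
                      .data$target_class, .data$replicate)
    }
    tab <- summarise(grp, n = sum(.data$w),
                     k = sum(.data$w[.data$mrna_class == "mRNA_targeting"]),
                     .groups = "drop")
    tab <- mutate(tab, view = view)
    out[[ci]] <- tab
  }
  tab <- bind_rows(out)
  res <- purrr::pmap_dfr(tab, function(locus_id, target_class, replicate,
                                       n, k, view) {
    base <- tibble(locus_id = locus_id, target_class = target_class,
                   view = view, replicate = replicate, n = n, k = k)
    if (n < 1)
      return(mutate(base, proportion = NA_real_, direction = NA_character_,
                    p_value = NA_real_, null_lower = NA_real_,
                    null_upper = NA_real_))
    bt <- binomial_bias_test(k, n, direction)
    mutate(base, proportion = bt$proportion, direction = bt$direction,
           p_value = bt$p_value, null_lower = bt$null_lower,
           null_upper = bt$null_upper)
  })
  arrange(res, .data$locus_id, .data$target_class, .data$view,
          .data$replicate)
}

#' Binning configuration
#'
#' @param bin_fraction Bin width as a fraction of genome length (default
#'   0.03, i.e. 34 bins; the last bin absorbs the remainder).
#' @param smooth_window Centred moving-average window (bins) for the
#'   across-replicate mean curve.
#' @return An object of class `binning_config`.
#' @export
binning_config <- function(bin_fraction = 0.03, smooth_window = 5L) {
  check_prob(bin_fraction, "bin_fraction")
  if (bin_fraction <= 0) abort_param("bin_fraction must be > 0")
  structure(list(bin_fraction = bin_fraction,
                 smooth_window = as.integer(smooth_window)),
            class = "binning_config")
}

moving_average <- function(x, window) {
  half <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    mean(x[idx])
  }, 0)
}

#' Per-strand binned distribution of protospacer hits
#'
#' The genome is divided into bins spanning `bin_fraction` of its length
#' (`ceil(1/bin_fraction)` bins; the last absorbs the remainder); each
#' hit is assigned by the midpoint of its interval. Counts and
#' per-replicate proportions are reported per strand, together with a
#' centred moving-average smoothing of the across-replicate mean and a
#' motif-frequency track (per-bin occurrence count over both strands,
#' normalised to the genome total).
#'
#' @param hits Hit tibble for one genome (needs `start`, `end`, `strand`,
#'   `replicate_counts`).
#' @param genome [genome_record()].
#' @param cfg [binning_config()].
#' @param motif Optional IUPAC motif for the frequency track.
#' @param view `"unique"` or `"absolute"` weighting.
#' @return A `bin_counts`: list with `bins` (tibble: `bin`, `bin_start`,
#'   `bin_end`, `strand`, `replicate`, `count`, `proportion`), `smoothed`
#'   (tibble: `bin`, `strand`, `mean_proportion`, `smoothed`),
#'   `motif_track` (tibble or NULL), `n_bins`, `genome_id`, `view`.
#' @export
bin_distribution <- function(hits, genome, cfg = binning_config(),
                             motif = NULL, view = c("unique", "absolute")) {
  view <- match.arg(view)
  glen <- nchar(genome$sequence)
  n_bins <- as.integer(ceiling(1 / cfg$bin_fraction))
  bin_w <- cfg$bin_fraction * glen
  long <- tidyr::unnest(
    select(hits, "start", "end", "strand", "replicate_counts"),
    "replicate_counts")
  long$w <- if (view == "unique") 1L else long$count
  # collapse each cluster's per-replicate rows to one unique observation
  if (view == "unique")
    long <- distinct_hits_per_replicate(long)
  long$bin <- pmin(floor(((long$start + long$end) / 2) / bin_w), n_bins - 1)
  reps <- sort(unique(long$replicate))
  if (!length(reps)) reps <- "pooled"
  grid <- expand.grid(bin = 0:(n_bins - 1), strand = c("+", "-"),
                      replicate = reps, stringsAsFactors = FALSE)
  counts <- long |>
    group_by(.data$bin, .data$strand, .data$replicate) |>
    summarise(count = sum(.data$w), .groups = "drop")
  bins <- as_tibble(grid) |>
    left_join(counts, by = c("bin", "strand", "replicate")) |>
    mutate(count = ifelse(is.na(.data$count), 0, .data$count)) |>
    group_by(.data$replicate) |>
    mutate(proportion = if (sum(.data$count) > 0)
      .data$count / sum(.data$count) else 0) |>
    ungroup() |>
    mutate(bin_start = as.integer(floor(.data$bin * bin_w)),
           bin_end = ifelse(.data$bin == n_bins - 1, glen,
                            as.integer(floor((.data$bin + 1) * bin_w))))
  smoothed <- bins |>
    group_by(.data$bin, .data$strand) |>
    summarise(mean_proportion = mean(.data$proportion), .groups = "drop") |>
    group_by(.data$strand) |>
    arrange(.data$bin, .by_group = TRUE) |>
    mutate(smoothed = moving_average(.data$mean_proportion,
                                     cfg$smooth_window)) |>
    ungroup()
  motif_track <- NULL
  if (!is.null(motif)) {
    subj <- Biostrings::DNAString(genome$sequence)
    occ <- c(Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(motif), subj, fixed = "subject")) - 1L,
      Biostrings::start(Biostrings::matchPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(motif)), subj,
        fixed = "subject")) - 1L)
    b <- pmin(floor((occ + nchar(motif) / 2) / bin_w), n_bins - 1)
    tb <- table(factor(b, levels = 0:(n_bins - 1)))
    motif_track <- tibble(bin = 0:(n_bins - 1), count = as.integer(tb),
                          frequency = as.integer(tb) / max(sum(tb), 1L))
  }
  structure(list(bins = bins, smoothed = smoothed,
                 motif_track = motif_track, n_bins = n_bins,
                 genome_id = genome$id, view = view),
            class = "bin_counts")
}

# one row per (hit, replicate) regardless of read count
distinct_hits_per_replicate <- function(long) {
  long |>
    group_by(.data$start, .data$end, .data$strand, .data$replicate) |>
    summarise(w = 1L, .groups = "drop")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("<bin_counts> %s: %d bins (%s view), %d replicate(s)\n",
              x$genome_id, x$n_bins, x$view,
              length(unique(x$bins$replicate))))
  invisible(x)
}

#' @export
tidy.bin_counts <- function(x, ...) x$bins
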