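#' Overlap-null model configuration
#'
#' @param n_iterations Monte-Carlo iterations (default 1000).
#' @param sample_size Simulated spacers per iteration (default 430, the
#'   pooled unique VI-B spacer count it emulates).
#' @param simulated_spacer_length Length of sampled spacers (default 30,
#'   the modal observed spacer length).
#' @param sam_motif IUPAC motif for PAM-adjacent sampling.
#' @param seed Integer seed.
#' @return An object of class `null_model_config`.
#' @export
null_model_config <- function(n_iterations = 1000L, sample_size = 430L,
                              simulated_spacer_length = 30L,
                              sam_motif = "NNNNNTAAA", seed = 1L) {
  if (n_iterations < 1) abort_param("n_iterations must be >= 1")
  if (sample_size < 1) abort_param("sample_size must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 sample_size = as.integer(sample_size),
                 simulated_spacer_length = as.integer(simulated_spacer_length),
                 sam_motif = sam_motif, seed = as.integer(seed)),
            class = "null_model_config")
}

#' Sample one null spacer pool from a genome
#'
#' `random` mode draws uniform start positions and strands and extracts
#' `simulated_spacer_length` bases; `pam_adjacent` mode draws uniformly
#' (with replacement) from all genomic placements, on either strand,
#' whose downstream guide-strand flank matches the SAM (`TAAA` at flank
#' offset 6-9 for the default `NNNNNTAAA`).
#'
#' @param genome [genome_record()].
#' @param cfg [null_model_config()].
#' @param mode `"random"` or `"pam_adjacent"`.
#' @return Character vector of `cfg$sample_size` sequences.
#' @export
sample_null_pool <- function(genome, cfg = null_model_config(),
                             mode = c("random", "pam_adjacent")) {
  mode <- match.arg(mode)
  glen <- nchar(genome$sequence)
  L <- cfg$simulated_spacer_length
  n <- cfg$sample_size
  if (mode == "random") {
    starts <- sample.int(glen - L + 1L, n, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
  } else {
    pl <- sam_placements(genome, L, cfg$sam_motif, "downstream_taaa")
    if (nrow(pl) == 0)
      abort_param("pam_adjacent sampling: no SAM placements on the genome")
    idx <- sample.int(nrow(pl), n, replace = TRUE)
    starts <- pl$start[idx]
    strands <- pl$strand[idx]
  }
  fwd <- substring(genome$sequence, starts + 1L, starts + L)
  ifelse(strands == "+", fwd, revcomp(fwd))
}

# maximum-likelihood normal fit: sample mean, population (divisor-n) sd
ml_normal_fit <- function(x) {
  mu <- mean(x)
  list(mu = mu, sigma = sqrt(mean((x - mu)^2)))
}

#' Monte-Carlo null distribution of inter-pool overlap
#'
#' Repeatedly samples a null spacer pool from the genome, records the
#' fraction of each sampled pool matched in the reference pool at the
#' cross-pool identity threshold, fits a normal distribution by maximum
#' likelihood (sample mean; population standard deviation), and — when an
#' observed overlap fraction is supplied — reports the one-tailed normal
#' upper-tail p alongside a rank-based empirical p
#' `(1 + #{fractions >= observed}) / (1 + n_iterations)`.
#'
#' @param genome [genome_record()] sampled from.
#' @param reference A `spacer_pool` (unique view) or character vector of
#'   unique sequences.
#' @param cfg [null_model_config()].
#' @param mode `"random"` or `"pam_adjacent"`.
#' @param observed Observed overlap fraction (optional).
#' @param cluster_cfg [cluster_config()] supplying the cross-pool
#'   identity threshold.
#' @return An object of class `overlap_null` with fields `mode`,
#'   `fractions`, `mu`, `sigma`, `observed`, `p_normal`, `p_empirical`.
#' @export
run_null <- function(genome, reference, cfg = null_model_config(),
                     mode = c("random", "pam_adjacent"), observed = NULL,
                     cluster_cfg = cluster_config()) {
  mode <- match.arg(mode)
  ref <- if (inherits(reference, "spacer_pool")) pool_sequences(reference)
         else reference
  if (!length(ref)) abort_param("reference pool is empty")
  # all iterations are drawn in one vectorised batch (one RNG stream, one
  # placement scan, one matching call); per-iteration fractions follow by
  # slicing the match indicators
  glen <- nchar(genome$sequence)
  L <- cfg$simulated_spacer_length
  total <- cfg$n_iterations * cfg$sample_size
  seqs <- withr::with_seed(derive_seed(cfg$seed, 4L), {
    if (mode == "random") {
      starts <- sample.int(glen - L + 1L, total, replace = TRUE) - 1L
      strands <- sample(c("+", "-"), total, replace = TRUE)
    } else {
      pl <- sam_placements(genome, L, cfg$sam_motif, "downstream_taaa")
      if (nrow(pl) == 0)
        abort_param("pam_adjacent sampling: no SAM placements on the genome")
      idx <- sample.int(nrow(pl), total, replace = TRUE)
      starts <- pl$start[idx]
      strands <- pl$strand[idx]
    }
    fwd <- substring(genome$sequence, starts + 1L, starts + L)
    ifelse(strands == "+", fwd, revcomp(fwd))
  })
  hit <- cpp_cross_match(seqs, ref, cluster_cfg$cross_pool_identity)
  fractions <- colMeans(matrix(!is.na(hit), nrow = cfg$sample_size))
  fit <- ml_normal_fit(fractions)
  mu <- fit$mu
  sigma <- fit$sigma
  p_normal <- p_emp <- NA_real_
  if (!is.null(observed)) {
    if (sigma == 0) {
      if (observed != mu)
        warn("degenerate normal fit (sigma = 0); p is 0 or 1")
      p_normal <- if (observed > mu) 0 else 1
    } else {
      p_normal <- pnorm(observed, mu, sigma, lower.tail = FALSE)
    }
    p_emp <- (1 + sum(fractions >= observed)) / (1 + cfg$n_iterations)
  }
  structure(list(mode = mode, fractions = fractions, mu = mu,
                 sigma = sigma, observed = observed, p_normal = p_normal,
                 p_empirical = p_emp, n_iterations = cfg$n_iterations,
                 sample_size = cfg$sample_size),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf("<overlap_null> %s: mu = %.4f, sigma = %.4f (%d iterations of %d spacers)\n",
              x$mode, x$mu, x$sigma, x$n_iterations, x$sample_size))
  if (!is.null(x$observed))
    cat(sprintf("observed = %.4f; normal-tail p = %.3g; empirical p = %.3g\n",
                x$observed, x$p_normal, x$p_empirical))
  invisible(x)
}

#' @export
tidy.overlap_null <- function(x, ...) {
  tibble(iteration = seq_along(x$fractions), fraction = x$fractions,
         mode = x$mode)
}

#' @export
glance.overlap_null <- function(x, ...) {
  tibble(mode = x$mode, mu = x$mu, sigma = x$sigma,
         observed = x$observed %||% NA_real_,
         p_normal = x$p_normal, p_empirical = x$p_empirical,
         n_iterations = x$n_iterations, sample_size = x$sample_size)
}

#' Observed overlap between two unique spacer pools
#'
#' Fraction of query representatives with at least one reference
#' representative at the cross-pool identity threshold (both pools in
#' unique view; typically phage-targeting spacers only).
#'
#' @param query,reference `spacer_pool`s or character vectors.
#' @param cfg [cluster_config()].
#' @return Overlap fraction in `[0, 1]`.
#' @export
observed_overlap <- function(query, reference, cfg = cluster_config()) {
  cross_pool_fraction(query, reference, cfg)$fraction
}
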