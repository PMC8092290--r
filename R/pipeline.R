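#' Assemble a full run configuration
#'
#' Bundles every stage configuration plus locus definitions, input paths
#' and the master seed. All stochastic stages derive their streams from
#' `seed`, so a configuration pins the whole run.
#'
#' @param loci Named list of [locus_model()]s (>= 1; the first owns the
#'   shared prespacer pool).
#' @param reads Tibble `locus_id`, `replicate`, `path` of amplicon FASTQ
#'   files (may be empty when only simulating).
#' @param phage_fasta,host_fasta,phage_gff,host_gff Input paths (optional
#'   when genomes are passed to [run_pipeline()] directly).
#' @param extraction,clustering,alignment,null_model,binning Stage
#'   configurations.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(loci = default_loci(), reads = NULL,
                       phage_fasta = NULL, host_fasta = NULL,
                       phage_gff = NULL, host_gff = NULL,
                       extraction = extraction_config(),
                       clustering = cluster_config(),
                       alignment = align_config(),
                       null_model = null_model_config(),
                       binning = binning_config(), seed = 1L) {
  if (!length(loci)) abort_param("at least one locus must be configured")
  structure(list(loci = loci, reads = reads, phage_fasta = phage_fasta,
                 host_fasta = host_fasta, phage_gff = phage_gff,
                 host_gff = host_gff, extraction = extraction,
                 clustering = clustering, alignment = alignment,
                 null_model = null_model, binning = binning,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  y <- yaml::read_yaml(path)
  loci <- lapply(y$loci, function(l) do.call(locus_model, l))
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  reads <- if (!is.null(y$reads)) as_tibble(bind_rows(y$reads)) else NULL
  run_config(loci = loci, reads = reads, phage_fasta = y$phage_fasta,
             host_fasta = y$host_fasta, phage_gff = y$phage_gff,
             host_gff = y$host_gff,
             extraction = do.call(extraction_config, y$extraction %||% list()),
             clustering = do.call(cluster_config, y$clustering %||% list()),
             alignment = do.call(align_config, y$alignment %||% list()),
             null_model = do.call(null_model_config, y$null_model %||% list()),
             binning = do.call(binning_config, y$binning %||% list()),
             seed = y$seed %||% 1L)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  y <- list(
    loci = lapply(unname(config$loci), function(l) {
      l <- unclass(l)
      l[lengths(l) > 0 | names(l) == "preexisting_spacers"]
    }),
    reads = if (!is.null(config$reads))
      lapply(seq_len(nrow(config$reads)), function(i)
        as.list(config$reads[i, ])),
    phage_fasta = config$phage_fasta, host_fasta = config$host_fasta,
    phage_gff = config$phage_gff, host_gff = config$host_gff,
    extraction = unclass(config$extraction),
    clustering = unclass(config$clustering),
    alignment = unclass(config$alignment),
    null_model = unclass(config$null_model),
    binning = unclass(config$binning), seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Simulate a complete synthetic study data set
#'
#' Convenience wrapper: generates phage and host genomes, simulates
#' acquisition events in every locus and emits amplicon reads, returning
#' everything needed to exercise the downstream pipeline against known
#' ground truth.
#'
#' @param seed Master seed.
#' @param params [acquisition_params()].
#' @param loci Named list of [locus_model()]s.
#' @param error_model [read_error_model()].
#' @param depth_per_event Reads per event copy.
#' @param phage_length,host_length Genome sizes (defaults 47 kb linear
#'   phage, 300 kb circular host — the host deliberately scaled down from
#'   chromosome size while preserving phage realism).
#' @param gc_fraction Shared GC content.
#' @return List with `phage`, `host`, `loci`, `params`, `truth`, `reads`.
#' @export
simulate_dataset <- function(seed = 1L, params = acquisition_params(),
                             loci = default_loci(),
                             error_model = read_error_model(),
                             depth_per_event = 2L,
                             phage_length = 47000L, host_length = 300000L,
                             gc_fraction = 0.32) {
  phage <- generate_genome(phage_length, gc_fraction, orf_density = 0.9,
                           seed = derive_seed(seed, 11L), id = "phage",
                           topology = "linear")
  host <- generate_genome(host_length, gc_fraction, orf_density = 0.88,
                          seed = derive_seed(seed, 12L), id = "host",
                          topology = "circular")
  truth <- simulate_acquisition(phage, host, loci, params,
                                seed = derive_seed(seed, 13L))
  reads <- emit_amplicon_reads(truth, loci, depth_per_event, error_model,
                               seed = derive_seed(seed, 14L))
  list(phage = phage, host = host, loci = loci, params = params,
       truth = truth, reads = reads)
}

#' Run the full analysis pipeline
#'
#' Stages run in order: extract -> cluster -> map -> motif -> target
#' statistics -> overlap null. A failure confined to one locus is
#' collected and reported rather than aborting the other locus.
#'
#' @param config A [run_config()] or path to its YAML.
#' @param phage,host Optional in-memory [genome_record()]s (otherwise
#'   read from the configured FASTA/GFF paths).
#' @param reads Optional in-memory read tibble with `locus_id`,
#'   `replicate`, `sequence`, `quality` (otherwise read from the
#'   configured FASTQ paths).
#' @param out_dir Optional directory for stage TSV outputs.
#' @return A `pipeline_report`: list with per-stage tibbles
#'   (`extraction`, `pools`, `mapping`, `hits`, `sam_rates`,
#'   `motif_counts`, `mrna_tests`, `bin_distributions`, `overlap`),
#'   `errors`, `seed`, `config_hash`, `version`.
#' @export
run_pipeline <- function(config, phage = NULL, host = NULL, reads = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  # fail fast on missing inputs
  for (p in c(config$phage_fasta, config$host_fasta, config$phage_gff,
              config$host_gff, config$reads$path))
    if (!is.null(p) && !file.exists(p))
      abort_format(sprintf("missing input file: %s", p))
  if (is.null(phage)) {
    phage <- read_genome_fasta(config$phage_fasta, topology = "linear")[[1]]
    if (!is.null(config$phage_gff))
      phage$features <- read_orf_features(config$phage_gff)
  }
  if (is.null(host)) {
    host <- read_genome_fasta(config$host_fasta, topology = "circular")[[1]]
    if (!is.null(config$host_gff))
      host$features <- read_orf_features(config$host_gff)
  }
  if (is.null(reads)) {
    if (is.null(config$reads) || nrow(config$reads) == 0)
      abort_param("no reads configured (zero replicates)")
    reads <- purrr::pmap_dfr(config$reads, function(locus_id, replicate,
                                                    path) {
      mutate(read_amplicon_fastq(path), locus_id = locus_id,
             replicate = replicate)
    })
  }
  genomes <- list(phage = phage, self = host)
  errors <- list()
  extraction <- list(); pools <- list(); mapping <- list(); hits <- list()
  sam_rates <- list(); pfms <- list()
  for (lname in names(config$loci)) {
    locus <- config$loci[[lname]]
    res <- tryCatch({
      lreads <- filter(reads, .data$locus_id == locus$locus_id)
      obs <- extract_spacers(lreads, locus, config$extraction)
      pool <- cluster_spacers(obs, config$clustering, locus$locus_id)
      mapped <- hierarchical_map(pool, phage, host, config$alignment)
      lhits <- mapped$hits
      if (nrow(lhits)) {
        lhits <- split(lhits, lhits$target_class) |>
          purrr::imap(function(h, cls)
            detect_sam(extract_flanks(h, genomes[[cls]]), locus)) |>
          bind_rows()
      }
      phage_hits <- filter(lhits, .data$target_class == "phage")
      rate <- if (nrow(phage_hits)) mean(phage_hits$sam, na.rm = TRUE)
              else NA_real_
      pfm <- tryCatch(build_pfm(phage_hits,
                                side = if (sam_convention(locus) ==
                                           "downstream_taaa")
                                  "downstream" else "upstream"),
                      error = function(e) NULL)
      list(summary = extraction_summary(obs), pool = pool,
           map_summary = mapped$summary, hits = lhits,
           sam = tibble(locus_id = locus$locus_id,
                        n_phage_hits = nrow(phage_hits), sam_rate = rate),
           pfm = pfm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[lname]] <- conditionMessage(res)
      next
    }
    extraction[[lname]] <- res$summary
    pools[[lname]] <- res$pool
    mapping[[lname]] <- res$map_summary
    hits[[lname]] <- res$hits
    sam_rates[[lname]] <- res$sam
    pfms[[lname]] <- res$pfm
  }
  all_hits <- bind_rows(hits)
  motif_counts <- bind_rows(
    mutate(count_motif(phage, "TAAA", "whole_genome"), genome_id = phage$id),
    mutate(count_motif(phage, "TAAA", "cds_only"), genome_id = phage$id),
    mutate(count_motif(host, "TAAA", "whole_genome"), genome_id = host$id),
    mutate(count_motif(host, "TAAA", "cds_only"), genome_id = host$id))
  mrna_tests <- NULL
  bin_dists <- list()
  if (nrow(all_hits)) {
    classified <- split(all_hits, all_hits$target_class) |>
      purrr::imap(function(h, cls)
        classify_mrna(h, genomes[[cls]]$features)) |>
      bind_rows()
    mrna_tests <- mrna_proportions(classified,
                                   grouping = c("pooled", "per_replicate"))
    for (cls in unique(all_hits$target_class)) {
      for (lname in names(config$loci)) {
        h <- filter(all_hits, .data$target_class == cls,
                    .data$locus_id == config$loci[[lname]]$locus_id)
        if (!nrow(h)) next
        for (v in c("unique", "absolute"))
          bin_dists[[paste(lname, cls, v, sep = ".")]] <-
            bin_distribution(h, genomes[[cls]], config$binning,
                             motif = "TAAA", view = v)
      }
    }
  }
  overlap <- NULL
  if (length(pools) >= 2 && nrow(all_hits)) {
    ref_locus <- names(config$loci)[1]
    qry_locus <- names(config$loci)[2]
    ref_seqs <- filter(all_hits, .data$locus_id ==
                         config$loci[[ref_locus]]$locus_id,
                       .data$target_class == "phage")$spacer
    qry_seqs <- filter(all_hits, .data$locus_id ==
                         config$loci[[qry_locus]]$locus_id,
                       .data$target_class == "phage")$spacer
    if (length(ref_seqs) && length(qry_seqs)) {
      obs <- observed_overlap(qry_seqs, ref_seqs, config$clustering)
      ncfg <- config$null_model
      ncfg$sample_size <- length(qry_seqs)
      ncfg$seed <- derive_seed(config$seed, 21L)
      nr <- run_null(phage, ref_seqs, ncfg, "random", observed = obs,
                     cluster_cfg = config$clustering)
      ncfg$seed <- derive_seed(config$seed, 22L)
      np <- run_null(phage, ref_seqs, ncfg, "pam_adjacent", observed = obs,
                     cluster_cfg = config$clustering)
      overlap <- list(observed = obs, query_size = length(qry_seqs),
                      random = nr, pam_adjacent = np)
    }
  }
  report <- structure(list(
    extraction = bind_rows(extraction), pools = pools,
    mapping = bind_rows(mapping), hits = all_hits,
    sam_rates = bind_rows(sam_rates), pfms = pfms,
    motif_counts = motif_counts, mrna_tests = mrna_tests,
    bin_distributions = bin_dists, overlap = overlap, errors = errors,
    seed = config$seed, config_hash = config_hash(unclass(config)),
    version = pkg_version_string()), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> spaceracq %s, seed %d, config %s\n",
              x$version, x$seed, x$config_hash))
  if (nrow(x$extraction)) print(x$extraction)
  if (nrow(x$mapping)) print(x$mapping)
  if (!is.null(x$overlap))
    cat(sprintf(
      "overlap: observed %.3f | null random mu %.3f sd %.3f | pam mu %.3f sd %.3f\n",
      x$overlap$observed, x$overlap$random$mu, x$overlap$random$sigma,
      x$overlap$pam_adjacent$mu, x$overlap$pam_adjacent$sigma))
  if (length(x$errors))
    cat("collected errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# spaceracq %s config %s seed %d", report$version,
                   report$config_hash, report$seed)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(
      df, path, sep = "\t", quote = FALSE, row.names = FALSE,
      append = TRUE))
    path
  }
  wt(report$extraction, "extraction_summary.tsv")
  wt(report$mapping, "mapping_summary.tsv")
  if (nrow(report$hits))
    wt(select(report$hits, -"replicate_counts"), "hits.tsv")
  wt(report$sam_rates, "sam_rates.tsv")
  wt(report$motif_counts, "motif_counts.tsv")
  if (!is.null(report$mrna_tests)) wt(report$mrna_tests, "mrna_tests.tsv")
  if (!is.null(report$overlap)) {
    wt(bind_rows(glance(report$overlap$random),
                 glance(report$overlap$pam_adjacent)), "overlap_null.tsv")
  }
  invisible(out_dir)
}

#' Parameter-recovery simulation study
#'
#' Sweeps grids of the acquisition parameters, runs the full pipeline on
#' each simulated data set and tabulates estimated versus true values
#' with exact binomial 99% confidence intervals (for the rate parameters)
#' and the overlap-null p-value (for the shared-pool sweep).
#'
#' @param pi_grid SAM-preference values to sweep (`NULL` to skip).
#' @param beta_grid Strand-bias values.
#' @param sigma_grid Self-fraction values.
#' @param rho_grid Shared-pool values.
#' @param n_events Events per locus per run.
#' @param seed Master seed.
#' @param phage_length,host_length Genome sizes for the sweep runs.
#' @param n_iterations Null iterations for the rho sweep.
#' @return Tibble: `parameter`, `true_value`, `estimate`, `truth_value`
#'   (realised ground-truth fraction), `n`, `ci_lower`, `ci_upper`,
#'   `p_overlap` (`NA` outside the rho sweep).
#' @export
run_simulation_study <- function(pi_grid = c(0, 0.63, 1),
                                 beta_grid = c(0.5), sigma_grid = c(0.05),
                                 rho_grid = NULL, n_events = 300L,
                                 seed = 1L, phage_length = 20000L,
                                 host_length = 40000L,
                                 n_iterations = 200L) {
  rows <- list()
  add <- function(parameter, true_value, estimate, truth_value, n,
                  p_overlap = NA_real_) {
    ci <- if (!is.na(n) && n > 0)
      stats::binom.test(round(truth_value * n), n,
                        conf.level = 0.99)$conf.int else c(NA_real_, NA_real_)
    rows[[length(rows) + 1L]] <<- tibble(
      parameter = parameter, true_value = true_value, estimate = estimate,
      truth_value = truth_value, n = n, ci_lower = ci[1], ci_upper = ci[2],
      p_overlap = p_overlap)
  }
  run_one <- function(params, run_seed) {
    ds <- simulate_dataset(run_seed, params, phage_length = phage_length,
                           host_length = host_length)
    cfg <- run_config(loci = ds$loci, seed = run_seed,
                      null_model = null_model_config(
                        n_iterations = n_iterations, seed = run_seed))
    list(ds = ds,
         report = run_pipeline(cfg, phage = ds$phage, host = ds$host,
                               reads = ds$reads))
  }
  k <- 0L
  for (p in pi_grid %||% numeric()) {
    k <- k + 1L
    r <- run_one(acquisition_params(n_events = n_events,
                                    pam_preference = p,
                                    shared_pool_fraction = 0),
                 derive_seed(seed, 30L + k))
    truth1 <- filter(r$ds$truth,
                     .data$locus_id == names(r$ds$loci)[1],
                     .data$target_class == "phage")
    est <- filter(r$report$sam_rates,
                  .data$locus_id == names(r$ds$loci)[1])$sam_rate
    add("pam_preference", p, est, mean(truth1$sam_adjacent, na.rm = TRUE),
        sum(!is.na(truth1$sam_adjacent)))
  }
  for (b in beta_grid %||% numeric()) {
    k <- k + 1L
    r <- run_one(acquisition_params(n_events = n_events, strand_bias = b,
                                    shared_pool_fraction = 0),
                 derive_seed(seed, 30L + k))
    est <- mean(r$report$hits$strand == "+")
    add("strand_bias", b, est, mean(r$ds$truth$strand == "+"),
        nrow(r$ds$truth))
  }
  for (s in sigma_grid %||% numeric()) {
    k <- k + 1L
    r <- run_one(acquisition_params(n_events = n_events, self_fraction = s,
                                    shared_pool_fraction = 0),
                 derive_seed(seed, 30L + k))
    est <- mean(r$report$hits$target_class == "self")
    add("self_fraction", s, est, mean(r$ds$truth$target_class == "self"),
        nrow(r$ds$truth))
  }
  for (rho in rho_grid %||% numeric()) {
    k <- k + 1L
    r <- run_one(acquisition_params(n_events = n_events,
                                    shared_pool_fraction = rho),
                 derive_seed(seed, 30L + k))
    ov <- r$report$overlap
    add("shared_pool_fraction", rho, ov$observed %||% NA_real_,
        rho, NA_integer_,
        p_overlap = if (!is.null(ov)) ov$random$p_normal else NA_real_)
  }
  bind_rows(rows)
}
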