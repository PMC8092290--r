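test_that("generate_genome is deterministic and honours orf_density", {
  g1 <- generate_genome(10000, gc_fraction = 0.32, orf_density = 0.5,
                        seed = 7)
  g2 <- generate_genome(10000, gc_fraction = 0.32, orf_density = 0.5,
                        seed = 7)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  span <- sum(g1$features$end - g1$features$start)
  expect_gt(span, 0.4 * 10000)
  expect_lt(span, 0.6 * 10000)
  g0 <- generate_genome(2000, orf_density = 0, seed = 1)
  expect_equal(nrow(g0$features), 0)
  expect_error(generate_genome(2000, orf_density = 0.99, seed = 1),
               class = "spaceracq_parameter_error")
  expect_error(generate_genome(500, seed = 1),
               class = "spaceracq_parameter_error")
  # GC content tracks the requested fraction
  gc <- mean(strsplit(g1$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.32), 0.03)
})

test_that("simulated acquisition honours its probability dials", {
  phage <- generate_genome(12000, seed = 2, id = "phage")
  host <- generate_genome(15000, seed = 3, id = "host",
                          topology = "circular")
  loci <- default_loci()
  tr_pi1 <- simulate_acquisition(phage, host, loci,
                                 acquisition_params(n_events = 50,
                                                    pam_preference = 1,
                                                    shared_pool_fraction = 0),
                                 seed = 5)
  expect_true(all(tr_pi1$sam_adjacent))
  tr_s0 <- simulate_acquisition(phage, host, loci,
                                acquisition_params(n_events = 50,
                                                   self_fraction = 0),
                                seed = 5)
  expect_true(all(tr_s0$target_class == "phage"))
  tr_rho1 <- simulate_acquisition(phage, host, loci,
                                  acquisition_params(n_events = 50,
                                                     shared_pool_fraction = 1),
                                  seed = 5)
  iic <- dplyr::filter(tr_rho1, locus_id == "II-C")
  vib <- dplyr::filter(tr_rho1, locus_id == "VI-B")
  expect_true(all(vib$spacer %in% iic$spacer))
  expect_true(all(tr_rho1$end - tr_rho1$start >= 27 &
                    tr_rho1$end - tr_rho1$start <= 32))
  # spacer field really is the crRNA-oriented genomic sequence
  i <- which(tr_s0$strand == "-")[1]
  fwd <- substr(phage$sequence, tr_s0$start[i] + 1, tr_s0$end[i])
  expect_equal(tr_s0$spacer[i], revcomp(fwd))
})

test_that("read emission is deterministic, depth-exact and reorientable", {
  phage <- generate_genome(8000, seed = 2, id = "phage")
  host <- generate_genome(8000, seed = 3, id = "host",
                          topology = "circular")
  loci <- default_loci()
  truth <- simulate_acquisition(phage, host, loci,
                                acquisition_params(n_events = 15,
                                                   copy_geom_prob = 1),
                                seed = 9)
  em0 <- read_error_model(substitution_rate = 0, insertion_rate = 0,
                          deletion_rate = 0, quality_sd = 0)
  r1 <- emit_amplicon_reads(truth, loci, depth_per_event = 3, em0, seed = 4)
  r2 <- emit_amplicon_reads(truth, loci, depth_per_event = 3, em0, seed = 4)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3 * nrow(truth))
  # with zero error rates every read contains its truth spacer verbatim
  by_event <- setNames(truth$spacer, truth$event_id)
  ev <- sub(":.*$", "", r1$read_id)
  expect_true(all(mapply(grepl, by_event[ev], r1$sequence, fixed = TRUE)))
})

test_that("injected substitution errors appear at the configured rate", {
  phage <- generate_genome(8000, seed = 2, id = "phage")
  host <- generate_genome(8000, seed = 3, id = "host",
                          topology = "circular")
  # preexisting spacers pin the downstream filler so the clean amplicon is
  # reconstructable
  loci <- lapply(default_loci(), function(l) {
    l$preexisting_spacers <- "ACGTACGTACGTACGTACGTACGTACGTAC"
    l
  })
  truth <- simulate_acquisition(phage, host, loci,
                                acquisition_params(n_events = 60,
                                                   copy_geom_prob = 1),
                                seed = 9)
  em <- read_error_model(substitution_rate = 0.01, insertion_rate = 0,
                         deletion_rate = 0, quality_sd = 0)
  reads <- emit_amplicon_reads(truth, loci, depth_per_event = 5, em,
                               seed = 4)
  loci_by_id <- setNames(loci, vapply(loci, `[[`, "", "locus_id"))
  mism <- 0L
  total <- 0L
  for (i in seq_len(nrow(reads))) {
    ev <- sub(":.*$", "", reads$read_id[i])
    tr <- truth[truth$event_id == ev, ]
    l <- loci_by_id[[tr$locus_id]]
    clean <- paste0(substr(l$leader, nchar(l$leader) - 19, nchar(l$leader)),
                    l$repeat_seq, tr$spacer, l$repeat_seq,
                    l$preexisting_spacers[[1]])
    a <- strsplit(clean, "")[[1]]
    b <- strsplit(reads$sequence[i], "")[[1]]
    expect_equal(length(a), length(b))
    mism <- mism + sum(a != b)
    total <- total + length(a)
  }
  rate <- mism / total
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("pool overlap recovered downstream is non-decreasing in the shared fraction", {
  phage <- generate_genome(9000, seed = 21, id = "phage")
  host <- generate_genome(9000, seed = 22, id = "host",
                          topology = "circular")
  loci <- default_loci()
  overlaps <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(rho) {
    truth <- simulate_acquisition(
      phage, host, loci,
      acquisition_params(n_events = 120, shared_pool_fraction = rho,
                         self_fraction = 0),
      seed = 77)
    pools <- lapply(split(truth$spacer, truth$locus_id), cluster_spacers)
    observed_overlap(pools$`VI-B`, pools$`II-C`)
  }, 0)
  expect_true(all(diff(overlaps) >= 0))
  expect_lt(overlaps[1], 0.15)
  expect_gt(overlaps[5], 0.85)
})

test_that("pam_preference = 1 with no available motif placement errors out", {
  withr::local_seed(42)
  seq <- genome_without(300)
  g <- toy_genome(seq, id = "nosam")
  host <- toy_genome(genome_without(300), id = "host2")
  expect_error(
    simulate_acquisition(g, host, default_loci(),
                         acquisition_params(n_events = 5,
                                            pam_preference = 1,
                                            self_fraction = 0,
                                            shared_pool_fraction = 0),
                         seed = 1),
    class = "spaceracq_parameter_error")
})

test_that("write_simulation emits one FASTQ per locus/replicate plus truth TSV", {
  ds <- small_dataset(seed = 4, n_events = 10)
  dir <- withr::local_tempdir()
  files <- write_simulation(ds$truth, ds$reads, dir)
  expect_true(all(file.exists(files$path)))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  back <- read_amplicon_fastq(files$path[1])
  expect_gt(nrow(back), 0)
})
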