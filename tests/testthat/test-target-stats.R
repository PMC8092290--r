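test_that("mRNA classification follows containment and strand complementarity", {
  feats <- tibble::tibble(feature_id = "orf1", start = 10L, end = 70L,
                          strand = "+")
  hits <- tibble::tibble(genome_id = "g",
                         start = c(20L, 20L, 60L),
                         end = c(50L, 50L, 90L),
                         strand = c("-", "+", "-"))
  cls <- classify_mrna(hits, feats)$mrna_class
  expect_equal(cls, c("mRNA_targeting", "non_mRNA", "intergenic_excluded"))
})

test_that("relabelling every ORF to the opposite strand swaps the mRNA classes", {
  withr::with_seed(81, {
    g <- generate_genome(8000, orf_density = 0.6, seed = 5)
    starts <- sample(7000, 120)
    hits <- tibble::tibble(genome_id = g$id, start = starts,
                           end = starts + 30L,
                           strand = sample(c("+", "-"), 120, replace = TRUE))
    a <- classify_mrna(hits, g$features)$mrna_class
    flipped <- dplyr::mutate(g$features,
                             strand = ifelse(strand == "+", "-", "+"))
    b <- classify_mrna(hits, flipped)$mrna_class
    expect_equal(b[a == "mRNA_targeting"],
                 rep("non_mRNA", sum(a == "mRNA_targeting")))
    expect_equal(b[a == "non_mRNA"],
                 rep("mRNA_targeting", sum(a == "non_mRNA")))
    expect_equal(b[a == "intergenic_excluded"],
                 rep("intergenic_excluded", sum(a == "intergenic_excluded")))
  })
})

test_that("one-tailed binomial tail matches exact summation and pbinom", {
  # saturated pool: p = 0.5^n exactly
  bt <- binomial_bias_test(19, 19, "above")
  expect_equal(bt$p_value, 0.5^19)
  expect_equal(signif(bt$p_value, 2), 1.9e-06)
  # hand-derived tail: sum_{i>=5} C(10,i)/2^10 = 638/1024
  expect_equal(binomial_bias_test(5, 10, "above")$p_value, 638 / 1024)
  expect_equal(binomial_bias_test(0, 1, "below")$p_value, 0.5)
  # oracle agreement to 1e-12 relative across sizes up to 1000
  withr::with_seed(82, {
    for (i in 1:40) {
      n <- sample(1:1000, 1)
      k <- sample(0:n, 1)
      expect_equal(binomial_bias_test(k, n, "above")$p_value,
                   oracle_binom_upper(k, n), tolerance = 1e-12)
      expect_equal(binomial_bias_test(k, n, "below")$p_value,
                   oracle_binom_lower(k, n), tolerance = 1e-12)
      expect_equal(binomial_bias_test(k, n, "above")$p_value,
                   pbinom(k - 1, n, 0.5, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })
  # auto direction is recorded, never silent
  expect_equal(binomial_bias_test(8, 10)$direction, "above")
  expect_equal(binomial_bias_test(2, 10)$direction, "below")
  expect_error(binomial_bias_test(2, 0), class = "spaceracq_parameter_error")
  td <- tidy(binomial_bias_test(5, 10))
  expect_equal(td$proportion, 0.5)
  expect_equal(td$null_lower, qbinom(0.025, 10, 0.5) / 10)
})

test_that("mrna_proportions builds pool-size-matched tests per locus and genome", {
  # all hits mRNA-targeting: proportion 1, p = 0.5^n
  feats <- tibble::tibble(feature_id = "f", start = 0L, end = 5000L,
                          strand = "+")
  n <- 12
  hits <- tibble::tibble(
    genome_id = "phage", locus_id = "II-C", target_class = "phage",
    start = seq(10L, by = 40L, length.out = n))
  hits$end <- hits$start + 30L
  hits$strand <- "-"
  hits$unique_count <- 1L
  hits$absolute_count <- 2L
  hits$replicate_counts <- replicate(n, tibble::tibble(replicate = "rep1",
                                                       count = 2L),
                                     simplify = FALSE)
  cl <- classify_mrna(hits, feats)
  res <- mrna_proportions(cl, views = "unique", grouping = "pooled")
  expect_equal(nrow(res), 1)
  expect_equal(res$proportion, 1)
  expect_equal(res$p_value, 0.5^n)
  expect_equal(res$direction, "above")
  # absolute view weights by cluster size
  res_abs <- mrna_proportions(cl, views = "absolute", grouping = "pooled")
  expect_equal(res_abs$n, 2L * n)
  # a single-hit pool stays NA-safe with a wide null band
  one <- cl[1, ]
  r1 <- mrna_proportions(one, views = "unique",
                         grouping = c("pooled", "per_replicate"))
  expect_true(all(r1$proportion %in% c(0, 1)))
  expect_true(all(r1$null_lower == 0 & r1$null_upper == 1))
})

test_that("balanced synthetic strand usage stays inside the binomial null band", {
  # beta = 0.5 acquisition: pooled mRNA proportions should sit inside the
  # 95% null interval in most seeded runs
  inside <- 0L
  for (seed in 1:10) {
    ds <- simulate_dataset(
      seed = seed + 100,
      params = acquisition_params(n_events = 60, self_fraction = 0,
                                  shared_pool_fraction = 0,
                                  uniform_weight = 1, hotspots = list()),
      depth_per_event = 1, phage_length = 9000, host_length = 9000)
    truth <- dplyr::filter(ds$truth, locus_id == "II-C")
    hits <- dplyr::mutate(truth, unique_count = 1L, absolute_count = 1L,
                          replicate_counts = replicate(
                            nrow(truth),
                            tibble::tibble(replicate = "rep1", count = 1L),
                            simplify = FALSE))
    cl <- classify_mrna(hits, ds$phage$features)
    res <- mrna_proportions(cl, views = "unique", grouping = "pooled")
    if (res$proportion >= res$null_lower && res$proportion <= res$null_upper)
      inside <- inside + 1L
  }
  expect_gte(inside, 9L)
})

test_that("binning arithmetic, conservation and proportion normalisation hold", {
  withr::with_seed(83, {
    g <- toy_genome(rand_dna(1000), id = "g")
    hits <- tibble::tibble(
      genome_id = "g", start = c(0L, 0L, 500L), end = c(30L, 30L, 530L),
      strand = c("+", "+", "-"),
      replicate_counts = list(tibble::tibble(replicate = "rep1", count = 3L),
                              tibble::tibble(replicate = "rep2", count = 1L),
                              tibble::tibble(replicate = "rep1", count = 2L)))
    bc <- bin_distribution(hits, g, binning_config(0.03), motif = "TAAA")
    expect_equal(bc$n_bins, 34)
    expect_equal(unique(bc$bins$bin_end[bc$bins$bin == 33]), 1000L)
    sums <- bc$bins |>
      dplyr::group_by(replicate) |>
      dplyr::summarise(s = sum(proportion))
    expect_true(all(abs(sums$s - 1) < 1e-12))
    # total binned count equals total mapped weight
    expect_equal(sum(bc$bins$count), 3)  # unique view: 3 hit/replicate pairs
    abs_bc <- bin_distribution(hits, g, view = "absolute")
    expect_equal(sum(abs_bc$bins$count), 6)
    # all hits at position 0 occupy bin 0 entirely
    h0 <- tibble::tibble(genome_id = "g", start = 0L, end = 30L,
                         strand = "+",
                         replicate_counts = list(
                           tibble::tibble(replicate = "rep1", count = 5L)))
    b0 <- bin_distribution(h0, g)
    expect_equal(sum(b0$bins$proportion[b0$bins$bin == 0]), 1)
  })
})

test_that("a planted positional hotspot is recovered by the smoothed curve", {
  phage <- generate_genome(20000, seed = 91, id = "phage")
  host <- generate_genome(9000, seed = 92, id = "host",
                          topology = "circular")
  truth <- simulate_acquisition(
    phage, host, default_loci(),
    acquisition_params(n_events = 250, self_fraction = 0,
                       pam_preference = 0, shared_pool_fraction = 0,
                       hotspots = list(c(center = 0.8, weight = 1,
                                         width = 0.04)),
                       uniform_weight = 0),
    seed = 93)
  hits <- dplyr::mutate(
    dplyr::filter(truth, locus_id == "II-C"),
    replicate_counts = purrr::map(replicate, ~tibble::tibble(
      replicate = .x, count = 1L)))
  bc <- bin_distribution(hits, phage)
  total <- bc$smoothed |>
    dplyr::group_by(bin) |>
    dplyr::summarise(s = sum(smoothed))
  argmax <- total$bin[which.max(total$s)]
  expect_lte(abs(argmax - floor(0.8 / 0.03)), 2)
})
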