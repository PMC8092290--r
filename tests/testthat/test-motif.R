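test_that("flank extraction follows guide-strand algebra on both strands", {
  withr::with_seed(61, {
    g <- toy_genome(rand_dna(500), id = "g")
    hits <- tibble::tibble(genome_id = "g", start = 100L, end = 130L,
                           strand = c("+", "-"))
    fl <- extract_flanks(hits, g)
    gs <- g$sequence
    expect_equal(fl$upstream[1], substr(gs, 86, 100))    # [85,100)
    expect_equal(fl$downstream[1], substr(gs, 131, 145)) # [130,145)
    expect_equal(fl$upstream[2], revcomp(substr(gs, 131, 145)))
    expect_equal(fl$downstream[2], revcomp(substr(gs, 86, 100)))
    expect_false(any(fl$upstream_truncated | fl$downstream_truncated))
    # linear-genome overhang is truncated and flagged
    edge <- extract_flanks(tibble::tibble(genome_id = "g", start = 3L,
                                          end = 33L, strand = "+"), g)
    expect_true(edge$upstream_truncated)
    expect_equal(nchar(edge$upstream), 3)
    # a circular genome wraps instead
    gc <- toy_genome(g$sequence, id = "gc", topology = "circular")
    edge2 <- extract_flanks(tibble::tibble(genome_id = "gc", start = 3L,
                                           end = 33L, strand = "+"), gc)
    expect_false(edge2$upstream_truncated)
    expect_equal(edge2$upstream,
                 paste0(substr(gs, 489, 500), substr(gs, 1, 3)))
  })
})

test_that("strand-flip involution leaves flank strings unchanged", {
  withr::with_seed(62, {
    g <- toy_genome(rand_dna(400), id = "g")
    glen <- 400L
    hits <- tibble::tibble(genome_id = "g",
                           start = sample(50:300, 20),
                           strand = sample(c("+", "-"), 20, replace = TRUE))
    hits$end <- hits$start + 30L
    fl <- extract_flanks(hits, g)
    gflip <- toy_genome(revcomp(g$sequence), id = "g")
    flipped <- tibble::tibble(genome_id = "g",
                              start = glen - hits$end,
                              end = glen - hits$start,
                              strand = ifelse(hits$strand == "+", "-", "+"))
    fl2 <- extract_flanks(flipped, gflip)
    expect_equal(fl2$upstream, fl$upstream)
    expect_equal(fl2$downstream, fl$downstream)
  })
})

test_that("SAM detection tests the exact motif offset per locus convention", {
  iic <- toy_locus_iic()
  vib <- toy_locus_vib()
  mk <- function(downstream, upstream = strrep("G", 15)) {
    tibble::tibble(upstream = upstream, downstream = downstream,
                   upstream_truncated = FALSE, downstream_truncated = FALSE)
  }
  # TAAA at positions 6-9 of the downstream flank
  expect_true(detect_sam(mk(paste0("GCGCG", "TAAA", "ACGTAC")), iic)$sam)
  # TAAA shifted to 5-8: offset matters
  expect_false(detect_sam(mk(paste0("GCGC", "TAAA", "ACGTACG")), iic)$sam)
  # VI-B: TTTA at upstream positions 7-10
  expect_true(detect_sam(mk(strrep("G", 15),
                            paste0("CCGCGC", "TTTA", "GCGCG")), vib)$sam)
  # truncated relevant flank is indeterminate
  tr <- mk(paste0("GCGCG", "TAAA", "ACGTAC"))
  tr$downstream_truncated <- TRUE
  expect_true(is.na(detect_sam(tr, iic)$sam))
})

test_that("the two locus conventions are strand-flipped views of one genomic motif", {
  withr::with_seed(63, {
    g <- toy_genome(rand_dna(400, gc = 0.32), id = "g")
    iic <- toy_locus_iic()
    vib <- toy_locus_vib()
    L <- 30L
    starts <- 15:(400 - L - 15)
    for (strand in c("+", "-")) {
      hits <- tibble::tibble(genome_id = "g", start = starts,
                             end = starts + L, strand = strand)
      a <- detect_sam(extract_flanks(hits, g), iic)$sam
      flipped <- dplyr::mutate(hits,
                               strand = ifelse(strand == "+", "-", "+"))
      b <- detect_sam(extract_flanks(flipped, g), vib)$sam
      expect_equal(a, b)
    }
  })
})

test_that("position frequency matrices report counts and information content", {
  fl <- tibble::tibble(upstream = strrep("G", 15),
                       downstream = rep("ACGTATAAAGGGTTT", 10),
                       upstream_truncated = FALSE,
                       downstream_truncated = FALSE)
  pfm <- build_pfm(fl, "downstream")
  expect_equal(pfm$n_sequences, 10)
  expect_equal(unname(colSums(pfm$counts)), rep(10, 15))
  expect_equal(pfm$information, rep(2, 15))
  # uniform columns carry zero information
  fl4 <- tibble::tibble(upstream = strrep("G", 15),
                        downstream = vapply(c("A", "C", "G", "T"), strrep,
                                            "", 15),
                        upstream_truncated = FALSE,
                        downstream_truncated = FALSE)
  pfm4 <- build_pfm(fl4, "downstream")
  expect_equal(pfm4$information, rep(0, 15))
  expect_error(build_pfm(fl[0, ], "downstream"),
               class = "spaceracq_parameter_error")
  td <- tidy(pfm)
  expect_equal(sum(td$count), 150)
})

test_that("SAM-planted events produce a TAAA-consensus PFM at offsets 6-9", {
  phage <- generate_genome(10000, seed = 71, id = "phage")
  host <- generate_genome(10000, seed = 72, id = "host",
                          topology = "circular")
  truth <- simulate_acquisition(phage, host, default_loci(),
                                acquisition_params(n_events = 120,
                                                   pam_preference = 1,
                                                   self_fraction = 0,
                                                   shared_pool_fraction = 0),
                                seed = 73)
  iic <- dplyr::filter(truth, locus_id == "II-C")
  fl <- extract_flanks(dplyr::mutate(iic, genome_id = "phage"), phage)
  pfm <- build_pfm(fl, "downstream")
  cons <- rownames(pfm$counts)[apply(pfm$counts, 2, which.max)]
  expect_equal(cons[6:9], c("T", "A", "A", "A"))
  expect_true(all(pfm$information[6:9] > 1.5))
})

test_that("motif counting agrees with hand enumeration and regex oracle", {
  g <- toy_genome("TAAATTTA", id = "tiny")
  res <- count_motif(g, "TAAA", "whole_genome")
  expect_equal(res$count_total, 2)
  expect_equal(res$count_coding_strand, 1)   # forward occurrence at 0
  expect_equal(res$count_template_strand, 1) # TTTA at 4 on the reverse
  # zero-A genome has no TAAA on either strand
  expect_equal(count_motif(toy_genome(strrep("GC", 50), id = "gc"),
                           "TAAA", "whole_genome")$count_total, 0)
  # one forward CDS covering everything: cds_only equals whole_genome
  withr::with_seed(64, {
    gs <- rand_dna(2000, gc = 0.32)
    feats <- tibble::tibble(feature_id = "f", start = 0L, end = 2000L,
                            strand = "+")
    gg <- toy_genome(gs, id = "g", features = feats)
    whole <- count_motif(gg, "TAAA", "whole_genome")
    cds <- count_motif(gg, "TAAA", "cds_only")
    # boundary effect only: occurrences must fit inside the feature
    expect_equal(cds$count_total, whole$count_total)
    expect_equal(cds$count_coding_strand, whole$count_coding_strand)
    # regex enumeration oracle on random genomes and IUPAC motifs
    for (m in c("TAAA", "AA", "TWAA", "RCGY")) {
      o <- oracle_count_motif(gs, m)
      r <- count_motif(gg, m, "whole_genome")
      expect_equal(r$count_coding_strand, unname(o["forward"]))
      expect_equal(r$count_template_strand, unname(o["reverse"]))
    }
  })
  # overlapping occurrences all count
  expect_equal(count_motif(toy_genome("AAAAA", id = "a"), "AA",
                           "whole_genome")$count_coding_strand, 4)
  expect_error(count_motif(g, "TAXA"), class = "spaceracq_parameter_error")
})

test_that("cds_only counting labels strands per feature orientation", {
  # TAAA inside a '-' CDS is a template-strand occurrence of the gene
  feats <- tibble::tibble(feature_id = c("plus", "minus"),
                          start = c(0L, 20L), end = c(12L, 40L),
                          strand = c("+", "-"))
  gs <- paste0("GGTAAAGGGGGG", "GGGGGGGG", "GGTAAAGGGGGGGGGGGGGG")
  g <- toy_genome(gs, id = "g", features = feats)
  res <- count_motif(g, "TAAA", "cds_only")
  expect_equal(res$count_total, 2)
  expect_equal(res$count_coding_strand, 1)
  expect_equal(res$count_template_strand, 1)
})

test_that("off-canonical SAM offsets surface in the offset histogram", {
  fl <- tibble::tibble(
    upstream = strrep("G", 15),
    downstream = c("GCGCGTAAAACGTAC",   # canonical offset 6
                   "GCGCTAAAGGGGGGG",   # shifted offset 5
                   "GGGGGGGGGGGGGGG"),
    upstream_truncated = FALSE, downstream_truncated = FALSE)
  h <- sam_offset_histogram(fl, "TAAA", "downstream")
  expect_equal(h$offset, c(5L, 6L))
  expect_equal(h$count, c(1L, 1L))
})
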