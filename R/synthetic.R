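#' CRISPR locus model
#'
#' Describes one CRISPR locus: its repeat, leader, transcription direction
#' and amplicon read orientation. The transcription direction alone
#' determines crRNA orientation and hence which side of a protospacer
#' carries the spacer acquisition motif (SAM): loci transcribed from within
#' the array toward the leader (subtype II-C style) read the SAM as
#' `NNNNNTAAA` downstream of the guide, while leader-to-array loci
#' (subtype VI-B style) see the reverse-complement placement `TTTANNNNN`
#' upstream.
#'
#' @param locus_id Label, e.g. `"II-C"` or `"VI-B"`.
#' @param repeat_seq Repeat sequence (>= 20 bp so extraction anchors fit).
#' @param leader Leader sequence (AT-rich region at the variable end).
#' @param transcription_direction `"array_to_leader"` (II-C style) or
#'   `"leader_to_array"` (VI-B style).
#' @param read_orientation Orientation of amplicon reads relative to the
#'   crRNA: `"as_crRNA"` or `"reverse_complement_of_crRNA"`.
#' @param preexisting_spacers Optional character vector of old spacers
#'   (used as downstream filler context when emitting reads).
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(locus_id, repeat_seq, leader,
                        transcription_direction = c("array_to_leader",
                                                    "leader_to_array"),
                        read_orientation = c("as_crRNA",
                                             "reverse_complement_of_crRNA"),
                        preexisting_spacers = character()) {
  transcription_direction <- match.arg(transcription_direction)
  read_orientation <- match.arg(read_orientation)
  repeat_seq <- toupper(repeat_seq)
  leader <- toupper(leader)
  if (nchar(repeat_seq) < 20)
    abort_param("locus repeat must be at least 20 bp")
  check_dna(repeat_seq, "repeat_seq", allow_n = FALSE)
  check_dna(leader, "leader", allow_n = FALSE)
  structure(list(locus_id = locus_id, repeat_seq = repeat_seq,
                 leader = leader,
                 transcription_direction = transcription_direction,
                 read_orientation = read_orientation,
                 preexisting_spacers = toupper(preexisting_spacers)),
            class = "locus_model")
}

# SAM side implied by the transcription direction
sam_convention <- function(locus) {
  if (locus$transcription_direction == "array_to_leader")
    "downstream_taaa" else "upstream_ttta"
}

#' Default dual-locus configuration
#'
#' A II-C-style locus (array-to-leader transcription, downstream SAM) and
#' a VI-B-style locus (leader-to-array, upstream SAM), with distinct 36-bp
#' repeats and AT-rich leaders.
#'
#' @return Named list of two [locus_model()]s; the first is the locus that
#'   owns the adaptation machinery (shared-pool events are copied from it).
#' @export
default_loci <- function() {
  list(
    `II-C` = locus_model(
      "II-C",
      repeat_seq = "GTTGTAGCTCCCTTTCTCATTTCGCAGTGCTACAAT",
      leader = "ATTTAAAATTTTCATAAATAAGTATTAAACTTTAAAATAGATTT",
      transcription_direction = "array_to_leader",
      read_orientation = "as_crRNA"),
    `VI-B` = locus_model(
      "VI-B",
      repeat_seq = "GTTGGAACTAAGGTAAAATTGAAGGAATTAAGCAAC",
      leader = "TATTTTTAAAGTATTTTAAATAAGTAAAATATTTAAAGTTTAAT",
      transcription_direction = "leader_to_array",
      read_orientation = "as_crRNA"))
}

#' Acquisition simulation parameters
#'
#' Defaults describe the emulated study conditions: SAM preference 0.63
#' (the fraction of phage-targeting II-C protospacers carrying the
#' canonical motif), no strand bias, a 5% self-targeting fraction, spacer
#' length mass concentrated at 30 bp, a positional hotspot at 0.85 of the
#' genome (the end opposite the phage morphogenesis genes) and a shared
#' prespacer pool fraction of 0.6 so that inter-locus sharing at the level
#' observed between the two arrays is recoverable.
#'
#' @param n_events Acquisition events per locus; either a single count for
#'   every locus or one count per locus (recycled in locus order).
#' @param n_replicates Number of biological replicates to simulate.
#' @param pam_preference Probability an event is sampled SAM-adjacent.
#' @param sam_motif IUPAC motif, leading `N`s giving the spacer-to-core
#'   offset (default `NNNNNTAAA`).
#' @param spacer_length_probs Named numeric over lengths 27..32.
#' @param strand_bias Probability the crRNA matches the forward strand.
#' @param self_fraction Probability an event targets the host genome.
#' @param hotspots List of `c(center, weight, width)` in genome-fraction
#'   space (truncated Gaussians).
#' @param uniform_weight Weight of the uniform positional component.
#' @param shared_pool_fraction Probability that an event in a non-first
#'   locus reuses a protospacer already sampled by the first locus.
#' @param copy_geom_prob Geometric success probability for per-event copy
#'   counts (`copies = 1 + rgeom(copy_geom_prob)`).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(n_events = 500L,
                               n_replicates = 3L,
                               pam_preference = 0.63,
                               sam_motif = "NNNNNTAAA",
                               spacer_length_probs = c(`27` = 0.03,
                                                       `28` = 0.05,
                                                       `29` = 0.10,
                                                       `30` = 0.62,
                                                       `31` = 0.12,
                                                       `32` = 0.08),
                               strand_bias = 0.5,
                               self_fraction = 0.05,
                               hotspots = list(c(center = 0.85, weight = 0.6,
                                                 width = 0.08)),
                               uniform_weight = 0.4,
                               shared_pool_fraction = 0.6,
                               copy_geom_prob = 0.6) {
  check_prob(pam_preference, "pam_preference")
  check_prob(strand_bias, "strand_bias")
  check_prob(self_fraction, "self_fraction")
  check_prob(shared_pool_fraction, "shared_pool_fraction")
  check_prob(copy_geom_prob, "copy_geom_prob")
  lens <- as.integer(names(spacer_length_probs))
  if (any(is.na(lens)) || any(lens < 27L | lens > 32L))
    abort_param("spacer_length_probs must be named with lengths in 27..32")
  if (any(spacer_length_probs < 0) || sum(spacer_length_probs) <= 0)
    abort_param("spacer_length_probs must be non-negative with positive sum")
  w <- c(vapply(hotspots, `[[`, 0, "weight"), uniform_weight)
  if (any(w < 0) || sum(w) <= 0)
    abort_param("hotspot/uniform weights must be non-negative, positive sum")
  if (!grepl("^N+[ACGT]+$", sam_motif))
    abort_param("sam_motif must be leading Ns followed by a literal core")
  structure(list(n_events = as.integer(n_events),
                 n_replicates = as.integer(n_replicates),
                 pam_preference = pam_preference, sam_motif = sam_motif,
                 spacer_length_probs = spacer_length_probs / sum(spacer_length_probs),
                 strand_bias = strand_bias, self_fraction = self_fraction,
                 hotspots = hotspots, uniform_weight = uniform_weight,
                 shared_pool_fraction = shared_pool_fraction,
                 copy_geom_prob = copy_geom_prob),
            class = "acquisition_params")
}

#' Sequencing error model for amplicon reads
#'
#' Ion-Torrent-like error profile: substitutions plus indels whose rate is
#' multiplied inside homopolymer runs.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-base rates
#'   (each in `[0, 0.2]`).
#' @param homopolymer_indel_multiplier Indel rate multiplier when a base
#'   repeats its predecessor.
#' @param quality_mean,quality_sd Gaussian Phred quality per base, clamped
#'   to `[2, 41]`.
#' @return An object of class `read_error_model`.
#' @export
read_error_model <- function(substitution_rate = 0.005,
                             insertion_rate = 0.001,
                             deletion_rate = 0.002,
                             homopolymer_indel_multiplier = 3,
                             quality_mean = 32, quality_sd = 3) {
  for (r in c(substitution_rate, insertion_rate, deletion_rate))
    if (r < 0 || r > 0.2) abort_param("error rates must lie in [0, 0.2]")
  if (quality_mean < 10 || quality_mean > 41)
    abort_param("quality_mean must lie in [10, 41]")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 homopolymer_indel_multiplier = homopolymer_indel_multiplier,
                 quality_mean = quality_mean, quality_sd = quality_sd),
            class = "read_error_model")
}

#' Generate a random annotated genome
#'
#' Bases are drawn i.i.d. at the requested GC fraction; non-overlapping
#' ORFs are laid down on alternating random strands with intergenic gaps
#' sized so that total CDS span tracks `orf_density`.
#'
#' @param length Genome length (>= 1000).
#' @param gc_fraction GC content (default 0.32, AT-rich like the
#'   *Flavobacterium* system and its phage).
#' @param orf_density Target fraction of the genome covered by CDS
#'   (must be <= 0.95).
#' @param seed Integer seed; output is deterministic given the arguments.
#' @param id Genome id.
#' @param topology `"linear"` or `"circular"`.
#' @return A [genome_record()] with features.
#' @export
generate_genome <- function(length, gc_fraction = 0.32, orf_density = 0.9,
                            seed = 1L, id = "genome",
                            topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (length < 1000) abort_param("genome length must be >= 1000")
  if (orf_density > 0.95) abort_param("orf_density must be <= 0.95")
  check_prob(gc_fraction, "gc_fraction")
  withr::with_seed(derive_seed(seed, 1L), {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
                 collapse = "")
    feats <- empty_features()
    if (orf_density > 0) {
      starts <- integer()
      ends <- integer()
      strands <- character()
      pos <- sample(50:300, 1)
      while (pos < length - 300) {
        glen <- 3L * sample(100:400, 1)
        if (pos + glen > length) glen <- (length - pos) %/% 3L * 3L
        if (glen < 150) break
        starts <- c(starts, pos)
        ends <- c(ends, pos + glen)
        strands <- c(strands, sample(c("+", "-"), 1))
        gap <- max(3L, round(glen * (1 - orf_density) / orf_density))
        pos <- pos + glen + gap
      }
      feats <- tibble(feature_id = sprintf("%s_orf%03d", id, seq_along(starts)),
                      start = as.integer(starts), end = as.integer(ends),
                      strand = strands)
    }
    genome_record(id, seq, topology, feats)
  })
}

# All genomic placements of a protospacer of length L whose SAM test is
# true under `convention`. The two conventions give the same intervals on
# opposite strands (the shared-SAM geometry).
sam_placements <- function(genome, spacer_length,
                           sam_motif = "NNNNNTAAA",
                           convention = c("downstream_taaa", "upstream_ttta")) {
  convention <- match.arg(convention)
  core <- sub("^N+", "", sam_motif)
  offset <- nchar(sam_motif) - nchar(core)  # Ns between protospacer and core
  glen <- nchar(genome$sequence)
  subj <- Biostrings::DNAString(genome$sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(core), subj, fixed = "subject")) - 1L
  rc <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(core)), subj,
    fixed = "subject")) - 1L
  L <- spacer_length
  k <- nchar(core)
  # '+' guide with downstream core: core at [t, t+k) => protospacer end = t - offset
  plus <- tibble(start = fwd - offset - L, end = fwd - offset, strand = "+")
  # '-' guide with downstream core: revcomp(core) at [q, q+k) on '+',
  # protospacer start = q + k + offset
  minus <- tibble(start = rc + k + offset, end = rc + k + offset + L,
                  strand = "-")
  pl <- bind_rows(plus, minus)
  # keep placements whose protospacer and full 15-bp flanks are in bounds
  pl <- filter(pl, .data$start >= 15, .data$end <= glen - 15)
  if (convention == "upstream_ttta")
    pl$strand <- ifelse(pl$strand == "+", "-", "+")
  pl
}

# realised SAM adjacency of one protospacer under a locus convention
sam_flag_at <- function(genome, start, end, strand, convention,
                        sam_motif = "NNNNNTAAA") {
  core <- sub("^N+", "", sam_motif)
  offset <- nchar(sam_motif) - nchar(core)
  k <- nchar(core)
  if (convention == "downstream_taaa") {
    if (strand == "+") {
      win <- genome_subseq(genome, end + offset, end + offset + k)
      if (win$truncated || nchar(win$sequence) < k) return(NA)
      win$sequence == core
    } else {
      win <- genome_subseq(genome, start - offset - k, start - offset)
      if (win$truncated || nchar(win$sequence) < k) return(NA)
      win$sequence == revcomp(core)
    }
  } else {
    # upstream TTTA == downstream convention evaluated on the other strand
    sam_flag_at(genome, start, end, if (strand == "+") "-" else "+",
                "downstream_taaa", sam_motif)
  }
}

hotspot_density <- function(frac, params) {
  dens <- rep(params$uniform_weight, length(frac))
  for (h in params$hotspots)
    dens <- dens + h[["weight"]] * stats::dnorm(frac, h[["center"]], h[["width"]])
  dens
}

sample_hotspot_start <- function(n, glen, L, params) {
  comp_w <- c(vapply(params$hotspots, `[[`, 0, "weight"), params$uniform_weight)
  comp <- sample.int(length(comp_w), n, replace = TRUE, prob = comp_w)
  starts <- integer(n)
  for (i in seq_len(n)) {
    if (comp[i] > length(params$hotspots)) {
      starts[i] <- sample.int(glen - L + 1L, 1L) - 1L
    } else {
      h <- params$hotspots[[comp[i]]]
      repeat {
        s <- round(rnorm(1, h[["center"]] * glen, h[["width"]] * glen))
        if (s >= 0 && s <= glen - L) break
      }
      starts[i] <- s
    }
  }
  starts
}

#' Simulate spacer acquisition events with ground truth
#'
#' Each event picks a target genome (host with probability
#' `self_fraction`), a spacer length, a position (hotspot mixture), a
#' crRNA strand (`strand_bias`) and SAM adjacency (`pam_preference`,
#' planted in the acquiring locus's own convention). In every locus after
#' the first, an event instead reuses a protospacer already sampled by the
#' first locus with probability `shared_pool_fraction`, copying its
#' interval and crRNA strand so the spacer sequences are identical — the
#' in-trans shared prespacer pool. The recorded `sam_adjacent` flag is the
#' realised flank state (planted or incidental), so downstream estimates
#' can be compared against it exactly.
#'
#' @param phage,host [genome_record()]s.
#' @param loci Named list of [locus_model()]s; the first owns the shared
#'   pool.
#' @param params [acquisition_params()].
#' @param seed Integer seed.
#' @return Ground-truth tibble: `event_id`, `locus_id`, `replicate`,
#'   `genome_id`, `target_class`, `start`, `end`, `strand`,
#'   `sam_adjacent`, `spacer`, `copies`.
#' @export
simulate_acquisition <- function(phage, host, loci, params, seed = 1L) {
  stopifnot(inherits(params, "acquisition_params"))
  lens <- as.integer(names(params$spacer_length_probs))
  genomes <- list(phage = phage, self = host)
  withr::with_seed(derive_seed(seed, 2L), {
    placements <- list()  # memo: convention|class|L
    get_placements <- function(cls, convention, L) {
      key <- paste(cls, convention, L, sep = "|")
      if (is.null(placements[[key]])) {
        placements[[key]] <<- sam_placements(genomes[[cls]], L,
                                             params$sam_motif, convention)
      }
      placements[[key]]
    }
    draw_event <- function(locus) {
      cls <- if (runif(1) < params$self_fraction) "self" else "phage"
      g <- genomes[[cls]]
      glen <- nchar(g$sequence)
      L <- sample(lens, 1, prob = params$spacer_length_probs)
      sam_wanted <- runif(1) < params$pam_preference
      conv <- sam_convention(locus)
      if (sam_wanted) {
        pl <- get_placements(cls, conv, L)
        if (nrow(pl) == 0)
          abort_param(sprintf(
            "pam_preference > 0 but no SAM placements of length %d on %s",
            L, g$id))
        w <- hotspot_density((pl$start + pl$end) / 2 / glen, params) *
          ifelse(pl$strand == "+", params$strand_bias, 1 - params$strand_bias)
        if (sum(w) <= 0) w <- rep(1, nrow(pl))
        row <- pl[sample.int(nrow(pl), 1, prob = w), ]
        start <- row$start; end <- row$end; strand <- row$strand
      } else {
        strand <- if (runif(1) < params$strand_bias) "+" else "-"
        start <- sample_hotspot_start(1L, glen, L, params)
        end <- start + L
      }
      fwd <- substr(g$sequence, start + 1L, end)
      list(target_class = cls, genome_id = g$id, start = start, end = end,
           strand = strand,
           spacer = if (strand == "+") fwd else revcomp(fwd),
           sam_adjacent = sam_flag_at(g, start, end, strand, conv,
                                      params$sam_motif))
    }
    rows <- list()
    donor_events <- list()
    ev <- 0L
    n_events <- rep_len(params$n_events, length(loci))
    for (li in seq_along(loci)) {
      locus <- loci[[li]]
      conv <- sam_convention(locus)
      for (k in seq_len(n_events[li])) {
        ev <- ev + 1L
        rep_id <- paste0("rep", sample.int(params$n_replicates, 1))
        shared <- li > 1L && length(donor_events) > 0 &&
          runif(1) < params$shared_pool_fraction
        if (shared) {
          src <- donor_events[[sample.int(length(donor_events), 1)]]
          e <- src
          e$sam_adjacent <- sam_flag_at(genomes[[src$target_class]],
                                        src$start, src$end, src$strand,
                                        conv, params$sam_motif)
        } else {
          e <- draw_event(locus)
        }
        if (li == 1L) donor_events[[length(donor_events) + 1L]] <- e
        rows[[ev]] <- tibble(
          event_id = sprintf("ev%05d", ev), locus_id = locus$locus_id,
          replicate = rep_id, genome_id = e$genome_id,
          target_class = e$target_class, start = e$start, end = e$end,
          strand = e$strand, sam_adjacent = e$sam_adjacent,
          spacer = e$spacer,
          copies = 1L + rgeom(1, params$copy_geom_prob))
      }
    }
    bind_rows(rows)
  })
}

mutate_read <- function(seq, em) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  prev <- c("", bases[-n])
  hp <- bases == prev
  mult <- ifelse(hp, em$homopolymer_indel_multiplier, 1)
  out <- character(0)
  alt <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    if (runif(1) < em$deletion_rate * mult[i]) next
    b <- bases[i]
    if (runif(1) < em$substitution_rate)
      b <- sample(setdiff(alt, b), 1)
    out <- c(out, b)
    if (runif(1) < em$insertion_rate * mult[i])
      out <- c(out, sample(alt, 1))
  }
  paste(out, collapse = "")
}

#' Emit error-bearing amplicon reads from ground truth
#'
#' Each read carries the full first repeat, the new spacer, the complete
#' next repeat and downstream filler (an old spacer where the locus has
#' one), preceded by leader-side primer context, in the orientation the
#' locus's sequencing primer implies. Reads are emitted already
#' primer-trimmed.
#'
#' @param truth Ground-truth tibble from [simulate_acquisition()].
#' @param loci Named list of [locus_model()]s (names matching
#'   `truth$locus_id`).
#' @param depth_per_event Reads per truth-event copy.
#' @param error_model [read_error_model()].
#' @param seed Integer seed; output is byte-deterministic given inputs.
#' @return Tibble `read_id`, `locus_id`, `replicate`, `sequence`,
#'   `quality` (Phred+33 string).
#' @export
emit_amplicon_reads <- function(truth, loci, depth_per_event = 3L,
                                error_model = read_error_model(),
                                seed = 1L) {
  if (depth_per_event < 1) abort_param("depth_per_event must be >= 1")
  em <- error_model
  loci_by_id <- setNames(loci, vapply(loci, `[[`, "", "locus_id"))
  withr::with_seed(derive_seed(seed, 3L), {
    zero_err <- em$substitution_rate == 0 && em$insertion_rate == 0 &&
      em$deletion_rate == 0
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      locus <- loci_by_id[[tr$locus_id]]
      filler <- if (length(locus$preexisting_spacers))
        locus$preexisting_spacers[[1]]
      else paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                        prob = c(.34, .16, .16, .34)), collapse = "")
      amp <- paste0(substr(locus$leader, nchar(locus$leader) - 19,
                           nchar(locus$leader)),
                    locus$repeat_seq, tr$spacer, locus$repeat_seq, filler)
      if (locus$read_orientation == "reverse_complement_of_crRNA")
        amp <- revcomp(amp)
      n_reads <- depth_per_event * tr$copies
      seqs <- character(n_reads)
      quals <- character(n_reads)
      for (j in seq_len(n_reads)) {
        s <- if (zero_err) amp else mutate_read(amp, em)
        q <- pmin(41L, pmax(2L, round(rnorm(nchar(s), em$quality_mean,
                                            em$quality_sd))))
        seqs[j] <- s
        quals[j] <- intToUtf8(q + 33L)
      }
      rows[[i]] <- tibble(
        read_id = sprintf("%s:%s:%s", tr$event_id, tr$locus_id, seq_len(n_reads)),
        locus_id = tr$locus_id, replicate = tr$replicate,
        sequence = seqs, quality = quals)
    }
    bind_rows(rows)
  })
}

#' Write simulated data to disk (FASTQ per locus/replicate + truth TSV)
#'
#' @param truth Ground-truth tibble.
#' @param reads Read tibble from [emit_amplicon_reads()].
#' @param dir Output directory (created if needed).
#' @return Tibble of written FASTQ paths with locus/replicate.
#' @export
write_simulation <- function(truth, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  groups <- dplyr::group_split(group_by(reads, .data$locus_id, .data$replicate))
  purrr::map_dfr(groups, function(g) {
    path <- file.path(dir, sprintf("%s_%s.fastq",
                                   gsub("[^A-Za-z0-9]", "", g$locus_id[1]),
                                   g$replicate[1]))
    write_fastq(g, path)
    tibble(locus_id = g$locus_id[1], replicate = g$replicate[1], path = path)
  })
}
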