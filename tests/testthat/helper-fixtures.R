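# Small constructed fixtures shared across test files.

toy_locus_iic <- function() {
  locus_model("II-C",
              repeat_seq = "GTTGTAGCTCCCTTTCTCATTTCGCAGTGCTACAAT",
              leader = "ATTTAAAATTTTCATAAATAAGTATTAAACTTTAAA",
              transcription_direction = "array_to_leader")
}

toy_locus_vib <- function(orientation = "as_crRNA") {
  locus_model("VI-B",
              repeat_seq = "GTTGGAACTAAGGTAAAATTGAAGGAATTAAGCAAC",
              leader = "TATTTTTAAAGTATTTTAAATAAGTAAAATATTTAA",
              transcription_direction = "leader_to_array",
              read_orientation = orientation)
}

toy_genome <- function(seq, id = "toy", topology = "linear",
                       features = NULL) {
  genome_record(id, seq, topology, features)
}

# a perfect amplicon read for a locus: leader context + repeat + spacer +
# full second repeat + filler, with flat quality
perfect_read <- function(spacer, locus, q = 40L, filler = NULL) {
  if (is.null(filler)) filler <- strrep("ACGT", 8)
  amp <- paste0(substr(locus$leader, nchar(locus$leader) - 19,
                       nchar(locus$leader)),
                locus$repeat_seq, spacer, locus$repeat_seq, filler)
  if (locus$read_orientation == "reverse_complement_of_crRNA")
    amp <- revcomp(amp)
  list(sequence = amp, quality = rep(q, nchar(amp)),
       quality_string = intToUtf8(rep(q + 33L, nchar(amp))))
}

reads_tibble <- function(spacers, locus, replicate = "rep1", q = 40L) {
  rows <- lapply(seq_along(spacers), function(i) {
    r <- perfect_read(spacers[i], locus, q)
    tibble::tibble(read_id = sprintf("r%03d", i), sequence = r$sequence,
                   quality = r$quality_string, replicate = replicate)
  })
  dplyr::bind_rows(rows)
}

# deterministic substitution at position p (A->C->G->T->A)
flip_base <- function(s, p) {
  chartr("ACGT", "CGTA", substr(s, p, p))
}

# genome free of a given core motif on both strands (rejection sampling)
genome_without <- function(len, cores = c("TAAA", "TTTA"), gc = 0.5,
                           max_tries = 200) {
  for (i in seq_len(max_tries)) {
    s <- rand_dna(len, gc)
    if (!any(vapply(cores, grepl, TRUE, x = s, fixed = TRUE))) return(s)
  }
  stop("could not build a motif-free genome")
}

small_dataset <- function(seed = 11, n_events = 80, ...,
                          phage_length = 12000, host_length = 16000) {
  simulate_dataset(seed = seed,
                   params = acquisition_params(n_events = n_events, ...),
                   phage_length = phage_length, host_length = host_length)
}
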