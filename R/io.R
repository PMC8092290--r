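#' Genome record
#'
#' A reference sequence with strand-aware ORF features. Coordinates inside
#' the package are uniformly 0-based half-open; conversion from the 1-based
#' inclusive conventions of GFF3/GenBank happens at the I/O boundary only.
#'
#' @param id Sequence identifier.
#' @param sequence DNA string over `A/C/G/T/N` (upper-cased; `U` mapped
#'   to `T`).
#' @param topology `"linear"` (physical ends defined, e.g. the phage) or
#'   `"circular"` (host chromosome).
#' @param features Tibble of ORF features with columns `feature_id`,
#'   `start`, `end` (0-based half-open) and `strand` (`"+"`/`"-"`), or
#'   `NULL`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular"),
                          features = NULL) {
  topology <- match.arg(topology)
  sequence <- chartr("u", "t", sequence)
  sequence <- chartr("U", "T", toupper(sequence))
  if (!nzchar(sequence)) abort_format(sprintf("genome '%s' has an empty sequence", id))
  check_dna(sequence, sprintf("genome '%s'", id))
  features <- validate_features(features %||% empty_features(), nchar(sequence), id)
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features),
            class = "genome_record")
}

empty_features <- function() {
  tibble(feature_id = character(), start = integer(), end = integer(),
         strand = character())
}

validate_features <- function(features, genome_len, id = "?") {
  features <- as_tibble(features)
  need <- c("feature_id", "start", "end", "strand")
  if (!all(need %in% names(features)))
    abort_format(sprintf("features of '%s' need columns %s", id,
                         paste(need, collapse = ", ")))
  if (any(features$end <= features$start))
    abort_format(sprintf("features of '%s' contain end <= start", id))
  if (!all(features$strand %in% c("+", "-")))
    abort_format(sprintf("features of '%s' have undefined strand", id))
  if (nrow(features) && (min(features$start) < 0 || max(features$end) > genome_len))
    abort_format(sprintf("features of '%s' fall outside [0, genome length)", id))
  features[need]
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, %d ORF feature(s)\n",
              x$id, format(nchar(x$sequence), big.mark = ","), x$topology,
              nrow(x$features)))
  invisible(x)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @param topology Topology assigned to every record in the file.
#' @return Named list of [genome_record()] objects (no features; attach
#'   those with [read_orf_features()]).
#' @export
read_genome_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_format(sprintf(
                    "malformed FASTA in %s: %s", path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    abort_format(sprintf("duplicate FASTA ids in %s: %s", path,
                         paste(dup, collapse = ", ")))
  if (any(Biostrings::width(set) == 0)) {
    bad <- ids[Biostrings::width(set) == 0][1]
    abort_format(sprintf("empty sequence for FASTA record '%s' in %s", bad, path))
  }
  out <- purrr::map2(ids, as.character(set),
                     function(id, s) genome_record(id, s, topology))
  setNames(out, ids)
}

#' Write genome records (or any named sequences) to FASTA
#'
#' @param x Named list of [genome_record()]s, or a named character vector
#'   of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.list(x) && length(x) && inherits(x[[1]], "genome_record"))
    x <- setNames(vapply(x, `[[`, "", "sequence"), vapply(x, `[[`, "", "id"))
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read amplicon reads from FASTQ (Phred+33)
#'
#' Reads 4-line FASTQ records in bounded-size chunks so arbitrarily large
#' files never have to fit in memory at once; records are validated as
#' they stream past.
#'
#' @param path FASTQ file.
#' @param chunk_records Number of records held per chunk while streaming.
#' @param callback Optional function applied to each chunk tibble; when
#'   supplied the function returns the list of callback results instead of
#'   the assembled tibble.
#' @return Tibble with columns `read_id`, `sequence`, `quality` (Phred+33
#'   string), unless `callback` is given.
#' @export
read_amplicon_fastq <- function(path, chunk_records = 50000L, callback = NULL) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  con <- file(path, open = "r")
  on.exit(close(con))
  chunks <- list()
  repeat {
    lines <- readLines(con, n = 4L * chunk_records)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L)
      abort_format(sprintf("truncated FASTQ record at end of %s", path))
    ids <- lines[seq(1, length(lines), by = 4)]
    seqs <- lines[seq(2, length(lines), by = 4)]
    plus <- lines[seq(3, length(lines), by = 4)]
    quals <- lines[seq(4, length(lines), by = 4)]
    if (any(substr(ids, 1, 1) != "@"))
      abort_format(sprintf("FASTQ header not starting with '@' in %s", path))
    if (any(substr(plus, 1, 1) != "+"))
      abort_format(sprintf("FASTQ separator line not starting with '+' in %s", path))
    ids <- sub("^@", "", sub("\\s.*$", "", ids))
    bad <- nchar(seqs) != nchar(quals)
    if (any(bad))
      abort_format(sprintf("sequence/quality length mismatch for record '%s' in %s",
                           ids[which(bad)[1]], path))
    tb <- tibble(read_id = ids, sequence = toupper(seqs), quality = quals)
    chunks[[length(chunks) + 1L]] <- if (is.null(callback)) tb else callback(tb)
  }
  if (is.null(callback)) {
    if (!length(chunks))
      return(tibble(read_id = character(), sequence = character(),
                    quality = character()))
    bind_rows(chunks)
  } else {
    chunks
  }
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param quality Character vector of quality strings.
#' @return List of integer vectors (scores in `[0, 93]`).
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) {
    s <- utf8ToInt(q) - 33L
    if (length(s) && (min(s) < 0 || max(s) > 93))
      abort_format("quality characters outside the Phred+33 range")
    s
  })
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    abort_format("sequence/quality length mismatch in reads to be written")
  con <- file(path, open = "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con)
  invisible(path)
}

#' Read ORF features, converting to 0-based half-open coordinates
#'
#' Only CDS-type features are retained. The `gff3` dialect is parsed with
#' rtracklayer; `genbank_table` expects a flat tab-separated CDS table with
#' columns `id`, `start`, `end`, `strand` (1-based inclusive, as exported
#' from a GenBank feature table).
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"genbank_table"`.
#' @return Tibble with `feature_id`, `start`, `end`, `strand`.
#' @export
read_orf_features <- function(path, dialect = c("gff3", "genbank_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  if (dialect == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) abort_format(sprintf(
                     "malformed GFF3 in %s: %s", path, conditionMessage(e))))
    gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*"))
      abort_format(sprintf("CDS with undefined strand in %s", path))
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      paste0("cds_", seq_along(gr))
    ids[is.na(ids)] <- paste0("cds_", which(is.na(ids)))
    feats <- tibble(feature_id = ids,
                    start = as.integer(BiocGenerics::start(gr)) - 1L,
                    end = as.integer(BiocGenerics::end(gr)),
                    strand = strand)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "start", "end", "strand")
    if (!all(need %in% names(tab)))
      abort_format(sprintf("genbank_table %s needs columns %s", path,
                           paste(need, collapse = ", ")))
    feats <- tibble(feature_id = as.character(tab$id),
                    start = as.integer(tab$start) - 1L,
                    end = as.integer(tab$end),
                    strand = as.character(tab$strand))
  }
  if (any(feats$end <= feats$start))
    abort_format(sprintf("feature with end < start in %s", path))
  if (!all(feats$strand %in% c("+", "-")))
    abort_format(sprintf("feature with unknown strand in %s", path))
  feats
}

#' Write ORF features as GFF3
#'
#' @param features Feature tibble (0-based half-open).
#' @param genome_id Sequence id for column 1.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_gff3 <- function(features, genome_id, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tspaceracq\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genome_id, features$start + 1L, features$end,
                     features$strand, features$feature_id))
  writeLines(lines, path)
  invisible(path)
}

#' Convert between 0-based half-open and 1-based inclusive intervals
#'
#' @param start,end Interval endpoints.
#' @return Two-column tibble `start`, `end` in the other convention.
#' @export
to_one_based <- function(start, end) tibble(start = start + 1L, end = end)

#' @rdname to_one_based
#' @export
to_zero_based <- function(start, end) tibble(start = start - 1L, end = end)
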