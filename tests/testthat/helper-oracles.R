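# Independent brute-force oracles used to cross-check the fast kernels.
# These share no code with the implementation: identity and alignment are
# enumerated position by position, motif counting goes through regex.

rand_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- 0L
  for (s in seq(-(la - 1), lb - 1)) {
    i <- seq_len(la)
    j <- i + s
    ok <- j >= 1 & j <= lb
    if (!any(ok)) next
    m <- sum(av[i[ok]] == bv[j[ok]] & av[i[ok]] != "N")
    best <- max(best, m)
  }
  best / min(la, lb)
}

oracle_share_word <- function(a, b, w) {
  ka <- substring(a, seq_len(nchar(a) - w + 1), seq_len(nchar(a) - w + 1) + w - 1)
  kb <- substring(b, seq_len(nchar(b) - w + 1), seq_len(nchar(b) - w + 1) + w - 1)
  ka <- ka[!grepl("N", ka)]
  kb <- kb[!grepl("N", kb)]
  length(intersect(ka, kb)) > 0
}

# greedy clustering with the same ordering rule, all in plain R
oracle_cluster <- function(seqs, thr, w) {
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (r in reps) {
      if (oracle_share_word(seqs[i], seqs[r], w) &&
          oracle_identity(seqs[i], seqs[r]) >= thr) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- i
    }
    assign[i] <- hit
  }
  assign
}

oracle_revcomp <- function(x) {
  chartr("ACGTRYKMBVDHSWN", "TGCAYRMKVBHDSWN",
         vapply(x, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

# exhaustive (diagonal x sub-span x strand) best ungapped local alignment
# under the tie-break order (score desc, mismatches asc, start asc, '+'
# before '-'); returns NULL when no sub-span scores positively
oracle_best_hit <- function(spacer, genome_seq, match = 2, mismatch = 6) {
  L <- nchar(spacer)
  gv <- strsplit(genome_seq, "")[[1]]
  G <- length(gv)
  grid <- expand.grid(i1 = seq_len(L), i2 = seq_len(L))
  grid <- grid[grid$i1 <= grid$i2, ]
  best <- NULL
  consider <- function(cand) {
    if (is.null(best)) { best <<- cand; return(invisible()) }
    b <- best
    replace <- (cand$score > b$score) ||
      (cand$score == b$score && cand$mm < b$mm) ||
      (cand$score == b$score && cand$mm == b$mm && cand$start < b$start) ||
      (cand$score == b$score && cand$mm == b$mm && cand$start == b$start &&
         cand$strand == "+" && b$strand == "-")
    if (replace) best <<- cand
  }
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else oracle_revcomp(spacer)
    pv <- strsplit(pat, "")[[1]]
    for (d in seq(-(L - 1), G - 1)) {
      i <- seq_len(L)
      g <- d + i
      ok <- g >= 1 & g <= G
      m <- rep(NA, L)
      m[ok] <- pv[ok] == gv[g[ok]] & pv[ok] != "N"
      sc <- ifelse(m, match, -mismatch)
      cs <- c(0, cumsum(ifelse(is.na(sc), 0, sc)))
      csm <- c(0, cumsum(ifelse(is.na(m), 0, as.integer(m))))
      valid <- grid$i1 >= which(ok)[1] & grid$i2 <= max(which(ok))
      if (!any(ok) || !any(valid)) next
      gg <- grid[valid, ]
      score <- cs[gg$i2 + 1] - cs[gg$i1]
      matches <- csm[gg$i2 + 1] - csm[gg$i1]
      mm <- (gg$i2 - gg$i1 + 1) - matches
      pos <- which(score > 0)
      if (!length(pos)) next
      ord <- pos[order(-score[pos], mm[pos], gg$i1[pos])]
      k <- ord[1]
      consider(list(score = score[k], mm = mm[k],
                    start = d + gg$i1[k] - 1, end = d + gg$i2[k],
                    strand = strand))
    }
  }
  best
}

iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(motif, "")[[1]]], collapse = "")
}

# overlapping occurrences on both strands via lookahead regex
oracle_count_motif <- function(genome_seq, motif) {
  fwd <- gregexpr(paste0("(?=", iupac_regex(motif), ")"), genome_seq,
                  perl = TRUE)[[1]]
  rev <- gregexpr(paste0("(?=", iupac_regex(oracle_revcomp(motif)), ")"),
                  genome_seq, perl = TRUE)[[1]]
  n_fwd <- if (fwd[1] == -1) 0L else length(fwd)
  n_rev <- if (rev[1] == -1) 0L else length(rev)
  c(forward = n_fwd, reverse = n_rev)
}

oracle_binom_upper <- function(k, n) sum(stats::dbinom(k:n, n, 0.5))
oracle_binom_lower <- function(k, n) sum(stats::dbinom(0:k, n, 0.5))
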