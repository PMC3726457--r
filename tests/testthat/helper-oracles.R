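# Brute-force reference implementations used as independent oracles.
# Deliberately slow and literal; they share no code path with the package.

# bases strictly between two closed intervals, by explicit base enumeration
oracle_interval_distance <- function(s1, e1, s2, e2) {
  b1 <- seq(s1, e1)
  b2 <- seq(s2, e2)
  if (length(intersect(b1, b2))) return(0)
  lo <- min(max(b1), max(b2))
  hi <- max(min(b1), min(b2))
  between <- setdiff(seq(lo, hi), c(b1, b2))
  length(between)
}

# quadratic any-exon/any-feature overlap
oracle_overlaps <- function(exons, features) {
  for (i in seq_len(nrow(exons))) {
    for (j in seq_len(nrow(features))) {
      shared <- intersect(seq(exons$start[i], exons$end[i]),
                          seq(features$start[j], features$end[j]))
      if (length(shared)) return(TRUE)
    }
  }
  FALSE
}

# exhaustive all-features nearest distance for one span
oracle_nearest <- function(s, e, features) {
  if (!nrow(features)) return(Inf)
  min(vapply(seq_len(nrow(features)), function(j) {
    oracle_interval_distance(s, e, features$start[j], features$end[j])
  }, numeric(1)))
}

oracle_revcomp <- function(dna) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(dna, "")[[1]]]), collapse = "")
}

# codon-by-codon translation against the standard-code lookup table;
# codons containing N are rendered X
oracle_translate_frame <- function(dna, offset) {
  code <- Biostrings::GENETIC_CODE
  chars <- strsplit(dna, "")[[1]]
  n <- length(chars) - offset
  out <- character(0)
  for (i in seq_len(n %/% 3)) {
    codon <- paste(chars[offset + (3 * i - 2):(3 * i)], collapse = "")
    out[i] <- if (grepl("N", codon)) "X" else unname(code[codon])
  }
  paste(out, collapse = "")
}

# longest stop-free codon run over six frames, by explicit codon walking;
# X (unknown) counts as a residue, * ends a run
oracle_longest_orf <- function(dna) {
  best <- 0L
  for (seq6 in c(dna, oracle_revcomp(dna))) {
    for (off in 0:2) {
      pep <- oracle_translate_frame(seq6, off)
      run <- 0L
      for (ch in strsplit(pep, "")[[1]]) {
        if (ch == "*") run <- 0L else {
          run <- run + 1L
          best <- max(best, run)
        }
      }
    }
  }
  best
}

# quadratic in-silico PCR site enumeration over one chromosome string
oracle_pcr <- function(chrom_seq, fwd, rev, max_product) {
  find_sites <- function(p) {
    n <- nchar(chrom_seq); k <- nchar(p)
    hits <- integer(0)
    for (i in seq_len(n - k + 1)) {
      if (substr(chrom_seq, i, i + k - 1) == p) hits <- c(hits, i)
    }
    hits
  }
  amp <- NULL
  combos <- list(c(fwd, rev), c(rev, fwd))  # both role orientations
  for (cmb in combos) {
    up <- find_sites(cmb[1])
    down <- find_sites(oracle_revcomp(cmb[2]))
    for (a in up) {
      for (b in down) {
        b_end <- b + nchar(cmb[2]) - 1
        if (b >= a && b_end >= a + nchar(cmb[1]) - 1 &&
            b_end - a + 1 <= max_product) {
          amp <- rbind(amp, data.frame(start = a, end = b_end))
        }
      }
    }
  }
  if (is.null(amp)) return(data.frame(start = numeric(0), end = numeric(0)))
  amp <- unique(amp)
  amp[order(amp$start, amp$end), , drop = FALSE]
}

# per-base bitmap coverage of an interval by blocks
oracle_coverage_percent <- function(blocks, int_start, int_end) {
  covered <- rep(FALSE, int_end - int_start + 1)
  for (j in seq_len(nrow(blocks))) {
    s <- max(blocks$start[j], int_start)
    e <- min(blocks$end[j], int_end)
    if (e >= s) covered[(s:e) - int_start + 1] <- TRUE
  }
  100 * sum(covered) / length(covered)
}

# sign of Kendall tau by exhaustive concordant/discordant pair counting
oracle_kendall_sign <- function(x, y) {
  conc <- disc <- 0L
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign((x[j] - x[i]) * (y[j] - y[i]))
      if (s > 0) conc <- conc + 1L
      if (s < 0) disc <- disc + 1L
    }
  }
  sign(conc - disc)
}

# all permutations of 1..n (recursive insertion)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  res <- list()
  for (p in combinat_perms(n - 1)) {
    for (i in 0:(n - 1)) {
      res[[length(res) + 1L]] <- append(p, n, after = i)
    }
  }
  res
}

# independent random DNA (sample + paste; not the package's byte path)
rand_dna_ref <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small helper: models from a compact spec list
make_model <- function(id, chrom, starts, ends, strand = "+", depth = 50) {
  transcript_model(id, chrom, data.frame(start = starts, end = ends),
                   strand = strand, depth = depth)
}

small_config <- function(seed = 1, n = 60, planted = 8) {
  cnt <- floor(c(0.46, 0.13, 0.41) * n)
  cnt[1] <- cnt[1] + n - sum(cnt)
  generator_config(seed = seed, n_transcripts = n, n_planted = planted,
                   n_two_exon = ceiling((n + 2) / 2),
                   homology_exact_counts = cnt)
}
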