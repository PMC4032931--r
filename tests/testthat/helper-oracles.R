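# Independent oracles used by the tests; deliberately naive implementations
# that share no code path with the package internals they check.

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Brute-force six-frame ORF enumeration: every start codon is walked to its
# first downstream stop independently, then starts sharing a stop are
# resolved to the most upstream one.
brute_force_orfs <- function(contigs, code, min_aa, readthrough_codon = NULL) {
  tab <- unclass(code)
  starts3 <- c("ATG", "GTG", "TTG")
  rows <- list()
  for (cid in names(contigs)) {
    fwd <- toupper(contigs[[cid]])
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else recodon::reverse_complement(fwd)
      for (frame in 0:2) {
        n_codon <- (L - frame) %/% 3
        if (n_codon < 1) next
        nt1 <- frame + 1 + 3 * (0:(n_codon - 1))
        codons <- substring(s, nt1, nt1 + 2)
        aa <- unname(tab[codons])
        aa[is.na(aa)] <- "X"
        stop_here <- aa == "*"
        if (!is.null(readthrough_codon)) {
          aa[stop_here & codons == readthrough_codon] <- "X"
          stop_here <- stop_here & codons != readthrough_codon
        }
        stop_pos <- which(stop_here)
        hits <- list()
        for (i in which(codons %in% starts3)) {
          after <- stop_pos[stop_pos > i]
          if (!length(after)) next
          term <- after[1]
          if (term - i < min_aa) next
          hits[[length(hits) + 1]] <- c(start = i, stop = term)
        }
        if (!length(hits)) next
        h <- do.call(rbind, hits)
        for (tm in unique(h[, "stop"])) {
          i <- min(h[h[, "stop"] == tm, "start"])
          b0 <- nt1[i] - 1
          e0 <- nt1[tm] + 2
          prot <- paste(aa[i:(tm - 1)], collapse = "")
          if (strand == "+") { st <- b0; en <- e0 }
          else { st <- L - e0; en <- L - b0 }
          rows[[length(rows) + 1]] <- data.frame(
            contig_id = cid, start = st, end = en, strand = strand,
            translation = prot, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      translation = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# Exhaustive substring validator: a substring is a tryptic peptide iff both
# ends sit on cleavage boundaries and it spans at most `missed` internal
# sites. Quadratic; for short proteins only.
all_tryptic_substrings <- function(protein, missed, range) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(res)
  is_site <- function(i) i >= 1 && i < n && res[i] %in% c("K", "R") &&
    res[i + 1] != "P"
  out <- character()
  for (i in seq_len(n)) for (j in i:n) {
    if (!(i == 1 || is_site(i - 1))) next
    if (!(j == n || is_site(j))) next
    len <- j - i + 1
    if (len < range[1] || len > range[2]) next
    internal <- if (j > i) sum(vapply(i:(j - 1), is_site, logical(1))) else 0
    if (internal <= missed)
      out <- c(out, paste(res[i:j], collapse = ""))
  }
  out
}

# Full-digest scan classification oracle: linear search of each variant's
# complete fragment list.
brute_force_classify <- function(peptides, variants, missed, range) {
  digests <- lapply(variants, function(v) {
    frags <- character()
    for (p in v$proteins)
      if (nchar(p)) frags <- c(frags, all_tryptic_fragments_fast(p, missed, range))
    frags
  })
  m <- matrix(FALSE, length(peptides), length(variants),
              dimnames = list(peptides,
                              vapply(variants, `[[`, "", "variant_id")))
  for (i in seq_along(peptides))
    for (j in seq_along(variants))
      m[i, j] <- any(digests[[j]] == peptides[i])
  m
}

# run-concatenation fragment enumeration (independent of tryptic_digest's
# bookkeeping, fast enough for whole proteomes)
all_tryptic_fragments_fast <- function(protein, missed, range) {
  m <- gregexpr("[KR](?!P)", protein, perl = TRUE)[[1]]
  sites <- m[m > 0 & m < nchar(protein)]
  bounds <- c(0, sites, nchar(protein))
  nf <- length(bounds) - 1
  out <- character()
  for (a in seq_len(nf)) for (b in a:min(nf, a + missed)) {
    len <- bounds[b + 1] - bounds[a]
    if (len >= range[1] && len <= range[2])
      out <- c(out, substr(protein, bounds[a] + 1, bounds[b + 1]))
  }
  out
}

# small hand-buildable codon observation object for threshold tests
make_obs <- function(counts, gc = 0.5) {
  codons <- recodon:::CODONS
  aa <- recodon:::AA20
  m <- matrix(0L, 64, 20, dimnames = list(codons, aa))
  m[rownames(counts), colnames(counts)] <- counts
  totals <- rowSums(m)
  expected <- recodon::expected_codon_frequency(recodon::gc_null_model(gc))
  usage <- (totals / sum(totals)) / expected
  structure(list(counts = m, totals = totals, expected = expected,
                 usage_ratio = usage, gc = gc, n_orfs = 1L,
                 n_orfs_used = 1L), class = "codon_obs")
}
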