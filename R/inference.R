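kmer_set <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Accumulate amino-acid observations per query codon
#'
#' The core of alignment-based code inference: each ORF translation is
#' assigned to its best-matching reference family (shared 5-mer prescreen,
#' then global alignment to the family consensus; only significant
#' alignments count). At every aligned column whose conservation reaches
#' `conservation_min`, the consensus residue is taken as the label of the
#' aligned query codon, incrementing a 64 x 20 count matrix. Codons
#' containing `N` are skipped. Expected codon frequencies come from the GC
#' null model, giving each codon a usage ratio
#' (observed share) / (expected share): near 1 for sense codons, near 0 for
#' a genuinely unused stop codon.
#'
#' @param orfs An `orf_set` (translations may contain `X` at read-through
#'   positions; `X` scores 0 in the alignment).
#' @param families List of `ref_family` objects.
#' @param gc GC fraction for the null model (e.g. [gc_fraction()] of the
#'   contigs).
#' @param conservation_min Minimum column conservation in `(0, 1]`.
#' @param min_kmer_hits Minimum shared 5-mers between an ORF and a family
#'   consensus before an alignment is attempted (a deterministic seeding
#'   heuristic that skips hopeless pairs).
#' @param top_n Number of top prescreen candidates to align per ORF.
#' @param gap_open,gap_ext,min_score_frac Passed to [align_to_family()].
#' @return A `codon_obs` object: list with `counts` (64 x 20 matrix),
#'   `totals`, `expected`, `usage_ratio` (per codon), `gc`, `n_orfs`,
#'   `n_orfs_used`.
#' @export
collect_observations <- function(orfs, families, gc, conservation_min = 0.9,
                                 min_kmer_hits = 3L, top_n = 3L,
                                 gap_open = 11, gap_ext = 1,
                                 min_score_frac = 0.4) {
  if (!inherits(orfs, "orf_set")) stop("'orfs' must be an orf_set")
  if (!length(families)) stop("'families' must be a non-empty list")
  if (!(conservation_min > 0 && conservation_min <= 1))
    stop("'conservation_min' must be in (0, 1]")

  counts <- matrix(0L, nrow = 64L, ncol = 20L,
                   dimnames = list(CODONS, AA20))
  model <- gc_null_model(gc)
  expected <- expected_codon_frequency(model)

  n_used <- 0L
  if (nrow(orfs)) {
    # 5-mer index over family consensus strings
    cons <- vapply(families, consensus_string, "")
    km <- lapply(cons, kmer_set)
    kmer_vec <- unlist(km, use.names = FALSE)
    fam_idx <- rep.int(seq_along(families), lengths(km))
    submat <- recoding_submat()

    for (i in seq_len(nrow(orfs))) {
      orf <- orfs[i, , drop = FALSE]
      qk <- kmer_set(orf$translation)
      if (!length(qk)) next
      hits <- tabulate(fam_idx[kmer_vec %in% qk], nbins = length(families))
      cand <- which(hits >= min_kmer_hits)
      if (!length(cand)) next
      cand <- cand[order(hits[cand], decreasing = TRUE)]
      cand <- cand[seq_len(min(top_n, length(cand)))]
      qres <- strsplit(orf$translation, "", fixed = TRUE)[[1]]
      self_score <- sum(submat[cbind(qres, qres)])
      best <- NULL
      for (f in cand) {
        # fast path: ungapped C-terminal anchor (global score with an
        # affine end gap over the query prefix); exact whenever the query
        # ends with a full-length homolog of the consensus, which the
        # full Needleman-Wunsch would align identically
        al <- NULL
        subject <- cons[[f]]
        ns <- nchar(subject)
        nq <- length(qres)
        if (ns <= nq && ns > 0L) {
          d <- nq - ns
          sres <- strsplit(subject, "", fixed = TRUE)[[1]]
          sc <- sum(submat[cbind(qres[(d + 1L):nq], sres)]) -
            if (d > 0L) gap_open + gap_ext * d else 0
          if (self_score > 0 && sc >= min_score_frac * self_score)
            al <- list(score = sc, self_score = self_score,
                       significant = TRUE,
                       map = data.frame(qpos = (d + 1L):nq,
                                        col = consensus_columns(families[[f]])))
        }
        if (is.null(al))
          al <- align_to_family(orf$translation, families[[f]],
                                gap_open = gap_open, gap_ext = gap_ext,
                                min_score_frac = min_score_frac,
                                submat = submat)
        if (al$significant && (is.null(best) || al$score > best$al$score))
          best <- list(f = f, al = al)
      }
      if (is.null(best)) next
      n_used <- n_used + 1L
      fam <- families[[best$f]]
      map <- best$al$map
      keep <- fam$conservation[map$col] >= conservation_min &
        fam$consensus[map$col] %in% AA20
      map <- map[keep, , drop = FALSE]
      if (!nrow(map)) next
      codons <- codon_at(orf, map$qpos - 1L)
      aa_lab <- fam$consensus[map$col]
      ok <- !grepl("N", codons, fixed = TRUE)
      if (any(ok)) {
        idx <- cbind(match(codons[ok], CODONS), match(aa_lab[ok], AA20))
        for (r in seq_len(nrow(idx)))
          counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
      }
    }
  }
  totals <- rowSums(counts)
  grand <- sum(totals)
  if (grand == 0) warning("no significant alignments; observation matrix is empty")
  usage_ratio <- if (grand > 0) (totals / grand) / expected
                 else setNames(rep(NA_real_, 64L), CODONS)
  structure(list(counts = counts, totals = totals, expected = expected,
                 usage_ratio = usage_ratio, gc = gc,
                 n_orfs = nrow(orfs), n_orfs_used = n_used),
            class = "codon_obs")
}

#' @export
print.codon_obs <- function(x, ...) {
  cat(sprintf("Codon observation matrix: %d observations from %d/%d ORFs (gc = %.3f)\n",
              sum(x$totals), x$n_orfs_used, x$n_orfs, x$gc))
  stops <- c("TAA", "TAG", "TGA")
  for (cd in stops) {
    top <- if (x$totals[cd] > 0)
      sprintf("modal %s (%.2f)", AA20[which.max(x$counts[cd, ])],
              max(x$counts[cd, ]) / x$totals[cd]) else "no observations"
    cat(sprintf("  %s: n = %d, usage ratio = %.3f, %s\n",
                cd, x$totals[cd],
                ifelse(is.na(x$usage_ratio[cd]), NA, x$usage_ratio[cd]), top))
  }
  invisible(x)
}

#' Predict the meaning of every codon
#'
#' Decision logic per codon. Canonical stop codons default to STOP: they are
#' only called recoded when evidence is strong on all three axes — enough
#' observations (`n >= min_obs`), a dominant amino acid
#' (`support >= min_freq`) and usage not depleted relative to the GC null
#' (`usage_ratio >= min_usage`). A depleted stop codon
#' (`usage_ratio < min_usage`) is called STOP outright, since a genuinely
#' unused stop yields at most a handful of spurious observations; a stop
#' codon with appreciable usage but too few conserved observations is
#' `insufficient_data`. Sense codons are `insufficient_data` below
#' `min_obs`, otherwise the modal amino acid provided its frequency reaches
#' `min_freq` (ties broken alphabetically and flagged).
#'
#' @param obs A `codon_obs` from [collect_observations()].
#' @param min_obs Minimum observations for a positive call.
#' @param min_freq Minimum modal-residue frequency.
#' @param min_usage Usage-ratio threshold separating depleted (stop-like)
#'   from used codons.
#' @return A `code_prediction`: data frame with one row per codon
#'   (`codon`, `canonical`, `predicted`, `n_obs`, `support_freq`,
#'   `usage_ratio`, `tie`), thresholds stored as attributes.
#' @export
predict_code <- function(obs, min_obs = 20L, min_freq = 0.5,
                         min_usage = 0.3) {
  if (!inherits(obs, "codon_obs")) stop("'obs' must be a codon_obs")
  if (min_obs <= 0 || min_freq <= 0 || min_usage <= 0)
    stop("thresholds must be positive")
  std <- standard_code_table()
  out <- data.frame(codon = CODONS, canonical = unname(std[CODONS]),
                    predicted = NA_character_, n_obs = as.integer(obs$totals),
                    support_freq = NA_real_,
                    usage_ratio = unname(obs$usage_ratio),
                    tie = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(64L)) {
    n <- out$n_obs[i]
    row <- obs$counts[i, ]
    if (n > 0) {
      mx <- max(row)
      modal <- AA20[row == mx]
      out$support_freq[i] <- mx / n
      out$tie[i] <- length(modal) > 1L
      modal <- sort(modal)[1]
    } else modal <- NA_character_
    ur <- out$usage_ratio[i]
    if (out$canonical[i] == STOP) {
      if (!is.na(ur) && ur < min_usage) {
        out$predicted[i] <- STOP
      } else if (n < min_obs) {
        out$predicted[i] <- "insufficient_data"
      } else if (!is.na(out$support_freq[i]) &&
                 out$support_freq[i] >= min_freq) {
        out$predicted[i] <- modal
      } else out$predicted[i] <- "insufficient_data"
    } else {
      if (n < min_obs) {
        out$predicted[i] <- "insufficient_data"
      } else if (out$support_freq[i] >= min_freq) {
        out$predicted[i] <- modal
      } else out$predicted[i] <- "insufficient_data"
    }
  }
  structure(out, class = c("code_prediction", "data.frame"),
            min_obs = min_obs, min_freq = min_freq, min_usage = min_usage)
}

#' @export
print.code_prediction <- function(x, ...) {
  cat("Genetic code prediction\n")
  stops <- x[x$canonical == STOP, , drop = FALSE]
  cat("  canonical stop codons:\n")
  for (i in seq_len(nrow(stops)))
    cat(sprintf("    %s -> %s (n = %d, support = %s, usage ratio = %s)\n",
                stops$codon[i], stops$predicted[i], stops$n_obs[i],
                ifelse(is.na(stops$support_freq[i]), "NA",
                       sprintf("%.2f", stops$support_freq[i])),
                ifelse(is.na(stops$usage_ratio[i]), "NA",
                       sprintf("%.3f", stops$usage_ratio[i]))))
  reas <- x[x$canonical != STOP & !is.na(x$predicted) &
              !x$predicted %in% c(x$canonical, "insufficient_data"), ,
            drop = FALSE]
  reas <- reas[reas$predicted != reas$canonical, , drop = FALSE]
  if (nrow(reas)) {
    cat("  sense codons predicted off-canonical:\n")
    for (i in seq_len(nrow(reas)))
      cat(sprintf("    %s: canonical %s, predicted %s\n",
                  reas$codon[i], reas$canonical[i], reas$predicted[i]))
  }
  invisible(x)
}

#' Sequence-logo table of normalized per-codon amino-acid frequencies
#'
#' For each codon, letter heights are the amino-acid frequencies in its
#' observation row scaled by the codon's usage ratio, so the total column
#' height equals the usage ratio: tall columns mean the codon is used as
#' often as the GC null expects, near-empty columns mean depletion (a true
#' stop). Codons with zero observations contribute no rows.
#'
#' @param obs A `codon_obs`.
#' @return A data frame with columns `codon`, `aa`, `height`, ordered by
#'   codon then descending height.
#' @export
logo_matrix <- function(obs) {
  if (!inherits(obs, "codon_obs")) stop("'obs' must be a codon_obs")
  rows <- list()
  for (i in seq_len(64L)) {
    n <- obs$totals[i]
    if (n == 0) next
    h <- (obs$counts[i, ] / n) * obs$usage_ratio[i]
    nz <- h > 0
    rows[[length(rows) + 1L]] <- data.frame(
      codon = CODONS[i], aa = AA20[nz], height = unname(h[nz]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(codon = character(), aa = character(),
                      height = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$codon, -out$height), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Barplot of per-codon usage ratios
#'
#' Quick visual analogue of a normalized codon logo: bar height is the
#' usage ratio; canonical stop codons are highlighted. A recoded stop codon
#' stands out as a stop-coloured bar at sense-codon height.
#'
#' @param x A `codon_obs`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the usage-ratio vector.
#' @export
plot.codon_obs <- function(x, ...) {
  ur <- x$usage_ratio
  ur[is.na(ur)] <- 0
  cols <- ifelse(CODONS %in% c("TAA", "TAG", "TGA"), "firebrick", "grey60")
  graphics::barplot(ur, names.arg = CODONS, las = 2, cex.names = 0.5,
                    col = cols, border = NA,
                    ylab = "observed / expected codon share", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(ur)
}
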