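#: monoisotopic residue masses (Da), standard proteomics table
RESIDUE_MASS <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047678, V = 99.068414, W = 186.079313, Y = 163.063329)

WATER_MASS <- 18.0105646837

#: default modifications: fixed carbamidomethylation of cysteine;
#: variable oxidation of methionine and N-terminal carbamylation
DEFAULT_FIXED_MODS <- c(C = 57.0214)
DEFAULT_VARIABLE_MODS <- list(
  oxidation_M = list(target = "M", shift = 15.994915, max = 3L),
  carbamyl_Nterm = list(target = "Nterm", shift = 43.005814, max = 1L))

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' emits every fragment with at most `missed_cleavages` internal cleavage
#' sites and length within `length_range`. Fragments are returned in
#' N-to-C order (duplicates retained); callers wanting a peptide set should
#' `unique()` the result.
#'
#' @param protein Protein string.
#' @param missed_cleavages Maximum internal missed cleavage sites (>= 0).
#' @param length_range Length bounds `c(min, max)` in residues.
#' @return Character vector of peptides.
#' @examples
#' tryptic_digest("MKAAAR", 0, c(1, 50))  # "MK", "AAAR"
#' @export
tryptic_digest <- function(protein, missed_cleavages = 2L,
                           length_range = c(6L, 50L)) {
  if (missed_cleavages < 0) stop("'missed_cleavages' must be >= 0")
  n <- nchar(protein)
  if (n == 0L) return(character())
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  cut <- if (n > 1L) which(res[-n] %in% c("K", "R") & res[-1L] != "P")
         else integer()
  bounds <- c(0L, cut, n)
  nf <- length(bounds) - 1L
  out <- character()
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + as.integer(missed_cleavages))
    for (j in i:jmax) {
      len <- bounds[j + 1L] - bounds[i]
      if (len >= length_range[1] && len <= length_range[2])
        out <- c(out, substr(protein, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  out
}

#' Unique tryptic peptide set of a proteome
#'
#' @param proteins Character vector of protein strings.
#' @inheritParams tryptic_digest
#' @return Sorted character vector of unique peptides.
#' @export
digest_proteome <- function(proteins, missed_cleavages = 2L,
                            length_range = c(6L, 50L)) {
  sort(unique(unlist(lapply(proteins, tryptic_digest,
                            missed_cleavages = missed_cleavages,
                            length_range = length_range))))
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, with fixed
#' modification shifts applied to every matching residue.
#'
#' @param sequence Peptide string over the 20-letter alphabet (vectorized).
#' @param fixed_mods Named numeric vector of mass shifts per residue,
#'   e.g. `c(C = 57.0214)` for carbamidomethylation.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G", fixed_mods = NULL)  # 75.032029
#' @export
peptide_mass <- function(sequence, fixed_mods = DEFAULT_FIXED_MODS) {
  vapply(sequence, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!length(res)) stop("empty peptide sequence")
    m <- RESIDUE_MASS[res]
    if (anyNA(m))
      stop("unknown residue symbol(s): ",
           paste(unique(res[is.na(m)]), collapse = ", "))
    total <- sum(m) + WATER_MASS
    if (length(fixed_mods))
      for (tgt in names(fixed_mods))
        total <- total + fixed_mods[[tgt]] * sum(res == tgt)
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' All theoretical modform masses of a peptide
#'
#' Enumerates combinations of variable modifications (each applied 0 up to
#' `min(sites, max)` times; `target = "Nterm"` has one site) on top of the
#' fixed-modification mass, yielding the set of alternative theoretical
#' masses a search engine would consider.
#'
#' @param sequence A single peptide string.
#' @inheritParams peptide_mass
#' @param variable_mods List of `list(target=, shift=, max=)` entries.
#' @return Numeric vector of masses; the first element is the unmodified
#'   (fixed-mods-only) mass.
#' @export
modform_masses <- function(sequence, fixed_mods = DEFAULT_FIXED_MODS,
                           variable_mods = DEFAULT_VARIABLE_MODS) {
  base <- peptide_mass(sequence, fixed_mods)
  if (!length(variable_mods)) return(base)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  choices <- lapply(variable_mods, function(vm) {
    sites <- if (identical(vm$target, "Nterm")) 1L else sum(res == vm$target)
    (0:min(sites, vm$max)) * vm$shift
  })
  combos <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  unique(base + rowSums(as.matrix(combos)))
}

#' Filter peptide identifications by database match, ppm error and spectra
#'
#' A peptide identification is retained iff (i) its sequence occurs in at
#' least one target protein of the search database, (ii) some theoretical
#' modform mass lies within `tol_ppm` of the observed neutral mass, and
#' (iii) its spectral count reaches `min_spectra`. Removal counts per
#' filter (first failing filter wins) are attached as the `filter_log`
#' attribute.
#'
#' @param ids Data frame of identifications with columns `peptide`,
#'   `observed_mass`, `spectral_count` (see [read_peptide_ids()]).
#' @param database A `search_db`, or a character vector of target proteins.
#' @param tol_ppm Mass tolerance in parts per million (>= 0).
#' @param min_spectra Minimum spectral count.
#' @inheritParams modform_masses
#' @return The retained rows of `ids`, with attribute `filter_log`.
#' @export
ppm_filter <- function(ids, database, tol_ppm = 10, min_spectra = 2L,
                       fixed_mods = DEFAULT_FIXED_MODS,
                       variable_mods = DEFAULT_VARIABLE_MODS) {
  if (tol_ppm < 0) stop("'tol_ppm' must be >= 0")
  targets <- if (inherits(database, "search_db")) database$targets
             else as.character(database)
  haystack <- paste(targets, collapse = "#")
  in_db <- vapply(ids$peptide, function(p) grepl(p, haystack, fixed = TRUE),
                  logical(1), USE.NAMES = FALSE)
  ppm_ok <- vapply(seq_len(nrow(ids)), function(i) {
    th <- modform_masses(ids$peptide[i], fixed_mods, variable_mods)
    any(abs(ids$observed_mass[i] - th) / th * 1e6 <= tol_ppm)
  }, logical(1))
  sp_ok <- ids$spectral_count >= min_spectra
  keep <- in_db & ppm_ok & sp_ok
  log <- c(input = nrow(ids),
           removed_not_in_database = sum(!in_db),
           removed_ppm = sum(in_db & !ppm_ok),
           removed_spectra = sum(in_db & ppm_ok & !sp_ok),
           retained = sum(keep))
  out <- ids[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  out
}

#' Classify peptides by the code variants that can produce them
#'
#' A variant supports a peptide iff the peptide belongs to the in-silico
#' tryptic peptide set of some protein of that variant; a peptide is unique
#' to a variant iff exactly one variant supports it.
#'
#' @param peptides Character vector of peptide sequences.
#' @param variants List of `proteome_variant` objects.
#' @inheritParams tryptic_digest
#' @return Logical matrix, peptides x variants (colnames = variant ids).
#' @export
classify_peptides <- function(peptides, variants, missed_cleavages = 2L,
                              length_range = c(6L, 50L)) {
  if (!length(variants)) stop("'variants' must be non-empty")
  sets <- lapply(variants, function(v)
    digest_proteome(v$proteins, missed_cleavages, length_range))
  m <- vapply(sets, function(s) peptides %in% s,
              logical(length(peptides)))
  if (length(peptides) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(peptides,
                      vapply(variants, `[[`, "", "variant_id"))
  m
}

#' Unique-peptide report and code decision
#'
#' Counts non-redundant peptide sequences unique to each code variant
#' (present in that variant's in-silico digest and no other's) and decides
#' for the variant with the most unique peptides when it leads the
#' runner-up by at least `decision_min_ratio`; otherwise the decision is
#' `"undetermined"`. Spectral counts play no role here — stringency
#' filtering happens upstream in [ppm_filter()].
#'
#' @param ids Retained identifications (data frame with `peptide`) or a
#'   character vector of peptide sequences.
#' @param variants List of `proteome_variant` objects.
#' @param decision_min_ratio Minimum lead of best over second-best unique
#'   count (`Inf` when the runner-up count is 0 and the best is positive).
#' @inheritParams tryptic_digest
#' @return A `uniqueness_report`: list with `per_variant` (data frame:
#'   `variant`, `unique_count`, `shared_count`), `n_peptides`,
#'   `n_unmatched`, `decision`, `runner_up_ratio`, `tie`.
#' @export
uniqueness_report <- function(ids, variants, decision_min_ratio = 10,
                              missed_cleavages = 2L,
                              length_range = c(6L, 50L)) {
  peptides <- if (is.data.frame(ids)) ids$peptide else as.character(ids)
  peptides <- unique(peptides)
  vids <- vapply(variants, `[[`, "", "variant_id")
  if (length(peptides)) {
    m <- classify_peptides(peptides, variants, missed_cleavages, length_range)
    support <- rowSums(m)
    unique_count <- colSums(m[support == 1L, , drop = FALSE])
    shared_count <- colSums(m[support > 1L, , drop = FALSE])
    n_unmatched <- sum(support == 0L)
  } else {
    unique_count <- shared_count <- setNames(rep(0L, length(vids)), vids)
    n_unmatched <- 0L
  }
  per_variant <- data.frame(variant = vids,
                            unique_count = as.integer(unique_count),
                            shared_count = as.integer(shared_count),
                            stringsAsFactors = FALSE)
  ord <- order(per_variant$unique_count, decreasing = TRUE)
  best <- per_variant[ord[1], ]
  second <- if (nrow(per_variant) > 1L) per_variant$unique_count[ord[2]] else 0L
  tie <- nrow(per_variant) > 1L && best$unique_count > 0L &&
    second == best$unique_count
  ratio <- if (best$unique_count == 0L) NA_real_
           else if (second == 0L) Inf else best$unique_count / second
  decision <- if (!tie && best$unique_count >= 1L && !is.na(ratio) &&
                  ratio >= decision_min_ratio) best$variant else "undetermined"
  structure(list(per_variant = per_variant,
                 n_peptides = length(peptides), n_unmatched = n_unmatched,
                 decision = decision, runner_up_ratio = ratio, tie = tie),
            class = "uniqueness_report")
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf("Peptide uniqueness report: %d non-redundant peptides (%d unmatched)\n",
              x$n_peptides, x$n_unmatched))
  pv <- x$per_variant[order(x$per_variant$unique_count, decreasing = TRUE), ]
  show <- pv[pv$unique_count > 0 | pv$variant %in% c("STOP", "G", "W"), ]
  for (i in seq_len(nrow(show)))
    cat(sprintf("  variant %-4s unique = %4d, shared = %d\n",
                show$variant[i], show$unique_count[i], show$shared_count[i]))
  cat(sprintf("  decision: %s (runner-up ratio %s%s)\n", x$decision,
              ifelse(is.na(x$runner_up_ratio), "NA",
                     format(x$runner_up_ratio, digits = 3)),
              if (isTRUE(x$tie)) ", tie" else ""))
  invisible(x)
}
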