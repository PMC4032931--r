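.recodon_env <- new.env(parent = emptyenv())

#' Substitution matrix for homology alignment
#'
#' BLOSUM62 with the ambiguity symbol `X` rescored to 0 against every
#' residue (and itself): residues encoded by the codon under investigation
#' are translated as `X`, and they must neither reward nor penalize the
#' alignment that decides which consensus residue they face.
#'
#' @return An integer substitution matrix.
#' @export
recoding_submat <- function() {
  if (is.null(.recodon_env$submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .recodon_env$submat <- m
  }
  .recodon_env$submat
}

#' Globally align a query protein to a family consensus
#'
#' Needleman-Wunsch alignment with affine gap penalties (defaults: open 11,
#' extend 1, BLOSUM62 with `X` scoring 0 everywhere) of an ORF translation
#' against the ungapped family consensus. An alignment is significant when
#' its score reaches `min_score_frac` of the query's self-alignment score —
#' a simple, length-normalized threshold; non-significant alignments are
#' excluded from codon counting.
#'
#' @param query Protein string (may contain `X`).
#' @param family A `ref_family`.
#' @param gap_open,gap_ext Affine gap penalties (positive costs).
#' @param min_score_frac Significance threshold as a fraction of the
#'   query self-score.
#' @param submat Substitution matrix; defaults to [recoding_submat()].
#' @return A list: `score`, `self_score`, `significant`, and `map`, a data
#'   frame of aligned positions with `qpos` (1-based query residue) and
#'   `col` (family alignment column).
#' @export
align_to_family <- function(query, family, gap_open = 11, gap_ext = 1,
                            min_score_frac = 0.4, submat = recoding_submat()) {
  if (!inherits(family, "ref_family")) stop("'family' must be a ref_family")
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop("'query' must be a non-empty protein string")
  subject <- consensus_string(family)
  if (!nzchar(subject)) stop("family consensus is empty")
  cols <- consensus_columns(family)

  qres <- strsplit(query, "", fixed = TRUE)[[1]]
  self_score <- sum(submat[cbind(qres, qres)])

  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_ext, type = "global")
  score <- Biostrings::score(pa)

  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- cumsum(ap != "-")
  si <- cumsum(as_ != "-")
  both <- ap != "-" & as_ != "-"
  map <- data.frame(qpos = qi[both], col = cols[si[both]])

  list(score = score, self_score = self_score,
       significant = self_score > 0 && score >= min_score_frac * self_score,
       map = map)
}
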