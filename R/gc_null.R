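#' GC-content null model of codon frequency
#'
#' The simplest codon-occurrence model consistent with a genome's GC
#' content: nucleotide positions are independent with
#' `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`. A codon's expected
#' frequency is the product of its three positional probabilities; the 64
#' frequencies sum to one. Observed codon usage in coding regions divided by
#' this expectation (the usage ratio) distinguishes a genuinely unused stop
#' codon (strong depletion) from a sense or recoded codon (near parity).
#'
#' @param gc GC fraction in `[0, 1]`.
#' @return A `gc_null` object: list with `gc` and `probs` (named nucleotide
#'   probabilities A, C, G, T).
#' @examples
#' m <- gc_null_model(0.332)
#' sum(expected_codon_frequency(m))  # 1
#' @export
gc_null_model <- function(gc) {
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1)
    stop("'gc' must be a single number in [0, 1]")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  structure(list(gc = gc, probs = probs), class = "gc_null")
}

#' @export
print.gc_null <- function(x, ...) {
  cat(sprintf("GC null codon model: gc = %.4f (P(G)=P(C)=%.4f, P(A)=P(T)=%.4f)\n",
              x$gc, x$probs["G"], x$probs["A"]))
  invisible(x)
}

#' Expected codon frequency under the GC null model
#'
#' @param model A `gc_null` object.
#' @param codons Character vector of DNA codons without ambiguity codes.
#'   Defaults to all 64 codons.
#' @return Named numeric vector of expected frequencies, one per codon.
#' @examples
#' expected_codon_frequency(gc_null_model(0.5), "ATG")  # 1/64
#' @export
expected_codon_frequency <- function(model, codons = CODONS) {
  stopifnot(inherits(model, "gc_null"))
  codons <- toupper(codons)
  bad <- grepl("[^ACGT]", codons) | nchar(codons) != 3L
  if (any(bad))
    stop("codons must be unambiguous DNA triplets; offending: ",
         paste(unique(codons[bad]), collapse = ", "))
  p <- model$probs
  b1 <- substr(codons, 1L, 1L)
  b2 <- substr(codons, 2L, 2L)
  b3 <- substr(codons, 3L, 3L)
  setNames(p[b1] * p[b2] * p[b3], codons)
}

#' Empirical GC fraction of nucleotide sequences
#'
#' Fraction of G+C among unambiguous bases, pooled over all sequences.
#'
#' @param seqs Character vector of DNA strings.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seqs) {
  seqs <- toupper(paste(seqs, collapse = ""))
  n_gc <- nchar(gsub("[^GC]", "", seqs))
  n_at <- nchar(gsub("[^AT]", "", seqs))
  if (n_gc + n_at == 0L) stop("no unambiguous bases in input")
  n_gc / (n_gc + n_at)
}
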