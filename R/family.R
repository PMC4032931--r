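#' Construct a reference protein family from an alignment
#'
#' A family is a gapped multiple alignment of homologous proteins. Per
#' column, the consensus is the modal residue among non-gap members (ties
#' broken alphabetically) and the conservation is the fraction of all
#' members carrying that residue (gaps count against conservation, so a
#' column is only "conserved" when most members actually share a residue).
#'
#' @param members Character vector of equal-length aligned sequences
#'   (gaps as `-`), named by member id.
#' @param family_id Family identifier.
#' @return A `ref_family`: list with `family_id`, `members`, `consensus`
#'   (per-column character vector, `-` where all members are gapped) and
#'   `conservation` (per-column fraction in `[0, 1]`).
#' @export
reference_family <- function(members, family_id = "family") {
  if (!length(members)) stop("a family needs at least one member")
  members <- toupper(members)
  w <- unique(nchar(members))
  if (length(w) != 1L)
    stop("all family members must have equal aligned length")
  mat <- do.call(rbind, strsplit(members, "", fixed = TRUE))
  n <- nrow(mat)
  alph <- sort(setdiff(unique(as.vector(mat)), "-"))
  if (!length(alph)) stop("family contains only gaps")
  cnt <- vapply(alph, function(a) colSums(mat == a, dims = 1L),
                numeric(w))
  cnt <- matrix(cnt, nrow = w, dimnames = list(NULL, alph))
  # first max = alphabetically smallest modal residue (alph is sorted)
  top <- max.col(cnt, ties.method = "first")
  mx <- cnt[cbind(seq_len(w), top)]
  consensus <- ifelse(mx > 0, alph[top], "-")
  conservation <- mx / n
  structure(list(family_id = family_id, members = members,
                 consensus = consensus, conservation = conservation),
            class = "ref_family")
}

#' @export
print.ref_family <- function(x, ...) {
  cat(sprintf("Reference family '%s': %d members, %d columns, mean conservation %.2f\n",
              x$family_id, length(x$members), length(x$consensus),
              mean(x$conservation)))
  invisible(x)
}

#' Consensus of a family as an ungapped string
#'
#' Drops all-gap columns; the returned string is what queries are aligned
#' against. Use `consensus_columns()` for the mapping back to alignment
#' columns.
#'
#' @param family A `ref_family`.
#' @return A protein string.
#' @export
consensus_string <- function(family) {
  paste(family$consensus[family$consensus != "-"], collapse = "")
}

#' @rdname consensus_string
#' @return `consensus_columns`: integer vector of alignment column indices,
#'   one per consensus residue.
#' @export
consensus_columns <- function(family) {
  which(family$consensus != "-")
}

#' Read / write one reference family as aligned FASTA
#'
#' @param path Aligned FASTA file (gaps as `-`), one family per file.
#' @param family_id Id for the family; defaults to the file name.
#' @return `read_family_msa` returns a `ref_family`.
#' @export
read_family_msa <- function(path, family_id = NULL) {
  if (is.null(family_id))
    family_id <- sub("\\.[^.]*$", "", basename(path))
  seqs <- read_fasta(path, type = "protein_gapped")
  reference_family(seqs, family_id)
}

#' @rdname read_family_msa
#' @param family A `ref_family` to write.
#' @export
write_family_msa <- function(family, path) {
  write_fasta(family$members, path, type = "protein_gapped")
}
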