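#' Read sequences from FASTA
#'
#' Sequences are uppercased on read. `type` controls alphabet validation:
#' `"dna"` allows `A,C,G,T,N`, `"protein"` the 20 amino acids plus `X` and
#' `*`, `"protein_gapped"` additionally `-`.
#'
#' @param path FASTA file.
#' @param type One of `"dna"`, `"protein"`, `"protein_gapped"`.
#' @return Named character vector (possibly empty, with a warning, for an
#'   empty file). Duplicate or empty ids are rejected.
#' @export
read_fasta <- function(path, type = c("dna", "protein", "protein_gapped")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(), character()))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         ids[duplicated(ids)][1])
  allowed <- switch(type, dna = "ACGTN",
                    protein = paste0(paste(AA20, collapse = ""), "X*"),
                    protein_gapped = paste0(paste(AA20, collapse = ""), "X*-"))
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad))
    stop("record '", ids[which(bad)[1]], "' in ", path,
         " contains characters outside the ", type, " alphabet")
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type Alphabet (see [read_fasta()]); affects validation only.
#' @param width Wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path,
                        type = c("dna", "protein", "protein_gapped"),
                        width = 60L) {
  type <- match.arg(type)
  if (is.null(names(seqs)) && length(seqs))
    stop("'seqs' must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n)
      writeLines(substring(s, seq(1L, n, width),
                           pmin(seq(1L, n, width) + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read / write peptide identifications as TSV
#'
#' Columns: `peptide`, `observed_mass`, `spectral_count`, `mods`
#' (free-text modification annotation, may be empty) and optionally
#' `truth` for simulated data.
#'
#' @param path TSV file.
#' @return `read_peptide_ids` returns a data frame.
#' @export
read_peptide_ids <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "observed_mass", "spectral_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peptide table missing column(s): ", paste(miss, collapse = ", "))
  if (!"mods" %in% names(df)) df$mods <- ""
  df$mods <- as.character(df$mods)
  df$mods[is.na(df$mods)] <- ""
  if (any(df$observed_mass <= 0)) stop("observed_mass must be > 0")
  if (any(df$spectral_count < 1)) stop("spectral_count must be >= 1")
  df
}

#' @rdname read_peptide_ids
#' @param ids Data frame of identifications.
#' @export
write_peptide_ids <- function(ids, path) {
  utils::write.table(ids, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an observation or logo table as TSV
#'
#' For a `codon_obs`, writes the 64 x 20 count matrix with per-codon
#' totals, expected frequencies and usage ratios appended; for a logo data
#' frame (from [logo_matrix()]), writes it as-is.
#'
#' @param x A `codon_obs` or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if (inherits(x, "codon_obs")) {
    df <- data.frame(codon = CODONS, x$counts,
                     total = x$totals, expected = x$expected,
                     usage_ratio = x$usage_ratio,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Bundled synthetic contaminant proteins
#'
#' 44 synthetic stand-in sequences mimicking the size range of a common
#' laboratory contaminant list (keratins, proteases, albumin). They are
#' random sequences, not real contaminant proteins, and serve only to give
#' the search database the paper-style contaminant partition.
#'
#' @return Named character vector of 44 protein sequences.
#' @export
synthetic_contaminants <- function() {
  read_fasta(system.file("extdata", "synthetic_contaminants.fasta",
                         package = "recodon", mustWork = TRUE),
             type = "protein")
}
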