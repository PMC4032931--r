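#' @keywords internal
#' @importFrom stats setNames
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#: all 64 codons in alphabetical order (row/key order used throughout)
CODONS <- {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

#: the 20 proteinogenic amino acids, alphabetical (column order of count matrices)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP <- "*"

new_genetic_code <- function(table, name) {
  stopifnot(length(table) == 64L)
  table <- table[CODONS]
  std <- standard_code_table()
  diff <- which(table != std)
  reassigned <- data.frame(codon = CODONS[diff],
                           meaning = unname(table[diff]),
                           stringsAsFactors = FALSE)
  structure(table, name = name, reassigned = reassigned,
            class = "genetic_code")
}

standard_code_table <- function() {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  setNames(aa, codons)[CODONS]
}

#' The standard genetic code
#'
#' NCBI translation table 1: 61 sense codons, three stop codons
#' (TAA, TAG, TGA). Codons are DNA triplets (T, not U).
#'
#' @return A `genetic_code` object: a named character vector mapping each of
#'   the 64 codons to a one-letter amino acid or `"*"` (stop), with
#'   attributes `name` and `reassigned` (changes relative to the standard
#'   code, empty here).
#' @examples
#' code <- standard_genetic_code()
#' code["ATG"]   # "M"
#' code["TGA"]   # "*"
#' @export
standard_genetic_code <- function() {
  new_genetic_code(standard_code_table(), "standard")
}

#' Derive a variant genetic code
#'
#' Reassigns a single codon of a base code to a new meaning, e.g. the
#' opal stop codon TGA to glycine. Applying all 20 amino acids plus stop to
#' TGA yields the 21 code hypotheses used for variant proteome databases.
#'
#' @param base A `genetic_code` to start from.
#' @param codon A DNA codon, e.g. `"TGA"`.
#' @param meaning One of the 20 one-letter amino acids, `"*"` or `"STOP"`.
#' @return A `genetic_code`; its `reassigned` attribute lists differences
#'   from the standard code.
#' @examples
#' gly <- variant_genetic_code(standard_genetic_code(), "TGA", "G")
#' gly["TGA"]  # "G"
#' @export
variant_genetic_code <- function(base, codon, meaning) {
  stopifnot(inherits(base, "genetic_code"))
  codon <- toupper(codon)
  if (!(is.character(codon) && length(codon) == 1L && codon %in% CODONS))
    stop("'codon' must be one of the 64 DNA codons, got: ", codon)
  meaning <- toupper(meaning)
  if (identical(meaning, "STOP")) meaning <- STOP
  if (!(meaning %in% c(AA20, STOP)))
    stop("'meaning' must be a one-letter amino acid, '*' or 'STOP', got: ",
         meaning)
  tab <- unclass(base)
  attributes(tab) <- list(names = names(unclass(base)))
  tab[codon] <- meaning
  label <- if (meaning == STOP) "STOP" else meaning
  new_genetic_code(tab, paste0(attr(base, "name"), "+", codon, "=", label))
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", attr(x, "name"), "\n")
  stops <- names(x)[x == STOP]
  cat("  stop codons:", paste(stops, collapse = ", "), "\n")
  re <- attr(x, "reassigned")
  if (nrow(re)) {
    cat("  reassigned relative to standard:\n")
    for (i in seq_len(nrow(re)))
      cat("    ", re$codon[i], "->", re$meaning[i], "\n")
  } else {
    cat("  no reassignments relative to the standard code\n")
  }
  invisible(x)
}

#' Write / read a genetic code as a key-value text file
#'
#' One `codon<TAB>symbol` line per codon, preceded by a `# name:` comment,
#' so a code used in an analysis can be archived and reloaded exactly.
#'
#' @param code A `genetic_code`.
#' @param path File path.
#' @return `read_genetic_code` returns a `genetic_code`;
#'   `write_genetic_code` returns `path` invisibly.
#' @export
write_genetic_code <- function(code, path) {
  stopifnot(inherits(code, "genetic_code"))
  lines <- c(paste0("# name: ", attr(code, "name")),
             paste0(names(code), "\t", unname(unclass(code))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genetic_code
#' @export
read_genetic_code <- function(path) {
  lines <- readLines(path)
  name <- sub("^# name: ", "", lines[startsWith(lines, "# name:")][1])
  if (is.na(name)) name <- "unnamed"
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed genetic code file: expected 'codon<TAB>symbol' lines")
  tab <- setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  if (!setequal(names(tab), CODONS))
    stop("genetic code file must define exactly the 64 codons")
  new_genetic_code(tab, name)
}

#' Translate an in-frame nucleotide sequence
#'
#' Translates from position 1 of `seq` under an arbitrary genetic code.
#' Codons containing `N` translate to `X` (metagenomic contigs contain
#' ambiguity codes; downstream counting simply skips such positions). A
#' trailing stop codon terminates translation and is not included in the
#' protein. A trailing partial codon is dropped with a warning.
#'
#' @param seq A DNA string over `A,C,G,T,N` (case-insensitive), length >= 3.
#' @param code A `genetic_code`.
#' @param internal_stop Policy for stop codons before the last codon:
#'   `"terminate"` (translation ends at the first stop),
#'   `"readthrough_as_X"` (internal stops become `X`), or `"error"`.
#' @return A list with `protein` (character string), `stop_positions`
#'   (0-based codon indices of stop codons encountered, including a terminal
#'   stop) and `terminal_stop` (logical: sequence ended on a stop codon).
#' @examples
#' translate_dna("ATGGGATGA", standard_genetic_code())$protein   # "MG"
#' @export
translate_dna <- function(seq, code,
                          internal_stop = c("terminate", "readthrough_as_X",
                                            "error")) {
  internal_stop <- match.arg(internal_stop)
  stopifnot(inherits(code, "genetic_code"))
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a single non-empty DNA string")
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("'seq' contains characters outside A,C,G,T,N")
  n <- nchar(seq)
  if (n < 3L) stop("'seq' must be at least one codon (3 nt) long")
  if (n %% 3L != 0L) {
    warning("sequence length not a multiple of 3; trailing ",
            n %% 3L, " nt ignored")
    n <- n - n %% 3L
  }
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(unclass(code)[codons])
  aa[is.na(aa)] <- "X"                      # codons containing N
  stops <- which(aa == STOP)
  n_codon <- length(aa)
  terminal <- length(stops) > 0L && stops[length(stops)] == n_codon
  internal <- stops[stops < n_codon]
  if (internal_stop == "error" && length(internal))
    stop("internal stop codon at codon index ", internal[1] - 1L)
  if (internal_stop == "terminate" && length(stops)) {
    first <- stops[1]
    protein <- paste(aa[seq_len(first - 1L)], collapse = "")
    return(list(protein = protein, stop_positions = first - 1L,
                terminal_stop = first == n_codon))
  }
  aa[stops] <- "X"
  keep <- if (terminal) seq_len(n_codon - 1L) else seq_len(n_codon)
  list(protein = paste(aa[keep], collapse = ""),
       stop_positions = stops - 1L,
       terminal_stop = terminal)
}
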