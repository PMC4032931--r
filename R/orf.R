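#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A,C,G,T,N.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

START_CODONS <- c("ATG", "GTG", "TTG")

#' Find open reading frames under a candidate genetic code
#'
#' Scans all six frames of each contig. An ORF runs from a start codon
#' (ATG, GTG, TTG) to the first downstream stop codon under `code`; when
#' `readthrough_codon` is set, that codon is not treated as a stop, so
#' genes interrupted by a reassigned stop codon are recovered full length.
#' Positions read through translate to `X` in the reported translation
#' (their meaning is the hypothesis under test) and are recorded per ORF.
#' Within a frame, candidate starts sharing a stop resolve to the most
#' upstream start (the longest ORF). A deliberately simple caller: no
#' coding-potential scoring, no RBS model, no partial genes at contig edges.
#'
#' @param contigs Named character vector of DNA contigs (names become
#'   contig ids; unnamed input is numbered).
#' @param code A `genetic_code`.
#' @param min_aa Minimum translation length in residues (>= 1).
#' @param readthrough_codon Optional codon (e.g. `"TGA"`) to read through.
#' @return An `orf_set`: a data frame with one row per ORF and columns
#'   `orf_id`, `contig_id`, `start`, `end` (0-based half-open, forward
#'   strand), `strand`, `length_aa`, `translation`, `cds` (in-frame
#'   nucleotide sequence, reverse-complemented for minus-strand ORFs,
#'   including the terminal stop codon) and `readthrough_positions`
#'   (list column of 0-based protein coordinates). Attributes record the
#'   code name and readthrough codon.
#' @examples
#' find_orfs(c(ctg = "ATGAAATAA"), standard_genetic_code(), min_aa = 2)
#' @export
find_orfs <- function(contigs, code, min_aa = 30L, readthrough_codon = NULL) {
  stopifnot(inherits(code, "genetic_code"))
  if (!is.numeric(min_aa) || min_aa < 1) stop("'min_aa' must be >= 1")
  min_aa <- as.integer(min_aa)
  if (!is.null(readthrough_codon)) {
    readthrough_codon <- toupper(readthrough_codon)
    if (!readthrough_codon %in% CODONS)
      stop("'readthrough_codon' must be a valid DNA codon")
  }
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig_", seq_along(contigs))
  contigs <- toupper(contigs)
  tab <- unclass(code)

  rows <- list()
  for (cid in names(contigs)) {
    fwd <- contigs[[cid]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else reverse_complement(fwd)
      for (frame in 0:2) {
        n_codon <- (L - frame) %/% 3L
        if (n_codon < min_aa + 1L) next
        nt1 <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
        codons <- substring(s, nt1, nt1 + 2L)
        aa <- unname(tab[codons])
        aa[is.na(aa)] <- "X"
        is_stop <- aa == STOP
        if (!is.null(readthrough_codon)) {
          rt <- is_stop & codons == readthrough_codon
          is_stop <- is_stop & !rt
          aa[rt] <- "X"
        } else rt <- rep(FALSE, n_codon)
        stop_idx <- which(is_stop)
        if (!length(stop_idx)) next
        start_idx <- which(codons %in% START_CODONS)
        if (!length(start_idx)) next
        # terminating stop for each start = first stop at or after it
        rank <- findInterval(start_idx - 1L, stop_idx) + 1L
        ok <- rank <= length(stop_idx)
        start_idx <- start_idx[ok]; rank <- rank[ok]
        if (!length(start_idx)) next
        # most upstream start per stop
        first_start <- tapply(start_idx, rank, min)
        stops <- stop_idx[as.integer(names(first_start))]
        starts <- as.integer(first_start)
        len_aa <- stops - starts
        keep <- len_aa >= min_aa
        if (!any(keep)) next
        starts <- starts[keep]; stops <- stops[keep]; len_aa <- len_aa[keep]
        for (k in seq_along(starts)) {
          i0 <- starts[k]; i1 <- stops[k]
          b0 <- nt1[i0] - 1L               # 0-based on scanned strand
          e0 <- nt1[i1] + 2L
          prot <- paste(aa[i0:(i1 - 1L)], collapse = "")
          rtpos <- which(rt[i0:(i1 - 1L)]) - 1L
          if (strand == "+") { st <- b0; en <- e0 }
          else { st <- L - e0; en <- L - b0 }
          rows[[length(rows) + 1L]] <- list(
            contig_id = cid, start = st, end = en, strand = strand,
            length_aa = len_aa[k], translation = prot,
            cds = substr(s, b0 + 1L, e0),
            readthrough_positions = as.integer(rtpos))
        }
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(orf_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), length_aa = integer(),
                      translation = character(), cds = character(),
                      stringsAsFactors = FALSE)
    out$readthrough_positions <- list()
  } else {
    out <- data.frame(
      contig_id = vapply(rows, `[[`, "", "contig_id"),
      start = vapply(rows, `[[`, 0L, "start"),
      end = vapply(rows, `[[`, 0L, "end"),
      strand = vapply(rows, `[[`, "", "strand"),
      length_aa = vapply(rows, function(r) as.integer(r$length_aa), 0L),
      translation = vapply(rows, `[[`, "", "translation"),
      cds = vapply(rows, `[[`, "", "cds"),
      stringsAsFactors = FALSE)
    out$readthrough_positions <- lapply(rows, `[[`, "readthrough_positions")
    ord <- order(out$contig_id, out$start, out$end, out$strand)
    out <- out[ord, , drop = FALSE]
    out <- cbind(orf_id = sprintf("%s:%d-%d:%s", out$contig_id, out$start,
                                  out$end, out$strand),
                 out, stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  structure(out, class = c("orf_set", "data.frame"),
            code_name = attr(code, "name"),
            readthrough_codon = readthrough_codon)
}

#' Codon encoding a given residue of an ORF
#'
#' Maps a protein coordinate back to its codon, reverse-complemented for
#' minus-strand ORFs, so alignment columns can be attributed to codons.
#'
#' @param orf A single row of an `orf_set` (data frame with one row).
#' @param protein_pos 0-based residue index, `0 <= pos < length_aa`.
#' @return The codon string.
#' @export
codon_at <- function(orf, protein_pos) {
  if (nrow(orf) != 1L) stop("'orf' must be a single ORF (one row)")
  if (!is.numeric(protein_pos) || any(protein_pos < 0) ||
      any(protein_pos >= orf$length_aa))
    stop("'protein_pos' out of range [0, length_aa)")
  i <- as.integer(protein_pos)
  substring(orf$cds, 3L * i + 1L, 3L * i + 3L)
}

#' @export
print.orf_set <- function(x, ...) {
  cat(sprintf("ORF set: %d ORFs on %d contig(s) [code: %s%s]\n",
              nrow(x), length(unique(x$contig_id)), attr(x, "code_name"),
              if (!is.null(attr(x, "readthrough_codon")))
                paste0(", readthrough ", attr(x, "readthrough_codon")) else ""))
  if (nrow(x)) {
    n_rt <- sum(lengths(x$readthrough_positions) > 0L)
    cat(sprintf("  length range %d-%d aa; %d ORF(s) contain read-through codons\n",
                min(x$length_aa), max(x$length_aa), n_rt))
  }
  invisible(x)
}

#' Write ORF translations as protein FASTA
#'
#' Headers are `contig_id:start-end:strand`.
#'
#' @param orfs An `orf_set`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_orfs_fasta <- function(orfs, path, width = 60L) {
  prot <- setNames(orfs$translation, orfs$orf_id)
  write_fasta(prot, path, type = "protein", width = width)
}

#' Write ORFs as a BED-like table
#'
#' Six columns: contig, start, end, name, length_aa, strand
#' (0-based half-open coordinates).
#'
#' @inheritParams write_orfs_fasta
#' @return `path`, invisibly.
#' @export
write_orfs_bed <- function(orfs, path) {
  bed <- data.frame(orfs$contig_id, orfs$start, orfs$end, orfs$orf_id,
                    orfs$length_aa, orfs$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
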