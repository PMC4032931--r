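#' Build code-variant proteome databases
#'
#' Translates the bin's ORFs under one hypothesis per meaning of the target
#' codon. ORFs must have been called with read-through of the target codon
#' so that sequence downstream of a putative stop is available; in each
#' variant every read-through position carries that meaning's residue, and
#' the STOP variant truncates at the first read-through position (which is
#' what translation-with-stop produces). Proteins without read-through
#' positions are identical across variants. The paper-style three-way
#' comparison is `meanings = c("STOP", "G", "W")`; the exhaustive test uses
#' all 20 amino acids plus STOP.
#'
#' @param orfs An `orf_set` called with `readthrough_codon` equal to
#'   `target_codon`.
#' @param target_codon The codon whose meaning is hypothesized.
#' @param meanings Character vector of meanings: one-letter amino acids
#'   and/or `"STOP"`; `"all"` expands to all 20 amino acids plus STOP.
#' @return A list of `proteome_variant` objects, each a list with
#'   `variant_id`, `target_codon` and `proteins` (named character vector,
#'   no stop symbols).
#' @export
build_variant_proteomes <- function(orfs, target_codon = "TGA",
                                    meanings = "all") {
  if (!inherits(orfs, "orf_set")) stop("'orfs' must be an orf_set")
  target_codon <- toupper(target_codon)
  if (identical(meanings, "all")) meanings <- c("STOP", AA20)
  if (!length(meanings)) stop("'meanings' must be non-empty")
  meanings <- toupper(meanings)
  meanings[meanings == STOP] <- "STOP"
  bad <- setdiff(meanings, c(AA20, "STOP"))
  if (length(bad)) stop("invalid meanings: ", paste(bad, collapse = ", "))
  if (anyDuplicated(meanings)) stop("duplicate meanings")
  rt <- attr(orfs, "readthrough_codon")
  if (is.null(rt) || rt != target_codon)
    stop("ORFs must be called with readthrough_codon == target_codon (",
         target_codon, "), found: ", if (is.null(rt)) "none" else rt)

  base <- orfs$translation
  pos_list <- orfs$readthrough_positions
  ids <- orfs$orf_id
  lapply(meanings, function(m) {
    prot <- base
    for (i in which(lengths(pos_list) > 0L)) {
      p <- pos_list[[i]]
      if (m == "STOP") {
        prot[i] <- substr(prot[i], 1L, p[1])
      } else {
        ch <- strsplit(prot[i], "", fixed = TRUE)[[1]]
        ch[p + 1L] <- m
        prot[i] <- paste(ch, collapse = "")
      }
    }
    structure(list(variant_id = m, target_codon = target_codon,
                   proteins = setNames(prot, ids)),
              class = "proteome_variant")
  })
}

#' @export
print.proteome_variant <- function(x, ...) {
  cat(sprintf("Proteome variant '%s' (%s -> %s): %d proteins, %d residues\n",
              x$variant_id, x$target_codon, x$variant_id,
              length(x$proteins), sum(nchar(x$proteins))))
  invisible(x)
}

#' Assemble a target-decoy search database
#'
#' Targets are all variant proteins plus contaminants; decoys are the full
#' sequence reversal of every target, id-prefixed with `rev_`. Palindromic
#' targets (decoy equal to target) are flagged in the provenance table.
#'
#' @param variants List of `proteome_variant` objects.
#' @param contaminants Named character vector of contaminant protein
#'   sequences, or a FASTA path.
#' @return A `search_db`: list with `targets`, `decoys` (named character
#'   vectors of equal length) and `provenance` (data frame with `id`,
#'   `type`, `variant`, `palindrome`).
#' @export
add_decoys_and_contaminants <- function(variants, contaminants = character()) {
  if (is.character(contaminants) && length(contaminants) == 1L &&
      file.exists(contaminants))
    contaminants <- read_fasta(contaminants, type = "protein")
  tg <- list(); prov <- list()
  for (v in variants) {
    stopifnot(inherits(v, "proteome_variant"))
    ids <- paste0(names(v$proteins), "|variant=", v$variant_id)
    tg[[length(tg) + 1L]] <- setNames(v$proteins, ids)
    prov[[length(prov) + 1L]] <- data.frame(
      id = ids, type = "target", variant = v$variant_id,
      stringsAsFactors = FALSE)
  }
  if (length(contaminants)) {
    if (is.null(names(contaminants)))
      names(contaminants) <- paste0("contaminant_", seq_along(contaminants))
    tg[[length(tg) + 1L]] <- contaminants
    prov[[length(prov) + 1L]] <- data.frame(
      id = names(contaminants), type = "contaminant", variant = NA_character_,
      stringsAsFactors = FALSE)
  }
  targets <- unlist(tg)
  if (anyDuplicated(names(targets)))
    stop("duplicate sequence ids in search database: ",
         paste(unique(names(targets)[duplicated(names(targets))])[1:3],
               collapse = ", "))
  decoys <- vapply(targets, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1))
  names(decoys) <- paste0("rev_", names(targets))
  provenance <- do.call(rbind, prov)
  provenance$palindrome <- unname(targets == decoys)
  structure(list(targets = targets, decoys = decoys,
                 provenance = provenance),
            class = "search_db")
}

#' @export
print.search_db <- function(x, ...) {
  n_cont <- sum(x$provenance$type == "contaminant")
  cat(sprintf("Search database: %d targets (%d contaminants) + %d decoys = %d entries\n",
              length(x$targets), n_cont, length(x$decoys),
              length(x$targets) + length(x$decoys)))
  invisible(x)
}

#' Write a proteome variant (or search database) as FASTA
#'
#' Variant headers are `orf_id|variant=X`, 60-column wrapped.
#'
#' @param x A `proteome_variant` or `search_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins_fasta <- function(x, path) {
  seqs <- if (inherits(x, "proteome_variant")) {
    setNames(x$proteins, paste0(names(x$proteins), "|variant=", x$variant_id))
  } else if (inherits(x, "search_db")) {
    c(x$targets, x$decoys)
  } else stop("'x' must be a proteome_variant or search_db")
  seqs <- seqs[nzchar(seqs)]
  write_fasta(seqs, path, type = "protein")
}
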