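with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

sample_codons <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Simulate a genome bin with a planted genetic code
#'
#' Generates protein-coding genes whose codons are drawn i.i.d. from the GC
#' null model restricted to the sense codons of `code` — the model the
#' inference stage assumes, by construction. Under a code in which the
#' target stop codon is reassigned (e.g. TGA -> Gly), that codon is an
#' ordinary sense codon and most genes of realistic length contain it;
#' `recoded_gene_fraction` is a guaranteed floor on the fraction of genes
#' carrying at least one in-frame target codon (genes selected for the
#' guarantee are resampled until they contain one). Genes start with ATG,
#' end with a stop codon of `code`, sit on the forward strand and are
#' separated by random intergenic spacers.
#'
#' @param n_genes Number of genes.
#' @param gc GC fraction in (0, 1).
#' @param code The true `genetic_code` of the organism.
#' @param recoded_gene_fraction Minimum fraction of genes guaranteed to
#'   contain the reassigned codon (ignored when `code` has none).
#' @param mean_gene_aa Mean gene length in residues (gamma-distributed,
#'   minimum 80).
#' @param n_contigs Number of contigs the genes are distributed over.
#' @param intergenic_range Range of spacer lengths in nt.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list with `contigs` (named character), `true_code`,
#'   `true_proteins` (named character, translations under `true_code`),
#'   `genes` (data frame: gene, contig, start, end, strand,
#'   n_target_codons) and `target_codon` (`NA` if none reassigned).
#' @export
simulate_genome <- function(n_genes = 100L, gc = 0.332,
                            code = variant_genetic_code(
                              standard_genetic_code(), "TGA", "G"),
                            recoded_gene_fraction = 0.3,
                            mean_gene_aa = 200L, n_contigs = 5L,
                            intergenic_range = c(40L, 160L), seed = 1L) {
  stopifnot(inherits(code, "genetic_code"), n_genes >= 1,
            recoded_gene_fraction >= 0, recoded_gene_fraction <= 1)
  if (!(gc > 0 && gc < 1))
    stop("'gc' must be strictly inside (0, 1): start and stop codons need ",
         "both AT and GC bases")
  model <- gc_null_model(gc)
  freq <- expected_codon_frequency(model)
  sense <- names(unclass(code))[unclass(code) != STOP]
  stops <- names(unclass(code))[unclass(code) == STOP]
  sense_w <- freq[sense]
  stop_w <- freq[stops]
  re <- attr(code, "reassigned")
  target <- if (nrow(re)) re$codon[1] else NA_character_

  with_seed(seed, {
    lens <- pmax(80L, round(stats::rgamma(n_genes, shape = 10,
                                          rate = 10 / mean_gene_aa)))
    must_have <- if (!is.na(target))
      seq_len(round(recoded_gene_fraction * n_genes)) else integer()
    genes_nt <- character(n_genes)
    n_target <- integer(n_genes)
    for (g in seq_len(n_genes)) {
      repeat {
        body <- sample_codons(lens[g] - 1L, sense_w)
        if (!(g %in% must_have) || target %in% body) break
      }
      n_target[g] <- if (is.na(target)) 0L else sum(body == target)
      genes_nt[g] <- paste(c("ATG", body,
                             sample_codons(1L, stop_w)), collapse = "")
    }
    # distribute genes over contigs with random spacers
    contig_of <- sort(rep_len(seq_len(n_contigs), n_genes))
    spacer <- function() paste(sample(
      DNA_BASES,
      round(stats::runif(1, intergenic_range[1], intergenic_range[2])),
      replace = TRUE, prob = model$probs[DNA_BASES]), collapse = "")
    contigs <- character(n_contigs)
    coords <- data.frame(gene = sprintf("gene_%03d", seq_len(n_genes)),
                         contig = sprintf("ctg_%02d", contig_of),
                         start = NA_integer_, end = NA_integer_,
                         strand = "+", n_target_codons = n_target,
                         stringsAsFactors = FALSE)
    for (k in seq_len(n_contigs)) {
      s <- spacer()
      for (g in which(contig_of == k)) {
        coords$start[g] <- nchar(s)
        s <- paste0(s, genes_nt[g])
        coords$end[g] <- nchar(s)
        s <- paste0(s, spacer())
      }
      contigs[k] <- s
    }
    names(contigs) <- sprintf("ctg_%02d", seq_len(n_contigs))
    proteins <- vapply(genes_nt, function(x)
      translate_dna(x, code, "terminate")$protein, "", USE.NAMES = FALSE)
    list(contigs = contigs, true_code = code,
         true_proteins = setNames(proteins, coords$gene),
         genes = coords, target_codon = target)
  })
}

#' Simulate divergent reference protein families
#'
#' Each family is `n_members` mutated copies of one true protein: point
#' substitutions at `substitution_rate` per site (uniform over the other 19
#' residues), optionally per-member deletions (gaps) at `indel_rate`. With
#' no indels the members align trivially and the expected conservation of a
#' column is `(1-r)^m`-ish around `(1-r) + r/20` per member.
#'
#' @param true_proteins Named character vector of proteins.
#' @param n_members Members per family.
#' @param substitution_rate Per-site substitution probability in `[0, 1)`.
#' @param indel_rate Per-site, per-member deletion (gap) probability.
#' @param seed Integer seed.
#' @return A list of `ref_family` objects, one per input protein.
#' @export
simulate_reference_families <- function(true_proteins, n_members = 5L,
                                        substitution_rate = 0.15,
                                        indel_rate = 0, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1)
  with_seed(seed, {
    lapply(names(true_proteins), function(nm) {
      res <- strsplit(true_proteins[[nm]], "", fixed = TRUE)[[1]]
      L <- length(res)
      members <- vapply(seq_len(n_members), function(j) {
        r <- res
        mut <- stats::runif(L) < substitution_rate
        if (any(mut)) {
          orig <- match(r[mut], AA20)
          pick <- sample.int(19L, sum(mut), replace = TRUE)
          r[mut] <- AA20[pick + (pick >= orig)]
        }
        if (indel_rate > 0) {
          del <- stats::runif(L) < indel_rate
          r[del] <- "-"
        }
        paste(r, collapse = "")
      }, character(1))
      reference_family(setNames(members, paste0(nm, "_m", seq_len(n_members))),
                       family_id = paste0("fam_", nm))
    })
  })
}

#' Simulate noisy peptide identifications
#'
#' Emulates filtered search-engine output: `n_true` peptides sampled from
#' the tryptic digest of the true proteome, observed neutral mass equal to
#' the theoretical (fixed-modification) mass perturbed by Gaussian relative
#' error of `mass_error_ppm_sd` ppm, spectral counts geometric with mean
#' `spectral_count_mean`; plus a fraction of false identifications: random
#' tryptic-looking sequences with masses matching their own theoretical
#' mass (so only the database-membership filter can remove them). The true
#' false-identification structure of a real search (homology-biased) is not
#' modelled; labels are recorded in the `truth` column.
#'
#' @param true_proteins Named character vector (proteome under the true code).
#' @param n_true Number of true peptide identifications.
#' @param false_id_rate Expected fraction of false identifications among
#'   all identifications.
#' @param mass_error_ppm_sd Gaussian ppm error standard deviation.
#' @param spectral_count_mean Mean of the geometric spectral-count
#'   distribution (support 1, 2, ...).
#' @inheritParams tryptic_digest
#' @inheritParams peptide_mass
#' @param seed Integer seed.
#' @return Data frame with `peptide`, `observed_mass`, `spectral_count`,
#'   `mods` (empty string) and `truth` (logical). If the digest is smaller
#'   than `n_true`, sampling falls back to with-replacement and the result
#'   carries attribute `sampled_with_replacement = TRUE`.
#' @export
simulate_peptide_ids <- function(true_proteins, n_true = 1000L,
                                 false_id_rate = 0.01,
                                 mass_error_ppm_sd = 3,
                                 spectral_count_mean = 3,
                                 missed_cleavages = 2L,
                                 length_range = c(6L, 50L),
                                 fixed_mods = DEFAULT_FIXED_MODS,
                                 seed = 1L) {
  stopifnot(false_id_rate >= 0, false_id_rate < 1, mass_error_ppm_sd >= 0)
  pool <- digest_proteome(true_proteins, missed_cleavages, length_range)
  if (!length(pool)) stop("true proteome digest is empty")
  with_seed(seed, {
    replace <- length(pool) < n_true
    true_pep <- sample(pool, n_true, replace = replace)
    n_false <- stats::rbinom(1L, n_true,
                             false_id_rate / (1 - false_id_rate))
    false_pep <- vapply(seq_len(n_false), function(i) {
      len <- sample(seq(length_range[1], 25L), 1L)
      paste(c(sample(AA20, len - 1L, replace = TRUE),
              sample(c("K", "R"), 1L)), collapse = "")
    }, character(1))
    pep <- c(true_pep, false_pep)
    theo <- peptide_mass(pep, fixed_mods)
    eps <- stats::rnorm(length(pep), 0, mass_error_ppm_sd) * 1e-6
    counts <- stats::rgeom(length(pep),
                           prob = 1 / spectral_count_mean) + 1L
    out <- data.frame(peptide = pep,
                      observed_mass = theo * (1 + eps),
                      spectral_count = counts,
                      mods = "",
                      truth = c(rep(TRUE, n_true), rep(FALSE, n_false)),
                      stringsAsFactors = FALSE)
    ord <- sample.int(nrow(out))          # shuffle true/false together
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    if (replace) attr(out, "sampled_with_replacement") <- TRUE
    out
  })
}

#' Simulate a complete recoding study dataset
#'
#' Couples the genome, family and peptide generators with sub-seeds derived
#' from one master seed, producing everything the detection and validation
#' stages consume plus the ground truth they are judged against.
#'
#' @inheritParams simulate_genome
#' @inheritParams simulate_reference_families
#' @inheritParams simulate_peptide_ids
#' @return A `recoding_sim`: list with `contigs`, `true_code`,
#'   `true_proteins`, `genes`, `families`, `peptide_ids`, `target_codon`,
#'   `params`, `seed`.
#' @export
simulate_recoding_dataset <- function(n_genes = 100L, gc = 0.332,
                                      code = variant_genetic_code(
                                        standard_genetic_code(), "TGA", "G"),
                                      recoded_gene_fraction = 0.3,
                                      mean_gene_aa = 200L, n_contigs = 5L,
                                      n_members = 5L,
                                      substitution_rate = 0.15,
                                      n_true = 1000L, false_id_rate = 0.01,
                                      mass_error_ppm_sd = 3,
                                      spectral_count_mean = 3,
                                      missed_cleavages = 2L,
                                      length_range = c(6L, 50L),
                                      seed = 1L) {
  seed <- as.integer(seed) %% 536870912L    # headroom for derived seeds
  gen <- simulate_genome(n_genes = n_genes, gc = gc, code = code,
                         recoded_gene_fraction = recoded_gene_fraction,
                         mean_gene_aa = mean_gene_aa, n_contigs = n_contigs,
                         seed = seed)
  fam <- simulate_reference_families(gen$true_proteins,
                                     n_members = n_members,
                                     substitution_rate = substitution_rate,
                                     seed = seed + 1L)
  pep <- simulate_peptide_ids(gen$true_proteins, n_true = n_true,
                              false_id_rate = false_id_rate,
                              mass_error_ppm_sd = mass_error_ppm_sd,
                              spectral_count_mean = spectral_count_mean,
                              missed_cleavages = missed_cleavages,
                              length_range = length_range,
                              seed = seed + 2L)
  structure(list(contigs = gen$contigs, true_code = gen$true_code,
                 true_proteins = gen$true_proteins, genes = gen$genes,
                 families = fam, peptide_ids = pep,
                 target_codon = gen$target_codon,
                 params = list(n_genes = n_genes, gc = gc,
                               recoded_gene_fraction = recoded_gene_fraction,
                               mean_gene_aa = mean_gene_aa,
                               n_contigs = n_contigs, n_members = n_members,
                               substitution_rate = substitution_rate,
                               n_true = n_true, false_id_rate = false_id_rate,
                               mass_error_ppm_sd = mass_error_ppm_sd,
                               spectral_count_mean = spectral_count_mean),
                 seed = seed),
            class = "recoding_sim")
}

#' @export
print.recoding_sim <- function(x, ...) {
  cat(sprintf("Synthetic recoding dataset (seed %d)\n", x$seed))
  cat(sprintf("  genome: %d genes on %d contigs, %.0f kb, gc = %.3f, code: %s\n",
              nrow(x$genes), length(x$contigs),
              sum(nchar(x$contigs)) / 1000, gc_fraction(x$contigs),
              attr(x$true_code, "name")))
  cat(sprintf("  %d reference families; %d peptide identifications (%d false)\n",
              length(x$families), nrow(x$peptide_ids),
              sum(!x$peptide_ids$truth)))
  invisible(x)
}

#' Write a simulated dataset as a directory of standard files
#'
#' Emits `contigs.fasta`, `families/fam_*.afa` (aligned FASTA),
#' `peptides.tsv`, `true_code.txt` and `truth.json`.
#'
#' @param sim A `recoding_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "recoding_sim"))
  dir.create(file.path(dir, "families"), recursive = TRUE,
             showWarnings = FALSE)
  write_fasta(sim$contigs, file.path(dir, "contigs.fasta"), type = "dna")
  for (f in sim$families)
    write_family_msa(f, file.path(dir, "families",
                                  paste0(f$family_id, ".afa")))
  write_peptide_ids(sim$peptide_ids, file.path(dir, "peptides.tsv"))
  write_genetic_code(sim$true_code, file.path(dir, "true_code.txt"))
  truth <- list(target_codon = sim$target_codon,
                genes = sim$genes, seed = sim$seed, params = sim$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
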