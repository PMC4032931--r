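config_defaults <- function() {
  list(
    seed = 1L,
    # generator
    n_genes = 100L, gc = 0.332, planted_meaning = "G",
    target_codon = "TGA", recoded_gene_fraction = 0.3,
    mean_gene_aa = 200L, n_contigs = 5L, n_members = 5L,
    substitution_rate = 0.15, n_true_peptides = 1000L,
    false_id_rate = 0.01, mass_error_ppm_sd = 3, spectral_count_mean = 3,
    # ORF calling + inference
    min_orf_aa = 50L, conservation_min = 0.9, min_obs = 20L,
    min_freq = 0.5, min_usage = 0.3, gap_open = 11, gap_ext = 1,
    min_score_frac = 0.4,
    # proteomics validation
    meanings = "all", missed_cleavages = 2L, peptide_length_min = 6L,
    peptide_length_max = 50L, tol_ppm = 10, min_spectra = 2L,
    decision_min_ratio = 10,
    # io
    contaminants = "bundled", outdir = NA_character_,
    write_intermediates = FALSE)
}

#' Pipeline configuration
#'
#' All thresholds and generator parameters of the pipeline in one
#' validated object. Unknown keys are rejected; every threshold is checked
#' against its documented range. `planted_meaning = "STOP"` simulates a
#' standard-code genome (the negative control).
#'
#' @param ... Named overrides of the defaults (see [config_defaults]
#'   values in the vignette).
#' @return A `recoding_config` (named list).
#' @export
recoding_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all config overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "recoding_config")
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("config: ", msg)
  chk(cfg$gc > 0 && cfg$gc < 1, "gc must be in (0, 1)")
  chk(cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(cfg$recoded_gene_fraction >= 0 && cfg$recoded_gene_fraction <= 1,
      "recoded_gene_fraction must be in [0, 1]")
  chk(cfg$conservation_min > 0 && cfg$conservation_min <= 1,
      "conservation_min must be in (0, 1]")
  chk(cfg$min_obs > 0 && cfg$min_freq > 0 && cfg$min_usage > 0,
      "prediction thresholds must be positive")
  chk(cfg$min_freq <= 1, "min_freq must be <= 1")
  chk(cfg$tol_ppm >= 0, "tol_ppm must be >= 0")
  chk(cfg$min_spectra >= 1, "min_spectra must be >= 1")
  chk(cfg$missed_cleavages >= 0, "missed_cleavages must be >= 0")
  chk(cfg$peptide_length_min >= 1 &&
        cfg$peptide_length_max >= cfg$peptide_length_min,
      "peptide length range invalid")
  chk(toupper(cfg$target_codon) %in% CODONS, "target_codon invalid")
  pm <- toupper(cfg$planted_meaning)
  chk(pm %in% c(AA20, "STOP", STOP), "planted_meaning invalid")
  chk(identical(cfg$meanings, "all") ||
        all(toupper(cfg$meanings) %in% c(AA20, "STOP", STOP)),
      "meanings invalid")
  chk(cfg$decision_min_ratio >= 1, "decision_min_ratio must be >= 1")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip unchanged; unknown keys in the file are
#' rejected on read.
#'
#' @param path YAML file.
#' @return `read_config` returns a `recoding_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(recoding_config, vals)
}

#' @rdname read_config
#' @param config A `recoding_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "recoding_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.recoding_config <- function(x, ...) {
  cat("recodon pipeline configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Run the full detection + validation pipeline
#'
#' Executes the paper-style workflow on a simulated genome bin:
#' simulate -> call ORFs with read-through of the target codon -> collect
#' codon observations against the reference families -> predict the code
#' -> build variant proteomes and the decoy+contaminant search database ->
#' filter peptide identifications (database membership, ppm tolerance,
#' spectral count; contaminant-matching peptides are excluded from variant
#' classification and logged) -> count variant-unique peptides and decide.
#' Fully deterministic given the configuration (which includes the seed).
#'
#' @param config A `recoding_config`.
#' @param outdir Optional output directory; when set (or configured),
#'   intermediates and the JSON report are written there.
#' @return A `recoding_report`: list with `schema_version`, `config`,
#'   `genome` (summary), `prediction` (per-codon data frame), `target`
#'   (target-codon record), `uniqueness`, `filter_log`, `counts`.
#' @export
run_pipeline <- function(config = recoding_config(), outdir = NULL) {
  stopifnot(inherits(config, "recoding_config"))
  if (is.null(outdir) && !is.na(config$outdir)) outdir <- config$outdir
  pm <- toupper(config$planted_meaning)
  if (pm == STOP) pm <- "STOP"
  true_code <- if (pm == "STOP") standard_genetic_code()
               else variant_genetic_code(standard_genetic_code(),
                                         config$target_codon, pm)
  lr <- c(config$peptide_length_min, config$peptide_length_max)

  sim <- simulate_recoding_dataset(
    n_genes = config$n_genes, gc = config$gc, code = true_code,
    recoded_gene_fraction = config$recoded_gene_fraction,
    mean_gene_aa = config$mean_gene_aa, n_contigs = config$n_contigs,
    n_members = config$n_members,
    substitution_rate = config$substitution_rate,
    n_true = config$n_true_peptides, false_id_rate = config$false_id_rate,
    mass_error_ppm_sd = config$mass_error_ppm_sd,
    spectral_count_mean = config$spectral_count_mean,
    missed_cleavages = config$missed_cleavages, length_range = lr,
    seed = config$seed)

  orfs <- find_orfs(sim$contigs, standard_genetic_code(),
                    min_aa = config$min_orf_aa,
                    readthrough_codon = config$target_codon)
  gc_hat <- gc_fraction(sim$contigs)
  obs <- collect_observations(orfs, sim$families, gc = gc_hat,
                              conservation_min = config$conservation_min,
                              gap_open = config$gap_open,
                              gap_ext = config$gap_ext,
                              min_score_frac = config$min_score_frac)
  pred <- predict_code(obs, min_obs = config$min_obs,
                       min_freq = config$min_freq,
                       min_usage = config$min_usage)

  variants <- build_variant_proteomes(orfs,
                                      target_codon = config$target_codon,
                                      meanings = config$meanings)
  contaminants <- if (identical(config$contaminants, "bundled"))
    synthetic_contaminants() else read_fasta(config$contaminants, "protein")
  db <- add_decoys_and_contaminants(variants, contaminants)

  retained <- ppm_filter(sim$peptide_ids, db, tol_ppm = config$tol_ppm,
                         min_spectra = config$min_spectra)
  flog <- attr(retained, "filter_log")
  # peptides matching a contaminant are not informative about the code
  cont_hay <- paste(contaminants, collapse = "#")
  is_cont <- vapply(retained$peptide, function(p)
    grepl(p, cont_hay, fixed = TRUE), logical(1), USE.NAMES = FALSE)
  flog <- c(flog, removed_contaminant_match = sum(is_cont),
            classified = sum(!is_cont))
  retained <- retained[!is_cont, , drop = FALSE]

  uniq <- uniqueness_report(retained, variants,
                            decision_min_ratio = config$decision_min_ratio,
                            missed_cleavages = config$missed_cleavages,
                            length_range = lr)

  tgt <- pred[pred$codon == toupper(config$target_codon), , drop = FALSE]
  report <- structure(list(
    schema_version = "1.0",
    config = unclass(config),
    genome = list(n_contigs = length(sim$contigs),
                  total_nt = sum(nchar(sim$contigs)),
                  gc_observed = gc_hat, n_orfs = nrow(orfs),
                  n_orfs_aligned = obs$n_orfs_used,
                  true_code = attr(sim$true_code, "name")),
    prediction = pred,
    target = list(codon = tgt$codon, predicted = tgt$predicted,
                  n_obs = tgt$n_obs, support_freq = tgt$support_freq,
                  usage_ratio = tgt$usage_ratio),
    uniqueness = list(per_variant = uniq$per_variant,
                      n_peptides = uniq$n_peptides,
                      n_unmatched = uniq$n_unmatched,
                      decision = uniq$decision,
                      runner_up_ratio = uniq$runner_up_ratio,
                      tie = uniq$tie),
    filter_log = as.list(flog)),
    class = "recoding_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (isTRUE(config$write_intermediates)) {
      write_dataset(sim, file.path(outdir, "dataset"))
      write_orfs_fasta(orfs, file.path(outdir, "orfs.faa"))
      write_orfs_bed(orfs, file.path(outdir, "orfs.bed"))
      write_tsv(obs, file.path(outdir, "codon_observations.tsv"))
      write_tsv(logo_matrix(obs), file.path(outdir, "logo.tsv"))
      for (v in variants)
        write_proteins_fasta(v, file.path(
          outdir, paste0("proteome_variant_", v$variant_id, ".fasta")))
      write_proteins_fasta(db, file.path(outdir, "search_database.fasta"))
      write_peptide_ids(retained, file.path(outdir, "retained_peptides.tsv"))
    }
    write_report(report, file.path(outdir, "report.json"))
  }
  report
}

#' Write a pipeline report as JSON
#'
#' @param report A `recoding_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  rep2 <- report
  ru <- rep2$uniqueness$runner_up_ratio
  if (!is.null(ru) && (is.na(ru) || is.infinite(ru)))
    rep2$uniqueness$runner_up_ratio <- as.character(ru)
  jsonlite::write_json(unclass(rep2), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "columns")
  invisible(path)
}

#' @export
print.recoding_report <- function(x, ...) {
  cat("recodon pipeline report\n")
  cat(sprintf("  genome: %d ORFs from %d contigs (%.0f kb, observed GC %.3f), true code: %s\n",
              x$genome$n_orfs, x$genome$n_contigs, x$genome$total_nt / 1000,
              x$genome$gc_observed, x$genome$true_code))
  cat(sprintf("  inference: %s predicted as '%s' (n = %d, support = %s, usage ratio = %s)\n",
              x$target$codon, x$target$predicted, x$target$n_obs,
              ifelse(is.na(x$target$support_freq), "NA",
                     sprintf("%.2f", x$target$support_freq)),
              ifelse(is.na(x$target$usage_ratio), "NA",
                     sprintf("%.3f", x$target$usage_ratio))))
  pv <- x$uniqueness$per_variant
  pv <- pv[order(pv$unique_count, decreasing = TRUE), ]
  top <- pv[seq_len(min(3L, nrow(pv))), ]
  cat(sprintf("  validation: unique peptides %s; decision: %s\n",
              paste(sprintf("%s=%d", top$variant, top$unique_count),
                    collapse = ", "),
              x$uniqueness$decision))
  cat(sprintf("  peptides: %d input, %d classified\n",
              x$filter_log$input, x$filter_log$classified))
  invisible(x)
}
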