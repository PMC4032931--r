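test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_identical(tryptic_digest("MKAAAR", 0, c(1, 50)), c("MK", "AAAR"))
  expect_identical(tryptic_digest("AKPAR", 0, c(1, 50)), "AKPAR")
  expect_identical(tryptic_digest("MKAAAR", 1, c(1, 50)),
                   c("MK", "MKAAAR", "AAAR"))
  # length filter
  expect_identical(tryptic_digest("MKAAAR", 0, c(3, 50)), "AAAR")
  expect_identical(tryptic_digest("", 0, c(1, 50)), character())
})

test_that("zero-missed fragments reconstruct the protein; sets match the
           exhaustive substring oracle", {
  set.seed(33)
  for (rep in 1:8) {
    prot <- random_protein(60)
    expect_identical(paste(tryptic_digest(prot, 0, c(1, 1e6)),
                           collapse = ""), prot)
    for (missed in 0:2) {
      got <- sort(unique(tryptic_digest(prot, missed, c(2, 30))))
      want <- sort(unique(all_tryptic_substrings(prot, missed, c(2, 30))))
      expect_identical(got, want)
    }
  }
})

test_that("monoisotopic masses match the standard residue table", {
  expect_equal(peptide_mass("G", fixed_mods = NULL), 75.032025,
               tolerance = 1e-5)
  expect_equal(peptide_mass("PEPTIDE", fixed_mods = NULL), 799.359964,
               tolerance = 1e-5)
  expect_equal(peptide_mass("ACDEFGHIK", fixed_mods = NULL), 1018.454216,
               tolerance = 1e-5)
  # residue additivity holds exactly
  expect_equal(peptide_mass("GG", fixed_mods = NULL) -
                 peptide_mass("G", fixed_mods = NULL),
               57.021464, tolerance = 1e-9)
  # fixed carbamidomethylation on cysteine
  expect_equal(peptide_mass("C"), 103.009185 + 57.0214 + 18.0105647,
               tolerance = 1e-5)
  expect_error(peptide_mass("GZ"), "unknown residue")
  expect_error(peptide_mass(""), "empty")
})

test_that("modform enumeration covers variable-modification combinations", {
  # two oxidizable methionines x optional N-terminal carbamylation
  mm <- modform_masses("MMGK")
  base <- peptide_mass("MMGK")
  expect_equal(sort(mm),
               sort(base + rep(c(0, 15.994915, 2 * 15.994915), 2) +
                      rep(c(0, 43.005814), each = 3)),
               tolerance = 1e-9)
  expect_equal(modform_masses("GGK", variable_mods = NULL),
               peptide_mass("GGK"))
})

test_that("the ppm filter applies database, tolerance and spectra rules", {
  prot <- "MKAAAGGGKWWWTTTK"
  peps <- c("AAAGGGK", "WWWTTTK", "YYYDDDK")
  th <- peptide_mass(peps)
  ids <- data.frame(
    peptide = c("AAAGGGK", "AAAGGGK", "WWWTTTK", "YYYDDDK"),
    observed_mass = c(th[1], th[1] * (1 + 2e-5), th[2], 800),
    spectral_count = c(3L, 3L, 1L, 5L),
    mods = "", stringsAsFactors = FALSE)
  out <- ppm_filter(ids, prot, tol_ppm = 10, min_spectra = 2)
  expect_identical(out$peptide, "AAAGGGK")
  log <- attr(out, "filter_log")
  expect_equal(unname(log["input"]), 4)
  expect_equal(unname(log["removed_not_in_database"]), 1)
  expect_equal(unname(log["removed_ppm"]), 1)      # the 20-ppm deviation
  expect_equal(unname(log["removed_spectra"]), 1)  # single-spectrum peptide
  expect_equal(unname(log["retained"]), 1)
  # bookkeeping identity
  expect_equal(log[["input"]],
               sum(log[c("removed_not_in_database", "removed_ppm",
                         "removed_spectra", "retained")]))
  # exact mass passes at zero tolerance
  out0 <- ppm_filter(ids[3, ], prot, tol_ppm = 0, min_spectra = 1)
  expect_equal(nrow(out0), 1L)
})

test_that("peptides are classified by variant digest membership", {
  orfs <- find_orfs(c(g = "ATGAAATGAGGGAAAAAAGATTAA"), standard_genetic_code(),
                    min_aa = 3, readthrough_codon = "TGA")
  variants <- build_variant_proteomes(orfs, "TGA", c("STOP", "G", "W"))
  # G variant protein: MKGGKK D; peptide spanning the read-through
  m <- classify_peptides(c("MKGGK", "MKWGK", "MK"), variants,
                         missed_cleavages = 1, length_range = c(1, 50))
  expect_equal(m["MKGGK", ], c(STOP = FALSE, G = TRUE, W = FALSE))
  expect_equal(m["MKWGK", ], c(STOP = FALSE, G = FALSE, W = TRUE))
  expect_equal(m["MK", ], c(STOP = TRUE, G = TRUE, W = TRUE))

  # support sets are monotone in the proteome
  bigger <- variants
  bigger[[1]]$proteins <- c(bigger[[1]]$proteins, extra = "MKWGKK")
  m2 <- classify_peptides(c("MKGGK", "MKWGK", "MK"), bigger,
                          missed_cleavages = 1, length_range = c(1, 50))
  expect_true(all(m2 >= m))
})

test_that("uniqueness report reproduces the headline counting pattern", {
  set.seed(55)
  mk_pep <- function(n, len = 8)
    unique(vapply(seq_len(2 * n), function(i)
      paste(c(sample(setdiff(recodon:::AA20, c("K", "R", "P")), len - 1,
                     replace = TRUE), "K"), collapse = ""), ""))[seq_len(n)]
  gly_pep <- mk_pep(97)
  trp_pep <- setdiff(mk_pep(110), gly_pep)[1:3]
  mk_variant <- function(id, peps) structure(
    list(variant_id = id, target_codon = "TGA",
         proteins = setNames(paste(peps, collapse = ""), "p1")),
    class = "proteome_variant")
  variants <- list(mk_variant("STOP", "AAAAAAK"),
                   mk_variant("G", gly_pep), mk_variant("W", trp_pep))
  rep <- uniqueness_report(c(gly_pep, trp_pep), variants,
                           decision_min_ratio = 10,
                           missed_cleavages = 0, length_range = c(6, 50))
  pv <- setNames(rep$per_variant$unique_count, rep$per_variant$variant)
  expect_equal(pv[["G"]], 97L)
  expect_equal(pv[["W"]], 3L)
  expect_equal(pv[["STOP"]], 0L)
  expect_identical(rep$decision, "G")
  expect_equal(rep$runner_up_ratio, 97 / 3, tolerance = 1e-12)
})

test_that("uniqueness decisions handle emptiness, ties and weak leads", {
  v <- function(id, prot) structure(
    list(variant_id = id, target_codon = "TGA",
         proteins = c(p = prot)), class = "proteome_variant")
  vars <- list(v("A", "AAADDDK"), v("K", "EEEFFFK"))
  none <- uniqueness_report(character(), vars)
  expect_identical(none$decision, "undetermined")
  expect_equal(none$per_variant$unique_count, c(0L, 0L))

  tie <- uniqueness_report(c("AAADDDK", "EEEFFFK"), vars,
                           missed_cleavages = 0, length_range = c(6, 50))
  expect_identical(tie$decision, "undetermined")
  expect_true(tie$tie)

  # a 2:1 lead is below the default 10x requirement
  vars2 <- list(v("A", "AAADDDKCCCDDDK"), v("K", "EEEFFFK"))
  weak <- uniqueness_report(c("AAADDDK", "CCCDDDK", "EEEFFFK"), vars2,
                            missed_cleavages = 0, length_range = c(6, 50))
  expect_identical(weak$decision, "undetermined")
  expect_equal(weak$runner_up_ratio, 2)
  # unique + shared + unmatched partitions the peptides
  expect_equal(sum(weak$per_variant$unique_count) + weak$n_unmatched +
                 sum(weak$per_variant$shared_count > 0) * 0, 3L)
})
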