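std <- standard_genetic_code()

# one gene with an internal TGA whose true meaning is glycine, plus its
# perfectly conserved reference family
make_planted_case <- function(n_copies = 1) {
  set.seed(5)
  gly <- variant_genetic_code(std, "TGA", "G")
  sense_no_tga <- setdiff(names(std)[std != "*"], "TGA")
  body <- sample(sense_no_tga, 40, replace = TRUE)
  body[20] <- "TGA"
  gene <- paste(c("ATG", body, "TAA"), collapse = "")
  truth <- translate_dna(gene, gly)$protein
  contigs <- setNames(rep(gene, n_copies), paste0("c", seq_len(n_copies)))
  fam <- reference_family(setNames(rep(truth, 3),
                                   paste0("m", 1:3)), "fam1")
  orfs <- find_orfs(contigs, std, min_aa = 10, readthrough_codon = "TGA")
  list(orfs = orfs, families = list(fam), truth = truth)
}

test_that("a conserved TGA column is counted under its consensus residue", {
  cs <- make_planted_case()
  obs <- collect_observations(cs$orfs, cs$families, gc = 0.4)
  expect_equal(obs$counts["TGA", "G"], 1L)
  expect_equal(obs$totals[["TGA"]], 1)
  # all aligned columns of the fully conserved family are counted
  expect_equal(sum(obs$counts), nchar(cs$truth))
  expect_equal(obs$n_orfs_used, 1L)
})

test_that("counts scale with input copies; frequencies and ratios do not", {
  one <- collect_observations(make_planted_case(1)$orfs,
                              make_planted_case(1)$families, gc = 0.4)
  two <- collect_observations(make_planted_case(2)$orfs,
                              make_planted_case(2)$families, gc = 0.4)
  expect_equal(two$counts, one$counts * 2L)
  expect_equal(two$usage_ratio, one$usage_ratio)
})

test_that("observation collection is invariant to input order", {
  set.seed(12)
  gen <- simulate_genome(n_genes = 12, seed = 12)
  fams <- simulate_reference_families(gen$true_proteins, seed = 13)
  orfs <- find_orfs(gen$contigs, std, min_aa = 50, readthrough_codon = "TGA")
  a <- collect_observations(orfs, fams, gc = 0.35)
  perm <- sample(length(fams))
  b <- collect_observations(orfs[sample(nrow(orfs)), ], fams[perm],
                            gc = 0.35)
  expect_equal(a$counts, b$counts)
  expect_identical(predict_code(a)$predicted, predict_code(b)$predicted)
})

test_that("predict_code applies the documented decision rules", {
  # recoded stop codon: many observations, dominant residue, ample usage
  m <- matrix(0L, 2, 3, dimnames = list(c("TGA", "AAA"), c("G", "W", "K")))
  m["TGA", "G"] <- 45L; m["TGA", "W"] <- 5L; m["AAA", "K"] <- 60L
  obs <- make_obs(m)
  p <- predict_code(obs, min_obs = 20, min_freq = 0.5, min_usage = 0.3)
  expect_identical(p$predicted[p$codon == "TGA"], "G")
  expect_equal(p$support_freq[p$codon == "TGA"], 0.9)

  # depleted canonical stop -> STOP even with zero observations
  obs0 <- make_obs(matrix(100L, 1, 1, dimnames = list("AAA", "K")))
  p0 <- predict_code(obs0)
  expect_identical(p0$predicted[p0$codon == "TGA"], "*")
  expect_identical(p0$predicted[p0$codon == "TAA"], "*")

  # stop codon with usage but too few conserved observations
  obs2 <- make_obs(matrix(c(2L, 5L), 2, 1,
                          dimnames = list(c("TGA", "AAA"), "K")))
  p2 <- predict_code(obs2, min_obs = 20)
  expect_identical(p2$predicted[p2$codon == "TGA"], "insufficient_data")

  # sense codon below min_obs
  expect_identical(p0$predicted[p0$codon == "GGG"], "insufficient_data")
  # sense codon with enough data
  expect_identical(p0$predicted[p0$codon == "AAA"], "K")

  # tie broken alphabetically and flagged
  mt <- matrix(c(25L, 25L), 1, 2, dimnames = list("AAA", c("K", "N")))
  pt <- predict_code(make_obs(mt))
  expect_identical(pt$predicted[pt$codon == "AAA"], "K")
  expect_true(pt$tie[pt$codon == "AAA"])

  expect_error(predict_code(obs0, min_obs = 0), "positive")
})

test_that("logo heights per codon sum to the usage ratio", {
  cs <- make_planted_case()
  obs <- collect_observations(cs$orfs, cs$families, gc = 0.4)
  logo <- logo_matrix(obs)
  for (cd in unique(logo$codon)) {
    expect_equal(sum(logo$height[logo$codon == cd]),
                 unname(obs$usage_ratio[cd]))
  }
  expect_false("TTT" %in% logo$codon ||
                 obs$totals[["TTT"]] > 0)  # zero-observation codons absent
})

test_that("sense-codon usage ratios hover near parity at uniform GC", {
  gen <- simulate_genome(n_genes = 40, gc = 0.5, code = std,
                         recoded_gene_fraction = 0, seed = 99)
  fams <- simulate_reference_families(gen$true_proteins,
                                      substitution_rate = 0.05, seed = 100)
  orfs <- find_orfs(gen$contigs, std, min_aa = 50)
  obs <- collect_observations(orfs, fams, gc = 0.5)
  # sense codons are drawn uniformly from 61; expectation spans all 64,
  # so parity for a sense codon sits at 64/61
  sense <- names(std)[std != "*"]
  n <- sum(obs$totals)
  for (cd in sense[obs$totals[sense] >= 100]) {
    p <- 1 / 61
    sd_ur <- sqrt(p * (1 - p) / n) / (p * 61 / 64)
    expect_lt(abs(obs$usage_ratio[[cd]] - 64 / 61), 5 * sd_ur)
  }
  # and the three stops are depleted
  expect_true(all(obs$usage_ratio[c("TAA", "TAG", "TGA")] < 0.3))
})
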