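std <- standard_genetic_code()
gly <- variant_genetic_code(std, "TGA", "G")

test_that("the generator is deterministic in the seed", {
  a <- simulate_recoding_dataset(n_genes = 10, n_true = 50, seed = 42)
  b <- simulate_recoding_dataset(n_genes = 10, n_true = 50, seed = 42)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$peptide_ids, b$peptide_ids)
  expect_identical(lapply(a$families, `[[`, "members"),
                   lapply(b$families, `[[`, "members"))
  c <- simulate_recoding_dataset(n_genes = 10, n_true = 50, seed = 43)
  expect_false(identical(a$contigs, c$contigs))
})

test_that("generated genes obey the planted code and coordinates", {
  gen <- simulate_genome(n_genes = 25, seed = 3)
  expect_equal(nrow(gen$genes), 25L)
  for (g in seq_len(nrow(gen$genes))) {
    row <- gen$genes[g, ]
    nt <- substr(gen$contigs[[row$contig]], row$start + 1, row$end)
    expect_identical(substr(nt, 1, 3), "ATG")
    tr <- translate_dna(nt, gly, "terminate")
    expect_true(tr$terminal_stop)
    expect_identical(tr$protein, unname(gen$true_proteins[row$gene]))
    # recorded target-codon count matches the in-frame TGA count
    cods <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
    expect_equal(sum(cods[-length(cods)] == "TGA"), row$n_target_codons)
    # and each one encodes glycine in the true protein
    idx <- which(cods[-length(cods)] == "TGA")  # codon i -> residue i
    if (length(idx))
      expect_true(all(strsplit(tr$protein, "")[[1]][idx] == "G"))
  }
  # guaranteed floor: at least 30% of genes carry an in-frame TGA
  expect_gte(mean(gen$genes$n_target_codons > 0), 0.3)
  # standard-code genome contains no in-frame TGA in any gene
  gen0 <- simulate_genome(n_genes = 25, code = std,
                          recoded_gene_fraction = 0, seed = 3)
  expect_true(all(gen0$genes$n_target_codons == 0))
  expect_error(simulate_genome(gc = 0), "strictly inside")
})

test_that("genome GC matches the generative model's analytic expectation", {
  gen <- simulate_genome(n_genes = 100, gc = 0.332, seed = 17)
  freq <- expected_codon_frequency(gc_null_model(0.332))
  sense <- names(gly)[unclass(gly) != "*"]
  w <- freq[sense] / sum(freq[sense])
  gc_codon <- vapply(sense, function(cd)
    nchar(gsub("[^GC]", "", cd)) / 3, 0)
  gc_body <- sum(w * gc_codon)              # expected GC of sampled codons
  total_nt <- sum(nchar(gen$contigs))
  body_nt <- sum((gen$genes$end - gen$genes$start) - 6L)
  # starts are ATG (1/3 GC), stops TAA/TAG weighted by the null
  stop_w <- freq[c("TAA", "TAG")] / sum(freq[c("TAA", "TAG")])
  gc_exp <- (gc_body * body_nt +
               (1 / 3) * 3 * nrow(gen$genes) +
               sum(stop_w * c(0, 1 / 3)) * 3 * nrow(gen$genes) +
               0.332 * (total_nt - body_nt - 6 * nrow(gen$genes))) / total_nt
  sd3 <- 3 * sqrt(gc_exp * (1 - gc_exp) / total_nt)
  expect_lt(abs(gc_fraction(gen$contigs) - gc_exp), sd3 + 0.003)
})

test_that("reference families diverge at the configured rate", {
  prots <- setNames(c(random_protein(300), random_protein(300)),
                    c("p1", "p2"))
  f0 <- simulate_reference_families(prots, substitution_rate = 0, seed = 5)
  expect_true(all(vapply(f0, function(f) all(f$conservation == 1), TRUE)))
  expect_identical(unname(f0[[1]]$members[1]), unname(prots[1]))

  fams <- simulate_reference_families(prots, n_members = 5,
                                      substitution_rate = 0.15, seed = 6)
  cons <- unlist(lapply(fams, `[[`, "conservation"))
  # share of members keeping the original residue is 1 - rate; the modal
  # residue can only do better
  expect_gt(mean(cons), 0.85 - 3 * sqrt(0.85 * 0.15 / (5 * length(cons))))
  expect_lt(mean(cons), 0.92)
  # consensus equals the source protein at strongly conserved columns
  f <- fams[[1]]
  orig <- strsplit(prots[[1]], "")[[1]]
  strong <- f$conservation >= 0.8
  expect_true(all(f$consensus[strong] == orig[strong]))
})

test_that("peptide identifications carry calibrated noise and labels", {
  gen <- simulate_genome(n_genes = 30, seed = 9)
  ids <- simulate_peptide_ids(gen$true_proteins, n_true = 4000,
                              false_id_rate = 0.05, mass_error_ppm_sd = 3,
                              seed = 10)
  expect_true(all(ids$observed_mass > 0))
  expect_true(all(ids$spectral_count >= 1))
  # observed ppm error of true peptides: sd within 5% of target
  true_ids <- ids[ids$truth, ]
  th <- peptide_mass(true_ids$peptide)
  ppm <- (true_ids$observed_mass - th) / th * 1e6
  expect_lt(abs(stats::sd(ppm) - 3) / 3, 0.05)
  # false fraction within binomial error of the nominal rate
  p_false <- mean(!ids$truth)
  expect_lt(abs(p_false - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(ids)) + 0.005)
  # spectral counts are geometric with the configured mean
  expect_lt(abs(mean(ids$spectral_count) - 3), 0.3)

  # noiseless mode reproduces digest peptides exactly
  exact <- simulate_peptide_ids(gen$true_proteins, n_true = 200,
                                false_id_rate = 0, mass_error_ppm_sd = 0,
                                seed = 11)
  pool <- digest_proteome(gen$true_proteins)
  expect_true(all(exact$peptide %in% pool))
  expect_equal(exact$observed_mass, peptide_mass(exact$peptide),
               tolerance = 1e-12)
  expect_true(all(exact$truth))
})

test_that("datasets round-trip through the on-disk layout", {
  sim <- simulate_recoding_dataset(n_genes = 6, n_true = 40, seed = 77)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  ctg <- read_fasta(file.path(dir, "contigs.fasta"), "dna")
  expect_identical(ctg, sim$contigs)
  code <- read_genetic_code(file.path(dir, "true_code.txt"))
  expect_identical(unclass(code)[recodon:::CODONS],
                   unclass(sim$true_code)[recodon:::CODONS])
  ids <- read_peptide_ids(file.path(dir, "peptides.tsv"))
  expect_identical(ids$peptide, sim$peptide_ids$peptide)
  expect_equal(ids$observed_mass, sim$peptide_ids$observed_mass,
               tolerance = 1e-10)
  fam_files <- list.files(file.path(dir, "families"), full.names = TRUE)
  expect_length(fam_files, 6L)
  f1 <- read_family_msa(fam_files[1])
  expect_identical(f1$members, sim$families[[1]]$members)
})
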