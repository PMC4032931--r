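---
title: "Detecting stop-codon reassignment: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stop-codon reassignment: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recodon)
```

`recodon` decides whether a genome bin translates a canonical stop codon —
by default the opal codon TGA — as an amino acid, using two independent
lines of evidence: comparative (alignment of the bin's proteins to
conserved reference families) and proteogenomic (peptides identified by
mass spectrometry that are only explicable under one code hypothesis).
This vignette is the package's own account of the underlying models, the
parameters that matter, and the choices made where the design was
genuinely open.

## The comparative model

For every open reading frame called with read-through of the target codon,
the translation is aligned globally to the consensus of its best-matching
reference family. At alignment columns whose conservation is at least
`conservation_min`, the consensus residue is treated as a label for the
aligned query codon. Aggregating over all ORFs gives a 64 × 20 matrix of
codon–residue observations.

Two statistics per codon summarize the matrix:

* **support frequency** — the frequency of the modal residue among the
  codon's observations. A recoded codon faces the same residue at
  essentially every conserved position.
* **usage ratio** — the codon's share of all observations divided by its
  expected share under the GC null model. The null model assumes
  independent nucleotide positions with `P(G) = P(C) = gc/2`,
  `P(A) = P(T) = (1-gc)/2`; it is the simplest model expressible from GC
  content alone, and it is deliberately crude: it asks only whether a
  codon is *used at all* at roughly the rate composition predicts, not
  whether its usage is typical. The 64 frequencies sum to one, and the
  model is symmetric under complementation.

A genuinely unused stop codon appears in coding observations at most
through spurious alignments, so its usage ratio sits near zero; a sense or
recoded codon sits near parity. Note one systematic offset: observations
come only from sense codons, whose null shares sum to slightly less than
one, so a uniform sense codon has expected ratio ≈ 64/61, not exactly 1.
The thresholds are far from this offset, so it is left uncorrected.

### Decision rules

`predict_code()` applies, per codon:

* canonical stop codons default to STOP. They are called *recoded* only
  when all three axes agree: `n_obs >= min_obs`, modal support
  `>= min_freq`, and `usage_ratio >= min_usage`. A depleted stop codon
  (`usage_ratio < min_usage`) is called STOP outright even with very few
  observations — near-zero observations *are* the signature of a true
  stop, and demanding `min_obs` observations first would make the
  unused-codon case undecidable. A stop codon with appreciable usage but
  too few conserved observations returns `insufficient_data`.
* sense codons return `insufficient_data` below `min_obs`, otherwise the
  modal residue provided its support reaches `min_freq`. Ties are broken
  alphabetically and flagged.

Defaults: `conservation_min = 0.9`, `min_obs = 20`, `min_freq = 0.5`,
`min_usage = 0.3`. They are set so that a handful of spurious alignments
cannot flip a stop codon to "recoded" (hence `min_obs` well above noise
level), while a genuine recoding — which contributes hundreds of
observations in a 100-gene bin — passes comfortably.

### Alignment

Families are consumed as gapped multiple alignments; the query is aligned
to the *consensus* (modal residue per column), not to every member, so
family depth does not multiply counts. Alignment is global
Needleman–Wunsch with affine gaps (open 11, extend 1) under BLOSUM62 with
one modification: the ambiguity symbol `X` scores 0 against everything.
Read-through positions are translated as `X` precisely so that the residue
under test can neither attract nor repel the alignment that labels it.
Significance is score ≥ 40% of the query's self-score — length-normalized,
deterministic, and indifferent to family composition.

Two engineering layers sit in front of the aligner, both deterministic:
a shared 5-mer prescreen (only families sharing at least `min_kmer_hits`
5-mers with the query are attempted, best `top_n` candidates), and an
anchored fast path that scores the query's C-terminal window against the
full consensus with the same end-gap cost the global alignment would pay;
it is used only when it already clears the significance threshold, which
is exactly the situation (no indels) where the full alignment would
return the identical mapping. Anything else falls back to the full
affine-gap alignment.

## The proteogenomic model

ORFs called with read-through carry their read-through positions, so the
proteome can be re-translated under any hypothesis: each of the 20 amino
acids substitutes its residue at those positions, and the STOP hypothesis
truncates at the first one. Contaminant proteins and full-sequence
reversed decoys complete the search database.

Peptide identifications pass three filters: sequence membership in at
least one target protein, monoisotopic mass agreement within `tol_ppm`
(default 10 ppm) against *any* modform — combinations of fixed
carbamidomethyl-Cys (+57.0214 Da), variable Met oxidation (+15.994915 Da)
and N-terminal carbamylation (+43.005814 Da) — and a minimum spectral
count (default 2). Classification then asks, per code variant, whether the
peptide is producible from that variant's in-silico tryptic digest
(cleavage C-terminal to K/R except before P, ≤ 2 missed cleavages, length
6–50; common practice defaults). Uniqueness counts non-redundant peptide
*sequences*, not spectra; spectral counts act only as a stringency filter.
Peptides matching a contaminant are excluded from classification and
logged. The decision goes to the variant with the most unique peptides if
it leads the runner-up at least `decision_min_ratio`-fold (default 10),
otherwise `undetermined`; ties are flagged.

Isoleucine and leucine are kept distinct by default (sequence-level
matching); mass spectrometry cannot distinguish them, and a conservative
analysis could equate them by mapping both symbols to one character in
both database and identifications before classification.

## The synthetic-data generator

The generator emulates the study regime the pipeline targets: a low-GC
bin (default `gc = 0.332`) of `n_genes = 100` genes with mean length 200
residues — gene lengths gamma-distributed, floor 80, typical of
reduced-genome organisms — whose true code carries TGA→Gly. Codons are
drawn i.i.d. from the GC null restricted to the sense codons of the true
code; this makes the inference stage's normalization assumptions true by
construction, and is declared as the model under test, not a claim about
real genomes. Under the recoded code TGA is an ordinary sense codon, so
most genes of realistic length contain it; `recoded_gene_fraction = 0.3`
is a guaranteed *floor* on the fraction of genes carrying at least one
in-frame TGA (genes selected for the guarantee are resampled until they
do). Reading the parameter instead as an exclusive cap on TGA usage would
pin the codon's usage ratio to ≈ 0.32, directly on the `min_usage = 0.3`
decision boundary, and no threshold-based caller could be stable there.

Reference families are `n_members = 5` copies of each true protein with
point substitutions at `substitution_rate = 0.15` per site, uniform over
the other 19 residues (so the expected share of members keeping the
original residue is exactly 0.85); no indels by default, which keeps the
trivial alignment exact — an `indel_rate` option exists to stress the
aligner. Peptide identifications are `n_true = 1000` draws from the true
proteome's digest with Gaussian relative mass error (sd 3 ppm), a 1%
false-identification fraction of random tryptic-looking sequences, and
geometric spectral counts with mean 3. The false identifications are
uniform random, *not* homology-biased as real search errors are; the "1%
FDR" of a real pipeline is here a generator parameter, not an estimator.

What passing tests therefore show: the method recovers a planted recoding
under its own generative assumptions, at realistic sizes, against
independent brute-force oracles. What they do not show: robustness to
assembly chimerism, non-clonal bins, codon-usage bias beyond GC, biased
false identifications, or profile-HMM-grade remote homology — all outside
the generator's model and listed below as limitations.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open on the forward strand; minus-strand
  ORFs are reported in forward coordinates with the strand recorded.
* Codons containing `N` translate to `X` and are skipped by the counting
  stage rather than raising: metagenomic contigs contain ambiguity codes.
* Trailing partial codons are dropped with a warning; `gc = 0` or `1` is
  rejected by the genome generator (start and stop codons need both base
  classes) but fully supported by the null model, where absent-base codons
  get probability 0.
* Within a frame, candidate starts sharing a stop resolve to the most
  upstream start — deterministic, and it maximizes the codon observations
  available to inference. Nested ORFs across frames and strands are all
  retained; downstream stages tolerate redundancy.
* The empty peptide set, empty families, all-gap columns, palindromic
  decoys and zero-length STOP-variant truncations are all defined cases
  with tests.
* Every stochastic step takes an explicit integer seed and is bit
  reproducible; `run_pipeline()` writes byte-identical reports for a fixed
  configuration.

## Problem sizes

The shipped tests run the replicated end-to-end checks at the study's
default scale — 20 replicates of 100-gene genomes for each of the planted
and standard-code arms of the inference check, 20 replicates of the
1000-peptide validation check against all 21 variant proteomes, 20
brute-force ORF comparisons on 10 kb contigs, and a 10,000-identification
calibration of the ppm filter against the Gaussian tail probability —
sizes at which the binomial error bounds quoted in the tests are tight
enough to be meaningful.

## Known limitations

* Pairwise alignment to a family consensus is weaker than profile HMM
  search for remote homologs; the reference-family route here assumes
  reasonably close homologs exist.
* The GC null ignores codon-usage bias, amino-acid composition and
  strand asymmetry; a codon that is merely *rare* (but used) can drift
  toward `min_usage` in small bins.
* Gene calling has no coding-potential or RBS model and no partial genes
  at contig edges; it is a desk-scale stand-in for a real gene caller
  with the alternate code installed.
* Only one codon is reassigned per variant; simultaneous reassignment of
  several codons would need a larger hypothesis space.
* The bundled 44 contaminant sequences are synthetic stand-ins; real
  analyses should supply their laboratory's contaminant FASTA.
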