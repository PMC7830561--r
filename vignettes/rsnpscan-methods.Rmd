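---
title: "rsnpscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rsnpscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnpscan)
```

## Scope

`rsnpscan` implements a genome-wide regulatory-SNP (rSNP) analysis for a
two-cultivar crop panel: it predicts, for every promoter SNP, whether the
allele exchange creates or destroys a predicted transcription-factor
binding site (TFBS); it ranks rSNPs by phenotype association with an
iterated Boruta random-forest consensus; and it tests TFBS
over-representation in promoters of differentially expressed genes (DEGs)
against GC-matched background promoters. The package consumes standard
formats — genome FASTA, GFF3 gene models, VCF SNPs, JASPAR-format PFMs,
and DESeq2-style results tables — and never runs read alignment or
differential expression itself.

## The matrix similarity score

Motifs enter as position frequency matrices. Counts are converted to
frequencies column by column; a pseudocount of $\varepsilon = 10^{-4}$ is
then added to each frequency and the column renormalized,
$f \leftarrow (f + \varepsilon)/(1 + 4\varepsilon)$, which keeps every
frequency strictly positive without materially shifting JASPAR
frequencies. Each column $i$ carries an information weight

$$I(i) = \sum_{b \in \{A,C,G,T\}} f(i,b)\,\ln\!\big(4 f(i,b)\big),$$

which is 0 for a uniform column and approaches $\ln 4$ as the column
becomes fully conserved. A word $w$ of motif length $L$ scores

$$\mathrm{MSS}(w) = \frac{\mathrm{Current} - \mathrm{Min}}
  {\mathrm{Max} - \mathrm{Min}}, \qquad
  \mathrm{Current} = \sum_{i=1}^{L} I(i)\, f(i, w_i),$$

with Min and Max the per-position minima and maxima of $I(i)f(i,\cdot)$.
The per-position argmax word (the consensus) scores exactly 1 and the
argmin word exactly 0. This is the classic information-weighted min–max
match score; the package deliberately does **not** implement the
companion core-similarity score or per-matrix profile cut-offs — a single
global MSS threshold (default 0.85) is applied to every matrix, which is
how the analysis this package operationalizes was described. Ties in the
consensus are broken in A < C < G < T order; windows containing `N` are
skipped rather than scored, avoiding threshold artifacts near ambiguous
bases. A matrix whose columns are all uniform has Max = Min and is
rejected as unscorable. Scanning covers both strands by default (a
minus-strand site is scored on the reverse complement and reported in
input coordinates); a single-strand switch exists because the original
protocol did not state its strand policy.

## Allele-swap consequence classification

For each biallelic promoter SNP the engine extracts the ±25 bp flank
(51 bp, SNP central) and builds two copies differing only at the center:
one with the reference allele, one with the alternate. Both copies are
scanned with every PWM on both strands; sites below the MSS threshold or
not overlapping the SNP base are removed. Surviving sites are matched
across alleles by `(matrix_id, start, strand)` and labelled:

* **NoChange** — matched, $|\Delta \mathrm{MSS}| \le 10^{-9}$ (a pure
  floating-point guard; no biological tolerance is intended);
* **ScoreChange** — matched, larger difference;
* **LossOfTFBS** — present only on the reference allele;
* **GainOfTFBS** — present only on the alternate allele.

A SNP is an **rSNP** iff it has at least one Loss or Gain. Positional
identity is the strictest reproducible matching rule: a site that shifts
position between alleles counts as one Loss plus one Gain, not as a
score change. Consequences are symmetric by construction — exchanging
ref and alt exchanges Loss and Gain labels exactly, which the test suite
verifies record by record. A SNP inside two overlapping promoters yields
per-gene records but a single genome-wide rSNP call; per-tissue tables
are SNP × gene level and both tallies can be derived from the row-level
output.

## Promoter geometry

The TSS is the strand-aware gene boundary (start on `+`, end on `-`);
gene-level anchoring is used deliberately because transcript-level TSS
predictions are the least reliable part of draft crop annotations.
Promoters default to −500/+100 bp around the TSS (600 bp). Internally all
intervals are 0-based half-open; VCF and GFF3 keep their native 1-based
conventions and are converted at the I/O boundary, so coordinate
round-trips are exact: for every assigned SNP,
`pos = tss ± offset` reconstructs the VCF position bit for bit. Offset 0
is the TSS base itself; upstream offsets are negative. Windows running
past a chromosome edge are clipped and flagged, never silently
shortened. The promoter window used for rSNP selection defaults to the
enrichment window but is independently configurable, because the original
rSNP-selection window was never stated.

## TFBS enrichment

Per tissue, the foreground is the set of DEG promoters and the background
is sampled to match the foreground's GC-content histogram (bin width
0.05, one background promoter per foreground promoter by default,
foreground genes excluded, deficits borrowed from neighbouring bins with
a warning). The statistic is gene-level presence/absence: does a promoter
contain at least one site at the threshold. Each matrix is tested with a
one-sided Fisher exact test for over-representation, computed as the
upper hypergeometric tail — numerically identical to
`fisher.test(alternative = "greater")`, which the unit tests verify to
1e-12, but vectorizable. One-sided was chosen (and is recorded in the
output metadata) because the upstream protocol did not state sidedness
and the scientific question is over-representation. Bonferroni correction
uses the number of matrices actually tested, not the full library size,
and significance is `p_bonferroni < 0.01`.

## Boruta association

Genotypes (alt-allele counts 0/1/2; missing values mode-imputed per
feature) and binary cultivar labels feed an all-relevant feature
selection wrapper:

1. every feature gains a **shadow**: an independent row-permutation of
   itself, re-shuffled at every iteration;
2. a random forest is fit on the extended matrix and every column gets a
   variable-importance z-score: mean per-tree out-of-bag permutation
   importance divided by its standard deviation across trees (zero
   variance gives z = 0 with a warning);
3. a feature scores a *hit* when its z-score exceeds the maximum shadow
   z-score;
4. after each iteration a two-sided binomial test of accumulated hits
   against 0.5 (level 0.05) **confirms** features with significantly
   more hits and **rejects** those with significantly fewer; decided
   features are removed from the matrix;
5. the loop ends when everything is decided or an iteration cap (100) is
   reached; undecided features stay **Tentative** and never count as
   important.

No random-forest package ships in this environment, so the inner
classifier is implemented in compiled code: CART trees with the Gini
criterion, `mtry = floor(sqrt(p))`, grown to purity on bootstrap samples
drawn *within* each class — stratification is the documented answer to
the strong class imbalance of the motivating panel (280 vs 133 samples) —
with all randomness from a dedicated generator seeded per run, so results
are reproducible independent of R's RNG state. Because the bootstrap
depends on sample order, jointly permuting rows of the matrix and labels
can change individual decisions; this seeding artefact is the documented
exception to permutation invariance.

**Important rSNPs** are the intersection of the Confirmed sets over
repeated runs with independently derived seeds. Run seeds come from a
prefix-stable affine stream, so the consensus set shrinks (weakly) as the
number of runs grows — a property the tests exercise. The desk-scale
default is 20 runs; the published protocol's "e.g., 1000 times" is
illustrative and the run count is a parameter. Tentative features are
never important; this choice is flagged in the output because the
original treatment of Tentative was unstated.

## The synthetic world

The generator's defaults state one fixed world and every stage is tested
against it:

* two 200 kb chromosomes of i.i.d. bases at GC 0.37 (a typical Brassica
  genome-wide value); 60 non-overlapping genes on random strands with
  promoters fully inside chromosomes;
* 8 motifs of length 8–10 mixing sharp columns (dominant frequency
  0.90–0.97) and moderate ones (0.45–0.65), so that breaking the
  highest-information column of a consensus word reliably crosses the
  0.85 threshold;
* 50 planted gains, 50 losses, 100 neutral SNPs. A gain writes a
  consensus word with its highest-information column mutated to the
  anti-consensus base into a promoter; the SNP restores the consensus on
  the alternate allele. Losses are symmetric; neutrals are random
  substitutions kept clear of planted sites. Every candidate is
  **verified by the package's own classifier at generation time** and
  re-drawn on failure, so truth labels are exact and recovery tests are
  deterministic, not statistical;
* Hardy–Weinberg genotypes for a 280 + 133 panel (the motivating study's
  shape); non-associated SNPs share a class-common allele frequency
  drawn uniform(0.1, 0.5), associated SNPs differ by δ = 0.4 between
  classes, and empirical MAF > 0.05 is enforced;
* per-tissue DEG tables for flower, leaf, stem and root with planted
  up/down sets (|log2FC| > 2, padj < 0.05), 50% cross-tissue overlap,
  plus deliberate boundary rows (log2FC exactly ±2, padj exactly 0.05,
  padj NA) that must be excluded by the strict filter.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, population structure and kinship, transcript-level TSS uncertainty,
motif redundancy between related TF families, and realistic DEG effect
size distributions. A green recovery test therefore establishes that the
machinery is correct on unambiguous signal, not that real-data rSNP
calls at these thresholds have any particular precision.

## Numerical and degenerate-input choices

* PFM pseudocount $10^{-4}$ on frequencies (not counts), then
  renormalization — keeps $\ln$ terms finite with minimal distortion.
* NoChange/ScoreChange tolerance $10^{-9}$.
* MAF filter is strictly greater than 0.05; DEG thresholds are strict on
  both axes, and `padj = NA` is never significant, mirroring the
  independent-filtering semantics of the upstream DE tool.
* SNPs within 25 bp of a chromosome edge are flagged and skipped, not
  truncated.
* Multi-allelic VCF records are split; indels and non-ACGT alleles are
  dropped; a REF/genome mismatch is a hard error naming the site.
* Zero-width enrichment tables give p = 1; the sample odds ratio is
  reported as computed (may be Inf).
* One global pipeline seed fans out to per-stage seeds through a fixed
  hash, so stages rerun standalone reproduce the pipeline slice exactly,
  and two runs with one seed write byte-identical tables.

## A worked example

```{r example, eval = FALSE}
library(rsnpscan)

ds <- simulate_dataset(sim_config(seed = 1), outdir = "fixtures")
cfg <- pipeline_config(
  genome = ds$paths$genome, gff = ds$paths$gff, vcf = ds$paths$vcf,
  pfm = ds$paths$pfm,
  deg_tables = c(flower = "fixtures/deg_flower.tsv",
                 leaf   = "fixtures/deg_leaf.tsv",
                 stem   = "fixtures/deg_stem.tsv",
                 root   = "fixtures/deg_root.tsv"),
  genotypes = ds$paths$genotypes, labels = ds$paths$labels,
  out_dir = "out", seed = 1)
res <- run_pipeline(cfg)
length(res$rsnps)      # planted gains + losses, recovered exactly
res$important          # planted association SNPs
```

## Limitations

Site calls are PWM matches, not occupancy measurements; the MSS threshold
trades sensitivity for specificity and is not calibrated to a p-value.
Consequence labels ignore chromatin context and TF concentration. The
association stage tests marginal relevance only — linked SNPs inherit
importance from their neighbours, which is why the consensus-over-runs
rule exists, and no kinship correction is applied. Enrichment treats
promoters as exchangeable given GC content; other covariates (length is
fixed by construction, repeat content is not modelled) are unadjusted.
Finally, *all-relevant* selection is an in-sample notion: on a finite
panel, a marker can be strongly associated with the labels purely by
sampling, and Boruta will — correctly — confirm it in every run. The
consensus-over-runs rule suppresses run-to-run instability, not
sampling-level coincidence, so even a label-independent genotype matrix
occasionally yields a non-empty important set; the recovery tests
measure exactly this rate.
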