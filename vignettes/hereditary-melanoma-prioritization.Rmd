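---
title: "Prioritizing germline variants in a hereditary melanoma cohort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing germline variants in a hereditary melanoma cohort: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melscreen)
```

## The problem

Families with multiple primary melanomas (MPM) and a high nevus count often
test negative for the established high- and intermediate-risk susceptibility
genes (*CDKN2A*, *CDK4*, *MITF*, telomere-complex genes). `melscreen`
implements the downstream analysis used to hunt for new candidate genes in
such a cohort: whole-exome sequencing of a small case series that includes a
sibling pair, a multi-stage variant prioritization cascade, carrier-frequency
screening of the surviving candidates in larger case/index/control panels,
and region-based rare-variant aggregation tests of the candidate panel.

The package does not align reads, call variants, or compute functional
annotations — its inputs are annotated multi-sample VCFs (or carrier-count
tables), and annotation is consumed, never recomputed.

## The prioritization cascade

`run_cascade()` applies seven steps in a fixed order, each a pure filter:

1. **Quality gate** — every whole-exome-case genotype must be defined
   (not `./.`) and flagged quality-pass. Sharing logic cannot be evaluated on
   undefined calls.
2. **Cohort sharing** — Criteria 1 keeps variants carried by both members of
   the sibling pair *and* at least one other case; Criteria 2 keeps variants
   carried by at least two non-sibling cases; the default is their union.
   Carrier means at least one alternate allele.
3. **Annotation selection** — the *broad* approach keeps all exonic
   variants; the *stringent* approach keeps exonic and intronic variants
   supported by at least one of: an Ensembl high-quality flag, any ClinVar
   record, or a damaging call from SIFT / PolyPhen-2 / MetaSVM / MetaLR.
   Default: union.
4. **Allele-frequency exclusion** — variants at or above 1% in the global or
   European population are dropped. The threshold is inclusive
   (`af >= 0.01`), matching the "frequency ≥ 1% excluded" convention; a
   strictly-above variant is available by flag because the two phrasings
   coexist in practice. An *unknown* frequency is a distinct state and never
   triggers exclusion — coercing missing annotation to zero would silently
   admit common variants of poorly annotated sites, and coercing to common
   would discard exactly the novel variants the screen exists to find.
5. **Synonymous exclusion** — synonymous variants are dropped by default. A
   `keep_synonymous` flag restores them, because screens of this design have
   retained individual synonymous candidates (e.g. with suspected splice
   effects) despite the nominal rule; the package does not guess intent.
6. **Polyvariant-gene exclusion** — genes carrying four or more variants
   *among the survivors of the previous steps* are removed wholesale; highly
   polymorphic genes are unlikely dominant-susceptibility candidates. The
   count is deliberately taken inside the funnel, which makes this step
   order-sensitive with respect to steps 4–5 (tested explicitly).
7. **Final selection** — candidates must be carried by more than two
   patients (whole-exome plus screened cases; default threshold 3) and be
   called damaging by at least one of the seven predictor tools
   (SIFT, PolyPhen-2, MetaSVM, MetaLR, Provean, MutationTaster, FATHMM).

Every step returns a subset of its input, so the funnel report is monotone
and chains exactly; all ordering is by (chromosome, position, ref, alt) with
no randomness anywhere in the cascade.

The predictor vocabulary ("deleterious", "probably_damaging", "D", ...) is
normalized by a fixed table into damaging / tolerated / unknown, because
upstream tools do not share an output vocabulary and the cascade needs a
single tri-state per tool.

## Carrier-frequency screening

`screen_candidates()` computes, per variant and per group (MPM cases =
whole-exome + screened; familial indexes; healthy controls), the carrier
count over the samples with a defined genotype. Denominators therefore vary
per variant — in the published screen controls number 100, 200 or 300
depending on the variant — and the reconstruction encodes this as
missingness rather than as a global group size. Percentages are rounded
half-up to one decimal, the convention of the published table (verified on
all 39 cells).

Rarity is classified from the control carrier frequency: below 1% rare,
above 5% common, otherwise a polymorphism, with both boundaries assigned to
the polymorphism class. The boundary assignment is forced by the published
data: variants at exactly 1.0% and 5.0% control frequency are counted among
the non-rare polymorphisms there, while the prose describes the class as
"between 1% and 5%". Data wins over prose.

The autosomal-dominant consistency filter excludes any candidate observed
homozygous in a healthy control: an unaffected homozygote is incompatible
with the variant acting as a dominant susceptibility allele. X-chromosome
genotypes are treated as recorded (diploid counts, no sex-aware hemizygote
model) since the screen design gives no sex-specific rule.

## Aggregation tests

For a candidate panel the package tests the cumulative case/control signal
with three score tests under an intercept-only binomial null (no covariates
are modeled; the comparison is a pure case/control contrast):

* fitted mean \(\hat\mu = \bar y\), residuals \(r_i = y_i - \hat\mu\),
  variance \(\hat v = \hat\mu(1-\hat\mu)\);
* per-variant scores \(S_j = \sum_i G_{ij} r_i\) with Beta(1, 25) weights
  \(w_j\) evaluated at the empirical minor-allele fraction (the conventional
  up-weighting of rarer variants);
* **burden**: \(Q_B = (\sum_j w_j S_j)^2\), referred to a 1-df chi-square
  after normalization by the null variance of the collapsed burden;
* **SKAT**: \(Q_S = \sum_j w_j^2 S_j^2\), whose null law is a positively
  weighted sum of 1-df chi-squares with weights equal to the eigenvalues of
  \(\hat v \, Z_c^\top Z_c\), \(Z_c\) the column-centered weighted genotype
  matrix;
* **SKAT-O**: \(Q_\rho = (1-\rho) Q_S + \rho Q_B\) over the grid
  \(\rho \in \{0, 0.1^2, \dots, 0.5^2, 0.5, 1\}\); the omnibus p-value is
  obtained from the minimum per-\(\rho\) p-value by the standard
  decomposition into a shared 1-df component plus an independent remainder
  mixture, reducing the computation to a one-dimensional integral.

### Numerical choices

Tail probabilities of weighted chi-square sums are computed by numerical
inversion of the characteristic function (the construction behind Davies'
method) with a midpoint rule whose step bounds the aliasing error and whose
truncation point bounds the envelope tail; target absolute accuracy `1e-6`.
Single-eigenvalue and equal-eigenvalue spectra are evaluated by the exact
chi-square closed form. Tails below the inversion accuracy, and spectra for
which the inversion would need an impractical number of terms, fall back to
Liu-style moment matching on a noncentral chi-square, which keeps relative
precision far into the tail; a permutation fallback backs both. Eigenvalues
below `1e-10` of the spectral maximum are truncated for stability.

Inside SKAT-O, the per-\(\rho\) mixtures cap \(\rho\) at 0.999 to keep the
\(\rho\)-kernel full rank (the \(\rho = 1\) endpoint itself is the burden
test, and single-point grids return the component test exactly); the
remainder distribution in the omnibus integral is evaluated by moment
matching — the fast published variant of the construction — and the final
p-value is clamped to its theoretical envelope
\([\min_\rho p_\rho, \; n_\rho \min_\rho p_\rho]\). The omnibus p-value is
reported to an absolute accuracy of about `1e-4`, set by the per-\(\rho\)
inversions; every calibration and oracle comparison in the package operates
far above that resolution.

Small-sample moment adjustments (exact permutation moments of Q) are *not*
applied; where the chi-square asymptotics are doubtful — very rare variants,
tiny cohorts — the assumption-free permutation oracle
(`permutation_pvalue()`, seeded and reproducible) is the authoritative
answer, and the test suite compares asymptotic to permutation p-values only
on instances where the asymptotics are expected to hold (moderate allele
frequencies, n around 200). With ultra-rare variants at small n the
asymptotic SKAT p-value can drift by more than Monte-Carlo noise from the
exact permutation law; this is a known finite-sample property of the
variance-component test, not an implementation artifact.

### Reconstruction from published counts

`reconstruct_from_counts()` rebuilds individual-level genotypes from a
carrier-count table under a declared policy: carriers heterozygous,
disjoint within group (feasible in the published panel, where the 26 case
carriers exactly fill the 26 cases), groups padded to the largest
denominator with untyped sample-variant pairs mean-imputed per variant. The
alternative `truncate_common` policy subsets to the smallest common
denominator with proportional carrier rescaling. Both are logged. Because
the published table prints only margins, any reconstruction is one member
of an equivalence class; the aggregation p-values on the reconstruction are
therefore properties of the declared policy, not reproductions of the
original study's individual-level results — the disjoint reconstruction
concentrates carriers on distinct cases (every case carries exactly one
candidate), which yields a far stronger signal than the original data
plausibly had. They are validated instead against a large permutation
oracle on the same reconstruction.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: 8 whole-exome cases including
one sibling pair, 18 additionally screened cases, 37 familial indexes, 100
healthy controls. Background variants (default 400 — small enough that the
full closure test over 20 seeds runs in seconds, large enough to exercise
every exclusion branch) are split 60/40 into common polymorphisms, with
minor-allele fractions from a Beta(0.5, 3) truncated to [0.01, 0.5], and
rare variants with frequencies uniform on [0.001, 0.009] — values chosen to
populate both sides of the 1% filter; 30% of rare background variants carry
no population-frequency annotation, exercising the tri-state rule.
Genotypes are Hardy-Weinberg draws; screened/index/control genotypes drop
out at rate 1%, producing the per-variant denominators the screen must
handle. Predictor calls on background variants are independent per tool
with a 15% damaging rate, making the "at least one damaging tool" rule
discriminative rather than vacuous.

Planted variants realize declared sharing patterns (both siblings plus one
other case, or two non-sibling cases) with declared screened/index/control
carriers and annotation profiles; the default panel contains eight variants
designed to survive the cascade and eleven decoys each designed to fall at
one specific step, giving every planted variant an exact expected fate. Two
design guarantees keep the truth table exact: rare background genotype
vectors are redrawn while two or more whole-exome cases carry them (so
background can never satisfy the sharing criteria), and common background
variants always carry their (≥ 1%) frequency annotation (so the frequency
filter removes whatever the sharing filter admits). Within those
guarantees, genotypes remain Hardy-Weinberg draws. All randomness flows
through a single seeded generator; identical config + seed give
byte-identical output files.

What the generator does *not* emulate: linkage disequilibrium between
variants, relatedness beyond the one sibling pair, sequencing error
structure, sex chromosomes (all genotypes are diploid counts), and
population stratification. Passing the closure test therefore demonstrates
the cascade's logic, determinism and bookkeeping on data with the study's
*structure* — it does not certify performance on real exomes, where
annotation error and cryptic relatedness would dominate.

The null/effect case-control simulators used for statistical calibration
draw independent binomial genotypes; the effect simulator samples case
genotypes retrospectively under a per-variant multiplicative odds model
(controls approximate the population under the rare-disease assumption).
Calibration uses 26 cases vs 100 controls and 7 variants with minor-allele
fractions set to half the control carrier frequencies of the published
aggregation panel — the study's own scale — and 5,000 replicates, which
bounds the Monte-Carlo standard error of a 5% rejection rate at about 0.3
percentage points.

## Worked example

```{r example, eval = FALSE}
sim <- generate_cohort(simulation_config(), seed = 1, dir = "cohort_out")
cohort <- read_sample_sheet(sim$paths[["samples"]])
av <- read_vcf(sim$paths[["vcf"]], cohort = cohort)

res <- run_cascade(av, cohort)
res$funnel

scr <- screen_candidates(res$candidates, cohort)
scr$table

panel <- reconstruct_from_counts(aggregation_panel_counts())
aggregation_tests(panel$G, panel$y)
```

## Known limitations

* The cascade treats the gene symbol as the aggregation unit; overlapping
  genes or transcript-level effects are out of scope.
* The dominant-consistency rule uses recorded diploid genotypes on the X
  chromosome; male hemizygotes recorded as homozygous would be excluded by
  the same rule.
* Aggregation assumes unrelated samples; the sibling pair is part of the
  prioritization design, not of the case/control inference.
* Reconstructed genotype matrices carry imputed (non-integer) dosages for
  untyped sample-variant pairs under the default denominator policy.
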