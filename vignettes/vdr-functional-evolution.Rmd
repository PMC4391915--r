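---
title: "Models and methods: quantifying VDR functional evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying VDR functional evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdrevo)
```

# The problem

The vitamin D receptor (VDR, NR1I1) is a ligand-activated transcription
factor whose hormonally active ligand is 1α,25-dihydroxyvitamin D~3~
(1,25D~3~). Comparing receptor orthologs from basal vertebrates — a 1R
jawless fish (sea lamprey), a post-2R cartilaginous fish (little skate), a
primitive 2R ray-finned fish (Senegal bichir) — with human VDR and the
teleost 3R paralogs (VDRα/VDRβ of zebrafish and medaka) turns a set of
cell-based assays into an evolutionary question: which receptor functions
(ligand affinity, potency, maximal efficacy, coregulator recruitment) are
ancestral, and which are derived?

`vdrevo` implements the quantitative layer of such a study: reporter-assay
normalization, two nonlinear pharmacology models, classical group
comparisons, a bootstrap/permutation cluster analysis of the combined
functional profiles, and sequence-level homology summaries. Each stage also
has a synthetic generator producing inputs with exactly the statistical
structure the stage assumes, which is how the package tests itself end to
end without any external data.

# Dual-luciferase normalization

Raw reporter readings are normalized in up to three steps:

1. **Internal control** (`internal_normalize()`): each well's firefly
   reading is divided by its renilla reading, absorbing well-to-well
   transfection efficiency.
2. **Vehicle control** (`fold_normalize(..., reference = "vehicle")`):
   ratios are divided by the *arithmetic mean* ratio of the dose-0
   (ethanol) wells, giving fold activation. The reference mean is exactly 1
   afterwards.
3. **Receptor-alone baseline** (`reference = "baseline"`): for
   co-transfection and mammalian 2-hybrid work, folds are further divided
   by the mean fold of the receptor without coregulator constructs.

Two properties are worth stating because the tests rely on them: the
composition of steps 2 and 3 equals a single division by the product of the
two reference means, and the whole chain is invariant to rescaling all
firefly readings by a constant.

The reference aggregate is the arithmetic mean of per-well ratios — the
standard dual-luciferase convention and order-independent — rather than any
per-plate pairing. Normalization can be grouped (`group_by = "experiment"`)
so each plate is scaled independently before pooling; per-experiment
grouping is the default recommendation because inter-plate scale factors
are nuisance parameters, but the flag exists because pooling raw ratios
first is equally defensible when plates share a master mix.

# Concentration-response model

`fit_4pl()` fits the four-parameter logistic with variable slope in
log~10~-dose space:

$$f(d) = b + \frac{E_{max} - b}{1 + 10^{\,h\,(\log_{10} EC_{50} - \log_{10} d)}}$$

* **EC~50~** (nM): ligand concentration at half-maximal response.
* **E~max~** (fold): fitted top plateau — reported as the efficacy
  estimate, with the observed maximal mean fold (`emax_observed`) emitted
  alongside, since data that do not reach plateau make the two differ.
* **h**: Hill slope, dimensionless, 1 for ideal one-site occupancy.
* **b**: bottom plateau, a *free* parameter initialized at 1 (the fold
  scale's natural baseline), not constrained — normalization targets 1 but
  noise moves the fitted floor.

Vehicle wells are excluded from the fit (log 0 is undefined); they exist
for the normalization. The fit needs at least 5 distinct nonzero doses and
errors on flat response ("no dose dependence") rather than returning a
degenerate optimum.

**Confidence interval.** The 95% CI for EC~50~ is
$10^{\widehat{\log EC_{50}} \pm t_{0.975,\,n-4}\,SE}$, i.e. symmetric on
the log scale and asymmetric in nM — the shape printed intervals for such
assays have. Calibration is checked by simulation: over 500 synthetic
experiments at the human-receptor parameters the interval covers the
generating value ~95–98% of the time (the test accepts 90–99%). Coverage is
assessed at a design whose dose range brackets EC~50~ well; when the top
plateau is barely reached (an EC~50~ near the top of the dose ladder) the
asymptotic interval is known to undercover, which is a property of the
design, not of the estimator.

**Optimization.** Levenberg–Marquardt (`minpack.lm::nlsLM`) from a
deterministic start: log EC~50~ at the dose whose mean response is nearest
half-max, h = 1, E~max~ = largest mean fold, b = 1. On failure a small
deterministic grid of starts is tried; persistent failure returns
`converged = FALSE` with the optimizer message, never a silent answer. A
brute-force grid-search oracle in the test suite confirms the optimizer
finds the global least-squares minimum on fixed noisy datasets.

# Saturation binding

`specific_binding()` subtracts nonspecific from total counts elementwise;
negative values (possible at low specific signal) are kept and flagged, not
clipped, because clipping would bias the subsequent fit. `fit_one_site()`
then fits $y = B_{max}x/(K_d + x)$ by least squares, with the K~d~ standard
error from the asymptotic covariance. If the fitted K~d~ falls outside the
concentration range the fit warns: an unbracketed K~d~ is an extrapolation.
The fallback start for K~d~ scans a log-spaced grid by residual sum of
squares, which handles series lying entirely above or below K~d~.

# Group comparisons

`anova_tukey()` is a thin, contract-enforcing layer over classical one-way
ANOVA and Tukey's HSD (studentized range, pooled within-group mean square,
Tukey–Kramer for unequal n). With two groups it reduces exactly to the
pooled-variance t-test; with identical constants in every group the
textbook F statistic is 0/0, which the package defines as F = 0, p = 1
(no evidence of any difference) rather than NaN.

# Cluster stability and driver coregulators

The summary analysis operates on an `assay_matrix`: assays in rows (each
annotated as transactivation or 2-hybrid, plus presence/absence of the
coregulators RXR~WT~, RXR~AF2~, SRC1, GRIP1, ACTR — the Pickett-plot
panel), species in columns.

1. `zscore_rows()` standardizes each assay across species (mean 0, sample
   n−1 SD 1), removing inter-assay scale. The n−1 denominator matches the
   default of mainstream statistics environments. Constant rows are an
   error: they carry no inter-species information and cannot be scaled.
2. `cluster_species()` clusters columns with Manhattan distance and
   complete linkage. The agglomeration is implemented in-package with a
   *deterministic tie-break* (lexicographically smallest pair of clusters,
   each indexed by its smallest leaf), so resampled clusterings are
   bit-reproducible across platforms; the test suite verifies exact
   agreement with `stats::hclust` on a thousand random matrices, plus the
   monotone-heights property complete linkage guarantees.
3. `bootstrap_stability()` resamples assay *rows* with replacement (same
   count), re-standardizes, re-clusters, and scores each named species set:
   the recapitulation frequency is the fraction of replicates in which the
   set is the exact leaf set of an internal node ("clade" mode). Row
   z-scores are recomputed after every resample/permutation — a no-op for
   pure row resampling, but cheap and uniform.
4. `driver_analysis()` permutes the species values *within* each selected
   assay row independently — destroying that row's species signal while
   preserving its marginal distribution — and records how far each
   target's recapitulation frequency drops relative to the bootstrap
   baseline. Assays (or coregulator groups) whose permutation collapses a
   cluster are its drivers.

**Design choices that were genuinely open.**

* *Clade versus cut.* Recapitulation defaults to the exact-clade criterion
  because it is cut-free and matches the idea of a "subcluster"; a k-cut
  mode (`mode = "kcut"`, default k = 3, the number of empirical clusters
  in an eight-species receptor panel) is provided since membership at a
  fixed cut is the other defensible reading.
* *Co-occurrence.* The pairwise co-occurrence matrix reports the fraction
  of replicates in which two species fall in the same cluster at the k-cut
  (k = 3 by default). It is symmetric with unit diagonal by construction.
* *Resampling unit.* Bootstrap resamples whole assay rows; permutation
  shuffles within rows. Both modes exist because both operations answer
  different questions (stability of the pattern vs. attribution to
  assays), and the analysis uses them in that division of labour.
* *Null behaviour.* With no planted structure the frequency of any specific
  k-species clade matches its combinatorial chance level; the suite checks
  this against a direct simulation oracle.

The default `n_boot` is 10,000; the tests use 200–10,000 depending on the
tolerance they need, and the planted-structure checks use 5 + 5 assay rows
over 5 species, sizes at which exhaustive enumeration (all 27 ordered
bootstrap samples of a 3-row matrix) is feasible as an oracle.

# Sequence comparison

`longest_orf_translate()` scans the forward strand in three frames for the
longest ATG-initiated ORF with an in-frame stop (reverse-complement search
behind `both_strands = TRUE`, since inputs are oriented cDNAs), translating
with the standard code. `molecular_weight()` sums average
isotope-abundance-weighted residue masses plus one water; the constants are
tabulated in the package and cross-checked in the tests against an
independent implementation (`seqinr::pmw`).

`percent_identity()` uses Needleman–Wunsch global alignment (BLOSUM62,
affine gaps: open 10, extend 0.5, a gap of length L costing
10 + 0.5·L) via `Biostrings::pairwiseAlignment`, with identity = identical
aligned pairs / columns where both sequences have a residue (the
gap-excluded convention; a gap-included alternative is exposed via
`denominator = "columns"`). Published receptor homology tables derived from
*multiple* alignments will differ from pairwise values by a few points;
such tables are treated as approximate anchors, not bit-exact targets.
Domain-restricted comparisons (`domain = "DBD"` etc.) use user-supplied
0-based half-open residue intervals — domain boundaries are configuration,
not inference. A brute-force enumeration of every global alignment serves
as the scoring oracle for tiny sequences in the tests.

# The synthetic generators

The generators produce data *from the models the analysis fits*, under
noise models chosen once:

* **Luciferase and counts: multiplicative lognormal**, unit mean, CV
  `noise_cv`. Readings are positive and their spread grows with the mean;
  a lognormal is the simplest noise respecting both. Default CV 0.1, a
  typical inter-well figure for dual-luciferase work.
* **z-scored matrix stage: additive Gaussian** (`noise_sd`), natural on an
  already-standardized scale.
* **Hill slope defaults to 1** — the canonical one-site occupancy value;
  concentration-response studies of this receptor family report EC~50~ and
  E~max~ but rarely the slope.
* **Binding defaults**: B~max~ 8000 counts and a nonspecific slope of 500
  counts/nM give the ~10–20% nonspecific fraction at mid-range
  concentrations typical of charcoal-stripped binding assays; 9
  concentrations 0–1.6 nM in duplicate mirror saturation designs for
  high-affinity (sub-nanomolar) receptors.
* **Dose ladder**: 8 log-equispaced doses from 0.12 to 1200 nM (step
  ≈ 3.7×), bracketing low-nanomolar through ~100 nM potencies, plus
  vehicle wells that exercise the normalization path only.
* Every generator takes an explicit integer seed and uses a private RNG
  stream: identical spec + seed gives byte-identical output and the global
  RNG state is untouched.

What the generators deliberately do **not** emulate: plate-position
effects, edge evaporation, inter-experiment batch scale (beyond the
`group_by` hook), receptor expression differences, ligand depletion at
high B~max~, or correlated noise between total and nonspecific tubes.
Passing the recovery tests therefore demonstrates that the estimators are
correct and well-calibrated *under the stated models* — it does not certify
robustness to systematic artefacts real plates can carry.

# Problem sizes and numerical conventions

Parameter-recovery checks use 100 replicate synthetic experiments per
receptor (500 for CI calibration), 4 wells × 8 doses or 2 tubes × 9
concentrations each — enough for ~1% Monte-Carlo error on a median while
keeping the full suite around a minute. Convergence tolerance is the
`nlsLM` default with up to 500 iterations; z-score and normalization
identities are asserted to 1e−12; clustering-oracle agreement to 1e−10.
Ties in merge distances are broken lexicographically (above); ties in
"dose nearest half-max" resolve to the first match, which only affects the
starting point, not the optimum.

# Known limitations

* The asymptotic EC~50~ interval undercovers when the dose range fails to
  bracket the transition (see above); profile-likelihood intervals would be
  the next step.
* E~max~ is reported as the fitted plateau; for partial-agonist-like, flat
  curves the fitted and observed maxima can diverge, which is why both are
  emitted.
* No global (shared-parameter) fitting across constructs, no Scatchard
  views, no antagonist models.
* The cluster analysis treats assays as exchangeable rows; it does not
  model correlation between assays sharing a coregulator beyond what the
  driver permutation reveals.
* Percent identity from pairwise global alignment is not the same estimand
  as identity read off a multiple alignment; expect a few points of
  difference on divergent sequences.
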