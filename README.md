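# vdrevo

Quantitative comparison of vitamin D receptor (VDR) function across basal
vertebrates. The vitamin D receptor is a ligand-activated nuclear receptor;
comparing orthologs from deep-branching lineages (sea lamprey, little skate,
Senegal bichir) with human VDR and the teleost VDRα/VDRβ paralogs asks how
ligand potency, maximal transactivation efficacy and coregulator
interactions changed across two (and, in teleosts, three) rounds of whole
genome duplication. `vdrevo` implements the full analysis chain for this
kind of study, for anyone working with dual-luciferase reporter assays,
radioligand binding, and cross-species functional profiling of nuclear
receptors.

## What it computes

**Reporter-assay normalization.** Dual-luciferase wells are first divided
by the renilla internal control, then by the arithmetic mean of a reference
condition: the vehicle (ethanol) control for fold activation, and
optionally the receptor-alone baseline for coregulator/2-hybrid scales.

**Concentration-response pharmacology.** Fold activation is fit by
nonlinear least squares to the four-parameter logistic with variable slope,

f(d) = bottom + (E_MAX − bottom) / (1 + 10^(h·(log₁₀EC₅₀ − log₁₀d))),

reporting EC₅₀ with a 95% CI computed on the log₁₀ scale and
back-transformed (hence asymmetric in nM), the fitted top plateau E_MAX,
and the Hill slope h. Saturation binding is fit by the one-site hyperbola
y = B_max·x/(K_d + x) after subtracting nonspecific from total counts.
Group comparisons use one-way ANOVA with Tukey's HSD.

**Cluster stability and driver inference.** An assay × species matrix is
standardized row-wise as z-scores, species are clustered with Manhattan
distance and complete linkage, and named species sets ("clades") are scored
over bootstrap resamples of the assay rows; permuting species values within
chosen assay rows (e.g. all SRC1-containing assays) measures how much those
assays drive a cluster.

**Sequence characterization.** Longest-ORF translation, molecular weight
from average residue masses, and pairwise percent-identity tables
(Needleman–Wunsch global alignment, BLOSUM62, gap open 10 / extend 0.5),
optionally restricted to annotated receptor domains (A/B, DBD, hinge/CTE,
LBD, F).

Every pipeline input can also be *simulated* (`dr_sim_spec()`,
`binding_sim_spec()`, `matrix_sim_spec()`, `simulate_orf()`), so the whole
chain is testable without any data download.

## Worked example

```r
library(vdrevo)

## a synthetic human-VDR concentration-response experiment
spec  <- dr_sim_spec(ec50 = 5.38, emax = 51.3, bottom = 1, hill = 1,
                     replicates = 4, noise_cv = 0.1, seed = 42)
plate <- simulate_dose_response(spec)
fold  <- fold_normalize(internal_normalize(plate), reference = "vehicle")
fit_4pl(fold$dose_nM, fold$fold)
#> Four-parameter logistic concentration-response fit
#>   EC50: 5.474 nM (95% CI 3.939-7.606)
#>   E_MAX (top plateau): 58.74-fold  bottom: 0.2862  hill: 0.9231
#>   n = 32 wells, residual SS = 419.1
```

The fitted EC₅₀ (5.47 nM) recovers the generating value (5.38 nM) within
its confidence interval; the CI is wider above than below the estimate
because it is symmetric on the log scale.

```r
## cluster stability on a matrix with three planted species clusters
st <- bootstrap_stability(am,
        targets = list(C1 = c("Lamprey", "Bichir"),
                       C2 = c("Skate", "ZebrafishB", "MedakaB"),
                       C3 = c("ZebrafishA", "MedakaA", "Human")),
        n_boot = 1000, seed = 1)
st
#> Bootstrap cluster stability (1000 replicates, clade mode)
#>   C1 {Lamprey, Bichir}: 0.995
#>   C2 {Skate, ZebrafishB, MedakaB}: 0.947
#>   C3 {ZebrafishA, MedakaA, Human}: 0.962

driver_analysis(am, targets = list(C3 = c("ZebrafishA", "MedakaA", "Human")),
                grouping = c("SRC1", "GRIP1"), n_perm = 1000, seed = 1,
                n_boot = 1000)
#> Driver analysis: permuted 8 assay row(s) [SRC1, GRIP1], 1000 replicates
#>   target baseline_freq permuted_freq  delta
#> 1     C3         0.962         0.048 -0.914
```

Here `am` is a simulated assay matrix (see `matrix_sim_spec()`) in which
SRC1/GRIP1-flagged assays carry the cluster signal: the C3 cluster is
recovered in 96% of bootstrap replicates, and collapses to 5% once those
coregulator assays are permuted — the signature of a driver coregulator
group.

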