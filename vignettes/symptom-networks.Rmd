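---
title: "Directed symptom networks over mixed clinical data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed symptom networks over mixed clinical data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clgnet)
```

## The model

`clgnet` analyses a cross-sectional table of mixed discrete and continuous
clinical variables as a **conditional linear Gaussian (CLG) Bayesian
network**. A directed acyclic graph (DAG) factorizes the joint distribution
into one local distribution per variable given its parents:

* a **discrete** node carries a multinomial conditional probability table
  (CPT), one row per configuration of its (discrete) parents;
* a **continuous** node carries, for each configuration of its discrete
  parents, a linear regression on its continuous parents with Gaussian
  residuals.

Continuous parents of discrete nodes are structurally disallowed — this is
the standard CLG restriction, and the search enforces it through a
blacklist (`default_blacklist()`). The motivating application is a directed
symptom network of schizophrenia: demographics (discrete), symptom scales
(CDSS, PANSS subscales, CGI indices), cognitive domain scores (the five
MATRICS domains) and a quality-of-life total, with interest in which
cognitive domain sits upstream of the others and how symptoms relate to
quality of life.

## Structure learning

`hill_climb()` starts from the arcless graph and greedily applies the
single-arc addition, deletion or reversal with the largest positive BIC
delta, stopping at a local optimum. The score is the decomposable BIC on
the log-likelihood scale, `log L - (d/2) log n` per family, where `d`
counts free parameters (`(levels - 1) x prod(parent levels)` for CPTs; an
intercept, one slope per continuous parent and a variance per
discrete-parent configuration for regressions). Decomposability means a
move re-scores only the affected families; `audit_trace()` certifies that
these incremental deltas equal full rescores to 1e-8.

Numerical choices worth knowing:

* moves must improve the score by more than 1e-9 — floating-point noise
  must never introduce an arc;
* ties among equal-delta moves break lexicographically by (operator,
  parent, child), so runs are platform-deterministic;
* residual standard deviations are floored at 1e-6 (degenerate bootstrap
  resamples can make a configuration's regression exact);
* parent configurations with no observations fall back to uniform CPT rows
  (discrete) or the pooled regression (continuous), keeping bootstrap
  replicates well-defined.

`tabu_search()` extends the climb with a fingerprint list of the last
`tabu_length` visited structures and accepts the best non-tabu move even
when worsening, for up to `max_worsening_moves` consecutive non-improving
steps; with a budget of zero it reduces exactly to the greedy climb. On
well-separated structures both searches return the same skeleton — a
consistency check the package's tests repeat on every run. For problems of
up to six variables `enumerate_dags()` provides the exhaustive oracle the
search is validated against.

## Bootstrap model averaging

`bootstrap_networks()` relearns the structure on nonparametric resamples
(size n, with replacement). `arc_confidence()` turns the B structures into
per-pair **strength** (fraction of resamples containing the edge in either
direction) and **direction** fractions, and `averaged_network()` thresholds
them into a consensus DAG, orienting each retained pair by its majority
direction. Because pairs are thresholded independently, majority
orientations can rarely close a directed cycle; arcs are therefore inserted
strongest-first and an arc that would close a cycle — necessarily the
weakest in that cycle — is dropped and logged. The default inclusion
threshold is 0.5; `threshold = "auto"` estimates the cut as the point whose
step function is L1-closest to the empirical strength distribution. `B`
defaults to 200 in `bootstrap_networks()`; the pipeline's default
configuration uses B = 50, the replicate count at which the package's
end-to-end recovery properties are routinely checked, and both are plain
configuration entries.

## Path-model refit and fit indices

The learned DAG is refit as a **recursive path model** (`fit_path_model()`):
every endogenous variable is regressed on its parents. For a recursive
system with uncorrelated errors, equation-wise least squares is the
maximum-likelihood fit, and the estimates do not depend on the order in
which equations are solved. Discrete variables enter numerically
(`encode_for_sem()`): binary as 0/1, ordered (age band, education,
employment) as integer codes, nominal (race, marital status) as
first-level-reference dummies; every mapping is recorded in a coding
report because the choice affects coefficient interpretation.

Global fit uses the model-implied covariance
`Sigma = (I - B)^-1 Psi (I - B)^-T` with a saturated exogenous block, the
dominant SEM convention `T = (n - 1) F_ML`, and the standard CFI / TLI /
RMSEA formulas against the independence baseline. AIC and BIC come from
the Gaussian likelihood with the free-parameter count (paths + residual
variances + exogenous variance/covariance block); means are saturated in
all candidate models and therefore omitted. Exogenous covariances are
estimated (saturated) rather than fixed — the alternative changes absolute
AIC/BIC but not coefficients, and the saturated choice keeps the saturated
model's chi-square exactly zero. Coefficient p-values use the normal
reference, the large-sample ML convention; at n around 1450 the difference
from t is negligible. All path p-values are Holm-adjusted
(`holm_adjust()`, validated against the literal step-down definition).

The pipeline fits both the single-data network and the averaged network
and selects the reporting network by a deterministic rule — lower RMSEA,
then higher CFI, then lower BIC — recording both fits.

## Centrality and probability queries

`centrality()` reports directed degree (in/out/total) plus closeness and
betweenness on the undirected skeleton: a single orientation-free
closeness/betweenness per node with a separate degree breakdown matches
how symptom-network studies report these quantities. Standardized
betweenness divides by `(n-1)(n-2)/2`; closeness is already in [0, 1] on a
connected skeleton, and on a disconnected one the harmonic variant is
substituted (classic closeness is undefined across components) with a
notice. Both raw and standardized columns are emitted, since reporting
conventions differ.

`conditional_query()` estimates `P(event | evidence)` for median-threshold
events by rejection sampling: ancestral draws from the fitted network,
discard those violating the evidence. Rejection is unbiased and simple for
interval-valued evidence on continuous variables, where likelihood
weighting offers no advantage; the default 10^6 samples give Monte-Carlo
standard errors around 5e-4 on unconditional events. Medians are taken
from the analysis dataset (post-imputation), not from the model's implied
distribution; ties at the threshold satisfy neither `<` nor `>`. The
battery helper mirrors the usual reporting table: each cognitive domain
given low processing speed, and each parent of quality of life.

## Preprocessing

Rows with strictly more than 50% missing cells are dropped
(`filter_rows_by_missingness()`; a row at exactly the threshold is kept).
Remaining missing cells are imputed by the iterative random-forest
(missForest) scheme: initialize with mean/mode, sweep variables in order
of increasing missingness, fit a forest of each on all others, and stop
when the iteration-over-iteration difference criterion rises for both
variable kinds (or the only kind present), returning the previous sweep.
Forests use 100 trees and mtry of sqrt(p) for discrete targets and p/3 for
continuous ones — the missForest publication's defaults, since the
applied literature rarely reports these. One caveat the synthetic
experiments make explicit: forest imputation improves on mean imputation
wherever a variable has predictive neighbours (the continuous block), but
for near-exogenous discrete variables — as demographics typically are —
the Bayes-optimal single prediction is the modal level, so a forest cannot
beat mode imputation on classification error there and may do slightly
worse by fitting noise. Ages are binned into three bands;
the published labels (`<30`, `31-45`, `>45`) leave age 30 unassigned, so
the first band is implemented as "up to and including 30" on rounded
years — exhaustive and order-preserving. Cognitive scores are standardized
to mean 0, sd 1 (denominator n - 1).

## The synthetic generator

`make_catie_like_truth()` encodes a 21-variable ground-truth network whose
roster, marginal frequencies and coefficients emulate the CATIE
schizophrenia baseline: 74.4% male, about 15% employed, age bands around a
mean of 40.5 years, and standardized path coefficients at the published
effect sizes (processing speed to negative symptoms -0.25, negative
symptoms to QOL -0.33, general-to-negative 0.61, general-to-positive 0.64,
employment to QOL -0.32, processing speed to QOL +0.12, and so on).
Processing speed parents all four other cognitive domains. Where two
reported values conflicted in sign for the speed-to-QOL path, the
generator follows the detailed results narrative (+0.12, a positive
association) rather than the summary value. Residual variances are solved
by exact covariance propagation so every continuous variable has unit
marginal variance at `effect_scale = 1`: annotated coefficients then equal
population standardized coefficients, which is what makes the recovery
tests sharp. `effect_scale` multiplies every coefficient while leaving
residual variances fixed.

`generator_config()` defaults to n = 1460 records, 10 rows with more than
half their cells blanked (to exercise the row filter, leaving 1450
analyzable rows) and 2.4% missingness, injected completely at random —
the source study does not characterize its missingness mechanism, so MCAR
is an explicit assumption, not a claim about the real data. That is also
the honest boundary of what the generator shows: it reproduces the
roster, the dependence structure and the effect sizes, but real CATIE
data have item-level structure, ceiling/floor effects, informative
missingness and longitudinal follow-up that the generator does not
emulate. Passing recovery tests therefore validate the *pipeline*, not
any clinical claim.

## Problem sizes used in the checks

The package's property checks run at the study's own scale where that is
what the property asserts (n = 1450 path-coefficient recovery across 20
seeds; five full pipeline runs with B = 50 bootstrap replicates), and at
reduced scale where the property is scale-free (4-node exhaustive-search
comparisons at n = 2000; 3-node chains; 10^6-sample query fixtures).
These sizes are the package's own choices and are recorded in the tests.

## Known limitations

* Hill climbing returns one member of a Markov equivalence class; edge
  orientations that are not compelled by the data are search artifacts.
  The package deliberately does not estimate the equivalence class
  (CPDAG), matching the analysis it reimplements.
* The CLG family excludes continuous parents of discrete nodes by
  construction; discrete outcomes of continuous predictors cannot be
  expressed.
* Queries use rejection sampling: evidence with very low marginal
  probability leaves few effective samples (the result records
  `n_effective`, and impossible evidence is an error, not a zero).
* The SEM treats encoded discrete variables as numeric — standard
  practice for path models over mostly-continuous rosters, but the
  coefficients for nominal dummies depend on the reference level, which
  is why the coding report is part of the output.

## A small worked run

```{r, eval = FALSE}
library(clgnet)
out <- tempfile("clgnet-demo-")
bundle <- run_pipeline(pipeline_config(out_dir = out, seed = 7))
bundle$selection$table          # both networks' fit statistics
head(bundle$sem$network$paths)  # standardized coefficients, Holm-adjusted p
bundle$centrality$network       # degree / closeness / betweenness
bundle$queries                  # median-split conditional probabilities
```
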