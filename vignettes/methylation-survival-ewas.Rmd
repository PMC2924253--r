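---
title: "Methylation survival EWAS: models, screens and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation survival EWAS: models, screens and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`survewas` analyses Infinium-style DNA methylation arrays against a
time-to-event outcome: here, years from type 1 diabetes diagnosis to the
onset of diabetic nephropathy, with controls censored at their diabetes
duration. This vignette is the package's own account of the science: the
models and their assumptions, the tunable parameters, what the
synthetic-data generator emulates, the numerical choices, and the
limitations we know about.

## The data and the beta value

The unit of measurement is the per-CpG *beta value*,
$\beta = M / (M + U + \alpha)$, the methylated-channel intensity over the
total intensity, ranging from 0 (unmethylated) to 1 (fully methylated).
The offset $\alpha \ge 0$ defaults to 0 (the plain ratio); vendor software
commonly adds a stabilising constant (e.g. 100), so it is configurable —
whether a deposited matrix carries such an offset is usually not
documented, and both readings are supported. Promoter-array designs are
dominated by CpG-island probes, so the marginal beta distribution is
strongly bimodal: a large hypomethylated peak near 0.1 and a smaller
hypermethylated peak near 0.85.

A `beta_matrix` pairs the probes-by-samples values with a detection mask
(signal above background). Detection is an *input*: the package does not
recompute detection p-values from raw fluorescence, because intra-array
processing belongs to vendor software; the simulator emulates the mask
with a configurable dropout rate.

## Quality control

`sample_qc()` removes a sample iff its coverage (fraction of detected
probes) is below `min_sample_coverage` or its worse bisulphite-conversion
metric is below `bsce_min`; `probe_filter()` then keeps probes detected
in at least `min_probe_detection_rate` of the retained samples. The
defaults (0.75, 0.90, 0.95) are the package's choices: published QC
descriptions of this kind of cohort state which samples failed but not the
numeric cutoffs, so the defaults are set to reproduce the qualitative
behaviour (a handful of bad arrays removed from ~192, global coverage
around 80%) without claiming anyone's exact thresholds. All three are
configurable. Incomplete bisulphite conversion inflates apparent
methylation genome-wide, which is why the two conversion metrics also
reappear later as regression covariates.

## Quantile normalisation

`quantile_normalize()` maps every sample onto the mean of the per-sample
order statistics, removing inter-array intensity differences while
preserving within-sample ranks. Numerical semantics, chosen once and
frozen:

* with complete data the reference is exactly `rowMeans(apply(x, 2, sort))`;
* missing entries stay missing; a sample's ranks are computed on its
  observed values and the reference is linearly interpolated to that
  sample's own number of observations;
* tied values receive the mean of the reference values at their tied rank
  positions.

On complete, tie-free data the map is idempotent to machine precision and
agrees with the standard limma implementation; these are test-enforced.

## The mean-profile component and the SVD screen

An uncentred SVD of a beta matrix is dominated by its first component —
typically well over 90% of $\sum_k \sigma_k^2$ — which encodes the bimodal
mean methylation profile shared by all samples and carries no phenotype
information. `adjust_top_component()` subtracts the best rank-1
approximation (essentially normalising by the mean profile) so that the
remaining components can be judged.

Significance of the remaining components is assessed against a
permutation null (`permutation_null()`): each replicate independently
permutes every sample's values across probes (a distinct permutation per
sample), destroying inter-sample covariance while preserving each
sample's marginal distribution. Singular values of a randomised matrix
are a global property of the data, so the null spectrum is very tight and
few replicates (default 10, configurable upward) suffice.
`select_significant_components()` calls component $k$ significant iff its
observed variance fraction exceeds the *maximum* null fraction at rank
$k$ across replicates — the conservative reading of "larger than expected
under the null"; with a tight null, max and mean nearly coincide.

Two numerical choices matter here:

1. **Matched processing of replicates.** The observed matrix has had its
   top component removed, so it is exactly rank-deficient; a permuted
   replicate regains a chance top component. If replicate fractions were
   computed over the full permuted spectrum, every observed fraction
   would be inflated by roughly $n/(n-1)$ against the null and pure noise
   would be called significant at desk scale. Each replicate therefore
   has its own top singular value dropped and its fractions renormalised
   — by the Eckart–Young theorem this *is* the spectrum of the
   re-adjusted replicate, at no extra cost. At biobank scale
   ($n \approx 190$, $p \approx 27{,}000$) the correction is a 0.5%
   effect and invisible; at test scale it is decisive.
2. **Completion before SVD.** Missing entries are imputed by per-probe
   means (`impute_probe_means()`) because the factorisation needs a
   complete matrix; the per-CpG regressions below instead drop the
   affected samples, so imputed values never feed a hazard model.

`associate_components()` then screens each component's sample scores
against phenotypes and technical factors: linear-regression slope tests
for continuous/ordinal factors (conversion metrics, ages, durations),
Kruskal–Wallis for categorical ones (sex, cohort, chip, plate), and a
single-covariate Cox model for the time-to-event outcome. Cells are
binned at 1e-10, 1e-5, 1e-2 and 0.05 — a machine-readable stand-in for
the conventional heat-map display. A single-level factor yields an `NA`
cell with a warning rather than an error, since degenerate factors are
common in small subsets.

**Known limitation.** The permutation null tests exchangeability of
probes within samples, so *any* probe-level variance heterogeneity —
including the purely distributional kind created by a bimodal beta
mixture, where mid-methylated probes are several times more variable than
hypomethylated ones, and even the $\sqrt{2/n}$ sampling spread of row
variances in an iid matrix — registers as signal. On simulated data with
no sample-level structure at all the screen still calls components, and
it calls many components on realistic structured data. This is a property
of the method, not of the implementation; it is why the screen is paired
with the factor-association matrix (components matter when they correlate
with something) and why the supervised analysis adjusts for measured
confounders explicitly instead of regressing components out.

## The per-CpG Cox scan

The estimator at the package's core, `run_ewas()`, fits for every CpG $j$
a proportional-hazards model
$$ h(t \mid x) \;=\; h_0(t)\,
   \exp\!\left( \beta_j z_{j} + \gamma^\top c \right), $$
where $z_j$ is the CpG's methylation predictor and $c$ the confounder
set — by default chip, the two conversion-efficiency metrics, sex,
recruitment cohort and age at sample draw, dummy-coding categoricals and
dropping constants with a warning. Fitting maximises the partial
likelihood via the `survival` package's Newton machinery (Efron tie
handling by default, Breslow selectable; without tied event times the two
coincide, test-enforced to 1e-8). Reported per CpG: the log hazard ratio,
its exponential, the standard error from the observed information, the
Wald $z$ and two-sided $p$, the number of contributing samples, and
convergence/degeneracy flags. A constant predictor yields the degenerate
row (coef 0, infinite se, $p = 1$) rather than an error.

The predictor is standardised per CpG (zero mean, unit SD) by default, so
coefficients are log hazard ratios per SD of methylation — the scale on
which adjusted group differences are usually displayed; raw-beta scaling
is selectable since the Wald $z$ is invariant to linear rescaling but the
coefficient scale is a reporting choice.

Multiple testing uses Storey q-values (`estimate_qvalues()`):
$q_{(i)} = \hat\pi_0 \min_{j \ge i} m\,p_{(j)}/j$, with $\hat\pi_0$ from
the smoother over $\lambda \in \{0, 0.05, \ldots, 0.90\}$ (cubic
smoothing spline, evaluated at the largest $\lambda$, clipped to (0,1]).
`pi0_method = "fixed_1"` forces $\hat\pi_0 = 1$, which makes the q-values
exactly Benjamini–Hochberg; fewer than 20 p-values triggers that fallback
automatically. `count_directional()` splits calls at an FDR threshold by
coefficient sign: positive means higher methylation confers increased
risk of earlier nephropathy.

`combine_proximal_pairs()` tests co-directional change of CpG pairs
within 1 kb (inclusive) on the same chromosome. "Combined" is read as the
per-sample mean of the two standardised probe vectors, fed through the
same multivariate Cox model; a Stouffer combination of the two single-CpG
Wald scores, $(z_a + z_b)/\sqrt{2}$, is offered as an alternative mode
because the combination rule in the source analyses of this kind is
rarely spelled out. Both interpretations are documented as such.

## The synthetic-data generator

`simulate_dataset()` provides the statistical structure every other stage
assumes, with known ground truth (`sim_truth`) for recovery testing. Its
defaults are the package's study conditions and are not adjusted
per-test:

| parameter | default | what it emulates |
|---|---|---|
| `n_samples`, `n_probes` | 200 × 2,000 | desk-scale stand-in for ~190 × 27,578 |
| `case_fraction` | 0.5 | matched case/control design (96/96) |
| `mixture_weights` | 0.70/0.15/0.15 | hypo/mid/hyper probe classes |
| `mixture_centers` | 0.10/0.50/0.85 | bimodal beta histogram |
| `noise_sd` | 0.5 (logit) | array measurement noise |
| `batch_effect_sd` | 0.3 on 20% of probes | per-chip intensity shifts |
| `sex_effect_sd` | 1.0 on 4% of probes | X-linked dosage effects in females |
| `age_effect_sd` | 0.2 on 10% of probes | age-drift of methylation |
| `bsce_artifact_sd` | 0.3 on 10% of probes | conversion-efficiency artifact |
| `n_causal`, `causal_coef` | 10, 0.6/SD | planted survival signal |
| `baseline_hazard_scale` | 15 years | exponential baseline |
| `censor_time_range` | 5–40 years | administrative censoring |
| `detection_dropout_rate` | 0.005 | background-level failures |

All effects act on the logit of beta and are mapped back through the
logistic function, so simulated values are always strictly inside (0,1)
and the clipping count is structurally zero. Chips hold 12 samples and
are filled from a case/control-interleaved ordering, so each chip is
roughly 50:50 — mirroring how such studies randomise arrays. Chip,
cohort and conversion artifacts are overlaid *after* survival generation:
they confound the screen and the regression, as technical structure does
in reality, but never enter the generative hazard.

Survival: event times are exponential with rate
$\exp(\sum_k \beta_k z_k)/s$ over the standardised causal-probe scores,
censored uniformly over `censor_time_range`. The scale $s$ is calibrated
to the target event fraction by a deterministic bisection on
$\log s$ holding the exponential draws and censoring times fixed, so the
realised number of events matches the design (96 of 192, up to binomial
noise) and the whole dataset remains a pure function of the seed.

What the generator does **not** emulate: raw two-colour fluorescence,
bead-level replicates, probe cross-hybridisation, cell-type composition,
spatial chip artifacts, or correlated methylation blocks (probes are
conditionally independent given the planted factors). Passing recovery
tests on this generator therefore demonstrates correctness of the
estimators under the generative model, not performance on any real
cohort.

## Estimands, attenuation, and what the tests show

Two statistical facts about the default conditions are worth stating
plainly, because they determine what "recovery" can mean:

1. **Non-collapsibility.** The generative hazard conditions on all 10
   causal probes, but the scan fits one CpG at a time. The nine omitted
   probes act as an independent frailty of variance
   $9 \times 0.6^2 = 3.24$, and Cox coefficients are not collapsible:
   the marginal (per-CpG) log hazard ratio is attenuated to roughly
   $0.6/\sqrt{1 + 3.24} \approx 0.3$. The scan estimates the marginal
   estimand correctly — with a single planted CpG the conditional and
   marginal estimands coincide and coverage of the true 0.6 is nominal
   (test-enforced) — but against the *conditional* truth of 0.6 the
   multi-causal default shows attenuated coefficients, reduced
   sensitivity and under-covering intervals. Signs are unaffected.
2. **Null calibration needs a null.** Under the default design an
   `n_causal = 0` dataset is still not survival-null: age at draw
   deterministically contains follow-up time, and chip membership is
   case/control-linked, so age- and chip-affected probes genuinely
   associate with the outcome. That is confounding — the reason those
   factors are model covariates — not FDR miscalibration. The
   calibration suite therefore severs every systematic effect; under
   that fully null configuration p-values are uniform and the q<0.15
   false-call behaviour matches the nominal level.

## Problem sizes used by the test and acceptance suites

The suites run at 2,000 probes and 96–200 samples, with 10 permutation
replicates, 20–50 null replicates for calibration, and 3–10 seeds for
multi-seed properties; smaller matrices (tens of samples, hundreds of
probes) are used where a property is scale-free. These sizes are the
package's choices for routine verification; every threshold asserted in
the suites was chosen from the statistical analysis above, not fitted to
runs.

## Pipeline orchestration

`run_pipeline()` executes QC → quantile normalisation → imputation →
mean-profile adjustment → SVD screen → per-CpG scan → proximal pairs,
returns all stage objects plus a machine-readable summary (counts at
every stage, significant components, directional hits per FDR level), and
optionally writes per-stage artifacts, a log and a JSON summary; reruns
with the same inputs and seed are byte-identical. `export_figure_data()`
writes the diagnostic views as plain data files: per-group beta
histograms, observed-versus-null variance fractions, the
component-by-factor p/bin matrices, the EWAS p-value histogram, and
per-probe case/control Z-score summaries. Rendering is deliberately left
to the user; the data files are the contract.
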