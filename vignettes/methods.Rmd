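---
title: "Models and methods behind traitspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind traitspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

traitspace implements a complete analysis chain linking a low-dimensional
social-affective personality space to social trait judgments of faces and to
the representational geometry of single-neuron population responses, with an
autism-spectrum-like (ASD) group contrasted against a control group. This
vignette is the package's own account of the models it fits, the synthetic
cohort it tests itself on, and the numerical and design choices that were
genuinely open.

```{r setup, message = FALSE}
library(traitspace)
library(dplyr)
```

## The analysis chain

1. **Quality control.** Trial-level: rating trials with reaction times
   shorter than 100 ms or longer than 5000 ms are excluded (strict
   inequalities, so 100 and 5000 are kept). Block-level: a
   participant-module-trait block is excluded when strictly more than 30% of
   its trials were removed, or when the kept trials use fewer than three
   distinct rating values; when both hold the primary recorded reason is the
   reaction-time fraction. Participant-level: a participant is excluded when
   strictly more than three blocks were excluded. Neurons pass two screens: a
   session-mean response rate above 0.15 Hz, and a one-sided paired t-test of
   per-image response-window rates against per-image baseline-window rates at
   `alpha = 0.05`. The paired test and its alpha are stated assumptions (the
   form of the original responsiveness test is not public); both are
   configurable and recorded in the QC report.
2. **Personality space.** The 33 subscale scores of both groups pooled enter
   a Pearson correlation matrix. The factor count comes from a
   Cattell-Nelson-Gorsuch scree scan; the k-factor model is maximum-likelihood
   exploratory factor analysis with direct-quartimin (oblimin, gamma = 0)
   rotation; factor scores are Thurstone regression scores; the group contrast
   is OLS of each score on a group indicator plus sex, age and subjective
   socioeconomic status.
3. **Judgment statistics.** Ratings are averaged per participant-module-trait
   (the default analysis unit; a participant-level unit is available because
   the study's unit is ambiguous); groups are compared per trait with
   pooled-variance t-tests; factor-judgment structure is summarized by
   group-stratified correlations and by interaction regressions of one
   trait's means on the four factor scores, group, group-by-factor
   interactions and the demographic covariates.
4. **Neural RSA.** Per group and trait, consensus ratings of the 500 images
   are averaged, z-scored globally, sliced into one 10-example vector per
   identity, and converted to a 50 x 50 identity dissimilarity matrix with
   `d = 1 - Pearson`. The neuronal matrix averages baseline-normalized
   per-image rates across neurons and applies the same construction.
   Correspondence between matrices is the Spearman correlation of their 1225
   lower-triangle entries. The group difference in correspondence is tested
   by shuffling participant group labels (1000 runs by default), recomputing
   both consensus matrices each run, with an add-one-corrected p-value.
5. **Inter-subject RSA.** For every within-group pair of participants the
   absolute difference is taken in each trait's participant-level mean
   judgment and in each factor score; the dyadic judgment distance is
   regressed on the four factor distances, the dyad's group, and the
   group-by-factor interactions. Analytic OLS p-values are reported alongside
   an optional participant-level permutation, because dyads sharing a
   participant are not independent and OLS inference is anticonservative.
   The permutation scheme is matched to each term's null: factor main
   effects are tested by shuffling judgment values among participants
   within group (destroying every judgment-personality linkage), while the
   group term and the group-by-factor interactions are tested by shuffling
   participant group labels and rebuilding the within-group dyad set —
   shuffling values would build those terms' null under "no association in
   either group" and over-reject interactions whenever both groups share a
   coupling.

## The synthetic cohort and what it does (not) emulate

`sim_config()` fixes the study conditions; `simulate_study()` draws a full
study from them. The defaults encode the cohort the pipeline is designed for:
89 ASD-like and 307 control-like participants, 50 face identities x 10
examples organized in 10 modules (one example per identity per module, by a
per-identity random bijection), 10 traits on a 7-point scale, 33 subscales
from a planted 4-factor structure, and 120 neurons across amygdala, anterior
and posterior hippocampus in the proportions 340:222:105.

Key generative choices, each of which was open and is fixed here once:

* **Loadings.** Block simple structure with blocks 10/9/7/7, primary
  loadings uniform on [0.5, 0.8], cross-loadings Normal(0, 0.05), factor
  correlations 0.2, uniquenesses set so every implied subscale variance is
  exactly 1. Mean planted communality is then about 0.44, so recovered total
  variance explained sits in the low 40s of percent — the regime the method
  is meant to operate in. The ASD group mean is shifted by 0.6 SD on factor 1
  only.
* **Ratings.** A latent propensity `intercept + slope * example_trait +
  gamma' factor_scores + noise`, rounded and clipped to 1..7. Round-and-clip
  is the simplest monotone discretization and is exactly invertible at zero
  noise, which the oracle tests exploit. The coupling matrix `gamma` defaults
  to a prosocial pattern (empathy/prosociality and social agreeableness raise
  trustworthy/warm/charismatic judgments by 0.10-0.15 rating units per factor
  SD; antisociality lowers them slightly); the ASD group's couplings are the
  control couplings times `attenuation_asd` (default 0, the planted "absent
  association").
* **Identity-trait signal.** Each identity carries a latent 10-trait value;
  each photograph (example) jitters it with SD 1.0. The large jitter reflects
  naturalistic photographs — impressions of the same person vary considerably
  across images — and matters structurally: because the identity matrices
  correlate example vectors (which centers out each identity's mean), the
  geometry the RSA compares lives in the example-level variation, and both
  the rating and the neural side must carry it. The ASD group's ratings are
  driven by the mixture `(1 - lambda) * tau + lambda * tau_tilde` with an
  independent draw `tau_tilde`; `distortion_lambda` (default 0.5, a moderate
  misalignment chosen once; the recovery analyses use 0.8) weakens
  rating-neural alignment without changing the marginal rating distribution.
* **Neurons.** Poisson counts over a 1 s response window at rate
  `softplus(b + w' example_trait)`, with a 0.5 s baseline window (the window
  length is not public; it is configurable). Baselines are log-uniform on
  [0.05, 10] Hz, so about a fifth of units have baselines below 0.15 Hz
  (roughly a tenth still fail the session-mean rate screen once the
  response gain is applied); a
  further 30% are untuned (`w = 0`, no gain) and fail the responsiveness
  screen. Tuned units elevate their central rate 1.5x over baseline and draw
  weights Normal(mean = tuning_mean, sd = 0.3). The per-trait `tuning_mean`
  vector (trustworthy 0.5, warm 0.35, others 0.1) is the population-consensus
  component of coding and deliberately weights approach-related traits, the
  preferential coding reported for amygdala and hippocampal populations. It
  is load-bearing: the population matrix averages responses across neurons,
  which cancels zero-mean idiosyncratic tuning, so only this shared component
  survives into the population geometry. With a zero mean the neural matrix
  would carry no recoverable trait structure at all.
* **Nuisance processes.** Reaction times are lognormal (meanlog 6.9, sdlog
  0.4, i.e. ~1 s typical); a 2% contamination fraction is forced outside
  [100, 5000] ms, half below and half above, which keeps per-participant
  exclusion rates under 5%. Each participant completes 1-3 modules
  (uniform), matching the order of magnitude of participant-module units
  behind the study's group comparisons; the count is a parameter because the
  true per-participant module distribution is not public.

What the generator does **not** emulate: real images and any semantic
knowledge about the depicted people, attention-check behavior upstream of the
deposited data, spike-train temporal structure (only window-mean rates are
consumed downstream), electrode geometry, and non-Gaussian personality
distributions. Passing recovery tests therefore shows the pipeline is correct
and well-calibrated on data with the study's structure — not that the
substantive findings generalize.

## The factor-count rule

The Cattell-Nelson-Gorsuch scan fits least-squares slopes to eigenvalue
triples `i..i+2` and `i+3..i+5` for every start index and locates the elbow
at the window maximizing `slope2 - slope1`. Attributing a count to that
window is subtle: on screes with a sharp structure-to-noise cliff, the
maximizing window's *leading* triple straddles the cliff, while on smoothly
decaying screes the cliff falls *between* the triples. `cng_factor_count()`
therefore places the cut at the largest consecutive eigenvalue gap inside the
maximizing six-eigenvalue window, which returns the planted dimension in both
regimes (and exactly k on an ideal k-factor scree). A flat scree (all slope
differences zero, e.g. an identity correlation matrix) is an error, not an
arbitrary answer. At the default study conditions the rule recovers k = 4 in
roughly 93-95% of cohorts; the failures are draws in which the general-factor
drop between the first and second eigenvalues (a consequence of the 0.2
factor correlation) out-steepens the structure-noise cliff — screes that any
elbow reader, human or rule, would find ambiguous.

```{r cng}
cfg <- sim_config(seed = 1)
ch <- generate_cohort(cfg)
ss <- generate_subscales(ch$participants, ch$truth, cfg)
ev <- eigen(subscale_correlations(ss), symmetric = TRUE, only.values = TRUE)$values
cng_factor_count(ev)
```

## Numerical choices

* **ML EFA** profiles the likelihood over uniquenesses (given uniquenesses,
  optimal loadings come from the leading eigenpairs of the rescaled
  correlation matrix) and minimizes the discrepancy with L-BFGS-B and an
  analytic gradient, bounded in [0.005, 1]. Uniquenesses at the lower bound
  (Heywood cases) are clamped and flagged with a warning rather than
  aborting, for robustness at small n. The objective evaluations are traced;
  tests assert the converged objective never exceeds the initial one.
* **Oblimin** is direct quartimin by oblique gradient projection with
  column-normalized rotation matrices, step-halving line search, and a 1e-6
  gradient tolerance. Factors are ordered by explained variance and signed so
  each factor's largest-magnitude loading is positive; |loading| > 0.35
  defines the labeling set.
* **Factor scores** are regression (Thurstone) scores
  `Z Sigma^-1 L Phi` with `Sigma` the model-implied correlation matrix;
  Bartlett scoring was the rejected alternative (the original scoring method
  is unstated; regression scoring is the common default). Scores have exactly
  zero mean by construction.
* **Recovery matching.** Factor order and sign are not identified, so all
  recovery checks greedily pair planted and recovered columns by absolute
  Tucker congruence and align signs before comparing.
* **Dissimilarities.** `d = 1 - r` (not `1 - |r|`): self-dissimilarity is
  pinned at 0 and the signed form is what makes anticorrelated profiles
  maximally dissimilar (d = 2). Examples are paired across identities by
  example index; z-scoring is global across all 500 images, once, before
  slicing. Images without any consensus rating in a group are dropped
  pairwise; each identity must keep at least 5 of its 10 examples, else the
  construction errors (correlations over fewer points are too unstable).
* **Permutation tests** use the add-one correction, `p = (1 + #{null >=
  observed}) / (1 + n_perm)`, so p is never exactly zero; the neural-RSA test
  defaults to two-sided (the original sidedness is undisclosed) and its
  sidedness is recorded in the result object.
* **Dyadic regression.** Within-group dyads only by default: the binary
  group regressor is undefined for mixed pairs; a mixed-dyad third level is
  available behind `include_cross_group`. Distance columns are z-standardized
  across the stacked dyad table so coefficients are comparable across
  factors; the scaling parameters are stored in an attribute and a raw-scale
  fit is available.
* **Determinism.** Every generator and every permutation draws from its own
  seed derived deterministically from the root seed, so `run_pipeline()`
  reruns are byte-identical (the manifest lists MD5 hashes) and results are
  replayable regardless of call order.

## Problem sizes used in the package's own checks

The test suite exercises the pipeline at the full default cohort (396
participants, 120 neurons) where a single run suffices — loading and shift
recovery, planted-misalignment recovery (50 cohorts), and the factor-count
Monte-Carlo (100 cohorts) — and at reduced sizes where whole operating
characteristics must be estimated: permutation calibration uses 200 cohorts
of 30+30 participants and 20 neurons at 200 permutation runs, and the dyadic
permutation calibration uses 50 cohorts of 40+40 at 199 runs. These sizes
were chosen as the smallest at which the calibration bands are informative.

## Known limitations

* The pipeline analyses one neuronal population; per-region contrasts beyond
  a region filter, searchlight variants, and noise ceilings are out of scope.
* OLS inference on dyads ignores their dependence; the permutation option is
  provided and recommended for confirmatory use, and both are labeled in
  outputs.
* The CNG rule inherits the ambiguity of scree reading when a dominant
  general factor competes with the structure-noise cliff (see above).
* Likert discretization makes extreme planted propensities unidentifiable
  (ratings saturate at 1 and 7); the default intercept keeps saturation
  rare.
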