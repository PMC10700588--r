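---
title: "Scoring and modelling the experience, representation and recognition of emotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modelling the experience, representation and recognition of emotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectmap)
```

## The question and the measurement model

Constructionist accounts of emotion predict that people who experience
their own emotions distinctly and consistently should also hold clearer
visual templates of emotional expressions, and should therefore read
emotions off others' faces more accurately. `affectmap` operationalises
each link in that chain as a score computed from a specific behavioural
task, and then asks a structural model which scores predict recognition
ability and in which causal direction the data are most plausibly arranged.

Four measured constructs carry the analysis:

* **Emotion differentiation** — similarity judgments over pairs of
  affect-inducing images are embedded in a plane; the mean embedded
  distance between emotion clusters (anger, happiness, sadness) indexes how
  distinctly emotions are experienced, the within-cluster distance how
  variable each emotion is across instances.
* **Emotional consistency** — repeated forced choices ("which image makes
  you feel most angry?") over all 55 pairs of 11 images are scored for
  transitive coherence; the score is bounded by 220 and reached only by a
  strict preference order.
* **Representational consistency and differentiation** — the speed (percent
  of recorded, converted to pixels/frame) attributed to a point-light
  expression across four repetitions; `−1 × SD` per actor and emotion is
  consistency, absolute differences between mean emotion speeds are
  representational distances.
* **Recognition accuracy** — correct-scale rating minus the mean of the two
  incorrect-scale ratings on point-light displays, in [−10, 10].

Two auxiliary measures complete the set: *matching difficulty* (mean
absolute percent deviation when reproducing a displayed speed — perceptual
matching ability with no memory component) and the *representation-matching
composite*, the per-emotion product of representational consistency and
matching difficulty, which indexes how well a stored template can actually
be deployed against incoming input.

## The embedding

Ratings on the 0–10 similarity scale become dissimilarities
`δ = 10 − similarity` (the scale maximum minus the rating; the instrument's
anchors make 10 "maximally similar", so this is the natural reflection).
The landscape is a metric least-squares embedding: SMACOF stress
majorization minimising raw stress, reported as Kruskal's stress-1.
Numerical choices:

* dimension 2 by default (affect landscapes are conventionally read on a
  valence/arousal plane; the dimension is a parameter for sensitivity
  checks);
* initialisation from classical scaling plus 7 seeded random restarts
  (8 starts total), 300 iterations, relative stress tolerance `1e-6`,
  best-stress solution kept. The Guttman transform guarantees monotone
  stress descent, so the final stress can never exceed the classical start;
* zero distances in an iterate contribute zero weight to the transform
  (the `B` matrix entry is set to 0), which handles coincident points.

An exactly planar dissimilarity table is recovered to machine precision
(stress < 1e−8), which the tests use as an oracle.

## The consistency score

Rank scores count how often each image was chosen; each trial contributes
`rank(chosen) − rank(unchosen)`; the score is the sum. On a complete
pairwise design over k items the maximum is `k(k² − 1)/6` — 220 at k = 11 —
attained exactly by the transitive patterns, whose sorted ranks are
`k−1, …, 0`. Two properties worth stating precisely, because the second is
easy to get wrong:

* under uniformly random choices the *expected* score equals the number of
  trials (55 on the standard design) — derived analytically and verified by
  exhaustive enumeration on 3- and 4-item designs;
* a single choice swap never raises a perfect score, but it lowers it *only
  when the swapped pair is not adjacent* in the preference order: swapping
  an adjacent pair relabels the order and produces another transitive
  pattern that again scores the maximum.

Trap trials (a third image from an opposing category, or grayscale in the
colour control) are attention checks; the task forces a retry, so final
data contain 55 valid target choices and the scorer merely counts lapse
flags for quality control.

## The structural model search

The search mirrors a four-step procedure on the one-row-per-participant
score table (all variables z-scored):

1. **Screening.** Shadow-feature importance: every candidate is paired with
   a permuted copy, a random forest (permutation importance, 200 trees,
   100 iterations by default) is grown per iteration, and a candidate
   scores a hit when it beats the best shadow. A two-sided binomial test at
   α = 0.01 classifies candidates confirmed / rejected / tentative. Note a
   structural caveat: the binomial model treats iterations as independent
   evidence, but for a fixed data set the importance ranking is nearly
   deterministic, so type-I control is effectively at the data-set level —
   spurious in-sample associations can be "confirmed" at small n. The
   type-I tests therefore use cohorts large enough (n = 600) for chance
   associations to sit below the forest's noise floor.
2. **Fitting.** Maximum-likelihood covariance-structure estimation in the
   RAM parameterization: directed matrix `A` (paths and loadings, first
   loading per latent fixed to 1), symmetric `S` (variances, log-scale
   internally; free covariances between exogenous variables), implied
   covariance `F(I−A)⁻¹S(I−A)⁻ᵀFᵀ`. Quasi-Newton (BFGS) on the ML
   discrepancy with the analytic gradient, 5 seeded restarts, relative
   tolerance 1e−10; standard errors from the numerical Hessian;
   `BIC = −2 logL + k log N` with `N` the number of participants.
   Constructs scored per emotion (accuracy, emotional consistency, the
   representation-matching composite, between-cluster distance) are latent
   with their three per-emotion scores as reflective indicators; traits
   (AQ, TAS, non-verbal reasoning) are manifest. A mean-composite manifest
   model is available by passing an empty latent map.
3. **Sequential building.** Confirmed candidates enter in descending
   importance, each as a direct path to the outcome; an addition is kept
   only if the nested likelihood-ratio test against the same variable set
   with that path fixed to zero rejects at α = 0.05 ("significant
   improvement" had to be operationalised somewhere — a nested LRT is the
   natural choice); building stops at the first rejected addition.
4. **Path reversal.** Each structural edge is reversed one at a time and
   the model refit; the BIC evidence rule (|Δ| < 2 tie → original retained;
   2–6 positive; > 6 strong) fixes directions, the final model assembles
   the retained directions and must not lose to any of its own
   single-reversal variants by more than 6. Two-variable models are
   covariance-equivalent under reversal and land in the tie category with
   ΔBIC = 0, which the tests exercise. Indirect effects are path products
   with delta-method (Sobel) standard errors from the full parameter
   covariance; standardized indirect effects are products of standardized
   component paths.

A least-squares `association_screen()` is provided as plumbing for quick
participant-level checks (e.g. emotional consistency predicting
representational consistency with trait covariates); it deliberately does
not replace the structural model.

## The synthetic cohort generator

No generative model is printed for these tasks, so every distributional
choice here is an artifact decision, isolated in `cohort_config()`:

* **Affect plane.** Cluster centres sit on a circle of radius `m`
  (modularity, lognormal across participants) with anger and sadness 60°
  apart and happiness opposite — anger–sadness clusters overlap most,
  matching the usual valence/arousal asymmetry. Images scatter around
  their centre (SD `image_spread = 1`). Experienced positions add isotropic
  noise `sigma_exp`; similarity is the kernel `10·exp(−d/λ)` with `λ = 4`
  plane units, reported at the task's 4-decimal resolution.
* **Triplet choices** are the argmax of noisy evoked intensities
  (`N(3.5, 0.8)` per image, echoing the stimulus set's calibrated means);
  with probability `lapse_prob ~ Beta(1, 40)` the trap is selected first
  and the trial retried once, as in the task. The colour control uses an
  *independent* perceptual noise `sigma_control`, so control consistency
  carries no emotional signal by construction.
* **Speeds.** Latent representation speeds per emotion centre on the
  recorded stimulus speeds (3.85, 2.80, 1.63 px/frame for anger, happiness,
  sadness; per-actor factors 0.90–1.15) with SD 0.45. Attributed speeds are
  `N(s_e, sigma_rep)` converted to percent and clipped to the 25–300 dial
  (clipping, not resampling: observationally equivalent at the bound).
  Matching responses are `N(target, sigma_match)` with the displayed
  percent as target, clipped likewise; `sigma_match` is lognormal with
  median 30 percent points, which puts the cohort's median deviation near
  the high/low matching split reported for such tasks.
* **Coupling.** The precisions `1/sigma_exp` and `1/sigma_rep` share a
  Gaussian copula with correlation `rho_cons` (default 0.6): the generative
  link from consistent experience to consistent representation.
* **Recognition.** A stimulus plays at `v0 × kinematic/100`; each scale is
  rated `10·exp(−(v_stim − ŝ)²/(2τ²))` plus `N(0, 0.4)` rating noise, with
  τ = 1 px/frame and `ŝ ~ N(s_e, sigma_deploy)`. By default
  `sigma_deploy = sigma_rep × sigma_match / 30`: deploying a stored
  template against incoming input is limited by both the template's
  consistency and the participant's matching ability, so inconsistent
  representations are most costly for poor matchers — precisely the
  moderation the representation-matching composite indexes, and the reason
  the composite (not raw consistency) is the proximal predictor the model
  search recovers. Setting `deploy_via_matching = FALSE` gives the plain
  `sigma_rep` form.

What the generator deliberately does *not* emulate: reaction times,
questionnaire item-level structure, sex or cultural moderation, practice
and block structure, and any non-speed facial cue. Passing recovery tests
therefore show that the pipeline measures what this generative family
encodes — they do not certify the substantive theory on real data.

## Problem sizes and seeds

Simulation-backed checks run at sizes chosen to give stable Monte-Carlo
behaviour on a single CPU: association-recovery at ρ = 0.6 vs 0 uses 50
replicate cohorts of n = 400; model-search recovery uses 10 replicate
cohorts of n = 1000 (screening at 25 shadow iterations there) plus
collider-reversal checks at n = 2000; the random-choice limit uses 400
simulated participants against the exact expectation. All randomness flows
from explicit integer seeds; identical config and seed reproduce response
tables byte for byte.

## Known limitations

* The SEM fitter covers the model family this analysis needs (latents with
  reflective indicators, recursive and simple nonrecursive structures,
  ML + BIC/LRT); it is not a general SEM environment — no means structure,
  missing-data handling, robust or weighted estimators, or fit indices
  beyond logLik/AIC/BIC.
* Sequential building adds candidates only as direct predictors of the
  outcome; richer intermediate structure is the reversal step's job.
* The reversal step treats edges one at a time; genuinely bidirectional
  (feedback) pairs are representable in the fitter but retained only when
  specified in the input model, since single-edge flips cannot discover
  them.
* Median-split ties go to the high-matching group; ties have probability
  zero under the continuous simulator but can occur in rounded real data.
* The +2.52 display constant sometimes added to consistency scores in
  figures is presentation only and never enters any computation here.
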