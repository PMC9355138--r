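---
title: "Validating peer-crowd segmentation instruments: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating peer-crowd segmentation instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peercrowds)
```

## The problem

Adolescent health-communication campaigns are more effective when they are
targeted at *peer crowds* — macro-level reputational subcultures (Alternative,
Country, Hip Hop, Mainstream, Popular) with shared values, norms, and
distinctive health-risk profiles. Measuring crowd identification well is
therefore a segmentation problem: an instrument must yield a per-crowd
identification score, support assignment to a single primary crowd, and
predict the behaviors and traits that campaigns care about.

`peercrowds` implements the full validation workflow for a pair of such
instruments:

1. a **ranked-choice mindset survey**: seven questions, five crowd-mapped
   options each, with a first and second choice per question;
2. a **photo-grid survey**: two grids of crowd-mapped photos, three
   best-fit and three least-fit picks per grid.

The workflow computes subscale reliability (McDonald's $\omega$), builds the
$10\times10$ multi-trait multi-method (MTMM) matrix across the two
instruments, applies convergent/discriminant validity decision rules, and
runs a covariate-adjusted regression battery relating crowd scores to six
substance-use behaviors, a sad/hopeless indicator, adverse childhood
experiences (ACE), resilience (BRS), social prioritization (SPI), and
sensation seeking (BSSS).

## Scoring rules

**Mindset survey.** A crowd earns 2 points per rank-1 selection. Rank-2
selections earn 1 point, *except* Alternative and Mainstream, which earn 0.5
— a deliberate down-weighting to counter social-desirability pressure on
those options. Per-crowd scores span 0–14 in exact 0.5 steps (never
rounded); a respondent's five scores always total $14 + \sum_q w(\text{rank-2}_q)
\in [17.5, 21]$, which the test suite asserts from the raw choices.

**Photo-grid survey.** Each best-fit photo earns its crowd $+p$ points and
each least-fit photo $-p$. The published score range is $-12..12$ over two
grids (12 selections), which pins $p = 2$ under uniform per-selection
points; a rank-weighted alternative would also reproduce the range, so the
magnitude is exposed as `ibase_points` rather than hard-coded. With equal
best/least magnitudes, each respondent's five scores sum to zero.

**Primary crowd.** The unique argmax of the five scores; any tie at the
maximum (including all-zero) is `"Tied"`, which is a real reported category,
not an error.

**Auxiliary scales.** ACE is a 0–9 count of nine binary adversity items.
BRS is the mean of six 1–5 items with items 2, 4, 6 reverse-coded — the
reverse-coding set follows the published scale, not the validation study
(which doesn't restate it), and is overridable. SPI is the mean of eight
items linearly rescaled to the stated 0–10 range (the rescaling is our
documented choice; only the score range is published). BSSS is the mean of
eight 1–5 items. Past-30-day use frequencies are dichotomized at $\ge 1$
day. A missing item invalidates its instrument's score for that respondent;
the CSV loader rejects such rows with line numbers rather than imputing.

## Reliability: McDonald's omega

$\omega = (\sum_i \lambda_i)^2 / \left[ (\sum_i \lambda_i)^2 + \sum_i \theta_i \right]$
from a one-factor model fit to the item correlation matrix. Design choices:

* **Items.** Neither instrument has a published item definition for its
  crowd subscales. For the mindset survey, crowd $c$'s items are the seven
  per-question point contributions to $c$ (each 0, $w(c)$, or 2). For the
  photo grid, they are per-photo signed selection indicators ($+1$ best,
  $-1$ least, 0 otherwise) for $c$'s photos — four items under the default
  grid of two photos per crowd per grid.
* **Estimator.** Unweighted least squares on the off-diagonal correlations
  (robust for coarse, categorical-ish items), with maximum likelihood
  (`factanal`) as an option. Fitting on correlations makes $\omega$
  invariant to rescaling all items by a common positive constant.
* **Edge cases.** Two-item subscales are fit under an equal-loading
  constraint (just-identified otherwise). Negative uniquenesses (Heywood
  cases) are clamped to zero and flagged, keeping $\omega \in [0,1]$.
  Loadings are sign-fixed so their sum is non-negative. For pure-noise
  items the individual loadings are only weakly identified near zero (the
  ULS surface is flat at rate $n^{-1/4}$); the stable quantities — implied
  correlations and $\omega$ — vanish, and the tests assert those.

The published subscale omegas (0.44–0.78 for the photo grid, 0.56–0.77 for
the mindset survey) require the study's raw data, which are not deposited;
the package verifies the *estimator* (closed forms, parameter recovery,
agreement with ML) and carries the printed values in its fixture.

## MTMM validity evaluation

The $10\times10$ matrix holds Pearson correlations among all crowd scores
(five traits $\times$ two methods), with $\omega$ on the diagonal. P-values
come from the exact $t$ transform with $n-2$ degrees of freedom, two-sided,
at $\alpha = 0.05$ with no multiplicity correction (matching the published
analysis, whose weakest marker is $p<0.05$).

* **Convergent validity**: the same-crowd, cross-instrument correlation is
  positive and significant.
* **Discriminant validity**: every other cell is non-significant,
  significantly negative, or significantly positive but *strictly weaker
  than both* convergent coefficients of the crowds it involves. The
  both-comparison reading follows the published worked example, where a
  cross-crowd correlation of 0.18 is flagged because it exceeds one crowd's
  convergent coefficient (0.17) while remaining below the other's (0.26).
  Significant negative cells satisfy discriminant validity outright.

The printed matrix ships as a plain-text fixture with its significance
markers mapped to representative p-value bounds (`***` $\to 5\times10^{-4}$,
`**` $\to 5\times10^{-3}$, `*` $\to 0.025$, none $\to 0.5$), since exact
p-values are not printed. Evaluating the fixture reproduces the published
verdict: five convergent passes (coefficients 0.17–0.55) and exactly one
discriminant violation.

## Prediction battery

One model per instrument $\times$ crowd $\times$ outcome: logistic (IRLS,
Wald inference, AOR $= e^{\beta}$) for the seven dichotomous outcomes,
ordinary least squares for the four trait scores — 110 models. All models
adjust for age (continuous years), gender (reference: Female, with "another
identity" retained as its own level despite small cells), and
race/ethnicity (reference: NH white); region is excluded because the
published control set omits it. Each crowd score enters **its own model**
by default: the scores are ipsative (shared forced choices induce negative
correlations within an instrument), which makes joint entry unstable.
`mode = "joint"` is available since the published analysis does not state
which was used. Complete-case per model; per-cell failures (degenerate
outcomes, separation, rank deficiency) are flagged in the output rather
than aborting the battery.

## The synthetic cohort: what it emulates, and what it does not

No raw respondent data are deposited, so the package ships a generator
whose *stated world* mirrors the published sample's marginal structure:

* **Prevalences** of the five latent crowds follow the published primary
  crowd distribution (renormalized over non-tied categories:
  `r paste(sprintf("%s %.3f", names(default_crowd_prevalences()), default_crowd_prevalences()), collapse = ", ")`).
* **Behavior base rates** match the published prevalences (e.g. vaping
  18.6%, alcohol 29.0%); crowd effects on the log-odds scale follow the
  published sign pattern (elevated marijuana/sadness for Alternative,
  smokeless tobacco for Country, tobacco/vape/marijuana for Hip Hop,
  protective Mainstream effects across substances, alcohol for Popular),
  with magnitudes of 0.3–1.0 chosen once as realistic crowd contrasts.
* **Trait means** per crowd bracket the published overall means (ACE 2.85,
  BRS 3.01, SPI 3.39, BSSS 3.33) with the published SDs, signed per the
  published risk profiles.
* **Demographics** follow the published marginals and are independent of
  crowd by default, so regression adjustment is exercised without biasing
  recovery tests.
* **Response model.** The study describes no response-generating process,
  so we posit the minimal latent-structure model sufficient for recovery
  testing: a rank-1 mindset choice matches the latent crowd with
  probability `vmls_rank1_fidelity`, rank-2 follows a row-stochastic
  affinity matrix with a zero diagonal; photo picks favor own-crowd photos
  with probability `ibase_best_fidelity` and avoid them for least-fit picks
  with probability `ibase_least_affinity`. Fidelities have no published
  estimate; the defaults (0.55) were fixed once so that synthetic
  convergent correlations land in the published 0.2–0.6 band, and are
  illustrative, not estimated.

A green test on this cohort establishes that the *pipeline* recovers known
structure — not that real adolescents behave like the generator. In
particular the generator omits: recruitment channels and fraud, region
effects, crowd-correlated demographics (configurable but off), measurement
non-invariance, and item-level idiosyncrasies beyond independent noise.

One structural finding from building the negative control: because the
rank-2 affinity diagonal is forced to zero, the mindset instrument can
never be exactly uninformative — at chance-level rank-1 fidelity its rank-2
choices still *avoid* the latent crowd. Consequently a world where both
instruments are at or below chance produces positively correlated
own-crowd scores (two anti-signals agree). The meaningful negative control,
implemented in the acceptance suite, zeroes the fidelity of the instrument
under validation while the comparison instrument behaves normally; its
convergent correlations are then null-to-negative and convergent validity
correctly fails in every seed.

## Numerical and operational choices

* Determinism: the seed lives in the config; identical config implies
  byte-identical cohorts, manifests, and output files.
* Monte-Carlo test sizes follow the stated checks (50,000 for latent
  frequency convergence; 20,000 for effect recovery within $\pm0.03$
  log-odds / $\pm0.02$ linear; 5,000 for omega's closed form within 0.02
  and the null battery's binomial type-I band; 20 seeds of 1,000 for the
  negative control).
* The null-battery calibration counts significant cells against the
  Binomial 95% band over 110 correlated tests; correlation between cells
  makes the band approximate, which is the stated check.
* Use-day counts for positive users are uniform on 1–30; only the
  dichotomy is analyzed downstream.
* The pipeline writes CSV (comma-separated, UTF-8, header required, empty
  fields for missing), a JSON manifest with an MD5 config hash, and a
  plain-text report; the cohort config is dumped YAML-style for humans
  plus JSON for machines.

## Known limitations

* The photo-grid item definition (per-photo signed indicators) gives
  four-item subscales under the default grid; omega for such short, coarse
  scales is noisy, consistent with the modest published photo-grid
  reliabilities.
* The printed-matrix evaluation inherits the coarseness of significance
  markers; a cell's true p-value may sit anywhere below its bound.
* Joint-entry battery mode is provided but untested against published
  results, which cannot be reproduced without the raw data.
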