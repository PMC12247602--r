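---
title: "Methods: choice-preference estimation and surface-based TFCE inference"
author: "prefmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choice-preference estimation and surface-based TFCE inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`prefmorph` implements a complete analysis chain linking individual economic
preferences, estimated from binary choice data, to cortical surface
morphometry: softmax maximum-likelihood estimation of risk tolerance and
delay discounting, vertex-wise regression of surface metrics on those
preferences with demographic covariates, threshold-free cluster enhancement
(TFCE) with Freedman–Lane permutation inference and FDR correction on a
triangulated mesh, directional conjunction analysis, and a peak-area
multi-measure regression. A synthetic-data module generates cohorts with the
statistical structure the analysis assumes, so the whole chain runs and is
validated end-to-end without any imaging data.

## Choice models

Both tasks offer, on every trial, a variable option against a fixed $20
reference. The subjective value of a risky prospect (win `A` with
probability `p`) follows power utility,

$$SV = p \, A^{\alpha},$$

with risk tolerance $\alpha$ (the certain reference passes through the same
utility, $SV_{ref} = 20^{\alpha}$). A delayed reward (`A` after `D` days)
follows hyperbolic discounting,

$$SV = \frac{A}{1 + kD},$$

with discount rate $k$ per day. For the model-comparison analysis a third
family, hyperbolic probability discounting, values a gamble by its odds
against winning, $SV = A / (1 + h\,\theta)$ with $\theta = (1-p)/p$ — the
standard odds-against form; it expresses risk aversion on a scale that runs
opposite to $\alpha$.

Choices follow a softmax (logistic) rule,
$P(\text{accept}) = 1/(1 + e^{-\beta\,(SV_1 - SV_2)})$, where $\beta \ge 0$
scales choice determinism. Likelihoods clamp probabilities to
$[10^{-10}, 1 - 10^{-10}]$ so a deterministic-looking subject never produces
an infinite log-likelihood. Fitting maximizes the likelihood over
$(\text{parameter}, \beta)$ with bounded L-BFGS-B from multiple starts
(parameter starts log-spaced across the search box, $\beta$ starts spanning
$10^{-3}$–$10$; the five most promising pairs are polished). Search boxes
are $\alpha \in [0.01, 3]$, $k \in [10^{-5}, 2]$, $h \in [10^{-4}, 10^{3}]$,
$\beta \in [0, 100]$: the likelihood can be flat or multimodal for extreme
choosers, which multi-start plus bounds handles.

Goodness of fit is McFadden's pseudo-$R^2$,
$1 - \mathrm{NLL}/(n \log 2)$, i.e. the fitted likelihood relative to a
coin-flip chance model. Several estimate-quality flags are part of the
estimator's contract rather than afterthoughts:

* `one_sided` — every choice identical; the parameter is unidentified.
* `identifiable` — `FALSE` when no trial in the design ever flips
  preference across the whole admissible parameter range (an all-dominated
  design).
* `out_of_bounds` — the optimum is pinned at a search bound.
* `estimable` — a likelihood-ratio test of the fitted two-parameter model
  against the chance model at $p < .05$ (2 df). A fit failing this has an
  essentially flat likelihood; its point estimate is arbitrary and should
  not enter correlations of estimates.

Subjects are excluded when either task is one-sided, when
$\alpha \notin [0.34, 1.32]$, or when $k \notin [0.0017, 0.077]$ — screening
against ceiling and floor effects. Because exclusion is defined by strict
inequalities, the bounds themselves are retained (inclusive intervals).

## Synthetic cohorts

The generator's defaults are the study conditions the package validates
against: 156 subjects, 120 trials per task,
$\log_{10}\alpha \sim N(-0.20, 0.17)$ and
$\log_{10}k \sim N(-1.74, 0.36)$ drawn jointly with correlation $-0.3$
(configurable; "weakly to moderately negative" is the empirical pattern and
the exact value is not published), truncated to the screening bounds above.
Truncation mirrors a screened sample; note it necessarily shrinks the
realized SD below the drawn SD (about 0.135 for $\log_{10}\alpha$), since
the printed descriptives already describe a screened sample.

**Trial designs.** The risky design crosses 8 win probabilities log-spaced
over $[0.10, 0.99]$ with 15 expected values log-spaced over \$10–\$80
(`A = EV/p`), shuffled per subject. Like any fixed non-adaptive grid it
mixes informative trials with trials every subject decides the same way.
The intertemporal design pairs 15 critical discount rates (the `k` at which
a deterministic chooser is indifferent) log-spaced over
$[5\times10^{-4}, 0.25]$ — bracketing the admissible range — with 8
log-spaced integer delays in 1–180 days, setting `A = 20(1 + k^*D)` so
subjective values bracket the \$20 reference across the k-range. Both
designs keep every subject's expected accept proportion strictly inside
(0.02, 0.98) over the admissible parameter range, the identifiability
requirement a usable design must satisfy.

**Noise calibration.** Each subject receives an individual softmax $\beta$,
found by bisection so that the *expected* McFadden pseudo-$R^2$ of the
generating model (a closed form in the per-trial choice entropies) equals a
per-subject target drawn from $N(0.37, 0.125)$ for the risk task and
$N(0.57, 0.125)$ for the delay task, truncated to $[0.02, 0.95]$. The means
are the published mean fit qualities; the SD is the published standard
error ($0.01$) scaled to the cohort ($0.01\sqrt{156} \approx 0.125$). An
earlier design shared one $\beta$ per task across subjects, but that
provably cannot reproduce the published fit-quality spread: under power
utility the value-difference scale grows as $A^{\alpha}$, so a shared
$\beta$ makes high-$\alpha$ subjects near-deterministic and inflates the
spread of $R^2$ far beyond the published SE for the risk task while
deflating it for delay. Per-subject $\beta$ also matches how the original
analysis treats $\beta$ (fitted per subject). Calibration uses only
published moments.

**Covariates.** Age $\sim N(25, 6)$ truncated at 18; IQ $\sim N(111, 7)$
truncated at 90 (the screening floor); sex $\sim$ Bernoulli(90/156); total
intracranial volume $\sim N(1450, 130)$ cm³, a plausible adult scale.

**Surface metrics.** A subject's map is the sum of (i) a Gaussian random
field — white vertex noise smoothed to a requested FWHM (default 15 mm) and
rescaled to unit per-vertex SD; (ii) spatially uniform mean-centered
covariate contributions; and (iii) a planted linear effect of the
standardized preferences inside a geodesic disc, at full strength inside
60% of the disc radius and tapering smoothly (cosine) to zero at the
boundary. The default planted effect is $-0.55$ metric units per predictor
SD for *both* preferences in a 40 mm disc: this magnitude was calibrated
once, by simulation at the default cohort size, so that the full
TFCE-conjunction pipeline recovers the disc with per-vertex sensitivity in
the 0.8–0.95 range — a positive control that is neither trivial nor
hopeless. Negative signs match the direction of the association the
pipeline is designed to detect (more risk-tolerant and more impatient
subjects showing lower metric values).

## Mesh machinery

Meshes are stored with 1-based vertex indices — the natural convention in
R; formats that index from 0 on disk (GIFTI triangles, the plain-array
faces file) are converted on read and write. Coordinates are mm in a
right-handed RAS-like frame, so MNI-style sphere ROIs apply directly.

**Smoothing.** CAT12-style surface smoothing is emulated by iterated
symmetric neighbor exchange: one iteration applies
$x \leftarrow x + \tfrac{\lambda}{d_{max}} (Ax - dx)$ with adjacency matrix
$A$ and degrees $d$. The operator is symmetric with unit row sums, so the
vertex sum is preserved *exactly* on any mesh and nonnegative inputs stay
nonnegative for $\lambda \le 1$. Iteration count and $\lambda$ are set from
the lazy-random-walk variance relation
$\sigma^2_{dim} = m\,q\,\bar{h}^2/2$ (mean-squared edge length $\bar h^2$,
move probability $q$), targeting $\sigma = \mathrm{FWHM}/2.3548$. On a
subdivided icosphere the empirical kernel, measured by fitting a Gaussian
profile to a smoothed delta, lands within a few percent of the requested
FWHM once the FWHM spans a few edge lengths; below that the kernel is
dominated by mesh discreteness, which is why analysis FWHM defaults (20 mm
for complexity/gyrification, 12 mm for depth/thickness, 8 mm for the GMV
surrogate) should only be used with meshes at least that fine.

**Geodesics.** Geodesic discs and distances use edge-length-weighted
shortest paths (Dijkstra via igraph) — an upper bound on the true polyhedral
geodesic that is adequate at fixture scale and keeps the dependency surface
small.

## Vertex-wise inference

Each metric is regressed vertex-wise on the preference of interest plus
age, sex and IQ (plus TIV for the GMV surrogate). The t-statistic for the
predictor of interest is computed by partialling the nuisance columns out
of the predictor — algebraically identical to the full-model t, and fast
enough to recompute thousands of times.

**TFCE.** The enhanced statistic integrates
$e_v(h)^{E} h^{H}\,\mathrm{d}h$ over thresholds $h$, where $e_v(h)$ is the
vertex count of the supra-threshold connected component containing $v$.
Defaults are the canonical surface parameters $E = 0.5$, $H = 2$, with 100
equally spaced thresholds up to the map maximum per tail (the usual
adaptive step). The positive and negative tails are enhanced and tested
separately as one-sided analyses — matching directional hypotheses — and
each is FDR-corrected at the same level; a vertex can be significant in at
most one tail. The published analyses do not state whether their toolbox
tests tails jointly; per-tail testing is this package's documented choice.
The compiled implementation (union-find component labeling per threshold)
is tested for exact equality against a naive per-threshold relabeling
oracle.

**Permutation scheme.** Nuisance covariates rule out permuting raw data, so
the null is built with Freedman–Lane: fit the nuisance-only model once,
permute its residuals, add them back to the nuisance fit, refit the full
model, and TFCE-enhance the resulting t-map. Per-vertex p-values use the
positively biased estimator $p = (1 + \#\{T^{*} \ge T\})/(1 + B)$, which
can never be zero at finite $B$. Benjamini–Hochberg FDR is then applied
within the analysis mask, per tail, and significance is declared at
$q \le .05$. Everything is reproducible from a single integer seed.

A practical resolution constraint follows from the +1/+1 estimator: with
$B$ permutations the smallest attainable p is $1/(B+1)$, and BH on $V$
vertices requires $p \le q\,k/V$ for the $k$-th smallest p-value. With 500
permutations and 642 vertices, a cluster smaller than ~26 vertices can
never survive, whatever its effect size. The pipeline default is therefore
1,000 permutations at the 642-vertex validation mesh; published analyses at
~300k vertices use 10,000 for the same reason.

**Conjunction.** A vertex qualifies only if independently significant in
both component analyses at the requested signs; the conjunction map is the
mean of the two TFCE maps. Cluster tables report, per connected component
of a significance mask: the peak-TFCE vertex (ties broken by lowest index),
its mm coordinates, the peak TFCE value and the extent `k`.

**Peak-area regression.** The `top_n` conjunction vertices with the highest
mean TFCE (default 500, capped at the conjunction size; ties by vertex
index) are averaged per subject and per measure, and each preference is
regressed on all measure averages plus age, sex, IQ and the other
preference. Coefficients are reported standardized (all variables
z-scored); t and p come from the unstandardized fit and are invariant to
affine rescaling of any measure.

## Validation problem sizes

The suite validates the chain at sizes chosen for a desk-class machine:
behavioral consistency and parameter recovery over 10 simulated cohorts of
156 subjects; TFCE oracle equality on 50 random 162-vertex maps; FDR
control over 200 null replicates on a 642-vertex mesh with 500 permutations
each; and the planted-conjunction positive control over 20 replicates with
1,000 permutations. `scripts/acceptance.R` re-runs the behavioral
reproduction from scratch under a caller-supplied seed.

## Known limitations

* The synthetic subjects are exact softmax choosers. Real choice data
  contain lapses, side biases and other deviations from the fitted model;
  consequently the simulated coupling between model-based and model-free
  measures is somewhat tighter than in real cohorts, and passing tests here
  certify the estimation and inference machinery, not the behavior of real
  subjects.
* Synthetic metric maps are stationary Gaussian fields with uniform
  covariate loadings; real morphometry has spatially structured covariance,
  registration error and measure-specific artifacts. The FDR-control result
  holds under the simulated covariance, which is the standard caveat for
  any permutation-validated pipeline.
* Geodesic distances are graph shortest paths, biased slightly long on
  coarse meshes; disc ROIs inherit that bias.
* The probability-discounting comparison fixes the odds-against hyperbolic
  form; other forms of probability weighting are out of scope.
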