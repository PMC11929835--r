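---
title: "Models and methods behind skintact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind skintact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skintact)
```

`skintact` analyses how non-invasively measurable properties of
finger-pad skin — stratum corneum (SC) hydration and thickness,
cutometer deformability (R0, Ue, R2), Meissner corpuscle (MC) density,
ridge distance, sweat-gland density, and age — relate to tactile
friction and perception of micro-structured materials. This vignette
documents the models, the defaults and why they were chosen, the
numerical decisions, and the limits of what the synthetic validation
can show.

## Friction extraction

A trial is a 50 Hz recording of `(Fx, Fy, FN)` during circular
exploration of a mounted sample. The friction coefficient is the ratio
of the resultant tangential force to the normal force,
$\mu = \sqrt{F_x^2+F_y^2}/F_N$, evaluated per sample and summarized by
the **median over touch samples**. Touch is declared where
$F_N > 4\sigma$, with $\sigma$ the unloaded-sensor noise. Choices
behind this:

* $\sigma$ defaults to the SD of $F_N$ over the first second of the
  trace. "Sensor noise" has no standard operational definition; the
  leading idle window is the only part of a trial guaranteed to be
  contact-free.
* Samples at or below the threshold are excluded entirely, never
  interpolated: the ratio is undefined without contact, and the median
  makes the summary insensitive to how exactly the boundary samples
  fall.
* The median is taken over *samples*, not over exploration cycles.
  Per-cycle medians would weight slow cycles less; with roughly
  constant circling speed the two agree, and per-sample is simpler and
  robust (contaminating 10 % of touch samples moves the median by
  < 5 % in the test suite).
* Normal forces outside the instructed 0.8–1.2 N band are *flagged*
  (`fn_in_range_fraction`), not discarded — the band is experimenter
  guidance, not a validity bound.
* Cycles are counted by unwrapping the phase of $(F_x, F_y)$ over
  touch samples and dividing the accumulated angle by $2\pi$. The
  tangential force direction co-rotates with the finger, so this needs
  no kinematic data. Rates are reported missing when touch lasts under
  1 s or the tangential magnitude is degenerate.

Because $\mu$ is a ratio, it is exactly invariant under a common
rescaling of all three channels, and exactly equal to the generating
coefficient for noiseless simulated traces — both are tested.

## Stimulus geometry

Micropillar samples are hexagonal lattices with center-to-center
distance $2D$; the areal density is $1/(2\sqrt{3}D^2)$ and the bending
stiffness of a pillar is $\pi E D^4/(32 L^2)$ with $E = 1.7$ MPa. For
$D = 150\,\mu$m the closed form gives 12.8 mm⁻² where 12 is sometimes
quoted; we keep the closed form (the difference is rounding or edge
counting, and nothing downstream depends on it).

Rough surfaces are synthesized spectrally: Gaussian Fourier amplitudes
shaped by $C(q) \propto q^{-2-2H}$ between a long-wavelength cutoff
(default: half the grid extent) and a short-wavelength cutoff
(default 0.5 mm, the smallest wavelength present on the physical
samples), then rescaled so the realized RMS roughness equals the
target Sq exactly. Small-scale roughness is quantified by the RMS
curvature, computed with central second differences as
$$\kappa = \sqrt{\langle h_{xx}^2\rangle + \langle h_{yy}^2\rangle}.$$
Combining the two orthogonal directions by *summing* their mean
squares (rather than averaging them) makes the measure reduce to the
one-dimensional profile definition when the surface varies along a
single direction — for $h = A\sin qx$ it returns $Aq^2/\sqrt{2}$,
which is the analytic value the implementation is tested against (to
about the discretization error, $(q\,\Delta x)^2/12$). Cross
derivatives are excluded. The six rough samples' curvatures
(1.00–3.29 mm⁻¹) are shipped as fixed constants
(`rough_sample_curvatures()`); their assignment to the labels
S01–S09 is a package convention, with S01 the smoothest.

## Statistics

Pearson correlations carry two-sided p-values from
$t = R\sqrt{(n-2)/(1-R^2)}$ — the one-predictor regression test, which
is what "tested by ANOVA" amounts to for a single correlation.
Missing values are handled by pairwise deletion, so different
parameter pairs may have different n, as in real cohorts where MC
density is only measurable for a subset. No multiple-testing
correction is applied; p-values are reported raw.

The MC-density decay is fit by OLS of $\ln(\text{density})$ on age;
the half-life is $\ln 2/(-b)$ and is independent of the logarithm
base. Confidence intervals come from a percentile bootstrap that
resamples (age, density) *pairs*; the default 10⁴ resamples keep
interactive runtimes low (a fidelity flag allows 10⁶). Coverage of
the 95 % interval is verified by simulation (500 replicate cohorts of
56 participants, 1000 resamples each) in the test suite.

Welch's t-test is used for sex differences, as the variances have no
reason to be equal.

## Components and composites

PCA is performed on the **correlation** matrix — the variables mix
corneometer units, µm, mm⁻² and fractions, so covariance PCA would be
meaningless. Components with eigenvalue > 1 are retained (Kaiser),
varimax-rotated with Kaiser normalization (tolerance $10^{-6}$, the
`stats::varimax` iteration), and each rotated component is sign-fixed
so its largest-magnitude loading is positive; components are ordered
by rotated explained variance. Communalities are preserved by the
rotation to $10^{-8}$ and tested. Factor scores use Bartlett's
weighted-least-squares estimator
$\hat f = (L'\Psi^{-1}L)^{-1}L'\Psi^{-1}z$ with uniquenesses clamped
at $10^{-6}$; scores are computed and exported but downstream
correlation analyses use the plain composite averages, which is what
the composite-outcome rule defines.

Sampling adequacy uses the standard KMO ratio of squared correlations
to squared correlations plus squared anti-image partial correlations;
sphericity uses Bartlett's
$\chi^2 = -(n-1-(2p+5)/6)\ln\det R$ with $p(p-1)/2$ degrees of
freedom. Both are hand-implemented (no installed package provides
them) and verified against direct-determinant and block-structure
oracles.

The composites follow the loading-threshold rule (> 0.75): µ_rough
averages the six rough samples, µ_fibril the four pillar samples with
aspect ratio > 1 (40/120, 100/200, 100/300, 150/350), and the
aspect-ratio-1 samples (100/100, 150/150) enter neither — they load
across both friction components. S_perc is the mean of the z-scored
pillar-detection rate and the *negated* z-scored two-point threshold,
so larger values always mean finer perception.

## Regression and relative weights

`ols_fit` wraps `lm` with listwise deletion and reports R², t and p
per predictor. Johnson relative weights decompose R² over correlated
predictors: with standardized predictors and
$R_{xx} = V\Delta^2V'$, the symmetric square root
$\Lambda = V\Delta V'$ links predictors to their closest orthogonal
counterparts, $\beta = \Lambda^{-1}r_{xy}$, and
$\varepsilon_j = \sum_k \lambda_{jk}^2\beta_k^2$. The identities
$\sum_j \varepsilon_j = R^2$ and $\varepsilon_j = r_{jy}^2$ under
exact orthogonality are asserted to $10^{-8}$, and a two-predictor
closed form (the 2×2 eigenvectors are parameter-free) provides a
symbolic oracle. Predictor correlation matrices with condition number
above $10^8$ are rejected.

The interaction model centers both variables before forming their
product, which decorrelates the product from the main effects and
makes the main-effect coefficients interpretable at the means; it
reports the interaction coefficient, its t and p, and the R² gain
over the additive model.

## Psychometric fitting

The comparison model is $p(x) = 1 - 0.5\,e^{-(kx)^d}$: chance at zero
relative difference, certainty in the limit. The just-noticeable
difference is the 75 % point, $\mathrm{JND} = (\ln 2)^{1/d}/k$. The
relative difference of two curvatures $c_1 > c_2$ is
$(c_1-c_2)/((c_1+c_2)/2)$ by default (alternatives `/c_min`,
`/c_max` are available); the symmetric normalization treats the pair
as unordered, which matches how triplet rankings are scored.

Fitting maximizes the binomial likelihood over $(\log k, \log d)$
with a 16-point multi-start Nelder–Mead ($10^{-12}$ relative
tolerance). By default the likelihood carries a Firth-type Jeffreys
penalty $+\frac12\log\det I(\theta)$: the stimulus set places only
three pair differences (≈ 0.08–0.09) on the rising flank of the curve
with everything else saturated (≥ 0.44), a geometry in which the
plain MLE of the threshold is noticeably biased downward at study
scale and undefined for degenerate all-correct data. The penalty
removes the leading-order bias and keeps estimates finite;
`method = "mle"` gives the unpenalized fit. Both versions are exactly
equivariant under rescaling of the difference axis (tested), and the
recovery of a known threshold at study scale (60 participants × 15
pairs × 5 repetitions) is verified both per-replicate (median error)
and as a 25-replicate mean in the acceptance suite — the averaging
reflects that a single simulated study determines the threshold only
to about ±0.02 under this sparse design.

The triplet design groups 6 samples into 10 ordered triplets with
each sample appearing exactly 5 times, found by exhaustive
backtracking over the 20 possible triples (a brute-force enumeration
over all $\binom{20}{10}$ subsets confirms such designs exist).
Scoring pools all 30 within-triplet pair slots per participant; a
counting rule based on 10 distinct pairs is arithmetically
inconsistent with 3 pairs × 10 triplets over 15 possible pairs, so
the pooled aggregation is the default and the relative-difference
grouping collapses duplicates naturally.

Two-point discrimination follows the measurement protocol: distances
{0, 2, …, 8} mm in random order, the minimal distance reported as two
points retested together with 1 mm, the retest result winning.
Simulated observers use a latent threshold with Gaussian noise and no
lapses by default; a latent threshold of 3.5 mm records 4 mm, the
protocol's grid granularity being part of the measurement.

## The synthetic cohort: what it emulates

`cohort_config()` defaults define the simulated study population:

| parameter | mean | RSD | source of default |
|---|---|---|---|
| age | 34 y (SD 11, truncated 20–70) | — | study demographics |
| SC hydration | 50 a.u. | 25 % | RSD printed; mean plausible |
| SC thickness | 150 µm | 25 % | RSD printed; mean plausible |
| SG density | 6 mm⁻² | 21 % | RSD printed; mean plausible |
| ridge distance | 450 µm | 15 % | RSD printed; mean plausible |
| R0 | 0.12 mm | 31 % | RSD printed; mean plausible (below SC thickness) |
| Ue | 0.08 mm | 41 % | RSD printed; mean plausible |
| R2 | 0.65 | 9 % | RSD printed; mean plausible |
| MC density | 7.2 mm⁻² | 40 % | both printed |

All positive parameters are lognormal — strictly positive, right
skewed, and parameterizable directly by mean and RSD. Dependence is a
Gaussian copula whose target matrix carries the reported pairwise
correlations (R0–hydration 0.40, Ue–hydration 0.49, R2–thickness
0.39, R2–hydration 0.31, hydration–age −0.31); unspecified entries
default to zero, and the matrix is repaired to the nearest PSD matrix
by eigenvalue clipping (tolerance $10^{-8}$) before use. Copula
correlations attenuate slightly through lognormal margins; closure
tests require agreement within ±0.05 at n = 10⁴, which the defaults
meet without adjustment.

MC density is *not* a copula margin: it is generated structurally as
$\text{baseline}\cdot 2^{-\text{age}/19\,\text{y}} \cdot
\text{lognormal noise}$. The baseline and the noise RSD are solved at
configuration time from the target mean (7.2 mm⁻²) and total RSD
(40 %) given the age distribution's own contribution (CV of
$2^{-\text{age}/19}$ ≈ 0.32, computed by quadrature), so the marginal
targets are met by construction. A consequence worth knowing: an MC
RSD target below the age-induced variability is infeasible and is
rejected with a clear error.

Sex is assigned 37 F : 23 M; only sweat-gland density and ridge
distance receive (mean-preserving, log-scale) sex offsets, the only
parameters with a reported sex difference. A configurable
missingness rate (default off) emulates the incomplete-case
bookkeeping of real cohorts.

Friction coefficients are generated per sample as
$\mu_{ps} = m_s(1 + c_s\,s_{ps})$ with unit-variance scores
$s_{ps} = a\,g_p + b\,u_p + c\,\varepsilon_{ps}$: a class physiology
score $g$ (a fixed linear combination of standardized hydration,
thickness, Ue, R2 — hydration-led for rough samples, Ue-led for
fibrillar ones, mirroring the regression t-ordering), a class-shared
participant effect $u$, and per-sample noise. The coefficient $a$ is
solved in closed form so the population R² of the **class average**
on the four predictors equals the configured target (0.74 rough, 0.34
fibrillar). The rough-class participant-effect share of 0.85 puts
inter-sample correlations near 0.96; the fibrillar 0.5 puts them near
0.6. Aspect-ratio-1 samples mix both classes' scores and effects
equally, reproducing their intermediate loading pattern. Negative
draws are resampled from the exactly truncated noise distribution.
Sample means default to 0.92 for each rough sample and 1.2–2.0 for
pillars increasing with aspect ratio; per-sample RSDs default to
0.28–0.33 (rough) and 0.17–0.22 (pillars).

Perception links were calibrated once, by simulation at n = 20 000,
to make the composite S_perc correlate with MC density at ≈ 0.6 and
give a five-predictor regression R² of ≈ 0.40 rising to ≈ 0.47 when
the negative MC × hydration interaction enters; the calibrated
coefficients are the package defaults and are not study estimates.
The pillar-detection logit increases with bending stiffness and
decreases with pillar density, so coarse sparse pillars are detected
and fine dense ones are not.

Force traces embed a contact segment (normal force wandering slowly
around 1 N, tangential vector rotating at the circle rate with
magnitude $\mu\,F_N$) between idle flanks, with white Gaussian sensor
noise per channel (default 0.01 N). The sensor-noise model is an
assumption — the real instrument's noise spectrum is unknown — and
the normal-force wander is sinusoidal at 0.2 Hz for simplicity.

**What passing tests do and do not show.** The generator matches the
study's *second-order structure*: marginal spreads, printed pairwise
correlations, explained-variance shares, decay constants, psychometric
parameters. It does not model exploration kinematics, skin–pillar
contact mechanics, finger-size effects, inter-trial learning, or any
higher-moment structure of real data. Closure results (e.g. that the
regression recovers the configured R², or the JND the configured
threshold) validate the *estimators*, not the biology.

## Orchestration and reproducibility

`run_pipeline` derives every stage seed from one global seed
(`seed + k·10007 mod 2³¹−1`), so a bundle is reproducible end to end
and report CSVs carry `# seed=… config=…` headers; byte-identical
re-runs are asserted in the tests. Stage failures abort with the
stage name. Benchmark mode replaces generation by
`read_participant_table`, which maps deposited-style column aliases
onto the package vocabulary, preserves-and-flags unknown columns, and
reports malformed cells by row and column. Degrees of freedom then
follow from listwise deletion within each regression.

Problem sizes used in the shipped checks — 10⁴-participant cohorts
for marginal/correlation closure, 500 × 56 cohorts for bootstrap
coverage, 25 replicate psychometric studies for threshold recovery,
200 traces for extraction closure — were chosen so each check's
Monte-Carlo error is several times smaller than the tolerance it
asserts.

## Known limitations

* The benchmark path is exercised against synthetic stand-in tables;
  reproducing a deposited study table requires the user to supply it.
* Johnson weights assume a well-conditioned predictor correlation
  matrix; near-collinear predictor sets are rejected rather than
  regularized.
* The psychometric fit treats all observers as sharing one curve;
  no lapse-rate or per-participant threshold heterogeneity is
  estimated (the generator can produce heterogeneity, the fitter
  pools it).
* Two-point thresholds are discretized by the protocol grid, so
  correlations involving them are attenuated relative to the latent
  acuity.
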