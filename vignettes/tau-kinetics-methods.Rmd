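---
title: "Models and methods for tau seed accumulation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for tau seed accumulation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taukinetics)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the numerical and
statistical choices that were genuinely open, and what the synthetic
tests do and do not establish about real data.

## The reaction-diffusion model and its regimes

Tau seeds are replication-competent aggregates. Their local fraction
f(**r**, t) of the maximal sustainable concentration P_max is modelled
by the logistic reaction-diffusion (Fisher–KPP) equation

$$\frac{\partial f}{\partial t} = D \nabla^2 f + \kappa f (1 - f),$$

with an effective diffusion coefficient $D$ standing in for all
long-range transport between brain regions and an effective replication
rate $\kappa$ absorbing every local process — growth, fragmentation,
secondary nucleation, cell-to-cell transfer within a region, clearance.
Two assumptions matter. First, spatial resolution: the data the model
is built for resolve only whole brain regions, so "spreading" means
inter-regional transfer; local inhomogeneities are inside $\kappa$.
Second, saturation: a maximal seed concentration exists and is
approached logistically.

Two limiting behaviours follow. If replication is fast relative to
transport (small $D/\kappa$ for a compact starting distribution), a
sharp front sweeps the tissue at the pulled-front speed
$v = 2\sqrt{D\kappa}$: accumulation is *spreading-limited* and its time
scale involves both rates through their geometric mean. If transport is
fast, or seeds are present everywhere from the start, every location
rises together along the logistic solution and the time scale is set by
$\kappa$ alone: *replication-limited*. For a compact initial bump the
switch sits near $D/\kappa = 0.0025\, r_\mathrm{max}^2$, which for a
10 cm human brain and $\kappa = 0.14\,\mathrm{yr}^{-1}$ corresponds to
$D \approx 10^{-13}\,\mathrm{m^2 s^{-1}}$ (`critical_diffusion()`,
with year = 365.25 days in all unit conversions — this convention
reproduces the order-of-magnitude diffusion statements and is fixed
package-wide).

`classify_regime()` makes the distinction operational: at the first
stored time the spatial mean of $f$ crosses 0.5, the heterogeneity
index $\chi$ is the fraction of grid points still below `low = 0.05`.
$\chi > 0.25$ is labelled spreading-limited, $\chi < 0.05$
replication-limited, otherwise intermediate. The two thresholds are
configuration values chosen so that the label flips within a factor of
three of the $0.0025\, r_\mathrm{max}^2$ switch for a compact bump of
width $0.01\,r_\mathrm{max}$ — they are an explicit operational
criterion, not a derived quantity.

### Numerical scheme

`fkpp_simulate()` uses Strang splitting: the reaction substep is
advanced with the *exact* logistic flow on the log-odds scale, the
diffusion substep implicitly (backward Euler on the Neumann path-graph
Laplacian; a cached dense inverse for chains of up to 64 nodes, a
sparse Cholesky factor above that). Consequences that the tests rely
on: a spatially uniform field reproduces the closed-form logistic to
machine precision; pure diffusion conserves total mass exactly (the
Laplacian has zero row and column sums); the solution stays in
$[0, 1]$ by construction of both substeps. Zero-flux boundaries were
chosen because the brain is a closed volume for seeds; the default
interval grid has 201 points. The default step resolves the reaction
($\kappa\,\Delta t \le 0.05$) and keeps the front below half a grid
cell per step; a larger user-supplied step is rejected with the
maximum accurate step named in the error.

One numerical subtlety is documented here because it shapes a test:
pulled fronts approach $2\sqrt{D\kappa}$ with a slow logarithmic
transient (front position $\approx vt - c\log t$), so on a unit
interval the average speed from a steep initial condition sits
10–25% below the asymptote. Speed measurements therefore launch the
front from an initial profile with the travelling-wave tail
$e^{-\sqrt{\kappa/D}\,x}$ (`front_initial_condition()`) and
`measure_front_speed()` fits `position ~ time + log(time)` by default,
reporting the asymptotic coefficient. This is a property of the PDE,
not of the discretisation.

### The regional fit

`fit_regional_model()` represents the six sampled regions (EC, H, PHG,
AC, VA, PV — ordered by synaptic distance from the entorhinal cortex)
as equally spaced nodes of a chain. The measured Braak III profile,
divided by P_max, is the initial condition; $\kappa$ is held at the
cross-dataset value 0.14 yr⁻¹; $D$, P_max and the simulation-clock
offset t_start are optimised. Because the source measurements span
orders of magnitude and are displayed logarithmically, the loss is the
sum of squared residuals of log10 signal (a package decision; linear
residuals were the plausible alternative). t_start is constrained
between the Braak III and VI clock times, and stages observed before
the simulation starts are excluded from the loss. The optimiser is a
coarse grid scan followed by Nelder–Mead refinement: the loss couples
$D$ with t_start along a curved valley and carries small solver kinks
from step-count quantisation, which stall finite-difference
quasi-Newton methods short of the optimum. P_max is bounded below by
the largest observation (a ceiling cannot sit under the data).

`intervention_compare()` re-simulates the fitted configuration with
$D$ or $\kappa$ divided by 3 and reports the delay in reaching half of
P_max in spatial mean. In a replication-limited configuration the
$\kappa$ delay exceeds the $D$ delay by two orders of magnitude; on a
spatially uniform start, the closed form gives delay = (factor − 1) ×
t_half exactly, which the tests check.

## The Braak clock

Postmortem staging gives disease *stage*, not *time*. The conversion
assumes that progression, once started, is similar across individuals,
so that differences in the age composition of stages reflect mainly
onset-age differences. Under that assumption the probability of being
at stage $s$ given age is modelled as a Gaussian
$A\, e^{-(a - m_s)^2 / 2\sigma^2}$ with shared amplitude and SD and a
per-stage mean age $m_s$. Stages I–III peak safely below 100 years and
determine $(A, \sigma)$ jointly with their means (phase 1); stages
IV–VI are right-truncated by the absence of centenarians in the data,
so with $(A, \sigma)$ frozen, only their means are fitted, and the
model is evaluated on the observed bins only (phase 2). Truncation by
restriction — rather than renormalising a truncated Gaussian — is what
permits fitted means above 100 years, as the reference table reports
(105, 113, 118 for IV–VI). Stage durations are consecutive mean-age
differences (19, 14, 21, 8, 5 years from I to VI), and the cumulative
clock anchored at stage III (0, 21, 29, 34 years) is the default time
axis for Braak-staged measurements. The fit is unweighted least
squares on the probability curves, matching a curve-fitting rather
than count-likelihood description; substages are collapsed onto their
principal stage, with everything below stage I pooled.

## Replication-rate inference

For replication-limited data the signal model is the rescaled logistic
$S(t) = \alpha f_0 e^{\kappa t} / (1 - f_0 + f_0 e^{\kappa t})$ (plus a
baseline $b$ for PET). `posterior_grid()` evaluates the posterior of
$(\kappa, f_0, \alpha)$ on a product grid under Gaussian noise on
**log10 signal** — the log scale was chosen because the source data
are displayed and averaged in log space; a linear-space likelihood is
available behind the `likelihood_space` flag. The noise SD comes from
repeat measurements (`estimate_noise_sd()` pools within-group SDs of
log10 values). Priors: $1/x$ for $\kappa$ (axis $[10^{-3}, 10]$ yr⁻¹)
and for $f_0$ (axis $[10^{-10}, 10^{-2}]$, i.e. between roughly one
seed per brain and 1% of the final concentration), flat for $\alpha$.
Each brain region is analysed separately; the per-region posteriors
are marginalised over $(f_0, \alpha)$ and the marginals multiplied
pointwise (equal weight) into a dataset-level posterior — the same
product rule combines datasets.

Three numerical choices were calibrated by simulation rather than
taken on faith, using generated cohorts with known $\kappa$:

* **$\alpha$ axis spacing.** The axis is log-spaced for resolution,
  but its prior weights are the linear cell widths, so the prior
  remains flat in $\alpha$ itself.
* **$\alpha$ prior upper bound.** $\alpha$ is the plateau signal, so
  its prior starts at the largest observation. With a very loose upper
  bound (100× the maximum) the flat prior concentrates mass at large
  $\alpha$ and, through the $\alpha$–$f_0$–$\kappa$ correlation,
  biases the combined rate low by ≈ 0.45 posterior SDs. The default
  bound of 10× the maximum reduces the bias to ≈ 0.16 SDs and brings
  1-SD coverage to ≈ 0.7, near the nominal 0.68; `alpha_factor`
  exposes the choice.
* **$\kappa$ grid size.** 240 log-spaced points keep the
  discretisation error below the width of posteriors that have been
  sharpened by combination across six regions (SD ≈ 4% of $\kappa$,
  versus ≈ 8% cells at 120 points).

A small negative bias (≈ 0.1–0.2 SD) remains and is inherent to the
combination rule itself: each per-region marginal carries its own
$1/\kappa$ prior, so the product applies that prior six times. The
rule is kept because it is the procedure the inference scheme
specifies; users combining many datasets should be aware of it.
`lsq_median_fit()` provides the companion least-squares point estimate
to per-time medians, for display parity with published time-course
panels.

## PET rates

Longitudinal PET gives two SUVr values about two years apart, hence an
annualised rate $r = (S_2 - S_1)/\Delta t$ attached to the visit-mean
signal. Differentiating the logistic signal model gives
$r = (\kappa/\alpha)(S - b)(\alpha - (S - b))$, a parabola with roots
at $b$ and $b + \alpha$ and maximum $\kappa\alpha/4$. `fit_pet()` runs
constrained least squares with $\kappa, b > 0$ and $\alpha \le 4$
SUVr — a conservative ceiling on the plateau above baseline, well
beyond any measured signal; because realistic cohorts sample only the
rising branch, the optimum typically sits on that bound and the fit
reports it (`alpha_at_bound`). The loss is unweighted squared error on
$r$ (no weighting is implied by the data source; per-record weights
are accepted). All records enter by default regardless of diagnostic
group.

## Mouse kinetics

Transgenic-mouse seed time courses grow exponentially before a late
plateau. `fit_log_linear()` fits log signal against time by OLS, by
default restricted to months ≤ 4 and to time points measured in
*every* region (`filter_complete_timepoints()`) to avoid
missing-region bias. The natural-log slope is reported as $\kappa$
(per month) with the log10 slope alongside: published rates do not
always state their logarithm convention, and the two readings of a
printed "0.6 per month" imply doubling times of 1.16 versus 0.50
months (`doubling_time_from_printed_rate()`); the package never
silently chooses.

## Histology quantification

AT8-stained brightfield slides are quantified on the 0–255
hue/saturation/brightness scale (the convention of the thresholding
tool the windows were defined in — the printed bounds exceed 180°/100%
scales, which fixes the convention). Cells: hue 108–200, saturation
25–141, brightness 145–230; binarise, one 3×3 dilation, hole filling,
watershed on the negated distance transform (tolerance 1 px), then
keep particles with area ≥ 200 px² and circularity $4\pi A/P^2 > 0.5$
(perimeter from the labelled-object boundary). Tau: hue below 44 *or*
above 222 (a wrapping window — DAB browns straddle the hue origin; the
conjunctive reading is empty), saturation above 42, brightness below
206; the passing pixel count is the tau area, normalised by the cell
count into a burden. The area/circularity filter is applied after
watershed, matching the order of the named plugin chain. EBImage
provides the morphology; the windows, wrap semantics, and filters are
this package's.

## Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its seed and reproduces one study
design: `gen_seed_dataset()` — logistic signals on the Braak clock
(stages III–VI at 0/21/29/34 years) for 7/4/6/2 subjects across six
regions, initial fractions decaying geometrically (factor 0.3) from
the entorhinal cortex, lognormal noise of $\sigma_{\log_{10}} = 0.5$
(order-of-magnitude scatter, matching the visual spread of published
seed titers), two technical replicates so the noise SD is estimable;
`gen_stage_age_table()` — multinomial stage draws per age decade from
the Gaussian stage model (amplitude 0.32, SD 15 yr, reference means),
2332 individuals on an autopsy-like age pyramid, truncated at 100
years; `gen_pet_cohort()` — 101 baselines uniform over the rising
branch with Gaussian rate noise of 0.01 SUVr/yr around the
differentiated logistic at (κ = 0.17, α = 4, b = 1.06);
`gen_mouse_timecourses()` — shared exponential rate 0.6/month with
region-specific baselines and staggered missing late points;
`gen_histology_image()` — nuclei and tau disks in colours validated at
generation time against the segmentation windows (an out-of-window
colour is a generator error), with painted-pixel ground truth.

Passing tests on these data show that the estimators recover the
parameters of their own generating model at realistic noise and sample
sizes, and that the numerical machinery is correct. They do not show
that real tau data follow a logistic with lognormal noise, that real
stage-age distributions are Gaussian with a shared SD, or that real
slides are two uniform colours on a clean background; model adequacy
on real data is outside what synthetic recovery can establish.

## Problem sizes and limitations

Default problem sizes (201-point interval grids, six-node chains,
20-replicate recovery studies, 100-cohort calibration checks,
512² synthetic slides) were chosen so the full test suite documents
the statistical properties without excessive simulation; all scale up
by argument. Known limitations: no connectome-weighted spreading
(the chain geometry is deliberately minimal), no subject-level random
effects (subjects pool within stage), no onset-age/progression-rate
correlation in the Braak clock, no stain deconvolution or scanner
formats in histology, and the replication-limited signal model applies
only from Braak stage III onward — the early-stage regime, where
spatial structure forms, is explicitly out of scope.
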