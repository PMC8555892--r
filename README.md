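# taukinetics

Chemical kinetics of tau seed accumulation in Alzheimer's disease, as an
R package.

In Alzheimer's disease, aggregates of the tau protein both *replicate*
locally (existing seeds template new ones) and *spread* between brain
regions. Which of the two limits the overall rate of accumulation
decides where an intervention helps: slowing replication always slows
the disease, slowing spread only helps if spread is rate-limiting.
`taukinetics` implements the quantitative toolkit for answering that
question from seed-titer, immunohistochemistry, and tau-PET data: a
reaction-diffusion model of seeds on a chain of brain regions, a
Bayesian scheme for estimating the effective replication rate, a
calibration of neuropathological (Braak) stage to calendar time, and a
decomposition of replication into growth and multiplication. A
synthetic-data module emulates each study input so the entire pipeline
runs and is tested without any external download.

The package is written for quantitative neuroscientists and
biophysicists: every user-facing function takes a data frame and returns
a tibble, fitted objects have `tidy()`/`glance()` methods, and each
result type has an `autoplot()`.

## The model

The seed fraction f(**r**, t) ∈ [0, 1] (concentration relative to the
local maximum P_max) follows the Fisher–KPP reaction–diffusion
equation

    ∂f/∂t = D ∇²f + κ f (1 − f)

with effective diffusion coefficient D (spreading) and effective
replication rate κ. Two limits emerge: *spreading-limited* growth, a
propagating front whose time scale is set by the geometric mean
2√(Dκ), and *replication-limited* growth, where seeds are present
everywhere early and the field rises in place following the logistic
solution

    S(t) = α f₀ e^{κt} / (1 − f₀ + f₀ e^{κt}) + b,

with signal scale α, initial seed fraction f₀, and baseline b. For a
compact initial distribution the switch between regimes occurs near
D/κ = 0.0025 r_max². The doubling time of the seed population is
t₂ = ln 2 / κ. Replication decomposes into growth and multiplication
rates through the mean aggregate size μ (in monomers):
κ = √(k_growth · k_mult), μ = √(k_growth / k_mult).

Estimation pipeline:

* `fkpp_simulate()` / `classify_regime()` — solve the PDE on an
  interval or a six-region chain (EC, H, PHG, AC, VA, PV) and label
  the rate-limiting regime.
* `fit_regional_model()` / `intervention_compare()` — fit (D, P_max,
  t_start) to stage-resolved regional profiles with κ fixed, then ask
  what a 3-fold reduction of either rate would change.
* `conditional_stage_given_age()` / `fit_stage_gaussians()` /
  `stage_durations()` — the Braak clock: constrained Gaussian fits to
  a stage-by-age table give per-stage mean ages and hence years
  between stages (reference values: 21, 8, 5 years from stage III to
  VI).
* `infer_kappa()` — grid posterior over (κ, f₀, α) per brain region
  under lognormal noise, marginalised to κ and combined across
  regions (1/x priors for κ and f₀, flat prior for α).
* `fit_pet()` — longitudinal PET: annualised rate r = ΔS/Δt against
  mean signal, fitted to the differentiated logistic
  r = (κ/α)(S − b)(α − (S − b)) with α ≤ 4.
* `fit_log_linear()` — early-phase exponential fit to transgenic-mouse
  seed time courses, using only time points measured in every region.
* `tau_burden()` / `count_cells()` — AT8 immunohistochemistry: HSB
  thresholding, watershed cell counting with area/circularity filters,
  tau area per cell.
* `gen_*()` — seedable generators for all five study-like inputs.

## Worked example

Run the whole pipeline on synthetic data emulating the study designs
(a 19-subject, 6-region seed-amplification cohort on the Braak clock; a
2332-case stage-by-age table; a 101-person longitudinal PET cohort; a
3-region mouse time course; a synthetic AT8 slide):

```r
library(taukinetics)
res <- run_tau_pipeline(seed = 1)
res
#> <tau_pipeline>
#>   combined kappa = 0.171 /yr (doubling time 4.06 yr); PET kappa = 0.17 /yr
#>   regime: replication_limited; intervention delay kappa/3 = 171 yr vs D/3 = 1.7 yr
#>   mouse kappa = 0.735 /month; Braak durations 18.5, 16.1, 22.7, 3.15, 3.49 yr
```

The combined posterior over six regions recovers the generating
replication rate (0.17 per year, a doubling time of about 4 years):

```r
res$seed_inference
#> <tau_kappa_inference>
#>   combined kappa = 0.171 +/- 0.00635 per year (95% CI 0.156-0.181)
#>   doubling time = 4.06 years; 6 region(s); sigma_log10 = 0.557
```

The intervention comparison shows the hallmark of a
replication-limited system: dividing κ by 3 delays half-maximal
accumulation by ~171 years, dividing D by 3 delays it by under 2
years. The PET fit returns κ = 0.17 /yr with α at its bound of 4 and
baseline b ≈ 1.15 SUVr:

```r
glance(res$pet)
#> # A tibble: 1 × 8
#>   kappa alpha     b doubling_time alpha_at_bound degenerate residual     n
#> 1 0.170     4  1.15          4.08 TRUE           FALSE       0.00888   101
```

Closed-form helpers give the headline numbers directly:

```r
doubling_time(0.14)        # 4.95 years: seed number doubles every ~5 years
fibril_monomer_count(176)  # 749 monomers in a 176 nm fibril (~750)
decompose_rates(0.14, 750) # k_growth = 105 /yr, k_mult = 1.87e-4 /yr
m2yr_to_m2s(critical_diffusion(0.14, 0.1))  # regime-switch D ~ 1.1e-13 m2/s
```

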