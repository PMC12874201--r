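---
title: "Pseudo-first-order LSPR binding kinetics and calibration-free polymer molecular weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-first-order LSPR binding kinetics and calibration-free polymer molecular weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsprkin)
```

## The model

An analyte P flowed at constant concentration over a surface carrying its
binding partner Pa forms a 1:1 complex with association rate constant
`k_on` and dissociation rate constant `k_off`. Because continuous flow
holds [P] at its bulk value, the rate law is pseudo-first-order and the
bound signal follows

$$R(t) = R_{eq}\,(1 - e^{-k_{obs} t}), \qquad
  k_{obs} = k_{on}[P]_0 + k_{off}, \qquad
  R_{eq} = R_{max}\frac{[P]_0}{[P]_0 + K_D},$$

with $K_D = k_{off}/k_{on}$. After the injection ends the surface decays
as $R_{end}\,e^{-k_{off} t}$. The instrument response (RU) is treated as
strictly proportional to bound mass (about 0.1 pg per RU,
`ru_to_mass()`); no refractive-index modelling is attempted.

Fitting each association transient gives one `k_obs`; regressing `k_obs`
against analyte concentration gives `k_on` (slope) and `k_off`
(intercept). Two conventions matter for polymers:

* **Monomeric basis** — molarity of repeat units (mass / `M_o`), in mM.
  This is what is known at the bench when `M_n` is unknown.
* **Polymeric basis** — molarity of chains (mass / `M_n`), in uM. This
  is the chemically meaningful basis: chains, not repeat units, are the
  binding entities. The two are related by the degree of polymerization
  `DP = M_n / M_o` (`monomeric_to_polymeric()`).

A rate line fitted on the monomeric basis therefore has slope
$\alpha = k_{on}/DP$. Measuring the pair in **both orientations** — the
characterized polymer flowed over the unknown-coated surface (polymeric
basis, slope `k_on`) and the unknown polymer flowed over the
characterized-coated surface (monomeric basis, slope $\alpha$) — and
assuming the intrinsic `k_on` of the electrostatic pairing is identical
in the two orientations gives

$$DP = k_{on}/\alpha, \qquad M_n = DP \times M_o,$$

a chromatography-free molecular-weight determination
(`determine_mn()`, `run_full_pipeline()`). The symmetry assumption is
the method's load-bearing hypothesis: encounter between a cationic and
an anionic repeat unit should not depend on which chain is tethered,
provided ionic strength, temperature, flow and surface coverage are
held constant — but it cannot be verified independently by any
surface-tethered technique, and extrapolation to extreme molecular
weights is not guaranteed.

```{r headline}
res <- run_full_pipeline(pei_rates(), pazo_rates(),
                         known_polymer = pei_polymer(),
                         unknown_polymer = pazo_polymer())
res
```

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k_on` bounds (fit) | (1e-6, 10] | 1/s for `k_obs` | brackets bench-scale transients; 10/s is faster than 1 Hz sampling resolves |
| fit tolerance | 1e-10 (cost), 1000 iterations | — | far below data noise; Levenberg–Marquardt via `minpack.lm` |
| offset | fixed at 0 | RU | transients are baselined first; `free_offset = TRUE` to relax |
| baseline window | 10 s before injection, half-open | s | shortest stable pre-injection stretch; excludes the first in-injection sample, which already carries the bulk shift |
| rate-line weights | none (OLS) | — | unweighted OLS on replicate means reproduces the published slope/intercept exactly; inverse-variance weighting available |
| negative intercept | clamped to `k_off` = 0 with warning | 1/s | a rate cannot be negative; raw intercept retained |
| PEI `M_n` | 25,000 | g/mol | vendor characterization of this PEI is ambiguous (one source says ~10,000); 25,000 is the value consistent with the published concentration conversions, and it is an argument, not a constant |
| `M_n` reporting | DP to nearest integer, `M_n` to nearest 100 | — | matches the field's reporting convention; full precision kept in the object |

Initialization of the exponential fit uses the standard heuristic
`C0 = max(response)`, `k0 = 1/t63` with `t63` the first time the response
exceeds `0.632 C0`. The two-phase model
$A_f(1-e^{-k_f t}) + A_s(1-e^{-k_s t})$ is canonically ordered
`k_fast >= k_slow`; when the two rates nearly coincide or an amplitude
vanishes the fit is rank-deficient, flagged `degenerate`, and falls back
reportably to the one-phase model. `compare_models()` reports ΔR²,
small-sample-corrected AIC, and a residual sign-runs z statistic —
systematically asymmetric residuals (common in polyelectrolyte binding,
where multiphasic kinetics and rearrangements occur) show up there even
when R² > 0.95 for both models.

Uncertainty on `M_n` uses first-order (delta-method) propagation through
the slope ratio, assuming the two regressions are independent (they come
from separate experiments); the unit tests check it against a
Monte-Carlo oracle. Correlation between `k_on` and α is not modelled.

## The simulator

`simulate_sensorgram()` generates dual-channel traces as

    active    = baseline + bulk pulse + closed-form binding + N(0, σ²)
    reference = baseline + bulk pulse + independent N(0, σ²)

with the bulk refractive-index shift modelled as an ideal square pulse
spanning the injection window on both channels — exactly the artifact a
reference channel is designed to cancel. Defaults mirror the reference
protocol: 300 s association, 300 s dissociation, 1 Hz sampling,
monomeric concentrations {1, 0.5, 0.25, 0.125, 0.0625} mM in duplicate,
plus a 60 s pre-injection segment so baseline zeroing has data. `R_max`
(1000 RU) and the noise level (σ = 2 RU) are nominal values — published
traces report neither, and the instrument's stated wavelength resolution
does not map to RU noise without a calibration — so recovery results at
these settings demonstrate correctness of the estimators, not the error
budget of any particular instrument. The generator also omits drift,
spikes, temperature artifacts, and injection-timing jitter; passing
recovery tests therefore bounds estimator error under ideal noise, not
under real-instrument pathology.

`simulate_transport_limited()` adds the standard two-compartment
correction: the surface concentration $C_s$ is taken as quasi-steady
between delivery $k_m(C_{bulk} - C_s)$ and consumption by binding,
giving $C_s = (k_m C_{bulk} + k_{off}R)/(k_m + k_{on}(R_{max}-R))$, and
the ODE is integrated with `deSolve`. As $k_m \to \infty$ it converges
to the reaction-limited closed form (verified to <0.1% of $R_{eq}$);
small $k_m$ depresses the initial association slope, the signature of
mass-transport limitation seen when lowering the flow rate. This variant
exists for robustness testing; the headline analysis assumes
reaction-controlled kinetics, consistent with the flow-rate insensitivity
of the reference data.

```{r sim}
truth <- kinetic_params(0.037, 0.014)
cfg <- simulation_config(truth, pei_polymer(), noise_sd = 2, seed = 1)
fit <- fit_transient(preprocess_sensorgram(simulate_gradient(cfg)[[1]]))
fit
```

## Numerical and design choices

* **Rate-line estimator.** OLS via `stats::lm` on replicate-mean
  `k_obs`; the unit tests check it against closed-form centered normal
  equations at 1e-12 of the data scale. Unweighted OLS is the default
  because it reproduces the published slope/intercept from the published
  five-point tables; SEM-based weights are an explicit option.
* **Published polymeric concentrations are kept as printed.** The PEI
  table's conversion (1 mM → 1.7200 uM) implies DP ≈ 581.4, whereas
  `M_n`/`M_o` = 25,000/43.07 gives 580.4 (a 0.16% mismatch in the
  source's own numbers). `pei_rates()` therefore carries the printed
  `conc_uM` column, used verbatim; conversions computed by
  `monomeric_to_polymeric()` use the exact mass ratio.
* **Full precision vs reported rounding.** The slope-ratio solver keeps
  full precision (DP 642.09, `M_n` 257,479 g/mol from the printed
  tables) and separately reports the conventional rounded values
  (DP 642; `M_n` to the nearest 100 g/mol). Reported figures derived
  from rounded intermediates can differ from full-precision propagation
  by up to ~100 g/mol at this magnitude.
* **Eq-level convention.** `k_obs = k_on[P]0 + k_off` throughout: the
  intercept of the rate line *is* `k_off`, and the dissociation phase is
  not fitted separately.
* **Degenerate inputs.** Constant responses, all-equal concentration
  designs, missing reference channels, missing `M_n`, non-positive
  slopes, and sub-monomer DP all raise typed errors or warnings rather
  than propagating nonsense.
* **Problem sizes in the test suite.** Noiseless recovery is checked on
  a 5×5 (amplitude × rate) grid; OLS is cross-checked on 1000 random
  small designs; noisy end-to-end recovery uses duplicate 5-point
  gradients over 50 seeds; model-selection behaviour uses 40 seeds per
  scenario. These sizes give stable pass/fail behaviour at the stated
  tolerances while keeping the default test run fast.

## Known limitations

* `k_obs` from a single transient conflates any multiphasic behaviour
  into one rate; the two-phase model is descriptive, and its extra
  parameters are poorly constrained at low concentration.
* The K_D from rate ratios assumes the 1:1 reversible scheme;
  polyelectrolyte complexation can be effectively irreversible at low
  ionic strength, in which case the intercept (and hence K_D) is an
  upper bound dominated by regression uncertainty.
* Uncertainty on `M_n` is first-order and assumes slope independence.
* No global (shared-parameter) fitting across concentrations, no
  Bayesian estimation, no fitting of the dissociation phase, no
  polydispersity (`M_w/M_n`) estimation.
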