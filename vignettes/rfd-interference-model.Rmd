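---
title: "Modelling acute aerobic interference on rate of force development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling acute aerobic interference on rate of force development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfdinterfere)
```

## The model and its assumptions

Rate of force development (RFD) — the initial slope of an isometric mid-thigh
pull (IMTP) force-time curve, in N·s⁻¹ — is the performance quality most
sensitive to concurrent aerobic exercise in strength athletes. The package
models the *acute* dose-response of RFD to a single bout of aerobic exercise
of duration $d$ minutes as a delayed exponential decay:

$$\mathrm{RFD}(d) = \mathrm{RFD}_0\left[1 - \kappa\left(1 - e^{-\alpha (d - d_0)_+}\right)\right],$$

with $(x)_+ = \max(x, 0)$. The assumptions built into this form:

* duration is the sole driver of interference; modality (the model is framed
  around running), intensity, and athlete state are absorbed into the
  tunables;
* no decline occurs at or below the onset delay $d_0$;
* loss accrues fastest at short durations and saturates — the prediction can
  never fall below the floor $\mathrm{RFD}_0(1 - \kappa)$;
* the model describes the immediate post-exercise state only; recovery
  kinetics, chronic adaptation, and multi-bout accumulation are out of scope;
* the prediction is theoretical: no experimental dataset exists to fit
  $\alpha$ or $\kappa$, which is why the package exposes them as coach
  tunables rather than estimating them.

## Parameters

| parameter | units | default | role |
|-----------|-------|---------|------|
| `rfd0` | N·s⁻¹ | 15000 | baseline peak RFD; the prediction is homogeneous in it |
| `kappa` | — (in $[0,1]$) | 0.8 | maximal fractional loss; sets the floor and the $100\kappa\%$ asymptote |
| `alpha` | min⁻¹ | 0.3 | steepness of onset; at the default, $\sim73\%$ of the maximal loss region is reached by $d = 10$ |
| `d0` | min | 2 | onset delay; the positive-part operator keeps $d \le d_0$ at baseline exactly |
| `d_max` | min | 60 | supported duration domain; beyond it the closed form is still evaluated, with an extrapolation warning |

Parameters are validated once, at construction (`interference_model()`), with
errors naming the offending field; every downstream operation assumes a valid
model and is a pure function. Percent loss,
$100\,\kappa(1 - e^{-\alpha(d-d_0)_+})$, is independent of `rfd0`, so the same
percent column serves any athlete.

```{r}
m <- interference_model()
predict_table(c(0, 2, 5, 10, 20, 30, 60), m)
```

Display rounding follows the field's reporting convention — predicted RFD to
the nearest N·s⁻¹, percent loss to the nearest percent, athlete examples to
one decimal — while full double precision is always retained in the unrounded
columns.

## The linear comparison variant

A linear decline is the natural null against which to judge the exponential
shape, but only its qualitative form is given in the source material. The
package anchors the line at the same endpoints as the nonlinear model —
$(d_0, \mathrm{RFD}_0)$ and $(d_{max}, \mathrm{RFD}_0(1-\kappa))$ — and clamps
it constant outside that interval. Sharing the endpoints makes the comparison
interpretable: the exponential lies on or below its chord everywhere on
$(d_0, d_{max})$, with equality only at the anchors (the exponential is a hair
above the floor at $d_{max}$ itself: about 15 N·s⁻¹ in 15000 at the defaults,
i.e. within 1% of baseline scale).

## Sensitivity sweeps

`sweep_alpha()` and `sweep_kappa()` vary exactly one parameter over a grid and
re-run the tabular prediction per value; each row of the resulting matrix is
bit-identical to the corresponding direct `predict_table()` call (this is
enforced by test). The default grids, $\alpha \in \{0.05, 0.1, 0.2, 0.3,
0.5\}$ and $\kappa \in \{0.2, 0.4, 0.6, 0.8, 1.0\}$, bracket the selected
defaults (0.3, 0.8); the exact grids plotted in the source figures are not
published, so these are representative rather than replicas. Joint
$\alpha \times \kappa$ grids can be assembled by calling one sweep per value
of the other parameter; a single-parameter sweep is the default because the
coach-facing long-format output stays readable. At any fixed $d > d_0$,
predicted RFD is non-increasing in both $\alpha$ and $\kappa$.

## Simulated force-time curves

The interference model acts on a scalar (RFD); to visualise what that means
for an IMTP trace, `generate_curve()` synthesises a force-time curve whose
initial slope is exactly the predicted RFD. The functional form is the
simplest saturating curve with that property, a mono-exponential rise

$$F(t) = F_{peak}\left(1 - e^{-(\mathrm{RFD}/F_{peak})\,t}\right),$$

whose derivative at $t = 0$ is RFD by construction. Design choices:

* **Shared plateau.** The model scales only the slope, so all curves in a
  family (`curve_family()`) share `peak_force`; whether real post-exercise
  pulls would also lose peak force is unknowable from the source material, and
  the default assumes they do not. `peak_force` is an explicit parameter for
  exploration.
* **Sampling.** Default 1 ms grid (1000 Hz, a typical force-plate rate) over a
  5 s pull. Defaults are plumbing, not science: `curve_params()` exposes them
  all.
* **Noise.** Optional additive zero-mean Gaussian force noise with an explicit
  seed, drawn under a locally scoped RNG state so simulation never disturbs
  the caller's random stream. Identical seed and parameters give bit-identical
  curves. This is a minimal stand-in for force-plate noise; it does not
  emulate drift, quantisation, or onset-detection artefacts, so passing
  round-trip tests says nothing about processing real plate data.

`estimate_rfd_from_curve()` closes the loop: the least-squares slope of force
against time over an initial window $[0, w]$. A two-point difference would be
exact on the noiseless curve but fragile under noise; least squares over a
window trades a small, predictable curvature bias — approximately
$(\mathrm{RFD}/F_{peak})\,w/2$ as a fraction of RFD — for noise averaging. The
default $w = 0.02$ s keeps that bias at a few percent (3.75% at the default
baseline RFD and plateau) while spanning 21 samples at 1000 Hz.

Numerical characterisation of the estimator, as exercised by the tests:

* noiseless, $w = 0.005$ s: recovery within 2% for RFD from 1000 to
  20000 N·s⁻¹ (bias at the top of the range ≈ 1.25%);
* noiseless, $w = 0.01$ s at RFD 15000: error ≈ −1.9%;
* noisy (SD 20 N), $w = 0.02$ s at RFD 10000, sampled at $10^{-5}$ s over
  0.05 s: recovery within 5%. The sampling for this check was chosen from the
  bias/variance budget above — curvature bias ≈ 2.5% plus a slope-noise SD
  ≈ 0.75% — so the 5% bound holds with wide margin across seeds.

## Configuration and the command line

The artifact is a coach-facing tool, so a thin CLI wraps the package:
subcommands `predict`, `table`, `sweep-alpha`, `sweep-kappa`, `curves`,
`compare`, dispatched by `rfd_cli()` and shipped as the script
`inst/cli/rfdpredict.R`. The interface layer contains no numeric logic — tests
compare its output byte-for-byte against direct core calls — and logs to
standard error so piped CSV stays clean. Parameter precedence is defaults <
config file < flags. The config format is the flat `key = value` scalar
subset of TOML, read by a small in-package parser (parse errors carry line
numbers; unknown keys warn and are ignored). CSV output prints numerics at 17
significant digits so a re-parse reproduces the source exactly; JSON mirrors
the column names.

Two athlete baselines are packaged (`athlete_profiles()`): group-average IMTP
RFD of 16652 N·s⁻¹ (male national-caliber weightlifters) and 7663 N·s⁻¹
(female national-caliber weightlifters), usable via `--profile`.

## Numerical notes and edge cases

* All arithmetic is IEEE double; the closed form needs no special handling
  except the positive-part operator, implemented with `pmax()` so $d = d_0$
  lands exactly on baseline.
* For large $\alpha (d - d_0)$ the exponential underflows and consecutive
  predictions tie at the floor in double precision; strict-monotonicity
  properties therefore apply only while the exponential term is resolvable.
* Durations beyond `d_max` warn (extrapolation) rather than error: the closed
  form remains well-defined, and 60 minutes is the simulated range, not a
  mathematical bound. Negative durations are rejected.
* Empty duration or sweep grids are errors, and per-element domain errors name
  the offending value.

## Known limitations

The model is unvalidated by design: its outputs are hypotheses about
interference, not measurements. It ignores aerobic intensity and modality,
individual variation beyond what $\alpha$ and $\kappa$ absorb, recovery after
the bout, and chronic training effects. The simulated curves are a
visualisation device — real IMTP traces have onset ambiguity, noise structure,
and peak-force variability that the mono-exponential ignores. Test problem
sizes (duration grids of at most a few hundred points, curves of at most a few
thousand samples) were chosen because the closed-form model needs nothing
larger; every published quantity the package reproduces is recomputed by the
test suite or the acceptance script at run time.
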