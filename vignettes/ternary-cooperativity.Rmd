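---
title: "Modeling talin-kindlin cooperativity at integrin beta-tails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling talin-kindlin cooperativity at integrin beta-tails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternabind)
```

## The problem

Integrin activation requires two FERM-domain adaptor proteins — talin and
kindlin — to bind the short cytoplasmic tail of the beta-integrin subunit
(the "beta-CT") at juxtaposed motifs: talin's F3 domain engages the
membrane-proximal NPxY motif, kindlin the membrane-distal NxxY motif. The
central quantitative question is how the two adaptors influence each other
on the same tail: do they bind independently, compete, or reinforce one
another? `ternabind` implements the machinery to answer that question from
equilibrium measurements: coupled mass-action models of the ternary
complex, a thermodynamic-cycle consistency statistic on measured
dissociation constants, the curve-fitting protocols used by equilibrium
titration and displacement assays, the standard NMR titration observables,
and forward generators that simulate all of these measurements with known
ground truth. Concentrations and constants are in micromolar throughout.

## The energy square and the cycle statistic

The simplest description of ternary complex formation is a four-state
cycle: free tail `I`, talin-bound `TI`, kindlin-bound `KI`, and ternary
`TIK`. Each edge carries a step dissociation constant — `Kd_T` and `Kd_K`
for the free tail, and the starred constants `Kd_T*`, `Kd_K*` for the tail
pre-occupied by the other adaptor. Microscopic reversibility demands that
the product of association and dissociation constants around the closed
cycle equals one; in dissociation-constant form

$$Q \;=\; \frac{K_{d,T}^{*} \; K_{d,K}}{K_{d,T} \; K_{d,K}^{*}} \;=\; 1 .$$

`cycle_product()` evaluates `Q` for a set of four measured constants and
propagates uncertainty to first order by adding relative errors in
quadrature,

$$\sigma_Q = Q \sqrt{\textstyle\sum_i (s_i / v_i)^2},$$

which reproduces the printed plus/minus values of all four published
evaluations bundled with the package (`reference_constants("squares")`).
The propagation rule is a package choice — the original reports do not
state one — and `cycle_product_mc()` provides a Monte Carlo cross-check.
One caveat is documented rather than hidden: when a constant in the
denominator carries a ~50% relative error, the ratio distribution is
heavy-tailed and a plain Monte Carlo standard deviation diverges; the
robust spread (half the central 68.3% interquantile width) is the
meaningful comparison there, and first-order quadrature tracks it to
roughly 15–20% on such squares and to ~1% on well-determined ones.

`consistency_verdict()` converts `(Q, sigma_Q)` into a decision with
`z = |Q - 1| / sigma_Q` and a threshold of `z = 2` by default — chosen to
formalize the informal "approximately one" versus "clearly not one"
dichotomy at roughly the 5% level, and configurable. At 10% relative
measurement noise on all four constants the type-I error of this verdict
is about 0.05 (calibrated in the test suite over 10,000 simulated
squares). `classify_pair()` applies the analogous two-sample z statistic
on `log(Kd)` to one edge at a time, labeling it `independent`,
`competitive` (`Kd < Kd*`) or `reinforced` (`Kd > Kd*`).

```{r}
sq <- reference_constants("squares")[[1]] # wild-type adaptors, beta3 tail
consistency_verdict(sq)
```

## Equilibrium networks and the solver

Networks are defined by monomer totals, optional two-state conformer
groups, and complexes parameterized by *overall* formation constants from
the free components (`eq_network()`). This parameterization is
deliberate: because every complex is anchored to the free species, the
product of derived step constants around any cycle equals one *by
construction*, so thermodynamic inconsistency cannot be introduced
silently — `derived_step_kds()` is a read-only view. Formation constants
are stored on a log scale.

`solve_equilibrium()` finds the free concentrations by damped root-finding
on the log free concentrations of the monomer conservation equations:
a Levenberg–Marquardt iteration (analytic Jacobian, iteration budget 200)
started from three free-fraction guesses (0.5, 0.99, 1e-6 of each total),
followed by a plain Newton polish to a relative conservation tolerance of
1e-11. Working in log space keeps concentrations positive and handles
formation constants spanning many orders of magnitude; failure to reach
tolerance is a loud error that reports the worst residual, never a silent
approximation. The solver is deterministic. Monomers with zero totals and
the complexes containing them are eliminated exactly.

## Operational apparent affinities

Near-saturation competition experiments report an *apparent* constant: a
one-site isotherm fitted to a titration performed with a competitor held
at a fixed total. `apparent_kd()` mirrors that operational definition: it
simulates the occupancy titration (16-point two-fold dilution grid by
default, labeled species at 0.1 uM — trace level relative to
micromolar-scale constants), then fits against the **total** titrant
concentration, because that is the axis an experiment knows. The default
competitor total is four times its pooled binary constant, emulating the
3–6-fold-over-Kd excess used in such experiments; both are configurable.

## Why the asymmetric competition needs the direct contact

Measured apparent constants show a striking asymmetry: talin at
near-saturation weakens kindlin binding several-fold, while kindlin at
near-saturation leaves talin binding essentially unchanged. A useful
negative result constrains the model space: for *any* mass-action network
in which the two adaptors do not bind each other — including any two-state
tail — detailed balance over the pooled tail species forces
`Kd_T*/Kd_T = Kd_K*/Kd_K` exactly, so at matched relative competitor
saturations the two fold-changes must be equal (the test suite checks this
numerically). Pure tail allostery therefore cannot produce the pattern.

Two ingredients together can. First, a direct talin–kindlin contact: the
`TK` complex in solution sequesters the titrant, and because the fitted
axis is the *total* titrant concentration, the sequestration inflates the
apparent constant by a factor that grows with the *absolute* concentration
of the fixed partner. Talin is used at several hundred micromolar while
kindlin is used around 36 uM, so the inflation acts almost entirely on the
kindlin measurement. Second, the same contact stabilizes the ternary
complex (`chi > 1`), which offsets the underlying allosteric competition
on the talin side. `two_state_tail()` therefore accepts optional contact
parameters (`kd_TK`, `chi`), and `asymmetry_reference_model()` freezes one
parameterization, found by a coarse search and then fixed: inactive/active
tail constants of 110/2 uM for talin and 9/90 uM for kindlin, `L = 0.001`,
per-conformer coupling 10/1, `kd_TK = 50` uM, `chi = 16`, with talin
saturation at 400 uM and kindlin at 36 uM. Under the operational protocol
this gives apparent kindlin constants of 9.06 → 53.2 uM (5.9-fold) and
apparent talin constants of 104.4 → 98.5 uM (−6%). The contact affinity,
the coupling factors and the conformer constants are model-family
parameters: the experiments constrain the qualitative pattern, not their
individual values, and the package does not claim fitted values for them.

```{r}
p <- asymmetry_reference_params()
net <- asymmetry_reference_model()
c(kindlin_free = apparent_kd(net, titrant = "K")$value,
  kindlin_sat = apparent_kd(net, titrant = "K", competitor = "T",
                            competitor_total = p$talin_saturation)$value)
```

## Curve fitting

All fits are unweighted least squares via Levenberg–Marquardt with the
dissociation constant log-parameterized and bounded to `[1e-4, 1e5]` uM; a
constant pinned at a bound, an unresolved amplitude, or a failed optimizer
flags the fit as not converged — flags are never silently dropped.

* `fit_one_site()` fits `R(c) = R0 + A c/(c + Kd)`; with `depletion = TRUE`
  it uses the exact two-total quadratic bound fraction instead of the
  hyperbola. Depletion is off by default because the labeled species is
  held at or below 0.2 uM against micromolar constants; the test suite
  shows the plain hyperbola is several-fold biased once the labeled total
  reaches ten times the constant, and the quadratic corrects it.
* `fit_global()` shares one constant across replicate curves with
  per-curve baselines and (possibly opposite-signed) amplitudes.
* `fit_two_site_signed()` handles fusion-construct titrations whose two
  sites pull the normalized response in opposite directions. The
  `"simultaneous"` mode fits the full signed two-component sum and is
  exact to ~1e-6 on clean data. The `"piecewise"` mode reproduces the
  split-fit protocol (points up to 5 uM as one positive site, optionally
  clamping the plateau to a reference fit; points above 5 uM as one
  negative site): it is simple but *systematically biased*, because each
  segment absorbs the other component's unsaturated tail. On the noiseless
  (2.9, 25) uM reference curve the split protocol returns (2.09, 49.4) uM
  with a free high-segment baseline and (4.47, 9.70) uM with the clamped
  plateau; these values are frozen as regression tests so the bias is
  quantified, not hidden. Use the simultaneous mode for inference.
* `fit_dose_response()` fits the four-parameter logistic with top and
  bottom asymptotes frozen to the control values carried by the curve
  object, log-parameterized IC50, and a Hill slope free by default
  (fixable at 1) — the assays specify only "a dose–response curve", so the
  slope is left to the data. A curve that never descends 10% of the span
  below the top asymptote is refused.

## NMR titration observables

`csp()` is the weighted-average amide shift change
`sqrt(dH^2 + dN^2/6)`. `csp_profile()` flags residues whose CSP exceeds
`2 sigma`, where `sigma` is the root-mean-square CSP of the unperturbed
population estimated by iteratively excluding residues above `3 sigma`
until the included set is stable. The RMS-about-zero estimator is chosen
deliberately: CSPs are non-negative magnitudes, so under Gaussian shift
noise the RMS recovers the underlying per-dimension scale and the 2-sigma
cut flags ~4.6% of unperturbed residues (P < 0.05), whereas iterating the
exclusion at the significance threshold itself contracts the estimate
toward zero on perfectly well-behaved data. A single-pass estimate is
available with `sigma_method = "single"`. The published 0.018 ppm
threshold derives from unreleased peak lists and is a workflow target, not
a number this package can recompute.

`intensity_ratio_profile()` and `region_mean()` quantify line broadening
as titrated/reference intensity ratios (computed on peak heights) with
averages over annotated regions such as the alpha-helical segment
H758–K770 or the two binding-site motifs — author residue numbering is
used verbatim everywhere. `secondary_shift_profile()` computes
`(dCa - dCa_rc) - (dCb - dCb_rc)` against a packaged standard random-coil
carbon reference; `propensity()` maps the value linearly to a population
(`6 ppm` = fully formed helix, `-6 ppm` = fully formed strand, clamped).
Glycine, which has no C-beta, contributes its C-alpha deviation alone.
Peak matching uses assignment labels when present and nearest-neighbor
matching within tolerances of 0.05 ppm (1H) / 0.5 ppm (15N, 13C)
otherwise; ambiguous and unmatched peaks are reported, never dropped.

## Synthetic data: what it does and does not emulate

Each generator is a measurable forward model with an explicit seed, and
returns a `ground_truth_record` from which `regenerate()` reproduces the
dataset bit-identically. `gen_titration()` adds Gaussian noise to signed
sums of bound-class fractions (emulating normalized thermophoresis
responses with opposing trends); `gen_dose_response()` offers Gaussian or
lognormal noise (flow-cytometry intensities are positive and
right-skewed); `gen_square_measurements()` perturbs exactly-consistent
derived step constants by truncated multiplicative noise;
`gen_peak_tables()` produces fast-exchange peak tables in which annotated
site regions shift in proportion to occupancy (1H:15N split fixed at 1:5)
and are attenuated in proportion to the mass-weighted complex fraction,
with an optional extra ternary-specific broadening term.

The generators emulate the *statistical* structure of the measurements,
not the physics: no thermophoresis optics, no bell-shaped anomalous
traces, no intermediate-exchange line shapes, no membrane or lipid
energetics. Tests passing on synthetic data therefore demonstrate that the
estimators invert their own forward models at realistic noise levels — not
that any particular laboratory curve is free of the artifacts those
models exclude.

## Problem sizes and numerical choices in the test suite

The property sweeps use 1,000 random networks for mass-balance checks
(relative tolerance 1e-9), 500 triplicate titrations for recovery/coverage
(3% noise; median relative error < 5%, CI coverage 0.90–0.98), 10,000
simulated squares for the verdict calibration (type-I in [0.02, 0.08]),
and nested-bisection/closed-form oracles for solver equivalence at 1e-6 —
all chosen to run comfortably on a single CPU in a few minutes. Fits use
`ftol = ptol = 1e-15` so that noiseless round-trips are limited by machine
precision rather than optimizer stopping rules.

## Known limitations

Kinetics (on/off rates) are out of scope, as are membrane and nanodisc
surface effects, structural modeling, and Bayesian treatment of Kd
uncertainty. The first-order `sigma_Q` understates the spread for
constants with relative errors approaching 50% (use the Monte Carlo
robust spread there). The two-state-plus-contact reference model is one
member of a family consistent with the asymmetric pattern; its individual
parameters should not be read as measured quantities.
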