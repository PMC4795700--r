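---
title: "G protein regulation as balance/imbalance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G protein regulation as balance/imbalance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gefcycle)
```

## The model

A G protein `G` binds GDP or GTP in a conserved pocket; the GDP form is
inactive, the GTP form active. A guanine nucleotide exchange factor `E`
catalyses nucleotide exchange through a chain of enzyme complexes

```
E + G_GDP <-> E.G_GDP <-> E.G <-> E.G_GTP <-> E + G_GTP
```

Every step is an elementary, *reversible* reaction: `k1`, `k5` are the
bimolecular association rates of free GEF with GDP- and GTP-bound G protein,
`k2`, `k6` the corresponding dissociations, `k3`, `k7` nucleotide release
from the binary complexes, and `k4`, `k8` nucleotide rebinding (bimolecular
in the buffered pools `[GDP]`, `[GTP]`). The law of mass action gives six
coupled ODEs (species `e`, `e_gdp`, `e_gtp`, `e_g`, `g_gdp`, `g_gtp`) with
two exact conservation laws: total GEF `e0` and total G protein `g0`.
Inactivation enters as a GTPase flux `f` on free `g_gtp` only (the displayed
equations hydrolyse nothing on GEF-bound G protein, and we follow them):
`f = 0`, `f = kase*g_gtp` (intrinsic) or `f = kase*g_gtp*f0/(km + g_gtp)`
(GAP-mediated). Hydrolysed mass reappears as `g_gdp`.

Units are µM and seconds throughout; bimolecular rates in /µM/s. The
nucleotide pools are constant parameters, not species — cellular nucleotide
concentrations are buffered far above the protein concentrations considered
here.

## The quasi-steady-state reduction

Holding the free substrate concentrations fixed, the four enzyme species form
a linear cycle whose steady state is given by the King–Altman (directed
spanning tree) construction: for each complex-graph vertex `i`, the weight
`rho_i` is the sum over directed spanning trees rooted at `i` of the product
of edge labels, and occupancies are `X_i = e0 * rho_i / sum(rho)`. The
package enumerates the trees by brute force over the `choose(8,3) = 56`
three-edge subsets — the graph is tiny, and the enumeration doubles as a
transparent oracle target (the weighted counts are cross-checked against the
matrix–tree determinant `det(L[-r,-r])` in the tests). Each tree uses at most
one outgoing edge of `E`, and only those edges carry a free G protein
concentration, so every `rho_i` is *linear* in `[G_GDP]` and `[G_GTP]`:
collecting coefficients yields the summary constants `K0` (trees rooted at
`E`), `K1`, `K2` (denominator), and `K1d..K2g` (the three complex-occupancy
numerators). Substituting the occupancies into the `g_gtp` equation collapses
the dynamics to a single ODE,

```
d[G_GTP]/dt = kfwd ([G_GDP] - kappa [G_GTP]) e0 / (K0 + K1 [G_GDP] + K2 [G_GTP]) - f
```

with `kfwd = k1 k3 k8 [GTP] k6` (the forward-rate product, GTP pool
absorbed) and `kappa = (k2 k4 k5 k7)/(k1 k3 k6 k8) * [GDP]/[GTP]`. Two
identities tie the symbolic reduction to the tree algebra and are asserted in
the tests: `k6*K1t = kfwd` and `k5*K0 - k6*K2t = kfwd*kappa`. With `f = 0`
and `[G_GTP] = 0` the equation is the Michaelis–Menten form — the reduction
is the exact generalisation of that derivation to a reversible two-substrate
exchanger. It neglects mass held in complexes, so it approximates the full
model only when `e0 << g0`; the tests measure the error at `e0/g0` of 0.1,
0.01, 0.001 (0.09, 0.008, 0.0008 for the default fixture) and check that it
shrinks monotonically.

## Steady-state results

* **Balance.** Without GTPase activity the reversible cycle must reach
  detailed balance: `[G_GDP]/[G_GTP] = kappa` regardless of `e0`, `g0` or
  initial conditions, so the active fraction can never exceed
  `1/(kappa + 1)`.
* **GEFs are inhibitory on their own.** Closing the reduced equilibrium with
  G protein conservation *including* the complex occupancies gives
  `(kappa+1) x^2 + 2 b x - Ks g0 = 0`, `b = (e0 - g0 + (kappa+1) Ks)/2`,
  `Ks = K0/(K1 kappa + K2)`; the positive root (evaluated in the
  cancellation-free form) is the free active concentration, and
  `d[G_GTP]/db = (b/sqrt(b^2 + (kappa+1) Ks g0) - 1)/(kappa+1) < 0` proves it
  strictly decreases in `e0`: surplus GEF sequesters G protein into
  complexes. A subtlety worth recording: at detailed balance the complex
  occupancies equal their clamped-substrate steady-state values *exactly*, so
  this quadratic is exact for the full model, not only in the `e0 << g0`
  regime — the numerical oracle comparisons agree to machine precision.
* **Imbalance restores control.** With intrinsic hydrolysis, balancing the
  reduced exchange flux against `kase*[G_GTP]` under `g0 = [G_GDP]+[G_GTP]`
  gives `(K2-K1) x^2 + 2 bhat x - kappa_hat g0 e0 = 0`,
  `bhat = (K0 + K1 g0 + (kappa+1) kappa_hat e0)/2`, `kappa_hat = kfwd/kase`.
  The admissible root lies in `[0, g0/(kappa+1)]`, rises monotonically and
  sigmoidally in `kappa_hat*e0`, and approaches the ceiling as
  `kappa_hat*e0 -> Inf`. The main text's display of the intermediate
  substitution step contains an obvious transcription artifact (a stray
  symbol `y`); we re-derived the quadratic from the reduced model and
  recovered the final displayed form exactly, with the numerical steady-state
  oracle as arbiter. The GAP-mediated steady state has no closed form and is
  provided numerically only.

## Numerical choices

* **Integration.** No ODE-solver package is available in the deployment
  environment, so the package carries a compiled Dormand–Prince 5(4) stepper
  (default; rtol 1e-9, atol 1e-12) and an L-stable Rosenbrock 2(3) stepper
  with analytic Jacobians (`method = "ros23"`). Log-uniform rate draws
  spanning four decades produce stiffness ratios up to ~1e6 where the
  explicit method is stability-limited; the Rosenbrock method is used for
  steady-state relaxation and recommended for random-parameter trajectory
  studies.
* **Steady states.** `numeric_steady_state()` relaxes the full model briefly,
  then polishes on the conservation-reduced 4-unknown system: plain
  non-monotone Newton first (intermediate iterates may leave the physical
  region; the endpoint must be physical and converged), bounded
  pseudo-transient continuation as fallback. Convergence is declared on
  either the flux residual (`<= 1e-10 * max(e0, g0)` per second) or the
  Newton-step norm in concentration units — the flux criterion alone is
  unusable at both kinetic extremes (slow kinetics: small flux, large
  concentration error; fast kinetics: large flux noise floor at a fully
  converged state). Conservation holds exactly by construction of the
  reduced unknowns.
* **Quadratic roots** use the `q = c/(b + sqrt(b^2 + a c))` form to avoid
  cancellation when `b` dominates, and cover the degenerate linear case
  `K2 = K1` continuously.
* **Protocol discontinuities.** The integrator restarts at each segment
  boundary, so GEF-level switches are handled exactly. During washout
  ("free GEF removed until `e0` reaches its basal value") free enzyme is the
  only quantity removed: `e = max(0, e0_target - bound)`. This is the only
  reading that keeps total enzyme continuous and monotonically approaching
  the target — complexes are not deleted, they drain by dissociation.
* **Classification deadband.** Stimulation responses are classified on the
  change in free `g_gtp` over the stimulated window with a deadband of
  `1e-6 * g0` (robust to integrator noise); for random-parameter studies the
  deadband scales with the achievable dynamic range `g0/(kappa+1)`, since
  systems with extreme `kappa` operate entirely within a sliver of `g0`.

## The synthetic parameter world

The study that motivated this package used measured rate constants for the
Ran:RCC1:RanGAP1 system, but published them only in a supplementary table
that is not available to us. The package therefore states its own world
twice over:

* `gef_fixture()` is a **synthetic stand-in** (named so in code and files):
  association at 10 /µM/s, dissociations at 20 /s, nucleotide release at
  5–20 /s, rebinding at 1 /µM/s, pools `[GDP] = 50`, `[GTP] = 500` µM,
  `g0 = 10` µM, basal `e0 = 0.1` µM — magnitudes typical of fast
  small-GTPase exchange enzymology, with `kappa = 0.4` (ceiling 0.71) and
  basal enzyme load `e0/g0 = 0.01`. The intrinsic rate `kase = 0.1` /s was
  chosen once so that the basal system sits on the rising limb of the
  dose–response curve (basal activation 0.20, stimulated 0.57, against the
  0.71 ceiling); the GAP variant (`kcat = 5` /s, `Km = 1` µM, `f0 = 0.5` µM)
  mirrors sub-µM-Km GAPs.
* `sample_params()` draws the eight rates log-uniformly over 1e-2..1e2 and
  pools over 10..1000 µM, seeded, with `e0 = 0.1` and `g0 >= 100*e0`. Drawn
  `kappa` values span many orders of magnitude, which is precisely why the
  qualitative stimulation suite fixes the GTPase strength in the responsive
  region (basal activation at 30% of the ceiling, by root-solving) and runs
  each system in its own time units (windows of `12/kase`): the claim "GEF
  steps activate only in the presence of GTPase activity" is a statement
  about responsive systems observed at steady state, and is genuinely false
  for ceiling-pinned or hydrolysis-saturated parameter draws observed over
  arbitrary windows.

What a green test therefore establishes: the algebraic structure (detailed
balance, ceilings, monotonicity, reduction error scaling) for *any* valid
parameter set; and the qualitative stimulation phenomenology for the
documented synthetic regime. What it does not establish: quantitative
agreement with any measured G protein system, time courses outside the
responsive regime, spatial or stochastic effects, ternary GEF·G·GAP
complexes, or hydrolysis on GEF-bound G protein.

## Known limitations

* The irreversible variant (`k7 = 0`) makes `kappa = 0`; the detailed-balance
  invariant is reported "not applicable" rather than checked.
* `numeric_steady_state()` targets this six-species network; it is not a
  general steady-state solver.
* The spanning-tree engine is generic over small labelled digraphs but only
  the GEF cycle graph is part of the public contract.
* CSV/JSON outputs are deterministic by design (no timestamps), which makes
  reproducibility checks bytewise but means runs are distinguished only by
  their recorded config and seed.
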