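---
title: "Predicting metabolic rate structure from maximum entropy production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metabolic rate structure from maximum entropy production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroflux)
```

## The model

A metabolic network constrains every substrate molecule to travel along one
of a finite set of *elementary flux modes* (EFMs): support-minimal flux
vectors `v` with `S_int v = 0` and nonnegative flux through irreversible
reactions. Each glucose-normalized mode `j` is a balanced overall reaction
(per mole of glucose consumed) over external metabolites only, so its
reaction entropy, enthalpy and Gibbs energy follow from condition-adjusted
formation properties:

\[
\Delta s_j = \sum_i \nu_{i,j}\, s_i,\qquad
\Delta g_j = \sum_i \nu_{i,j}\, g_i,\qquad
\Delta h_j = \sum_i \nu_{i,j}\, h_i,
\]

with \(s_i = (h_i - g_i)/T\), so \(\Delta g_j = \Delta h_j - T\Delta s_j\)
holds by construction.

A culture in balanced exponential growth is treated as a steady-state CSTR
with dilution rate equal to the specific growth rate. The entropy and Gibbs
balances of that reactor give two entropy production rates: *type 1*, based
on the reaction affinity \(A_j = -\Delta g_j\) (it includes the enthalpic
heat exported to the surroundings), and *type 2*, based on reaction entropy
alone. Maximizing the production rate subject to a fixed macroscopic rate
and normalization yields a Boltzmann-type distribution over modes,

\[
p_j \;=\; \frac{1}{Z}\exp\!\Big({-\frac{\hat\xi\, \Delta s_j}{b\, Q R}}\Big),
\qquad Z = \sum_j \exp\!\Big({-\frac{\hat\xi\, \Delta s_j}{b\, Q R}}\Big),
\qquad c = -\ln Z,
\]

where \(\hat\xi\) is the specific glucose uptake rate in mol/(h·gCDW),
\(Q = 1\) per (h·gCDW) keeps the exponent dimensionless, \(R\) is the gas
constant in J/(K·mol), and \(b \in (0, 1]\) is the fraction of the
evolutionarily attainable maximum uptake rate the strain has realized. The
affinity (type 1) variant replaces \(\Delta s_j\) with \(A_j/T\). Plotting
\(\ln p_j\) against \(\hat\xi \Delta s_j / b\) gives a line of slope
\(-1/R\) for every strain simultaneously, which is what makes \(b\) a
unifying parameter.

`b` is fitted from one measured scalar: the overall reaction entropy
\(\Delta S_R\) of the growth equation, computed from the measured external
exchange stoichiometry. Because the expectation
\(\sum_j p_j(b)\,\Delta s_j\) is strictly increasing in \(b\) — from
\(\min_j \Delta s_j\) at \(b \to 0\) to the unweighted mode average at
\(b \to \infty\) — the root is unique whenever the measurement lies inside
that open interval. From the fitted distribution follow the overall
stoichiometry \(\nu_i = \sum_j \nu_{i,j} p_j\), the external rates
\(r_i = \hat\xi\,\nu_i\), the internal rates
\(r_k = \hat\xi \sum_j p_j v_{k,j}\) (which remain in the nullspace of
`S_int`), and the maxima \(\mu_{max} = \mu/b\), \(q_{s,max} = q_s/b\),
\(\tau_{min} = \ln 2/\mu_{max}\).

## Assumptions

* The culture is at a balanced steady state; the semicontinuous
  serial-transfer regime is approximated as a CSTR with dilution rate
  \(\mu\).
* The network's mode structure is assumed fully evolved, so only the
  scalar `b` separates the observed state from the attainable maximum.
* Every enumerated mode is included in the partition function except
  zero-glucose (futile) modes, which cannot carry a share of glucose
  uptake and are segregated by `normalize_to_glucose()`.
* pH is constant at 7, where the transformed formation properties of the
  proton are zero, so the charge-closing proton term of each mode does not
  change its reaction thermodynamics (the proton flux itself is still
  reported as a prediction).
* Mg²⁺ binding is not modeled.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `T` | K | 310.15 | culture temperature (37 °C) |
| `pH` | — | 7 | buffered minimal medium |
| `ionic_strength` | mol/L | 0.25 | typical M9-like medium; enters the extended Debye–Hückel term \(RT\,\alpha(T)(z^2-n_H)\sqrt I/(1+1.6\sqrt I)\) |
| `Q` | 1/(h·gCDW) | 1 | dimensional bookkeeping constant separated from the Lagrange multiplier; \(\hat\xi\) must be in mol (not mmol) before the exponent |
| `R` | J/(K·mol) | 8.314 | gas constant; rescaling the entropy units and `R` together leaves `p` unchanged |
| `b_range` | — | \([10^{-4}, 10^4]\) | bracket for the scalar solve on \(\ln b\), tolerance 1e-12 |
| glucose feed | g/L | 2 | 11.1 mM feed; the worked "medium conversion" point consumes half |
| `gas_flow` | L/h | 0.9 | 1 vvm aeration for the 15 mL culture volume; drives the water gas/liquid split |

Sign conventions: reactant coefficients are negative, glucose is exactly
−1 in every normalized mode, `qs` is stored as a positive magnitude, and
reported maximum uptake rates carry explicit sign metadata (the uptake
convention prints them negative).

## What the synthetic generators emulate — and what they do not

`synthetic_thermo()` emulates the qualitative thermodynamic structure of a
real aerobic network: every mode spontaneous (\(\Delta g_j < 0\)),
exothermic (\(\Delta h_j < 0\)), with positive reaction entropy and a
strong positive correlation between affinity and entropy (enthalpy model
\(\Delta h_j = -a\,T\,\Delta s_j(1+\varepsilon)\), default \(a = 4\),
\(\varepsilon \sim N(0, 0.05)\)). Reaction entropies are drawn uniformly
from 1000–3000 J/(K·mol glucose); at the measured uptake rates
(\(\hat\xi \approx 0.012\)) and \(b \approx 0.4\) this reproduces the
realistic magnitudes of the exponent and of \(c = -\ln Z\).

`synthetic_system()` additionally builds consistent external
stoichiometries: glucose −1, a biomass-like product (molar mass 24.2 g/mol,
matching CH₁.₆N₀.₂₆O₀.₃₈P₀.₀₂₃S₀.₀₀₆), two minor byproducts, and two
volatile entropy-carrying products (CO₂- and water-like) that share the
residual reaction entropy. Spreading the entropy over two large product
coefficients mirrors a real growth equation, where measurement noise on
individual exchange coefficients partially averages out in \(\Delta S_R\);
with a single carrier the noise would transfer one-to-one and the fit error
would be overstated.

What passing tests on these fixtures do **not** show: that the curated
species table is complete or accurate for any particular organism, that a
genome-scale network can be enumerated (the tableau algorithm is desk-scale,
up to ~10⁴ modes), or that measured ¹³C-flux data will be reproduced — the
generators have no measurement model beyond multiplicative Gaussian
stoichiometric noise.

## Numerical choices

* **Doubles, not exact rationals.** Stoichiometric coefficients are stored
  as doubles; elementarity and steady-state tests use a 1e-9 tolerance. At
  the scale this package targets (small decimal coefficients, ≤ 10⁴
  modes) double arithmetic is exact or far below tolerance, and the
  enumeration is verified against a brute-force support-subset oracle on
  every fixture network.
* **Mode enumeration.** Reversible reactions are split into nonnegative
  forward/backward halves; the classical tableau imposes one metabolite
  constraint at a time, combining positive/negative ray pairs and pruning
  rays whose support strictly contains another ray's support. Trivial
  fwd+bwd two-cycles are removed, halves are recombined to signed net
  fluxes, and sign-reversal duplicates (possible only on fully reversible
  support) keep the representative whose first nonzero flux is positive.
  Output order is lexicographic by reaction support; each mode is scaled to
  max-|flux| 1 before glucose normalization, so runs are reproducible.
* **Log-sum-exp everywhere.** Both the mode distribution and the
  pseudoisomer weights are computed with max-shift stabilization;
  normalization holds to 1e-10 over at least six decades of
  \(\hat\xi/b\). At extreme exponents individual probabilities can
  underflow to exactly zero in double precision; the normalization is
  unaffected.
* **Root solve with LM cross-check.** The primary fit is a bracketed
  `uniroot` on \(\ln b\) (unique root by monotonicity). The n+2-unknown
  least-squares formulation, reduced to \((\ln b, c)\), is retained via
  `minpack.lm::nls.lm` and agrees to better than 1e-6 relative in `b`.
* **Degenerate inputs.** A measured \(\Delta S_R\) at or below the
  attainable minimum raises an infeasibility error naming the bound; a
  value at or above the uniform mean reports "at the uniform limit".
  Zero-glucose modes are segregated, never silently dropped. Outlet
  concentrations slightly below zero are floored with a warning; larger
  violations are an infeasible operating point.
* **Pseudoisomer enthalpies** use simple \(p_i\)-weighting (not a
  van't-Hoff-consistent derivative weighting); the ionic-strength enthalpy
  correction is the Gibbs–Helmholtz transform of the same \(\alpha(T)\)
  polynomial used for the Gibbs term, so the Gibbs relation stays exact.
* **Water** is treated as a reactant at 55.34 mol/L with an optional
  gas-phase component; the effective property is the mole-fraction average
  of the liquid and gas forms. The shipped default aeration (1 vvm) gives a
  gas fraction well below 1; the conventions used are echoed into output
  metadata.

## Design decisions that were genuinely open

* **External metabolites** are identified by the `.Ext` suffix *and* an
  explicit override list, because file-based imports may flag boundary
  species differently.
* **Proton handling**: when a proton-balance reaction is present the proton
  is excluded from the steady-state constraint (the balance reaction closes
  it); otherwise it is constrained like any species.
* **Mode scaling** is per mole glucose (−1), not smallest-integer, because
  every downstream equation is written per mole of glucose.
* **Outlier exclusion** in flux comparisons is always explicit and recorded
  in the output; there is no automatic outlier detection, because the known
  outliers in this problem class (ATP maintenance bookkeeping) have a
  mechanistic explanation that a residual filter would obscure.
* **Identifiability of `b`.** Recovery tests draw `b` from the observed
  evolutionary regime (0.25–0.65). This is deliberate: as
  \(b \to \infty\) the distribution flattens, \(\Delta S_R\) approaches
  the unweighted mode average, and the fit sensitivity
  \(\mathrm{d}\ln b/\mathrm{d}\ln \Delta S_R\) diverges — near the uniform
  limit no finite noise level permits accurate recovery. The suite asserts
  this degradation explicitly instead of hiding it.

## Problem sizes

The test suite and the acceptance script run fixture networks of 3–8
reactions (1–4 modes), synthetic thermodynamic sets of 50–500 modes, 20–60
fit replicates, and a 2000-point normalization grid; these sizes were chosen
so the whole suite exercises every code path in well under a minute while
keeping the stochastic medians stable.

## Known limitations

* Enumeration is exact but exponential in the worst case; a configurable
  candidate cap aborts cleanly rather than thrash.
* The species table shipped in `extdata` covers the external metabolites of
  a glucose-grown aerobic culture plus fixtures; it is not a general
  thermodynamic database, and no group-contribution estimation is provided
  for missing species.
* Constant-temperature evaluation only; no heat-capacity corrections, no
  Mg²⁺ binding, no kLa oxygen transfer, no dynamic CSTR simulation.
* The comparison module passes measured uncertainties through; it does not
  model them.
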