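---
title: "Property-energy consistent contraction and the scaled-shift benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property-energy consistent contraction and the scaled-shift benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecnmr)
```

## The problem

DFT calculations of ^1^H and ^13^C NMR chemical shifts of large natural
products live or die by the basis set: shielding constants converge slowly
with basis size, and cost grows roughly as the cube of the number of
contracted functions. Shielding-oriented basis sets attack this by tuning a
compact set specifically for the shielding operator. This package
implements the machinery around one such family of methods:

1. a data model for segmented-contracted Gaussian basis sets, with the
   structural moves that define "less contracted" variants (releasing a
   p-primitive into its own function, full uncontraction);
2. the **property-energy consistent (PEC)** Monte-Carlo optimizer of
   contraction coefficients: among randomly sampled coefficient sets whose
   shieldings sit within a *diapason* (acceptance half-width) of target
   values, select the one with the lowest total molecular energy;
3. contraction-quality metrics (MACE/MAPCE) against fully uncontracted
   references;
4. a benchmark protocol mapping computed shieldings onto experimental
   shifts by per-nucleus linear regression, scored with the corrected mean
   absolute error (CMAE).

Shielding and energy evaluation is a *backend contract*: any engine can be
attached through `qc_backend_function()`; a deterministic quadratic
surrogate (`make_surrogate()`, `qc_backend_surrogate()`) ships for testing.

## The PEC model

Let $c$ collect the free contraction coefficients of the variable shell
(canonically the carbon p-shell) and $\tilde\sigma_n(c)$ the isotropic
shielding of fitting nucleus $n$. With target values
$\sigma_{\mathrm{ideal},n}$ the optimizer solves

$$\bar\Delta(c) = \frac{1}{N_\mathrm{fit}} \sum_n
  \left|\tilde\sigma_n(c) - \sigma_{\mathrm{ideal},n}\right|
  \;\le\; \varepsilon,
  \qquad
  \sum_n \tilde E_n(c) \to \min,$$

i.e. the summed total energy is minimized over the set of coefficient
vectors whose mean absolute shielding deviation stays within the diapason
$\varepsilon$. The fitting set is acetylene, ethylene and methane — small
molecules spanning sp, sp$^2$ and sp$^3$ carbon shieldings — and the
targets are computed with the *fully uncontracted p-shell* on carbon
(original contracted sets elsewhere), which defines the best shielding the
contraction can aspire to. This constrained problem is multimodal in $c$,
which is why candidates are sampled rather than found by a directed
Newton-type search.

### Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `diapason` | ppm | 0.01 | the level the final mean deviation must not exceed |
| `energy_tol` | Hartree | 1e-5 | energy resolution of the constraint decision and the stop rule |
| `n_samples` | – | 500/round | sampling budget; unstated upstream, so a logged knob |
| `proposal_width` | relative | 0.1 | Gaussian sd per coefficient is `width * max(|c|, 0.1)` |
| `max_rounds` | – | 20 | recentering rounds |
| `width_decay` | – | 0.5 | per-feasible-round shrink of the proposal width |
| `seed` | – | mandatory | full reproducibility of the sampled stream |

### Schedule and numerical choices

The sampling schedule is not specified by the method's description, so the
package declares one: rounds of `n_samples` Gaussian perturbations
recentered on the incumbent. While no feasible candidate has been seen the
incumbent descends on $\bar\Delta$ at full width (otherwise an infeasible
start far from the diapason could never be recovered); once feasible, only
feasible candidates with strictly lower energy replace it, so the
incumbent's energy is non-increasing and always feasible from first
feasibility onward. The width then decays geometrically — near the
constraint boundary the attainable energy resolution is first-order in the
width, so refinement to below `energy_tol` requires widths of that order.
Convergence is declared after three consecutive rounds improving the
energy by less than `energy_tol`, *and* only once the width has decayed by
10^3^; stalls at wide proposals are sampling luck, not convergence. If no
feasible candidate is ever seen the starting coefficients are returned,
flagged infeasible. Candidate columns are rescaled so their dominant
coefficient is exactly 1, fixing the scale degeneracy of contraction
coefficients; the flag is off for abstract surrogate landscapes, whose
coefficient vector has no column structure. Backend failures mark a
candidate invalid rather than aborting; a run in which every candidate is
rejected raises a typed error carrying the round trace.

```{r pec-demo}
spec <- make_surrogate(seed = 1, dim = 2)
res <- pec_optimize(surrogate_problem(spec),
                    pec_config(seed = 1, n_samples = 1000, max_rounds = 40,
                               renormalize = FALSE),
                    qc_backend_surrogate(spec))
glance(res)
```

## Contraction metrics

`mace()` is the mean absolute deviation (ppm) of shieldings computed with
a contracted scheme from the totally-uncontracted-in-all-shells reference
on the spectator atom; `mapce()` is its percentage counterpart with the
reference magnitude in the denominator (kept in absolute value so nuclei
with negative shieldings do not break the metric; a zero reference is a
named error). `contraction_reference()` encodes the measurement recipe —
spectator uncontracted, all other atoms in the original contracted sets;
for hydrogen the contracted side is the released-p variant, whose p-shell
is fully uncontracted after a single release. MACE is translation
invariant and scales linearly under a common scaling of both sides; MAPCE
is the opposite. Both are property-tested.

## The scaled-shift benchmark

Computed shieldings $\sigma_\mathrm{calc}$ are mapped onto experimental
shifts by one unconstrained OLS line per nucleus kind and basis scheme,
$\delta_\mathrm{exp} = A\,\sigma_\mathrm{calc} + B$, fitted globally
across all compounds (per-compound fits are a diagnostic, not the
protocol). Scaled shifts $\delta_\mathrm{scaled} = A\sigma_\mathrm{calc} +
B$ then score

$$\mathrm{CMAE} = \frac{1}{N}\sum_{n=1}^{N}
  \left|\delta_{\mathrm{scaled},n} - \delta_{\mathrm{exp},n}\right|.$$

Because $A$ and $B$ are refitted, the CMAE is invariant under *any* affine
transform of the computed shieldings (tested to 10^-10^ ppm): it measures
scatter about the line, not systematic slope or offset error — that is
what "corrected" means. Outliers are ranked and reported but never
removed; equivalent nuclei can be collapsed to an averaged computed
shielding with `collapse_equivalent()` (tables may also arrive
pre-averaged with `n_equivalent` set — both conventions import).
`cost_ratio(N, N0) = (N/N0)^3` turns contracted-function counts
(`count_molecular_functions()`) into the conventional cubic estimate of
relative DFT cost.

```{r benchmark-demo}
rec <- make_shift_dataset(synthetic_shift_spec("1H", seed = 1))
glance(cmae(rec))
```

## What the synthetic world does and does not establish

The generators state a world matching the benchmark's shape, chosen once:

* **Shift datasets**: 23 compounds; 713 proton and 767 carbon shifts
  (the benchmark's totals); true map $A = -1$ with intercepts 31.5 ppm
  (^1^H) and 186 ppm (^13^C), standard magnitudes for TMS-referenced
  hybrid-DFT shielding scales; Gaussian residual sd 0.36 / 2.5 ppm so the
  folded-normal CMAE limit $\mathrm{sd}\sqrt{2/\pi}$ sits at the observed
  benchmark accuracy (≈0.29 / ≈2.0 ppm); 2 % outliers of 1.3 / 9 ppm,
  the magnitude of the documented worst deviations (un-modelled
  rovibrational and conformational error is not systematic and survives
  regression correction).
* **Surrogate landscapes**: per-molecule quadratic property and energy
  maps over 1–6 coefficients with positive-definite curvatures; all
  molecules share the property center (so the feasible set is nonempty by
  construction) while energy centers are displaced 0.3–0.6 away (so the
  constrained optimum exercises the property/energy trade-off); base
  property values are the canonical carbon targets 108.06, 50.87 and
  192.94 ppm. Because the maps share a center, the constrained optimum is
  a trust-region subproblem with an exact secular-equation solution — the
  independent oracle the optimizer is tested against.
* **Geometries**: shipped XYZ fixtures carry synthetic equilibrium
  geometries at standard hybrid-DFT/triple-zeta-quality bond lengths,
  with provenance headers; they are placeholders for engine-optimized
  geometries.

A green surrogate test establishes that the optimizer solves the stated
constrained problem to `energy_tol`; it says nothing about real GIAO-DFT
landscapes, whose response to contraction coefficients is neither
quadratic nor noise-free. Likewise the shipped `pecS-*-synthetic.basis`
files reproduce only the published contraction *schemes* and function
counts (5/14 for hydrogen, 18/34 for carbon at levels 1/2, and the stated
~50/30 % contraction ratios); their exponents and coefficients are
invented, so they support structural and counting operations, not
chemistry.

## Deliberate design choices

* Spherical-harmonic function counting (p = 3, d = 5, f = 7): the
  convention that reproduces the published set sizes; Cartesian counting
  would not.
* Exponents stored tight→diffuse; `release_primitive()` defaults to the
  primitive with the largest absolute-coefficient weight spread (for a
  single contracted function, its dominant primitive), overridable by
  index, since the published sets do not say which p-primitive was
  released — an importer consuming the published tables accepts either.
* Coefficients are stored and re-serialized exactly as published (17
  significant digits on export, no renormalization on import), so tables
  round-trip bit-exactly.
* One shell block per angular momentum: same-l blocks and SP entries are
  merged/split into segmented form on import, with a warning for true
  general-contraction inputs.
* The energy constraint is interpreted as the *sum* of fitting-molecule
  energies (as printed), not per-molecule constraints.
* Units are fixed at the backend boundary (Å in; ppm and Hartree out);
  engine adapters own any conversion, and should converge SCF to 1e-9
  Hartree so that 1e-5-Hartree constraint decisions are not noise.

## Known limitations

* No quantum-chemistry engine is bundled, and none is available in the
  build environment; the published contraction-error and CMAE figures are
  therefore observables this package can *organize* but not *recompute*
  here. The acceptance tests that require an engine or the
  non-redistributable supplementary tables state that dependency and fail
  honestly rather than skip.
* Elements beyond row 3, ECP/relativistic blocks and exponent
  optimization are out of scope; the optimizer varies one shell's
  contraction coefficients only.
* Solvent models are an engine concern; the PEC loop itself is defined
  gas-phase.
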