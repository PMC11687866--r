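---
title: "Methods: constraint-based models of outer-retina energy supply"
author: "retbudget"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retbudget)
```

# The problem

Photoreceptors are among the most energy-hungry neurons in the body, yet
they sit behind two diffusion barriers: the choriocapillaris (CC) supplies
the outer retina across Bruch's membrane and the retinal pigment
epithelium (RPE), while the retinal circulation reaches only the inner
portion of the perifoveal photoreceptors and is absent at the foveal pit.
This package estimates the *supply side* of an outer-retina energy budget:
the maximal rate of ATP generation per mm² of retinal surface that the
RPE–photoreceptor (PR) complex can sustain given what the two circulations
can deliver, and how nutrient exchange per rod shifts with age and
eccentricity.

# Model and assumptions

## Flux balance analysis

A metabolic network with stoichiometric matrix $S$ and flux bounds
$lb \le v \le ub$ is analysed at steady state, $S v = 0$. The maximal ATP
yield is the linear-programming optimum of the PR ATP-hydrolysis flux
(ATP + H₂O → ADP + Pᵢ + H⁺, the `*_PR` demand in the coupled model).
Assumptions inherited from FBA: steady state (no dynamics of the
light-to-dark transition), perfect efficiency (the optimum is a ceiling,
not a prediction of operating point), and no enzyme kinetics or
thermodynamic driving forces.

FBA optima are degenerate; any reported flux *vector* therefore comes from
parsimonious FBA (pFBA), which among optimal vertices minimises
$\sum_j |v_j|$, making intermediate fluxes reproducible across solvers.
Flux variability analysis (FVA) brackets per-reaction fluxes subject to
retaining a stated fraction of the optimum. Loop screening is a post-check
(`loop_check()`): a sign-constrained circulation test on the internal
reactions, rather than a mixed-integer loopless formulation — cycles are
only ever inspected, not optimised against.

## Sign conventions and units

Exchange reactions are written `metabolite → ∅`: positive flux is export,
uptake is negative, and an uptake limit $U$ becomes a lower bound $-U$.
A measured lactate *efflux* is imposed as an export **floor** (lower bound
$+L$), not an equality: the tissue must push at least the measured lactate
out. This floor semantics is what makes the light/glucose-only condition
infeasible (see below), which is the behaviour the pipeline is designed to
reproduce and explore. All fluxes are pmol·s⁻¹·mm⁻² of retinal surface.

## Cell-specific models

Expression values per cell type are discretized into five confidence
categories: **not present** below a single detection threshold of `1e-5`
(the boundary between the not-present and low bands is taken as one
threshold; separate `1e-5`/`1e-4` cutoffs would leave an unassigned gap),
**low** up to the first quartile, **medium** up to the third quartile,
**high** above it, **unknown** for missing values. Quartiles are
linear-interpolation (type-7) quantiles over the *present* values only —
computing them over all genes would let the non-expressed mass drag the
quartiles down.

Gene categories reach reactions through GPR rules: an `and` complex takes
its weakest member (a NOT_PRESENT subunit silences the complex; an unknown
subunit makes the complex unknown, since function cannot be claimed), an
`or` node takes the strongest member of known confidence, ignoring unknown
isoenzymes when any sibling is known.

Extraction is a deterministic cost-optimisation reaction-dependency
assessment: costs per unit absolute flux of 0 (high), 1 (medium/unknown),
10 (low), 1000 (not present); for biomass and every high-confidence
reaction a cost-minimising flux supporting `1e-4` through the target is
solved, and every reaction used above `1e-8` in any such solution is
retained. The published algorithm this emulates uses stochastic sampling;
the deterministic reformulation preserves its retention logic (penalised
classes enter only when no cheaper route exists) while making the output a
pure function of its inputs. Reactions the pipeline must keep regardless —
the ATP-hydrolysis demand and the template's exchange set — are restored
after pruning (`restore_mandatory()`), and any not-present reaction kept
because biomass is impossible without it is flagged in the
`forced_low_confidence` attribute.

## Coupling

Two cell models are fused into one RPE–PR model. Every id takes its cell
suffix (`_RPE`, `_PR`); a shared interface compartment `e_RPE_PR` is
created by duplicating, for each side, the reactions that link the
extracellular space to the cell interior (suffixes `_RPE-PR` and
`_PR_RPE`), with purely extracellular reactions duplicated under
`_eRPE_PR`; after fusion, reactions with identical stoichiometric
signatures are merged keeping the widest bounds. **Exchange (boundary)
reactions are deliberately not duplicated into the interface**: a
boundary set there would be a third opening to the circulation, and the
coupled model must have exactly two — `e_RPE` against the
choriocapillaris and `e_PR` against the retinal circulation. Interface
transfers default to unbounded; the one transfer the constraint tables
fix (oxygen from the interface into the PR cytosol) is carried as a named
config constant whose default `NA` leaves it unconstrained, since the
fixed value lives in supplementary material not reproduced here.

# Exchange constraints

Built per site × illumination condition from printed physiological
constants (`build_constraint_set()`):

* **Oxygen.** Macaque outer-retina uptake from oxygen-profile
  measurements: perifovea 2.46 (light) / 3.74 (dark), fovea 2.34 / 2.72.
  At the perifovea the retinal circulation contributes 11% (light) or 15%
  (dark), split off to the `e_PR` interface; the fovea has no retinal
  circulation, so its `e_PR` oxygen bound is zero. The profile method
  estimates PR consumption only, so an RPE add-on of 0.30 — a plate
  respirometry rate of ~200 pmol·min⁻¹ over an 11 mm² well,
  `rpe_oxygen_per_area(200, 11)` — is added to the RPE-side bound. Full
  precision is kept internally; two-decimal values appear only in
  printing.
* **Fick ceiling.** `fick_max_flux()` evaluates $J = D\alpha\Delta P f/L$
  with $D = 1.97\times10^{-5}$ cm²·s⁻¹, $\Delta P = 100$ mmHg, exchange
  area fraction $f = 0.7$, and $L = 58$ μm (perifovea) or 77 μm (fovea).
  The oxygen solubility is implemented as $\alpha = 1.38$
  pmol·mm⁻³·mmHg⁻¹: quoted solubility figures for this calculation are
  often dimensionally incomplete ("138 pmol·mmHg⁻¹"), and 1.38 per mm³
  (≈1.38 μM·mmHg⁻¹) is the unique physiological reading that reproduces
  both printed ceilings (3.29 and 2.47) from the same constants.
* **Glucose and lactate.** Whole-retina arteriovenous differences convert
  to per-area fluxes over the spherical cat eye
  ($0.65 \cdot 4\pi r^2 = 988.3$ mm² at $r = 11$ mm, `av_to_flux()`), and
  transfer to the macaque by holding the metabolite-to-oxygen flux ratio
  constant (`scale_by_oxygen_ratio()`). The raw AV tables are
  supplementary material not reproduced here, so the shipped config
  carries **synthetic stand-in** per-area values chosen once on
  physiological grounds: glucose uptake 2.0/4.6 (perifovea light/dark)
  and 1.7/3.3 (fovea), lactate export floors 4.75/8.2 and 3.8/5.8. They
  are marked as such in `inst/extdata/constraints.toml` and are
  user-overridable. The choice preserves the structure the analysis
  turns on: in light the floor exceeds twice the glucose bound (glycolysis
  yields at most two lactates per glucose), so glucose-only light runs are
  infeasible; dark runs are feasible with modest spare oxygen.
* **Amino acids.** No AV data exist, so each amino acid's uptake bound is
  the glucose bound scaled by its plasma-to-glucose concentration ratio
  (`amino_acid_bounds()`), applied at both circulation interfaces at the
  perifovea and RPE-side only at the fovea (no retinal circulation).
  The plasma table shipped is a synthetic stand-in with database-typical
  concentrations (glucose 5 mM, ten amino acids of 60–570 μM). Transporter
  kinetics and competition are not modelled.
* **Everything else** may leave the system freely but not enter; water is
  free in both directions.

# Synthetic data

The generators in `synthdata` (`make_toy_network()`, `make_expression()`,
`make_aging_dataset()`) are first-class, tested code; every generator is a
pure function of its spec and seed (the global RNG state is restored).

**Toy network.** Twelve reactions by default: glucose, oxygen and lactate
exchanges and transporters, glycolysis (glc → 2 lac + 2 ATP), full
oxidation (glc + 6 O₂ → 6 CO₂ + 32 ATP), an ATP-hydrolysis demand, a CO₂
demand, a reversible water sink, and a biomass sink. Whole-number yields
keep the closed form exact: with glucose bound $G$, oxygen bound $O$ and
lactate floor $L$, the optimum is
$32\,g_{ox} + 2\,(G - g_{ox})$ with
$g_{ox} = \min(G - L/2,\; O/6)$, infeasible when $2G < L$. The optional
amino-acid route is alanine-like — oxidisable (15 ATP, 3 O₂) or
convertible to lactate — and the optional fatty-acid route is
palmitate-like (106 ATP, 23 O₂). The per-oxygen yields are ordered
glucose (5.33) > amino acid (5.0) > fatty acid (4.6), so oxygen is always
spent on glucose first, amino acids rescue the lactate floor, and lipid
gains are bounded by spare oxygen — the qualitative behaviour of the
genome-scale analysis. What the toy network does *not* emulate: pathway
redundancy, cofactor balancing beyond ATP/ADP/Pᵢ, compartment-specific
isoforms, or the scale (thousands of reactions) of a real reconstruction;
passing tests on it validate the machinery, not genome-scale numbers.
The pipeline accepts a real reconstruction through the same SBML
interface when one is supplied.

**Expression matrices** plant exact not-present and missing fractions and
derive ground-truth low/medium/high labels from rank positions against the
type-7 quantile knots, so `discretize()` recovers the labels for all
non-boundary genes.

**Aging tables** generate flow deficits increasing with age, CC densities
through the true calibration line $y = 72.6 - 1.29x$ plus Gaussian noise,
rod densities from a smooth hump curve
$d(x) = d_{max} (x/x_0)^2 e^{2(1 - x/x_0)}$ scaled by age factors with a
deliberately non-monotone oldest group (densities can rise again in the
oldest cohort through survivor variation), and a cone-area fraction
declining with eccentricity.

# Aging analysis

The OCTA flow-deficit → CC-density calibration is an ordinary
least-squares line fitted per decade (`fit_calibration()`), applied with
clamping to [0, 100]%. Profiles along eccentricity interpolate linearly
between samples and extend the end values outward (the most central value
holds to the fovea, the most peripheral onward). Rod densities are fitted
with raw polynomials; degree 5 is the default — the lowest degree that
tracks the synthetic hump within 5% across 0.5–5 mm while staying stable
under leave-one-out refits — and is config-addressable since the source
analyses state only "polynomial fits". Eccentricities under 0.5 mm are
excluded: cones dominate there and rod-density estimates are unreliable.
The rod inner-segment area is $(1 - \text{cone fraction})/\text{rod
density}$; the CC baseline is the youngest group's mean CC density, the
rod baseline the `"25"` group's IS area at the same eccentricity, and the
combined fractional change in exchange per rod is the product
`frac_cc × frac_rod_area` (one-dimensional exchange: both the vascular
area fraction and the rod's collecting cross-section gate the flux).

# Numerical choices

* **LP solver.** A dense bounded-variable two-phase simplex written for
  this package. Stoichiometric LPs carry exact conservation relations
  (linearly dependent rows of $S$), which are reduced away before solving
  with a consistency check on the dropped rows; degenerate optimal faces
  (routine in FVA subproblems with the objective pinned at its optimum)
  are handled by falling back to Bland's anti-cycling rule when progress
  stalls. Feasibility/optimality tolerance `1e-9`; steady-state residuals
  of accepted solutions are asserted below `1e-6`.
* **Bounds.** Infinite bounds are clamped to ±1e6; an optimum pinned at
  the clamp is reported as unbounded rather than returned as a number.
* **Degenerate optima.** `fba()` may return any optimal vertex; every
  flux vector surfaced to the user comes from `pfba()`.
* **Feasibility thresholds** are located by walking the stated 0.10
  grid (not bisection), matching the decrement procedure that produced
  the published threshold granularity; a grid that never crosses the
  boundary is reported as open, and infeasibility is a result value, not
  an exception.
* **Determinism.** Coupling orders metabolites and reactions
  canonically; signature-identical duplicates merge keeping the
  lexicographically first id and widest bounds; the run manifest hashes
  config and results with no timestamps, so identical runs hash
  identically.

# Problem sizes

The shipped analyses run on the toy scale by design: 12–19 reactions per
cell model, ≈50 reactions coupled, a 16-cell condition grid in a few
seconds, 200-replicate calibration Monte Carlo, and 50-draw LP-vs-oracle
property checks. These sizes make every expected value either a closed
form or an independently enumerable optimum.

# Known limitations

Steady-state only; a single generic amino-acid pool in the toy network
rather than per-acid carbon skeletons; the RPE oxygen add-on flows to the
shared pool in the toy coupled model because the toy RPE has no
maintenance demand of its own; glucose enters RPE-side only in the
default config; supplementary-table constants (cat AV values, fixed
interface O₂ transfer) are represented by labelled synthetic stand-ins or
placeholders; and absolute genome-scale yields require an external
reconstruction and expression datasets that are not bundled.
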