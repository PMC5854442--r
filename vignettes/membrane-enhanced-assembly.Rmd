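---
title: "Membrane-enhanced protein assembly: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-enhanced protein assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaeff)
library(dplyr)
```

## The model and its assumptions

Two soluble proteins P₁ and P₂ bind one another (association constant
K_a^PP) and each reversibly binds one copy of a specific membrane lipid M
(K_a^P1M, K_a^P2M). That generates nine distinct species — free proteins
and lipid, the solution complex, each singly lipid-anchored protein and
complex, and the doubly-anchored complex — connected by ten reversible
reactions. The assumptions to keep in mind:

* **Single lipid site per protein.** Multivalent lipid engagement (e.g.
  AP-2 engaging several PI(4,5)P₂) is represented only implicitly, by an
  effective affinity; it reduces the free lipid pool, which the user can
  mimic by lowering `M_0`.
* **Well-mixed compartments.** There are no spatial gradients. Membrane
  species diffuse and react in 2D with constants related to their 3D
  counterparts by the length σ: K_a^2D = K_a^3D/(2σ). σ is a thermodynamic
  property of each binding pair (nanometre scale, dominated by the
  entropic cost of surface confinement); we use one σ for all three
  interactions, because detailed balance around the reaction cycles
  otherwise fails (the cycle products of equilibrium constants no longer
  equal one, so no true equilibrium exists). Unequal values are accepted
  only with an explicit override and a warning, and the network builder
  refuses them.
* **Protein–protein affinity is dimension-independent** until both
  partners are anchored: the same K_a^PP applies in solution and for a
  membrane-tethered protein binding a solution partner, because the same
  interface exchange drives the bond. Only the doubly-membrane-bound
  encounter uses the 2D constant.
* **Equilibrium.** The theory describes the equilibrium state; kinetics
  come from the ODE and stochastic layers.

All internal computation uses μm/μm²/μm³/seconds with per-molecule
association constants; molar quantities appear only at the interface.
This keeps Avogadro factors out of every equation. The lipid total must
always carry an explicit unit tag (`"um-2"`, `"M"` or `"um-3"`), because
holding a surface density fixed while varying V/A changes the physics —
large V/A at fixed μm⁻² means proteins outnumber lipids and the
enhancement collapses.

## The effective constant and the free-lipid interpolation

The effective association constant is defined on species sums: all
complexes (solution + membrane) over the products of unbound protein
pools. Dividing by K_a^PP gives the enhancement

$$\frac{K_a^{eff}}{K_a^{PP}} =
\frac{\gamma\,K_1 K_2 M^2 + (K_1 + K_2)M + 1}{(1 + K_1 M)(1 + K_2 M)},
\qquad \gamma = \frac{V}{2A\sigma},$$

with $K_n = K_a^{PnM}$ and $M$ the *free* lipid at equilibrium. This
relation is exact — `test-acceptance.R` verifies it to ~10⁻¹⁵ relative
against the full network across random parameter sets — so all
approximation error lives in predicting $M$. The dimensionless products
$K_n M$ are each protein's membrane stickiness (its membrane:solution
ratio); the enhancement rises monotonically with stickiness for γ > 1 and
saturates at γ, and drops below 1 only when V/A < 2σ.

$M$ is interpolated between two exactly solvable limits:

* **No complex formation** (K_a^PP = 0): a single-site binding balance
  with an averaged protein–lipid constant; the non-negative quadratic
  root, evaluated with the numerically stable branch (no subtractive
  cancellation on either side of $M_0 \gtrless P_{tot}$). The average is
  weighted by the *equilibrium free* protein levels, obtained by a short
  fixed-point refinement; weighting by totals instead is noticeably worse
  when the two affinities differ by more than ~10-fold (errors of 10⁻³
  rather than 10⁻⁶ in the excess-lipid regime).
* **Complete pairing** (K_a^PP → ∞): every pairable protein is a two-site
  complex binding lipid with the second event γ-scaled (2D); the lipid
  balance closes to a cubic, solved by `polyroot` with a monotone
  bisection fallback. When the totals are unequal, the unpaired surplus
  of the more abundant protein binds lipid with its own single-site
  equilibrium; this choice preserves lipid conservation.

The interpolation weight λ is the fraction of the limiting protein bound
in complex, computed from the dimerization quadratic at the effective
constant obtained by plugging the no-complex free lipid into the
enhancement relation. This single-pass definition is the default; an
opt-in mode (`self_consistent = TRUE`) feeds the λ-dependent constant
back until convergence (relative tolerance 10⁻¹⁰, 100 iterations), and
both modes are exposed because the single-pass value is what the rest of
the package is calibrated against.

Accuracy, measured against the exact network equilibrium: ≤10⁻⁶ relative
when lipids exceed proteins 100-fold or more; a few ×10⁻³ in the hard
regime where lipids are outnumbered and K_a^PP reaches 10⁹ M⁻¹ (the
panel-style sweep in the tests); fully random lipid-starved corners can
reach ~10–15% because the true free lipid escapes the bracket formed by
the two limits — use `solve_equilibrium()` when the lipid budget is that
tight.

## Exact network equilibrium and kinetics

Because the network obeys detailed balance, every species concentration
is a product of free-monomer concentrations and an equilibrium weight
accumulated along any reaction path (path independence *is* the
detailed-balance check, asserted at build time to 10⁻⁹). The solver runs
damped Newton iteration on the log free-monomer concentrations — positive
by construction, converging from the fully-unbound start — to relative
conservation residuals of 10⁻¹³. The Newton step is length-capped by
*rescaling* (direction-preserving), with a halving line search.

Time courses integrate mass-action ODEs with `deSolve::lsoda` (rtol
10⁻¹⁰), starting from all proteins unbound in solution. Rates follow the
convention: every reaction gets k_off = 1 s⁻¹ and k_on = k_off·K_a unless
k_on would exceed the diffusion limit 4πσD_tot, in which case k_on is
capped and k_off lowered so K_a is exact. D³ᴰ = 50 μm²/s and
D²ᴰ = 0.5 μm²/s per species are the defaults. Equilibria are therefore
independent of k_off and D — a property the tests assert — and the
equilibration-time metric (first entry into a ±1% band around the final
complex level, a convention exposed as a parameter) shows the expected
ordering: weak lipid binding (K_a^PM ~ 10⁴ M⁻¹) slows relaxation relative
to pure solution binding, because reaching the membrane is rate limiting.

The scaffold variant (two lipid-binding proteins P₃, P₄ bridged by a
scaffold S with one independent site for each, S itself not binding
lipid) enumerates 14 species and 20 reactions. Its effective two-step
constant — bridged triples over the product of the three not-in-triple
pools — is a reconstruction; it is validated only by its properties: it
collapses to the solution reference without lipid binding, grows
monotonically with scaffold concentration while the scaffold is
sub-stoichiometric (beyond the peripheral-protein totals the prozone
effect makes bridging non-monotone), and is bounded by γ² because *both*
assembly legs can become 2D searches.

## The stochastic layer

The rule-based Gillespie engine tracks individual molecules, typed
binding sites, bonds and connected components. It is non-spatial: lipids
are a population; a complex is membrane-associated exactly when it
contains a bound lipid; encounters between two membrane complexes use
k_on^2D/A, all others k_on^3D/V ("reaching the membrane is a 3D
search"); dissociation is dimension-free. Per-event cost is kept constant
by maintaining running pair-count aggregates (total and membrane-only
free-site cross sums per rule) updated incrementally as components merge
and split. Intra-complex bond formation (ring closure, e.g. hexagon
closure in a clathrin lattice) is excluded by default since a non-spatial
model cannot judge geometric compatibility; a per-rule first-order
ring-closure rate is available. An opt-in invariant checker
(`options(kaeff.ssa_check = TRUE)`) recomputes every aggregate from
scratch each event.

Prebuilt models: the pair model (for cross-validation against the ODE
network — agreement within Monte-Carlo error is an acceptance property);
clathrin trimers (three leg sites binding legs of other trimers, three
non-competing adaptor sites) with AP-2 (one clathrin site, one lipid
site); and BAR proteins (dimer site, non-competing oligomer site, lipid
site) in homodimer or mismatched heterodimer stoichiometry.

## Problem sizes and simulated conditions

Equilibrium results depend only on concentrations and the V/A ratio, not
on the absolute volume, so stochastic experiments run in small volumes at
the stated concentrations and geometry. Choices used by the tests and the
acceptance script:

* Pair-model cross-validation: 1 μM of each protein, lipid 10³ μm⁻² at
  V/A = 1 μm, simulated in V = 0.4–0.5 μm³ (≈240–300 copies per protein);
  12–24 seeded replicates, 12 s simulated, 5 s burn-in, equilibrium read
  as the time-average of bond counts after burn-in.
* Clathrin experiment: V/A = 9.46 μm, lipid 54,668 μm⁻², clathrin and
  AP-2 at 0.4 μM, clathrin–AP-2 K_d 22 μM, AP-2–lipid K_d 2.86 μM,
  lattice-contact K_d swept over 10–100 μM, in V = 0.25 μm³ (≈60 trimers);
  paired runs with and without the lipid population. Polymerized means
  sharing a complex with ≥1 other trimer. Nucleation pathways are tallied
  from the bond-formation channel of every lattice contact: 2D
  (membrane-localized dimerization) versus 3D with exactly one
  membrane-bound partner (direct recruitment from solution).
* BAR oligomerization: oligomer contacts at K_d = 500 μM; solution-only
  oligomerization at sub-μM expression stays far below 1%, matching the
  weak-binding chain estimate (bound-site fraction ≈ K_a[P]).

What the synthetic conditions do *not* emulate: spatial heterogeneity and
diffusion gradients, membrane curvature feedback, lipid clustering,
competition from the wider proteome, and ring closure. Passing tests
therefore demonstrate correctness of the equilibrium/kinetic bookkeeping
and of the dimensionality-reduction mechanism, not a quantitative
prediction for any particular in-vivo system.

## Numerical choices and degenerate inputs

* Quadratics are always solved on the stable branch (rationalized form
  when the linear coefficient is negative); λ and fractions are clamped
  to [0, 1] against floating-point drift.
* K_a^PP = 0 short-circuits λ = 0; K_a^PM,av = 0 returns M_eq = M_0; an
  empty protein pool returns zero complexes and 0% complexation rather
  than 0/0.
* Extreme affinities (up to 10¹⁵ M⁻¹) are handled by the stable-branch
  quadratics; the enhancement ratio is evaluated directly from
  stickiness products, which stay finite in double precision.
* The critical lipid concentration (smallest M₀ with K_a^eff within ε of
  the γ ceiling, default ε = 0.01) is found by bisection that maintains a
  bracketing upper point and stops when its normalized excess over 1−ε is
  ≤10⁻⁶; it is flagged `NA` when γ ≤ 1 or a partner does not bind lipid.
* Sweep drivers verify every theory point against the exact network and
  flag rows outside tolerance instead of failing silently.

## Using the data tables

`load_fixture("table1")` returns the 37-protein table (copy numbers,
protein–lipid K_d with censored `>100 μM` entries flagged rather than
substituted, AP-2's cargo-bound affinity, provenance per row);
`load_fixture("geometry")` and `load_fixture("lipids")` the cell
geometries and lipid densities; `concentration_from_copies()` converts
copy numbers to cytoplasmic concentrations. Per-pair protein–protein
affinities are shipped only as an editable placeholder template
(`pair_kd_template`) — they are scattered across primary literature and
deliberately not invented here, which is also why per-pair enhancement
scans are structured as user-driven sweeps rather than packaged results.

## Known limitations

* The free-lipid interpolation degrades when lipids are heavily
  outnumbered *and* binding is strong (use the exact solver there).
* The scaffold effective constant is a reconstruction with property-level
  validation only.
* The stochastic engine's pair selection uses rejection sampling with a
  1000-draw cap; in pathological states (all eligible sites in one giant
  complex) a draw can be abandoned, which re-enters the propensity loop
  and leaves equilibrium unaffected but is not a formally exact SSA step
  in that corner.
* Distinct lipid pools for the two proteins are supported in the theory
  layer only, not in the network/SSA layers.
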