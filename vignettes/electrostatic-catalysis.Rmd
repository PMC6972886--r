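---
title: "From biased trajectories to electrostatic catalysis: the metacage analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From biased trajectories to electrostatic catalysis: the metacage analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Supramolecular hosts such as the tetrahedral Ga₄L₆¹²⁻ nanocage accelerate
the alkyl–alkyl reductive elimination from cationic gold(III) complexes by
orders of magnitude. A mechanistic account of that acceleration needs three
ingredients: (i) free-energy surfaces for the catalyzed and uncatalyzed
reactions in a low-dimensional reaction space, (ii) validated transition
states on those surfaces, and (iii) a decomposition of the activation
free-energy change into physical contributions — here, the interaction of
electric fields generated by distinct parts of the environment (bulk
solvent, a single complexed water, the charged cage) with the dipoles of
the two breaking Au–C bonds.

metacage implements that analysis chain as reusable, tested components.
The chain is method-level, not system-level: the electronic-structure
trajectories behind the original study are not reproducible at desk scale,
so a synthetic-data module supplies model potentials, stochastic dynamics
and point-charge environments with analytically known answers. Every stage
is validated against those known answers.

## Reaction space

Two collective variables (CVs) span the reaction:

* the distance between the carbons of the two leaving methyl groups (Å);
* the gold–carbon coordination number, a smooth bond count
  $$\mathrm{CN} = \frac{1}{2}\sum_{i\in\{1,2\}}
    \frac{1-(r_i/R_0)^{8}}{1-(r_i/R_0)^{14}},$$
  with `R0 = 2.1` Å by default (a typical Au(III)–C bond length; the
  reference protocol leaves the number unstated). The exponent pair (8, 14)
  is implemented exactly as specified even though (6, 12) is the more
  common default elsewhere. The removable singularity at `r = R0` is
  evaluated analytically as the limit `p/q` inside a guard band
  `|r/R0 − 1| < 1e−9`; the function is continuous and strictly decreasing,
  with range (0, 1] — properties the test suite checks by dense sampling.

## Enhanced sampling and unbiasing

Well-tempered metadynamics deposits Gaussians of nominal height 0.005
Hartree (3.1375 kcal/mol) every 30 steps of a 0.5 fs timestep; with bias
factor γ the deposited height is damped by
$\exp[-V_B(s)/(k_B\Delta T)]$, $\Delta T = (\gamma-1)T$. γ is not stated in
the reference protocol; the default is γ = 15, a typical well-tempered
value, and it is always recorded in output metadata. Hill widths
(σ = 0.2 per CV) are likewise declared defaults, not reconstructions. The
unbiased surface is the scaled negative of the accumulated bias,
$F(s) = -\frac{\gamma}{\gamma-1}V_B(s)$ (plain $-V_B$ for standard
metadynamics, exposed via `bias_factor = Inf`), normalized to min 0.

Two numerical choices matter here:

* **Hill truncation.** Each Gaussian is cut off at 6.5σ. The dropped tail
  of one hill is bounded by $h\,e^{-c^2/2}$, i.e. 6.6×10⁻¹⁰·h at 6.5σ, so
  even thousands of kcal-scale hills stay within 10⁻⁶ kcal/mol of the
  untruncated sum — a bound the tests verify against a brute-force oracle.
  A 5σ cutoff (3.7×10⁻⁶·h per hill) cannot meet that bound.
* **Stopping rule.** Runs halt once the dividing surface has been crossed
  at least three times *and* at least 50 ps of biased dynamics have
  accumulated, mirroring the reference protocol ("crossed at least three
  times, gathering over 50 ps"). The time floor is essential: stopping at
  the literal third crossing leaves a 30–60-hill bias whose graininess
  (single hills are half the 6 kcal/mol test barrier) produces 30–80%
  barrier errors, while the 50 ps floor brings recovery within a few
  percent. "At least every 30 steps" is read as a fixed pace of 30; the
  adaptive variant is out of scope.

## Stand-in dynamics

The synthetic walker follows overdamped Langevin dynamics on model
surfaces — a quartic double well
$V = h[(x/a)^2-1]^2 + \tfrac12 k y^2 (+\,t\,x)$ with barrier `h`, minima at
(±a, 0) and saddle (0, 0), or a harmonic well for calibration. Only
basin-commitment behaviour matters for the committor and FES stages, so
inertia is omitted. Discretisation uses the Leimkuhler–Matthews
(overdamped BAOAB-limit) update — consecutive noise increments averaged —
which samples harmonic configurational statistics exactly and keeps the
equipartition check (Var x = k_BT/k) within a fraction of a percent at the
0.5 fs production timestep. Plain Euler–Maruyama would be ~30% off at the
same step.

Stability bounds the friction: overdamped Euler-type updates need
$\Delta t\,V''/\gamma < 2$. The generic default is γ = 1 fs⁻¹ (adequate
for the harmonic calibration well, V'' = 1), but the study double wells
have V'' = 8h/a² ≈ 32–48 kcal/mol/Å², so the pipeline configuration uses
γ = 50 fs⁻¹, chosen once from the stability bound. The study wells use
h = 6 ("uncatalyzed") and h = 4 kcal/mol ("catalyzed"), a = 1 Å, and a
transverse stiffness k = 8 kcal/mol per CV² so that the reaction channel
is well collimated relative to the barrier (a soft channel lets the
well-tempered bias creep over the transverse wall long before the surface
converges). For the same reason the metadynamics walker is confined by
harmonic restraining walls (x ∈ [−2.5, 2.5], y ∈ [−1.5, 1.5],
k_wall = 100), the standard practice for bounded CVs; the trajectory
domain box remains a hard error ("domain escape") for unbiased runs.

Determinism is a contract: every stochastic operation takes a seed, and
identical seeds give bitwise-identical results (the committor's shots
consume one seeded stream, equivalent to per-shot sub-seeds).

## Minimum-energy paths

The zero-temperature string method relaxes a 30-image path for up to 3000
steps: steepest descent along the bicubic-interpolated gradient, then
reparameterization to equal arc length (piecewise linear). Bicubic Hermite
interpolation (finite-difference node derivatives) is used because its
gradient is continuous across cells — descent on bilinear gradients stalls
at cell edges. Endpoints are free so reactant and product images settle
into their basin minima rather than being pinned.

The reference protocol states only the image and step counts, so the step
size is this package's choice: per-image adaptive steps (halved when a
move would raise that image's energy or leave the grid, grown 1.2× after
acceptance) with a displacement cap of half a grid cell per iteration.
The cap is load-bearing: an uncapped accepted step can carry an image
across the barrier to a lower-energy point and fold the path. A fixed tiny
step (10⁻³ × grid spacing was considered) provably cannot converge the
transverse profile in 3000 iterations.

The barrier ΔG‡ is the transition-state energy minus the reactant-side
minimum — the side of the path's first image, not the global minimum,
which matters for tilted wells. The TS is refined by densely resampling
the interpolated surface along the path across the three highest images.
On analytic double wells this recovers the saddle to ~10⁻⁴ CV units and
the barrier to ~0.1%; the acceptance checks require 0.02 and 2%.

## Committor validation

Candidate transition-state frames are selected from a CV series by the
reference windows ±0.05 Å in methyl–methyl distance and ±0.005 in
coordination number. Commitment probabilities are estimated by shooting
overdamped Langevin trajectories from the candidate point until first
entry into rectangular reactant/product windows (default: centered on the
string's RS/PS minima with half-width 0.3× their separation; the protocol
says only "fall in the equilibrium well"). Timeouts are reported separately
and excluded from p, with a warning above 10%.

A candidate is accepted as a transition state when the Wilson 95%
confidence interval of p_product intersects the band [0.40, 0.60]. The
CI-intersection semantics (rather than a hard band on the point estimate)
are chosen deliberately: the reference analysis accepted both a 57%/43%
ensemble and an early 38%/62% ensemble measured on ~50 geometries, and a
small-sample 38% estimate is statistically compatible with 0.4–0.6. The
Wilson interval comes from `stats::prop.test(correct = FALSE)`.

## Rates and the electrostatic decomposition

Rate ratios use transition-state theory,
$k_{cat}/k_{uncat} = \exp(\Delta\Delta G^\ddagger / RT)$ with
RT = 0.5925 kcal/mol at 298.15 K. Note that the printed activation
energies of the original analysis (33 vs 24 kcal/mol) imply
exp(9/RT) ≈ 3.95×10⁶, not the 3.3×10⁷ printed there — presumably the
published factor used unrounded barriers. The package computes, it does
not reconcile.

The electrostatic stabilization of the transition state for one source
group is
$$\Delta G^{elec} = \sum_{i=1,2} -K\,
  (\mu^i_{TS}E^i_{TS} - \mu^i_{RS}E^i_{RS}),$$
with fields in MV/cm projected on the Au→C bond unit vectors (positive =
opposite to the electron flow, the stabilizing orientation), bond dipoles
in Debye, and K = 0.048 kcal/mol per Debye·MV/cm. K is derived from CODATA
constants at call time (3.33564×10⁻³⁰ C·m × 10⁸ V/m × N_A / 4184 =
0.0480) and asserted against its conventional rounding rather than
hard-coded. Bond dipoles use a symmetric two-point model about the bond
midpoint, μ = ½(q_C − q_Au)·d·4.8032 D; the original study's exact dipole
convention is in supplementary material not available here, so the
convention is documented and swappable by supplying precomputed dipoles.
Fields computed from raw point charges are evaluated at the bond midpoint
(the reference evaluates a potential derivative without stating the probe
point). The packaged snapshot tables carry the published worked-example
fields and dipoles verbatim; their per-group stabilizations and the net
catalyzed-minus-uncatalyzed contribution (~−4.9 kcal/mol) follow by
direct evaluation of the formula above.

## What the synthetic data does and does not show

The generator emulates: 2-D CV trajectories on double-well surfaces with
tunable barriers, hill streams at the reference schedule, and grouped
point-charge environments (a bulk shell of ± partial charges at 8–14 Å, a
single 3-point complexed water at 3 Å, and a 12-point −1 e cage shell at
7 Å) around a two-bond Au(CH₃)₂ probe with analytically known projected
fields. Passing tests therefore demonstrate that the *analysis chain* is
correct: unbiasing recovers known barriers within 15%, the string finds
analytic saddles, committors at saddles are ½, grouped Coulomb fields
superpose exactly.

They do not demonstrate anything about real gold/cage systems: there is no
electronic structure, no explicit solvent, no charge fitting, and the
stand-in dynamics have neither inertia nor solvent memory. The published
barriers (37/33/24 kcal/mol), committor fractions and field magnitudes
require periodic DFT molecular dynamics and enter this package only as
inputs (the worked-example tables) or as consistency checks on formulas.

## Problem sizes

The shipped configuration runs each metadynamics pathway for 50–100 ps
(100 000–200 000 steps, ~3300 hills), reconstructs on a 200×200 grid,
relaxes a 30-image string for up to 3000 steps, and shoots 400 committor
trajectories with a 20 000-step timeout — a few seconds per stage on one
CPU. These sizes are the package's study conditions; they were chosen so
the well-tempered bias is smooth on the scale of the test barriers.

## Known limitations

* The FES estimator is direct hill summation; no reweighting estimators.
* The string is strictly zero-temperature; no finite-T or swarm variants.
* Committor shooting is momentum-free; recrossing dynamics that depend on
  inertia are outside the model.
* The dipole model is the two-point midpoint convention; other conventions
  must be supplied as precomputed dipoles.
* The hill reader accepts the PLUMED-style column order and a CP2K-style
  Hartree dialect; restart/wavefunction formats are out of scope.
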