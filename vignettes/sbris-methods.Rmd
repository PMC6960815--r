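---
title: "SBRIS Monte Carlo: model, samplers and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SBRIS Monte Carlo: model, samplers and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbris)
```

## The model

`sbris` simulates one weak flexible polyelectrolyte as a chain of point
nodes with an ionizable site every third position — the pattern of linear
poly(ethylene imine), where a titratable amine alternates with two
methylene carbons.  A chain with `N` sites has `3N - 2` nodes and
`M = 3N - 3` bonds.  The microstate couples two kinds of degrees of
freedom:

* a binary protonation vector `s` (site `i` carries charge `+1` when
  protonated), and
* the conformation: one rotational isomeric state per rotatable bond
  (trans `φ = 0`, gauche± `φ = ±120°`) plus, optionally, the continuous
  bond lengths and bond angles.

Only the middle bond between two consecutive ionizable sites rotates; the
other bonds stay trans, which is the minimal choice that still couples
ionization to conformation.  The chain is symmetric (no tacticity), so the
two gauche states must be isoenergetic; the constructors enforce this.

The free energy in `kBT` units is a sum of independent terms (see
`total_free_energy()` for the reference implementation):

| term | form | default parameters |
|---|---|---|
| torsion | `Σ ε_rot(φ_j)` | `ε_rot ≡ 0` (all states isoenergetic) |
| proton binding | `ln10 (pH − pK) Σ s_i` | `pK = 9`; dropped in ccMC |
| short range | `ln10 Σ ε_int(φ_{3i−1}) q_i q_{i+1}` | `ε_int(t) = 1`, `ε_int(g±) = 3` (log10 units) |
| long range | `Σ_{j≥i+2} (ℓB/d) e^{−κd} q_i q_j` | `ℓB = 0.7` nm, `κ⁻¹ = 0.304/√I` nm |
| stretching | `Σ k_l/2 (l − l₀)²` | `l₀ = 0.15` nm, `k_l = 300` kcal/mol/Å² |
| bending | `Σ k_α/2 (α − α₀)²` | `α₀ = 120°`, `k_α = 0.01` kcal/mol/deg² |
| excluded volume | hard spheres, pairs ≥ 4 bonds apart | radii 1.55 Å (sites) / 1.7 Å (inert); off by default |
| work | `−F r_z / kBT` | `kBT = 4.1164` pN nm |

Unit conventions: lengths in nm and angles in degrees at every interface,
radians internally; energies internally in `kBT` at the fixed working
temperature 298.15 K (1 kcal/mol = 1.6878 kBT).  `ε_int` is given in
log10 units so that, through the `ln10` prefactor, it acts as a pK shift:
a protonated neighbour across a trans bond raises the effective pK of a
site by `ε_int(t)`.

Two design readings of ambiguous sums are fixed here once: the long-range
pair list runs over ionizable-site indices with `j ≥ i + 2`, because the
nearest-neighbour site pair is carried by the chemically specific
short-range term (double counting would otherwise shift the titration
curve); and the excluded-volume sum runs over *all* node pairs, inert
nodes included, separated by at least four bonds — closer pairs are
controlled by the bonded terms.  Whether the original excluded-volume
convention included inert nodes is not decidable from the model statement;
including them is the more physical choice for a chain with finite-size
groups.

## Samplers

`run_simulation()` drives a compiled Metropolis kernel in one of two
modes:

* **SGCMC** (semi-grand canonical, constant pH): site occupancies
  fluctuate against a proton bath; the degree of protonation
  `θ = ⟨N₊⟩/N` and the binding capacitance `C = ⟨(N₊ − Nθ)²⟩` are
  outputs.
* **ccMC** (constant charge): every site carries the smeared charge `θ`
  (an input, normally the zero-force SGCMC average), the proton-binding
  term drops out, and pair energies scale with `θ²`.  This is exact only
  at large separations, which is precisely why comparing the two modes
  measures the effect of charge fluctuations and correlations.

The move set is the minimal ergodic set for these degrees of freedom:

1. *Protonation flip* (SGCMC only): toggle one uniformly chosen site;
   geometry unchanged.
2. *Pivot*: assign one uniformly chosen rotatable bond one of its two
   alternative states and rigidly rotate the shorter chain arm about the
   bond axis (frame invariance makes rotating either arm equivalent; the
   shorter one is cheaper).
3. *Elastic step* (optional): perturb one uniformly chosen bond length or
   bond angle by a Gaussian step (defaults `σ_l = 0.0044` nm,
   `σ_α = 7.7°`, one thermal standard deviation of the reference force
   constants, giving ~50–60 % acceptance) and translate/pivot the shorter
   arm accordingly.  Internal coordinates are proposed with a flat
   measure, so the sampled marginals of an unconstrained bond are the
   plain Gaussians `var(l) = kBT/k_l`, `var(α) = kBT/k_α` — this is the
   convention under which the harmonic parameters have their usual
   meaning, and it is verified against those closed forms in the tests.
4. *Reorientation*: rigid-body rotation of the whole chain about a random
   axis by a uniform angle.  Arm pivots conserve the laboratory direction
   of the central bond, so without this move the global orientation is
   not ergodic and `⟨r_z⟩` would retain an arbitrary frame bias; the move
   only couples to the mechanical work term and costs no pair-energy
   evaluations.  By default it takes 5 % of attempts
   (`p_reorient`), the rest being shared by the move mix (defaults
   0.25/0.75 flip/pivot rigid, 0.2/0.6/0.2 with elastic sampling).

Moves are accepted with the Metropolis probability `min(1, e^{−ΔE})`;
hard-sphere overlap makes `ΔE = +∞`.  All proposals are symmetric, so
detailed balance holds by construction; the sampler is additionally
validated against exact enumeration (below).  Energy changes are computed
incrementally (only cross-arm pairs are re-evaluated); setting
`check_every` re-derives the total energy from scratch — including the
geometric bond lengths and angles — at intervals and reports the worst
drift, which the tests hold below 1e−9 kBT over tens of thousands of
moves.

Each replicate starts all-trans with protonation drawn from the ideal
(non-interacting) titration probability, runs `n_equilibration` discarded
attempts, then `n_steps` production attempts ("configurations" are counted
as elementary attempts).  Replicates use sub-seeds derived from the master
seed by a fixed splitmix rule inside the kernel, independent of R's RNG
state, so a run is reproducible bit for bit.  Elastic degrees of freedom
can be sampled at any force; they are off by default because at low force
they only renormalise `l₀` and `α₀` fluctuations without affecting the
ionization–conformation coupling, and the rigid chain samples several
times faster.

## Observables and uncertainties

* `θ` and `C` from the sampled proton counts; `C` is also available as
  `N ∂θ/∂μ` by finite differences over pH
  (`capacitance_from_titration()`), and the two identities are compared in
  the tests.
* `P(g)`: gauche fraction **per rotatable bond**.  Dividing by all `M`
  bonds would cap the free-chain limit near 0.22; the observed limit of
  2/3 for an uncharged chain (three isoenergetic states) forces the
  rotatable-only denominator, which is therefore the default
  (`gauche_probability()` exposes both).
* Persistence length, two estimators: from the mean square end-to-end
  distance, `lp = ⟨r²⟩/(2Ml₀) + l₀/2` (the quantity usually plotted; the
  default), and from the summed projections of downstream bonds on a
  central reference bond (`persistence_length_projection()`, used for
  validation — the two agree within 10 % for uncharged chains of ≥ 50
  rotatable bonds).
* Uncertainties are standard errors over independent replicates;
  `block_standard_error()` provides an autocorrelation-aware per-replicate
  estimate, validated against the analytic variance of an AR(1) process.

## The exact oracle

For chains with a state space up to 10⁶ microstates (N ≲ 8 rigid sites),
`enumerate_states()` sums Boltzmann weights over every protonation ×
rotational microstate using the plain-R energy functions — a code path
deliberately independent of the compiled kernel.  An applied force is
handled exactly by integrating each conformation over global orientations:
a conformation with end-to-end distance `r` acquires the weight
`sinh(x)/x`, and contributes `r L(x)` to the mean extension, with
`x = βFr` and `L` the Langevin function.  The sampler is required to match
the oracle within 3 standard errors for `θ`, `C`, `P(g)`, `⟨r²⟩` and
`⟨r_z⟩` across random parameter draws, with and without excluded volume
and force — this is the primary correctness gate.

## Scaling analysis

Force–extension curves are analysed in the two low-force regimes:

* `fit_linear_regime()`: below 0.3 pN, `Lz/(Ml₀) = βF lK/3` with the Kuhn
  length `lK = 2lp − l₀` (fluctuation–dissipation).  A zero-intercept
  weighted fit returns `lK`; consistency with `2lp − l₀` from the
  zero-force run within 15 % is part of the acceptance suite.
* `fit_pincus()`: between 0.3 and 1 pN, `Lz ∝ F^{1/ν−1}`; the log–log
  slope gives the exponent `ν`, with `ν = 1/2` the phantom-chain and
  `ν = 3/5` the swollen-chain limit.  The fit is **unweighted** by
  default: near the top of the window the curve bends towards saturation
  exactly where the extensions are most precise, so `1/SE²` weighting
  concentrates the fit where the power law is weakest and systematically
  inflates `ν` (by ~0.05 for the fully charged chain in our runs).
  Amplitudes are floated per condition.  Fitted exponents outside
  `[0.45, 0.8]` are flagged with a warning rather than silently reported.
* `fit_nu_vs_theta()`: ordinary least squares of `ν = mθ + n`, with `θ`
  taken from the zero-force SGCMC runs.

A known limitation surfaced by these tools: with the reference parameters
at full protonation and `I = 0.001` M, the screening length (9.6 nm) is
comparable to the contour length (19.1 nm) and the electrostatic
persistence length exceeds the chain length (the
Odijk–Skolnick–Fixman estimate `ℓB/(4κ²b²)` with site spacing
`b = 0.39` nm gives ≈ 100 nm), so the chain is effectively a rigid rod:
`√⟨r²⟩ = 18.9` nm at zero force, and the sampled `Lz(F)` reproduces the
exact rigid-rod alignment curve `r L(βFr)` across the whole 0.3–1 pN
window.  The fitted "Pincus" exponent there (≈ 0.65) therefore
characterises rod alignment rather than blob stretching and sits above
the swollen-chain value 3/5; it should be read with that caveat.  At
intermediate charge the window is a genuine stretching regime and the
`ν(θ)` relation is close to linear.

## Numerical choices

* Screened pair energies below 1e−12 kBT are cut off (distance precomputed
  from `ℓB` and `κ`); incremental and full evaluations use the same
  potential, so the consistency check is exact, and the truncation is far
  below every reported uncertainty.
* The geometry construction uses the natural-extension frame (node 1 at
  the origin, first bond along z, second bond in the x–z plane).  When
  consecutive bonds are exactly collinear (a straight rod, `α = 180°`)
  the torsion reference plane is undefined and an arbitrary perpendicular
  is chosen; this cannot occur during sampling with `α₀ = 120°` because
  angle proposals reaching 180° are rejected.
* Contour length: the geometric all-trans extension `M l₀ cos((π−α₀)/2)`
  is the default normalisation for extension curves; the site-based form
  `N l₀ cos((π−α₀)/2)` is also exposed (`contour_length(form =
  "sites")`) because published curves are sometimes normalised per
  ionizable site.  Which convention a given figure used is not always
  decidable; the normalisation never affects fitted exponents.
* Pivot tie-break: at the exact mid-bond the tail arm is rotated.
* Degenerate inputs are errors, not silent fixes: fewer than two sites,
  asymmetric gauche energies, coincident charged sites, non-positive
  separations in the Kirkwood–Shumaker formula, capacitance requested
  from constant-charge samples, enumeration beyond 10⁶ states.

## What the tests show — and what they do not

The test bench runs at desk scale: 10⁵–4×10⁶ attempts and 2–4 replicates
per condition, chains of 2–50 sites (the full production scale of the
underlying study — 5×10⁷ equilibration plus 10⁹ attempts and 8–16
replicates, available via `preset = "full"` — improves only the error
bars, not the estimators).  Exact-enumeration agreement is a sharp
correctness statement for the sampler at small N; titration plateaus,
capacitance extrema, free-chain limits, fluctuation–dissipation
consistency and the stiffening effect of frozen charge fluctuations are
reproduced at N = 50 with desk sampling.  Quantities that mix slowly —
extensions of nearly rod-like chains at low force — carry the largest
residual sampling error.  The model itself omits explicit counterions and
ion condensation, dielectric discontinuities, solvent structure,
tacticity and hydrogen-bond-specific torsional preferences; conclusions
about real titrating polymers inherit the Debye–Hückel level of the
electrostatics.
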