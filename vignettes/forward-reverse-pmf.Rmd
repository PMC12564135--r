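---
title: "Forward–reverse pulling free energies and bilayer observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward–reverse pulling free energies and bilayer observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frpmf)
```

## The problem

Small lignin-derived aromatics — guaiacyl and syringyl units and short
oligomers built from them — adsorb to and insert into ceramide bilayers,
the lipid matrix of the skin's outermost barrier. The central quantity is
the potential of mean force (PMF) ΔU(z) of a solute's centre of mass along
the bilayer normal z: it decides whether a solute sits on the surface,
inserts into the headgroup region, or crosses. Around it sit the standard
trajectory observables that characterise the interaction: distance
distributions from the headgroup plane, number-density profiles across the
interface, solvent-accessible surface area (SASA), hydrogen-bond
statistics, aggregation into clusters, and compact-versus-extended
conformational equilibria.

`frpmf` implements this analysis chain at desk scale. Because all-atom
trajectories of such systems run to microseconds, the package pairs every
analysis with a synthetic generator whose ground truth is known exactly:
one-dimensional overdamped Langevin dynamics of solute centres of mass on
a chosen membrane potential, constant-velocity steered pulls accumulating
mechanical work, and a toy three-dimensional bilayer scene with plantable
hydrogen bonds, clusters and conformer mixtures. Every analyzer is
validated against that generator or an independent analytic/brute-force
oracle.

## The forward–reverse estimator

A harmonic guide of stiffness $k$ moving at constant speed $v$ drags the
solute coordinate from one end of the interval to the other, accumulating
the work $W(\lambda) = \int k(\lambda - z)\, d\lambda$. Under overdamped
dynamics and a stiff spring, work is a function of the guide position
$\lambda$, and the PMF follows from the direction-averaged works alone:

$$\Delta U(z) = \tfrac12\big(\langle W_F(z)\rangle - \langle W_R(z)\rangle\big),
\qquad
W_d(z) = \tfrac12\big(\langle W_F(z)\rangle + \langle W_R(z)\rangle\big),$$

with the dissipated work $W_d \ge 0$ and, in linear response,
$W_d'(z) = \gamma(z)\,v$ with friction $\gamma = k_B T / D$, which is how
`estimate_friction_diffusion()` reconstructs a position-dependent
diffusivity $D(z) = k_B T\, v / W_d'(z)$.

### Why the reverse work must be re-indexed

The subtraction only cancels dissipation when both works refer to the
*same spatial segment*. A forward trace accumulates $W_F$ from the low end
of the interval; a reverse trace accumulates its work from the high end.
`bin_work()` therefore maps a descending trace onto the shared axis as
$W_R(z) = W_{\mathrm{tot}} - W_{\mathrm{cum}}(z)$ — the work spent between
the guide passing $z$ and finishing the pull — which is the reverse work
over the segment $[z_{\mathrm{low}}, z]$. With this alignment the
forward and reverse dissipations over that segment are equal in linear
response for *any* position-dependent friction, so they cancel in
$\Delta U$ and add in $W_d$, and $W_d$ rises from exactly zero at the low
end. The re-indexing is keyed on the traversal sense of each trace; the
$F/R$ *labels* only decide the sign of the subtraction, which makes the
label-swap antisymmetry of the estimator exact (swapping every label
negates $\Delta U$ node for node). Which physical direction is called
"forward" is a labelling convention the estimator does not depend on, so
the package does not impose one.

### Anchoring and errors

$\Delta U$ is shifted so that it vanishes at a chosen anchor (default:
the top grid node, the bulk-adjacent surface end of the protocol);
changing the anchor shifts the profile by a constant only. Standard errors
propagate as $\tfrac12\sqrt{SE_F^2 + SE_R^2}$ from the per-direction
standard errors of the mean work.

## The generators

**Unbiased dynamics.** `simulate_langevin_1d()` integrates the
Euler–Maruyama update
$z \leftarrow z - D\,U'(z)\,dt/(k_B T) + \sqrt{2 D\, dt}\,\eta$ with
reflecting boundaries at the potential's domain edges. The scheme is the
simplest with a controlled step: the package enforces
$dt \cdot D \cdot \max|U''| / (k_B T) < 0.1$ wherever parameters meet a
concrete potential, and `suggest_dt()` returns a step a safety factor
(default 5%) below that bound. Gradients are tabulated on a 4001-point
grid and interpolated linearly in the compiled inner loop; for a
tabulated potential a natural cubic spline supplies a continuously
differentiable interpolant.

**Steered pulls.** `simulate_smd_pull()` adds the moving harmonic guide
and accumulates work by the trapezoidal rule at every integration step.
Initial positions are drawn from the Boltzmann distribution of the
potential restrained by the guide spring at its start — the
reproducible, stiff-spring-consistent counterpart of starting pulls from
a variety of pre-equilibrated configurations. One numerical choice
deserves emphasis: during pulls, the reflecting walls are placed a few
spring lengths *outside* the potential domain, with the gradient
continued by its edge value. If the walls instead coincided with the
traversal endpoints, the restrained particle would start from a truncated
half-Gaussian and drag a spurious, constant work offset of order
$k\,\sigma^2$ through the whole profile (about 0.4 kcal/mol under the
default conditions) — an artefact of the wall, not a feature of the
potential. With the margin in place, the flat-potential null recovers
$\Delta U \equiv 0$ within statistical error.

**Scenes.** `build_bilayer_scene()` realises a two-leaflet slab of
pseudo-lipids (one headgroup nitrogen `NF` per lipid at $\pm$`leaflet_z`,
default 20 Å, plus four chain carbons pointing inward), water pseudo-atoms
filling the outer slabs at a requested number density, and an $m \times m$
lateral grid of solutes whose centre-of-mass heights follow supplied
Langevin paths. The default study shapes mirror the simulated systems:
800 lipids (400 per leaflet) and 3×3 or 5×5 solute grids, i.e.
solute-to-lipid ratios of 1:89 and 1:32. The toy solute is a short
zig-zag chain `O4–C1–…–C6–O9` with a hydroxyl donor on O4; conformers are
realised by an in-plane hinge at the mid-chain atom solved so the O4–O9
end-to-end distance hits the requested modes exactly (defaults 5.5 and
8.0 Å, equal weights — the compact and extended states of the study
solutes). Planted features are exact by construction: requested
hydrogen-bond geometries are emitted at their stated donor–acceptor
distances and H–D–A angles, and planted cluster members are placed with
2 Å centre offsets, which for this template guarantees an any-atom
contact under the default 3.5 Å cutoff.

**Random streams.** Each component (dynamics, scene, planting, pulls)
derives its own named sub-seed from the user's single seed, so fixtures
are bitwise reproducible and stages can be re-run independently.

## What the generator does and does not emulate

The generator produces the *geometry* the analyzers consume — leaflets,
density peaks near ±20 Å, plantable bonds, clusters and conformers — and
the *statistics* of one-dimensional solute motion on a known PMF. It has
no force field, no explicit water hydrogens beyond what bond planting
needs, no lipid internal dynamics, and solute orientation is a static
random rotation. Passing tests therefore demonstrate that the analyzers
and the estimator are correct implementations of their definitions and
that the estimator recovers a known free-energy landscape under the
stated pulling protocol; they do not validate any force field or predict
absolute observables of real bilayers.

## Defaults that matter

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| pull speed `v` | 0.1 | Å/ns | study protocol between bilayer centre (0 Å) and surface (19 Å) |
| spring `k_spring` | 10 | kcal/mol/Å² | guide–particle lag < 0.5 Å at v = 0.1 with D ≥ 50 Å²/ns; not printed in the study, so configurable |
| pulls per direction | 20 | — | "several pulls"; enough for sub-0.3 kcal/mol RMSE under default noise |
| PMF grid | 0.5 | Å | resolves the few-Å features of membrane PMFs |
| PMF anchor | 19 | Å | bulk-adjacent surface endpoint |
| H-bond criterion | 3.5 Å, 30° | — | widely used geometric default; absolute counts are criterion-dependent, so the criterion is always written into the metadata sidecars |
| cluster cutoff | 3.5 | Å | the hydrogen-bond length scale that drives aggregation |
| bins | 0.5 (density), 1.0 (distance), 15° (dihedral) | — | resolve the described features; configurable |
| `kB` | 1.9872041e-3 | kcal/mol/K | fixed constant; units are Å, ns, kcal/mol, K throughout |

## Numerical conventions

* **Histogram alignment.** All uniform binning places bin *centres* on
  multiples of the width, so round planted values (5.5 Å, integer bond
  counts) fall mid-bin and recovery does not depend on floating-point
  tie-breaking at edges. Bins are right-open with the last bin closed.
* **Periodicity.** Minimum-image wrapping applies in x and y only; z is
  non-periodic, matching the slab geometry of the profile axes.
* **Bilayer centre and leaflets.** The centre is the mean z of all
  lipid-species atoms, per frame; leaflet membership is the sign of
  (z − centre), also per frame, so a flip-flopping lipid changes leaflet.
* **COM sign convention.** `com_z_distance()` reports solute COM minus the
  reference-plane mean: negative means inserted below the upper-leaflet
  nitrogen plane.
* **SASA.** Shrake–Rupley with a deterministic golden-section spiral point
  set (default 960 points), so areas are exactly reproducible without a
  seed; occluders default to all non-water atoms. The radius table is
  Bondi-style and configurable; since areas depend on it, it is logged in
  the metadata.
* **Stiff-spring bias.** The estimator recovers the free energy of the
  guide-restrained system; the residual bias is of order
  $(k_B T/2)\,U''/k$ per node (≈0.05 kcal/mol at the defaults), well
  inside the acceptance tolerance. The consistency test uses a stiffer
  spring (k = 40) so the 1/√n statistics dominate.
* **Degenerate inputs.** Zero-step paths return the initial state;
  empty XYZ files are valid zero-frame trajectories; selections naming
  unknown atoms warn and match nothing rather than erroring; single-pull
  directions report `NA` standard errors; non-positive dissipation slopes
  yield `NA` diffusivities, never negative ones.

## Problem sizes

The test and acceptance studies are sized to finish in seconds to a few
minutes on one core while keeping every statistical criterion
well-powered: the double-well recovery uses the full 0–19 Å protocol at
v = 0.1 Å/ns with 20 pulls per direction (≈7 × 10⁶ steps per pull at the
stability-bounded dt); null and diffusivity studies use shorter intervals
at faster speeds with 100 pulls per direction; Langevin physics checks
use 2 × 10⁶-step paths; oracle suites use 100 randomized frames of at
most 300 atoms.

## Known limitations

* The Langevin generator is one-dimensional in the solute COM; lateral
  diffusion, orientation dynamics and solute–solute correlations during
  pulls are not modelled (pulls assume isolated molecules, consistent
  with the low solute-to-lipid ratios of the study systems).
* The FR estimator assumes the stiff-spring, linear-response regime;
  at fast pulls over rough potentials the dissipation subtraction is
  only approximate, and the reported SE does not include the
  spring-convolution bias.
* DCD support is read-only (via `bio3d`); PDB and multi-frame XYZ are the
  round-trip formats.
* H-bond lifetimes/kinetics, lipid order parameters, area per lipid and
  bilayer thickness are out of scope.
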