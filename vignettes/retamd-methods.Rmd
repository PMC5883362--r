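---
title: "Adaptive temperature-accelerated dynamics with soft ratcheting: models, parameters and validation"
author: "retamd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive temperature-accelerated dynamics with soft ratcheting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retamd)
```

## The model

`retamd` simulates the exploration of a receptor surface by a flexible
ligand with temperature-accelerated molecular dynamics (TAMD) extended by
two control mechanisms: a distance-adaptive artificial temperature and a
soft-ratcheting filter on collective-variable targets.

The physical coordinates $x$ (all atoms, receptor and ligand) follow
underdamped Langevin dynamics under the extended potential

$$U_\kappa(x, z) = V(x) + \tfrac{\kappa}{2}\,\lVert \theta(x) - z \rVert^2,$$

where $\theta(x)$ are $N$ collective variables — geometric centers of
ordered ligand atom groups, so each CV is a point in 3-space — and $z$
are their auxiliary targets.  The targets evolve by overdamped Langevin
dynamics,

$$\bar\gamma\,\dot z = \kappa\,(\theta(x) - z) + \sqrt{2\,\bar\gamma\,\bar\beta^{-1}}\,\eta^z(t),$$

thermostatted at the artificial thermal energy $\bar\beta^{-1}$ rather
than the physical $\beta^{-1}$.  When the targets move slowly relative to
the physical relaxation, $z$ samples the free-energy surface $F(z)$
defined at the physical temperature, but at the artificial one — so
free-energy barriers, including the unbinding barrier of a bound ligand,
are crossed much earlier.

Two additions turn plain TAMD into a surface-exploration tool:

* **Adaptive artificial temperature.**
  $\bar\beta^{-1} = k/\min(D) + h$, with $\min(D)$ the smallest
  ligand–receptor atom distance.  Close to the receptor the targets are
  driven hard (promoting escape from the current site); far from it the
  drive decays to the baseline $h$, so a detached ligand is not blown
  away.  The law is strictly decreasing in the distance and is refreshed
  every step from the instantaneous $\min(D)$.
* **Soft ratcheting.**  Each target proposal is scored by the distances
  $D_i$ from each target point $z_i$ to its nearest receptor atom.  If
  at least one proposed $D_i^{\mathrm{new}}$ is smaller than the current
  $D_i$, the proposal is accepted unconditionally.  Otherwise it is
  accepted with probability $\min(1, f_1 f_2 \cdots f_N)$ where
  $$f_i = \exp\!\big[-(D_i - D_i^{\mathrm{new}})^2\big] \big/ \big(c\,D_i^2\big),$$
  with distances entering as Ångström numerics.  Larger $c$ makes
  outward moves strictly less likely (the acceptance probability is
  non-increasing in $c$), which is what keeps short, light ligands from
  drifting off the surface.  The algebraically alternative reading
  $\exp[-(\Delta D)^2/(c D^2)]$ — under which larger $c$ would be *more*
  permissive, contradicting the intended role of $c$ — is available
  behind `ratchet_factor(..., form = "exponent")` but is not the
  default.  On rejection the previous targets are retained for the next
  physical step.

### Discretization

* Physical coordinates: **BAOAB** splitting of underdamped Langevin
  dynamics.  BAOAB gives robust configurational sampling at moderate
  timesteps and reduces exactly to velocity Verlet as $\gamma \to 0$
  with zero noise (the frictionless energy-conservation test in the
  suite relies on this).
* Targets: **Euler–Maruyama**, one target step per physical step.
  Explicit stability requires $\Delta t\,\kappa/\bar\gamma \lesssim 0.1$,
  which constrains how small $\bar\gamma$ may be at a given timestep.
  Notably, a literal combination of $\kappa = 100$ kcal/(mol Å²) with
  $\bar\gamma = 0.02$ ps⁻¹ is not integrable by any explicit scheme at a
  timestep that also resolves the physical system, and would make the
  targets relax toward $\theta$ in $2\times10^{-4}$ ps — faster than any
  physical mode, the opposite of the slow-target regime TAMD requires.
  The toy presets therefore use $\bar\gamma$ in the range 2–25 (internal
  units; see below), chosen once for stability and timescale separation.
* Noise: three independent L'Ecuyer-CMRG substreams (physical noise,
  target noise, acceptance uniforms) derived from one master seed, so a
  ratchet rejection never desynchronizes the physical trajectory, and
  identical seeds give bit-identical trajectories on one platform.

### Units

Lengths are in Å, energies in kcal/mol, masses in amu.  Time is measured
in the reduced unit implied by setting the conversion factor between
kcal/mol and amu·Å²/ps² to one; thermal energies and friction constants
quoted below are numerically interpreted in that system.  The Boltzmann
constant $k_B = 1.9872\times10^{-3}$ kcal/(mol·K) is used only to report
temperatures: $\beta^{-1} = 0.6$ kcal/mol corresponds to $\approx 302$ K,
i.e. 300 K at the resolution the thermostat is usually quoted.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `kappa` | 100 | kcal/(mol Å²) | CV–target spring; large enough that $z \approx \theta$ |
| `gamma` | 2 (1 in toy presets) | ps⁻¹ | physical Langevin friction |
| `beta_inv` | 0.6 | kcal/mol | physical thermal energy ($\approx$ 300 K) |
| `gamma_bar` | 50 (8 in toy presets) | ps⁻¹-equivalent | target friction; sets target mobility |
| `k_adapt` | 40 (pt13) / 30 (pt7, pt3) | Å·kcal/mol | adaptive-temperature numerator |
| `h_adapt` | 10 | kcal/mol | adaptive-temperature baseline |
| `c_ratchet` | 0.02 (pt13, pt7) / 0.7 (pt3) | – | ratchet strictness |
| `dt` | 0.005–0.015 | reduced ps | timestep; resolves the stiffest bond at $\omega\,dt \lesssim 0.15$ |

The three named presets `pt13`, `pt7`, `pt3` bundle the $(c, k, h)$
triples used for 13-, 7- and 3-residue peptides, with 3, 2 and 1
collective variables respectively (contiguous residue blocks).  Shorter
peptides are lighter and drift away more easily, hence the smaller $k$
(weaker near-receptor drive) and, for the 3-mer, a much stricter $c$.
All preset values are ordinary `retamd_params` fields and can be
overridden.

## The synthetic systems

The package is validated entirely on built-in systems; no structure
downloads are required.

**Double well.**  A single particle in
$V(x) = \Delta[(x_1/a)^2 - 1]^2 + \tfrac12 k_t(x_2^2 + x_3^2)$, with the
particle itself as the CV.  `make_double_well()` also returns the
free energy along the CV by numerical quadrature — including, when
`kappa` is supplied, the harmonic mollification
$F_\kappa(z) = -\beta^{-1}\ln\int e^{-\beta[V(x) + \kappa(x-z)^2/2]}dx$
that the target dynamics actually samples, so histogram comparisons are
exact rather than asymptotic in $\kappa$.

**Coarse-grained complex.**  `make_cg_complex()` builds a receptor of
~200 beads harmonically anchored to jittered sites on a 15 Å sphere, and
a ligand chain (3 Å bonds, 1–3 distance springs) laid over a binding
site.  The site mimics a reader domain recognizing one modified residue:
the three receptor beads nearest the central ligand bead (the *probe*,
an acylated-lysine analog) are drawn onto a 3 Å shell around it, forming
a concave cup, and attract the probe through a finite Gaussian well
(depth 3 kcal/mol per pair, width 0.8 Å).  All other receptor–ligand
pairs interact only through a weak background attraction (0.05 kcal/mol)
and a flat-bottom harmonic excluded volume, whose bounded forces keep
the integrator stable even under strong target dragging.  A flat-bottom
spherical restraint at receptor radius + 12 Å contains the ligand.
Ligand partial charges cycle through $\pm 0.45$ and $\pm 0.1$, so polar
and hydrophobic contact classes (and the doubly-classified case) all
occur.

These defaults were fixed by a one-time calibration with three
requirements: (i) the bound state must be stable under plain Langevin
dynamics at $\beta^{-1} = 0.6$ over $10^4$-step runs (realized binding
$\approx 9$ kcal/mol, fifteen thermal energies); (ii) under the
adaptive-temperature presets ($\bar\beta^{-1} \approx 20$–25 near
contact) the probe must leave the site and not re-bind, which requires a
receptor surface large relative to the peptide footprint and low enough
physical drag that the dragged CVs diffuse across the sphere within a
run; (iii) the recapture cross-section of the site must stay small,
hence the narrow recognition well on a single probe bead.  After
freezing, the behavior was confirmed across sixteen seeds: plain
dynamics keeps the site–probe contact fraction above 80% in every run,
and the enhanced runs end with a final-quarter fraction below 10% in
all but one seed (occasional transient re-binding is expected for a
recurrent two-dimensional surface walk at this run length).  Because
the endpoint is stochastic, the validation reports the median over
three independent replicas rather than a single run.

What the toy complex does **not** emulate: solvent and ions, realistic
force-field energetics, sequence-specific interactions, receptor
conformational change, and the rugged multi-pocket topography of a real
protein surface.  Passing the dissociation test therefore demonstrates
that the adaptive-temperature/ratcheting machinery produces the intended
qualitative behavior — controlled unbinding with continued surface
proximity — not that any particular biological contact map would be
reproduced.

## Analysis pipeline

Contacts are receptor–ligand atom pairs strictly below 4 Å (all atoms
participate; no heavy-atom filter).  A pair is *hydrophobic* when both
partial charges satisfy $|q| < 0.2$ and *polar* when the charges have
opposite signs; a pair may be both, either, or neither, and *total*
counts every contact once.  A config switch (`disjoint = TRUE`) makes
the classes mutually exclusive by additionally requiring
$|q| \ge 0.2$ for polar.  Per-residue sums over a trajectory are
rescaled by the largest per-residue total (so the profile lies in
$[0,1]$ with maximum exactly 1 when any contact exists); per-atom counts
are retained and rescaled by the largest per-atom count for hot-spot
detection (thresholds 0.5 and 0.8) and for B-factor surface maps, where
atoms with strictly zero contacts are flagged by occupancy 0.
Site-contact tables report, per binding-site residue, the percentage of
frames with at least one atom pair to a probe residue under the cutoff,
formatted to one decimal place.  Backbone $\varphi/\psi$ dihedrals
follow the right-handed IUPAC sign convention and are computed from
N/CA/C atom naming; chain termini carry no $\varphi$ (first) or $\psi$
(last), and residues with missing backbone atoms are skipped with a
warning.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle:

* **Exact statistics.**  With $\bar\beta = \beta$, no adaptation and no
  ratcheting, the joint $(x, z)$ process samples the Gibbs measure of
  $U_\kappa$ exactly; a $10^5$-step run on an isotropic harmonic
  potential is compared with the closed-form Gaussian covariance
  ($\mathrm{Var}\,x = \beta^{-1}/k$,
  $\mathrm{Var}\,z = \beta^{-1}(1/k + 1/\kappa)$,
  $\mathrm{Cov} = \beta^{-1}/k$) within three batch-means standard
  errors.
* **Free-energy sampling.**  A $10^6$-step target trajectory on the
  double well is binned and compared with
  $\exp(-\bar\beta F_\kappa(z))$ from quadrature; the total-variation
  distance is required below 0.05.  The regime (mass 0.05,
  $\gamma = 10$, $\kappa = 25$, $\bar\gamma = 8$,
  $\bar\beta^{-1} = 10$ — far above the 2 kcal/mol barrier —
  $dt = 0.005$) was chosen so that the physical drag on the CV is small
  against $\bar\gamma$ (physical drag cools the effective CV
  temperature below $\bar\beta^{-1}$, a real and measurable TAMD
  artifact) and the wells exchange hundreds of times per run.
* **Acceleration.**  Fifty paired runs (shared physical-noise stream)
  race the dragged system against plain Langevin dynamics to the barrier
  top of a 4.5 kcal/mol well.  The barrier is 7.5 physical thermal
  energies — spontaneous crossing is Kramers-suppressed beyond desk
  scale — yet only ~1.5 artificial thermal energies, and the win
  criterion is $\ge 95\%$ of pairs.
* **Exact laws.**  The ratchet acceptance frequency over $10^5$ trials
  per tuple matches $\min(1, \Pi f_i)$ within three binomial standard
  errors; the adaptive law reproduces hand arithmetic at the preset
  parameters; contact sets equal exhaustive $O(n^2)$ scans; dihedrals of
  constructed geometries match an independently coded closed form to
  $10^{-6}$ degrees.

`scripts/acceptance.R` repeats these computations end to end from a
single command-line seed and writes the resulting numbers as JSON.

## Numerical notes and limitations

* Distances in the ratchet exponent are bare Å numerics; the formula is
  dimensionally informal by construction.
* The product $\Pi f_i$ is capped at 1 only as a whole, not per factor.
* $D_i$ in the acceptance test is computed from the *proposed targets*,
  not from the post-step CV values, matching the role of the targets as
  the controlled degrees of freedom.
* $\min(D)$ for the adaptive temperature uses physical ligand atoms;
  the per-CV $D_i$ use target points.  Both are nearest-atom distances.
* No periodic boundary conditions; toys run in open space with the
  spherical confinement described above.
* Mass-weighted CV centers, dihedral or contact CVs, constraint
  algorithms, and free-energy estimation from the adaptive runs
  (the method accelerates exploration; it does not produce weights
  suitable for reweighting a free-energy surface) are out of scope.
* The tool-level CLI reads toy systems only; PDB-derived systems are
  driven through the package functions, with structures and charges
  supplied as standard PDB plus a serial-keyed TSV.
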