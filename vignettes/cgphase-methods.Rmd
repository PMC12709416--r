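---
title: "Models and methods behind cgphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cgphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgphase)
```

cgphase studies liquid-liquid phase separation of intrinsically
disordered proteins (IDPs) with a residue-level coarse-grained model,
and provides the analysis stack that turns slab simulations into phase
diagrams, contact statistics and atomistic interaction censuses.  The
motivating system is the *C. elegans* Mutator-focus scaffold MUT-16,
whose disordered C-terminus splits into a client-binding region (M8BR,
residues 633-772) and a foci-forming region (FFR, 773-944), and its
client MUT-8, whose N-terminal prion-like domain is recruited into
MUT-16 condensates largely through arginine-tyrosine contacts.  The
package is, however, sequence-agnostic: any protein with a per-residue
parameter table can be simulated and analysed.

## The energy model

Each residue is a single bead in implicit solvent.  Three terms define
the potential energy:

* **Bonds.** Consecutive beads interact through a harmonic potential
  $U_b(r) = \tfrac{k}{2}(r - l)^2$ with $k = 8368$ kJ mol$^{-1}$
  nm$^{-2}$ and $l = 0.38$ nm.
* **Short-range pair interactions** use the Ashbaugh-Hatch form: below
  the Lennard-Jones minimum $2^{1/6}\sigma_{ij}$ the potential is
  $U_{LJ} + \varepsilon(1-\lambda_{ij})$, between the minimum and the
  2.0-nm cutoff it is $\lambda_{ij} U_{LJ}$, with
  $\varepsilon = 0.8368$ kJ mol$^{-1}$.  The pair parameters are
  arithmetic means of per-residue diameters $\sigma$ and stickiness
  values $\lambda \in [0,1]$; the packaged defaults carry the
  CALVADOS2-style stickiness scale.  The printed equations truncate
  without shifting, so plain truncation is the default;
  `shift_at_cutoff = TRUE` subtracts the cutoff value for
  energy-conservation studies.
* **Electrostatics** are Debye-Hückel screened Coulomb interactions,
  $U_{DH}(r) = f\, q_i q_j \exp(-r/\lambda_D) / (\epsilon_r r)$,
  with screening length 1 nm, relative dielectric 80 and a 4.0-nm
  cutoff — physiological screening.  The molar conversion constant
  $f = 138.935$ kJ mol$^{-1}$ nm e$^{-2}$ makes the expression
  dimensionally consistent in MD units.  Aspartate and glutamate carry
  $-1$ e, arginine and lysine $+1$ e; histidine defaults to neutral
  (`his_charge` is configurable because fixed-pH bead models admit
  either convention), and terminal charges ($+1$/$-1$ e on the first
  and last bead) default on, the convention of this model family.

Bonded (1-2) pairs are excluded from both nonbonded sums.  Forces are
the exact analytic gradients; the test suite verifies them against
central differences at $10^{-6}$ relative tolerance and verifies the
pair-list path against an independently written all-pairs double loop.

## Dynamics

`langevin_run()` integrates Langevin dynamics with the BAOAB splitting
at a 10-fs timestep, which gives accurate configurational averages at
this step size.  Friction defaults to 0.01 ps$^{-1}$ per bead: the
thermostat is then weak and sampling is efficiently diffusive.  The
friction is a free thermostat parameter, not a physical observable; for
*validation of the thermostat itself* the dimer checks use 1 ps$^{-1}$,
because the kinetic-energy autocorrelation time is $\sim 1/(2\gamma)$
and a $10^6$-step run at 0.01 ps$^{-1}$ would leave the kinetic
temperature with a sampling error ($\sim$8%) larger than the 2% band
being verified.  A Verlet neighbour list (0.3-nm skin) is rebuilt
automatically whenever any bead has moved half a skin; list and
brute-force energies agree exactly by construction and by test.

For a harmonically bonded dimer the radial mode carries $k_BT/2$ of
potential energy; the exact equilibrium average with the $r^2$ Jacobian
is 1.2523 kJ/mol at 300 K, 0.4% above $k_BT/2 = 1.2472$, which is why
the acceptance check allows a small band around the equipartition
value.

Initial configurations are grown by `build_slab_system()` as
bond-length random walks with a minimum non-bonded separation.
Production slab runs confine the walks to a central slab
(`slab_thickness`), so coexistence is reached by evaporation from a
dense film rather than by slow droplet coalescence; with a 0.55-nm
packing distance the initial repulsive energy is a few kJ/mol per
contact and the system thermalizes immediately.

## Phase analysis

`z_density_profile()` bins bead mass along the slab axis.  Frames are
first centred: the densest 5-nm window of the mass histogram seeds a
fixed-point refinement with a raised-cosine circular weight, an update
that commutes with periodic translation, so profiles are invariant to
box wrap-around.  `coexistence_densities()` locates the two interfaces
by fitting a symmetric difference-of-tanh front (initialised from the
half-maximum width), then averages the central plateau and the outer
plateau, excluding a buffer of at least 2 nm — widened to four interface
widths when the fitted front is broad — around each interface midpoint.
Flat profiles (contrast below 2x the mean) are flagged as single-phase
and excluded from fitting.  Statistical errors come from block
averaging over five equal trajectory blocks.

`fit_critical_point()` is the package's classic model-fitting surface:
it performs the two-step fit
$\rho_h - \rho_l = B(1 - T/T_c)^{\beta}$ with $\beta = 0.325$ fixed
(3D Ising), then the rectilinear-diameter law
$(\rho_h+\rho_l)/2 = \rho_c + C(T_c - T)$ with $T_c$ held, and returns
a `critical_fit` object with `print`, `summary`, `coef`, `predict` and
`plot` methods:

```{r}
curve <- gen_coexistence_data(Tc = 296, B = 1400, rho_c = 350, C = 2,
                              noise_rel = 0)
fit <- fit_critical_point(curve)
fit
head(predict(fit, c(270, 290)))
```

## Contact maps

`interchain_contact_map()` scores a residue pair as in contact when its
minimum-image distance falls below the cutoff: the pair-specific
$2^{1/6}\sigma_{ij}$ at residue-bead resolution, or a fixed distance
(0.6 nm near-atomic, 0.45 nm atomistic, residue distance = minimum over
constituent atoms) at grouped resolutions.  Binary matrices are
averaged over chain pairs and frames; homotypic maps additionally over
ordered pairs, then symmetrised.  Reductions: `project_1d()` (per
residue), `region_average()` (per region pair, e.g. M8BR/FFR blocks)
and `residue_type_map()` (20x20 amino-acid pairs, normalized by the
number of contributing position pairs or not).

`lambda_contact_correlation()` asks how much of the type-pair contact
statistics is explained by stickiness alone.  Because the model
combines stickiness as an arithmetic mean, the default pair score is
$(\lambda_i+\lambda_j)/2$; the literal product form
$\lambda_i\lambda_j/2$ that sometimes appears in print is
dimensionally odd under this combination rule, so it is kept available
as an explicit option (`score = "product_half"`) and recorded in the
result rather than silently substituted.

## Atomistic interaction geometry

Three detectors act on coordinates of side-chain groups:

* **cation-pi**: charged nitrogen within 6 Å of the aromatic-ring
  centre and ring-centre-to-nitrogen vector aligned with the ring
  normal (|cos| > 0.8).  For arginine all three guanidinium nitrogens
  (NE, NH1, NH2) are candidates and any passing nitrogen counts — the
  charge is delocalised; lysine uses NZ.  Atom lists are configurable.
* **sp2-pi**: guanidinium and ring centres within 8 Å, normals parallel
  (|cos| > 0.8; the absolute value because plane-normal signs are
  arbitrary), and centres displaced 1.5 Å along their normals — each
  oriented toward the partner plane, which detects stacking; orienting
  along fixed normals is exposed as an option — within 4 Å.
* **hydrogen bond**: donor-acceptor distance at most 3.5 Å and
  donor-H-acceptor angle at least 150 degrees, standard MD practice
  (the criterion is not printed anywhere authoritative for this
  pipeline, so it is a documented default); a heavy-atom-only fallback
  serves hydrogen-free structures.

Observations can be assembled directly from atomistic structures with
`pi_frames_from_pdb()` (bio3d-backed multi-model PDB reading, with a
minimal `"chain resno resname"` selection grammar); hydrogen-free
structures fall back to the heavy-atom hydrogen-bond gate.
`interaction_percentages()` reports per-kind percentages over (frame,
pair) observations and the conditional hydrogen-bond percentage
*given* the pair already forms the cation-pi interaction — the
statistic that distinguishes arginine (which can add a backbone
hydrogen bond while stacked) from lysine.  `predict_ion_profiles()`
implements Donnan partitioning: per bin, local electroneutrality plus a
fixed activity product $c_+ c_- = c_0^2$ yield closed-form small-ion
concentrations from the local charged-residue concentrations, so a
net-positive condensate accumulates anions.

## Synthetic data and what passing tests mean

Every analysis stage has a generator producing inputs with known ground
truth: homopolymer systems (`make_homopolymer()`,
`homopolymer_system()`), coexistence curves drawn exactly from the
scaling law (`gen_coexistence_data()`, defaulting to the scaffold's
296-K critical temperature and a dense branch near 800 mg/mL),
contact-structure trajectories (`gen_contact_fixture()`), and
pi-geometry fixtures with closed-form labels (`build_pi_fixture()`).
All generators are seed-deterministic.

`gen_contact_fixture()` deserves a note: an arbitrary binary contact
pattern is not always realisable as 3D coordinates, so the generator
places chains constructively (spaced scaffold, per-column attachment),
refines with a penalty relaxation that moves both endpoints, and
verifies the realised pattern by brute force.  When a placement fails,
*coordinates* are redrawn — never the contact states, which would bias
the empirical map — and a packing error is raised only after bounded
restarts.

The generators emulate the geometric and statistical structure the
analyses assume — known plateaus, known contact probabilities, known
interaction geometry.  They do not emulate force-field realism,
sequence heterogeneity of real proteins, or finite-size effects of
production slabs; a passing suite therefore certifies the machinery
(energies, integrator, estimators, detectors), not the biological
accuracy of any particular parameter set.

## Problem sizes and numerical choices

Desk-scale study conditions, used throughout the tests: 10 chains of 50
beads in a 10 x 10 x 60 nm slab for the stickiness contrast (a
λ = 1.0 homopolymer at 260 K condenses to a peak local density more
than 5x the box mean; λ = 0.1 does not), 100,000 steps (1 ns) with the
second half analysed, three seeds.  The dilute-branch temperature scan
uses 25 chains of 10 beads at 250-350 K: short chains have a
desk-measurable vapor pressure, whereas 50-mers at λ = 1.0 barely
evaporate below 500 K.  The production protocol of the underlying study
(100 chains of the 312-residue construct, 20 x 20 x 280 nm, 10 μs,
temperature ladder 260-300 K) is the cluster-scale configuration the
same code paths support.

Other numerical choices: overlapping beads (r below $10^{-6}$ nm) raise
a singularity error rather than returning infinities; non-finite
coordinates abort a run with the step index; the critical fit bounds
$T_c$ above the highest fitted temperature and refuses curves with
fewer than three phase-separated points; interface fits that wander out
of range fall back to the half-maximum estimate; residue-type pairs
absent from the sequences are NA, never divided by zero.

## Known limitations

* The dilute-phase densities of strongly sticky desk-scale systems are
  upper bounds dominated by interface tails; production-scale slabs are
  required for quantitative saturation concentrations — expect the
  model family's documented one-to-two order-of-magnitude deviation
  from experimental values on top.
* The packaged stickiness table is a bundled convenience; quantitative
  work on a real protein should supply the authoritative parameter
  file via `load_parameter_table()`.
* No finite-size-scaling correction is applied to $T_c$ and the
  critical exponent is never fitted.
* Region boundaries for the scaffold default to FFR = 773-944, the
  simulated and purified construct; the 945 endpoint that appears in
  some descriptions is available via `mut16_regions(ffr_end = 945)`.
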