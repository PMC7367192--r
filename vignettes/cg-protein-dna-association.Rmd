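---
title: "Coarse-grained models and kinetics of protein-DNA association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained models and kinetics of protein-DNA association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cgbind` models the diffusional association of a small, positively charged
protein domain with short double-stranded DNA.  The motivating system is the
A1 domain of von Willebrand factor (vWF), a blood protein whose A1 domain
(net charge +6 e) binds ds DNA through an arginine triad
(R1392/R1395/R1399 on helix H4), with a secondary arginine (R1336) and an
adjacent lysine patch (K1405-K1408) playing minor roles.  The package
provides, end to end:

* coarse-grained (CG) structure builders for ds DNA and proteins,
* screened-electrostatics energetics,
* an overdamped Langevin (Brownian) dynamics engine with rigid bodies,
* rigid-body Brownian-dynamics (BD) docking and a
  Northrup-Allison-McCammon (NAM) association-rate estimator,
* trajectory/pose analysis (contacts, occupancy densities, DNA bending,
  RMSF, resampled Kolmogorov-Smirnov comparisons), and
* closed-form and fitted binding kinetics (first-order association fits,
  diffusion-limited encounter times, binding isotherms,
  counterion-condensation regression, two-component FCS fits).

Everything runs from synthetic inputs: an ideal B-DNA generator, a mock
A1-like helical bundle, planted trajectories for testing the analysis
machinery, and parametric datasets for validating the fits.

# The coarse-grained models

## DNA: a rigid base-pair chain with explicit phosphate charges

Each base pair is one rigid unit: a neutral core bead (radius 0.8 nm) on the
helical axis plus its backbone phosphate beads (radius 0.25 nm, charge -1 e,
at 0.9 nm from the axis).  Phosphates sit on internucleotide linkages, so a
duplex of N base pairs carries exactly 2(N-1) phosphates — there are no
5'-terminal phosphates — giving the 42-bp fragment its net charge of -82 e.

Consecutive units interact through a quadratic energy in six step
coordinates.  The displacement of the next origin is expressed in the
current base-pair frame (shift, slide, rise) and the relative rotation is
parameterized by its rotation vector (tilt, roll, twist), i.e. the SO(3) log
map.  This mid-frame-free variant of the usual base-pair step convention was
chosen because its forces and torques are available in closed form through
the inverse right Jacobian of the log map; the test suite verifies them
against central finite differences to 1e-6.

Default step parameters (`bp_step_params()`):

| parameter | default | rationale |
|---|---|---|
| rest rise | 0.334 nm | canonical B-DNA |
| rest twist | 36 deg | canonical B-DNA |
| tilt/roll stiffness | Lp kT/h with Lp = 50 nm | bending persistence length of B-DNA; the analytic calibration k = Lp kT/h is verified by simulation (tangent-correlation fit) |
| twist stiffness | C kT/h with C = 100 nm | torsional persistence length of B-DNA |
| shift/slide/rise stiffness | 2000 kJ/mol/nm^2 | ~0.035 nm thermal fluctuations, the scale of B-DNA step displacement variability |

When fitting the tangent-tangent correlation to extract the realized
persistence length, the s = 1 neighbour pair is excluded: tangents estimated
from origin differences carry white noise from the shear (shift/slide)
fluctuations, which biases only the first correlation point.

## Protein: one bead per residue on an elastic network

Residues become beads of radius 0.35 nm at the alpha-carbon position, with
integer charges (Arg/Lys +1 e, Asp/Glu -1 e, His configurable, default 0,
termini uncharged — the protonation convention behind the +6 e net charge of
A1 at neutral pH).  All bead pairs within 1.0 nm are connected by springs of
stiffness 500 kJ/mol/nm^2 at their observed distances, the standard
elastic-network regime that keeps a Rossmann fold effectively rigid.  In
two-molecule simulations the protein is treated as a single rigid body by
default (`sim_config(rigid = ...)` exposes the choice), which is consistent
with the fold's rigidity and is an order of magnitude cheaper.

## The mock A1 domain

`generate_mock_a1()` builds a four-helix bundle spanning author residues
1325-1419 whose charged surface mimics A1: the arginine triad packs as a
contiguous patch on one helix (pairwise distances < 1.5 nm), the lysine
patch sits on the same helix below the triad, R1336 lies on the N-terminal
segment more than 2.5 nm from the triad centroid, and two distal glutamates
tune the net charge to +6 e.  The generator validates all of these
constraints and fails rather than emit a structure violating them.  The mock
reproduces the charge anisotropy that drives electrostatic steering; it does
not reproduce A1's fold, loops or shape beyond that.

# Energetics

Inter-molecular bead pairs interact through

* a Debye-Hueckel screened Coulomb term in point-charge form,
  E = ke q1 q2 exp(-kappa r) / (eps_r r), truncated at five Debye lengths
  and shifted to zero there (truncation error below thermal noise), and
* a purely repulsive WCA soft sphere that vanishes at bead contact
  (sigma_ij = (r_i + r_j) 2^(-1/6), eps = 1 kJ/mol).

Binding in this model is therefore electrostatics-driven by construction:
the short-range term only enforces excluded volume.  Intra-molecular
nonbonded interactions are not applied (DNA self-avoidance is irrelevant at
these fragment lengths; protein shape is maintained by the network or by
rigidity).  Interaction energies decompose into `coulomb` and `short_range`
parts; at 0.15 M the screened Coulomb well of a docked complex is a few
kJ/mol, which is the appropriate scale for a screened ion-pair lattice — it
should not be compared with unscreened force-field Coulomb sums, which are
two orders of magnitude larger.

# Dynamics

The integrator is the Ermak-McCammon overdamped update: drift beta D F dt
plus Gaussian noise of variance 2 D dt per degree of freedom, with isotropic
translational and rotational diffusion for rigid bodies (rotation via the
exponential map, re-orthonormalized every step).  Defaults: dt = 1e-3 ns;
Stokes-Einstein diffusion coefficients at the simulation temperature
(protein hydrodynamic radius 2.0 nm, base-pair unit 1.0 nm, rigid DNA uses
rod formulas); deterministic, bit-reproducible noise streams per seed.

All dynamic simulations default to physiological temperature (310.15 K)
with the matching water viscosity (Vogel equation) and permittivity
(Malmberg-Maryott), the conventional condition for blood-protein systems;
the electrostatic parameter set doubles as the thermostat, so the two
temperatures are kept consistent.  Stand-alone energetic calculators default
to the 298.15 K / eps_r 78.5 textbook convention.

Association campaigns start the two molecules at a 6 nm centre-of-geometry
separation with uniformly random orientations (rejecting initial overlaps),
inside a reflecting sphere of radius 22.5 nm whose volume defines the
molecular concentration, [C] = 1/(N_A V) = 3.5e-5 M — the dilute,
single-pair regime the reference association experiments used.  First
contacts are detected at every integration step as the minimum
inter-molecular surface-to-surface bead distance falling below 0.6 nm, the
CG transcription of the usual atomistic minimum-atom-distance criterion.

# BD docking and the NAM rate

Docking treats both molecules as rigid.  Trajectories start on a b-surface
(15 nm centre-to-centre, beyond five Debye lengths plus the molecular
extent), move with adaptive time steps (large in the force-free far zone,
capped at 0.02 ns near contact), and terminate on reaction or on crossing
the q-surface.  The default q is 30 nm: because the NAM recrossing
correction makes the estimator independent of q wherever the interaction
potential has decayed (U(30 nm)/kT < 1e-14 at 0.15 M), the shorter escape
leg buys a several-fold speedup at no cost in expectation.  Along each
trajectory the minimum-interaction-energy configuration is recorded (one
encounter per trajectory — a coarser but equivalent variant of recording
every deep local minimum); `bd_dock()` returns the `n_select` lowest-energy
poses, and `cluster_poses()` groups them by ligand-displacement RMSD
(average-linkage hierarchical clustering, cut either at a 1.0 nm height or
into a fixed number of clusters) with the lowest-energy member as each
cluster's representative.

The NAM estimate is kon = k_D(b) beta_inf, with k_D from numerical
quadrature of the Smoluchowski-Debye integral over the net-charge screened
Coulomb potential, and beta_inf = beta / (1 - (1 - beta) k_D(b)/k_D(q)) the
recrossing-corrected reaction probability.  The reaction criterion is
config-exposed; the package default counts distinct protein residues in
ion-pair contact with phosphates (surface distance <= 0.75 nm, >= 2
residues), the CG analogue of the polar-atom contact lists atomistic BD
tools use, optionally restricted to a native binding face
(`reaction_residues`).

## Known limitation: the rate sits at the diffusion-limited ceiling

At CG resolution with isotropic beads, a captured protein dwells near the
-82 e rod and reorients many times before escaping, so essentially every
diffusional collision eventually satisfies any contact-based reaction
criterion: a sensitivity scan over 2-4 required residues, 0.15-0.75 nm
contact distances, and binding-face restriction moves beta only from 0.22 to
0.16.  The NAM estimate therefore reproduces the diffusion-limited collision
rate onto the rod (~1e10 M^-1 s^-1, i.e. 4 pi D R_eff with an effective rod
capture radius of ~4 nm) rather than the roughly one-order-of-magnitude
lower stereospecific complex-formation rate that atomistic-resolution BD
yields for this system.  The estimator itself is exact: in the neutral
touching-spheres limit it matches the Smoluchowski closed form to 1e-4.
Recovering reaction-probability selectivity would need orientation-dependent
short-range terms (desolvation, shape complementarity) that are outside this
model.

# Analysis

* **Contact profiles** — per-residue and per-base-pair fractions of frames
  with any inter-molecular surface distance below 0.6 nm.
* **Region classification** — each frame is assigned to exactly one of
  {region 1 (triad), region 2 (R1336), both, lysine patch, other, none};
  arginine regions take precedence over the lysine patch so the categories
  partition the frames.
* **Occupancy densities** — frames are least-squares superposed on the
  reference molecule (Kabsch, proper rotations only) and partner beads are
  binned on a 0.2 nm grid, then z-normalized to sigma units (grid mean 0,
  standard deviation 1; no smoothing).
* **DNA bending angle** — the angle between the first principal axes of the
  base-pair origins of the two fragment halves, each axis oriented along
  the chain.  This half-fragment-axis estimator was chosen because, for a
  42-bp chain at Lp = 50 nm, its modal angle falls in the
  experimentally-reported ~20 degree range; the distribution mode is
  estimated by a kernel density maximum.
* **RMSF** — per-bead root-mean-square deviation from the mean position
  after optional superposition onto the first frame.
* **Resampled KS test** — repeated subsampling without replacement with the
  two-sample KS test (asymptotic or exact two-sided p as `ks.test`
  chooses), reporting the fraction of rounds with p >= alpha; used to ask
  whether bound and unbound bending-angle ensembles differ.

# Binding statistics

* `fit_kon()` fits 1 - exp(-kon [C] t) to the empirical cumulative
  association curve evaluated on a uniform time grid over the full run
  length (fitting only at event times over-weights the early burst of a
  non-exponential first-contact distribution); a censored-exponential
  maximum-likelihood alternative is provided.
* `encounter_time()` evaluates the diffusion-controlled rate
  k = 4 pi D_rel / Int_a^Inf exp(U(r)/kT) r^-2 dr by quadrature and converts
  it at concentration C to tau = 1/(k C).
* `fit_isotherm()` fits the general 1:1 binding isotherm (amplitude and
  offset co-fitted, optional Hill exponent) by weighted Levenberg-Marquardt
  least squares; degenerate and non-saturating titrations are flagged, not
  silently fitted.
* `counterion_regression()` regresses log10 Ka on log10 salt; the slope
  estimates the number of counterions released on binding.  The salt axis is
  molar; that choice affects only the intercept, never the slope.  Note that
  an unweighted fit of three titration points spanning 20-60 mM gives a
  slope near -4.5; error-weighted fits of the same points can steepen the
  slope, so both modes are available.
* `fit_fcs_two_component()` fits
  G(tau) = (1/N)[(1 - f) g(tau; tauD1) + f g(tau; tauD2)] with the
  3D-Gaussian-volume decay g, the fast diffusion time and aspect ratio held
  fixed, and f constrained to [0, 1]; a fitted tauD2 <= tauD1 is flagged
  unidentifiable.

## The point-charge encounter-time estimate

For +6 e and -82 e point charges at [C] = 3.5e-5 M the quadrature gives
two sharply different answers depending on screening.  With the full
Debye-Hueckel potential at 0.15 M, screening removes the attraction beyond
~4 nm and tau is a few microseconds for any plausible radii/diffusion
parameters — the ionic atmosphere almost completely hides the charges from
each other at encounter distances.  In the unscreened Coulomb (Debye) limit
the attraction is enormous (Onsager radius ~350 nm) and tau drops to tens
of nanoseconds, the scale actually observed for first contacts in the
association campaigns (where the molecules start a few nanometres apart and
screening hardly matters).  `encounter_params_s3()` therefore declares, as
this package's substitute for the original point-charge calculation, the
unscreened limit at physiological temperature with Stokes-Einstein radii of
2.0 and 2.6 nm and a 4.6 nm contact distance; `scripts/acceptance.R` and
the test suite compute tau from it at run time.

# The synthetic-data generators

`generate_bdna()` emits the minimum-energy (ideal, straight) conformation
of the rigid base-pair chain for any sequence; the CG topology is
sequence-independent by design, matching the observed
sequence-independence of the binding.  `generate_planted_trajectory()`
realizes exact contact schedules by end-on placement of the DNA along a
target residue's outward normal and verifies the realized schedule frame by
frame — infeasible schedules (e.g. a single helix residue that cannot be
touched without its neighbours at CG bead sizes) raise an error instead of
silently approximating.  `generate_datasets()` samples from exactly the
generative models the fits assume, so noiseless round trips recover ground
truth to numerical precision and noisy recoveries quantify estimator
variance, not model mismatch.

What passing these tests shows about real data is deliberately limited: the
generators share the fits' assumptions (i.i.d. Gaussian noise, single-site
isotherms, two-component FCS).  They validate the estimators, not the
models' adequacy for any particular instrument's output.

# Problem sizes and numerical choices

The validation suite and the acceptance script use desk-scale campaign
sizes chosen as the package's own defaults: 3e6 Langevin steps (3 us) for
the free-DNA bending distribution; 42 association replicas (the size of the
reference campaign) of up to 50-210 ns; 5e3 BD docking runs for rate
estimates and a few hundred for pose sets.  Other numerical choices:
nonbonded cutoff at five Debye lengths with energy shift; docking time step
adapted as dt = gap^2/(32 D) between 1e-3 and 0.5 ns (0.02 ns cap inside
the interaction zone); per-trajectory step cap of 3e5 (runs hitting the cap
count as escapes and are rare); quadratures by adaptive `integrate()` with
the Boltzmann exponent clamped at 700 to avoid overflow on steep repulsive
barriers.

# Limitations

* No hydrodynamic interactions, explicit ions, polarizability or dielectric
  boundaries; electrostatics is pairwise screened Coulomb.
* The NAM reaction probability is capture-dominated at this resolution (see
  above), so absolute docking-rate estimates sit at the diffusion-limited
  ceiling.
* The mock protein reproduces charge topology, not fold geometry; analyses
  that depend on surface shape (e.g. groove complementarity) are outside
  scope.  One visible consequence: bound DNA partially wraps the compact
  bundle, skewing the bound bending-angle distribution upward by ~8-9
  degrees in the median — the same direction as, but stronger than, the
  mild skew expected for the full-size domain — so bound/unbound bending is
  "moderately shifted" here rather than statistically indistinguishable.
* Sequence effects enter only through fragment length; base-pair step
  stiffness is sequence-averaged.
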