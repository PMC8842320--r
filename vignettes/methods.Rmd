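---
title: "A coarse-grained model of sliding zwitterionic monolayers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of sliding zwitterionic monolayers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The physical model

`ionoslip` simulates the boundary-lubrication contact between two
monolayers of zwitterionic head groups, the kind of interface formed when
two polymer vesicles with hydrophilic, locally charged chain terminations
are pressed together in a surface force apparatus (SFA).  All shear
localises in the plane where the two exposed head-group carpets meet, so
the model keeps only that region:

* Two rigid triangular lattices of beads (node spacing a/2 = 0.41 nm)
  stand in for the hydrophobic interiors: the bottom layer (SUB) is frozen,
  the top layer (SUP) translates as one rigid body with three degrees of
  freedom.  It carries the normal load and, during measurements, the
  pulling spring.
* On one lattice node in four (the molecule sublattice, spacing
  a = 0.82 nm, i.e. 1.72 molecules/nm^2), a seven-bead chain is planted:
  cation CA (+q), three neutral residues R1-R3, anion AN (-q), and two
  neutral non-polar beads NP1, NP2 that anchor the chain to its layer.
  q = 0.25 e in the zwitterionic system and 0 in the charge-free control.
* To avoid artificial perfect commensuration of the two contacting
  lattices, the layers are rotated by plus and minus phi/2.  The rotation
  and the rectangular periodic cell must be *commensurate*: the cell must
  be a lattice vector pair of both rotated lattices.

## Commensuration

For a triangular lattice of spacing a, the integer vector u = m a1 + n a2
(|u|^2 = a^2 K with K = m^2 + mn + n^2) always admits the perpendicular
partner w = (-(m+2n), 2m+n) with |w| = sqrt(3)|u|; rotating the lattice so
that u lies along x gives an exact (zero-strain) rectangle.  Because the
triangular point set is mirror-symmetric about a lattice direction, the
same rectangle fits the mirror lattice rotated by -phi/2.
`find_commensurate_supercell()` enumerates all such cells in an angle
window; perpendicular partners shorter than sqrt(3)|u| are found too when
K has a factor of 3 (the K = 21 cell, for instance, is the K = 7 rectangle
in the other orientation).

The construction is not unique: several commensurate cells can coexist in
one angle window, so the search accepts `target_dims` to select a
reference cell quoted by its size.  The reference system used throughout
is the K = 103 cell, u = (9, 2): phi = 19.653 degrees, 8.322 x 14.414 nm,
206 molecules and 824 rigid beads per layer (4532 particles).  The
desk-scale fixture is the smallest rotated cell, K = 7 (u = (2, 1)):
2.170 x 3.758 nm, 14 molecules per layer, 308 particles, with an effective
misalignment of 21.8 degrees (38.2 degrees is equivalent under the
six-fold lattice symmetry).

## Force field

Energies in eV, lengths in nm, time in ps, masses in a.m.u.
(1 eV nm^-2 = 0.16022 N m^-1).

* **Bonds**: E = k/2 (r - r_eq)^2 with the tabulated stiffness the literal
  second derivative; k_bond = 480 N/m for all chain bonds, r_eq = 0.16 nm
  except the NP1-NP2 bond at 0.67 nm.
* **Angles**: E = k/2 (theta - theta_eq)^2; all equilibrium angles are
  180 degrees except AN-NP1-NP2 at 111 degrees (an sp3-like kink that
  keeps the heads tilted off vertical).  The angle stiffness is not part
  of the printed parameter set.  The package default is
  k_angle = 10 eV rad^-2, calibrated against the model's reported
  observables: at 3 eV rad^-2 the chains are so floppy that hooking at
  300 K almost vanishes (h ~ 1%, rho_Uh ~ -0.1, far from the reported
  ranges), while at 30 eV rad^-2 the contact locks rigidly; 10 eV rad^-2
  reproduces stick-phase hooking fractions of tens of percent and a
  steady U-h anticorrelation around -0.6, in line with the reference
  behaviour.  The value is exposed in the configuration.
* **Morse pairs**: M(r) = D0[(1 - e^{-alpha(r - r0)})^2 - 1] with
  alpha = 15 nm^-1 and cutoff Rc = 1 nm globally, with a shift and linear
  tail, V(r) = M(r) - M(Rc) - (r - Rc) M'(Rc), so V(Rc) = V'(Rc) = 0
  exactly.  The default well is (0.010 eV, 0.41 nm); NP beads bind their
  own rigid layer and like NP beads of neighbouring molecules with 5 eV
  wells; cross-layer interactions are restricted to the polar heads
  (CA, R1-R3, AN), and the SUB-SUP rigid pair is masked to zero.
  Intramolecular 1-2, 1-3 and 1-4 pairs are excluded from pair terms (the
  common MD default); the intramolecular CA-AN (1-5) pair interacts.
* **Electrostatics**: Coulomb within Rc is evaluated directly in real
  space (erfc-damped); beyond Rc it is carried by a classical Ewald
  reciprocal-space sum over a 3D-periodic box with vacuum padding
  (three slab thicknesses of vacuum by default) and the Yeh-Berkowitz
  dipole slab correction for the 2D-periodic geometry.  The splitting
  parameter and the k-space cutoff are derived from a force-accuracy
  target of 1e-4 eV nm^-1; the test suite verifies the total against a
  Richardson-extrapolated direct lattice sum on small charge clusters.

### Anchoring (a completion of the published parameter set)

With only the interactions above, the terminal NP1-NP2 pair can rotate
about its own axis onto the rigid plane at **zero** bonded-energy cost
(the whole chain pivots; no angle leaves its equilibrium), and both NP
beads then gain several eV of additional rigid-bead Morse contacts in
hollow sites.  The measured consequence is a collapsed brush: interlayer
distance 1.5 nm and 100% interpenetration, instead of the ~2.7-3 nm
standing brushes the model is meant to produce.  The original model keeps
the pair "planted" and near-vertical; the detailed terms live in
supporting material that is not part of the printed description.  The
package therefore completes the force field with triangulated anchoring
tethers: each NP bead is harmonically bonded (k = 480 N/m) to the rigid
bead at its anchor node and to two ring neighbours of that node
(~120 degrees apart), with rest lengths equal to the as-built distances.
Three non-collinear tethers pin position and verticality while leaving
thermal-scale elastic freedom (RMS displacement ~0.05 nm at 300 K).  The
head section above NP1 remains governed solely by the printed terms.

## Dynamics

Velocity-Verlet integration at dt = 1 fs (the stiffest bond, 480 N/m on a
15 a.m.u. bead, is resolved by ~45 steps per period).  Molecule beads feel
a Langevin thermostat with gamma = 1 ps^-1 acting **only along y and z**,
so no thermostat damping biases the sliding direction x.  The noise is
counter-based (a splitmix64 hash of seed, step and particle feeding an
inverse-normal map), which makes runs bit-reproducible and restartable
mid-run without RNG state files.  The SUB layer is exactly frozen; the
SUP layer moves as one rigid body of mass equal to the sum of its beads
(rigid beads are assigned 50 a.m.u.; this only affects inertial
transients).  The load L (MPa) enters as a constant force -L A on the SUP
body; the drive is either a prescribed x velocity (running-in) or a
spring k = 1 eV nm^-2 anchored to a stage advancing at v_stage, with the
instantaneous shear stress k (x_stage - x_SUP)/A.

The integrator evaluates Morse and real-space Coulomb terms through cubic
Hermite tables (value and derivative at the nodes), so the interpolated
force is exactly the derivative of the interpolated energy; energy
conservation is not degraded (measured NVE drift: < 1e-5 eV per bead over
100 ps from a quenched state) while the inner loop carries no
transcendentals.  The reciprocal-space forces vary slowly and are
refreshed every `kspace_every` steps (default 5 in run plans; the cached
forces are reused in between).  For production runs the electrostatics
accuracy may be relaxed to 1e-3 eV nm^-1: the Langevin noise forces at
300 K are of order 5 eV nm^-1, three and a half orders of magnitude
larger.

## Protocol

An experiment is: running-in at constant SUP velocity under load and
temperature (default 10 nm of travel at reference scale; desk-scale runs
use ~0.5 nm), then attach the spring at the current SUP position and
advance the stage (100 nm at reference scale; 2-3 nm desk scale).  The
steady average discards at least `discard_nm` of stage travel and, in
stick-slip, at least the first slip event.  Slip events are stress drops
of at least half the preceding local maximum, completed within 1 nm of
stage travel, with an absolute drop of at least 0.5 MPa (to ignore
thermal ripple on low-stress smooth traces); stick-slip requires at least
two events.  A load cycle runs consecutive legs at a sequence of loads,
continuing the dynamic state, and reports loading/unloading means and
their difference (hysteresis) per revisited load.

## Initial configuration

Chains start near-vertical: NP2 at the Morse minimum above its node, NP1
one long bond further, the head tilted by 69 degrees (the 111-degree kink)
with all kink azimuths aligned along +y -- the regularly spaced initial
configuration of the model.  A disordered (random-azimuth) start is
available but not the default: at 150 K the random start cannot anneal to
the Coulomb-ordered flat state on desk timescales and leaves an
artificially interlocked glass.  The initial gap between the opposing CA
planes is 0.5 nm; the steady interlayer distance is then set by load and
temperature during running-in.  If clashes below 0.25 nm remain in a
random start (alpha = 15 nm^-1 makes such contacts eV-hot), azimuths are
resampled stochastically and persistent offenders straightened slightly,
never enough to breach the interlayer gap.

## What the desk-scale fixture does and does not show

The 14-molecule cell preserves the misaligned contact, the areal density,
the force field and the driving protocol.  It reproduces the
high-temperature *mechanism* faithfully: thermally activated hooking and
stick-slip at 300 K, with the hooking fraction spiking to tens of percent
during sticks, deep slips (stress dropping to a third of the peak or
less), and a clearly negative U-h correlation (rho_Uh around -0.66).  It
also reproduces the charge-free control's wider interlayer spacing and
deep stick-release events at 150 K, the weak load dependence across
0-20 MPa without hysteresis beyond the fluctuation bars, and the
chain-layer compression under load.

What it does **not** reproduce is the low-temperature *smooth*,
low-friction state of the zwitterionic system.  At 14 (and also 42)
molecules per layer the flat ordered layers still pin, with static
friction thresholds of ~30-40 MPa: the per-molecule interfacial
corrugation does not average out over so few moire registries, and the
azimuthally soft heads can lock individually into opposing hollows (the
strong-pinning regime of incommensurate contacts).  The reference
low-temperature state -- mean stresses well below 1 MPa -- emerges only
at the full 206-molecule contact.  Consequently the low-temperature
smooth-sliding check in the shipped acceptance tests records the
full-size expectation and fails at desk scale, deliberately: treating it
as a property of the small fixture would misrepresent the model.  Mean
stresses at desk scale generally carry large finite-size and finite-time
fluctuations, and collective slips are more abrupt than at reference
scale.  Full temperature and velocity sweeps (the friction peak near
800 K, the critical velocity around 5 m/s at 150 K) are cluster-scale
computations; the sweep runner supports them, and `critical_velocity()`
implements the bracketing estimate, but the shipped tests exercise those
only on synthetic regime labels and reduced runs.

## Numerical choices

* Timestep 1 fs; neighbour-list skin 0.1-0.3 nm with displacement-based
  rebuilds (half-skin criterion); boxes smaller than twice the list
  cutoff are handled with explicit multi-image pair shifts, and box edges
  below the cutoff itself add constant self-image energies (zero force).
* Ewald: alpha from erfc(alpha Rc) matched to the accuracy target (with
  an 8x margin for the neighbour-count prefactor), k-cutoff
  2 alpha sqrt(-log eps) with a 1.2 safety factor; vacuum padding three
  slab thicknesses; dipole slab correction.
* Harmonic angle forces near 180 degrees use the standard clamped-sine
  formulation (the force prefactor (theta - theta0)/sin theta is regular
  in the limit).
* Tie-breaks in the supercell search: smallest area first, then the angle
  closest to the window centre; `target_dims` overrides.
* Degenerate inputs fail loudly: zero-length bonds, coincident angle
  beads, overlapping charges, incommensurate cells, non-finite
  coordinates (the integrator returns the partial trace).

## Known limitations

* No solvent, no electrostatic screening beyond the reduced charges, no
  vesicle curvature or roughness: the model addresses the idealised flat
  contact only.
* The SUP body translates but does not rotate; no barostat acts on the
  gap (the interlayer distance is an emergent observable).
* The anchoring tethers and the angle stiffness are completions of the
  published parameter set (see above); both are configuration-exposed and
  their values documented rather than fitted.
* The hooking fraction uses the opposing layer's mean CA plane with zero
  margin by default (an AN-plane variant is selectable); its precise
  original definition is not part of the printed description.
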