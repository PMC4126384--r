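---
title: "Multi-scale white-matter micromechanics with axonrve: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale white-matter micromechanics with axonrve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Axons in central-nervous-system white matter are undulated (tortuous)
fibers embedded in a compliant glial/extracellular matrix (ECM).  Under
tissue-level tension they first straighten largely independently of the
matrix (non-affine kinematics) and progressively couple to it as stretch
increases (affine kinematics).  This strain-dependent coupling shapes both
the axon-level strains thought to drive axonal injury and the tissue-level
stress-stretch response.  `axonrve` implements the full pipeline needed to
study this numerically and to identify the axon shear modulus from a
measured tension curve:

1. a randomized pseudo-3D representative volume element (RVE) of undulated
   axons in a cuboid ECM domain (`build_rve()`),
2. a transitional kinematic model (TKM) of stretch-dependent fractional
   axon-matrix coupling (`coupling_rule()`, `update_coupling_state()`),
3. a total-Lagrangian hyperelastic finite element solver for staged
   uniaxial tension (`staged_simulation()`), and
4. inverse identification of the axon shear modulus by golden-section
   search on the squared stress-stretch error
   (`identify_shear_modulus()`, `sensitivity_scan()`).

Units are micrometres, kilopascals and kPa·um² throughout.

## Constitutive model

Both phases are isotropic one-term Ogden solids.  With principal
stretches $\lambda_i$, $J = \lambda_1\lambda_2\lambda_3$ and isochoric
stretches $\bar\lambda_i = J^{-1/3}\lambda_i$,

$$W = \frac{2\mu}{\alpha^2}\left(\bar\lambda_1^\alpha + \bar\lambda_2^\alpha
      + \bar\lambda_3^\alpha - 3\right) + \frac{\kappa}{2}(J-1)^2 .$$

$\mu$ is the shear modulus (kPa) and $\alpha$ the dimensionless
nonlinearity; the defaults $\mu = 32.8$ kPa and $\alpha = 8.22$ are the
values fitted to embryonic chick spinal-cord tension data, and the axon is
taken three times stiffer than the ECM with both phases sharing $\alpha$
(`wm_materials()`).  The tissue is treated as nearly incompressible: the
volumetric penalty $\kappa = 100\,\mu$ (about Poisson ratio 0.495) exists
only for the FE solver.  The closed-form uniaxial nominal stress of the
exactly incompressible law,

$$S(\lambda) = \frac{2\mu}{\alpha}\left(\lambda^{\alpha-1} -
      \lambda^{-\alpha/2-1}\right),$$

is used for the fiber trusses, for synthetic target curves and as the
oracle for the FE patch test; the FE/closed-form gap due to the finite
penalty is below 2% up to $\lambda = 1.25$.

## RVE generator

The default domain is a $0.4 \times 10 \times 5.68$ um cuboid loaded along
z, with axons of fixed 0.4 um diameter.  Each axon is a natural cubic
spline through random waypoints spanning the two z-faces; transverse
waypoint amplitudes are rescaled iteratively (bisection) until the
realized tortuosity — arc length over chord — matches a target drawn from
a truncated normal distribution.  Choices worth recording:

* **Undulation distribution.** The underlying experimental distribution is
  not printed in the source literature; we use a truncated normal with
  mean 1.13, sd 0.06 on [1.02, 1.30], chosen so the population mean falls
  inside the physiological 1.05–1.25 range.  Fully configurable.
* **Axial alignment.** Each axon's exit point equals its entry point plus
  a small transverse offset (sd 0.5 um).  Independent uniform endpoints
  would produce a fiber population oblique by ~30° on average,
  contradicting the axially aligned spinal-cord microstructure the RVE
  emulates.
* **Clipping.** Out-of-bounds centerline samples are projected onto the
  box faces rather than deleted; on a centerline representation this is
  the reproducible analogue of trimming a swept solid, and it can only
  reduce tortuosity.
* **Volume fraction.** Axon volume is the swept-circle volume
  $\pi r^2 \times$ arc length; fiber overlap is not subtracted because the
  embedded-element method does not remove matrix volume either.  Axons are
  added until the summed volume first reaches the 53% target; the
  population is then trimmed to whichever of $n$ or $n-1$ axons is closer,
  and all undulation amplitudes are rescaled by one common factor
  $\tau' - 1 = \gamma(\tau - 1)$ so the achieved fraction equals the
  target exactly.  Without this rescale the stopping rule alone could
  overshoot by up to one axon (~3.5 volume-%), violating the ±1% contract.
  Under the defaults about 15 axons result.  The axon *count* is emergent:
  the printed reference count of 33 axons at 53% volume fraction is not
  reproducible by swept-volume arithmetic (33 axons of mean undulation
  1.13 contain ~27 um³ of fiber in a 22.7 um³ box), so the generator
  targets the fraction, not the count — see "Known limitations".
* **Reproducibility.** One top-level seed; per-axon sub-seeds are derived
  by a counter scheme (`seed + 9973 i + 104729 salt`), so axon $i$ is
  independent of how many axons follow.  The same seed yields a
  byte-identical geometry serialization.

## Transitional kinematic model

Each axon is partitioned into 50 equal-arc sub-segments.  If an axon's
*current* (deformed) undulation is below the threshold 1.08, the fraction
of its length coupled to the matrix is 8%, 20% and 44% for applied
stretches up to 1.06, 1.12 and 1.25 respectively; at or above the
threshold the axon does not interact with the matrix except for its two
end nodes, which are always tied at the RVE surfaces.  Conventions the
source text leaves open, fixed here:

* exactly 1.08 is *uncoupled* (strict "less than");
* a stretch exactly at a stage break uses that break's fraction;
* fractions refer to arc length (equal-arc sub-segments);
* which sub-segments couple is not specified; the default policy couples
  the *straightest* segments (lowest local tortuosity) first, since those
  reach affine kinematics first; `"random"` and `"from_ends"` policies are
  available;
* coupled sets grow monotonically — a segment never uncouples — and the
  undulation used at each update is recomputed from the deformed fiber
  polyline.

Coupling is held constant within a stage and updated between stages,
matching the staged protocol (1.0–1.06, 1.06–1.12, 1.12–1.25) with
interaction updates after each step.

## Finite element model

The ECM is meshed with 8-node hexahedra (2×2×2 Gauss, total-Lagrangian);
each axon is a chain of nonlinear two-node trusses over its 51 sub-segment
boundary nodes, with axial force $S(\lambda_f)\,\pi r^2$ referenced to the
segment rest length.  The embedded-element tie is realized as penalty
springs between each fiber node and the matrix displacement interpolated
trilinearly at the node's reference location: stiffness
$k_\mathrm{high} = 10^3 \mu_\mathrm{ecm} h$ for coupled nodes and end
ties, $k_\mathrm{low} = 10^{-3} \mu_\mathrm{ecm} h$ for uncoupled nodes
($h$ = element size).  $k_\mathrm{low}$ is a numerical regularization for
otherwise transversely floating truss nodes; halving it changes the
homogenized stress by far less than 0.5%.  Boundary conditions: $U_z = 0$
on the $z=0$ face, prescribed $U_z$ on the opposite face, lateral faces
traction-free, rigid modes removed by pinning the in-plane translations at
one corner plus one in-plane rotation dof — pins that the homogeneous
uniaxial solution satisfies exactly, so the patch test is unbiased.

Numerics: 6 increments per stage; full Newton with an incremental
*affine predictor* (every node first follows the homogeneous
incompressible map), a trust-region cap of 0.25 um on each step, an
Armijo line search on the potential energy, and a Levenberg diagonal
shift when the tangent is indefinite.  These safeguards matter: a slack,
uncoupled fiber chain has transverse stiffness of only $k_\mathrm{low}$
until it is taut, and plain Newton diverges on it.  The consistent
tangent is obtained by central finite differencing of the analytic
spectral stress (truncation ~1e-8 relative) and symmetrized; the
convergence test is residual norm below $10^{-8}$ of the increment's
initial residual or an absolute floor of $10^{-8}$ kPa·um² (~$10^{-9}$ of
the face reactions, the round-off floor of the FD tangent).  The
homogenized nominal stress S33 is the z-reaction sum on the moving face
divided by the reference cross-section (4 um²), which agrees with the
volume-averaged first Piola stress to better than 1%.

Problem sizes: production meshes use $h = 0.2$ um (2800 elements); the
shipped tests and the acceptance script use $h = 0.5$–0.6 um (~150–220
elements, ~3800–6800 dof with fibers), where S33 differs by under 1% from
$h = 0.35$ um — the response is dominated by the nearly homogeneous matrix
plus fiber recruitment, not by mesh resolution.

## Inverse identification

The target stress-stretch curve is compared with the simulated curve at
$m = 20$ equidistant stretch points over $(1, \lambda_{max}]$ (the
zero-stress point at $\lambda = 1$ carries no information), both curves
linearly interpolated.  The squared error $E(\mu) = \sum_i
(S_{exp,i} - S_{sim,i})^2$ is minimized over the bracket (20, 50) kPa by
textbook two-interior-point golden-section search, lower point evaluated
first, terminating when the uncertainty interval $\varphi^{-1}(b-a)$
drops below 1.0 kPa — with this bracket and tolerance the first iterate
is always 31.46 kPa and exactly nine objective evaluations occur,
independent of the objective.  Forward evaluations are memoized on the
quantized modulus; the RVE geometry, mesh and seed are held fixed across
all evaluations.  Because the experimental curve is not tabulated,
`synth_target_curve()` reconstructs it from the printed fitted Ogden
parameters (32.8 kPa, 8.22).

A useful structural fact: at fixed $\alpha$ every stiffness in the model
(ECM, axon, penalty terms) scales linearly with $\mu$, so the
displacement field is $\mu$-invariant and $S_{sim}(\lambda;\mu)$ is
exactly proportional to $\mu$.  $E(\mu)$ is therefore a parabola in
$\mu$ — guaranteeing the unimodality the golden search assumes — and
self-consistency recovery (target generated by the forward model itself)
is exact up to the search tolerance.

## What the synthetic data do and do not show

The generator emulates: fiber undulation with a realistic population
spread, axial alignment, a prescribed fiber volume fraction, and the
non-affine-to-affine coupling transition.  It does not emulate: axon
diameter distributions, axon-axon contact or exclusion, viscoelasticity,
or true swept-solid fiber geometry (fibers are embedded truss chains — no
transverse fiber stiffness, no local stress concentration around a fiber
surface).  Passing tests therefore validate the *pipeline* — geometry
statistics, FE consistency (patch test against the closed form, Taylor
tests, objectivity), the TKM bookkeeping, and the optimizer's anchors —
on real microscopy-derived geometries the quantitative response will
additionally depend on features outside this model.

## Known limitations

* The printed 53% volume fraction and the printed 33-axon count of the
  reference RVE are mutually inconsistent under swept-volume accounting;
  this package follows the volume fraction (~15 axons emerge).  The
  consequence is mechanical: the in-plane fiber area fraction at any
  cross-section equals the volume fraction, and with only ~53% fiber
  area at one-third matrix stiffness the composite cannot reach the
  stiffness of the homogeneous Ogden target curve for any modulus inside
  the (20, 50) kPa bracket — the identification against the synthetic
  tissue curve clamps at the bracket's upper interior point (the
  acceptance suite computes and reports exactly this).  Reproducing the
  reference identification value requires roughly twice the fiber
  content (the 33-axon configuration), which the volume-fraction
  contract excludes.  Self-consistency recovery, which tests the inverse
  machinery itself, is unaffected and accurate to well within the search
  tolerance.
* Coupling re-tie: when a sub-segment couples at a later stage, its
  penalty spring re-anchors the fiber node to the matrix displacement at
  the node's *reference* location, snapping it toward the affine image;
  continuous coupling evolution within a stage is out of scope, matching
  the staged protocol.
* Lateral boundary conditions are traction-free (the loading literature
  leaves them unstated); periodic boundaries are not implemented.
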