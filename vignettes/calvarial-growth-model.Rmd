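---
title: "Modelling post-operative calvarial growth in sagittal craniosynostosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-operative calvarial growth in sagittal craniosynostosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sagittal craniosynostosis is the premature fusion of the midline sagittal
suture of an infant's skull. Because the calvaria cannot widen across the
fused suture, the growing brain drives compensatory anteroposterior growth
and the head becomes long and narrow (scaphocephaly, low cephalic index).
Reconstructive surgery (here the Renier "H" technique) removes the fused
strip, reinserts it as two bone squares, and adds lateral cuts and wedges so
that subsequent brain growth can reshape the vault.

`calvaria` models the six years after surgery at desk scale: the
intracranial volume (ICV) expands quasi-statically against the calvaria
through frictional contact while new bone forms across sutures and
craniotomy gaps. The pipeline predicts skull dimensions and cephalic index
over time, suture/craniotomy patency timelines, and the contact pressure
the growing brain experiences, and wraps a grid of sensitivity experiments
around those outputs.

## Geometry: a parametric stand-in for patient CT

Patient CT segmentations are not publicly available, so the package
generates a parametric synthetic calvaria that preserves the topology and
label adjacency the algorithms actually consume:

* the skull is a closed ellipsoidal shell (inner semi-axes by default
  roughly 70 x 47 x 48 mm before volume calibration, bone thickness 3 mm)
  whose anteroposterior axis is the polar axis of the surface grid. This
  orientation makes every suture a coordinate band: the coronal and
  lambdoid sutures are latitude rings, the metopic/sagittal midline and the
  squamosal lines are meridian strips, so suture widths are meshed exactly;
* the intracranial volume is a separately meshed ellipsoidal brain
  (five lobes labelled by anatomical sectors), optionally wrapped in a
  bonded 2.5 mm CSF layer ("CSF present" model); the enclosed ICV is
  rescaled to the pre-operative 659 ml to well under 1%;
* a circular foramen magnum opening is cut at the skull base; its rim and a
  nasion patch are the fixed-boundary node sets;
* the Renier-"H" craniotomies are label changes on the same mesh: a 35 mm
  wide midline cut across the parietal region carrying two reinserted bone
  squares surrounded by 10 mm open kerf gaps, plus one wedge per side
  reaching the squamosal suture. The cut keeps a 5 mm parietal bridge
  towards the lambdoid suture and stays clear of the anterior fontanelle,
  as the surgeon would.

Suture widths default to values realistic for a 4-month-old (metopic 3,
coronal 5, lambdoid 5, squamosal 3 mm; anterior fontanelle 25 mm across;
the fused sagittal 2 mm). At the 0.1 mm/month formation rate these widths
also reproduce the clinically reported closure pattern (coronal closing
between roughly 30 and 40 months, fontanelle still open at 6 years), which
is what the default volume-to-age mapping assumes.

## Growth: the thermal-expansion analogy

Brain growth is imposed as an isotropic stress-free strain on the
intracranial elements - mathematically identical to uniform thermal
expansion. The pre-operative ICV (659 ml) expands to the follow-up ICV
(1245 ml) in six equal-ratio intervals, i.e. the same linear strain
`(1245/659)^(1/18) - 1` per interval, about 3.6% of linear growth each.
Each interval is solved in `n_sub = 3` sub-increments; every sub-increment
is a fresh static solve on the updated, unstressed geometry
(updated-coordinate stepping), so large total growth accumulates through
small linear steps and per-step elastic strains stay small.

Because the skull resists expansion elastically, a prescribed strain alone
would under-deliver volume. The expansion is therefore volume-feedback
controlled: each interval's strain is computed from the currently achieved
ICV towards that interval's scheduled volume. The final ICV lands within
about 1.5% of the target.

Ages are read off a monotone ICV-to-age table. Only its endpoints are
clinically pinned (659 ml at 4 months, 1245 ml at 76 months); the default
table places the six interval volumes at 7, 12, 24, 36, 50 and 76 months -
the strongly concave volume growth of infancy, with snapshot ages at the
milestones where outcomes are conventionally reported. The table is fully
configurable.

## Mechanics

All materials are linear isotropic: bone 3000 MPa (Poisson 0.3), sutures
and craniotomy gaps 30 MPa (0.3), brain 100 MPa (0.48), CSF 40 MPa (0.48).
Elements are linear tetrahedra by default (quadratic available through
`as_tet10()` for verification problems); the patch test is satisfied to
machine precision, which anchors the solver's consistency.

Contact between the intracranial surface and the inner calvaria uses the
published interface parameters: friction coefficient 0.1, normal penalty
stiffness 600 N/mm per unit area (pressure = stiffness x penetration), and
a 0.5 mm penetration tolerance. The implementation details are where a
desk-scale re-implementation must make choices:

* **Pairing.** The two surfaces are generated from the same grid and start
  coincident, so slave nodes pair with their nearest master vertex and use
  area-averaged vertex normals. Pairs against open-boundary rim vertices
  (the foramen magnum) are not penalised.
* **Smooth unilateral law.** The normal force follows a softplus law
  `p = kn * w * log(1 + exp(pen/w))` whose width is set per pair so the
  smoothing toe has a fixed 3 MPa force scale. For stiff bone-backed pairs
  this is indistinguishable from the sharp penalty (the thermally loaded
  sphere-in-shell benchmark matches the closed-form interface pressure to
  well under 1%); for compliant pairs it removes the on/off switching that
  otherwise destabilises fixed-point contact iterations.
* **Stiffness capping.** A penalty much stiffer than the structure behind
  the master surface adds no accuracy but destabilises staggered updates,
  so the penalty is capped per master vertex at twice the local `E/h` of
  the adjacent master-side elements (never below 6% of the nominal value).
  Commercial solvers apply analogous scaling. Capped pairs work at larger
  penetrations; penetration beyond the nominal tolerance can then occur at
  pressure hot spots but is always resisted, never free.
* **Friction.** Coulomb friction is tanh-regularised: the tangential
  traction is `mu*p * tanh(kt*slip/(mu*p))`, implemented as a per-node
  secant stiffness. It sticks at small slip, saturates at the Coulomb cap,
  and is exactly zero in the frictionless limit. A small always-on
  tangential spring (0.1% of the normal penalty) anchors the otherwise
  neutral rigid rotation of a frictionless contact-held body.
* **Iteration.** Pairing, normals, the contact law linearisation and the
  friction secant are refreshed each round; the update is adaptively damped,
  nodes whose penetration oscillates with sign-alternating jumps get their
  penalty softened locally, and if the residual stalls at a small value
  while the mean contact pressure is stationary the equilibrium of the
  frozen linearised state is accepted. If a step still fails, the growth
  step is bisected and retried (up to 1/8 steps).

Solves use a sparse Cholesky factorisation; the convergence target is a
0.2% relative displacement stationarity per sub-increment.

## Bone formation

**Gradual (front-based) formation** converts suture/craniotomy elements
within a growing radius of the adjacent bone: 0.1 mm per month of volume
growth for sutures, 0.8 mm/month for craniotomy gaps. Conversion is gated
by the element hydrostatic strain (mean of the principal strains,
accumulated over the interval) lying within 0-50%; the window is applied to
the strain magnitude, since a slightly compressed kerf corner should not
block healing and the sign convention is not otherwise determined.
Converted elements take full bone stiffness immediately and never revert.

Two bookkeeping choices matter at desk scale and are made deliberately:

* distances are measured from the *original* bone margin in the
  *pre-operative reference frame*, against the cumulative radius
  `rate x months since surgery` (an arrival-time formulation). Recomputing
  the front each interval against the deformed geometry - the obvious
  alternative - quantises propagation at coarse meshes (a 10 mm kerf
  spanned by one element never converts if no single interval's radius
  reaches its centroid) and double-counts growth stretching relative to
  the literature healing rates, which were calibrated on growing skulls;
* the single-step operation `gradual_formation_step()` retains the
  plain per-step semantics (current front, `rate x months` radius) for
  direct use and testing.

With these rules the 10 mm kerf gaps, healing bilaterally at 0.8 mm/month
from their bone margins, are fully ossified at the 12-month snapshot -
the post-operative healing timeline reported clinically.

**Bulk formation** instead ramps the modulus of the whole suture and
craniotomy regions: the first interval runs at the baseline 30 MPa, the
final interval at full bone stiffness, geometrically in between. This is
the computationally cheaper alternative; it stiffens regions wholesale
rather than from their margins.

Test 5's accelerated metopic/fontanelle closure uses per-region rate
overrides (0.6 mm/month) plus a hard relabel at 24 months for any
remaining elements, mirroring the clinical description of closure being
complete by then.

## Outputs

* `measure()` reports length (glabella to opisthocranion), width (euryon
  to euryon), height (basion to bregma) and the cephalic index
  `width/length x 100` - the formula consistent with every printed clinical
  value (one source text describes it as width times height over 100, which
  its own tables contradict). Values are rounded half away from zero to two
  decimals.
* `patency()` tracks the unossified fraction of every suture/craniotomy
  region over the snapshot ages; `closure_ages()` reports first-zero ages.
* `pressure_report()` aggregates contact pressure over the intracranial
  surface faces per brain lobe (min/max/mean). All faces enter the
  statistics, so minima are typically zero and means are whole-surface
  averages.
* `cross_section()` extracts planar outlines of the outer skull surface
  for overlay figures.

## The sensitivity grid

`builtin_configs()` reproduces the experiment set: the baseline model;
Test 1 (bone 421 MPa, Poisson 0.22), Test 2 (craniotomy modulus 3 kPa) and
Test 3 (brain modulus 3 kPa) as material sensitivities; Tests 4 and 5 as
formation-rate sensitivities (suture rate 0.2 mm/month; plus
metopic/fontanelle 0.6 mm/month closing by 24 months); and the 2x2 grid of
intracranial content (CSF present/absent) against formation method
(gradual/bulk). Tests 2 and 3 run with three times the sub-increments
because their extreme stiffness ratios degrade contact conditioning.

```{r}
library(calvaria)
cfgs <- builtin_configs(mesh_size = 12)
bundle <- run_experiment(cfgs$baseline)
summary(bundle$run)
plot(patency(bundle$run))
```

## Problem sizes, determinism and limitations

The default desk-scale mesh (`mesh_size = 10` mm, three radial brain
layers) has roughly 10-15 thousand linear tetrahedra; the test suite runs
the sensitivity grid at `mesh_size = 16` with two brain layers (about
4-6 thousand elements) and the acceptance computation at `mesh_size = 12`.
A full six-interval run takes on the order of one to a few minutes at
these sizes. Simulations are deterministic for a fixed seed (randomness
enters only through optional meshing jitter, off by default).

What the synthetic geometry does and does not show:

* it preserves the label topology, the contact mechanics, the formation
  kinetics and the volume schedule, so closure *timing*, pressure
  *orderings* and morphometric *trends* are meaningful;
* it is not the patient's skull: absolute lengths/widths and the printed
  per-lobe pressure values of the source study depend on the CT geometry
  and are not reproducible here - only the worked cephalic-index examples
  and qualitative patterns are checked against the printed values;
* element sizes of 10-16 mm cannot resolve the sub-millimetre suture
  slivers whose high strains self-limit closure in a full-resolution
  model. At desk scale sutures therefore close completely (except the
  anterior fontanelle), the gradual and bulk scenarios converge to similar
  final stiffness, and their pressure contrast shrinks to a few percent
  where the source study reports a factor of two. The orderings are
  asserted in the acceptance tests but sit within numerical noise at the
  coarsest meshes;
* CSF is a bonded solid layer, not a fluid; the skull base and face are a
  single rigid-ish block; bone is homogeneous and isotropic.

Numerical choices that a reviewer would want on record: solver tolerance
0.2% displacement stationarity; contact smoothing force scale 3 MPa;
penalty cap `2 E/h` with a 6% floor; tangential penalty 5% of normal with
a 0.1% stabilisation spring; strain window applied to `|eh|`; growth
volume-feedback enabled whenever contact is present; snapshot ages at the
interval ends only (closure ages are therefore reported at snapshot
resolution).
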