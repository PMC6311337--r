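---
title: "Planning oblique pubic-body screw corridors: models, phantoms and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning oblique pubic-body screw corridors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

When a pelvic reconstruction plate is laid along the pelvic brim starting at
the outer edge of the pubic tubercle, its two innermost screws must be
driven obliquely into the pubic body: medially enough to miss the obturator
foramen, and within an anterior--posterior window bounded by the two
cortices.  `pubicorridor` reproduces this planning workflow on triangulated
hemipelvis surface meshes.  The measured quantities are

* the insertion sites **S**, **M** (inner screw) and **L** (outer screw) on
  the curve offset 5 mm from the pelvic brim, at 6.5 mm and 19.5 mm of arc
  from S (the plate's first two holes);
* per screw the **maximum anterior/posterior inclination angles**
  (MAIA/MPIA, posterior reported negative) and the screw length at maximal
  anterior inclination (L1, L2);
* the **obturator-tangential screw** from L: the most laterally inclined
  3.5 mm cylinder that still stays within bone, its length L0, medial
  inclination angle (MIA) and anterior/posterior inclination angle (APIA);
* the **medial inclination angle of the insertion plane** (the angle
  between the OM line and the cortical-perpendicular reference at M);
* the **safe-region pattern** seen along the tangential screw axis (blunt
  V, sharp V, or disjoint anterior/posterior boundaries);
* two pelvimetric distances (intertubercular, symphysis vertical extent);
* per-sex cohort statistics: pooled-variance two-sample t tests from
  (mean, sd, n) summaries, exact two-group pooling for "Total" rows, and a
  one-sample Kolmogorov--Smirnov normality screen.

## Containment model

A screw is a cylinder (default diameter 3.5 mm) from an on-surface entry
point.  Containment is decided by sampling the lateral surface
(`n_axial` x `n_circ`, default 64 x 16, plus 16 tip-cap points) and requiring
every sample to lie inside the watertight mesh, with two deliberate
allowances:

* **Tolerance `tol` (0.05 mm).**  A sample may sit up to `tol` outside the
  surface.  This absorbs triangulation and sampling granularity at
  sub-degree angular resolution.
* **Entry band `entry_band` (0.5 mm).**  Samples less than 0.5 mm below
  the entry tangent plane are exempt.  A cylinder whose cap centre sits on
  the cortex necessarily protrudes above the surface once tilted; the
  exempt band is the not-yet-inserted part of the screw and also absorbs
  the local slope of a curved entry surface under the screw head.

Both allowances are part of the *definition* of containment and are shared
verbatim by the analytic strip oracle, so oracle and mesh search answer the
same question.  Inside/outside queries use ray casting (parity of
crossings) over a uniform spatial grid, with automatic ray retries on
numerically grazing hits.

Three numerical choices matter for reproducibility:

* **Aligned circumferential sampling.**  During a tilt search the sampling
  frame is rotated so one sample ring position coincides exactly with the
  tilt direction; the extreme fibre of the screw is then sampled without
  angular quantisation error (and ring staggering is disabled).
* **Fixed-pitch axial stations during length bisection.**  Sample stations
  are placed on a fixed axial lattice rather than re-scaled with each
  candidate length, which makes containment monotone in length --
  otherwise stations shift as the length changes and bisection can
  terminate on sampling noise rather than geometry.
* **Bisection brackets as certificates.**  Angle searches return the last
  contained and first violating tilt (bracket width `ang_tol`, 0.05 deg);
  lengths are bisected to `len_tol` (0.01 mm).  Every reported maximal
  angle is certified: containment holds one tolerance below it and fails
  one tolerance above it.

## Angle conventions

The reference line at an entry point is the in-plane direction
perpendicular to the local cortical tangent, i.e. the measuring-plane
projection of the inward surface normal (the normal is averaged over a 2 mm
patch, with the contribution of faces much larger than the patch capped at
the patch area).  Anterior tilts are positive, posterior negative; the
anterior side is identified from the landmarks (away from the brim), never
from a world axis, which makes all measurements invariant under rigid
motions *and* mirroring.  Measuring planes follow the cross-section
construction: plane 3 is spanned by the perpendicular from M to the brim
and the direction to the lowest symphysis point O (the inner insertion
plane), plane 4 is orthogonal to it through O and M (where the plane MIA is
read), the outer screw plane passes through L parallel to plane 3, and
planes 1/2 carry the tangential screw's APIA and MIA.

Under both length policies a direction is feasible at a tilt iff the
minimum implantable screw (14 mm) fits; the policies differ only in the
reported screw: the fixed 14 mm screw for posterior tilts, the maximal
tangent length at the limiting angle for anterior tilts.

The tangential search minimises the medial tilt psi of a direction family
at L (psi toward the symphysis, phi anterior/posterior) subject to a
contained length of at least `tangential_min_length` (35 mm, capped at 70 %
of the L-to-O distance on small bones).  The length floor is what
distinguishes the corridor that passes *medial* to the foramen from
directions that would stop short against its inner cortex; the returned
direction is certified tangent (clearance to the foramen-side cortex below
0.1 mm on the phantoms).

## Safe-region classification

Viewed along the tangential screw axis, faces seen edge-on
(|normal . axis| < 0.35) with an anterior or posterior in-plane normal
component form the projected anterior and posterior cortical boundaries.
Each boundary is condensed to a polyline (median projected height per
lateral bin), extended across the projected bone silhouette with its end
slopes, and the two are intersected.  A crossing within the silhouette with
apex angle >= 90 deg (configurable) is a blunt V, below 90 deg a sharp V,
and no crossing is the disjoint pattern.  Triangular and rectangular prism
phantoms with built apex angles of 120 deg, 40 deg and parallel walls are
recovered exactly.

## Phantoms instead of CT data

No imaging data ship with the package; two parametric phantom families
stand in.

**Strip phantoms** are closed slabs with planar cortices exactly `T` apart.
The maximal tilt of a screw entering the top face has a closed form (the
band-clipped screw rectangle first touches a wall when
`L sin(theta) + r cos(theta)` reaches the entry clearance plus `tol`), and
an independent dense 0.01-degree sweep with exact polygon clipping serves
as the reference oracle.  Closed form and sweep agree to 0.02 deg over a
grid of thicknesses and entry offsets; the 3D bisection agrees with the
sweep to 0.1 deg and screw lengths to 0.1 mm.

**Pubis phantoms** idealise the pubic body + superior ramus as a curved
bone plate: a star-shaped outline in the sagittal-ish plane (flat vertical
symphyseal face, arched superior boundary carrying the brim and a gentle
tubercle bump, an inferior boundary that dips below the obturator ring),
a circular obturator through-hole, and anterior/posterior walls whose
separation follows a medially-thick (13 mm) to laterally-thin (7.6 mm)
cortical neck profile within 8 mm of the superior boundary, stepping open
steeply below that *lip* into the broad body (up to +16 mm anteriorly,
+3.2 mm posteriorly).  The lip is carried exactly by a mesh edge ring.
This reproduces the anatomy the measurement method depends on: posterior
clearance at the plate sites equal to the 5 mm brim offset, anterior
clearance set by the neck thickness, long anterior screws running along the
flared cortex once the lip is cleared, and a foramen that caps the lateral
inclination of the outer corridor.  The generator is deterministic for a
fixed spec, watertight by construction, and emits all landmarks exactly on
the surface.

What these phantoms do *not* model: cortical/trabecular distinction, local
surface roughness and osteophytes, true obturator ring topology (the hole
is a cylinder), and inter-individual shape variation beyond the sampled
size parameters.  Passing tests therefore certify the *measurement
machinery* -- searches, certificates, invariances -- not anatomical
realism of any single number.

## Virtual cohorts

`sample_cohort()` draws per-subject parameters from per-sex normals with
one integer master seed and per-subject substreams (`seed + index`):
intertubercular distance 58.40 +/- 6.03 mm (male) vs 61.98 +/- 9.04 mm
(female) and symphysis vertical extent 41.82 +/- 4.65 mm vs
39.85 +/- 3.26 mm (the published morphometric dimorphism), ramus length
55 vs 48 mm with the outer-screw-length spreads (6.36 / 8.65 mm) -- the
deliberate ~7 mm size dimorphism -- and a sex-independent cortical
thickness scale (1 +/- 0.04, i.e. a 4 % coefficient of variation typical
of cortical thickness).  Wide physiological clamps (for example ramus
length 36--78 mm) protect mesh generation in the far tails; the obturator
radius scales with ramus length.  Because the outline scales with ramus
length while the plate offsets (5 / 6.5 / 19.5 mm) and the neck thickness
profile are absolute, the measured outer screw length tracks bone size
while the maximal anterior inclination angle does not differ by sex -- the
configured effect structure that the replicate study in the test suite
verifies (40 + 40 subjects per cohort, 50 seeded replicates, outer-screw
measures at reduced sampling density 32 x 8 and mesh resolution 60 x 5;
these problem sizes keep a replicate under ~15 s without changing any
conclusion at full resolution).

## Statistics

The between-sex test is the pooled-variance Student t from (mean, sd, n)
summaries -- for the equal-n tables it coincides with the Welch statistic
-- with two-sided p values; "Total" rows use exact two-group pooling
(size-weighted mean, within- plus between-group sums of squares).  The KS
normality screen tests against a normal with the sample's own mean and sd;
because the parameters are estimated from the same sample the p value is
conservative (a Lilliefors correction would reject more often), which is
documented rather than corrected to mirror the common SPSS workflow.  The
printed reference tables ship as plain-text data; `audit_printed_tables()`
recomputes every printed t from its own summaries and flags entries off by
more than 0.5 -- the audit reports discrepancies (two entries in the
tangential-screw table cannot be derived from their own printed summaries)
and never silently corrects them.

## Known limitations and open choices

* "Approximately 5 mm from the pelvic boundary" is implemented as geodesic
  surface distance (tangent-plane marching with re-projection); on planar
  faces this is the exact Euclidean offset.  The offset side is chosen by
  matching the surface sheet of a hint landmark (the tubercle edge
  midpoint), which is reflection-safe, and an error is raised when the
  offset does not fit on that sheet.
* If the offset curve crosses the tubercle edge more than once, the most
  medial crossing defines S.
* The symphysis "vertical" distance is the straight distance between the
  upper and lower boundary landmarks (no body axis is defined); a
  projected variant is exposed as an option.
* The blunt/sharp V threshold (90 deg) is a configuration choice; the
  published pattern taxonomy names no numeric criterion.
* The tangential screw's APIA is emergent from the tangency search, not an
  input constraint.
* The plane-MIA and the tangential-screw MIA are distinct quantities and
  both are reported.
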