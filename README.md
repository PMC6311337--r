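# pubicorridor

Safe screw-corridor planning in the pubic body on triangulated bone meshes.

When a 3.5 mm pelvic reconstruction plate is placed starting at the outer
edge of the pubic tubercle and laid along the pelvic brim, its two innermost
screws must be driven obliquely into the pubic body: medially enough to
clear the obturator foramen, and inside the anterior–posterior window
bounded by the cortices. `pubicorridor` implements that planning workflow
for surgeons and digital-anatomy researchers working with CT-derived
hemipelvis surface models:

* **Plate placement** — the curve offset 5 mm from the pelvic brim across
  the superior surface, and the insertion sites S, M (inner screw, 6.5 mm
  of arc from S) and L (outer screw, 19.5 mm).
* **Corridor measurement** — for a virtual screw of diameter *d* = 3.5 mm
  entering at M or L, the maximum anterior and posterior inclination angles
  (MAIA, MPIA; posterior negative) found by bisection on a
  cylinder-in-mesh containment test, and the screw length at maximal
  anterior inclination (L1, L2). In a parallel-walled bone of thickness *T*
  with entry clearance *c* to a wall, the maximal tilt θ\* of a screw of
  length *L* and radius *r* solves *L* sin θ\* + *r* cos θ\* = *c* — the
  closed form behind the package's analytic strip oracle.
* **The obturator-tangential screw** — the most laterally inclined
  contained screw from L (tangent to the foramen-side inner cortex), its
  length L0, medial inclination angle (MIA) and anterior/posterior
  inclination angle (APIA); plus the safe-region pattern (blunt V, sharp V
  or disjoint anterior/posterior boundaries) seen along its axis.
* **Cohort statistics** — pooled-variance two-sample *t* from per-sex
  (mean, sd, n) summaries, exact two-group pooling for "Total" rows, a KS
  normality screen, three-table reports, and an audit that recomputes
  published *t* values from their own printed summaries.
* **Phantoms** — parametric strip and pubis phantoms (with obturator
  foramen, tubercle and symphyseal face) and virtual cohorts drawn from
  sex-specific morphometric distributions, so every measurement can be
  exercised against analytic ground truth without patient data.

Meshes are read from STL (binary/ASCII) or PLY; landmarks travel as JSON
(brim polyline, tubercle edge curve *m*, lowest symphysis point O,
symphysis boundaries, obturator loop, tubercle apex).

## Worked example

```r
library(pubicorridor)

# a deterministic pubis phantom standing in for a segmented hemipelvis
ph  <- generate_pubis_phantom(pubis_phantom_spec())
res <- analyze_hemipelvis(ph$mesh, ph$landmarks)
res
#> corridor_result
#>   inner screw:      MAIA  26.61 deg  MPIA  -20.30 deg  L1  39.09 mm  plane MIA 22.27 deg
#>   outer screw:      MAIA  14.20 deg  MPIA  -19.64 deg  L2  54.86 mm
#>   tangential screw: MIA   12.70 deg  APIA   12.49 deg  L0  58.91 mm
#>   safe region: disjoint
#>   symphysis height 41.04 mm, intertubercular 60.00 mm
```

Reading: from the inner site M a screw can lean up to 26.6° anterior and
20.3° posterior before breaching a cortex; at maximal anterior inclination
a 39 mm screw fits. The insertion plane through M and O is tipped 22.3°
medially. From the outer site L the obturator-tangential screw (the lateral
safety bound) runs 58.9 mm at 12.7° of medial inclination; the projected
anterior and posterior safe-region boundaries do not cross (disjoint
pattern). All angles are certified by containment brackets: containment
holds one angular tolerance (0.05°) below each reported maximum and fails
one above.

The statistics stage works straight from summary triples:

```r
two_sample_t_from_summaries(group_summary(55.71, 6.36, 40),
                            group_summary(48.68, 8.65, 40))$t
#> [1] 4.141172
pool_groups(group_summary(55.71, 6.36, 40),
            group_summary(48.68, 8.65, 40))
#> group_summary: mean 52.195, sd 8.332, n 80
```

Batch use goes through `cmd_simulate()` / `cmd_measure()` /
`cmd_cohort_report()` / `cmd_audit_tables()` or the thin command-line front
end installed at `inst/cli/pubicorridor`.

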