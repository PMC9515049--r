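# needleplan

Condition-based access-path planning for percutaneous needle
interventions on triangle-mesh anatomy.

Percutaneous procedures (biopsies, ablations, drainages) reach an
internal target through the skin with a needle-like instrument. The
insertion point fixes the entire access path, and choosing it from 2D
slice images is slow and error-prone. `needleplan` rates every point of
a skin surface mesh as a candidate insertion point for a given target:
binary **hard conditions** exclude inadmissible paths, continuous **soft
conditions** score the admissible ones, and the resulting quality map
can be rendered as a classed heatmap on the skin. The package is aimed
at researchers prototyping planning and visualization pipelines for
image-guided interventions; it works on synthetic phantoms it generates
itself, so no patient data is required.

## The model

A candidate path is the segment from a sampled skin point to the target.
Hard conditions (all must hold):

* clearance to every risk structure ≥ safety margin *m* = 2 mm,
* path length *L* ≤ needle length *L*<sub>max</sub> = 150 mm,
* angle to the vertical axis θ<sub>axis</sub> ≤ 60°,
* the path crosses the skin exactly once (line of sight).

Admissible paths get three condition quality values, clamped to [0, 1]:

```
CQV_dist  = (d − m) / (d_max − m)                      d_max = 10 mm
CQV_path  = 1 − (L − L_vert) / (L_max − L_vert)
CQV_angle = 1 − θ (1 − 0.9)/25            if θ ≤ 25°
          = 0.9 − 0.9 (θ − 25)/(60 − 25)  otherwise
```

where *d* is the path clearance, *L*<sub>vert</sub> the vertical depth
of the target below the skin, and θ the angle between the path and the
transverse imaging plane (25° reflects typical CT gantry tilt). The
**path quality value** is `min(CQV_dist, CQV_path, CQV_angle)` — a path
only scores high when it has no weak condition. Admissible points are
divided into four quality classes on a single-hue green scale (darker =
better); inadmissible points are hidden.

Clearance has two backends: the exact segment-to-mesh distance (capped
at *d*<sub>max</sub>, the default) and the incremental method that grows
a cylinder around the path in 0.25 mm radius steps until a risk
structure is hit, keeping the last safe radius.

## Worked example

```r
library(needleplan)

# 200 x 200 mm slab skin, target 50 mm deep, one 3 mm risk sphere
# at lateral offset 10 mm half way down the vertical path
sc <- fixture_scene("slab_risk")
map <- plan_paths(sc, params = planning_params(sampling_density = 0.02),
                  seed = 42)
map
#> <insertion_map: 838 candidates, 489 admissible (target 1, seed 42, surface sampler)>
#>   path quality: min 0.011  median 0.589  max 0.976
map$counts
#>       sampled     hard_pass          risk        length         angle line_of_sight
#>           838           489             6             0           343             0
```

838 skin points were sampled; 489 are admissible. 343 candidates fail
the 60° angle limit (the admissible region of this scene is the disc of
radius 50·tan 60° ≈ 86.6 mm around the target's vertical projection)
and 6 violate the 2 mm safety margin around the risk sphere.

The vertical path itself, evaluated directly:

```r
evaluate_candidate(c(0, 0, 0), sc$targets[1, ], sc)
#>   path_length_mm clearance_mm theta_plane_deg cqv_dist cqv_path cqv_angle quality
#> 1             50            7               0    0.625        1         1   0.625
```

Its clearance is 7 mm (10 mm offset minus the 3 mm radius), giving
`CQV_dist = (7 − 2)/(10 − 2) = 0.625`; length and angle are optimal, so
the path quality is 0.625 — the distance condition is the bottleneck.

Rendering and target overlay:

```r
img <- render_heatmap(map, quality_class_scheme(mode = "full"))
write_heatmap_png(img, "heatmap.png")
export_colored_mesh(map, path = "skin_full.ply")
compute_target_overlay(sc$targets[1, ], sc)
#> <target_overlay: depth 50.0 mm, pin "5.0", ring fill 0.333, 5 cylinder(s)>
```

The same pipeline is available from the shell via the launcher in
`inst/cli/`:

```sh
needleplan phantom --kind slab --out scene/
needleplan plan --scene scene/ --density 0.02 --seed 42 --out plan/
needleplan render --scene scene/ --plan plan/ --mode full
```

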