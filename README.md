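# ieegloc

Headless localization of intracranial EEG electrodes from a post-implant CT.

Epilepsy-surgery patients are implanted with sEEG shafts (linear depth
arrays) and ECoG grids/strips (subdural surface arrays). Analysing the
recordings requires the millimetre position of every contact in the
patient's brain. Each metal contact shows up in the post-implant CT as a
bright, roughly Gaussian density; `ieegloc` turns those densities — plus a
co-registered parcellation and cortical surface from the preoperative MRI —
into an auditable electrode table, fully scripted, no GUI.

What it does, and the core of each method:

* **Contact refinement** — from a seed coordinate, iterate the
  intensity-weighted centroid `sum((I - thr) * x) / sum(I - thr)` of
  above-threshold CT voxels within 2 mm until it moves < 0.01 mm.
* **Shaft automation** — from two clicked contacts, extrapolate
  (`p_k = 2 c_{k-1} - c_{k-2}`) or interpolate (re-aimed march toward the
  refined far endpoint) the whole shaft, snapping every prediction to the
  brightest admissible CT voxel within 2 mm, excluding voxels within
  1.5 mm of already-placed contacts.
* **Anatomic labeling** — majority vote over the 3×3×3 voxel cube centered
  on the contact, ties resolved by the center voxel's label.
* **Brain-shift correction** — ECoG contacts found inside the closed pial
  envelope (generalized winding number) are moved to the exact nearest
  surface point, then relaxed under
  `sum ||s_i − proj_i||² + λ sum (||s_i − s_j|| − ||o_i − o_j||)²`
  over adjacent pairs, re-projecting every sweep. sEEG contacts are never
  touched; native and shifted coordinates are both kept.
* **Value mapping** — `vertexvalue = v · exp(−d · decay_factor/max_radius)`
  with defaults `decay_factor = 1.5`, `max_radius = 1` mm, unassigned
  beyond the cutoff; multiple in-range electrodes average with
  inverse-distance weights; discrete mode copies the nearest electrode.
* **Interoperability** — template tables from an electrode plan, value
  import that ignores blank/`n/a` cells, plain-text TSV and BIDS-iEEG
  (`*_electrodes.tsv` + `*_coordsystem.json`) export.
* **Synthetic fixtures** — deterministic CT/parcellation/mesh generators
  with ground truth, so the whole pipeline is testable without patient
  data.

## Worked example

Localize an 8-contact shaft on a synthetic CT with known ground truth:

```r
library(ieegloc)

fix <- make_shaft_fixture(n = 8, spacing = 3.5, curvature_radius = 80,
                          seed = 42)
tab <- localize_plan(
  fix$volume,
  electrode_plan(contact_group("LA", "sEEG", 8, spacing = 3.5)),
  tibble::tibble(group = "LA", which = c("first", "second"),
                 x = fix$truth[1:2, 1], y = fix$truth[1:2, 2],
                 z = fix$truth[1:2, 3]))
tab[, 1:8]
#> # A tibble: 8 × 8
#>   number channel group index     x     y     z provenance
#>    <int> <chr>   <chr> <int> <dbl> <dbl> <dbl> <chr>
#> 1      1 LA1     LA        1  11.9  22.1  24.0 refined
#> 2      2 LA2     LA        2  15.4  22.2  24.0 refined
#> 3      3 LA3     LA        3  18.9  22.4  24.0 extrapolated
#> 4      4 LA4     LA        4  22.4  22.8  24.0 extrapolated
#> 5      5 LA5     LA        5  25.9  23.4  24.0 extrapolated
#> 6      6 LA6     LA        6  29.3  24.0  24.0 extrapolated
#> 7      7 LA7     LA        7  32.7  24.9  24.0 extrapolated
#> 8      8 LA8     LA        8  36.1  25.9  24.0 extrapolated
```

The two seeded contacts are `refined`; the rest were predicted from the
shaft geometry and snapped to the CT (`extrapolated`). The mean distance to
the generating ground truth here is 0.011 mm. From there,
`label_table()` adds anatomy columns, `correct_brain_shift()` adds
`*_shifted` coordinates for interior ECoG contacts, `map_values()` paints
per-electrode values onto mesh vertices, and `export_bids()` writes
`sub-XX_electrodes.tsv` / `sub-XX_coordsystem.json`.

The same pipeline runs from the shell:

```sh
ieegloc simulate --out sim --seed 1
ieegloc localize --ct sim/ct.nii.gz --plan sim/plan.json --seeds sim/seeds.tsv --out loc
ieegloc label    --table loc/electrodes.tsv --parcellation sim/parcellation.nii.gz --lut sim/lut.txt --out lab
ieegloc export-bids --table lab/electrodes_labeled.tsv --out bids
```

(`ieegloc` is installed into the package's `exec/` directory; equivalently
call `ieegloc::ieegloc_cli(c("simulate", "--out", "sim"))` from R.)

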