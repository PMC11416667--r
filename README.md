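# enclavekit

Tools for studying **genealogical demixing** in growing bacterial monolayer
colonies. When a surface-attached founder cell divides, the descendants of
its two daughters (the two *progeny chains*) do not intermix as the colony
expands — they consolidate into two contiguous *genealogical enclaves*.
`enclavekit` is aimed at quantitative microbiologists and biophysicists who
want to detect, quantify and model that self-organisation from segmented
time-lapse microscopy, without fluorescent labels.

The package covers the full analysis stack:

* **Label-free lineage tracking** of per-frame integer label masks:
  frame-to-frame centroid matching with a mutual-uniqueness cutoff
  (d_c ≈ 0.75 µm), division detection via *dummy centroids* placed at
  ±l_c/4 along the mother axis, pole-displacement rescue of fast movers,
  and a drift-compensated division-rescue pass; progeny chains are rooted
  at the founder's two daughters.
* **Enclave analytics**: cell-contact graphs (10 µm radius, 1.2 µm
  boundary tolerance, exact polygon distances), enclave polygons by
  nearest-chain partition of the colony region, centroid separation Δc,
  the interface length identity
  `L_interface = (Ps1 + Ps2 − L_colony) / 2`,
  moving-box Shannon entropy `SE(B) = −p_r ln p_r − p_g ln p_g`
  (box s ≈ 5.5 µm, stride s/2) with a label-permutation null
  (2×10⁵ iterations at production scale), spline interface curvature, and
  invasion-front regions with mean invasion widths.
* **Nematic order and topological defects**: structure-tensor orientation
  fields, the moving-grid order parameter
  `S_R = sqrt(⟨cos 2Φ⟩² + ⟨sin 2Φ⟩²)`, S ≤ 0.3 candidate mining, and
  winding-number charges quantised to ±1/2, with interface / boundary /
  bulk classification (d_i ≈ 1.5 µm) and frame-to-frame defect tracking.
* **A stochastic lattice model** of enclave formation: log-normal division
  clocks (48 ± 13 min and 21 ± 6 min reference parameterisations, CV ≈
  0.27), Moore-neighbourhood daughter placement, inverse-run-length
  weighted shoving, plus the two-step placement (weakened adhesion) and
  per-chain rate-imbalance variants.
* **A ground-truthed synthetic colony generator** — off-lattice
  spherocylinders with exponential elongation, log-normal division times
  and overlap relaxation, rendered to 16-bit label masks — so the whole
  pipeline is testable end to end without external data.

## Worked example

```r
library(enclavekit)

# grow a 64-cell colony at the 25 C clock statistics and track it label-free
cfg    <- generator_config(mean_division = 48, sd_division = 13,
                           n_target = 64, seed = 1)
run    <- grow_rod_colony(cfg)
forest <- build_progeny_chains(run$frames)
forest
#> <lineage_forest> 88 frames, 126 tracks, 62 divisions, 0 unresolved

# enclave geometry of the final frame
last <- run$frames[[length(run$frames)]]
enclave_partition(last)
#> <enclave_partition> areas = (118.9, 71.5) um^2, delta_c = 7.28 um,
#>   L_interface = 32.25 um (measured 32.29), exposed = (0.57, 0.45)

# arrangement entropy against its permutation null
null <- randomized_entropy_null(last, iterations = 1000, seed = 1)
sprintf("observed SE %.4f vs null mean %.4f (percentile %.3f)",
        null$observed, null$null_mean, null$percentile)
#> "observed SE 0.2654 vs null mean 0.4574 (percentile 0.000)"
```

The tracker reconstructed every division (62 events, no unresolved cells),
the two enclaves share the colony area and its exposed outline roughly
half-and-half while staying spatially separated (Δc = 7.3 µm, interface
identity and direct measurement agreeing to 0.1%), and the observed
arrangement entropy of 0.265 sits far below the null mean of 0.457 — every
one of 1000 random recolourings of the same positions is more mixed than
the real genealogical arrangement.

The lattice model reproduces the directional effects at colony scale:

```r
ens <- lattice_ensemble(list(c(48, 13), c(21, 6)), n_target = 128,
                        n_seeds = 20, base_seed = 0)
aggregate(cbind(se, contacts) ~ mean + sd, ens, mean)
#>   mean sd        se  contacts
#> 1   21  6 0.2574510 0.2087728
#> 2   48 13 0.2632234 0.2091964
```

A command-line front end for the same steps ships in
`inst/scripts/enclavekit` (subcommands `generate-colony`,
`simulate-lattice`, `track`, `analyze-enclaves`, `demo`).

See `vignettes/genealogical-demixing.Rmd` for the models, parameter
defaults and numerical choices.

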