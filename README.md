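# orcascape

Where do stranded killer whales come from? Sea-surface water δ¹⁸O varies by
several per mil across the North Atlantic, with a sharp drop north of the
Gulf Stream, and the phosphate of whale tooth dentine and bone records the
seawater the animal lived in. `orcascape` implements the full inference
chain for a cohort of 22 stranded North Atlantic killer whales (packaged as
a fixture), for stable-isotope ecologists who want the calculation to be
reproducible and testable:

1. **Inverse calibration.** Tissue and seawater values are linked by
   δ¹⁸O_P = β₀ + β₁·δ¹⁸O_marine (β₀ = 18.73 ± 0.30 ‰, β₁ = 0.81 ± 0.23);
   each whale's source-water value is (x − β₀)/β₁ with a first-order
   Taylor (delta-method) SE propagating both parameter SDs and the 0.22 ‰
   analytical error:
   SE² = (σₓ² + σ²_β₀)/β₁² + (x − β₀)²·σ²_β₁/β₁⁴.
2. **Suess correction.** δ¹³C is moved to a common reference year (2013)
   at −0.023 ‰ yr⁻¹, dated by the tissue deposition midpoint (year of
   death minus half the GLG age).
3. **Isoscape assignment.** Every grid cell of a sea-surface δ¹⁸O isoscape
   whose value falls in a whale's 95 % CI is assigned to it (closed
   interval, extraction only, no isoscape-side variance).
4. **Cohort statistics.** Tie-corrected Kruskal–Wallis, Dunn's post-hoc
   with Benjamini–Hochberg adjustment, UPGMA clustering of δ¹⁸O_P with a
   deterministic tie-break, per-region summaries, and within-tooth
   (per-GLG) variation indices — all implemented in-package and tested
   against independent oracles.
5. **Synthetic validation.** Generators for North-Atlantic-like isoscapes
   and cohorts with known ground truth, including an end-to-end CI
   coverage experiment.

## Worked example

```r
library(orcascape)

records <- orca_specimens()                 # the 22-whale fixture
est <- estimate_marine(records, calibration_model(), ci_level = 0.95)
head(est[, c("specimen_id", "d18O_p", "m_hat", "se", "ci_lo", "ci_hi")], 3)
#>     specimen_id d18O_p     m_hat        se     ci_lo      ci_hi
#> 1   ECA-AB-1948  16.89 -2.271605 0.7918326 -3.823568 -0.7196415
#> 2 ECA-CS-1977-1  16.02 -3.345679 1.0552052 -5.413843 -1.2775149
#> 3 ECA-CS-1977-2  17.27 -1.802469 0.6876738 -3.150285 -0.4546533
```

A tooth δ¹⁸O_P of 16.02 ‰ implies source water at −3.35 ± 1.06 ‰ —
¹⁸O-depleted, high-latitude water — with a 95 % CI of (−5.41, −1.28).
`verify_fixture()` recomputes the whole published per-specimen table:

```r
verify_fixture()
#> [PASS] marine point estimates (22 specimens, 2 d.p.) (22/22 match)
#> [PASS] propagated SEs (22 specimens, 2 d.p.) (22/22 match)
#> [PASS] Suess-adjusted d13C (unflagged ECA/NWA rows, 2 d.p.) (15/15 match)
#> [PASS] per-region d18O_P summaries (4/4 regions match)
#> [PASS] ECA/NWA marine range (min -3.44, max 4.53)
#> [PASS] UPGMA k = 3 cluster sizes {17, 4, 1} (17, 4, 1)
```

Assignment against a (here synthetic) isoscape, and the cluster structure:

```r
grid <- gen_isoscape(sim_config(seed = 20260925))
masks <- assign_specimens(est, grid)
subset(assignment_summary(masks, grid), empty)
#>    specimen_id n_cells fraction empty lat_min lat_max lat_mean
#> 17 NWA-BP-1998       0        0  TRUE      NA      NA       NA

sort(lengths(cut_tree(upgma_cluster(records), 3)), decreasing = TRUE)
#> [1] 17  4  1
```

The whale with the highest δ¹⁸O_P (22.40 ‰) maps to an estimated source
value (+4.53 ‰) above anything on the grid — an honestly empty
distribution — and the k = 3 cut isolates exactly the five high-δ¹⁸O_P
whales (one singleton, one cluster of four) from the main cluster of 17.

The `analysis/` directory holds the full narrative workflow as numbered
scripts (`01_load_specimens.R` … `06_synthetic_validation.R`); each prints
what it found and writes its tables under `results/`. `run_pipeline()`
performs the same read → calibrate → Suess → assign → stats chain in one
call and writes a per-specimen results table plus masks, dendrogram and a
stats report.

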