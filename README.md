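# magnetoquant

Quantification toolkit for magnetogenetic neuromodulation studies in freely
moving mice. When genetically targeted neurons are switched with magnetic
fields, the effect is read out across several modalities at once — and each
has its own quantification chain:

* **Trajectory behavior** — freezing of gait (no change of position of
  head, center, or extremities for ≥ 1 s, with an explicit displacement
  tolerance ε per 0.4 s analysis step), ambulation time, distance,
  activity %, and >90°/360° rotation counts, on tracks scored at 150
  positions per minute per keypoint.
* **Field-map conditioning** — bilinear interpolation of a gaussmeter map
  B(x, y) (mT) and per-bin occupancy/freezing summaries
  (rate = freezing time / occupancy time per field bin), with the
  high-DMF (0.5–1.3 T) / low-DMF (0.1–0.27 T) regime labels.
* **Fiber photometry** — isosbestic correction
  `net = F465 − fit(F405)`, `ΔF/F% = 100·(net − median(net))/denominator`
  with a guarded denominator, optional 15 Hz low-pass, epoch means, and
  TTL-event-aligned averaging.
* **ROI fluorescence** — `ΔF/F0 = (F − F0)/F0` on background-subtracted
  traces (negative for chloride/MQAE quench), per-cell peaks, and
  trapezoidal AUC over a stated window (48–180 s convention).
* **PET** — final dose, `%ID/g = 100·C/(dose/weight)`,
  striatum/cerebellum reference ratios, and per-animal field-exposure over
  baseline ratios.
* **Cell counting** — Gaussian blur → threshold 30 → size filter 20 px →
  DAPI colocalization → % double-positive over marker-expressing cells.
* **Synthetic data** — seeded generators for every input modality with
  known ground truth (two-state freeze/ambulate locomotion, dual-channel
  photometry with shared artifacts, exponentially decaying field maps,
  disk-cell images), so the full pipeline is testable without animals.

## Worked example

Generate a 5-minute open-field session with a known 30% freeze fraction,
score it, and check the detector against the generator's ground truth:

```r
library(magnetoquant)

st <- generate_track(track_synth_params(duration = 300,
                                        freeze_fraction = 0.3, seed = 2))
rs <- resample_track(st$track)          # 2.5 Hz analysis grid
det <- detect_freezing(rs)              # ε = 0.5 cm, min 1 s
c(detected = det$freezing_time,
  truth = sum(st$freeze_intervals$t_end - st$freeze_intervals$t_start))
#> detected    truth
#>     96.4     98.4
```

The 2 s gap is the detector's stated resolution: bouts shorter than
1.2 s (three analysis steps) are invisible under the 1 s rule. Now map the
same behavior onto a low-DMF field gradient whose freeze gate sits at
180 mT and summarise freezing by field bin:

```r
grid <- generate_field_grid(field_synth_params(peak_mT = 270, distal_mT = 100))
stc <- generate_track_field_coupled(track_synth_params(duration = 300, seed = 11),
                                    grid, threshold_mT = 180)
rsc <- resample_track(stc$track)
bin_behavior_by_field(rsc, grid, detect_freezing(rsc)$bouts,
                      c(100, 140, 180, 220, 270))
#>   B_low B_high occupancy_time freezing_time freezing_rate
#> 1   100    140           78.8             0     0.0000000
#> 2   140    180           62.8             0     0.0000000
#> 3   180    220           74.4            24     0.3225806
#> 4   220    270           84.0            34     0.4047619
```

Freezing is elevated only in bins at or above 180 mT — the binned rates
recover the gate. The same pattern of generate → analyse → compare against
ground truth runs for photometry (`generate_photometry()` →
`compute_dff()` → `align_to_events()`), ROI traces (`dff0()`,
`peak_dff0()`, `auc_dff0()`), PET tables (`percent_id_per_g()`,
`dmf_over_baseline()`), and cell images (`generate_cell_image()` →
`count_cfos()`).

An end-to-end run over all stages, from one YAML/list config and one seed,
with CSV/JSON outputs and a deterministic report:

```r
run_pipeline(list(seed = 1), "out/")
```

A thin command-line wrapper over the same functions ships at
`inst/cli/behave.R` (subcommands `score`, `fieldbin`, `photometry`, `roi`,
`pet`, `cfos`, `run`).

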