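# mmrlink

Analysis pipeline linking MEG **mismatch responses (MMR)** at the
cortical-label level to behavioral **phonetic discrimination (d′)** —
for auditory-neuroscience studies comparing listener groups with
different language backgrounds on an oddball speech contrast.

The package takes *label-level source time courses* (per subject and
condition, a `labels × time × 3` array of free-orientation dipole
vectors) plus trial-level AX discrimination tables, and provides:

* **Behavior** — hit/false-alarm scoring and
  `d′ = Φ⁻¹(h*) − Φ⁻¹(f*)` with documented edge corrections
  (`score_ax()`, `dprime()`).
* **MMR** — subtract-then-norm vector mismatch magnitudes, label
  averaging, ROI/time-window means with a `[start, end)` convention,
  log transform (`compute_mmr()`, `roi_window_mean()`, `log_mmr()`).
* **Group inference** — pooled/Welch t tests with Cohen's d, and a
  spatiotemporal **threshold-free cluster enhancement (TFCE)**
  permutation test with max-statistic familywise control, compiled in
  C++ (`two_sample_t()`, `tfce_permutation_test()`).
* **Neural–behavioral link** — ROI regression `d′ ~ logMMR × group`
  with simple slopes (`fit_roi_interaction_model()`), and time-resolved
  **linear SVR decoding** of d′ from all labels under leave-one-out
  cross-validation, with a pooled permutation null and its empirical
  99th-percentile threshold (`decode_pipeline()`). The ε-SVR solver is
  a built-in SMO (C++), pinned to reference LIBSVM solutions in tests.
* **Synthetic cohorts** — a generator with recorded ground truth
  (two groups × 15 subjects, 150 labels, −100…900 ms epochs, a
  post-200 ms MMR larger in the nonnative group, and a log-MMR→d′
  coupling confined to the native group's left frontotemporal labels),
  plus oddball sequence generation (`simulate_cohort()`,
  `generate_oddball_sequence()`).

See `vignettes/mmr-neurobehavioral-pipeline.Rmd` for the models,
parameter choices, and known limitations (including an honest account of
a recovery target the 15 + 15 / 40-trial design cannot meet).

## Worked example

```r
library(mmrlink)

cfg <- sim_config(seed = 3)            # the default stated world
cohort <- simulate_cohort(cfg)
scores <- score_ax(cohort$behavior)
mmr <- compute_mmr_matrix(cohort$evoked, cohort$groups)

## group-level TFCE permutation map
grp <- mmr$groups$group[match(mmr$subjects, mmr$groups$subject_id)]
map <- tfce_permutation_test(mmr$data[grp == "nonnative", , ],
                             mmr$data[grp == "native", , ],
                             cohort$adjacency, n_perm = 1024, seed = 1)
map
#> <tfce_map> 150 x 201 samples, 1024 permutations, min p = 0.0009756 (E=0.5, H=2, dh=0.1337, stat=t)

## ROI interaction regression (left inferior frontal gyrus)
fits <- roi_regression_suite(mmr, scores, cfg$roi_label_ids)
fits$left_IFG
#> <roi_regression> left_IFG: R^2 = 0.496, model p = 0.0004126 (n = 30)
#>            term estimate     se       t         p
#> 1   (Intercept)  1.59132 0.3621  4.3946 0.0001661
#> 2       log_mmr -0.06514 0.3827 -0.1702 0.8661534
#> 3         group  0.25468 0.4047  0.6294 0.5345966
#> 4 log_mmr:group  1.48761 0.5436  2.7367 0.0110400

## time-resolved SVR decoding, native group only
native <- mmr_group_slice(mmr, "native")
dp <- scores$dprime[match(native$subjects, scores$subject_id)]
res <- decode_pipeline(native, dp, n_perm_per_time = 100, seed = 5)
res
#> <decode_result> 201 time samples, threshold (p99) = 0.237, 23 significant
#>   final model: r = 0.776 (one-sided p = 0.000334), R^2 = 0.517
```

Reading the output: the TFCE map's smallest familywise-corrected p
(0.001) flags the planted post-200 ms group difference; the left-IFG
model shows the d′ ~ log-MMR relation is carried by the interaction
(native-group slope ≈ −0.07 + 1.49 ≈ 1.4, nonnative ≈ −0.07,
interaction p = 0.011), and the decoder finds a significant window
(0.26–0.57 s, overlapping the planted 200–500 ms coupling) whose pooled
leave-one-out predictions correlate r = 0.78 with measured d′.

## Command line

The umbrella script is installed under the package's `exec/` directory:

```sh
MMRLINK=$(Rscript -e 'cat(system.file("exec", "mmrlink", package = "mmrlink"))')
Rscript "$MMRLINK" run-all --seed 7 --out out/       # simulate → … → decode
Rscript "$MMRLINK" simulate --seed 7 --out cohort/
Rscript "$MMRLINK" score-behavior --in cohort/behavior.tsv --out scores.tsv
```

`run-all` writes every stage's TSV outputs plus `manifest.json`
(version, config, per-stage child seeds, md5 checksums — no timestamps,
so a repeated seed reproduces the manifest byte for byte).

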