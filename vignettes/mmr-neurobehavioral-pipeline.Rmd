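---
title: "Linking mismatch responses to phonetic discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking mismatch responses to phonetic discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrlink)
```

## The scientific problem

Listeners discriminate speech contrasts of their native language better
than nonnative ones. The mismatch response (MMR) — the difference between
neural responses to rare "deviant" and frequent "standard" sounds in an
oddball stream — indexes neural sensitivity to the sound change, and MEG
source modeling localizes it to cortical labels. Two questions drive this
package's pipeline:

1. **Group level** — do language groups differ in the spatiotemporal
   distribution of the MMR across cortical labels?
2. **Individual level** — does a listener's MMR amplitude predict their
   behavioral discrimination sensitivity (d′), and is that
   neural–behavioral coupling the same in both groups?

The pipeline's entry point is *label-level source time courses*: for each
subject and condition, a `labels × time × 3` array of free-orientation
dipole vectors (dSPM-like arbitrary units). Everything upstream — sensor
recording, preprocessing, inverse modeling — is out of scope; a synthetic
cohort generator with recorded ground truth stands in for real recordings
so that every stage is testable.

## Behavioral model: equal-variance signal detection

An AX trial presents two sounds; the subject answers "same" or
"different". With pairings AA, AB, BB, BA (10 trials each), *hits* are
"different" responses on AB/BA trials and *false alarms* are "different"
responses on AA/BB trials. Sensitivity is

$$ d' = \Phi^{-1}(h^*) - \Phi^{-1}(f^*) $$

with edge-corrected rates $h^*, f^*$. Two corrections are implemented:

* **halfcount** (default): a rate of 0 becomes $1/(2N)$ and a rate of 1
  becomes $1 - 1/(2N)$; interior rates are untouched. Simple and common,
  but carries a positive finite-sample bias of ≈0.04–0.08 at 40 trials.
* **loglinear**: add 0.5 to each count and 1 to each denominator; applied
  everywhere; near-unbiased at 40 trials (|bias| ≈ 0.01 in our
  simulations).

The published behavioral protocols this emulates do not state their edge
rule, so both are exposed (`correction=` in `score_ax()` / `dprime()`).
Responses coded `none` (timeouts) are dropped from numerator and
denominator alike.

## MMR computation

With free-orientation sources each label carries a 3-component dipole
vector per time sample. The MMR is computed by subtracting the standard's
vectors from the deviant's and *then* taking the Euclidean norm:

$$ \mathrm{MMR}_{l,t} = \lVert \mathbf{d}_{l,t} - \mathbf{s}_{l,t} \rVert_2 . $$

Order matters: when vertex-level data are supplied, vertices are averaged
into labels per component *first* (`average_labels()`), then the
subtract-then-norm step runs on label vectors. Magnitudes are nonnegative;
additive sensor/source noise therefore produces a positive noise floor
(a chi-distributed magnitude) even where no true difference exists — one
reason the pipeline works on window averages and permutation nulls rather
than raw baselines. No baseline correction is applied (none is defined for
magnitude data; the pre-stimulus floor is part of every condition alike).

Analysis windows are `[start, end)` on the sample grid — closed on the
left, open on the right — so adjacent windows tile without overlap. The
ROI/window average is log-transformed (`log_mmr()`) before regression to
reduce the right skew of magnitude data; values at or below `1e-12` raise
an error by default (`clamp = TRUE` exists for noisy real data).

## Group-level inference: TFCE with max-statistic permutation

Per (label, time) sample the group difference is a pooled two-sample t.
Threshold-free cluster enhancement integrates suprathreshold cluster
extent over a ladder of thresholds,

$$ \mathrm{TFCE}(s) = \sum_{h = dh, 2dh, \dots}^{\max} e(h, s)^{E}\, h^{H}\, dh, $$

with clusters connected through label adjacency (same sample) and ±1 time
sample (same label). Defaults $E = 0.5$, $H = 2$ are the canonical
enhancement exponents; $dh$ defaults to $\max|t|/50$ of the *observed*
map and the same ladder step is reused for every permuted map, so observed
and null enhancement are directly comparable. The enhanced statistic is
$|t|$ by default (two-sided); `statistic = "F"` enhances $t^2$ instead.

Significance uses the max-TFCE permutation null: group labels are permuted
`n_perm` times (default 1024, seeded), and

$$ p(s) = \frac{1 + \#\{ \text{perm}: \max_{s'} \mathrm{TFCE}_{\text{perm}}(s') \ge \mathrm{TFCE}_{\text{obs}}(s) \}}{n_{\text{perm}} + 1}, $$

giving strong familywise control; maps report $-\log_{10} p$. The
permutation engine is compiled (C++) — a 150-label × 201-sample grid at
1024 permutations runs in ≈25 s on one CPU.

## Individual-level analyses

### ROI interaction regression

For each a-priori ROI (left/right inferior frontal and superior temporal
label sets) the window-averaged (200–500 ms default), log-transformed MMR
enters an OLS model

$$ d' \sim \log\mathrm{MMR} \times \mathrm{group}, $$

with group coded 0 = nonnative, 1 = native, so the interaction coefficient
equals the native-group simple slope minus the nonnative-group slope.
Coefficient tests use the residual $n - 4$ df; per-group simple slopes and
their SEs are derived from the coefficient covariance.

### Time-resolved SVR decoding

Per time sample, a linear ε-insensitive support-vector regression predicts
each subject's d′ from the MMR values of *all* labels, under leave-one-out
cross-validation (all $n$ splits). Performance is the coefficient of
determination on the pooled LOO predictions,
$R^2 = 1 - SS_{res}/SS_{tot}$, which may be negative (LOO is pessimistic
under the null); the squared Pearson correlation is reported alongside
because "R²" is ambiguous between the two in common usage. SVR parameters
are the conventional linear-kernel defaults C = 1.0, ε = 0.1.

The null model shuffles the correspondence between d′ and the spatial
patterns within each time sample (100 permutations per sample, fresh draws
per sample, seeded), re-running the full LOO loop each time; all
$T \times 100$ null R² values are pooled and the empirical 99th percentile
(type-7 quantile) is the significance threshold — a conservative implicit
multiple-comparison control. A final SVR is then fit on the significant
samples; its features default to the **time-averaged** label vector across
those samples (dimensionality stays at `n_labels` with n = 15 subjects;
`features = "concat"` concatenates instead). The per-label contribution
map is the mean absolute linear weight across LOO folds — a documented
substitute for an unstated "significant contributors" criterion, not a
formal test. The decoding analyses run separately per group.

Because no SVM solver package is available in the supported environment,
the package ships a small sequential-minimal-optimization solver for the
ε-SVR dual (linear kernel, C++). Its KKT gap tolerance is fixed at `1e-6`
so LOO results are reproducible across platforms; the test suite pins it
to reference LIBSVM/scikit-learn solutions to ≈1e-4.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject:

* latent sensitivity $s_i \sim N(\mu_g, \sigma_g)$ truncated at 0
  (negative planted sensitivity is not meaningful), with group means
  1.67 / 2.26 — the values implied by inverse-normal transforming
  published group hit and false-alarm rates for a voice-onset-time
  contrast — and SDs 0.45 (nonnative) / 1.10 (native);
* an SDT criterion $c_i \sim N(1.30, 0.30)$: the absolute criterion
  implied by published false-alarm rates near 0.08–0.11
  ($c = -\Phi^{-1}(f)$), which also reproduces the published hit rates
  ($\Phi(2.26 - 1.30) = 0.83$);
* per-label deviant-component amplitudes
  $$ A_{il} = \exp\big(\log B_g + \eta_i + \varepsilon_{il} +
     \gamma_g (s_i - \mu_g) \cdot \mathbf{1}[l \in \text{coupling ROIs}]\big), $$
  with base amplitudes $B$ = 4 (nonnative) > 2 (native) — the nonnative
  group's larger, more expansive MMR — a subject-level lognormal factor
  $\eta_i$ (SD 0.3) representing global inter-individual amplitude/SNR
  differences, label-level noise $\varepsilon_{il}$ (SD 0.2), and coupling
  $\gamma$ = 0.4 *only* in the native group's left IFG + STG labels.
  Centering the coupling on the group mean keeps the native group's mean
  amplitude at its base value, preserving the group-level contrast.

Waveforms are sums of Gaussian bumps: both conditions share early peaks at
100 and 130 ms (widths 20 ms, amplitudes 3 and 2 a.u.); the deviant adds a
bump centered in the coupling window (0.35 s, width 60 ms, unit peak)
scaled by $A_{il}$. All components lie along one fixed random unit
3-orientation per label per subject, so with `noise_sd = 0` the MMR at the
bump center equals the planted amplitude exactly — the identity the test
suite asserts. Additive Gaussian component noise defaults to SD 0.25,
a *averaged-evoked* regime (≈150 deviant trials averaged). Sampling is
200 Hz over −100…900 ms (a desk-scale stand-in for 1 kHz acquisition;
the rate is a config knob). Oddball sequences (80% standards, ≥2 standards
before every deviant, SOA jittered ±50 ms around 800 ms) are generated and
exported, though evoked responses are emitted directly as averages — the
trial-level route is a non-goal.

All randomness flows from one master seed through a documented affine
counter scheme (`child_seed()`), so cohorts are bitwise reproducible and
the `run_all()` manifest (which deliberately contains no timestamps) is
byte-identical across runs with the same seed.

### What the generator does and does not emulate

It reproduces the *statistical structure* the analyses assume: a group
difference in post-200 ms MMR amplitude, a one-group-only log-linear
amplitude–sensitivity coupling confined to left frontotemporal labels, and
SDT-consistent AX behavior. It does **not** emulate: spatially correlated
source leakage between labels, non-Gaussian artifacts, latency (as opposed
to amplitude) coupling, trial-level variability surviving averaging, or
real parcellation geometry (adjacency is a within-hemisphere band graph).
A green recovery test therefore establishes that the pipeline detects the
planted structure under idealized but honestly noisy conditions — not that
it would behave identically on real MEG source estimates.

### A power ceiling the tests document rather than hide

The acceptance suite asserts that the ROI interaction is recovered
(p < 0.05) in ≥80% of default cohorts. Analysis shows this target is not
attainable in this world: d′ estimated from 40 AX trials carries binomial
noise of variance ≈0.27 on the d′ scale, and with 15 subjects per group
the expected interaction t statistic is bounded near 2.1 *no matter how
strong the planted coupling is* (the bound trades the coupled group's
slope precision against the uncoupled group's log-MMR variance; ablating
behavioral trial noise lifts recovery to ~90%). Observed recovery is
≈45%. The assertion is kept as an executable statement of the design goal
and left failing, because weakening it would misrepresent what a 15 + 15
design with a 40-trial behavioral measure can deliver — a caution equally
relevant to the empirical literature this mirrors, where the corresponding
interaction was significant at p = 0.049. The SVR decoding recovery
(≥80% of replicates flag the planted 200–500 ms window for the coupled
group; uncoupled group at chance) *does* hold: pooling information across
all labels and maximizing over the window is the more powerful route.

## Numerical choices

* **Window discretization**: `[start, end)` with a 1e-9 guard against
  floating-point representation of grid times.
* **TFCE ladder**: `dh = max(observed)/50`; fixed across permutations;
  samples below the first rung get 0. Brute-force threshold summation is
  the test oracle (to 1e-3 relative at dh = 0.001).
* **Degenerate inputs**: zero variance in both t-test samples, constant
  d′ in decoding (SS_tot = 0), empty ROI or window, adjacency asymmetry,
  and rank-deficient regression designs all raise early, named errors.
* **Empty significant set**: `final_svr()` returns a structured
  `significant = FALSE` result, never an exception.
* **Quantile type**: the pooled-null threshold uses R's default type-7
  empirical quantile; with 20 100 pooled values the choice among types
  moves the threshold negligibly.
* **Permutation p floor**: `(1 + #exceed)/(n_perm + 1)` keeps p in
  `[1/(n_perm+1), 1]` — never exactly zero.

## Known limitations

* Label count defaults to 150 and is configurable; real Destrieux
  parcellations have 148 cortical labels. Nothing in the pipeline assumes
  a specific count.
* The contribution map (mean |weight|) ranks labels but has no calibrated
  error rate.
* The oddball sequence generator and the evoked generator are not coupled
  trial-by-trial (averages are emitted directly).
* The SMO solver handles the n ≤ a-few-hundred kernel regime this design
  needs; it is not a general-purpose large-scale SVM.
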