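---
title: "Seizure network analysis with ictalnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure network analysis with ictalnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalnet)
```

## What the package computes

`ictalnet` analyses how functional brain networks form and dissolve across
the clinically delineated phases of epileptic seizures recorded with
stereotactic EEG (SEEG), and relates them to structural connectivity from
diffusion tractography. The pipeline has five stages, each usable on its
own:

1. **Signal windows.** An EDF recording plus a sidecar JSON of event
   annotations (seizure id, phase, start/end seconds, involved contacts)
   is sliced into event windows; a segment store of fixed-duration windows
   is also available (`segment_recording()`).
2. **Nonlinear coupling.** For every ordered pair of contacts the
   nonlinear correlation coefficient h² is computed over the whole event
   window, with a lag scan (`event_coupling_matrix()`).
3. **Directed event graphs.** Thresholds derived once from a pre-ictal
   baseline turn each event's coupling matrix into a directed graph with
   weak and strong edges (`fit_baseline()`, `build_event_graph()`).
4. **Graph motifs.** Cosine similarity between adjacency rows feeds an
   average-linkage agglomeration whose dendrograms describe how contacts
   cluster into modules during each event (`cosine_similarity()`,
   `agglomerate()`).
5. **Phase statistics and tracts.** Per-pair h² changes against a control
   period are tested with exact Wilcoxon signed-rank statistics under
   Benjamini–Hochberg FDR control (`pair_differences()`,
   `phase_signed_rank()`); streamlines between labeled electrode ROIs are
   counted and compared to control means (`tract_count_matrix()`,
   `difference_vs_controls()`).

## The nonlinear correlation coefficient h²

Given amplitude samples $x$ of a predictor channel and $y$ of a target
channel, the observed range of $x$ is divided into $B$ equal-width bins.
The regression curve $f$ linearly interpolates the points (bin midpoint,
mean of $y$ in the bin); empty bins are skipped, and beyond the outermost
occupied midpoints $f$ extrapolates as a constant. Then

$$h^2(y \mid x) \;=\; \max\!\left(0,\; 1 -
  \frac{\sum_i (y_i - f(x_i))^2}{\sum_i (y_i - \bar y)^2}\right),$$

clamped to $[0,1]$. Because $f$ is an arbitrary curve rather than a line,
h² captures nonlinear dependence that Pearson correlation misses (a purely
quadratic coupling has $r^2 \approx 0$ but $h^2 \approx 0.99$), and it is
asymmetric: $h^2(y\mid x) \ne h^2(x \mid y)$ in general.

Two numerical subtleties are worth stating:

* **The binning bias.** $h^2(x \mid x)$ equals 1 only when the curve can
  pass through every sample (for instance two-level, square-wave-like
  amplitudes). For continuous signals the midpoint-knot discretization
  leaves a small residual — about 0.0015 at the defaults — which vanishes
  as the bin count grows. The statistic is best read as "explained
  variance up to binning resolution".
* **Positive bias under independence.** With finite windows the binned
  means track noise, so independent channels score a small positive h²
  (95th percentile about 0.03–0.05 at $n = 2000$, 10 bins). This is why
  edge detection is always relative to a baseline-derived threshold,
  never to zero.

### Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_bins` | 10 | bins | stable curves for windows of 1000+ samples |
| `min_points_per_bin` | 10 | samples | shrinks `n_bins` (with a warning) on short windows |
| `lag_range_ms` | ±100 | ms | covers physiological propagation delays at modest cost |
| `lag_step_samples` | 1 | samples | exhaustive scan inside the range |

Bins are equal-width on the observed predictor range (not equal-count):
this matches the classical description of the estimator and makes h²
invariant under separate affine rescaling of either channel. One h² is
computed per ordered pair over the *whole* event window — the temporal
bin of the analysis is the clinical event itself, with no sub-windowing —
so each event yields a single coupling matrix.

### Direction of coupling

The lag scan shifts the target relative to the predictor and keeps the
maximizing lag (ties resolve toward the smallest absolute lag, then the
negative one). Two direction signals coexist:

* for **nonlinear** coupling the h² magnitudes of the two directions
  genuinely differ (predicting the squared signal from its source
  succeeds; inverting a many-to-one map does not);
* for **linear** coupling the two magnitudes are statistically
  indistinguishable — explained variance is symmetric for jointly
  Gaussian signals — and the reliable signal is the *sign of the
  maximizing lag*: the driven channel lags its driver.

`build_event_graph(rule = "winner_take_all")` therefore offers both
criteria (`direction = "h2"` or `"lag"`). This was a genuinely open
design point; simulation settled it (the lag sign recovers planted linear
directions essentially always, while the magnitude comparison is a coin
flip), and the lag criterion is the one used in the package's own
recovery benchmarks.

## Baseline thresholds and event graphs

All off-diagonal h² values of the baseline-window coupling matrix are
pooled; with mean $\mu_b$ and sample standard deviation $\sigma_b$, the
edge thresholds are $t_1 = \mu_b + \sigma_b$ (weak, dashed) and
$t_2 = \mu_b + 2\sigma_b$ (strong, solid), fit once and applied to every
event of every seizure. Inequalities are strict at both thresholds. A
baseline shorter than 20 s triggers a warning rather than an error. By
default each ordered pair is thresholded independently, so reciprocal
edges can coexist; winner-take-all is available as described above.
Per-pair thresholds are deliberately *not* offered: with one baseline
window there is a single pooled estimate worth trusting.

Note that $t_1$ sits one standard deviation above the baseline mean *by
construction*: if baseline and event coupling are drawn from the same
distribution, roughly the upper sixth of null pairs will clear it. Weak
edges are therefore descriptive; analyses that need controlled error
rates should use strong edges or the signed-rank machinery.

## Cosine similarity and dendrograms

With adjacency matrix $M$ (binary by default: 1 for any edge; a weighted
mode encodes weak = 1, strong = 2), the similarity of vertices $x, y$ is

$$\sigma_{xy} = \frac{\sum_k M_{xk} M_{yk}}
  {\sqrt{\sum_k M_{xk}^2 \sum_k M_{yk}^2}},$$

the cosine between the two out-neighbour rows; for binary rows this is
$\mathrm{overlap}/\sqrt{\deg_x \deg_y}$, which is exactly the closed form
behind the worked values in the test suite (e.g. $3/\sqrt{12} =
0.866025$). Binary adjacency is the default because those closed forms
reproduce reported electrode-pair similarities; a weighted variant exists
for sensitivity analyses but a few reported values (0.59625, 0.251899)
match neither convention and the discrepancy is left unresolved rather
than papered over. Rows that are all zero get $\sigma = 0$ against
everything, including themselves.

Clustering agglomerates on the dissimilarity $d = 1 - \sigma$ with
**average linkage**: monotone (no dendrogram inversions), standard, and
faithful to "merge the most similar groups first". Ties break toward the
pair containing the lexicographically smallest member label, so
dendrograms are bit-reproducible; isolated vertices sit at $d = 1$ from
everything and join last at the maximal height. Similarity values are
rounded to 6 decimals for distribution binning, and the zero bin is
excluded by default (it would swamp the histogram with never-interacting
pairs).

## Phase-change statistics

For each unordered pair of contacts *on distinct electrodes* (same-lead
pairs mostly measure volume conduction), the two directed h² values are
collapsed to one — the maximum by default, the mean behind a flag — and
the seizure-matched control-period value is subtracted, one difference
per seizure. Seizures lacking a phase simply contribute nothing for that
phase. The control period defaults to the same pre-ictal baseline used
for thresholding but is independently configurable, since a thresholding
window and a statistical control window need not coincide.

`signed_rank()` drops zero differences, uses the exact tie-aware null
distribution of the rank sum for up to 25 effective differences (computed
by convolution over doubled ranks, so midranks stay integral), and a
tie-corrected normal approximation above. `bh_adjust()` is the classical
step-up: sort the $m$ p-values, compare $p_{(i)}$ with $c_i = iq/m$, and
reject the largest prefix with $p_{(i)} \le c_i$, reporting the per-rank
critical values and the cutoff index. Each phase forms its own testing
family. `top_pairs()` returns the $k = 25$ smallest-p pairs with their
per-seizure difference vectors for boxplots.

## Structural tracts

The imaging stage consumes *outputs* of an upstream pipeline — a NIfTI
label volume (one integer label per electrode or gyrus ROI) and a TCK
streamline file in world millimetres — and performs only the final,
bespoke step: each streamline endpoint is mapped to its nearest voxel via
the inverse affine, and a streamline whose endpoints carry two distinct
nonzero labels increments that pair's count once. Tracts are undirected;
the diagonal is forced to zero; streamlines touching background are
ignored. Whether endpoints or whole-path intersections should count is
not settled in the field, so a `mode = "path"` sensitivity check links
every label the polyline's vertices visit; endpoint semantics remain the
default because the quantity of interest is connections *between* ROIs.
Registration, segmentation and tractography themselves (FLIRT, FAST,
FIRST, CSD, iFOD2, …) are out of scope — published tools do them better.
TRK input is not supported; MRtrix-style TCK is the expected interchange
format.

## The synthetic generator

Because clinical SEEG and imaging data cannot ship with a package, every
stage is validated against a generator with known ground truth:

* **Sources** are 1–40 Hz band-limited Gaussian noise at 200 Hz (delta
  rhythms representable, tests fast). A planted edge makes the target
  `gain · f(source delayed by lag) + noise_sd · noise` with `f` linear,
  quadratic, or `tanh(3x)`; the expected h² of the true direction is
  roughly `gain² / (gain² + noise_sd²)`.
* **Scenarios** concatenate phases, each with its own coupling; the onset
  phase superimposes a 4–5 Hz rhythmic-delta oscillation on the involved
  contacts, matching the onset pattern of insular-onset seizures (8
  seizures with 42–58 s onsets are the emulated regime; the demo scenario
  uses a 20 s baseline and a 45 s onset).
* **Baselines carry weak background coupling** (gains 0.15–0.25 buried in
  noise). This is deliberate: the threshold model presupposes the spread
  of real pre-ictal coupling, and a perfectly independent baseline gives
  it a degenerate, near-zero standard deviation that no recording ever
  shows — the thresholds would then sit inside the null distribution's
  tail and admit spurious edges.
* **Recovery scoring** uses disjoint planted pairs
  (`recovery_scenario()`): a hub topology induces genuine transitive
  correlations between co-driven channels, so it cannot separate detector
  error from model limitation. The benchmark regime is gain 0.9, noise
  0.1, 5000-sample windows, winner-take-all with lag direction, strong
  edges, strict direction scoring, 20 seeds; the suite requires pooled
  precision and recall of at least 0.8 (observed: 1.0).
* **Streamline phantoms** lay out disjoint cubic ROIs on a lattice with a
  background gap, plant exactly the requested number of streamlines per
  pair (plus background-to-background distractors), and are recovered
  exactly by the counting stage.

What the generator does *not* emulate: neural mass dynamics, 1/f spectra,
artifacts, montage effects, volume conduction, or realistic DWI physics.
A passing suite therefore certifies the *statistical machinery* — that
the estimator, thresholds, clustering and tests do what they claim on
data with the assumed structure — not clinical performance on patient
recordings.

## Problem sizes and determinism

Simulation-based checks are sized for a desk machine: 20-seed recovery
runs use 6 channels and 25 s phases; the null calibration of the
signed-rank test uses 500 pairs of 8 seizures with 5.12 s windows; the
dendrogram and B-H oracle sweeps use 8-vertex and up-to-100-test cases.
All randomness flows from explicit seeds; `run_pipeline()` seeds
everything from its config, hashes the config into the manifest, and
rewrites byte-identical artifacts when rerun.

## Known limitations

* h² on short windows (< 1000 samples) forces bin-count reduction and
  loses sensitivity; the whole-event convention assumes events of tens of
  seconds.
* Weak (1 sd) edges admit a predictable fraction of null pairs — use them
  descriptively.
* The EDF writer covers the ordinary 16-bit case (one sampling rate,
  integral record layout); EDF+ annotations are skipped on read in favour
  of sidecar JSON.
* Tract counting trusts the label volume's affine; no dilation of labels
  is performed, so ROIs should already include the voxels the upstream
  delineation intended.
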