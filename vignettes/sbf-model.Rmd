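---
title: "Recovering illusory edges from sparse transformation events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering illusory edges from sparse transformation events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbfsim)
```

## The phenomenon and the display

Spatiotemporal boundary formation (SBF) is the perception of continuous
illusory contours, shape, and motion from sparse, sequential changes of
texture elements. The minimal display approaching the conditions for
seeing a single illusory edge is a *sawtooth* array of dots in which one
dot at a time disappears and later reappears. Physically the display is a
sequence of isolated flashes; perceptually, within certain spatiotemporal
limits, it is a moving bar with two crisp illusory edges. Outside those
limits it reverts to element-to-element apparent motion.

`build_sawtooth()` constructs the array: dots at horizontal spacing
$h$, with vertical offsets following the triangle wave
$0, s, 2s, s, 0, \dots$ (period four columns, so a rise–fall excursion
touches five dots), giving a peak-to-trough extent of $2s$. With equal
horizontal and vertical steps and spacings up to 2.0°, the tallest pattern
used in the experiments extends 4°. The non-collinearity of the sawtooth is
essential: for collinear elements the transformation times carry no
information about edge orientation.

All spatial quantities are in degrees of visual angle, durations in
milliseconds, speeds in deg/s. Monitor pixel geometry and viewing distance
are not modeled; coordinates are x rightward, y upward, origin at the
first dot.

## Timing algebra

A display condition is equivalently described by the physics of the
virtual bar (width $w$, speed $v$, spacing $h$) or by the timing triple

* **EOD** — element offset duration, the time a dot stays invisible,
* **ISI** — inter-stimulus interval, reappearance-to-next-disappearance,
* **SOA** — stimulus onset asynchrony, $\mathrm{SOA} = \mathrm{ISI} +
  \mathrm{EOD}$,

linked by $v = h/\mathrm{SOA}$ and $w = v\,\mathrm{EOD}$
(`timing_from_bar()`, `bar_from_timing()`; exact algebraic inverses,
round-tripping to $10^{-12}$ relative error). When $w > h$ a second dot
disappears before the first reappears and the ISI is negative. The
identity $\mathrm{SOA} = \mathrm{ISI} + \mathrm{EOD}$ is enforced exactly
on every constructed triple.

## Event scheduling

`schedule_bar_events()` treats disappearance as the moment the bar's
leading edge *reaches* the dot center and reappearance as the moment the
trailing edge *passes* it (crossings are computed at dot centers, not
rims). Event times are kept continuous and exact in schedules; frame
quantization happens only at rasterization (`rasterize_schedule()`, floor
rule: an event takes effect at the first frame whose start time is at or
after the event time; default refresh 100 Hz). The rationale is that the
analyses operate on nominal SOA/EOD values, not frame-quantized ones — a
100 Hz display cannot realize 76 ms exactly, and we treat the frame raster
as a rendering concern. A quantized pathway is available through
rasterization for sensitivity checks.

Oblique bars moving horizontally produce element-dependent intervals —
shorter between dots on paths parallel to the bar, longer perpendicular to
it — which is how edge orientation is encoded purely temporally.
`schedule_shape_events()` generalizes to a simple polygon moving over a
field of elements with a binary property (`flip_in`/`flip_out` events from
exact boundary-crossing computation). Simultaneous events are ordered by
element id; sweep reversal at the field edge is implemented as schedule
concatenation with mirrored velocity.

## Edge recovery: the crossing model

A straight edge with unit normal $\mathbf{n}$ moving at constant normal
speed $s$ crosses position $\mathbf{p}_i$ at
$t_i = t_0 + \mathbf{n}\cdot\mathbf{p}_i / s$ — *linear in position*. We
therefore fit $t = a + \mathbf{g}\cdot\mathbf{p}$ by least squares
(`recover_edge()`, with `recover_edge_triple()` the exact three-event
case) and read off $\mathbf{n} = \mathbf{g}/\lVert\mathbf{g}\rVert$,
$s = 1/\lVert\mathbf{g}\rVert$. This formulation was chosen over the
equivalent homogeneous one ($ax + by + ct = 1$) because its residuals are
in time units, directly interpretable against timing noise, and because
degeneracies map cleanly onto perceptual categories:

* collinear positions make the design rank-deficient →
  `ambiguous_collinear` (the point-aperture problem; never a numeric
  orientation);
* simultaneous times over non-collinear positions give
  $\mathbf{g} = 0$ → `inconsistent` (no finite-speed edge);
* fewer than three distinct positions → `insufficient`.

Orientation is reported mod 180° with $s \ge 0$ and the motion direction
carried separately in $\mathbf{n}$, removing the $(\theta + 180°, -s)$
ambiguity. Collinearity is tested as the ratio of singular values of the
centered positions (threshold `collinearity_tol`, default $10^{-9}$,
relative to the pairwise-distance scale). A fit whose residual RMS exceeds
`residual_tol` (default 10 ms, comfortably above plausible timing noise
but below the display's timing structure) is not reported as a unique
edge.

`estimate_bar()` recovers the leading edge from gated disappearances and
the trailing edge from gated reappearances, then estimates width as
$s \times$ mean per-element occlusion duration. A second, independent
route — the perpendicular separation of the two recovered edge lines at a
common time — is computed as a cross-check; a relative discrepancy beyond
`width_check_tol` (default 0.25, loose enough that measurement noise in
either route does not trigger it) marks the schedule `inconsistent` and
withholds the width.

## Temporal gating

Integration of events into an edge is limited by time, not by the number
of available events. `gate_events()` chains same-kind events whose
consecutive intervals are at most `soa_gate_ms` (default 80 ms: illusory
contours weaken steeply past ~76 ms and are never seen past ~100 ms) and
requires that at least three consecutive events of a chain fall inside a
`window_ms` window (default 165 ms; at the 80 ms gate three events span
160 ms). We read the window as a constraint on capturing three events —
not on the whole chain — so that a long display at a short SOA still
forms a single integrable group, which matches the phenomenology: the bar
is seen continuously throughout such a display. `predict_percept()` is
the resulting deterministic rule: SBF iff $\mathrm{SOA} = h/v$ is within
the gate; otherwise apparent motion. No spatial gate is implemented: the
data leave open whether the breakdown beyond ~1° spacing is a hard
spatial limit or an SOA limit in disguise, and the SOA-only model is the
more parsimonious reading. Disappearances and reappearances are never
mixed within one group; the trailing edge is recovered from
reappearances by the same machinery, not by pooling.

## Motion-energy exploration

The package includes the conjecture that large motion-energy filters act
as spatiotemporal *edge* detectors when no frame contains oriented
contrast. `build_filter_bank()` constructs oriented quadrature pairs
(Gabor under a Gaussian spatial envelope; complex exponential under an
even Gaussian temporal envelope), by default pairing filters at the
inter-element scale with one spanning the sawtooth's full height.
`apply_energy()` projects frames onto the pair, convolves with the
temporal kernel (full, zero-padded), and sums squared moduli over lags.
Kernel shapes and parameters are config-exposed: the conjecture names a
framework, not parameters, so defaults favor broad tuning (one cycle per
envelope, $\sigma$ = extent/4; temporal $\sigma$ = 12.5 ms under a 50 ms
extent). Both spatial kernels are mean-centered so that a blank movie
yields exactly zero energy on the discrete grid, and the even temporal
envelope makes time reversal of a movie exactly swap direction-paired
energies. The demonstrable ambiguity — a vertical-preferring and an
oblique-preferring large filter both respond above half their maximum to
both a vertical- and an oblique-bar stimulus — is reproduced in the test
suite.

Because raw energies alone cannot disambiguate orientation, the testable
readout operates on the event space–time points: for each candidate
orientation, `constant_velocity_readout()` regresses event time on the
position projected onto the candidate normal; only the generating
orientation yields a perfectly linear relation (linearity score
$1 - \mathrm{RSS}/\mathrm{TSS}$), and the winner provably coincides with
the crossing-model solution on noiseless schedules. The energy-map route
is exploratory; the readout is the defined, testable form of the
conjecture. No adjudication between local element-motion signals and
large-edge signals is modeled; both channel outputs are simply reported.

## The simulated observer

The experiments are regenerated with a parametric observer because no
observer model accompanies the original human data; it is the minimal
mechanistic chain *display → noise → gate → recovery → decision*, each
link anchored to a reported behavior:

* **Detection** is a (soft) threshold on SOA: $p = \mathrm{logistic}
  \big((\tau - \mathrm{SOA})/\beta\big)$ with $\tau$ = 76 ms default and
  $\beta = 0$ giving a hard step. SOA enters at millisecond precision
  (the display clock), so the 76.19 ms condition counts as the published
  76 ms landmark.
* **Recovery**: on detection, the trial's event schedule (perturbed by
  Gaussian time/position noise) is gated and passed to `estimate_bar()`.
* **Choice**: the 4AFC response is the candidate width nearest the
  estimate (ties to the lower index); on any failure the observer
  defaults to the narrowest width, as participants reported doing when
  they saw no bar.
* **Rating**: $\mathrm{round}(1 + 6p)$ on success, 1 on failure. The
  rating tracks the detection probability — a monotone decreasing map of
  SOA onto 1..7 — rather than a separately graded scale, so that for the
  deterministic observer the per-cell mean ratings are an affine function
  of the per-cell slopes. This makes the objective and subjective
  measures perfectly concordant by construction (Spearman rho = 1),
  which is the designed idealization of the strong human concordance;
  with a soft threshold the ratings become graded. EOD modulation of
  ratings at intermediate SOAs is deliberately not modeled: no functional
  form for it is established, and an invented one would only blur the
  SOA-step structure the analyses target.
* **Lapses**: with probability `lapse_rate` the width choice is uniform.

Analyses mirror the published pipeline: per (velocity × spacing) cell,
the slope of judged width (the degree value of the chosen alternative) on
true width is the *size perception accuracy*; ratings are averaged per
cell; concordance is the Spearman rank correlation across the 50 cells;
`replot_by_timing()` re-expresses every condition in (SOA, EOD, ISI) via
the timing identities; and `estimate_soa_threshold()` recovers the
observer's threshold by a change-point fit of a step function to the
slope-vs-SOA pattern, with candidate change points midway between
consecutive distinct cell SOAs. The published human headline numbers
(slopes 0.702/0.083 in the first experiment, rho = 0.893, the slight
compression of the widest bar) are qualitative anchors; they require
human observers and are not targets of the simulation.

## What the generator does and does not emulate

The synthetic displays reproduce the experimental conditions exactly as
designed: four bar widths (0.13–0.53°), speeds 2.6 and 13.2 deg/s with
0.4° spacing and 15 repetitions (120 trials) in the first experiment;
five speeds × ten spacings (0.2–2.0°) × four widths × ten repetitions
(2000 trials, 50 cells) in the second. Simulated trials use a 9-dot array
rather than the full 33-dot screen-wide array: the recovery contract is
invariant to array length (a vertical bar produces the same constant-SOA
event stream), and the shorter array keeps a full experiment fast; the
33-dot geometry is pinned where the physical screen layout itself is the
object of interest. The dot count 33 is treated as a pinned constant of
the original apparatus, not derived from the 13.42° screen width.

Not emulated: eye movements and pursuit (which the phenomenon depends on
for sparse displays), gradual occlusion at dot rims, luminance/gamma of a
physical monitor, equiluminant or second-order transformation classes
beyond the binary property flip, and linking of recovered fragments into
closed global shapes. Passing tests therefore certify the geometry,
timing, and inference machinery — not a prediction of individual human
thresholds.

## Numerical choices and limitations

* Tie-breaks: simultaneous events order by element id; 4AFC ties resolve
  to the lower index; change-point candidates are midpoints of
  consecutive distinct SOAs.
* Problem sizes: unit tests use 9–33-dot arrays, 30–200 random
  conditions/triples per property, and full 120/2000-trial experiment
  runs (about five seconds per 2000-trial simulation); movies for the
  energy pathway are rasterized at 15 px/deg, 100 Hz.
* Seeds: every stochastic routine takes an explicit seed
  (`withr::with_seed` internally); identical config + seed gives
  byte-identical CLI outputs.
* The solver is exact for noiseless schedules by construction; with
  additive time noise of sd $\sigma$ the residual RMS concentrates at
  $\sigma\sqrt{(n-k)/n}$ for $n$ events and $k = 3$ parameters, which the
  tests verify at $\sigma = 2$ ms.
* Known limitations: the rating map is a placeholder (see above); the
  observer has no spatial integration limit; the energy pathway is
  exploratory and its absolute energy units are arbitrary; the aperture
  ambiguity of the single recovered bar's global motion direction is
  inherent and left unresolved, as it is for a bar seen through any
  aperture.
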