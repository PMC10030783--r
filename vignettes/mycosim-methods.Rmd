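---
title: "Excitation waves on mycelium insole networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitation waves on mycelium insole networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mycosim` models a pressure-sensing fungal insole in two complementary
ways. A *simulator* treats the mycelium colonising a foot-shaped substrate
as a two-dimensional excitable medium: pressing the insole excites the
network locally, a wave of excitation spreads along the hyphal strands, and
virtual electrodes read out the passing activity. An *analysis pipeline*
mirrors the laboratory side: multi-channel differential voltage recordings,
sampled at 1 Hz by a data logger, are scanned for spikes whose counts,
timing and amplitudes are compared across mechanical load conditions.
Because neither the original colony artwork nor the raw recordings are
public, both inputs are covered by seeded synthetic generators that are
first-class, tested code.

## The excitable-medium model

The dynamics on each conductive node are the two-variable FitzHugh--Nagumo
(FHN) kinetics,

$$\frac{\partial u}{\partial t} = c_1\, u (u-a)(1-u) - c_2\, u v + I + D_u \nabla^2 u,
\qquad
\frac{\partial v}{\partial t} = b (u - v),$$

with `u` a trans-membrane potential and `v` a slow recovery current. The
cubic term has stable rest states at $u=0$ and $u=1$ and an unstable
threshold at $u=a$; the $c_2 uv$ term is the slow negative feedback. The
defaults are the study conditions throughout: $D_u = 1$, $a = 0.13$,
$b = 0.013$, $c_1 = 0.26$, $I = 0$, integrated by explicit Euler with
$\Delta t = 0.015$ on a grid with spacing $\Delta x = 2$. The diffusion
number $D_u \Delta t/\Delta x^2 = 0.00375$ sits far inside the explicit
stability region. Two printing ambiguities in the source material were
resolved the standard way: the first equation's left-hand side is
$\partial u/\partial t$ (its right-hand side holds the `u` kinetics), and
$c_1$ multiplies the cubic term while $c_2$ scales the $uv$ coupling, so
that $c_2$ is the excitability dial.

### Masked grid, boundaries, and the discrete Laplacian

The domain is a binary *conductive template*: only mycelium-occupied nodes
carry fields, everything else is held at exactly zero. The Laplacian is
the five-node stencil $(\sum_{\mathrm{4-neigh}} u - 4u)/\Delta x^2$, and
no-flux boundaries ($\partial u/\partial n = 0$) are realised by mirroring
the centre value into any off-grid or non-conductive neighbour, which
cancels that neighbour's contribution. The stencil sums its four addends
as `(up + down) + (left + right)`: under any reflection or rotation of the
grid the pair sums only commute and never reassociate, so a symmetric
initial condition stays symmetric *bit-exactly* — a property the test
suite checks over 20&nbsp;000 iterations. Updates are synchronous (all
nodes read the pre-step fields), and any non-finite value aborts the run
with the offending iteration number.

### Excitability endpoints

The working range of $c_2$ is 0.015--0.05. `fhn_excitability_scan()` runs
a centre-stimulated wave on a uniform $100\times100$ grid at both
endpoints and records which one sustains a wave reaching all four edges.
With the defaults above the *lower* endpoint $c_2 = 0.015$ is the
excitable one: the weak $uv$ feedback cannot extinguish the excited state,
and a latched front (with $u \approx 0.93$ behind it) propagates at about
$1.5\times10^{-3}$ nodes per iteration, consistent with the continuum
front-speed estimate $\sqrt{2 D_u c_1}\,(1/2 - a)\,\Delta t/\Delta x
\approx 2\times10^{-3}$. At $c_2 = 0.05$ the same stimulus decays. The
published labelling of the endpoints is the opposite; the package
documents the observed behaviour and nowhere hard-codes a label.

Two consequences of the measured front speed are worth stating plainly.
First, spanning a long insole grid (hundreds of nodes) takes a few times
$10^5$ iterations, not a few times $10^4$; the network-spanning validation
therefore reports the coverage fraction it actually reaches within its
$10^5$-iteration horizon. Second, the critical nucleus at the excitable
endpoint has radius $\approx D_u/v_{\mathrm{front}} \approx 3.7$ length
units ($\approx 1.9$ nodes), so the default 9-node stimulus disc (radius
1.8 nodes) is marginally *sub*-critical on a uniform grid. Experiments
that need a travelling wave use a radius-3 disc (about 29 nodes, still a
single site); the excitability scan uses the symmetric union of four
discs on the central nodes.

### Stimulation

A stimulus is instantaneous: at its scheduled iteration, `u` is set to a
fixed value (default 1) on the conductive nodes within a Euclidean radius
of the site. This models a pressure event as a local excitation and keeps
the external current `I` an independent, normally zero, parameter. A
stimulus whose disc contains no conductive node warns and does nothing.

## Read-outs

*Electrode potentials.* An electrode at node $x$ reports
$p_x = \sum_{y:\,|x-y|<2} (u_y - v_y)$ over the conductive nodes of its
$3\times3$ Moore neighbourhood (the strict inequality excludes the
distance-2 orthogonal neighbours). The printed form of this sum uses the
centre fields $(u_x - v_x)$, which would reduce to a neighbour count times
a constant; the package defaults to the neighbour-field reading and keeps
the literal one behind `summand = "centre"`.

*Activity.* The number of conductive nodes with $u$ strictly above 0.1.

*Coverage frequency.* Per node, the number of iterations $u$ exceeded
0.1, normalised by the grid-wide maximum; an all-zero map stays all-zero
rather than dividing by zero, so never-excited regions are exactly 0.

*Snapshots.* Binary frames of the sites with $u > 0.04$, recorded every
100th step by convention.

The default 16-electrode layout follows the medial axis of the insole
mask with `E1` in the toe lobe and `E2` in the heel lobe (mirroring the
two stimulation loci), and `E3..E16` filling in from toe to heel; any
layout can be supplied as a tibble.

## Spikes and Boolean gates

Spike detection uses topographic prominence: a local maximum is a spike
when its height above the higher of its two flanking minima — searched
outwards to the nearest higher sample or the trace end — reaches the
threshold (0.03 mV for experimental traces). Plateaus report their middle
sample. Prominence is insensitive to baseline shifts and scales linearly
with the trace, properties the tests assert, and the implementation is
cross-checked against an independent reference implementation. An
optional amplitude cap (default 0.1 mV in the census, following the
"small spikes" convention) discards larger events, and an optional
minimum separation keeps the more prominent of two crowding peaks.

Gate extraction interprets the three stimulation scenarios
$(x,y) \in \{(0,1), (1,0), (1,1)\}$ — $x$ true meaning excitation around
`E1`, $y$ around `E2` — as logical inputs, and a spike as logical TRUE.
Per electrode, the pooled spike times of the three scenario runs are
partitioned into events by single-linkage chaining: a new event starts
wherever the gap exceeds the separation threshold ($10^3$ iterations by
default); spikes within the simultaneity window ($2\times10^2$
iterations) necessarily chain into one event, and each event records
which scenarios contributed. The presence triple is the truth table of a
Boolean function restricted to the three tested inputs, which fixes the
8-way lookup (CONST-FALSE, AND, x-AND-NOT-y, SELECT-x, NOT-x-AND-y,
SELECT-y, XOR, OR); the lookup is verified in the tests by brute-force
enumeration of all Boolean functions of two variables. Event timing uses
apex times. The census tabulates gate labels per electrode and aggregate
counts per type.

## Synthetic data generators

*Mycelium templates.* Colony images are thresholded pointwise
($r > 170$, $g > 170$, $b < 200$, strict) into a conductive matrix and
thickened by one pass of $3\times3$ morphological dilation — the reading
adopted for the source's "dilution operation", since dilation is the
standard operation that makes thin strands wide enough to conduct a wave.
Where no image is available, `generate_mycelium()` grows a network of
correlated branching random walks inside a foot-shaped mask: walkers take
fixed-length steps with Gaussian heading noise, occasionally branch at
$\pm\pi/4$, bounce at the mask boundary, and their rasterised paths are
dilated. The walker budget scales with the mask area so strand density is
comparable across grid scales; with defaults the largest 8-connected
component holds essentially all conductive nodes, which the spanning
tests require ($\ge 90\%$). The generator emulates the *statistical* look
of a colony — dense, loopy, mildly inhomogeneous strands — not the
vessel-like hierarchy of real mycelium, and no vectorised hyphal graph is
extracted; passing tests therefore speak to wave propagation on
strand-like random media, not to any particular real colony.

*Recordings.* `synthesize_recording()` emulates the logger output:
per-channel baseline drift (sine, default amplitude 0.01 mV, period
3600 s), AR(1) Gaussian measurement noise with marginal sd 0.005 mV and a
60 s correlation time — chosen because the logger stores the average of
up to ten measurements per second, so the residual noise at 1 Hz is slow
rather than white — and biphasic spikes (a Gaussian depolarisation lobe
with a smaller recovery undershoot, width 10 samples) planted at Poisson
times. Rates are per 30-minute window and default to 2 under no load and
8 under even load, echoing the bench observation that spiking densifies
under weight; amplitudes default to mean 0.06 mV, sd 0.01 mV (below the
0.1 mV cap). Spikes closer than ten widths are re-drawn so each planted
spike is individually resolvable. The generator returns the exact planted
times and amplitudes, making recall/precision of the detector measurable.

Amplitude comparisons use spike prominence, not absolute voltage, because
drift makes absolute height meaningless. Prominences carry a small upward
bias from the undershoot lobes and drift (both conditions equally), so
only *contrasts* between conditions are meaningful; with identical
planted distributions the even-minus-no-load contrast is near zero, and a
planted 30% reduction under even load is recovered as negative on every
channel in nearly all seeded replicates.

## Numerical choices and edge cases

- Schedule windows are half-open `[start, end)` in samples; the shared
  boundary sample belongs to the later interval.
- A spike whose apex falls within a few samples of a window edge can lose
  prominence (its flank is truncated) — inherent to windowed detection.
- `detect_spikes()` requires at least 3 samples; prominence must be
  positive.
- Logger ingestion snaps non-uniform time stamps to the sampling grid,
  flags missing seconds as gaps (filled with `NA`), and clips values to
  the ±156 mV acquisition range with a warning.
- All generators take an integer seed and are bit-reproducible; the
  simulator itself uses no randomness.
- Coverage counts accumulate after every step; potentials/activity records
  include the post-stimulus initial state as iteration 0.

## Validation problem sizes

The shipped checks use a uniform $100\times100$ grid (excitability,
symmetry), a $100\times220$ grid with stimuli 60 nodes apart
(superposition of disjoint wave systems), a half-scale
$182\times492$ synthetic insole run for $10^5$ iterations (network
spanning), 50 random $20\times20$ masked templates against a per-node
double-loop oracle (solver equivalence, $\le 10^{-12}$), and 100 seeded
synthetic recordings of three 30-minute windows (detector recall,
precision and census agreement; amplitude-effect sign recovery).

## Known limitations

- The additivity of two disjoint wave systems is exact only until the
  fronts' sub-threshold diffusive feet interact (decay length
  $D_u/v \approx 1.9$ nodes): activity counts superpose exactly for most,
  but not all, of the approach to visible front contact. After contact,
  combined activity stays at or above either single run.
- With Gaussian noise, prominence excursions past any fixed absolute
  threshold are rare but not impossible over millions of samples, so the
  detector's precision against planted spikes is very high yet not
  structurally 1.0; the acceptance script reports the measured value.
- At the excitable endpoint the medium is effectively bistable (no
  refractory tail at these constants), so repeated wave trains and
  spiral re-entry are outside the defaults' regime.
- The simulator is 2-D, explicit-Euler, single-resolution; no adaptive
  stepping, implicit schemes or 3-D domains.
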