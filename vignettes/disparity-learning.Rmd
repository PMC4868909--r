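---
title: "Adaptive disparity learning with time-staggered winner-take-all synapses"
author: "stereoWTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive disparity learning with time-staggered winner-take-all synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoWTA)
```

# The model

Stereopsis extracts depth from the horizontal positional offset (binocular
disparity) between the two eyes' images. In primate cortex, ocular dominance
(OD) columns interlace left- and right-eye views of the same visual location,
and disparity-selective neurons emerge during early development from
binocular experience rather than being wired at birth. `stereoWTA` is a
behavioral simulator of an adaptive system built on that idea: cells whose
receptive fields cover an interlaced left|right window *learn* a preferred
disparity through competitive synaptic dynamics, and a bank of such cells
then acts as a set of matched filters that label every pixel of a rectified
stereo pair with the disparity of the best-responding cell.

The simulator has four layers, mirroring its module structure:

1. **ts-WTA unit** (`tsWtaParams`, `runCompetition`): one pair of
   floating-gate synapses competing over time for a fixed resource.
2. **Disparity cell** (`trainCell`, `tuningCurve`): an h x w grid of ts-WTA
   units with a common output node, trained on interlaced disparity
   patterns; diffusive coupling between cells (`coupleCells`,
   `trainEnsemble`) makes neighbouring cells adopt a common preference.
3. **Stereo pipeline** (`extractAndSplice`, `disparityMap`): per-pixel
   disparity estimation by splicing epipolar patches and letting a trained
   bank compete.
4. **Reaction–diffusion lattice** (`rdLattice`, `evolveRD`, `mapStats`): a
   phenomenological model of disparity-*map* formation on a cortical sheet.

Throughout, the weight variable is a floating-gate voltage $V_{fg}$:
*injection* lowers it (strengthening), *tunneling* raises it (weakening).
Intra-pulse device physics is not simulated — the RC time constants of the
circuit being emulated (1 kΩ × 10 pF = 10 ns) are negligible against the
0.02 s input pulses, so pulses are discrete events and all resistive
networks are solved quasi-statically.

# The ts-WTA unit

A unit holds two synapses with voltages $(v_1, v_2)$ in an admissible range
$[V_{min}, V_{max}]$ (default 4–6 V). Synaptic efficacy is a saturating
exponential, strictly decreasing in the gate voltage:

$$e(v) = \exp(-\kappa\,(v - V_{min})), \qquad \kappa = 6\ \mathrm{V}^{-1},$$

so the weakest admissible synapse retains $e^{-12} \approx 6\times10^{-6}$
of the strongest efficacy (the validity check requires at most 1%). The two
synapses share a fixed activation budget $i_B$ (the bias-current resource):
when synapse $a$ is pulsed while $b$ is off, the cell's activation is the
active synapse's *share* of the budget,

$$A = \min\!\left(i_B,\; i_B\,\frac{e_a}{e_a + e_b}\right).$$

This resource-sharing reading matters. A per-pulse learning rule with a
fixed threshold $\theta$ compares the feedback against an absolute level;
if the activation depended only on the active synapse, each synapse would
be independently bistable and the outcome of a competition would be decided
by each synapse's position relative to a fixed separatrix, not by the
*relative* bias — the stronger-biased synapse would not reliably win for
arbitrary pairs drawn from the 4.8–5.5 V initialization band. With shared
resource, $A_1 + A_2 = i_B$ for any pair, so "stronger than the competitor"
and "above threshold" coincide when $\theta$ sits below the midpoint.

A pulse updates the stimulated synapse by the threshold-linear rule

$$\Delta v = -\eta_{inj}\,[f - \theta]_+ + \eta_{tun}\,[\theta - f]_+,$$

where $f$ is the feedback level, and the unstimulated synapse passively
weakens by $\eta_{leak}$ (slow elimination of unused synapses). Results are
clipped to $[V_{min}, V_{max}]$.

## Calibration of the rate constants

The source analysis gives no behavioral rate constants, only two laws the
competition must obey: (L1) under equal alternating stimulation the synapse
with the lower initial voltage wins; (L2) a stimulation ratio of at least
3:1 overrides a bias gap of up to 0.1 V. The shipped defaults
($\eta_{inj}=\eta_{tun}=0.05$, $\eta_{leak}=0.004$, $\theta=0.2\,i_B$) were
fixed once by a closed-form stall analysis plus a grid check, before any
acceptance run, and are not revisited:

* Under alternation, the per-cycle drift of the gap is
  $-\eta_{inj}(A_1 - A_2) < 0$ whenever $v_1 < v_2$, so the gap always
  amplifies (L1) and the loser's activation eventually falls below
  $\theta$, after which tunneling plus leak drive it to the top rail.
* For L2 with ratio $r$ and adverse gap $g$, the relative drift per cycle is
  $-\eta_{inj}[(r{+}1)A_2 - i_B] - (r{-}1)(\eta_{inj}\theta - \eta_{leak})$;
  requiring it negative at $r=3$ yields the stall boundary
  $A_2 > 0.35 - 10\,\eta_{leak}$ (in units of $i_B$), i.e. a maximal
  recoverable gap of $\ln\!\frac{1-A_2^\ast}{A_2^\ast}/\kappa \approx
  0.13\ \mathrm{V}$ at the defaults — comfortably above the 0.1 V the law
  demands. A larger leak widens this margin, which is why
  $\eta_{leak} = 0.004$ rather than a still smaller value.

An exact tie ($v_1 = v_2$, equal schedule) resolves deterministically to
the first-pulsed synapse: its first pulse breaks the symmetry and positive
feedback amplifies it. A physical circuit would break such ties by noise;
a deterministic, reproducible resolution was preferred here.

# The disparity cell

A cell's receptive field is an $h \times w$ grid of ts-WTA units covering a
spliced binocular window: a left subfield of $w_L = \lfloor w/2 \rfloor$
columns next to a right subfield of $w_R = \lceil w/2 \rceil$ columns (the
9-column field splits 4 | 5). Such a field can encode
$\min(w_L, w_R) = \lfloor w/2 \rfloor$ integer disparities starting at 0 —
four for a 9-wide field, twenty for a 40-wide field
(`representableDisparities`).

A stimulus is a binary interlaced pattern; its ON bits pulse synapse 1 of
the corresponding unit and its OFF bits pulse synapse 2 — the stimulus and
its bitwise complement alternate, guaranteeing the time-staggered drive
each unit needs. The cell's response is the grid-size-normalized sum of the
units' resource shares, so responses lie in $[0, i_B]$ for any field size
and an undeveloped (symmetric) field responds $i_B/2$ to every stimulus.

## Feedback routing: why the winner-selective rule

Training presents each disparity pattern and its complement once per epoch
in random order ("random-inside-epoch"), for 80 epochs by default. The
cell's output is fed back to every unit and gates injection versus
tunneling. How exactly the scalar output maps onto the per-unit feedback
level is the one genuinely open design choice in this architecture, and
three natural readings fail reproducibly:

* **Raw global response against a fixed low threshold.** All stimuli evoke
  responses near $i_B/2$, far above $\theta$: every template strengthens
  equally and the field saturates flat with no selectivity.
* **Unit-gated feedback** (response × the unit's own share). Each unit then
  has fast, pattern-independent positive feedback in its own share and
  polarizes toward its random initial bias long before the slow cell-level
  response differences can impose coherence: the field freezes as a random
  mosaic.
* **Affine range-normalized response.** Mid-ranked stimuli still sit above
  threshold, strengthen their own templates, and slowly erode the leader.

What the architecture actually asserts is a *cell-level* winner-take-all:
the input pattern that evokes the maximum response is the pattern the cell
eventually learns, with the intra-cell diffusive grid making the units
cooperate. The implemented feedback path realizes that directly: each
epoch, the stimulus with the maximum response is routed the full injection
drive ($f = 1$), its complement the full tunneling drive ($f = 0$), and
every other stimulus the neutral level ($f = \theta$, a fixed point of the
update). The per-pulse rule at each unit is untouched. Under this routing
the initial argmax is amplified and locks in: across seeded runs the
learned disparity equals the pre-training argmax whenever the initial
maximum is unique, the peak response saturates at $i_B$, and the
peak-to-mean-of-others ratio settles near 2 (the test suite checks > 1.5).

## Polarity

Complementing a pattern and shifting its subfield commute, so a pattern
and its complement encode the *same* disparity, in opposite contrast
polarity. A free-running cell may lock onto either polarity; tuning curves
therefore score each disparity as the maximum response over the two
polarities, and `hwhh` measures tuning sharpness on that curve
(half-width at half-height, linearly interpolated, one-sided if only one
side crosses half-height). Pipeline filter banks additionally require the
base polarity, because window binarization produces base-polarity bits;
`makeCellBank` seeds each cell with a small innate bias (0.15 V) toward its
target template, which fixes both the learned disparity and its polarity —
the "genetic bias" of the source architecture.

## Diffusive coupling

Coupled cells connect at their *diffusion* nodes through a coupling
resistor (100 Ω by default) while each cell's output feeds its own
diffusion node through the 1 kΩ feedback resistance; a one-way buffer
guarantees the diffusion node can never back-drive the output. Solving
Kirchhoff's current law once per topology gives a mixing matrix $M$ with
diffusion levels $D = M\,O$; during ensemble training each cell's
winner-selective feedback operates on its *mixed* levels, so a strongly
biased cell steers which stimulus its neighbours reinforce. With the
default 10:1 conductance ratio two coupled cells effectively share
$(O_1 + O_2)/2$ and converge to the stronger cell's preference, while
uncoupled controls frequently disagree; an infinite coupling resistance
reduces $M$ to the identity and reproduces standalone training exactly.

# Synthetic stimuli and stereo pairs

`makeDisparityPattern` offers three styles:

* `random_dot` (training default): a seeded Bernoulli(1/2) left subfield,
  right subfield shifted by $d$ with zero fill. Each disparity uses its own
  derived child seed, so patterns of different disparities agree on ~50% of
  bits. This is deliberate: with single-bar patterns any two disparities
  agree on 7/9 of their columns, which caps the attainable peak/other
  tuning ratio at ~1.29; random interlaced fields (also the closer analogue
  of ocular-dominance input) allow ratios near 2.
* `bar`: one vertical ON bar per subfield, displaced by $d$ in the right
  subfield — the minimal, visually interpretable stimulus.
* `ramp`: the binarized spliced window that a monotone luminance ramp
  produces at disparity $d$ — the generator-matched stimuli used by the
  stereo pipeline (below).

`makeStereoPair` builds a rectified pair with a per-region ground-truth
disparity (left-referenced; the right image is the per-region horizontal
shift of the left, with occluded columns filled from the nearest source and
flagged). The default texture is a horizontal luminance ramp with strictly
increasing intensity *and* strictly increasing slope (quadratic). The
reason is structural, not cosmetic: the pipeline's cells are fixed
templates, and a window is binarized at its own median, which depends only
on the *ranks* of the window values. For any strictly monotone texture
those ranks are invariant to horizontal translation, so every interior
window at true disparity $d$ binarizes to exactly the ramp pattern of
disparity $d$, wherever the pixel sits. Periodic textures (bars, random
dots) are phase-ambiguous for a single-template bank — a window one pixel
off the template's phase matches a *different* disparity's template — so
per-pixel accuracy on them is structurally impossible without a bank of
templates per phase. The increasing slope keeps the horizontal gradient
itself strictly monotone, so the same invariance survives the edge
prefilter.

`addImagingNoise` models the two dominant nuisances of a real camera pair:
an interocular brightness offset (default 0.05 of the intensity range)
with optional gain mismatch, plus mild iid pixel noise (default
$\sigma = 0.003$). These defaults were chosen once as representative
magnitudes before the acceptance experiments were run.

# The stereo pipeline

For every pixel, `extractAndSplice` takes an $h \times w_L$ patch of the
left image and an $h \times w_R$ patch from the same epipolar rows of the
right image, both anchored with the patch top-left at
$(\mathrm{row} - \lfloor h/2 \rfloor, \mathrm{col} - \lfloor w/2 \rfloor)$,
and concatenates them — a 9×4 | 9×5 splice gives the 9×9 window the cells
were trained on; 10×20 | 10×20 gives 10×40 for the 20-disparity geometry.
Windows that need border padding are completed by replication and flagged
invalid. The window is binarized at its median (parameter-free,
offset- and contrast-invariant within the window) and every cell of the
bank responds; the highest response wins and its disparity labels the
pixel (`detectDisparity`, ties resolve to the lowest disparity and are
flagged). Zero-contrast windows are degenerate under median binarization
and are likewise flagged invalid.

Two prefilters mirror the classical remedies for imperfect imagery:
`gaussianPrefilter` (separable, reflective boundaries, $\sigma = 0$ is the
identity) suppresses pixel noise, and `edgePrefilter` (Sobel gradient
magnitude) cancels smooth illumination differences between the cameras —
a brightness offset on one image shifts all its ranks across the splice
seam and destroys raw intensity matching, while differentiation removes it
entirely. In `disparityMap` the filters are applied at image level, which
is equivalent to filtering each window for interior pixels and avoids
smearing across the splice seam. On the noisy default pair the
edge + Gaussian chain (σ = 2; vertical smoothing is distortion-free for
the row-constant ramp) strictly reduces the average error relative to the
unfiltered pipeline — the claim is directional; the residual error stays
substantial in absolute terms because differentiation amplifies iid noise
against the fine-grained monotone texture.

`averageError` is the percentage of valid pixels whose estimated disparity
differs from ground truth. Accuracy claims are evaluated on
`interiorMask` pixels — those whose window, including the columns its
right patch draws on up to the maximum disparity, lies inside a single
ground-truth region: a windowed matcher is genuinely ambiguous across
region boundaries, and those pixels are excluded rather than scored.

**What this does and does not show.** The pipeline demonstrates the
architecture end-to-end on generator-matched synthetic imagery. It does
not generalize to arbitrary natural textures: template cells carry no
phase invariance, so real-image performance would require either
phase-indexed banks or normalized descriptors. This limitation is a
property of the template-matching architecture being modelled, not of the
implementation.

# Reaction–diffusion map formation

The map model evolves a real-valued lattice $X$ (sites initialized
uniformly in $[0, D{-}1]$) by explicit Euler updates

$$X \leftarrow X + \alpha\, f(X) + D_u\, \nabla^2 X,$$

with $\nabla^2$ the 4-neighbour Laplacian (reflecting boundary by default,
wrap available) and $f$ a multistable reaction whose stable roots are the
integer disparities: with $u = x - \mathrm{round}(x)$ (round clamped to
$0..D{-}1$), $f = -u(1 - 4u^2)$ inside a well and $-u(4u^2 - 1)$ beyond the
outermost roots. $f$ is continuous, odd around every root, vanishes at the
half-integer separatrices, and has unit slope magnitude at the roots, so
the explicit update is stable for $\alpha < 1$; diffusion is stable for
$D_u \le 0.25$, with the checkerboard mode marginal at exactly 0.25 (the
pure-diffusion oracle test therefore runs at $D_u = 0.2$). The written
update equations of the source are shorthand; this
reaction-plus-Laplacian reading is the package's documented construction,
chosen to realize the stated stable-root structure, not asserted as the
authors' literal formula.

Without diffusion every site converges independently to the nearest root of
its initial value — a closed-form oracle the tests check site-by-site. With
diffusion, clusters of equal disparity emerge with gradual variation across
boundaries. The defaults $\alpha = 0.5$, $D_u = 0.04$ were calibrated at
design time on 64×64 lattices: at $D_u \ge 0.06$ diffusion homogenizes the
field toward its mean faster than the outer wells can capture it and the
extreme disparities disappear (diversity < 1), while $D_u = 0.04$ preserves
all four disparities and still consolidates the cluster count several-fold
relative to $D_u = 0$. `mapStats` quantifies the three tenets of a feature
map: *continuity* (mean absolute 4-neighbour difference), *diversity*
(fraction of disparities present after rounding), and cluster structure
(4-connected components of equal rounded disparity).

# Problem sizes, seeds and reproducibility

The shipped experiments use the geometry of the modelled system: 9×9
receptive fields, four disparities, eight training stimuli, 80 epochs, an
80×80 four-quadrant stereo pair, and 64×64 lattices for 200 steps; the
population experiments use 200 independently seeded cells, 50 coupled /
uncoupled pairs and 20 lattice seeds. These sizes run the whole suite in a
few minutes on one CPU and were chosen as the package's standard
experiment scale. A single global seed fans out through `childSeed` into
per-component streams, so any stage can be reproduced in isolation;
`runTrain` outputs are byte-identical across repeated runs of the same
configuration. The parameter-sweep harness (`sweepSpec`, `runSweep`)
re-checks the registered behavioral invariants — the two win-laws, active
tunneling elimination, the resource cap and range clipping — over a grid
of rate constants; the supplementary stress analysis this stands in for
names no concrete parameter list, so the harness sweeps the behavioral
rates.

# Known limitations

* No subpixel or vertical disparity; no occlusion reasoning beyond
  flagging; one disparity learned per cell.
* Template detection requires generator-matched (monotone-texture) imagery,
  as discussed above.
* The hardware figures of the modelled system (learning in seconds,
  millisecond detection, milliwatt power, SPICE-level tuning widths) are
  circuit properties outside a behavioral simulator's scope; tuning
  sharpness here is a qualitative property (a strict, pronounced maximum),
  not a numeric match.
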