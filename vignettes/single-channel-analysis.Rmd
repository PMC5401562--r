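---
title: "Single-channel analysis of trimeric cation channels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel analysis of trimeric cation channels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichan)
```

Trimeric intracellular cation (TRIC) channels are homotrimers in which each
monomer carries its own ion-conducting pore. In excised-patch recordings such
channels show a ladder of conductance levels -- closed (C), one, two or three
open pores (O1--O3) -- and, when a patch holds two trimers, up to six open
levels. `trichan` implements the quantitative pipeline for this kind of data:
a generative gating model, acquisition-realistic trace synthesis, all-points
amplitude histograms with Gaussian-mixture decomposition, multi-level
idealization, open-probability and dwell-time statistics, current--voltage
and Goldman--Hodgkin--Katz (GHK) selectivity analysis, and the geometric
measurements (helix tilt against the trimer C3 axis, pore-radius
classification) used to connect function to structure.

This vignette documents the models, the defaults and the reasoning behind
the design choices, in that order of importance.

## The gating model and its simulator

Each monomer is modelled as a two-state (closed/open) Markov switch with
opening rate $k_{\mathrm{open}}$ and closing rate $k_{\mathrm{close}}$
(both s$^{-1}$), gating independently of its neighbours. The number of open
monomers $m \in \{0,\dots,N\}$ then follows an aggregated birth--death chain
with rates

$$\text{up}(m) = (N-m)\,k_{\mathrm{open}}, \qquad
  \text{down}(m) = m\,k_{\mathrm{close}},$$

whose stationary law is Binomial$(N, p)$ with
$p = k_{\mathrm{open}}/(k_{\mathrm{open}}+k_{\mathrm{close}})$.
`simulate_state_path()` performs an exact Gillespie simulation of this chain
with inverse-CDF exponential waiting times, so one integer seed reproduces a
path bit-for-bit. Three analytic consequences are used as test oracles
throughout: the binomial occupancy law, the closed-level exit rate
$N\,k_{\mathrm{open}}$ (so mean closed dwell $1/(N k_{\mathrm{open}})$), and
the unweighted open probability $1-(1-p)^N$.

Level conductances are free parameters rather than multiples of the
single-pore conductance, because measured multimeric levels are sub-additive:
the wild-type fixture used across the test-suite carries
$(0, 42.2, 100.6, 163.7)$ pS, the measured C/O1/O2/O3 ladder of a bacterial
TRIC trimer. An important consequence is that conductance recovery must be
validated per level, not per pore.

### Trace rendering

`render_trace()` maps the occupancy path to per-sample currents
$I_m = \gamma_m (V - E_{\mathrm{rev}})/1000$ (pA from pS and mV), with
$E_{\mathrm{rev}}$ from the GHK model of the recording solutions. Acquisition
is emulated at 50 kHz with a Gaussian low-pass filter whose $-3$ dB point is
the configured cutoff (default 0.5 kHz; the time-domain kernel uses the
standard $\sigma_t = 0.1325/f_c$). A 50 Hz notch filter is not emulated:
synthetic data has no mains interference.

Noise is added *after* the filter as white Gaussian samples of standard
deviation `noise_sd`. That makes `noise_sd` the baseline noise of the
recorded trace -- the width of the histogram peaks -- which is the quantity
one reads off real recordings; it is a simplification in that real filtered
noise is correlated between samples, and no flicker or capacitive components
are modelled. Published recordings never state a generator-side noise
amplitude, so the default `noise_sd = 0.35` pA puts adjacent levels
of the wild-type ladder $\geq 7\sigma$ apart, comparable to the
well-resolved histogram peaks of published recordings (the smallest gap,
C to O1 at $+60$ mV, is 2.53 pA).

## Amplitude histograms and mixture decomposition

`build_histogram()` uses uniform right-open bins (default width 0.03 pA)
anchored so one edge falls exactly at 0 pA. `fit_mixture()` fits $k$
Gaussians to counts versus bin centres by Levenberg--Marquardt least squares
(`minpack.lm`), with $k$ supplied by the user (4 for one trimer, 7 for two),
never chosen automatically. Counts are fitted unweighted by default -- the
reproducible convention when the original fits were done in a plotting
package with unstated weighting -- with Poisson weighting as an option.
Component standard deviations are free by default; a shared-sd constraint
exists and is echoed in the fit object so reports cannot silently mix the
two conventions.

Initialisation: bin counts are smoothed by a 5-bin moving average (enough to
stabilise local-maxima detection at 0.03 pA bins without displacing peaks),
the $k$ highest maxima seed the means, and half-widths at half maximum seed
the sds. Components are reported sorted by mean, ties broken by ascending
sd; a component with less than 0.1% of the total fitted area is flagged
degenerate, the signature of asking for more components than the histogram
resolves. Non-convergence is reported via the `converged` flag, not an
error.

On 20 s of simulated wild-type recording (10$^6$ samples) the four-Gaussian
fit recovers all three open-level conductances to about 0.1%, well inside
the 2% the test-suite demands.

## Idealization and dwell statistics

`idealize()` assigns each sample to the nearest level mean (thresholds at
midpoints between adjacent means; a sample exactly on a midpoint goes to the
lower level, a deterministic tie-break), then merges runs shorter than the
dead time into the temporally preceding event. The default dead time is
$0.3/f_c$ -- twice the nominal Gaussian-filter rise time $T_r \approx
0.15/f_c$, about 0.6 ms at 500 Hz -- because events shorter than the filter
response cannot reach half amplitude and survive as spurious partial-level
blips otherwise. Both the threshold scheme and the dead time are artifact
decisions (acquisition packages do not publish theirs) and are carried in
the record so reports can echo them.

`npo()` implements the unweighted definition $NP_o = t_o/T$: time at *any*
open level over total time. This is deliberately the verbatim convention of
the experimental literature for multi-channel patches even though a
level-weighted variant (mean number of open pores,
$\sum_m m f_m$) is more informative for independence checks; the weighted
variant is exported under the distinct name `npo_weighted()` so the two can
never be silently confused. Dwell summaries drop boundary-truncated
(censored) first/last sojourns by default. `compare_groups()` defaults to
the Welch test (the pooled-variance Student test is an option, and the
variant is a visible argument, since published methods rarely state which
was used).

`binomial_occupancy_check()` is the independence diagnostic: it compares
level time fractions with Binomial$(N,\hat p)$ by chi-square, using an
effective sample size of one approximately independent snapshot per 10 mean
event durations -- deliberately conservative relative to the chain's
correlation time $1/(k_{\mathrm{open}}+k_{\mathrm{close}})$, so the test
under- rather than over-rejects independent gating. Exact binomial
fractions give a statistic of exactly zero; all-or-none occupancy (the
cooperative signature) gives a divergent one.

## I/V fitting and GHK selectivity

`fit_iv()` is ordinary least squares $I = aV + b$: slope conductance
$1000a$ pS, reversal potential $-b/a$, standard errors by the usual
regression formulas with first-order propagation (including the $a,b$
covariance) for $E_{\mathrm{rev}}$. The GHK current is convex in $V$ under
bi-ionic conditions, so reversal-potential fits should use a window of
about $|V| \leq 40$ mV (the `v_max` argument); wide-range fits are for
conductance. With only two points the fit is exact and standard errors are
undefined (`NA`); a slope within two standard errors of zero makes the
reversal potential undefined and is an error.

The GHK layer uses the inside-out sign convention throughout: $V$ = bath
(cytoplasmic) minus pipette (extracellular), positive current = cation flow
bath $\to$ pipette. With K$^+$ in the pipette and Na$^+$ in the bath this
makes the reversal potential positive exactly when $P_K/P_{Na} > 1$, as
printed for the wild-type channel. The bi-ionic inversion is

$$\frac{P_K}{P_{Na}} =
  \frac{[\mathrm{Na}]_{\mathrm{bath}}}{[\mathrm{K}]_{\mathrm{pipette}}}
  \exp\!\left(\frac{E_{\mathrm{rev}} F}{RT}\right),$$

with $F = 96485.332$ C/mol and $R = 8.31446$ J/(mol K) fixed. The default
temperature is 295.65 K (22.5 degrees C, the midpoint of a 21--24 degrees C
room-temperature session; $RT/F = 25.48$ mV): selectivity work rarely
prints the temperature used for the conversion, and at this value the
canonical worked examples ($E_{\mathrm{rev}} = 4.84$ mV $\leftrightarrow$
ratio 1.21; 1.92 mV $\leftrightarrow$ 1.08 at 210/210 mM) reproduce to
printed precision:

```{r ghk}
cond <- bi_ionic_conditions(p_ratio = 1.21) # 210 K (pipette) / 210 Na (bath)
ghk_reversal(cond)
bi_ionic_permeability(4.84, cond)
bi_ionic_permeability(1.92, cond)
```

Divalent cations are modelled as impermeant (permeability 0) and excluded
from the voltage equation -- the empirical conclusion for TRIC channels --
and a nonzero divalent permeability is refused rather than silently
mishandled; an extended GHK with divalent terms is out of scope. Chloride
enters the voltage equation with sides swapped, as usual for anions.

Simulated I/V experiments (`simulate_iv_dataset()`) anchor the GHK current
scale so the slope conductance *at the reversal potential* equals a measured
channel conductance (default 163.7 pS, a fully open trimer) and emulate the
experimental protocol: each voltage's mean current averages `n_per_point`
noisy measurements, mirroring per-patch replication. One caveat the
test-suite makes explicit: fitting a straight line to the convex bi-ionic
GHK curve over $\pm 40$ mV biases the zero crossing upward by a few tenths
of a millivolt (about $+0.5$ mV at ratio 1.21). This is a property of the
linear-fit protocol itself, shared with the experimental analysis that the
protocol emulates, so the package reproduces rather than corrects it.

## Structure geometry

The geometric module works on C-alpha coordinates from PDB/mmCIF files
(read via `bio3d`) or on synthetic assemblies built in code.

* `fit_helix_axis()` -- dominant principal direction (first right-singular
  vector) of the centred C-alpha cloud. Principal-direction fitting was
  chosen over cylinder fitting because kinked transmembrane helices are
  handled by splitting them into sub-spans (M2a/M2b style), each fitted
  independently; helix spans are user-supplied via a TSV config (automatic
  secondary-structure assignment is out of scope).
* `trimer_c3_axis()` -- the rotation axis of the least-squares (Kabsch)
  superposition mapping chain A onto chain B; the A-onto-C superposition is
  a consistency check that warns beyond 2 degrees. The rotation angle
  (ideally 120 degrees) is reported.
* `tilt_angle()` -- $\eta = \arccos|\hat u \cdot \hat v|$ in degrees,
  folded into $[0, 90]$ since helix axes have no preferred sign.
* `classify_pore_profile()` -- labels pore-radius profiles by the strict
  1.15 / 2.30 Angstrom thresholds (dehydrated / hydrated K$^+$ radius);
  radii exactly at a threshold are `intermediate`. Maximal constricted runs
  are reported as gates with minimum radius and axial extent. Pore radii
  themselves come from an external profiler; computing them is out of
  scope.

Coordinates are Angstrom throughout and residue numbering follows the
source file. Published tilt tables are only approximately reproducible from
deposited structures because the exact helix residue ranges behind them are
not published; the package therefore validates the machinery on constructed
fixtures (ideal helices at known tilts, exact C3 trimers, jittered and
rigidly rotated copies) where the ground truth is exact, and treats
agreement with published tables as a soft cross-check to within about 5
degrees when the user supplies their own span assignments.

## Problem sizes, tolerances, and what the tests show

The test-suite validates parameter recovery at sizes chosen to keep
Monte-Carlo error well below the asserted tolerances: occupancy and dwell
laws on paths of $10^5$--$10^6$ transitions (tolerances 2--5%), mixture
recovery on $10^5$--$10^6$ samples (means within 0.05 pA, sds within 5%,
conductances within 2%), reversal-potential recovery over seeded replicate
experiments compared against the printed between-patch SEMs. Passing these
shows the pipeline is a correct and well-calibrated implementation of its
own generative model; it cannot show that real patches obey that model
(real recordings add correlated noise, drift, sub-conductance states and
possible inter-monomer cooperativity, none of which are generated). The
independence diagnostic exists precisely so that real data can be tested
against the model rather than assumed to follow it.

Degenerate inputs follow explicit contracts rather than conventions:
zero-variance group comparisons return $t = 0, p = 1$; the GHK current at
$V = 0$ uses the analytic continuation; empty dwell lists, single-level
idealization requests and zero driving forces are errors.
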