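---
title: "Modeling C-terminus-mediated inhibition of CaV1.3 channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling C-terminus-mediated inhibition of CaV1.3 channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavcmi)
```

## The biological problem

CaV1.3 L-type Ca²⁺ channels open on depolarization and then partially shut
again through Ca²⁺-dependent inactivation (CDI): Ca²⁺ entering the channel
acts through calmodulin to inactivate it, so a Ca²⁺ current decays within
tens of milliseconds toward an "end-stage" level while a Ba²⁺ current
through the same channels (Ba²⁺ does not trigger CDI) decays only through
slow voltage-dependent inactivation (VDI). C-terminus-mediated inhibition
(CMI) is a distinct inhibitory mode: C-terminal channel fragments (the
preIQ₃–IQ region together with the proximal and distal C-terminal
regulatory domains) cooperate to compete calmodulin off the channel.
Channels that lose calmodulin cannot undergo CDI and gate with strongly
reduced open probability — phenomenologically, as if they were frozen in
the end-stage of CDI.

The experimental signature of CMI is therefore very specific: peak current
falls, the CDI index falls, but the current at 300 ms is unchanged, so the
lower limit of CMI is set by end-stage CDI. Conventional inhibitions
(pore blockers, run-down) instead scale the whole trace, so peak and
late current fall together and the CDI index is untouched. This package
implements that quantitative framework: the two-state mixture current
model, the gating indices, the FRET two-hybrid binding model used to
characterize the underlying protein interactions, synthetic-data
generators for all of it, and a minimal dopaminergic-neuron model carrying
the channel mechanism.

## The whole-cell current model

For a voltage step to $V$ the Ca²⁺ current is

$$I(t) = c_m\, g\, (V - E_{rev})\, m_\infty(V)\, m(t)\,
  \big[(1-w)\, h_{Ca}(t,V) + w\, r_{300}(V)\big]$$

with Boltzmann activation $m_\infty(V) = 1/(1+e^{-(V-V_{1/2})/k})$,
optional activation kinetics $m(t) = 1 - e^{-t/\tau_{act}}$ (the default
$\tau_{act}=0$ makes activation instantaneous and the peak analytic), and
a single-exponential CDI gate

$$h_{Ca}(t,V) = r_\infty(V) + (1 - r_\infty(V))\,e^{-t/\tau_{CDI}},
\qquad 1 - r_\infty(V) = (1 - r_{\infty,max})\,u(V),$$

where $u(V)$ is the peak current magnitude at $V$ normalized to its
maximum over the step family. Scaling CDI depth by $u(V)$ produces the
U-shaped inactivation profile that mirrors the V-shaped current-density
profile: the more Ca²⁺ a voltage admits, the deeper the inactivation.

CMI is the mixture weight $w \in [0,1]$: a fraction $w$ of channels sits
in a non-inactivating state pinned at the end-stage amplitude
$r_{300}(V) = h_{Ca}(300\,\mathrm{ms}, V)$, the rest behave normally.
Pinning at the 300-ms amplitude (rather than the asymptotic floor
$r_\infty$, from which it differs by $e^{-300/\tau_{CDI}} \approx
2\times10^{-9}$ at the defaults) makes the 300-ms current *exactly*
invariant in $w$ — the constant-I300 rule — which is the property the
whole analysis hinges on. Ba²⁺ traces carry no CDI and decay as
$e^{-t/\tau_{VDI}}$.

### Why VDI is not a second factor on the Ca²⁺ trace

Slow VDI is carrier-independent in origin, but over a 300-ms Ca²⁺ step it
contributes only a few percent at 50 ms ($e^{-50/1640} \approx 0.97$) and
is experimentally inseparable from the CDI floor: the calibration below
absorbs it into $r_{\infty,max}$ and $\tau_{CDI}$. Multiplying the Ca²⁺
trace by an explicit VDI exponential on top of the calibrated CDI law
would double-count it and shift every index by ~1 % (e.g. the baseline
CDI index from 0.77 to 0.78). VDI is therefore modeled explicitly only
where it is the sole inactivation — the Ba²⁺ carrier — which is also
exactly what the Ba²⁺ data constrain.

## Indices and calibration

`trace_indices()` computes the standard quantities: peak current
$I_{peak}$, timed amplitudes $I_{50}, I_{100}, I_{300}, I_{1000}$
(nearest-sample lookup; with 0.5-ms sampling the difference from
interpolation is negligible and reproducibility wins), remaining
fractions $r_{50}, r_{300}$, the CDI-strength index $S_{Ca} = 1 - r_{50}$
at −10 mV, and capacitance-normalized densities $J_{peak}, J_{300}$.
All indices are defined on magnitudes; stored currents are inward-negative.

The frozen defaults are not arbitrary: `calibrate_cdi_params()` solves the
exactly-determined system linking three measured numbers — the baseline
CDI index (0.77), the CMI peak fraction (0.35) and the CMI CDI index
(0.41) — to the three model parameters:

```{r}
calibrate_cdi_params(0.77, 0.35, 0.41)
```

which motivates the defaults $\tau_{CDI} = 15$ ms, $r_{\infty,max} = 0.20$
and the canonical CMI scenario weight $w = (1-0.35)/(1-0.20) = 0.8125$.
The remaining defaults ($V_{1/2} = -20$ mV, $k = 7$ mV, $E_{rev} = +45$
mV, conductance density set so $J_{Ca}(-10\,\mathrm{mV}) = -20$ pA/pF,
$\tau_{VDI} = 1640$ ms giving $r_{50,Ba} \approx 0.97$) are plausibility
choices with no measured values behind them; every one is overridable in
`gating_params()` and through the YAML config. The driving force is
linear in $(V - E_{rev})$ rather than GHK because every index in scope is
a ratio or a relative amplitude.

A note on feasibility: the calibration system has a unique admissible
solution for a broad region of inputs; it is rejected as infeasible when
the implied floor reaches or exceeds $r_{50}$ (equivalently, when
$\,f_{peak}(1-S_{Ca}^{CMI}) \ge 1-S_{Ca}^{base}$), when the implied
weight leaves $(0,1]$, or when the requested peak fraction in
`mixture_weight_for_peak_fraction()` falls below the given end-stage
floor — the "lower limit of CMI".

## Induction, run-down, classification

Drug-induced CMI is modeled as a perfusion-limited saturating exponential
$w(t) = w_{final}(1 - e^{-(t-t_{onset})/\tau_{perf}})$ with
$\tau_{perf} = 75$ s, so the weight reaches ≥97 % of plateau within 4–5
minutes — solution exchange, not chemistry, being rate-limiting. One
sweep is simulated per 30-s repetition interval. Run-down scales the
conductance by $e^{-t/\tau_{decay}}$ per sweep.

`classify_inhibition()` encodes the decision table: a significant drop
(relative change > 10 % by default) in peak and CDI index *without* a
drop in $I_{300}$ is CMI; drops in peak and $I_{300}$ with the CDI index
unaltered are conventional; neither is "none"; anything else "mixed".
Fixed relative tolerances replace significance tests deliberately — the
classifier is a definition, not an inference procedure — and indices are
computed per cell and then averaged, matching how such cohorts are
reported. With 2 % RMS recording noise, a single trace gives the CDI
index an SD of roughly 3–4 %, so classification at the 10 % threshold is
reliable only on cohort means (five cells suffice); the tests exercise
exactly that configuration.

## The FRET two-hybrid binding model

Binding between fluorophore-tagged fragments is quantified by the
saturating isotherm

$$FR = 1 + \frac{FR_{max} - 1}{1 + K_d / D_{free}},$$

fitted by unweighted nonlinear least squares over $(\log K_d, FR_{max})$
(Levenberg–Marquardt via `minpack.lm`; the log parameterization keeps
$K_d$ positive and conditions the problem; initialization at the median
$D_{free}$ and the largest observed $FR$). Points are binned by five
adjacent cells sorted by $D_{free}$ before fitting, as such data are
displayed; a trailing partial bin is kept when it holds at least
⌈bin/2⌉ cells. Binning points on a curved isotherm introduces a small
convexity bias (<1 % in $K_d$ for the default layouts) — far below the
noise floor, but the reason binned and raw fits are compared at 1 %
rather than machine tolerance in the tests. Fits are refused as
unidentifiable when the donor range spans less than 10-fold or when the
fitted dynamic range $FR_{max}-1$ is under 3× the residual RMS (flat
data, the signature of very weak binding). A nonparametric bootstrap
(resampling points) supplies a percentile interval for $K_d$. $D_{free}$
is instrument-relative, so recovered affinities are comparable only
within a setup; the recovery tests use the reference values purely as
generating parameters.

## Synthetic data

The generators emulate the statistical structure the analysis assumes and
nothing more: per-cell capacitance and expression scales are lognormal
(strictly positive, right-skewed, standard for transient transfection;
default CV 0.3), recording noise is additive Gaussian with SD 2 % of each
trace's peak (leak assumed perfectly subtracted; no 1/f or line noise),
FRET donor intensities are log-uniform so the saturating curve is sampled
evenly, and FR noise is homoscedastic Gaussian (SD 0.15) floored at 0.5.
Every generator is reproducible from its seed and restores the caller's
RNG state. Passing tests on these cohorts shows the pipeline recovers
known parameters under the assumed noise model — not that real recordings
satisfy that model; series-resistance artifacts, imperfect leak
subtraction and correlated noise are all outside it.

## The SNc pacemaker model

Substantia nigra pars compacta dopaminergic neurons pace autonomously
(~1–4 Hz) with CaV1.3 carrying much of the drive, which ties this channel
to Parkinson's disease and motivates asking what CMI-like inhibition does
to pacemaking. Detailed host-neuron models from the literature are not reproduced here; the
package's neuron is a deliberately minimal single compartment whose only
claim is to carry the CaV1.3 mechanism faithfully:

- HH-style Na⁺/K⁺ spike currents and an ohmic leak whose depolarized
  reversal (−59 mV) supplies the background drive;
- the L-type current $I_{CaL} = g_{CaL}(1-b)\,m_\infty(V)\,[(1-w)h +
  w\,r_{\infty,max}]\,(V-E_{Ca})$, the dynamic counterpart of the trace
  model: a fraction $w$ of the conductance is pinned at the end-stage
  availability, the rest carries Ca²⁺-driven CDI;
- a CDI gate relaxing toward $h_\infty(\mathrm{Ca}) = r_{\infty,max} +
  (1-r_{\infty,max})/(1+(\mathrm{Ca}/K_{CDI})^4)$ with fast onset
  (35 ms) and slow recovery (1.2 s) — recovery from CDI is much slower
  than onset for these channels, and that single slow recovery variable
  is what sets the pacemaker period;
- a one-pool submembrane Ca²⁺ with linear extrusion (τ = 40 ms), fast
  enough that Ca²⁺ tracks the current and the CDI gate is the only slow
  state;
- the Na⁺/K⁺ gating functions shifted +22 mV relative to the leak/CaL
  frame, so the subthreshold oscillation is carried by leak + CaL + CDI
  alone and spikes simply ride its crests (with classic unshifted
  kinetics the subthreshold Na window current destroys the slow wave and
  forces tonic fast firing);
- an optional SK-type Ca²⁺-activated K⁺ conductance (default 0),
  retained as a standard knob for this cell type but not part of the
  frozen baseline.

Integration is fixed-step RK4 at dt = 0.025 ms — determinism and simple
regression testing beat adaptive steppers here; halving dt changes the
baseline rate by under 0.01 %. Event rates count upward crossings of
0 mV (pacemaking, 2-ms refractory) or of the mean level (oscillation
mode, i.e. `g_na = 0`, 50-ms refractory), discarding a 1-s settling
transient; Ca²⁺ influx is the time-averaged $|I_{CaL}|$ (pA ≡ pC/s).

The defaults were tuned once — by a coarse Latin-hypercube search over
the subthreshold parameters followed by local refinement — against the
qualitative program: baseline pacemaking inside 1–4 Hz; rate and Ca²⁺
influx non-increasing in $w$; a 28 % conductance block slowing both while
a voltage-clamp harness on the same mechanism shows the CDI index
unchanged; oscillation mode showing the same orderings. They were then
frozen; the tests are regression tests against that frozen point, and all
rate statements are ordinal because no quantitative rates are available
to target. At high CMI weight ($w \gtrsim 0.75$) the model goes quiescent
rather than merely slow — the monotone orderings still hold, but the
graded-slowing regime spans roughly $w \in [0, 0.6]$.

The clamp harness (`cal_clamp_trace()`) closes the loop between the two
model levels: clamping the dynamic mechanism to a −10 mV step yields a
decaying Ca²⁺ current whose $S_{Ca}$ decreases with $w$ while the 300-ms
current varies by <1 % across $w$ — the dynamic analogue of the
constant-I300 construction.

## Problem sizes and numerical choices

The test suite simulates 300-ms steps at 0.5-ms sampling (601 samples),
cohorts of 5–200 cells, FRET cohorts of 60 cells binned to 12 points with
20-seed recovery batteries and 200-fold bootstraps, and neuron runs of
6–20 s simulated time; the full suite runs in well under a minute, the
neuron property battery dominating. Ties in nearest-sample lookup resolve
to the earlier sample (`which.min`). Degenerate inputs — flat or
all-zero traces, header-only files, sub-10-fold donor ranges, infeasible
calibration triples, mixture weights outside $[0,1]$ — raise errors
rather than returning guesses.

## Known limitations

The channel model is phenomenological: no Markov states, no mechanistic
calmodulin/Ca²⁺ transduction, no GHK flux, no activation-shift effect of
the C-terminal modules on $V_{1/2}$ (reported elsewhere, not modeled
here, so `w` leaves activation untouched). The neuron is a single
compartment with no dendritic structure, no dopamine handling and no
oxidant-stress coupling; its parameters are a frozen working point, not a
fit to recordings. Absolute FRET affinities are instrument-relative.
Synthetic cohorts share the noise model stated above; conclusions about
real data inherit those assumptions.
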