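---
title: "The beta component of gamma-band auditory steady-state responses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The beta component of gamma-band ASSRs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Cortical circuits entrain to periodic auditory stimuli (auditory
steady-state responses, ASSRs). In schizophrenia the 40 Hz response to
40 Hz stimulation is robustly reduced, and some studies additionally report
an *increased* 20 Hz subharmonic under 40 Hz drive while others do not.
This package implements a small excitatory–inhibitory microcircuit of theta
neurons in which a single GABAergic alteration — prolonged IPSC decay —
produces that 20 Hz component through *beat-skipping*: the prolonged
inhibition vetoes the population response to every other drive cycle,
moving spectral power from 40 Hz to its subharmonic. The central result the
package reproduces is that this beta component exists only within a narrow
window of stimulus input strengths, which offers an explanation for the
inconsistent experimental reports.

## Model

Each cell $k$ is a theta neuron, a one-variable phase model of an excitable
membrane:

$$\frac{d\theta_k}{dt} = 1 - \cos\theta_k + (b + S_k + N(t))(1 + \cos\theta_k),$$

with time in ms. A spike is the phase crossing $\pi$. For constant
suprathreshold input $I$ the model fires periodically with period
$\pi/\sqrt{I}$; for $b < 0$ it is excitable with a stable rest phase
$\theta^* = -\arccos\!\big((1+b)/(1-b)\big)$.

The synaptic input is a signed sum over presynaptic gating variables,
$S_k = \sum_j \alpha_j\, g_{jk}\, s_{jk}$ with $\alpha_j = +1$ for
excitatory and $-1$ for inhibitory presynaptic cells, and each gating
variable obeys

$$\frac{ds_{jk}}{dt} = -\frac{s_{jk}}{\tau_j}
  + e^{-\eta(1+\cos\theta_j)} \frac{1-s_{jk}}{\tau_R},$$

so transmitter release is switched on (activation $\approx 1$) only while
the presynaptic phase is near the spike phase $\pi$, rises with
$\tau_R = 0.1$ ms and decays with the synapse-class time constant
($\tau_{exc} = 2$ ms, $\tau_{inh} = 8$ ms in the control circuit).
Background activity arrives as Poisson noise spikes, each eliciting the
difference-of-exponentials EPSP

$$N(t) = H(t-t_n)\, A g_{max}
  \frac{e^{-(t-t_n)/\tau_{exc}} - e^{-(t-t_n)/\tau_R}}{\tau_{exc}-\tau_R}.$$

The network couples 20 pyramidal cells and 10 fast-spiking (PV$^+$-like)
interneurons all-to-all (self-synapses included; a flag excludes them, with
no visible effect on any result in this package). A single pacemaker cell
delivers the rhythmic drive: it is itself a theta neuron under constant
input $I_p = (\pi f/1000)^2$, whose closed-form period equals the
click-train interval $1000/f$ ms, starting at phase $\pi$ so the first
click lands at stimulus onset. Its efferent synapses use $\tau_{exc}$
kinetics (the natural choice for an excitatory drive; nothing in the
circuit distinguishes a dedicated drive time constant) and weights
$I \cdot g_{de} = I \cdot 0.3$ onto pyramidal cells and
$I \cdot g_{di} = I \cdot 0.08$ onto interneurons, where $I$ is the
input-strength factor that the main experiment sweeps.

The simulated MEG signal sums all excitatory synaptic gating variables with
a pyramidal postsynaptic target. The package's default restricts this to
the recurrent E$\to$E synapses and excludes the pacemaker's own gating
(`include_drive_in_meg = FALSE`): including the drive synapses injects a
pure 40 Hz component of fixed amplitude that is present even when the
network itself does not respond, which contradicts the defining feature of
the weak-input regime (both band powers near zero when the drive fails to
synchronise the network). Band powers are read from the exact 20 and 40 Hz
bins of the magnitude-squared Fourier transform of the 20-trial
time-domain average; with 500 ms trials the resolution is 2 Hz, so both
frequencies fall on exact bins and no window or detrending is needed. The
normalisation is $|X_k/n|^2$ — an on-bin sinusoid of amplitude $a$ has band
power $a^2/4$ independent of the sampling resolution, which is what makes
the time-step-refinement check meaningful.

## Disease-variant circuits

Four alterations map onto the model:

* **IPSC** (reduced GAT1 reuptake): inhibitory decay time raised from 8 to
  28 ms. Applied to all inhibitory synapses by default; a flag
  (`ipsc_ie_only`) restricts it to synapses onto pyramidal cells, which
  behaves almost identically.
* **IPSC+gGABA** (reduced GABA synthesis): additionally, $g_{ie}$ and
  $g_{ii}$ scaled by a level swept from 100% down to 10%.
* **IPSC+bInh** (NMDAR hypofunction at interneurons): additionally, the
  interneuron applied current lowered to $-$`bInh_level`, swept over
  magnitudes 0.01–0.6. These values are interpreted as absolute currents:
  the mildest published setting ($-0.01$) then *equals* the control current,
  which is exactly how the mildest curve behaves (identical to the IPSC
  model — the package tests this equality). The alternative reading, as
  decrements below control, is available behind `bInh_as_decrement`.
* **Full**: all three, with the GABA grid (10% steps) paired one-to-one
  with ten interneuron-excitability magnitudes subsampled from the bInh
  grid (its endpoints retained) so that both alterations strengthen
  together; the pairing is a declared convention and the grid is
  overridable.

## Parameters that are package choices

Three constants are required by the equations but have no published value;
each was fixed once, before any acceptance measurement, by the behaviour of
the *control* circuit, and is exposed in `model_parameters()`:

* `eta = 5` (gating activation scale). The standard value of the
  theta-neuron synapse model this circuit family uses. It sets how long the
  release window around the spike phase stays open; 5 gives strong control
  entrainment at every drive frequency. Nearby values behave the same
  (4 narrows the beta window slightly, 6 is indistinguishable from 5).
* `noise_rate = 0.002` spikes/ms per cell (one background EPSP per cell per
  500 ms trial on average). Each noise EPSP peaks near 0.26, far above the
  firing threshold $|b| = 0.01$, so the rate — not the amplitude, which is
  published — controls how disruptive the background is. The calibration
  criteria: the control network entrains cleanly at 20/30/40 Hz; an
  *undriven* network shows no spectral peak above the band median (the
  package's negative control); and trials vary visibly, so that averaging
  over 20 noise realisations is meaningful. Rates at or above 0.005
  progressively destroy beat-skipping because stray suprathreshold EPSPs
  fill in the vetoed cycles.
* `b = -0.01` (applied current). The parameter table this model descends
  from is reproduced with one correction: an applied current of $-0.1$
  silences the interneuron population (drive $0.08 < |b|$ and the brief
  E-volley input cannot traverse the larger excitability gap in time), and
  without interneuron volleys there is no prolonged-IPSC veto and no 20 Hz
  component at any input strength. With $-0.01$ — the value used throughout
  this model family, and the value the mildest interneuron-excitability
  setting ($-0.01$) coincides with — the full phenomenology appears.

Every trial starts from rest: all gating variables at 0 and every cell at
the stable fixed point of its own applied current, so trial-to-trial
variability comes from the background noise alone. This matters for the
time-domain average: beat-skipping has a parity (which cycles are skipped),
and a deterministic common initial state locks the parity to the stimulus
onset, letting the 20 Hz component survive averaging. Randomising initial
phases per trial (`init = "random"`) randomises the parity and partially
cancels the beta component — the cancellation mechanism that makes
averaging hazardous for detecting this component in the first place.

## The experiments and the emergence criterion

`run_condition()` simulates 20 trials of one condition, averages the MEG
signals in time, and reads the band powers from the spectrum of the
average. `run_replication()`, `run_input_sweep()` and
`run_combination_sweep()` assemble the four experiment families (the
`analysis/` scripts are thin drivers over these). Seeds flow
deterministically: base seed $\to$ condition seed (hashed from the
condition's content, so the same condition reproduces identically in any
sweep) $\to$ trial seed $\to$ per-cell noise seed.

"A substantial 20 Hz component" is never quantified in the source
literature; the package's declared criterion (`beta_window()`) is the
midpoint between the sweep's minimum and maximum 20 Hz power. The window is
reported as the first factor above threshold and the first factor past the
20 Hz maximum below it, by majority over five base seeds. For combination
families the threshold is pooled across the family's whole grid, so levels
where the component has vanished contribute counts of zero rather than
re-thresholding their own noise floor.

The beat-skipping index (`beat_skipping_index()`) counts pyramidal
population spikes per drive cycle (after a 100 ms onset window), classifies
the two cycle parities by their mean counts, and reports
$1 - \text{low}/\text{high}$. It is computed per trial and averaged,
because the skipped parity can differ between trials. One subtlety the
index exposes: in this reconstruction the *count* alternation of the
pyramidal population is sharpest near 90% input strength (index
$\approx 0.95$), while at 100–110% the pyramidal cells respond to every
cycle and the alternation lives in the interneuron population and in the
synchrony of the pyramidal volleys — strong 20 Hz power with a count-based
index near zero. The index therefore marks the entry into the beta window
rather than tracking the 20 Hz power throughout it (across the sweep the
two remain positively rank-correlated).

## Numerics

Forward Euler with $dt = 500/8192 \approx 0.061$ ms, all phases and gating
variables advanced from the state at $t$. Phases are wrapped to
$[0, 2\pi)$; spikes are upward $\pi$ crossings with linear interpolation
between samples. The gating update cannot leave $[0,1]$ for $dt < \tau_R$;
the integrator asserts this rather than clamping, and reports the step
index on any non-finite state. Halving the time step changes converged band
powers by well under 5% (the control circuit's 20 Hz bin is background
floor, about $10^{-3}$ of its 40 Hz power, and is checked as such rather
than as a converged quantity). The compiled core (Rcpp) is
formula-for-formula identical to a plain-R reference integrator kept for
cross-checking; synapses sharing a presynaptic cell and decay time share
one gating state, which is exact, not an approximation.

Problem sizes throughout the tests and the acceptance script are the full
study protocol — 30 cells plus pacemaker, 8192-point 500 ms trials, 20
trials per condition — except that structural unit tests use 250 ms/4096
point trials (same step size, 4 Hz resolution keeps both target
frequencies on-bin) and the combination-narrowing check uses the coarser
10%-step GABA grid.

## What the generator does and does not emulate

The simulator doubles as the data generator: there is no external data.
It emulates the entrainment physiology this model family was built for —
gamma-band locking to click-train drive, its degradation under prolonged
inhibition, and subharmonic transfer via beat-skipping. It does not emulate
cochlear or thalamic preprocessing, amplitude-modulated or chirp stimuli,
axonal delays, conductance-based membrane dynamics, other interneuron
classes (SST$^+$, VIP$^+$), or realistic MEG forward models and sensor
noise. Passing tests therefore support claims about this microcircuit
mechanism, not about quantitative features of recorded human ASSRs.

## Known limitations

* The emergence window reproduces as 90–120% of the default input strength
  against the reported 80–120%: the lower edge sits one grid step high.
  The edge location is sensitive to exactly the quantities that are
  unpublished (noise rate, activation scale, initial state), so a one-step
  offset is within the reconstruction uncertainty.
* At exactly 100% input strength the count-based beat-skipping index is
  near zero even though the 20 Hz component is at its strongest (see
  above); analyses that need the index should read it across the sweep,
  not at a single factor.
* Absolute power values are in arbitrary units tied to the gating-sum MEG
  convention; only comparisons between conditions are meaningful.
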