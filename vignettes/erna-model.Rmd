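---
title: "A vesicle-depletion Kuramoto model of evoked resonant neural activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A vesicle-depletion Kuramoto model of evoked resonant neural activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ernasim)
```

## The model

Evoked resonant neural activity (ERNA) is a high-frequency (> 200 Hz),
high-amplitude oscillation recorded at the stimulation site in the
subthalamic nucleus (STN) during deep brain stimulation (DBS). Its most
striking slow feature is a peak-frequency decay over tens of seconds of
continuous stimulation, from roughly 340 Hz at onset toward a ~260 Hz
steady state, summarized by the empirical curve

$$f_\mathrm{ERNA}(t) = 260 + 80\,e^{-0.07 t}\ \mathrm{Hz},$$

with $t$ the time since stimulation onset. `ernasim` implements a minimal
single-population model of this phenomenon: $N$ stochastic Kuramoto phase
oscillators (default $N = 50$, representing STN neurons) with all-to-all
coupling whose strength decays through synaptic vesicle depletion,

$$d\theta_i = \Big[\omega_i + k(t)\,\langle f(\theta_j - \theta_i)\rangle_j
  + I(t)\, g(\theta_i)\Big] dt + \zeta\, dW_i ,$$

where

* $\omega_i \sim \mathcal{N}(\Omega, \sigma^2)$ (sampled in Hz, stored in
  rad/s) are natural frequencies;
* $f(x) = f_0 + f_1\cos x + f_2 \sin x + f_3 \cos 2x + f_4 \sin 2x$ is a
  second-order Fourier coupling function of pairwise phase differences;
* $g$ is the phase-response curve (PRC), a sine by default; a second-order
  Fourier PRC and a tabulated (e.g. Hodgkin–Huxley-derived) PRC are
  selectable alternatives;
* $I(t) = I \cdot I_\mathrm{fact} \cdot u(t)$, with $u$ a pulse train that is
  1 for exactly one integration timestep at each stimulation pulse
  ($u(t) = 1$ iff $t \bmod 1/f_\mathrm{stim} < \Delta t$) and
  $I_\mathrm{fact}$ a dimensionless amplitude factor;
* $\zeta$ scales independent Wiener noise per oscillator.

Network synchrony is measured by the order parameter
$Z = \frac1N \sum_j e^{i\theta_j}$; $\mathrm{Re}(Z)$ serves as the
recorded-signal surrogate and $|Z|$ as the ERNA amplitude surrogate.

One deliberate design decision departs from a literal reading of the phase
equation: the pairwise coupling sum is implemented as a population *mean*,
with the baseline coupling strength `kmu` absorbing the scale. This makes the
dynamics invariant to the network size, consistent with the reported
robustness of the model's predictions when the population is grown from 50
to 200 oscillators.

## Vesicle pools and the coupling decay

Three vesicle pools (readily-releasable RRP, recycling RP, reserve RtP)
deplete impulsively at stimulation pulses and replenish continuously:

$$\frac{dn_\mathrm{pool}}{dt} = \frac{1 - n_\mathrm{pool}}{\tau_\mathrm{pool}}
 - \sum_j \delta(t - t_j)\, p_\mathrm{pool}\, n_\mathrm{pool},$$

and the coupling strength follows the *dominant pool*:

$$k(t) = k_\mu \cdot \max\big(M_\mathrm{RRP} n_\mathrm{RRP},\,
  M_\mathrm{RP} n_\mathrm{RP},\, M_\mathrm{RtP} n_\mathrm{RtP}\big).$$

Between pulses the exact exponential update
$n \mapsto 1 - (1-n)e^{-\Delta t/\tau}$ is used instead of Euler stepping
(cheaper and free of discretization error; the equivalence is tested).
Within a pulse timestep the order of events is: deplete pools, compute
$k(t)$, advance phases, replenish. Dominance ties break toward the more
readily releasable pool. $M_\mathrm{RRP} = 1$ normalizes the off-stimulation
coupling to exactly $k_\mu$; $M_\mathrm{RP} = 0.6$ and $M_\mathrm{RtP} = 0.3$
follow the relative-size-times-inverse-distance construction rule with
round defaults, exposed in the configuration.

Stimulation amplitude enters twice: it scales the stimulation intensity
($I \cdot I_\mathrm{fact}$) and every per-pulse release probability
($p_\mathrm{pool} \cdot I_\mathrm{fact}$). The linear scaling is only
meaningful near the fitted operating point; `Ifact` is validated to
$[0.8, 1.1]$.

### Pool calibration

The exact fitted pool values are not published; `calibrate_pool_parameters()`
derives them from the pools' stated timescales:

* Replenishment: invert $1 - e^{-t/\tau} = 0.95$ for "replenishes to 95%
  within $t$" ($t$ = 2 s for RRP, 8 s for RP, 120 s for RtP).
* RRP depletion: the constraint "depleted within approximately 10 pulses of
  100 Hz stimulation" describes observed behaviour under pulsed stimulation,
  where replenishment acts between pulses. The release probability is
  therefore found by root-finding on the with-replenishment iteration so the
  occupancy first drops below 10% at exactly pulse 10
  ($p_\mathrm{RRP} \approx 0.238$; the no-replenishment closed form
  $1 - 0.1^{1/10} \approx 0.206$ would need ~13 pulses once replenishment is
  accounted for).
* RP and RtP depletion: these pools' timescale statements ("seconds",
  "minutes") pin down depletion *rates*, so the closed form
  $(1-p)^k = 0.1$ is inverted directly (at 100 Hz over 2 s and 120 s
  respectively). Forcing sub-10% occupancy against their own replenishment
  would require release probabilities that destroy the characteristic slow
  dynamics — at 130 Hz the calibrated RtP gives the decay rate
  $\lambda = 1/\tau + p f \approx 0.05\ \mathrm{s}^{-1}$ and a steady-state
  occupancy near 0.5, which is what produces the slow ERNA frequency decay
  and its plateau.

Under sustained stimulation at rate $f$ each pool approaches the pre-pulse
fixed point $n^* = (1 - e^{-1/(f\tau)}) / (1 - (1-p)e^{-1/(f\tau)})$
(`pool_steady_state()`), which the simulated traces match to numerical
accuracy.

## How the model produces the ERNA phenomenology

The reference parameter regime works as follows (all of this is emergent
behaviour of the fitted equations, verified by the test suite):

* **Off stimulation** the second coupling harmonic ($f_4 > 0$) organizes the
  population into two tight, nearly antipodal clusters. Balanced clusters
  nearly cancel in $Z$, so $|Z|$ stays low (below the 0.2 synchrony
  threshold), while the small cluster-size imbalance leaves a low-amplitude
  rhythm in $\mathrm{Re}(Z)$ at the clusters' common rotation frequency
  $\approx \Omega + \frac{k_\mu}{2\pi}(f_0 + f_3)$ — the ~40 Hz
  off-stimulation peak. Because the imbalance is set by the random initial
  conditions at $N = 50$, the measured off-peak varies by tens of Hz from
  realization to realization; only its average over realizations is a stable
  quantity.
* **On stimulation** the pulsed drive through the sine PRC, together with
  the weakened inter-cluster repulsion once the pools deplete, merges the
  clusters into a single synchronized group ($|Z|$ close to 1). The group
  rotates at $\approx \Omega + \frac{k(t)}{2\pi}(f_0 + f_1 + f_3)$, so as
  the pools deplete and $k(t)$ falls from $k_\mu$ toward
  $k_\mu M_\mathrm{RtP} n^*_\mathrm{RtP}$, the spectral peak decays from its
  onset transient toward the ~260 Hz steady state on the reserve pool's
  timescale.
* **Harmonic entrainment**: while the collective frequency sweeps past
  integer multiples of the stimulation rate, the pulse train can lock it
  transiently — visible as brief plateaus at 390 Hz ($3 \times 130$) early
  in stimulation, and a stabilizing influence near 260 Hz
  ($2 \times 130$) at steady state.
* **Return to baseline**: the fitted odd part of the coupling function is
  negatively skewed — $f_2 < 0$ means the majority cluster repels its own
  members toward the antipodal well created by the second harmonic. When
  stimulation ends, the coupling strength is still at its depleted minimum
  for the second or two the readily-releasable pool needs to refill; in that
  low-barrier window the noise and the $f_2$ repulsion dissolve the merged
  cluster back into the balanced two-cluster configuration, which the
  recovering coupling then locks in. The same repulsion actively equalizes
  cluster sizes off stimulation. Without the negative skew the merged
  cluster survives stimulation offset indefinitely and the model never
  returns to baseline — this is why the skew is a structural requirement and
  its sign is excluded from positive values in the fitting bounds.
* The negative $f_0$ (a phase-indiscriminate inhibitory load, interpretable
  as pallidal input) is what lets the network run far below the mean natural
  frequency off stimulation while the oscillators keep a high intrinsic rate.

## Fitting

The two-part cost follows the published design: the on-stimulation cost sums
absolute deviations between the model's peak-PSD frequency (240–400 Hz band,
100 ms windows, sampled every 100 ms over 100 s of stimulation) and the
target decay curve; the off-stimulation cost is zero while the maximal
off-stimulation $|Z|$ stays below 0.2 and grows linearly above
($Z_\mathrm{max}/0.2 - 1$); the total is $0.9\,\mathrm{CostOn} +
0.1\,\mathrm{CostOff}$. Whether the 100 ms cost windows overlap is left
ambiguous in the source material; both modes are implemented and
non-overlapping windows are the default (overlapping windows are reserved
for figure-style output).

`pattern_search()` is a generalized pattern search with coordinate polling
($2d$ directions), mesh expansion 2 on success, contraction 0.5 on failure,
termination on mesh < tol or an evaluation budget — the standard
derivative-free scheme. Defaults: initial mesh 0.25 of the bound range
(0.1 for the shipped reference fit), tolerance $10^{-3}$. One seeded
realization is used per cost evaluation, which makes the objective
deterministic; averaging across seeds is available but quadruples cost for
modest smoothing.

The 10 free parameters are $\Omega, \sigma, k_\mu, \zeta, I, f_0..f_4$; the
integration timestep ($\Delta t = 10^{-4}$ s) and the PRC are held fixed
(the source material does not state whether its optimizer varied the noise
level; we fit $\zeta$). Bounds are documented in `default_fit_bounds()`;
a constrained variant pins $\Omega = 20$ Hz (`constrain_omega = TRUE`) to
reproduce the low-natural-frequency control experiment, which fails to
produce the high-frequency decay — one of the model's key negative results.

### The shipped reference fit

The originally fitted parameter values were never published, so the package
ships its own reference fit, produced with `fit_erna()`:

1. An analytic design pass places the regime: the off-stimulation two-cluster
   rotation at ~40 Hz fixes $\Omega + \frac{k_\mu}{2\pi}(f_0+f_3)$ (after
   correcting for the average cluster-imbalance shift
   $\frac{k_\mu f_1}{2\pi N}$); the 260 Hz asymptote and 80 Hz decay
   amplitude fix $\Omega + \frac{k_\mu}{2\pi}(f_0+f_1+f_3)$ against the
   reserve-pool occupancy profile at 130 Hz.
2. A generalized pattern search (260 evaluations of the full 120 s fitting
   protocol, one seeded realization per evaluation, bounds around the design
   regime chosen to keep the off-stimulation state in its two-cluster,
   sub-threshold-synchrony regime) polishes $\Omega$, $k_\mu$ and the
   coupling coefficients against the two-part cost.
3. Structural corrections that the cost function cannot see, applied as
   model-design steps and re-verified over 15 realizations each: the odd
   part of the coupling function is made negatively skewed
   ($f_2 = -0.45$) so the post-stimulation state dissolves back to baseline
   (see above); the noise level ($\zeta = 17$) is set where the late
   steady-state peak stays captured near the stimulation harmonic without
   upward unlocking excursions; and $f_0$ absorbs the analytic off-peak
   centering correction.

The result is frozen in `reference_parameters()` and doubles as the default
`model_parameters()`. The fitted coupling function keeps the published
character: a negative shift ($f_0 < 0$), a negatively skewed odd part, and a
second harmonic stronger than the first.

## Spectral analysis choices

Welch spectrograms of $\mathrm{Re}(Z)$ use 1 s windows with 25% overlap for
long recordings and 100 ms windows (50% overlap for figures, non-overlapping
for the cost) otherwise. Within each window the PSD is Welch-averaged over
Hann-tapered segments of half the window length at 50% segment overlap,
zero-padded to the next power of two at or above the window length; the
published analysis states the exact windowing internals matter little for
the extracted features, and the Parseval identity is tested. No notch
filters are applied. Peak extraction uses the 240–400 Hz band on
stimulation and 1–100 Hz off stimulation, with ties broken toward the lower
frequency. Measurement noise for the long-term paradigm is white Gaussian
noise at 20 dB SNR relative to the measured signal power.

The recorded trace defaults to a 2-step stride (5 kHz at the default
timestep), keeping the full 0–400 Hz analysis band below 1.6% of Nyquist
aliasing concerns while holding a 1200 s trace at 6M rows; the long-term
paradigm uses a 4-step stride (2.5 kHz) for the same reason.

## What the simulations do and do not emulate

The generator reproduces the study conditions: 50 oscillators, 0.1 ms
Euler–Maruyama steps, 20 s settling plus 100 s of 130 Hz stimulation for
fitting, 15 realizations of noise/frequencies/initial conditions for all
averaged outputs, 1200 s alternating schedules with fully replenished pools
at onset, frequency sweeps across the clinical 70–180 Hz range (default set
90/130/150/180 Hz; the fourth value is our choice inside the clinical
range), amplitude factors 0.8–1.1, and post-stimulation bursting of 10
pulses at 130 Hz per second for 20 s starting 1 s after termination of
continuous stimulation (the exact burst phase is not published).

It does **not** emulate: intra-pulse (< 1 s) ERNA dynamics and evoked
potential shapes, stimulation artefacts (so no artefact removal or skipped
pulses are needed), spatial heterogeneity, inter-pool vesicle recycling, or
multiple interacting neural structures. Passing tests therefore speak to the
slow (tens of seconds to minutes) dynamics only.

Scaled-down problem sizes in the test suite (3 seeds instead of 15, shorter
protocols for sweeps and recovery) are the package's chosen smoke sizes; the
acceptance script and the examples in the README run the full published
sizes.

## Numerical notes and limitations

* Pulse times snap to the integration grid (a pulse fires at the first grid
  step at or after $j/f_\mathrm{stim}$); floating-point ties at exact period
  boundaries resolve to a single pulse.
* Phases are wrapped every step, so trigonometric accuracy does not degrade
  over long runs; with noise, coupling and stimulation all zero, the phase
  advance is exactly linear to machine precision.
* Non-finite phases (possible only under absurd parameter magnitudes) raise
  a structured error naming the parameters; the fitter maps it to infinite
  cost and keeps searching.
* The off-stimulation ~40 Hz peak has a realization-to-realization spread of
  tens of Hz at $N = 50$ (cluster-imbalance effect described above); this is
  a property of the model at that population size, not a numerical artifact.
* The per-window peak-frequency estimator carries an intrinsic
  realization-to-realization spread of roughly 15–20 Hz at $N = 50$ over
  short (tens of seconds) protocols: the stochastic trajectories decorrelate
  under sub-Hz parameter changes, so single-realization peak series are only
  comparable through their ensemble trend. This is why the published
  analyses average 15 realizations, and it bounds how precisely any
  derivative-free search can match one generated peak series to another on a
  small budget.
* The reserve pool's calibrated depletion rate at 130 Hz
  ($\approx 0.05\ \mathrm{s}^{-1}$) is somewhat slower than the empirical
  0.07 s$^{-1}$ decay rate, so the fitted frequency course decays mildly
  slower than the target curve mid-decay; the pool parameters are fixed by
  the biological timescales, not fitted, and this residual is the price of
  that choice.

## Reproducibility

Every source of randomness derives from one master seed through labelled
child seeds (`seed_tree()`): natural frequencies, initial phases, dynamical
noise and measurement noise can each be varied independently. Identical
seeds give bit-identical traces on the same platform; run manifests record
seeds, configuration and output checksums.
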