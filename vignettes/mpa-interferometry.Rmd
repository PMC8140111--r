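---
title: "Interferometric micropipette aspiration: model, demodulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interferometric micropipette aspiration: model, demodulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifmpa)
```

## The measurement problem

Micropipette aspiration (MPA) draws a soft body — a hydrogel bead, an egg, an
oocyte — into a glass capillary of internal radius $R_p$ by suction $\Delta P$
and reads its mechanics from the aspirated length $L_p$. Camera-based MPA is
limited to hundreds of nanometres of displacement resolution and needs image
post-processing. An all-optical variant replaces the camera with two
low-finesse Fabry–Pérot cavities multiplexed on a single broadband source and
spectrometer:

* the **fiber-to-sample cavity**: an optical fiber inside the capillary points
  at the aspirated surface; its length *shrinks* by $L_p(t)$ as the sample is
  drawn in. The medium (water, $n = 1.331$) sets the cavity's refractive
  index.
* the **pressure cavity**: a sealed air cavity ($n = 1$) in front of a MEMS
  membrane whose deflection is proportional to pressure
  ($S = 76.59$ Pa/nm); suction *lengthens* it.

`ifmpa` implements this instrument as software: a physics-forward simulator
of the interferogram stream, the spectral demodulation chain back to
displacement and pressure, and the quasi-static and dynamic viscoelastic
analyses.

## Forward model

The spectrometer samples the band 1510–1595 nm at 166 pm pixel pitch (512
pixels), evenly in wavenumber $k$. Each cavity of optical path length (OPL)
$n_i d_i$ contributes a two-beam fringe, so a frame is

$$ I(k) = E_0(k)\Big[1 + \sum_i V_i \cos(2 k\, n_i d_i + \phi_{0,i})\Big] + \varepsilon(k), $$

with $E_0$ a Gaussian source envelope (50 nm FWHM at 1550 nm), $V_i$ fringe
visibilities, $\phi_{0,i}$ static phase origins drawn once per cavity from
the experiment seed, and $\varepsilon$ additive white Gaussian intensity
noise. Higher-order reflections and reflector cross-terms are neglected
(low finesse). The default noise sd (0.005 of the envelope peak) was chosen
so the demodulated displacement noise floor at 1 kHz is sub-nanometre
(measured ≈ 0.15 nm), matching the instrument class being emulated; it is a
*model* of detector noise, not a characterization of any specific detector.

The simulator (`simulate_experiment()`) evaluates a piecewise pressure
protocol (`pressure_protocol()`, with presets for trapezoidal aspiration,
triangular hysteresis cycling, and oscillatory DMA runs), computes the
ground-truth kinematics, and renders every frame:

* sample cavity length: rest $-\;L_p(t)$,
* MEMS cavity length: rest $+\;P(t)/S$.

Suction is a positive number throughout.

### Sample mechanics

The linearized aspiration model for an incompressible body ($\nu = 0.5$,
fixed) of radius $R_c$ reads

$$ \frac{\Delta P}{E} = \frac{\beta_1\big[1 - (R_p/R_c)^{\beta_3}\big]}{3}\,\frac{L_p}{R_p}, \qquad \beta_1 = 2.0142,\ \beta_3 = 2.1187, $$

which the simulator inverts: an elastic sample responds with
$L_p \propto P$ exactly. Viscoelastic samples (a fixed $E'$, $E''$ table, or
the two-term power law $E^*(\omega) = A(i\omega)^\alpha + B(i\omega)^{3/4}$)
respond to each sinusoidal protocol segment in steady state with amplitude
$L_0 = R_p P_0 / (G\,|E^*(\omega)|)$ and phase lag $\delta = \arg E^*(\omega)$,
where $G$ is the bracketed geometry factor over 3. Ramps and holds of
viscoelastic samples follow $|E^*|$ at a quasi-static reference frequency
(the lowest protocol frequency by default): creep transients are **not**
modelled, because no constitutive creep law is available for the emulated
specimens. This is the main feature of real data the generator does not
reproduce — real hydrogels creep visibly during pressure holds — and it is
why quasi-static fits are restricted to the loading ramp, where an elastic
description is adequate for both simulated and real data.

## Demodulation

The Fourier transform of a mean-subtracted, Hann-windowed frame over the
uniform $k$ grid is the *cavity space*: each cavity appears as a magnitude
peak at its OPL, on bins of width $\pi/(N\,\mathrm{d}k)$ (≈ 14 µm here).
`select_peak()` picks the working bin inside a user/probe window (with a
prominence check against the spectrum-wide background and a 5-bin DC guard);
`track_phase()` reads the complex value at that fixed bin across frames,
unwraps its argument and zeroes it at the first frame. Displacements follow
from

$$ \delta\mathrm{OPL}(t) = \phi(t)\,\frac{\bar\lambda_\mathrm{eff}}{4\pi}, \qquad
   L_p = -\,\delta\mathrm{OPL}/n_\mathrm{medium}, \qquad
   P = S\cdot\delta\mathrm{OPL}\ \mathrm{[nm]}. $$

Numerical choices worth recording:

* **Effective wavelength.** The phase at a fixed bin advances as
  $2 k_\mathrm{eff}\,\delta\mathrm{OPL}$ with $k_\mathrm{eff}$ the centroid of
  (window × envelope) over the $k$ grid — 1550.7 nm at the default specs, not
  the nominal 1550 nm. `effective_wavelength()` computes it; using the
  nominal centre would leave a ≈ 5×10⁻⁴ relative scale error (≈ 1 nm per 2 µm
  of motion). With the calibrated value the noise-free simulate→demodulate
  round trip is accurate to ≈ 0.002 nm RMS over a full aspiration ramp, and
  to < 0.05 nm out to 1.6 mm cavities.
* **Fixed-bin reading.** Only phase *variation* carries information, so the
  bin is never interpolated; peak drift over an experiment is a small
  fraction of a bin at aspiration scales (µm motion vs 14 µm bins).
* **Unwrap safety.** Inter-frame phase steps at or beyond $0.95\pi$ raise a
  warning instead of being silently unwrapped: such motion is under-sampled
  and the trace unreliable.
* **Range.** The sampling theorem bounds recoverable OPL at
  $\pi/(2\,\mathrm{d}k) \approx \bar\lambda^2/(4\cdot 166\,\mathrm{pm})
  \approx 3.62$ mm; `nyquist_opl()` exposes the bound and longer cavities
  are refused. A 1.6 mm water-filled cavity (OPL 2.13 mm) sits comfortably
  inside it.
* **Traces are differential**: both channels are zeroed at the first frame,
  so recovered series are relative to the capture state. Quasi-static fits
  carry an intercept for exactly this reason.

## Preprocessing

Demodulated channels are low-passed with a third-order Butterworth filter
(maximally flat passband), applied forward–backward so it is zero-phase:
DMA phase lags are bias-free by construction (`lowpass()`). The default
25 Hz cutoff can be re-derived from data with `select_cutoff()`: the lowest
frequency at which the maximum-normalized periodogram drops below −40 dB and
stays below for 2 Hz of bandwidth. The −40 dB reference level is normalized
to the PSD maximum to make the criterion scale-invariant; with no crossing
(flat spectra) the default is returned. The filter is an IIR design: the
"maximally flat passband" property that motivates the choice *is* the
Butterworth property, and a finite-impulse-response filter with that
response does not exist in the strict sense.

## Quasi-static analysis

`fit_elastic_modulus()` regresses $L_p$ on $P$ (ordinary least squares,
with intercept) over an explicit time segment — the presets locate the first
loading ramp from the protocol definition (`ramp_window()`) rather than
detecting it from data. The modulus is $E = R_p/(G\,s)$ from the slope $s$.
The intercept choice absorbs the capture offset of differential traces; on
noise-free forward data the fit inverts the model to machine precision.

## Dynamic mechanical analysis

Each oscillation burst is fitted per channel by linear least squares on the
basis $\{\sin\omega t, \cos\omega t, 1, t\}$ (`fit_oscillation()`); the
$\{1, t\}$ terms implement the linear drift correction for incomplete creep
and are orthogonal to the oscillation over the burst's integer period count,
so amplitude and phase are unbiased. The phase lag
$\delta = \delta_P - \delta_L$ is wrapped into $(-\pi, \pi]$; values in
$[-0.01, 0)$ rad are clamped to 0 (noise around the perfectly elastic
limit), anything outside $[0, \pi/2]$ is rejected as unphysical. Then

$$ |E^*| = \frac{3 R_p}{\beta_1[1-(R_p/R_c)^{\beta_3}]}\cdot\frac{P_0}{L_0},
   \qquad E' = |E^*|\cos\delta,\quad E'' = |E^*|\sin\delta. $$

`power_law_fit()` fits $E^*(\omega) = A(i\omega)^\alpha + B(i\omega)^{3/4}$
to the per-frequency moduli on stacked real/imaginary residuals. For fixed
$\alpha$ the model is linear in $(A, B)$, so the fit profiles $\alpha$ on a
0.02 grid over $[0, 1]$ and polishes the best cell with a bounded 1-D
optimizer; negative linear solutions fall back to the best single-term
boundary fit ($A = 0$ or $B = 0$). This profiled strategy replaces a
multi-start nonlinear search and cannot miss the global optimum by more than
the grid polish. The frequency-unit convention of $\omega$ (rad/s vs Hz) is
an explicit, recorded flag, default rad/s; printed parameter sets from the
instrument literature do not pin the convention down, so both are supported
and results always carry the one used.

## Problem sizes and determinism

Simulations run at the instrument's native 1 kHz frame rate for the
validation experiments (tens to ~200 s of protocol, i.e. up to ~2×10⁵ frames
of 512 pixels); unit tests use shorter protocols and reduced frame rates
(100–500 Hz) where the physics is rate-independent. Every stochastic element
(intensity noise, per-cavity phase origins) derives from the acquisition
seed, and identical configurations are bit-identical.

## What passing tests do and do not show

Parameter-recovery tests demonstrate that the *analysis chain is faithful to
the forward model*: sub-nanometre demodulation fidelity, exact quasi-static
inversion, unbiased DMA moduli under noise and drift. They do not validate
the forward model against a physical instrument — real probes add envelope
ripple, wavelength-dependent visibility, detector nonlinearity, mechanical
drift of the probe assembly, and sample creep, none of which are in the
generator. The geometry constants $\beta_1, \beta_3$ are taken as exact;
uncertainty in $R_p$ and $R_c$ propagates directly into moduli and is the
dominant systematic in practice.

## Known limitations

* No creep/viscoelastic transients on ramps and holds (steady-state
  sinusoidal response only).
* Parasitic cavity visibilities are static during aspiration.
* No absolute cavity-length or refractive-index estimation; traces are
  differential.
* The protocol model assumes the programmed pressure is delivered exactly;
  pump dynamics are out of scope.
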