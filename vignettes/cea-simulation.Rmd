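---
title: "Simulating concurrent excitation and acquisition MRI with active analog cancellation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating concurrent excitation and acquisition MRI with active analog cancellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceasim)
```

## The problem

Concurrent excitation and acquisition (CEA) records the MR signal while a
long, low-power frequency-swept RF pulse is still being transmitted. The
payoff is access to species with T2\* far below any achievable echo time,
near-100% acquisition efficiency, and nearly silent scans; the price is that
the transmit waveform couples directly into the receive coil at up to
100 dB above the spin signal. `ceasim` is a desk-scale, fully synthetic
model of the complete signal chain that makes CEA work: passive geometric
decoupling, an actively controlled analog cancellation circuit with an
automated feedback loop, digital removal of the residual leakage, and
convolution-based image reconstruction from radial acquisitions. Every
component is driven by code-generated fixtures, so the whole chain can be
exercised, tested and perturbed without hardware.

## Signal model

All signals are complex baseband envelopes at the Larmor carrier; the
carrier itself is never synthesized. Amplitudes are arbitrary voltage-like
units: no absolute B1 calibration is attempted, and one scalar
(`b1_scale`, in Hz of nutation per unit amplitude) stands in for coil
efficiency where the Bloch oracle needs physical flip angles.

The received signal during transmission is

$$ s_{Rx}(t) = A_{cpl}\, u_{Tx}(t)\, e^{j\varphi_{cpl}} + s_{MR}(t), $$

and the analog canceller subtracts a tapped, re-weighted copy,

$$ s(t) = s_{Rx}(t) - A\, u_{Tx}(t)\, e^{j\varphi}. $$

The coupling amplitude is factored as
`10^(-geometric_isolation_db/20) * a_cpl`, separating the passive isolation
of orthogonal coils (default 30 dB, consistent with a total of ~90 dB when
the analog stage contributes ~60 dB) from the load-dependent part. An
optional linear off-resonance variation (`freq_slope`, dB/kHz and
degrees/kHz) models the frequency dependence of the physical coupling
path; the default of `NULL` (flat) matches the on-resonance calibration
situation, and the end-to-end tests use 0.01 dB/kHz and 0.06°/kHz,
back-computed from a total isolation that decays from ~90 dB at the centre
to ~60 dB a few tens of kHz off-centre.

### Actuator models

The phase shifter and attenuator are modeled through their transfer
curves, not their device physics:

* phase: $\varphi(V) = 280° \cdot \operatorname{atan}(V/v_0) /
  \operatorname{atan}(12/v_0)$ with $v_0 = 4$ V — monotone, saturating
  (varactor-like), anchored to 280° of coverage between 0 and 12 V, with a
  fixed 0.8 dB insertion loss;
* attenuation: 1.3 dB at 6.0 V, linear at 1.2 dB/V down to 3.0 V, and a
  quadratic continuation below 3.0 V matched in value and slope at the
  knee and reaching 30 dB at 0 V.

Only the anchors of these curves are published for the real hardware; the
interpolating shapes are package choices, monotone by construction.

## The feedback loop

`calibrate_canceller()` minimizes the mean received magnitude
$\sum_{n=1}^{N} |s_{Rx}[n]|/N$ over a 4 ms rectangular calibration
acquisition. "Gradient descent" on a scalar objective with two actuators is
realized as coordinate descent with sign probing: evaluate one step up and
down, walk in the decreasing direction until the objective rises. One
iteration is one objective evaluation (one simulated calibration
acquisition). The schedule is: phase passes at 0.3 V then 0.1 V,
attenuator passes at 0.05 V then 5 mV, then — if the threshold has not been
reached — alternating phase/attenuation passes with step sizes halved down
to `refine_floor`.

`refine_floor` defaults to 0.5 mV. This is the one place the package
deliberately refines below the printed step schedule: with the arctangent
phase curve, the slope near 0 V is ≈56°/V, so even a 5 mV phase grid
leaves a worst-case phase error of ≈0.14°, which caps the analog
suppression near 52 dB — incompatible with the 89 dB total isolation the
loop is expected to reach on every channel. Programmable supplies resolve
well below a millivolt, and the nonlinearity of the phase curve is exactly
why variable step sizes are needed; the 0.5 mV floor keeps the worst-case
quantization residual above 89 dB total across the whole coverage.

Thresholds are specified as total isolation in dB and converted internally
to an objective amplitude using the uncancelled coupled signal (before
geometric isolation) as the reference, so "92 dB" means 62 dB from the
analog stage on a 30 dB baseline. `monitor_and_retrigger()` re-runs the
loop from the current setting whenever a channel change pushes the
objective back above threshold; because the restart is warm, re-adjustments
take fewer iterations than the initial calibration. `perturb_load()`
constructs load changes that raise the objective by a prescribed amount
(0.05–0.15 in the fixture's voltage units for the hand-motion scenario) by
solving for the jump magnitude along a random direction in the complex
leakage plane.

## Spin simulation

`fid_response()` evaluates the phantom's impulse response
$h[m] = \sum_i M_{0,i}\, e^{-m\,dt/T_{2,i}^*}\, e^{+2\pi i \phi_i(m\,dt)}$
with phase accumulated through the exact trapezoidal integral of the
ramped readout gradient; positive gradient frequency accrues positive
phase, and `grid_reconstruct()` uses the forward DFT so that this
convention maps +x to +x. `cea_signal()` forms the small-tip CEA signal as
the causal discrete convolution of `h` with the pulse samples. The
convolution model is an LTI approximation: it is exact under a constant
gradient and degrades under ramps (each spin's phase history then depends
on absolute time, not just delay), which is why the oracle comparisons are
run at `ramp_time = 0`.

`bloch_simulate()` is the validation oracle: per-isochromat Rodrigues
rotations about the effective field, T2\* decay on the transverse
components each step, optional T1. It refuses step rotations above 0.5 rad.
Agreement with the convolution model is ≤2% relative RMS at 0.5° effective
flip and degrades monotonically as the flip grows — the expected failure
mode of the small-tip assumption. T1 and repetition-to-repetition steady
state are ignored (effective flips here are fractions of a degree).

Radial geometry: 2D spokes are equal-angle over the full circle so that
every spoke has an antipodal partner; 3D uses a deterministic spherical
spiral. The per-spoke trajectory is $k(t) = \gamma \int_0^t G\,dt'$ with
sample m at $t = m\,dt$, so the trapezoid endpoint is
$\gamma G (T_{acq} - t_{ramp}/2)$, and the deconvolved response sample
h[0] sits exactly at the k-space centre.

## Digital cancellation

After analog cancellation converges at the calibration frequency, the
remaining leakage is frequency dependent. For chirp acquisitions the model
is the pick-up coil (PUC) trace, normalized to unit peak and
phase-corrected by a quadratic polynomial in time, scaled by a profile
linear in instantaneous frequency on each side of the sweep centre. Two
numerical choices matter:

* the side coefficients are **complex**. The physical residual crosses
  zero at the calibration frequency and re-emerges with the opposite sign
  (a π phase step); a non-negative magnitude profile cannot represent
  that, and a magnitude-only fit stalls near −9 dB of removal where the
  complex fit reaches below −60 dB;
* the quadratic phase fit is run from two initializations — the smoothed
  unwrapped phase difference against the PUC (captures genuine drifts) and
  zero (robust when the sign flip makes the raw difference bimodal) — and
  the lower-residual fit wins.

For HS8 acquisitions the leakage is the theoretical pulse times a
quadratic/linear time modulation and a phase constant, fitted by simulated
annealing (geometric cooling at 0.95, Gaussian proposals, 2000
evaluations, mandatory seed) followed by an exact linear least-squares
polish of the complex modulation coefficients at the annealed phase
constant — the model is linear in those coefficients, so the polish
deterministically finishes what the annealer starts.

### What a leak fit cannot do, and the joint estimator

A fundamental identifiability limit: a swept pulse times *any* smooth
frequency modulation is exactly the form of both the residual leakage and
the spin system's own swept response (for a single isochromat, the
tone-minus-chirp phase difference is itself a quadratic in time). A
per-trace least-squares fit of the leak model therefore absorbs a
substantial fraction of in-band MR signal no matter how it is regularized —
the projection of a single-isochromat CEA signal onto the model span is
20–40% in energy across realistic T2\* values. This is precisely why
practical CEA processing compares candidate corrections against a
Bloch-calculated reference before subtracting.

The pipeline (`reconstruct_spokes(correct = "chirp" | "hs8")`) therefore
estimates the leakage **jointly across spokes** using conjugate symmetry:
the leakage is identical on every spoke (the hardware chain does not know
the gradient direction), while for a real-valued object the
antipodal-averaged deconvolved response is real. The complex model
coefficients are fitted by least squares on the *imaginary part* of the
mean deconvolved response, where the object cannot contribute. The single
unidentifiable direction — a leak component whose deconvolution is purely
real at the k-space centre, degenerate with the object's total mass — is
left untouched by the minimum-norm solve and only shifts the image DC. On
leak-free data this estimator perturbs the reconstructed image by under
1%; with leakage 20 dB above the MR signal it brings the end-to-end image
error to ≈0.08 normalized RMS.

## Reconstruction

`deconvolve()` solves $h = (U^*U + \lambda I)^{-1} U^* s_{MR}$ where $U$
is the lower-triangular Toeplitz operator of the pulse. With $\lambda = 0$
a rank-tolerant SVD pseudo-inverse is used (tolerance: machine epsilon ×
largest singular value × max dimension). A band-limited sweep cannot
encode frequencies outside its band, so the operator's singular spectrum
splits into an in-band plateau and an out-of-band floor ~80 dB down;
`reconstruct_spokes()` defaults to $\lambda = (0.01\,\sigma_{max})^2$,
which suppresses the out-of-band directions and leaves the in-band
solution essentially untouched (the noise-free in-band round trip is exact
to <1e−6 without regularization, and ≈2% with it under response
truncation).

Response length is chosen by an RMSE elbow: candidates are scanned in
ascending order and the scan stops at the first candidate whose successor
improves the fit RMSE $\|s_{MR} - U h_L\|/\sqrt{n}$ by less than 1%.

Centre-shift correction cross-correlates the full diameter magnitude
profile `[rev |h_b|, |h_a|]` of each antipodal pair with its own reverse;
the peak lag (3-point parabolic refinement) equals minus twice the common
sub-sample k-centre offset, and half the estimate is applied to each spoke
as a spectral linear phase with opposite signs.

Gridding follows standard Kaiser-Bessel practice: density compensation
$\propto |k|^{d-1} \Delta k$ with the actual per-sample spacing of the
ramped trajectory (the centre sample gets a small finite weight), kernel
width 4 on a 2× oversampled grid with β from the usual width/oversampling
formula, forward FFT, deapodization by the kernel transform, central crop,
magnitude.

## Fixtures and study conditions

The generator presets are fixed study conditions, not tuning knobs:

* `"tubes"` — 8 disks on a ring plus two smaller attached tubes with
  distinct shorter T2\*;
* `"fe-series"` — 6 vials at 0.02, 0.029, 0.038, 0.056, 0.071 and 0.1 M
  iron with $1/T_2^*$ linear in concentration; the default relaxivity of
  $2\times10^5\,(\mathrm{s\,M})^{-1}$ puts the highest concentration near
  50 µs;
* `"two-disk"` and `"point"` — reconstruction test objects.

The default 2D protocols are desk-scale analogues of the full 3D ones:
128 spokes of 512 samples (a 4.1 ms window for the 16 kHz chirp, 1 ms for
the 128 kHz HS8), 4 mT/m with a ramped gradient, 0.12 m field of view at
matrix 48. These sizes keep a full simulate-calibrate-correct-reconstruct
cycle within seconds while preserving every structural feature of the
large protocols: the geometry is chosen self-consistently so that the
phantoms lie inside the frequency band the pulse actually sweeps
(±47 mm at 16 kHz/4 mT/m) and the recovered response length (144 samples)
reaches the matrix's Nyquist radius. Calibration ensembles use coupling
phases uniform in the shifter's coverage, amplitudes within ±3 dB of
unity, 30 dB geometric baseline, and starting voltages within ±1.5 V of
the channel's optimum (the hardware loop likewise starts from
experimentally assigned initial points).

What the synthetic data do *not* emulate: receiver saturation and ADC
quantization, transmit amplifier nonlinearity, cable-to-cable coupling,
B0/B1 inhomogeneity, flow, and the frequency structure of a measured
coupling path beyond a linear slope. Passing tests therefore demonstrate
the correctness and robustness of the algorithms under the stated models,
not hardware performance.

## Numerical conventions and edge cases

* Pulse sample m sits at $t = (m-1)\,dt$; requested durations snap to the
  sample grid. The HS8 τ grid is symmetric (`seq(-1, 1)`), so the envelope
  is exactly even and both edges sit at the truncation level (default 1%,
  $\beta = \operatorname{asech}(0.01)$).
* HS8 phase is accumulated by trapezoidal integration of the
  instantaneous frequency; no closed form exists for the HS8 frequency
  modulation.
* Out-of-range actuator voltages are clamped with a warning; a zero
  residual reports the documented isolation ceiling of 200 dB; descent
  steps that leave the voltage range are skipped.
* The raw-data container is a versioned JSON document; floating-point
  fields are serialized as 17-significant-digit decimal strings so that
  write/read round trips are bit exact.
* All randomness flows from explicit seeds; the annealer and the
  full-chain simulator are bit-reproducible under a fixed seed.

## Known limitations

* The convolution signal model is first-order in flip angle and LTI in the
  gradient; ramped-gradient acquisitions carry a model error of order
  $\gamma G x\, t_{ramp}/2$ in phase that the reconstruction inherits.
* The per-trace leakage fits cannot separate in-band MR signal from
  leakage (see above); only the joint conjugate-symmetry estimator is
  safe on signal-bearing data, and it needs antipodal spoke coverage.
* Re-calibration episodes flag, but do not re-acquire, spokes measured
  while the loop is adjusting.
* 3D gridding shares the 2D code path but is exercised at small matrix
  sizes only; large 3D problems are out of scope for a pure-R
  implementation.
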