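# ceasim

A desk-scale simulator and reconstruction toolkit for **concurrent
excitation and acquisition (CEA) MRI** with automated active analog
cancellation.

In conventional MRI the receiver is blanked while the RF pulse plays out, so
tissue whose transverse relaxation time T2\* is shorter than the pulse is
invisible. CEA samples the MR signal *while* transmitting a long,
low-power frequency-swept pulse — but the transmit waveform couples into the
receive coil up to ~100 dB above the spin signal. `ceasim` models the whole
chain that makes this feasible, for people studying in-band full-duplex
cancellation loops and swept-pulse reconstruction without access to the
hardware:

1. **Analog cancellation** (`coupler_split`, `apply_canceller`,
   `combine_traces`): a directional coupler taps a copy `c·u_Tx` (c = 0.28)
   of the transmit waveform, a voltage-controlled phase shifter (280° of
   coverage over 0–12 V) and attenuator (1.3 dB at 6 V, −1.2 dB/V on 3–6 V)
   shape it, and a power combiner subtracts it from the received signal:

       s_Rx(t) = A_cpl · u_Tx(t) · e^{j φ_cpl} + s_MR(t)
       s(t)    = s_Rx(t) − A · u_Tx(t) · e^{j φ}

2. **Automated feedback calibration** (`calibrate_canceller`,
   `monitor_and_retrigger`): coordinate descent on the two control voltages
   minimizing the mean received magnitude `Σ|s_Rx|/N` during 4 ms
   rectangular calibration pulses — coarse-to-fine steps
   (0.3 → 0.1 V phase, 0.05 → 0.005 V attenuation, then alternating halved
   refinement passes), threshold stopping, and re-triggering when a load
   change (e.g. a moving hand) raises the leakage.

3. **Spin simulation** (`cea_signal`, `bloch_simulate`, `full_chain`):
   small-tip CEA signal as a causal convolution of the transmit pulse with
   the phantom's FID `h[n]`,
   `s_MR[n] = h[0]u_Tx[n] + h[1]u_Tx[n−1] + …`, validated against a
   rotation-matrix Bloch integrator; radial 2D/3D acquisitions under ramped
   frequency-encoding gradients.

4. **Digital residual cancellation** (`fit_chirp_leakage`,
   `fit_hs8_leakage`): removal of the frequency-dependent leakage left
   after analog cancellation — a per-side linear-in-frequency model with a
   quadratic phase correction against the pick-up coil (PUC) monitor for
   chirps, and a simulated-annealing-fitted quadratic/linear time
   modulation for HS8 pulses.

5. **Reconstruction** (`deconvolve`, `center_shift_correction`,
   `grid_reconstruct`): per-spoke recovery of `h` by the pseudo-inverse
   `h = (U*U + λI)^{-1} U* s_MR` of the pulse's Toeplitz convolution
   operator, RMSE-based response-length selection, sub-sample k-space
   centre-shift correction from opposite-spoke cross-correlation, and
   Kaiser-Bessel gridding with density compensation and deapodization.

Everything is synthesized in code: digital phantoms (multi-tube,
iron-concentration series with 1/T2\* linear in concentration, point and
two-disk test objects), pulses (rect, edge-smoothed chirp, HS8), front-end
and coupling parameters, and acquisition protocols.

## Worked example

```r
library(ceasim)
set.seed(7)

# a coupling channel: 30 dB of geometric (orthogonal-coil) isolation,
# coupling phase 150 deg
fe <- frontend()
ch <- coupling_channel(a_cpl = 1.1, phi_cpl_deg = 150,
                       geometric_isolation_db = 30)

# automated feedback calibration of the canceller
cal <- calibrate_canceller(fe, ch,
  cfg = controller_config(threshold_isolation_db = 92, max_iter = 300),
  initial = canceller_setting(5.5, 1.5))
cal
#> <cea_calibration: converged in 46 iterations, total isolation 95.4 dB
#>  (analog 65.4 dB), V1 = 3.1625 V, V_att = 0.9256 V>

# simulate a full 2D radial CEA acquisition of a two-disk phantom and
# reconstruct it
fx <- gen_fixture(list(phantom = "two-disk", protocol = "chirp-2d", seed = 5))
prot <- fx$protocol
spokes <- full_chain(fx$phantom, prot, fe, ch, cal$setting,
                     noise_cfg = list(sigma_rx = 1e-6, tx_noise_frac = 0),
                     seed = 2)
img <- reconstruct_spokes(spokes, prot, L = 144, correct = "chirp")
img
#> <cea_image: 48 x 48, FOV 0.12 m, voxel 2.5 mm>

ref <- reference_image(fx$phantom, prot, L = 144)
image_nrmse(img, ref)
#> 0.066
```

The calibration converges in 46 objective evaluations to 95.4 dB of total
transmit-receive isolation (65.4 dB from the analog cancellation stage on
top of the 30 dB geometric baseline). The reconstructed image differs from
the leakage-free analytic reference by a normalized RMS error of 0.066.
`write_image()` exports images as NIfTI; `write_raw()`/`read_raw()` store
complete datasets with provenance.

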