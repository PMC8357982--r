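# sprphase

Single-shot phase retrieval and refractive-index sensing benchmarks for
surface plasmon resonance (SPR) back-focal-plane (BFP) microscopy.

## The problem

An SPR sensor — a 20–60 nm gold film between immersion oil (n₀ = 1.52) and
an aqueous sample (n_s) — imprints a dark resonance arc on the back focal
plane of a high-NA objective: radial pupil position maps to the in-plane
momentum β = n₀·sinθ₀, and the p-polarized reflectance |r_p(β)|² dips at
the plasmonic angle β_p = n₀·sinθ_p. The position of that dip tracks the
sample refractive index (sensitivity S = Δβ_p/Δn_s ≈ 1.18 RIU/RIU for
50 nm gold at 633 nm), but the *phase* of r_p is a far steeper function of
β than its amplitude. Measuring phase normally needs an interferometer.

This package implements and benchmarks an alternative: a context
aggregation network (CAN) — a fully convolutional image-to-image regressor
with exponentially dilated 3×3 convolutions, adaptive per-channel
normalization and leaky rectifiers — trained on *simulated* BFP
amplitude/phase pairs so that a single grayscale BFP frame yields the full
pupil phase map. The plasmonic angle is then read from the maximum of
dφ/dβ along the pure-p axis. Its refractive-index limit of detection
(LOD = 3.3σ/S, with σ from a Poisson shot-noise Monte Carlo at 60% quantum
efficiency) is compared against two classical dip readouts: 3rd-degree
polynomial fitting of the intensity line-scan minimum, and azimuthal
averaging of ±45° rotated line scans.

Everything is simulated from first principles — multilayer transfer-matrix
Fresnel optics, a crossed-polarizer pupil field E = r_p·cos²φ + r_s·sin²φ,
Poisson photon statistics — so the package needs no external data.

## Worked example

```r
library(sprphase)

# a 50 nm gold sensor in water, He-Ne illumination, NA 1.49 objective
grid  <- pupil_grid(512)
stack <- gold_stack(50, ns = 1.33)          # wavelength 633 nm by default
field <- synthesize_bfp(stack, grid)
q     <- crop_quadrant(field, 1)            # 256 x 256 amplitude + phase

# classical dip readout on the clean quadrant
intensity_dip_angle(q$amplitude^2, grid, beta_min = 1.34)
#> Plasmonic position (intensity_poly3): n0*sin(theta_p) = 1.4417 from 1 quadrant(s)

# sensitivity between water and a 1.34 sample
spr_sensitivity(gold_stack(50, 1.33), gold_stack(50, 1.34), "poly3", grid)
#> [1] 1.186249

# shot-noise-limited detection limit of that readout at 2500 pJ
monte_carlo_lod(stack, "poly3", noise_config(2500), n_trials = 500,
                grid = grid, seed = 1)
#> LOD (poly3, 2500 pJ): 3.3 sigma / S = 3.3 x 1.01e-05 / 1.1922 = 2.79e-05 RIU (500 trials)
```

The printed `1.4417` is the dip position in n₀·sinθ units (between the
water critical angle 1.33 and the aperture limit 1.49); `1.186` says the
dip moves by 1.19 momentum units per refractive-index unit; the last line
converts the Monte Carlo spread of 500 noisy dip measurements into a
99.9%-confidence detection limit of 2.8×10⁻⁵ RIU.

Training and using the learned phase readout:

```r
ds    <- generate_dataset(200, seed = 77, size_px = 256)   # desk scale
cfg   <- can_config(input_size = 128, base_channels = 32,
                    learning_rate = 2e-3, epochs = 10, batch_size = 1,
                    norm = "instance", seed = 78)
model <- train_can(build_can(cfg), ds)
g128  <- pupil_grid(256)                    # 128 px quadrants
q128  <- crop_quadrant(synthesize_bfp(stack, g128), 1)
phase <- predict_phase(model, q128$amplitude / max(q128$amplitude))
dl_plasmonic_angle(phase, g128, beta_min = 1.34)
```

`run_pipeline(pipeline_config("smoke"))` wires all stages
(dataset → training → measurement → LOD benchmark) end to end and writes
dataset, checkpoint, JSON estimates, CSV benchmark and a manifest. A thin
command-line front end with the same stages lives in `inst/cli/sprphase.R`.

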