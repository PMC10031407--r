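# flapsense

Insect wings are not just actuators: strain-sensitive mechanosensors
(campaniform sensilla) embedded in the wing report its deformation, and the
wing's own structure — stiffness gradients, damping — shapes what those
sensors can read out. `flapsense` asks a concrete version of that question:
**can a handful of spiking strain sensors on a flapping wing detect a slow
body rotation, and how does the answer depend on the wing's stiffness
profile and damping?**

The package implements the full computational chain as an analysis
workflow, with no external data:

1. **Wing model** (`simulate_strain()`): a hawkmoth-scale 25 mm x 50 mm x
   127 µm rectangular plate (ρ = 1180 kg m⁻³, ν = 0.35), clamped at the
   base, flapping with the two-harmonic stroke
   φ(t) = A₁ sin(2πf₁t) + A₂ sin(2πf₂t) (A₁ = π/12, A₂ = π/60,
   f₁ = 25 Hz, f₂ = 2f₁). Young's modulus is either uniform or decays
   log-linearly from the leading-edge base to the trailing-edge tip,
   E(X,Y) = E_c·10^(−m_x X)·10^(−m_y Y) / mean(10^(−m_x x)·10^(−m_y y)),
   with m_x = m_y = 26.67 m⁻¹ giving two orders of magnitude of stiffness
   spread about the mean E_c. Viscous damping is mass-proportional with
   total coefficient c = 2ζmω_n, ω_n recomputed per stiffness setup by an
   eigenfrequency analysis. The plate (Kirchhoff bending, ACM elements on
   a 25 × 50 mesh whose nodes are the 1 mm sensor grid) is integrated with
   backward Euler (BDF order 1, dt = 2·10⁻⁴ s) in the co-rotating wing
   frame, forced by the rigid-frame inertial loads of the prescribed
   flapping plus an optional body rotation (roll/pitch/yaw, 1 rad s⁻¹,
   ramped over one wingbeat) and by the motion-induced membrane stresses
   acting on the current deflection — the gyroscopic channel that carries
   the rotation signature. Output is the top-surface spanwise strain
   ε_xx = −(h/2)∂²w/∂x² at every node and step.
2. **Neural encoding** (`encode_strain()`): at each grid node, strain is
   convolved with the sensory temporal feature
   f(t) = cos(2πω(t+τ))·exp(−(t+τ)²/δ²) (ω = 1/2π ms⁻¹, τ = 5 ms,
   δ = 4 ms), squashed to a firing probability
   N(g) = 1/(1+exp(−α(g−β))) (α = 5·10⁵, β = 10⁻⁴), and spikes are drawn
   per 0.1 ms bin against uniform variates with a 15 ms absolute
   refractory period. Each condition yields 100 stochastic trials of
   per-wingbeat first-spike latencies (0 = no spike).
3. **Sensor placement** (`sspoc_place()`): SSPOC — standardize the
   training trials, PCA to an m = 3 subspace Ψ, Fisher LDA direction w,
   then the sparsest weights s solving
   min λ‖s‖₁ + (1−λ)‖s‖₂² s.t. Ψᵀs = w (λ = 0.9, ADMM with exact
   constraint projection); the top 10 |s| are the sensors.
4. **Evaluation** (`train_eval()`, `evaluate_detection()`, `run_sweep()`):
   1-D LDA on the raw first-spike times of the chosen sensors, midpoint
   decision boundary, accuracy on the held-out 10% of trials; 20
   optimization iterations per configuration, plus random-placement
   baselines for the placement-sensitivity statistic
   acc_opt/acc_rand − 1.
5. **Modal analysis** (`pod_decompose()`, `accuracy_vs_modes()`): SVD of
   the node × time strain field of one wingbeat, eigenvalue spectra, and
   detection accuracy as a function of the number of retained modes.

## Worked example

```r
library(flapsense)

spec <- wing_spec(gradient = "gradient", E_mean = 3e9, zeta = 2)
s_flap <- simulate_strain(spec, kinematics(rotation_axis = "none"))
s_yaw  <- simulate_strain(spec, kinematics(rotation_axis = "yaw"))

max(abs(s_flap$eps))                       # peak flapping strain
#> [1] 0.000818
log10(max(abs(s_flap$eps[, s_flap$wingbeat_window])) /
      max(abs(s_yaw$eps[, s_yaw$wingbeat_window] -
              s_flap$eps[, s_flap$wingbeat_window])))
#> [1] 3.06                                # rotation sits ~3 orders below

det <- evaluate_detection(s_flap, s_yaw, encoding_params(),
                          sspoc_params(n_iterations = 6), seed = 42,
                          n_random = 3)
det
#> <detection_result> accuracy 90.8% +/- 4.4% (SEM, 6 iterations);
#>   random 55.6%, sensitivity 0.64
```

Reading: flapping produces strain of order 10⁻³; a 1 rad s⁻¹ yaw rotation
perturbs it about three orders of magnitude less, yet ten well-placed
spiking sensors detect the rotation in ~90% of held-out wingbeat trials
(individual iterations reach 100%), while ten random sensors sit near
chance — placement carries most of the performance.

The numbered scripts under `analysis/` run the full study: example-wing
simulation, encoding and placement, modal analysis, the
stiffness × gradient × damping sweep, and placement sensitivity. Each
writes tidy CSV tables to `results/`.

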