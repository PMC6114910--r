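# lampreysim

Closed-loop neuromechanical simulation of lamprey-style (anguilliform)
swimming in R.

Swimming vertebrates do not just send a motor program down the spinal cord:
the central pattern generator (CPG) that rhythmically activates the muscles
also *listens* to the body it is driving, through stretch receptors (edge
cells, in the lamprey) that sense body curvature. `lampreysim` is for
researchers in computational neuromechanics who want to study that loop:
how different functional forms of curvature feedback — one carrying only
the magnitude of bending, one carrying magnitude and direction — reshape
the swimming rhythm, the muscle duty cycle, the body wave, and the
energetic cost of steady swimming.

## The model

The package implements the full chain, each layer behind its own interface:

* **CPG** — a double chain (left/right × 280 segments) of phase oscillators,

  dθ<sub>k,i</sub>/dt = ω + Σ<sub>j</sub> α<sub>ij</sub> sin(θ<sub>k,j</sub> − θ<sub>k,i</sub> − ψ<sub>ij</sub>) + α<sub>c</sub> sin(θ<sub>k,i</sub> − θ<sub>k*,i</sub>) + η(κ<sub>i</sub>),

  with exponentially decaying asymmetric ipsilateral coupling
  (A<sub>a</sub> = 1, A<sub>d</sub> = 10 rad/s, λ<sub>a</sub> = 40,
  λ<sub>d</sub> = 5 segments), antiphase-stabilizing contralateral coupling
  α<sub>c</sub> = 81.87 rad/s, ω = 2π rad/s, and tuned phase shift
  ψ̄ = 2π/280. Activation is the thresholded phase, σ = 1 iff
  sin θ ≥ τ, with τ = cos(π·0.36) calibrated for the control duty cycle of
  0.36.
* **Curvature feedback** — smoothed midline curvature κ<sub>i</sub> enters
  each oscillator additively, either as *magnitude* feedback
  η<sub>m</sub>|κ<sub>i</sub>| (symmetric; shifts frequency) or
  *directional* feedback (−1)<sup>k</sup>η<sub>d</sub>κ<sub>i</sub>
  (antisymmetric; shifts duty cycle).
* **Muscle** — mass-action calcium kinetics gated by σ, work-dependent
  deactivation, and a Hill-type contractile element in series with an
  elastic element: P<sub>c</sub> = P<sub>0</sub> α(v<sub>c</sub>)
  λ(l<sub>c</sub>) C<sub>b</sub>, tapered with the squared local width.
* **Body** — a three-filament spring network (640-segment midline, two
  320-segment lateral sides) calibrated to a macroscopic bending stiffness
  of E = 0.76 MPa, with a passive head over the first eighth of the body.
* **Fluid** — 2D incompressible Navier–Stokes on a periodic staggered grid
  (FFT projection, Crank–Nicolson diffusion) coupled by the 4-point
  immersed-boundary kernel, plus a fast overdamped resistive backend with
  anisotropic slender-body drag for desk-scale closed-loop runs.
* **Metrics** — swimming speed, tailbeat amplitude and frequency, body
  wavelength, duty cycle, Strouhal number 2fA/U, neuromechanical phase lag,
  curvature and activation wave speeds (Hilbert transform) and their ratio,
  and cost of transport with partially weighted negative work.
* **Synthetic fixtures** — traveling-wave kinematics and activation
  patterns with exact analytic ground truth, used to validate every
  estimator without running the solver.

Results are tibbles with `tidy()`, `glance()` and `autoplot()` methods.

## A worked example

The control rhythm, straight from the CPG layer:

```r
library(lampreysim)

p <- cpg_params()                 # paper constants, tau = cos(0.36*pi)
r <- run_cpg(p, duration = 3, dt = 2.5e-4)
duty_cycle(list(time = r$time, sigma_left = r$sigma_left,
                sigma_right = r$sigma_right))
#> [1] 0.36
```

Every segment is active for 36% of a 1 s cycle — the control-case
calibration. Driving the CPG open-loop with a prescribed curvature wave
(amplitude as in full-scale swimming) shows the two feedback classes doing
qualitatively different things:

```r
drv <- make_curvature_driver(wave_spec(duration = 6))
for (g in c(-0.0675, 0, 0.0675)) {
  fb <- if (g == 0) feedback_config("none") else
    feedback_config("magnitude", gain = g)
  rr <- run_cpg(p, 6, 1e-3, feedback_config = fb, kappa_fn = drv)
  n <- length(rr$time); i0 <- which.min(abs(rr$time - 2))
  f <- mean((rr$theta_left[n, ] - rr$theta_left[i0, ]) /
              (rr$time[n] - rr$time[i0])) / (2 * pi)
  cat(sprintf("eta_m = %+.4f: frequency %.4f Hz\n", g, f))
}
#> eta_m = -0.0675: frequency 0.9957 Hz
#> eta_m = +0.0000: frequency 1.0000 Hz
#> eta_m = +0.0675: frequency 1.0043 Hz
```

Magnitude feedback shifts the rhythm frequency monotonically with gain.
Directional feedback at the same curvature leaves the period at exactly
1 Hz and instead shifts the duty cycle (0.3699 at η<sub>d</sub> = −15 down
to 0.3504 at +15 cm·rad/s).

A full desk-scale closed-loop run — CPG → calcium → muscle → body → drag →
curvature → CPG — takes about a minute:

```r
res <- run_simulation(reduced_config(duration = 6))
res$metrics$duty_cycle     #> 0.36
res$metrics$frequency      #> ~1.0 Hz tailbeat
res$metrics$speed          #> ~0.003 L/s: the desk swimmer creeps, but it
                           #> creeps in the right direction (opposite to the
                           #> head-to-tail neural wave)
```

The full-stiffness body in water on a fine Navier–Stokes grid (the regime
with swimming speed 0.52 L/s, amplitude 0.12 L and wavelength 0.75 L) is a
cluster-scale computation; the desk regime keeps the neural and muscular
layers at full parameters and is documented in the methods vignette
(`vignettes/closed-loop-swimming.Rmd`).

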