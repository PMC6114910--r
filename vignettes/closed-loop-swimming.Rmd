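---
title: "A closed-loop neuromechanical model of undulatory swimming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop neuromechanical model of undulatory swimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lampreysim` simulates the closed sensorimotor loop of anguilliform (lamprey-
style) swimming: a spinal central pattern generator (CPG) activates muscle,
muscle bends the body, the body interacts with the fluid, and the emergent
body curvature feeds back into the CPG through stretch-sensitive edge cells.
This vignette is the package's own account of each model layer, the
parameters that matter, the numerical choices, and what the desk-scale test
regime does and does not show.

## The CPG: a double chain of phase oscillators

Each of the 280 active body segments carries one oscillator per side. Phases
evolve as

$$\dot\theta_{k,i} = \omega
  + \sum_j \alpha_{i,j}\,\sin(\theta_{k,j} - \theta_{k,i} - \psi_{ij})
  + \alpha_c \sin(\theta_{k,i} - \theta_{k^*\!,i})
  + \eta(\kappa_i),$$

with natural frequency $\omega = 2\pi$ rad/s, ipsilateral coupling
$\alpha_{i,j} = A_a e^{-|i-j|/\lambda_a}$ ascending and
$A_d e^{-|i-j|/\lambda_d}$ descending ($A_a = 1$, $A_d = 10$ rad/s,
$\lambda_a = 40$, $\lambda_d = 5$ segments), tuned phase shift
$\psi_{ij} = (i-j)\,\bar\psi$ with $\bar\psi = 2\pi/280$, and contralateral
coupling $\alpha_c = 81.87$ rad/s — ten times the strongest descending
connection.

**Sign of the contralateral term.** The term is implemented as
$\alpha_c\sin(\theta_{k,i} - \theta_{k^*\!,i})$, which vanishes at the
antiphase offset and damps deviations from it at the linearized rate
$2\alpha_c \approx 164\,\mathrm{s^{-1}}$: left–right antiphase — the
biological behavior the term exists to represent — is a strong attractor.
Writing the same term with an extra $+\pi$ inside the sine flips that sign
and makes antiphase *repelling*: floating-point round-off then drives the
chains into in-phase co-contraction within a fraction of a second and the
collective frequency drifts off $\omega$, destroying the propagating
activation pattern. We therefore use the antiphase-stabilizing form
throughout; with it the tuned traveling-wave state (ipsilateral offsets
$\bar\psi$, contralateral offset $\pi$) is a relative equilibrium at exactly
$\omega$, and small random perturbations of the initial phases decay back to
it, so steady-state results do not depend on the start.

Muscle activation is the thresholded phase: segment $i$, side $k$ is active
iff $\sin\theta_{k,i} \ge \tau$. For a uniformly advancing phase the on-
fraction is $(\pi - 2\arcsin\tau)/2\pi$, so the threshold for a target duty
cycle $d$ is $\tau = \cos(\pi d)$ in closed form; the shipped default
`calibrate_threshold(0.36)` $\approx 0.4258$ gives the control-case duty
cycle of 0.36 at a 1 s period.

## Curvature feedback

Midline curvature $\kappa = (x'y'' - y'x'')/((x'^2+y'^2)^{3/2})$ is computed
by central differences, mapped to the oscillator positions (the first eighth
of the body is a passive head), smoothed with an 11-segment boxcar
($i-5 \dots i+5$), and silenced on the last 5 segments. Positive curvature
is a bend toward the right side. Two feedback laws are provided:

* **magnitude** $\eta = \eta_m |\kappa_i|$ — symmetric on both sides;
  excitatory for $\eta_m > 0$. It shifts the rhythm frequency and leaves the
  left–right phasing alone. Stable range $|\eta_m| < 0.09$ cm·rad/s.
* **directional** $\eta = (-1)^k \eta_d \kappa_i$ ($k=1$ left, $2$ right) —
  a right bend with $\eta_d > 0$ excites the right side and inhibits the
  left. It shifts the duty cycle and leaves the frequency alone. Stable
  range $|\eta_d| < 20$ cm·rad/s.

Because the directional signal is antisymmetric across each segment it
partially cancels, which is why the workable directional gains are two
orders of magnitude larger than the magnitude gains.

## Muscle: calcium kinetics and a Hill-type contractile unit

Free ($C_f$) and bound ($C_b$) calcium follow mass-action kinetics gated by
the binary activation $\sigma$:
$\dot C_f = (k_4 C_b - k_3 C_f)(1-C_b) + k_1(C - C_f - C_b) +
k_2 C_f (C - S - C_f - C_b)$ and $\dot C_b = -(k_4 C_b - k_3 C_f)(1-C_b)$,
with $k_1 = \sigma\bar k_1$, $k_2 = (1-\sigma)\bar k_2$,
$k_3 = \bar k_3 m$, $k_4 = \bar k_4 m$. The totals satisfy $S > C > 1$
(defaults $C = 2$, $S = 6$) so the muscle can fully activate and fully
sequester within a cycle; with the sarcoplasmic exchange off
($k_1 = k_2 = 0$) the sum $C_f + C_b$ is conserved exactly, which the tests
use as a conservation oracle. The work variable $m$ implements
work-dependent deactivation: $\dot m = -k_{m1} P_c v_c$ while shortening
($v_c < 0$; shortening is negative by convention, so positive work grows
$m$) and $-k_{m2}(m-1)$ otherwise, with $P_c$ normalized by $P_0$ so $m$
stays O(1).

Contractile force is the product $P_c = P_0\,\alpha(v_c)\,\lambda(l_c)\,C_b$
scaled by the local taper factor (the squared width ratio: force is
proportional to physiological cross-sectional area, with elliptical
out-of-plane cross-sections). The force–velocity curve $\alpha$ is a
standard Hill hyperbola in shortening and a shallow capped linear branch in
lengthening; the length–tension curve $\lambda$ is quadratic and capped at
zero; both are normalized to 1 at $(v_c = 0,\, l_c = l_{c0})$. **These two
shapes, and all kinetic rate constants, are re-fitted defaults, not
transcribed values** — the source model's table is external to what this
package reproduces — and every one of them is a `muscle_params()` argument.

The series element (SE) carries the transmitted force as a state:
$\dot P = k_{se}(v_l - v_c)$, where $v_l$ is the segment elongation rate and
$v_c$ comes from inverting the Hill curve at the force the SE demands.
Three regularizations keep this well-posed across activation onset and
shut-off: the inverted lengthening velocity is bounded (3 maximal shortening
speeds), the CE length is clamped to $[0.5, 1.5]\,l_{c0}$ and recoils to
$l_{c0}$ when slack (activation below `a_floor`), and $P$ is clamped to
$[0, P_0\alpha_{max}]$. A calcium-dependent passive stiffness
(`k_cb`·$C_b$) and a tension-only skin spring act in parallel.

## Body and fluid

The full-fidelity body is three filaments — a 640-segment midline and two
320-segment lateral sides — joined by Hookean midline links, transverse and
diagonal crosslinks, plus next-nearest midline links whose energy is
quartic in the local kink angle (they guard against node-scale folding
without adding linear bending stiffness). The single stiffness scale of the
network is calibrated so the macroscopic bending stiffness matches
$E = 0.76$ MPa: the rest geometry is mapped onto a circular arc of small
curvature, the network's elastic energy is matched to the beam energy
$\tfrac12 E \kappa^2 \int I(s)\,ds$ (cross-sections circular with diameter
equal to the local width), and because the energy is linear in the scale the
calibration is a single linear solve. `bending_stiffness_check()` exposes
the same measurement.

The fluid is the 2D incompressible Navier–Stokes system on a uniform
periodic MAC grid (7.5 L × 3.0 L domain): explicit central advection,
spectral Crank–Nicolson diffusion, and an exact FFT pressure projection
(discrete divergence at machine precision). The body couples to the grid by
the 4-point regularized delta kernel; spreading and interpolation are exact
adjoints, total force is conserved, and momentum changes only by the applied
force. The solver reproduces Taylor–Green decay to better than 1%. Boundary
conditions are periodic only; no-stress boundaries and adaptive mesh
refinement (which full-fidelity runs of this model family use) are a
documented fidelity gap.

## The desk-scale regime and the overdamped beam backend

Running the full body (E = 0.76 MPa) against the explicit immersed-boundary
coupling requires time steps of order $10^{-6}$–$10^{-7}$ s — the measured
energy-injection rate of the explicit coupling grows as
$k\,ds\,\Delta t/(2\rho h^2)$, the classic stiff-IB limit — full-fidelity
runs of this kind take on the order of a day on a small cluster. Full-fidelity
hydrodynamic numbers (control speed 0.52 L/s, amplitude 0.12 L, wavelength
0.75 L, the cost-of-transport percentages) are therefore **cluster-scale
targets**; this package does not claim them at desk scale.

For desk-scale closed-loop work the `"resistive"` backend implements the
local-drag body the way resistive models are meant to be built:

* the midline is a discrete elastic beam — axial springs $EA/l$ per link and
  bending stiffness $B(s) = E\,I(s)$ on the turning angles — advanced by a
  backward-Euler step with an analytic sparse Jacobian, unconditionally
  stable in the spring stiffness;
* muscle tensions enter as bending-moment couples
  $M = (T_\mathrm{right} - T_\mathrm{left})\,w/2$ spread over the straddled
  nodes. This is mechanically equivalent for a thin body and removes the
  axial compression channel through which bilateral muscle tension buckles a
  soft spring column;
* the local drag is anisotropic (normal twice tangential, the slender-body
  ratio), which is what lets an undulating chain generate net thrust in a
  resistive medium — the desk swimmer progresses opposite to its neural
  wave, as it should;
* lateral filaments are reconstructed kinematically (offset $\pm w/2$ along
  the node normal) to provide muscle segment lengths and elongation rates
  and the full 1283-node trajectory output.

The desk conditions, chosen once: $E = 10^{-4}$ MPa, $P_0 = 60$ dyn,
$k_{se} = 9000$ dyn/cm, tangential drag 0.03 dyn·s/cm, $\Delta t = 1$ ms,
6 s of simulated time. The structural tail width is floored at 2% L and the
bending-width profile at 5% L: the nominal 0.1% L tail tip has
$EI \propto w^4 \to 0$ and simply curls up without fluid inertia to steady
it. Midline coordinates are pre-smoothed (boxcar half-width 6 nodes) before
curvature differencing, since second differences amplify node-scale
position noise by $1/h^2$. These choices produce a clean 1 Hz head-to-tail
curvature wave with duty cycle 0.360, body wave amplitude about
$|\kappa| \sim 0.1\ \mathrm{cm^{-1}}$, and net forward progression.

What the desk regime preserves faithfully is the **neural layer**: the CPG,
threshold, calcium/muscle kinetics and both feedback laws run at full
parameters, and the quantities the feedback study is about — tailbeat
frequency, duty cycle, and their responses to the two gain classes — are
measured on the closed loop. What it does not preserve is curvature
*amplitude* (about 0.1/cm versus roughly 0.45/cm at full fidelity), so
feedback effects proportional to $|\kappa|$ are about four times weaker
than in the full model. The directional duty-cycle response is still
cleanly resolved in closed loop; the magnitude-mode frequency response is
not, and is instead demonstrated with the open-loop curvature driver
(`make_curvature_driver()`) at the full curvature amplitude, where
frequency rises strictly monotonically with $\eta_m$ while the duty cycle
stays constant, and directional drive shifts duty while leaving the period
at exactly 1 s. One consequence worth stating plainly: the magnitude-mode
cost-of-transport sign (lower cost at high positive gain) rides on the
frequency shift and does not reproduce at desk curvature; the corresponding
desk assertion in the test suite is deliberately left failing rather than
weakened.

```{r}
library(lampreysim)

# control closed-loop run at desk scale
res <- run_simulation(reduced_config(duration = 6))
glance(res$metrics)

# directional feedback: duty falls with gain, frequency does not move
sweep <- gain_sweep(reduced_config(duration = 6), "directional",
                    gains = c(-15, -7.5, 7.5, 15))
autoplot(sweep)
```

## Synthetic fixtures

`make_traveling_wave()` builds midline kinematics
$y(s,t) = A(s)\sin(2\pi(ft - s/\lambda))$ over a uniform translation, with
analytically exact curvature carried alongside, so every analysis operation
(speed, tailbeat amplitude/frequency, wavelength, Hilbert wave speeds,
phase-lag profiles, duty cycle) can be validated against known ground
truth. Defaults mirror the steady control swimmer (1 Hz, 0.75 L wavelength,
0.12 L tail amplitude, 0.52 L/s). `make_activation_pattern()` places binary
onsets at a prescribed lag after the *numerically located* curvature peaks
(the amplitude envelope shifts the peak off the carrier phase, so an
analytic quarter-period rule would be wrong), and
`make_curvature_driver()` feeds the same wave into the CPG's feedback port
without any mechanics. The fixtures emulate steady periodic kinematics
only — no start-up transient, no vortex wake, no amplitude irregularity — so
passing the round-trip tests validates the estimators, not the
hydrodynamics.

## Numerical choices, in one place

* RK4 with a fixed 1 ms step (2.5e-4 s where duty-cycle resolution to
  <0.1% is asserted) for CPG and muscle ODEs; phases stored unwrapped.
* Explicit (frozen-over-the-step) coupling between the neural, muscle and
  body layers; body/fluid substepping available for the IB backend.
* Backward-Euler with displacement-triggered Jacobian refresh for the
  overdamped beam; sparse LU from the Matrix package.
* Curvature peaks by local-maximum search; activation onsets as 0-to-1
  transitions; phase-lag pairing by minimal time difference with ties to
  the earlier onset; the local activation period normalizes the lag.
* Wave speeds as central-difference ratios of temporal to spatial phase
  derivatives (oscillator phase for the neural wave; the angle of the
  FFT-built analytic signal for the curvature wave), averaged over
  $s \in (0.5, 0.8)$ and the last 7 beats; speeds are reported positive for
  head-to-tail propagation, and the wavespeed ratio is unaffected by that
  sign convention.
* Cost of transport sums positive work plus 0.3 of |negative work| (the
  weight is configurable; it is a modeling choice, not a fixed constant)
  over the
  last full cycle, divided by period and body mass (area × density for the
  2D body).
* The body wavelength estimator doubles the mean spacing of curvature zero
  crossings along the body.

## Known limitations

* Periodic fluid boundaries (not no-stress), uniform grid (no adaptive
  refinement), 2D only.
* Desk-scale hydrodynamic magnitudes are not the full-fidelity ones; they
  are clearly labeled as such wherever they appear.
* The Hill-curve shapes and calcium rate constants are plausible re-fitted
  defaults.
* Rate-of-stretch (curvature-velocity) feedback, feedback delays, and
  perturbation/turning experiments are out of scope.
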