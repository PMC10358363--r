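---
title: "Population-rate modelling and fitting of interneuron theta-phase preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-rate modelling and fitting of interneuron theta-phase preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

During the hippocampal theta rhythm (4–12 Hz), each class of CA1 interneuron
fires preferentially at a particular phase of the oscillation. `thetafit`
models a microcircuit of seven interneuron populations (PV basket `pvbas`,
OLM `olm`, CCK basket `cckbas`, ivy `ivy`, neurogliaform `ngf`, bistratified
`bis`, axo-axonic `aac`) driven by three theta-modulated excitatory inputs
(CA3 and CA1 pyramidal populations, entorhinal cortex layer 3), and asks
whether short-term synaptic plasticity can stabilize the experimentally
observed phase relations. The package's job is threefold:

1. simulate the network's population firing rates *deterministically and
   differentiably* with the conductance-based refractory density (CBRD)
   method;
2. fit all 301 trainable parameters (six Tsodyks–Markram constants per each
   of the 49 connections, plus one external current per simulated
   population) by Adam gradient descent so that the simulated rates match
   von Mises theta-phase target profiles;
3. validate the fitted population model against a direct Monte Carlo
   simulation of finite ensembles of leaky integrate-and-fire (LIF) neurons.

## Units

Fixed package-wide: time in ms, voltage in mV, conductance in mS/cm²,
current in µA/cm². Rates are carried internally in spikes/ms and exposed in
spikes/s.

## Target profiles

Each population's target (and each external input's drive) is a von Mises
profile

$$FR(t) = \frac{FR_{mean}}{I_0(\kappa)}\,
  e^{\kappa \cos(2\pi\omega_\theta t - \phi)},$$

whose time average over an integer number of cycles is exactly
$FR_{mean}$. Experimentalists report modulation as the resultant length
$R$ rather than $\kappa$; `kappa_from_R()` applies the standard
three-branch approximation (polynomial below $R=0.53$, rational correction
to $R=0.85$, asymptote above). The branch mismatches are below 0.05 in
$\kappa$, which bounds the error on the recovered $R$ by about 0.01 — the
tolerance used whenever a generated profile's $R$ is checked. $I_0$ is
evaluated with R's `besselI`, accurate across the $\kappa$ range in use.
Phase convention: $\theta(t) = \mathrm{wrap}(2\pi\omega_\theta t)$ into
$(-\pi,\pi]$, zero at the peak of the reference cosine, so a profile peaks
exactly at its $\phi$.

The shipped registry (`target_registry()`) carries the ten reference rows
(three inputs, seven interneuron classes) with $R$ between 0.2 and 0.3,
$\omega_\theta = 7$ Hz, mean rates from 0.5 to 30 spikes/s and phases
between $-\pi/2$ and $\pi$.

## The CBRD solver

Each simulated population is represented by a density $\rho(t, t^*)$ of
neurons over refractory age $t^*$ (time since last spike) and the mean
membrane potential $V(t, t^*)$ of neurons at that age, on a uniform
$N$-point grid ($N = 400$, $\Delta t^* = 0.5$ ms by default, time step
$\Delta t = 0.1$ ms; the scheme requires $\Delta t \le \Delta t^*$). Both
fields are advected along $t^*$ at unit speed; $\rho$ loses mass at the
hazard rate $H$ and the lost mass re-enters at $t^* = 0$, where $V$ is
reset. The population rate is $\nu(t) = \rho(t, 0)$.

The hazard has a noise part and a drift part,

$$H = \frac{A(T)}{\tau_M} + \frac{2\,[\mathrm{d}V/\mathrm{d}t]_+}
  {\sqrt{2}\,\sigma_m} F_T(T),
  \qquad T = \frac{V_T - V}{\sqrt{2}\,\sigma_m},$$

with $A$ the polynomial-exponential approximation of the self-similar
hazard, $F_T = \sqrt{2/\pi}\, e^{-T^2}/(1+\mathrm{erf}\,T)$, and
$\tau_M = C_m/g_{tot}$. Only depolarizing drift (V rising toward threshold)
contributes, through the rectifier; this is the single most consequential
reading of the model equations and is documented here deliberately: with
the opposite sign the drift term would *reduce* the hazard and the solver
could not reproduce drift-dominated firing at all. Grid ages below the 3 ms
absolute refractory period have $H = 0$; the age-zero bin is always
non-firing.

### Numerical scheme

Advection uses the flux-limited second-order upwind scheme with a
monotonized-central limiter
$\mathrm{sign}(a)\min(0.5|a+b|, 2|a|, 2|b|)$ (zero at local extrema).
Boundary conditions: the right (oldest-age) bin absorbs inflow; the left
bin receives the full hazard-removed mass and $V$ is pinned to $V_{reset}$.
Because the interior scheme is in flux form and the re-injection equals the
sink sum exactly, total mass $\sum\rho\,\Delta t^*$ is conserved to machine
precision (the package's tests assert $10^{-12}$ over thousands of steps,
far inside the $10^{-3}$ contract).

Three numerical choices matter beyond the textbook scheme:

* **Exponential sink.** The hazard sink is applied as
  $\rho\,(1-e^{-H\Delta t})$ per step rather than $\rho H \Delta t$. The
  two agree to first order, but under strong drive $H\Delta t$ exceeds 1
  (the drift hazard grows like $\sqrt{2}|T|$ far above threshold) and the
  Euler form flips $\rho$ negative and diverges. The exponential form is
  the exact solution of the within-bin decay and is stable for arbitrarily
  large $H$ — essential because the optimizer freely explores strong-drive
  parameter regions.
* **Stable $F_T$ tail.** For $T < -4$, $1+\mathrm{erf}(T)$ underflows;
  $F_T$ is then evaluated through the log of the normal CDF. Its
  derivative uses the identity $F_T' = F_T(-2T - \sqrt{2}F_T)$.
* **Denormal flushing.** The advected density tails underflow into
  subnormal numbers, which are pathologically slow; they are flushed to
  zero inside solver calls (a ~10× speedup with no effect above
  $10^{-250}$).

The initial condition places all mass in the oldest age bin with
$V = E_L$; every statistic discards a burn-in (default two theta cycles).

## Synapses

Each of the 49 pathways carries one mean-field Tsodyks–Markram state
$(u, x, y)$ — utilization, recovered and active resource — driven by the
presynaptic *population rate*, so the same synapse model serves both
engines. The conductance is $g_{syn,max}\, y$ and the current
$g\,(E_{syn}-V)$, with $E_{syn} = 0$ mV for the excitatory inputs (AMPA)
and $-75$ mV for interneuron connections (GABA-A). Explicit Euler updates
use the pre-step utilization for the post-spike jump
$u_+ = u + U_{inc}(1-u)$; after each step $u$ is projected onto $[0,1]$
and $(x,y)$ onto the simplex $x+y\le 1$ (inactive in the smooth regime,
but explicit Euler can overshoot at large $\nu_{pre}\,\Delta t$).

The no-STP ablation freezes $u \equiv U_{inc}$ and $x \equiv 1$, leaving
$\dot y = -y/\tau_d + U_{inc} w\, \nu_{pre}$: the conductance pathway is
preserved while depression and facilitation are removed.

Because $w$ and $\nu_{pre}$ enter the equations only as a product, scaling
a drive's rate and inversely scaling $w$ leaves the dynamics *identical* —
the package tests this exactly. It is the formal version of the argument
that input rates are identified only up to the connection-density scale.

## Gradients: a hand-derived adjoint

All operations of the solver are differentiable almost everywhere, and the
gradient of the fitting loss with respect to every trainable parameter is
computed by a reverse-mode adjoint pass written next to the forward solver
in C++: the forward rollout records the state trajectory, and the backward
sweep transposes each assignment of the forward step, recomputing the
nonlinear intermediates (hazard, limiter slopes, synapse updates) from the
stored states. Kinked operations (rectifier, limiter, clamps) use their
almost-everywhere derivative. The adjoint costs about twice the forward
pass and ~60 bytes per grid point per step of memory (≈370 MB for the full
network's four-cycle window).

`gradient_check()` compares the adjoint gradient of the full loss with
central finite differences; on the reference constructions (the external
current of a single population on a 50 ms window; the full parameter set
of a driven population with recurrent self-inhibition) the maximum
relative error is $10^{-5}$–$10^{-4}$, and the package's acceptance test
asserts $10^{-3}$.

One caveat is worth knowing when doing gradient work with this solver: the
loss surface carries *scheme-scale ripple*. The flux limiter switches
branches as sharp density fronts shift across grid cells, so in regimes
with steep fronts (strong suprathreshold drive, short windows that include
the onset transient) the loss is continuous but kinked at parameter scales
of $10^{-5}$–$10^{-4}$, and a finite difference then measures a locally
averaged slope that can deviate from the pointwise adjoint derivative by
percent on the affected parameters. This is a property of the landscape,
not an error in either derivative: Adam, which averages gradients across
iterations anyway, is insensitive to it, and both routes agree closely
wherever the dynamics are settled.

## The optimization problem

The simulation loss compares log-compressed rates in spikes/s,

$$L_{sim} = \sum_{k=1}^{K}\sum_{t}
  \bigl(\ln(\rho_{target}+1) - \ln(\rho_{sim}+1)\bigr)^2,$$

on a loss window of two theta cycles after a two-cycle burn-in (both are
config fields; the window keeps each iteration's cost at ~5,700 solver
steps). A logarithmic barrier $-0.001\ln(100\,\theta)$ on
$g_{syn,max}, \tau_r, \tau_f, \tau_d, U_{inc}, w$ and $1-U_{inc}$ keeps
every synapse parameter strictly inside its bounds; it is evaluated in
natural parameter space.

Adam (learning rate 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$) updates the
parameters in an unconstrained space: log for positive parameters, logit
for $U_{inc}$, identity for $I_{ext}$. The log map was chosen over a
softplus after measurement: softplus is nearly the identity for large
values, so a fixed-size Adam step could move a 500 ms recovery constant by
only ~0.5 ms over 500 iterations, whereas under the log map a ±50%
parameter change is the same raw-space distance (≈0.405) for every
positive parameter regardless of scale. The barrier gradient is chained
through the same map, so bounds cannot be overshot and the barrier's Eq-30
form is preserved exactly at evaluation.

The solver is deterministic, so fits are bitwise reproducible.

### What the parameter-recovery test shows

The full 301-parameter fit is a long optimization (hours) whose optimum is
not unique; the test suite therefore exercises the machinery on a
one-population toy problem — a theta-modulated excitatory drive plus
recurrent self-inhibition — whose target was *generated by the solver
itself* at known parameters, restarting from ±50% perturbations of all
twelve synapse constants. The recurrent loop matters: with a single
feed-forward connection the external-current parameter compensates most of
the mismatch within a few hundred iterations and the optimizer then crawls
along a flat valley, while the richer recurrent dynamics leave enough
redundant descent directions to reach the target trace in budget. This
checks end-to-end correctness of loss, adjoint and optimizer — if any
gradient were wrong, descent of this self-consistent problem would stall —
but it does not certify that the biological network's optimum is unique or
biologically correct. Note also that Adam's travel distance is bounded by
(learning rate × iterations) in raw space, so a 500-iteration budget can
only recover perturbations within ~0.5 raw units; the toy perturbs
parameters by ±50%, i.e. ≈0.4 raw units each.

## Monte Carlo validation

`run_mc()` simulates the same network with finite LIF ensembles (4,000
neurons per population by default), stochastic Heun integration (an
Euler–Maruyama variant is available behind a flag and pinned to <2% rate
difference), Poisson-generator realizations of the external drives, and
the identical mean-field synapses driven by the instantaneous ensemble
rate $n_{fired}/(N\Delta t)$.

Two conventions keep the engines mutually consistent:

* **Noise scaling.** The hazard's $T = (V_T-V)/(\sqrt 2\,\sigma_m)$ treats
  $\sigma_m$ as the stationary subthreshold *voltage* dispersion, so the
  MC noise is parameterized in the matching Ornstein–Uhlenbeck form
  $\mathrm{d}V \mathrel{+}= \sigma_m\sqrt{2\Delta t/\tau_M}\,\xi$, which
  has stationary SD $\sigma_m$ under the instantaneous total conductance.
* **Refractoriness.** Neurons integrate their membrane equation during the
  3 ms refractory window but cannot fire — the same semantics as the
  density solver, where $V(t^*)$ evolves at all ages while $H$ is masked.
  (No interspike interval can ever be shorter than the refractory period;
  the tests check this on rasters.)

The steady-state agreement test runs three single-population regimes
(fluctuation-driven $I_{ext}=0.95$, peri-threshold 1.0, drift-dominated
1.2) and requires 5% relative agreement of the mean rates. The MC oracle
runs at $\Delta t = 0.05$ ms there: at the production 0.1 ms step the MC
estimator *itself* carries a 5–7% discrete-time threshold-crossing bias in
the fluctuation-driven regime (halving $\Delta t$ moves the MC rate toward
the CBRD value, not away), and an oracle's own discretization error must
be controlled for a 5% comparison to mean anything.

The pairwise connection probability (0.5) is kept as a network-level
config field but does **not** scale $w$ by default: with mean-field
synapses every postsynaptic neuron sees the same conductance trace, the
fitted $w$ already absorbs the connection density, and the validation of a
fitted parameter set only makes sense with identical parameters in both
engines. `run_mc(apply_connection_prob = TRUE)` applies the scaling for
users who want the sparse-network reading.

## Analysis

`circular_stats()` summarizes a rate trace by its rate-weighted first
trigonometric moment (mean phase, resultant length $R$, mean rate) over an
integer number of cycles. `decompose_conductances()` splits each
population's synaptic input by source and polarity and forms the E/I
ratio with guarded division; `peak_alignment()` locates conductance and
rate peaks by the circular first moment (robust to ripple; literal argmax
behind a flag). `frequency_sweep()` re-runs the solver at other theta
frequencies changing only the drives' frequency — the fitted parameters
are fixed — to test whether the phase relations generalize across the
4–12 Hz band. MC traces are smoothed with a 2 ms causal boxcar before
circular statistics (the raw estimator at $N{=}4000$, $\Delta t{=}0.1$ ms
is too noisy to compare curves); CBRD traces are not smoothed.

## The shipped network and fitted parameters

`default_network()` loads the reference configuration: 10 populations,
49 connections, 301 trainable parameters. The text never enumerates the
edge list, so the shipped `default_network.yaml` is an editable
transcription from standard CA1 connectivity: the three excitatory sources
project onto the interneuron classes they innervate anatomically, the
interneuron classes inhibit each other densely, and `aac` sends no edges
inside the network (axo-axonic terminals target pyramidal axon initial
segments, which are outside this model) — its dynamics is dominated by the
external current. Initial parameter values are documented midrange
defaults ($U_{inc}=0.25$, $\tau_f=100$, $\tau_r=500$, $\tau_d=5$ ms,
$g_{syn,max}=0.05$; connection density $w=1$ for interneuron pathways and
$w=300$ for the external excitatory pathways, reflecting the orders-of-
magnitude larger number of pyramidal and entorhinal synapses per
interneuron — with $w=1$ the sub-spikes-per-second drives would be
functionally disconnected and the optimizer would have to build theta
modulation out of recurrent resonances, an inhibition-dominated and
frequency-fragile solution family); per-population initial
$I_{ext} = 1.0$, the
rheobase, so that every population starts active. The latter matters: a
deeply silent network has hazard gradients that underflow to zero — the
dead-network analogue of dead ReLU units — and gradient descent cannot
wake it. Initial parameter sets should always produce some activity in
every population.

`fitted_reference_parameters()` loads a parameter set produced by running
the package's own optimizer on this configuration at 7 Hz (Adam, learning
rate 0.001, two-cycle burn-in, two-cycle loss window, default solver
resolution); it is the basis of the frequency-generalization and
conductance-decomposition analyses and of the no-STP comparison. It is a
*reference fit*, not a canonical optimum: the loss surface has the usual
scale degeneracies and restarts land at equivalent but distinct parameter
vectors.

## Problem sizes used in the tests

The test suite is designed for a desk-scale run: unit tests use reduced
grids (N = 80–200, dt = 0.1–0.2 ms) and 1–2 population networks; the
steady-state MC comparisons use 4,000 neurons × 10 s; the toy recovery fit
runs 500 iterations at N = 200, dt = 0.2 ms; ablation and sweep checks
reuse the shipped fitted parameters rather than refitting the full
network. All statements about the full network's optimum come from the
shipped reference fit.

## What the synthetic conditions do and do not show

The generator reproduces the study's idealized conditions: homogeneous
populations, stationary von Mises drives, mean-field synapses, a rigid
theta clock. Real CA1 data have heterogeneous cells, nonstationary theta
frequency and amplitude, spike-timing (not rate) coupling, and pyramidal
feedback that is modelled here only as a prescribed drive. Passing tests
therefore certify the solver, gradients, optimizer and statistics — not
that the fitted parameters are the biological ones.

## Known limitations

* LIF membranes only: no spike-frequency adaptation or H-currents, which
  shape OLM and other interneurons' phase response in reality.
* The CBRD age grid truncates at $N\,\Delta t^* = 200$ ms; populations
  with mean rates well below ~5 spikes/s pool mass in the oldest bin,
  which is handled consistently but coarsens their interspike-interval
  distribution.
* The no-STP ablation freezes the synapse at full resources; other
  ablation conventions (e.g. steady-state-matched conductance) would give
  different silent sets.
* Serialization is CSV/JSON only.
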