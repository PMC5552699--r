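---
title: "Designing functional subnetworks: models, tuning rules and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing functional subnetworks: models, tuning rules and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snsdesign)
```

## The model

`snsdesign` works with networks of non-spiking leaky-integrator neurons.
Each neuron is a single compartment whose membrane potential, expressed as
the activation $U = V - E_r$ above its resting potential, obeys

$$C_m \frac{dU}{dt} = -G_m U + \sum_i G_{s,i}\,(\Delta E_{s,i} - U) + I_{app}.$$

The membrane potential is read as a proxy for firing rate; sodium/potassium
spike currents are deliberately absent. Synapses are piecewise-linear
conductances of the presynaptic activation: zero below threshold,
$g_s U_{pre}/R$ over the operating range $R$, and saturated at $g_s$ above
it. $\Delta E_s$ is the synaptic reversal potential relative to the
*postsynaptic* rest, so $\Delta E_s \ge R$ is excitatory everywhere on the
operating range and $\Delta E_s \le 0$ inhibitory.

Units are fixed package-wide: mV, nA, µS, nF and ms. This makes
$\tau = C_m/G_m$ come out in ms and, with the typical $G_m = 1$ µS, lets a
constant current $I$ settle at $U^* = I$, so port currents can be read
directly as commanded activations. Membrane state is *not* clamped below
rest: only synaptic output rectifies. A subtraction network's output may
therefore go negative in simulation, encoding the sign of its result, even
though any downstream synapse transmits nothing for it.

The closed-form equilibrium of one neuron under fixed presynaptic
activations,

$$U^* = \frac{\sum_i \frac{g_{s,i}}{R} U_{pre,i}\, \Delta E_{s,i} + I_{app}}
             {G_m + \sum_i \frac{g_{s,i}}{R} U_{pre,i}},$$

is the basis of every tuning rule. Its activity-dependent denominator is
also the source of every approximation error the verification tools
quantify.

## Tuning rules

**Transmission** (`tune_transmission`). A pathway with gain $k_{syn}$
(post $= k_{syn}\,\cdot$ pre at full drive) needs
$g_s = k_{syn} R / (\Delta E_s - k_{syn} R)$, feasible only when
$\Delta E_s > k_{syn} R$. The gain is calibrated at $U_{pre} = R$; below
full drive the realized gain is $k_{syn}(1+g_s)$ divided by the
activity-dependent denominator, which is why raising $\Delta E_s$ (and so
shrinking $g_s$) always improves linearity. The default excitatory reversal
is 194 mV relative to rest (calcium at 134 mV absolute against a −60 mV
rest), which gives the canonical 115 nS at $k_{syn}=1$, $R=20$ mV.

**Modulation** (`tune_modulation`). A shunting synapse with reversal at or
near rest divides the postsynaptic neuron's sensitivity by entering only
the denominator: $g_s = (c_{syn}R - R)/(\Delta E_s - c_{syn}R)$, where
$c_{syn} \in [0,1]$ is the residual sensitivity at full presynaptic drive.
The full-shunt case $c_{syn}=0$ becomes $g_s = -R/\Delta E_s$ and requires
$\Delta E_s < 0$ — at $\Delta E_s = 0$ the rule divides by zero and at
$\Delta E_s > 0$ it would demand a negative conductance.

**The six designers** assemble these pathways:

* `design_addition()` — two transmission pathways onto one output.
* `design_subtraction()` — transmission plus an inhibitory pathway with
  $g_{s,2} = -(\Delta E_{s,1}/\Delta E_{s,2})\, g_{s,1}$, which nulls the
  output exactly at co-activation $(R, R)$. Reports display conductances
  with the conventional sequential rounding ($g_{s,1}$ to the nearest nS
  first), hence 558 nS for the default design; full precision is kept
  internally.
* `design_division()` — unity transmission plus a $\Delta E_s = 0$ shunt
  with $g_{s,2} = (1-c_{syn})/c_{syn}$.
* `design_multiplication()` — disinhibition: input 2 shunts a tonically
  driven interneuron ($I_{app} = R$), which shunts the output; both
  modulation synapses are identical full-shunt pathways.
* `design_differentiator()` — two copies of the input low-passed with
  different capacitances ($C_{m,2} = 1000\,\tau_d$,
  $C_{m,1} = C_{m,2} - 1000\,k_d$, both in nF for $\tau_d, k_d$ in s) and
  subtracted. Ramp slope $A$ maps to a plateau
  $k_{syn,out}(C_{m,2}-C_{m,1})A$; cutoff $\omega_c = 1/\tau_d$.
* `design_integrator()` — two mutually inhibiting neurons with tonic drive
  $R$ and $g_s \Delta E_s = -R$ enforced exactly, producing a line
  attractor.

Every designer returns a `DesignReport` carrying the functional inputs, the
derived biophysical values, and its full constraint list with margins;
`design_valid()` is true only when every constraint holds.

### Choices the design left open

* **Arithmetic-network capacitance.** The arithmetic subnetworks are tuned
  at steady state, so $C_m$ only sets settling speed; the default is 5 nF
  ($\tau = 5$ ms), a typical value for fast sensory processing.
* **Differentiator output neuron.** Its capacitance is not constrained by
  the tuning rules; the default 1 nF keeps the subtraction stage's lag two
  to three orders of magnitude below $\tau_d$, so the two filter poles
  dominate.
* **Differentiator overall gain.** The tabulated rule $k_{syn} = 1/k_d$
  normalizes the ramp-to-plateau gain; since one may equally keep
  $k_{syn} = 1$ and accept gain $k_d$, the stage gain is an explicit
  `k_syn_out` argument with $1/k_d$ as the default.
* **Subtraction inhibitory floor.** "As negative as biology permits" is
  taken as −100 mV absolute, i.e. −40 mV relative to a −60 mV rest.

## What the verification tools measure

**Response surfaces** (`sweep_surface`) evaluate the exact network steady
state over a lattice on $[0,R]^2$ and compare it with the ideal operator on
its validity region (addition: $U_1+U_2 \le R$; subtraction: $U_1 \ge U_2$;
division and multiplication: the full square). Deviations are reported
*full-scale*, as a fraction of $R$: a value-relative error is undefined
where the ideal output is zero (the subtraction diagonal, the
multiplication axes), and full-scale error is the measure a control
engineer budgets against. With the default biophysical parameters the
measured maxima are 2.7% (addition), 10.1% (subtraction), 2.7% (division)
and 2.9% (multiplication, against its closed-form disinhibition
prediction).

Two of these deserve comment. The subtraction error is dominated by the
large inhibitory conductance that a mildly negative reversal potential
forces: it loads the output denominator, compressing responses away from
the calibration corner. This is inherent to the design, not a tuning
mistake, and shrinks only if $\Delta E_{s,2}$ can be made more negative.
The multiplication network's closed-form prediction itself neglects the
transmission pathway's conductance; the *denominator* part of that neglect
is genuinely small (`multiplication_denominator_variation()` reports
0.55% < 1% for the default design), but the numerator part — the
transmission pathway injects $(1+g_{s,1})U_1$ rather than $U_1$ of
equivalent current — moves the surface by up to 2.9% of $R$ at mid-range
states. The two figures quantify different approximations and should not
be conflated.

**Frequency response** (`bode_differentiator`) linearizes the subtraction
stage as an ideal difference with gain `k_syn_out`:
$H(j\omega) = k_{syn,out}\left[(1+j\omega\tau_1)^{-1} -
(1+j\omega\tau_2)^{-1}\right]$. At low frequency $|H| \to
k_{syn,out}(\tau_2-\tau_1)\,\omega$ — differentiation — and above
$\omega_c = 1/\tau_2$ the response rolls off, which is precisely the
noise-rejection property that motivates building a differentiator this way.
The linearization is checked against sinusoid-driven simulation (amplitude
ratio within 5% at $0.1/\tau_d$, $1/\tau_d$ and $10/\tau_d$) using
small-signal inputs around a small positive bias, so that both synapses
stay in their linear branch and the activity-dependent denominator stays
near rest.

The same caveat governs ramp-based **parameter recovery**
(`measure_ramp_step_response`): the subtraction stage's realized gain
carries the factor $(1+g_{s,1})\big/\big(1 + (g_{s,1}U_1 +
g_{s,2}U_2)/R\big)$, so plateau/slope recovers $k_d \cdot k_{syn,out}$ to
2% only where that factor is near 1 — small stage gain and inputs well
inside the operating range. The shipped checks use $k_{syn,out} = 0.1$,
$\tau_d = 0.6$ s and slopes of a few $10^{-4}$ nA/ms over 15 $\tau_d$
segments, with the plateau averaged from $5\tau_d$ after ramp onset. At
high gains the compression is visible and intentional — it is the same
denominator nonlinearity measured by the subtraction surface.

**Integrator analysis** (`integrator_analyze`, `equilibrium_curve`). With
$g_s \Delta E_s = -R$ the drift Jacobian has identical rows at *every*
state, so one eigenvalue is exactly zero and the other is $-(a+b)/C_m$ with
$a = 1 + g_s U_1 / R$, $b = 1 + g_s U_2 / R$. The Jacobian is computed by
central differences (exact for this bilinear field up to round-off, which
is why the null eigenvalue verifies below $10^{-10}$) and cross-checked
against the analytic matrix. The state-dependent integration rate
$k_i = a/(C_m(a+b))$ is bounded by $1/(C_m(2+g_s))$ and
$(1+g_s)/(C_m(2+g_s))$; the mean rate $1/(2C_m)$ is attained on the
symmetric state. An integrator driven hard enough eventually pushes one
neuron past $R$; the synapse then saturates, marginality is lost outside
the operating range, and the network acquires an ordinary stable
equilibrium. The steady-state solver finds that saturated equilibrium —
line-attractor behaviour is a property of the operating range, not of the
whole state space.

## Numerical choices

* **Integration**: fixed-step classical Runge–Kutta via
  `deSolve::ode(method = "rk4")`; default step $\min(\tau)/20$, warning
  above $\min(\tau)/10$. The systems are first-order and non-stiff; RK4 at
  these steps leaves discretization error far below the behavioural
  tolerances (halving the step changes final states by $<10^{-6}$ mV).
* **Steady state**: feedforward networks are solved exactly in topological
  order; cyclic ones by damped fixed-point iteration (damping 0.5, update
  tolerance $10^{-9}$ mV, cap $10^5$ sweeps). Any returned solution is
  verified against the drift ($|dU/dt| < 10^{-6}$ mV/ms); failure is
  reported through the `converged` attribute and a warning, never silently.
* **"Settled" initialisation** simulates $20\max(\tau)$ with zero external
  drive before recording, which places the integrator on its symmetric
  equilibrium reproducibly without solving the equilibrium quadratic.
* **Determinism**: all stimuli are deterministic; the optional white-noise
  stimulus requires an explicit seed and restores the global RNG stream.
  The fixture corpus (`random_feasible_designs`) is seeded (default
  20170809, an arbitrary documented constant) and also restores the RNG
  stream; infeasible draws are rejected and resampled.

## What the built-in verification does and does not show

The fixture generators emulate the *design conditions*: constant or simple
programmed currents, networks assembled exactly as the designers specify,
parameters drawn from the feasible ranges ($k_{syn} \in [0.2, 1.5]$,
$R \in \{10, 20, 40\}$ mV, $c_{syn} \in [0.05, 0.9]$, reversal potentials
clear of the feasibility boundaries). They do not emulate sensor noise,
parameter drift, temperature effects, or interactions with a mechanical
plant — passing tests certify the mathematics of the design method at its
own operating conditions, not closed-loop robustness on hardware.

Problem sizes used by the shipped verification: 21×21 steady-state
lattices per arithmetic surface; 100 random designs for the
solver-vs-oracle cross-check; 50 random states for the null-eigenvalue
check; 8 $(C_m, g_s)$ combinations for integration-rate bounds with a
100 ms fit window after a $10\tau$ transient; ramp segments of
$15\tau_d$ at 0.5 ms steps and a $10^4$ ms drift watch for the memory
property. These sizes keep the full suite under a minute of simulation
while leaving each check's tolerance limited by the method, not by the
sample.

## Known limitations

* Subtraction (and any high-gain differentiator built on it) is
  systematically compressive away from its calibration corner; budget
  roughly 10% of $R$ at the default reversal potentials.
* The gain of every pathway is exact only at full presynaptic drive;
  mid-range gains run up to $(1+g_s)$ higher.
* Eigen-analysis of the integrator is numeric; no symbolic coordinate
  transform is provided, only its testable consequences (the null
  direction, $\lambda_2$, and the $k_i$ bounds).
* The simulator is fixed-step and single-rate; a very fast output neuron
  alongside second-scale filter neurons makes small steps expensive. The
  shipped checks accept a documented under-resolution warning for the
  1 nF output compartment, whose pole is three decades above the
  frequencies of interest.
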