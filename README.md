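# snsdesign

Analytic design of small conductance-based neural circuits that compute —
for roboticists and computational neuroscientists who use *synthetic
nervous systems* (dynamical neural models) as controllers and want to set
their parameters by constraint equations instead of hand-tuning, genetic
search or learning.

## The model and the method

Neurons are non-spiking leaky integrators in shifted coordinates
(activation *U* above rest, with membrane voltage read as a rate proxy):

    Cm dU/dt = -Gm U + Σᵢ (gs,i/R) Upre,i (ΔEs,i − U) + Iapp

Synapses are piecewise-linear conductances: zero below threshold, linear
over an operating range *R*, saturated above it. ΔEs is the reversal
potential relative to the postsynaptic rest. All quantities use one fixed
unit convention — mV, nA, µS, nF, ms — so τ = Cm/Gm is in ms and published
biophysical values can be used verbatim.

Setting the single-neuron equilibrium

    U* = (Σ (gs/R)·Upre·ΔEs + Iapp) / (Gm + Σ (gs/R)·Upre)

equal to a desired function of the inputs yields closed-form tuning rules.
Two primitive pathways follow — signal *transmission*
(`gs = k_syn·R/(ΔEs − k_syn·R)`, post = k_syn·pre at full drive) and
signal *modulation* (`gs = (c_syn·R − R)/(ΔEs − c_syn·R)`, a shunt that
scales sensitivity) — and from them six designers:

| function | computes | mechanism |
|---|---|---|
| `design_addition()` | k₁U₁ + k₂U₂ | two transmission pathways |
| `design_subtraction()` | k(U₁ − U₂) | transmission + inhibition nulled at (R, R) |
| `design_division()` | U₁/(1 + (1−c)/(cR)·U₂) | shunt with reversal at rest |
| `design_multiplication()` | U₁·U₂/R | disinhibition of a tonic interneuron |
| `design_differentiator()` | band-limited dI/dt | two lags subtracted (ω_c = 1/τ_d) |
| `design_integrator()` | ∫u dt | line attractor from gs·ΔEs = −R |

Each designer returns a report with every constraint checked and a ready
`sns_network`. Verification tools measure what the designs actually do:
`sweep_surface()` (steady-state lattice vs the ideal operator),
`bode_differentiator()` (linearized frequency response),
`integrator_analyze()` (Jacobian, eigenvalues, integration-rate bounds),
and `simulate_network()` (fixed-step RK4 with stimulus programs).

## Worked example

Design a unity-gain subtraction network on a 20 mV operating range:

```r
library(snsdesign)
rep <- design_subtraction(k_syn = 1, R = 20)
rep
#> <sns_design> subtraction subnetwork
#> functional parameters:
#>   k_syn        1
#>   R            20
#> derived parameters:
#>   gs1          0.114943
#>   gs2          0.557471
#>   dEs1         194
#>   dEs2         -40
#> display (rounded as conventionally reported):
#>   gs1          115 nS
#>   gs2          558 nS
#> constraints: 4/4 satisfied (design valid)
```

The excitatory pathway needs 115 nS against the calcium reversal potential
(194 mV above rest); the inhibitory pathway, reversing at −40 mV, needs
558 nS to null the output at full co-activation. Driving the inputs at 15
and 5 mV:

```r
round(steady_state_network(rep$network, c(in1 = 15, in2 = 5)), 4)
#>    pre1    pre2    post
#> 15.0000  5.0000  9.0973
```

The output is 9.1 mV against an ideal 10 — the compression of the
inhibitory load on the output denominator, quantified across the whole
input square by `sweep_surface(rep)`.

A memory circuit, and proof it will not drift:

```r
int <- design_integrator(k_i_mean = 0.1, k_i_range = 0.1)  # Cm 5 nF, gs 2 uS, dEs -10 mV
an <- integrator_analyze(int, 7.3205, 7.3205)   # the symmetric equilibrium
an$eigenvalues
#> [1]  0.00000 -0.69282
an$k_i
#> [1] 0.1
```

The zero eigenvalue holds at *every* state while `gs*dEs = -R`, so the
network integrates its input at a rate between `k_i_min` and `k_i_max`
(here 0.05–0.15 per ms) and holds its value when the input is removed.

A command-line wrapper over the same functions ships at
`inst/cli/sns.R` (`design`, `simulate`, `steady-state`, `sweep`,
`analyze`, `verify`), reading and writing networks as JSON and
trajectories as CSV.

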