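Package: snsdesign
Title: Functional Subnetwork Design for Synthetic Nervous Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic design, simulation and verification of small networks of
    non-spiking leaky-integrator neurons coupled by piecewise-linear
    conductance synapses. Closed-form tuning rules map functional parameters
    (operating range, pathway gains, time constants, integration rates) onto
    biophysical ones (synaptic conductances, reversal potentials, membrane
    capacitances, tonic drives) so that three- and four-neuron subnetworks
    perform addition, subtraction, multiplication, division, temporal
    differentiation and temporal integration of encoded signals. Includes a
    fixed-step Runge-Kutta simulator with stimulus programs, steady-state
    solvers, response-surface sweeps against ideal operators, linearized
    frequency-response analysis of the differentiator, and Jacobian and
    eigenvalue analysis of the line-attractor integrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
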