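# Shared fixtures built in code at test time.

single_neuron_net <- function(Cm = 5, Gm = 1, Iapp_tonic = 0) {
  network_spec(list(neuron_spec("n", Cm = Cm, Gm = Gm,
                                Iapp_tonic = Iapp_tonic)),
               inputs = list(inp = "n"))
}

# scalar evaluation of the single-neuron equilibrium, written out longhand
# so it is independent of steady_state_neuron()
eq13_by_hand <- function(gs, dEs, U_pre, R, Iapp = 0) {
  g <- gs / R * pmin(pmax(U_pre, 0), R)
  (sum(g * dEs) + Iapp) / (1 + sum(g))
}
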