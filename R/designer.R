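# Closed-form designers: functional parameters in, fully parameterized
# network + constraint report out.
#
# Reversal-potential defaults follow typical biophysics: 194 mV relative to
# rest (calcium, 134 mV absolute against -60 mV rest) for excitatory
# transmission, -40 mV for subtraction inhibition (a -100 mV absolute
# floor), -1 mV for the multiplication network's shunting modulation. All
# overridable.

#' Tune a signal-transmission synapse
#'
#' A transmission pathway makes the postsynaptic steady-state activation
#' `k_syn` times the presynaptic activation at full drive (`U_pre = R`).
#' The required maximal conductance is `gs = k_syn*R / (dEs - k_syn*R)`,
#' feasible only when `dEs > k_syn*R`.
#'
#' @param k_syn Voltage gain of the pathway (>= 0; 0 yields a null pathway).
#' @param R Operating range, mV.
#' @param dEs Reversal potential relative to postsynaptic rest, mV.
#' @return Maximal conductance `gs` in uS.
#' @examples
#' tune_transmission(1, 20, 194)    # 0.1149425 uS, i.e. 115 nS
#' @export
tune_transmission <- function(k_syn, R, dEs) {
  stopifnot(is.finite(k_syn), is.finite(R), is.finite(dEs), R > 0, k_syn >= 0)
  if (k_syn == 0) return(0)
  if (dEs <= k_syn * R)
    stop("infeasible transmission design: requires dEs > k_syn*R (",
         dEs, " <= ", k_syn * R, ")")
  k_syn * R / (dEs - k_syn * R)
}

#' Tune a signal-modulation synapse
#'
#' A modulation pathway scales the postsynaptic neuron's sensitivity to its
#' other inputs by `c_syn` when the presynaptic neuron is fully active,
#' exploiting a reversal potential at or near rest (shunting):
#' `gs = (c_syn*R - R) / (dEs - c_syn*R)`. The full-shunt case `c_syn = 0`
#' reduces to `gs = -R/dEs` and needs `dEs < 0`.
#'
#' @param c_syn Modulation factor in `[0, 1]` (1 = no modulation).
#' @param R Operating range, mV.
#' @param dEs Reversal potential relative to postsynaptic rest, mV; must
#'   satisfy `dEs < c_syn * R`.
#' @return Maximal conductance `gs` in uS.
#' @examples
#' tune_modulation(0.05, 20, 0)   # 19 uS
#' tune_modulation(0, 20, -1)     # 20 uS
#' @export
tune_modulation <- function(c_syn, R, dEs) {
  stopifnot(is.finite(c_syn), is.finite(R), is.finite(dEs), R > 0)
  if (c_syn < 0 || c_syn > 1)
    stop("infeasible modulation design: c_syn must lie in [0, 1]")
  if (c_syn == 0) {
    if (dEs == 0)
      stop("infeasible modulation design: c_syn = 0 with dEs = 0 divides by zero")
    if (dEs > 0)
      stop("infeasible modulation design: c_syn = 0 with dEs > 0 gives gs < 0, ",
           "physically not realizable")
    return(-R / dEs)
  }
  if (dEs >= c_syn * R && c_syn < 1)
    stop("infeasible modulation design: requires dEs < c_syn*R")
  if (c_syn == 1) return(0)
  (c_syn * R - R) / (dEs - c_syn * R)
}

constraint_row <- function(description, satisfied, margin) {
  data.frame(description = description, satisfied = satisfied,
             margin = margin, stringsAsFactors = FALSE)
}

new_design_report <- function(kind, functional, derived, constraints,
                              network, display = list()) {
  structure(
    list(kind = kind, functional = functional, derived = derived,
         constraints = constraints, network = network, display = display),
    class = "sns_design"
  )
}

#' @export
print.sns_design <- function(x, ...) {
  cat("<sns_design> ", x$kind, " subnetwork\n", sep = "")
  cat("functional parameters:\n")
  for (p in names(x$functional))
    cat(sprintf("  %-12s %g\n", p, x$functional[[p]]))
  cat("derived parameters:\n")
  for (p in names(x$derived))
    cat(sprintf("  %-12s %g\n", p, x$derived[[p]]))
  if (length(x$display)) {
    cat("display (rounded as conventionally reported):\n")
    for (p in names(x$display))
      cat(sprintf("  %-12s %s\n", p, x$display[[p]]))
  }
  ok <- all(x$constraints$satisfied)
  cat("constraints: ", sum(x$constraints$satisfied), "/",
      nrow(x$constraints), " satisfied",
      if (ok) " (design valid)\n" else " (DESIGN INVALID)\n", sep = "")
  for (i in seq_len(nrow(x$constraints)))
    cat(sprintf("  [%s] %s (margin %.4g)\n",
                if (x$constraints$satisfied[i]) "ok" else "FAIL",
                x$constraints$description[i], x$constraints$margin[i]))
  invisible(x)
}

#' Is a design report valid?
#'
#' @param report An `sns_design`.
#' @return `TRUE` only if every listed constraint is satisfied.
#' @export
design_valid <- function(report) {
  stopifnot(inherits(report, "sns_design"))
  all(report$constraints$satisfied)
}

# nearest-nS display string for a conductance in uS
format_nS <- function(gs_uS) sprintf("%d nS", as.integer(round(gs_uS * 1000)))

#' Design an addition subnetwork
#'
#' Two transmission pathways converge on one output neuron so that, at
#' steady state, `U_post ~= k1*U1 + k2*U2` over the region `U1 + U2 <= R`.
#' Accuracy improves as the excitatory reversal potentials are raised
#' (which shrinks `gs` and with it the activity-dependent denominator of
#' the output equilibrium), hence "maximize dEs".
#'
#' @param k1,k2 Transmission gains of the two pathways.
#' @param R Operating range, mV.
#' @param dEs1,dEs2 Reversal potentials (relative) of the two synapses, mV.
#' @param Cm Membrane capacitance used for every neuron, nF (the arithmetic
#'   subnetworks are tuned at steady state; Cm only sets settling speed).
#' @return An `sns_design` report whose `$network` is the 3-neuron circuit.
#' @export
design_addition <- function(k1 = 1, k2 = 1, R = 20, dEs1 = 194, dEs2 = 194,
                            Cm = 5) {
  gs1 <- tune_transmission(k1, R, dEs1)
  gs2 <- tune_transmission(k2, R, dEs2)
  net <- network_spec(
    neurons = list(neuron_spec("pre1", Cm = Cm), neuron_spec("pre2", Cm = Cm),
                   neuron_spec("post", Cm = Cm)),
    synapses = list(synapse_spec("pre1", "post", gs1, dEs1, R),
                    synapse_spec("pre2", "post", gs2, dEs2, R)),
    inputs = list(in1 = "pre1", in2 = "pre2"),
    metadata = list(designer = "design_addition",
                    functional = list(k1 = k1, k2 = k2, R = R))
  )
  cons <- rbind(
    constraint_row("dEs1 - k1*R > 0 (transmission feasibility, pathway 1; maximize dEs1)",
                   dEs1 - k1 * R > 0 || k1 == 0, dEs1 - k1 * R),
    constraint_row("dEs2 - k2*R > 0 (transmission feasibility, pathway 2; maximize dEs2)",
                   dEs2 - k2 * R > 0 || k2 == 0, dEs2 - k2 * R),
    constraint_row("gs1 >= 0", gs1 >= 0, gs1),
    constraint_row("gs2 >= 0", gs2 >= 0, gs2)
  )
  new_design_report(
    "addition",
    functional = list(k_syn_1 = k1, k_syn_2 = k2, R = R),
    derived = list(gs1 = gs1, gs2 = gs2, dEs1 = dEs1, dEs2 = dEs2),
    constraints = cons, network = net,
    display = list(gs1 = format_nS(gs1), gs2 = format_nS(gs2))
  )
}

#' Design a subtraction subnetwork
#'
#' An excitatory transmission pathway and an inhibitory pathway converge on
#' the output so that `U_post ~= k_syn*(U1 - U2)`, with the inhibitory
#' conductance chosen to null the output exactly at `U1 = U2 = R`:
#' `gs2 = -(dEs1/dEs2) * gs1`, which requires `dEs2 < 0`.
#'
#' The displayed conductances follow the conventional sequential rounding:
#' `gs1` is rounded to the nearest nS before `gs2` is computed from it, so
#' the default design prints 558 nS. Full precision is kept internally.
#'
#' @inheritParams design_addition
#' @param k_syn Gain of the subtraction.
#' @param dEs1 Excitatory reversal potential (relative), mV; maximize.
#' @param dEs2 Inhibitory reversal potential (relative), mV; must be < 0 and
#'   should be as negative as biology permits ("minimize").
#' @return An `sns_design` report.
#' @export
design_subtraction <- function(k_syn = 1, R = 20, dEs1 = 194, dEs2 = -40,
                               Cm = 5) {
  if (dEs2 >= 0)
    stop("infeasible subtraction design: dEs2 must be < 0 ",
         "(an inhibitory pathway)")
  gs1 <- tune_transmission(k_syn, R, dEs1)
  gs2 <- -(dEs1 / dEs2) * gs1
  gs1_nS <- round(gs1 * 1000)
  gs2_seq_nS <- round(-(dEs1 / dEs2) * gs1_nS)
  net <- network_spec(
    neurons = list(neuron_spec("pre1", Cm = Cm), neuron_spec("pre2", Cm = Cm),
                   neuron_spec("post", Cm = Cm)),
    synapses = list(synapse_spec("pre1", "post", gs1, dEs1, R),
                    synapse_spec("pre2", "post", gs2, dEs2, R)),
    inputs = list(in1 = "pre1", in2 = "pre2"),
    metadata = list(designer = "design_subtraction",
                    functional = list(k_syn = k_syn, R = R))
  )
  cons <- rbind(
    constraint_row("dEs1 - k_syn*R > 0 (transmission feasibility; maximize dEs1)",
                   dEs1 - k_syn * R > 0, dEs1 - k_syn * R),
    constraint_row("dEs2 < 0 (inhibitory pathway; minimize dEs2)",
                   dEs2 < 0, -dEs2),
    constraint_row("gs2 > 0", gs2 > 0, gs2),
    constraint_row("null at (R, R): gs1*dEs1 + gs2*dEs2 = 0",
                   abs(gs1 * dEs1 + gs2 * dEs2) < 1e-9,
                   -abs(gs1 * dEs1 + gs2 * dEs2))
  )
  new_design_report(
    "subtraction",
    functional = list(k_syn = k_syn, R = R),
    derived = list(gs1 = gs1, gs2 = gs2, dEs1 = dEs1, dEs2 = dEs2),
    constraints = cons, network = net,
    display = list(gs1 = sprintf("%d nS", as.integer(gs1_nS)),
                   gs2 = sprintf("%d nS", as.integer(gs2_seq_nS)))
  )
}

#' Design a division subnetwork
#'
#' A unity-gain transmission pathway carries the numerator signal; a
#' modulation pathway with `dEs = 0` (a GABA-like shunt at rest) divides
#' it, approximating
#' `U_post ~= U1 / (1 + (1-c_syn)/(c_syn*R) * U2)`.
#' The modulation conductance is `gs2 = (1 - c_syn)/c_syn`.
#'
#' @inheritParams design_addition
#' @param c_syn Modulation factor, strictly between 0 and 1. `c_syn = 1/R`
#'   makes the output 1 mV when both inputs are at `R`.
#' @param dEs1 Excitatory reversal potential (relative), mV.
#' @return An `sns_design` report.
#' @export
design_division <- function(c_syn, R = 20, dEs1 = 194, Cm = 5) {
  if (!is.finite(c_syn) || c_syn <= 0 || c_syn >= 1)
    stop("infeasible division design: requires 0 < c_syn < 1")
  gs1 <- tune_transmission(1, R, dEs1)
  gs2 <- tune_modulation(c_syn, R, 0)
  net <- network_spec(
    neurons = list(neuron_spec("pre1", Cm = Cm), neuron_spec("pre2", Cm = Cm),
                   neuron_spec("post", Cm = Cm)),
    synapses = list(synapse_spec("pre1", "post", gs1, dEs1, R),
                    synapse_spec("pre2", "post", gs2, 0, R)),
    inputs = list(in1 = "pre1", in2 = "pre2"),
    metadata = list(designer = "design_division",
                    functional = list(c_syn = c_syn, R = R))
  )
  cons <- rbind(
    constraint_row("k_syn = 1 transmission feasible: dEs1 - R > 0 (maximize dEs1)",
                   dEs1 - R > 0, dEs1 - R),
    constraint_row("0 < c_syn < 1", c_syn > 0 && c_syn < 1,
                   min(c_syn, 1 - c_syn)),
    constraint_row("dEs2 = 0 (shunting modulation at rest)", TRUE, 0),
    constraint_row("gs2 = (1 - c_syn)/c_syn > 0", gs2 > 0, gs2)
  )
  new_design_report(
    "division",
    functional = list(c_syn = c_syn, R = R),
    derived = list(gs1 = gs1, gs2 = gs2, dEs1 = dEs1, dEs2 = 0),
    constraints = cons, network = net,
    display = list(gs1 = format_nS(gs1), gs2 = sprintf("%g uS", gs2))
  )
}

#' Design a multiplication subnetwork
#'
#' Disinhibition implements `U_post ~= U1 * U2 / R`: the second input
#' inhibits a tonically active interneuron (tonic drive `Iapp = R`), which
#' in turn shunts the output. Both modulation synapses are identical
#' full-shunt pathways (`c_syn = 0`, so `gs = -R/dEs`, requiring `dEs < 0`),
#' and the first input arrives over a unity-gain transmission synapse.
#' The closed-form predicted output is available from
#' [predict_multiplication()].
#'
#' @inheritParams design_addition
#' @param dEs1 Excitatory reversal potential (relative) of the transmission
#'   synapse, mV.
#' @param dEs23 Shared reversal potential (relative) of the two modulation
#'   synapses, mV; must be < 0. `-1` makes the output scale 1:1 with
#'   `U1*U2/R`.
#' @return An `sns_design` report whose `$network` is the 4-neuron circuit.
#' @export
design_multiplication <- function(R = 20, dEs1 = 194, dEs23 = -1, Cm = 5) {
  if (dEs23 >= 0)
    stop("infeasible multiplication design: dEs23 must be < 0 ",
         "(full-shunt modulation)")
  gs1 <- tune_transmission(1, R, dEs1)
  gs2 <- tune_modulation(0, R, dEs23)
  net <- network_spec(
    neurons = list(neuron_spec("pre1", Cm = Cm), neuron_spec("pre2", Cm = Cm),
                   neuron_spec("inter", Cm = Cm, Iapp_tonic = R),
                   neuron_spec("post", Cm = Cm)),
    synapses = list(synapse_spec("pre1", "post", gs1, dEs1, R),
                    synapse_spec("pre2", "inter", gs2, dEs23, R),
                    synapse_spec("inter", "post", gs2, dEs23, R)),
    inputs = list(in1 = "pre1", in2 = "pre2"),
    metadata = list(designer = "design_multiplication",
                    functional = list(R = R, dEs = dEs23))
  )
  cons <- rbind(
    constraint_row("k_syn = 1 transmission feasible: dEs1 - R > 0 (maximize dEs1)",
                   dEs1 - R > 0, dEs1 - R),
    constraint_row("dEs2 = dEs3 < 0 (maximize, i.e. close to 0)",
                   dEs23 < 0, -dEs23),
    constraint_row("gs3 = gs2 = -R/dEs (identical modulation pathways)",
                   TRUE, 0),
    constraint_row("interneuron tonic drive Iapp = R", TRUE, 0)
  )
  new_design_report(
    "multiplication",
    functional = list(R = R),
    derived = list(gs1 = gs1, gs2 = gs2, gs3 = gs2, dEs1 = dEs1,
                   dEs2 = dEs23, dEs3 = dEs23, Iapp_inter = R),
    constraints = cons, network = net,
    display = list(gs1 = format_nS(gs1), gs2 = sprintf("%g uS", gs2))
  )
}

#' Closed-form predicted output of the multiplication network
#'
#' Evaluates the algebraic prediction
#' `U_post = (-U1*U2/dEs + U1 + U2 - R) / (1 - R/dEs)`
#' obtained by treating the transmission input as an equivalent applied
#' current. With `dEs = -1` this is `(U1*U2 + U1 + U2 - R)/(1 + R)`, which
#' scales 1:1 with `U1*U2/R` at the corners of the operating square.
#'
#' @param report An `sns_design` of kind `"multiplication"`.
#' @param U1,U2 Input activations, mV (vectorized).
#' @return Predicted output activation(s), mV.
#' @export
predict_multiplication <- function(report, U1, U2) {
  stopifnot(inherits(report, "sns_design"), report$kind == "multiplication")
  dEs <- report$derived$dEs2
  R <- report$functional$R
  (-U1 * U2 / dEs + U1 + U2 - R) / (1 - R / dEs)
}

#' Design a temporal-differentiation subnetwork
#'
#' Two first-order neurons with unequal membrane capacitances low-pass the
#' same input with different lags; subtracting the slow copy from the fast
#' one yields a band-limited derivative (a Reichardt-style detector). For a
#' ramp input of slope `A` nA/ms the steady output is
#' `k_syn_out * (Cm2 - Cm1) * A` mV; the cutoff angular frequency is
#' `omega_c = 1/tau_d`.
#'
#' `k_d` and `tau_d` are accepted in seconds and converted under the
#' `Gm = 1` uS convention (1 s of gain = 1000 nF of capacitance
#' difference). Feasibility requires `tau_d > k_d` so that
#' `Cm1 = Cm2 - 1000*k_d > 0`.
#'
#' @param k_d Differentiator gain, s.
#' @param tau_d Lag time constant, s (`Cm2 = 1000*tau_d` nF).
#' @param R Operating range, mV.
#' @param k_syn_out Gain of the output subtraction stage. The default
#'   `1/k_d` normalizes the overall ramp-to-plateau gain to 1 s; pass 1 to
#'   keep the raw `k_d` gain.
#' @param dEs1,dEs2 Reversal potentials of the subtraction stage, mV.
#' @param Cm_out Output-neuron capacitance, nF; small so the subtraction
#'   stage adds negligible lag.
#' @return An `sns_design` report; `$functional$omega_c` is the cutoff in
#'   rad/s.
#' @export
design_differentiator <- function(k_d, tau_d, R = 20, k_syn_out = 1 / k_d,
                                  dEs1 = 194, dEs2 = -40, Cm_out = 1) {
  stopifnot(is.finite(k_d), is.finite(tau_d), k_d > 0)
  Cm2 <- 1000 * tau_d
  Cm1 <- Cm2 - 1000 * k_d
  if (Cm1 <= 0)
    stop("infeasible differentiator design: tau_d must exceed k_d ",
         "(Cm1 = Cm2 - 1000*k_d must be > 0)")
  sub <- design_subtraction(k_syn = k_syn_out, R = R, dEs1 = dEs1,
                            dEs2 = dEs2)
  gs1 <- sub$derived$gs1
  gs2 <- sub$derived$gs2
  net <- network_spec(
    neurons = list(neuron_spec("u1", Cm = Cm1), neuron_spec("u2", Cm = Cm2),
                   neuron_spec("post", Cm = Cm_out)),
    synapses = list(synapse_spec("u1", "post", gs1, dEs1, R),
                    synapse_spec("u2", "post", gs2, dEs2, R)),
    inputs = list(input = c("u1", "u2")),
    metadata = list(designer = "design_differentiator",
                    functional = list(k_d = k_d, tau_d = tau_d, R = R,
                                      k_syn_out = k_syn_out))
  )
  cons <- rbind(
    constraint_row("Cm1 > 0 (tau_d > k_d)", Cm1 > 0, Cm1),
    constraint_row("Cm1 < Cm2", Cm1 < Cm2, Cm2 - Cm1),
    sub$constraints
  )
  new_design_report(
    "differentiation",
    functional = list(k_d = k_d, tau_d = tau_d, R = R,
                      k_syn_out = k_syn_out, omega_c = 1 / tau_d),
    derived = list(Cm1 = Cm1, Cm2 = Cm2, gs1 = gs1, gs2 = gs2,
                   dEs1 = dEs1, dEs2 = dEs2, Cm_out = Cm_out),
    constraints = cons, network = net,
    display = list(gs1 = sub$display$gs1, gs2 = sub$display$gs2)
  )
}

#' Design a temporal-integration subnetwork
#'
#' Two mutually inhibiting neurons with tonic drive `Iapp = R` form a line
#' attractor: when the synapses satisfy `gs*dEs = -R` exactly, the system
#' Jacobian has identical rows, one eigenvalue is zero everywhere, and the
#' state neither leaks nor drifts. An applied current `u` then moves the
#' state along the equilibrium curve at rate `k_i * u`, with
#' `k_i` between `k_i_min = 1/(Cm*(2+gs))` and
#' `k_i_max = (1+gs)/(Cm*(2+gs))`; the mean rate is `1/(2*Cm)`.
#'
#' The designer inverts those relations: `Cm = 1/(2*k_i_mean)` and
#' `gs = 2*Cm/(1/k_i_range - Cm)`, then `dEs = -R/gs`. Feasibility requires
#' `1/k_i_range > Cm`.
#'
#' @param k_i_mean Intended mean integration rate, 1/ms.
#' @param k_i_range Intended spread `k_i_max - k_i_min`, 1/ms.
#' @param R Operating range, mV.
#' @return An `sns_design` report echoing `k_i_min` and `k_i_max`.
#' @export
design_integrator <- function(k_i_mean, k_i_range, R = 20) {
  stopifnot(is.finite(k_i_mean), is.finite(k_i_range), k_i_mean > 0,
            k_i_range > 0)
  Cm <- 1 / (2 * k_i_mean)
  if (1 / k_i_range <= Cm)
    stop("infeasible integrator design: requires 1/k_i_range > Cm ",
         "(k_i_range must be below 2*k_i_mean)")
  gs <- 2 * Cm / (1 / k_i_range - Cm)
  dEs <- -R / gs
  net <- network_spec(
    neurons = list(neuron_spec("u1", Cm = Cm, Iapp_tonic = R),
                   neuron_spec("u2", Cm = Cm, Iapp_tonic = R)),
    synapses = list(synapse_spec("u2", "u1", gs, dEs, R),
                    synapse_spec("u1", "u2", gs, dEs, R)),
    inputs = list(u = "u1"),
    metadata = list(designer = "design_integrator",
                    functional = list(k_i_mean = k_i_mean,
                                      k_i_range = k_i_range, R = R))
  )
  ki_min <- 1 / (Cm * (2 + gs))
  ki_max <- (1 + gs) / (Cm * (2 + gs))
  cons <- rbind(
    constraint_row("1/k_i_range > Cm (conductance pole)",
                   1 / k_i_range > Cm, 1 / k_i_range - Cm),
    constraint_row("gs > 0", gs > 0, gs),
    constraint_row("marginal stability: gs*dEs = -R exactly",
                   abs(gs * dEs + R) <= 1e-12 * R,
                   -abs(gs * dEs + R)),
    constraint_row("tonic drive Iapp = R on both neurons", TRUE, 0)
  )
  new_design_report(
    "integration",
    functional = list(k_i_mean = k_i_mean, k_i_range = k_i_range, R = R),
    derived = list(Cm = Cm, gs = gs, dEs = dEs, Iapp = R,
                   k_i_min = ki_min, k_i_max = ki_max),
    constraints = cons, network = net,
    display = list(gs = sprintf("%g uS", gs), Cm = sprintf("%g nF", Cm))
  )
}
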