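# Core data model: neurons, synapses, networks, and the instantaneous
# current / steady-state equations every other module reuses.
#
# Unit convention, fixed package-wide: potentials in mV, currents in nA,
# conductances in uS, capacitances in nF, time in ms (nF/uS = ms). All
# analysis is in shifted coordinates U = V - E_r, so rest is U = 0 and the
# resting potential itself is display metadata only.

#' Define a non-spiking neuron
#'
#' A single leaky-integrator compartment. With membrane conductance `Gm` and
#' capacitance `Cm`, the activation `U` (potential above rest, mV) obeys
#' `Cm * dU/dt = -Gm*U + I_syn + I_app`, a first-order lag with time constant
#' `tau = Cm/Gm` ms.
#'
#' @param name Neuron identifier (unique within a network).
#' @param Cm Membrane capacitance in nF (> 0).
#' @param Gm Membrane conductance in uS (> 0). The design rules assume the
#'   typical value 1 uS, under which a constant applied current `I` settles
#'   at `U* = I`.
#' @param Iapp_tonic Constant intrinsic applied current in nA (tonic drive).
#' @return An object of class `sns_neuron`.
#' @seealso [synapse_spec()], [network_spec()]
#' @export
neuron_spec <- function(name, Cm = 5, Gm = 1, Iapp_tonic = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(Cm) || Cm <= 0) stop("neuron '", name, "': Cm must be > 0 (nF)")
  if (!is.finite(Gm) || Gm <= 0) stop("neuron '", name, "': Gm must be > 0 (uS)")
  structure(
    list(name = name, Cm = Cm, Gm = Gm, Iapp_tonic = Iapp_tonic),
    class = "sns_neuron"
  )
}

#' Define a piecewise-linear conductance synapse
#'
#' The instantaneous conductance is a threshold-linear function of the
#' presynaptic activation: zero below `Elo`, the maximum `gs` above
#' `Elo + R`, and linear in between. `dEs` is the synaptic reversal
#' potential measured relative to the *postsynaptic* neuron's rest, so
#' `dEs >= R` makes the synapse depolarizing over the whole operating range
#' and `dEs <= 0` makes it hyperpolarizing.
#'
#' @param pre,post Names of the presynaptic and postsynaptic neurons.
#' @param gs Maximal conductance in uS (>= 0).
#' @param dEs Reversal potential relative to postsynaptic rest, in mV.
#' @param R Operating range `E_hi - E_lo` of the presynaptic activation, mV
#'   (> 0).
#' @param Elo Lower threshold in presynaptic U-space, mV. Defaults to 0,
#'   i.e. the presynaptic resting potential.
#' @return An object of class `sns_synapse`.
#' @export
synapse_spec <- function(pre, post, gs, dEs, R, Elo = 0) {
  stopifnot(is.character(pre), is.character(post))
  if (!is.finite(gs) || gs < 0)
    stop("synapse ", pre, "->", post, ": gs must be >= 0 (uS)")
  if (!is.finite(R) || R <= 0)
    stop("synapse ", pre, "->", post, ": R must be > 0 (mV)")
  structure(
    list(pre = pre, post = post, gs = gs, dEs = dEs, R = R, Elo = Elo),
    class = "sns_synapse"
  )
}

#' Assemble a network of neurons and synapses
#'
#' The unit of design, simulation and serialization: named neurons, the
#' synapses between them, and named external-input ports through which
#' stimulus currents are injected.
#'
#' @param neurons List of [neuron_spec()] objects; names must be unique.
#' @param synapses List of [synapse_spec()] objects; endpoints must refer to
#'   declared neurons.
#' @param inputs Named list mapping port name to a character vector of
#'   neuron names that receive the port's current. A plain named character
#'   vector is also accepted.
#' @param metadata Free-form list recording provenance (which designer built
#'   the network, with which functional parameters).
#' @return An object of class `sns_network`.
#' @export
network_spec <- function(neurons, synapses = list(), inputs = list(),
                         metadata = list()) {
  if (inherits(neurons, "sns_neuron")) neurons <- list(neurons)
  if (inherits(synapses, "sns_synapse")) synapses <- list(synapses)
  if (is.character(inputs)) inputs <- as.list(inputs)
  nm <- vapply(neurons, function(n) n$name, character(1))
  if (anyDuplicated(nm)) stop("neuron names must be unique: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(neurons) <- nm
  for (s in synapses) {
    for (end in c(s$pre, s$post))
      if (!end %in% nm)
        stop("synapse ", s$pre, "->", s$post,
             " references undeclared neuron '", end, "'")
  }
  if (length(inputs)) {
    if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
      stop("input ports must be named")
    for (p in names(inputs)) {
      bad <- setdiff(inputs[[p]], nm)
      if (length(bad))
        stop("input port '", p, "' references undeclared neuron '",
             bad[1], "'")
    }
  }
  structure(
    list(neurons = neurons, synapses = synapses, inputs = inputs,
         metadata = metadata),
    class = "sns_network"
  )
}

#' @export
print.sns_network <- function(x, ...) {
  cat("<sns_network> ", length(x$neurons), " neurons, ",
      length(x$synapses), " synapses, ",
      length(x$inputs), " input ports\n", sep = "")
  for (n in x$neurons)
    cat(sprintf("  neuron %-8s Cm=%g nF  Gm=%g uS  Iapp=%g nA\n",
                n$name, n$Cm, n$Gm, n$Iapp_tonic))
  for (s in x$synapses)
    cat(sprintf("  synapse %s -> %s  gs=%g uS  dEs=%g mV  R=%g mV\n",
                s$pre, s$post, s$gs, s$dEs, s$R))
  if (length(x$inputs))
    cat("  ports: ",
        paste(sprintf("%s -> %s", names(x$inputs),
                      vapply(x$inputs, paste, character(1), collapse = "+")),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

neuron_names <- function(net) names(net$neurons)

#' Instantaneous synaptic conductance
#'
#' Evaluates the clamped piecewise-linear conductance of a synapse at a
#' presynaptic activation: 0 below `Elo`, `gs` above `Elo + R`, linear in
#' between. Total over all real `U_pre`, never negative, never above `gs`.
#'
#' @param syn A [synapse_spec()].
#' @param U_pre Presynaptic activation(s), mV above presynaptic rest.
#' @return Conductance(s) in uS, same length as `U_pre`.
#' @examples
#' s <- synapse_spec("a", "b", gs = 0.115, dEs = 194, R = 20)
#' synaptic_conductance(s, c(-5, 10, 30))
#' @export
synaptic_conductance <- function(syn, U_pre) {
  g <- syn$gs * (U_pre - syn$Elo) / syn$R
  pmin(pmax(g, 0), syn$gs)
}

# External currents per neuron from a per-port current vector.
port_currents <- function(net, external) {
  I <- stats::setNames(numeric(length(net$neurons)), neuron_names(net))
  if (length(external)) {
    if (is.null(names(external))) stop("external currents must be named by port")
    unknown <- setdiff(names(external), names(net$inputs))
    if (length(unknown))
      stop("unknown input port(s): ", paste(unknown, collapse = ", "))
    for (p in names(external))
      I[net$inputs[[p]]] <- I[net$inputs[[p]]] + external[[p]]
  }
  I
}

#' Network drift: per-neuron dU/dt
#'
#' Evaluates the right-hand side of the shifted membrane equation
#' `Cm * dU/dt = -Gm*U + sum_i Gs_i * (dEs_i - U) + I_app` for every neuron,
#' with the clamped piecewise-linear conductances of
#' [synaptic_conductance()].
#'
#' @param net An [network_spec()][network_spec] object.
#' @param state Named numeric vector of activations U (mV), covering all
#'   neurons.
#' @param external Named numeric vector of currents per input port (nA).
#' @return Named numeric vector of dU/dt in mV/ms.
#' @export
neuron_derivative <- function(net, state, external = numeric()) {
  nm <- neuron_names(net)
  if (!all(nm %in% names(state)))
    stop("state must cover all neurons: missing ",
         paste(setdiff(nm, names(state)), collapse = ", "))
  U <- state[nm]
  I <- port_currents(net, external)
  dU <- stats::setNames(numeric(length(nm)), nm)
  for (n in net$neurons)
    dU[n$name] <- -n$Gm * U[n$name] + n$Iapp_tonic + I[n$name]
  for (s in net$synapses) {
    G <- synaptic_conductance(s, U[[s$pre]])
    dU[s$post] <- dU[s$post] + G * (s$dEs - U[[s$post]])
  }
  for (n in net$neurons) dU[n$name] <- dU[n$name] / n$Cm
  dU
}

#' Closed-form equilibrium of a single neuron
#'
#' Solves `dU/dt = 0` for one neuron given fixed presynaptic activations:
#' `U* = (sum_i gs_i/R_i * Upre_i * dEs_i + Iapp) / (Gm + sum_i gs_i/R_i * Upre_i)`
#' where each `Upre_i` is clamped to `[0, R_i]` before entering the
#' conductance (the piecewise-linear synapse).
#'
#' @param synapses Data frame (or list coercible to one) with columns
#'   `gs`, `dEs`, `U_pre`, `R`. May have zero rows.
#' @param Iapp Applied current, nA.
#' @param Gm Membrane conductance, uS.
#' @return Equilibrium activation `U*` in mV.
#' @examples
#' steady_state_neuron(data.frame(gs = 0.114943, dEs = 194, U_pre = 10, R = 20))
#' @export
steady_state_neuron <- function(synapses = NULL, Iapp = 0, Gm = 1) {
  num <- Iapp
  den <- Gm
  if (!is.null(synapses) && NROW(synapses) > 0) {
    synapses <- as.data.frame(synapses)
    g <- synapses$gs / synapses$R * pmin(pmax(synapses$U_pre, 0), synapses$R)
    num <- num + sum(g * synapses$dEs)
    den <- den + sum(g)
  }
  num / den
}

# Topological order of neurons, or NULL if the synapse graph has a cycle.
topological_order <- function(net) {
  nm <- neuron_names(net)
  indeg <- stats::setNames(integer(length(nm)), nm)
  succ <- stats::setNames(vector("list", length(nm)), nm)
  for (s in net$synapses) {
    indeg[s$post] <- indeg[s$post] + 1L
    succ[[s$pre]] <- c(succ[[s$pre]], s$post)
  }
  order <- character(0)
  ready <- nm[indeg == 0L]
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    order <- c(order, v)
    for (w in succ[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(order) < length(nm)) NULL else order
}

#' Network steady state
#'
#' Solves for the equilibrium activation of every neuron under constant
#' external port currents. Feedforward networks are solved exactly in
#' topological order through [steady_state_neuron()]; networks with cycles
#' are solved by damped fixed-point iteration (damping 0.5) to the requested
#' tolerance. A converged solution satisfies `|dU/dt| < 1e-6` mV/ms on
#' every neuron.
#'
#' Non-convergence (expected for the marginally stable integrator under
#' nonzero external drive, which has no equilibrium) is reported through the
#' `converged` attribute and a warning, never silently.
#'
#' @param net An `sns_network`.
#' @param external Named numeric vector of constant port currents (nA).
#' @param tol Fixed-point tolerance on the activation update, mV.
#' @param max_iter Iteration cap for cyclic networks.
#' @return Named numeric vector of equilibrium activations `U*` (mV) with
#'   attributes `converged` (logical) and `residual` (max |dU/dt|, mV/ms).
#' @export
steady_state_network <- function(net, external = numeric(), tol = 1e-9,
                                 max_iter = 1e5) {
  nm <- neuron_names(net)
  I <- port_currents(net, external)
  pre_of <- lapply(stats::setNames(nm, nm), function(v)
    Filter(function(s) s$post == v, net$synapses))
  solve_one <- function(v, U) {
    syns <- pre_of[[v]]
    tab <- if (length(syns))
      data.frame(gs = vapply(syns, `[[`, 0, "gs"),
                 dEs = vapply(syns, `[[`, 0, "dEs"),
                 U_pre = vapply(syns, function(s) U[[s$pre]], 0),
                 R = vapply(syns, `[[`, 0, "R"))
    n <- net$neurons[[v]]
    steady_state_neuron(tab, Iapp = n$Iapp_tonic + I[[v]], Gm = n$Gm)
  }
  U <- stats::setNames(numeric(length(nm)), nm)
  order <- topological_order(net)
  converged <- TRUE
  if (!is.null(order)) {
    for (v in order) U[v] <- solve_one(v, U)
  } else {
    damping <- 0.5
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      U_new <- U
      for (v in nm) U_new[v] <- solve_one(v, U)
      if (max(abs(U_new - U)) < tol) {
        U <- U_new
        converged <- TRUE
        break
      }
      U <- (1 - damping) * U + damping * U_new
    }
  }
  residual <- max(abs(neuron_derivative(net, U, external)))
  if (!converged || residual >= 1e-6)
    warning("steady_state_network did not converge (residual ",
            signif(residual, 3), " mV/ms); the network may have no ",
            "equilibrium under this drive (e.g. a driven integrator)")
  structure(U, converged = converged && residual < 1e-6, residual = residual)
}

#' Sensor-to-current mapping
#'
#' Affine encoding of a mechanical quantity onto the neural operating range:
#' a sensor value `theta` in `[theta_min, theta_max]` maps to an applied
#' current in `[0, R]` nA, so that (with `Gm` = 1 uS) the sensory neuron's
#' equilibrium activation encodes the sensor state. The inverse map decodes
#' a commanded activation back into sensor units.
#'
#' @param theta_min,theta_max Sensor range (any consistent unit);
#'   `theta_max > theta_min`.
#' @param R Operating range, mV.
#' @return An object of class `sns_sensor_map`.
#' @export
sensor_map <- function(theta_min, theta_max, R) {
  if (!is.finite(theta_min) || !is.finite(theta_max) ||
      theta_max <= theta_min)
    stop("degenerate sensor range: theta_max must exceed theta_min")
  if (!is.finite(R) || R <= 0) stop("R must be > 0 (mV)")
  structure(list(theta_min = theta_min, theta_max = theta_max, R = R),
            class = "sns_sensor_map")
}

#' @rdname sensor_map
#' @param m An `sns_sensor_map`.
#' @param theta Sensor value(s); values outside the range are clamped with a
#'   warning.
#' @return `map_sensor_to_current()`: applied current(s) in nA on `[0, R]`.
#' @export
map_sensor_to_current <- function(m, theta) {
  stopifnot(inherits(m, "sns_sensor_map"))
  if (any(theta < m$theta_min | theta > m$theta_max)) {
    warning("theta outside [theta_min, theta_max]; clamping")
    theta <- pmin(pmax(theta, m$theta_min), m$theta_max)
  }
  m$R * (theta - m$theta_min) / (m$theta_max - m$theta_min)
}

#' @rdname sensor_map
#' @param U_comm Commanded activation(s), mV.
#' @return `map_activity_to_command()`: sensor-unit command(s).
#' @export
map_activity_to_command <- function(m, U_comm) {
  stopifnot(inherits(m, "sns_sensor_map"))
  m$theta_min + U_comm / m$R * (m$theta_max - m$theta_min)
}

#' Reversal potential relative to rest
#'
#' Converts an absolute synaptic reversal potential to the shifted
#' convention used throughout: `dEs = Es - Er_post`. E.g. the calcium
#' reversal potential 134 mV against a typical rest of -60 mV gives the
#' 194 mV excitatory default.
#'
#' @param Es Absolute reversal potential, mV.
#' @param Er_post Postsynaptic resting potential, mV.
#' @return Relative reversal potential, mV.
#' @export
relative_reversal <- function(Es, Er_post = -60) Es - Er_post
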