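# Time-domain integration of network dynamics under stimulus programs.
# Fixed-step classical Runge-Kutta (deSolve, method "rk4"); deterministic
# and bit-reproducible for a given network, stimulus and step size.

#' Stimulus segment
#'
#' One piece of a stimulus program. Kinds:
#' `"zero"` (no current), `"constant"`/`"step"` (a held amplitude),
#' `"ramp"` (`offset + slope * t_local`), `"sine"`
#' (`offset + amplitude * sin(omega * t_local + phase)`), and `"noise"`
#' (zero-order-hold Gaussian noise with an explicit seed, for optional
#' robustness probes).
#'
#' @param kind Segment kind, see above.
#' @param duration Segment length, ms (> 0).
#' @param amplitude Current amplitude, nA (constant/step/sine).
#' @param slope Ramp slope, nA/ms.
#' @param offset Baseline current added to ramp/sine segments, nA.
#' @param omega Angular frequency, rad/ms (sine).
#' @param phase Phase, rad (sine).
#' @param sd,seed,hold Noise standard deviation (nA), RNG seed, and hold
#'   interval (ms) for `"noise"` segments.
#' @return A `stim_segment` list.
#' @export
stim_segment <- function(kind = c("constant", "step", "ramp", "sine", "zero",
                                  "noise"),
                         duration, amplitude = 0, slope = 0, offset = 0,
                         omega = 0, phase = 0, sd = 0, seed = NULL,
                         hold = 1) {
  kind <- match.arg(kind)
  if (!is.finite(duration) || duration <= 0)
    stop("stimulus segment duration must be positive (ms)")
  if (kind == "noise" && is.null(seed))
    stop("noise segments require an explicit seed")
  structure(list(kind = kind, duration = duration, amplitude = amplitude,
                 slope = slope, offset = offset, omega = omega,
                 phase = phase, sd = sd, seed = seed, hold = hold),
            class = "stim_segment")
}

#' Stimulus program for one input port
#'
#' @param port Input-port name the program drives.
#' @param segments A [stim_segment()] or list of them, played in order;
#'   times beyond the last segment yield zero current.
#' @return An object of class `sns_stimulus`.
#' @export
stimulus_spec <- function(port, segments) {
  if (inherits(segments, "stim_segment")) segments <- list(segments)
  stopifnot(length(segments) > 0,
            all(vapply(segments, inherits, TRUE, "stim_segment")))
  structure(list(port = port, segments = segments), class = "sns_stimulus")
}

segment_value <- function(seg, tl) {
  switch(seg$kind,
    zero = rep(0, length(tl)),
    constant = rep(seg$amplitude, length(tl)),
    step = rep(seg$amplitude, length(tl)),
    ramp = seg$offset + seg$slope * tl,
    sine = seg$offset + seg$amplitude * sin(seg$omega * tl + seg$phase),
    noise = {
      idx <- pmax(floor(tl / seg$hold), 0) + 1
      n <- max(idx)
      vals <- withr_seed_rnorm(seg$seed, n, seg$sd)
      seg$offset + vals[idx]
    })
}

# deterministic noise draws without disturbing the global RNG stream
withr_seed_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Evaluate a stimulus program
#'
#' @param stim An [stimulus_spec()].
#' @param t Time(s) in ms from program start.
#' @return Current(s) in nA.
#' @export
stimulus_current <- function(stim, t) {
  stopifnot(inherits(stim, "sns_stimulus"))
  durations <- vapply(stim$segments, `[[`, 0, "duration")
  starts <- cumsum(c(0, durations))
  out <- numeric(length(t))
  for (i in seq_along(stim$segments)) {
    inseg <- t >= starts[i] & (t < starts[i + 1] |
                               (i == length(stim$segments) & t == starts[i + 1]))
    if (any(inseg))
      out[inseg] <- segment_value(stim$segments[[i]], t[inseg] - starts[i])
  }
  out
}

external_at <- function(stimuli, t) {
  if (!length(stimuli)) return(numeric())
  stats::setNames(vapply(stimuli, stimulus_current, 0, t = t),
                  vapply(stimuli, `[[`, "", "port"))
}

#' Simulate a network
#'
#' Integrates the membrane equations with fixed-step classical Runge-Kutta
#' on a uniform grid. The default step is `min(tau)/20`; a warning is
#' issued when the supplied step exceeds `min(tau)/10`.
#'
#' @param net An `sns_network`.
#' @param stimuli List of [stimulus_spec()] programs (at most one per port).
#' @param T Total simulated time, ms.
#' @param dt Step size, ms; default `min(Cm/Gm)/20`.
#' @param init Initial state: `"rest"` (all zeros), `"settled"` (simulate
#'   `20 * max(tau)` with zero external drive first, then start recording),
#'   or a named numeric vector of activations.
#' @return An `sns_simulation` with elements `t` (ms), `U` (time x neuron
#'   matrix, mV), `I_ext` (time x port matrix, nA) and `dt`.
#' @export
simulate_network <- function(net, stimuli = list(), T, dt = NULL,
                             init = "rest") {
  stopifnot(inherits(net, "sns_network"), is.finite(T), T >= 0)
  if (inherits(stimuli, "sns_stimulus")) stimuli <- list(stimuli)
  ports <- vapply(stimuli, `[[`, "", "port")
  if (anyDuplicated(ports)) stop("multiple stimulus programs for one port")
  bad <- setdiff(ports, names(net$inputs))
  if (length(bad)) stop("stimulus references unknown port(s): ",
                        paste(bad, collapse = ", "))
  nm <- neuron_names(net)
  tau <- vapply(net$neurons, function(n) n$Cm / n$Gm, 0)
  if (is.null(dt)) dt <- min(tau) / 20
  if (dt > min(tau) / 10)
    warning("dt = ", dt, " ms exceeds min(tau)/10 = ", signif(min(tau) / 10, 4),
            " ms; the fastest neuron may be under-resolved")

  if (identical(init, "rest")) {
    U0 <- stats::setNames(numeric(length(nm)), nm)
  } else if (identical(init, "settled")) {
    pre <- simulate_network(net, list(), T = 20 * max(tau), dt = dt,
                            init = "rest")
    U0 <- pre$U[nrow(pre$U), ]
  } else {
    stopifnot(is.numeric(init), all(nm %in% names(init)))
    U0 <- init[nm]
  }

  if (T == 0) {
    return(structure(list(
      t = numeric(0),
      U = matrix(numeric(0), nrow = 0, ncol = length(nm),
                 dimnames = list(NULL, nm)),
      I_ext = matrix(numeric(0), nrow = 0, ncol = length(stimuli),
                     dimnames = list(NULL, ports)),
      dt = dt), class = "sns_simulation"))
  }
  times <- seq(0, T, by = dt)
  if (times[length(times)] < T) times <- c(times, T)
  # precompiled right-hand side: same membrane equation as
  # neuron_derivative(), flattened to index vectors for speed
  Cm <- vapply(net$neurons, `[[`, 0, "Cm")
  Gm <- vapply(net$neurons, `[[`, 0, "Gm")
  Ia <- vapply(net$neurons, `[[`, 0, "Iapp_tonic")
  ns <- length(net$synapses)
  spre <- match(vapply(net$synapses, `[[`, "", "pre"), nm)
  spost <- match(vapply(net$synapses, `[[`, "", "post"), nm)
  sgs <- vapply(net$synapses, `[[`, 0, "gs")
  sdEs <- vapply(net$synapses, `[[`, 0, "dEs")
  sR <- vapply(net$synapses, `[[`, 0, "R")
  sElo <- vapply(net$synapses, `[[`, 0, "Elo")
  port_idx <- lapply(stimuli, function(s) match(net$inputs[[s$port]], nm))
  deriv <- function(t, y, parms) {
    I <- Ia
    for (k in seq_along(stimuli)) {
      ix <- port_idx[[k]]
      I[ix] <- I[ix] + stimulus_current(stimuli[[k]], t)
    }
    Is <- numeric(length(y))
    if (ns) {
      g <- pmin(pmax(sgs * (y[spre] - sElo) / sR, 0), sgs)
      contrib <- g * (sdEs - y[spost])
      for (k in seq_len(ns)) Is[spost[k]] <- Is[spost[k]] + contrib[k]
    }
    list((-Gm * y + Is + I) / Cm)
  }
  sol <- deSolve::ode(y = unname(U0), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  U <- unname(sol[, -1, drop = FALSE])
  colnames(U) <- nm
  if (any(!is.finite(U))) {
    bad_ix <- which(!is.finite(U), arr.ind = TRUE)[1, ]
    stop("non-finite state at t = ", times[bad_ix[1]], " ms, neuron '",
         nm[bad_ix[2]], "'")
  }
  I_ext <- if (length(stimuli)) {
    m <- vapply(stimuli, function(s) stimulus_current(s, times),
                numeric(length(times)))
    m <- matrix(m, nrow = length(times),
                dimnames = list(NULL, ports))
    m
  } else {
    matrix(numeric(0), nrow = length(times), ncol = 0)
  }
  structure(list(t = times, U = U, I_ext = I_ext, dt = dt),
            class = "sns_simulation")
}

#' @export
print.sns_simulation <- function(x, ...) {
  cat("<sns_simulation> ", length(x$t), " samples, dt = ", x$dt, " ms, ",
      ncol(x$U), " neurons (",
      paste(colnames(x$U), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Plateau heights of a differentiator's ramp response
#'
#' For each ramp segment in a stimulus program, averages the output
#' activation over the window starting `settle * tau_d` after segment onset
#' and extending to the segment's end. A tuned differentiator's plateau is
#' `k_syn_out * (Cm2 - Cm1) * slope`. Segments shorter than
#' `(settle + 1) * tau_d` are flagged `reliable = FALSE`.
#'
#' @param result An `sns_simulation`.
#' @param neuron Output neuron name.
#' @param stim The [stimulus_spec()] that was applied (ramp segments are
#'   located from it).
#' @param tau_d Differentiator time constant, ms.
#' @param settle Settling multiple of `tau_d` before the window opens.
#' @return Data frame with one row per ramp segment: `slope` (nA/ms),
#'   `t_start`, `t_end` (ms), `plateau` (mV), `reliable`.
#' @export
measure_ramp_step_response <- function(result, neuron, stim, tau_d,
                                       settle = 5) {
  stopifnot(inherits(result, "sns_simulation"),
            neuron %in% colnames(result$U),
            inherits(stim, "sns_stimulus"))
  durations <- vapply(stim$segments, `[[`, 0, "duration")
  starts <- cumsum(c(0, durations))
  rows <- list()
  for (i in seq_along(stim$segments)) {
    seg <- stim$segments[[i]]
    if (seg$kind != "ramp") next
    w0 <- starts[i] + settle * tau_d
    w1 <- starts[i + 1]
    reliable <- durations[i] >= (settle + 1) * tau_d
    sel <- result$t >= w0 & result$t <= w1
    plateau <- if (any(sel)) mean(result$U[sel, neuron]) else NA_real_
    rows[[length(rows) + 1]] <-
      data.frame(segment = i, slope = seg$slope, t_start = w0, t_end = w1,
                 plateau = plateau, reliable = reliable & any(sel))
  }
  if (!length(rows))
    stop("stimulus program contains no ramp segments")
  do.call(rbind, rows)
}

#' Integration rate from a simulated trajectory
#'
#' Least-squares slope of a neuron's activation over a time window, used to
#' measure an integrator's response to a constant drive `u` (the slope
#' divided by `u` estimates `k_i`). If the trajectory leaves `[0, R]` inside
#' the window the fit is truncated at the first excursion and flagged.
#'
#' @param result An `sns_simulation`.
#' @param neuron Neuron name.
#' @param t_start,t_end Fit window, ms.
#' @param R Operating range used for the saturation check, mV; `NULL` skips
#'   the check.
#' @return List with `slope` (mV/ms), `truncated` (logical) and `window`
#'   (the ms range actually used).
#' @export
measure_integration_rate <- function(result, neuron, t_start, t_end,
                                     R = NULL) {
  stopifnot(inherits(result, "sns_simulation"),
            neuron %in% colnames(result$U))
  sel <- which(result$t >= t_start & result$t <= t_end)
  if (length(sel) < 3) stop("fit window contains fewer than 3 samples")
  u <- result$U[sel, neuron]
  truncated <- FALSE
  if (!is.null(R)) {
    out <- which(u < 0 | u > R)
    if (length(out)) {
      if (out[1] < 3) stop("trajectory saturated at the window start")
      sel <- sel[seq_len(out[1] - 1)]
      u <- result$U[sel, neuron]
      truncated <- TRUE
      warning("trajectory left [0, R] inside the fit window; fit truncated")
    }
  }
  fit <- stats::lm(u ~ result$t[sel])
  list(slope = unname(stats::coef(fit)[2]), truncated = truncated,
       window = range(result$t[sel]))
}
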