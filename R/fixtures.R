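# Deterministic generators of test networks and oracle values, so the
# whole verification suite runs from formulas with no stored goldens.

#' Independent scalar fixed-point steady state
#'
#' Solves the network equilibrium by plain Jacobi iteration of the
#' single-neuron closed form - every neuron's equilibrium is recomputed
#' from the previous sweep's activations until the update falls below
#' `tol`. Deliberately independent of [steady_state_network()]'s
#' topological/damped solver so the two can cross-check each other.
#'
#' @param net An `sns_network`.
#' @param external Named port currents, nA.
#' @param tol Convergence tolerance, mV.
#' @param max_iter Iteration cap.
#' @return Named equilibrium vector (mV); errors on non-convergence.
#' @export
steady_state_oracle <- function(net, external = numeric(), tol = 1e-12,
                                max_iter = 1e5) {
  nm <- neuron_names(net)
  I <- port_currents(net, external)
  U <- stats::setNames(numeric(length(nm)), nm)
  for (it in seq_len(max_iter)) {
    U_new <- U
    for (v in nm) {
      syns <- Filter(function(s) s$post == v, net$synapses)
      tab <- if (length(syns))
        data.frame(gs = vapply(syns, `[[`, 0, "gs"),
                   dEs = vapply(syns, `[[`, 0, "dEs"),
                   U_pre = vapply(syns, function(s) U[[s$pre]], 0),
                   R = vapply(syns, `[[`, 0, "R"))
      n <- net$neurons[[v]]
      U_new[v] <- steady_state_neuron(tab, Iapp = n$Iapp_tonic + I[[v]],
                                      Gm = n$Gm)
    }
    if (max(abs(U_new - U)) < tol) return(U_new)
    U <- U_new
  }
  stop("oracle fixed point did not converge in ", max_iter, " iterations")
}

#' Worked example designs with closed-form oracle values
#'
#' The six subnetwork designs at their conventional biophysical parameter
#' values (R = 20 mV; excitatory reversal 194 mV; inhibitory -40 mV;
#' shunting -1 mV), each carrying the conductances and derived quantities
#' its tuning formulas imply, recomputed at call time.
#'
#' @return Named list of fixture cases; each has `name`, `report`, and an
#'   `oracle` list of expected values with `tolerance`.
#' @export
worked_examples <- function() {
  list(
    addition = list(
      name = "addition",
      report = design_addition(1, 1, R = 20, dEs1 = 194, dEs2 = 194),
      oracle = list(gs1 = 20 / 174, gs2 = 20 / 174, gs1_nS = 115,
                    tolerance = 1e-12)
    ),
    subtraction = list(
      name = "subtraction",
      report = design_subtraction(1, R = 20, dEs1 = 194, dEs2 = -40),
      oracle = list(gs1 = 20 / 174, gs2 = (194 / 40) * (20 / 174),
                    gs2_nS_sequential = 558, tolerance = 1e-12)
    ),
    division = list(
      name = "division",
      report = design_division(0.05, R = 20, dEs1 = 194),
      oracle = list(gs2 = 19, tolerance = 1e-12)
    ),
    multiplication = list(
      name = "multiplication",
      report = design_multiplication(R = 20, dEs1 = 194, dEs23 = -1),
      oracle = list(gs2 = 20, dEs2 = -1, tolerance = 1e-12)
    ),
    differentiation = list(
      name = "differentiation",
      report = design_differentiator(k_d = 0.5, tau_d = 1, R = 20),
      oracle = list(Cm1 = 500, Cm2 = 1000, omega_c = 1, tolerance = 1e-12)
    ),
    integration = list(
      name = "integration",
      report = design_integrator(k_i_mean = 0.1, k_i_range = 0.1, R = 20),
      oracle = list(Cm = 5, gs = 2, dEs = -10, gs_dEs = -20,
                    tolerance = 1e-12)
    )
  )
}

#' Seeded corpus of random feasible designs
#'
#' Draws arithmetic designs with functional parameters sampled from
#' feasible ranges (`k_syn` in `[0.2, 1.5]`, `R` in `{10, 20, 40}`,
#' `c_syn` in `[0.05, 0.9]`, reversal potentials clear of the feasibility
#' boundaries); infeasible draws are rejected and resampled. The same seed
#' always yields the identical corpus. Each case carries random input
#' activations in `[0, R]^2` for steady-state cross-checks.
#'
#' @param seed Integer RNG seed.
#' @param n Number of cases (`n = 0` gives an empty list).
#' @return List of cases: `name`, `kind`, `report`, `inputs` (named
#'   `c(in1=, in2=)`).
#' @export
random_feasible_designs <- function(seed = 20170809, n = 20) {
  stopifnot(n >= 0)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  kinds <- c("addition", "subtraction", "division", "multiplication")
  i <- 0
  while (i < n) {
    kind <- sample(kinds, 1)
    R <- sample(c(10, 20, 40), 1)
    report <- tryCatch(switch(kind,
      addition = {
        k1 <- stats::runif(1, 0.2, 1.5); k2 <- stats::runif(1, 0.2, 1.5)
        dEs1 <- stats::runif(1, k1 * R + 20, 400)
        dEs2 <- stats::runif(1, k2 * R + 20, 400)
        design_addition(k1, k2, R, dEs1, dEs2)
      },
      subtraction = {
        k <- stats::runif(1, 0.2, 1.5)
        design_subtraction(k, R, dEs1 = stats::runif(1, k * R + 20, 400),
                           dEs2 = stats::runif(1, -80, -10))
      },
      division = design_division(stats::runif(1, 0.05, 0.9), R,
                                 dEs1 = stats::runif(1, R + 20, 400)),
      multiplication = design_multiplication(
        R, dEs1 = stats::runif(1, R + 20, 400),
        dEs23 = stats::runif(1, -5, -0.5))
    ), error = function(e) NULL)
    if (is.null(report) || !design_valid(report)) next  # reject, resample
    i <- i + 1
    out[[i]] <- list(
      name = sprintf("%s_%03d", kind, i), kind = kind, report = report,
      inputs = c(in1 = stats::runif(1, 0, R), in2 = stats::runif(1, 0, R))
    )
  }
  out
}

#' Run the built-in verification fixtures
#'
#' Recomputes every worked example's oracle values and checks the design
#' reports against them.
#'
#' @return Data frame with columns `case`, `quantity`, `expected`,
#'   `actual`, `pass`.
#' @export
run_verification <- function() {
  rows <- list()
  add_row <- function(case, quantity, expected, actual, tol) {
    rows[[length(rows) + 1]] <<- data.frame(
      case = case, quantity = quantity, expected = expected,
      actual = actual, pass = abs(actual - expected) <= tol)
  }
  ex <- worked_examples()
  for (case in ex) {
    d <- case$report$derived
    o <- case$oracle
    tol <- o$tolerance
    for (q in setdiff(names(o), "tolerance")) {
      actual <- switch(q,
        gs1_nS = round(d$gs1 * 1000),
        gs2_nS_sequential = as.numeric(sub(" nS", "", case$report$display$gs2)),
        gs_dEs = d$gs * d$dEs,
        omega_c = case$report$functional$omega_c,
        d[[q]])
      add_row(case$name, q, o[[q]],
              actual, if (grepl("nS", q)) 0.5 else tol)
    }
    valid <- design_valid(case$report)
    add_row(case$name, "constraints_satisfied", 1, as.numeric(valid), 0)
  }
  do.call(rbind, rows)
}
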