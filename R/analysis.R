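# Verification mathematics: response surfaces against ideal operators,
# linearized frequency response of the differentiator, and
# Jacobian/eigenvalue/k_i analysis of the line-attractor integrator.

#' Ideal operator value for a designed subnetwork
#'
#' The target each arithmetic design approximates:
#' addition `k1*U1 + k2*U2`; subtraction `k_syn*(U1 - U2)`; division
#' `U1 / (1 + (1-c)/(c*R) * U2)`; multiplication the closed-form
#' disinhibition prediction of [predict_multiplication()].
#'
#' @param report An `sns_design` of an arithmetic kind.
#' @param U1,U2 Input activations, mV (vectorized).
#' @return Ideal output activation(s), mV.
#' @export
ideal_operator <- function(report, U1, U2) {
  stopifnot(inherits(report, "sns_design"))
  f <- report$functional
  switch(report$kind,
    addition = f$k_syn_1 * U1 + f$k_syn_2 * U2,
    subtraction = f$k_syn * (U1 - U2),
    division = U1 / (1 + (1 - f$c_syn) / (f$c_syn * f$R) * U2),
    multiplication = predict_multiplication(report, U1, U2),
    stop("no ideal operator for kind '", report$kind, "'"))
}

in_validity_region <- function(kind, U1, U2, R) {
  switch(kind,
    addition = U1 + U2 <= R + 1e-12,
    subtraction = U1 >= U2 - 1e-12,
    rep(TRUE, length(U1)))
}

#' Steady-state response surface of an arithmetic design
#'
#' Evaluates the exact network steady state on an `n_grid x n_grid` lattice
#' over `[0, R]^2` of input activations (injected as port currents, which
#' with `Gm = 1` set the input neurons' equilibria), compares it with the
#' design's ideal operator, and summarises the deviation over the
#' operator's validity region (addition: `U1 + U2 <= R`; subtraction:
#' `U1 >= U2`; division and multiplication: the full square).
#'
#' Deviations are reported full-scale, i.e. as a fraction of `R`; this is
#' the only relative measure that stays finite where the ideal output is
#' zero.
#'
#' @param report An `sns_design` of kind addition, subtraction, division or
#'   multiplication.
#' @param n_grid Lattice points per axis.
#' @return An `sns_surface`: list with `grid` (data.frame `U1, U2, actual,
#'   ideal, in_region`), `max_abs_error` (mV) and `max_rel_error`
#'   (fraction of `R`), both over the validity region.
#' @export
sweep_surface <- function(report, n_grid = 21) {
  stopifnot(inherits(report, "sns_design"),
            report$kind %in% c("addition", "subtraction", "division",
                               "multiplication"))
  R <- report$functional$R
  u <- seq(0, R, length.out = n_grid)
  grid <- expand.grid(U1 = u, U2 = u)
  net <- report$network
  grid$actual <- mapply(function(a, b) {
    ss <- steady_state_network(net, c(in1 = a, in2 = b))
    unname(ss[["post"]])
  }, grid$U1, grid$U2)
  grid$ideal <- ideal_operator(report, grid$U1, grid$U2)
  grid$in_region <- in_validity_region(report$kind, grid$U1, grid$U2, R)
  err <- abs(grid$actual - grid$ideal)[grid$in_region]
  structure(list(kind = report$kind, R = R, grid = grid,
                 max_abs_error = max(err),
                 max_rel_error = max(err) / R),
            class = "sns_surface")
}

#' @export
print.sns_surface <- function(x, ...) {
  cat("<sns_surface> ", x$kind, ": ", nrow(x$grid), " lattice points, ",
      "max |actual - ideal| = ", signif(x$max_abs_error, 4), " mV (",
      signif(100 * x$max_rel_error, 3), "% of R) over the validity region\n",
      sep = "")
  invisible(x)
}

#' Linearized frequency response of the differentiator
#'
#' Transfer function from applied current to output activation of the
#' two-time-constant difference network, treating the subtraction stage as
#' an ideal difference with gain `k_syn_out`:
#' `H(jw) = k_syn_out * (1/(1 + jw*tau1) - 1/(1 + jw*tau2))`,
#' `tau_i = Cm_i / Gm`. At low frequency `|H| -> k_syn_out*(tau2 - tau1)*w`
#' (differentiation); above `omega_c = 1/tau2` the response rolls off,
#' band-limiting the derivative.
#'
#' @param Cm1,Cm2 Membrane capacitances, nF, with `Cm2 > Cm1 > 0`.
#' @param k_syn_out Subtraction-stage gain.
#' @param omega Angular frequency grid, rad/s; defaults to a log grid
#'   spanning `omega_c / 100` to `100 * omega_c`.
#' @return Data frame `omega` (rad/s), `magnitude` (mV per nA),
#'   `magnitude_db`, `phase_deg`, with attributes `omega_c` (rad/s) and
#'   `k_d` (s).
#' @export
bode_differentiator <- function(Cm1, Cm2, k_syn_out = 1, omega = NULL) {
  stopifnot(is.finite(Cm1), is.finite(Cm2), Cm2 > Cm1, Cm1 > 0)
  tau1 <- Cm1 / 1000   # s, under Gm = 1 uS
  tau2 <- Cm2 / 1000
  omega_c <- 1 / tau2
  if (is.null(omega))
    omega <- 10^seq(log10(omega_c) - 2, log10(omega_c) + 2,
                    length.out = 121)
  H <- k_syn_out * (1 / (1 + 1i * omega * tau1) - 1 / (1 + 1i * omega * tau2))
  out <- data.frame(omega = omega, magnitude = Mod(H),
                    magnitude_db = 20 * log10(Mod(H)),
                    phase_deg = Arg(H) * 180 / pi)
  attr(out, "omega_c") <- omega_c
  attr(out, "k_d") <- tau2 - tau1
  out
}

integrator_params <- function(report) {
  stopifnot(inherits(report, "sns_design"), report$kind == "integration")
  list(R = report$functional$R, gs = report$derived$gs,
       dEs = report$derived$dEs, Cm = report$derived$Cm)
}

#' Jacobian, eigenvalues and integration rate of the integrator at a state
#'
#' Builds the drift Jacobian numerically (central differences, exact for
#' this bilinear vector field up to round-off) at the given state,
#' cross-checkable against the analytic form `-(1/Cm) * [[b, a], [b, a]]`
#' with `a = 1 + gs/R * U1`, `b = 1 + gs/R * U2`, which holds when the
#' marginality constraint `gs*dEs = -R` does. Eigenvalues are sorted
#' descending; under the constraint the leading one is zero at *every*
#' state (identical Jacobian rows) and the other is `-(a + b)/Cm`.
#'
#' The state-dependent integration rate is
#' `k_i = a / (Cm * (a + b))`, bounded by `k_i_min = 1/(Cm*(2+gs))` and
#' `k_i_max = (1+gs)/(Cm*(2+gs))`, with mean `1/(2*Cm)` (attained on the
#' symmetric state `U1 = U2`) and range `gs/(Cm*(2+gs)) = k_i_max - k_i_min`.
#'
#' @param report An `sns_design` of kind `"integration"`.
#' @param U1,U2 State at which to evaluate, mV.
#' @return An `sns_integrator_analysis` list: `a`, `b`, `jacobian`,
#'   `jacobian_analytic`, `eigenvalues` (descending), `k_i`, `k_i_min`,
#'   `k_i_max`, `k_i_mean`, `k_i_range`, `marginal` (was `gs*dEs = -R`
#'   satisfied).
#' @export
integrator_analyze <- function(report, U1, U2) {
  p <- integrator_params(report)
  net <- report$network
  marginal <- abs(p$gs * p$dEs + p$R) <= 1e-9 * p$R
  if (!marginal)
    warning("gs*dEs != -R: the design is not marginally stable and the ",
            "leading eigenvalue will not be zero")
  f <- function(x) unname(neuron_derivative(
    net, stats::setNames(x, c("u1", "u2"))))
  x0 <- c(U1, U2)
  J <- matrix(0, 2, 2)
  h <- 1e-4 * pmax(1, abs(x0))
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h[j]
    J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * h[j])
  }
  a <- 1 + p$gs / p$R * U1
  b <- 1 + p$gs / p$R * U2
  J_analytic <- -(1 / p$Cm) * matrix(c(b, b, a, a), 2, 2)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- sort(Re(ev), decreasing = TRUE)
  structure(list(
    a = a, b = b, jacobian = J, jacobian_analytic = J_analytic,
    eigenvalues = ev,
    k_i = a / (p$Cm * (a + b)),
    k_i_min = 1 / (p$Cm * (2 + p$gs)),
    k_i_max = (1 + p$gs) / (p$Cm * (2 + p$gs)),
    k_i_mean = 1 / (2 * p$Cm),
    k_i_range = p$gs / (p$Cm * (2 + p$gs)),
    marginal = marginal
  ), class = "sns_integrator_analysis")
}

#' Equilibrium curve of the integrator
#'
#' The locus of zero-drift states: `U2 = R*(U1 - R) / (gs*(dEs - U1))`.
#' When `gs*dEs = -R` the same curve satisfies both neurons' equilibrium
#' conditions, forming the line attractor. Endpoints: `U1 = R` gives
#' `U2 = 0` and `U1 = 0` gives `U2 = R`. The pole at `U1 = dEs` (negative,
#' outside the operating range) yields `NA` with a warning.
#'
#' @param report An `sns_design` of kind `"integration"`.
#' @param U1 Sample activations, mV.
#' @return `U2` samples, mV.
#' @export
equilibrium_curve <- function(report, U1) {
  p <- integrator_params(report)
  at_pole <- abs(p$dEs - U1) < 1e-12 * max(1, abs(p$dEs))
  if (any(at_pole))
    warning("equilibrium curve pole at U1 = dEs = ", p$dEs, " mV")
  U2 <- p$R * (U1 - p$R) / (p$gs * (p$dEs - U1))
  U2[at_pole] <- NA_real_
  U2
}

#' Variation of the multiplication output denominator
#'
#' The closed-form output of the multiplication network treats the
#' transmitted input as an equivalent applied current, dropping its
#' `gs1*U1/R` contribution to the output-neuron denominator. This measures
#' the largest percent change of that denominator, `(1 - R/dEs) +
#' gs1*U1/R`, across the transmitted input's full range `U1` in `[0, R]`,
#' relative to its value at `U1 = 0` - the quantity that justifies the
#' approximation (about 0.55% with the default parameters).
#'
#' @param report An `sns_design` of kind `"multiplication"`.
#' @param n Grid points over `[0, R]`.
#' @return Maximum percent change (%).
#' @export
multiplication_denominator_variation <- function(report, n = 2001) {
  stopifnot(inherits(report, "sns_design"), report$kind == "multiplication")
  R <- report$functional$R
  gs1 <- report$derived$gs1
  dEs <- report$derived$dEs2
  U1 <- seq(0, R, length.out = n)
  den <- (1 - R / dEs) + gs1 * U1 / R
  100 * max(abs(den - den[1]) / den[1])
}
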