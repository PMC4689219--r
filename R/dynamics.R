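#' Right-hand side of the fate-switch circuit
#'
#' Instantaneous rates of change of the three state variables: NANOG `N`,
#' endogenous GATA `G`, and exogenous GATA `G_X`. Exogenous and endogenous
#' GATA repress NANOG through their sum, reflecting that the induced GATA
#' factor substitutes for the endogenous one in the circuit.
#'
#' @param state Named or unnamed numeric triple `(N, G, G_X)`, all >= 0.
#' @param t Time \[h\]; only used to evaluate the pulse indicator.
#' @param params A [fate_model()] object.
#' @param dose Maximum exogenous production rate `D` \[conc/h\] while the
#'   pulse is on.
#' @param protocol A [pulse_protocol()]; when `NULL` the drive is off and
#'   the system is autonomous.
#' @return Numeric triple `c(dN, dG, dG_X)` \[conc/h\].
#' @examples
#' m <- fate_model()
#' circuit_rates(c(0, 0, 0), 0, m)           # empty-cell production rates
#' circuit_rates(c(2, 0, 0), 1, m, dose = 0.3, protocol = pulse_protocol())
#' @export
circuit_rates <- function(state, t, params, dose = 0, protocol = NULL) {
  check_flag_class(params, "fate_model")
  if (length(state) != 3L || anyNA(state))
    stop("'state' must be a numeric triple (N, G, G_X)", call. = FALSE)
  if (any(state < 0))
    stop("state components must be non-negative", call. = FALSE)
  on <- !is.null(dose) && dose > 0 && !is.null(protocol) &&
    t >= protocol$t_start && t < protocol$t_end
  rates_raw(state, params, if (on) dose else 0)
}

# Unchecked core used by the integrator; `input` is the current exogenous
# production rate (dose during the pulse, 0 otherwise).
rates_raw <- function(state, params, input) {
  N <- state[[1L]]; G <- state[[2L]]; GX <- state[[3L]]
  c(params$alpha_N * fs_nanog(params) /
      (1 + ((G + GX) / params$K_GN)^params$h_N) - params$gamma_N * N,
    params$alpha_G * fs_gata(params) /
      (1 + (N / params$K_NG)^params$h_G) - params$gamma_G * G,
    input - params$gamma_X * GX)
}

#' NANOG steady state of the GATA-free circuit
#'
#' The NANOG level at which production and degradation balance when both
#' GATA species are absent: `alpha_N * f_N(s) / gamma_N`. Evaluated at
#' `s = 0` (no MAPK signaling) this is the pre-culture NANOG level used as
#' the default initial condition, reflecting cells kept in a MEK inhibitor
#' before induction.
#'
#' @inheritParams circuit_rates
#' @return NANOG concentration \[conc\].
#' @examples
#' autonomous_steady_nanog(fate_model(mode = "none"))  # alpha_N / gamma_N
#' @export
autonomous_steady_nanog <- function(params) {
  check_flag_class(params, "fate_model")
  params$alpha_N * fs_nanog(params) / params$gamma_N
}

# Pre-culture initial state: NANOG at its signaling-free steady level,
# no endogenous or exogenous GATA (MEK-inhibitor pre-culture convention).
preculture_state <- function(params) {
  p0 <- params
  p0$s <- 0
  c(N = autonomous_steady_nanog(p0), G = 0, G_X = 0)
}

#' Closed-form exogenous GATA pulse response
#'
#' The exogenous species obeys a linear ODE decoupled from the rest of the
#' circuit, so its pulse response is available in closed form: exponential
#' rise toward `dose/gamma_X` during the pulse, exponential decay after.
#'
#' @param t Numeric vector of times \[h\].
#' @param dose Maximum exogenous production rate `D` \[conc/h\].
#' @param gamma_X Degradation rate of the exogenous species \[1/h\].
#' @param protocol A [pulse_protocol()].
#' @return `G_X(t)` for each time.
#' @examples
#' gx_pulse(c(0, 3, 6, 12), dose = 0.3, gamma_X = 0.5, pulse_protocol())
#' @export
gx_pulse <- function(t, dose, gamma_X, protocol) {
  check_flag_class(protocol, "pulse_protocol")
  tt <- pmax(t - protocol$t_start, 0)
  dur <- protocol$t_end - protocol$t_start
  peak <- dose / gamma_X * (1 - exp(-gamma_X * dur))
  ifelse(tt < dur,
         dose / gamma_X * (1 - exp(-gamma_X * tt)),
         peak * exp(-gamma_X * (tt - dur)))
}

# Integrate one piecewise-constant-input segment with lsoda.
ode_segment <- function(y0, times, params, input, rtol, atol, rootfun = NULL) {
  f <- function(t, y, parms) list(rates_raw(y, params, input))
  if (is.null(rootfun)) {
    deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol)
  } else {
    deSolve::lsodar(y = y0, times = times, func = f, parms = NULL,
                    rtol = rtol, atol = atol, rootfunc = rootfun)
  }
}

#' Simulate one cell through a pulse-chase protocol
#'
#' Integrates the three-variable circuit for a single cell with a given
#' exogenous dose, using an adaptive stiff-capable solver (`lsoda`). The
#' integration is split at the pulse boundaries so the input discontinuity
#' never falls inside an adaptive step.
#'
#' @inheritParams circuit_rates
#' @param times Strictly increasing sampling grid \[h\], within
#'   `[t_start or earlier, t_final]`.
#' @param initial Initial state `(N, G, G_X)`; default is the pre-culture
#'   state `(alpha_N/gamma_N, 0, 0)`.
#' @param rtol,atol Solver tolerances.
#' @return A `"cell_trace"`: a data frame with columns `time`, `N`, `G`,
#'   `G_X`, carrying the dose, parameters and protocol as attributes.
#' @examples
#' tr <- simulate_cell(fate_model(), dose = 0.3, pulse_protocol(),
#'                     times = seq(0, 30, by = 0.5))
#' head(tr)
#' @export
simulate_cell <- function(params, dose, protocol, times, initial = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  check_flag_class(params, "fate_model")
  check_flag_class(protocol, "pulse_protocol")
  check_number(dose, "dose", lower = 0)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be a strictly increasing grid of length >= 2",
         call. = FALSE)
  if (max(times) > protocol$t_final + 1e-9)
    stop("'times' must not extend beyond t_final", call. = FALSE)
  initial <- initial %||% preculture_state(params)
  if (length(initial) != 3L || any(initial < 0))
    stop("'initial' must be a non-negative triple (N, G, G_X)", call. = FALSE)
  y0 <- c(N = unname(initial[[1L]]), G = unname(initial[[2L]]),
          G_X = unname(initial[[3L]]))

  cuts <- c(protocol$t_start, protocol$t_end)
  knots <- sort(unique(c(times, cuts[cuts > min(times) & cuts < max(times)])))
  out <- matrix(NA_real_, nrow = length(knots), ncol = 3L,
                dimnames = list(NULL, names(y0)))
  seg_edges <- sort(unique(c(min(times), cuts[cuts > min(times) & cuts < max(times)],
                             max(times))))
  y <- y0
  for (i in seq_len(length(seg_edges) - 1L)) {
    a <- seg_edges[i]; b <- seg_edges[i + 1L]
    seg_times <- knots[knots >= a - 1e-12 & knots <= b + 1e-12]
    if (length(seg_times) < 2L) seg_times <- c(a, b)
    input <- if (a >= protocol$t_start && a < protocol$t_end) dose else 0
    sol <- ode_segment(y, seg_times, params, input, rtol, atol)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("integration failed for dose %g", dose), call. = FALSE)
    idx <- match(round(seg_times, 12), round(knots, 12))
    out[idx, ] <- sol[, -1L, drop = FALSE]
    y <- sol[nrow(sol), -1L]
  }
  keep <- match(round(times, 12), round(knots, 12))
  df <- data.frame(time = times, N = out[keep, "N"], G = out[keep, "G"],
                   G_X = out[keep, "G_X"])
  # clip solver-tolerance undershoots
  df$N <- pmax(df$N, 0); df$G <- pmax(df$G, 0); df$G_X <- pmax(df$G_X, 0)
  structure(df, dose = dose, params = params, protocol = protocol,
            class = c("cell_trace", "data.frame"))
}

# Extend an autonomous (input-off) integration until the rate norm drops
# below `tol` or `t_max` is reached; returns final state and convergence flag.
settle_state <- function(state, params, t_max = 300, tol = 1e-6,
                         rtol = 1e-8, atol = 1e-10) {
  y0 <- c(N = unname(state[[1L]]), G = unname(state[[2L]]),
          G_X = if (length(state) >= 3L) unname(state[[3L]]) else 0)
  root <- function(t, y, parms)
    sqrt(sum(rates_raw(y, params, 0)^2)) - tol
  sol <- ode_segment(y0, c(0, t_max), params, 0, rtol, atol, rootfun = root)
  yf <- sol[nrow(sol), -1L]
  list(state = pmax(yf, 0),
       converged = sqrt(sum(rates_raw(yf, params, 0)^2)) <= tol * 1.01)
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("Single-cell trace: %d frames over [%g, %g] h, dose D = %g\n",
              nrow(x), min(x$time), max(x$time), attr(x, "dose")))
  print.data.frame(utils::head(as.data.frame(x), 4L), row.names = FALSE)
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' @export
plot.cell_trace <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$N, x$G, x$G_X), type = "l", lty = 1,
                    col = c("forestgreen", "purple", "red3"),
                    xlab = "time [h]", ylab = "concentration [a.u.]", ...)
  graphics::legend("topright", c("N", "G", "G_X"), lty = 1,
                   col = c("forestgreen", "purple", "red3"), bty = "n")
  invisible(x)
}
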