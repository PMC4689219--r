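.fs_env <- new.env(parent = emptyenv())

default_config_raw <- function() {
  if (is.null(.fs_env$defaults)) {
    path <- system.file("extdata", "default-config.yaml", package = "fateswitch",
                        mustWork = TRUE)
    .fs_env$defaults <- yaml::read_yaml(path)
  }
  .fs_env$defaults
}

#' Mutual-repression fate-switch model parameters
#'
#' Constructs the parameter set of the three-variable gene-regulatory circuit
#' in which NANOG (`N`) and endogenous GATA (`G`) repress each other through
#' Hill functions, and an exogenous GATA species (`G_X`) produced during an
#' induction pulse adds to the repressive GATA pool. An FGF/MAPK signaling
#' level `s` can couple into the circuit in one of two modes: by inhibiting
#' NANOG production (`"inhibits_nanog"`, the default, reflecting signaling
#' acting on the epiblast program) or by promoting endogenous GATA production
#' (`"promotes_gata"`); `"none"` removes the coupling.
#'
#' The governing equations are
#' \deqn{dN/dt = \alpha_N f_N(s) \frac{1}{1+((G+G_X)/K_{GN})^{h_N}} - \gamma_N N}
#' \deqn{dG/dt = \alpha_G f_G(s) \frac{1}{1+(N/K_{NG})^{h_G}} - \gamma_G G}
#' \deqn{dG_X/dt = D\,u(t) - \gamma_X G_X}
#' with \eqn{f_N(s) = 1/(1+(s/K_s)^m)} in mode `inhibits_nanog` (else 1) and
#' \eqn{f_G(s) = s^m/(K_s^m + s^m)} in mode `promotes_gata` (else 1);
#' \eqn{u(t)} is 1 during the induction pulse and 0 otherwise, and the
#' per-cell maximum exogenous production rate \eqn{D} is the only modeled
#' source of cell-to-cell variability.
#'
#' Defaults are calibrated so that the autonomous circuit is bistable (two
#' stable states, NANOG-high/GATA-low and NANOG-low/GATA-high, separated by a
#' saddle) at saturated signaling, and are read from the packaged
#' configuration file (see [load_config()]).
#'
#' @param alpha_N,alpha_G Maximum production rates \[conc/h\].
#' @param K_GN,K_NG Repression thresholds \[conc\]: total GATA on NANOG, and
#'   NANOG on endogenous GATA.
#' @param h_N,h_G Hill exponents (>= 1).
#' @param gamma_N,gamma_G,gamma_X First-order degradation rates \[1/h\].
#' @param s Signaling level (dimensionless, >= 0; 1 = saturated).
#' @param K_s Signaling half-effect constant.
#' @param m Signaling Hill exponent.
#' @param mode Signaling coupling mode: `"none"`, `"promotes_gata"` or
#'   `"inhibits_nanog"`.
#' @return An object of class `"fate_model"`: a validated named list of
#'   parameters.
#' @examples
#' m <- fate_model()
#' m
#' fate_model(s = 0.25)  # partial MEK inhibition
#' @seealso [pulse_protocol()], [simulate_cell()], [find_equilibria()]
#' @export
fate_model <- function(alpha_N = NULL, alpha_G = NULL, K_GN = NULL, K_NG = NULL,
                       h_N = NULL, h_G = NULL, gamma_N = NULL, gamma_G = NULL,
                       gamma_X = NULL, s = NULL, K_s = NULL, m = NULL,
                       mode = NULL) {
  d <- default_config_raw()$model
  p <- list(
    alpha_N = alpha_N %||% d$alpha_N, alpha_G = alpha_G %||% d$alpha_G,
    K_GN = K_GN %||% d$K_GN, K_NG = K_NG %||% d$K_NG,
    h_N = h_N %||% d$h_N, h_G = h_G %||% d$h_G,
    gamma_N = gamma_N %||% d$gamma_N, gamma_G = gamma_G %||% d$gamma_G,
    gamma_X = gamma_X %||% d$gamma_X,
    s = s %||% d$s, K_s = K_s %||% d$K_s, m = m %||% d$m,
    mode = mode %||% d$mode)
  validate_fate_model(p)
}

validate_fate_model <- function(p) {
  for (nm in c("alpha_N", "alpha_G", "K_GN", "K_NG", "gamma_N", "gamma_G",
               "gamma_X", "K_s"))
    check_number(p[[nm]], nm, lower = 0, strict_lower = TRUE)
  for (nm in c("h_N", "h_G", "m")) check_number(p[[nm]], nm, lower = 1)
  check_number(p$s, "s", lower = 0)
  if (!is.character(p$mode) || length(p$mode) != 1L ||
      !p$mode %in% c("none", "promotes_gata", "inhibits_nanog"))
    stop("'mode' must be one of \"none\", \"promotes_gata\", \"inhibits_nanog\"",
         call. = FALSE)
  structure(p, class = "fate_model")
}

# Signaling attenuation factors on the two production terms.
fs_nanog <- function(params) {
  if (params$mode == "inhibits_nanog")
    1 / (1 + (params$s / params$K_s)^params$m) else 1
}

fs_gata <- function(params) {
  if (params$mode == "promotes_gata")
    params$s^params$m / (params$K_s^params$m + params$s^params$m) else 1
}

#' @export
print.fate_model <- function(x, ...) {
  cat("Mutual-repression fate-switch model\n")
  cat(sprintf("  production : alpha_N = %g, alpha_G = %g [conc/h]\n",
              x$alpha_N, x$alpha_G))
  cat(sprintf("  repression : K_GN = %g, K_NG = %g [conc]; h_N = %g, h_G = %g\n",
              x$K_GN, x$K_NG, x$h_N, x$h_G))
  cat(sprintf("  turnover   : gamma_N = %g, gamma_G = %g, gamma_X = %g [1/h]\n",
              x$gamma_N, x$gamma_G, x$gamma_X))
  cat(sprintf("  signaling  : s = %g, K_s = %g, m = %g, mode = %s\n",
              x$s, x$K_s, x$m, x$mode))
  invisible(x)
}

#' Induction pulse-chase protocol
#'
#' Timing of the doxycycline-like induction pulse driving exogenous GATA
#' production, and the end of the chase period at which populations are
#' scored. The default is a 6 h pulse followed by a chase until 30 h.
#'
#' @param t_start Pulse onset \[h\].
#' @param t_end Pulse offset \[h\]; the pulse interval is half-open,
#'   `[t_start, t_end)`.
#' @param t_final End of simulation \[h\].
#' @return An object of class `"pulse_protocol"`.
#' @examples
#' pulse_protocol()                 # 6 h pulse, 30 h chase
#' pulse_protocol(t_end = 2)        # shorter pulse
#' @export
pulse_protocol <- function(t_start = NULL, t_end = NULL, t_final = NULL) {
  d <- default_config_raw()$protocol
  p <- list(t_start = t_start %||% d$t_start, t_end = t_end %||% d$t_end,
            t_final = t_final %||% d$t_final)
  for (nm in names(p)) check_number(p[[nm]], nm)
  if (!(p$t_start < p$t_end && p$t_end <= p$t_final))
    stop("protocol must satisfy t_start < t_end <= t_final", call. = FALSE)
  structure(p, class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("Pulse protocol: induction [%g, %g) h, chase until %g h\n",
              x$t_start, x$t_end, x$t_final))
  invisible(x)
}

#' Per-cell dose distribution of the exogenous drive
#'
#' Distribution of the maximum exogenous GATA transcription rate `D` across
#' cells — the only source of cell-to-cell variability in the model. The
#' default is long-tailed log-normal, mimicking the broad induced-reporter
#' distributions seen by flow cytometry, with its median placed near the
#' critical dose at saturated signaling so that a standard pulse splits a
#' population into both fates.
#'
#' @param family `"lognormal"`, `"uniform"` or `"fixed"`.
#' @param location Log-mean (lognormal), midpoint (uniform) or the common
#'   value (fixed).
#' @param scale Log-sd (lognormal) or half-width (uniform); ignored for
#'   `"fixed"`.
#' @return An object of class `"dose_distribution"`.
#' @examples
#' dose_distribution()
#' dose_distribution("fixed", location = 0.5)
#' @export
dose_distribution <- function(family = NULL, location = NULL, scale = NULL) {
  d <- default_config_raw()$population
  family <- family %||% d$dose_family
  if (!is.character(family) || length(family) != 1L ||
      !family %in% c("lognormal", "uniform", "fixed"))
    stop("'family' must be one of \"lognormal\", \"uniform\", \"fixed\"",
         call. = FALSE)
  location <- location %||% d$dose_location
  scale <- scale %||% d$dose_scale
  check_number(location, "location")
  check_number(scale, "scale", lower = 0)
  if (family == "fixed") check_number(location, "location", lower = 0)
  if (family == "uniform" && location - scale < 0)
    stop("uniform dose distribution must have location - scale >= 0 ",
         "(doses are non-negative)", call. = FALSE)
  structure(list(family = family, location = location, scale = scale),
            class = "dose_distribution")
}

#' @export
print.dose_distribution <- function(x, ...) {
  cat(sprintf("Dose distribution: %s(location = %g, scale = %g)\n",
              x$family, x$location, x$scale))
  invisible(x)
}

#' Measurement noise model for synthetic data
#'
#' Multiplicative log-normal intensity noise plus an additive Gaussian
#' background, with an optional probability that a recorded end-point fate
#' label is wrong. A measured intensity is
#' `x * exp(e) + b`, with `e ~ N(0, sigma_mult)` and
#' `b ~ N(background, background_sd)`.
#'
#' @param sigma_mult Log-sd of the multiplicative noise (>= 0).
#' @param background Mean additive background \[a.u.\].
#' @param background_sd Background sd \[a.u.\].
#' @param label_flip Probability in \[0, 0.5) that a fate label is flipped.
#' @return An object of class `"noise_model"`.
#' @examples
#' noise_model()
#' noise_model(sigma_mult = 0, background = 0, background_sd = 0)  # noise-free
#' @export
noise_model <- function(sigma_mult = NULL, background = NULL,
                        background_sd = NULL, label_flip = NULL) {
  d <- default_config_raw()$noise
  p <- list(sigma_mult = sigma_mult %||% d$sigma_mult,
            background = background %||% d$background,
            background_sd = background_sd %||% d$background_sd,
            label_flip = label_flip %||% d$label_flip)
  check_number(p$sigma_mult, "sigma_mult", lower = 0)
  check_number(p$background, "background")
  check_number(p$background_sd, "background_sd", lower = 0)
  check_number(p$label_flip, "label_flip", lower = 0, upper = 0.5 - 1e-12)
  structure(p, class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "Noise model: sigma_mult = %g, background = %g +/- %g, label_flip = %g\n",
    x$sigma_mult, x$background, x$background_sd, x$label_flip))
  invisible(x)
}

#' @export
coef.fate_model <- function(object, ...) {
  unlist(object[vapply(object, is.numeric, logical(1L))])
}

#' Simulate cell populations from a fate-switch model
#'
#' [stats::simulate()] method: draws `nsim` cells through the pulse-chase
#' protocol. A thin wrapper around [simulate_population()].
#'
#' @param object A [fate_model()].
#' @param nsim Number of cells.
#' @param seed Optional integer seed.
#' @param protocol A [pulse_protocol()].
#' @param dist A [dose_distribution()].
#' @param ... Passed on to [simulate_population()].
#' @return A `"fate_population"` object.
#' @examples
#' pop <- simulate(fate_model(), nsim = 4, seed = 1)
#' @export
simulate.fate_model <- function(object, nsim = 1, seed = NULL,
                                protocol = pulse_protocol(),
                                dist = dose_distribution(), ...) {
  simulate_population(object, protocol, dist, n = nsim, seed = seed, ...)
}
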