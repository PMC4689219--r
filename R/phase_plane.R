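#' Default phase-plane bounds
#'
#' Rectangle `[0, 1.5 alpha_N/gamma_N] x [0, 1.5 alpha_G/gamma_G]` in the
#' autonomous `(N, G)` plane, comfortably enclosing all nullcline
#' intersections at any signaling level.
#'
#' @inheritParams circuit_rates
#' @param factor Multiple of the uncoupled maximum levels to cover.
#' @return List with components `N` and `G`, each a `c(lower, upper)` range.
#' @examples
#' phase_bounds(fate_model())
#' @export
phase_bounds <- function(params, factor = 1.5) {
  check_flag_class(params, "fate_model")
  list(N = c(0, factor * params$alpha_N / params$gamma_N),
       G = c(0, factor * params$alpha_G / params$gamma_G))
}

check_bounds <- function(bounds) {
  if (!is.list(bounds) || !all(c("N", "G") %in% names(bounds)) ||
      length(bounds$N) != 2L || length(bounds$G) != 2L ||
      bounds$N[2L] <= bounds$N[1L] || bounds$G[2L] <= bounds$G[1L])
    stop("'bounds' must be list(N = c(lo, hi), G = c(lo, hi)) with lo < hi",
         call. = FALSE)
  invisible(bounds)
}

# Autonomous (G_X = 0) rate field; N, G may be vectors.
rate_field <- function(N, G, params) {
  list(dN = params$alpha_N * fs_nanog(params) /
         (1 + (G / params$K_GN)^params$h_N) - params$gamma_N * N,
       dG = params$alpha_G * fs_gata(params) /
         (1 + (N / params$K_NG)^params$h_G) - params$gamma_G * G)
}

# Analytic Jacobian of the autonomous system at (N, G).
circuit_jacobian <- function(N, G, params) {
  A <- params$alpha_N * fs_nanog(params)
  B <- params$alpha_G * fs_gata(params)
  rG <- (G / params$K_GN)^params$h_N
  rN <- (N / params$K_NG)^params$h_G
  dNdG <- if (G > 0) -A * params$h_N * rG / (G * (1 + rG)^2) else 0
  dGdN <- if (N > 0) -B * params$h_G * rN / (N * (1 + rN)^2) else 0
  matrix(c(-params$gamma_N, dGdN, dNdG, -params$gamma_G), 2L, 2L)
}

#' Nullclines of the autonomous circuit
#'
#' Zero-rate curves of the two-variable system with no exogenous drive.
#' Both nullclines are explicit: on the NANOG nullcline
#' `N = alpha_N f_N(s) / (gamma_N (1 + (G/K_GN)^h_N))`, and symmetrically
#' for the GATA nullcline. Their intersections are the equilibria.
#'
#' @inheritParams circuit_rates
#' @param bounds Rectangle as from [phase_bounds()] (the default).
#' @param resolution Number of points per curve.
#' @return List with elements `N` and `G`, each a data frame of `(N, G)`
#'   points tracing the corresponding nullcline inside `bounds`.
#' @examples
#' nc <- nullclines(fate_model())
#' head(nc$N)
#' @export
nullclines <- function(params, bounds = phase_bounds(params),
                       resolution = 200) {
  check_flag_class(params, "fate_model")
  check_bounds(bounds)
  check_number(resolution, "resolution", lower = 2)
  A <- params$alpha_N * fs_nanog(params)
  B <- params$alpha_G * fs_gata(params)
  Gg <- seq(bounds$G[1L], bounds$G[2L], length.out = resolution)
  Ng <- seq(bounds$N[1L], bounds$N[2L], length.out = resolution)
  ncN <- data.frame(N = A / (params$gamma_N * (1 + (Gg / params$K_GN)^params$h_N)),
                    G = Gg)
  ncG <- data.frame(N = Ng,
                    G = B / (params$gamma_G * (1 + (Ng / params$K_NG)^params$h_G)))
  list(N = ncN[ncN$N >= bounds$N[1L] & ncN$N <= bounds$N[2L], ],
       G = ncG[ncG$G >= bounds$G[1L] & ncG$G <= bounds$G[2L], ])
}

#' Equilibria of the autonomous circuit
#'
#' Finds all intersections of the two nullclines inside `bounds`, refines
#' each with a damped Newton iteration on the analytic Jacobian, and
#' classifies stability from the Jacobian eigenvalues. In the bistable
#' regime the circuit has exactly three equilibria: a stable
#' NANOG-high/GATA-low (epiblast-like) state, a saddle, and a stable
#' NANOG-low/GATA-high (primitive-endoderm-like) state.
#'
#' @inheritParams nullclines
#' @param scan_resolution Grid size of the initial sign-change scan.
#' @return A data frame of class `"equilibrium_set"` with columns `N`, `G`,
#'   `stability` (`"stable"`, `"saddle"` or `"unstable"`), and complex
#'   eigenvalue columns `eig1`, `eig2`, sorted by `N` descending.
#' @examples
#' find_equilibria(fate_model())
#' @export
find_equilibria <- function(params, bounds = phase_bounds(params),
                            scan_resolution = 400) {
  check_flag_class(params, "fate_model")
  check_bounds(bounds)
  A <- params$alpha_N * fs_nanog(params)
  B <- params$alpha_G * fs_gata(params)
  # Along the G nullcline G(N) is explicit; equilibria are roots of the
  # N-rate restricted to that curve (1-D problem), then refined in 2-D.
  g_of_n <- function(N) B / (params$gamma_G * (1 + (N / params$K_NG)^params$h_G))
  f <- function(N) {
    G <- g_of_n(N)
    A / (1 + (G / params$K_GN)^params$h_N) - params$gamma_N * N
  }
  Ns <- seq(max(bounds$N[1L], 0), bounds$N[2L], length.out = scan_resolution)
  v <- vapply(Ns, f, numeric(1L))
  flips <- which(diff(sign(v)) != 0)
  seeds <- lapply(flips, function(i) {
    r <- stats::uniroot(f, c(Ns[i], Ns[i + 1L]), tol = 1e-13)$root
    c(N = r, G = g_of_n(r))
  })
  # damped Newton refinement of the 2-D rate field
  refine <- function(x) {
    for (iter in 1:60) {
      rf <- rate_field(x[1L], x[2L], params)
      r <- c(rf$dN, rf$dG)
      if (sqrt(sum(r^2)) < 1e-12) break
      J <- circuit_jacobian(x[1L], x[2L], params)
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        xn <- pmax(x - lam * step, 0)
        rn <- rate_field(xn[1L], xn[2L], params)
        if (sqrt(rn$dN^2 + rn$dG^2) <= sqrt(sum(r^2)) || lam < 1e-4) break
        lam <- lam / 2
      }
      x <- xn
    }
    rf <- rate_field(x[1L], x[2L], params)
    if (sqrt(rf$dN^2 + rf$dG^2) >= 1e-10) NULL else x
  }
  eqs <- list()
  for (sd in seeds) {
    x <- refine(sd)
    if (is.null(x)) {
      warning("root refinement did not converge from a seed; seed discarded")
      next
    }
    dup <- any(vapply(eqs, function(e)
      sqrt(sum((e - x)^2)) < 1e-6, logical(1L)))
    if (!dup &&
        x[1L] >= bounds$N[1L] - 1e-9 && x[1L] <= bounds$N[2L] + 1e-9 &&
        x[2L] >= bounds$G[1L] - 1e-9 && x[2L] <= bounds$G[2L] + 1e-9)
      eqs[[length(eqs) + 1L]] <- x
  }
  if (length(eqs) == 0L)
    stop("no equilibria found inside bounds: model misconfigured",
         call. = FALSE)
  rows <- lapply(eqs, function(x) {
    ev <- eigen(circuit_jacobian(x[1L], x[2L], params),
                only.values = TRUE)$values
    ev <- ev[order(Re(ev), decreasing = TRUE)]
    re <- Re(ev)
    if (any(abs(re) <= 1e-9))
      stop("marginal equilibrium (eigenvalue real part ~ 0): ",
           "system at a bifurcation", call. = FALSE)
    stab <- if (all(re < 0)) "stable" else if (prod(re) < 0) "saddle"
            else "unstable"
    data.frame(N = x[1L], G = x[2L], stability = stab,
               eig1 = as.complex(ev[1L]), eig2 = as.complex(ev[2L]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$N, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, params = params, bounds = bounds,
            class = c("equilibrium_set", "data.frame"))
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("Equilibria of the autonomous circuit (%d found)\n", nrow(x)))
  df <- data.frame(N = signif(x$N, 6), G = signif(x$G, 6),
                   stability = x$stability,
                   "Re(eig)" = sprintf("%.4g, %.4g", Re(x$eig1), Re(x$eig2)),
                   check.names = FALSE)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

the_saddle <- function(eqs) {
  sad <- which(eqs$stability == "saddle")
  if (length(sad) == 0L) stop("no saddle point in bounds", call. = FALSE)
  if (length(sad) > 1L)
    stop("more than one saddle found: outside model scope", call. = FALSE)
  c(N = eqs$N[sad], G = eqs$G[sad])
}

stable_attractors <- function(eqs) {
  st <- eqs[eqs$stability == "stable", , drop = FALSE]
  if (nrow(st) == 0L) stop("no stable equilibrium found", call. = FALSE)
  st
}

# Classify a settled (N, G) point by its nearest stable equilibrium;
# returns "GATA_high" or "NANOG_high".
classify_attractor <- function(N, G, attractors) {
  d2 <- (attractors$N - N)^2 + (attractors$G - G)^2
  a <- attractors[which.min(d2), ]
  if (a$G > a$N) "GATA_high" else "NANOG_high"
}

#' Separatrix of the bistable circuit
#'
#' The stable manifold of the saddle: the boundary in the `(N, G)` plane
#' separating initial conditions that flow to the NANOG-high state from
#' those that flow to the GATA-high state. Computed by integrating the
#' time-reversed flow from two points offset by `eps` along the saddle's
#' stable eigenvector, truncated at `bounds`.
#'
#' @inheritParams nullclines
#' @param eps Offset of the two seeds from the saddle.
#' @param t_max Maximum (reversed) integration time \[h\].
#' @return Data frame of `(N, G)` points tracing the separatrix, with the
#'   saddle location as attribute `"saddle"`.
#' @examples
#' sep <- separatrix(fate_model())
#' head(sep)
#' @export
separatrix <- function(params, bounds = phase_bounds(params), eps = 1e-5,
                       t_max = 400) {
  check_flag_class(params, "fate_model")
  check_bounds(bounds)
  eqs <- find_equilibria(params, bounds)
  sad <- the_saddle(eqs)
  J <- circuit_jacobian(sad["N"], sad["G"], params)
  ed <- eigen(J)
  stable_idx <- which.min(Re(ed$values))
  if (Re(ed$values[stable_idx]) >= 0)
    stop("saddle has no stable eigendirection", call. = FALSE)
  v <- Re(ed$vectors[, stable_idx]); v <- v / sqrt(sum(v^2))
  pad <- 1e-9
  rev_f <- function(t, y, parms) {
    rf <- rate_field(y[1L], y[2L], params)
    list(c(-rf$dN, -rf$dG))
  }
  out_of_bounds <- function(t, y, parms)
    min(y[1L] - bounds$N[1L], bounds$N[2L] - y[1L],
        y[2L] - bounds$G[1L], bounds$G[2L] - y[2L]) + pad
  branch <- function(sgn) {
    y0 <- c(sad["N"], sad["G"]) + sgn * eps * v
    sol <- deSolve::lsodar(y = y0, times = seq(0, t_max, by = 0.05),
                           func = rev_f, parms = NULL, rtol = 1e-9,
                           atol = 1e-11, rootfunc = out_of_bounds)
    sol[, -1L, drop = FALSE]
  }
  b1 <- branch(+1); b2 <- branch(-1)
  pts <- rbind(b2[rev(seq_len(nrow(b2))), , drop = FALSE],
               matrix(sad, 1L, 2L), b1)
  df <- data.frame(N = pts[, 1L], G = pts[, 2L])
  df <- df[df$N >= bounds$N[1L] - 1e-6 & df$N <= bounds$N[2L] + 1e-6 &
             df$G >= bounds$G[1L] - 1e-6 & df$G <= bounds$G[2L] + 1e-6, ]
  rownames(df) <- NULL
  structure(df, saddle = sad, params = params, bounds = bounds)
}

#' Fraction of phase space draining to the GATA-high attractor
#'
#' Forward-integrates a regular lattice of initial conditions in `bounds`
#' until convergence and reports the fraction of points whose trajectory
#' reaches the GATA-high (primitive-endoderm-like) attractor. The relative
#' basin size shrinks as MAPK signaling is lowered in the NANOG-inhibition
#' coupling mode.
#'
#' @inheritParams nullclines
#' @param resolution Lattice points per axis.
#' @param t_max Integration-time cap per point \[h\].
#' @return Fraction in \[0, 1\]; the number of non-converged points is
#'   attached as attribute `"unresolved"` (they are excluded from the
#'   denominator).
#' @examples
#' basin_fraction(fate_model(), resolution = 8)
#' @export
basin_fraction <- function(params, bounds = phase_bounds(params),
                           resolution = 25, t_max = 300) {
  check_flag_class(params, "fate_model")
  check_bounds(bounds)
  check_number(resolution, "resolution", lower = 2)
  eqs <- find_equilibria(params, bounds)
  att <- stable_attractors(eqs)
  Ns <- seq(bounds$N[1L], bounds$N[2L], length.out = resolution)
  Gs <- seq(bounds$G[1L], bounds$G[2L], length.out = resolution)
  gata <- 0L; tot <- 0L; unresolved <- 0L
  for (N0 in Ns) for (G0 in Gs) {
    st <- settle_state(c(N0, G0, 0), params, t_max = t_max)
    if (!st$converged) { unresolved <- unresolved + 1L; next }
    tot <- tot + 1L
    if (classify_attractor(st$state[[1L]], st$state[[2L]], att) == "GATA_high")
      gata <- gata + 1L
  }
  if (tot == 0L) stop("no trajectory converged within t_max", call. = FALSE)
  structure(gata / tot, unresolved = unresolved)
}

#' Path-integral quasi-potential landscape
#'
#' Estimates a quasi-potential surface `U(N, G)` for the autonomous circuit
#' by the path-integral construction: trajectories are launched from a
#' uniform lattice of initial points, and along each trajectory the
#' potential decreases by the squared speed, `dU = -||v||^2 dt`, so `U`
#' is non-increasing along the flow and the attractors sit at local minima.
#' Per-basin surfaces (cell-wise minima over trajectories, each trajectory
#' anchored at 0 on its attractor) are aligned by matching their values at
#' the saddle's grid cell, then the global minimum is shifted to 0.
#'
#' @inheritParams nullclines
#' @param resolution Grid cells per axis of the output surface.
#' @param n_traj Number of launched trajectories (lattice of
#'   `ceiling(sqrt(n_traj))^2` points; >= 100).
#' @param seed Optional integer seed (reserved; the lattice construction is
#'   deterministic).
#' @param dt Sampling step along trajectories \[h\].
#' @param t_max Trajectory length \[h\].
#' @return An object of class `"potential_grid"`: list with `N_axis`,
#'   `G_axis`, matrix `U` (min-shifted to 0, `NA` where unreachable),
#'   `basin` (attractor index per cell), `equilibria`, `saddle`, and
#'   `depths`, the aligned potential drop from the saddle cell to each
#'   attractor (named `NANOG_high`, `GATA_high`).
#' @examples
#' qp <- quasi_potential(fate_model(), resolution = 40, n_traj = 100)
#' qp$depths
#' @export
quasi_potential <- function(params, bounds = phase_bounds(params),
                            resolution = 100, n_traj = 400, seed = NULL,
                            dt = 0.05, t_max = 80) {
  check_flag_class(params, "fate_model")
  check_bounds(bounds)
  check_number(n_traj, "n_traj", lower = 100)
  eqs <- find_equilibria(params, bounds)
  att <- stable_attractors(eqs)
  if (nrow(att) < 2L) stop("quasi-potential requires a bistable regime",
                           call. = FALSE)
  sad <- the_saddle(eqs)
  Naxis <- seq(bounds$N[1L], bounds$N[2L], length.out = resolution)
  Gaxis <- seq(bounds$G[1L], bounds$G[2L], length.out = resolution)
  cell_of <- function(x, axis) {
    i <- findInterval(x, axis + c(diff(axis) / 2, Inf))
    pmin(pmax(i + 1L, 1L), length(axis))
  }
  side <- ceiling(sqrt(n_traj))
  starts <- expand.grid(
    N = seq(bounds$N[1L], bounds$N[2L], length.out = side),
    G = seq(bounds$G[1L], bounds$G[2L], length.out = side))
  f <- function(t, y, parms) {
    rf <- rate_field(y[1L], y[2L], params)
    list(c(rf$dN, rf$dG))
  }
  times <- seq(0, t_max, by = dt)
  # per-basin accumulation grids (attractor order = rows of `att`)
  Ug <- replicate(nrow(att), matrix(NA_real_, resolution, resolution),
                  simplify = FALSE)
  for (k in seq_len(nrow(starts))) {
    sol <- deSolve::ode(y = c(N = starts$N[k], G = starts$G[k]), times = times,
                        func = f, parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    Np <- sol[, 2L]; Gp <- sol[, 3L]
    rf <- rate_field(Np, Gp, params)
    sp2 <- rf$dN^2 + rf$dG^2
    # trapezoidal accumulation of -||v||^2 dt, then anchor the attractor
    # end at 0 so trajectories within a basin share a reference
    dU <- -(head(sp2, -1L) + tail(sp2, -1L)) / 2 * dt
    U <- c(0, cumsum(dU))
    U <- U - U[length(U)]
    b <- which.min((att$N - Np[length(Np)])^2 + (att$G - Gp[length(Gp)])^2)
    ci <- cell_of(Np, Naxis); cj <- cell_of(Gp, Gaxis)
    for (q in seq_along(U)) {
      cur <- Ug[[b]][ci[q], cj[q]]
      if (is.na(cur) || U[q] < cur) Ug[[b]][ci[q], cj[q]] <- U[q]
    }
  }
  # align basins at the saddle cell (fall back to nearest doubly-defined cell)
  ridge_cell <- c(cell_of(sad["N"], Naxis), cell_of(sad["G"], Gaxis))
  offsets <- rep(0, length(Ug))
  if (length(Ug) >= 2L) {
    both <- which(!is.na(Ug[[1L]]) & !is.na(Ug[[2L]]), arr.ind = TRUE)
    if (nrow(both) == 0L)
      stop("basins share no grid cell; increase n_traj or resolution",
           call. = FALSE)
    d2 <- (Naxis[both[, 1L]] - sad["N"])^2 + (Gaxis[both[, 2L]] - sad["G"])^2
    m <- both[which.min(d2), , drop = FALSE]
    ridge_cell <- c(m[1L], m[2L])
    offsets[2L] <- Ug[[1L]][m[1L], m[2L]] - Ug[[2L]][m[1L], m[2L]]
  }
  U <- Ug[[1L]]
  for (b in seq_along(Ug)[-1L]) {
    Ub <- Ug[[b]] + offsets[b]
    take <- !is.na(Ub) & (is.na(U) | Ub < U)
    U[take] <- Ub[take]
  }
  basin <- matrix(NA_integer_, resolution, resolution)
  for (b in seq_along(Ug)) {
    Ub <- Ug[[b]] + offsets[b]
    upd <- !is.na(Ub) & !is.na(U) & abs(Ub - U) < 1e-12
    basin[upd] <- b
  }
  shift <- min(U, na.rm = TRUE)
  U <- U - shift
  u_at <- function(N, G) U[cell_of(N, Naxis), cell_of(G, Gaxis)]
  u_sad <- u_at(sad["N"], sad["G"])
  if (is.na(u_sad)) u_sad <- U[ridge_cell[1L], ridge_cell[2L]]
  depths <- vapply(seq_len(nrow(att)), function(b)
    u_sad - u_at(att$N[b], att$G[b]), numeric(1L))
  names(depths) <- ifelse(att$G > att$N, "GATA_high", "NANOG_high")
  structure(list(N_axis = Naxis, G_axis = Gaxis, U = U, basin = basin,
                 equilibria = eqs, saddle = sad, depths = depths,
                 params = params, bounds = bounds),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("Quasi-potential grid %d x %d over N [%g, %g], G [%g, %g]\n",
              length(x$N_axis), length(x$G_axis),
              min(x$N_axis), max(x$N_axis), min(x$G_axis), max(x$G_axis)))
  cat(sprintf("  defined cells: %d / %d\n", sum(!is.na(x$U)), length(x$U)))
  cat("  basin depths (saddle - attractor):\n")
  for (nm in names(x$depths))
    cat(sprintf("    %-10s %.4g\n", nm, x$depths[[nm]]))
  invisible(x)
}

#' @export
plot.potential_grid <- function(x, ...) {
  graphics::image(x$N_axis, x$G_axis, x$U,
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  xlab = "N [a.u.]", ylab = "G [a.u.]", ...)
  graphics::points(x$equilibria$N, x$equilibria$G,
                   pch = ifelse(x$equilibria$stability == "stable", 19, 4))
  invisible(x)
}

#' Phase portrait of the autonomous circuit
#'
#' Bundles nullclines, equilibria and (in the bistable regime) the
#' separatrix into one object with print and plot methods.
#'
#' @inheritParams nullclines
#' @return An object of class `"phase_portrait"`.
#' @examples
#' pp <- phase_portrait(fate_model())
#' pp
#' @export
phase_portrait <- function(params, bounds = phase_bounds(params),
                           resolution = 200) {
  nc <- nullclines(params, bounds, resolution)
  eqs <- find_equilibria(params, bounds)
  sep <- if (sum(eqs$stability == "saddle") == 1L)
    separatrix(params, bounds) else NULL
  structure(list(nullclines = nc, equilibria = eqs, separatrix = sep,
                 bounds = bounds, params = params),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat("Phase portrait of the autonomous NANOG/GATA circuit\n")
  print(x$equilibria)
  cat(if (is.null(x$separatrix)) "  no separatrix (not bistable)\n"
      else sprintf("  separatrix: %d points through the saddle\n",
                   nrow(x$separatrix)))
  invisible(x)
}

#' @export
plot.phase_portrait <- function(x, ...) {
  b <- x$bounds
  graphics::plot(NA, xlim = b$N, ylim = b$G, xlab = "N [a.u.]",
                 ylab = "G [a.u.]", ...)
  graphics::lines(x$nullclines$N$N, x$nullclines$N$G, col = "steelblue")
  graphics::lines(x$nullclines$G$N, x$nullclines$G$G, col = "darkorange")
  if (!is.null(x$separatrix))
    graphics::lines(x$separatrix$N, x$separatrix$G, col = "red3", lty = 2)
  graphics::points(x$equilibria$N, x$equilibria$G,
                   pch = ifelse(x$equilibria$stability == "stable", 19, 4),
                   cex = 1.2)
  graphics::legend("topright",
                   c("N nullcline", "G nullcline", "separatrix"),
                   col = c("steelblue", "darkorange", "red3"),
                   lty = c(1, 1, 2), bty = "n")
  invisible(x)
}
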