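test_that("nullcline endpoints match the hand-solved single-species balances", {
  m <- fate_model()
  nc <- nullclines(m)
  # N nullcline at G = 0: production/degradation balance with signaling
  expect_equal(nc$N$N[nc$N$G == 0],
               m$alpha_N * fateswitch:::fs_nanog(m) / m$gamma_N)
  # G nullcline at N = 0
  expect_equal(nc$G$G[nc$G$N == 0],
               m$alpha_G * fateswitch:::fs_gata(m) / m$gamma_G)
  expect_error(nullclines(m, bounds = list(N = c(1, 1), G = c(0, 1))),
               "bounds")
})

test_that("symmetric parameters give mirror-image nullclines and a diagonal separatrix", {
  m <- fate_model(mode = "none")  # alpha, K, h, gamma all symmetric
  nc <- nullclines(m, resolution = 101)
  # the N nullcline maps onto the G nullcline under (N, G) -> (G, N)
  expect_equal(nc$N$N, nc$G$G, tolerance = 1e-12)
  expect_equal(nc$N$G, nc$G$N, tolerance = 1e-12)
  sep <- separatrix(m)
  expect_lt(max(abs(sep$N - sep$G)), 1e-4)
  expect_lt(abs(as.numeric(basin_fraction(m, resolution = 12)) - 0.5), 0.1)
})

test_that("equilibrium finder agrees with a 400x400 sign-change oracle", {
  for (m in list(fate_model(), fate_model(s = 0.25),
                 fate_model(mode = "promotes_gata"))) {
    b <- phase_bounds(m)
    eq <- find_equilibria(m, b)
    cells <- sign_change_cells(m, b, nx = 400)
    # every refined equilibrium sits inside a sign-change cell...
    for (i in seq_len(nrow(eq))) {
      d <- sqrt((cells$N - eq$N[i])^2 + (cells$G - eq$G[i])^2)
      expect_lt(min(d), 2 * cells$half_diag[1L])
    }
    # ...and every cluster of sign-change cells hosts an equilibrium
    for (j in seq_len(nrow(cells))) {
      d <- sqrt((eq$N - cells$N[j])^2 + (eq$G - cells$G[j])^2)
      expect_lt(min(d), 4 * cells$half_diag[1L])
    }
    # residual contract
    for (i in seq_len(nrow(eq))) {
      rf <- fateswitch:::rate_field(eq$N[i], eq$G[i], m)
      expect_lt(sqrt(rf$dN^2 + rf$dG^2), 1e-8)
    }
  }
})

test_that("degenerate circuits have the predicted single equilibrium", {
  # near-silent endogenous GATA: only the NANOG-only state survives
  m1 <- fate_model(alpha_G = 1e-8)
  eq1 <- find_equilibria(m1)
  expect_equal(nrow(eq1), 1L)
  expect_equal(eq1$stability, "stable")
  expect_equal(eq1$N, autonomous_steady_nanog(m1), tolerance = 1e-6)
  # repression removed: uncoupled linear system
  m2 <- fate_model(K_GN = 1e6, K_NG = 1e6, mode = "none")
  eq2 <- find_equilibria(m2, bounds = list(N = c(0, 3), G = c(0, 3)))
  expect_equal(nrow(eq2), 1L)
  expect_equal(eq2$stability, "stable")
  expect_equal(c(eq2$N, eq2$G), c(2, 2), tolerance = 1e-6)
})

test_that("stability classes are confirmed by perturbed forward integration", {
  m <- fate_model()
  eq <- find_equilibria(m)
  for (i in seq_len(nrow(eq))) {
    returned <- 0L
    for (dN in c(-1e-3, 1e-3)) {
      start <- c(max(eq$N[i] + dN, 0), max(eq$G[i] + 1e-3, 0), 0)
      st <- fateswitch:::settle_state(start, m)
      d <- sqrt((st$state[[1L]] - eq$N[i])^2 + (st$state[[2L]] - eq$G[i])^2)
      if (d < 1e-3) returned <- returned + 1L
    }
    if (eq$stability[i] == "stable") expect_equal(returned, 2L)
    else expect_lt(returned, 2L)  # saddle: at least one side departs
  }
})

test_that("points on either side of the separatrix flow to opposite attractors", {
  m <- fate_model()
  b <- phase_bounds(m)
  sep <- separatrix(m, b)
  att <- fateswitch:::stable_attractors(find_equilibria(m, b))
  sad <- attr(sep, "saddle")
  # offset test points along the saddle's unstable direction
  J <- fateswitch:::circuit_jacobian(sad["N"], sad["G"], m)
  ed <- eigen(J)
  vu <- Re(ed$vectors[, which.max(Re(ed$values))])
  for (h in c(0.02, 0.1)) {
    f1 <- settle_fate(sad["N"] + h * vu[1L], sad["G"] + h * vu[2L], m, att)
    f2 <- settle_fate(sad["N"] - h * vu[1L], sad["G"] - h * vu[2L], m, att)
    expect_false(f1 == f2)
  }
})

test_that("separatrix side labels agree with forward-integrated basins", {
  m <- fate_model()
  b <- phase_bounds(m)
  sep <- separatrix(m, b)
  att <- fateswitch:::stable_attractors(find_equilibria(m, b))
  pts <- expand.grid(N = seq(0.05, b$N[2L] - 0.05, length.out = 14),
                     G = seq(0.05, b$G[2L] - 0.05, length.out = 14))
  side <- mapply(separatrix_side, N = pts$N, G = pts$G,
                 MoreArgs = list(sep = sep))
  fate <- mapply(settle_fate, N = pts$N, G = pts$G,
                 MoreArgs = list(params = m, attractors = att))
  ok <- !is.na(fate) & side != 0
  # side sign -> fate mapping is consistent for at least 99% of points
  tab <- table(side[ok], fate[ok])
  agree <- (sum(apply(tab, 1L, max))) / sum(tab)
  expect_gte(agree, 0.99)
})

test_that("lowering signaling shrinks the GATA-high basin", {
  bf1 <- basin_fraction(fate_model(s = 1), resolution = 12)
  bf2 <- basin_fraction(fate_model(s = 0.25), resolution = 12)
  expect_gt(bf1, bf2)
  expect_equal(attr(bf1, "unresolved"), 0L)
})

test_that("basin fraction is zero without an endogenous GATA attractor", {
  m <- fate_model(alpha_G = 1e-8)
  expect_equal(as.numeric(basin_fraction(m, resolution = 8)), 0)
})

test_that("quasi-potential has minima at the attractors and decreases along flow", {
  m <- fate_model()
  qp <- quasi_potential(m, resolution = 50, n_traj = 196)
  att <- fateswitch:::stable_attractors(qp$equilibria)
  cell_of <- function(x, axis) which.min(abs(axis - x))
  for (i in seq_len(nrow(att))) {
    ci <- cell_of(att$N[i], qp$N_axis); cj <- cell_of(att$G[i], qp$G_axis)
    u0 <- qp$U[ci, cj]
    expect_false(is.na(u0))
    nb <- expand.grid(di = -1:1, dj = -1:1)
    for (k in seq_len(nrow(nb))) {
      ui <- ci + nb$di[k]; uj <- cj + nb$dj[k]
      if (ui < 1 || uj < 1 || ui > 50 || uj > 50) next
      if (!is.na(qp$U[ui, uj])) expect_gte(qp$U[ui, uj], u0)
    }
  }
  # U non-increasing along forward trajectories (within alignment tolerance)
  set.seed(7)
  tolU <- 0.05 * diff(range(qp$U, na.rm = TRUE))
  for (rep in 1:20) {
    start <- c(runif(1, 0, 3), runif(1, 0, 3), 0)
    tr <- simulate_cell(m, 0, pulse_protocol(t_final = 40),
                        times = seq(0, 40, by = 0.5), initial = start)
    us <- mapply(function(N, G)
      qp$U[cell_of(N, qp$N_axis), cell_of(G, qp$G_axis)], tr$N, tr$G)
    us <- us[!is.na(us)]
    expect_lte(max(diff(us)), tolU)
  }
})

test_that("lower signaling makes the GATA basin shallower relative to the NANOG basin", {
  qp1 <- quasi_potential(fate_model(s = 1), resolution = 50, n_traj = 196)
  qp2 <- quasi_potential(fate_model(s = 0.25), resolution = 50, n_traj = 196)
  r1 <- qp1$depths[["GATA_high"]] / qp1$depths[["NANOG_high"]]
  r2 <- qp2$depths[["GATA_high"]] / qp2$depths[["NANOG_high"]]
  expect_gt(r1, r2)
})
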