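# Independent brute-force oracles for the ROC stack and phase-plane code.

# Mann-Whitney pair statistic: wins + half-ties over all pos x neg pairs.
auc_brute <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Max TPR - FPR over the full threshold enumeration (predict positive iff
# value >= t); every distinct prediction set is covered by evaluating at
# each unique value plus the infinite sentinels.
best_J_brute <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  cand <- c(-Inf, sort(unique(values)), Inf)
  max(vapply(cand, function(t) mean(pos >= t) - mean(neg >= t), numeric(1L)))
}

# Cells of an nx x nx lattice where both rate components change sign
# among the four corners: a brute-force equilibrium locator.
sign_change_cells <- function(params, bounds, nx = 400) {
  Ns <- seq(bounds$N[1L], bounds$N[2L], length.out = nx)
  Gs <- seq(bounds$G[1L], bounds$G[2L], length.out = nx)
  A <- params$alpha_N * fateswitch:::fs_nanog(params)
  B <- params$alpha_G * fateswitch:::fs_gata(params)
  dN <- outer(Ns, Gs, function(N, G)
    A / (1 + (G / params$K_GN)^params$h_N) - params$gamma_N * N)
  dG <- outer(Ns, Gs, function(N, G)
    B / (1 + (N / params$K_NG)^params$h_G) - params$gamma_G * G)
  sN <- sign(dN); sG <- sign(dG)
  ii <- seq_len(nx - 1L)
  flipN <- (sN[ii, ii] != sN[ii + 1L, ii]) | (sN[ii, ii] != sN[ii, ii + 1L]) |
    (sN[ii, ii] != sN[ii + 1L, ii + 1L])
  flipG <- (sG[ii, ii] != sG[ii + 1L, ii]) | (sG[ii, ii] != sG[ii, ii + 1L]) |
    (sG[ii, ii] != sG[ii + 1L, ii + 1L])
  idx <- which(flipN & flipG, arr.ind = TRUE)
  data.frame(N = (Ns[idx[, 1L]] + Ns[idx[, 1L] + 1L]) / 2,
             G = (Gs[idx[, 2L]] + Gs[idx[, 2L] + 1L]) / 2,
             half_diag = sqrt(diff(Ns[1:2])^2 + diff(Gs[1:2])^2) / 2)
}

# Signed side of the separatrix polyline for a query point (sign of the
# cross product with the nearest segment).
separatrix_side <- function(sep, N, G) {
  d2 <- (sep$N - N)^2 + (sep$G - G)^2
  i <- which.min(d2)
  j <- if (i < nrow(sep)) i + 1L else i - 1L
  a <- c(sep$N[min(i, j)], sep$G[min(i, j)])
  b <- c(sep$N[max(i, j)], sep$G[max(i, j)])
  sign((b[1L] - a[1L]) * (G - a[2L]) - (b[2L] - a[2L]) * (N - a[1L]))
}

# Forward-integrated fate of an autonomous (N, G) start.
settle_fate <- function(N, G, params, attractors) {
  st <- fateswitch:::settle_state(c(N, G, 0), params)
  if (!st$converged) return(NA_character_)
  fateswitch:::classify_attractor(st$state[[1L]], st$state[[2L]], attractors)
}
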