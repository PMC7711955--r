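# Independent oracles used to cross-check the package's optimizers.

# Bound-ligand concentration by bisection on the raw mass-balance equations
# (P - x)(L - x) = Kd * x, solved for the complex concentration x.
bound_by_bisection <- function(protein, ligand, kd) {
  if (ligand == 0 || protein == 0) return(0)
  f <- function(x) (protein - x) * (ligand - x) - kd * x
  stats::uniroot(f, c(0, min(protein, ligand)), tol = 1e-12)$root
}

# Exhaustive 3-D grid search (about 1% resolution) followed by a Nelder-Mead
# polish, for the titration model. Independent of nlsLM.
titration_grid_oracle <- function(curve, protein_total) {
  L <- curve$ligand_total_uM
  I <- curve$intensity_au
  rss <- function(p) {
    if (p[1] < 0) return(Inf)
    sum((I - predict_intensity(L, p[1], p[2], p[3], protein_total))^2)
  }
  kd_grid <- exp(seq(log(max(min(L[L > 0]), 1e-3) / 5), log(max(L) * 5), length.out = 40))
  apo_grid <- seq(I[1] * 0.9, I[1] * 1.1, length.out = 15)
  holo_grid <- seq(I[length(I)] * 0.9, I[length(I)] * 1.1, length.out = 15)
  best <- NULL
  best_rss <- Inf
  for (k in kd_grid) for (a in apo_grid) for (h in holo_grid) {
    v <- rss(c(k, a, h))
    if (v < best_rss) { best_rss <- v; best <- c(k, a, h) }
  }
  opt <- stats::optim(best, rss, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(kd = opt$par[1], i_apo = opt$par[2], i_holo = opt$par[3], rss = opt$value)
}

# Grid + polish oracle for the ITC model; the dilution heat is profiled out
# analytically (linear least squares) at each grid node.
itc_grid_oracle <- function(titration, exclude_first = TRUE) {
  P <- attr(titration, "cell_protein_uM")
  S <- attr(titration, "syringe_ligand_uM")
  V <- attr(titration, "cell_volume_uL")
  v <- titration$volume_uL
  q <- titration$heat_ucal
  use <- rep(TRUE, length(q)); if (exclude_first) use[1] <- FALSE
  rss_profiled <- function(n, kd, dh) {
    if (n <= 0 || kd <= 0) return(list(rss = Inf, q_dil = 0))
    base <- predict_injection_heats(n, kd, dh, 0, P, S, V, v)
    r <- q[use] - base[use]
    qd <- sum(r * v[use]) / sum(v[use]^2)
    list(rss = sum((r - qd * v[use])^2), q_dil = qd)
  }
  n_grid <- seq(0.8, 1.2, length.out = 17)
  kd_grid <- exp(seq(log(P / 500), log(P), length.out = 30))
  dh_grid <- seq(-12, -4, length.out = 25)
  best <- NULL; best_rss <- Inf
  for (n in n_grid) for (k in kd_grid) for (d in dh_grid) {
    v_ <- rss_profiled(n, k, d)
    if (v_$rss < best_rss) { best_rss <- v_$rss; best <- c(n, k, d) }
  }
  opt <- stats::optim(best, function(p) rss_profiled(p[1], p[2], p[3])$rss,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  pr <- rss_profiled(opt$par[1], opt$par[2], opt$par[3])
  list(n_sites = opt$par[1], kd = opt$par[2], dh = opt$par[3],
       q_dil = pr$q_dil, rss = pr$rss)
}

# Closed-form OLS slope/intercept from the normal equations.
normal_equations_line <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Dense-grid sign-change search for the 0.5 crossing of a fraction curve.
tm_grid_oracle <- function(fraction_curve, step = 0.01) {
  f_interp <- stats::approxfun(fraction_curve$temp_C, fraction_curve$fraction)
  grid <- seq(min(fraction_curve$temp_C), max(fraction_curve$temp_C), by = step)
  v <- f_interp(grid) - 0.5
  i <- which(diff(sign(v)) != 0)[1]
  grid[i]
}

expected_nt_codes <- function() {
  tibble::tibble(
    variant_id = c("G3S", "G3D", "V9I", "T16M", "Y20N", "A29T"),
    expression = 3L,
    thermal = c(3L, 3L, 3L, 2L, 2L, 3L),
    proteolysis = c(3L, 3L, 3L, 2L, 3L, 3L),
    fad_binding = c(3L, 3L, 3L, 1L, 2L, 2L),
    dic_binding = 3L
  )
}

RT25 <- 1.987e-3 * 298.15
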