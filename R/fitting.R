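# Goodness of fit (uncentered correlation), the analytic gradient of the
# buildup observables with respect to log-timescales, grid search and
# L-BFGS-B refinement, and the randomized-grouping significance test.

#' Uncentered correlation coefficient
#'
#' `R_u = sum(x y) / sqrt(sum(x^2) sum(y^2))`: scale-free in each argument
#' but, unlike the Pearson correlation, penalizes a nonzero intercept.
#' Equals 1 iff one vector is a positive scalar multiple of the other.
#'
#' @param calc,obs equal-length numeric vectors (length >= 2, nonzero
#'   norm).
#' @export
uncentered_correlation <- function(calc, obs) {
  stopifnot(length(calc) == length(obs), length(calc) >= 2)
  nx <- sum(calc^2); ny <- sum(obs^2)
  if (nx == 0 || ny == 0) stopf("zero-norm vector in uncentered correlation")
  sum(calc * obs) / sqrt(nx * ny)
}

# match table rows to (pseudoatom-pair, mixing-time) coordinates
fit_context <- function(model, table) {
  glab <- names(model$system$groups)
  g1 <- match(table$group1, glab)
  g2 <- match(table$group2, glab)
  bad <- is.na(g1) | is.na(g2)
  if (any(bad)) {
    miss <- unique(c(table$group1[is.na(g1)], table$group2[is.na(g2)]))
    stopf("buildup table refers to unknown pseudoatoms: %s",
          paste(miss, collapse = ", "))
  }
  times <- sort(unique(table$mixing_time_ms)) / 1000
  ti <- match(table$mixing_time_ms / 1000, times)
  M <- matrix(0, length(glab), model$n_spins)
  for (k in seq_along(glab)) M[k, model$system$groups[[k]]] <- 1
  list(g1 = g1, g2 = g2, times = times, ti = ti,
       obs = table$intensity, M = M, n_groups = length(glab))
}

# R and (optionally) its derivatives with respect to log tau_c and each
# free log-timescale
relaxation_with_grad <- function(model, tau_c, taus, omega0, free = NULL) {
  ns <- model$n_spins
  K <- solomon_K()
  inv_tau <- 1 / taus[model$rate_names]
  R <- matrix(0, ns, ns)
  dR <- lapply(free, function(f) matrix(0, ns, ns))
  names(dR) <- free
  w3 <- c(0, omega0, 2 * omega0)
  for (p in model$pairs) {
    decay <- as.vector(p$coeffs %*% inv_tau)
    tp <- 1 / (1 / tau_c + decay)
    lor <- lapply(w3, function(w) 1 / (1 + w^2 * tp^2))
    Jw <- vapply(seq_along(w3),
                 function(q) 2 * sum(p$a * tp * lor[[q]]), numeric(1)) *
      ANG6_TO_M6
    sigma <- K * (6 * Jw[3] - Jw[1])
    rho <- K * (Jw[1] + 3 * Jw[2] + 6 * Jw[3])
    R[p$i, p$j] <- R[p$i, p$j] + sigma
    R[p$j, p$i] <- R[p$j, p$i] + sigma
    R[p$i, p$i] <- R[p$i, p$i] + rho
    R[p$j, p$j] <- R[p$j, p$j] + rho
    for (f in free) {
      dtp <- if (f == "tau_c") tp^2 / tau_c else
        tp^2 * p$coeffs[, f] / taus[[f]]
      dJ <- vapply(seq_along(w3), function(q) {
        w <- w3[q]
        2 * sum(p$a * (1 - w^2 * tp^2) * lor[[q]]^2 * dtp)
      }, numeric(1)) * ANG6_TO_M6
      ds <- K * (6 * dJ[3] - dJ[1])
      dr <- K * (dJ[1] + 3 * dJ[2] + 6 * dJ[3])
      dR[[f]][p$i, p$j] <- dR[[f]][p$i, p$j] + ds
      dR[[f]][p$j, p$i] <- dR[[f]][p$j, p$i] + ds
      dR[[f]][p$i, p$i] <- dR[[f]][p$i, p$i] + dr
      dR[[f]][p$j, p$j] <- dR[[f]][p$j, p$j] + dr
    }
  }
  list(R = R, dR = dR)
}

# divided-difference matrix for the Frechet derivative of the matrix
# exponential; W_ij = (e^li - e^lj)/(li - lj), W_ii = e^li
exp_divided_diff <- function(l) {
  n <- length(l)
  el <- exp(l)
  L <- matrix(l, n, n)
  D <- L - t(L)
  W <- matrix(el, n, n) - matrix(el, n, n, byrow = TRUE)
  small <- abs(D) < 1e-12 * max(abs(l), 1)
  W[!small] <- W[!small] / D[!small]
  W[small] <- matrix(el, n, n)[small]
  W
}

# R_u and its gradient over theta = log(timescales); theta named with
# "tau_c" and free rate names
ru_objective <- function(theta, model, ctx, omega0, grad = TRUE) {
  tau_c <- exp(theta[["tau_c"]])
  free <- names(theta)
  taus <- model$taus
  for (f in setdiff(free, "tau_c")) taus[[f]] <- exp(theta[[f]])
  rg <- relaxation_with_grad(model, tau_c, taus, omega0,
                             free = if (grad) free else NULL)
  e <- eigen(rg$R, symmetric = TRUE)
  U <- e$vectors
  M <- ctx$M
  MU <- M %*% U
  calc <- numeric(length(ctx$obs))
  dcalc <- if (grad) {
    stats::setNames(rep(list(numeric(length(ctx$obs))), length(free)), free)
  }
  E <- if (grad) lapply(rg$dR, function(D) crossprod(U, D %*% U))
  for (t in seq_along(ctx$times)) {
    tm <- ctx$times[t]
    sel <- ctx$ti == t
    B <- MU %*% (exp(-tm * e$values) * t(MU))
    calc[sel] <- B[cbind(ctx$g1[sel], ctx$g2[sel])]
    if (grad) {
      W <- exp_divided_diff(-tm * e$values)
      for (f in free) {
        dB <- MU %*% (W * (-tm * E[[f]])) %*% t(MU)
        dcalc[[f]][sel] <- dB[cbind(ctx$g1[sel], ctx$g2[sel])]
      }
    }
  }
  obs <- ctx$obs
  nx <- sum(calc^2); ny <- sum(obs^2)
  if (nx == 0 || ny == 0) return(list(Ru = 0, grad = rep(0, length(free))))
  Ru <- sum(calc * obs) / sqrt(nx * ny)
  out <- list(Ru = Ru, calc = calc)
  if (grad) {
    dRu_dcalc <- obs / sqrt(nx * ny) - Ru * calc / nx
    out$grad <- vapply(free, function(f) sum(dRu_dcalc * dcalc[[f]]),
                       numeric(1))
  }
  out
}

#' Score an ensemble against a NOE buildup table
#'
#' Computes the uncentered correlation between calculated and observed
#' buildup intensities at fixed timescales.
#'
#' @param ensemble a `ke_ensemble`.
#' @param table buildup table (see [read_buildup_table()]).
#' @param scheme a [ke_scheme()].
#' @param tau_c tumbling time, seconds.
#' @param spectrometer_mhz proton frequency, MHz.
#' @param cutoff pair cutoff, Angstrom.
#' @param model optional precomputed [relaxation_model()].
#' @return list with `Ru`, `calc` (aligned with `table` rows).
#' @export
score_ensemble <- function(ensemble, table, scheme, tau_c,
                           spectrometer_mhz = 900, cutoff = 5.5,
                           model = NULL) {
  model <- model %||% relaxation_model(ensemble, scheme,
                                       spin_system(ensemble, spectrometer_mhz),
                                       cutoff = cutoff)
  ctx <- fit_context(model, table)
  theta <- c(tau_c = log(tau_c))
  res <- ru_objective(theta, model, ctx, model$system$omega0, grad = FALSE)
  list(Ru = res$Ru, calc = res$calc)
}

#' Grid search over tumbling and exchange timescales
#'
#' Evaluates the uncentered correlation on the outer grid of `tau_c` and
#' `tau_ensemble` values.  The pair prefactors are computed once: only the
#' timescales change across the grid.
#'
#' @inheritParams score_ensemble
#' @param tau_c_grid,tau_ensemble_grid grids in seconds; defaults are 25
#'   log-spaced points over 1-50 ns and `tau_c`-centered +/- 3 decades.
#' @return list with `surface` (matrix, rows `tau_c`), `best` (named list
#'   with `tau_c`, `tau_ensemble`, `Ru`).
#' @export
grid_search <- function(ensemble, scheme, table,
                        tau_c_grid = 10^seq(log10(1e-9), log10(50e-9),
                                            length.out = 25),
                        tau_ensemble_grid = NULL,
                        spectrometer_mhz = 900, cutoff = 5.5, model = NULL) {
  stopifnot(length(tau_c_grid) >= 1)
  if (is.null(tau_ensemble_grid)) {
    mid <- exp(mean(log(tau_c_grid)))
    tau_ensemble_grid <- mid * 10^seq(-3, 3, length.out = 25)
  }
  model <- model %||% relaxation_model(ensemble, scheme,
                                       spin_system(ensemble, spectrometer_mhz),
                                       cutoff = cutoff)
  ctx <- fit_context(model, table)
  surface <- matrix(NA_real_, length(tau_c_grid), length(tau_ensemble_grid),
                    dimnames = list(signif(tau_c_grid, 6),
                                    signif(tau_ensemble_grid, 6)))
  for (a in seq_along(tau_c_grid)) {
    for (b in seq_along(tau_ensemble_grid)) {
      taus <- model$taus
      taus[["ensemble"]] <- tau_ensemble_grid[b]
      rg <- relaxation_with_grad(model, tau_c_grid[a], taus,
                                 model$system$omega0, free = NULL)
      e <- eigen(rg$R, symmetric = TRUE)
      MU <- ctx$M %*% e$vectors
      calc <- numeric(length(ctx$obs))
      for (t in seq_along(ctx$times)) {
        sel <- ctx$ti == t
        B <- MU %*% (exp(-ctx$times[t] * e$values) * t(MU))
        calc[sel] <- B[cbind(ctx$g1[sel], ctx$g2[sel])]
      }
      surface[a, b] <- uncentered_correlation(calc, ctx$obs)
    }
  }
  ix <- which(surface == max(surface), arr.ind = TRUE)[1, ]
  list(surface = surface,
       best = list(tau_c = tau_c_grid[ix[1]],
                   tau_ensemble = tau_ensemble_grid[ix[2]],
                   Ru = max(surface)))
}

#' Optimize motional timescales against NOE data
#'
#' Maximizes the uncentered correlation over `log` timescales with
#' L-BFGS-B, using the analytic gradient obtained by chaining the
#' spectral-density derivatives through the Frechet derivative of
#' `expm(-tau_m R)`.
#'
#' @inheritParams score_ensemble
#' @param start named vector of starting timescales in seconds; must
#'   include `tau_c`, and may include any of the scheme timescales
#'   (`ensemble`, `pincer`) to free them.  Timescales not named stay fixed
#'   at the scheme's values.
#' @param maxit maximum L-BFGS-B iterations.
#' @return list with `timescales` (all, seconds), `Ru`, `converged`,
#'   `start_Ru`.
#' @export
optimize_timescales <- function(ensemble, scheme, table, start,
                                spectrometer_mhz = 900, cutoff = 5.5,
                                model = NULL, maxit = 500) {
  stopifnot("tau_c" %in% names(start), all(start > 0))
  model <- model %||% relaxation_model(ensemble, scheme,
                                       spin_system(ensemble, spectrometer_mhz),
                                       cutoff = cutoff)
  bad <- setdiff(names(start), c("tau_c", model$rate_names))
  if (length(bad)) stopf("unknown timescales in start: %s",
                         paste(bad, collapse = ", "))
  ctx <- fit_context(model, table)
  omega0 <- model$system$omega0
  theta0 <- log(start)
  fn <- function(th) {
    names(th) <- names(start)
    -ru_objective(th, model, ctx, omega0, grad = FALSE)$Ru
  }
  gr <- function(th) {
    names(th) <- names(start)
    -ru_objective(th, model, ctx, omega0, grad = TRUE)$grad
  }
  start_Ru <- -fn(theta0)
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      lower = -30, upper = 0,
                      control = list(maxit = maxit, factr = 10))
  Ru <- -opt$value
  if (Ru < start_Ru) {  # guard: never return worse than the start
    opt$par <- theta0
    Ru <- start_Ru
  }
  timescales <- model$taus
  fitted <- exp(opt$par)
  names(fitted) <- names(start)
  for (f in setdiff(names(start), "tau_c")) timescales[[f]] <- fitted[[f]]
  list(timescales = c(tau_c = unname(fitted[["tau_c"]]), timescales),
       Ru = Ru, converged = opt$convergence == 0, start_Ru = start_Ru)
}

#' Randomized-grouping significance test for hierarchical kinetics
#'
#' Re-optimizes the timescales for the ensemble's reference grouping and
#' for `n_random` random groupings with the same group sizes, and reports
#' the fraction of random groupings whose optimized correlation meets or
#' exceeds the reference, as `(count + 1)/(n_random + 1)`.
#'
#' @inheritParams optimize_timescales
#' @param n_random number of random groupings (>= 1).
#' @param seed RNG seed for the random groupings.
#' @return list with `p_value`, `reference_Ru`, `random_Ru` (vector).
#' @export
randomization_test <- function(ensemble, scheme, table, start,
                               n_random, seed = 1,
                               spectrometer_mhz = 900, cutoff = 5.5,
                               maxit = 100) {
  stopifnot(n_random >= 1, scheme$kind == "hierarchical")
  if (is.null(ensemble$group_labels)) {
    stopf("randomization test requires ensemble group_labels")
  }
  ref <- optimize_timescales(ensemble, scheme, table, start,
                             spectrometer_mhz, cutoff, maxit = maxit)
  labels <- ensemble$group_labels
  random_Ru <- with_seed(seed, {
    vapply(seq_len(n_random), function(k) {
      ens_k <- ensemble
      ens_k$group_labels <- sample(labels)
      optimize_timescales(ens_k, scheme, table, start,
                          spectrometer_mhz, cutoff, maxit = maxit)$Ru
    }, numeric(1))
  })
  list(p_value = (sum(random_Ru >= ref$Ru) + 1) / (n_random + 1),
       reference_Ru = ref$Ru, random_Ru = random_Ru)
}
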