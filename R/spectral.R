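# Internal and full correlation functions, spectral densities, the
# extended model-free closed forms, and the distance-averaging-power
# analysis for two-distance exchange systems.

#' Pair spectral description
#'
#' Bundles the exponential prefactors and decay constants of one proton
#' pair with the overall tumbling time.  Internal decay rates `lambda_k`
#' (s^-1, <= 0) combine with isotropic tumbling via the modified rates
#' `lambda'_k = lambda_k - 1/tau_c` and effective times
#' `tau'_k = -1/lambda'_k`.
#'
#' @param a prefactors in Angstrom^-6.
#' @param lambda internal decay rates, s^-1 (nonpositive; one zero entry
#'   carries the plateau).
#' @param tau_c isotropic tumbling time, seconds.
#' @return a `ke_pair_spectral`.
#' @export
pair_spectral <- function(a, lambda, tau_c) {
  stopifnot(length(a) == length(lambda), tau_c > 0, all(lambda <= 1e-9))
  structure(list(a = a, lambda = pmin(lambda, 0), tau_c = tau_c),
            class = "ke_pair_spectral")
}

effective_times <- function(ps) 1 / (1 / ps$tau_c - ps$lambda)

#' Internal correlation function
#'
#' `C_I(tau) = sum_k a_k exp(lambda_k tau)` (Angstrom^-6); the plateau
#' `C_I(Inf)` is the zero-eigenvalue prefactor.
#'
#' @param ps a `ke_pair_spectral`.
#' @param tau lag times in seconds (>= 0).
#' @export
internal_correlation <- function(ps, tau) {
  vapply(tau, function(t) sum(ps$a * exp(ps$lambda * t)), numeric(1))
}

#' Full correlation function including isotropic tumbling
#'
#' `C(tau) = exp(-tau/tau_c) * C_I(tau)`.
#'
#' @inheritParams internal_correlation
#' @export
correlation_function <- function(ps, tau) {
  exp(-tau / ps$tau_c) * internal_correlation(ps, tau)
}

#' Spectral density function
#'
#' `J(omega) = 2 sum_k a_k tau'_k / (1 + omega^2 tau'_k^2)` in
#' Angstrom^-6 s, with `tau'_k = 1/(1/tau_c - lambda_k)`.
#'
#' @param ps a `ke_pair_spectral`.
#' @param omega angular frequencies, rad/s.
#' @export
spectral_density <- function(ps, omega) {
  tp <- effective_times(ps)
  vapply(omega, function(w) 2 * sum(ps$a * tp / (1 + w^2 * tp^2)),
         numeric(1))
}

#' Extended model-free parameter set
#'
#' @param S_f2,S_s2 fast/slow order parameters in `[0, 1]`.
#' @param tau_f,tau_s,tau_c fast, slow and tumbling times in seconds.
#' @return list with the parameters plus the tumbling-corrected
#'   `tau_f_prime = tau_f tau_c/(tau_f + tau_c)` and `tau_s_prime`.
#' @export
emf_params <- function(S_f2, S_s2, tau_f, tau_s, tau_c) {
  stopifnot(S_f2 >= 0, S_f2 <= 1, S_s2 >= 0, S_s2 <= 1,
            tau_f > 0, tau_s > 0, tau_c > 0)
  list(S_f2 = S_f2, S_s2 = S_s2, tau_f = tau_f, tau_s = tau_s,
       tau_c = tau_c,
       tau_f_prime = tau_f * tau_c / (tau_f + tau_c),
       tau_s_prime = tau_s * tau_c / (tau_s + tau_c))
}

#' Extended model-free internal correlation function
#'
#' `C_I(t) = S_f2 S_s2 + (1 - S_f2) exp(-t/tau_f) +
#' S_f2 (1 - S_s2) exp(-t/tau_s)` (unit internuclear distance).
#'
#' @param p an [emf_params()] list.
#' @param t lag times in seconds.
#' @export
emf_internal_correlation <- function(p, t) {
  p$S_f2 * p$S_s2 + (1 - p$S_f2) * exp(-t / p$tau_f) +
    p$S_f2 * (1 - p$S_s2) * exp(-t / p$tau_s)
}

#' Extended model-free spectral density
#'
#' Closed-form two-timescale reference: `J(omega) = 2 (S_f2 S_s2 tau_c /
#' (1 + omega^2 tau_c^2) + (1 - S_f2) tau_f' / (1 + omega^2 tau_f'^2) +
#' S_f2 (1 - S_s2) tau_s' / (1 + omega^2 tau_s'^2))`.  The third-term
#' coefficient is `S_f2 (1 - S_s2)`, the Fourier transform of the
#' slow-timescale term of [emf_internal_correlation()].
#'
#' @param p an [emf_params()] list.
#' @param omega angular frequencies, rad/s.
#' @export
emf_spectral_density <- function(p, omega) {
  2 * (p$S_f2 * p$S_s2 * p$tau_c / (1 + omega^2 * p$tau_c^2) +
         (1 - p$S_f2) * p$tau_f_prime / (1 + omega^2 * p$tau_f_prime^2) +
         p$S_f2 * (1 - p$S_s2) * p$tau_s_prime /
           (1 + omega^2 * p$tau_s_prime^2))
}

# J(0) of the two-distance exchange system, closed form: collinear vectors
# make the dipolar 5-vectors parallel, so a_0 = <r^-3>^2 and
# a_1 = <r^-6> - <r^-3>^2 with decay -1/tau_ex.
two_distance_J0 <- function(p_A, r_A, r_B, tau_ex, tau_c) {
  geom <- build_two_distance_toy(r_A, r_B, p_A)
  rm <- two_state_matrix(p_A, tau_ex)
  pf <- averaged_prefactors(geom, rm)
  ps <- pair_spectral(pf$a, pf$lambda, tau_c)
  spectral_density(ps, 0)
}

#' Fit the effective distance-averaging power
#'
#' For a two-state system with distances `r_A`, `r_B` exchanging on
#' `tau_ex`, computes `J(0)` at populations
#' `p_A = 0, 0.2, 0.4, 0.6, 0.8, 1` and fits the power `n` of
#' `J(0) = 2 tau_c (p_A r_A^-n + (1 - p_A) r_B^-n)^(6/n)` by least squares
#' (on `J(0)/(2 tau_c)`).  `n` runs from 3 (`<r^-3>^2` averaging, fast
#' exchange) to 6 (`<r^-6>`, slow exchange).
#'
#' @param r_A,r_B distances in Angstrom (must differ enough to be
#'   identifiable).
#' @param tau_ex exchange timescale, seconds.
#' @param tau_c tumbling time, seconds.
#' @param p_grid populations at which `J(0)` is evaluated.
#' @return fitted power `n`.
#' @export
fit_averaging_power <- function(r_A, r_B, tau_ex, tau_c,
                                p_grid = seq(0, 1, 0.2)) {
  stopifnot(tau_ex > 0, tau_c > 0)
  if (abs(log(r_B / r_A)) < 0.01) {
    stopf("r_B/r_A too close to 1: averaging power not identifiable")
  }
  j0 <- vapply(p_grid, two_distance_J0, numeric(1),
               r_A = r_A, r_B = r_B, tau_ex = tau_ex, tau_c = tau_c)
  y <- j0 / (2 * tau_c)
  obj <- function(n) {
    sum(((p_grid * r_A^-n + (1 - p_grid) * r_B^-n)^(6 / n) - y)^2)
  }
  stats::optimize(obj, c(2.5, 6.5), tol = 1e-10)$minimum
}

#' Averaging power across an exchange-timescale grid
#'
#' @inheritParams fit_averaging_power
#' @param tau_ex_grid exchange timescales, seconds; default 61 log-spaced
#'   points spanning `tau_c * 10^(-3..3)`.
#' @return data.frame with `tau_ex`, `tau_ex_rel` (units of `tau_c`), `n`.
#' @export
scan_averaging_power <- function(r_A, r_B, tau_c,
                                 tau_ex_grid = tau_c *
                                   10^seq(-3, 3, length.out = 61)) {
  n <- vapply(tau_ex_grid, fit_averaging_power, numeric(1),
              r_A = r_A, r_B = r_B, tau_c = tau_c)
  data.frame(tau_ex = tau_ex_grid, tau_ex_rel = tau_ex_grid / tau_c, n = n)
}

#' Hyperbolic midpoint of the averaging-power transition
#'
#' Fits `n = 3 + 3/((tau_1/2 / tau_ex) + 1)` to the `n(tau_ex)` curve by
#' least squares over the grid; `tau_1/2` is the exchange timescale at
#' which the effective power is 4.5.
#'
#' @inheritParams scan_averaging_power
#' @return `tau_1/2` in units of `tau_c`.
#' @export
fit_halfpoint <- function(r_A, r_B, tau_c,
                          tau_ex_grid = tau_c *
                            10^seq(-3, 3, length.out = 61)) {
  span <- log10(max(tau_ex_grid) / min(tau_ex_grid))
  if (span < 6 - 1e-9) {
    stopf("tau_ex grid must span at least three decades either side of tau_c")
  }
  sc <- scan_averaging_power(r_A, r_B, tau_c, tau_ex_grid)
  obj <- function(lt) sum((3 + 3 / (exp(lt) / sc$tau_ex + 1) - sc$n)^2)
  lo <- log(min(tau_ex_grid)); hi <- log(max(tau_ex_grid))
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
  if (opt$minimum <= lo + 1e-6 || opt$minimum >= hi - 1e-6) {
    stopf("halfpoint fit did not converge to an interior optimum")
  }
  exp(opt$minimum) / tau_c
}
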