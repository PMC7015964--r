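# Dipole-dipole interaction tensors and the averaged exponential
# prefactors of the internal correlation function.

#' Cartesian dipole interaction tensor
#'
#' The symmetric traceless 3x3 tensor of a single internuclear vector,
#' `D = (3 v v^T - r^2 I) / r^5`, in Angstrom^-3.
#'
#' @param v internuclear vector `c(x, y, z)` in Angstrom.
#' @export
dipole_matrix <- function(v) {
  r2 <- sum(v^2)
  if (r2 <= 0) stopf("zero-length internuclear vector")
  (3 * tcrossprod(v) - r2 * diag(3)) / r2^2.5
}

#' Dipole tensor in 5-vector form
#'
#' Recasts the traceless symmetric tensor as the 5-vector
#' `d = r^-5 [ (3 z^2 - r^2)/2, (sqrt(3)/2)(x^2 - y^2), sqrt(3) x z,
#' sqrt(3) y z, sqrt(3) x y ]`, the unique scaling for which
#' `d_i . d_j = tr(D_i D_j) / 6` holds exactly (so `d . d = r^-6` for any
#' single state).
#'
#' @param v internuclear vector `c(x, y, z)` in Angstrom.
#' @return numeric length-5 vector in Angstrom^-3.
#' @export
dipole_vector <- function(v) {
  r2 <- sum(v^2)
  if (r2 <= 0) stopf("zero-length internuclear vector")
  x <- v[1]; y <- v[2]; z <- v[3]
  c((3 * z^2 - r2) / 2,
    sqrt(3) / 2 * (x^2 - y^2),
    sqrt(3) * x * z,
    sqrt(3) * y * z,
    sqrt(3) * x * y) / r2^2.5
}

# states x 5 matrix of dipole vectors for a ke_geometry
dipole_vectors <- function(geometry, normalize = FALSE) {
  v <- geometry$vectors
  if (normalize) v <- v / geometry$r
  t(apply(v, 1, dipole_vector))
}

#' Correlation strength between two states
#'
#' `c(s_i, s_j) = tr(D_i D_j)/6 = d_i . d_j`, in Angstrom^-6.
#'
#' @param d_i,d_j dipole tensors in 5-vector form.
#' @export
correlation_strength <- function(d_i, d_j) sum(d_i * d_j)

# population-weighted group sum g = sum_B w_B |dbar_B|^2 for one partition
partition_g <- function(partition, pi, dmat) {
  g <- 0
  for (b in unique(partition)) {
    sel <- partition == b
    w <- sum(pi[sel])
    if (w <= 0) next
    dbar <- colSums(pi[sel] * dmat[sel, , drop = FALSE]) / w
    g <- g + w * sum(dbar^2)
  }
  g
}

#' Exponential prefactors of the internal correlation function
#'
#' For a spin-pair geometry whose states exchange under the given rate
#' matrix, computes the prefactor `a_k` attached to each unique eigenvalue
#' `lambda_k`, so that `C_I(tau) = sum_k a_k exp(lambda_k tau)`.
#'
#' Two routes are available: `"fast"` evaluates the grouped-partition
#' recipes carried by the structured rate-matrix constructors in time
#' proportional to `s * l`; `"general"` forms the spectral projectors
#' `A_lambda` explicitly and evaluates `a_lambda = (Pi A_lambda) . C`
#' (O(s^2) per eigenvalue).  Both must agree; the general path is the
#' testing oracle.
#'
#' @param geometry a `ke_geometry`; one state per rate-matrix state.
#' @param rm a `ke_rate_matrix`.
#' @param method `"fast"` or `"general"`.
#' @return list with `lambda` (s^-1, 0 first), `a` (Angstrom^-6), and for
#'   the fast path `coeffs`, the matrix of per-eigenvalue timescale
#'   coefficients (columns named by timescale).
#' @export
averaged_prefactors <- function(geometry, rm, method = c("fast", "general")) {
  method <- match.arg(method)
  s <- nrow(rm$Q)
  if (nrow(geometry$vectors) != s) {
    stopf("geometry has %d states but rate matrix has %d",
          nrow(geometry$vectors), s)
  }
  dmat <- dipole_vectors(geometry)
  pi <- rm$pi
  if (method == "fast" && !is.null(rm$recipes)) {
    a <- vapply(rm$recipes, function(rec) {
      sum(vapply(rec$terms,
                 function(tm) tm$coeff * partition_g(tm$partition, pi, dmat),
                 numeric(1)))
    }, numeric(1))
    decays <- recipe_decay_rates(rm)
    nm <- names(rm$taus)
    coeffs <- do.call(rbind, lapply(rm$recipes, function(rec) {
      out <- stats::setNames(numeric(length(nm)), nm)
      out[names(rec$rates)] <- rec$rates
      out
    }))
    ord <- order(decays)
    list(lambda = -decays[ord], a = a[ord],
         coeffs = coeffs[ord, , drop = FALSE])
  } else {
    ss <- spectral_structure(rm)
    C <- tcrossprod(dmat)
    a <- vapply(ss$projectors, function(A) sum((pi * A) * C), numeric(1))
    ord <- order(ss$values, decreasing = TRUE)
    list(lambda = ss$values[ord], a = a[ord])
  }
}

#' Angular order parameter of a spin pair
#'
#' `S^2 = |<d>|^2` over unit-normalized internuclear vectors: the plateau
#' of the angular correlation function (1 = rigid, 0 = isotropic).
#'
#' @param geometry a `ke_geometry`.
#' @param populations optional override of the geometry populations.
#' @export
order_parameter <- function(geometry, populations = NULL) {
  pi <- populations %||% geometry$populations
  dmat <- dipole_vectors(geometry, normalize = TRUE)
  s2 <- sum(colSums(pi * dmat)^2)
  min(max(s2, 0), 1)
}
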