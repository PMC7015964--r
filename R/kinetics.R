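# Transition-rate matrices over ensemble states and their spectral
# structure.  Two routes to the exponential prefactors are maintained
# throughout: the O(s^3) eigendecomposition (projector matrices A_lambda,
# always available as the oracle) and the O(s*l) grouped fast path, in
# which each unique eigenvalue carries a small recipe of state partitions
# and integer coefficients.
#
# A recipe entry is list(rates = named numeric, terms = list of
# list(partition = integer vector over states, coeff = numeric)).  The
# decay rate of the entry is sum(rates * 1/tau) over the named timescales;
# the projector it encodes is sum_i coeff_i * G(partition_i), where
# G(partition) has rows equal to the population-normalized block profile.

new_rate_matrix <- function(Q, pi, taus, recipes) {
  structure(list(Q = Q, pi = pi, taus = taus, recipes = recipes),
            class = "ke_rate_matrix")
}

#' @export
print.ke_rate_matrix <- function(x, ...) {
  cat(sprintf("<ke_rate_matrix> %d states; timescales: %s\n", nrow(x$Q),
              paste(sprintf("%s=%.3g s", names(x$taus), x$taus),
                    collapse = ", ")))
  invisible(x)
}

# partitions used by the structured schemes
part_all <- function(s) rep(1L, s)
part_singletons <- function(s) seq_len(s)

#' Uniform N-site jump rate matrix
#'
#' All off-diagonal rates equal `1/(N * tau)`, so the exchange process has
#' a single internal timescale: eigenvalues are one 0 and `N - 1` copies of
#' `-1/tau`.
#'
#' @param N number of states (>= 2).
#' @param tau overall exchange timescale in seconds.
#' @param rate_name label for the timescale (default `"ensemble"`).
#' @return a `ke_rate_matrix`.
#' @export
uniform_jump_matrix <- function(N, tau, rate_name = "ensemble") {
  stopifnot(N >= 2, tau > 0)
  k <- 1 / (N * tau)
  Q <- matrix(k, N, N)
  diag(Q) <- -(N - 1) * k
  taus <- stats::setNames(tau, rate_name)
  recipes <- list(
    list(rates = stats::setNames(0, rate_name),
         terms = list(list(partition = part_all(N), coeff = 1))),
    list(rates = stats::setNames(1, rate_name),
         terms = list(list(partition = part_singletons(N), coeff = 1),
                      list(partition = part_all(N), coeff = -1)))
  )
  new_rate_matrix(Q, rep(1 / N, N), taus, recipes)
}

#' Two-level hierarchical rate matrix
#'
#' Members are partitioned into groups of sizes `group_sizes`.  Inter-group
#' rates are `1/(N * tau_slow)`; intra-group rates within group i are
#' `(1/tau_fast - (1 - N_i/N)/tau_slow) / N_i`, which keeps the overall
#' escape timescale equal to `tau_fast` while the group-to-group process
#' relaxes on `tau_slow`.  The spectrum has exactly three distinct
#' eigenvalues: 0, `-1/tau_slow` and `-1/tau_fast`.
#'
#' @param group_sizes integer sizes `N_i` (sum N).
#' @param tau_slow,tau_fast timescales in seconds; every intra-group rate
#'   must stay nonnegative (requires `tau_slow >= tau_fast` in practice).
#' @param rate_names labels for the two timescales.
#' @param membership optional integer/factor vector assigning each state to
#'   a group (overrides the contiguous-block layout implied by
#'   `group_sizes`).
#' @return a `ke_rate_matrix`.
#' @export
hierarchical_matrix <- function(group_sizes, tau_slow, tau_fast,
                                rate_names = c("pincer", "ensemble"),
                                membership = NULL) {
  if (!is.null(membership)) {
    membership <- as.integer(factor(membership))
    group_sizes <- as.integer(table(membership))
  }
  stopifnot(all(group_sizes >= 1), tau_slow > 0, tau_fast > 0)
  if (length(group_sizes) == 1L) {
    return(uniform_jump_matrix(group_sizes, tau_fast,
                               rate_name = rate_names[2]))
  }
  N <- sum(group_sizes)
  member <- membership %||% rep(seq_along(group_sizes), group_sizes)
  k_inter <- 1 / (N * tau_slow)
  Q <- matrix(k_inter, N, N)
  for (g in seq_along(group_sizes)) {
    Ni <- group_sizes[g]
    k_intra <- (1 / tau_fast - (1 - Ni / N) / tau_slow) / Ni
    if (k_intra < 0) {
      stopf("negative intra-group rate in group %d: tau_slow too fast relative to tau_fast",
            g)
    }
    Q[member == g, member == g] <- k_intra
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  taus <- stats::setNames(c(tau_slow, tau_fast), rate_names)
  zero <- stats::setNames(c(0, 0), rate_names)
  slow <- stats::setNames(c(1, 0), rate_names)
  fast <- stats::setNames(c(0, 1), rate_names)
  recipes <- list(
    list(rates = zero,
         terms = list(list(partition = part_all(N), coeff = 1))),
    list(rates = slow,
         terms = list(list(partition = member, coeff = 1),
                      list(partition = part_all(N), coeff = -1))),
    list(rates = fast,
         terms = list(list(partition = part_singletons(N), coeff = 1),
                      list(partition = member, coeff = -1)))
  )
  new_rate_matrix(Q, rep(1 / N, N), taus, recipes)
}

#' Rotation rate matrix for a methyl or aromatic group
#'
#' Individual transition rates are `1/(3 tau)` for a three-fold methyl and
#' `1/(2 tau)` for a two-fold aromatic ring flip, i.e. a uniform jump over
#' the rotational states with overall timescale `tau`.
#'
#' @param symmetry_order 2 (aromatic) or 3 (methyl).
#' @param tau rotation timescale in seconds.
#' @param rate_name label; defaults to `"aromatic"`/`"methyl"` by order.
#' @return a `ke_rate_matrix`.
#' @export
rotation_rate_matrix <- function(symmetry_order, tau, rate_name = NULL) {
  stopifnot(symmetry_order %in% c(2L, 3L), tau > 0)
  if (is.null(rate_name)) {
    rate_name <- if (symmetry_order == 2L) "aromatic" else "methyl"
  }
  uniform_jump_matrix(symmetry_order, tau, rate_name = rate_name)
}

# degenerate 1-state "rate matrix" (rigid structure scoring)
single_state_matrix <- function() {
  new_rate_matrix(matrix(0, 1, 1), 1, stats::setNames(numeric(0), character(0)),
                  list(list(rates = stats::setNames(numeric(0), character(0)),
                            terms = list(list(partition = 1L, coeff = 1)))))
}

#' Asymmetric two-state exchange matrix
#'
#' Rates `k_AB = (1 - p_A)/tau_ex`, `k_BA = p_A/tau_ex`, so the stationary
#' populations are `(p_A, 1 - p_A)` and the single nonzero eigenvalue is
#' `-1/tau_ex`.
#'
#' @param p_A population of state A.
#' @param tau_ex exchange timescale in seconds.
#' @param rate_name label for the timescale.
#' @return a `ke_rate_matrix`.
#' @export
two_state_matrix <- function(p_A, tau_ex, rate_name = "ex") {
  stopifnot(p_A >= 0, p_A <= 1, tau_ex > 0)
  Q <- matrix(c(-(1 - p_A), 1 - p_A, p_A, -p_A), 2, 2, byrow = TRUE) / tau_ex
  taus <- stats::setNames(tau_ex, rate_name)
  recipes <- list(
    list(rates = stats::setNames(0, rate_name),
         terms = list(list(partition = part_all(2L), coeff = 1))),
    list(rates = stats::setNames(1, rate_name),
         terms = list(list(partition = part_singletons(2L), coeff = 1),
                      list(partition = part_all(2L), coeff = -1)))
  )
  new_rate_matrix(Q, c(p_A, 1 - p_A), taus, recipes)
}

#' Kronecker sum of two rate matrices
#'
#' Generator of two kinetically independent exchange processes on the
#' product state space: `Q_o = Q (x) I + I (x) Q_r`.  State `(i, j)` maps
#' to row `(i - 1) * s_r + j`.  Eigenvalues are all pairwise sums of the
#' operands' eigenvalues; stationary populations are the outer product.
#' Shared timescale names accumulate their eigenvalue coefficients (two
#' independent methyl rotations give decay `-2/tau_methyl`).
#'
#' @param A,B `ke_rate_matrix` objects.
#' @return a `ke_rate_matrix`.
#' @export
kronecker_sum <- function(A, B) {
  sa <- nrow(A$Q); sb <- nrow(B$Q)
  shared <- intersect(names(A$taus), names(B$taus))
  if (any(abs(A$taus[shared] - B$taus[shared]) >
            1e-12 * abs(A$taus[shared]))) {
    stopf("shared timescale name with conflicting values in Kronecker sum")
  }
  Q <- kronecker(A$Q, diag(sb)) + kronecker(diag(sa), B$Q)
  pi <- as.vector(kronecker(A$pi, B$pi))  # (i,j) -> (i-1)*sb + j
  taus <- c(A$taus, B$taus[setdiff(names(B$taus), names(A$taus))])
  recipes <- list()
  for (ra in A$recipes) {
    for (rb in B$recipes) {
      rates <- merge_rates(ra$rates, rb$rates)
      terms <- list()
      for (ta in ra$terms) {
        for (tb in rb$terms) {
          terms[[length(terms) + 1L]] <- list(
            partition = combine_partitions(ta$partition, tb$partition),
            coeff = ta$coeff * tb$coeff
          )
        }
      }
      recipes[[length(recipes) + 1L]] <- list(rates = rates, terms = terms)
    }
  }
  new_rate_matrix(Q, pi, taus, merge_recipes(recipes))
}

merge_rates <- function(a, b) {
  nm <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(nm)), nm)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

combine_partitions <- function(pa, pb) {
  # product partition over the (i, j) product space, row-major in i
  grid <- expand.grid(j = seq_along(pb), i = seq_along(pa))
  as.integer(interaction(pa[grid$i], pb[grid$j], drop = TRUE))
}

rates_signature <- function(rates) {
  rates <- rates[order(names(rates))]
  paste(sprintf("%s=%.12g", names(rates), rates), collapse = ";")
}

# merge recipe entries whose eigenvalues coincide symbolically
merge_recipes <- function(recipes) {
  sig <- vapply(recipes, function(r) rates_signature(r$rates), "")
  out <- list()
  for (s in unique(sig)) {
    grp <- recipes[sig == s]
    terms <- do.call(c, lapply(grp, `[[`, "terms"))
    out[[length(out) + 1L]] <- list(rates = grp[[1]]$rates, terms = terms)
  }
  out
}

# decay rate (positive, s^-1) of each recipe entry at the current timescales
recipe_decay_rates <- function(rm) {
  vapply(rm$recipes, function(r) sum(r$rates / rm$taus[names(r$rates)]),
         numeric(1))
}

#' Stationary distribution of a rate matrix
#'
#' @param Q square generator matrix (rows sum to zero).
#' @return population vector solving `pi Q = 0`, `sum(pi) = 1`.
#' @export
stationary_distribution <- function(Q) {
  s <- nrow(Q)
  M <- rbind(t(Q), rep(1, s))
  pi <- qr.solve(M, c(rep(0, s), 1))
  if (any(pi < -1e-10)) stopf("no nonnegative stationary distribution found")
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Transition-probability propagator
#'
#' `P(tau) = expm(tau * Q)` evaluated by spectral decomposition.
#'
#' @param rm a `ke_rate_matrix` (or plain generator matrix).
#' @param tau lag time in seconds.
#' @export
propagator <- function(rm, tau) {
  ss <- spectral_structure(rm)
  P <- matrix(0, nrow(ss$projectors[[1]]), ncol(ss$projectors[[1]]))
  for (k in seq_along(ss$values)) {
    P <- P + exp(ss$values[k] * tau) * ss$projectors[[k]]
  }
  P
}

#' Spectral structure of a rate matrix (eigendecomposition path)
#'
#' Clusters eigenvalues within `degeneracy_tol` (relative) and builds the
#' spectral projector `A_lambda` of each cluster by summing the
#' column-times-row outer products of the eigendecomposition.  When the
#' stationary distribution satisfies detailed balance the problem is
#' symmetrized for numerical stability.
#'
#' @param rm a `ke_rate_matrix` or plain generator matrix.
#' @param degeneracy_tol relative clustering tolerance (default 1e-10:
#'   far above eigensolver noise, far below the smallest rate ratios that
#'   arise when picosecond methyl and 100-microsecond aromatic processes
#'   share one matrix).
#' @return list with `values` (unique eigenvalues, 0 first),
#'   `multiplicity`, `projectors` (list of `A_lambda`), `pi`.
#' @export
spectral_structure <- function(rm, degeneracy_tol = 1e-10) {
  if (inherits(rm, "ke_rate_matrix")) {
    Q <- rm$Q; pi <- rm$pi
  } else {
    Q <- rm; pi <- stationary_distribution(Q)
  }
  s <- nrow(Q)
  db <- max(abs(pi * Q - t(pi * Q)))  # detailed balance residual
  scale <- max(abs(Q), 1)
  if (all(pi > 0) && db <= 1e-9 * scale) {
    sq <- sqrt(pi)
    S <- (sq * Q) %*% diag(1 / sq, s)  # D^{1/2} Q D^{-1/2}, symmetric
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    V <- (1 / sq) * e$vectors
    Vinv <- t(e$vectors) %*% diag(sq, s)
    vals <- e$values
  } else {
    e <- eigen(Q)
    if (max(abs(Im(e$values))) > 1e-9 * scale) {
      stopf("complex eigenvalues; rate matrix is not reversible")
    }
    V <- Re(e$vectors); Vinv <- solve(V); vals <- Re(e$values)
  }
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]; V <- V[, ord, drop = FALSE]
  Vinv <- Vinv[ord, , drop = FALSE]
  # cluster within tolerance
  tol <- degeneracy_tol * max(abs(vals), 1)
  cl <- cumsum(c(TRUE, diff(vals) < -tol))
  values <- vapply(split(vals, cl), mean, numeric(1))
  mult <- vapply(split(vals, cl), length, integer(1))
  if (any(abs(values) <= tol & mult > 1L)) {
    stopf("rate matrix is reducible (zero eigenvalue not simple)")
  }
  values[which.max(values)] <- 0
  projectors <- lapply(split(seq_len(s), cl), function(idx) {
    V[, idx, drop = FALSE] %*% Vinv[idx, , drop = FALSE]
  })
  list(values = unname(values), multiplicity = unname(mult),
       projectors = unname(projectors), pi = pi)
}

# Materialize the projector encoded by a recipe entry:
# sum_i coeff_i * G(partition_i), with G rows the population profile of the
# state's block.  Used only for validation against the eigen path.
recipe_projector <- function(entry, pi) {
  s <- length(pi)
  A <- matrix(0, s, s)
  for (tm in entry$terms) {
    G <- matrix(0, s, s)
    for (b in unique(tm$partition)) {
      sel <- tm$partition == b
      w <- sum(pi[sel])
      G[sel, sel] <- matrix(rep(pi[sel] / w, each = sum(sel)),
                            nrow = sum(sel))
    }
    A <- A + tm$coeff * G
  }
  A
}
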