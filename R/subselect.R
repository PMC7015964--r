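# Greedy subensemble selection maximizing the uncentered correlation, and
# matched random-subensemble baselines.

# optimized R_u of a member subset (timescales warm-started from `start`)
score_subset <- function(ensemble, scheme, table, mask, start,
                         spectrometer_mhz, cutoff, maxit) {
  sub <- subset_ensemble(ensemble, mask)
  optimize_timescales(sub, scheme, table, start,
                      spectrometer_mhz = spectrometer_mhz, cutoff = cutoff,
                      maxit = maxit)
}

#' Greedy subensemble selection against NOE data
#'
#' Starts from a random ~50% inclusion of the members.  In each round
#' every single-member swap (include an excluded member or exclude an
#' included one) is evaluated by re-optimizing the timescales, warm-started
#' from the current best values; the swap with the greatest improvement in
#' the uncentered correlation is accepted.  Rounds continue until no swap
#' improves by more than `improve_tol`.  Swaps that would leave fewer than
#' two members are never taken.  Ties are broken by the lowest member
#' index, and the whole trajectory is deterministic for a fixed seed.
#'
#' @inheritParams optimize_timescales
#' @param seed RNG seed for the initial inclusion mask.
#' @param improve_tol minimum correlation improvement to accept a swap.
#' @param maxit L-BFGS-B iteration cap per candidate evaluation.
#' @return a `ke_selection`: list with `mask` (logical over members),
#'   `Ru`, `timescales`, and `history` (one row per accepted swap:
#'   member, `Ru`, timescales).
#' @export
greedy_subselect <- function(ensemble, scheme, table, start, seed = 1,
                             spectrometer_mhz = 900, cutoff = 5.5,
                             improve_tol = 1e-9, maxit = 60) {
  N <- n_members(ensemble)
  stopifnot(N >= 3)
  mask <- with_seed(seed, {
    m <- stats::runif(N) < 0.5
    while (sum(m) < 2) m <- stats::runif(N) < 0.5
    m
  })
  cur <- score_subset(ensemble, scheme, table, mask, start,
                      spectrometer_mhz, cutoff, maxit)
  warm <- cur$timescales[names(start)]
  history <- data.frame(member = NA_integer_, Ru = cur$Ru)
  repeat {
    best_gain <- improve_tol
    best_m <- NA_integer_
    best_fit <- NULL
    for (m in seq_len(N)) {
      cand <- mask
      cand[m] <- !cand[m]
      if (sum(cand) < 2) next
      fit <- score_subset(ensemble, scheme, table, cand, warm,
                          spectrometer_mhz, cutoff, maxit)
      if (fit$Ru - cur$Ru > best_gain) {
        best_gain <- fit$Ru - cur$Ru
        best_m <- m
        best_fit <- fit
      }
    }
    if (is.na(best_m)) break
    mask[best_m] <- !mask[best_m]
    cur <- best_fit
    warm <- cur$timescales[names(start)]
    history <- rbind(history, data.frame(member = best_m, Ru = cur$Ru))
  }
  structure(list(mask = mask, Ru = cur$Ru, timescales = cur$timescales,
                 history = history),
            class = "ke_selection")
}

#' @export
print.ke_selection <- function(x, ...) {
  cat(sprintf("<ke_selection> %d/%d members, R_u = %.4f (%d accepted swaps)\n",
              sum(x$mask), length(x$mask), x$Ru, nrow(x$history) - 1L))
  invisible(x)
}

#' Random subensembles with a prescribed size distribution
#'
#' Uniform draws of member subsets without replacement, one per requested
#' size; deterministic for a fixed seed.  Used as the matched baseline for
#' greedy selections.
#'
#' @param ensemble a `ke_ensemble` (only its member count is used).
#' @param sizes subset sizes, each between 2 and the member count.
#' @param n number of draws; sizes are recycled over the draws.
#' @param seed RNG seed.
#' @return list of logical inclusion masks.
#' @export
random_subensembles <- function(ensemble, sizes, n = length(sizes),
                                seed = 1) {
  N <- n_members(ensemble)
  stopifnot(all(sizes >= 2), all(sizes <= N), n >= 1)
  sizes <- rep_len(sizes, n)
  with_seed(seed, {
    lapply(sizes, function(sz) {
      mask <- logical(N)
      mask[sample.int(N, sz)] <- TRUE
      mask
    })
  })
}
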