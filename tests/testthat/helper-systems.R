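# Shared fixture builders: all inputs are generated in code.

# ALA with a methyl plus two remote protons, small Gaussian spread
make_methyl_ensemble <- function(n_members = 3, seed = 3, sd = 0.2) {
  atoms <- data.frame(
    atom_id = c("1.HB1", "1.HB2", "1.HB3", "1.HA", "2.HN"),
    resno = c(1, 1, 1, 1, 2),
    resname = c("ALA", "ALA", "ALA", "ALA", "GLY"),
    atom_name = c("HB1", "HB2", "HB3", "HA", "HN"),
    stringsAsFactors = FALSE
  )
  base <- rbind(c(0, 0, 0), c(1.78, 0, 0), c(0.89, 1.54, 0),
                c(0.6, 0.5, 2.4), c(3.4, 1.2, 1.0))
  co <- array(0, c(5, 3, n_members))
  set.seed(seed)
  for (k in seq_len(n_members)) {
    co[, , k] <- base + matrix(stats::rnorm(15, sd = sd), ncol = 3)
  }
  ens <- ke_ensemble(atoms, co)
  ens$rotation_groups <- detect_rotation_groups(ens)
  ens
}

# PHE ring protons (flip-exchangeable HD/HE pairs) plus one remote proton
make_aromatic_ensemble <- function(n_members = 2, seed = 8, sd = 0.1) {
  atoms <- data.frame(
    atom_id = paste0("1.", c("HD1", "HD2", "HE1", "HE2", "HB2")),
    resno = 1, resname = "PHE",
    atom_name = c("HD1", "HD2", "HE1", "HE2", "HB2"),
    stringsAsFactors = FALSE
  )
  # flattened hexagon-ish arrangement
  base <- rbind(c(2.14, 1.24, 0), c(-2.14, 1.24, 0),
                c(2.14, 3.71, 0), c(-2.14, 3.71, 0), c(0.5, -1.8, 0.8))
  co <- array(0, c(5, 3, n_members))
  set.seed(seed)
  for (k in seq_len(n_members)) {
    co[, , k] <- base + matrix(stats::rnorm(15, sd = sd), ncol = 3)
  }
  ens <- ke_ensemble(atoms, co)
  ens$rotation_groups <- detect_rotation_groups(ens)
  ens
}

# two-macrostate ensemble with group labels (planted hierarchical kinetics)
make_grouped_ensemble <- function(n_open = 5, n_closed = 3, n_protons = 8,
                                  shift = c(1.0, -0.8, 0.6),
                                  seed_open = 31, seed_closed = 32,
                                  sd = 0.25) {
  gA <- generate_synthetic_ensemble(n_open, n_protons,
                                    displacement_scale = sd, seed = seed_open)
  gB <- generate_synthetic_ensemble(n_closed, n_protons,
                                    displacement_scale = sd, seed = seed_closed)
  gB$coords <- gB$coords +
    array(rep(shift, each = n_protons), c(n_protons, 3, n_closed))
  co <- array(0, c(n_protons, 3, n_open + n_closed))
  co[, , seq_len(n_open)] <- gA$coords
  co[, , n_open + seq_len(n_closed)] <- gB$coords
  ens <- ke_ensemble(gA$atoms, co,
                     group_labels = c(rep("open", n_open),
                                      rep("closed", n_closed)))
  ens$rotation_groups <- list()
  ens
}

# reconstruct the projector matrix encoded by a fast-path recipe entry
recipe_projector <- function(entry, pi) kinens:::recipe_projector(entry, pi)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}

# merge prefactors whose decay rates are indistinguishable at the
# eigendecomposition's clustering resolution, so that both routes can be
# compared even when timescales differ by many orders of magnitude
collapse_pf <- function(pf, tol = 1e-8) {
  ord <- order(pf$lambda, decreasing = TRUE)
  l <- pf$lambda[ord]; a <- pf$a[ord]
  gap <- tol * max(abs(l), 1)
  cl <- cumsum(c(TRUE, diff(l) < -gap))
  list(lambda = vapply(split(l, cl), mean, numeric(1)),
       a = vapply(split(a, cl), sum, numeric(1)))
}
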