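w0 <- 2 * pi * 900e6
K_solomon <- (1e-7)^2 * (1.054571817e-34)^2 * (2.6752218744e8)^4 / 10

# independent closed-form Solomon rates for a rigid pair at distance r (A)
rigid_rates <- function(r, tau_c, w = w0) {
  Jl <- function(om) 2 * tau_c / (1 + om^2 * tau_c^2) * (r * 1e-10)^-6
  list(sigma = K_solomon * (6 * Jl(2 * w) - Jl(0)),
       rho = K_solomon * (Jl(0) + 3 * Jl(w) + 6 * Jl(2 * w)))
}

test_that("a rigid pair reproduces the closed-form Solomon rates", {
  ens <- generate_synthetic_ensemble(1, 2, displacement_scale = 0, seed = 1)
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9)
  tau_c <- 4.3e-9
  mod <- relaxation_model(ens, sch)
  R <- relaxation_matrix(mod, tau_c)
  cf <- rigid_rates(3, tau_c)  # generator lattice spacing is 3 A
  expect_rel_equal(R[1, 2], cf$sigma, 1e-10)
  expect_rel_equal(R[1, 1], cf$rho, 1e-10)
  expect_equal(R, t(R))
  # macromolecular limit: J(0) dominates, sigma < 0
  expect_lt(R[1, 2], 0)
})

test_that("extreme narrowing gives sigma > 0 and sigma/rho -> 1/2", {
  ens <- generate_synthetic_ensemble(1, 2, displacement_scale = 0, seed = 1)
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9)
  mod <- relaxation_model(ens, sch)
  R <- relaxation_matrix(mod, tau_c = 1e-13)
  expect_gt(R[1, 2], 0)
  expect_equal(R[1, 2] / R[1, 1], 0.5, tolerance = 1e-3)
})

test_that("two-spin buildup equals the analytic 2x2 matrix exponential", {
  ens <- generate_synthetic_ensemble(1, 2, displacement_scale = 0, seed = 1)
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9)
  sys <- spin_system(ens)
  mod <- relaxation_model(ens, sch, sys)
  tau_c <- 4.3e-9
  R <- relaxation_matrix(mod, tau_c)
  rho <- R[1, 1]; sigma <- R[1, 2]
  tms <- c(0, 0.05, 0.2, 0.5)
  cv <- buildup_curves(R, sys, tms)
  cross <- cv[cv$group1 != cv$group2, ]
  closed <- 0.5 * exp(-(rho + sigma) * tms) - 0.5 * exp(-(rho - sigma) * tms)
  expect_equal(cross$intensity[order(cross$mixing_time)],
               closed[order(tms)], tolerance = 1e-12)
  # zero mixing time: identity transfer
  expect_equal(cv$intensity[cv$mixing_time == 0 & cv$group1 != cv$group2], 0)
  expect_equal(cv$intensity[cv$mixing_time == 0 & cv$group1 == cv$group2],
               rep(1, 2))
})

test_that("transfer decays monotonically and stays symmetric", {
  ens <- generate_synthetic_ensemble(4, 6, displacement_scale = 0.3, seed = 6)
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9)
  sys <- spin_system(ens)
  mod <- relaxation_model(ens, sch, sys)
  R <- relaxation_matrix(mod, 4e-9)
  e <- eigen(R, symmetric = TRUE)
  tms <- seq(0, 0.6, 0.1)
  totals <- vapply(tms, function(tm) {
    Tm <- e$vectors %*% (exp(-tm * e$values) * t(e$vectors))
    expect_equal(Tm, t(Tm), tolerance = 1e-12)
    sum(rowSums(Tm))
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
  expect_true(all(totals > 0))
})

test_that("methyl pairs equal brute-force enumeration over relabeled members", {
  ens <- make_methyl_ensemble(n_members = 3)
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9, tau_methyl = 1e-12)
  # methyl proton HB1 (atom 1) against remote HA (atom 4)
  fast <- kinens:::pair_basis(ens, sch, 1, 4, method = "fast")
  # brute force: triple the ensemble, relabel methyl hydrogens cyclically
  rm <- kronecker_sum(uniform_jump_matrix(3, 2e-9),
                      rotation_rate_matrix(3, 1e-12))
  vecs <- matrix(0, 9, 3)
  s <- 0
  for (m in 1:3) {
    for (r in 0:2) {
      s <- s + 1
      relabeled <- c(1, 2, 3)[(((1:3) - 1 + r) %% 3) + 1][1]
      vecs[s, ] <- ens$coords[4, , m] - ens$coords[relabeled, , m]
    }
  }
  brute <- averaged_prefactors(ke_geometry(vecs, populations = rm$pi), rm,
                               method = "general")
  ord <- order(brute$lambda, decreasing = TRUE)
  expect_equal(fast$lambda, brute$lambda[ord], tolerance = 1e-6)
  expect_rel_equal(fast$a, brute$a[ord], 1e-10)

  # intra-methyl pair: both protons relabel jointly under one rotation
  fastm <- kinens:::pair_basis(ens, sch, 1, 2, method = "fast")
  genm <- kinens:::pair_basis(ens, sch, 1, 2, method = "general")
  ordm <- order(genm$lambda, decreasing = TRUE)
  expect_rel_equal(fastm$a, genm$a[ordm], 1e-10)
})

test_that("methyl-methyl pairs expand over 9 rotational states", {
  # VAL-like residue with two methyls close together
  atoms <- data.frame(
    atom_id = paste0("1.", c("HG11", "HG12", "HG13", "HG21", "HG22", "HG23")),
    resno = 1, resname = "VAL",
    atom_name = c("HG11", "HG12", "HG13", "HG21", "HG22", "HG23"),
    stringsAsFactors = FALSE)
  base <- rbind(c(0, 0, 0), c(1.78, 0, 0), c(0.89, 1.54, 0),
                c(0.3, 0.4, 3.0), c(2.0, 0.4, 3.2), c(1.1, 1.9, 3.1))
  co <- array(0, c(6, 3, 2))
  set.seed(12)
  for (k in 1:2) co[, , k] <- base + matrix(stats::rnorm(18, sd = 0.1), ncol = 3)
  ens <- ke_ensemble(atoms, co)
  ens$rotation_groups <- detect_rotation_groups(ens)
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9, tau_methyl = 1e-12)
  fast <- kinens:::pair_basis(ens, sch, 1, 4, method = "fast")
  gen <- kinens:::pair_basis(ens, sch, 1, 4, method = "general")
  ord <- order(gen$lambda, decreasing = TRUE)
  expect_rel_equal(fast$a, gen$a[ord], 1e-10)
  # the double-rotation decay -2/tau_methyl appears in the basis
  expect_true(any(abs(fast$lambda + 2e12) / 2e12 < 1e-6))
})

test_that("aromatic ring flips give QD/QE pseudoatoms and consistent prefactors", {
  ens <- make_aromatic_ensemble()
  sys <- spin_system(ens)
  expect_setequal(unique(sys$labels), c("F1.QD", "F1.QE", "F1.HB2"))
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9, tau_aromatic = 1e-4)
  fast <- kinens:::pair_basis(ens, sch, 1, 5, method = "fast")
  gen <- kinens:::pair_basis(ens, sch, 1, 5, method = "general")
  ord <- order(gen$lambda, decreasing = TRUE)
  expect_rel_equal(fast$a, gen$a[ord], 1e-10)
})

test_that("simulated tables are deterministic and noiseless at sd = 0", {
  ens <- make_methyl_ensemble()
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9)
  tms <- seq(0.05, 0.3, 0.05)
  t1 <- simulate_buildup_table(ens, sch, tau_c = 4e-9, mixing_times = tms)
  sys <- spin_system(ens)
  mod <- relaxation_model(ens, sch, sys)
  cv <- buildup_curves(relaxation_matrix(mod, 4e-9), sys, tms)
  cv <- cv[cv$group1 != cv$group2, ]
  expect_equal(t1$intensity, cv$intensity)
  expect_equal(t1$mixing_time_ms, cv$mixing_time * 1000)
  # noise is reproducible per seed and multiplicative
  n1 <- simulate_buildup_table(ens, sch, 4e-9, tms, noise_sd = 0.05, seed = 7)
  n2 <- simulate_buildup_table(ens, sch, 4e-9, tms, noise_sd = 0.05, seed = 7)
  n3 <- simulate_buildup_table(ens, sch, 4e-9, tms, noise_sd = 0.05, seed = 8)
  expect_identical(n1$intensity, n2$intensity)
  expect_false(identical(n1$intensity, n3$intensity))
  # default experimental grid: 34 mixing times, 5-500 ms
  t34 <- simulate_buildup_table(ens, sch, tau_c = 4e-9)
  expect_equal(sort(unique(t34$mixing_time_ms)), seq(5, 500, 15))
})

test_that("buildup tables round-trip through TSV, replicate optional", {
  ens <- make_methyl_ensemble()
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9)
  tab <- simulate_buildup_table(ens, sch, 4e-9, seq(0.05, 0.2, 0.05))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_buildup_table(tab, f)
  back <- read_buildup_table(f)
  expect_equal(back$intensity, tab$intensity, tolerance = 1e-12)
  # replicate column tolerated when missing
  tab2 <- tab[, setdiff(names(tab), "replicate")]
  write_buildup_table(tab2, f)
  back2 <- read_buildup_table(f)
  expect_equal(back2$replicate, rep(1L, nrow(tab2)))
})

test_that("scoring the generating ensemble against its own table gives R_u = 1", {
  ens <- make_methyl_ensemble()
  sch <- ke_scheme("uniform", tau_ensemble = 2e-9)
  tab <- simulate_buildup_table(ens, sch, 4e-9, seq(0.05, 0.35, 0.05))
  sc <- score_ensemble(ens, tab, sch, 4e-9)
  expect_equal(sc$Ru, 1, tolerance = 1e-12)
})
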