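test_that("structured rate matrices have the advertised spectra", {
  # uniform N-site jump: rates 1/(N tau), one zero + N-1 degenerate
  u <- uniform_jump_matrix(4, 1)
  expect_equal(u$Q[1, 2], 0.25)
  expect_equal(diag(u$Q), rep(-0.75, 4))
  ev <- sort(eigen(u$Q, only.values = TRUE)$values)
  expect_equal(ev, c(-1, -1, -1, 0), tolerance = 1e-12)

  u2 <- uniform_jump_matrix(2, 1)
  expect_equal(u2$Q, matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2), tolerance = 1e-15)

  # hierarchical: exactly three distinct eigenvalues {0, -1/slow, -1/fast}
  h <- hierarchical_matrix(c(5, 3), 1e-6, 1.4e-9)
  sh <- spectral_structure(h)
  expect_equal(sh$values, c(0, -1e6, -1 / 1.4e-9), tolerance = 1e-9)
  expect_equal(sum(sh$multiplicity), 8)
  expect_equal(sh$multiplicity[1], 1)
  expect_error(hierarchical_matrix(c(5, 3), 1e-9, 1e-6),
               "negative intra-group rate")
  # membership permutation must not change the spectrum
  hp <- hierarchical_matrix(NULL, 1e-6, 1.4e-9,
                            membership = c(1, 2, 1, 1, 2, 1, 2, 1))
  expect_equal(spectral_structure(hp)$values, sh$values, tolerance = 1e-9)
  # single group degenerates to the uniform jump
  h1 <- hierarchical_matrix(4, 123, 1)
  expect_equal(h1$Q, uniform_jump_matrix(4, 1)$Q)

  # rotations: uniform jumps over 2 or 3 sites with rates 1/(order tau)
  r3 <- rotation_rate_matrix(3, 1e-12)
  expect_equal(r3$Q[1, 2], 1 / 3e-12)
  expect_equal(sort(eigen(r3$Q, only.values = TRUE)$values),
               c(-1e12, -1e12, 0), tolerance = 1e-3)
  r2 <- rotation_rate_matrix(2, 1e-4)
  expect_equal(r2$Q, matrix(c(-5e3, 5e3, 5e3, -5e3), 2, 2))
})

test_that("constructed generators satisfy the Markov invariants", {
  mats <- list(uniform_jump_matrix(7, 2e-9),
               hierarchical_matrix(c(4, 3), 1e-7, 1e-9),
               two_state_matrix(0.3, 1e-8),
               kronecker_sum(uniform_jump_matrix(3, 2e-9),
                             rotation_rate_matrix(3, 1e-12)))
  for (rm in mats) {
    s <- nrow(rm$Q)
    expect_lt(max(abs(rowSums(rm$Q))) / max(abs(rm$Q)), 1e-12)
    expect_equal(as.vector(rm$pi %*% rm$Q) / max(abs(rm$Q)), rep(0, s),
                 tolerance = 1e-12)
    # detailed balance
    flux <- rm$pi * rm$Q
    expect_lt(max(abs(flux - t(flux))) / max(abs(flux)), 1e-12)
    # propagator rows are probability vectors
    P <- propagator(rm, 0.5 / max(abs(diag(rm$Q))))
    expect_equal(rowSums(P), rep(1, s), tolerance = 1e-10)
    expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
  }
})

test_that("spectral projectors resolve the identity and are orthogonal", {
  mats <- list(uniform_jump_matrix(6, 1e-9),
               hierarchical_matrix(c(3, 2, 4), 1e-7, 1e-9),
               two_state_matrix(0.8, 1e-8),
               kronecker_sum(uniform_jump_matrix(4, 2e-9),
                             rotation_rate_matrix(2, 1e-4)))
  for (rm in mats) {
    ss <- spectral_structure(rm)
    s <- nrow(rm$Q)
    expect_equal(Reduce(`+`, ss$projectors), diag(s), tolerance = 1e-9)
    for (a in seq_along(ss$projectors)) {
      for (b in seq_along(ss$projectors)) {
        prod <- ss$projectors[[a]] %*% ss$projectors[[b]]
        target <- if (a == b) ss$projectors[[a]] else matrix(0, s, s)
        expect_equal(prod, target, tolerance = 1e-9)
      }
    }
    expect_equal(sum(ss$multiplicity), s)
  }
})

test_that("fast-path recipes reproduce brute-force projectors entrywise", {
  cases <- list(
    uniform = uniform_jump_matrix(5, 2e-9),
    hierarchical = hierarchical_matrix(c(5, 3), 1e-6, 1.4e-9),
    rotation = rotation_rate_matrix(3, 1e-12),
    two_state = two_state_matrix(0.3, 5e-9),
    methyl_pair = kronecker_sum(uniform_jump_matrix(4, 2e-9),
                                rotation_rate_matrix(3, 1e-12)),
    double_rotation = kronecker_sum(
      kronecker_sum(uniform_jump_matrix(3, 2e-9),
                    rotation_rate_matrix(3, 1e-12)),
      rotation_rate_matrix(3, 1e-12))
  )
  for (nm in names(cases)) {
    rm <- cases[[nm]]
    ss <- spectral_structure(rm)
    decays <- kinens:::recipe_decay_rates(rm)
    expect_equal(sort(-decays), sort(ss$values), tolerance = 1e-8)
    for (k in seq_along(rm$recipes)) {
      A_fast <- recipe_projector(rm$recipes[[k]], rm$pi)
      j <- which.min(abs(ss$values + decays[k]))
      expect_lt(max(abs(A_fast - ss$projectors[[j]])), 1e-10)
    }
  }
})

test_that("the uniform jump projector at zero is the flat matrix", {
  u <- uniform_jump_matrix(4, 1e-9)
  ss <- spectral_structure(u)
  expect_equal(ss$projectors[[1]], matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(ss$projectors[[2]], diag(4) - matrix(0.25, 4, 4),
               tolerance = 1e-12)
})

test_that("Kronecker sums compose spectra and stationary laws", {
  A <- uniform_jump_matrix(2, 1 / 3)     # eigenvalues {0, -3}
  B <- rotation_rate_matrix(3, 1 / 5)    # eigenvalues {0, -5, -5}
  AB <- kronecker_sum(A, B)
  ev <- sort(eigen(AB$Q, only.values = TRUE)$values)
  expect_equal(ev, sort(c(0, -3, -5, -5, -8, -8)), tolerance = 1e-9)
  expect_equal(AB$pi, rep(1 / 6, 6))
  # identity element: 1-state zero matrix
  one <- kinens:::single_state_matrix()
  expect_equal(kronecker_sum(A, one)$Q, A$Q)
  # repeated timescale names accumulate eigenvalue coefficients
  MM <- kronecker_sum(kronecker_sum(kinens:::single_state_matrix(),
                                    rotation_rate_matrix(3, 1e-12)),
                      rotation_rate_matrix(3, 1e-12))
  expect_equal(sort(unique(round(kinens:::recipe_decay_rates(MM), 3))),
               c(0, 1e12, 2e12))
  # a shared name with a conflicting value is refused
  expect_error(
    kronecker_sum(rotation_rate_matrix(3, 1e-12),
                  rotation_rate_matrix(3, 2e-12)),
    "conflicting")
})

test_that("degenerate or irregular generators are rejected", {
  # reducible: block-diagonal has two zero eigenvalues
  Q <- matrix(0, 4, 4)
  Q[1:2, 1:2] <- uniform_jump_matrix(2, 1)$Q
  Q[3:4, 3:4] <- uniform_jump_matrix(2, 1)$Q
  rm <- kinens:::new_rate_matrix(Q, rep(0.25, 4), c(ensemble = 1), NULL)
  expect_error(spectral_structure(rm), "reducible")
})

test_that("a single-state matrix has the trivial spectral structure", {
  one <- kinens:::single_state_matrix()
  ss <- spectral_structure(one)
  expect_equal(ss$values, 0)
  expect_equal(ss$projectors[[1]], matrix(1, 1, 1))
})
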