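test_that("quantum propagation matches closed forms and a brute-force oracle", {
  ## degenerate pair: P_2(t) = sin^2(t), complete transfer at pi/2
  times <- seq(0, 6, length.out = 601)
  tr <- evolve_quantum(tight_binding_hamiltonian(make_sc_chain(2, 1)), "1",
                       times)
  expect_all_close(tr$populations[, "2"], sin(times)^2, 1e-10)

  ## 6-cycle: P_4(t) = (1/9)(2 sin t - sin 2t)^2, so P_4(2 pi/3) = 3/4
  ring <- tight_binding_hamiltonian(make_two_path("I", 1, 1))
  tr <- evolve_quantum(ring, "1", times)
  expect_all_close(tr$populations[, "4"], oracle_ring6_p4(times), 1e-10)
  tr34 <- evolve_quantum(ring, "1", 2 * pi / 3)
  expect_equal(unname(tr34$populations[1, "4"]), 0.75, tolerance = 1e-12)

  ## arbitrary network vs the independent eigen/projector oracle
  net <- make_three_path("B")
  M <- tight_binding_hamiltonian(net)$matrix
  tr <- evolve_quantum(net |> tight_binding_hamiltonian(), "1", times)
  expect_all_close(tr$populations, oracle_populations(M, 1, times), 1e-9)
})

test_that("quantum propagation is unitary and time-reversible", {
  nets <- list(make_sc_chain(9, 0.8), make_two_path("III", 1, 0.3),
               make_trumpet16(1))
  for (net in nets) {
    H <- tight_binding_hamiltonian(net)
    tr <- evolve_quantum(H, net$allosteric, seq(0, 30, length.out = 501))
    expect_all_close(rowSums(tr$populations), 1, 1e-10)
    ## time reversal: applying the exact backward propagator exp(+iHt)
    ## (built independently here) to the package's W(t) returns W(0)
    M <- as.matrix(tight_binding_hamiltonian(net)$matrix)
    e <- eigen(M, symmetric = TRUE)
    i0 <- match(net$allosteric, net$sites$id)
    for (tt in c(3.7, 11.2)) {
      pm <- evolve_quantum(H, net$allosteric, c(-tt, tt))
      ## real symmetric H, real start: W(-t) = conj(W(t))
      expect_all_close(pm$populations[1, ], pm$populations[2, ], 1e-10)
      Uback <- e$vectors %*% diag(exp(1i * e$values * tt)) %*% t(e$vectors)
      w0 <- as.vector(Uback %*% pm$amplitudes[2, ])
      target <- numeric(n_sites(net)); target[i0] <- 1
      expect_all_close(Mod(w0 - target), 0, 1e-10)
    }
  }
})

test_that("long-time averages equal the spectral-projector formula", {
  ## 6-cycle and 5-chain, degenerate eigenvalues grouped in the oracle
  for (net in list(make_two_path("I", 1, 1), make_sc_chain(5, 1))) {
    M <- tight_binding_hamiltonian(net)$matrix
    tr <- evolve_quantum(tight_binding_hamiltonian(net), "1",
                         seq(0, 2000, length.out = 40001))
    eff <- transfer_efficiency(tr, 1000)
    expect_all_close(eff$P_mean, oracle_longtime_average(M, 1), 1e-3)
    expect_true(eff$converged)
  }
})

test_that("stepwise propagation reduces to the exact propagator", {
  net <- make_sc_chain(5, 1)
  H <- tight_binding_hamiltonian(net)
  const <- function(t) H
  tr_step <- evolve_stepwise(const, "1", dt = 0.01, t_end = 20, keep = 2000)
  tr_exact <- evolve_quantum(H, "1", tr_step$times)
  ## piecewise-constant steps of a constant H are exact
  expect_all_close(tr_step$populations, tr_exact$populations, 1e-8)
  expect_lt(tr_step$meta$norm_drift, 1e-9)

  ## Richardson self-convergence for a genuinely time-dependent schedule
  sched <- function(t) {
    M <- oracle_chain_matrix(4, 1 + 0.3 * sin(t))
    M
  }
  s1 <- evolve_stepwise(sched, 1, dt = 0.01, t_end = 8, keep = 800)
  s2 <- evolve_stepwise(sched, 1, dt = 0.005, t_end = 8, keep = 800)
  s3 <- evolve_stepwise(sched, 1, dt = 0.0025, t_end = 8, keep = 800)
  err12 <- max(abs(s1$populations - s2$populations))
  err23 <- max(abs(s2$populations - s3$populations))
  expect_lt(err23, err12)        # first-order scheme: halving dt helps
  expect_lt(err23, 5e-3)
})

test_that("Lanczos reduction is exact at full order and faithful at short times", {
  net <- make_two_path("II", 1, 0.6)
  H <- tight_binding_hamiltonian(net)
  n <- n_sites(net)
  red <- lanczos_reduce(H, "1", n)
  expect_true(all(red$beta >= 0))
  ## orthonormal Krylov basis
  G <- crossprod(red$basis)
  expect_all_close(G, diag(red$m), 1e-8)
  ## m = dim(H): same spectrum
  eT <- eigen(reduction_hamiltonian(red)$matrix, symmetric = TRUE,
              only.values = TRUE)$values
  eH <- eigen(H$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_all_close(sort(eT), sort(eH), 1e-8)

  ## an SC chain is already tridiagonal: alpha/beta reproduce it
  chain <- tight_binding_hamiltonian(make_sc_chain(6, 0.7))
  redc <- lanczos_reduce(chain, "1", 6)
  expect_all_close(redc$alpha, rep(0, 6), 1e-10)
  expect_all_close(abs(redc$beta), rep(0.7, 5), 1e-10)

  ## interior eigenvalues stay within the spectral range of H
  red3 <- lanczos_reduce(H, "1", 3)
  e3 <- eigen(reduction_hamiltonian(red3)$matrix, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(e3), min(eH) - 1e-10)
  expect_lte(max(e3), max(eH) + 1e-10)

  ## trumpet16, m = 8: door-state dynamics faithful for t in [0, 3];
  ## fidelity improves monotonically with m
  Ht <- tight_binding_hamiltonian(make_trumpet16(1))
  times <- seq(0, 3, length.out = 301)
  full <- evolve_quantum(Ht, "1", times)$populations[, 1]
  err_m <- vapply(c(2L, 3L, 8L), function(m) {
    rr <- lanczos_reduce(Ht, "1", m)
    redtr <- evolve_quantum(reduction_hamiltonian(rr), "k1", times)
    max(abs(redtr$populations[, 1] - full))
  }, numeric(1))
  expect_lt(err_m[3], 1e-3)
  expect_true(all(diff(err_m) <= 1e-12))

  ## breakdown: door state in an invariant subspace terminates early
  blocky <- hamiltonian(as.matrix(Matrix::bdiag(oracle_chain_matrix(3),
                                                oracle_chain_matrix(4))))
  redb <- lanczos_reduce(blocky, 1, 7)
  expect_true(redb$breakdown)
  expect_identical(redb$m, 3L)
})

test_that("classical master chain relaxes to uniform and conserves probability", {
  times <- c(0, 10^seq(-1, 4, length.out = 60))
  tr36 <- evolve_master_chain(36, 1, 1, times)
  expect_all_close(tr36$populations[length(times), ], 1 / 36, 1e-3)
  tr6 <- evolve_master_chain(6, 1, 1, times)
  expect_all_close(tr6$populations[length(times), ], 1 / 6, 1e-3)
  expect_all_close(rowSums(tr6$populations), 1, 1e-10)
  expect_true(all(tr6$populations >= 0))
  ## monotone contraction toward uniform
  d2 <- rowSums((tr6$populations - 1 / 6)^2)
  expect_true(all(diff(d2) <= 1e-12))
})

test_that("generic kinetic propagator handles rate generators", {
  ## K = 0: nothing moves
  tr <- evolve_kinetic(matrix(0, 3, 3), c(1, 0, 0), seq(0, 5, by = 0.5))
  expect_true(all(tr$populations[, 1] == 1))
  ## two-state balance: stationary P1 = k21 / (k12 + k21)
  k12 <- 0.7; k21 <- 0.2
  K <- matrix(c(-k12, k12, k21, -k21), 2)
  tr <- evolve_kinetic(K, c(1, 0), seq(0, 200, by = 1))
  expect_equal(unname(tr$populations[201, 1]), k21 / (k12 + k21),
               tolerance = 1e-9)
  ## symmetric generator: uniform stationary distribution
  Ks <- oracle_chain_matrix(4, 0.5)
  diag(Ks) <- -colSums(Ks)
  tr <- evolve_kinetic(Ks, c(0, 1, 0, 0), seq(0, 500, by = 5))
  expect_all_close(tr$populations[101, ], 0.25, 1e-6)
  ## invalid generators are rejected
  expect_error(evolve_kinetic(matrix(c(-1, 1, -0.1, 0.1), 2), c(1, 0), 0:3),
               "off-diagonal")
  expect_error(evolve_kinetic(matrix(c(-1, 0.5, 0.2, -0.2), 2), c(1, 0), 0:3),
               "sum to zero")
})

test_that("trajectories enforce their container invariants", {
  expect_error(trajectory(c(0, 1), matrix(c(0.6, 0.6, 0.5, 0.5), 2)),
               "sum to 1")
  expect_error(trajectory(c(1, 0), matrix(c(1, 1, 0, 0), 2)), "increasing")
  tr <- trajectory(c(0, 1), matrix(c(1, 0.5, 0, 0.5), 2), kind = "classical")
  expect_s3_class(tr, "trajectory")
})
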