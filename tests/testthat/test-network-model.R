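test_that("site networks validate their structural invariants", {
  ok <- site_network(c(a = 0, b = 1), data.frame(i = "a", j = "b", h = 0.5),
                     allosteric = "a", active = "b")
  expect_s3_class(ok, "site_network")
  expect_identical(n_sites(ok), 2L)

  expect_error(site_network(data.frame(id = c("a", "a"), energy = 0),
                            data.frame(i = "a", j = "a", h = 1), "a", "a"),
               "duplicated id")
  expect_error(site_network(c(a = 0, b = 0),
                            data.frame(i = "a", j = "c", h = 1), "a", "b"),
               "unknown site")
  expect_error(site_network(c(a = 0, b = 0),
                            data.frame(i = "a", j = "a", h = 1), "a", "b"),
               "self-coupling")
  expect_error(site_network(c(a = 0, b = 0),
                            data.frame(i = c("a", "b"), j = c("b", "a"),
                                       h = c(1, 1)), "a", "b"),
               "duplicated pair")
  expect_error(site_network(c(a = 0, b = 0),
                            data.frame(i = "a", j = "b", h = 1), "a", "a"),
               "must differ")
  expect_error(site_network(c(a = 0, b = 0),
                            data.frame(i = "a", j = "b", h = 1), "a", "z"),
               "active")
})

test_that("tight-binding Hamiltonian places energies and couplings correctly", {
  ## smallest nontrivial case: degenerate pair
  H2 <- tight_binding_hamiltonian(make_sc_chain(2, 1))
  expect_equal(unname(H2$matrix), matrix(c(0, 1, 1, 0), 2))

  ## the 8-site two-path case III matrix, including the (1, 8) = c*h corner
  h <- 0.7; cc <- 0.4
  H <- tight_binding_hamiltonian(make_two_path("III", h, cc))$matrix
  M <- matrix(0, 8, 8)
  M[1, 2] <- M[2, 3] <- M[3, 4] <- h
  M[4, 5] <- M[5, 6] <- M[6, 7] <- M[7, 8] <- M[1, 8] <- cc * h
  M <- M + t(M)
  expect_equal(unname(H), M)

  ## couplings listed one way only still give an exactly symmetric matrix
  net <- site_network(c(a = 0, b = 0, c = 0),
                      data.frame(i = c("a", "a"), j = c("b", "c"),
                                 h = c(0.3, -0.2)),
                      allosteric = "a", active = "c")
  Hm <- tight_binding_hamiltonian(net)$matrix
  expect_identical(Hm, t(Hm))
})

test_that("every fixture Hamiltonian is Hermitian and relabeling acts by conjugation", {
  fixtures <- list(make_sc_chain(6, 1), make_three_path("B"),
                   make_two_path("II", 1, 0.5), make_trumpet16(1),
                   make_double_trumpet22(1), make_grouped20("bridge"))
  for (net in fixtures) {
    M <- tight_binding_hamiltonian(net)$matrix
    expect_lt(max(abs(M - t(M))), 1e-12)
  }
  ## permuting site order of a 6-ring conjugates H by the permutation matrix
  ring <- make_two_path("I", 1, 1)
  perm <- c(3, 1, 6, 2, 5, 4)
  net_p <- site_network(ring$sites[perm, ], ring$couplings,
                        allosteric = ring$allosteric, active = ring$active)
  Hp <- tight_binding_hamiltonian(net_p)$matrix
  H <- tight_binding_hamiltonian(ring)$matrix
  P <- diag(6)[perm, ]
  expect_equal(unname(Hp), unname(P %*% H %*% t(P)))
})

test_that("hamiltonian constructor rejects non-Hermitian input", {
  M <- matrix(c(0, 1, 2, 0), 2)
  expect_error(hamiltonian(M), "Hermitian")
})

test_that("vibronic Hamiltonian reduces, block-diagonalizes and converges", {
  net <- site_network(c(a = 0.2, b = -0.1),
                      data.frame(i = "a", j = "b", h = 0.3),
                      allosteric = "a", active = "b")
  ## zero modes: identical to the tight-binding matrix
  Hv0 <- vibronic_hamiltonian(net, vibronic_spec(numeric(0),
                                                 matrix(0, 2, 0), integer(0)))
  expect_equal(Hv0$matrix, tight_binding_hamiltonian(net)$matrix)

  ## uncoupled mode (g = 0): spectrum = electronic + oscillator sums
  vib0 <- vibronic_spec(0.9, matrix(0, 2, 1), 3)
  Hv <- vibronic_hamiltonian(net, vib0)
  expect_equal(dim(Hv$matrix), c(8L, 8L))
  eel <- eigen(tight_binding_hamiltonian(net)$matrix, symmetric = TRUE,
               only.values = TRUE)$values
  eosc <- 0.9 * (0:3 + 0.5)
  expect_equal(sort(eigen(Hv$matrix, symmetric = TRUE,
                          only.values = TRUE)$values),
               sort(as.vector(outer(eel, eosc, "+"))))

  ## single uncoupled site: ladder spectrum E + omega (n + 1/2)
  net1 <- site_network(c(a = 0.4, far = 50),
                       data.frame(i = character(), j = character(),
                                  h = numeric()),
                       allosteric = "a", active = "far")
  vib1 <- vibronic_spec(1.3, matrix(0, 2, 1), 3)
  ev <- eigen(vibronic_hamiltonian(net1, vib1)$matrix, symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(sort(ev)[1:4], 0.4 + 1.3 * (0:3 + 0.5), tolerance = 1e-12)

  ## displaced oscillator: lowest eigenvalue -> E + omega/2 - g^2 omega
  g <- 0.5
  vibg <- vibronic_spec(1, matrix(c(g, 0), 2, 1), 30)
  ev <- eigen(vibronic_hamiltonian(net1, vibg)$matrix, symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(min(ev), oracle_displaced_min(0.4, 1, g), tolerance = 1e-8)
  ## truncation convergence: n_max = 10 is farther from the limit
  ev10 <- eigen(vibronic_hamiltonian(net1,
                                     vibronic_spec(1, matrix(c(g, 0), 2, 1),
                                                   10))$matrix,
                symmetric = TRUE, only.values = TRUE)$values
  expect_gte(abs(min(ev10) - oracle_displaced_min(0.4, 1, g)),
             abs(min(ev) - oracle_displaced_min(0.4, 1, g)))

  expect_error(vibronic_spec(1, matrix(0, 2, 1), -1), "n_max")
  expect_error(vibronic_spec(-1, matrix(0, 2, 1), 2), "omega")
})

test_that("harmonic-oscillator thermodynamics obey the closed forms and limits", {
  for (omega in c(0.5, 1, 2.7)) {
    for (temperature in c(0.2, 1, 5)) {
      th <- harmonic_thermo(omega, temperature)
      ## entropy identity S = ln Q + E / T
      expect_equal(th$S, log(th$Q) + th$E / temperature, tolerance = 1e-12)
      ## energy equals the numerical derivative -d ln Q / d beta
      expect_equal(th$E, oracle_harmonic_E(omega, temperature),
                   tolerance = 1e-6)
    }
  }
  ## ground-state limit: E -> omega/2, S -> 0
  th <- harmonic_thermo(2, 0.02)
  expect_equal(th$E, 1, tolerance = 1e-10)
  expect_lt(abs(th$S), 1e-10)
  ## classical limit: E -> k_B T
  th <- harmonic_thermo(0.01, 10)
  expect_equal(th$E, 10, tolerance = 1e-3)
  expect_error(harmonic_thermo(1, 0), "temperature")
  expect_error(harmonic_thermo(0, 1), "omega")
})

test_that("wavenumber conversion uses the reference energy", {
  expect_equal(energy_from_wavenumber(1000), 1)
  expect_equal(energy_from_wavenumber(100), 0.1)
  expect_equal(energy_from_wavenumber(250, reference = 500), 0.5)
  expect_error(energy_from_wavenumber(100, reference = 0), "reference")
})
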