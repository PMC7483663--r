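## Independent oracles used across the test files. These deliberately avoid
## the package's own propagation/fitting code paths.

## brute-force quantum populations via matrix exponential of a Hermitian
## matrix (series-free: spectral decomposition recomputed here on purpose,
## but through base eigen on the *complexified* matrix and explicit
## projectors, not the package's propagator)
oracle_populations <- function(M, start, times) {
  n <- nrow(M)
  e <- eigen(M)
  V <- e$vectors
  Vi <- solve(V)
  w0 <- numeric(n); w0[start] <- 1
  t(vapply(times, function(t) {
    w <- V %*% diag(exp(-1i * e$values * t), n) %*% Vi %*% w0
    as.numeric(Mod(w)^2)
  }, numeric(n)))
}

## spectral-projector long-time average: sum over distinct eigenvalues of
## |<a| Pi_E |i>|^2, grouping eigenvalues closer than 1e-9
oracle_longtime_average <- function(M, start) {
  e <- eigen(M, symmetric = TRUE)
  n <- nrow(M)
  groups <- cumsum(c(TRUE, abs(diff(e$values)) > 1e-9))
  out <- numeric(n)
  for (g in unique(groups)) {
    V <- e$vectors[, groups == g, drop = FALSE]
    amp <- V %*% Conj(t(V))[, start]   # Pi_E |start>
    out <- out + Mod(amp)^2
  }
  out
}

## 6-cycle active-site population: P_4(t) = (1/9) (2 sin t - sin 2t)^2
oracle_ring6_p4 <- function(t) (2 * sin(t) - sin(2 * t))^2 / 9

## central finite-difference energy of the harmonic oscillator,
## E = -d ln Q / d beta, with Q evaluated directly
oracle_harmonic_E <- function(omega, temperature, eps = 1e-6) {
  lnQ <- function(beta) -beta * omega / 2 - log1p(-exp(-beta * omega))
  beta <- 1 / temperature
  -(lnQ(beta + eps) - lnQ(beta - eps)) / (2 * eps)
}

## displaced-oscillator ground-state energy: E + omega/2 - g^2 omega
oracle_displaced_min <- function(E, omega, g) E + omega / 2 - g^2 * omega

## quick chain Hamiltonian matrix (bypasses the generators)
oracle_chain_matrix <- function(N, h = 1) {
  M <- matrix(0, N, N)
  for (i in seq_len(N - 1)) { M[i, i + 1] <- h; M[i + 1, i] <- h }
  M
}

expect_all_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
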