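#' Trajectory container
#'
#' Stores a time grid with per-basis-state populations and, for quantum
#' runs, the complex amplitudes. Quantum populations are |W_i(t)|^2 and sum
#' to one at every stored time; classical populations are nonnegative and
#' sum to one.
#'
#' @param times increasing numeric grid.
#' @param populations numeric matrix, one row per time, one column per basis
#'   label.
#' @param amplitudes optional complex matrix of the same shape (quantum).
#' @param kind `"quantum"` or `"classical"`.
#' @param labels basis labels (defaults to population column names).
#' @param meta named list of run metadata (propagator, dt, seed, ...).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, populations, amplitudes = NULL,
                       kind = c("quantum", "classical"), labels = NULL,
                       meta = list()) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  populations <- as.matrix(populations)
  if (is.unsorted(times, strictly = TRUE)) stop("times: must be increasing")
  if (nrow(populations) != length(times))
    stop("populations: one row per time required")
  if (is.null(labels)) labels <- colnames(populations)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(populations)))
  colnames(populations) <- labels
  sums <- rowSums(populations)
  if (any(abs(sums - 1) > 1e-9))
    stop("populations: rows must sum to 1 within 1e-9 (max deviation ",
         format(max(abs(sums - 1))), ")")
  if (kind == "classical" && any(populations < -1e-12))
    stop("populations: classical populations must be nonnegative")
  structure(list(times = times, populations = populations,
                 amplitudes = amplitudes, kind = kind,
                 labels = as.character(labels), meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$kind, ", ", length(x$times), " times in [",
      format(min(x$times)), ", ", format(max(x$times)), "], ",
      ncol(x$populations), " states\n", sep = "")
  invisible(x)
}

#' Default characterization time grid
#'
#' The default window [0, 4 N / |h|] sampled at `points` + 1 times: long
#' enough to capture the first passage at the active site for all the model
#' systems shipped with the package (up to 22 sites).
#'
#' @param N number of sites.
#' @param h coupling scale (|h| sets the natural time unit).
#' @param points number of sampling intervals.
#' @return numeric vector of times.
#' @export
default_time_grid <- function(N, h = 1, points = 2000) {
  seq(0, 4 * N / abs(h), length.out = points + 1L)
}

## index of a basis label (or numeric index passed through)
label_index <- function(start, labels) {
  if (is.numeric(start)) {
    i <- as.integer(start)
    if (i < 1L || i > length(labels)) stop("start: index out of range")
    return(i)
  }
  i <- match(as.character(start), labels)
  if (is.na(i)) stop("start: unknown basis label '", start, "'")
  i
}

#' Exact quantum propagation
#'
#' Evolves a state initially localized on one basis state under a constant
#' Hermitian Hamiltonian, W(t) = U exp(-i Lambda t) U^H W(0), via a single
#' eigendecomposition. Norm is conserved exactly up to round-off.
#'
#' @param H a `hamiltonian` (or Hermitian matrix).
#' @param start basis label (or index) populated at t = 0.
#' @param times time grid (need not start at 0).
#' @return A quantum `trajectory` with amplitudes and populations.
#' @examples
#' H <- tight_binding_hamiltonian(make_sc_chain(2, 1))
#' tr <- evolve_quantum(H, "1", seq(0, pi, length.out = 201))
#' max(tr$populations[, "2"])  # reaches 1 at t = pi/2
#' @export
evolve_quantum <- function(H, start, times) {
  M <- as_ham_matrix(H)
  n <- nrow(M)
  labels <- ham_labels(H, n)
  scale <- max(abs(M), 1)
  if (max(abs(M - Conj(t(M)))) > 1e-12 * scale) stop("H: not Hermitian")
  i0 <- label_index(start, labels)
  e <- eigen(if (is.complex(M)) M else (M + t(M)) / 2, symmetric = TRUE)
  U <- e$vectors
  c0 <- Conj(t(U))[, i0]                     # U^H e_start
  W <- vapply(times, function(t) as.vector(U %*% (exp(-1i * e$values * t) * c0)),
              complex(n))
  W <- t(W)
  colnames(W) <- labels
  trajectory(times, Mod(W)^2, amplitudes = W, kind = "quantum",
             labels = labels,
             meta = list(propagator = "eigen", start = labels[i0],
                         h_max = max(abs(M - diag(diag(M))))))
}

#' Piecewise-constant stepwise propagation
#'
#' Propagates under a time-dependent Hamiltonian by applying the exact
#' exponential of the Hamiltonian frozen at the start of each step:
#' W(t + dt) = exp(-i H(t) dt) W(t). Each step is unitary, so the norm is
#' conserved up to round-off; the total drift is checked against 1e-6 and a
#' warning with diagnostics is raised if exceeded. For a constant schedule
#' the result converges to [evolve_quantum()] as dt -> 0 (and agrees to
#' round-off at any dt).
#'
#' @param H_of_t function of time returning a `hamiltonian` or Hermitian
#'   matrix (evaluated at the start of each step).
#' @param start basis label (or index) populated at t = 0.
#' @param dt step size, > 0.
#' @param t_end final time.
#' @param keep approximate number of stored time points.
#' @return A quantum `trajectory`.
#' @export
evolve_stepwise <- function(H_of_t, start, dt, t_end, keep = 4000) {
  if (dt <= 0) stop("dt: must be > 0")
  H0 <- as_ham_matrix(H_of_t(0))
  n <- nrow(H0)
  labels <- ham_labels(H_of_t(0), n)
  i0 <- label_index(start, labels)
  W <- complex(n); W[i0] <- 1 + 0i
  steps <- ceiling(t_end / dt)
  every <- max(1L, floor(steps / keep))
  nk <- floor(steps / every) + 1L
  times <- numeric(nk); P <- matrix(0, nk, n); A <- matrix(0i, nk, n)
  times[1L] <- 0; P[1L, ] <- Mod(W)^2; A[1L, ] <- W
  k <- 1L
  hmax <- 0
  for (s in seq_len(steps)) {
    M <- as_ham_matrix(H_of_t((s - 1L) * dt))
    hmax <- max(hmax, abs(M - diag(diag(M))))
    e <- eigen(if (is.complex(M)) M else (M + t(M)) / 2, symmetric = TRUE)
    W <- as.vector(e$vectors %*% (exp(-1i * e$values * dt) *
                                    crossprod(Conj(e$vectors), W)))
    if (s %% every == 0L) {
      k <- k + 1L
      times[k] <- s * dt; P[k, ] <- Mod(W)^2; A[k, ] <- W
    }
  }
  drift <- abs(sum(Mod(W)^2) - 1)
  if (drift > 1e-6)
    warning(sprintf("norm drift %.3g after %d steps (dt = %g)", drift, steps, dt))
  ## renormalize stored rows against round-off so the container invariant holds
  P <- P[1:k, , drop = FALSE] / rowSums(P[1:k, , drop = FALSE])
  colnames(P) <- labels
  trajectory(times[1:k], P, amplitudes = A[1:k, , drop = FALSE],
             kind = "quantum", labels = labels,
             meta = list(propagator = "stepwise", dt = dt, start = labels[i0],
                         norm_drift = drift, h_max = hmax))
}

#' Lanczos tridiagonalization from a door state
#'
#' Standard Lanczos recursion with full reorthogonalization starting from a
#' basis (door) state: produces an m x m tridiagonal matrix T whose
#' eigenvalues lie within the spectral range of H and whose short-time
#' dynamics from the first Krylov vector reproduce the full dynamics of the
#' door state. On breakdown (off-diagonal beta ~ 0, i.e. an invariant
#' subspace was found) the recursion stops early and the result is flagged.
#'
#' @param H a `hamiltonian` (or Hermitian matrix).
#' @param door basis label (or index) of the door state.
#' @param m requested Krylov dimension, 1 <= m <= dim(H).
#' @return An object of class `tridiagonal_reduction` with fields `alpha`
#'   (diagonal), `beta` (off-diagonal, >= 0), `basis` (orthonormal Krylov
#'   vectors as columns), `m` (achieved dimension), `breakdown` (logical).
#' @export
lanczos_reduce <- function(H, door, m) {
  M <- as_ham_matrix(H)
  n <- nrow(M)
  labels <- ham_labels(H, n)
  m <- as.integer(m)
  if (m < 1L || m > n) stop("m: must satisfy 1 <= m <= dim(H)")
  i0 <- label_index(door, labels)
  V <- matrix(if (is.complex(M)) 0i else 0, n, m)
  v <- V[, 1L]; v[i0] <- 1
  V[, 1L] <- v
  alpha <- numeric(m); beta <- numeric(max(m - 1L, 0L))
  breakdown <- FALSE
  m_out <- m
  for (k in seq_len(m)) {
    w <- M %*% V[, k]
    alpha[k] <- Re(sum(Conj(V[, k]) * w))
    w <- w - alpha[k] * V[, k]
    if (k > 1L) w <- w - beta[k - 1L] * V[, k - 1L]
    ## full reorthogonalization (twice is enough)
    for (rep in 1:2) w <- w - V[, 1:k, drop = FALSE] %*%
      crossprod(Conj(V[, 1:k, drop = FALSE]), w)
    if (k < m) {
      b <- sqrt(Re(sum(Conj(w) * w)))
      if (b < 1e-12 * max(abs(M), 1)) {
        breakdown <- TRUE
        m_out <- k
        break
      }
      beta[k] <- b
      V[, k + 1L] <- as.vector(w) / b
    }
  }
  structure(list(alpha = alpha[seq_len(m_out)],
                 beta = if (m_out > 1L) beta[seq_len(m_out - 1L)] else numeric(0),
                 basis = V[, seq_len(m_out), drop = FALSE],
                 m = m_out, breakdown = breakdown, door = labels[i0]),
            class = "tridiagonal_reduction")
}

#' @export
print.tridiagonal_reduction <- function(x, ...) {
  cat("<tridiagonal_reduction> m =", x$m,
      if (x$breakdown) "(early termination)" else "", "\n")
  invisible(x)
}

#' Hamiltonian of a Lanczos reduction
#'
#' Assembles the tridiagonal matrix T of a [lanczos_reduce()] result as a
#' `hamiltonian` over Krylov labels `k1, k2, ...`; evolving it from `"k1"`
#' reproduces the door-state dynamics of the full system over a limited time
#' range.
#'
#' @param red a `tridiagonal_reduction`.
#' @return A `hamiltonian`.
#' @export
reduction_hamiltonian <- function(red) {
  stopifnot(inherits(red, "tridiagonal_reduction"))
  m <- red$m
  T <- diag(red$alpha, m)
  if (m > 1L) {
    idx <- cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)
    T[idx] <- red$beta
    T[idx[, 2:1, drop = FALSE]] <- red$beta
  }
  hamiltonian(T, paste0("k", seq_len(m)))
}

#' Classical master equation on a degenerate chain
#'
#' Solves dP_i/dt = h P_{i-1} - 2 h P_i + h P_{i+1} with single-neighbor end
#' rows (dP_1/dt = h P_2 - h P_1 and its mirror) and P_start(0) = 1, by exact
#' matrix exponential of the symmetric generator. The long-time limit is the
#' uniform distribution 1/N.
#'
#' @param N chain length, >= 2.
#' @param h hopping rate, > 0.
#' @param start initial site index.
#' @param times time grid.
#' @return A classical `trajectory`.
#' @export
evolve_master_chain <- function(N, h = 1, start = 1L, times) {
  N <- as.integer(N)
  if (N < 2L) stop("N: need at least 2 sites")
  if (h <= 0) stop("h: must be > 0")
  K <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) { K[i, i + 1L] <- h; K[i + 1L, i] <- h }
  diag(K) <- -colSums(K)
  e <- eigen(K, symmetric = TRUE)
  c0 <- e$vectors[start, ]                 # V^T e_start (V orthogonal)
  P <- t(vapply(times, function(t)
    as.vector(e$vectors %*% (exp(e$values * t) * c0)), numeric(N)))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  colnames(P) <- site_ids(N)
  trajectory(times, P, kind = "classical",
             meta = list(propagator = "master_chain", h = h, start = start))
}

#' Generic kinetic propagation P(t) = exp(K t) P0
#'
#' Propagates a probability distribution under a continuous-time rate
#' generator K (column convention: off-diagonal K[i, j] >= 0 is the j -> i
#' rate, columns sum to zero). On a uniform grid the one-step exponential is
#' computed once and iterated; otherwise exp(K t) is computed per time.
#'
#' @param K square generator matrix.
#' @param P0 initial distribution (nonnegative, sums to 1).
#' @param times time grid starting at 0.
#' @return A classical `trajectory`.
#' @export
evolve_kinetic <- function(K, P0, times) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("K: must be square")
  offdiag <- K - diag(diag(K))
  if (any(offdiag < -1e-12)) stop("K: off-diagonal rates must be >= 0")
  if (any(abs(colSums(K)) > 1e-9 * max(abs(K), 1)))
    stop("K: columns must sum to zero (generator convention)")
  P0 <- as.numeric(P0)
  if (length(P0) != n || any(P0 < 0) || abs(sum(P0) - 1) > 1e-9)
    stop("P0: must be a distribution over ", n, " states")
  labels <- if (!is.null(rownames(K))) rownames(K) else site_ids(n)
  dts <- diff(times)
  uniform <- length(times) > 1L && diff(range(dts)) < 1e-12 * max(dts)
  P <- matrix(0, length(times), n)
  if (uniform && abs(times[1L]) < 1e-15) {
    E1 <- as.matrix(Matrix::expm(K * dts[1L]))
    p <- P0
    P[1L, ] <- p
    for (k in 2L:length(times)) { p <- E1 %*% p; P[k, ] <- p }
  } else {
    for (k in seq_along(times))
      P[k, ] <- as.numeric(as.matrix(Matrix::expm(K * times[k])) %*% P0)
  }
  P[P < 0] <- 0
  P <- P / rowSums(P)
  colnames(P) <- labels
  trajectory(times, P, kind = "classical",
             meta = list(propagator = "kinetic"))
}

#' Write a trajectory to CSV
#'
#' Column layout: `time`, one `P_<label>` column per basis state and, when
#' amplitudes are present and `amplitudes = TRUE`, `ReW_<label>` and
#' `ImW_<label>` columns. Times are written in natural units by default; with
#' `time_unit = "pi"` they are rescaled by 1/pi (the period of a degenerate
#' pair at h = 1 being pi).
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param amplitudes write amplitude columns when available.
#' @param time_unit `"natural"` or `"pi"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, amplitudes = !is.null(traj$amplitudes),
                             time_unit = c("natural", "pi")) {
  time_unit <- match.arg(time_unit)
  tt <- traj$times / if (time_unit == "pi") pi else 1
  df <- data.frame(time = tt)
  pp <- traj$populations
  colnames(pp) <- paste0("P_", traj$labels)
  df <- cbind(df, as.data.frame(pp, check.names = FALSE))
  if (isTRUE(amplitudes) && !is.null(traj$amplitudes)) {
    re <- Re(traj$amplitudes); im <- Im(traj$amplitudes)
    colnames(re) <- paste0("ReW_", traj$labels)
    colnames(im) <- paste0("ImW_", traj$labels)
    df <- cbind(df, as.data.frame(re, check.names = FALSE),
                as.data.frame(im, check.names = FALSE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file.
#' @param kind `"quantum"` or `"classical"`; defaults to quantum when
#'   amplitude columns are present.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, kind = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  pcols <- grep("^P_", names(df), value = TRUE)
  labels <- sub("^P_", "", pcols)
  P <- as.matrix(df[, pcols, drop = FALSE])
  colnames(P) <- labels
  recols <- paste0("ReW_", labels)
  A <- NULL
  if (all(recols %in% names(df))) {
    A <- as.matrix(df[, recols, drop = FALSE]) +
      1i * as.matrix(df[, paste0("ImW_", labels), drop = FALSE])
    colnames(A) <- labels
  }
  if (is.null(kind)) kind <- if (is.null(A)) "classical" else "quantum"
  trajectory(df$time, P, amplitudes = A, kind = kind, labels = labels)
}
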