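#' Coupling schedules
#'
#' Describes how couplings change in time during propagation:
#' `"constant"` (Markovian, no change), `"population_coupled"` (each
#' consecutive coupling is updated from the instantaneous population of the
#' transition's starting site, h(t) = (1 + x P_i(t)) h — a non-Markovian
#' rule), or `"random_environment"` (at regular event times a random subset
#' of couplings receives an additive uniform perturbation — environmental
#' modulation).
#'
#' @param kind schedule kind.
#' @param x population-coupling factor (e.g. +0.2 "small-up", -0.8
#'   "large-down").
#' @param fraction fraction of couplings perturbed per event, in [0, 1].
#' @param amplitude perturbation amplitude as a multiple of the base
#'   coupling.
#' @param events_per_period perturbation events per natural period pi/|h|
#'   (e.g. 1/8, 1/4 or 1), > 0.
#' @param seed mandatory integer seed for the stochastic kind.
#' @param persist if `TRUE`, perturbations on edges not redrawn at an event
#'   are kept; default re-draws the whole perturbation at each event.
#' @return An object of class `coupling_schedule`.
#' @export
coupling_schedule <- function(kind = c("constant", "population_coupled",
                                       "random_environment"),
                              x = 0, fraction = 0, amplitude = 0,
                              events_per_period = 1, seed = NULL,
                              persist = FALSE) {
  kind <- match.arg(kind)
  if (fraction < 0 || fraction > 1) stop("fraction: must lie in [0, 1]")
  if (kind == "random_environment") {
    if (events_per_period <= 0) stop("events_per_period: must be > 0")
    if (is.null(seed)) stop("seed: mandatory for stochastic schedules")
  }
  structure(list(kind = kind, x = x, fraction = fraction,
                 amplitude = amplitude, events_per_period = events_per_period,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 persist = isTRUE(persist)),
            class = "coupling_schedule")
}

#' Population-coupled coupling value
#'
#' The non-Markovian update rule: the coupling of the i -> i+1 transition is
#' scaled by the fraction of the perturbation wave currently at the starting
#' site, h(t) = (1 + x * P_i(t)) * h.
#'
#' @param h base coupling.
#' @param x coupling factor (the paper's cases use +-0.2 and +-0.8).
#' @param P_source population of the transition's starting site, in [0, 1].
#' @return the updated coupling.
#' @examples
#' population_coupled_h(1, 0.2, 1)  # 1.2
#' @export
population_coupled_h <- function(h, x, P_source) {
  if (any(P_source < -1e-12 | P_source > 1 + 1e-12))
    stop("P_source: must lie in [0, 1]")
  (1 + x * P_source) * h
}

## assert net is a sequential chain in site order; return couplings h_1..h_{N-1}
chain_couplings <- function(net) {
  ids <- net$sites$id
  N <- length(ids)
  cp <- net$couplings
  if (nrow(cp) != N - 1L) stop("network: not a sequential chain")
  ii <- match(cp$i, ids); jj <- match(cp$j, ids)
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  if (!setequal(lo, seq_len(N - 1L)) || any(hi != lo + 1L))
    stop("network: not a sequential chain")
  h <- numeric(N - 1L)
  h[lo] <- cp$h
  h
}

#' Propagation with population-coupled couplings
#'
#' Stepwise propagation of a sequential chain in which, at the start of each
#' step, every consecutive coupling h_{i,i+1} is recomputed from the current
#' population of one end of the bond via [population_coupled_h()], then one
#' exact exponential step of length dt is taken (explicit piecewise-constant
#' scheme). With x = 0 this reproduces the Markovian chain trajectory.
#'
#' With the wave launched at site 1, driving the bond from its *distal* end
#' (site i+1, the end nearer the active site) reproduces the reported
#' behavior of this model: a coupling that increases with the passing wave
#' (x > 0) shortens the arrival time and delivers a smaller, narrower wave,
#' and vice versa. Driving from the proximal end (site i) inverts the
#' amplitude trend; it is provided for comparison.
#'
#' @param net a sequential-chain `site_network`.
#' @param x population-coupling factor.
#' @param dt step size; default 0.005 / |h_max|.
#' @param t_end final time; default 4 N / |h_max|.
#' @param driver which end of bond (i, i+1) supplies the population:
#'   `"distal"` (site i+1, default) or `"proximal"` (site i).
#' @param keep approximate number of stored times.
#' @return A quantum `trajectory`.
#' @export
evolve_population_coupled <- function(net, x, dt = NULL, t_end = NULL,
                                      driver = c("distal", "proximal"),
                                      keep = 4000) {
  driver <- match.arg(driver)
  validate_site_network(net)
  h0 <- chain_couplings(net)
  N <- n_sites(net)
  hs <- max(abs(h0))
  if (is.null(dt)) dt <- 0.005 / hs
  if (is.null(t_end)) t_end <- 4 * N / hs
  en <- net$sites$energy
  i0 <- label_index(net$allosteric, net$sites$id)
  W <- complex(N); W[i0] <- 1 + 0i
  steps <- ceiling(t_end / dt)
  every <- max(1L, floor(steps / keep))
  nk <- floor(steps / every) + 1L
  times <- numeric(nk); P <- matrix(0, nk, N)
  times[1L] <- 0; P[1L, ] <- Mod(W)^2
  k <- 1L
  H <- matrix(0, N, N); diag(H) <- en
  idx_up <- cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L)
  idx_lo <- idx_up[, 2:1, drop = FALSE]
  drv <- if (driver == "distal") seq_len(N - 1L) + 1L else seq_len(N - 1L)
  for (s in seq_len(steps)) {
    Pnow <- Mod(W)^2
    hv <- population_coupled_h(h0, x, Pnow[drv])
    H[idx_up] <- hv; H[idx_lo] <- hv
    e <- eigen(H, symmetric = TRUE)
    W <- as.vector(e$vectors %*% (exp(-1i * e$values * dt) *
                                    crossprod(e$vectors, W)))
    if (s %% every == 0L) {
      k <- k + 1L
      times[k] <- s * dt; P[k, ] <- Mod(W)^2
    }
  }
  drift <- abs(sum(Mod(W)^2) - 1)
  if (drift > 1e-6) warning(sprintf("norm drift %.3g", drift))
  P <- P[1:k, , drop = FALSE] / rowSums(P[1:k, , drop = FALSE])
  colnames(P) <- net$sites$id
  trajectory(times[1:k], P, kind = "quantum", labels = net$sites$id,
             meta = list(propagator = "population_coupled", x = x, dt = dt,
                         driver = driver, norm_drift = drift, h_max = hs))
}

## run fun() under a private RNG stream, restoring the caller's state
with_seed <- function(seed, fun) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  fun()
}

#' Propagation with random environmental coupling modulation
#'
#' At deterministic event times spaced `period / events_per_period` apart
#' (period = pi / |h_max|, the natural period of the system), a random
#' subset of `ceiling(fraction * n_edges)` couplings from the edge pool is
#' perturbed by independent additive uniform draws in
#' [-amplitude * h_edge, +amplitude * h_edge] applied to the base coupling;
#' unselected edges revert to their base value unless `persist = TRUE`. The
#' edge pool is the network's couplings plus optional candidate long-range
#' pairs (`extra_pairs`, base coupling 0) — random creation of new
#' non-sequential couplings and random modification of existing ones are not
#' distinguished. Randomness lives only in which edges and which deltas;
#' trajectories are bit-reproducible for a given seed.
#'
#' @param net a `site_network`.
#' @param fraction fraction of the edge pool perturbed per event, in [0, 1].
#' @param amplitude perturbation amplitude as a multiple of each edge's base
#'   coupling (extra pairs use the network's max |h| as base scale).
#' @param events_per_period events per natural period (1/8, 1/4, 1, ...).
#' @param seed integer seed (mandatory).
#' @param dt step size; default 0.01 / |h_max|.
#' @param t_end final time; default 4 N / |h_max|.
#' @param extra_pairs optional data frame (`i`, `j`) of candidate
#'   non-sequential pairs added to the pool with base coupling 0.
#' @param persist keep perturbations on edges not redrawn at an event.
#' @param keep approximate number of stored times.
#' @return A quantum `trajectory`; the seed and schedule are recorded in
#'   `meta`.
#' @export
evolve_random_environment <- function(net, fraction, amplitude,
                                      events_per_period, seed,
                                      dt = NULL, t_end = NULL,
                                      extra_pairs = NULL, persist = FALSE,
                                      keep = 4000) {
  validate_site_network(net)
  if (missing(seed) || is.null(seed)) stop("seed: mandatory")
  if (fraction < 0 || fraction > 1) stop("fraction: must lie in [0, 1]")
  if (events_per_period <= 0) stop("events_per_period: must be > 0")
  ids <- net$sites$id
  N <- length(ids)
  hs <- max_coupling(net)
  if (is.null(dt)) dt <- 0.01 / hs
  if (is.null(t_end)) t_end <- 4 * N / hs
  pool <- net$couplings
  if (!is.null(extra_pairs) && nrow(extra_pairs)) {
    pool <- rbind(pool, data.frame(i = as.character(extra_pairs$i),
                                   j = as.character(extra_pairs$j), h = 0,
                                   stringsAsFactors = FALSE))
  }
  ne <- nrow(pool)
  base_h <- pool$h
  scale_h <- ifelse(base_h != 0, abs(base_h), hs)
  n_pick <- ceiling(fraction * ne)
  interval <- (pi / hs) / events_per_period
  ii <- match(pool$i, ids); jj <- match(pool$j, ids)
  i0 <- label_index(net$allosteric, ids)
  steps <- ceiling(t_end / dt)
  every <- max(1L, floor(steps / keep))
  nk <- floor(steps / every) + 1L

  with_seed(seed, function() {
    W <- complex(N); W[i0] <- 1 + 0i
    times <- numeric(nk); P <- matrix(0, nk, N)
    times[1L] <- 0; P[1L, ] <- Mod(W)^2
    k <- 1L
    cur_h <- base_h
    next_event <- 0
    n_events <- 0L
    for (s in seq_len(steps)) {
      t_now <- (s - 1L) * dt
      if (n_pick > 0L && t_now >= next_event - 1e-12) {
        if (!persist) cur_h <- base_h
        sel <- sample.int(ne, n_pick)
        cur_h[sel] <- base_h[sel] +
          stats::runif(n_pick, -amplitude, amplitude) * scale_h[sel]
        next_event <- next_event + interval
        n_events <- n_events + 1L
      }
      H <- matrix(0, N, N); diag(H) <- net$sites$energy
      H[cbind(ii, jj)] <- cur_h; H[cbind(jj, ii)] <- cur_h
      e <- eigen(H, symmetric = TRUE)
      W <- as.vector(e$vectors %*% (exp(-1i * e$values * dt) *
                                      crossprod(e$vectors, W)))
      if (s %% every == 0L) {
        k <- k + 1L
        times[k] <- s * dt; P[k, ] <- Mod(W)^2
      }
    }
    drift <- abs(sum(Mod(W)^2) - 1)
    if (drift > 1e-6) warning(sprintf("norm drift %.3g", drift))
    Pm <- P[1:k, , drop = FALSE] / rowSums(P[1:k, , drop = FALSE])
    colnames(Pm) <- ids
    trajectory(times[1:k], Pm, kind = "quantum", labels = ids,
               meta = list(propagator = "random_environment",
                           fraction = fraction, amplitude = amplitude,
                           events_per_period = events_per_period,
                           seed = as.integer(seed), persist = persist,
                           n_events = n_events, dt = dt, norm_drift = drift,
                           rng = "Mersenne-Twister", h_max = hs))
  })
}

#' Propagate a network under a coupling schedule
#'
#' Dispatcher: constant schedules use the exact eigendecomposition
#' propagator, population-coupled and random-environment schedules use their
#' stepwise propagators.
#'
#' @param net a `site_network`.
#' @param schedule a `coupling_schedule` (or `NULL` for constant).
#' @param times time grid for the constant case.
#' @param dt,t_end,keep stepwise parameters for time-dependent schedules.
#' @return A quantum `trajectory`.
#' @export
evolve_network <- function(net, schedule = NULL, times = NULL, dt = NULL,
                           t_end = NULL, keep = 4000) {
  validate_site_network(net)
  if (is.null(schedule)) schedule <- coupling_schedule("constant")
  stopifnot(inherits(schedule, "coupling_schedule"))
  if (schedule$kind == "constant") {
    if (is.null(times)) {
      if (is.null(t_end)) t_end <- 4 * n_sites(net) / max_coupling(net)
      times <- seq(0, t_end, length.out = keep + 1L)
    }
    evolve_quantum(tight_binding_hamiltonian(net), net$allosteric, times)
  } else if (schedule$kind == "population_coupled") {
    evolve_population_coupled(net, schedule$x, dt = dt, t_end = t_end,
                              keep = keep)
  } else {
    evolve_random_environment(net, schedule$fraction, schedule$amplitude,
                              schedule$events_per_period, schedule$seed,
                              dt = dt, t_end = t_end,
                              persist = schedule$persist, keep = keep)
  }
}
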