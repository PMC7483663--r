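## Programmatic generators for the model systems: degenerate chains,
## three-path hubs, two-path (ring-like) networks, trumpet and double-trumpet
## layered networks, their effective chains, and grouped 20-state systems.
## All generators are pure functions of their arguments; sites are numbered
## from 1 with the allosteric site first.

site_ids <- function(n) as.character(seq_len(n))

edges_df <- function(i, j, h) {
  data.frame(i = as.character(i), j = as.character(j), h = as.numeric(h),
             stringsAsFactors = FALSE)
}

degenerate_sites <- function(n) {
  data.frame(id = site_ids(n), energy = 0, stringsAsFactors = FALSE)
}

#' Sequentially coupled chain of degenerate sites
#'
#' N identical sites of energy zero with nearest-neighbor coupling h; the
#' allosteric site is the first site and the active site the last. This is
#' the reference sequential-coupling (SC) system.
#'
#' @param N number of sites, >= 2.
#' @param h nearest-neighbor coupling.
#' @return A `site_network`.
#' @examples
#' make_sc_chain(5, 1)
#' @export
make_sc_chain <- function(N, h = 1) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N: need at least 2 sites")
  ids <- site_ids(N)
  site_network(degenerate_sites(N),
               edges_df(ids[-N], ids[-1L], h),
               allosteric = ids[1L], active = ids[N])
}

#' Three-path hub systems
#'
#' Case A: a hub (site 1) coupled to three branch sites 2, 3, 4 with
#' couplings h, h/sqrt(2), h/sqrt(3). Case B: the same hub with each branch
#' extended by one pendant site (2-5, 3-6, 4-7) at the branch's own coupling.
#' Branch populations under dynamics scale with the square of the branch
#' coupling. The active site is taken as the end of the strongest (h)
#' branch: site 2 (case A) or site 5 (case B).
#'
#' @param case `"A"` (4 sites) or `"B"` (7 sites).
#' @param h coupling of the strongest branch.
#' @return A `site_network`.
#' @export
make_three_path <- function(case = c("A", "B"), h = 1) {
  case <- match.arg(case)
  w <- h / sqrt(1:3)
  if (case == "A") {
    site_network(degenerate_sites(4L),
                 edges_df(rep("1", 3), c("2", "3", "4"), w),
                 allosteric = "1", active = "2")
  } else {
    site_network(degenerate_sites(7L),
                 rbind(edges_df(rep("1", 3), c("2", "3", "4"), w),
                       edges_df(c("2", "3", "4"), c("5", "6", "7"), w)),
                 allosteric = "1", active = "5")
  }
}

#' Two-path systems between sites 1 and 4
#'
#' The principal path is 1-2-3-4 with coupling h. A second path connects
#' site 1 to site 4 through 2 (case I, 6 sites), 3 (case II, 7 sites) or
#' 4 (case III, 8 sites) extra sites, every second-path edge carrying
#' coupling c*h. Case I with c = 1 is the 6-cycle; case III is the
#' sequential-coupling approximation of the FMO light-harvesting complex
#' and its Hamiltonian has the ring form with entries h on the principal
#' bonds and c*h elsewhere, including element (1, 8).
#'
#' @param case `"I"`, `"II"` or `"III"`.
#' @param h principal-path coupling.
#' @param c second-path factor in [0, 1].
#' @return A `site_network` with allosteric site 1 and active site 4.
#' @export
make_two_path <- function(case = c("I", "II", "III"), h = 1, c = 1) {
  case <- match.arg(case)
  if (c < 0 || c > 1) stop("c: must lie in [0, 1]")
  n_extra <- c(I = 2L, II = 3L, III = 4L)[[case]]
  N <- 4L + n_extra
  ids <- site_ids(N)
  ## second path 1 - N - (N-1) - ... - 5 - 4
  p2 <- c(1L, seq(N, 5L), 4L)
  cp <- rbind(edges_df(ids[1:3], ids[2:4], h),
              edges_df(ids[p2[-length(p2)]], ids[p2[-1L]], c * h))
  site_network(degenerate_sites(N), cp, allosteric = "1", active = "4")
}

## layered networks: layer k has sizes[k] sites; splits are binary trees,
## merges their mirror; the edge weight between layers k and k+1 is chosen
## so that the dynamics restricted to layer-uniform (bright) states equals a
## chain with the layer-to-layer effective couplings h_eff:
## edge = h_eff * sqrt(m_k * m_{k+1}) / n_edges(k, k+1).
layered_network <- function(sizes, h_eff) {
  stopifnot(length(h_eff) == length(sizes) - 1L)
  N <- sum(sizes)
  offs <- cumsum(c(0L, sizes))
  layer_sites <- lapply(seq_along(sizes), function(k) offs[k] + seq_len(sizes[k]))
  ii <- integer(0); jj <- integer(0); hh <- numeric(0)
  for (k in seq_len(length(sizes) - 1L)) {
    a <- layer_sites[[k]]; b <- layer_sites[[k + 1L]]
    m <- length(a); mp <- length(b)
    if (mp == 2L * m) {            # binary split: parent p -> children 2p-1, 2p
      ei <- rep(a, each = 2L)
      ej <- b[as.vector(rbind(2L * seq_len(m) - 1L, 2L * seq_len(m)))]
    } else if (m == 2L * mp) {     # binary merge (mirror of a split)
      ej <- rep(b, each = 2L)
      ei <- a[as.vector(rbind(2L * seq_len(mp) - 1L, 2L * seq_len(mp)))]
    } else if (m == 1L || mp == 1L) {  # funnel: all-to-one
      ei <- rep(a, times = mp); ej <- rep(b, each = m)
    } else stop("unsupported layer size transition")
    w <- h_eff[k] * sqrt(m * mp) / length(ei)
    ii <- c(ii, ei); jj <- c(jj, ej); hh <- c(hh, rep(w, length(ei)))
  }
  site_network(degenerate_sites(N), edges_df(ii, jj, hh),
               allosteric = "1", active = as.character(N))
}

## layer-to-layer effective couplings, exactly as printed for the 16-site
## trumpet: sqrt(h/2), sqrt(prev/2), sqrt(prev/2), sqrt(h/8)
trumpet_heff <- function(h) {
  e12 <- sqrt(h / 2)
  e23 <- sqrt(e12 / 2)
  e34 <- sqrt(e23 / 2)
  e45 <- sqrt(h / 8)
  c(e12, e23, e34, e45)
}

#' Trumpet system: 16 sites in five layers
#'
#' Layered binary-split network 1 -> 2 -> 4 -> 8 -> 1 connecting the
#' allosteric site to the active site. Inter-layer edges are uniform within
#' a layer pair and scaled so the layer-uniform (bright-state) dynamics
#' equals the 5-state effective chain of [effective_chain()].
#'
#' @param h base coupling that sets the effective-coupling cascade.
#' @return A 16-site `site_network` with layer sizes (1, 2, 4, 8, 1).
#' @export
make_trumpet16 <- function(h = 1) {
  if (h == 0) stop("h: must be nonzero")
  layered_network(c(1L, 2L, 4L, 8L, 1L), trumpet_heff(h))
}

#' Double-trumpet system: 22 sites in seven layers
#'
#' Symmetric split-then-merge network with layer sizes
#' (1, 2, 4, 8, 4, 2, 1); the effective couplings mirror the trumpet
#' cascade (h_eff(1,2) = h_eff(6,7), etc.), making the network invariant
#' under the exchange of layers k and 8-k.
#'
#' @inheritParams make_trumpet16
#' @return A 22-site `site_network`.
#' @export
make_double_trumpet22 <- function(h = 1) {
  if (h == 0) stop("h: must be nonzero")
  e <- trumpet_heff(h)[1:3]
  layered_network(c(1L, 2L, 4L, 8L, 4L, 2L, 1L), c(e, rev(e)))
}

#' Effective chain of a layered trumpet system
#'
#' The reduced sequential system whose states are the layer-uniform (bright)
#' superpositions of a trumpet: a 5-state chain for the 16-site trumpet,
#' a 7-state chain for the 22-site double trumpet, with the printed
#' effective couplings h_eff(1,2) = sqrt(h/2), h_eff(2,3) = sqrt(h_eff(1,2)/2),
#' h_eff(3,4) = sqrt(h_eff(2,3)/2) and (trumpet) h_eff(4,5) = sqrt(h/8);
#' the double trumpet mirrors the first three.
#'
#' @param model `"trumpet16"` or `"double_trumpet22"`.
#' @param h base coupling.
#' @return A 5- or 7-state degenerate chain `site_network`.
#' @export
effective_chain <- function(model = c("trumpet16", "double_trumpet22"), h = 1) {
  model <- match.arg(model)
  e <- trumpet_heff(h)
  hh <- if (model == "trumpet16") e else c(e[1:3], rev(e[1:3]))
  n <- length(hh) + 1L
  ids <- site_ids(n)
  site_network(degenerate_sites(n), edges_df(ids[-n], ids[-1L], hh),
               allosteric = "1", active = ids[n])
}

#' Grouped 20-state system
#'
#' Four groups of five degenerate states; within a group the coupling is
#' sequential with strength h. Neighboring groups are connected with
#' coupling ratio*h either between every pair of states of adjacent groups
#' (`"all_to_all"`) or only from the last state of one group to the first
#' state of the next (`"bridge"`). The perturbation starts at state 1 and is
#' characterized at state 20.
#'
#' @param mode `"all_to_all"` or `"bridge"`.
#' @param h intra-group sequential coupling.
#' @param ratio inter-group coupling as a fraction of h, in (0, 1].
#' @return A 20-site `site_network`.
#' @export
make_grouped20 <- function(mode = c("all_to_all", "bridge"), h = 1, ratio = 0.1) {
  mode <- match.arg(mode)
  if (ratio <= 0 || ratio > 1) stop("ratio: must lie in (0, 1]")
  ii <- integer(0); jj <- integer(0); hh <- numeric(0)
  for (g in 0:3) {
    ii <- c(ii, g * 5L + 1:4); jj <- c(jj, g * 5L + 2:5)
    hh <- c(hh, rep(h, 4L))
  }
  for (g in 0:2) {
    if (mode == "bridge") {
      ii <- c(ii, g * 5L + 5L); jj <- c(jj, g * 5L + 6L)
      hh <- c(hh, ratio * h)
    } else {
      grid <- expand.grid(a = g * 5L + 1:5, b = (g + 1L) * 5L + 1:5)
      ii <- c(ii, grid$a); jj <- c(jj, grid$b)
      hh <- c(hh, rep(ratio * h, nrow(grid)))
    }
  }
  site_network(degenerate_sites(20L), edges_df(ii, jj, hh),
               allosteric = "1", active = "20")
}

#' Build a model system by name
#'
#' Dispatcher used by the command-line interface: maps a model name and its
#' parameters to the corresponding generator.
#'
#' @param name one of `"sc_chain"`, `"three_path_A"`, `"three_path_B"`,
#'   `"two_path_I"`, `"two_path_II"`, `"two_path_III"`, `"trumpet16"`,
#'   `"double_trumpet22"`, `"effective_chain_trumpet16"`,
#'   `"effective_chain_double_trumpet22"`, `"grouped20_all_to_all"`,
#'   `"grouped20_bridge"`.
#' @param N chain length (sc_chain only).
#' @param h coupling scale.
#' @param c two-path second-path factor.
#' @param ratio grouped-system inter-group coupling fraction.
#' @return A `site_network`.
#' @export
make_model <- function(name, N = 10, h = 1, c = 1, ratio = 0.1) {
  switch(name,
         sc_chain = make_sc_chain(N, h),
         three_path_A = make_three_path("A", h),
         three_path_B = make_three_path("B", h),
         two_path_I = make_two_path("I", h, c),
         two_path_II = make_two_path("II", h, c),
         two_path_III = make_two_path("III", h, c),
         trumpet16 = make_trumpet16(h),
         double_trumpet22 = make_double_trumpet22(h),
         effective_chain_trumpet16 = effective_chain("trumpet16", h),
         effective_chain_double_trumpet22 = effective_chain("double_trumpet22", h),
         grouped20_all_to_all = make_grouped20("all_to_all", h, ratio),
         grouped20_bridge = make_grouped20("bridge", h, ratio),
         stop("unknown model name: ", name))
}
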