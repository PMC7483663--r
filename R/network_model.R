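#' Site networks
#'
#' A site network is the basic model object: an ordered set of sites, each
#' carrying one scalar energy (dimensionless, hbar = 1), a list of undirected
#' weighted couplings between distinct sites, and two designated sites -- the
#' allosteric (sensor) site where the perturbation starts and the active site
#' where the wave is characterized.
#'
#' @param sites data frame with columns `id` (character, unique) and
#'   `energy` (numeric), or a named numeric vector of site energies.
#' @param couplings data frame with columns `i`, `j` (site ids) and `h`
#'   (numeric coupling). Each unordered pair may appear at most once and
#'   self-couplings are not allowed; the induced matrix is symmetric by
#'   construction.
#' @param allosteric,active ids of the allosteric and active sites; must be
#'   existing, distinct site ids.
#' @return An object of class `site_network`.
#' @examples
#' net <- site_network(c(s1 = 0, s2 = 0),
#'                     data.frame(i = "s1", j = "s2", h = 1),
#'                     allosteric = "s1", active = "s2")
#' @export
site_network <- function(sites, couplings, allosteric, active) {
  if (is.numeric(sites) && !is.null(names(sites))) {
    sites <- data.frame(id = names(sites), energy = unname(sites),
                        stringsAsFactors = FALSE)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("id", "energy") %in% names(sites)))
    stop("sites: need columns 'id' and 'energy'")
  sites$id <- as.character(sites$id)
  sites$energy <- as.numeric(sites$energy)
  if (is.null(couplings) || nrow(as.data.frame(couplings)) == 0L) {
    couplings <- data.frame(i = character(), j = character(), h = numeric(),
                            stringsAsFactors = FALSE)
  } else {
    couplings <- as.data.frame(couplings, stringsAsFactors = FALSE)
    if (!all(c("i", "j", "h") %in% names(couplings)))
      stop("couplings: need columns 'i', 'j' and 'h'")
    couplings$i <- as.character(couplings$i)
    couplings$j <- as.character(couplings$j)
    couplings$h <- as.numeric(couplings$h)
  }
  net <- structure(
    list(sites = sites[, c("id", "energy")],
         couplings = couplings[, c("i", "j", "h")],
         allosteric = as.character(allosteric),
         active = as.character(active)),
    class = "site_network")
  validate_site_network(net)
}

#' Validate a site network
#'
#' Checks the structural invariants: unique site ids, existing and distinct
#' allosteric/active sites, no self-couplings, no duplicated unordered pair,
#' coupling endpoints that are known sites.
#'
#' @param net object to validate.
#' @return `net`, invisibly unchanged, or an error naming the offending field.
#' @export
validate_site_network <- function(net) {
  if (!inherits(net, "site_network")) stop("not a site_network")
  ids <- net$sites$id
  if (anyDuplicated(ids)) stop("sites: duplicated id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!is.finite(net$sites$energy))) stop("sites: non-finite energy")
  if (length(net$allosteric) != 1L || !(net$allosteric %in% ids))
    stop("allosteric: not an existing site id")
  if (length(net$active) != 1L || !(net$active %in% ids))
    stop("active: not an existing site id")
  if (net$allosteric == net$active)
    stop("active: must differ from allosteric site")
  cp <- net$couplings
  if (nrow(cp)) {
    unknown <- setdiff(c(cp$i, cp$j), ids)
    if (length(unknown))
      stop("couplings: unknown site id(s): ", paste(unknown, collapse = ", "))
    if (any(cp$i == cp$j)) stop("couplings: self-coupling not allowed")
    key <- paste(pmin(cp$i, cp$j), pmax(cp$i, cp$j))
    if (anyDuplicated(key))
      stop("couplings: duplicated pair(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    if (any(!is.finite(cp$h))) stop("couplings: non-finite h")
  }
  net
}

#' @export
print.site_network <- function(x, ...) {
  cat("<site_network> ", nrow(x$sites), " sites, ", nrow(x$couplings),
      " couplings; allosteric = ", x$allosteric, ", active = ", x$active,
      "\n", sep = "")
  invisible(x)
}

#' Number of sites
#' @param net a `site_network`.
#' @return integer site count.
#' @export
n_sites <- function(net) nrow(net$sites)

## largest |coupling|, used for natural time scales (1/|h|)
max_coupling <- function(net) {
  if (!nrow(net$couplings)) return(1)
  max(abs(net$couplings$h))
}

#' Hamiltonian over a labeled basis
#'
#' Thin container for a Hermitian matrix plus basis labels. Hermiticity is
#' enforced at construction within a 1e-12 relative tolerance.
#'
#' @param matrix square numeric or complex matrix.
#' @param labels character vector of basis labels, one per row.
#' @return An object of class `hamiltonian` with elements `matrix`, `labels`.
#' @export
hamiltonian <- function(matrix, labels = NULL) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("matrix: must be square")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(matrix)))
  if (length(labels) != nrow(matrix))
    stop("labels: length must equal matrix dimension")
  scale <- max(abs(matrix), 1)
  if (max(abs(matrix - Conj(t(matrix)))) > 1e-12 * scale)
    stop("matrix: not Hermitian within 1e-12 relative tolerance")
  structure(list(matrix = matrix, labels = as.character(labels)),
            class = "hamiltonian")
}

#' @export
print.hamiltonian <- function(x, ...) {
  cat("<hamiltonian> dim", nrow(x$matrix), "x", ncol(x$matrix), "\n")
  invisible(x)
}

#' @export
dim.hamiltonian <- function(x) dim(x$matrix)

## accept either a hamiltonian or a bare matrix
as_ham_matrix <- function(H) {
  if (inherits(H, "hamiltonian")) H$matrix else H
}
ham_labels <- function(H, n) {
  if (inherits(H, "hamiltonian")) H$labels else as.character(seq_len(n))
}

#' Tight-binding Hamiltonian of a site network
#'
#' Builds the one-state-per-site Hamiltonian: diagonal entries are the site
#' energies, off-diagonal entries (i, j) carry the listed coupling h_ij and
#' are zero for unlisted pairs. The result is a real symmetric matrix over
#' the site basis.
#'
#' @param net a validated `site_network`.
#' @return A `hamiltonian` whose labels are the site ids.
#' @examples
#' H <- tight_binding_hamiltonian(make_sc_chain(2, 1))
#' H$matrix  # [[0, 1], [1, 0]]
#' @export
tight_binding_hamiltonian <- function(net) {
  validate_site_network(net)
  ids <- net$sites$id
  n <- length(ids)
  H <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(H) <- net$sites$energy
  cp <- net$couplings
  if (nrow(cp)) {
    ii <- match(cp$i, ids)
    jj <- match(cp$j, ids)
    H[cbind(ii, jj)] <- cp$h
    H[cbind(jj, ii)] <- cp$h
  }
  hamiltonian(H, ids)
}

#' Vibronic mode specification
#'
#' Describes a set of harmonic bath modes shared by all sites, with a
#' per-site linear (diagonal) vibronic coupling. Mode l has frequency
#' `omega[l]` and couples to site j with strength `g[j, l]`; each mode's
#' oscillator ladder is truncated at quantum number `n_max[l]`.
#'
#' @param omega numeric vector of mode frequencies, all > 0.
#' @param g numeric matrix of couplings, one row per site, one column per
#'   mode (a vector is accepted for a single mode).
#' @param n_max integer truncation(s), >= 0; scalar recycled across modes.
#' @return An object of class `vibronic_spec`.
#' @export
vibronic_spec <- function(omega, g, n_max) {
  omega <- as.numeric(omega)
  if (length(omega) && any(omega <= 0)) stop("omega: all frequencies must be > 0")
  if (is.null(dim(g))) g <- matrix(g, ncol = max(1L, length(omega)))
  g <- as.matrix(g)
  if (length(omega) && ncol(g) != length(omega))
    stop("g: need one column per mode")
  n_max <- as.integer(n_max)
  if (any(n_max < 0)) stop("n_max: must be >= 0")
  if (length(omega)) n_max <- rep_len(n_max, length(omega))
  structure(list(omega = omega, g = g, n_max = n_max), class = "vibronic_spec")
}

## ladder operator b on a truncated oscillator basis |0..n_max>
lowering_op <- function(n_max) {
  d <- n_max + 1L
  b <- matrix(0, d, d)
  if (n_max > 0) b[cbind(seq_len(n_max), seq_len(n_max) + 1L)] <- sqrt(seq_len(n_max))
  b
}

#' Vibronic (exciton-bath) Hamiltonian
#'
#' Builds the Hamiltonian of N electronic sites coupled to M shared harmonic
#' modes with diagonal linear vibronic coupling:
#' site energies and inter-site couplings as in the tight-binding case, plus
#' for each mode l a term omega_l * g_{j,l} (b_l + b_l^dagger) acting on site
#' j and the oscillator energy omega_l (b_l^dagger b_l + 1/2). Off-diagonal
#' (electronic) exciton-bath coupling is out of scope.
#'
#' The basis is site-major with mode quanta in mixed-radix order: label
#' `"<site>|n1,...,nM"`. With zero modes the result equals the tight-binding
#' Hamiltonian.
#'
#' @param net a `site_network`.
#' @param vib a `vibronic_spec`.
#' @return A `hamiltonian` on the truncated product basis of dimension
#'   N * prod(n_max + 1).
#' @export
vibronic_hamiltonian <- function(net, vib) {
  stopifnot(inherits(vib, "vibronic_spec"))
  Hel <- tight_binding_hamiltonian(net)$matrix
  n <- nrow(Hel)
  M <- length(vib$omega)
  if (M == 0L) return(hamiltonian(Hel, net$sites$id))
  if (nrow(vib$g) != n) stop("g: need one row per site")
  dims <- vib$n_max + 1L
  ident <- lapply(dims, diag)
  ## per-mode operators embedded in the full oscillator product space
  embed <- function(op, l) {
    out <- 1
    for (k in seq_len(M)) out <- kronecker(out, if (k == l) op else ident[[k]])
    out
  }
  d_osc <- prod(dims)
  H <- kronecker(Hel, diag(d_osc))
  for (l in seq_len(M)) {
    b <- lowering_op(vib$n_max[l])
    x <- b + t(b)
    num <- t(b) %*% b
    H <- H + kronecker(diag(vib$omega[l] * vib$g[, l], n), embed(x, l))
    H <- H + kronecker(diag(n),
                       vib$omega[l] * embed(num + diag(0.5, nrow(num)), l))
  }
  quanta <- do.call(expand.grid, rev(lapply(dims, function(d) 0:(d - 1L))))
  quanta <- quanta[, rev(seq_len(ncol(quanta))), drop = FALSE]  # mode-1 slowest
  osc_lab <- apply(quanta, 1L, paste, collapse = ",")
  labels <- as.vector(t(outer(net$sites$id, osc_lab, paste, sep = "|")))
  hamiltonian(H, labels)
}

#' Harmonic-oscillator thermodynamics
#'
#' Partition function, mean energy and entropy of a quantum harmonic
#' oscillator in internal units (hbar = 1, k_B = 1):
#' Q = exp(-beta omega / 2) / (1 - exp(-beta omega)),
#' E = -d ln Q / d beta = omega/2 + omega / (exp(beta omega) - 1),
#' S = ln Q + E / T.
#'
#' @param omega oscillator frequency, > 0.
#' @param temperature temperature, > 0 (k_B = 1).
#' @return list with components `Q`, `E`, `S`.
#' @examples
#' th <- harmonic_thermo(1, 0.05)  # ground-state limit: E -> omega/2, S -> 0
#' @export
harmonic_thermo <- function(omega, temperature) {
  if (any(omega <= 0)) stop("omega: must be > 0")
  if (any(temperature <= 0)) stop("temperature: must be > 0")
  beta <- 1 / temperature
  bw <- beta * omega
  lnQ <- -bw / 2 - log1p(-exp(-bw))
  E <- omega / 2 + omega / expm1(bw)
  S <- lnQ + E / temperature
  list(Q = exp(lnQ), E = E, S = S)
}

#' Convert wavenumber input to internal energy units
#'
#' Maps an energy given in cm^-1 to the dimensionless internal scale via a
#' reference energy: `E_internal = E_cm / reference`. The default reference,
#' 1000 cm^-1, makes a 1000 cm^-1 coupling equal to h = 1 (and 100 cm^-1
#' equal to 0.1, the grouped-system inter-group value).
#'
#' @param wavenumber energy in cm^-1.
#' @param reference reference energy in cm^-1 that maps to 1.
#' @return dimensionless energy.
#' @export
energy_from_wavenumber <- function(wavenumber, reference = 1000) {
  if (reference <= 0) stop("reference: must be > 0")
  wavenumber / reference
}
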