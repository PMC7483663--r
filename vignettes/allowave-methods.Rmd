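---
title: "Quantum perturbation waves on site networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum perturbation waves on site networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allowave)
```

## The model

Allosteric regulation moves information between two macromolecular sites
that are typically 30–40 Å apart. `allowave` models the macromolecule as a
network of coupled sites — domains, residues, or any sufficiently unitary
fragments — and treats the perturbation created at the allosteric (sensor)
site as a quantum wave on that network. The Hamiltonian collects one scalar
energy per site and one real coupling per interacting pair,

$$H = \sum_j E_j\,|s_j\rangle\langle s_j| +
      \sum_{j \neq k} V_{jk}\,|s_j\rangle\langle s_k|,$$

and the perturbation, localized on the allosteric site at $t = 0$, evolves
unitarily, $W(t) = e^{-iHt}\,W(0)$, with site populations
$P_i(t) = |W_i(t)|^2$. The quantum treatment is the point: a classical
master equation on the same chain spreads the perturbation uniformly over
all sites ($P_i \to 1/N$), losing the preferential sensor-to-active-site
relationship, whereas the coherent wave travels ballistically and arrives
at the far end nearly intact. `evolve_master_chain()` and
`evolve_kinetic()` provide the classical comparison.

Sites may also carry vibrational structure: `vibronic_hamiltonian()` adds a
set of shared harmonic modes with diagonal linear (exciton–bath style)
coupling,

$$H_{vib} = \sum_{j,l} \omega_l\, g_{j,l} (b_l + b_l^\dagger)
            |s_j\rangle\langle s_j|
          + \sum_l \omega_l (b_l^\dagger b_l + \tfrac12),$$

on a truncated oscillator product basis. Off-diagonal exciton–bath terms
and Duschinsky rotation are deliberately out of scope. The bath is written
with a shared mode index and per-site couplings $g_{j,l}$; a site-local
bath is recovered by zeroing $g$ on the other sites. For a single site
this is the displaced oscillator, whose ground energy
$E + \omega/2 - g^2\omega$ the test suite uses as a truncation-convergence
oracle. `harmonic_thermo()` supplies the oscillator partition function,
mean energy and entropy ($\hbar = k_B = 1$) used to reason about energetic
versus entropic transitions between groups of vibronic states.

## Units

Internal units set $\hbar = 1$ and $k_B = 1$; energies and couplings are
dimensionless and time is measured in units of $1/|h|$. Output can be
rescaled to multiples of $\pi$ (`time_unit = "pi"`), the period of a
degenerate pair at $h = 1$. Inputs quoted in cm$^{-1}$ are mapped through
`energy_from_wavenumber()`, whose default reference (1000 cm$^{-1}$
$\mapsto h = 1$) matches the grouped-system examples where inter-group
couplings of 100 cm$^{-1}$ are 10% of the intra-group 1000 cm$^{-1}$.

## First-passage signature: $t_a$, $A_a$, $B_a$

The allosteric event is characterized by the *first* passage of the wave at
the active site: the arrival time $t_a$, the amplitude $A_a$, and the
temporal broadening $B_a$. `first_passage_signature()` implements:

* **Peak detection.** The first local maximum of $P_a(t)$ whose height is at
  least 5% of that site's global maximum (the threshold guards against
  numerical ripples). The first peak is used deliberately — multipath
  systems routinely show *higher* recurrences later (the 6-site two-path
  system at $c = 0.5$ peaks at 0.77 on first passage and 0.97 on a later
  revival), and the first arrival is the physically meaningful event.
* **Refinement.** $t_a$ and $A_a$ are the vertex of the parabola through the
  three samples around the discrete maximum; on the grids used here this is
  accurate to about $10^{-10}$ for smooth peaks.
* **Broadening.** $B_a$ is the full width of the peak at $2/3$ of its
  height, with the crossings linearly interpolated. For the degenerate pair
  ($P_2 = \sin^2 t$) this evaluates to
  $\pi\,(180 - 109.471)/180 \approx 1.2310$ — the tetrahedral-angle form of
  the two-site closed expression.
* **Gaussian fit.** A least-squares fit of $c_1 e^{-(t-c_2)^2/c_3^2}$
  (via `minpack.lm`) over the window $[t_a - c_4,\, t_a + c_4]$, where
  $c_4$ is the distance to the nearer point at which the population falls
  to 1% of the peak. The fit internals ($c_1..c_4$, residual RMS) are
  reported, and a residual RMS above 5% of $A_a$ flags the shape as
  non-Gaussian — typical for strongly decreasing coupling feedback, where
  the wave deforms.

The reported $t_a$ and $A_a$ are the refined peak values, not the fit
parameters $c_2$ and $c_1$: an unweighted Gaussian fit over the 1% window
systematically overshoots the amplitude of a $\sin^2$-like lobe (it gives
1.028 where the two-site closed form says exactly 1, and 0.763 where the
6-ring's exact first passage is 0.750), and the closed-form values are the
quantities the model is meant to reproduce. For near-Gaussian passages the
two conventions agree to a few percent and the fit internals let the user
compare.

Measured this way, the degenerate-pair signature is
$t_a = \pi/(2|h|)$, $A_a = 1$, $B_a \approx 1.2310$ at $h = 1$, and the
measured $B_a$ scales as $1/|h|$ (a width in time). The printed two-site
closed form quotes $B_a \propto h^2$; that scaling is inconsistent with the
time-domain width of $\sin^2(|h|t)$ and is not used — the package reports
the measured width and leaves the $h$-scaling empirical. Likewise the
chain-length fit of the measured width *increases* with $N$ (the traveling
packet spreads), so no assertion ties it to a decreasing printed quadratic;
the amplitude and arrival-time scaling laws below are the validated ones.

### Envelope mode for grouped systems

In the grouped state-set models the active-state population is a fast
intra-group oscillation under a slow inter-group envelope (two well
separated oscillation times). A literal first-local-maximum rule lands on
an early ripple at a few percent; what the figures of such systems show as
"the" first passage is the envelope's first crest. With `envelope = TRUE`
the detector computes a running maximum over a window of $4\pi/|h|$
(twice the intra-group period), ends the first passage at the first
significant envelope drop (1% of the global maximum, once the envelope has
reached the detection threshold), and reports the refined raw maximum
within that passage; the Gaussian fit and width are then computed on the
moving-average smoothed curve. The window parameter is exposed
(`envelope_window`) and the mode is opt-in precisely because plain systems
must keep the literal first peak.

## Transfer efficiency

Long after the first arrival, the time-averaged population
$\langle P_a \rangle = \tau^{-1}\int_0^\tau P_a\,dt$ measures how much of
the perturbation the active site retains on average.
`transfer_efficiency()` uses trapezoidal averaging and reports convergence
by doubling $\tau$ (converged when no site average moves by more than
$10^{-3}$). For constant Hamiltonians the average must match the spectral
projector sum $\sum_E |\langle a|\Pi_E|i\rangle|^2$ over distinct
eigenvalues (degeneracies grouped at $10^{-9}$); the test suite asserts
this equivalence at $\tau = 500$ on the 6-ring and the 5-chain, where the
exact values are $5/18$ for the end sites and $1/9$ for the intermediates —
well above the $1/6$ of complete classical diffusion.

## Scaling laws in chain length

`scan_chain_lengths()` builds degenerate chains over $N = 4..15$ (the
near-linear regime), extracts the signature per $N$, and fits
$F = a_1 + a_2 N + a_3 N^2$ by ordinary least squares for each of $t_a$,
$A_a$, $B_a$. For Markovian chains at $h = 1$ the amplitude fit lands at
$a \approx (1.117, -0.039, 7.6\times10^{-4})$, within the fit-convention
tolerance of the reference quadratic $(1.1368, -0.0407, 8.2\times10^{-4})$;
arrival time is the most linear of the three. Non-Gaussian per-$N$ fits are
flagged but kept, matching the reduced precision expected for
coupling-decrease feedback.

## Time-dependent couplings

**Population-coupled (non-Markovian) rule.** Each chain bond is updated
every step as $h_{i,i+1}(t) = (1 + x P(t))\,h$ before an exact exponential
step of length $dt$ is taken (explicit piecewise-constant scheme; each step
is exactly unitary). The driving population defaults to the bond's
*distal* end, site $i+1$, the end nearer the active site. This choice is
empirical: driving from the distal end reproduces the reference behavior of
this model — positive feedback ($x > 0$) shortens the arrival and delivers
a smaller, narrower wave, negative feedback delays and heightens it, with
$N = 10$ amplitudes $(0.744, 0.799, 0.804, 0.812, 0.850)$ for
$x = (+0.8, +0.2, 0, -0.2, -0.8)$ — whereas driving from the proximal end
(site $i$) inverts the amplitude trend. The proximal variant remains
available via `driver = "proximal"`. Default $dt = 0.005/|h|$: halving it
moves the fitted $a_1$ of the small-up arrival-time quadratic by less than
$10^{-3}$.

**Random environmental modulation.** `evolve_random_environment()` models
the environment re-shuffling couplings: at deterministic event times spaced
$(\pi/|h|)/\text{events\_per\_period}$ apart, a random subset of
$\lceil \text{fraction} \cdot n_{edges}\rceil$ couplings receives an
independent additive uniform draw in $[-a\,h, +a\,h]$ on top of its base
value (perturbations re-drawn at each event by default; a `persist` flag
keeps undrawn edges perturbed, since either reading is defensible).
Candidate long-range pairs can be added to the pool with base coupling 0,
so creating new couplings and modifying existing ones are treated
uniformly. Randomness is confined to edge choice and draw values; the
generator is a seeded Mersenne-Twister stream isolated from the caller's
RNG state and the seed is recorded in the trajectory metadata, so runs are
bit-reproducible. At 20% amplitude the chain dynamics barely move
($|\Delta t_a|/t_a < 0.1$); at 80% the arriving wave is visibly smaller and
broader, and more frequent events strengthen both effects.

## Model library

* `make_sc_chain(N, h)` — the reference degenerate chain.
* `make_three_path(case, h)` — a hub with branches at $h$, $h/\sqrt2$,
  $h/\sqrt3$ (case A), optionally extended by pendants (case B); branch
  populations scale exactly as the squared branch coupling. Neither source
  designates an active site for these, so the end of the strongest branch
  is used.
* `make_two_path(case, h, c)` — principal path 1–2–3–4 at $h$ plus a second
  path through 2, 3 or 4 extra sites at $c\,h$; case I with $c = 1$ is the
  6-cycle, case III the 8-site ring whose Hamiltonian carries the corner
  element $(1,8) = c\,h$.
* `make_trumpet16(h)` / `make_double_trumpet22(h)` — layered binary
  split (and re-merge) networks with layer sizes $(1,2,4,8,1)$ and
  $(1,2,4,8,4,2,1)$. Only the layer-to-layer effective couplings are
  prescribed ($h^{eff}_{1,2} = \sqrt{h/2}$, each next
  $\sqrt{h^{eff}/2}$, and $\sqrt{h/8}$ into the active site, implemented
  exactly as printed); the microscopic edge weights are the package's
  choice. Each edge between layers of sizes $m, m'$ carries
  $h^{eff}\sqrt{m m'}/n_{edges}$, which makes the layer-uniform (bright)
  subspace dynamics *exactly* the effective chain of `effective_chain()` —
  the test suite asserts layer-summed populations agree with the 5-state
  chain to $10^{-9}$. The alternative reading of the printed cascade
  (successive division by $\sqrt2$) coincides at $h=1$ only for the last
  coupling and is not instantiated.
* `make_grouped20(mode, h, ratio)` — four groups of five sequentially
  coupled states, inter-group coupling `ratio * h` (default 10%) either
  bridge-wise (last state to first state) or all-to-all between adjacent
  groups. Bridge coupling funnels roughly 60% of the wave into state 20;
  all-to-all spreads it, leaving roughly 10% — in both cases arriving far
  later than a plain 20-chain.

All generators are pure functions; every output validates the network
invariants (unique ids, symmetric couplings, no duplicate pairs, distinct
designated sites).

## Lanczos reduction

`lanczos_reduce()` tridiagonalizes $H$ from a door state with full (twice
re-orthogonalized) Gram-Schmidt, returning $\alpha$, $\beta \ge 0$ and the
Krylov basis; `reduction_hamiltonian()` turns the result into an $m \times
m$ chain whose state `k1` reproduces the door-state dynamics over a limited
time. Near-zero $\beta$ terminates the recursion early with a breakdown
flag — the door state then generates an invariant subspace, on which the
reduction is *exact* (the trumpet's bright subspace is the canonical
example: 5 Krylov vectors suffice). Reduced eigenvalues always lie inside
the spectral range of $H$; at $m = \dim H$ (door state cyclic) the spectra
agree to round-off, and short-time fidelity improves monotonically with
$m$.

## Numerical choices

* Constant-$H$ propagation uses one symmetric eigendecomposition; every
  evaluated time is exact, and norms are conserved to round-off
  (populations are validated to sum to 1 within $10^{-9}$).
* Stepwise propagation freezes $H$ at the start of each step and applies
  its exact exponential; norm drift above $10^{-6}$ triggers a diagnostic
  warning. The scheme is first order in $dt$ for genuinely time-dependent
  schedules; a Richardson check (halving $dt$) is part of the test suite.
* The classical propagators exponentiate the exact generator (symmetric
  eigendecomposition for the chain, `Matrix::expm` iterated on uniform
  grids for generic generators) rather than time stepping.
* Default characterization grid: $[0,\, 4N/|h|]$ at 2000–4000 points,
  which holds the first passage interior to the grid for every shipped
  model ($N \le 22$); the two-site closed-form tests use denser grids
  (16001 points) to exercise the $10^{-6}$ agreement of the refined peak.
* Scan sizes: $N = 4..15$ with $dt = 0.005$ stepping for feedback
  schedules; a full small-up scan takes a few seconds on one core.
* Degenerate eigenvalues are grouped at $|\Delta E| < 10^{-9}$ in the
  long-time-average oracle; Lanczos breakdown threshold is
  $10^{-12}\max|H|$.
* The master-equation time variable is time in natural units (the
  occasional alternative symbol in the source formulation is treated as
  typographic).

## What the model library does and does not emulate

The generators produce the idealized study conditions: degenerate sites,
uniform couplings, perfectly symmetric topologies, no dissipation. Passing
tests therefore demonstrate the *mechanisms* — coherent ballistic
transport, constructive two-path interference, envelope-slow inter-group
transfer, robustness to moderate coupling noise — not fidelity to any real
protein. Real systems add static disorder in site energies, open-system
dephasing and relaxation, and structure-derived couplings; none of these
are modeled (no Lindblad/HEOM dynamics, no spectral-density baths, no
mapping from structures to sites). The random-environment schedule is a
deliberately minimal stand-in for environmental modulation: uncorrelated,
piecewise-constant, amplitude-bounded.

## Known limitations

* Amplitude and arrival-time conventions depend on peak-detection details;
  reference quadratic coefficients are reproduced within conventions
  (a few percent on $a_1$), not bit-exactly.
* The broadening's coupling- and length-scaling is reported as measured;
  printed reference scalings for $B_a$ are mutually inconsistent and are
  not asserted (see above).
* The envelope detector's drop rule (1% of global maximum) is tuned for
  well-separated time scales; systems with comparable intra- and
  inter-group periods may need a custom `envelope_window`.
* Stepwise schedules are first-order accurate; for strongly varying
  feedback ($|x| = 0.8$) halve `dt` when precision matters.
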