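# allowave

Time-dependent quantum simulation of allosteric signal propagation on site
networks.

## The problem

In allostery, a perturbation created by ligand binding at one site of a
macromolecule travels tens of Ångströms and changes the behavior of a
distant active site — efficiently, without dissolving into the countless
degrees of freedom in between. A classical hopping (master-equation)
picture on a network of coupled sites cannot explain that selectivity: it
spreads the perturbation uniformly, ending at `P_i = 1/N` on every site.
`allowave` implements the alternative: treat the perturbation as a quantum
wave on the site network, the same device used for exciton transport in
photosynthetic light-harvesting complexes.

The package is for modelers who want to explore how network topology,
couplings, vibronic structure and time-dependent coupling rules shape the
arrival of a signal at a target site — not for deriving site decompositions
from protein structures.

## The model

A network of `N` sites (energies `E_j`, undirected couplings `h_jk`) defines
a tight-binding Hamiltonian

    H = Σ_j E_j |s_j⟩⟨s_j| + Σ_{j≠k} V_jk |s_j⟩⟨s_k|,

optionally extended by shared harmonic modes with diagonal linear vibronic
coupling. The perturbation starts localized on the allosteric site,
`W(0) = |i⟩`, and evolves as `W(t) = exp(−iHt) W(0)` with site populations
`P_i(t) = |W_i(t)|²` (ħ = 1, k_B = 1; time in units of `1/|h|`). Its first
passage at the active site `a` is summarized by three numbers:

* `t_a` — arrival time (position of the first qualifying peak of `P_a(t)`),
* `A_a` — amplitude (height of that peak; `1 − A_a` is the attenuation),
* `B_a` — broadening (full width of the peak at 2/3 of its height),

plus the long-time transfer efficiency `⟨P_a⟩ = τ⁻¹ ∫ P_a dt`. Couplings
may be constant (Markovian), fed back from the instantaneous populations
(`h_{i,i+1}(t) = (1 + x·P(t))·h`, non-Markovian), or randomly modulated by
the environment. A Lanczos reduction maps large sparse networks onto short
effective chains for short-time dynamics, and a model library generates the
canonical study systems (chains, multipath networks, trumpets, grouped
state sets).

## Worked example

```r
library(allowave)

net  <- make_sc_chain(10, 1)                     # 10 degenerate sites, h = 1
traj <- evolve_network(net, t_end = 30, keep = 4000)
first_passage_signature(traj, "10")
#> <wave_signature> site 10: t_a = 6.1211, A_a = 0.8038, B_a = 1.3978
```

The wave crosses nine bonds in `t_a ≈ 6.12` natural time units and arrives
with 80% of the initial population in one peak of width ≈ 1.40 — the chain
transmits the signal almost intact. Long-time averages stay biased toward
the two special sites:

```r
H <- tight_binding_hamiltonian(net)
transfer_efficiency(evolve_quantum(H, "1", seq(0, 1000, length.out = 20001)), 500)
#> <efficiency_report> tau = 500 , converged = TRUE
#>      1      2      3      4      5      6      7      8      9     10
#> 0.1365 0.0907 0.0908 0.0910 0.0915 0.0907 0.0911 0.0911 0.0909 0.1357
```

versus exactly `0.1` everywhere for the classical master equation
(`evolve_master_chain(10, 1, 1, times)`). Population-coupled feedback that
strengthens bonds as the wave passes (`x = +0.2`) makes the wave arrive
earlier, smaller and narrower:

```r
first_passage_signature(evolve_population_coupled(net, 0.2, t_end = 30), "10")
#> <wave_signature> site 10: t_a = 5.8247, A_a = 0.7987, B_a = 1.1975
```

A thin command-line interface wraps the same functions:

```sh
allowave models sc_chain --N 10 -o net.json
allowave simulate --network net.json -o traj.csv
allowave characterize --traj traj.csv --site 10 -o report.json
```

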