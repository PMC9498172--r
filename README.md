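# cmih

Conditional mutual information estimation and conditional-independence
testing for **mixed data** — samples whose variables combine qualitative
(categorical, equality-only) and quantitative (real-valued) components.
Intended for practitioners who need a CI oracle over mixed tables: causal
discovery, graphical model inference, feature selection, monitoring data
with status flags next to continuous loads.

## What it computes

Conditional mutual information characterises conditional independence:
`I(X;Y|Z) = 0` iff `X ⟂ Y | Z`. Writing `Xᵗ`/`Xˡ` for the
quantitative/qualitative sub-vectors of a block, the hybrid estimator
**CMIh** uses the decomposition

    Î(X;Y|Z) = Ĥ(Xᵗ,Zᵗ|Xˡ,Zˡ) + Ĥ(Yᵗ,Zᵗ|Yˡ,Zˡ) − Ĥ(Xᵗ,Yᵗ,Zᵗ|Xˡ,Yˡ,Zˡ) − Ĥ(Zᵗ|Zˡ)
             + Ĥ(Xˡ,Zˡ)       + Ĥ(Yˡ,Zˡ)       − Ĥ(Xˡ,Yˡ,Zˡ)          − Ĥ(Zˡ)

in which conditioning only ever involves qualitative tuples: the marginal
qualitative entropies are plug-in histogram estimates, and each conditional
quantitative entropy is a frequency-weighted Kozachenko–Leonenko kNN
estimate within qualitative bins, `Ĥ = ψ(n_b) − ψ(k_b) + (d/n_b) Σ log ξᵢ`,
with `ξᵢ` twice the Chebyshev distance to the `k_b`-th neighbour and
`k_b = max(⌊n_b/10⌋, 1)` chosen per term from its own bin size.

On top of the estimator:

* `cmi_knn()` — the classical baselines FP (Frenzel–Pompe), RAVK
  (Rahimzamani et al.) and MS (Mesner–Shalizi), sharing the form
  `meanᵢ[ψ(kᵢ) − f(n_XZ,ᵢ) − f(n_YZ,ᵢ) + f(n_Z,ᵢ)]`, including the exact
  reproduction of MS's degeneracy to 0 on mixed data.
* `cmi_test()` — permutation tests of `H0: X ⟂ Y | Z` with three schemes:
  global (GloT), local (LocT), and **LocAT**, the local adaptive scheme
  whose permutation neighbourhoods use an `(0–∞)`/Chebyshev adaptive
  distance and a per-point neighbour count clamped to the qualitative
  stratum size. P-value: `mean(permuted ≥ observed)`, a multiple of `1/B`.
* `sim_setting()` / `sim_structure()` / `ground_truth()` — benchmark
  generators with analytic truths (Gaussian, mixed-uniform, zero-inflated
  Poisson, multidimensional variants; chain/fork/collider structures), and
  `mse_experiment()` / `acceptance_rate_experiment()` harnesses.

## Worked example

```r
library(cmih)
set.seed(1)

# X ~ U{0..4} (qualitative), Y|X ~ U([x, x+2]) (quantitative),
# plus an independent qualitative conditioner Z ~ Bi(3, 0.5).
sim <- sim_setting("cmi_mixed", n = 1000)
est <- cmih(sim$sample, sim$x, sim$y, sim$z)
est
#> CMIh conditional mutual information estimate
#>   I(X;Y|Z) = 1.0764 nats  (n = 1000)
#>   entropy terms (sign * value):
#>    + H(Xt,Zt|Xl,Zl)         0.0000
#>    + H(Yt,Zt|Yl,Zl)         1.7907
#>    - H(Xt,Yt,Zt|Xl,Yl,Zl)   0.7143
#>    - H(Zt|Zl)               0.0000
#>    + H(Xl,Zl)               2.8841
#>    + H(Yl,Zl)               1.2805
#>    - H(Xl,Yl,Zl)            2.8841
#>    - H(Zl)                  1.2805
ground_truth("cmi_mixed")
#> [1] 1.05492
```

The estimate (1.076 nats) sits near the analytic value 1.055: the
independent conditioner contributes nothing (its entropy terms cancel in
the printed breakdown), and the X–Y dependence is carried by the
conditional kNN terms. Testing confirms the dependence, and the same test
on a conditionally independent construction does not reject:

```r
cmi_test(sim$sample, sim$x, sim$y, sim$z, B = 500, seed = 2)$p.value
#> [1] 0     # every permuted statistic fell below the observed 1.04

sim0 <- sim_setting("cmi_mixed_indep", n = 1000, seed = 3)
cmi_test(sim0$sample, sim0$x, sim0$y, sim0$z, B = 500, seed = 4)$p.value
#> [1] 0.99
```

A thin command-line front end is available in `exec/cmih`
(`estimate`, `test`, `benchmark-mse`, `benchmark-rates` subcommands) for
CSV/TSV files with a `name,type,block` column-spec sidecar.

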