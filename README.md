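# medeadyn

Deterministic population-genetic dynamics of *Medea* and *peel*
toxin–antidote gene-drive elements under partial selfing.

## The problem

*Medea* elements are selfish alleles that act in heterozygous mothers: the
mother deposits a toxin in every egg, and only embryos inheriting the allele
(and with it the zygotic antidote) are spared. *peel* elements are the
sperm-delivered analogue, keyed to the father's genotype. In the selfing
*Caenorhabditis* nematodes, both alleles at a locus can act as antagonistic
elements, each killing the opposite homozygote class among the progeny of
heterozygous parents — a configuration that looks like it should produce
heterozygote advantage and balancing selection, but under mixed mating does
the opposite: the common allele deterministically drives the rare one
extinct (positive frequency dependence), with an unstable interior
equilibrium acting as an invasion threshold.

`medeadyn` implements this model for theoreticians and empiricists working
on gene drive and mating-system evolution: exact genotype-frequency
recursions with a cross-by-cross mating-table oracle, closed-form thresholds
and equilibria, a sex-structured androdioecious extension, and numerical
separatrix scans.

## The model

A single biallelic locus with genotypes M1M1, M1M2, M2M2 at frequencies
X, Y, Z (allele frequency p = X + Y/2, q = 1 − p). Hermaphrodites self with
fixed probability S and mate at random otherwise. Allele M1 kills M2M2
progeny of exposed broods with penetrance k1; M2 kills M1M1 progeny with
penetrance k2. One generation of selection maps

```
w̄  = 1 − (Y/2) [ k1 (S/2 + q(1−S)) + k2 (S/2 + p(1−S)) ]
p′  = ( p − (Y/2) k2 (S/2 + p(1−S)) ) / w̄
Y′  = ( S Y/2 + (1−S) 2 p q ) / w̄
```

The interior equilibrium p̂ depends only on S and the penetrance ratio
r = k1/k2, and is always unstable: above p̂ the M1 allele sweeps, below it
M1 is eliminated. Closed forms give p̂, the equilibrium heterozygosity Ŷ,
the critical selfing rate S_C above which an invader at frequency p is
excluded, and the critical penetrance ratio r_C an invader needs to sweep.

The androdioecious module adds the *Caenorhabditis* mating system:
hermaphrodites self (all-hermaphrodite broods) or outcross with males
(mixed broods), males arise only from outcrossing, and the cost-of-males
parameter b scales the hermaphrodite share of each outcross brood. There,
Medea and peel elements genuinely differ — peels are exposed through the
always-more-heterozygous males — and a weaker peel can displace a stronger
Medea.

## Worked example

An invading Medea with penetrance 0.9 against a resident with penetrance
0.5 (ratio r = 1.8) in a population selfing at S = 0.6:

```r
library(medeadyn)

eq <- equilibrium(S = 0.6, k1 = 0.9, k2 = 0.5)
eq
#> <drive_equilibrium> p_hat = 0.280294, Y_hat = 0.268366 (unstable; S = 0.6, r = 1.8, K = 0.735153)
```

An invader at frequency 0.2 sits below the threshold p̂ ≈ 0.28, so it is
eliminated:

```r
classify_fate(state_from_pq(0.2, 0), model_params(0.6, 0.9, 0.5))
#> # A tibble: 1 × 5
#>   fate  p_start   p_final generations_run comparator
#>   <chr>   <dbl>     <dbl>           <int> <chr>
#> 1 loss      0.2 0.0000380             100 after_n
```

The critical selfing rate below which that same invader would have swept:

```r
critical_selfing(p = 0.2, r = 1.8)
#> [1] 0.3678161
```

Numerical threshold scans (fate of every starting frequency after 100
generations) recover the analytic separatrix to grid resolution:

```r
threshold_scan(model_params(0, 0.9, 0.5), S_grid = c(0.2, 0.4, 0.6, 0.8))
#>     S threshold bracket_lo bracket_hi flag
#> 1 0.2    0.1185      0.118      0.119   ok
#> 2 0.4    0.2135      0.213      0.214   ok
#> 3 0.6    0.2805      0.280      0.281   ok
#> 4 0.8    0.3255      0.325      0.326   ok
```

Trajectories are tibbles (`iterate_trajectory()`), plotted with
`autoplot()`; ternary phase portraits come from `vector_field()` +
`plot_vector_field()`.

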