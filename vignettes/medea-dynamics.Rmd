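---
title: "Toxin-antidote drive dynamics under partial selfing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Toxin-antidote drive dynamics under partial selfing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(medeadyn)
```

## The model and its assumptions

`medeadyn` models one biallelic locus whose alleles can each act as a
parental-effect toxin-antidote element. A *Medea*-type allele acts through
the mother: a heterozygous egg parent loads a toxin into every egg, and
only progeny inheriting that allele carry the antidote, so the opposite
homozygote class dies with penetrance k. A *peel*-type allele is the
paternal mirror image, keyed to the sperm parent's genotype. With both
alleles active (penetrances k1 for M1 and k2 for M2), selfing a
heterozygote exposes both homozygote progeny classes; heterozygous progeny
always carry both antidotes and are never killed.

The population is infinite and generations are discrete: hermaphrodites
self with fixed probability `S` and mate at random otherwise, and the map
from one generation's genotype frequencies `(X, Y, Z)` to the next is
deterministic. There is no mutation, no drift, no carrier fitness cost, no
spatial structure, and no recombination with other loci — the model
isolates the interaction between mating system and parental-effect killing.

Every recursion in the package has two independent implementations. The
mating table (`mating_table()`) enumerates all 3 selfing and 9 outcross
parental combinations with their Mendelian progeny shares and survival
weights; `step_from_table()` sums and normalizes the columns, the
normalizer being the mean fitness. The compact steps (`step_monoecious()`,
`step_androdioecious()`) implement the algebraically reduced recursions.
The test suite holds the two routes to within `1e-12` of each other on
1000 random states per model; the compact route is the production path and
the table is the oracle.

Under monoecy, the maternal and paternal exposure rules produce identical
recursions (random mating makes the egg and sperm roles exchangeable, and
under selfing they coincide in one individual), so the monoecious module
treats element types as interchangeable and the mating table is always
written with the maternal rule.

## Parameters

* `S` (dimensionless, `[0, 1]`) — fraction of broods from selfing.
* `k1`, `k2` (`[0, 1]`) — killing penetrances; a single-element model sets
  the other penetrance to 0. Monoecious equilibria depend on the
  penetrances only through the ratio `r = k1/k2`; androdioecious dynamics
  depend on their magnitudes too.
* `b` (`> 0`, androdioecy only) — hermaphrodite offspring per outcross
  relative to per selfing. A fixed brood size gives the classical two-fold
  cost of males, `b = 1/2`; sperm-replenishing outcrosses give `b` near 1.
  Default 1; values roughly in `[0.5, 2]` are biologically plausible.
* `element1`, `element2` — `"medea"`, `"peel"`, or `"none"`; under
  androdioecy the type decides whether the egg parent's (medea) or sperm
  parent's (peel) heterozygosity triggers exposure.

## Androdioecy

The sex-structured model follows the *Caenorhabditis* mating system:
hermaphrodites self (all offspring hermaphrodite) or mate with males
(offspring split between hermaphrodites and males), and males arise only
from outcrossing. The state is the pair of sex-specific genotype triples.
Each generation, the hermaphrodite pool receives selfing contributions at
unit weight and outcross contributions at weight `b`; the male pool
receives outcross contributions only and is therefore independent of `b`.
The two pools are normalized separately; the population sex ratio is not
tracked, because the genotype dynamics do not need it.

Three structural consequences, each enforced by tests: at `S = 1` the
model reduces to monoecious pure selfing (the male pool gets no input; the
step reports male frequencies as `NA` and a zero male normalizer rather
than carrying stale values); at `S = 0` it reduces to monoecious random
mating for both sexes; and for pure-Medea models the male heterozygosity
drops out of the recursion entirely, while for peels it takes the place of
hermaphrodite heterozygosity in the outcross terms. Since males descend
exclusively from outcrosses they are at least as heterozygous as
hermaphrodites, which is why a peel element spreads faster than an equally
penetrant Medea and can displace a stronger one.

When a single population allele frequency is reported for a sex-structured
state (plots, fate classification), the two sexes are averaged with equal
weights by default. The model gives no canonical weighting — the
recursions never define a combined pool — so `population_mean_p()` records
the rule used in its output, and the hermaphrodite-only and custom-weight
rules are available. Fate classification is insensitive to the choice
because both sexes converge to the same boundary.

## Closed forms and numerical choices

**Interior equilibrium.** Setting the allele-frequency change to zero gives
an implicit relation independent of heterozygosity; clearing denominators
yields the quadratic `(1-S)(1-r) p^2 + (S(1+r)/2 + (1-S)(r-1)) p - S/2 = 0`,
which has exactly one root in `(0, 1)` for `S > 0` and r away from 1
(the polynomial is negative at 0 and positive at 1).
`internal_equilibrium_p()` solves this quadratic, always verifies the
implicit-relation residual (tolerance `1e-10`), and falls back to bracketed
root-finding on the implicit form if verification fails. The equivalent
radical expression in the literature is kept internally
(`.eq_explicit_radical`) purely as a cross-check; it is 0/0 at `r = 1` and
`S = 1`, which the quadratic route handles as explicit limits (`1/2` and
`1/(1+r)`).

**Equilibrium heterozygosity.** At fixed p̂ the heterozygosity map has the
fixed points of `(K/2) Y^2 - (1 - S/2) Y + 2 (1-S) p̂ q̂ = 0`, with
`K = k1(S/2 + q̂(1-S)) + k2(S/2 + p̂(1-S))`. The smaller root is the
attracting fixed point of the one-dimensional Y map and the one on the
genotype simplex; `equilibrium_heterozygosity()` computes both roots,
filters by feasibility, and the tests validate the choice against direct
fixed-point iteration of the recursion (including the degenerate corner
`S = 0`, `k1 = k2 = 1`, `p = 0.5`, where the double root `Y = 1` is
approached only algebraically).

**Thresholds.** `critical_selfing()` and `critical_ratio()` evaluate the
printed closed forms. Values outside `[0, 1]` (including the infinite
value at `p = 1/2`, where the denominator vanishes identically) are
reported as "no threshold in range" — `NA` with the raw value attached —
rather than clamped, since they mean the invader's fate does not change
over the admissible selfing range.

**Stability.** The interior equilibrium's instability is established by
iteration (nudge by `1e-4` on either side and watch the trajectory reach
the opposite boundaries), not by Jacobian eigenvalues; this matches how
the thresholds are actually used and avoids a second analytic surface to
maintain.

**Simplex hygiene.** States are renormalized after each step; a correction
larger than `1e-9` is logged. A zero normalizer (every progeny class
killed) raises a distinct degenerate-extinction condition
(`medeadyn_extinction`, CLI exit code 3) rather than returning `NaN`; it is
reachable only from pathological corners of parameter space.

## Numerical separatrix scans

`threshold_scan()` classifies the fate of every all-homozygote start
`(X = p0, Y = 0)` on a frequency grid — by default 0.001 to 0.999 in steps
of 0.001, selfing rates 0 to 0.99 in steps of 0.01, both sexes identical
under androdioecy with `b = 1` — judging fate by whether the allele
frequency is above or below its start after 100 generations, and reports
the threshold as the midpoint of the loss/fix bracket. In the monoecious
model the sign of the per-generation frequency change is independent of
heterozygosity, so the separatrix is the vertical line `p = p̂`, the
directional comparator is decisive away from the line, and optional
bisection (`refine = TRUE`) sharpens the bracket to `1e-6`. An `absorbing`
comparator (run to within `epsilon` of a boundary) is available as a
robustness check; the two agree everywhere except within one grid step of
the threshold.

Cells with no fate flip are reported honestly: `"none"` when every start
shares one fate (e.g. `S = 0` with unequal penetrances, where the stronger
element always sweeps) and `"degenerate"` at `S = 1`, where homozygote
starts never change (selection needs heterozygotes and pure selfing never
creates them) and every frequency is an equilibrium.

The packaged tests and examples run the scans on thinned grids — a handful
of selfing rates, and frequency steps of 0.001 (monoecious, where the scan
is checked against the closed form to within one grid step) or 0.005
(androdioecious shape checks) — chosen so the whole suite completes in
well under a minute while still pinning every qualitative feature: the
threshold's monotone rise with selfing for Medea-vs-Medea, the small
deviation (< 0.1) of androdioecious Medea thresholds from the monoecious
curve, the interior maximum in S for nearly-equal antagonistic peels, and
the sub-0.5 threshold with which an equally penetrant peel displaces a
resident Medea.

```{r example, fig.width = 5, fig.height = 3.5}
eq <- equilibrium(S = 0.6, k1 = 0.9, k2 = 0.5)
glance(eq)

scan <- threshold_scan(model_params(0, 0.9, 0.5),
                       S_grid = seq(0.1, 0.9, 0.2))
scan[, c("S", "threshold", "bracket_lo", "bracket_hi", "flag")]
autoplot(scan)
```

## Random fixtures

`generate_fixtures()` exists for property testing, not for emulating data:
the model is deterministic, so the only synthetic inputs are genotype
states (uniform on the simplex via normalized exponentials, i.e. a flat
Dirichlet) and parameters (uniform on their declared ranges; `b` on
`[0.5, 2]`). Fixtures are reproducible per seed. Because they cover the
whole state space rather than biologically typical corners, oracle
equivalence over fixtures demonstrates algebraic correctness of the
recursions — it says nothing about which parameter regions real
*Caenorhabditis* populations occupy.

## Known limitations

The package inherits the model's idealizations: infinite population size
(no drift, although drift is precisely what lets rare alleles cross the
unstable threshold in nature), no carrier costs, no reproductive
compensation within broods, no sex linkage or sex-specific penetrance, no
male production by X nondisjunction, and no spatial or group structure.
Fate classification after a fixed horizon can report `undecided` for
starts numerically at the separatrix; absorption to a boundary under
obligate outcrossing is algebraic rather than geometric, so absorbing-mode
classification there needs generous generation caps. These are properties
of the dynamics, not bugs; the directional comparator is the intended
instrument.
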