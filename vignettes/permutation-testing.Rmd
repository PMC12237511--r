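---
title: "Permutation testing for quantitative-trait GWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation testing for quantitative-trait GWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permforge)
```

## The testing problem

A genome-wide association study of a continuous phenotype tests, for each of
m variants, whether the additive allele count is linearly associated with the
trait. permforge scores each variant with the simple-regression F statistic

$$F = \frac{\rho^2}{1-\rho^2}\,(n_{\mathrm{eff}}-2),
\qquad
\rho = \frac{\sum_i (x_i-\bar X)(y_i-\bar Y)}
            {\sqrt{\sum_i (x_i-\bar X)^2\sum_i (y_i-\bar Y)^2}},$$

where $x$ is the vector of allele counts (0/1/2, possibly missing) and $y$
the adjusted phenotype. With m in the millions, asymptotic p-values make
false positives inevitable at conventional thresholds, and analytic
multiple-testing corrections rely on a theoretical null that real genotype
data need not follow. Permutation testing instead simulates the null by
shuffling phenotypes across individuals, which breaks genotype–phenotype
association while preserving the genotype correlation structure.

A permuted p-value is $p = (x+1)/(b+1)$, where $x$ counts the permuted
statistics that tie or exceed the observed one among $b$ permutations. Two
consequences shape everything downstream:

* the smallest attainable p-value is $1/(b+1)$, so resolving the
  genome-wide threshold $5\times10^{-8}$ needs
  `min_permutations(5e-8)` = `r format(min_permutations(5e-8), big.mark = " ")`
  permutations per variant — about $2\times10^7$;
* the count $x$ uses the *inclusive* convention ($F_{\mathrm{perm}} \ge
  F_{\mathrm{obs}}$), the conservative choice under which $(x+1)/(b+1)$ is a
  valid p-value.

Two drivers reduce the cost in different ways.

**maxT** (`run_maxt()`) builds the null distribution from the *maximum* F
across variants within each permutation. Ranking each observed F in that
distribution yields `emp2`, a family-wise-error-controlling adjusted
p-value; around 1000 permutations suffice for control at $\alpha=0.05$
regardless of m. The pointwise `emp1` is reported alongside.

**Adaptive permutation** (`run_adaptive()`) stops permuting a variant once
its exceedance count reaches a limit R: clearly null variants are abandoned
after a few hundred permutations, concentrating effort on the interesting
ones. A stopped variant reports $p=(x+1)/(B+1)$ with $B$ the permutations it
actually saw; survivors of all $b_{\max}$ permutations report
$p=(x+1)/(b_{\max}+1)$.

## One-time covariate adjustment

`adjust_phenotype()` residualizes the raw phenotype on an intercept plus
optional covariates, $y = b - C(C^{\mathsf T}C)^{-1}C^{\mathsf T}b$, once,
before any permutation; permutations then shuffle the adjusted $y$. The
alternative — refitting covariates inside every permutation — multiplies the
cost of the whole procedure by the regression cost and is deliberately not
offered. Adjusting once means the permutation null treats covariate effects
as fixed; this is the standard trade-off for permutation GWAS at scale.

## The kernel: why only the numerator is recomputed

Under phenotype permutation the denominator of $\rho$ is constant: the
genotype sum of squares does not involve $y$, and the phenotype sum of
squares is permutation-invariant. Each permutation therefore only needs the
numerators $\sum_i (a_{ji}-\bar a_j)\,y_{\pi(i)}$ for all variants j — a
single genotype-matrix × phenotype-vector product. `kernel_matrix()` centers
each variant row by its non-missing mean once and writes exact zeros at
missing entries, so a missing genotype contributes exactly nothing to the
numerator (mean imputation). This is the only missingness policy consistent
with keeping the denominator constant while streaming the genotype matrix;
the exact alternative — recomputing the phenotype mean and sum of squares
over each variant's non-missing pattern in every permutation — is available
as `f_exact_pairwise()` for validation, and coincides with the kernel when
nothing is missing.

With missing genotypes the effective sample size in F is the per-variant
non-missing count (`n_obs`), matching common GWAS practice; the phenotype
sum of squares uses all samples. Degenerate variants — monomorphic or
all-missing — are flagged, report p = 1, and are excluded from the maxT
maxima so they cannot dilute the null distribution.

### Blocking

`block_plan()` mirrors a buffered streaming design: a variant record is
`ceiling(n/4)` bytes of 2-bit codes rounded up to 64-byte (512-bit) units,
and a buffer of `buffer_bytes` (default $2^{26}$) holds
`floor(buffer_bytes / record)` records per block. Blocking is a throughput
concept and must never change results. Because optimized BLAS products
change their accumulation order with the row count, the blocked kernel
`dot_products_blocked()` accumulates each variant row independently in fixed
left-to-right order — making its output bitwise identical for *every*
partition — while the drivers use the equivalent fast matrix product (the
two agree to floating-point rounding).

### Emulated fixed point

`dot_products_fixed()` emulates an integer multiply-accumulate pipeline:
phenotype and per-variant means are quantized to a signed fixed-point format
(default Q16.16: 32 total bits, 16 fractional, 64-bit accumulator) with
round-to-nearest-even and saturation (counts surfaced in results), genotype
codes are exact small integers, and products are accumulated wide. Every
intermediate is an exact multiple of $2^{-32}$ within double precision, so
the emulation is faithful to integer arithmetic. The default widths keep the
no-overflow guarantee
`accumulator_bits >= total_bits + ceiling(log2(n)) + 2` up to n = 262 144
samples. Fixed point is opt-in (`fixed_point = fixed_point_format()`);
floating point is the reference path, because the approximation is
acceptable exactly when what matters is the *comparison* of statistics, not
their values — permuted p-values are rank-based.

Fidelity is characterized normwise: the maximum absolute deviation of a
block's numerators over the block's largest |numerator| (about $4\times
10^{-6}$ for Q16.16 on a 500×200 block), plus an identical top-10 magnitude
ranking. A componentwise relative error is not a meaningful target here: any
random block contains numerators arbitrarily close to zero, where a bounded
absolute quantization error produces an unbounded ratio. The componentwise
*absolute* bound $n\,2^{-\mathrm{frac}}\max(2, \max|y|)$ is asserted as the
operation's contract. Near-singular correlations ($|\rho|\to 1$) can exceed
the float path's clipping slack under quantization; fixed-point mode is not
recommended for data with near-perfect association.

### Reproducible permutations

A `permutation_plan(seed, n_perm, n)` defines the stream. The k-th
permutation is generated from a counter-derived seed feeding
Mersenne-Twister + rejection sampling (`sample.int`), so any permutation is
retrievable in O(1), the maxT and adaptive drivers share identical streams
given the same seed, and external oracles can replay them. The generator
identity string (`mt19937-rejection/counter-lcg-v1`) is recorded in every
result and output file; identical configuration and seed give byte-identical
result files.

## Adaptive scheduling choices

The dropping schedule starts at the minimum permutations per variant
(`mps`, default 121) and the interval grows by 20% every 5 checkpoints
(`growth = 1.2`, `drops_per_growth = 5`); checkpoint positions are rounded-up
running sums, capped to end exactly at `b_max`. Exceedances are counted at
every permutation, but dropping is evaluated only at checkpoints — removing
variants means regenerating the kernel matrix, which a buffered design does
in batches. `B` is then the checkpoint's permutation count, and `x` is
capped at R in the reported p-value. `strict = TRUE` instead drops at the
exact permutation where x reaches R, for comparison; checkpointed `B` is
never earlier than strict `B`.

The exceedance limit defaults to R = 10, the customary choice in the
sequential/adaptive permutation literature (roughly: after 10 exceedances
the p-value estimate's relative error is already dominated by its own
randomness, not by stopping); it is configurable and recorded in all
metadata. Both the limit and the inclusive tie convention are surfaced
rather than hard-coded because published tools differ on them.

maxT ranks F itself, not $|\rho|$: the two orderings coincide only when
`n_obs` is constant across variants, and F is the statistic being reported.

## Synthetic data: what it does and does not emulate

`sim_spec()` + `simulate_genotypes()` + `simulate_phenotype()` generate
independent Hardy–Weinberg variants (per-variant MAF uniform on
`maf_range`, default 0.05–0.5), independent per-entry missingness, and a
phenotype that is Gaussian noise (`noise_sd = 1`) plus optional additive
planted effects and covariate contributions. `beta_for_r2()` converts a
target per-variant variance-explained into an allele-copy effect.
`make_fixture()` writes the PLINK trio, covariate file and a ground-truth
TSV. Defaults were chosen once as ordinary values for a common-variant
quantitative-trait simulation and are not tuned.

What this generator deliberately lacks: linkage disequilibrium (variants are
independent), population structure and relatedness, MAF-dependent
missingness, and non-Gaussian trait distributions. Passing calibration tests
on these fixtures therefore demonstrates correctness of the *procedures*
(error control under a true null, exactness of the formulas, determinism),
not robustness to structured real data. Under independence maxT behaves
almost like Bonferroni; its practical advantage appears under dependence,
which the generator does not produce by default.

## Numerical choices

* Correlations outside $[-1,1]$ by at most $10^{-9}$ are clipped (rounding
  slack); larger excursions raise an error, since they indicate a broken
  numerator, not rounding. $\rho^2 = 1$ maps to an infinite F that compares
  greater than every finite statistic.
* Exceedance ties are exact floating-point comparisons. Validation fixtures
  meant to match oracles *exactly* use integer-valued phenotypes and
  genotype rows whose sums are divisible by n, making all statistics exact
  in double precision so tie decisions cannot depend on summation order.
* Quantization rounds half to even and saturates; saturation counts are
  reported, never silent.
* `.fam` phenotypes of −9 or NA mark missing phenotype; those samples are
  dropped before adjustment, with a logged count. PLINK's convention leaves
  this policy to the tool; dropping is the only option that does not invent
  data.
* Result files render doubles with 17 significant digits so they parse back
  to the same value.

## Validation scale

The shipped tests exercise the full stack at desk scale, chosen to keep the
suite fast while leaving each check statistically meaningful: exhaustive
enumeration of all 5040 permutations of n = 7 against a brute-force oracle;
400 null replicates (m = 50, n = 100, 200 permutations) for family-wise
error calibration against the 95% binomial band; planted-effect recovery at
m = 1000, n = 500 with per-variant R² = 0.2 over 999 permutations; and
kernel fidelity on a 500×200 block. `scripts/acceptance.R` recomputes all of
these from scratch.

## Limitations

* Quantitative traits only; no logistic/case-control support and no linear
  mixed models (related individuals must be handled upstream).
* SNP-major PLINK 1 binary input only; sample-major files are rejected, not
  converted; no VCF/BGEN/dosage input.
* Single-process; determinism is guaranteed by construction rather than by
  reduction across workers.
* Covariates are adjusted once, not per permutation (by design, see above).
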