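# Independent reference implementations used to validate the package's own
# paths. These deliberately avoid the package's kernel/driver code: naive
# loops, stats::cor / stats::lm, and exhaustive enumeration.

# all n! permutations of 1..n as an (n!) x n matrix, lexicographic
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    idx <- seq(r + 1L, r + nrow(sub))
    out[idx, 1] <- first
    out[idx, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

# per-variant F via stats::cor, complete-case over the variant's pattern,
# with the kernel's conventions (mean-imputed numerator is NOT used here:
# this version is only applied to data without missingness)
oracle_f <- function(codes, y) {
  apply(codes, 1, function(a) {
    r <- stats::cor(a, y)
    if (abs(r) >= 1) Inf else r^2 / (1 - r^2) * (length(a) - 2)
  })
}

# brute-force maxT over an explicit permutation matrix (rows = permutations)
oracle_maxt <- function(codes, y, perms) {
  f_obs <- oracle_f(codes, y)
  n_perm <- nrow(perms)
  m <- nrow(codes)
  x1 <- numeric(m)
  maxima <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    fp <- oracle_f(codes, y[perms[k, ]])
    x1 <- x1 + (fp >= f_obs)
    maxima[k] <- max(fp)
  }
  x2 <- vapply(f_obs, function(f) sum(maxima >= f), numeric(1))
  list(f_obs = f_obs, emp1 = (x1 + 1) / (n_perm + 1),
       emp2 = (x2 + 1) / (n_perm + 1), maxima = maxima)
}

# naive double-loop centered dot products with mean imputation
oracle_dot_products <- function(codes, y) {
  m <- nrow(codes)
  out <- numeric(m)
  for (j in seq_len(m)) {
    a <- codes[j, ]
    obs <- which(!is.na(a))
    abar <- mean(a[obs])
    s <- 0
    for (i in obs) s <- s + (a[i] - abar) * y[i]
    out[j] <- s
  }
  out
}

# pointwise permutation p-values replaying the package's stream but with an
# independent statistic path (cor-based); only valid without missing data
oracle_pointwise <- function(codes, y, plan) {
  f_obs <- oracle_f(codes, y)
  x <- numeric(nrow(codes))
  for (k in seq_len(plan$n_perm)) {
    fp <- oracle_f(codes, y[perm_at(plan, k)])
    x <- x + (fp >= f_obs)
  }
  (x + 1) / (plan$n_perm + 1)
}

# integer-exact toy dataset: every row sum divisible by n and an integer
# phenotype summing to 0, so all numerators/denominators are exact in
# double precision and summation order cannot perturb tie decisions
exact_toy <- function() {
  codes <- rbind(
    c(0L, 1L, 1L, 1L, 1L, 1L, 2L),
    c(2L, 2L, 1L, 1L, 1L, 0L, 0L),
    c(2L, 0L, 2L, 0L, 2L, 1L, 0L),
    c(1L, 2L, 0L, 1L, 2L, 0L, 1L))
  rownames(codes) <- paste0("snp_", 1:4)
  colnames(codes) <- paste0("ind_", 1:7)
  list(codes = codes, b_raw = c(5, -3, 2, 0, -1, 4, -7))
}

# small random dataset helper; when r2 is given, variant 1 carries a planted
# effect calibrated against its realized allele frequency
rand_data <- function(m, n, missing_rate = 0, seed = 1, r2 = NULL) {
  spec <- sim_spec(m = m, n = n, missing_rate = missing_rate, seed = seed)
  g <- simulate_genotypes(spec)
  if (!is.null(r2)) {
    maf_hat <- mean(g$codes[1, ], na.rm = TRUE) / 2
    if (maf_hat > 0.5) maf_hat <- 1 - maf_hat
    maf_hat <- max(maf_hat, 1e-3)
    spec <- sim_spec(m = m, n = n, missing_rate = missing_rate,
                     causal_idx = 1L, betas = beta_for_r2(r2, maf_hat),
                     seed = seed)
  }
  ph <- simulate_phenotype(g, spec)
  list(geno = g, codes = g$codes, b_raw = ph$b_raw,
       pheno = adjust_phenotype(ph$b_raw))
}
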