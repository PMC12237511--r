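# covariate adjustment, per-variant summaries, F statistic, p-value formulas

test_that("phenotype adjustment centers and residualizes correctly", {
  expect_equal(adjust_phenotype(c(1, 2, 3))$y, c(-1, 0, 1))

  # an intercept-only covariate "matrix" equals plain centering
  b <- c(2.5, 1.1, 4.7, 3.3, 0.2)
  ps0 <- adjust_phenotype(b)
  expect_equal(ps0$y, b - mean(b))
  expect_lt(abs(mean(ps0$y)), 1e-9 * max(abs(b)))

  # against an independently solved normal-equation system
  b2 <- c(2, 1, 4, 3)
  z <- c(1, 2, 3, 4)
  C <- cbind(1, z)
  beta_ne <- solve(t(C) %*% C, t(C) %*% b2)
  ps <- adjust_phenotype(b2, covariates = cbind(z = z))
  expect_equal(ps$y, drop(b2 - C %*% beta_ne), tolerance = 1e-10)
  expect_equal(ps$ss_y, sum(ps$y^2))

  set.seed(9)
  Z <- matrix(rnorm(50 * 3), 50)
  b3 <- rnorm(50)
  C3 <- cbind(1, Z)
  res_ne <- drop(b3 - C3 %*% solve(t(C3) %*% C3, t(C3) %*% b3))
  expect_equal(adjust_phenotype(b3, Z)$y, res_ne, tolerance = 1e-10)
})

test_that("degenerate phenotypes and designs are rejected by name", {
  expect_error(adjust_phenotype(rep(2, 10)), "zero phenotype variance")
  z <- rnorm(10)
  expect_error(adjust_phenotype(rnorm(10), cbind(a = z, b = 2 * z)),
               "collinear.*b")
  expect_error(adjust_phenotype(c(1, 2)), "at least 3")
})

test_that("snp_summary matches hand sums and a naive loop", {
  s <- snp_summary(c(0L, 1L, 2L))
  expect_equal(s[c("mean", "ss_x", "n_obs")], list(mean = 1, ss_x = 2, n_obs = 3L))
  s2 <- snp_summary(c(2L, 2L, NA, 2L))
  expect_equal(s2$mean, 2)
  expect_equal(s2$ss_x, 0)
  expect_identical(s2$n_obs, 3L)
  expect_true(s2$degenerate)
  expect_true(snp_summary(c(NA_integer_, NA_integer_))$degenerate)

  set.seed(4)
  a <- sample(c(0:2, NA), 1000, replace = TRUE, prob = c(.3, .3, .3, .1))
  obs <- a[!is.na(a)]
  mu <- 0; for (v in obs) mu <- mu + v; mu <- mu / length(obs)
  ss <- 0; for (v in obs) ss <- ss + (v - mu)^2
  s3 <- snp_summary(a)
  expect_identical(s3$mean, mu)
  expect_equal(s3$ss_x, ss, tolerance = 1e-12)
  expect_identical(s3$n_obs, length(obs))

  # vectorized summaries agree with the scalar path row by row
  codes <- matrix(sample(c(0:2, NA), 200, replace = TRUE), nrow = 20)
  sm <- permforge:::snp_summaries(codes)
  for (j in seq_len(20)) {
    sj <- snp_summary(codes[j, ])
    expect_equal(sm$mean[j], sj$mean)
    expect_equal(sm$ss_x[j], sj$ss_x, tolerance = 1e-12)
    expect_identical(sm$n_obs[j], sj$n_obs)
  }
})

test_that("F from the numerator equals the squared OLS slope t-statistic", {
  expect_equal(f_from_numerator(0, 2, 5, 10)$f, 0)
  # proportional genotype/phenotype -> rho^2 = 1 -> +Inf sentinel
  a <- c(0, 1, 2, 1, 0)
  y <- a - mean(a)
  s <- snp_summary(as.integer(a))
  ft <- f_from_numerator(sum((a - s$mean) * y), s$ss_x, sum(y^2), 5)
  expect_identical(ft$f, Inf)
  expect_gt(ft$f, 1e300)  # the sentinel beats any finite F

  set.seed(12)
  for (rep in 1:25) {
    a <- rbinom(50, 2, runif(1, 0.1, 0.5))
    if (var(a) == 0) next
    y <- rnorm(50); y <- y - mean(y)
    s <- snp_summary(as.integer(a))
    num <- sum((a - s$mean) * y)
    f <- f_from_numerator(num, s$ss_x, sum(y^2), 50)$f
    tstat <- summary(lm(y ~ a))$coefficients["a", "t value"]
    expect_equal(f, tstat^2, tolerance = 1e-8)
  }
})

test_that("correlations outside [-1,1] clip within 1e-9 and error beyond", {
  f1 <- f_from_numerator(sqrt(2 * 5) * (1 + 1e-10), 2, 5, 10)
  expect_identical(f1$rho, 1)
  expect_error(f_from_numerator(sqrt(2 * 5) * (1 + 1e-6), 2, 5, 10),
               "upstream numerator bug")
})

test_that("permutation p-value formulas follow (x+1)/(b+1) and Eq.-3 branches", {
  expect_equal(perm_pvalue(0, 19), 0.05)
  expect_equal(perm_pvalue(99, 99), 1)
  expect_equal(perm_pvalue(4, 99), 0.05)
  expect_error(perm_pvalue(5, 4), "exceedance")

  expect_equal(adaptive_pvalue(2, R = 10, B = 999, b_max = 999), 0.003)
  expect_equal(adaptive_pvalue(10, R = 10, B = 500, b_max = 999), 11 / 501)
  expect_equal(adaptive_pvalue(0, R = 10, B = 19, b_max = 19),
               perm_pvalue(0, 19))
  expect_error(adaptive_pvalue(11, R = 10, B = 500, b_max = 999), "exceed")
  expect_error(adaptive_pvalue(2, R = 10, B = 500, b_max = 999),
               "b_max permutations")

  # p is never below the resolution floor, never above 1
  for (np in c(1, 7, 100)) {
    p <- perm_pvalue(0:np, np)
    expect_true(all(p >= 1 / (np + 1) & p <= 1))
  }
})

test_that("minimum permutation counts hit the resolution bound", {
  expect_identical(min_permutations(0.05), 19)
  expect_identical(min_permutations(1), 0)
  b <- min_permutations(5e-8)
  expect_identical(b, 19999999)
  expect_lte(1 / (b + 1), 5e-8)
  expect_gt(1 / b, 5e-8)
  expect_error(min_permutations(0), "alpha")
})

test_that("allele flipping leaves F and permutation p-values unchanged", {
  d <- rand_data(m = 30, n = 60, missing_rate = 0.1, seed = 21)
  flipped <- 2L - d$codes  # NA preserved automatically
  r1 <- run_maxt(d$codes, d$pheno, n_perm = 50, seed = 5)
  r2 <- run_maxt(flipped, d$pheno, n_perm = 50, seed = 5)
  expect_equal(tidy(r1)$f_obs, tidy(r2)$f_obs, tolerance = 1e-12)
  expect_identical(tidy(r1)$emp1, tidy(r2)$emp1)
  expect_identical(tidy(r1)$emp2, tidy(r2)$emp2)
})

test_that("ss_y is permutation invariant", {
  d <- rand_data(m = 5, n = 40, seed = 31)
  y <- d$pheno$y
  set.seed(2)
  for (i in 1:20) {
    expect_equal(sum(y[sample(40)]^2), d$pheno$ss_y, tolerance = 1e-12)
  }
})

test_that("pairwise-complete reference equals the kernel when nothing is missing", {
  d <- rand_data(m = 40, n = 80, missing_rate = 0, seed = 41)
  ref <- f_exact_pairwise(d$codes, d$pheno$y)
  r <- run_maxt(d$codes, d$pheno, n_perm = 1, seed = 1)
  expect_equal(tidy(r)$f_obs, ref$f, tolerance = 1e-10)
})

test_that("samples with missing phenotype are dropped before analysis", {
  tmp <- withr::local_tempdir()
  spec <- sim_spec(m = 10, n = 30, seed = 3)
  fix <- make_fixture(spec, file.path(tmp, "mp"))
  fam <- utils::read.table(file.path(tmp, "mp.fam"))
  fam$V6[c(2, 7)] <- -9
  utils::write.table(fam, file.path(tmp, "mp.fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  plink <- read_plink(file.path(tmp, "mp"))
  expect_message(prep <- prepare_data(plink), "2 sample")
  expect_identical(prep$pheno$n, 28L)
  expect_identical(ncol(prep$genotypes$codes), 28L)
})
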