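# maxT and adaptive drivers

test_that("maxT is symmetric for identical variants and emp2 dominates emp1", {
  d <- rand_data(m = 20, n = 50, seed = 61)
  codes <- d$codes
  codes[2, ] <- codes[1, ]  # duplicate row
  rownames(codes) <- paste0("v", 1:20)
  r <- run_maxt(codes, d$pheno, n_perm = 100, seed = 4)
  td <- tidy(r)
  expect_identical(td$emp1[1], td$emp1[2])
  expect_identical(td$emp2[1], td$emp2[2])
  expect_true(all(td$emp2 >= td$emp1))
  expect_identical(length(r$null_maxima), 100L)
  # emp2 invariant: (#{null maxima >= F_j} + 1) / (n_perm + 1)
  for (j in c(1, 5, 20)) {
    expect_identical(td$emp2[j],
                     (sum(r$null_maxima >= td$f_obs[j]) + 1) / 101)
  }
})

test_that("degenerate variants report p = 1 and never dilute the null maxima", {
  d <- rand_data(m = 10, n = 40, seed = 71)
  codes <- d$codes
  codes[3, ] <- 1L                 # monomorphic
  codes[7, ] <- NA_integer_        # all missing
  r <- run_maxt(codes, d$pheno, n_perm = 50, seed = 6)
  td <- tidy(r)
  expect_true(all(td$degenerate[c(3, 7)]))
  expect_identical(td$emp1[c(3, 7)], c(1, 1))
  expect_identical(td$emp2[c(3, 7)], c(1, 1))
  expect_identical(td$f_obs[3], 0)
  # maxima computed over the 8 live variants only: rerun without the
  # degenerate rows and compare (to rounding; the matrix shapes differ)
  r2 <- run_maxt(codes[-c(3, 7), ], d$pheno, n_perm = 50, seed = 6)
  expect_equal(r$null_maxima, r2$null_maxima, tolerance = 1e-12)
  expect_error(run_maxt(codes[c(3, 7), ], d$pheno, n_perm = 5, seed = 1),
               "all variants are degenerate")
})

test_that("maxT over the exhaustive permutation group matches brute force exactly", {
  toy <- exact_toy()
  pheno <- adjust_phenotype(toy$b_raw)
  perms <- all_permutations(7L)
  expect_identical(nrow(perms), 5040L)
  r <- run_maxt(toy$codes, pheno, perms = perms)
  oracle <- oracle_maxt(toy$codes, pheno$y, perms)
  td <- tidy(r)
  expect_equal(td$f_obs, unname(oracle$f_obs), tolerance = 1e-12)
  expect_identical(td$emp1, unname(oracle$emp1))
  expect_identical(td$emp2, unname(oracle$emp2))
})

test_that("the dropping schedule follows the grow-by-20%-every-5 recurrence", {
  cfg <- adaptive_config(b_max = 1e7, mps = 121)
  cps <- dropping_schedule(cfg)
  expect_identical(cps[1:6], c(121, 242, 363, 484, 605, 751))
  # and with the other documented minimum-permutation setting
  cps36 <- dropping_schedule(adaptive_config(b_max = 1e6, mps = 36))
  expect_identical(cps36[1:6], c(36, 72, 108, 144, 180, ceiling(180 + 36 * 1.2)))

  # mps >= b_max -> a single checkpoint at b_max
  expect_identical(dropping_schedule(adaptive_config(b_max = 50, mps = 50)), 50)

  set.seed(10)
  for (i in 1:100) {
    b_max <- sample(50:5000, 1)
    cfg <- adaptive_config(b_max = b_max, mps = sample(5:b_max, 1),
                           growth = runif(1, 1.05, 2),
                           drops_per_growth = sample(1:8, 1))
    cps <- dropping_schedule(cfg)
    expect_true(all(diff(cps) > 0))
    expect_lte(max(cps), b_max)
    expect_identical(cps[length(cps)], as.double(b_max))
  }
})

test_that("with an unreachable limit, adaptive p equals the pointwise permutation p", {
  d <- rand_data(m = 15, n = 40, seed = 81)
  b_max <- 300
  cfg <- adaptive_config(R = b_max + 1, b_max = b_max, mps = 50)
  ad <- run_adaptive(d$codes, d$pheno, cfg, seed = 9)
  td <- tidy(ad)
  expect_false(any(td$dropped))
  expect_true(all(td$B == b_max))
  # independent oracle replaying the identical stream
  p_ref <- oracle_pointwise(d$codes, d$pheno$y,
                            permutation_plan(9, b_max, 40))
  expect_identical(td$emp_p, unname(p_ref))
  # and the package's own maxT emp1 from the same seed agrees too
  r <- run_maxt(d$codes, d$pheno, n_perm = b_max, seed = 9)
  expect_identical(td$emp_p, tidy(r)$emp1)
})

test_that("a null variant is dropped at the first checkpoint with near-certainty", {
  # genotype orthogonalized against y: observed F ~ 0, so essentially every
  # permuted F ties or exceeds it and x reaches R well before checkpoint 1
  hits <- 0L
  for (s in 1:50) {
    set.seed(s + 1000)
    n <- 30
    a <- rep(c(0L, 1L, 2L), each = 10)
    xc <- a - mean(a)
    y0 <- rnorm(n); y0 <- y0 - mean(y0)
    y <- y0 - (sum(xc * y0) / sum(xc * xc)) * xc
    codes <- rbind(a, rbinom(n, 2, 0.4), rbinom(n, 2, 0.4))
    rownames(codes) <- c("null", "r1", "r2")
    ps <- adjust_phenotype(y)
    cfg <- adaptive_config(R = 10, b_max = 200, mps = 25)
    ad <- run_adaptive(codes, ps, cfg, seed = s)
    td <- tidy(ad)
    if (td$dropped[1] && td$B[1] == 25) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("dropped variants obey the Eq.-3 second branch and effort bounds", {
  d <- rand_data(m = 60, n = 80, r2 = 0.25, seed = 91)
  cfg <- adaptive_config(R = 10, b_max = 400, mps = 40)
  ad <- run_adaptive(d$codes, d$pheno, cfg, seed = 13)
  td <- tidy(ad)
  expect_true(any(td$dropped))
  drp <- td[td$dropped, ]
  expect_true(all(drp$x == cfg$R))
  expect_true(all(drp$B %in% ad$schedule))
  expect_identical(drp$emp_p, (drp$x + 1) / (drp$B + 1))
  expect_true(all(drp$emp_p >= (cfg$R + 1) / (cfg$b_max + 1)))
  surv <- td[!td$dropped & !td$degenerate, ]
  expect_true(all(surv$B == cfg$b_max))
  expect_identical(surv$emp_p, (surv$x + 1) / (cfg$b_max + 1))
  # the planted causal variant survives to b_max with a small p
  expect_false(td$dropped[1])
  expect_identical(td$emp_p[1], 1 / (cfg$b_max + 1))
})

test_that("strict mode drops at the exact permutation x reaches R", {
  d <- rand_data(m = 25, n = 50, seed = 101)
  cfg <- adaptive_config(R = 5, b_max = 150, mps = 30)
  ad <- run_adaptive(d$codes, d$pheno, cfg, seed = 3, strict = TRUE)
  td <- tidy(ad)
  drp <- td[td$dropped, ]
  expect_true(nrow(drp) > 0)
  expect_true(all(drp$x == 5))
  # strict B is a permutation index, not necessarily a checkpoint
  expect_true(all(drp$B >= 5 & drp$B < 150))
  # checkpointed B for the same data is always >= strict B (never earlier)
  ad2 <- run_adaptive(d$codes, d$pheno, cfg, seed = 3)
  td2 <- tidy(ad2)
  shared <- td$dropped & td2$dropped
  expect_true(all(td2$B[shared] >= td$B[shared]))
})

test_that("the active set shrinks monotonically across checkpoints", {
  d <- rand_data(m = 50, n = 60, seed = 111)
  cfg <- adaptive_config(R = 8, b_max = 300, mps = 30)
  ad <- run_adaptive(d$codes, d$pheno, cfg, seed = 17)
  td <- tidy(ad)
  # reconstruct the active count after each checkpoint from drop records
  active_after <- vapply(ad$schedule, function(cp) {
    sum(!td$degenerate) - sum(td$dropped & td$B <= cp)
  }, numeric(1))
  expect_true(all(diff(active_after) <= 0))
})

test_that("a planted strong effect reaches the maxT p-value floor", {
  hits <- 0L
  for (s in 1:10) {
    d <- rand_data(m = 1000, n = 500, r2 = 0.2, seed = s + 200)
    r <- run_maxt(d$codes, d$pheno, n_perm = 999, seed = s)
    if (tidy(r)$emp2[1] == 1 / 1000) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("fixed-point and floating-point drivers agree on this scale", {
  d <- rand_data(m = 50, n = 100, r2 = 0.1, seed = 121)
  r_fl <- run_maxt(d$codes, d$pheno, n_perm = 100, seed = 5)
  r_fx <- run_maxt(d$codes, d$pheno, n_perm = 100, seed = 5,
                   fixed_point = fixed_point_format())
  expect_equal(tidy(r_fx)$f_obs, tidy(r_fl)$f_obs, tolerance = 1e-3)
  # identical ranking of the strongest signals
  expect_identical(order(tidy(r_fx)$f_obs, decreasing = TRUE)[1:5],
                   order(tidy(r_fl)$f_obs, decreasing = TRUE)[1:5])
})
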