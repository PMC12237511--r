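# Core statistics for quantitative-trait association testing.
#
# Per variant, association is scored with the simple-regression F statistic
#   F = rho^2 / (1 - rho^2) * (n_eff - 2),
# where rho is Pearson's correlation between the allele-count vector and the
# adjusted phenotype. Under phenotype permutation the denominator of rho is
# constant, so the permutation kernel only recomputes the centered-genotype /
# phenotype dot product (the numerator); see engine.R.

#' Adjust a phenotype for covariates
#'
#' Residualizes the raw phenotype on an intercept plus optional covariates:
#' with covariate matrix `C` (a leading column of ones is prepended
#' internally), `y = b - C (C'C)^{-1} C' b`; without covariates, `y = b -
#' mean(b)`. The adjustment is performed once, before any permutation.
#'
#' @param b_raw Numeric phenotype vector of length n (no missing values;
#'   samples with missing phenotype are dropped upstream, see
#'   [prepare_data()]).
#' @param covariates Optional n x c numeric matrix (or data frame) of
#'   covariates, without an intercept column.
#' @return A `phenotype_set` with elements `b_raw`, `C` (the design matrix
#'   actually used, intercept included, or `NULL`), `y` (zero-mean adjusted
#'   phenotype), `ss_y` (its sum of squares) and `n`.
#' @examples
#' adjust_phenotype(c(1, 2, 3))$y  # -1 0 1
#' @export
adjust_phenotype <- function(b_raw, covariates = NULL) {
  b_raw <- as.numeric(b_raw)
  n <- length(b_raw)
  if (anyNA(b_raw)) {
    stop("phenotype contains missing values; drop those samples first",
         call. = FALSE)
  }
  if (n < 3) stop("need at least 3 phenotyped samples", call. = FALSE)
  if (stats::var(b_raw) == 0) {
    stop("zero phenotype variance: the phenotype is constant", call. = FALSE)
  }
  if (is.null(covariates) || NCOL(covariates) == 0) {
    C <- NULL
    y <- b_raw - mean(b_raw)
  } else {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n) {
      stop("covariate matrix must have one row per phenotyped sample",
           call. = FALSE)
    }
    C <- cbind(`(intercept)` = 1, covariates)
    if (is.null(colnames(covariates))) {
      colnames(C)[-1] <- paste0("covar", seq_len(ncol(covariates)))
    }
    qrC <- qr(C)
    if (qrC$rank < ncol(C)) {
      dropped <- colnames(C)[qrC$pivot[seq(qrC$rank + 1L, ncol(C))]]
      stop("covariate matrix is rank deficient; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    y <- qr.resid(qrC, b_raw)
  }
  ss_y <- sum(y * y)
  if (ss_y <= 0) {
    stop("zero phenotype variance after covariate adjustment", call. = FALSE)
  }
  structure(list(b_raw = b_raw, C = C, y = y, ss_y = ss_y, n = n),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("<phenotype_set> n = %d, %s, ss_y = %.6g\n", x$n,
              if (is.null(x$C)) "mean-centered"
              else sprintf("adjusted for %d covariate(s)", ncol(x$C) - 1L),
              x$ss_y))
  invisible(x)
}

#' Per-variant genotype summary
#'
#' Mean, centered sum of squares, standard deviation and non-missing count of
#' one allele-count vector, all over the non-missing entries only. A variant
#' with no non-missing entries is flagged degenerate rather than raising an
#' error; degenerate variants are excluded from testing and report p = 1.
#'
#' @param a Integer vector of codes in \{0, 1, 2, NA\}.
#' @return A list with `mean`, `ss_x`, `n_obs`, `sd` and `degenerate`.
#' @examples
#' snp_summary(c(0L, 1L, 2L))  # mean 1, ss_x 2, n_obs 3
#' @export
snp_summary <- function(a) {
  obs <- !is.na(a)
  n_obs <- sum(obs)
  if (n_obs == 0L) {
    return(list(mean = NA_real_, ss_x = 0, n_obs = 0L, sd = NA_real_,
                degenerate = TRUE))
  }
  av <- as.numeric(a[obs])
  m <- sum(av) / n_obs
  ss <- sum((av - m)^2)
  list(mean = m, ss_x = ss, n_obs = n_obs,
       sd = if (n_obs > 1) sqrt(ss / (n_obs - 1)) else NA_real_,
       degenerate = ss == 0)
}

# Vectorized summaries over the rows of a codes matrix. ss_x == 0 covers both
# monomorphic and all-missing rows; `all_missing` distinguishes them.
snp_summaries <- function(codes) {
  obs <- !is.na(codes)
  n_obs <- rowSums(obs)
  sums <- rowSums(codes, na.rm = TRUE)
  mean <- ifelse(n_obs > 0, sums / n_obs, NA_real_)
  sumsq <- rowSums(codes * codes, na.rm = TRUE)
  ss_x <- pmax(sumsq - ifelse(n_obs > 0, sums^2 / n_obs, 0), 0)
  tibble::tibble(
    snp_id = rownames(codes) %||% paste0("snp_", seq_len(nrow(codes))),
    mean = mean, ss_x = ss_x, n_obs = as.integer(n_obs),
    sd = ifelse(n_obs > 1, sqrt(ss_x / pmax(n_obs - 1, 1)), NA_real_),
    all_missing = n_obs == 0L,
    degenerate = n_obs == 0L | ss_x == 0
  )
}

#' F statistic from a precomputed numerator
#'
#' Converts the centered dot product `num = sum over non-missing i of
#' (a_i - mean(a)) * y_i` into Pearson's correlation
#' `rho = num / sqrt(ss_x * ss_y)` and the F statistic
#' `F = rho^2 / (1 - rho^2) * (n_eff - 2)`. `rho` values outside `[-1, 1]`
#' by at most `1e-9` are clipped (floating-point slack); larger excursions
#' indicate an upstream bug and raise an error. `rho^2 = 1` yields `Inf`,
#' which compares greater than every finite F. A monomorphic variant
#' (`ss_x = 0`) is degenerate: F is 0 and flagged.
#'
#' All arguments are vectorized over variants (`ss_y` is a scalar).
#'
#' @param num Numerator(s) of rho.
#' @param ss_x Centered genotype sum(s) of squares (non-missing entries).
#' @param ss_y Adjusted-phenotype sum of squares (> 0).
#' @param n_eff Effective sample size(s): the per-variant non-missing count.
#' @return A tibble with columns `rho`, `f` and `degenerate`.
#' @export
f_from_numerator <- function(num, ss_x, ss_y, n_eff) {
  if (length(ss_y) != 1L || ss_y <= 0) {
    stop("ss_y must be a positive scalar", call. = FALSE)
  }
  k <- max(length(num), length(ss_x), length(n_eff))
  num <- rep_len(as.numeric(num), k)
  ss_x <- rep_len(as.numeric(ss_x), k)
  n_eff <- rep_len(as.numeric(n_eff), k)
  rho <- .rho_vec(num, ss_x, ss_y)
  degenerate <- ss_x <= 0
  r2 <- rho * rho
  f <- ifelse(r2 >= 1, Inf, r2 / (1 - r2) * (n_eff - 2))
  f[degenerate] <- 0
  tibble::tibble(rho = rho, f = f, degenerate = degenerate)
}

# clipped correlations from numerators; errors on excursions > 1e-9
.rho_vec <- function(num, ss_x, ss_y) {
  rho <- numeric(length(num))
  ok <- ss_x > 0
  rho[ok] <- num[ok] / sqrt(ss_x[ok] * ss_y)
  excess <- abs(rho) - 1
  if (any(excess > 1e-9)) {
    stop("correlation exceeds [-1, 1] by more than 1e-9 (max excess ",
         format(max(excess), digits = 3), "); upstream numerator bug",
         call. = FALSE)
  }
  pmin(pmax(rho, -1), 1)
}

# hot-loop variant of f_from_numerator: F values only, no tibble
.f_vec <- function(num, ss_x, ss_y, n_eff) {
  rho <- .rho_vec(num, ss_x, ss_y)
  r2 <- rho * rho
  f <- ifelse(r2 >= 1, Inf, r2 / (1 - r2) * (n_eff - 2))
  f[ss_x <= 0] <- 0
  f
}

#' Pointwise permutation p-value
#'
#' `p = (x + 1) / (n_perm + 1)`, where `x` is the number of permuted test
#' statistics that tie or exceed the observed one among `n_perm`
#' permutations. Always lies in `[1/(n_perm+1), 1]`.
#'
#' @param x Exceedance count(s), `0 <= x <= n_perm`.
#' @param n_perm Number of permutations performed.
#' @return Numeric p-value(s).
#' @examples
#' perm_pvalue(0, 19)  # 0.05
#' @export
perm_pvalue <- function(x, n_perm) {
  stopifnot(n_perm >= 1)
  if (any(x < 0 | x > n_perm)) {
    stop("exceedance count must lie in [0, n_perm]", call. = FALSE)
  }
  (x + 1) / (n_perm + 1)
}

#' Adaptive permutation p-value
#'
#' Early-stopping estimate: a variant whose permuted statistic exceeded the
#' observed one fewer than `R` times after the full `b_max` permutations gets
#' `p = (x + 1) / (b_max + 1)`; a variant stopped at the exceedance limit
#' (`x = R`) after `B` permutations gets `p = (x + 1) / (B + 1)`.
#'
#' @param x Exceedance count, `x <= R`.
#' @param R Exceedance limit.
#' @param B Permutations performed for this variant.
#' @param b_max Maximum permutations per variant.
#' @return Numeric p-value(s).
#' @examples
#' adaptive_pvalue(2, R = 10, B = 999, b_max = 999)  # 0.003
#' adaptive_pvalue(10, R = 10, B = 500, b_max = 999) # 11/501
#' @export
adaptive_pvalue <- function(x, R, B, b_max) {
  if (any(x > R)) stop("exceedance count exceeds the limit R", call. = FALSE)
  if (any(B > b_max)) stop("B cannot exceed b_max", call. = FALSE)
  if (any(x < R & B < b_max)) {
    stop("a variant with x < R must have run all b_max permutations",
         call. = FALSE)
  }
  ifelse(x < R, (x + 1) / (b_max + 1), (x + 1) / (B + 1))
}

#' Minimum permutation count for a significance threshold
#'
#' The smallest number of permutations `b` whose minimum attainable permuted
#' p-value, `1/(b + 1)`, reaches `alpha`. At the conventional genome-wide
#' threshold `alpha = 5e-8` this is 19 999 999, i.e. about 2e7 permutations
#' per variant.
#'
#' @param alpha Significance threshold in (0, 1].
#' @return An integer-valued double (counts can exceed `.Machine$integer.max`
#'   for very small `alpha`).
#' @examples
#' min_permutations(0.05)  # 19
#' @export
min_permutations <- function(alpha) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be a single value in (0, 1]", call. = FALSE)
  }
  b <- max(0, ceiling(1 / alpha) - 1)
  while (1 / (b + 1) > alpha) b <- b + 1
  while (b > 0 && 1 / b <= alpha) b <- b - 1
  b
}

#' Exact pairwise-complete F statistics (reference path)
#'
#' Recomputes, for each variant, Pearson's correlation and F over the
#' complete cases of that variant only — including the phenotype mean and sum
#' of squares over the variant's non-missing pattern. This is the slow
#' reference against which the streaming kernel's mean-imputation policy is
#' validated: the two coincide exactly when no genotypes are missing.
#'
#' @param geno Genotypes ([genotype_matrix()], `plink_data` or codes matrix).
#' @param y Numeric phenotype vector (adjusted or raw; it is re-centered over
#'   each variant's complete cases).
#' @return A tibble with `snp_id`, `rho`, `f`, `n_obs` and `degenerate`.
#' @export
f_exact_pairwise <- function(geno, y) {
  codes <- .codes_of(geno)
  stopifnot(ncol(codes) == length(y))
  res <- lapply(seq_len(nrow(codes)), function(j) {
    a <- codes[j, ]
    obs <- !is.na(a)
    n_obs <- sum(obs)
    if (n_obs < 3) return(c(NA_real_, 0, n_obs, 1))
    xv <- as.numeric(a[obs])
    yv <- y[obs]
    if (stats::var(xv) == 0 || stats::var(yv) == 0) {
      return(c(NA_real_, 0, n_obs, 1))
    }
    r <- stats::cor(xv, yv)
    f <- if (abs(r) >= 1) Inf else r^2 / (1 - r^2) * (n_obs - 2)
    c(r, f, n_obs, 0)
  })
  res <- do.call(rbind, res)
  tibble::tibble(
    snp_id = rownames(codes) %||% paste0("snp_", seq_len(nrow(codes))),
    rho = res[, 1], f = res[, 2], n_obs = as.integer(res[, 3]),
    degenerate = res[, 4] == 1
  )
}

#' Align genotypes, phenotype and covariates for analysis
#'
#' Drops samples whose `.fam` phenotype is missing (`NA` or the PLINK missing
#' code -9), aligns the optional covariate table by (FID, IID), and adjusts
#' the phenotype. The number of dropped samples is reported via `message()`.
#'
#' @param plink A `plink_data` object from [read_plink()].
#' @param covar Optional covariate tibble from [read_covar()].
#' @return A list with `genotypes` (columns restricted to phenotyped
#'   samples), `pheno` (a `phenotype_set`) and `n_dropped`.
#' @export
prepare_data <- function(plink, covar = NULL) {
  stopifnot(inherits(plink, "plink_data"))
  ph <- plink$samples$phenotype
  keep <- !is.na(ph) & ph != -9
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " sample(s) dropped for missing phenotype")
  }
  if (sum(keep) < 3) {
    stop("fewer than 3 samples with a non-missing phenotype", call. = FALSE)
  }
  codes <- plink$genotypes$codes[, keep, drop = FALSE]
  covmat <- NULL
  if (!is.null(covar)) {
    key <- paste(plink$samples$fid, plink$samples$iid)[keep]
    ckey <- paste(covar$fid, covar$iid)
    idx <- match(key, ckey)
    if (anyNA(idx)) {
      stop("covariate file is missing ", sum(is.na(idx)),
           " phenotyped sample(s)", call. = FALSE)
    }
    covmat <- as.matrix(covar[idx, setdiff(names(covar), c("fid", "iid")),
                              drop = FALSE])
  }
  pheno <- adjust_phenotype(ph[keep], covmat)
  geno <- genotype_matrix(codes, snp_ids = rownames(codes),
                          sample_ids = colnames(codes))
  list(genotypes = geno, pheno = pheno, n_dropped = n_dropped)
}
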