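# Synthetic GWAS fixtures with known ground truth: independent
# Hardy-Weinberg genotypes, planted additive effects, optional covariates,
# and PLINK-format output. Desk-scale stand-in for large simulated panels.

#' Specify a synthetic dataset
#'
#' @param m Variant count.
#' @param n Sample count.
#' @param maf_range Interval within (0, 0.5] from which each variant's minor
#'   allele frequency is drawn uniformly. Default `c(0.05, 0.5)` — common
#'   variants, the regime where additive single-variant tests are standard.
#' @param missing_rate Independent per-entry missingness probability in
#'   `[0, 1)`.
#' @param causal_idx Integer indices of variants with planted effects.
#' @param betas Per-causal effect sizes (phenotype units per allele copy).
#' @param n_covariates Number of standard-normal covariates.
#' @param covariate_betas Covariate effect sizes (recycled to
#'   `n_covariates`; default 1).
#' @param noise_sd Residual standard deviation of the phenotype. Default 1.
#' @param seed Generator seed.
#' @return A `sim_spec`.
#' @export
sim_spec <- function(m, n, maf_range = c(0.05, 0.5), missing_rate = 0,
                     causal_idx = integer(0), betas = numeric(0),
                     n_covariates = 0L, covariate_betas = 1,
                     noise_sd = 1, seed = 1L) {
  stopifnot(m >= 1, n >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            noise_sd > 0, n_covariates >= 0)
  causal_idx <- as.integer(causal_idx)
  if (length(causal_idx) &&
      (any(causal_idx < 1) || any(causal_idx > m) || anyDuplicated(causal_idx))) {
    stop("causal_idx must be distinct indices in 1..m", call. = FALSE)
  }
  betas <- rep_len(as.numeric(betas), length(causal_idx))
  covariate_betas <- if (n_covariates > 0) {
    rep_len(as.numeric(covariate_betas), n_covariates)
  } else numeric(0)
  structure(list(m = as.integer(m), n = as.integer(n),
                 maf_range = as.numeric(maf_range),
                 missing_rate = missing_rate,
                 causal_idx = causal_idx, betas = betas,
                 n_covariates = as.integer(n_covariates),
                 covariate_betas = covariate_betas,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Effect size for a target per-variant R-squared
#'
#' For a Hardy-Weinberg variant with minor allele frequency `maf` (genotype
#' variance `2 maf (1 - maf)`), the allele-copy effect that explains a
#' fraction `r2` of the phenotype variance against residual noise
#' `noise_sd`.
#'
#' @param r2 Target proportion of variance explained, in (0, 1).
#' @param maf Minor allele frequency.
#' @param noise_sd Residual standard deviation.
#' @return Effect size in phenotype units per allele copy.
#' @export
beta_for_r2 <- function(r2, maf, noise_sd = 1) {
  stopifnot(r2 > 0, r2 < 1, maf > 0, maf < 1)
  noise_sd * sqrt(r2 / (1 - r2)) / sqrt(2 * maf * (1 - maf))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each variant draws its minor allele frequency uniformly from
#' `spec$maf_range`; genotypes are independent Binomial(2, MAF) allele
#' counts, masked missing independently at `spec$missing_rate`.
#' Reproducible from `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return A [genotype_matrix()] with the drawn MAFs in the `"maf"`
#'   attribute.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(.perm_seed(spec$seed, 1), function() {
    maf <- stats::runif(spec$m, spec$maf_range[1], spec$maf_range[2])
    codes <- matrix(stats::rbinom(spec$m * spec$n, 2L, rep(maf, spec$n)),
                    nrow = spec$m, ncol = spec$n)
    if (spec$missing_rate > 0) {
      codes[stats::runif(length(codes)) < spec$missing_rate] <- NA_integer_
    }
    g <- genotype_matrix(codes,
                         snp_ids = sprintf("snp_%d", seq_len(spec$m)),
                         sample_ids = sprintf("ind_%d", seq_len(spec$n)))
    attr(g, "maf") <- maf
    g
  })
}

#' Simulate a phenotype with planted effects
#'
#' `b_raw = sum_causal beta_j * dosage_j + Z %*% covariate_betas + noise`,
#' where causal dosages are mean-imputed (missing entries replaced by the
#' variant mean) so the planted R-squared stays well-defined under
#' missingness, covariates `Z` are standard normal, and noise is Gaussian
#' with `spec$noise_sd`.
#'
#' @param geno A [genotype_matrix()] from [simulate_genotypes()].
#' @param spec The same [sim_spec()].
#' @return A list with `b_raw`, `covariates` (n x c matrix or `NULL`) and a
#'   `truth` tibble (causal index, beta, MAF).
#' @export
simulate_phenotype <- function(geno, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  codes <- .codes_of(geno)
  stopifnot(nrow(codes) == spec$m, ncol(codes) == spec$n)
  .with_seed(.perm_seed(spec$seed, 2), function() {
    b <- stats::rnorm(spec$n, 0, spec$noise_sd)
    for (i in seq_along(spec$causal_idx)) {
      a <- codes[spec$causal_idx[i], ]
      mu <- mean(a, na.rm = TRUE)
      dos <- ifelse(is.na(a), mu, a)
      b <- b + spec$betas[i] * dos
    }
    Z <- NULL
    if (spec$n_covariates > 0) {
      Z <- matrix(stats::rnorm(spec$n * spec$n_covariates), nrow = spec$n)
      colnames(Z) <- paste0("covar", seq_len(spec$n_covariates))
      b <- b + drop(Z %*% spec$covariate_betas)
    }
    maf <- attr(geno, "maf")
    truth <- tibble::tibble(
      causal_idx = spec$causal_idx,
      snp_id = rownames(codes)[spec$causal_idx],
      beta = spec$betas,
      maf = if (!is.null(maf)) maf[spec$causal_idx] else NA_real_)
    list(b_raw = b, covariates = Z, truth = truth)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Generates genotypes and phenotype from `spec` and writes the PLINK trio
#' (phenotype in the `.fam` file), an optional PLINK-dialect covariate file,
#' and a commented ground-truth TSV (causal indices, betas, MAFs, seed).
#'
#' @param spec A [sim_spec()].
#' @param prefix Output path prefix.
#' @return Invisibly, a list with the generated data and file paths.
#' @export
make_fixture <- function(spec, prefix) {
  geno <- simulate_genotypes(spec)
  ph <- simulate_phenotype(geno, spec)
  n <- spec$n
  sid <- colnames(geno$codes)
  samples <- tibble::tibble(fid = sid, iid = sid, pid = "0", mid = "0",
                            sex = 0L, phenotype = ph$b_raw)
  variants <- tibble::tibble(chrom = "1", snp_id = rownames(geno$codes),
                             cm = 0, pos = seq_len(spec$m),
                             allele1 = "A", allele2 = "B")
  paths <- write_plink(geno, prefix, variants = variants, samples = samples)
  covar_path <- NULL
  if (!is.null(ph$covariates)) {
    covar_path <- paste0(prefix, ".covar")
    utils::write.table(
      data.frame(FID = sid, IID = sid, ph$covariates, check.names = FALSE),
      covar_path, quote = FALSE, row.names = FALSE, sep = " ")
  }
  truth_path <- paste0(prefix, ".truth.tsv")
  con <- file(truth_path, "wt")
  writeLines(c(sprintf("# seed: %d", spec$seed),
               sprintf("# m: %d", spec$m),
               sprintf("# n: %d", spec$n),
               sprintf("# missing_rate: %s", format(spec$missing_rate)),
               sprintf("# noise_sd: %s", format(spec$noise_sd))), con)
  close(con)
  suppressWarnings(utils::write.table(
    as.data.frame(ph$truth), truth_path, append = TRUE, quote = FALSE,
    row.names = FALSE, sep = "\t"))
  invisible(list(genotypes = geno, b_raw = ph$b_raw,
                 covariates = ph$covariates, truth = ph$truth,
                 paths = c(paths, covar = covar_path, truth = truth_path)))
}
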