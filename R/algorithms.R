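# The two permutation-testing drivers.
#
# maxT: for each permutation the maximum F over all (non-degenerate)
# variants is recorded; the adjusted p-value of variant j ranks its observed
# F within that null distribution of maxima, which strongly controls the
# family-wise error rate. Pointwise (EMP1) p-values rank each variant's
# observed F within its own permuted statistics.
#
# Adaptive: every variant sees the same shared permutation stream;
# exceedances (F_perm >= F_obs, inclusive) are counted every permutation but
# variants are dropped only at checkpoints of a growing schedule, mirroring
# a buffer-regeneration design where removing variants is an expensive
# operation performed in batches.

# Shared per-run precomputation: summaries, kernel matrix, observed F.
.prep_run <- function(geno, pheno, fixed_point = NULL) {
  codes <- .codes_of(geno)
  stopifnot(inherits(pheno, "phenotype_set"))
  if (ncol(codes) != pheno$n) {
    stop("genotype sample count (", ncol(codes),
         ") does not match phenotype length (", pheno$n, ")", call. = FALSE)
  }
  sm <- snp_summaries(codes)
  n_sat <- 0L
  if (is.null(fixed_point)) {
    xc <- kernel_matrix(codes, means = ifelse(sm$n_obs > 0, sm$mean, 0))
    y <- pheno$y
    numer <- function(x_block, y_perm) dot_products(x_block, y_perm)
  } else {
    stopifnot(inherits(fixed_point, "fixed_point_format"))
    .check_fmt_for_n(fixed_point, ncol(codes))
    m_q <- quantize(ifelse(sm$n_obs > 0, sm$mean, 0), fixed_point)
    y_q <- quantize(pheno$y, fixed_point)
    n_sat <- m_q$n_saturated + y_q$n_saturated
    xc <- codes - dequantize(m_q)
    xc[is.na(xc)] <- 0
    storage.mode(xc) <- "double"
    y <- dequantize(y_q)   # permuting the dequantized vector == permuting
    numer <- function(x_block, y_perm) as.vector(x_block %*% y_perm)
  }
  obs <- f_from_numerator(numer(xc, y), sm$ss_x, pheno$ss_y, sm$n_obs)
  list(codes = codes, sm = sm, xc = xc, y = y, numer = numer,
       f_obs = obs$f, rho_obs = obs$rho, degenerate = sm$degenerate,
       n_saturated = n_sat)
}

#' maxT permutation testing
#'
#' Computes observed F statistics for every variant, then for each of
#' `n_perm` phenotype permutations recomputes all F values through the
#' permutation kernel (constant denominators, numerator-only updates) and
#' records the maximum over non-degenerate variants. Adjusted p-values
#' (`emp2`) rank each observed F within the null maxima; pointwise p-values
#' (`emp1`) rank it within the variant's own permuted statistics. Both use
#' the inclusive convention (a permuted statistic that ties the observed one
#' counts as an exceedance) and `p = (x+1)/(n_perm+1)`.
#'
#' Degenerate variants (all-missing or monomorphic) report `emp1 = emp2 = 1`
#' with a flag and never contribute to the null maxima.
#'
#' @param geno Genotypes ([genotype_matrix()], `plink_data` or codes matrix).
#' @param pheno A `phenotype_set` from [adjust_phenotype()].
#' @param n_perm Number of permutations (1000 is typically sufficient for
#'   family-wise control at 0.05, independent of the number of variants).
#' @param seed Master seed for the permutation stream.
#' @param fixed_point Optional [fixed_point_format()] to run the kernel in
#'   emulated fixed point; `NULL` (default) uses floating point.
#' @param perms Optional explicit permutation matrix (rows = permutations of
#'   `1..n`) replacing the seeded stream, e.g. an exhaustive enumeration.
#' @return A `maxt_result`; see [tidy.maxt_result()].
#' @export
run_maxt <- function(geno, pheno, n_perm = 1000, seed = 1,
                     fixed_point = NULL, perms = NULL) {
  t0 <- proc.time()[["elapsed"]]
  pr <- .prep_run(geno, pheno, fixed_point)
  if (!is.null(perms)) {
    perms <- as.matrix(perms)
    stopifnot(ncol(perms) == pheno$n)
    n_perm <- nrow(perms)
    plan <- NULL
  } else {
    plan <- permutation_plan(seed, n_perm, pheno$n)
  }
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (all(pr$degenerate)) {
    stop("no testable variant: all variants are degenerate", call. = FALSE)
  }

  m <- nrow(pr$xc)
  live <- !pr$degenerate
  x_point <- numeric(m)       # pointwise exceedance counts
  null_max <- numeric(n_perm)
  ss_x <- pr$sm$ss_x
  n_obs <- pr$sm$n_obs
  ss_y <- pheno$ss_y
  for (k in seq_len(n_perm)) {
    p_k <- if (is.null(plan)) perms[k, ] else perm_at(plan, k)
    fp <- .f_vec(pr$numer(pr$xc, pr$y[p_k]), ss_x, ss_y, n_obs)
    x_point <- x_point + (fp >= pr$f_obs)
    null_max[k] <- max(fp[live])
  }
  x_adj <- vapply(pr$f_obs, function(f) sum(null_max >= f), numeric(1))
  emp1 <- perm_pvalue(x_point, n_perm)
  emp2 <- perm_pvalue(x_adj, n_perm)
  emp1[pr$degenerate] <- 1
  emp2[pr$degenerate] <- 1

  structure(list(
    result = tibble::tibble(
      snp_id = pr$sm$snp_id,
      f_obs = pr$f_obs,
      p_asym = ifelse(pr$degenerate, NA_real_,
                      stats::pf(pr$f_obs, 1, pmax(n_obs - 2, 1),
                                lower.tail = FALSE)),
      emp1 = emp1, emp2 = emp2,
      n_obs = n_obs, degenerate = pr$degenerate),
    null_maxima = null_max,
    plan = plan,
    n_perm = n_perm, seed = if (is.null(plan)) NA_integer_ else plan$seed,
    rng_id = if (is.null(plan)) "explicit-permutations" else plan$rng_id,
    fixed_point = fixed_point, n_saturated = pr$n_saturated,
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "maxt_result")
}

#' @export
print.maxt_result <- function(x, ...) {
  cat(sprintf(
    "<maxt_result> %d variant(s), %d permutation(s)%s\n",
    nrow(x$result), x$n_perm,
    if (is.null(x$fixed_point)) "" else " [fixed-point kernel]"))
  cat(sprintf("  min emp2 = %.6g (floor %.6g)\n",
              min(x$result$emp2), 1 / (x$n_perm + 1)))
  invisible(x)
}

#' Adaptive permutation configuration
#'
#' @param R Exceedance limit: a variant is dropped once `R` permuted
#'   statistics have tied or exceeded its observed one (evaluated at
#'   checkpoints). Default 10, following the adaptive-permutation
#'   literature; the choice is surfaced in all output metadata.
#' @param b_max Maximum permutations per variant.
#' @param mps Minimum permutations per variant: the first checkpoint, and
#'   the initial dropping interval. Default 121.
#' @param growth Dropping-interval growth factor; the interval is multiplied
#'   by this every `drops_per_growth` checkpoints. Default 1.2.
#' @param drops_per_growth Checkpoints between interval growths. Default 5.
#' @return An `adaptive_config`.
#' @export
adaptive_config <- function(R = 10L, b_max, mps = 121L, growth = 1.2,
                            drops_per_growth = 5L) {
  stopifnot(length(R) == 1, R >= 1, length(b_max) == 1, b_max >= 1,
            length(mps) == 1, mps >= 1,
            growth > 1, drops_per_growth >= 1)
  if (mps > b_max) {
    stop("mps (minimum permutations per variant, ", mps,
         ") exceeds b_max (", b_max, ")", call. = FALSE)
  }
  structure(list(R = as.integer(R), b_max = as.double(b_max),
                 mps = as.double(mps), growth = growth,
                 drops_per_growth = as.integer(drops_per_growth)),
            class = "adaptive_config")
}

#' Checkpoint schedule for adaptive dropping
#'
#' The dropping interval starts at `mps` and is multiplied by `growth` after
#' every `drops_per_growth` checkpoints (default: increases by 20% every 5
#' drops). Checkpoint positions are the rounded-up running sums of the
#' real-valued interval, strictly increasing and capped so the final
#' checkpoint equals `b_max`.
#'
#' @param cfg An [adaptive_config()].
#' @return Increasing numeric vector of checkpoint permutation counts, the
#'   last equal to `b_max`.
#' @examples
#' head(dropping_schedule(adaptive_config(b_max = 1e6, mps = 121)), 6)
#' # 121 242 363 484 605 751
#' @export
dropping_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "adaptive_config"))
  cps <- numeric(0)
  cum <- 0
  interval <- cfg$mps
  k <- 0L
  repeat {
    cum <- cum + interval
    k <- k + 1L
    cp <- ceiling(cum)
    if (cp >= cfg$b_max) {
      cps <- c(cps, cfg$b_max)
      break
    }
    if (!length(cps) || cp > cps[length(cps)]) cps <- c(cps, cp)
    if (k %% cfg$drops_per_growth == 0L) interval <- interval * cfg$growth
  }
  cps
}

#' Adaptive permutation testing
#'
#' All variants start active and share one permutation stream. At each
#' permutation, every active variant's exceedance count `x_j` is incremented
#' when its permuted F ties or exceeds the observed F. At each checkpoint of
#' [dropping_schedule()], active variants with `x_j >= R` are dropped with
#' `B` = the checkpoint's permutation count and `p = (min(x, R)+1)/(B+1)`;
#' the kernel matrix is regenerated to the surviving variants. Variants
#' surviving all `b_max` permutations report `p = (x+1)/(b_max+1)`.
#'
#' With `strict = TRUE` a variant is instead dropped immediately at the
#' permutation where `x` reaches `R` (exact early stopping, for comparison
#' with the checkpointed design).
#'
#' @inheritParams run_maxt
#' @param cfg An [adaptive_config()].
#' @param strict Drop at the exact permutation `x` reaches `R` instead of at
#'   checkpoint granularity.
#' @return An `adaptive_result`; see [tidy.adaptive_result()].
#' @export
run_adaptive <- function(geno, pheno, cfg, seed = 1, fixed_point = NULL,
                         strict = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(inherits(cfg, "adaptive_config"))
  pr <- .prep_run(geno, pheno, fixed_point)
  if (all(pr$degenerate)) {
    stop("no testable variant: all variants are degenerate", call. = FALSE)
  }
  m <- nrow(pr$xc)
  b_max <- cfg$b_max
  plan <- permutation_plan(seed, b_max, pheno$n)
  schedule <- dropping_schedule(cfg)

  x <- numeric(m)
  B <- rep(NA_real_, m)
  dropped_at <- rep(NA_integer_, m)     # checkpoint index (1-based)
  active <- which(!pr$degenerate)
  xc_act <- pr$xc[active, , drop = FALSE]
  f_act <- pr$f_obs[active]
  ssx_act <- pr$sm$ss_x[active]
  nobs_act <- pr$sm$n_obs[active]
  ss_y <- pheno$ss_y
  next_cp <- 1L

  for (k in seq_len(b_max)) {
    if (!length(active)) break
    fp <- .f_vec(pr$numer(xc_act, pr$y[perm_at(plan, k)]),
                 ssx_act, ss_y, nobs_act)
    x[active] <- x[active] + (fp >= f_act)
    drop_now <- FALSE
    if (strict) {
      drop_now <- any(x[active] >= cfg$R)
      cp_idx <- NA_integer_
    } else if (next_cp <= length(schedule) && k == schedule[next_cp]) {
      drop_now <- TRUE
      cp_idx <- next_cp
      next_cp <- next_cp + 1L
    }
    if (drop_now) {
      hit <- x[active] >= cfg$R
      if (any(hit)) {
        gone <- active[hit]
        B[gone] <- k
        dropped_at[gone] <- if (strict) {
          # first checkpoint at or after k, for reporting only
          match(TRUE, schedule >= k)
        } else cp_idx
        keep <- !hit
        active <- active[keep]
        # buffer regeneration: rebuild the kernel matrix on survivors
        xc_act <- xc_act[keep, , drop = FALSE]
        f_act <- f_act[keep]
        ssx_act <- ssx_act[keep]
        nobs_act <- nobs_act[keep]
      }
    }
  }

  dropped <- !is.na(B) & B < b_max
  B[is.na(B)] <- b_max
  B[!dropped] <- b_max
  dropped_at[!dropped] <- NA_integer_
  # a variant that reaches the limit only at the final checkpoint ran all
  # b_max permutations; Eq.-3 branches coincide there once x is capped at R
  x_rep <- pmin(x, cfg$R)
  pvals <- adaptive_pvalue(x_rep, cfg$R, B, b_max)
  pvals[pr$degenerate] <- 1
  x_rep[pr$degenerate] <- NA_real_

  structure(list(
    result = tibble::tibble(
      snp_id = pr$sm$snp_id,
      f_obs = pr$f_obs,
      x = x_rep, B = B, dropped = dropped & !pr$degenerate,
      dropped_at = dropped_at,
      emp_p = pvals,
      n_obs = pr$sm$n_obs, degenerate = pr$degenerate),
    schedule = schedule, config = cfg, plan = plan,
    seed = plan$seed, rng_id = plan$rng_id, strict = strict,
    fixed_point = fixed_point, n_saturated = pr$n_saturated,
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "adaptive_result")
}

#' @export
print.adaptive_result <- function(x, ...) {
  cat(sprintf(
    "<adaptive_result> %d variant(s), R = %d, b_max = %s%s\n",
    nrow(x$result), x$config$R, format(x$config$b_max, big.mark = ","),
    if (x$strict) " [strict dropping]" else ""))
  cat(sprintf("  %d dropped early, %d ran to completion\n",
              sum(x$result$dropped),
              sum(!x$result$dropped & !x$result$degenerate)))
  invisible(x)
}
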