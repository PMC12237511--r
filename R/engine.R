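# The permutation engine: reproducible permutation streams, genotype-block
# planning, and the blocked dot-product kernels (floating-point reference
# path and emulated fixed-point path).
#
# The kernel computes, per variant j, the numerator of Pearson's rho:
#   num_j = sum over non-missing i of (a_ji - abar_j) * y_perm[i].
# Missing genotypes are mean-imputed, i.e. contribute exactly 0 after
# centering, so the centered matrix is built once (with zeros at missing
# entries) and each permutation is a single matrix-vector product.

.RNG_ID <- "mt19937-rejection/counter-lcg-v1"

#' Plan a reproducible permutation stream
#'
#' Defines a deterministic sequence of `n_perm` index permutations of
#' `1..n`. The k-th permutation is retrievable in O(1) with
#' [perm_at()]: each permutation draws its own RNG substream from a
#' counter-derived seed, so the maxT and adaptive drivers (and any external
#' oracle) can replay the identical stream. The generator identity is
#' recorded in result metadata.
#'
#' @param seed Integer master seed.
#' @param n_perm Number of permutations (>= 0).
#' @param n Number of samples (>= 2).
#' @return A `permutation_plan`.
#' @export
permutation_plan <- function(seed, n_perm, n) {
  stopifnot(length(seed) == 1, is.finite(seed),
            length(n_perm) == 1, n_perm >= 0)
  if (n < 2) stop("need at least 2 samples to permute", call. = FALSE)
  structure(list(seed = as.integer(seed) %% 2147483647L,
                 n_perm = as.integer(n_perm), n = as.integer(n),
                 rng_id = .RNG_ID),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat(sprintf("<permutation_plan> seed %d, %d permutation(s) of n = %d [%s]\n",
              x$seed, x$n_perm, x$n, x$rng_id))
  invisible(x)
}

# Counter-derived per-permutation seed. All intermediates stay below 2^53 so
# double arithmetic is exact; results stay below 2^31.
.perm_seed <- function(seed, k) {
  s <- (as.double(seed) * 48271) %% 2147483647
  s <- (s + as.double(k) * 16807) %% 2147483647
  as.integer((s * 69621) %% 2147483647)
}

# Run fn() under a seeded RNG without disturbing the caller's RNG state.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  fn()
}

#' Retrieve the k-th permutation of a plan
#'
#' @param plan A [permutation_plan()].
#' @param k Permutation index in `1..n_perm`.
#' @return An integer permutation of `1..n`.
#' @export
perm_at <- function(plan, k) {
  stopifnot(inherits(plan, "permutation_plan"), k >= 1, k <= plan$n_perm)
  .with_seed(.perm_seed(plan$seed, k), function() sample.int(plan$n))
}

#' Materialize a permutation stream
#'
#' @param plan A [permutation_plan()].
#' @return An `n_perm` x `n` integer matrix; row k is the k-th permutation.
#' @export
permutation_stream <- function(plan) {
  stopifnot(inherits(plan, "permutation_plan"))
  out <- matrix(NA_integer_, nrow = plan$n_perm, ncol = plan$n)
  for (k in seq_len(plan$n_perm)) out[k, ] <- perm_at(plan, k)
  out
}

#' Plan genotype-data blocking
#'
#' Splits the m variant records across kernel invocations given a genotype
#' buffer capacity. A variant record occupies `ceiling(n/4)` bytes of 2-bit
#' codes, rounded up to a 64-byte multiple (the kernel consumes 512-bit
#' blocks, i.e. 256 genotype values, per cycle); the number of variants per
#' block is `floor(buffer_bytes / snp_block_bytes)` and the number of blocks
#' is `ceiling(n_snps / n_snps_per_block)`. Blocking never changes results —
#' numerators are identical (bitwise) for any buffer size.
#'
#' @param n_snps Number of variants.
#' @param n_samples Number of samples.
#' @param buffer_bytes Genotype buffer capacity in bytes (default 2^26).
#' @return A `block_plan` with `n_snps_per_block`, `n_blocks`,
#'   `snp_block_bytes`, `buffer_bytes` and the block row ranges.
#' @export
block_plan <- function(n_snps, n_samples, buffer_bytes = 2^26) {
  stopifnot(n_snps >= 1, n_samples >= 1)
  snp_block_bytes <- 64 * ceiling(ceiling(n_samples / 4) / 64)
  n_per <- floor(buffer_bytes / snp_block_bytes)
  if (n_per < 1) {
    stop(sprintf(
      "buffer of %d bytes cannot hold one variant record of %d bytes",
      buffer_bytes, snp_block_bytes), call. = FALSE)
  }
  n_blocks <- as.integer(ceiling(n_snps / n_per))
  starts <- seq(1L, n_snps, by = n_per)
  structure(list(n_snps = as.integer(n_snps),
                 n_snps_per_block = as.integer(n_per),
                 n_blocks = n_blocks,
                 snp_block_bytes = as.integer(snp_block_bytes),
                 buffer_bytes = buffer_bytes,
                 block_start = as.integer(starts),
                 block_end = as.integer(pmin(starts + n_per - 1L, n_snps))),
            class = "block_plan")
}

#' @export
print.block_plan <- function(x, ...) {
  cat(sprintf(
    "<block_plan> %d variant(s) in %d block(s) of <= %d (record %d B, buffer %s B)\n",
    x$n_snps, x$n_blocks, x$n_snps_per_block, x$snp_block_bytes,
    format(x$buffer_bytes, big.mark = ",")))
  invisible(x)
}

#' Build the centered kernel matrix
#'
#' Centers each variant row by its non-missing mean and writes exact zeros at
#' missing entries (mean imputation), so the kernel numerator is a plain
#' matrix-vector product.
#'
#' @param geno Genotypes (any accepted form).
#' @param means Optional precomputed per-variant means (computed once; they
#'   do not change across permutations).
#' @return A double m x n matrix.
#' @export
kernel_matrix <- function(geno, means = NULL) {
  codes <- .codes_of(geno)
  if (is.null(means)) {
    obs <- !is.na(codes)
    means <- rowSums(codes, na.rm = TRUE) / pmax(rowSums(obs), 1)
  }
  xc <- codes - means
  xc[is.na(xc)] <- 0
  storage.mode(xc) <- "double"
  xc
}

#' Kernel numerators for one permuted phenotype
#'
#' `num_j = sum over non-missing i of (a_ji - abar_j) * y_perm[i]` for every
#' variant row of the centered block.
#'
#' @param xc Centered kernel matrix (a block of [kernel_matrix()] rows).
#' @param y_perm Permuted adjusted phenotype, length `ncol(xc)`.
#' @return Numeric vector of numerators, one per variant row.
#' @export
dot_products <- function(xc, y_perm) {
  if (ncol(xc) != length(y_perm)) {
    stop("phenotype length does not match the number of samples",
         call. = FALSE)
  }
  as.vector(xc %*% y_perm)
}

#' Blocked kernel numerators
#'
#' Runs the kernel block by block according to a [block_plan()] and
#' concatenates. Each variant row is accumulated independently in a fixed
#' left-to-right order, so the result is bitwise identical for every block
#' partition (optimized BLAS matrix products are not: their accumulation
#' order depends on the number of rows). Agrees with [dot_products()] to
#' floating-point rounding.
#'
#' @param xc Centered kernel matrix.
#' @param y_perm Permuted adjusted phenotype.
#' @param plan A [block_plan()] for `nrow(xc)` variants.
#' @return Numeric vector of numerators.
#' @export
dot_products_blocked <- function(xc, y_perm, plan) {
  stopifnot(inherits(plan, "block_plan"), plan$n_snps == nrow(xc),
            ncol(xc) == length(y_perm))
  out <- numeric(nrow(xc))
  for (b in seq_len(plan$n_blocks)) {
    idx <- seq(plan$block_start[b], plan$block_end[b])
    blk <- xc[idx, , drop = FALSE]
    out[idx] <- vapply(seq_along(idx),
                       function(j) sum(blk[j, ] * y_perm), numeric(1))
  }
  out
}

#' Fixed-point number format
#'
#' Signed fixed-point format with `total_bits` total width, `frac_bits`
#' fractional bits, and a wide accumulator. The accumulator invariant
#' `accumulator_bits >= total_bits + ceiling(log2(n)) + 2` guarantees the
#' dot-product accumulation cannot overflow; it is checked against the
#' actual sample count when a kernel runs. The default (32/16/64) keeps that
#' guarantee for up to 262 144 samples, the phenotype-buffer bound the
#' hardware-style design documents.
#'
#' @param total_bits Total word width (<= 64).
#' @param frac_bits Fractional bits (0 < frac_bits < total_bits).
#' @param accumulator_bits Accumulator width.
#' @return A `fixed_point_format`.
#' @export
fixed_point_format <- function(total_bits = 32L, frac_bits = 16L,
                               accumulator_bits = 64L) {
  stopifnot(frac_bits > 0, frac_bits < total_bits, total_bits <= 64,
            accumulator_bits >= total_bits)
  structure(list(total_bits = as.integer(total_bits),
                 frac_bits = as.integer(frac_bits),
                 accumulator_bits = as.integer(accumulator_bits)),
            class = "fixed_point_format")
}

#' @export
print.fixed_point_format <- function(x, ...) {
  cat(sprintf("<fixed_point_format> Q%d.%d, %d-bit accumulator\n",
              x$total_bits - x$frac_bits, x$frac_bits, x$accumulator_bits))
  invisible(x)
}

.check_fmt_for_n <- function(fmt, n) {
  need <- fmt$total_bits + ceiling(log2(max(n, 2))) + 2
  if (fmt$accumulator_bits < need) {
    stop(sprintf(
      "accumulator too narrow: %d bits < %d required for n = %d samples",
      fmt$accumulator_bits, need, n), call. = FALSE)
  }
  invisible(fmt)
}

#' Quantize to fixed point
#'
#' Round-to-nearest-even of `v * 2^frac_bits`, stored as a signed integer
#' mantissa. Values outside the representable range saturate; the saturation
#' count is attached as the `"n_saturated"` attribute and a warning is
#' raised (the drivers surface the count in result metadata).
#'
#' @param v Numeric vector.
#' @param fmt A [fixed_point_format()].
#' @return A `fixed_point` object holding `mantissa` (double-stored
#'   integers) and `fmt`.
#' @examples
#' dequantize(quantize(0.3, fixed_point_format(frac_bits = 2, total_bits = 8)))
#' @export
quantize <- function(v, fmt = fixed_point_format()) {
  stopifnot(inherits(fmt, "fixed_point_format"))
  scale <- 2^fmt$frac_bits
  mant <- round(v * scale)              # round() is round-half-to-even
  lim <- 2^(fmt$total_bits - 1) - 1
  sat <- abs(mant) > lim
  if (any(sat)) {
    warning(sum(sat), " value(s) saturated the ", fmt$total_bits,
            "-bit fixed-point range", call. = FALSE)
    mant <- pmin(pmax(mant, -lim), lim)
  }
  structure(list(mantissa = mant, fmt = fmt, n_saturated = sum(sat)),
            class = "fixed_point")
}

#' Dequantize a fixed-point value
#'
#' @param q A `fixed_point` object from [quantize()].
#' @return Numeric vector `mantissa / 2^frac_bits`.
#' @export
dequantize <- function(q) {
  stopifnot(inherits(q, "fixed_point"))
  q$mantissa / 2^q$fmt$frac_bits
}

#' Kernel numerators in emulated fixed point
#'
#' Emulates the hardware multiply-accumulate: the per-variant mean and the
#' phenotype are quantized to `fmt`, genotype codes (exact small integers)
#' are centered by the quantized mean, and products are accumulated in the
#' wide accumulator, then dequantized. Every intermediate is an exact
#' multiple of `2^(-2*frac_bits)` within double precision, so the emulation
#' is bit-faithful to integer arithmetic. The result deviates from the
#' floating-point numerator by at most `n * 2^(-frac_bits) * max(2, max|y|)`.
#'
#' @param codes Genotype codes block (matrix, rows = variants).
#' @param means Per-variant non-missing means (un-quantized; quantized
#'   internally).
#' @param y_q Quantized phenotype (a `fixed_point` from [quantize()]) or a
#'   numeric vector to be quantized with `fmt`.
#' @param fmt A [fixed_point_format()].
#' @return Numeric vector of dequantized numerators with attribute
#'   `"n_saturated"`.
#' @export
dot_products_fixed <- function(codes, means, y_q, fmt = fixed_point_format()) {
  codes <- .codes_of(codes)
  n <- ncol(codes)
  .check_fmt_for_n(fmt, n)
  n_sat <- 0L
  if (!inherits(y_q, "fixed_point")) {
    y_q <- quantize(y_q, fmt)
  } else {
    stopifnot(identical(y_q$fmt, fmt))
  }
  n_sat <- n_sat + y_q$n_saturated
  m_q <- quantize(means, fmt)
  n_sat <- n_sat + m_q$n_saturated
  # centered codes in fixed point: a - deq(mean_q) is an exact multiple of
  # 2^-frac; times deq(y_q) gives exact multiples of 2^-2frac -> the double
  # accumulation below is exact integer arithmetic in disguise
  xc_q <- codes - dequantize(m_q)
  xc_q[is.na(xc_q)] <- 0
  storage.mode(xc_q) <- "double"
  yv <- dequantize(y_q)
  acc <- as.vector(xc_q %*% yv)
  # overflow guard on the accumulator mantissa
  lim <- 2^(fmt$accumulator_bits - 1) - 1
  if (any(abs(acc) * 2^(2 * fmt$frac_bits) > lim)) {
    stop("fixed-point accumulator overflow; widen accumulator_bits",
         call. = FALSE)
  }
  structure(acc, n_saturated = n_sat)
}
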