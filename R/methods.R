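# broom-style accessors and ggplot2 methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Tidy a maxT result
#'
#' @param x A `maxt_result` from [run_maxt()].
#' @param ... Unused.
#' @return A tibble with one row per variant: `snp_id`, `f_obs` (observed F),
#'   `p_asym` (asymptotic F-test p), `emp1` (pointwise permutation p),
#'   `emp2` (maxT family-wise adjusted p), `n_obs`, `degenerate`.
#' @method tidy maxt_result
#' @export
tidy.maxt_result <- function(x, ...) x$result

#' @rdname tidy.maxt_result
#' @method tidy adaptive_result
#' @export
tidy.adaptive_result <- function(x, ...) x$result

#' Glance at a maxT result
#'
#' @param x A `maxt_result` or `adaptive_result`.
#' @param ... Unused.
#' @return A one-row tibble of run-level metadata.
#' @method glance maxt_result
#' @export
glance.maxt_result <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x$result),
    n_perm = x$n_perm,
    n_degenerate = sum(x$result$degenerate),
    min_emp2 = min(x$result$emp2),
    p_floor = 1 / (x$n_perm + 1),
    seed = x$seed,
    rng_id = x$rng_id,
    fixed_point = !is.null(x$fixed_point),
    n_saturated = x$n_saturated,
    elapsed = x$elapsed)
}

#' @rdname glance.maxt_result
#' @method glance adaptive_result
#' @export
glance.adaptive_result <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x$result),
    R = x$config$R,
    b_max = x$config$b_max,
    mps = x$config$mps,
    n_dropped = sum(x$result$dropped),
    n_checkpoints = length(x$schedule),
    min_p = min(x$result$emp_p),
    seed = x$seed,
    rng_id = x$rng_id,
    strict = x$strict,
    fixed_point = !is.null(x$fixed_point),
    n_saturated = x$n_saturated,
    elapsed = x$elapsed)
}

#' Plot a maxT result
#'
#' `type = "null"` draws the null distribution of per-permutation maximum F
#' values with the observed statistics as a rug; `type = "pvalues"` draws
#' per-variant `-log10` adjusted p-values in variant order.
#'
#' @param object A `maxt_result`.
#' @param type `"null"` or `"pvalues"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot maxt_result
#' @export
autoplot.maxt_result <- function(object, type = c("null", "pvalues"), ...) {
  type <- match.arg(type)
  td <- object$result[!object$result$degenerate, ]
  if (type == "null") {
    ggplot2::ggplot(tibble::tibble(max_f = object$null_maxima),
                    ggplot2::aes(x = .data$max_f)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
      ggplot2::geom_rug(data = td, ggplot2::aes(x = .data$f_obs),
                        colour = "firebrick", inherit.aes = FALSE) +
      ggplot2::labs(x = "per-permutation maximum F",
                    y = "permutations",
                    title = "maxT null distribution",
                    subtitle = "rug: observed per-variant F") +
      ggplot2::theme_minimal()
  } else {
    td$order <- seq_len(nrow(td))
    ggplot2::ggplot(td, ggplot2::aes(x = .data$order,
                                     y = -log10(.data$emp2))) +
      ggplot2::geom_point(size = 0.8, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
      ggplot2::labs(x = "variant", y = expression(-log[10] * "(emp2)"),
                    title = "maxT family-wise adjusted p-values") +
      ggplot2::theme_minimal()
  }
}

#' Plot an adaptive result
#'
#' Permutations performed per variant (log scale) against observed F,
#' coloured by drop status, with the checkpoint schedule as horizontal
#' guides.
#'
#' @param object An `adaptive_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adaptive_result
#' @export
autoplot.adaptive_result <- function(object, ...) {
  td <- object$result[!object$result$degenerate, ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$f_obs, y = .data$B,
                                   colour = .data$dropped)) +
    ggplot2::geom_hline(yintercept = object$schedule,
                        colour = "grey85", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey40",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "observed F", y = "permutations performed (B)",
                  colour = "dropped early",
                  title = "adaptive permutation effort per variant",
                  subtitle = "horizontal guides: checkpoint schedule") +
    ggplot2::theme_minimal()
}
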