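#' Fit an empirical CDF mapping for quantile transformation
#'
#' Builds the rank-based mapping that places a set of reference values on
#' the equal-likelihood (0, 1) scale. Each reference value is assigned its
#' plotting position; tied values receive averaged ranks, so ties always
#' map to the same transformed value.
#'
#' Plotting positions:
#' * `"midrank"` (default): u = (r - 0.5) / N — symmetric, never reaches 0
#'   or 1;
#' * `"weibull"`: u = r / (N + 1).
#'
#' @param values Finite numeric reference values (at least one).
#' @param rank_convention `"midrank"` or `"weibull"`.
#' @return An object of class `eq_ecdf` usable with [predict()]: a list
#'   with the sorted unique reference values `x`, their plotting positions
#'   `u`, the convention and the reference size `n`.
#' @details The mapping is idempotent on its reference values: predicting
#'   at a reference value returns that value's plotting position exactly.
#'   New values between reference points are interpolated linearly; values
#'   outside the reference range are clamped to the extreme plotting
#'   positions, so every output stays strictly inside (0, 1).
#' @export
#' @examples
#' f <- fit_ecdf(c(1, 2, 3, 4))
#' predict(f, c(1, 2, 3, 4)) # 0.125 0.375 0.625 0.875
fit_ecdf <- function(values, rank_convention = c("midrank", "weibull")) {
  rank_convention <- arg_match(rank_convention)
  if (length(values) == 0) {
    abort_eq("Cannot fit an ECDF on an empty set of values.",
             "exoquality_validation_error")
  }
  if (any(!is.finite(values))) {
    abort_eq("All reference values must be finite.",
             "exoquality_validation_error")
  }
  u_all <- plotting_positions(values, rank_convention)
  ord <- order(values)
  x_sorted <- values[ord]
  u_sorted <- u_all[ord]
  keep <- !duplicated(x_sorted)
  structure(
    list(x = x_sorted[keep], u = u_sorted[keep],
         rank_convention = rank_convention, n = length(values)),
    class = "eq_ecdf"
  )
}

plotting_positions <- function(values, rank_convention) {
  r <- rank(values, ties.method = "average")
  n <- length(values)
  switch(rank_convention,
         midrank = (r - 0.5) / n,
         weibull = r / (n + 1))
}

#' @describeIn fit_ecdf Evaluate the fitted mapping at new values;
#'   reference values reproduce their plotting positions, others are
#'   interpolated and clamped into the open unit interval.
#' @param object A fitted `eq_ecdf` mapping.
#' @param newdata Numeric values at which to evaluate the mapping.
#' @param ... Unused.
#' @export
predict.eq_ecdf <- function(object, newdata, ...) {
  if (any(!is.finite(newdata))) {
    abort_eq("Cannot transform non-finite values.",
             "exoquality_validation_error")
  }
  if (length(object$x) == 1L) {
    return(rep(object$u, length(newdata)))
  }
  approx(object$x, object$u, xout = newdata, rule = 2)$y
}

#' @export
print.eq_ecdf <- function(x, ...) {
  cat(sprintf("<eq_ecdf> %s plotting positions on %d reference values (%d unique)\n",
              x$rank_convention, x$n, length(x$x)))
  invisible(x)
}

#' Quantile-transform a measurement table
#'
#' Applies the probabilistic rescaling that makes assays with different
#' units directly comparable: within each assay, every raw value is
#' replaced by its plotting position under the assay's own empirical CDF,
#' yielding values in the open interval (0, 1) whose distribution is as
#' close to uniform as ties permit. Because the mapping depends on ranks
#' only, any strictly increasing change of an assay's measurement scale
#' leaves the transformed values — and everything computed from them —
#' unchanged.
#'
#' @param data A valid measurement table (see [validate_measurements()]).
#' @param scope Which records share one ECDF per assay: `"all"` (default;
#'   all methods, samples and replicates pooled, enabling cross-method
#'   comparison), `"per_group"` or `"per_method"` (sensitivity analyses).
#' @param rank_convention Plotting position convention, see [fit_ecdf()].
#'
#' @return The input tibble with an added `transformed` column, of class
#'   `eq_transformed`. Attributes `scope`, `rank_convention` and
#'   `provenance` (per pooling unit: the fitted [fit_ecdf()] mapping)
#'   record how to reproduce or invert the transformation; the raw
#'   `value` column is kept.
#' @export
#' @examples
#' d <- simulate_study(sim_config(n_samples = 3, seed = 1))
#' transform_quantile(d)
transform_quantile <- function(data,
                               scope = c("all", "per_group", "per_method"),
                               rank_convention = c("midrank", "weibull")) {
  scope <- arg_match(scope, error_call = current_env())
  rank_convention <- arg_match(rank_convention)
  data <- validate_measurements(data)
  pool_vars <- switch(scope,
                      all = "assay",
                      per_group = c("assay", "group"),
                      per_method = c("assay", "method"))
  out <- data %>%
    group_by(across(all_of(pool_vars))) %>%
    mutate(transformed = plotting_positions(.data$value, rank_convention)) %>%
    ungroup()
  provenance <- out %>%
    group_by(across(all_of(pool_vars))) %>%
    summarise(.fit = list(fit_ecdf(.data$value, rank_convention)),
              .groups = "drop")
  structure(out,
            class = c("eq_transformed", class(out)),
            scope = scope,
            rank_convention = rank_convention,
            provenance = provenance)
}

is_transformed <- function(data) {
  is.data.frame(data) && "transformed" %in% names(data)
}
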