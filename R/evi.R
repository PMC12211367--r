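#' EV Inconsistency matrix
#'
#' Computes the EV Inconsistency value (EVI) for every (method, sample)
#' cell of a quantile-transformed measurement table. Per assay, the
#' standard deviation of the transformed values across that cell's
#' replicates is taken; the per-assay standard deviations are then
#' aggregated over the assays present in the cell.
#'
#' Because the transformed values live in (0, 1), the mean-aggregated EVI
#' is bounded by the largest possible standard deviation of unit-interval
#' values (about 0.577 for 4 replicates), and an EVI of 0.2 reads as an
#' expected 20% deviation of the isolate on resampling. EVI is zero
#' exactly when every assay's transformed replicate values are constant in
#' the cell.
#'
#' @param transformed A measurement table carrying a `transformed` column,
#'   as returned by [transform_quantile()].
#' @param aggregation How per-assay standard deviations are combined:
#'   `"mean"` (default; keeps EVI on the fractional scale the index is
#'   reported on) or `"sum"` (the literal aggregate standard deviation).
#' @param sd_mode `"sample"` (default, n-1 denominator) or `"population"`
#'   (n denominator) standard deviation across replicates.
#'
#' @return A tibble of class `eq_evi` with columns `method`, `sample_id`,
#'   `evi`, `n_assays` (assays contributing to the cell), and attributes
#'   recording the aggregation settings. Cells are only computed from
#'   assays with at least two replicates; assays below that are dropped
#'   from the cell with a warning, and a cell with no usable assay is
#'   omitted entirely (its EVI is undefined).
#' @export
evi_matrix <- function(transformed, aggregation = c("mean", "sum"),
                       sd_mode = c("sample", "population")) {
  aggregation <- arg_match(aggregation)
  sd_mode <- arg_match(sd_mode)
  if (!is_transformed(transformed)) {
    abort_eq(
      "`transformed` must carry a `transformed` column; run transform_quantile() first.",
      "exoquality_config_error")
  }
  per_assay <- transformed %>%
    group_by(.data$method, .data$sample_id, .data$assay) %>%
    summarise(n_rep = dplyr::n(),
              sd_t = replicate_sd(.data$transformed, sd_mode),
              .groups = "drop")
  dropped <- per_assay %>% filter(.data$n_rep < 2)
  if (nrow(dropped) > 0) {
    warn(sprintf(
      "%d (method, sample, assay) cell(s) with < 2 replicates excluded from EVI.",
      nrow(dropped)), class = "exoquality_dropped_cells")
  }
  out <- per_assay %>%
    filter(.data$n_rep >= 2) %>%
    group_by(.data$method, .data$sample_id) %>%
    summarise(
      evi = if (aggregation == "mean") mean(.data$sd_t) else sum(.data$sd_t),
      n_assays = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$method, .data$sample_id)
  structure(out,
            class = c("eq_evi", class(out)),
            aggregation = aggregation, sd_mode = sd_mode)
}

replicate_sd <- function(x, sd_mode) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- stats::sd(x)
  if (sd_mode == "population") s * sqrt((n - 1) / n) else s
}

#' EV Inconsistency value for one cell
#'
#' Convenience scalar form of [evi_matrix()] for a single
#' (method, sample) cell.
#'
#' @inheritParams evi_matrix
#' @param method,sample_id The cell to evaluate.
#' @return A single non-negative number.
#' @export
compute_evi <- function(transformed, method, sample_id,
                        aggregation = c("mean", "sum"),
                        sd_mode = c("sample", "population")) {
  cell <- transformed %>%
    filter(.data$method == !!method, .data$sample_id == !!sample_id)
  if (nrow(cell) == 0) {
    abort_eq(sprintf("No records for method '%s', sample '%s'.",
                     method, sample_id),
             "exoquality_undefined_evi")
  }
  usable <- cell %>%
    dplyr::count(.data$assay) %>%
    filter(.data$n >= 2)
  if (nrow(usable) == 0) {
    abort_eq(sprintf(
      "EVI undefined for method '%s', sample '%s': no assay has >= 2 replicates.",
      method, sample_id),
      "exoquality_undefined_evi")
  }
  m <- suppressWarnings(
    evi_matrix(cell, aggregation = aggregation, sd_mode = sd_mode))
  m$evi[1]
}

#' ExoQuality Index per isolation method
#'
#' Aggregates an EV Inconsistency matrix into the per-method ExoQuality
#' Index: EQI = 1 - mean over samples of the method's EVI values, reported
#' both as a fraction and as a percentage. With mean aggregation the index
#' lies in (1 - 0.577, 1] for 4 replicates; higher values mean the method
#' is expected to yield more consistent EV populations on re-isolation.
#'
#' @param matrix An `eq_evi` tibble from [evi_matrix()].
#' @return A tibble of class `eq_eqi` with one row per method: `method`,
#'   `mean_evi`, `eqi` (fraction), `eqi_percent`, `n_samples`, plus the
#'   aggregation settings as attributes.
#' @export
compute_eqi <- function(matrix) {
  if (!inherits(matrix, "eq_evi")) {
    abort_eq("`matrix` must be an `eq_evi` object from evi_matrix().",
             "exoquality_config_error")
  }
  if (nrow(matrix) == 0) {
    abort_eq("EVI matrix has no entries.", "exoquality_validation_error")
  }
  out <- matrix %>%
    as_tibble() %>%
    group_by(.data$method) %>%
    summarise(mean_evi = mean(.data$evi),
              eqi = 1 - .data$mean_evi,
              eqi_percent = 100 * .data$eqi,
              n_samples = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$method)
  structure(out,
            class = c("eq_eqi", class(out)),
            aggregation = attr(matrix, "aggregation"),
            sd_mode = attr(matrix, "sd_mode"))
}

#' End-to-end ExoQuality Index from raw measurements
#'
#' Convenience pipeline: quantile-transform the raw table, compute the EVI
#' matrix, and aggregate into per-method EQI values.
#'
#' @inheritParams transform_quantile
#' @inheritParams evi_matrix
#' @return An `eq_eqi` tibble (see [compute_eqi()]) whose `evi` attribute
#'   holds the intermediate `eq_evi` matrix.
#' @export
#' @examples
#' d <- simulate_study(sim_config(seed = 7))
#' eqi(d)
eqi <- function(data, scope = "all", rank_convention = "midrank",
                aggregation = "mean", sd_mode = "sample") {
  transformed <- transform_quantile(data, scope = scope,
                                    rank_convention = rank_convention)
  m <- evi_matrix(transformed, aggregation = aggregation, sd_mode = sd_mode)
  res <- compute_eqi(m)
  attr(res, "evi") <- m
  attr(res, "scope") <- scope
  attr(res, "rank_convention") <- rank_convention
  res
}

#' Convention sweep over the open analysis choices
#'
#' The index leaves several conventions open: the aggregation of per-assay
#' standard deviations (mean vs sum), the replicate standard-deviation
#' estimator (sample vs population), the plotting position (midrank vs
#' Weibull), the pooling scope of the transformation, and — when PDI is
#' derived from size profiles — whether the PDI numerator is the maximal
#' or the modal size. `eqi_sweep()` recomputes the per-method EQI under
#' every combination, which is how a reported index value can be matched
#' to the convention that produced it.
#'
#' @param data A valid measurement table.
#' @param profiles Optional NTA profile table; when given, `size_mean_nm`,
#'   `pdi` (and concentration, if binned) records are re-derived from it
#'   under each `max_def` and merged with `data` before the sweep.
#' @param scopes Pooling scopes to sweep over (default `"all"` and
#'   `"per_group"`).
#' @return A tibble with one row per (convention combination, method):
#'   columns `aggregation`, `sd_mode`, `rank_convention`, `scope`,
#'   (`max_def`,) `method`, `mean_evi`, `eqi_percent`.
#' @export
eqi_sweep <- function(data, profiles = NULL,
                      scopes = c("all", "per_group")) {
  combos <- tidyr::expand_grid(
    aggregation = c("mean", "sum"),
    sd_mode = c("sample", "population"),
    rank_convention = c("midrank", "weibull"),
    scope = scopes,
    max_def = if (is.null(profiles)) NA_character_
              else c("max-size", "mode-size")
  )
  purrr::pmap_dfr(combos, function(aggregation, sd_mode, rank_convention,
                                   scope, max_def) {
    d <- data
    if (!is.null(profiles)) {
      derived <- suppressWarnings(
        derive_measurements(profiles,
                            group_map = dplyr::distinct(
                              as_tibble(data), .data$sample_id, .data$group),
                            max_def = max_def))
      d <- data %>%
        filter(!.data$assay %in% unique(derived$assay)) %>%
        bind_rows(derived)
    }
    res <- suppressWarnings(
      eqi(d, scope = scope, rank_convention = rank_convention,
          aggregation = aggregation, sd_mode = sd_mode))
    as_tibble(res) %>%
      select("method", "mean_evi", "eqi_percent") %>%
      mutate(aggregation = aggregation, sd_mode = sd_mode,
             rank_convention = rank_convention, scope = scope,
             max_def = max_def, .before = 1)
  })
}

# ---- broom-style and plotting methods -------------------------------------

#' Tidy an ExoQuality result
#'
#' @param x An `eq_eqi` or `eq_evi` object.
#' @param ... Unused.
#' @return A plain tibble of the per-method (or per-cell) values.
#' @export
tidy.eq_eqi <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.eq_eqi
#' @export
tidy.eq_evi <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an ExoQuality result
#'
#' @param x An `eq_eqi` object.
#' @param ... Unused.
#' @return A one-row tibble: number of methods, the best (highest-EQI)
#'   method and its index, and the EQI range.
#' @export
glance.eq_eqi <- function(x, ...) {
  tibble(
    n_methods = nrow(x),
    best_method = x$method[which.max(x$eqi)],
    best_eqi_percent = max(x$eqi_percent),
    eqi_range_percent = max(x$eqi_percent) - min(x$eqi_percent),
    aggregation = attr(x, "aggregation"),
    sd_mode = attr(x, "sd_mode")
  )
}

#' Generic tidiers
#'
#' `tidy()` returns the per-unit estimates of a result as a plain tibble;
#' `glance()` returns a one-row summary.
#' @param x An object produced by this package.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
print.eq_eqi <- function(x, ...) {
  cat(sprintf("# ExoQuality Index (aggregation = %s, sd = %s)\n",
              attr(x, "aggregation"), attr(x, "sd_mode")))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Plot an EV Inconsistency matrix as a heatmap
#'
#' @param object An `eq_evi` object.
#' @param ... Unused.
#' @return A ggplot: samples on the x axis, methods on the y axis, tiles
#'   coloured by EVI.
#' @method autoplot eq_evi
#' @export
autoplot.eq_evi <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$sample_id, y = .data$method,
                               fill = .data$evi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "EVI") +
    ggplot2::labs(x = "Sample", y = "Isolation method",
                  title = "EV Inconsistency value per method and sample") +
    ggplot2::theme_minimal()
}

#' Plot per-method ExoQuality Index values
#'
#' @param object An `eq_eqi` object.
#' @param ... Unused.
#' @return A ggplot bar chart of EQI (%) per isolation method.
#' @method autoplot eq_eqi
#' @export
autoplot.eq_eqi <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = stats::reorder(.data$method,
                                                  -.data$eqi_percent),
                               y = .data$eqi_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Isolation method", y = "ExoQuality Index (%)",
                  title = "Expected consistency of EV isolation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
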