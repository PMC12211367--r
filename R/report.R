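#' Raw stratified summaries
#'
#' Replicate-pooled mean, standard deviation and count of the raw values
#' per (group, method, assay) — the tabular form of the stratified
#' box-plot panels of a method-comparison figure.
#'
#' @param data A valid measurement table.
#' @return A tibble with columns `group`, `method`, `assay`, `mean`,
#'   `sd`, `n`, sorted by its first three columns; deterministic.
#' @export
summarize_raw <- function(data) {
  data <- validate_measurements(data)
  data %>%
    group_by(.data$group, .data$method, .data$assay) %>%
    summarise(mean = mean(.data$value),
              sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
              n = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$group, .data$method, .data$assay)
}

#' Wide-format transformed values for a scatter-plot matrix
#'
#' Spreads a transformed measurement table into one column per assay
#' (rows keyed by sample, method and replicate), the layout used for a
#' pairwise scatter matrix of the rescaled assays.
#'
#' @param transformed Output of [transform_quantile()].
#' @return A tibble with key columns plus one column of transformed
#'   values per assay.
#' @export
pairplot_data <- function(transformed) {
  if (!is_transformed(transformed)) {
    abort_eq("`transformed` must come from transform_quantile().",
             "exoquality_config_error")
  }
  as_tibble(transformed) %>%
    select("sample_id", "group", "method", "replicate", "assay",
           "transformed") %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "transformed") %>%
    arrange(.data$sample_id, .data$method, .data$replicate)
}

#' Density panel of transformed assay values by method
#'
#' The univariate view of the rescaled measurements: one density per
#' isolation method, facetted by assay. Overlapping densities indicate an
#' isolation-independent assay; separated ones a method-dependent assay.
#'
#' @param transformed Output of [transform_quantile()].
#' @return A ggplot object.
#' @export
plot_transformed_densities <- function(transformed) {
  if (!is_transformed(transformed)) {
    abort_eq("`transformed` must come from transform_quantile().",
             "exoquality_config_error")
  }
  ggplot2::ggplot(as_tibble(transformed),
                  ggplot2::aes(x = .data$transformed,
                               colour = .data$method)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~assay) +
    ggplot2::labs(x = "Transformed value (equal-likelihood scale)",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Run the full consistency pipeline and write a report bundle
#'
#' Executes read (or accept in-memory data), optional NTA derivation,
#' quantile transformation, EVI computation and EQI aggregation, and
#' writes the tabular outputs plus a machine-readable manifest to an
#' output directory. Every file is written atomically, outputs are
#' byte-identical across reruns with identical inputs and settings, and
#' the manifest records everything needed to reproduce the run (settings,
#' package version, input digests).
#'
#' @param input A measurement CSV path or an in-memory measurement table.
#' @param out_dir Output directory, created if needed.
#' @param nta_input Optional NTA profile CSV path or table; its derived
#'   records replace any same-assay records in `input`.
#' @param scope,rank_convention,aggregation,sd_mode Conventions, see
#'   [transform_quantile()] and [evi_matrix()].
#' @param max_def PDI numerator convention for NTA derivation.
#' @param sweep If `TRUE`, additionally write `eqi_sweep.csv` with the
#'   per-method EQI under every convention combination.
#' @param col_map Passed to [read_measurements()] when `input` is a path.
#'
#' @return Invisibly, a list of class `eq_report`: the tables
#'   (`raw_summaries`, `transformed`, `pairplot`, `evi`, `eqi`, and
#'   `sweep` if requested) and the `manifest`.
#' @details Files written: `raw_summaries.csv`, `transformed.csv`,
#'   `pairplot_data.csv`, `evi_matrix.csv`, `eqi.csv`, `manifest.json`
#'   (and `eqi_sweep.csv`). On any stage error the partial outputs are
#'   removed and the error is re-raised with a stage tag.
#' @export
run_pipeline <- function(input, out_dir, nta_input = NULL,
                         scope = "all", rank_convention = "midrank",
                         aggregation = "mean", sd_mode = "sample",
                         max_def = "max-size", sweep = FALSE,
                         col_map = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "read"
  result <- tryCatch({
    input_digest <- NA_character_
    if (is.character(input)) {
      input_digest <- unname(tools::md5sum(input))
      data <- read_measurements(input, col_map = col_map)
    } else {
      data <- validate_measurements(input)
    }
    nta_digest <- NA_character_
    profiles <- NULL
    if (!is.null(nta_input)) {
      stage <- "nta"
      if (is.character(nta_input)) {
        nta_digest <- unname(tools::md5sum(nta_input))
        profiles <- read_nta_profiles(nta_input)
      } else {
        profiles <- validate_nta_profiles(nta_input)
      }
      derived <- derive_measurements(
        profiles,
        group_map = distinct(data, .data$sample_id, .data$group),
        max_def = max_def)
      data <- data %>%
        filter(!.data$assay %in% unique(derived$assay)) %>%
        bind_rows(derived) %>%
        validate_measurements()
    }
    stage <- "transform"
    transformed <- transform_quantile(data, scope = scope,
                                      rank_convention = rank_convention)
    stage <- "evi"
    evi <- evi_matrix(transformed, aggregation = aggregation,
                      sd_mode = sd_mode)
    stage <- "eqi"
    eqi_tab <- compute_eqi(evi)
    stage <- "report"
    raw <- summarize_raw(data)
    pair <- pairplot_data(transformed)
    sweep_tab <- if (sweep) eqi_sweep(data, profiles = profiles) else NULL

    out_csv <- function(tab, name) {
      path <- file.path(out_dir, name)
      write_atomic(path, function(tmp) {
        readr::write_csv(as_tibble(tab), tmp, progress = FALSE)
      })
      written <<- c(written, path)
      path
    }
    out_csv(raw, "raw_summaries.csv")
    out_csv(as_tibble(transformed) %>%
              rename(transformed_value = "transformed"),
            "transformed.csv")
    out_csv(pair, "pairplot_data.csv")
    out_csv(evi, "evi_matrix.csv")
    out_csv(as_tibble(eqi_tab) %>%
              select("method", "eqi_percent", "mean_evi", "n_samples"),
            "eqi.csv")
    if (!is.null(sweep_tab)) out_csv(sweep_tab, "eqi_sweep.csv")

    manifest <- list(
      package = "exoquality",
      version = as.character(utils::packageVersion("exoquality")),
      settings = list(scope = scope, rank_convention = rank_convention,
                      aggregation = aggregation, sd_mode = sd_mode,
                      max_def = max_def, sweep = sweep),
      inputs = list(measurements_digest = input_digest,
                    nta_digest = nta_digest),
      design = list(
        n_samples = n_distinct(data$sample_id),
        n_methods = n_distinct(data$method),
        n_assays = n_distinct(data$assay),
        n_records = nrow(data)
      ),
      outputs = basename(written)
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    write_atomic(manifest_path, function(tmp) {
      jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
    })
    written <- c(written, manifest_path)

    structure(list(raw_summaries = raw, transformed = transformed,
                   pairplot = pair, evi = evi, eqi = eqi_tab,
                   sweep = sweep_tab, manifest = manifest,
                   out_dir = out_dir),
              class = "eq_report")
  }, error = function(e) {
    unlink(written)
    abort_eq(sprintf("Pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)),
             "exoquality_pipeline_error", parent = e)
  })
  invisible(result)
}

#' @export
print.eq_report <- function(x, ...) {
  cat(sprintf("<eq_report> written to '%s'\n", x$out_dir))
  print(x$eqi, ...)
  invisible(x)
}
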