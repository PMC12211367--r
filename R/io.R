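#' Read a long-format EV measurement table
#'
#' Reads the replicate-level measurement schema: one row per sample x
#' isolation method x assay x replicate with a numeric value. The file must
#' be comma-separated UTF-8 with a header row and a `.` decimal point.
#'
#' @param path Path to a CSV file with columns `sample_id`, `group`,
#'   `method`, `assay`, `replicate`, `value` (after applying `col_map`).
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(sample_id = "patient", value = "measurement")`. Columns not listed
#'   are looked up under their canonical names. This makes the reader
#'   tolerant of differently-labelled exports of the same schema.
#'
#' @return A validated tibble with the six canonical columns:
#'   `sample_id`, `group`, `method` and `assay` as character, `replicate`
#'   as integer, `value` as double. Assay labels outside
#'   [canonical_assays] are kept and flagged with a message.
#'
#' @details Row order in the file does not affect any downstream result;
#'   records are returned sorted by (sample, method, assay, replicate).
#'   A missing column raises a schema error naming the column; a
#'   non-numeric or non-finite value raises a row-level error giving the
#'   file line number; a duplicated (sample, method, assay, replicate) key
#'   raises a uniqueness error.
#'
#' @seealso [write_measurements()] for the inverse, [validate_measurements()]
#'   for validating an in-memory table.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' d <- simulate_study(sim_config(n_samples = 2, seed = 1))
#' write_measurements(d, path)
#' read_measurements(path)
read_measurements <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort_eq(sprintf("File '%s' does not exist.", path), "exoquality_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "group", "method", "assay", "replicate", "value")
  lookup <- setNames(required, required)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), required)
    if (length(bad) > 0) {
      abort_eq(paste0("Unknown canonical column(s) in `col_map`: ",
                      paste(bad, collapse = ", "), "."),
               "exoquality_config_error")
    }
    lookup[names(col_map)] <- unname(col_map)
  }
  missing <- lookup[!lookup %in% names(raw)]
  if (length(missing) > 0) {
    abort_eq(sprintf("Missing required column(s): %s.",
                     paste(unname(missing), collapse = ", ")),
             "exoquality_schema_error")
  }
  data <- tibble(
    sample_id = as.character(raw[[lookup[["sample_id"]]]]),
    group     = as.character(raw[[lookup[["group"]]]]),
    method    = as.character(raw[[lookup[["method"]]]]),
    assay     = as.character(raw[[lookup[["assay"]]]]),
    replicate = suppressWarnings(as.integer(raw[[lookup[["replicate"]]]])),
    value     = suppressWarnings(as.numeric(raw[[lookup[["value"]]]]))
  )
  # +1 for the header row: report file line numbers, not data row indices.
  bad_value <- which(!is.finite(data$value))
  if (length(bad_value) > 0) {
    abort_eq(sprintf(
      "Non-numeric or non-finite `value` at line(s): %s.",
      paste(bad_value + 1L, collapse = ", ")),
      "exoquality_value_error")
  }
  bad_rep <- which(is.na(data$replicate) | data$replicate < 1L)
  if (length(bad_rep) > 0) {
    abort_eq(sprintf(
      "`replicate` must be a positive integer; offending line(s): %s.",
      paste(bad_rep + 1L, collapse = ", ")),
      "exoquality_value_error")
  }
  validate_measurements(data)
}

#' Validate an in-memory measurement table
#'
#' Checks the invariants of the replicate-level schema: required columns,
#' finite non-negative values, positive integer replicate indices and
#' uniqueness of the (sample, method, assay, replicate) key. Assay labels
#' outside the five canonical ones are allowed and flagged with a message.
#'
#' @param data A data frame with columns `sample_id`, `group`, `method`,
#'   `assay`, `replicate`, `value`.
#' @return The validated data as a tibble, sorted by key (invisibly
#'   identical content regardless of input row order).
#' @export
validate_measurements <- function(data) {
  required <- c("sample_id", "group", "method", "assay", "replicate", "value")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_eq(sprintf("Missing required column(s): %s.",
                     paste(missing, collapse = ", ")),
             "exoquality_schema_error")
  }
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    abort_eq("Measurement table has no rows.", "exoquality_validation_error")
  }
  if (any(!is.finite(data$value))) {
    abort_eq("All `value` entries must be finite.", "exoquality_value_error")
  }
  if (any(data$value < 0)) {
    abort_eq("All assays are magnitudes: `value` must be >= 0.",
             "exoquality_value_error")
  }
  if (any(is.na(data$replicate)) || any(data$replicate < 1) ||
      any(data$replicate != round(data$replicate))) {
    abort_eq("`replicate` must be a positive integer index.",
             "exoquality_value_error")
  }
  dup <- data %>%
    dplyr::count(.data$sample_id, .data$method, .data$assay,
                 .data$replicate) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_eq(sprintf(
      "Duplicate (sample_id, method, assay, replicate) key(s), e.g. (%s, %s, %s, %d).",
      dup$sample_id[1], dup$method[1], dup$assay[1], dup$replicate[1]),
      "exoquality_uniqueness_error")
  }
  unknown <- setdiff(unique(data$assay), canonical_assays)
  if (length(unknown) > 0) {
    rlang::inform(paste0("Non-canonical assay label(s) retained: ",
                         paste(unknown, collapse = ", "), "."),
                  class = "exoquality_unknown_assay")
  }
  data %>%
    mutate(sample_id = as.character(.data$sample_id),
           group = as.character(.data$group),
           method = as.character(.data$method),
           assay = as.character(.data$assay),
           replicate = as.integer(.data$replicate),
           value = as.double(.data$value)) %>%
    arrange(.data$sample_id, .data$method, .data$assay, .data$replicate)
}

#' Write a measurement table to CSV
#'
#' The inverse of [read_measurements()]: writes the canonical six-column
#' schema so that a write-then-read round trip reproduces the dataset
#' exactly at full numeric precision.
#'
#' @param data A valid measurement table (see [validate_measurements()]).
#' @param path Output CSV path; written atomically.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  data <- validate_measurements(data)
  write_atomic(path, function(tmp) {
    readr::write_csv(data, tmp, progress = FALSE)
  })
  invisible(path)
}

#' Describe the crossed design of a measurement table
#'
#' @param data A valid measurement table.
#' @return A list with the ordered sets `assays`, `methods`, `samples`, the
#'   sample-to-group map `groups`, and `n_records`.
#' @export
study_design <- function(data) {
  data <- validate_measurements(data)
  groups <- data %>% distinct(.data$sample_id, .data$group)
  list(
    assays = sort(unique(data$assay)),
    methods = sort(unique(data$method)),
    samples = sort(unique(data$sample_id)),
    groups = setNames(groups$group, groups$sample_id),
    n_records = nrow(data)
  )
}

#' Read NTA size profiles
#'
#' Reads nanoparticle tracking analysis size profiles in either of two CSV
#' layouts, distinguished by their column names:
#' * per-particle: `sample_id`, `method`, `replicate`, `size_nm` — one row
#'   per tracked particle;
#' * binned: `sample_id`, `method`, `replicate`, `size_nm`, `concentration`
#'   — one row per size bin, with the particle concentration in that bin.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per particle or per bin, carrying the key
#'   columns plus `size_nm` (and `concentration` for the binned layout),
#'   with attribute `layout` set to `"particles"` or `"binned"`.
#' @details All sizes must be strictly positive and finite; binned
#'   concentrations must be non-negative with at least one strictly
#'   positive bin per profile. Violations raise a validation error.
#' @export
read_nta_profiles <- function(path) {
  if (!file.exists(path)) {
    abort_eq(sprintf("File '%s' does not exist.", path), "exoquality_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "method", "replicate", "size_nm")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_eq(sprintf("Missing required column(s): %s.",
                     paste(missing, collapse = ", ")),
             "exoquality_schema_error")
  }
  layout <- if ("concentration" %in% names(raw)) "binned" else "particles"
  profiles <- tibble(
    sample_id = as.character(raw$sample_id),
    method = as.character(raw$method),
    replicate = suppressWarnings(as.integer(raw$replicate)),
    size_nm = suppressWarnings(as.numeric(raw$size_nm))
  )
  if (layout == "binned") {
    profiles$concentration <- suppressWarnings(as.numeric(raw$concentration))
  }
  validate_nta_profiles(profiles)
}

#' Validate an in-memory NTA profile table
#'
#' @param profiles A data frame in the layout returned by
#'   [read_nta_profiles()]: key columns plus `size_nm`, and `concentration`
#'   for binned profiles.
#' @return The validated tibble with attribute `layout`.
#' @export
validate_nta_profiles <- function(profiles) {
  required <- c("sample_id", "method", "replicate", "size_nm")
  missing <- setdiff(required, names(profiles))
  if (length(missing) > 0) {
    abort_eq(sprintf("Missing required column(s): %s.",
                     paste(missing, collapse = ", ")),
             "exoquality_schema_error")
  }
  profiles <- as_tibble(profiles)
  layout <- if ("concentration" %in% names(profiles)) "binned" else "particles"
  if (nrow(profiles) == 0) {
    abort_eq("Empty NTA profile table.", "exoquality_validation_error")
  }
  if (any(!is.finite(profiles$size_nm)) || any(profiles$size_nm <= 0)) {
    abort_eq("All sizes must be strictly positive and finite.",
             "exoquality_validation_error")
  }
  if (layout == "binned") {
    if (any(!is.finite(profiles$concentration)) ||
        any(profiles$concentration < 0)) {
      abort_eq("Bin concentrations must be finite and non-negative.",
               "exoquality_validation_error")
    }
    zero <- profiles %>%
      group_by(.data$sample_id, .data$method, .data$replicate) %>%
      summarise(any_pos = any(.data$concentration > 0), .groups = "drop") %>%
      filter(!.data$any_pos)
    if (nrow(zero) > 0) {
      abort_eq(sprintf(
        "Profile (%s, %s, replicate %d) has all-zero concentrations.",
        zero$sample_id[1], zero$method[1], zero$replicate[1]),
        "exoquality_validation_error")
    }
  }
  out <- profiles %>%
    mutate(replicate = as.integer(.data$replicate)) %>%
    arrange(.data$sample_id, .data$method, .data$replicate, .data$size_nm)
  attr(out, "layout") <- layout
  out
}

#' Write NTA profiles to CSV
#'
#' @param profiles A valid NTA profile table.
#' @param path Output CSV path; written atomically.
#' @return `path`, invisibly.
#' @export
write_nta_profiles <- function(profiles, path) {
  profiles <- validate_nta_profiles(profiles)
  write_atomic(path, function(tmp) {
    readr::write_csv(profiles, tmp, progress = FALSE)
  })
  invisible(path)
}
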