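#' Particle dispersity index of a size profile
#'
#' The PDI summarises the heterogeneity of a particle size distribution as
#' the largest particle size divided by the standard deviation of the
#' profile, `max(sizes) / sd(sizes)`. Both quantities are in nm, so the
#' index is dimensionless and invariant under rescaling of all sizes.
#'
#' @param size_nm Particle sizes in nm (per-particle profile), or bin
#'   centers when `concentration` is supplied.
#' @param concentration Optional per-bin particle concentrations; when
#'   given, the standard deviation is the concentration-weighted
#'   (population) form over bin centers and the maximum is taken over bins
#'   with strictly positive concentration.
#' @param max_def Which size the numerator uses: `"max-size"` (default,
#'   largest size present) or `"mode-size"` (size of maximal concentration;
#'   for per-particle input, the per-particle maximum is used either way
#'   unless sizes repeat).
#'
#' @return A single positive finite number.
#' @details A monodisperse profile (zero size standard deviation) has no
#'   finite PDI; this raises a degenerate-profile error rather than
#'   returning infinity.
#' @export
#' @examples
#' compute_pdi(c(100, 150, 200)) # 200 / 50 = 4
compute_pdi <- function(size_nm, concentration = NULL,
                        max_def = c("max-size", "mode-size")) {
  max_def <- arg_match(max_def)
  if (length(size_nm) == 0 || any(!is.finite(size_nm)) || any(size_nm <= 0)) {
    abort_eq("Sizes must be a non-empty vector of positive finite numbers.",
             "exoquality_validation_error")
  }
  if (is.null(concentration)) {
    s <- stats::sd(size_nm)
    mx <- switch(max_def,
                 "max-size" = max(size_nm),
                 "mode-size" = size_mode(size_nm, rep(1, length(size_nm))))
  } else {
    w <- check_weights(size_nm, concentration)
    m <- sum(w * size_nm) / sum(w)
    s <- sqrt(sum(w * (size_nm - m)^2) / sum(w))
    mx <- switch(max_def,
                 "max-size" = max(size_nm[w > 0]),
                 "mode-size" = size_mode(size_nm, w))
  }
  if (!is.finite(s) || s <= 0) {
    abort_eq(
      "Degenerate (monodisperse) profile: size standard deviation is zero, PDI is undefined.",
      "exoquality_degenerate_profile")
  }
  mx / s
}

check_weights <- function(size_nm, concentration) {
  if (length(concentration) != length(size_nm)) {
    abort_eq("`size_nm` and `concentration` must have equal length.",
             "exoquality_validation_error")
  }
  if (any(!is.finite(concentration)) || any(concentration < 0) ||
      sum(concentration) <= 0) {
    abort_eq("Concentrations must be non-negative with a positive sum.",
             "exoquality_validation_error")
  }
  concentration
}

size_mode <- function(size_nm, w) {
  size_nm[which.max(w)][1]
}

#' Summarise NTA size profiles
#'
#' Reduces each (sample, method, replicate) profile to the scalar summaries
#' that feed the consistency metric: mean size, size standard deviation,
#' maximum and modal size, total particle concentration, and the particle
#' dispersity index PDI = max size / size sd.
#'
#' @param profiles An NTA profile table as returned by
#'   [read_nta_profiles()] or [validate_nta_profiles()]; the `layout`
#'   attribute (or the presence of a `concentration` column) selects the
#'   computation.
#' @param max_def Passed to [compute_pdi()]; `"max-size"` (default) or
#'   `"mode-size"`.
#'
#' @return A tibble with one row per profile: `sample_id`, `method`,
#'   `replicate`, `mean_size`, `sd_size`, `max_size`, `mode_size`,
#'   `total_concentration`, `pdi`.
#'
#' @details For per-particle input, mean/sd/max are the ordinary sample
#'   statistics of the size list (sd with the n-1 denominator), the modal
#'   size is left `NA` (every particle is its own "bin"), and the total
#'   concentration is `NA` — NTA instruments report it separately for that
#'   layout. For binned input, mean and sd are concentration-weighted over
#'   bin centers (population form), `max_size` is the largest bin center
#'   with strictly positive concentration, `mode_size` the bin center of
#'   maximal concentration (lowest such center on ties), and
#'   `total_concentration` the sum of the per-bin concentrations.
#'   A profile whose size sd is zero gets `pdi = NA` with a warning; its
#'   other summaries are kept.
#' @export
summarize_profiles <- function(profiles, max_def = c("max-size", "mode-size")) {
  max_def <- arg_match(max_def)
  profiles <- validate_nta_profiles(profiles)
  layout <- attr(profiles, "layout")
  grouped <- profiles %>%
    group_by(.data$sample_id, .data$method, .data$replicate)
  if (layout == "binned") {
    out <- grouped %>%
      summarise(
        mean_size = sum(.data$concentration * .data$size_nm) /
          sum(.data$concentration),
        sd_size = sqrt(sum(.data$concentration *
                             (.data$size_nm - mean_size)^2) /
                         sum(.data$concentration)),
        max_size = max(.data$size_nm[.data$concentration > 0]),
        mode_size = size_mode(.data$size_nm, .data$concentration),
        total_concentration = sum(.data$concentration),
        .groups = "drop"
      )
  } else {
    out <- grouped %>%
      summarise(
        mean_size = mean(.data$size_nm),
        sd_size = if (dplyr::n() > 1) stats::sd(.data$size_nm) else 0,
        max_size = max(.data$size_nm),
        mode_size = NA_real_,
        total_concentration = NA_real_,
        .groups = "drop"
      )
  }
  numerator <- if (max_def == "mode-size" && layout == "binned") {
    out$mode_size
  } else {
    out$max_size
  }
  out <- out %>%
    mutate(pdi = ifelse(.data$sd_size > 0, numerator / .data$sd_size,
                        NA_real_))
  n_degen <- sum(is.na(out$pdi))
  if (n_degen > 0) {
    warn(sprintf(
      "%d monodisperse profile(s): PDI undefined (size sd = 0), set to NA.",
      n_degen), class = "exoquality_degenerate_profile_warning")
  }
  out
}

#' Derive measurement records from NTA profiles
#'
#' Converts NTA profile summaries into replicate-level measurement records
#' (`size_mean_nm`, `pdi`, and `particle_concentration_per_mL` when the
#' binned layout provides it), keyed identically to the input profiles and
#' ready to merge into a measurement table.
#'
#' @param profiles An NTA profile table (see [read_nta_profiles()]).
#' @param group_map Optional data frame with columns `sample_id`, `group`
#'   assigning a group label per sample; samples not listed get
#'   `"unspecified"`.
#' @param existing Optional measurement table the records will be merged
#'   into; a key collision with it raises a uniqueness error.
#' @param max_def Passed to [compute_pdi()].
#'
#' @return A measurement tibble in the canonical six-column schema.
#'   Replicates whose PDI is undefined (monodisperse profile) contribute no
#'   `pdi` record — a warning is raised — but keep their size record.
#' @export
derive_measurements <- function(profiles, group_map = NULL, existing = NULL,
                                max_def = c("max-size", "mode-size")) {
  if (nrow(as_tibble(profiles)) == 0) {
    return(tibble(sample_id = character(), group = character(),
                  method = character(), assay = character(),
                  replicate = integer(), value = double()))
  }
  sums <- summarize_profiles(profiles, max_def = max_def)
  long <- sums %>%
    select("sample_id", "method", "replicate",
           size_mean_nm = "mean_size",
           particle_concentration_per_mL = "total_concentration",
           pdi = "pdi") %>%
    tidyr::pivot_longer(cols = c("size_mean_nm",
                                 "particle_concentration_per_mL", "pdi"),
                        names_to = "assay", values_to = "value") %>%
    filter(!is.na(.data$value))
  if (is.null(group_map)) {
    long$group <- "unspecified"
  } else {
    long <- long %>%
      left_join(as_tibble(group_map)[, c("sample_id", "group")],
                by = "sample_id") %>%
      mutate(group = dplyr::coalesce(.data$group, "unspecified"))
  }
  out <- long %>%
    select("sample_id", "group", "method", "assay", "replicate", "value") %>%
    arrange(.data$sample_id, .data$method, .data$assay, .data$replicate)
  if (!is.null(existing)) {
    clash <- dplyr::semi_join(
      out, as_tibble(existing),
      by = c("sample_id", "method", "assay", "replicate"))
    if (nrow(clash) > 0) {
      abort_eq(sprintf(
        "Derived record(s) collide with existing keys, e.g. (%s, %s, %s, %d).",
        clash$sample_id[1], clash$method[1], clash$assay[1],
        clash$replicate[1]),
        "exoquality_uniqueness_error")
    }
  }
  out
}
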