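# Fixture builders and from-first-principles oracles used across the suite.

# A complete crossed measurement table with deterministic or supplied values.
make_dataset <- function(n_samples = 2, n_methods = 2, n_assays = 2,
                         n_replicates = 2, values = NULL,
                         assay_labels = NULL) {
  if (is.null(assay_labels)) {
    assay_labels <- paste0("assay_", seq_len(n_assays))
  }
  d <- tidyr::expand_grid(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    method = paste0("M", seq_len(n_methods)),
    assay = assay_labels,
    replicate = seq_len(n_replicates)
  )
  d$group <- ifelse(as.integer(factor(d$sample_id)) %% 2 == 1,
                    "tumor", "healthy")
  d$value <- if (is.null(values)) seq_len(nrow(d)) else values
  d[, c("sample_id", "group", "method", "assay", "replicate", "value")]
}

random_small_dataset <- function() {
  n_a <- sample(1:3, 1)
  n_r <- sample(2:3, 1)
  n_m <- sample(1:3, 1)
  n_s <- sample(1:3, 1)
  d <- make_dataset(n_samples = n_s, n_methods = n_m, n_assays = n_a,
                    n_replicates = n_r)
  d$value <- stats::rlnorm(nrow(d), meanlog = 2, sdlog = 1)
  d
}

# Mid-rank plotting positions computed by explicit counting, independent of
# the package's rank()-based path.
brute_midrank <- function(x) {
  n <- length(x)
  vapply(x, function(xi) {
    r_bar <- sum(x < xi) + (sum(x == xi) + 1) / 2
    (r_bar - 0.5) / n
  }, numeric(1))
}

# EVI for one (method, sample) cell from first principles: explicit loops
# over assays and replicates, variance via sums of squared deviations.
brute_evi <- function(transformed_df, method, sample_id,
                      aggregation = "mean", sd_mode = "sample") {
  sub <- transformed_df[transformed_df$method == method &
                          transformed_df$sample_id == sample_id, ]
  sds <- c()
  for (a in unique(sub$assay)) {
    v <- sub$transformed[sub$assay == a]
    n <- length(v)
    if (n < 2) next
    m <- sum(v) / n
    ss <- 0
    for (x in v) ss <- ss + (x - m)^2
    denom <- if (sd_mode == "sample") n - 1 else n
    sds <- c(sds, sqrt(ss / denom))
  }
  if (length(sds) == 0) return(NA_real_)
  if (aggregation == "mean") mean(sds) else sum(sds)
}

quiet_validate <- function(expr) suppressMessages(expr)

# Full pipeline reduced to the numbers the invariance checks compare.
compute_index_pair <- function(d) {
  res <- suppressMessages(suppressWarnings(eqi(d)))
  list(evi = attr(res, "evi")$evi, eqi = res$eqi_percent)
}
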