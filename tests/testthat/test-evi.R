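test_that("cell-level EVI matches hand-computed standard deviations", {
  # one assay, transformed replicates {0.2, 0.4}: sd = 0.2 / sqrt(2)
  d <- make_dataset(n_samples = 1, n_methods = 1, n_assays = 1,
                    n_replicates = 2, values = c(1, 2))
  tr <- quiet_validate(transform_quantile(d))
  tr$transformed <- c(0.2, 0.4)
  expect_equal(compute_evi(tr, "M1", "S01"), 0.2 / sqrt(2))
  expect_equal(compute_evi(tr, "M1", "S01", aggregation = "sum"),
               0.2 / sqrt(2))

  # two assays with per-assay sds 0.1 and 0.3: mean 0.2, sum 0.4
  d2 <- make_dataset(n_samples = 1, n_methods = 1, n_assays = 2,
                     n_replicates = 2)
  tr2 <- quiet_validate(transform_quantile(d2))
  tr2 <- tr2[order(tr2$assay, tr2$replicate), ]
  tr2$transformed <- c(0.4, 0.4 + 0.1 * sqrt(2), 0.2, 0.2 + 0.3 * sqrt(2))
  expect_equal(compute_evi(tr2, "M1", "S01"), 0.2)
  expect_equal(compute_evi(tr2, "M1", "S01", aggregation = "sum"), 0.4)
  # population sd shrinks by sqrt((n-1)/n)
  expect_equal(compute_evi(tr2, "M1", "S01", sd_mode = "population"),
               0.2 * sqrt(1 / 2))

  # identical replicates in every assay give exactly zero
  d0 <- make_dataset(values = 5)
  tr0 <- quiet_validate(transform_quantile(d0))
  m0 <- evi_matrix(tr0)
  expect_true(all(m0$evi == 0))
})

test_that("EVI equals a from-first-principles brute force on random data", {
  for (seed in 1:25) {
    d <- withr::with_seed(seed, random_small_dataset())
    tr <- quiet_validate(transform_quantile(d))
    for (agg in c("mean", "sum")) {
      for (sdm in c("sample", "population")) {
        m <- evi_matrix(tr, aggregation = agg, sd_mode = sdm)
        for (i in seq_len(nrow(m))) {
          expect_equal(m$evi[i],
                       brute_evi(tr, m$method[i], m$sample_id[i],
                                 aggregation = agg, sd_mode = sdm),
                       tolerance = 1e-14)
        }
      }
    }
  }
})

test_that("the matrix covers the design and respects symmetries", {
  d <- simulate_study(sim_config(seed = 3))
  tr <- transform_quantile(d)
  m <- evi_matrix(tr)
  expect_equal(nrow(m), 4 * 11)
  expect_true(all(m$evi >= 0))
  expect_true(all(m$n_assays == 5))
  # bounded by the max sd of unit-interval values for 4 replicates
  expect_true(all(m$evi <= sqrt(4 / (4 - 1)) * 0.5))

  # copying one method's records onto another yields identical rows
  d2 <- d[d$method != "ps_affinity", ]
  copy <- d2[d2$method == "capture_release", ]
  copy$method <- "ps_affinity"
  d2 <- rbind(d2, copy)
  m2 <- evi_matrix(quiet_validate(transform_quantile(
    validate_measurements(d2))))
  a <- m2[m2$method == "capture_release", c("sample_id", "evi")]
  b <- m2[m2$method == "ps_affinity", c("sample_id", "evi")]
  expect_equal(a$evi, b$evi)

  # permuting method labels permutes rows identically
  relabel <- c(capture_release = "Z", membrane_affinity = "A",
               ps_affinity = "Q", ultracentrifugation = "B")
  d3 <- d
  d3$method <- unname(relabel[d3$method])
  m3 <- evi_matrix(transform_quantile(d3))
  key <- paste(relabel[m$method], m$sample_id)
  key3 <- paste(m3$method, m3$sample_id)
  expect_equal(m3$evi[match(key, key3)], m$evi)
})

test_that("cells with too few replicates are dropped, not imputed", {
  d <- make_dataset(n_samples = 1, n_methods = 1, n_assays = 2,
                    n_replicates = 2)
  d <- d[!(d$assay == "assay_2" & d$replicate == 2), ]
  tr <- quiet_validate(transform_quantile(d))
  expect_warning(evi_matrix(tr), class = "exoquality_dropped_cells")
  m <- suppressWarnings(evi_matrix(tr))
  expect_equal(m$n_assays, 1L)

  # a cell with no usable assay has undefined EVI
  d1 <- d[d$replicate == 1, ]
  tr1 <- quiet_validate(transform_quantile(d1))
  expect_error(compute_evi(tr1, "M1", "S01"),
               class = "exoquality_undefined_evi")
  expect_error(compute_evi(tr1, "M1", "nope"),
               class = "exoquality_undefined_evi")
})

test_that("EQI is one minus the per-method mean EVI, on both scales", {
  d <- make_dataset(n_samples = 2, n_methods = 1, n_assays = 1,
                    n_replicates = 2)
  tr <- quiet_validate(transform_quantile(d))
  m <- evi_matrix(tr)
  m$evi <- c(0.1, 0.3)
  res <- compute_eqi(m)
  expect_equal(res$mean_evi, 0.2)
  expect_equal(res$eqi, 0.8)
  expect_equal(res$eqi_percent, 80)
  expect_equal(res$n_samples, 2L)

  g <- glance(res)
  expect_equal(g$n_methods, 1L)
  expect_equal(g$best_eqi_percent, 80)
  expect_s3_class(tidy(res), "tbl_df")
  expect_error(compute_eqi(m[0, ]), class = "exoquality_validation_error")
})

test_that("results are deterministic and plots build", {
  d <- simulate_study(sim_config(n_samples = 3, seed = 8))
  r1 <- eqi(d)
  r2 <- eqi(d)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_s3_class(autoplot(attr(r1, "evi")), "ggplot")
  expect_s3_class(autoplot(r1), "ggplot")
})
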