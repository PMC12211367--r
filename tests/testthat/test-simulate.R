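test_that("configuration is validated and the default mirrors the study design", {
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$n_samples, 11L)
  expect_equal(cfg$n_replicates, 4L)
  expect_equal(nrow(cfg$methods), 4)
  expect_equal(cfg$assays$label, canonical_assays)
  expect_equal(sort(table(largest_remainder_groups(cfg$groups, 11))),
               sort(c(tumor = 6, healthy = 5)),
               ignore_attr = TRUE)

  expect_error(sim_config(n_samples = 0), class = "exoquality_config_error")
  expect_error(sim_config(n_replicates = 1), class = "exoquality_config_error")
  expect_error(sim_config(groups = c(a = 0.6, b = 0.6)),
               class = "exoquality_config_error")
  bad <- default_methods()
  bad$replicate_cv[1] <- -0.1
  expect_error(sim_config(methods = bad), class = "exoquality_config_error")
})

test_that("simulation is seeded, complete and restores the caller's RNG", {
  cfg <- sim_config(seed = 21)
  d1 <- simulate_study(cfg)
  d2 <- simulate_study(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 11 * 4 * 5 * 4)
  expect_true(all(d1$value > 0))

  set.seed(123)
  before <- .Random.seed
  invisible(simulate_study(cfg))
  expect_identical(.Random.seed, before)

  # a different seed gives different data
  expect_false(identical(simulate_study(sim_config(seed = 22)), d1))
})

test_that("zero replicate noise collapses the index to perfect consistency", {
  methods <- default_methods()
  methods$replicate_cv <- 0
  d <- simulate_study(sim_config(methods = methods, seed = 4))
  res <- eqi(d)
  m <- attr(res, "evi")
  expect_true(all(m$evi == 0))
  expect_true(all(res$eqi_percent == 100))
})

test_that("method bias shifts locations but replicate noise drives the index", {
  # same CVs, very different biases: EQIs should be close
  methods <- tibble::tibble(
    label = c("A", "B"), bias = c(0.2, 5), replicate_cv = 0.1)
  base <- sim_config(methods = methods, seed = 6)
  r <- recovery_experiment(base, n_runs = 30)
  expect_lt(abs(diff(r$summary$mean_eqi_percent)), 3 * max(
    r$summary$sd_eqi_percent / sqrt(30)) + 1)
})

test_that("NTA-backed simulation derives size and PDI records from profiles", {
  cfg <- sim_config(n_samples = 2, seed = 9)
  out <- simulate_study(cfg, nta = TRUE)
  expect_named(out, c("measurements", "profiles"))
  expect_identical(attr(out$profiles, "layout"), "particles")
  expect_equal(nrow(out$profiles), 2 * 4 * 4 * cfg$nta$n_particles)
  sizes <- summarize_profiles(out$profiles)
  derived_sizes <- out$measurements[out$measurements$assay == "size_mean_nm", ]
  joined <- merge(sizes, derived_sizes,
                  by = c("sample_id", "method", "replicate"))
  expect_equal(joined$value, joined$mean_size)
  # full assay panel is still present
  expect_setequal(unique(out$measurements$assay), canonical_assays)
})

test_that("per-assay method parameters are honoured", {
  methods <- tibble::tibble(
    label = c("A", "B"),
    bias = list(setNames(c(1, 1, 1, 1, 1), canonical_assays),
                setNames(c(2, 1, 1, 1, 1), canonical_assays)),
    replicate_cv = list(setNames(rep(0, 5), canonical_assays),
                        setNames(rep(0, 5), canonical_assays)))
  d <- simulate_study(sim_config(n_samples = 3, methods = methods, seed = 2))
  wide <- tidyr::pivot_wider(
    d[d$assay == "size_mean_nm" & d$replicate == 1, ],
    names_from = "method", values_from = "value")
  expect_equal(wide$B, 2 * wide$A)
})

test_that("ranking recovery behaves at its symmetric and single-run limits", {
  methods <- tibble::tibble(label = c("A", "B"), bias = 1,
                            replicate_cv = c(0.1, 0.1))
  cfg <- sim_config(n_samples = 4, methods = methods, seed = 10,
                    assays = default_assays()[1:2, ])
  r1 <- recovery_experiment(cfg, n_runs = 1)
  expect_equal(r1$n_runs, 1)
  expect_true(r1$correct_fraction %in% c(0, 1))
  expect_equal(nrow(r1$runs), 2)

  one <- sim_config(methods = methods[1, ], seed = 1)
  expect_error(recovery_experiment(one, n_runs = 2),
               class = "exoquality_config_error")
  expect_s3_class(tidy(r1), "tbl_df")
  expect_equal(glance(r1)$n_runs, 1)
})
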