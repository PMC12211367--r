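test_that("per-particle summaries are the sample statistics of the sizes", {
  p <- tibble::tibble(sample_id = "S1", method = "M1", replicate = 1L,
                      size_nm = c(100, 150, 200))
  s <- summarize_profiles(p)
  expect_equal(s$mean_size, 150)
  expect_equal(s$sd_size, 50)          # n-1 denominator
  expect_equal(s$max_size, 200)
  expect_equal(s$pdi, 4)               # 200 / 50
  expect_true(is.na(s$total_concentration))
})

test_that("binned summaries are concentration-weighted over bin centers", {
  b <- tibble::tibble(sample_id = "S1", method = "M1", replicate = 1L,
                      size_nm = c(100, 200), concentration = c(1, 1))
  s <- summarize_profiles(b)
  expect_equal(s$mean_size, 150)
  expect_equal(s$max_size, 200)
  expect_equal(s$mode_size, 100)       # ties resolve to the lowest center
  expect_equal(s$total_concentration, 2)
  # weighted population sd: sqrt(mean((x - 150)^2)) = 50
  expect_equal(s$sd_size, 50)

  # zero-concentration bins do not contribute to the maximum
  b2 <- tibble::tibble(sample_id = "S1", method = "M1", replicate = 1L,
                       size_nm = c(100, 200, 400),
                       concentration = c(1, 1, 0))
  expect_equal(summarize_profiles(b2)$max_size, 200)
})

test_that("a single-bin profile is degenerate: sd 0 and no PDI", {
  b <- tibble::tibble(sample_id = "S1", method = "M1", replicate = 1L,
                      size_nm = 120, concentration = 5)
  expect_warning(summarize_profiles(b),
                 class = "exoquality_degenerate_profile_warning")
  s <- suppressWarnings(summarize_profiles(b))
  expect_equal(s$sd_size, 0)
  expect_equal(s$mode_size, 120)
  expect_equal(s$max_size, 120)
  expect_true(is.na(s$pdi))
})

test_that("PDI is max size over size sd and rejects monodisperse input", {
  expect_equal(compute_pdi(c(100, 150, 200)), 4)
  expect_equal(compute_pdi(c(100, 300)), 300 / (sqrt(2) * 100))
  expect_error(compute_pdi(c(150, 150, 150)),
               class = "exoquality_degenerate_profile")
  expect_error(compute_pdi(numeric(0)),
               class = "exoquality_validation_error")
})

test_that("size rescaling scales the moments linearly but leaves PDI fixed", {
  for (seed in 1:5) {
    sizes <- withr::with_seed(seed, stats::rlnorm(50, log(140), 0.3))
    c_fac <- withr::with_seed(seed, stats::runif(1, 0.2, 5))
    p1 <- tibble::tibble(sample_id = "S1", method = "M1", replicate = 1L,
                         size_nm = sizes)
    p2 <- p1
    p2$size_nm <- p2$size_nm * c_fac
    s1 <- summarize_profiles(p1)
    s2 <- summarize_profiles(p2)
    expect_equal(s2$mean_size, c_fac * s1$mean_size)
    expect_equal(s2$sd_size, c_fac * s1$sd_size)
    expect_equal(s2$max_size, c_fac * s1$max_size)
    expect_equal(s2$pdi, s1$pdi)
    expect_equal(compute_pdi(sizes * c_fac), compute_pdi(sizes))
  }
})

test_that("weighted and per-particle paths agree on unit-weight singleton bins", {
  sizes <- withr::with_seed(3, round(stats::rlnorm(40, log(120), 0.25), 6))
  sizes <- unique(sizes)
  particles <- tibble::tibble(sample_id = "S1", method = "M1",
                              replicate = 1L, size_nm = sizes)
  bins <- tibble::tibble(sample_id = "S1", method = "M1", replicate = 1L,
                         size_nm = sizes, concentration = 1)
  sp <- summarize_profiles(particles)
  sb <- summarize_profiles(bins)
  expect_equal(sb$mean_size, sp$mean_size)
  expect_equal(sb$max_size, sp$max_size)
  # the binned path uses the population sd; rescale to compare
  n <- length(sizes)
  expect_equal(sb$sd_size, sp$sd_size * sqrt((n - 1) / n))
})

test_that("derive_measurements emits mergeable records and drops degenerate PDI", {
  cfg <- sim_config(n_samples = 1, n_replicates = 4, seed = 2)
  profiles <- simulate_study(cfg, nta = TRUE)$profiles
  one <- profiles[profiles$method == profiles$method[1], ]
  recs <- derive_measurements(one)
  # per-particle layout: size + pdi per replicate, no concentration
  expect_setequal(unique(recs$assay), c("size_mean_nm", "pdi"))
  expect_equal(nrow(recs), 2 * 4)

  expect_equal(nrow(derive_measurements(one[0, ])), 0)

  # a monodisperse replicate loses its pdi record but keeps its size record
  degen <- tibble::tibble(
    sample_id = "S1", method = "M1", replicate = c(1L, 1L, 2L),
    size_nm = c(100, 200, 150))
  expect_warning(derive_measurements(degen),
                 class = "exoquality_degenerate_profile_warning")
  recs2 <- suppressWarnings(derive_measurements(degen))
  expect_equal(sum(recs2$assay == "pdi"), 1)
  expect_equal(sum(recs2$assay == "size_mean_nm"), 2)

  # key collisions with an existing table are refused
  existing <- recs[, ]
  expect_error(derive_measurements(one, existing = existing),
               class = "exoquality_uniqueness_error")
})
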