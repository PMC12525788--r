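test_that("same seed reproduces the study bit for bit", {
  cfg <- tiny_config(n1 = 12, n2 = 10, n3 = 8)
  s1 <- generate_study(cfg, seed = 7)
  s2 <- generate_study(cfg, seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_study(cfg, seed = 8)
  expect_false(identical(s1[["2021"]]$absorbance, s3[["2021"]]$absorbance))
})

test_that("season TMQ distributions hit their target moments and bounds", {
  p21 <- year_params(2021, 288, 7.75, 0.68, 14.46)
  set.seed(51)
  draws <- sample_tmq(p21, 1e5, shape = 5)
  expect_lt(abs(mean(draws) - 7.75), 0.39)     # within 5% of the mean
  expect_gte(min(draws), 0.68)
  expect_lte(max(draws), 14.46)
  # left skew: more mass above the mean than a symmetric law would put
  expect_lt(mean(draws < 7.75), 0.5)

  expect_equal(sample_tmq(year_params(1, 5, 3, 3, 3), 4), rep(3, 4))
  set.seed(52); a <- sample_tmq(p21, 50)
  set.seed(52); b <- sample_tmq(p21, 50)
  expect_identical(a, b)
  expect_error(sample_tmq(year_params(1, 5, 1.0, 0.9, 20), 5), "infeasible")
})

test_that("analyte band contribution is exactly linear in TMQ when noise is off", {
  cfg <- synthetic_config(noise_sd = 0, hplc_error_sd = 0,
                          scatter = list(mult_sd = 0, add_sd = 0,
                                         tilt_sd = 0),
                          loading_sdlog = 0)
  set.seed(53)
  s <- generate_spectra(c(0, 1, 2), cfg)
  x0 <- s$absorbance[1, ]; x1 <- s$absorbance[2, ]; x2 <- s$absorbance[3, ]
  expect_equal(x2 - x0, 2 * (x1 - x0), tolerance = 1e-12)

  # single unit band, nothing else: pure Gaussian of known shape
  cfg1 <- synthetic_config(noise_sd = 0, hplc_error_sd = 0,
                           scatter = list(mult_sd = 0, add_sd = 0,
                                          tilt_sd = 0),
                           loading_sdlog = 0,
                           tmq_bands = band_table(2106, 10, 1e-3))
  s1 <- generate_spectra(c(0, 1), cfg1)
  diff <- s1$absorbance[2, ] - s1$absorbance[1, ]
  expect_equal(diff, 1e-3 * exp(-((cfg1$grid - 2106)^2) / (2 * 100)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generate_study wires sizes, reference noise and year labels", {
  cfg <- tiny_config(n1 = 15, n2 = 12, n3 = 9)
  sets <- generate_study(cfg, seed = 54)
  expect_equal(vapply(sets, n_samples, 0L), c("2021" = 15L, "2022" = 12L,
                                              "2023" = 9L))
  expect_equal(unique(sets[["2022"]]$year), 2022L)
  expect_equal(length(sets[["2023"]]$reference), 9)

  cfg0 <- tiny_config(n1 = 15, n2 = 12, n3 = 9, hplc_error_sd = 0)
  sets0 <- generate_study(cfg0, seed = 54)
  expect_equal(sets0[["2021"]]$reference, sets0[["2021"]]$true_tmq)

  # default-sized study matches the three-season design
  expect_equal(vapply(synthetic_config()$years, `[[`, 0L, "n"),
               c("2021" = 288L, "2022" = 313L, "2023" = 179L))
})

test_that("zero season offsets give unbiased across-season validation", {
  biases <- vapply(1:6, function(seed) {
    cfg <- tiny_config(n1 = 50, n2 = 50, n3 = 40)
    for (nm in names(cfg$years)) cfg$years[[nm]]$offset <- 0
    sets <- generate_study(cfg, seed = seed)
    sc <- study_config(seed = seed, max_factors = 10)
    v <- run_validation_strategy(sets, c("2021", "2022"), "2023", 0, sc)
    v$validation$bias / (v$validation$se / sqrt(v$validation$n))
  }, 0)
  # standardized biases should look like noise, not a systematic shift
  expect_lt(abs(mean(biases)), 2.5)
  expect_lt(max(abs(biases)), 6)
})
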