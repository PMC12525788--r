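test_that("group averages and two-spectrum SD profile closed forms", {
  grid <- seq(1100, 1120, 2)
  x <- sin(grid / 5)
  set <- spectra_set(rbind(x, 2 - x, x + 1), grid, c("a", "b", "c"),
                     step = NULL)
  expect_equal(group_average(set, "a")$values, x, ignore_attr = TRUE)
  expect_equal(group_average(set, c("a", "b"))$values,
               rep(1, length(grid)), ignore_attr = TRUE)
  expect_equal(group_average(set, c("b", "a"))$values,
               group_average(set, c("a", "b"))$values)
  expect_error(group_average(set, character(0)), "empty")

  prof <- sd_profile(group_average(set, "a"), group_average(set, "c"))
  expect_equal(prof$sd, rep(1 / sqrt(2), length(grid)), ignore_attr = TRUE)
  expect_equal(sd_profile(c(0.4), c(0.1), 1)$sd, 0.3 / sqrt(2))
  # matches the textbook two-value SD and is symmetric
  set.seed(41)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(sd_profile(a, b, seq_len(50))$sd,
               apply(rbind(a, b), 2, sd))
  expect_equal(sd_profile(a, b, seq_len(50))$sd,
               sd_profile(b, a, seq_len(50))$sd)
})

test_that("find_peaks ranks local maxima and enforces separation", {
  wl <- seq(2000, 2400, 2)
  spike <- exp(-((wl - 2106) / 6)^2)
  prof <- structure(list(wavelengths = wl, sd = spike), class = "sd_profile")
  expect_equal(find_peaks(prof, top_k = 1)$wavelength, 2106)

  # a shoulder 10 nm from the 2254 band is its own local maximum but must
  # be suppressed by the separation rule
  two <- spike + 0.8 * exp(-((wl - 2254) / 3)^2) +
    0.5 * exp(-((wl - 2264) / 3)^2)
  prof2 <- structure(list(wavelengths = wl, sd = two), class = "sd_profile")
  pk <- find_peaks(prof2, top_k = 3, min_separation = 20)
  expect_equal(pk$wavelength[1:2], c(2106, 2254))
  expect_false(2264 %in% pk$wavelength)

  flat <- structure(list(wavelengths = wl, sd = rep(0.2, length(wl))),
                    class = "sd_profile")
  expect_equal(nrow(find_peaks(flat)), 0)
})

test_that("injected analyte bands are recovered from low/high group averages", {
  hits <- 0L
  n_seeds <- 8
  for (seed in seq_len(n_seeds)) {
    cfg <- tiny_config(
      n1 = 120, n2 = 10, n3 = 10,
      tmq_bands = band_table(c(2106, 2254), c(8, 8), c(8e-4, 7e-4)))
    sets <- generate_study(cfg, seed = seed)
    wa <- run_wavelength_analysis(sets[["2021"]], study_config(seed = seed),
                                  n_each = 50, top_k = 2)
    found <- sort(wa$peaks$wavelength[1:2])
    if (all(abs(found - c(2106, 2254)) <= 4)) hits <- hits + 1L
  }
  expect_gte(hits, n_seeds - 1L)
})

test_that("extreme_groups picks the reference tails deterministically", {
  set.seed(43)
  set <- generate_spectra(runif(30, 1, 15), synthetic_config())
  set$reference <- set$true_tmq
  g <- extreme_groups(set, 5)
  expect_length(g$low, 5)
  expect_true(max(set$reference[match(g$low, set$sample_id)]) <=
                min(set$reference[match(g$high, set$sample_id)]))
  expect_error(extreme_groups(set, 20), "at least")
})
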