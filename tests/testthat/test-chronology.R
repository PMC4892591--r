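make_series <- function(widths, first_year = 1900L, id = "c1", site = "s1")
  ring_series(id, site, first_year, widths)

test_that("growth-curve fallback picks the right conservative model", {
  ## constant series -> straight line with zero slope
  s <- make_series(rep(1.5, 40))
  fit <- fit_growth_curve(s)
  expect_equal(fit$model, "straight_line")
  expect_equal(unname(fit$parameters[["slope"]]), 0, tolerance = 1e-10)
  expect_equal(fit$fitted_values, rep(1.5, 40), tolerance = 1e-10)

  ## noise-free negative exponential is recovered to < 1e-3 relative error
  tt <- 1:120
  s2 <- make_series(2.0 * exp(-0.05 * tt) + 0.3)
  fit2 <- fit_growth_curve(s2)
  expect_equal(fit2$model, "negative_exponential")
  expect_lt(max(abs(fit2$parameters - c(2.0, 0.05, 0.3)) / c(2.0, 0.05, 0.3)), 1e-3)

  ## increasing series: neither conservative model is admissible -> spline
  s3 <- make_series(0.5 + 0.02 * (1:60))
  fit3 <- fit_growth_curve(s3)
  expect_equal(fit3$model, "smoothing_spline")
  expect_true(all(fit3$fitted_values > 0))
})

test_that("ratio indexing is exact and homogeneous", {
  s <- make_series(c(2, 2.2, 1.8, 2.1, 2.0, 1.9, 2.3, 2.2, 2.0, 1.9, 2.1, 2.0))
  fit <- structure(list(model = "straight_line", parameters = c(0, 0),
                        fitted_values = s$widths), class = "growth_curve_fit")
  idx <- detrend_to_index(s, fit)
  expect_equal(idx$values, rep(1, 12))

  s2 <- make_series(2 * s$widths)
  idx2 <- detrend_to_index(s2, fit)
  expect_equal(idx2$values, 2 * idx$values)

  bad <- structure(list(model = "straight_line", parameters = c(0, 0),
                        fitted_values = rep(0.005, 12)), class = "growth_curve_fit")
  expect_error(detrend_to_index(s, bad), "floor")
})

test_that("noise-free simulated indices reproduce 1 + common signal", {
  cfg <- network_sim_config(n_sites = 2L, cores_per_site = 3L,
                            first_year = 1880L, last_year = 2000L,
                            common_signal_fraction = 0.5, site_noise_sd = 0,
                            group_effect = 0, seed = 4L)
  net <- generate_network(cfg)
  tr <- cfg$age_trend
  by_site <- split(net$series, vapply(net$series, function(s) s$site_id, character(1)))
  for (cores in by_site) {
    idx <- lapply(cores, function(s) {
      age <- seq_along(s$widths)
      fit <- structure(list(model = "negative_exponential",
                            parameters = c(a = tr[["a"]], b = tr[["b"]], k = tr[["k"]]),
                            fitted_values = tr[["a"]] * exp(-tr[["b"]] * age) + tr[["k"]]),
                       class = "growth_curve_fit")
      detrend_to_index(s, fit)
    })
    crn <- build_chronology(idx)
    expect_equal(crn$index,
                 unname(1 + net$truth$common_signal[as.character(crn$years)]),
                 tolerance = 1e-6)
  }
})

test_that("biweight mean matches an independent reference and is robust", {
  expect_equal(biweight_mean(c(0.9, 1.0, 1.1)), 1.0, tolerance = 1e-9)
  expect_equal(biweight_mean(0.73), 0.73)
  expect_equal(biweight_mean(c(0.8, 1.2)), 1.0)

  x <- c(1.0, 1.0, 1.0, 1.0, 5.0)
  b <- biweight_mean(x)
  expect_lt(abs(b - 1.0), abs(mean(x) - 1.0))
  expect_equal(b, ref_biweight(x), tolerance = 1e-9)

  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 2))
    m <- biweight_mean(v)
    expect_equal(m, ref_biweight(v), tolerance = 1e-5)
    ## bounded, shift- and scale-equivariant
    expect_gte(m, min(v)); expect_lte(m, max(v))
    expect_equal(biweight_mean(2.5 * v - 3), 2.5 * m - 3, tolerance = 1e-5)
  }
  expect_error(biweight_mean(numeric()), "empty")
})

test_that("chronology building handles single and identical cores", {
  vals <- c(1.1, 0.9, 1.0, 1.2, 0.8, 1.0, 1.05, 0.95, 1.0, 1.1,
            0.9, 1.0, 1.2, 0.8, 1.0, 1.05, 0.95, 1.0, 1.1, 0.9,
            1.0, 1.2, 0.8, 1.0, 1.05, 0.95, 1.0, 1.1, 0.9, 1.0)
  one <- structure(list(core_id = "a", site_id = "s", first_year = 1950L,
                        values = vals), class = "index_series")
  crn1 <- build_chronology(list(one))
  expect_equal(crn1$index, vals)
  expect_true(is.na(crn1$rbar))

  three <- lapply(c("a", "b", "c"), function(id)
    structure(list(core_id = id, site_id = "s", first_year = 1950L, values = vals),
              class = "index_series"))
  crn3 <- build_chronology(three)
  expect_equal(crn3$index, vals)
  expect_equal(crn3$rbar, 1)
})

test_that("estimated rbar matches the one-factor covariance algebra", {
  f <- 0.5; sigma_s <- 0.1; sigma_c <- 0.15; ge <- 0.8
  a2 <- sigma_s^2 * f / (1 - f)
  shared <- a2 + (ge^2 * a2) + sigma_s^2
  expected <- shared / (shared + sigma_c^2)
  tr <- c(a = 1.5, b = 0.02, k = 0.3)
  rb <- vapply(1:50, function(i) {
    cfg <- network_sim_config(n_sites = 1L, cores_per_site = 6L,
                              first_year = 1800L, last_year = 2000L,
                              common_signal_fraction = f, site_noise_sd = sigma_s,
                              core_noise_sd = sigma_c, group_effect = ge,
                              extreme_year_prob = 0, age_trend = tr,
                              seed = 700L + i)
    net <- generate_network(cfg)
    idx <- lapply(net$series, function(s) {
      age <- seq_along(s$widths)
      fit <- structure(list(model = "negative_exponential",
                            parameters = tr,
                            fitted_values = tr[["a"]] * exp(-tr[["b"]] * age) + tr[["k"]]),
                       class = "growth_curve_fit")
      detrend_to_index(s, fit)
    })
    build_chronology(idx)$rbar
  }, numeric(1))
  expect_lt(abs(mean(rb) - expected), 2 * stats::sd(rb) / sqrt(50) + 0.01)
})

test_that("SSS follows the Wigley formula and its limits", {
  res <- sss_profile(0.3, c(5L, 40L), 40L)
  expect_equal(res$sss[1], 5 * (1 + 39 * 0.3) / (40 * (1 + 4 * 0.3)), tolerance = 1e-12)
  expect_equal(round(res$sss[1], 4), 0.7216)
  expect_equal(res$sss[2], 1)                      # n = N
  expect_equal(sss_profile(1, 3L, 10L)$sss, 1)     # rbar = 1
  expect_error(sss_profile(0, 3L, 10L), "positive")
  expect_error(sss_profile(-0.2, 3L, 10L), "positive")

  ## monotone nondecreasing in n, equal to 1 at n = N
  for (rbar in seq(0.1, 0.9, by = 0.2)) {
    for (N in c(5L, 15L, 40L)) {
      sss <- sss_profile(rbar, seq_len(N), N)$sss
      expect_true(all(diff(sss) >= -1e-12))
      expect_true(all(sss >= 0 & sss <= 1 + 1e-12))
      expect_equal(sss[N], 1)
    }
  }
})

test_that("SSS truncation matches a brute-force scan", {
  depth <- c(1L, 1L, 2L, 4L, 8L, 8L, 8L, 8L, 8L, 8L)
  sss <- sss_profile(0.4, depth, 8L)$sss
  crn <- structure(list(site_id = "s", years = 1901:1910,
                        index = rep(1, 10), depth = depth, rbar = 0.4,
                        eps = NA_real_, sss = sss, mean_sensitivity = 0,
                        reliable_span = NULL, n_cores = 8L), class = "chronology")
  cut <- truncate_by_sss(crn, 0.85)
  ## oracle: exhaustive scan for the earliest start with all SSS >= 0.85
  starts <- which(vapply(seq_along(sss), function(i) all(sss[i:length(sss)] >= 0.85),
                         logical(1)))
  expect_equal(cut$reliable_span[1], (1901:1910)[min(starts)])
  expect_true(all(is.na(cut$index[seq_len(min(starts) - 1L)])))
  expect_equal(cut$depth, depth)  # depth history retained

  ## all reliable -> no truncation
  crn$sss <- rep(0.95, 10)
  expect_equal(truncate_by_sss(crn, 0.85)$reliable_span[1], 1901L)
  ## nothing reliable -> error reporting the maximum
  crn$sss <- rep(0.5, 10)
  expect_error(truncate_by_sss(crn, 0.85), "max SSS")
})

test_that("mean sensitivity matches hand evaluation", {
  expect_equal(mean_sensitivity(rep(3, 10)), 0)
  expect_equal(mean_sensitivity(c(1, 2)), 2 / 3, tolerance = 1e-12)
  expect_equal(mean_sensitivity(c(1, 2, 1)), 2 / 3, tolerance = 1e-12)
  expect_error(mean_sensitivity(c(1, -1, 2)), "zero")
  expect_error(mean_sensitivity(3), "at least 2")
})

test_that("index means stay near 1 on default synthetic bundles", {
  net <- generate_network(network_sim_config(n_sites = 4L, cores_per_site = 3L,
                                             first_year = 1850L, last_year = 2000L,
                                             seed = 31L))
  chrons <- chronologies_from_network(net, truncate = FALSE)
  for (cr in chrons) {
    expect_true(all(cr$index > 0))
    expect_gt(mean(cr$index), 0.8)
    expect_lt(mean(cr$index), 1.2)
  }
})
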