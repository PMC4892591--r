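#' Configuration for a synthetic ring-width network
#'
#' Defines a multi-site, multi-core ring-width simulation with a shared
#' interannual signal whose strength may change over time. Each core is
#' generated multiplicatively as `age trend x (1 + signal + noise)`, the
#' same structure that ratio detrending assumes, so detrending is an exact
#' inverse in the noise-free case.
#'
#' The stochastic index of core `c` at site `s` in year `t` is
#' `1 + a_t C_t + b_t G_{g(s),t} + sigma_site eta_{s,t} + sigma_core xi_{s,c,t}`
#' where `C` is the network-wide common signal, `G` is a two-group site
#' signal (emulating a secondary loading axis), `eta` is site-level noise
#' shared by all cores of a site and `xi` is per-core noise. The common
#' amplitude `a_t = sigma_site * sqrt(f_t / (1 - f_t))` makes
#' `common_signal_fraction` `f_t` the fraction of site-level variance
#' carried by the common signal; when `sigma_site = 0` the amplitude falls
#' back to `0.1 * sqrt(f_t)`.
#'
#' @param n_sites number of sites.
#' @param cores_per_site number of cores per site.
#' @param first_year,last_year calendar span of the simulation.
#' @param age_trend numeric `(a, b, k)` of the negative-exponential age
#'   trend `a * exp(-b * age) + k`, in mm.
#' @param common_signal_fraction either a single value in `[0, 1)` or a
#'   function of calendar year returning such values.
#' @param site_noise_sd standard deviation of site-level index noise.
#' @param core_noise_sd standard deviation of per-core index noise;
#'   defaults to `1.5 * site_noise_sd` (within-site rbar near 0.4).
#' @param group_effect amplitude of the two-group site signal relative to
#'   the common amplitude (default 0.8, which puts the secondary loading
#'   axis near the 11% variance share typical of such networks).
#' @param extreme_year_prob probability per year of a +/-3 SD shock applied
#'   to the common signal.
#' @param stagger_fraction core start years are drawn uniformly from the
#'   first `stagger_fraction` of the span (default 0.35), so sample depth
#'   grows toward the present while reliable spans still cover the late
#'   record.
#' @param seed integer seed; fully determines the output.
#' @return a `network_sim_config` list.
#' @export
network_sim_config <- function(n_sites = 17L, cores_per_site = 5L,
                               first_year = 1700L, last_year = 2005L,
                               age_trend = c(a = 1.5, b = 0.02, k = 0.3),
                               common_signal_fraction = function(year) ifelse(year < 1985, 0.3, 0.6),
                               site_noise_sd = 0.1,
                               core_noise_sd = NULL,
                               group_effect = 0.8,
                               extreme_year_prob = 0.02,
                               stagger_fraction = 0.35,
                               seed = 1L) {
  if (last_year <= first_year) stop("last_year must exceed first_year", call. = FALSE)
  if (n_sites < 1L || cores_per_site < 1L) stop("need at least one site and core", call. = FALSE)
  ffun <- if (is.function(common_signal_fraction)) common_signal_fraction
          else function(year) rep(common_signal_fraction, length(year))
  fvals <- ffun(seq(first_year, last_year))
  if (any(fvals < 0) || any(fvals >= 1))
    stop("common_signal_fraction must lie in [0, 1) over the simulated span", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites), cores_per_site = as.integer(cores_per_site),
                 first_year = as.integer(first_year), last_year = as.integer(last_year),
                 age_trend = age_trend, common_signal_fraction = ffun,
                 site_noise_sd = site_noise_sd,
                 core_noise_sd = core_noise_sd %||% (1.5 * site_noise_sd),
                 group_effect = group_effect,
                 extreme_year_prob = extreme_year_prob,
                 stagger_fraction = stagger_fraction, seed = as.integer(seed)),
            class = "network_sim_config")
}

#' Generate a synthetic ring-width network with known ground truth
#'
#' Simulates every core of a [network_sim_config()] and returns both the
#' ring-width series and a `sim_truth` record (common signal, per-core
#' parameters, true extreme years, site groups) sufficient to score
#' parameter recovery downstream. Core start years are staggered so sample
#' depth grows toward the present. Widths are floored at 0.01 mm (the
#' `.rwl` precision unit); if more than 5% of all values need flooring the
#' configuration is rejected.
#'
#' @param config a [network_sim_config()].
#' @return a list with elements `series` (list of [ring_series()]) and
#'   `truth` (class `sim_truth`).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  set.seed(config$seed)
  years <- seq(config$first_year, config$last_year)
  nyr <- length(years)
  span <- nyr
  f <- config$common_signal_fraction(years)
  C <- stats::rnorm(nyr)
  extreme <- stats::runif(nyr) < config$extreme_year_prob
  C[extreme] <- C[extreme] + 3 * sample(c(-1, 1), sum(extreme), replace = TRUE)
  a_t <- if (config$site_noise_sd > 0) config$site_noise_sd * sqrt(f / (1 - f)) else 0.1 * sqrt(f)
  b_t <- config$group_effect * a_t
  G <- matrix(stats::rnorm(nyr * 2L), nyr, 2L)
  site_group <- rep_len(1:2, config$n_sites)
  tr <- config$age_trend
  series <- list()
  params <- list()
  n_clip <- 0L; n_vals <- 0L
  for (s in seq_len(config$n_sites)) {
    eta <- stats::rnorm(nyr)
    site_index <- 1 + a_t * C + b_t * G[, site_group[s]] + config$site_noise_sd * eta
    offsets <- sort(round(stats::runif(config$cores_per_site, 0, config$stagger_fraction * span)))
    offsets[1L] <- 0
    offsets <- pmin(offsets, span - 30L)  # every core keeps >= 30 years
    for (cc in seq_len(config$cores_per_site)) {
      i0 <- offsets[cc] + 1L
      idx <- site_index[i0:nyr] + config$core_noise_sd * stats::rnorm(nyr - i0 + 1L)
      age <- seq_len(nyr - i0 + 1L)
      growth <- tr[["a"]] * exp(-tr[["b"]] * age) + tr[["k"]]
      w <- growth * idx
      n_vals <- n_vals + length(w)
      n_clip <- n_clip + sum(w < 0.01)
      w <- pmax(w, 0.01)
      cid <- sprintf("s%02dc%02d", s, cc)
      series[[cid]] <- ring_series(cid, sprintf("site%02d", s), years[i0], w)
      params[[cid]] <- data.frame(core_id = cid, site_id = sprintf("site%02d", s),
                                  group = site_group[s], start_year = years[i0],
                                  stringsAsFactors = FALSE)
    }
  }
  if (n_clip > 0.05 * n_vals)
    stop(sprintf("width floor reached for %.1f%% of values; rejecting configuration",
                 100 * n_clip / n_vals), call. = FALSE)
  truth <- structure(list(
    years = years,
    common_signal = stats::setNames(a_t * C, years),
    signal_fraction = stats::setNames(f, years),
    signal_amplitude = stats::setNames(a_t, years),
    extreme_years = years[extreme],
    cores = do.call(rbind, params),
    site_group = stats::setNames(site_group, sprintf("site%02d", seq_len(config$n_sites))),
    site_noise_sd = config$site_noise_sd,
    core_noise_sd = config$core_noise_sd,
    group_effect = config$group_effect,
    clipped_fraction = n_clip / n_vals,
    seed = config$seed), class = "sim_truth")
  list(series = series, truth = truth)
}

#' Configuration for synthetic monthly climate
#'
#' Monthly climate is generated as a fixed seasonal climatology plus
#' piecewise-linear trends plus AR(1) anomalies; selected year-month cells
#' can be coupled to the common signal of a co-generated ring-width
#' network at a configured correlation.
#'
#' @param variables subset of `c("tmp", "tmx", "tmn", "pre")`.
#' @param first_year,last_year calendar span.
#' @param ar1 named lag-1 autocorrelation of monthly anomalies per
#'   variable, each in (-1, 1).
#' @param monthly_means named list of 12-vectors of monthly climatology
#'   per variable; defaults emulate a highland continental climate
#'   (cold dry winters, cool wet summers).
#' @param monthly_sds named list of 12-vectors (or scalars) of monthly
#'   anomaly SDs.
#' @param trend_segments list of `list(variable, from, to, slope)` entries;
#'   slope in units per year, applied cumulatively inside `[from, to]` and
#'   held constant after `to`.
#' @param coupling list of `list(variable, month, lag, rho)` entries: the
#'   anomaly of `variable` in calendar year `t - lag`, month `month`, is
#'   given correlation `rho` with the network common signal of growth
#'   year `t`.
#' @param seed integer seed.
#' @return a `climate_sim_config` list.
#' @export
climate_sim_config <- function(variables = c("tmp", "tmx", "tmn", "pre"),
                               first_year = 1951L, last_year = 2005L,
                               ar1 = c(tmp = 0.3, tmx = 0.3, tmn = 0.3, pre = 0.1),
                               monthly_means = NULL, monthly_sds = NULL,
                               trend_segments = list(),
                               coupling = list(),
                               seed = 1L) {
  variables <- match.arg(variables, c("tmp", "tmx", "tmn", "pre"), several.ok = TRUE)
  if (last_year <= first_year) stop("last_year must exceed first_year", call. = FALSE)
  if (any(abs(ar1[variables]) >= 1)) stop("ar1 coefficients must lie in (-1, 1)", call. = FALSE)
  tmp_clim <- c(-2.5, -0.5, 2.5, 6.0, 9.5, 12.5, 13.5, 13.0, 11.0, 7.0, 2.0, -1.5)
  def_means <- list(tmp = tmp_clim, tmx = tmp_clim + 8, tmn = tmp_clim - 7,
                    pre = c(5, 8, 15, 30, 60, 110, 140, 130, 90, 40, 10, 4))
  def_sds <- list(tmp = rep(1.0, 12), tmx = rep(1.1, 12), tmn = rep(1.3, 12),
                  pre = c(4, 5, 8, 12, 20, 35, 40, 38, 28, 15, 6, 3))
  structure(list(variables = variables, first_year = as.integer(first_year),
                 last_year = as.integer(last_year), ar1 = ar1,
                 monthly_means = monthly_means %||% def_means,
                 monthly_sds = monthly_sds %||% def_sds,
                 trend_segments = trend_segments, coupling = coupling,
                 seed = as.integer(seed)), class = "climate_sim_config")
}

#' Generate a synthetic monthly climate table
#'
#' @param config a [climate_sim_config()].
#' @param truth optional `sim_truth` from [generate_network()]; required
#'   when `config$coupling` is non-empty.
#' @return a data.frame with columns `year`, `month` and one column per
#'   configured variable (temperatures in degrees C, precipitation in mm).
#' @export
generate_climate <- function(config, truth = NULL) {
  stopifnot(inherits(config, "climate_sim_config"))
  if (length(config$coupling) && is.null(truth))
    stop("coupling requested without a co-generated network (truth missing)", call. = FALSE)
  set.seed(config$seed)
  years <- seq(config$first_year, config$last_year)
  nyr <- length(years)
  nm <- nyr * 12L
  out <- data.frame(year = rep(years, each = 12L), month = rep(1:12, nyr))
  for (v in config$variables) {
    mu <- rep(config$monthly_means[[v]], nyr)
    sdv <- rep_len(config$monthly_sds[[v]], 12L)
    sds <- rep(sdv, nyr)
    a <- config$ar1[[v]]
    innov <- stats::rnorm(nm, sd = sqrt(1 - a^2))
    z <- as.numeric(stats::filter(innov, a, method = "recursive"))  # unit-variance AR(1)
    ## couple named cells to the network common signal
    for (cp in config$coupling) {
      if (!identical(cp$variable, v)) next
      rho <- cp$rho
      Cs <- truth$common_signal
      Cstd <- (Cs - mean(Cs)) / stats::sd(Cs)
      gy <- as.integer(names(Cs))
      cy <- gy - (cp$lag %||% 0L)
      keep <- cy %in% years
      pos <- (match(cy[keep], years) - 1L) * 12L + cp$month
      z[pos] <- rho * Cstd[keep] + sqrt(1 - rho^2) * z[pos]
    }
    vals <- mu + sds * z
    ## piecewise-linear trends
    for (seg in config$trend_segments) {
      if (!identical(seg$variable, v)) next
      yr_all <- out$year
      add <- pmax(pmin(yr_all, seg$to) - seg$from, 0) * seg$slope
      vals <- vals + add
    }
    if (v == "pre") vals <- pmax(vals, 0)
    out[[v]] <- vals
  }
  class(out) <- c("climate_table", "data.frame")
  out
}

#' Write a simulated bundle to disk
#'
#' Writes one Tucson `.rwl` file per site, the climate table as
#' tab-separated text, and the ground truth as a flat key-value text file,
#' and returns a manifest of what was written.
#'
#' @param network result of [generate_network()].
#' @param climate result of [generate_climate()] (may be `NULL`).
#' @param truth the `sim_truth` to record (defaults to `network$truth`).
#' @param directory output directory, created if needed.
#' @return a data.frame manifest (file, kind) with the seed as an
#'   attribute.
#' @export
write_fixture_bundle <- function(network, climate, truth = network$truth, directory) {
  if (!length(network$series)) stop("empty network; nothing written", call. = FALSE)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  sites <- vapply(network$series, function(s) s$site_id, character(1))
  files <- character(); kinds <- character()
  for (sid in unique(sites)) {
    path <- file.path(directory, paste0(sid, ".rwl"))
    if (path %in% files) stop("overlapping filenames in bundle", call. = FALSE)
    write_rwl(network$series[sites == sid], path)
    files <- c(files, path); kinds <- c(kinds, "rwl")
  }
  if (!is.null(climate)) {
    path <- file.path(directory, "climate.tsv")
    utils::write.table(climate, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, path); kinds <- c(kinds, "climate")
  }
  if (!is.null(truth)) {
    path <- file.path(directory, "truth.tsv")
    kv <- c(sprintf("seed\t%d", truth$seed),
            sprintf("site_noise_sd\t%g", truth$site_noise_sd),
            sprintf("core_noise_sd\t%g", truth$core_noise_sd),
            sprintf("group_effect\t%g", truth$group_effect),
            sprintf("extreme_years\t%s", paste(truth$extreme_years, collapse = ",")),
            sprintf("common_signal.%s\t%.10g", names(truth$common_signal), truth$common_signal),
            sprintf("signal_fraction.%s\t%.10g", names(truth$signal_fraction), truth$signal_fraction))
    writeLines(kv, path)
    files <- c(files, path); kinds <- c(kinds, "truth")
  }
  manifest <- data.frame(file = files, kind = kinds, stringsAsFactors = FALSE)
  attr(manifest, "seed") <- if (!is.null(truth)) truth$seed else NA_integer_
  manifest_path <- file.path(directory, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' Simulate growth with a winter-temperature sensitivity threshold
#'
#' Generates annual (January temperature, previous November-December
#' temperature, growth index) triples in which the linear
#' temperature-growth coupling collapses below a threshold: the effective
#' January slope below `theta` is `slope_ratio` times the slope above it.
#' Used to test threshold recovery by the response-surface machinery.
#'
#' @param n_years number of years (default 55, a typical instrumental
#'   overlap).
#' @param theta threshold in degrees C.
#' @param slope_above growth index change per degree C above threshold.
#' @param slope_ratio ratio of below- to above-threshold slope.
#' @param novdec_slope growth response to the Nov-Dec predictor.
#' @param noise_sd SD of the growth noise.
#' @param seed integer seed.
#' @return a data.frame with columns `year`, `jan`, `novdec`, `growth` and
#'   attribute `theta`.
#' @export
simulate_threshold_growth <- function(n_years = 55L, theta = -7, slope_above = 0.12,
                                      slope_ratio = 0.2, novdec_slope = 0.04,
                                      noise_sd = 0.08, seed = 1L) {
  set.seed(seed)
  jan <- stats::runif(n_years, -11, -4)
  novdec <- -5.5 + 0.5 * (jan - mean(jan)) + stats::rnorm(n_years, sd = 1)
  eff <- ifelse(jan >= theta, jan - theta, slope_ratio * (jan - theta))
  growth <- 1 + slope_above * eff + novdec_slope * (novdec + 5.5) +
    stats::rnorm(n_years, sd = noise_sd)
  out <- data.frame(year = seq_len(n_years) + 1950L, jan = jan, novdec = novdec,
                    growth = growth)
  attr(out, "theta") <- theta
  out
}
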