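#' Fit a conservative growth curve to a ring-width series
#'
#' Tries, in order, a negative exponential `a * exp(-b * t) + k`
#' (`a > 0`, `b > 0`, `k >= 0`), a straight line with non-positive slope,
#' and a stiff smoothing spline whose frequency-response gain is 0.5 at a
#' period of `spline_fraction` times the mean segment length. A model is
#' admissible only if it converges, satisfies its constraints and yields
#' strictly positive fitted values; the first admissible model wins.
#'
#' @param series a [ring_series()].
#' @param strategy ordered subset of `c("negexp", "line", "spline")`.
#' @param spline_fraction fraction of the mean segment length at which the
#'   spline's 50% frequency cutoff is placed (default 0.67).
#' @param mean_segment_length mean segment length (years) of the site the
#'   series belongs to; defaults to the series' own length.
#' @return a `growth_curve_fit` with fields `model`, `parameters`,
#'   `fitted_values`.
#' @export
fit_growth_curve <- function(series, strategy = c("negexp", "line", "spline"),
                             spline_fraction = 0.67, mean_segment_length = NULL) {
  stopifnot(inherits(series, "ring_series"))
  y <- series$widths
  n <- length(y)
  if (n < 10L) stop("series too short to detrend (need >= 10 years)", call. = FALSE)
  tt <- seq_len(n)
  msl <- mean_segment_length %||% n
  strategy <- match.arg(strategy, c("negexp", "line", "spline"), several.ok = TRUE)
  make <- function(model, parameters, fitted) {
    structure(list(model = model, parameters = parameters,
                   fitted_values = as.numeric(fitted)), class = "growth_curve_fit")
  }
  for (model in strategy) {
    fit <- switch(model,
      negexp = {
        k0 <- max(min(y) * 0.5, 0)
        a0 <- max(mean(y[seq_len(max(3L, n %/% 10L))]) - k0, 1e-3)
        b0 <- 2 / n
        res <- tryCatch(
          minpack.lm::nlsLM(y ~ a * exp(-b * tt) + k,
                            start = list(a = a0, b = b0, k = k0),
                            lower = c(a = 1e-8, b = 1e-8, k = 0),
                            control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(res)) NULL else {
          p <- stats::coef(res)
          fv <- stats::fitted(res)
          # require a genuinely decaying curve, not a constant in disguise
          if (p[["a"]] > 1e-5 && p[["b"]] > 1e-5 && p[["k"]] >= 0 && all(fv > 0.01))
            make("negative_exponential", p, fv) else NULL
        }
      },
      line = {
        res <- stats::lm(y ~ tt)
        slope <- stats::coef(res)[[2]]
        fv <- stats::fitted(res)
        if (slope <= 1e-12 && all(fv > 0.01))
          make("straight_line", c(intercept = stats::coef(res)[[1]], slope = slope), fv)
        else NULL
      },
      spline = {
        p <- max(spline_fraction * msl, 4)
        fv <- whittaker_spline(y, p)
        if (all(fv > 0.01))
          make("smoothing_spline", c(cutoff_period = p, fraction = spline_fraction), fv)
        else NULL
      })
    if (!is.null(fit)) return(fit)
  }
  stop("no admissible growth model produced positive fitted values for core ",
       series$core_id, call. = FALSE)
}

## discrete cubic smoothing (Whittaker-type) smoother for annual data;
## lambda solved from a 50% frequency-response gain at period p:
## gain(f) = 1 / (1 + lambda (2 sin(pi f))^4)  =>  lambda = (2 sin(pi/p))^-4
whittaker_spline <- function(y, p) {
  n <- length(y)
  lambda <- 1 / (2 * sin(pi / p))^4
  D <- diff(diag(n), differences = 2L)
  as.numeric(solve(diag(n) + lambda * crossprod(D), y))
}

#' Detrend a ring-width series to a dimensionless index
#'
#' Indices are the ratio of raw widths to fitted growth values, which
#' preserves positivity and (for well-behaved input) a mean near 1.
#'
#' @param series a [ring_series()].
#' @param fit the matching `growth_curve_fit`.
#' @return an `index_series` (fields `core_id`, `site_id`, `first_year`,
#'   `values`).
#' @export
detrend_to_index <- function(series, fit) {
  stopifnot(inherits(series, "ring_series"), inherits(fit, "growth_curve_fit"))
  if (length(fit$fitted_values) != length(series$widths))
    stop("fit not aligned to series", call. = FALSE)
  if (any(fit$fitted_values <= 0.01))
    stop("fitted growth values at or below the 0.01 mm width floor; refusing to index",
         call. = FALSE)
  structure(list(core_id = series$core_id, site_id = series$site_id,
                 first_year = series$first_year,
                 values = series$widths / fit$fitted_values,
                 model = fit$model), class = "index_series")
}

#' Tukey biweight robust mean
#'
#' Iteratively reweighted location estimate with biweight weights
#' `w = (1 - u^2)^2` for `|u| < 1`, `u = (x - m) / (c * MAD)`, `c = 9`,
#' started at the median and iterated until `|dm| < 1e-6` or 50
#' iterations. With one value it returns that value; with two, their
#' arithmetic mean; with zero MAD, the median.
#'
#' @param values numeric vector, at least one value.
#' @return the robust location, a single number.
#' @export
biweight_mean <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("biweight_mean of empty input", call. = FALSE)
  if (n == 1L) return(values)
  if (n == 2L) return(mean(values))
  m <- stats::median(values)
  s <- stats::mad(values, center = m, constant = 1)
  if (s == 0) return(m)
  for (i in seq_len(50L)) {
    u <- (values - m) / (9 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * values) / sum(w)
    if (abs(m_new - m) < 1e-6) return(m_new)
    m <- m_new
  }
  m
}

#' Build a site chronology from index series
#'
#' Averages core indices year by year with the Tukey biweight, records
#' sample depth, and computes rbar (mean pairwise Pearson correlation over
#' common overlaps of at least `min_overlap` years), EPS, the SSS profile
#' and mean sensitivity.
#'
#' @param indices list of `index_series` for one site.
#' @param site_id site identifier; defaults to the first series' site.
#' @param min_overlap minimum shared years for a pair to enter rbar
#'   (default 30); shorter pairs are excluded and recorded.
#' @return a `chronology` object with fields `site_id`, `years`, `index`,
#'   `depth`, `rbar`, `eps`, `sss`, `mean_sensitivity`, `reliable_span`.
#' @export
build_chronology <- function(indices, site_id = NULL, min_overlap = 30L) {
  if (!length(indices)) stop("no index series supplied", call. = FALSE)
  site_id <- site_id %||% indices[[1]]$site_id
  yr_range <- range(unlist(lapply(indices, series_years)))
  years <- seq(yr_range[1], yr_range[2])
  mat <- matrix(NA_real_, length(years), length(indices),
                dimnames = list(years, vapply(indices, function(s) s$core_id, character(1))))
  for (j in seq_along(indices)) {
    s <- indices[[j]]
    mat[as.character(series_years(s)), j] <- s$values
  }
  depth <- rowSums(!is.na(mat))
  if (!any(depth >= 1)) stop("no year with at least one core", call. = FALSE)
  keep <- depth >= 1
  years <- years[keep]; mat <- mat[keep, , drop = FALSE]; depth <- depth[keep]
  index <- apply(mat, 1L, function(row) biweight_mean(row[!is.na(row)]))
  ## rbar over pairwise overlaps
  p <- ncol(mat)
  cors <- numeric(); excluded <- character()
  if (p >= 2L) {
    for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (sum(ok) >= min_overlap) {
        cors <- c(cors, stats::cor(mat[ok, i], mat[ok, j]))
      } else {
        excluded <- c(excluded, paste(colnames(mat)[c(i, j)], collapse = "/"))
      }
    }
  }
  rbar <- if (length(cors)) mean(cors) else NA_real_
  N <- p
  eps <- if (is.finite(rbar) && rbar > 0) N * rbar / (N * rbar + 1 - rbar) else NA_real_
  sss <- if (is.finite(rbar) && rbar > 0) sss_profile(rbar, depth, N)$sss else rep(NA_real_, length(depth))
  structure(list(site_id = site_id, years = years, index = as.numeric(index),
                 depth = as.integer(depth), rbar = rbar, eps = eps,
                 sss = as.numeric(sss),
                 mean_sensitivity = mean_sensitivity(as.numeric(index)),
                 reliable_span = NULL, n_cores = p,
                 excluded_pairs = excluded), class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("chronology %s: %d cores, %d-%d, rbar=%.3f, EPS=%.3f, MS=%.3f\n",
              x$site_id, x$n_cores, min(x$years), max(x$years),
              x$rbar, x$eps, x$mean_sensitivity))
  if (!is.null(x$reliable_span))
    cat(sprintf("  reliable span (SSS >= threshold): %d-%d\n",
                x$reliable_span[1], x$reliable_span[2]))
  invisible(x)
}

#' Subsample signal strength and EPS
#'
#' Wigley's subsample signal strength for per-year sample depth `n` given
#' the full replication `N` and the mean inter-series correlation `rbar`:
#' `SSS(t) = n (1 + (N - 1) rbar) / (N (1 + (n - 1) rbar))`. The expressed
#' population signal `EPS = N rbar / (N rbar + 1 - rbar)` is reported once.
#'
#' @param rbar mean inter-series correlation, in (0, 1].
#' @param depth integer vector of per-year sample depths, each in `1..N`.
#' @param N full number of series.
#' @return list with `sss` (per-year) and `eps` (scalar).
#' @export
sss_profile <- function(rbar, depth, N) {
  stop_if_not_scalar(rbar, "rbar")
  if (rbar <= 0) stop("rbar must be positive; SSS undefined for signal-free sites",
                      call. = FALSE)
  if (rbar > 1) stop("rbar cannot exceed 1", call. = FALSE)
  if (any(depth < 1) || any(depth > N)) stop("depth must lie in 1..N", call. = FALSE)
  sss <- depth * (1 + (N - 1) * rbar) / (N * (1 + (depth - 1) * rbar))
  eps <- N * rbar / (N * rbar + 1 - rbar)
  list(sss = sss, eps = eps)
}

#' Truncate a chronology where the SSS drops below a threshold
#'
#' The reliable span starts at the earliest year from which SSS stays at
#' or above `threshold` through the end of the record. Index values before
#' that year are dropped (set to `NA`); the depth history is retained.
#'
#' @param chronology a [build_chronology()] result.
#' @param threshold SSS threshold (default 0.85).
#' @return the chronology with `reliable_span` set.
#' @export
truncate_by_sss <- function(chronology, threshold = 0.85) {
  stopifnot(inherits(chronology, "chronology"))
  sss <- chronology$sss
  if (all(!is.finite(sss)))
    stop("SSS profile unavailable (rbar missing); cannot truncate", call. = FALSE)
  ok <- is.finite(sss) & sss >= threshold
  if (!any(ok))
    stop(sprintf("no year meets SSS >= %g (max SSS = %.3f)", threshold, max(sss, na.rm = TRUE)),
         call. = FALSE)
  ## earliest year from which ok holds continuously to the end
  bad <- which(!ok)
  start_idx <- if (length(bad)) max(bad) + 1L else 1L
  if (start_idx > length(sss))
    stop(sprintf("no year meets SSS >= %g continuously to the end (max SSS = %.3f)",
                 threshold, max(sss, na.rm = TRUE)), call. = FALSE)
  chronology$reliable_span <- c(chronology$years[start_idx], max(chronology$years))
  chronology$index[seq_len(start_idx - 1L)] <- NA_real_
  chronology
}

#' Mean sensitivity of an annual series
#'
#' The classic dendrochronological variability statistic: the mean
#' absolute scaled year-to-year difference
#' `MS = mean(|2 (x[t+1] - x[t]) / (x[t+1] + x[t])|)`.
#'
#' @param x numeric series of length >= 2.
#' @return a single number.
#' @export
mean_sensitivity <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("mean sensitivity needs at least 2 values", call. = FALSE)
  s <- x[-1] + x[-length(x)]
  if (any(s == 0)) stop("consecutive values sum to zero; mean sensitivity undefined",
                        call. = FALSE)
  mean(abs(2 * diff(x) / s))
}

#' Export a chronology as a delimited table
#'
#' @param chronology a `chronology`.
#' @param path optional output path (tab-separated); when `NULL` the table
#'   is only returned.
#' @return data.frame with columns year, index, depth, sss.
#' @export
chronology_table <- function(chronology, path = NULL) {
  stopifnot(inherits(chronology, "chronology"))
  out <- data.frame(year = chronology$years, index = chronology$index,
                    depth = chronology$depth, sss = chronology$sss)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}

#' Build all site chronologies from a directory of .rwl files
#'
#' Convenience wrapper: reads every `.rwl` file, detrends each core with
#' [fit_growth_curve()] (site mean segment length feeds the spline
#' cutoff), averages with the biweight and truncates by SSS.
#'
#' @param rwl_dir directory containing one `.rwl` file per site.
#' @param sss_threshold SSS truncation threshold; `NA` skips truncation.
#' @param spline_fraction passed to [fit_growth_curve()].
#' @return named list of `chronology` objects.
#' @export
build_site_chronologies <- function(rwl_dir, sss_threshold = 0.85, spline_fraction = 0.67) {
  files <- sort(list.files(rwl_dir, pattern = "\\.rwl$", full.names = TRUE))
  if (!length(files)) stop("no .rwl files in ", rwl_dir, call. = FALSE)
  out <- list()
  for (f in files) {
    cores <- read_rwl(f)
    msl <- mean(vapply(cores, function(s) length(s$widths), numeric(1)))
    idx <- lapply(cores, function(s) {
      detrend_to_index(s, fit_growth_curve(s, spline_fraction = spline_fraction,
                                           mean_segment_length = msl))
    })
    crn <- build_chronology(idx)
    if (is.finite(sss_threshold)) crn <- truncate_by_sss(crn, sss_threshold)
    out[[crn$site_id]] <- crn
  }
  out
}
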