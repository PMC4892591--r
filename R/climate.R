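## month labels of the 17-month dendroclimatic year:
## previous May ... previous December, current January ... current September
dendro_month_labels <- function() {
  c(paste0("p", month.abb[5:12]), month.abb[1:9])
}

#' Read a monthly climate table
#'
#' Delimited text with columns `year`, `month` and any of `tmp`, `tmx`,
#' `tmn`, `pre` (temperatures in degrees C, precipitation totals in mm).
#'
#' @param path file path (any whitespace/tab-delimited table with a
#'   header).
#' @return a `climate_table` data.frame.
#' @export
read_climate_table <- function(path) {
  x <- utils::read.table(path, header = TRUE)
  if (!all(c("year", "month") %in% names(x)))
    stop("climate table needs 'year' and 'month' columns", call. = FALSE)
  if (anyDuplicated(x[c("year", "month")]))
    stop("duplicate year-month rows in climate table", call. = FALSE)
  class(x) <- c("climate_table", "data.frame")
  x
}

#' Lay out one climate variable over the dendroclimatic year
#'
#' Builds the growth-year matrix with 17 columns: previous May through
#' previous December (months 5-12 of year `t - 1`) and current January
#' through current September (months 1-9 of year `t`). Growth years with
#' any missing month are dropped.
#'
#' @param climate a climate table (columns `year`, `month`, variables).
#' @param variable one of the variable columns.
#' @return numeric matrix, rows named by growth year, 17 columns named
#'   `pMay ... pDec, Jan ... Sep`, with the variable as attribute.
#' @export
build_dendro_matrix <- function(climate, variable) {
  if (!variable %in% names(climate))
    stop("variable '", variable, "' absent from climate table", call. = FALSE)
  key <- paste(climate$year, climate$month)
  val <- stats::setNames(climate[[variable]], key)
  years <- sort(unique(climate$year))
  gy <- years[years - 1 >= min(years)]  # growth year t needs year t-1
  labs <- dendro_month_labels()
  m <- matrix(NA_real_, length(gy), 17L, dimnames = list(gy, labs))
  for (i in seq_along(gy)) {
    t <- gy[i]
    m[i, ] <- val[c(paste(t - 1, 5:12), paste(t, 1:9))]
  }
  complete <- !apply(m, 1L, anyNA)
  m <- m[complete, , drop = FALSE]
  if (!nrow(m)) stop("no complete dendroclimatic year could be formed", call. = FALSE)
  attr(m, "variable") <- variable
  m
}

#' Seasonal composite over contiguous dendroclimatic months
#'
#' Unweighted mean of named monthly columns, which must form a contiguous
#' run within the 17-month dendroclimatic year (e.g. `pNov, pDec, Jan`).
#'
#' @param matrix a [build_dendro_matrix()] result.
#' @param months character vector of column labels.
#' @return numeric vector named by growth year.
#' @export
seasonal_mean <- function(matrix, months) {
  if (!length(months)) stop("empty month set", call. = FALSE)
  labs <- dendro_month_labels()
  pos <- match(months, labs)
  if (anyNA(pos)) stop("unknown month label(s): ", paste(months[is.na(pos)], collapse = ", "),
                       call. = FALSE)
  if (length(pos) > 1L && !all(diff(sort(pos)) == 1L))
    stop("months must be contiguous within the dendroclimatic year", call. = FALSE)
  rowMeans(matrix[, months, drop = FALSE])
}

#' Climate-growth correlation function
#'
#' Pearson correlations between an annual growth series and each of the
#' 17 dendroclimatic months, with two-tailed critical correlations at the
#' 95% and 99% levels from the t distribution
#' (`r_crit = t / sqrt(df + t^2)`, `df = n - 2`). Optional seasonal
#' composites are appended.
#'
#' @param growth numeric growth series named by year.
#' @param matrix a [build_dendro_matrix()] result.
#' @param seasons optional named list of month-label vectors, e.g.
#'   `list(NovJan = c("pNov", "pDec", "Jan"))`.
#' @return a `correlation_function`: data.frame (`predictor`, `r`) plus
#'   attributes `n`, `r_crit95`, `r_crit99`.
#' @export
correlation_function <- function(growth, matrix, seasons = NULL) {
  yrs <- intersect(names(growth), rownames(matrix))
  n <- length(yrs)
  if (n < 20L) stop("fewer than 20 overlapping years", call. = FALSE)
  g <- growth[yrs]
  r <- apply(matrix[yrs, , drop = FALSE], 2L, stats::cor, y = g)
  preds <- colnames(matrix)
  if (!is.null(seasons)) {
    for (nm in names(seasons)) {
      sm <- seasonal_mean(matrix, seasons[[nm]])
      r <- c(r, stats::cor(sm[yrs], g))
      preds <- c(preds, nm)
    }
  }
  crit <- function(alpha) {
    tc <- stats::qt(1 - alpha / 2, df = n - 2)
    tc / sqrt(n - 2 + tc^2)
  }
  out <- data.frame(predictor = preds, r = as.numeric(r), stringsAsFactors = FALSE)
  structure(out, n = n, r_crit95 = crit(0.05), r_crit99 = crit(0.01),
            class = c("correlation_function", "data.frame"))
}

#' Moving correlation function
#'
#' Pearson correlation in a fixed sliding window, assigned to the center
#' year of the window (for even windows, the lower-middle year), with a
#' 95% confidence band from the Fisher z transform:
#' `tanh(atanh(r) +/- 1.96 / sqrt(window - 3))`.
#'
#' @param growth,predictor numeric annual series named by year.
#' @param window window length in years (default 30).
#' @return data.frame `center_year`, `r`, `lower`, `upper` with the
#'   window length as attribute.
#' @export
moving_correlation <- function(growth, predictor, window = 30L) {
  yrs <- intersect(names(growth), names(predictor))
  yrs <- as.character(sort(as.integer(yrs)))
  n <- length(yrs)
  if (n < window) stop("overlap shorter than the window", call. = FALSE)
  g <- growth[yrs]; p <- predictor[yrs]
  r <- rolling_cor(as.numeric(g), as.numeric(p), window)
  centers <- as.integer(yrs)[seq_len(n - window + 1L)] + (window - 1L) %/% 2L
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  half <- 1.96 / sqrt(window - 3)
  out <- data.frame(center_year = centers, r = r,
                    lower = tanh(z - half), upper = tanh(z + half))
  attr(out, "window") <- window
  out
}

## lag-1 autocorrelation
ar1_coef <- function(x) {
  x <- x - mean(x)
  sum(x[-1] * x[-length(x)]) / sum(x^2)
}

#' Monte Carlo stability test for a moving correlation
#'
#' Tests whether the variability of a moving-correlation track exceeds
#' what stationary stochastic series with the same persistence and
#' overall cross-correlation would produce (the Gershunov-style
#' construction). The observed statistic is the variance of the moving
#' correlations; the null draws `M` surrogate pairs of bivariate AR(1)
#' processes whose lag-1 autocorrelations are fitted from the inputs and
#' whose innovation correlation reproduces the observed full-period
#' correlation; `p = (1 + #(null >= observed)) / (M + 1)`.
#'
#' @param growth,predictor numeric annual series named by year.
#' @param window moving-correlation window (default 30).
#' @param M number of surrogate pairs (default 1000).
#' @param seed integer seed.
#' @return a `stability_test` list: `statistic`, `null`, `p_value`,
#'   `window`, `M`, `seed`, `ar1`, `r_full`.
#' @export
stability_test <- function(growth, predictor, window = 30L, M = 1000L, seed = 1L) {
  yrs <- intersect(names(growth), names(predictor))
  yrs <- as.character(sort(as.integer(yrs)))
  n <- length(yrs)
  if (n < window + 10L) stop("overlap must exceed the window by at least 10 years",
                             call. = FALSE)
  g <- as.numeric(growth[yrs]); q <- as.numeric(predictor[yrs])
  track <- rolling_cor(g, q, window)
  observed <- stats::var(track)
  a <- ar1_coef(g); b <- ar1_coef(q)
  if (abs(a) >= 1 || abs(b) >= 1) stop("fitted AR(1) coefficient outside (-1, 1)",
                                       call. = FALSE)
  r_full <- stats::cor(g, q)
  rho <- r_full * (1 - a * b) / sqrt((1 - a^2) * (1 - b^2))
  rho <- pmin(pmax(rho, -1), 1)
  set.seed(seed)
  z1 <- matrix(stats::rnorm(n * M), n, M)
  z2 <- matrix(stats::rnorm(n * M), n, M)
  e1 <- z1
  e2 <- rho * z1 + sqrt(1 - rho^2) * z2
  x <- e1; y <- e2
  x[1L, ] <- e1[1L, ] / sqrt(1 - a^2)   # stationary start
  y[1L, ] <- e2[1L, ] / sqrt(1 - b^2)
  for (t in 2:n) {
    x[t, ] <- a * x[t - 1L, ] + e1[t, ]
    y[t, ] <- b * y[t - 1L, ] + e2[t, ]
  }
  null <- vapply(seq_len(M), function(j) stats::var(rolling_cor(x[, j], y[, j], window)),
                 numeric(1))
  p <- (1 + sum(null >= observed - 1e-15)) / (M + 1)  # tolerance for exact ties
  structure(list(statistic = observed, null = null, p_value = p, window = window,
                 M = M, seed = seed, ar1 = c(growth = a, predictor = b),
                 r_full = r_full), class = "stability_test")
}

#' @export
print.stability_test <- function(x, ...) {
  cat(sprintf("moving-correlation stability test: var(r) = %.5f, M = %d, p = %.4f\n",
              x$statistic, x$M, x$p_value))
  cat(sprintf("  AR(1): growth %.3f, predictor %.3f; full-period r = %.3f\n",
              x$ar1[1], x$ar1[2], x$r_full))
  invisible(x)
}
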