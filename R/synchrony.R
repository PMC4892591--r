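#' Assemble a year-by-site matrix of chronology indices
#'
#' @param chronologies list of `chronology` objects (or an already-built
#'   numeric matrix with years as rownames, returned unchanged).
#' @param period integer vector `c(first, last)`; every chronology must
#'   cover it with non-missing indices.
#' @return numeric matrix, rows = years, columns = sites.
#' @export
chronology_matrix <- function(chronologies, period = NULL) {
  if (is.matrix(chronologies)) {
    m <- chronologies
    if (!is.null(period)) {
      yrs <- as.character(seq(period[1], period[2]))
      if (!all(yrs %in% rownames(m))) stop("matrix does not cover the period", call. = FALSE)
      m <- m[yrs, , drop = FALSE]
    }
    return(m)
  }
  if (is.null(period)) {
    starts <- vapply(chronologies, function(cr) {
      ok <- which(is.finite(cr$index)); cr$years[min(ok)]
    }, numeric(1))
    ends <- vapply(chronologies, function(cr) max(cr$years), numeric(1))
    period <- c(max(starts), min(ends))
  }
  yrs <- seq(period[1], period[2])
  m <- matrix(NA_real_, length(yrs), length(chronologies),
              dimnames = list(yrs, vapply(chronologies, function(cr) cr$site_id, character(1))))
  for (j in seq_along(chronologies)) {
    cr <- chronologies[[j]]
    pos <- match(yrs, cr$years)
    if (anyNA(pos) || anyNA(cr$index[pos]))
      stop("chronology ", cr$site_id, " does not cover ", period[1], "-", period[2],
           call. = FALSE)
    m[, j] <- cr$index[pos]
  }
  m
}

#' Principal component analysis on the correlation matrix
#'
#' Eigendecomposition of the Pearson correlation matrix of the chronology
#' network over a common period. Variance shares are `100 * lambda_i / p`;
#' loadings are eigenvectors scaled by `sqrt(lambda)`; every component is
#' oriented so its mean loading is positive (ties leave the sign as
#' computed).
#'
#' @param chronologies list of `chronology` objects or a year-by-site
#'   matrix.
#' @param period `c(first, last)` analysis period.
#' @return a `pca_result`: `eigenvalues`, `shares` (percent), `loadings`,
#'   `scores` (standardized-variable scores, named by year), `period`.
#' @export
correlation_pca <- function(chronologies, period = NULL) {
  m <- chronology_matrix(chronologies, period)
  p <- ncol(m)
  if (p < 2L) stop("need at least two chronologies", call. = FALSE)
  R <- stats::cor(m)
  e <- eigen(R, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  vec <- e$vectors
  for (j in seq_len(p)) {
    mj <- mean(vec[, j])
    if (mj < 0) vec[, j] <- -vec[, j]
  }
  loadings <- sweep(vec, 2L, sqrt(lambda), `*`)
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(p)))
  scores <- scale(m) %*% vec
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(p)))
  yrs <- suppressWarnings(as.integer(rownames(m)))
  structure(list(eigenvalues = lambda, shares = 100 * lambda / p,
                 loadings = loadings, scores = scores,
                 period = if (length(yrs) && all(is.finite(yrs))) range(yrs) else NULL),
            class = "pca_result")
}

#' Running-window PC1 variance share
#'
#' Windows of `window` years advance by `step` years from the period
#' start; the last window that fits is extended (anchored) to the period
#' end, so it may be longer than `window` (a 50-year window lagged by 10
#' over 1825-2005 ends with the 51-year window labeled "1955-2005").
#' Chronologies are standardized within each window (the PCA is on the
#' window's correlation matrix).
#'
#' @param chronologies list of `chronology` objects or a year-by-site
#'   matrix.
#' @param window window length in years (default 50).
#' @param step lag between window starts (default 10).
#' @param period `c(first, last)`.
#' @return data.frame with columns `start`, `end`, `label`, `pc1_share`.
#' @export
running_pc1_share <- function(chronologies, window = 50L, step = 10L, period = NULL) {
  m <- chronology_matrix(chronologies, period)
  yrs <- as.integer(rownames(m))
  first <- min(yrs); last <- max(yrs)
  if (window > length(yrs)) stop("window longer than the analysis period", call. = FALSE)
  starts <- seq(first, last - window + 1L, by = step)
  ends <- starts + window - 1L
  ends[length(ends)] <- last  # anchor the final window to the period end
  share <- vapply(seq_along(starts), function(i) {
    w <- m[as.character(seq(starts[i], ends[i])), , drop = FALSE]
    correlation_pca(w)$shares[1L]
  }, numeric(1))
  data.frame(start = starts, end = ends,
             label = sprintf("%d-%d", starts, ends),
             pc1_share = share, stringsAsFactors = FALSE)
}

#' Flag extreme wide and narrow rings
#'
#' A year is flagged `wide` when the index exceeds `mean + k * SD` and
#' `narrow` when it falls below `mean - k * SD`, with mean and SD taken
#' over the full analysis period (one pair of limits per chronology).
#'
#' @param chronology a `chronology` or a numeric vector named by year.
#' @param period optional `c(first, last)` restriction.
#' @param k SD multiple (default 1.5).
#' @return character vector (`"wide"`, `"narrow"`, `"none"`) named by
#'   year.
#' @export
flag_extremes <- function(chronology, period = NULL, k = 1.5) {
  if (inherits(chronology, "chronology")) {
    x <- stats::setNames(chronology$index, chronology$years)
  } else x <- chronology
  x <- x[is.finite(x)]
  if (!is.null(period)) {
    yrs <- as.integer(names(x))
    x <- x[yrs >= period[1] & yrs <= period[2]]
  }
  if (length(x) < 10L) stop("need at least 10 years to flag extremes", call. = FALSE)
  mu <- mean(x); s <- stats::sd(x)
  if (s == 0) stop("zero standard deviation; extremes undefined", call. = FALSE)
  flags <- rep("none", length(x))
  flags[x > mu + k * s] <- "wide"
  flags[x < mu - k * s] <- "narrow"
  stats::setNames(flags, names(x))
}

#' Network-wide extreme ring frequency
#'
#' Counts, per year, how many chronologies are flagged wide and narrow.
#'
#' @param flag_list list of [flag_extremes()] results on a shared year
#'   axis.
#' @return data.frame with columns `year`, `wide`, `narrow`.
#' @export
extreme_frequency <- function(flag_list) {
  if (!length(flag_list)) stop("no flags supplied", call. = FALSE)
  years <- sort(unique(unlist(lapply(flag_list, names))))
  wide <- narrow <- integer(length(years))
  for (fl in flag_list) {
    pos <- match(names(fl), years)
    wide[pos] <- wide[pos] + (fl == "wide")
    narrow[pos] <- narrow[pos] + (fl == "narrow")
  }
  data.frame(year = as.integer(years), wide = wide, narrow = narrow)
}
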