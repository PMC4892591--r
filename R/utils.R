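# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## derive a reproducible child seed from a master seed; stays below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %% 2147483629)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

## rolling Pearson correlation via cumulative sums; x, y equal-length vectors
rolling_cor <- function(x, y, window) {
  n <- length(x)
  if (n < window) stop("series shorter than window", call. = FALSE)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  idx <- window:n
  sx <- cx[idx] - c(0, cx)[idx - window + 1L]
  sy <- cy[idx] - c(0, cy)[idx - window + 1L]
  sxx <- cxx[idx] - c(0, cxx)[idx - window + 1L]
  syy <- cyy[idx] - c(0, cyy)[idx - window + 1L]
  sxy <- cxy[idx] - c(0, cxy)[idx - window + 1L]
  num <- window * sxy - sx * sy
  den <- sqrt(pmax(window * sxx - sx^2, 0)) * sqrt(pmax(window * syy - sy^2, 0))
  r <- ifelse(den > 0, num / den, NA_real_)
  pmin(pmax(r, -1), 1)
}

## years covered by a per-core series object
series_years <- function(x) seq(x$first_year, length.out = length(x$widths %||% x$values))
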