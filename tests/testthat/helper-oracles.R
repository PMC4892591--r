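# shared fixtures and independent reference implementations

## independent biweight reference: literal textbook iteration, coded
## differently from the package (explicit loops, median/MAD from scratch)
ref_biweight <- function(x, c_tune = 9, tol = 1e-9, max_iter = 200) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) med <- mean(sort(x)[length(x) / 2 + 0:1])
  adev <- abs(x - med)
  mad <- sort(adev)[ceiling(length(adev) / 2)]
  if (length(adev) %% 2 == 0) mad <- mean(sort(adev)[length(adev) / 2 + 0:1])
  if (mad == 0) return(med)
  m <- med
  for (it in seq_len(max_iter)) {
    num <- 0; den <- 0
    for (xi in x) {
      u <- (xi - m) / (c_tune * mad)
      if (abs(u) < 1) {
        w <- (1 - u^2)^2
        num <- num + w * xi
        den <- den + w
      }
    }
    m_new <- if (den > 0) num / den else m
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

## exhaustive best 2-partition of the rows of X by the k-means objective
best_2partition <- function(X) {
  p <- nrow(X)
  best <- NULL
  for (code in 1:(2^(p - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(code))[1:(p - 1)] + 1L)
    if (length(unique(lab)) < 2L) next
    sse <- sum(vapply(1:2, function(g) {
      Y <- X[lab == g, , drop = FALSE]
      sum(sweep(Y, 2, colMeans(Y))^2)
    }, numeric(1)))
    if (is.null(best) || sse < best$sse) best <- list(sse = sse, lab = lab)
  }
  best$lab
}

## stationary bivariate AR(1) pair with innovation correlation rho
sim_ar1_pair <- function(n, a = 0.4, b = 0.4, rho = 0.5, seed = 1) {
  set.seed(seed)
  e1 <- rnorm(n)
  e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
  x <- as.numeric(stats::filter(e1, a, method = "recursive"))
  y <- as.numeric(stats::filter(e2, b, method = "recursive"))
  list(x = stats::setNames(x, seq_len(n)), y = stats::setNames(y, seq_len(n)))
}

## build site chronologies straight from a generated network
chronologies_from_network <- function(net, truncate = TRUE) {
  sites <- split(net$series, vapply(net$series, function(s) s$site_id, character(1)))
  lapply(sites, function(cores) {
    msl <- mean(vapply(cores, function(s) length(s$widths), numeric(1)))
    idx <- lapply(cores, function(s)
      detrend_to_index(s, fit_growth_curve(s, mean_segment_length = msl)))
    crn <- build_chronology(idx)
    if (truncate) crn <- truncate_by_sss(crn) else crn
  })
}

## one synthetic end-to-end demonstration run, cached across test files
.demo_cache <- new.env(parent = emptyenv())
demo_report <- function() {
  if (is.null(.demo_cache$report))
    .demo_cache$report <- run_synthetic_demo(seed = 1L, mcf_M = 300L)
  .demo_cache$report
}
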