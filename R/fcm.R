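#' Extract site-by-year interval matrix from chronologies
#'
#' Rows are sites, columns the years of one inclusive interval (e.g. a
#' 16-year cold or warm window); entries are chronology index values.
#'
#' @param chronologies list of `chronology` objects.
#' @param years inclusive `c(first, last)` year range.
#' @return numeric matrix, sites x years.
#' @export
extract_interval_matrix <- function(chronologies, years) {
  yrs <- seq(years[1], years[2])
  p <- length(chronologies)
  m <- matrix(NA_real_, p, length(yrs),
              dimnames = list(vapply(chronologies, function(cr) cr$site_id, character(1)),
                              yrs))
  for (i in seq_len(p)) {
    cr <- chronologies[[i]]
    pos <- match(yrs, cr$years)
    if (anyNA(pos) || anyNA(cr$index[pos]))
      stop("site ", cr$site_id, " does not cover ", years[1], "-", years[2], call. = FALSE)
    m[i, ] <- cr$index[pos]
  }
  m
}

#' Fuzzy C-means clustering of site response vectors
#'
#' Standard alternating optimization of the fuzzy objective
#' `J = sum_ij u_ij^m ||x_i - c_j||^2` with Euclidean distance:
#' `c_j = sum_i u_ij^m x_i / sum_i u_ij^m` and
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2 / (m - 1))`. A site exactly on a
#' centroid receives membership 1 there. The best of `restarts` seeded
#' random initializations (by final `J`) is returned, with clusters
#' ordered by descending fuzzy cardinality. Rows are z-scored (mean 0,
#' SD 1) before clustering when `scale_rows = TRUE`.
#'
#' @param X numeric matrix, objects in rows.
#' @param k number of clusters (default 2).
#' @param m fuzzifier, > 1 (default 2).
#' @param tol convergence tolerance on the maximum membership change.
#' @param max_iter maximum iterations per start.
#' @param restarts number of seeded initializations (default 10).
#' @param seed integer seed.
#' @param scale_rows z-score each row before clustering (default TRUE).
#' @return an `fcm_result`: `memberships` (rows sum to 1), `centroids`,
#'   `objective`, `objective_trace` (non-increasing), `cardinalities`,
#'   `centroid_distance`, `pseudo_F`, `hard_labels`, `iterations`,
#'   `restarts`, `seed`.
#' @export
fcm <- function(X, k = 2L, m = 2.0, tol = 1e-5, max_iter = 300L, restarts = 10L,
                seed = 1L, scale_rows = TRUE) {
  X <- as.matrix(X)
  p <- nrow(X)
  if (p <= k) stop("need more objects than clusters", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  if (scale_rows) {
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0)) stop("constant row(s): ", paste(rownames(X)[sds == 0], collapse = ", "),
                            call. = FALSE)
    X <- t(scale(t(X)))
  }
  if (all(stats::dist(X) < 1e-12)) stop("degenerate input: all rows identical", call. = FALSE)
  memberships_from <- function(centroids) {
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centroids) +
      outer(rep(1, p), rowSums(centroids^2))
    d2 <- pmax(d2, 0)
    u <- matrix(0, p, k)
    zero <- d2 < 1e-24
    for (i in seq_len(p)) {
      if (any(zero[i, ])) {
        u[i, which(zero[i, ])[1L]] <- 1
      } else {
        ## scale by the row minimum so small fuzzifiers cannot overflow
        inv <- (d2[i, ] / min(d2[i, ]))^(-1 / (m - 1))
        u[i, ] <- inv / sum(inv)
      }
    }
    list(u = u, d2 = d2)
  }
  best <- NULL
  for (rs in seq_len(restarts)) {
    set.seed(derive_seed(seed, rs))
    ## initialize centroids at k distinct data rows
    centroids <- X[sample(p, k), , drop = FALSE]
    u <- memberships_from(centroids)$u
    trace <- numeric()
    iter <- 0L
    repeat {
      iter <- iter + 1L
      um <- u^m
      centroids <- (t(um) %*% X) / colSums(um)
      upd <- memberships_from(centroids)
      u_new <- upd$u
      trace <- c(trace, sum(u_new^m * upd$d2))
      delta <- max(abs(u_new - u))
      u <- u_new
      if (delta < tol || iter >= max_iter) break
    }
    if (any(diff(trace) > 1e-8 * max(trace[1], 1)))
      stop("fuzzy objective increased across iterations; numerical failure", call. = FALSE)
    J <- trace[length(trace)]
    if (is.null(best) || J < best$J)
      best <- list(u = u, centroids = centroids, J = J, trace = trace, iter = iter)
  }
  u <- best$u; centroids <- best$centroids
  card <- colSums(u)
  ord <- order(card, decreasing = TRUE)
  u <- u[, ord, drop = FALSE]; centroids <- centroids[ord, , drop = FALSE]
  card <- card[ord]
  dimnames(u) <- list(rownames(X), paste0("cluster", seq_len(k)))
  rownames(centroids) <- paste0("cluster", seq_len(k))
  res <- structure(list(memberships = u, centroids = centroids, fuzzifier = m,
                        objective = best$J, objective_trace = best$trace,
                        cardinalities = card,
                        centroid_distance = if (k == 2L)
                          sqrt(sum((centroids[1L, ] - centroids[2L, ])^2)) else
                          as.matrix(stats::dist(centroids)),
                        hard_labels = stats::setNames(max.col(u), rownames(X)),
                        iterations = best$iter, restarts = restarts, seed = seed,
                        scaled = scale_rows, data = X), class = "fcm_result")
  res$pseudo_F <- pseudo_f(X, res)
  res
}

#' Pseudo-F partition quality statistic
#'
#' Fuzzy Calinski-Harabasz ratio of membership-weighted between-cluster
#' to within-cluster dispersion:
#' `[sum_ij u_ij^m ||c_j - xbar||^2 / (k - 1)] / [sum_ij u_ij^m ||x_i - c_j||^2 / (p - k)]`.
#' Zero within-cluster dispersion yields `+Inf` with attribute
#' `degenerate = TRUE`.
#'
#' @param X the (row-scaled, if the fit scaled) data matrix; when `NULL`
#'   the matrix stored in `result` is used.
#' @param result an `fcm_result`.
#' @return a single number (possibly `Inf`).
#' @export
pseudo_f <- function(X = NULL, result) {
  stopifnot(inherits(result, "fcm_result"))
  X <- if (is.null(X)) result$data else as.matrix(X)
  u <- result$memberships
  um <- u^result$fuzzifier
  k <- ncol(u); p <- nrow(X)
  xbar <- colMeans(X)
  between <- sum(colSums(um) * rowSums(sweep(result$centroids, 2L, xbar)^2))
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(result$centroids) +
    outer(rep(1, p), rowSums(result$centroids^2))
  within <- sum(um * pmax(d2, 0))
  if (within <= .Machine$double.eps * between) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (between / (k - 1)) / (within / (p - k))
}

#' Count years with significant between-cluster differences
#'
#' Hard-assigns each site to its maximum-membership cluster, then runs a
#' Welch two-sample t-test per year (column) between the two groups and
#' counts years with `p < alpha`.
#'
#' @param X sites-by-years matrix (the clustering input, unscaled or
#'   scaled - the test is per-column on what is supplied).
#' @param result an `fcm_result` with `k = 2`.
#' @param alpha significance level (default 0.05).
#' @return integer count of significant years.
#' @export
cluster_contrast_years <- function(X, result, alpha = 0.05) {
  stopifnot(inherits(result, "fcm_result"))
  X <- as.matrix(X)
  lab <- result$hard_labels
  g1 <- X[lab == 1L, , drop = FALSE]
  g2 <- X[lab == 2L, , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g2) < 2L)
    stop("a cluster has fewer than 2 members; year-wise test undefined", call. = FALSE)
  pv <- vapply(seq_len(ncol(X)), function(j)
    stats::t.test(g1[, j], g2[, j])$p.value, numeric(1))
  sum(pv < alpha)
}

#' Compare cold- and warm-interval partitions
#'
#' Builds the summary record for two fitted intervals: centroid distance,
#' fuzzy cardinalities, pseudo-F and the count of significantly different
#' years, plus the warm-minus-cold differences.
#'
#' @param cold,warm `fcm_result`s fitted on the same site set.
#' @param cold_X,warm_X the interval matrices used for the year-wise
#'   contrast test; when `NULL`, the (scaled) matrices stored in the
#'   results are used.
#' @return data.frame with rows `cold`, `warm`, `warm_minus_cold`.
#' @export
partition_summary <- function(cold, warm, cold_X = NULL, warm_X = NULL) {
  stopifnot(inherits(cold, "fcm_result"), inherits(warm, "fcm_result"))
  if (!identical(rownames(cold$memberships), rownames(warm$memberships)))
    stop("cold and warm partitions cover different site sets", call. = FALSE)
  row_of <- function(res, X) {
    nsig <- tryCatch(cluster_contrast_years(if (is.null(X)) res$data else X, res),
                     error = function(e) NA_integer_)
    c(cluster_distance = unname(res$centroid_distance),
      group1 = unname(res$cardinalities[1L]), group2 = unname(res$cardinalities[2L]),
      pseudo_F = unname(res$pseudo_F), n_significant_years = nsig)
  }
  a <- row_of(cold, cold_X); b <- row_of(warm, warm_X)
  out <- rbind(cold = a, warm = b, warm_minus_cold = b - a)
  as.data.frame(out)
}
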