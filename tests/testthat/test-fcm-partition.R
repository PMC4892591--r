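two_clouds <- function(n_per = 4L, sep = 6, d = 3L, seed = 1L, jitter = 0.3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, 0, jitter), n_per),
             matrix(rnorm(n_per * d, sep, jitter), n_per))
  rownames(X) <- paste0("o", seq_len(2 * n_per))
  X
}

test_that("interval matrices are 16 columns of covered index years", {
  crn <- structure(list(site_id = "s1", years = 1950:2005,
                        index = seq(0.8, 1.2, length.out = 56),
                        depth = rep(3L, 56), rbar = 0.4, eps = NA_real_,
                        sss = rep(0.9, 56), mean_sensitivity = 0.1,
                        reliable_span = c(1950L, 2005L), n_cores = 3L),
                   class = "chronology")
  m <- extract_interval_matrix(list(crn), c(1965, 1980))
  expect_equal(dim(m), c(1L, 16L))
  expect_equal(unname(m[1, "1965"]), crn$index[crn$years == 1965])
  expect_error(extract_interval_matrix(list(crn), c(1940, 1955)), "s1")
})

test_that("well-separated clouds give crisp memberships that sum to one", {
  X <- two_clouds(seed = 2)
  res <- fcm(X, k = 2, seed = 3, scale_rows = FALSE)
  expect_equal(unname(rowSums(res$memberships)), rep(1, 8), tolerance = 1e-9)
  expect_equal(sum(res$cardinalities), 8, tolerance = 1e-9)
  expect_true(all(apply(res$memberships, 1, max) > 0.95))
  expect_equal(as.integer(sort(table(res$hard_labels))), c(4L, 4L))
  ## construction recovered
  expect_equal(length(unique(res$hard_labels[1:4])), 1L)
  expect_equal(length(unique(res$hard_labels[5:8])), 1L)
  ## objective trace never increases
  expect_true(all(diff(res$objective_trace) <= 1e-8))
})

test_that("a point equidistant from a symmetric 2-cloud split is half-half", {
  X <- rbind(matrix(c(-4, 0, -4.2, 0.2, -3.8, -0.2), 3, byrow = TRUE),
             matrix(c(4, 0, 4.2, -0.2, 3.8, 0.2), 3, byrow = TRUE),
             c(0, 0))
  rownames(X) <- paste0("o", 1:7)
  res <- fcm(X, k = 2, seed = 4, scale_rows = FALSE)
  expect_equal(unname(res$memberships[7, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("near-crisp FCM agrees with exhaustive k-means enumeration", {
  for (i in 1:5) {
    set.seed(i)
    p <- sample(6:8, 1)
    X <- matrix(rnorm(p * 3), p) + rbinom(p, 1, 0.5) * 1.5
    rownames(X) <- paste0("o", seq_len(p))
    lab <- fcm(X, k = 2, m = 1.05, seed = i, scale_rows = FALSE)$hard_labels
    ref <- best_2partition(X)
    expect_true(all(lab == ref) || all(lab == 3L - ref))
  }
})

test_that("fcm matches the e1071 reference on separated data", {
  skip_if_not_installed("e1071")
  X <- two_clouds(seed = 5)
  mine <- fcm(X, k = 2, m = 2, seed = 6, scale_rows = FALSE)
  ref <- e1071::cmeans(X, centers = mine$centroids, m = 2, iter.max = 300)
  expect_equal(unname(mine$memberships), unname(ref$membership), tolerance = 1e-3)
  expect_equal(unname(mine$centroids), unname(ref$centers), tolerance = 1e-3)
})

test_that("fcm is invariant to row order and per-row affine transforms", {
  set.seed(7)
  X <- matrix(rnorm(6 * 16), 6) + c(0, 0, 0, 2, 2, 2)
  rownames(X) <- paste0("s", 1:6)
  res <- fcm(X, seed = 8)
  perm <- c(4, 1, 6, 2, 5, 3)
  res_p <- fcm(X[perm, ], seed = 8)
  expect_equal(res_p$memberships[rownames(X), ], res$memberships, tolerance = 1e-4)
  ## after row z-scoring an affine change of one site's indices is absorbed
  X2 <- X; X2[3, ] <- 5 * X2[3, ] - 2
  res_a <- fcm(X2, seed = 8)
  expect_equal(res_a$memberships, res$memberships, tolerance = 1e-9)
  ## degenerate inputs are refused
  expect_error(fcm(matrix(1:16, 4, 16, byrow = TRUE,
                          dimnames = list(paste0("s", 1:4), NULL))),
               "identical|constant")
  expect_error(fcm(X[1:2, ], k = 2), "more objects")
  expect_error(fcm(X, m = 1), "exceed 1")
})

test_that("pseudo-F rises with separation and flags point masses", {
  mean_pf <- vapply(c(0, 1.5, 3, 6), function(sep) {
    mean(vapply(1:20, function(i) {
      X <- two_clouds(sep = sep, jitter = 1, seed = 100 * sep + i)
      fcm(X, seed = i, scale_rows = FALSE)$pseudo_F
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_pf) > 0))

  ## separated beats pooled-and-shuffled on every draw
  wins <- vapply(1:25, function(i) {
    X <- two_clouds(sep = 5, jitter = 0.8, seed = i)
    set.seed(i)
    Xs <- apply(X, 2, sample)
    rownames(Xs) <- rownames(X)
    fcm(X, seed = i, scale_rows = FALSE)$pseudo_F >
      fcm(Xs, seed = i, scale_rows = FALSE)$pseudo_F
  }, logical(1))
  expect_true(all(wins))

  ## two exact point masses: infinite pseudo-F with a degeneracy flag
  Xpm <- rbind(matrix(0, 3, 4), matrix(5, 3, 4)) +
    0  # exact duplicates within each mass
  rownames(Xpm) <- paste0("o", 1:6)
  res <- fcm(Xpm, seed = 9, scale_rows = FALSE)
  expect_true(is.infinite(res$pseudo_F))
  expect_true(isTRUE(attr(res$pseudo_F, "degenerate")))
})

test_that("between-cluster year tests count separated columns", {
  ## literally identical groups: every Welch p is 1, count 0
  base <- matrix(rnorm(32), 2, 16)
  X <- rbind(base, base)
  rownames(X) <- paste0("s", 1:4)
  res <- structure(list(memberships = matrix(0.5, 4, 2,
                                             dimnames = list(rownames(X), NULL)),
                        fuzzifier = 2,
                        hard_labels = stats::setNames(c(1L, 1L, 2L, 2L), rownames(X)),
                        data = X, centroids = rbind(colMeans(base), colMeans(base))),
                   class = "fcm_result")
  expect_equal(cluster_contrast_years(X, res), 0L)

  ## 10 of 16 columns separated by 3 pooled SDs (8 sites per group, the
  ## network's scale): count >= 9 almost always
  counts <- vapply(1:100, function(i) {
    set.seed(i)
    X2 <- matrix(rnorm(16 * 16), 16)
    X2[9:16, 1:10] <- X2[9:16, 1:10] + 3
    rownames(X2) <- paste0("s", 1:16)
    r2 <- structure(list(hard_labels = stats::setNames(rep(1:2, each = 8), rownames(X2))),
                    class = "fcm_result")
    cluster_contrast_years(X2, r2)
  }, integer(1))
  expect_gte(mean(counts >= 9), 0.95)

  ## all 16 columns at 5 SDs: every year significant
  all16 <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    X3 <- matrix(rnorm(8 * 16), 8)
    X3[5:8, ] <- X3[5:8, ] + 5
    rownames(X3) <- paste0("s", 1:8)
    r3 <- structure(list(hard_labels = stats::setNames(rep(1:2, each = 4), rownames(X3))),
                    class = "fcm_result")
    cluster_contrast_years(X3, r3)
  }, integer(1))
  expect_true(all(all16 == 16L))

  ## singleton groups are refused
  r4 <- structure(list(hard_labels = stats::setNames(c(1L, 2L, 2L, 2L), paste0("s", 1:4))),
                  class = "fcm_result")
  expect_error(cluster_contrast_years(matrix(rnorm(64), 4,
                                             dimnames = list(paste0("s", 1:4), NULL)), r4),
               "fewer than 2")
})

test_that("partition summaries contrast warm and cold intervals", {
  ## identical inputs give zero differences
  X <- two_clouds(seed = 10, n_per = 5, sep = 3, d = 16, jitter = 1)
  a <- fcm(X, seed = 11, scale_rows = FALSE)
  b <- fcm(X, seed = 11, scale_rows = FALSE)
  ps <- partition_summary(a, b)
  expect_true(all(abs(ps["warm_minus_cold", ]) < 1e-12))

  ## differing site sets are refused
  X2 <- X; rownames(X2)[1] <- "other"
  expect_error(partition_summary(a, fcm(X2, seed = 11, scale_rows = FALSE)),
               "different site sets")

  ## stronger common forcing in the warm interval raises pseudo-F
  wins <- vapply(1:100, function(i) {
    set.seed(i)
    pat <- rnorm(16); pat <- pat / sqrt(sum(pat^2))
    mk <- function(delta) {
      M <- matrix(rnorm(10 * 16), 10)
      M[6:10, ] <- M[6:10, ] + delta * matrix(pat, 5, 16, byrow = TRUE) * 4
      rownames(M) <- paste0("s", 1:10)
      M + 1
    }
    fc <- fcm(mk(0.8), seed = i)
    fw <- fcm(mk(2.0), seed = i + 5000)
    partition_summary(fc, fw)["warm_minus_cold", "pseudo_F"] > 0
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
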