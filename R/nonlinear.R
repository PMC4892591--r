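## strict local extrema indices; plateaus contribute their middle point
local_extrema <- function(x) {
  n <- length(x)
  keep <- c(TRUE, diff(x) != 0)
  idx <- which(keep)
  xv <- x[idx]
  if (length(xv) < 3L) return(list(max = integer(), min = integer()))
  d <- sign(diff(xv))
  turn <- diff(d)
  imax <- which(turn < 0) + 1L
  imin <- which(turn > 0) + 1L
  ## map back to original positions (middle of plateaus)
  run_end <- c(idx[-1L] - 1L, n)
  mid <- (idx + run_end) %/% 2L
  list(max = mid[imax], min = mid[imin])
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

## IMF mode condition: extrema and zero-crossing counts differ by <= 1
is_imf_like <- function(x) {
  ex <- local_extrema(x)
  abs(length(ex$max) + length(ex$min) - zero_crossings(x)) <= 1L
}

## cubic-spline envelope through given extrema, with extrema mirrored
## about both ends to stabilize the boundary
envelope <- function(x, idx) {
  n <- length(x)
  px <- idx; py <- x[idx]
  take <- seq_len(min(2L, length(px)))
  lx <- 2 - rev(px[take]); ly <- rev(py[take])
  takr <- seq(to = length(px), length.out = min(2L, length(px)))
  rx <- 2 * n - px[takr]; ry <- py[takr]
  ox <- c(lx, px, rev(rx)); oy <- c(ly, py, rev(ry))
  keep <- !duplicated(ox)
  stats::spline(ox[keep], oy[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Sifts a series into intrinsic mode functions (IMFs) using cubic-spline
#' upper/lower envelopes through local extrema with mirrored boundary
#' extrema. Sifting of one IMF stops when the normalized squared
#' difference between successive siftings falls below 0.2 (or a soft cap
#' of 10 siftings is reached) and the component satisfies the IMF mode
#' condition - extrema and zero-crossing counts differing by at most
#' one - with a hard cap of 30 siftings; decomposition stops when the residual has fewer than 2
#' extrema (or after `max_imfs` modes). The decomposition is exactly
#' additive: `rowSums(imfs) + residual == input`.
#'
#' @param x numeric series, length >= 10.
#' @param max_imfs cap on the number of IMFs (default 10).
#' @return list with `imfs` (matrix, one column per IMF; zero columns for
#'   monotone input) and `residual`.
#' @export
emd <- function(x, max_imfs = 10L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("series too short for EMD (need >= 10)", call. = FALSE)
  imfs <- matrix(numeric(0), n, 0L)
  residual <- x
  for (k in seq_len(max_imfs)) {
    ex <- local_extrema(residual)
    ## both envelopes must be constructible or the residual is the trend
    if (length(ex$max) < 2L || length(ex$min) < 2L) break
    h <- residual
    for (s in seq_len(30L)) {
      ex_h <- local_extrema(h)
      if (length(ex_h$max) < 2L || length(ex_h$min) < 2L) break
      up <- envelope(h, ex_h$max)
      lo <- envelope(h, ex_h$min)
      m <- (up + lo) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      ## accept once the sifting has settled (or the soft cap of 10 sifts is
      ## reached) and the component satisfies the IMF mode condition; the
      ## hard cap of 30 guards against non-convergence
      if ((sd_crit < 0.2 || s >= 10L) && is_imf_like(h)) break
    }
    imfs <- cbind(imfs, h)
    residual <- residual - h
    ex_r <- local_extrema(residual)
    if (length(ex_r$max) + length(ex_r$min) < 2L) break
  }
  if (ncol(imfs)) colnames(imfs) <- paste0("IMF", seq_len(ncol(imfs)))
  list(imfs = imfs, residual = residual)
}

#' Ensemble empirical mode decomposition
#'
#' Averages the EMD decompositions of `ensemble_size` white-noise-added
#' copies of the input (noise SD = `noise_sd_fraction` times the input
#' SD). IMFs are aligned by index and zero-padded to a common count; the
#' final averaged residual is the nonlinear trend. With
#' `noise_sd_fraction = 0` and `ensemble_size = 1` this reduces exactly
#' to [emd()].
#'
#' @param x numeric series, length >= 10.
#' @param ensemble_size number of noise realizations (default 100).
#' @param noise_sd_fraction noise SD as a fraction of the series SD
#'   (default 0.2).
#' @param seed integer seed.
#' @return an `eemd_result`: `imfs`, `trend` (the averaged residual),
#'   `ensemble_size`, `noise_sd_fraction`, `seed`.
#' @export
eemd <- function(x, ensemble_size = 100L, noise_sd_fraction = 0.2, seed = 1L) {
  if (ensemble_size < 1L) stop("ensemble_size must be at least 1", call. = FALSE)
  x <- as.numeric(x)
  n <- length(x)
  noise_sd <- noise_sd_fraction * stats::sd(x)
  members <- vector("list", ensemble_size)
  set.seed(seed)
  for (e in seq_len(ensemble_size)) {
    xe <- x + if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
    members[[e]] <- emd(xe)
  }
  n_imf <- max(vapply(members, function(mm) ncol(mm$imfs), integer(1)), 0L)
  imfs <- matrix(0, n, n_imf)
  trend <- numeric(n)
  for (mm in members) {
    ni <- ncol(mm$imfs)
    if (ni) imfs[, seq_len(ni)] <- imfs[, seq_len(ni)] + mm$imfs
    trend <- trend + mm$residual
  }
  imfs <- imfs / ensemble_size
  trend <- trend / ensemble_size
  if (n_imf) colnames(imfs) <- paste0("IMF", seq_len(n_imf))
  structure(list(imfs = imfs, trend = trend, ensemble_size = ensemble_size,
                 noise_sd_fraction = noise_sd_fraction, seed = seed),
            class = "eemd_result")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_forward <- function(w, X) {
  H <- sigmoid(sweep(X %*% w$W1, 2L, w$b1, `+`))
  as.numeric(H %*% w$W2 + w$b2)
}

ann_loss <- function(w, X, y) mean((y - ann_forward(w, X))^2) / 2

ann_grad <- function(w, X, y) {
  n <- nrow(X)
  H <- sigmoid(sweep(X %*% w$W1, 2L, w$b1, `+`))
  yhat <- as.numeric(H %*% w$W2 + w$b2)
  err <- (yhat - y) / n
  dW2 <- t(H) %*% err
  db2 <- sum(err)
  dH <- outer(err, as.numeric(w$W2)) * H * (1 - H)
  dW1 <- t(X) %*% dH
  db1 <- colSums(dH)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

## pack/unpack the weight list to a flat parameter vector for the optimizer
ann_pack <- function(w) c(as.numeric(w$W1), w$b1, as.numeric(w$W2), w$b2)
ann_unpack <- function(theta, d, hidden) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(d * hidden)], d, hidden); i <- i + d * hidden
  b1 <- theta[i + seq_len(hidden)]; i <- i + hidden
  W2 <- matrix(theta[i + seq_len(hidden)], hidden, 1L); i <- i + hidden
  list(W1 = W1, b1 = b1, W2 = W2, b2 = theta[i + 1L])
}

#' Train a small feed-forward growth network
#'
#' Fits a 2-input, one-hidden-layer (logistic units), linear-output
#' network mapping winter temperature predictors to a growth index.
#' Inputs and target are standardized; weights minimize the squared error
#' plus a small ridge penalty by BFGS with analytic backpropagation
#' gradients, run in chunks with early stopping on a held-out validation
#' split (the weights with the best validation loss seen are kept); the
#' best of `restarts` seeded initializations by validation loss is
#' returned. The recorded training-objective trajectory is
#' non-increasing.
#'
#' @param predictors numeric matrix or data.frame with 2 columns (e.g.
#'   previous Nov-Dec mean temperature and current January temperature,
#'   degrees C).
#' @param target numeric growth index series, same length.
#' @param hidden number of hidden units (default 4).
#' @param epochs maximum optimizer iterations per restart (default 2000).
#' @param decay ridge penalty on the weights (default 1e-3).
#' @param seed integer seed (drives the validation split and weight
#'   initializations).
#' @param validation_fraction held-out fraction for early stopping
#'   (default 0.2).
#' @param restarts number of seeded restarts (default 5).
#' @param patience optimizer chunks (of 100 iterations) without
#'   validation improvement before stopping (default 4).
#' @return a `growth_ann` with weights, standardization parameters and a
#'   training record (`train_loss` trajectory, `val_loss`, `epochs_run`).
#' @export
train_growth_ann <- function(predictors, target, hidden = 4L, epochs = 2000L,
                             decay = 1e-3, seed = 1L,
                             validation_fraction = 0.2, restarts = 5L,
                             patience = 4L) {
  X <- as.matrix(predictors)
  y <- as.numeric(target)
  n <- nrow(X)
  if (n < 30L) stop("need at least 30 training years", call. = FALSE)
  x_mu <- colMeans(X); x_sd <- apply(X, 2L, stats::sd)
  y_mu <- mean(y); y_sd <- stats::sd(y)
  if (any(x_sd == 0)) stop("constant predictor column", call. = FALSE)
  if (y_sd == 0) y_sd <- 1
  Xs <- sweep(sweep(X, 2L, x_mu), 2L, x_sd, `/`)
  ys <- (y - y_mu) / y_sd
  set.seed(seed)
  n_val <- max(1L, round(validation_fraction * n))
  val_idx <- sample(n, n_val)
  Xt <- Xs[-val_idx, , drop = FALSE]; yt <- ys[-val_idx]
  Xv <- Xs[val_idx, , drop = FALSE]; yv <- ys[val_idx]
  d <- ncol(X)
  obj <- function(theta) {
    w <- ann_unpack(theta, d, hidden)
    ann_loss(w, Xt, yt) + decay * sum(theta^2)
  }
  grad <- function(theta) {
    w <- ann_unpack(theta, d, hidden)
    g <- ann_grad(w, Xt, yt)
    ann_pack(g) + 2 * decay * theta
  }
  chunk <- 100L
  n_chunks <- max(1L, as.integer(ceiling(epochs / chunk)))
  best <- NULL
  for (rs in seq_len(restarts)) {
    set.seed(derive_seed(seed, rs))
    theta <- stats::runif(d * hidden + hidden + hidden + 1L, -0.7, 0.7)
    train_trace <- obj(theta)
    best_val <- ann_loss(ann_unpack(theta, d, hidden), Xv, yv)
    best_theta <- theta
    since_improve <- 0L
    for (ch in seq_len(n_chunks)) {
      opt <- stats::optim(theta, obj, grad, method = "BFGS",
                          control = list(maxit = chunk))
      if (!is.finite(opt$value)) stop("non-finite loss during training", call. = FALSE)
      theta <- opt$par
      train_trace <- c(train_trace, opt$value)
      vl <- ann_loss(ann_unpack(theta, d, hidden), Xv, yv)
      if (vl < best_val - 1e-12) {
        best_val <- vl; best_theta <- theta; since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= patience) break
      }
      if (opt$convergence == 0L) break  # optimizer converged inside the chunk
    }
    if (is.null(best) || best_val < best$val_loss)
      best <- list(w = ann_unpack(best_theta, d, hidden), val_loss = best_val,
                   train_trace = train_trace, restart = rs)
  }
  structure(list(weights = best$w, hidden = hidden, decay = decay,
                 x_center = x_mu, x_scale = x_sd, y_center = y_mu, y_scale = y_sd,
                 train_loss = best$train_trace, val_loss = best$val_loss,
                 epochs_run = (length(best$train_trace) - 1L) * chunk,
                 restart = best$restart, seed = seed,
                 train_range = apply(X, 2L, range)), class = "growth_ann")
}

#' Predict growth from a trained network
#'
#' @param object a `growth_ann`.
#' @param newdata matrix/data.frame with the two predictor columns in
#'   training order.
#' @param ... unused.
#' @return numeric predictions on the original growth-index scale.
#' @export
predict.growth_ann <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, `/`)
  ann_forward(object$weights, Xs) * object$y_scale + object$y_center
}

#' Evaluate a response surface over a winter-temperature grid
#'
#' Predicts the growth index over a regular (January temperature,
#' previous November-December temperature) grid. Grid ranges must stay
#' within 3 degrees C of the training envelope; cells outside the
#' envelope itself are flagged as extrapolation.
#'
#' @param model a trained [train_growth_ann()] (first predictor =
#'   Nov-Dec, second = January, matching the training column order).
#' @param jan_range `c(min, max)` January axis, degrees C.
#' @param novdec_range `c(min, max)` Nov-Dec axis, degrees C.
#' @param step grid step (default 0.1).
#' @return a `response_surface` data.frame (`jan`, `novdec`,
#'   `predicted_index`, `extrapolated`) with grid attributes.
#' @export
response_surface <- function(model, jan_range = c(-11, -6.5),
                             novdec_range = c(-6.8, -4.0), step = 0.1) {
  stopifnot(inherits(model, "growth_ann"))
  jan <- seq(jan_range[1], jan_range[2], by = step)
  novdec <- seq(novdec_range[1], novdec_range[2], by = step)
  if (!length(jan) || !length(novdec)) stop("empty grid", call. = FALSE)
  tr <- model$train_range  # columns in training order: novdec, jan
  if (jan_range[1] < tr[1, 2] - 3 || jan_range[2] > tr[2, 2] + 3 ||
      novdec_range[1] < tr[1, 1] - 3 || novdec_range[2] > tr[2, 1] + 3)
    stop("grid extends more than 3 degrees C beyond the training envelope", call. = FALSE)
  grid <- expand.grid(jan = jan, novdec = novdec, KEEP.OUT.ATTRS = FALSE)
  pred <- predict(model, cbind(novdec = grid$novdec, jan = grid$jan))
  extrap <- grid$jan < tr[1, 2] | grid$jan > tr[2, 2] |
    grid$novdec < tr[1, 1] | grid$novdec > tr[2, 1]
  out <- data.frame(jan = grid$jan, novdec = grid$novdec,
                    predicted_index = pred, extrapolated = extrap)
  attr(out, "jan_values") <- jan
  attr(out, "novdec_values") <- novdec
  attr(out, "step") <- step
  class(out) <- c("response_surface", "data.frame")
  out
}

#' Detect a temperature sensitivity threshold on a response surface
#'
#' Averages the surface over the non-scanned axis, then fits a continuous
#' two-segment piecewise-linear model with the knot at each interior grid
#' point and keeps the least-squares best. Reports the breakpoint, the
#' below/above slope ratio, and flags the breakpoint unidentifiable when
#' the broken line improves on a single straight line by less than 5% of
#' its residual sum of squares.
#'
#' @param surface a [response_surface()].
#' @param axis which axis to scan (default `"jan"`).
#' @return a `sensitivity_threshold` list: `breakpoint`, `slope_below`,
#'   `slope_above`, `slope_ratio`, `identifiable`, `profile`.
#' @export
detect_sensitivity_threshold <- function(surface, axis = c("jan", "novdec")) {
  axis <- match.arg(axis)
  other <- setdiff(c("jan", "novdec"), axis)
  xs <- attr(surface, paste0(axis, "_values"))
  if (length(xs) < 10L) stop("need at least 10 grid points along the scanned axis",
                             call. = FALSE)
  prof <- tapply(surface$predicted_index, surface[[axis]], mean)
  prof <- as.numeric(prof[as.character(xs)])
  if (length(unique(round(prof, 12))) < 3L)
    stop("profile has fewer than 3 distinct values", call. = FALSE)
  line_fit <- stats::lm(prof ~ xs)
  sse_line <- sum(stats::resid(line_fit)^2)
  best <- NULL
  for (ki in 3:(length(xs) - 2L)) {
    kappa <- xs[ki]
    hinge <- pmax(xs - kappa, 0)
    fit <- stats::lm(prof ~ xs + hinge)
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, kappa = kappa, coef = stats::coef(fit))
  }
  slope_below <- unname(best$coef[["xs"]])
  slope_above <- slope_below + unname(best$coef[["hinge"]])
  tiny <- 1e-12 * (sum((prof - mean(prof))^2) + 1e-300)
  identifiable <- sse_line > tiny && (sse_line - best$sse) / sse_line > 0.05
  structure(list(breakpoint = if (identifiable) best$kappa else NA_real_,
                 knot = best$kappa,
                 slope_below = slope_below, slope_above = slope_above,
                 slope_ratio = slope_below / slope_above,
                 identifiable = identifiable,
                 profile = data.frame(x = xs, mean_index = prof)),
            class = "sensitivity_threshold")
}

#' @export
print.sensitivity_threshold <- function(x, ...) {
  if (x$identifiable)
    cat(sprintf("sensitivity threshold: %.2f degC (slopes %.4f below / %.4f above, ratio %.2f)\n",
                x$breakpoint, x$slope_below, x$slope_above, x$slope_ratio))
  else
    cat(sprintf("no identifiable threshold (profile close to linear; slope ratio %.2f)\n",
                x$slope_ratio))
  invisible(x)
}
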