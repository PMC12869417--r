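## Quantile-offset uncertainty module: sigmoid-bounded multiplicative offsets
## around the reconstruction, trained with the pinball (quantile) loss or the
## residual-magnitude (ResM) heuristic.

#' Raw quantile bounds from sigmoid-scaled offsets
#'
#' Builds the lower/upper quantile estimates from per-pixel offset fields in
#' `[0, 1]`: `lower = x - s_lower * x`, `upper = x + s_upper * x`. The bounds
#' always bracket `x`, and `lower >= 0` wherever `x >= 0`.
#'
#' @param x Reconstruction magnitude image.
#' @param s_lower,s_upper Offset fields in `[0, 1]`, same shape as `x`.
#' @return Object of class `quantile_bounds` with fields `lower`, `upper`,
#'   `x`.
#' @export
#' @examples
#' quantile_bounds(matrix(10), matrix(0.2), matrix(0.3)) # bounds 8 and 13
quantile_bounds <- function(x, s_lower, s_upper) {
  check_same_dim(x, s_lower, "x and s_lower")
  check_same_dim(x, s_upper, "x and s_upper")
  if (any(s_lower < 0 | s_lower > 1) || any(s_upper < 0 | s_upper > 1)) {
    stop_mriuq("offset fields must lie in [0, 1]",
               class = "mriuq_argument_error")
  }
  structure(list(lower = x - s_lower * x, upper = x + s_upper * x, x = x),
            class = "quantile_bounds")
}

#' Pinball (quantile) loss
#'
#' Mean over pixels of `level * (y - q)` where `y > q` and
#' `(1 - level) * (q - y)` otherwise; minimized (for a constant predictor) by
#' the empirical `level`-quantile of `y`.
#'
#' @param q_hat Predicted quantile array.
#' @param y Ground-truth array of the same shape.
#' @param level Quantile level in (0, 1).
#' @return Nonnegative scalar.
#' @export
pinball_loss <- function(q_hat, y, level) {
  check_same_dim(q_hat, y, "prediction and target")
  check_scalar_in(level, 0, 1, "level")
  r <- y - q_hat
  mean(ifelse(r > 0, level * r, (level - 1) * r))
}

#' Total quantile-regression loss for an interval
#'
#' With target coverage `alpha_coverage` and miscoverage
#' `a = 1 - alpha_coverage`, the lower bound is trained at level `a/2` and the
#' upper at `1 - a/2`; the total loss is the sum of the two pinball losses.
#'
#' @param bounds A `quantile_bounds`.
#' @param y Ground-truth image.
#' @param alpha_coverage Target interval coverage in (0, 1), e.g. 0.90.
#' @return Nonnegative scalar.
#' @export
qr_total_loss <- function(bounds, y, alpha_coverage = 0.9) {
  stopifnot(inherits(bounds, "quantile_bounds"))
  check_scalar_in(alpha_coverage, 0, 1, "alpha_coverage")
  a <- 1 - alpha_coverage
  pinball_loss(bounds$lower, y, a / 2) + pinball_loss(bounds$upper, y, 1 - a / 2)
}

#' Residual-magnitude (ResM) loss
#'
#' Squared-error regression of a single symmetric interval half-width onto the
#' absolute residual: mean of `(offset - |x - y|)^2`. Invariant to the sign of
#' `x - y`.
#'
#' @param offset Nonnegative half-width field (`s * x` for a sigmoid offset
#'   `s`).
#' @param x Reconstruction.
#' @param y Ground truth.
#' @return Nonnegative scalar.
#' @export
resm_loss <- function(offset, x, y) {
  check_same_dim(offset, x, "offset and x")
  check_same_dim(x, y, "x and y")
  if (any(offset < 0)) {
    stop_mriuq("'offset' must be nonnegative", class = "mriuq_argument_error")
  }
  mean((offset - abs(x - y))^2)
}

## ---- OffsetPredictor contract -------------------------------------------

#' Predict per-pixel offset fields for a reconstruction
#'
#' Generic of the OffsetPredictor contract. Every predictor maps a magnitude
#' image to sigmoid-bounded offset fields in `[0, 1]` of the same shape:
#' a list with elements `s_lower` and `s_upper` (equal for symmetric / ResM
#' predictors).
#'
#' @param predictor An `offset_predictor` object.
#' @param x Reconstruction magnitude image.
#' @return List with matrices `s_lower`, `s_upper` in `[0, 1]`.
#' @export
predict_offsets <- function(predictor, x) UseMethod("predict_offsets")

#' Analytic offset predictor
#'
#' Wraps deterministic functions of the image as an OffsetPredictor; useful
#' for tests and for closed-form uncertainty rules.
#'
#' @param fn_lower Function `x -> s` returning values in `[0, 1]`.
#' @param fn_upper Optional second function; defaults to `fn_lower`
#'   (symmetric).
#' @return An `analytic_predictor`.
#' @export
analytic_predictor <- function(fn_lower, fn_upper = fn_lower) {
  stopifnot(is.function(fn_lower), is.function(fn_upper))
  structure(list(fn_lower = fn_lower, fn_upper = fn_upper),
            class = c("analytic_predictor", "offset_predictor"))
}

#' @export
predict_offsets.analytic_predictor <- function(predictor, x) {
  sl <- predictor$fn_lower(x)
  su <- predictor$fn_upper(x)
  list(s_lower = clamp01(sl), s_upper = clamp01(su))
}

clamp01 <- function(s) pmin(pmax(s, 0), 1)

#' Featurized sigmoid-linear offset predictor
#'
#' The default trainable predictor: per-pixel image features (intensity, local
#' standard deviation, gradient magnitude, high-frequency residual, intercept)
#' are combined linearly and passed through a sigmoid, yielding offsets in
#' `(0, 1)`. QR mode carries two independent weight vectors (lower/upper
#' offsets); ResM mode a single shared one (symmetric offsets). Features are
#' standardized per input image.
#'
#' @param mode `"QR"` (two offset fields) or `"ResM"` (one symmetric field).
#' @param seed Seed for the weight initialization.
#' @return A `feature_predictor` with small random initial weights.
#' @export
feature_predictor <- function(mode = c("QR", "ResM"), seed = 1L) {
  mode <- match.arg(mode)
  k <- length(.feature_names)
  w <- withr::with_seed(seed, rnorm(2L * k, 0, 0.01))
  structure(list(mode = mode, seed = seed,
                 w_lower = w[seq_len(k)],
                 w_upper = if (mode == "QR") w[k + seq_len(k)] else NULL),
            class = c("feature_predictor", "offset_predictor"))
}

.feature_names <- c("intercept", "intensity", "local_sd", "grad_mag",
                    "highfreq", "alias_max", "alias_mean", "context",
                    "intensity_x_alias", "intensity_sq", "alias_max_sq",
                    "intensity_x_context", "bright_pair", "abs_intensity")

# Per-pixel feature matrix (n_pixels x K), standardized per image. Beyond
# plain intensity/texture, the aliasing-partner features look at the
# quarter/half-FOV-shifted positions along the phase-encode axis: at
# acceleration R a ghost of a bright structure lands FOV/R away, so a pixel
# whose partners are bright is at risk of ghost contamination (and a bright
# pixel with dark partners is likely real signal).
predictor_features <- function(x) {
  xs <- x / max(max(x), .Machine$double.eps)
  k5 <- uniform_kernel_1d(5L)
  mu <- conv_separable(xs, k5)
  v <- pmax(conv_separable(xs * xs, k5) - mu^2, 0)
  gx <- xs - xs[c(1, seq_len(nrow(xs) - 1)), , drop = FALSE]
  gy <- xs - xs[, c(1, seq_len(ncol(xs) - 1)), drop = FALSE]
  grad <- sqrt(gx^2 + gy^2)
  hf <- abs(xs - conv_separable(xs, gaussian_kernel_1d(2)))
  w <- ncol(xs)
  shift_pe <- function(m, s) m[, ((seq_len(w) - 1 + s) %% w) + 1, drop = FALSE]
  p1 <- shift_pe(xs, w %/% 4)
  p2 <- shift_pe(xs, w %/% 2)
  p3 <- shift_pe(xs, (3 * w) %/% 4)
  alias_max <- pmax(p1, p2, p3)
  alias_mean <- (p1 + p2 + p3) / 3
  ctx <- conv_separable(xs, uniform_kernel_1d(11L))
  std <- function(f) {
    f <- as.vector(f)
    s <- stats::sd(f)
    if (s > 0) (f - mean(f)) / s else f * 0
  }
  int_s <- std(xs)
  alias_s <- std(alias_max)
  ctx_s <- std(ctx)
  cbind(intercept = rep(1, length(xs)), intensity = int_s,
        local_sd = std(sqrt(v)), grad_mag = std(grad), highfreq = std(hf),
        alias_max = alias_s, alias_mean = std(alias_mean),
        context = ctx_s, intensity_x_alias = std(xs * alias_max),
        # nonlinear expansions: the conditional error scale is strongly
        # nonlinear in intensity and ghost-partner brightness
        intensity_sq = int_s^2, alias_max_sq = alias_s^2,
        intensity_x_context = int_s * ctx_s,
        bright_pair = pmax(int_s, 0) * pmax(alias_s, 0),
        abs_intensity = abs(int_s))
}

#' @export
predict_offsets.feature_predictor <- function(predictor, x) {
  f <- predictor_features(x)
  d <- dim(x)
  sl <- matrix(plogis(drop(f %*% predictor$w_lower)), d[1], d[2])
  su <- if (predictor$mode == "QR") {
    matrix(plogis(drop(f %*% predictor$w_upper)), d[1], d[2])
  } else sl
  list(s_lower = sl, s_upper = su)
}

#' Raw quantile bounds for a reconstruction pair
#'
#' Convenience wrapper: predict offsets for `pair$x` and form
#' [quantile_bounds()].
#'
#' @param predictor An `offset_predictor`.
#' @param pair A `recon_pair`.
#' @return A `quantile_bounds`.
#' @export
predict_bounds <- function(predictor, pair) {
  stopifnot(inherits(pair, "recon_pair"))
  s <- predict_offsets(predictor, pair$x)
  quantile_bounds(pair$x, s$s_lower, s$s_upper)
}

## ---- training ------------------------------------------------------------

#' Training configuration for the uncertainty module
#'
#' @param alpha_coverage Target interval coverage in (0, 1); default 0.90,
#'   i.e. the lower/upper offsets estimate the 0.05 and 0.95 conditional
#'   quantiles.
#' @param mode `"QR"` (pinball losses at `a/2`, `1 - a/2`) or `"ResM"`
#'   (squared loss on the absolute residual).
#' @param n_iter Full-batch Adam iterations.
#' @param lr Adam learning rate.
#' @param seed Seed controlling initialization.
#' @return Object of class `uq_training_config`.
#' @export
uq_config <- function(alpha_coverage = 0.9, mode = c("QR", "ResM"),
                      n_iter = 600L, lr = 0.05, seed = 1L) {
  check_scalar_in(alpha_coverage, 0, 1, "alpha_coverage")
  mode <- match.arg(mode)
  structure(list(alpha_coverage = alpha_coverage, mode = mode,
                 n_iter = as.integer(n_iter), lr = lr, seed = seed),
            class = "uq_training_config")
}

#' Train an offset predictor on reconstruction pairs
#'
#' Full-batch Adam on the total quantile loss (QR mode) or the ResM loss,
#' with analytic (sub)gradients through the sigmoid offsets. The
#' reconstructor is assumed frozen: pairs are precomputed. Fully seeded and
#' deterministic.
#'
#' @param pairs Nonempty list of `recon_pair`s.
#' @param predictor A `feature_predictor` (its `mode` must match the config).
#' @param config A `uq_training_config`.
#' @param val_pairs Optional list of `recon_pair`s for a validation-loss
#'   history.
#' @return The trained predictor, with attribute `"history"` (data frame of
#'   per-iteration training and, if requested, validation loss) and
#'   `"config"`.
#' @export
train_uq <- function(pairs, predictor, config = uq_config(),
                     val_pairs = NULL) {
  if (length(pairs) == 0) {
    stop_mriuq("training set is empty", class = "mriuq_data_error")
  }
  stopifnot(inherits(predictor, "feature_predictor"),
            inherits(config, "uq_training_config"))
  if (predictor$mode != config$mode) {
    stop_mriuq("predictor mode and config mode disagree",
               class = "mriuq_argument_error")
  }
  feats <- do.call(rbind, lapply(pairs, function(p) predictor_features(p$x)))
  xv <- unlist(lapply(pairs, function(p) as.vector(p$x)), use.names = FALSE)
  yv <- unlist(lapply(pairs, function(p) as.vector(p$y)), use.names = FALSE)
  n <- length(xv)
  a <- 1 - config$alpha_coverage
  mode <- config$mode

  k <- ncol(feats)
  theta <- if (mode == "QR") c(predictor$w_lower, predictor$w_upper) else
    predictor$w_lower

  loss_grad <- function(th) {
    if (mode == "QR") {
      wl <- th[seq_len(k)]; wu <- th[k + seq_len(k)]
      sl <- plogis(drop(feats %*% wl))
      su <- plogis(drop(feats %*% wu))
      l <- xv * (1 - sl)
      u <- xv * (1 + su)
      tl <- a / 2; tu <- 1 - a / 2
      rl <- yv - l; ru <- yv - u
      loss <- mean(ifelse(rl > 0, tl * rl, (tl - 1) * rl)) +
        mean(ifelse(ru > 0, tu * ru, (tu - 1) * ru))
      dl <- ifelse(rl > 0, -tl, 1 - tl) / n        # dLoss/dl per pixel
      du <- ifelse(ru > 0, -tu, 1 - tu) / n
      gl <- drop(crossprod(feats, dl * (-xv) * sl * (1 - sl)))
      gu <- drop(crossprod(feats, du * xv * su * (1 - su)))
      list(loss = loss, grad = c(gl, gu))
    } else {
      s <- plogis(drop(feats %*% th))
      h <- s * xv
      e <- abs(xv - yv)
      loss <- mean((h - e)^2)
      g <- drop(crossprod(feats, 2 * (h - e) * xv * s * (1 - s) / n))
      list(loss = loss, grad = g)
    }
  }

  val_loss <- if (!is.null(val_pairs)) {
    vfeats <- do.call(rbind, lapply(val_pairs, function(p) predictor_features(p$x)))
    vx <- unlist(lapply(val_pairs, function(p) as.vector(p$x)), use.names = FALSE)
    vy <- unlist(lapply(val_pairs, function(p) as.vector(p$y)), use.names = FALSE)
    function(th) {
      if (mode == "QR") {
        sl <- plogis(drop(vfeats %*% th[seq_len(k)]))
        su <- plogis(drop(vfeats %*% th[k + seq_len(k)]))
        tl <- a / 2; tu <- 1 - a / 2
        rl <- vy - vx * (1 - sl); ru <- vy - vx * (1 + su)
        mean(ifelse(rl > 0, tl * rl, (tl - 1) * rl)) +
          mean(ifelse(ru > 0, tu * ru, (tu - 1) * ru))
      } else {
        mean((plogis(drop(vfeats %*% th)) * vx - abs(vx - vy))^2)
      }
    }
  } else NULL

  # Adam, full batch
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- data.frame(iter = seq_len(config$n_iter), train_loss = NA_real_,
                     val_loss = NA_real_)
  for (it in seq_len(config$n_iter)) {
    lg <- loss_grad(theta)
    if (!is.finite(lg$loss)) {
      stop_mriuq(sprintf(
        "non-finite training loss at iteration %d (lr=%g); reduce the learning rate",
        it, config$lr
      ), class = "mriuq_training_error")
    }
    m <- b1 * m + (1 - b1) * lg$grad
    v <- b2 * v + (1 - b2) * lg$grad^2
    mh <- m / (1 - b1^it)
    vh <- v / (1 - b2^it)
    theta <- theta - config$lr * mh / (sqrt(vh) + eps)
    hist$train_loss[it] <- lg$loss
    if (!is.null(val_loss)) hist$val_loss[it] <- val_loss(theta)
  }

  predictor$w_lower <- unname(theta[seq_len(k)])
  if (mode == "QR") predictor$w_upper <- unname(theta[k + seq_len(k)])
  attr(predictor, "history") <- hist
  attr(predictor, "config") <- config
  predictor
}

#' Serialize a trained predictor to a JSON checkpoint
#'
#' @param predictor A `feature_predictor`.
#' @param path Output file path.
#' @export
write_predictor <- function(predictor, path) {
  stopifnot(inherits(predictor, "feature_predictor"))
  cfg <- attr(predictor, "config")
  jsonlite::write_json(list(
    mode = predictor$mode, seed = predictor$seed,
    w_lower = predictor$w_lower, w_upper = predictor$w_upper,
    features = .feature_names,
    config = if (!is.null(cfg)) unclass(cfg) else NULL
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a predictor checkpoint written by [write_predictor()]
#'
#' @param path Checkpoint path.
#' @return A `feature_predictor`.
#' @export
read_predictor <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- feature_predictor(mode = j$mode, seed = j$seed)
  p$w_lower <- as.numeric(j$w_lower)
  if (j$mode == "QR") p$w_upper <- as.numeric(j$w_upper)
  if (!is.null(j$config)) {
    attr(p, "config") <- do.call(uq_config, j$config[c("alpha_coverage", "mode",
                                                       "n_iter", "lr", "seed")])
  }
  p
}
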