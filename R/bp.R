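#' Hidden-layer transfer function (tansig)
#'
#' `tansig(u) = 2/(1 + exp(-2u)) - 1`, the hyperbolic-tangent sigmoid.
#' @param u Numeric.
#' @return Values in (-1, 1).
#' @export
tansig <- function(u) 2 / (1 + exp(-2 * u)) - 1

#' Output-layer transfer function (relu)
#'
#' `relu(u) = max(0, u)`.
#' @param u Numeric.
#' @return Non-negative values.
#' @export
relu <- function(u) pmax(0, u)

N_INPUT <- 8L
N_HIDDEN <- 20L

#' Initialize network parameters
#'
#' The classifier is a fixed 8-20-1 multilayer perceptron: 8 feature
#' inputs, 20 tansig hidden units, 1 relu output unit.  Weights and
#' thresholds are drawn uniformly from \[-0.5, 0.5\] under the given seed,
#' so initialization is reproducible.
#'
#' @param seed RNG seed.
#' @param n_in,n_hidden Layer widths (defaults 8 and 20; tests use smaller
#'   nets for the finite-difference oracle).
#' @return A list of class `network_params` with `w1` (hidden x in), `b1`,
#'   `w2` (1 x hidden), `b2`.
#' @export
bp_init <- function(seed = 1, n_in = N_INPUT, n_hidden = N_HIDDEN) {
  with_seed(seed, {
    structure(
      list(w1 = matrix(stats::runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
           b1 = stats::runif(n_hidden, -0.5, 0.5),
           w2 = matrix(stats::runif(n_hidden, -0.5, 0.5), 1, n_hidden),
           b2 = stats::runif(1, -0.5, 0.5)),
      class = "network_params"
    )
  })
}

#' Forward pass
#'
#' `EZ = tansig(w1 x + b1)`, `EY = relu(w2 EZ + b2)`.
#'
#' @param params A `network_params` list.
#' @param x Numeric vector of length `n_in`, or an `n x n_in` matrix.
#' @return List with `y` (numeric vector of outputs), `z` (hidden
#'   activations, n x n_hidden) and `y_in` (output pre-activation).
#' @export
bp_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (!all(is.finite(x))) stop("non-finite input to the network", call. = FALSE)
  z_in <- x %*% t(params$w1) + matrix(params$b1, nrow(x), length(params$b1),
                                      byrow = TRUE)
  z <- tansig(z_in)
  y_in <- as.numeric(z %*% t(params$w2)) + params$b2
  list(y = relu(y_in), z = z, y_in = y_in)
}

# Pack/unpack parameters as a flat vector: c(w1, b1, w2, b2), column-major.
pack_params <- function(p) c(as.vector(p$w1), p$b1, as.vector(p$w2), p$b2)

unpack_params <- function(v, n_in, n_hidden) {
  i1 <- n_hidden * n_in
  structure(
    list(w1 = matrix(v[seq_len(i1)], n_hidden, n_in),
         b1 = v[i1 + seq_len(n_hidden)],
         w2 = matrix(v[i1 + n_hidden + seq_len(n_hidden)], 1, n_hidden),
         b2 = v[i1 + 2 * n_hidden + 1]),
    class = "network_params"
  )
}

# Residuals r = EY - Tg and their Jacobian d r / d theta (n x n_params),
# by backpropagation.  Column order matches pack_params().
bp_residual_jacobian <- function(params, x, targets) {
  n_hidden <- nrow(params$w1); n_in <- ncol(params$w1)
  fw <- bp_forward(params, x)
  r <- fw$y - targets
  dy <- as.numeric(fw$y_in > 0)                  # relu'
  dz <- (dy * matrix(params$w2, length(dy), n_hidden, byrow = TRUE)) *
    (1 - fw$z^2)                                 # tansig' = 1 - z^2
  J_w1 <- dz[, rep(seq_len(n_hidden), n_in), drop = FALSE] *
    x[, rep(seq_len(n_in), each = n_hidden), drop = FALSE]
  J_w2 <- dy * fw$z
  list(r = r, J = cbind(J_w1, dz, J_w2, dy))
}

#' Training-error gradient by backpropagation
#'
#' Gradient of `ERR = sum((EY - Tg)^2) / 2` with respect to the flat
#' parameter vector (order: `w1`, `b1`, `w2`, `b2`, column-major).
#'
#' @param params A `network_params` list.
#' @param x `n x n_in` feature matrix.
#' @param targets Length-n target vector.
#' @return Numeric gradient vector.
#' @export
bp_gradient <- function(params, x, targets) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  rj <- bp_residual_jacobian(params, x, targets)
  as.numeric(crossprod(rj$J, rj$r))
}

#' Training-error value
#'
#' `ERR = (EY - Tg)' (EY - Tg) / 2`, the sum-of-squares objective the
#' network is trained to.
#'
#' @inheritParams bp_gradient
#' @return Scalar error.
#' @export
bp_err <- function(params, x, targets) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  sum((bp_forward(params, x)$y - targets)^2) / 2
}

#' Training configuration
#'
#' @param algorithm `"lm"` (Levenberg-Marquardt, the default training
#'   function) or `"gd"` (plain steepest descent); both minimize the same
#'   sum-of-squares objective.
#' @param target_mse Stop when the mean squared residual falls to or below
#'   this goal (default 1e-3).
#' @param max_epochs Maximum accepted update steps (default 1000).
#' @param learning_rate Step size for `"gd"`.
#' @param mu0 Initial Levenberg-Marquardt damping.
#' @param seed RNG seed for weight initialization.
#' @param n_restarts Maximum number of deterministic re-initializations
#'   (seeds `seed`, `seed + 1000`, ...) tried when a run fails to reach
#'   the error goal.  A relu output unit whose pre-activation starts
#'   negative on every sample has a zero gradient, so a restart is the
#'   principled escape from such a dead start; the first run reaching the
#'   goal (or the best run overall) is kept, and the whole procedure stays
#'   deterministic given `seed`.
#' @param input_scaling `"minmax"` (default; per-feature min-max to
#'   \[0, 1\], fitted on the training data only -- the raw features mix
#'   seconds, pixels and binary flags), `"zscore"` or `"none"`.
#' @param decision_threshold Output cut for the fall decision (default 0.5;
#'   outputs at the threshold classify as fall).
#' @return A list of class `train_config`.
#' @export
train_config <- function(algorithm = c("lm", "gd"), target_mse = 1e-3,
                         max_epochs = 1000, learning_rate = 0.005,
                         mu0 = 1e-2, seed = 1, n_restarts = 10,
                         input_scaling = c("minmax", "zscore", "none"),
                         decision_threshold = 0.5) {
  if (target_mse <= 0) stop("`target_mse` must be positive", call. = FALSE)
  if (max_epochs < 0) stop("`max_epochs` must be >= 0", call. = FALSE)
  structure(
    list(algorithm = match.arg(algorithm), target_mse = target_mse,
         max_epochs = max_epochs, learning_rate = learning_rate,
         mu0 = mu0, seed = seed, n_restarts = n_restarts,
         input_scaling = match.arg(input_scaling),
         decision_threshold = decision_threshold),
    class = "train_config"
  )
}

fit_scaling <- function(x, kind) {
  switch(kind,
    none   = list(kind = "none"),
    minmax = list(kind = "minmax", lo = apply(x, 2, min),
                  span = pmax(apply(x, 2, max) - apply(x, 2, min), 1e-12)),
    zscore = list(kind = "zscore", mu = colMeans(x),
                  sd = pmax(apply(x, 2, stats::sd), 1e-12)))
}

apply_scaling <- function(x, sc) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  switch(sc$kind,
    none   = x,
    minmax = sweep(sweep(x, 2, sc$lo), 2, sc$span, "/"),
    zscore = sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/"))
}

#' Train the fall classifier
#'
#' Minimizes the sum-of-squares training error by Levenberg-Marquardt
#' (default) or steepest descent, starting from seeded uniform
#' initialization.  Training is deterministic given the seed.  With
#' `max_epochs = 0` the initialization is returned unchanged.
#'
#' @param x `n x 8` feature matrix (or a data.frame of the 8 feature
#'   columns).
#' @param targets Length-n vector of 0 (non-fall) / 1 (fall); both classes
#'   must be present.
#' @param config A [train_config()].
#' @return A list of class `trained_classifier` with `params`, `scaling`,
#'   `config`, `final_err` (sum-of-squares objective), `final_mse`,
#'   `epochs`, `err_trace` (objective after each accepted step).
#' @export
bp_train <- function(x, targets, config = train_config()) {
  x <- as.matrix(x)
  targets <- as.numeric(targets)
  if (!all(targets %in% c(0, 1)))
    stop("`targets` must be coded 0/1", call. = FALSE)
  if (length(unique(targets)) < 2)
    stop("training data contain a single class; both fall and non-fall ",
         "examples are required", call. = FALSE)
  if (nrow(x) != length(targets))
    stop("`targets` must align with the rows of `x`", call. = FALSE)

  sc <- fit_scaling(x, config$input_scaling)
  xs <- apply_scaling(x, sc)
  n <- nrow(xs)

  run_once <- function(init_seed) {
    params <- bp_init(init_seed, n_in = ncol(xs))
    theta <- pack_params(params)
    n_in <- ncol(xs); n_hidden <- nrow(params$w1)
    err <- bp_err(params, xs, targets)
    trace <- err
    mu <- config$mu0
    epochs <- 0L
    while (config$max_epochs > 0 &&
           2 * err / n > config$target_mse &&
           epochs < config$max_epochs) {
      rj <- bp_residual_jacobian(params, xs, targets)
      if (config$algorithm == "gd") {
        theta <- theta - config$learning_rate *
          as.numeric(crossprod(rj$J, rj$r))
        params <- unpack_params(theta, n_in, n_hidden)
        err <- bp_err(params, xs, targets)
      } else {
        JtJ <- crossprod(rj$J)
        Jtr <- crossprod(rj$J, rj$r)
        accepted <- FALSE
        for (try in 1:40) {
          step <- tryCatch(
            solve(JtJ + diag(mu, ncol(JtJ)), -Jtr),
            error = function(e) NULL)
          if (!is.null(step)) {
            theta_new <- theta + as.numeric(step)
            params_new <- unpack_params(theta_new, n_in, n_hidden)
            err_new <- bp_err(params_new, xs, targets)
            if (is.finite(err_new) && err_new < err) {
              theta <- theta_new; params <- params_new; err <- err_new
              mu <- max(mu * 0.2, 1e-12)
              accepted <- TRUE
              break
            }
          }
          mu <- mu * 5
          if (mu > 1e12) break
        }
        if (!accepted) break                 # converged / stalled
      }
      epochs <- epochs + 1L
      trace <- c(trace, err)
    }
    list(params = params, err = err, trace = trace, epochs = epochs)
  }

  best <- NULL
  restarts <- max(1L, if (config$max_epochs > 0) config$n_restarts else 1L)
  for (r in seq_len(restarts)) {
    fit <- run_once(config$seed + (r - 1L) * 1000L)
    if (is.null(best) || fit$err < best$err) best <- fit
    if (2 * best$err / n <= config$target_mse) break
  }

  structure(
    list(params = best$params, scaling = sc, config = config,
         final_err = best$err,
         final_mse = mean((bp_forward(best$params, xs)$y - targets)^2),
         epochs = best$epochs, err_trace = best$trace),
    class = "trained_classifier"
  )
}

#' Network output for feature vectors
#'
#' @param clf A `trained_classifier`.
#' @param x Feature vector or matrix (raw scale; the classifier applies its
#'   stored input scaling).
#' @return Numeric vector of relu outputs.
#' @export
bp_predict <- function(clf, x) {
  bp_forward(clf$params, apply_scaling(as.matrix(x), clf$scaling))$y
}

#' Binary fall decision
#'
#' Fall iff the network output reaches the decision threshold (ties
#' classify as fall).
#'
#' @inheritParams bp_predict
#' @return Character vector of `"fall"` / `"non_fall"`.
#' @export
bp_classify <- function(clf, x) {
  ifelse(bp_predict(clf, x) >= clf$config$decision_threshold,
         "fall", "non_fall")
}

#' Save a trained classifier as flat JSON
#'
#' Weights, thresholds, scaling and configuration are written at full
#' numeric precision, so `load_model(save_model(clf, p))` reproduces the
#' classifier bit-exactly.
#'
#' @param clf A `trained_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(clf, path) {
  # numeric payloads are stored as C17 decimal strings (column-major for
  # matrices), which round-trip IEEE doubles exactly
  num <- function(x) sprintf("%.17g", as.numeric(x))
  sc <- clf$scaling
  sc[names(sc) != "kind"] <- lapply(sc[names(sc) != "kind"], num)
  obj <- list(
    architecture = c(ncol(clf$params$w1), nrow(clf$params$w1), 1),
    w1 = num(clf$params$w1), b1 = num(clf$params$b1),
    w2 = num(clf$params$w2), b2 = num(clf$params$b2),
    scaling = sc,
    config = unclass(clf$config),
    final_err = clf$final_err, final_mse = clf$final_mse,
    epochs = clf$epochs
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a classifier saved by [save_model()]
#'
#' @param path Path to a model JSON file.
#' @return A `trained_classifier`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- structure(
    list(w1 = matrix(as.numeric(obj$w1), nrow = obj$architecture[2]),
         b1 = as.numeric(obj$b1),
         w2 = matrix(as.numeric(obj$w2), nrow = 1),
         b2 = as.numeric(obj$b2)),
    class = "network_params"
  )
  sc <- obj$scaling
  sc[names(sc) != "kind"] <- lapply(sc[names(sc) != "kind"],
                                    function(v) as.numeric(v))
  cfg <- obj$config
  class(cfg) <- "train_config"
  structure(
    list(params = params, scaling = sc, config = cfg,
         final_err = obj$final_err, final_mse = obj$final_mse,
         epochs = obj$epochs, err_trace = NULL),
    class = "trained_classifier"
  )
}
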