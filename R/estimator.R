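# A 2-input / H-hidden(tanh) / 1-output perceptron with 4H + 1 weight and
# bias parameters, trained by full-batch backpropagation to minimise RMSE,
# and the nested leave-one-out cross-validation that selects H.

pack_theta <- function(m) {
  c(as.numeric(m$input_weights), m$hidden_biases, m$output_weights,
    m$output_bias)
}

unpack_theta <- function(theta, H) {
  list(input_weights = matrix(theta[seq_len(2 * H)], nrow = H),
       hidden_biases = theta[2 * H + seq_len(H)],
       output_weights = theta[3 * H + seq_len(H)],
       output_bias = theta[4 * H + 1])
}

#' Initialise a small tanh perceptron
#'
#' Weights are drawn uniformly on `(-1, 1)/sqrt(fan_in)`; the model has
#' exactly `4H + 1` parameters (2H input weights, H hidden biases, H
#' output weights, one output bias).
#'
#' @param H hidden-unit count (>= 1).
#' @param seed integer seed; identical seeds give identical weights.
#' @param feature_set label of the input pair, `"CPS+VC_LMS"` or
#'   `"SPL+VC_LMS"`.
#' @return an object of class `coughvc_mlp` (input scaling unset until
#'   trained).
#' @export
init_mlp <- function(H, seed = 1L, feature_set = c("CPS+VC_LMS",
                                                   "SPL+VC_LMS")) {
  stopifnot(H >= 1)
  feature_set <- match.arg(feature_set)
  w <- with_seed(seed, list(
    input_weights = matrix(runif(2 * H, -1, 1) / sqrt(2), nrow = H),
    hidden_biases = runif(H, -1, 1) / sqrt(2),
    output_weights = runif(H, -1, 1) / sqrt(H),
    output_bias = 0))
  structure(c(w, list(hidden_units = as.integer(H),
                      input_scaling = NULL,
                      feature_set = feature_set, seed = seed)),
            class = "coughvc_mlp")
}

#' Number of free parameters of a perceptron
#' @param model a `coughvc_mlp`.
#' @return integer, always `4H + 1`.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "coughvc_mlp"))
  length(pack_theta(model))
}

scale_features <- function(X, scaling) {
  sweep(sweep(as.matrix(X), 2, scaling$center), 2, scaling$scale, "/")
}

#' Predict vital capacity from a feature pair
#'
#' Forward pass `output_bias + sum_j v_j tanh(b_j + w_j . x_scaled)` with
#' the per-feature centering/scaling fitted during training.
#'
#' @param object a trained `coughvc_mlp`.
#' @param features numeric length-2 vector, or an n x 2 matrix/data.frame.
#' @param ... unused.
#' @return predicted vital capacity (L), one value per row.
#' @export
predict.coughvc_mlp <- function(object, features, ...) {
  if (is.null(object$input_scaling))
    stop("unscaled model: train it (or set input_scaling) before predicting")
  X <- if (is.null(dim(features))) matrix(features, ncol = 2)
       else as.matrix(features)
  stopifnot(ncol(X) == 2, all(is.finite(X)))
  Xs <- scale_features(X, object$input_scaling)
  A <- tanh(sweep(Xs %*% t(object$input_weights), 2, object$hidden_biases,
                  "+"))
  drop(A %*% object$output_weights) + object$output_bias
}

#' Training configuration for the perceptron
#'
#' Full-batch gradient descent with backtracking (the step is halved until
#' the loss decreases and grown 1.1x on acceptance), a gradient-norm
#' stopping rule, and seeded random restarts keeping the best final loss.
#'
#' @param max_epochs maximum epochs per restart.
#' @param grad_tol gradient-norm stopping tolerance (on standardised data).
#' @param step0 initial step size.
#' @param n_restarts random restarts (the supplied model's own weights are
#'   the first start).
#' @param plateau_tol relative loss-decrease threshold over a 25-epoch
#'   window below which training stops early (0 disables).
#' @return a list of class `coughvc_mlp_hyper`.
#' @export
mlp_hyper <- function(max_epochs = 5000, grad_tol = 1e-6, step0 = 0.1,
                      n_restarts = 5, plateau_tol = 1e-9) {
  structure(list(max_epochs = max_epochs, grad_tol = grad_tol,
                 step0 = step0, n_restarts = n_restarts,
                 plateau_tol = plateau_tol),
            class = "coughvc_mlp_hyper")
}

#' Train the perceptron on measured vital capacities
#'
#' Minimises the RMSE between predictions and measured VC. Features and
#' target are standardised internally on the training data only (the fitted
#' scaling is stored in the model; the target scaling is folded back into
#' the output weights, so predictions are in liters).
#'
#' @param model a `coughvc_mlp` from [init_mlp()].
#' @param X n x 2 feature matrix/data.frame.
#' @param y measured vital capacities (L), > 0.
#' @param hyper an [mlp_hyper()].
#' @param seed seed for the restart draws (default: the model's seed).
#' @return the trained model, with attributes `train_rmse` and `epochs`.
#' @export
train_mlp <- function(model, X, y, hyper = mlp_hyper(), seed = model$seed) {
  stopifnot(inherits(model, "coughvc_mlp"),
            inherits(hyper, "coughvc_mlp_hyper"))
  X <- as.matrix(X)
  stopifnot(ncol(X) == 2, nrow(X) == length(y), all(is.finite(X)),
            all(is.finite(y)))
  if (any(y <= 0)) stop("measured vital capacities must be positive")
  H <- model$hidden_units
  if (nrow(X) < 4 * H + 1)
    warning("fewer observations (", nrow(X), ") than parameters (",
            4 * H + 1, ")")
  # population SD: keeps training exactly invariant under row duplication
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  scaling <- list(center = colMeans(X),
                  scale = pmax(apply(X, 2, pop_sd), 1e-12))
  Xs <- scale_features(X, scaling)
  y_c <- mean(y)
  y_s <- max(pop_sd(y), 1e-12)
  ys <- (y - y_c) / y_s
  starts <- c(list(pack_theta(model)),
              lapply(seq_len(max(0, hyper$n_restarts - 1)), function(r) {
                m <- init_mlp(H, seed = stream_seed(seed, "restart", r),
                              feature_set = model$feature_set)
                pack_theta(m)
              }))
  best <- NULL
  for (th0 in starts) {
    fit <- .mlp_gd(Xs, ys, th0, as.integer(hyper$max_epochs),
                   hyper$grad_tol, hyper$step0,
                   if (is.null(hyper$plateau_tol)) 0 else hyper$plateau_tol)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  w <- unpack_theta(best$theta, H)
  w$output_weights <- w$output_weights * y_s
  w$output_bias <- w$output_bias * y_s + y_c
  out <- model
  out[names(w)] <- w
  out$input_scaling <- scaling
  attr(out, "train_rmse") <- sqrt(best$loss) * y_s
  attr(out, "epochs") <- best$epochs
  out
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

#' Nested leave-one-out cross-validation of the perceptron
#'
#' Outer loop: leave-one-out over the N observations. Inner loop: the N-1
#' training observations are shuffled (seeded) and split into halves of
#' size ceiling/floor; for each candidate H both orientations (train on
#' one half, validate on the other) are evaluated and their RMSEs
#' averaged; the H with the lowest mean inner RMSE is selected (ties to
#' the smallest H). A final model with the selected H is trained on all
#' N-1 observations and predicts the held-out one, so no prediction ever
#' sees its own measured value.
#'
#' @param X n x 2 feature matrix/data.frame.
#' @param y measured vital capacities (L).
#' @param H_grid candidate hidden-unit counts (default 1:3).
#' @param seed master seed; all fold shuffles and restarts derive from it
#'   and from fold/H indices only (never from the data values).
#' @param hyper an [mlp_hyper()].
#' @param feature_set label stored in the result.
#' @return an object of class `coughvc_nested_cv` with `predictions` (one
#'   per observation), `chosen_H` per fold, `inner_rmse` (fold x H
#'   matrix), and overall `rmse`.
#' @export
nested_cv <- function(X, y, H_grid = 1:3, seed = 1L, hyper = mlp_hyper(),
                      feature_set = "CPS+VC_LMS") {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, ncol(X) == 2)
  if (n < 8) stop("nested CV needs at least 8 observations")
  preds <- numeric(n)
  chosen <- integer(n)
  inner <- matrix(NA_real_, n, length(H_grid),
                  dimnames = list(NULL, paste0("H", H_grid)))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ord <- with_seed(stream_seed(seed, "inner_split", i), sample(tr))
    n_a <- ceiling(length(tr) / 2)
    half_a <- ord[seq_len(n_a)]
    half_b <- ord[-seq_len(n_a)]
    for (h_idx in seq_along(H_grid)) {
      H <- H_grid[h_idx]
      rs <- vapply(1:2, function(orient) {
        trn <- if (orient == 1) half_a else half_b
        val <- if (orient == 1) half_b else half_a
        m <- init_mlp(H, seed = stream_seed(seed, "inner_init",
                                            i * 100 + H * 10 + orient))
        m$feature_set <- feature_set
        m <- train_mlp(m, X[trn, , drop = FALSE], y[trn], hyper = hyper)
        rmse(predict(m, X[val, , drop = FALSE]), y[val])
      }, numeric(1))
      inner[i, h_idx] <- mean(rs)
    }
    best_H <- H_grid[which.min(inner[i, ])]   # which.min: ties -> smallest
    chosen[i] <- best_H
    mf <- init_mlp(best_H, seed = stream_seed(seed, "outer_init", i))
    mf$feature_set <- feature_set
    mf <- train_mlp(mf, X[tr, , drop = FALSE], y[tr], hyper = hyper)
    preds[i] <- predict(mf, X[i, , drop = FALSE])
  }
  structure(list(predictions = preds, chosen_H = chosen,
                 inner_rmse = inner, rmse = rmse(preds, y),
                 feature_set = feature_set, seed = seed,
                 H_grid = H_grid),
            class = "coughvc_nested_cv")
}

#' @export
print.coughvc_nested_cv <- function(x, ...) {
  cat(sprintf("<nested LOO CV [%s]: n = %d, RMSE = %.3f L, chosen H: %s>\n",
              x$feature_set, length(x$predictions), x$rmse,
              paste(names(table(x$chosen_H)), table(x$chosen_H),
                    sep = "x", collapse = ", ")))
  invisible(x)
}

#' Serialise a trained perceptron to JSON
#' @param model a trained `coughvc_mlp`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mlp_json <- function(model, path) {
  stopifnot(inherits(model, "coughvc_mlp"))
  obj <- list(hidden_units = model$hidden_units,
              input_weights = model$input_weights,
              hidden_biases = model$hidden_biases,
              output_weights = model$output_weights,
              output_bias = model$output_bias,
              input_scaling = model$input_scaling,
              feature_set = model$feature_set,
              seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a perceptron serialised by [write_mlp_json()]
#' @param path JSON path.
#' @return a `coughvc_mlp`.
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- as.integer(obj$hidden_units)
  structure(list(input_weights = matrix(unlist(obj$input_weights), nrow = H),
                 hidden_biases = as.numeric(obj$hidden_biases),
                 output_weights = as.numeric(obj$output_weights),
                 output_bias = as.numeric(obj$output_bias),
                 hidden_units = H,
                 input_scaling = lapply(obj$input_scaling, as.numeric),
                 feature_set = obj$feature_set,
                 seed = obj$seed),
            class = "coughvc_mlp")
}
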