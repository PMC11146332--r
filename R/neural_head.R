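# One-hidden-layer MLP regression heads trained by L-BFGS with analytic
# gradients; one head per input combination, fed by interim vectors.

ACTIVATIONS <- c("identity", "logistic", "tanh", "relu")

act_fun <- function(name) {
  switch(name,
    identity = list(f = function(z) z, df = function(z, a) 1),
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(z, a) a * (1 - a)),
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    relu = list(f = function(z) pmax(z, 0),
                df = function(z, a) (z > 0) + 0),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

#' Specification of a neural head
#'
#' @param input_dim Length of the interim vector (9, 27, 81 or 243 for the
#'   standard combinations; any positive value is accepted for the raw-input
#'   baseline network).
#' @param hidden_units Hidden-layer size (>= 1).
#' @param activation One of `"identity"`, `"logistic"`, `"tanh"`, `"relu"`.
#' @return An object of class `head_spec`.
#' @export
head_spec <- function(input_dim, hidden_units, activation = "tanh") {
  stopifnot(input_dim >= 1, hidden_units >= 1)
  activation <- match.arg(activation, ACTIVATIONS)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 activation = activation),
            class = "head_spec")
}

#' Training configuration for a neural head
#'
#' The optimizer is limited-memory BFGS (quasi-Newton): at each iteration
#' the search direction is `d_k = -H_k grad E(w_k)` with `H_k` the
#' limited-memory inverse-Hessian estimate, and the step `w_{k+1} = w_k +
#' eta_k d_k` with the step length `eta_k` chosen by the optimizer's line
#' search. The loss is mean squared error.
#'
#' @param max_iterations Iteration cap (default 400).
#' @param tolerance Projected-gradient stopping threshold (default 1e-8).
#' @param seed Integer seed for the small random weight initialisation.
#' @param history L-BFGS memory size (default 10).
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_iterations = 400, tolerance = 1e-8,
                            seed = 1L, history = 10L) {
  stopifnot(max_iterations >= 1, tolerance > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed),
                 history = as.integer(history)),
            class = "training_config")
}

pack_weights <- function(w) {
  c(as.numeric(w$W1), w$b1, w$W2, w$b2)
}

unpack_weights <- function(par, d, h) {
  i <- 0L
  W1 <- matrix(par[seq_len(d * h)], d, h); i <- d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- par[i + seq_len(h)]; i <- i + h
  b2 <- par[i + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(w, X, act) {
  Z <- sweep(X %*% w$W1, 2, w$b1, "+")
  A <- act$f(Z)
  yhat <- drop(A %*% w$W2) + w$b2
  list(Z = Z, A = A, yhat = yhat)
}

#' Fit a neural head
#'
#' Trains a one-hidden-layer perceptron (linear output unit) on interim
#' vectors by L-BFGS with analytic gradients of the mean-squared-error
#' loss. Weights are initialised as small uniform values scaled by layer
#' fan-in under `cfg$seed`, so the same seed and data give identical
#' weights.
#'
#' @param X Matrix of inputs (rows = samples) of width `spec$input_dim`.
#' @param y Numeric target vector (ET0, mm per day).
#' @param spec A [head_spec()].
#' @param cfg A [training_config()].
#' @return An object of class `trained_head` with elements `spec`, `weights`
#'   (list `W1`, `b1`, `W2`, `b2`) and `meta` (seed, iterations, final
#'   loss, convergence flag).
#' @export
fit_head <- function(X, y, spec, cfg = training_config()) {
  stopifnot(inherits(spec, "head_spec"), inherits(cfg, "training_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (ncol(X) != spec$input_dim) {
    stop(sprintf("input has %d columns, spec expects %d", ncol(X),
                 spec$input_dim), call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("X and y lengths differ", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite training inputs", call. = FALSE)
  }
  if (nrow(X) < spec$hidden_units) {
    stop("fewer samples than hidden units", call. = FALSE)
  }
  d <- spec$input_dim; h <- spec$hidden_units; n <- nrow(X)
  act <- act_fun(spec$activation)

  par0 <- with_seed(cfg$seed, function() {
    a1 <- 1 / sqrt(d); a2 <- 1 / sqrt(h)
    c(stats::runif(d * h, -a1, a1), stats::runif(h, -a1, a1),
      stats::runif(h, -a2, a2), stats::runif(1, -a2, a2))
  })

  objective <- function(par) {
    w <- unpack_weights(par, d, h)
    fw <- mlp_forward(w, X, act)
    mean((fw$yhat - y)^2)
  }
  gradient <- function(par) {
    w <- unpack_weights(par, d, h)
    fw <- mlp_forward(w, X, act)
    r <- 2 * (fw$yhat - y) / n
    gW2 <- drop(crossprod(fw$A, r))
    gb2 <- sum(r)
    gZ <- outer(r, w$W2) * act$df(fw$Z, fw$A)
    gW1 <- crossprod(X, gZ)
    gb1 <- colSums(gZ)
    c(as.numeric(gW1), gb1, gW2, gb2)
  }

  fit <- stats::optim(par0, objective, gradient, method = "L-BFGS-B",
                      control = list(maxit = cfg$max_iterations,
                                     pgtol = cfg$tolerance,
                                     lmm = cfg$history))
  structure(list(
    spec = spec,
    weights = unpack_weights(fit$par, d, h),
    meta = list(seed = cfg$seed, iterations = fit$counts[["function"]],
                final_loss = fit$value, converged = fit$convergence == 0)
  ), class = "trained_head")
}

#' @export
print.trained_head <- function(x, ...) {
  cat(sprintf("<trained_head> %d-%d-1 %s, final MSE %.4g\n",
              x$spec$input_dim, x$spec$hidden_units, x$spec$activation,
              x$meta$final_loss))
  invisible(x)
}

#' Predict from a trained head
#'
#' @param h A [fit_head()] result.
#' @param X Matrix of inputs of width `spec$input_dim` (a vector is treated
#'   as a single sample).
#' @return Numeric vector of predictions, mm per day.
#' @export
predict_head <- function(h, X) {
  stopifnot(inherits(h, "trained_head"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != h$spec$input_dim) {
    stop(sprintf("input has %d columns, head expects %d", ncol(X),
                 h$spec$input_dim), call. = FALSE)
  }
  mlp_forward(h$weights, X, act_fun(h$spec$activation))$yhat
}

cv_fold_ids <- function(n, k) {
  # deterministic interleaved assignment; balanced, no RNG involvement
  ((seq_len(n) - 1L) %% k) + 1L
}

#' Grid search over hidden size and activation
#'
#' Evaluates every (hidden_units, activation) pair by k-fold
#' cross-validation (deterministic interleaved folds) and returns the spec
#' with the smallest mean validation MSE. Ties are broken toward fewer
#' hidden units, then toward the earlier activation in `activations`.
#'
#' @param X,y Training inputs and targets.
#' @param hidden_grid Integer vector of hidden sizes (default 2:16).
#' @param activations Character vector of activations to try.
#' @param cfg A [training_config()].
#' @param folds Number of cross-validation folds (default 5, >= 2).
#' @return The winning [head_spec()], with the grid's mean validation
#'   errors attached as attribute `cv_table`.
#' @export
grid_search_head <- function(X, y, hidden_grid = 2:16,
                             activations = c("tanh", "relu", "logistic",
                                             "identity"),
                             cfg = training_config(), folds = 5L) {
  stopifnot(length(hidden_grid) >= 1, folds >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  fold <- cv_fold_ids(n, folds)
  grid <- expand.grid(hidden = sort(unique(as.integer(hidden_grid))),
                      activation = activations, stringsAsFactors = FALSE)
  grid$cv_mse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    spec <- head_spec(ncol(X), grid$hidden[g], grid$activation[g])
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (sum(tr) < spec$hidden_units) return(NA_real_)
      head_f <- fit_head(X[tr, , drop = FALSE], y[tr], spec, cfg)
      mean((predict_head(head_f, X[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    grid$cv_mse[g] <- mean(errs)
  }
  if (all(is.na(grid$cv_mse))) stop("degenerate folds", call. = FALSE)
  # order: score, then fewer hidden units, then activation order as supplied
  act_rank <- match(grid$activation, activations)
  best <- order(grid$cv_mse, grid$hidden, act_rank)[1L]
  out <- head_spec(ncol(X), grid$hidden[best], grid$activation[best])
  attr(out, "cv_table") <- grid
  out
}
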