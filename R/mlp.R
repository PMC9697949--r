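# Feed-forward quantification network: 8 spline features in, one hidden
# layer, 2 linear outputs (log2 ethanol %, log2 acetone %). Trained by BFGS
# on the sum-of-squares loss with analytic gradients; the weight snapshot
# with the lowest test-subset error seen during optimization is kept.

#' Log2 concentration targets
#'
#' Network targets are base-2 logarithms of the mass fractions in percent,
#' matching the serial-dilution design (levels 2^-7 .. 2^-1 % map to the
#' integers and half-integers -7 .. -1).
#'
#' @param c_ethanol,c_acetone Concentration vectors in percent; must be > 0.
#' @return A matrix with columns `log2_ethanol`, `log2_acetone`.
#' @examples
#' target_transform(0.5, 0.0078125)  # -1, -7
#' @export
target_transform <- function(c_ethanol, c_acetone) {
  if (any(c_ethanol <= 0) || any(c_acetone <= 0))
    stop("target_transform: concentrations must be strictly positive")
  cbind(log2_ethanol = log2(c_ethanol), log2_acetone = log2(c_acetone))
}

#' Invert the log2 target transform
#'
#' @param y A matrix (or length-2 vector) of log2 concentrations.
#' @return A matrix with columns `c_ethanol_pct`, `c_acetone_pct`.
#' @export
inverse_target_transform <- function(y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  out <- 2^y
  colnames(out) <- c("c_ethanol_pct", "c_acetone_pct")
  out
}

#' Random learning/test/validation split
#'
#' Permutes the sample indices from a seed and partitions them 70/15/15:
#' the test and validation subsets each get `floor(0.15 n)` samples and the
#' learning subset the remainder, so n = 169 gives 119/25/25.
#'
#' @param n Number of samples (>= 3).
#' @param ratios Length-3 proportions (learning, test, validation), summing
#'   to 1.
#' @param seed Integer seed for the permutation.
#' @return An object of class `dataset_split`: disjoint integer index
#'   vectors `learning`, `test`, `validation` covering `1:n`.
#' @export
split_dataset <- function(n, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  if (n < 3) stop("split_dataset: need n >= 3")
  if (abs(sum(ratios) - 1) > 1e-8) stop("split_dataset: ratios must sum to 1")
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- floor(ratios[2] * n)
  n_val <- floor(ratios[3] * n)
  structure(list(
    learning = sort(perm[seq_len(n - n_test - n_val)]),
    test = sort(perm[n - n_test - n_val + seq_len(n_test)]),
    validation = sort(perm[n - n_val + seq_len(n_val)])
  ), class = "dataset_split")
}

#' Hidden-layer activation functions
#'
#' The four candidate activations of the topology search: `lin` (identity),
#' `log` (logistic, `1/(1+e^-x)`), `exp` (decaying exponential `e^-x`) and
#' `tanh`. Output neurons are always linear.
#'
#' @param name One of `"lin"`, `"log"`, `"exp"`, `"tanh"` (case-insensitive).
#' @param x Numeric input.
#' @return Activation values (or derivatives for `activation_deriv`).
#' @export
activation <- function(name, x) {
  switch(tolower(name),
         lin = x,
         log = stats::plogis(x),
         exp = exp(-x),
         tanh = tanh(x),
         stop("activation: unknown activation '", name, "'"))
}

#' @rdname activation
#' @export
activation_deriv <- function(name, x) {
  switch(tolower(name),
         lin = rep(1, length(x)),
         log = { s <- stats::plogis(x); s * (1 - s) },
         exp = -exp(-x),
         tanh = 1 - tanh(x)^2,
         stop("activation_deriv: unknown activation '", name, "'"))
}

n_params <- function(p_in, h, p_out) p_in * h + h + h * p_out + p_out

unpack_params <- function(par, p_in, h, p_out) {
  i <- 0
  W1 <- matrix(par[i + seq_len(p_in * h)], p_in, h); i <- i + p_in * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * p_out)], h, p_out); i <- i + h * p_out
  b2 <- par[i + seq_len(p_out)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(w, X, act) {
  Z <- X %*% w$W1 + matrix(w$b1, nrow(X), length(w$b1), byrow = TRUE)
  H <- activation(act, Z)
  dim(H) <- dim(Z)
  Y <- H %*% w$W2 + matrix(w$b2, nrow(X), length(w$b2), byrow = TRUE)
  list(Z = Z, H = H, Y = Y)
}

# sum-of-squares loss and its analytic gradient on (X, T)
mlp_loss <- function(par, X, Tm, h, act) {
  w <- unpack_params(par, ncol(X), h, ncol(Tm))
  f <- mlp_forward(w, X, act)
  sum((f$Y - Tm)^2)
}

mlp_grad <- function(par, X, Tm, h, act) {
  w <- unpack_params(par, ncol(X), h, ncol(Tm))
  f <- mlp_forward(w, X, act)
  dY <- 2 * (f$Y - Tm)
  dW2 <- crossprod(f$H, dY)
  db2 <- colSums(dY)
  dZ <- (dY %*% t(w$W2)) * activation_deriv(act, f$Z)
  dim(dZ) <- dim(f$Z)
  dW1 <- crossprod(X, dZ)
  db1 <- colSums(dZ)
  c(as.vector(dW1), db1, as.vector(dW2), db2)
}

init_params <- function(p_in, h, p_out, seed) {
  set.seed(seed)
  c(stats::runif(p_in * h, -0.5, 0.5) / sqrt(p_in),
    stats::runif(h, -0.5, 0.5) / sqrt(p_in),
    stats::runif(h * p_out, -0.5, 0.5) / sqrt(h),
    stats::runif(p_out, -0.5, 0.5) / sqrt(h))
}

scale_features <- function(X, center, scale) {
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

#' Train one quantification network
#'
#' Trains an `8-h-2` perceptron by BFGS on the sum-of-squares loss over the
#' learning subset. Inputs are standardized with learning-subset statistics
#' and targets are mapped to `[-1, 1]` per output (learning-subset range),
#' so saturating activations stay in their useful range. During
#' optimization, every evaluated weight vector is scored on the test subset
#' and the snapshot with the lowest test error is returned (the test set's
#' role is to monitor the learning process). Reported errors are mean
#' squared error per sample per output on the scaled-target scale, for each
#' subset.
#'
#' @param features Numeric matrix (n x 8) of spline features.
#' @param targets Numeric matrix (n x 2) of log2 concentrations.
#' @param split A [split_dataset()] result.
#' @param hidden_size Number of hidden neurons.
#' @param activation Hidden activation name (see [activation()]).
#' @param seed Integer seed for the weight initialization.
#' @param maxit,reltol BFGS iteration cap and relative convergence
#'   tolerance passed to [stats::optim()].
#' @return An object of class `mlp_model`: weights, scalers, configuration
#'   and the per-subset `errors` list.
#' @export
train_mlp <- function(features, targets, split, hidden_size = 4L,
                      activation = "tanh", seed = 1L,
                      maxit = 400L, reltol = 1e-12) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  stopifnot(nrow(features) == nrow(targets))
  act <- tolower(activation)
  li <- split$learning; ti <- split$test; vi <- split$validation
  if (length(li) <= n_params(ncol(features), hidden_size, ncol(targets)))
    warning("train_mlp: learning set (", length(li),
            ") not larger than the number of free weights (",
            n_params(ncol(features), hidden_size, ncol(targets)), ")")

  x_center <- colMeans(features[li, , drop = FALSE])
  x_scale <- apply(features[li, , drop = FALSE], 2, stats::sd)
  x_scale[x_scale == 0 | !is.finite(x_scale)] <- 1
  Xs <- scale_features(features, x_center, x_scale)

  y_lo <- apply(targets[li, , drop = FALSE], 2, min)
  y_hi <- apply(targets[li, , drop = FALSE], 2, max)
  y_center <- (y_lo + y_hi) / 2
  y_scale <- (y_hi - y_lo) / 2
  y_scale[y_scale == 0] <- 1
  Ys <- scale_features(targets, y_center, y_scale)

  XL <- Xs[li, , drop = FALSE]; YL <- Ys[li, , drop = FALSE]
  XT <- Xs[ti, , drop = FALSE]; YT <- Ys[ti, , drop = FALSE]

  h <- as.integer(hidden_size)
  par0 <- init_params(ncol(Xs), h, ncol(Ys), seed)

  tracker <- new.env(parent = emptyenv())
  tracker$best_test <- Inf
  tracker$best_par <- par0
  fn <- function(par) {
    val <- mlp_loss(par, XL, YL, h, act)
    if (!is.finite(val)) return(.Machine$double.xmax)
    if (length(ti) > 0) {
      te <- mlp_loss(par, XT, YT, h, act)
      if (is.finite(te) && te < tracker$best_test) {
        tracker$best_test <- te
        tracker$best_par <- par
      }
    }
    val
  }
  gr <- function(par) mlp_grad(par, XL, YL, h, act)
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  final_par <- if (length(ti) > 0) tracker$best_par else opt$par
  if (!all(is.finite(final_par)) || !is.finite(mlp_loss(final_par, XL, YL, h, act)))
    stop("train_mlp: training failure, non-finite loss")

  mse <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    mlp_loss(final_par, Xs[idx, , drop = FALSE], Ys[idx, , drop = FALSE], h, act) /
      (length(idx) * ncol(Ys))
  }
  w <- unpack_params(final_par, ncol(Xs), h, ncol(Ys))
  structure(list(
    hidden_size = h, activation = act,
    W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    errors = list(learning = mse(li), test = mse(ti), validation = mse(vi)),
    initial_loss = mlp_loss(par0, XL, YL, h, act),
    final_learning_loss = mlp_loss(final_par, XL, YL, h, act),
    seed = as.integer(seed), optim_convergence = opt$convergence
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d-%d-%d, hidden activation %s\n",
              nrow(x$W1), x$hidden_size, ncol(x$W2), x$activation))
  cat(sprintf("  errors (MSE/sample/output, scaled targets): learning %.3g, test %.3g, validation %.3g\n",
              x$errors$learning, x$errors$test, x$errors$validation))
  invisible(x)
}

#' Predict analyte concentrations from spline features
#'
#' Forward pass through a trained network: scale the features, evaluate the
#' network, unscale the outputs and invert the log2 transform.
#'
#' @param object A trained `mlp_model`.
#' @param features A length-8 vector, or a matrix / data frame with 8
#'   feature columns (`f1`..`f8` are picked out of a wider table).
#' @param ... Unused.
#' @return A data frame with the log2 predictions and the concentrations in
#'   percent and ppm (1 % = 10,000 ppm) for both analytes.
#' @export
predict.mlp_model <- function(object, features, ...) {
  X <- as_feature_matrix(features)
  Xs <- scale_features(X, object$x_center, object$x_scale)
  Ys <- mlp_forward(object, Xs, object$activation)$Y
  Y <- sweep(sweep(Ys, 2, object$y_scale, "*"), 2, object$y_center, "+")
  if (any(!is.finite(Y))) stop("predict.mlp_model: non-finite network output")
  conc <- inverse_target_transform(Y)
  data.frame(log2_ethanol = Y[, 1], log2_acetone = Y[, 2],
             c_ethanol_pct = conc[, 1], c_acetone_pct = conc[, 2],
             c_ethanol_ppm = conc[, 1] * 1e4, c_acetone_ppm = conc[, 2] * 1e4)
}

#' Extract the 8-column feature matrix
#'
#' @param features Vector, matrix or data frame; data frames may carry
#'   extra columns, in which case `f1`..`f8` are used.
#' @return An n x 8 numeric matrix.
#' @export
as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    fcols <- paste0("f", 1:8)
    if (all(fcols %in% names(features))) features <- features[fcols]
    features <- as.matrix(features)
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != 8)
    stop("as_feature_matrix: expected 8 feature columns, got ", ncol(features))
  storage.mode(features) <- "double"
  features
}

#' Enumerate the topology-search candidates
#'
#' One row per trained network of the grid search: every combination of
#' hidden size, activation and restart. With hidden sizes 2..9, all four
#' activations and 1000 restarts this enumerates the full 32,000-network
#' search.
#'
#' @param hidden_sizes Integer vector of hidden-layer sizes.
#' @param activations Character vector of activation names.
#' @param restarts Restarts (independently initialized trainings) per cell.
#' @return A data frame with columns `hidden_size`, `activation`, `restart`.
#' @export
grid_candidates <- function(hidden_sizes = 2:9,
                            activations = c("lin", "log", "exp", "tanh"),
                            restarts = 20L) {
  expand.grid(restart = seq_len(restarts), activation = activations,
              hidden_size = hidden_sizes,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 3:1]
}

#' Topology grid search
#'
#' Trains `restarts` networks for every (hidden size, activation) cell,
#' aggregates the mean and minimum subset errors per cell, and selects the
#' network with the smallest validation error. Optionally a parsimony rule
#' restricts the choice to the smallest hidden layer whose best validation
#' error is within `prefer_smallest_within` of the global minimum.
#'
#' @param features,targets,split As in [train_mlp()].
#' @param hidden_sizes Hidden sizes to scan (default 2..9).
#' @param activations Activations to scan (default all four).
#' @param restarts Restarts per cell (default 20).
#' @param seed Master seed; per-restart seeds are derived from it.
#' @param maxit BFGS iteration cap per training.
#' @param prefer_smallest_within Parsimony tolerance on the validation
#'   error (absolute, scaled-target MSE), or `NULL` (default) for the
#'   global minimum.
#' @return A list of class `grid_search` with elements `report` (one row
#'   per cell: mean/min learning, test and validation errors, `n_restarts`,
#'   `n_failed`), `best_model`, `best_cell` and the per-candidate `candidates`
#'   data frame.
#' @export
grid_search <- function(features, targets, split,
                        hidden_sizes = 2:9,
                        activations = c("lin", "log", "exp", "tanh"),
                        restarts = 20L, seed = 1L, maxit = 400L,
                        prefer_smallest_within = NULL) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  cand <- grid_candidates(hidden_sizes, activations, restarts)
  cand$seed <- NA_integer_
  cand$learning_err <- cand$test_err <- cand$validation_err <- NA_real_
  cand$failed <- FALSE
  best_by_h <- list()  # best model per hidden size, for the parsimony rule
  for (k in seq_len(nrow(cand))) {
    s <- derive_seed(seed, k)
    cand$seed[k] <- s
    m <- tryCatch(
      suppressWarnings(train_mlp(features, targets, split, cand$hidden_size[k],
                                 cand$activation[k], seed = s, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(m) || !is.finite(m$errors$validation)) {
      cand$failed[k] <- TRUE
      next
    }
    cand$learning_err[k] <- m$errors$learning
    cand$test_err[k] <- m$errors$test
    cand$validation_err[k] <- m$errors$validation
    hkey <- as.character(cand$hidden_size[k])
    if (is.null(best_by_h[[hkey]]) ||
        m$errors$validation < best_by_h[[hkey]]$errors$validation)
      best_by_h[[hkey]] <- m
  }

  cells <- unique(cand[, c("hidden_size", "activation")])
  agg <- function(f, col) vapply(seq_len(nrow(cells)), function(i) {
    v <- cand[[col]][cand$hidden_size == cells$hidden_size[i] &
                       cand$activation == cells$activation[i] & !cand$failed]
    if (length(v) == 0) NA_real_ else f(v)
  }, numeric(1))
  report <- data.frame(
    hidden_size = cells$hidden_size, activation = cells$activation,
    mean_learning_err = agg(mean, "learning_err"),
    mean_test_err = agg(mean, "test_err"),
    mean_validation_err = agg(mean, "validation_err"),
    min_validation_err = agg(min, "validation_err"),
    n_restarts = restarts,
    n_failed = vapply(seq_len(nrow(cells)), function(i)
      sum(cand$failed[cand$hidden_size == cells$hidden_size[i] &
                        cand$activation == cells$activation[i]]), numeric(1))
  )

  if (all(cand$failed)) stop("grid_search: every candidate failed")
  hs <- sort(as.integer(names(best_by_h)))
  best_vals <- vapply(as.character(hs), function(k) best_by_h[[k]]$errors$validation,
                      numeric(1))
  global_min <- min(best_vals)
  chosen_h <- if (!is.null(prefer_smallest_within))
    hs[which(best_vals <= global_min + prefer_smallest_within)[1]]
  else hs[which.min(best_vals)]
  best_model <- best_by_h[[as.character(chosen_h)]]

  structure(list(report = report, best_model = best_model,
                 best_cell = list(hidden_size = best_model$hidden_size,
                                  activation = best_model$activation,
                                  validation_err = best_model$errors$validation,
                                  seed = best_model$seed),
                 candidates = cand),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("grid_search: %d candidates over %d cells; selected %d-%d-%d (%s), validation error %.4g\n",
              nrow(x$candidates), nrow(x$report), nrow(x$best_model$W1),
              x$best_model$hidden_size, ncol(x$best_model$W2),
              x$best_model$activation, x$best_cell$validation_err))
  invisible(x)
}
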