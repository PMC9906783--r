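#' Hyperparameter search space for the neural-network regressor
#'
#' Single-hidden-layer feed-forward networks (with optional input-to-output
#' bypass connections) sampled by random search: hidden width, L2 weight
#' decay, optimizer iteration budget, and the bypass toggle. The search
#' budget is the number of candidate configurations evaluated by
#' validation MAE.
#'
#' @param size_range integer range of hidden-layer widths.
#' @param decay_log10_range log10 range of the L2 weight decay.
#' @param maxit_choices candidate optimizer iteration caps.
#' @param skip_choices candidate bypass-connection settings.
#' @param budget number of sampled configurations (default 20; raise for a
#'   more thorough search).
#' @return object of class `hyperparam_space`.
#' @export
hyperparam_space <- function(size_range = c(4L, 24L),
                             decay_log10_range = c(-5, -1),
                             maxit_choices = c(200L, 500L),
                             skip_choices = c(TRUE, FALSE),
                             budget = 20L) {
  stopifnot(budget >= 1, size_range[2] >= size_range[1],
            decay_log10_range[2] > decay_log10_range[1])
  structure(as.list(environment()), class = "hyperparam_space")
}

.sample_hyperparams <- function(space) {
  list(size = sample(seq(space$size_range[1], space$size_range[2]), 1),
       decay = 10^stats::runif(1, space$decay_log10_range[1],
                               space$decay_log10_range[2]),
       maxit = sample(space$maxit_choices, 1),
       skip = sample(space$skip_choices, 1))
}

.fit_nnet <- function(Z, y, hp, seed) {
  set.seed(seed)
  nnet::nnet(Z, y, size = hp$size, decay = hp$decay, maxit = hp$maxit,
             skip = hp$skip, linout = TRUE, trace = FALSE,
             MaxNWts = 100000)
}

.mae <- function(a, b) mean(abs(a - b))

#' Train a neural-network property regressor
#'
#' Protocol: standardize features on train + validation and drop invariant
#' columns; sample `space$budget` hyperparameter configurations, fit each
#' on the training rows, and keep the configuration with the lowest
#' validation MAE; retrain the chosen configuration on the combined
#' train + validation data. Predictions are floored at zero (negative
#' emission energies, lifetimes or spectral integrals are unphysical).
#' The last hidden layer is retained as a latent-space extractor and the
#' training-set latent vectors are cached for distance-based uncertainty
#' quantification.
#'
#' @param X feature matrix (raw scale), rows named by complex id.
#' @param y non-negative response vector aligned with `X`.
#' @param train,val row indices (or rownames) of the training and
#'   validation partitions.
#' @param space a [hyperparam_space()].
#' @param seed integer seed controlling sampling and weight initialization.
#' @param target name of the modeled property (metadata).
#' @return object of class `ir_model` (kind `"ann"`).
#' @export
train_ann <- function(X, y, train, val, space = hyperparam_space(),
                      seed = 1, target = "y") {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values")
  tr <- .resolve_rows(X, train); va <- .resolve_rows(X, val)
  prep <- fit_preprocessor(X[c(tr, va), , drop = FALSE])
  Z <- apply_preprocessor(prep, X)
  set.seed(seed)
  cands <- lapply(seq_len(space$budget), function(i) .sample_hyperparams(space))
  val_mae <- vapply(seq_along(cands), function(i) {
    fit <- .fit_nnet(Z[tr, , drop = FALSE], y[tr], cands[[i]], seed + i)
    pred <- pmax(as.numeric(stats::predict(fit, Z[va, , drop = FALSE])), 0)
    .mae(pred, y[va])
  }, numeric(1))
  best <- cands[[which.min(val_mae)]]
  fit <- .fit_nnet(Z[c(tr, va), , drop = FALSE], y[c(tr, va)], best,
                   seed + space$budget + 1L)
  latents <- .nnet_hidden(fit, Z[c(tr, va), , drop = FALSE])
  structure(
    list(kind = "ann", fit = fit, prep = prep, target = target,
         hyperparams = best, val_mae = min(val_mae),
         latent_cache = latents, train_ids = rownames(X)[c(tr, va)]),
    class = "ir_model"
  )
}

# hidden-layer activations of a fitted single-hidden-layer nnet
.nnet_hidden <- function(fit, Z) {
  n_in <- fit$n[1]; n_hid <- fit$n[2]
  w <- fit$wts
  H <- matrix(0, nrow(Z), n_hid)
  for (h in seq_len(n_hid)) {
    off <- (h - 1) * (n_in + 1)
    b <- w[off + 1]
    wi <- w[off + 1 + seq_len(n_in)]
    H[, h] <- 1 / (1 + exp(-(b + Z %*% wi)))
  }
  H
}

.resolve_rows <- function(X, idx) {
  if (is.character(idx)) {
    out <- match(idx, rownames(X))
    if (anyNA(out)) stop("unknown row ids in split")
    out
  } else as.integer(idx)
}

#' Train a random-forest property regressor
#'
#' Standard impurity-based random forest (via the randomForest package) on
#' standardized features, with floored predictions.
#'
#' @inheritParams train_ann
#' @param ntree number of trees.
#' @return an `ir_model` (kind `"rf"`).
#' @export
train_rf <- function(X, y, train, val = NULL, seed = 1, ntree = 300,
                     target = "y") {
  X <- as.matrix(X)
  tr <- .resolve_rows(X, train)
  if (!is.null(val)) tr <- c(tr, .resolve_rows(X, val))
  prep <- fit_preprocessor(X[tr, , drop = FALSE])
  Z <- apply_preprocessor(prep, X)
  set.seed(seed)
  fit <- randomForest::randomForest(Z[tr, , drop = FALSE], y[tr],
                                    ntree = ntree)
  structure(
    list(kind = "rf", fit = fit, prep = prep, target = target,
         train_ids = rownames(X)[tr]),
    class = "ir_model"
  )
}

#' Train a ridge-regression property baseline
#'
#' Penalized linear fit (SVD-based, via MASS) on standardized features,
#' with floored predictions.
#'
#' @inheritParams train_rf
#' @param lambda ridge penalty (default 1e-3; use a tiny value for
#'   near-ordinary least squares).
#' @return an `ir_model` (kind `"ridge"`).
#' @export
train_ridge <- function(X, y, train, val = NULL, lambda = 1e-3,
                        target = "y") {
  X <- as.matrix(X)
  tr <- .resolve_rows(X, train)
  if (!is.null(val)) tr <- c(tr, .resolve_rows(X, val))
  prep <- fit_preprocessor(X[tr, , drop = FALSE])
  Z <- apply_preprocessor(prep, X)
  if (ncol(Z) == 1) {
    # one-predictor closed form (MASS::lm.ridge needs >= 2 columns)
    z <- Z[tr, 1] - mean(Z[tr, 1]); yc <- y[tr] - mean(y[tr])
    beta <- sum(z * yc) / (sum(z^2) + lambda)
    coefs <- c(mean(y[tr]) - beta * mean(Z[tr, 1]), beta)
    names(coefs) <- c("", colnames(Z))
  } else {
    df <- data.frame(y = y[tr], Z[tr, , drop = FALSE])
    fit <- MASS::lm.ridge(y ~ ., data = df, lambda = lambda)
    coefs <- stats::coef(fit)
  }
  structure(
    list(kind = "ridge", fit = list(intercept = coefs[1],
                                    beta = coefs[-1]),
         prep = prep, target = target, train_ids = rownames(X)[tr]),
    class = "ir_model"
  )
}

#' Predict with a trained phosphor property model
#'
#' @param object an `ir_model`.
#' @param X feature matrix on the raw scale (same columns as training).
#' @param ... unused.
#' @return numeric predictions, floored at zero.
#' @export
predict.ir_model <- function(object, X, ...) {
  Z <- apply_preprocessor(object$prep, as.matrix(X))
  p <- switch(object$kind,
    ann = as.numeric(stats::predict(object$fit, Z)),
    rf = as.numeric(stats::predict(object$fit, Z)),
    ridge = as.numeric(object$fit$intercept + Z %*% object$fit$beta),
    stop("unknown model kind")
  )
  pmax(p, 0)
}

#' @export
print.ir_model <- function(x, ...) {
  cat("<ir_model> kind=", x$kind, ", target=", x$target, ", ",
      length(x$train_ids), " training complexes\n", sep = "")
  invisible(x)
}

#' Impurity-based feature importances of a random-forest model
#'
#' Mean decrease in node impurity per feature, normalized to sum to 1.
#'
#' @param model an `ir_model` of kind `"rf"`.
#' @return named numeric vector summing to 1.
#' @export
rf_importances <- function(model) {
  if (model$kind != "rf") stop("importances require a random-forest model")
  imp <- randomForest::importance(model$fit, type = 2)[, 1]
  imp / sum(imp)
}

#' Aggregate feature importances by ligand block
#'
#' Sums importances over features whose names carry a `cn_`/`nn_` block
#' prefix, quantifying the relative weight of cyclometalating versus
#' ancillary ligand descriptors in a fitted model.
#'
#' @param importances named numeric vector (e.g. from [rf_importances()]).
#' @return named numeric vector `c(cn = ..., nn = ...)`.
#' @export
aggregate_importance_by_ligand <- function(importances) {
  nm <- names(importances)
  c(cn = sum(importances[startsWith(nm, "cn_")]),
    nn = sum(importances[startsWith(nm, "nn_")]))
}

#' Evaluate a model on a held-out set
#'
#' Reports the mean absolute error in native units and the scaled MAE,
#' defined as MAE divided by the response range over the full modeled
#' (post-filter) dataset -- a unit-free figure comparable across targets.
#'
#' @param model an `ir_model`.
#' @param X_test,y_test held-out features and responses.
#' @param y_range range (max - min) of the target over the modeled dataset;
#'   defaults to the range of `y_test`.
#' @return list with `mae` and `scaled_mae`.
#' @export
evaluate_model <- function(model, X_test, y_test, y_range = NULL) {
  if (length(y_test) == 0) stop("empty test set")
  pred <- predict(model, X_test)
  mae <- .mae(pred, y_test)
  if (is.null(y_range)) y_range <- diff(range(y_test))
  list(mae = mae, scaled_mae = mae / y_range)
}
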