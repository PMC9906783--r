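#' Latent-space embedding of inputs under a neural-network model
#'
#' Last-hidden-layer activations of the network (the layer from which the
#' final prediction is made by linear readout), computed after the model's
#' own preprocessing. Only defined for models of kind `"ann"`.
#'
#' @param model an `ir_model` of kind `"ann"`.
#' @param X raw-scale feature matrix.
#' @return numeric matrix, one latent vector per row of `X`.
#' @export
latent_embed <- function(model, X) {
  if (model$kind != "ann") stop("latent embedding requires an ANN model")
  Z <- apply_preprocessor(model$prep, as.matrix(X))
  .nnet_hidden(model$fit, Z)
}

#' Latent-space distance uncertainty metric
#'
#' Mean Euclidean distance from each query latent vector to its `k`
#' nearest neighbors among the training-set latent vectors. Larger values
#' flag queries unlike anything the model was trained on.
#'
#' @param query latent matrix (rows = queries) or single vector.
#' @param training_latents matrix of cached training latents.
#' @param k neighbor count (default 10).
#' @return numeric vector of raw distances, one per query.
#' @export
uq_distance <- function(query, training_latents, k = 10) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  if (nrow(training_latents) < k) {
    stop("need at least k = ", k, " training latent vectors")
  }
  apply(query, 1, function(q) {
    d2 <- colSums((t(training_latents) - q)^2)
    mean(sqrt(sort(d2)[seq_len(k)]))
  })
}

#' Calibrate a UQ normalization and acceptance cutoff
#'
#' From the raw latent distances of a reference set (typically the
#' random-split test set of the final model): the normalization constant is
#' the maximum reference distance, so the most distant reference complex
#' has a normalized metric of 1.0; the cutoff is `mean + n_sd * SD` of the
#' normalized reference distances (default two standard deviations above
#' the mean), optionally capped.
#'
#' @param reference_distances raw distances of the reference set.
#' @param n_sd standard-deviation multiplier (default 2).
#' @param cap upper bound on the cutoff (default `Inf`).
#' @return list with `normalization` and `cutoff`.
#' @export
calibrate_cutoff <- function(reference_distances, n_sd = 2, cap = Inf) {
  stopifnot(length(reference_distances) >= 1, n_sd > 0)
  norm <- max(reference_distances)
  if (norm <= 0) stop("degenerate reference set: all latent distances are zero")
  z <- reference_distances / norm
  sdv <- if (length(z) > 1) stats::sd(z) else 0
  list(normalization = norm, cutoff = min(mean(z) + n_sd * sdv, cap))
}

#' Model error as a function of the UQ cutoff
#'
#' For a grid of normalized cutoffs, retains the test complexes whose
#' normalized latent distance is at or below the cutoff and reports the
#' retained fraction and the MAE over the retained subset. Empty bins are
#' flagged with `NA` MAE.
#'
#' @param model an `ir_model` of kind `"ann"`.
#' @param X_test,y_test held-out features and responses.
#' @param normalization normalization constant from [calibrate_cutoff()]
#'   (default: max test distance).
#' @param cutoffs normalized cutoff grid (default 20 evenly spaced values).
#' @param k neighbor count.
#' @return data.frame with columns `cutoff`, `retained_fraction`, `mae`.
#' @export
error_vs_cutoff <- function(model, X_test, y_test, normalization = NULL,
                            cutoffs = seq(0.05, 1, length.out = 20), k = 10) {
  d <- uq_distance(latent_embed(model, X_test), model$latent_cache, k)
  if (is.null(normalization)) normalization <- max(d)
  z <- d / normalization
  pred <- predict(model, X_test)
  err <- abs(pred - y_test)
  out <- lapply(cutoffs, function(ct) {
    keep <- z <= ct
    data.frame(cutoff = ct, retained_fraction = mean(keep),
               mae = if (any(keep)) mean(err[keep]) else NA_real_)
  })
  do.call(rbind, out)
}

#' UQ-gated screening of hypothetical complexes
#'
#' Predicts all three target properties for each candidate complex and
#' gates each prediction by its per-model normalized latent distance; a
#' candidate is accepted overall only if it passes the gate for every
#' model. Among accepted candidates, the top and bottom `q_extreme`
#' quantiles of each predicted property are marked extreme, and ligand
#' occurrence frequencies among those extremes are tabulated (the route by
#' which promising ligands are identified).
#'
#' @param candidates data.frame with `complex_id`, `cn_id`, `nn_id`.
#' @param X feature matrix for the candidates (rows aligned).
#' @param models named list of three `ir_model` ANNs
#'   (`em5050`, `lifetime`, `si`).
#' @param policies named list of per-model calibrations, each a list with
#'   `normalization` and `cutoff` (from [calibrate_cutoff()]).
#' @param q_extreme per-tail quantile defining extreme predictions
#'   (default 0.025).
#' @param k neighbor count for the UQ metric.
#' @return object of class `screening_report`: list with `table`
#'   (per-candidate predictions, normalized distances, gates, acceptance),
#'   `accepted_ids`, and `ligand_frequencies` (per target and tail).
#' @export
screen_complexes <- function(candidates, X, models, policies,
                             q_extreme = 0.025, k = 10) {
  stopifnot(all(names(models) %in% names(policies)))
  tab <- candidates
  accept_all <- rep(TRUE, nrow(tab))
  for (m in names(models)) {
    model <- models[[m]]
    pol <- policies[[m]]
    d <- uq_distance(latent_embed(model, X), model$latent_cache, k)
    z <- d / pol$normalization
    ok <- z <= pol$cutoff
    tab[[paste0("pred_", m)]] <- predict(model, X)
    tab[[paste0("uq_", m)]] <- z
    tab[[paste0("accept_", m)]] <- ok
    accept_all <- accept_all & ok
  }
  tab$accepted <- accept_all
  acc <- tab[tab$accepted, , drop = FALSE]
  freqs <- list()
  for (m in names(models)) {
    p <- acc[[paste0("pred_", m)]]
    if (nrow(acc) == 0) {
      freqs[[m]] <- list(high = table(character(0)),
                         low = table(character(0)))
      next
    }
    hi <- p >= stats::quantile(p, 1 - q_extreme)
    lo <- p <= stats::quantile(p, q_extreme)
    freqs[[m]] <- list(
      high = sort(table(c(acc$cn_id[hi], acc$nn_id[hi])), decreasing = TRUE),
      low = sort(table(c(acc$cn_id[lo], acc$nn_id[lo])), decreasing = TRUE)
    )
  }
  structure(list(table = tab, accepted_ids = acc$complex_id,
                 ligand_frequencies = freqs, q_extreme = q_extreme),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report> ", nrow(x$table), " candidates, ",
      length(x$accepted_ids), " accepted by all UQ gates\n", sep = "")
  invisible(x)
}
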