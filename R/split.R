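#' Random train/validation/test split
#'
#' Partitions complexes at the given fractions (default 70/15/15).
#' Sizes are `floor(n*train)` and `floor(n*val)` with the remainder going
#' to test, so 1380 complexes split 966/207/207. Reproducible under `seed`.
#'
#' @param ids character vector of complex ids (or any unit ids).
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed.
#' @return list with character vectors `train`, `val`, `test` and
#'   `mode = "random"`.
#' @export
make_random_split <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  n <- length(ids)
  if (n < 3) stop("need at least 3 complexes to split")
  set.seed(seed)
  perm <- sample(ids)
  n_train <- floor(n * fractions[1] + 1e-9)
  n_val <- floor(n * fractions[2] + 1e-9)
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[(n_train + n_val + 1):n],
       mode = "random", seed = seed)
}

#' Ligand-grouped train/validation/test split
#'
#' Every complex containing at least one held-out ligand goes to the test
#' set and is excluded from training and validation entirely; the remaining
#' complexes are split train/val. This probes generalization to unseen
#' ligand chemistry.
#'
#' @param complexes data.frame with `complex_id`, `cn_id`, `nn_id`.
#' @param held_out_ligand_ids non-empty character vector of ligand ids.
#' @param val_fraction fraction of the non-held-out complexes used for
#'   validation (default 0.15/0.85, mirroring the random split's ratio).
#' @param seed integer seed for the train/val shuffle.
#' @return list with `train`, `val`, `test` complex-id vectors,
#'   `held_out_ligand_ids` and `mode = "grouped"`.
#' @export
make_grouped_split <- function(complexes, held_out_ligand_ids,
                               val_fraction = 0.15 / 0.85, seed = 1) {
  if (length(held_out_ligand_ids) == 0) stop("held-out ligand set is empty")
  held <- complexes$cn_id %in% held_out_ligand_ids |
    complexes$nn_id %in% held_out_ligand_ids
  if (all(held)) stop("held-out ligands cover the entire dataset")
  test <- complexes$complex_id[held]
  rest <- complexes$complex_id[!held]
  set.seed(seed)
  perm <- sample(rest)
  n_val <- floor(length(rest) * val_fraction)
  list(train = perm[(n_val + 1):length(perm)],
       val = perm[seq_len(n_val)],
       test = test,
       held_out_ligand_ids = held_out_ligand_ids,
       mode = "grouped", seed = seed)
}

#' Select the most dissimilar ligands of each role
#'
#' Ranks ligands by their mean Dice similarity (circular fingerprints) to
#' all same-role peers and returns the `k` least similar of each role --
#' the protocol used to pick held-out ligands for grouped splits. Ties are
#' broken lexicographically by ligand id.
#'
#' @param library a `ligand_library`.
#' @param k_cn,k_nn how many CN / NN ligands to select.
#' @param radius,nbits fingerprint parameters.
#' @return character vector of selected ligand ids (CN first).
#' @export
select_dissimilar_ligands <- function(library, k_cn, k_nn,
                                      radius = 3, nbits = 2048) {
  pick <- function(ligs, k) {
    stopifnot(k <= length(ligs))
    if (k == 0) return(character(0))
    fps <- lapply(ligs, morgan_fingerprint, radius = radius, nbits = nbits)
    ids <- names(ligs)
    mean_sim <- vapply(seq_along(fps), function(i) {
      others <- setdiff(seq_along(fps), i)
      if (!length(others)) return(0)
      mean(vapply(others, function(j)
        dice_similarity(fps[[i]], fps[[j]]), numeric(1)))
    }, numeric(1))
    ids[order(mean_sim, ids)][seq_len(k)]
  }
  c(pick(library$cn, k_cn), pick(library$nn, k_nn))
}

#' Filter dim complexes before training
#'
#' Removes complexes whose emission spectral integral is below `threshold`
#' (default 1e5 photon counts), but only for the `em5050` and `lifetime`
#' prediction tasks, where measurements on dim phosphors are noisy; models
#' of the spectral integral itself keep all complexes.
#'
#' @param complexes data.frame with a `spectral_integral_counts` column.
#' @param target one of `"em5050"`, `"lifetime"`, `"si"`.
#' @param threshold photon-count threshold.
#' @return the filtered (or unchanged) data.frame.
#' @export
filter_dim <- function(complexes, target, threshold = 1e5) {
  target <- match.arg(target, c("em5050", "lifetime", "si"))
  if (target == "si") return(complexes)
  complexes[complexes$spectral_integral_counts >= threshold, , drop = FALSE]
}

#' Fit a feature preprocessor (standardize, drop invariant columns)
#'
#' Centers and scales each feature to zero mean and unit variance over the
#' fitting data (train + validation) and drops columns with zero variance
#' there.
#'
#' @param X numeric feature matrix (rows = complexes).
#' @return object of class `preprocessor` with `mean`, `sd`, `keep`.
#' @export
fit_preprocessor <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- which(sdv > 0 & is.finite(sdv))
  structure(list(mean = mu, sd = sdv, keep = keep,
                 names = colnames(X)), class = "preprocessor")
}

#' Apply / invert a fitted preprocessor
#' @param prep a `preprocessor`.
#' @param X matrix with the columns the preprocessor was fitted on.
#' @return transformed matrix on the retained columns.
#' @export
apply_preprocessor <- function(prep, X) {
  X <- as.matrix(X)
  k <- prep$keep
  sweep(sweep(X[, k, drop = FALSE], 2, prep$mean[k]), 2, prep$sd[k], "/")
}

#' @rdname apply_preprocessor
#' @param Z transformed matrix to map back to the original scale.
#' @export
invert_preprocessor <- function(prep, Z) {
  k <- prep$keep
  sweep(sweep(as.matrix(Z), 2, prep$sd[k], "*"), 2, prep$mean[k], "+")
}
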