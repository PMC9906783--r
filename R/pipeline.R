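#' Featurize a set of complexes with a chosen feature family
#'
#' Dispatch over the implemented representations:
#' `"electronic"` (12 ligand descriptors), `"ligand-rac"` (70 ligand-only
#' autocorrelations), `"rac"` (196 whole-complex autocorrelations),
#' `"cd-rac"` (222 Coulomb-decay autocorrelations; complexes are assembled
#' with an idealized 3D embedding), `"morgan"` (concatenated fingerprint
#' bits), and `"dice"` / `"tanimoto"` (similarity to a reference schema).
#'
#' @param complexes data.frame with `complex_id`, `cn_id`, `nn_id`.
#' @param library a `ligand_library` resolving all ids.
#' @param set feature family name.
#' @param electronics `electronic_table` (required for `"electronic"`).
#' @param schema `similarity_schema` (required for `"dice"`/`"tanimoto"`).
#' @param radius,nbits fingerprint parameters for `"morgan"`.
#' @return numeric matrix, one named row per complex.
#' @export
featurize_complexes <- function(complexes, library,
                                set = c("electronic", "ligand-rac", "rac",
                                        "cd-rac", "morgan", "dice",
                                        "tanimoto"),
                                electronics = NULL, schema = NULL,
                                radius = 3, nbits = 2048) {
  set <- match.arg(set)
  if (set == "electronic") {
    if (is.null(electronics)) stop("'electronic' features need a table")
    return(electronic_feature_matrix(complexes, electronics))
  }
  if (set %in% c("dice", "tanimoto") && is.null(schema)) {
    stop("similarity features need a reference schema")
  }
  per_pair <- function(cn_id, nn_id) {
    cn <- get_ligand(library, cn_id)
    nn <- get_ligand(library, nn_id)
    switch(set,
      `ligand-rac` = ligand_racs(cn, nn),
      rac = complex_racs(assemble_complex(cn, nn)),
      `cd-rac` = cd_racs(assemble_complex(cn, nn, embed = TRUE)),
      morgan = morgan_features(cn, nn, radius, nbits),
      dice = dice_features(cn, nn, schema, "dice"),
      tanimoto = dice_features(cn, nn, schema, "tanimoto")
    )
  }
  # featurization is ligand-level for every family, so compute once per
  # distinct (cn, nn) pair component and reuse across the grid
  pairs <- unique(complexes[, c("cn_id", "nn_id")])
  feats <- lapply(seq_len(nrow(pairs)), function(i)
    per_pair(pairs$cn_id[i], pairs$nn_id[i]))
  key <- paste(pairs$cn_id, pairs$nn_id)
  m <- do.call(rbind, feats[match(paste(complexes$cn_id, complexes$nn_id),
                                  key)])
  rownames(m) <- complexes$complex_id
  m
}

.target_column <- function(target) {
  switch(target, em5050 = "em5050_eV", lifetime = "lifetime_us",
         si = "spectral_integral_counts", stop("unknown target ", target))
}

#' Run the end-to-end modeling pipeline on a synthetic dataset
#'
#' simulate -> featurize -> dim-filter -> split -> train (ANN) -> evaluate
#' -> calibrate the latent-space UQ cutoff on the test set. All randomness
#' derives from one master seed (dataset, split and training seeds are
#' fixed offsets of it). Artifacts (config snapshot, dataset CSVs, split
#' manifest, metrics, UQ calibration) are written under `out_dir` when
#' given.
#'
#' @param target `"em5050"`, `"lifetime"` or `"si"`.
#' @param feature_set feature family (see [featurize_complexes()]).
#' @param split_mode `"random"` or `"grouped"`.
#' @param n_cn,n_nn synthetic library sizes.
#' @param trend generating [trend_model()].
#' @param space ANN [hyperparam_space()].
#' @param n_held_out numbers of dissimilar CN/NN ligands held out in
#'   grouped mode (default `c(3, 2)`).
#' @param seed master seed.
#' @param out_dir optional artifact directory.
#' @return list with the dataset, split, model, test metrics and UQ
#'   calibration.
#' @export
run_pipeline <- function(target = "em5050", feature_set = "electronic",
                         split_mode = c("random", "grouped"),
                         n_cn = 60, n_nn = 23, trend = trend_model(),
                         space = hyperparam_space(budget = 8L),
                         n_held_out = c(3, 2), seed = 1, out_dir = NULL) {
  split_mode <- match.arg(split_mode)
  ds <- make_dataset(n_cn, n_nn, trend, seed)
  modeled <- filter_dim(ds$complexes, target)
  if (split_mode == "random") {
    split <- make_random_split(modeled$complex_id, seed = seed + 10L)
  } else {
    held <- select_dissimilar_ligands(ds$library, n_held_out[1],
                                      n_held_out[2])
    split <- make_grouped_split(modeled, held, seed = seed + 10L)
  }
  schema <- NULL
  if (feature_set %in% c("dice", "tanimoto")) {
    # reference schema restricted to ligands present in train+val rows:
    # held-out ligands must not leak into the representation
    tv <- modeled[modeled$complex_id %in% c(split$train, split$val), ]
    schema <- similarity_schema(
      ds$library,
      cn_ids = intersect(names(ds$library$cn), unique(tv$cn_id)),
      nn_ids = intersect(names(ds$library$nn), unique(tv$nn_id)))
  }
  X <- featurize_complexes(modeled, ds$library, feature_set,
                           electronics = ds$electronics, schema = schema)
  y <- stats::setNames(modeled[[.target_column(target)]], modeled$complex_id)
  model <- train_ann(X, y, split$train, split$val, space, seed = seed + 20L,
                     target = target)
  Xte <- X[split$test, , drop = FALSE]
  metrics <- evaluate_model(model, Xte, y[split$test],
                            y_range = diff(range(y)))
  d_ref <- uq_distance(latent_embed(model, Xte), model$latent_cache)
  uq <- calibrate_cutoff(d_ref)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(ds, file.path(out_dir, "data"))
    jsonlite::write_json(
      list(target = target, feature_set = feature_set,
           split_mode = split_mode, n_cn = n_cn, n_nn = n_nn, seed = seed,
           budget = space$budget),
      file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(split[c("train", "val", "test", "mode")],
                         file.path(out_dir, "split.json"))
    jsonlite::write_json(c(metrics, uq, n_test = length(split$test)),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(dataset = ds, split = split, model = model, metrics = metrics,
       uq = uq)
}

#' Compare feature families across targets and split protocols
#'
#' Trains one ANN per (feature set, target, split mode) cell on a shared
#' synthetic dataset and tabulates test MAE and scaled MAE -- the synthetic
#' analogue of a feature-set benchmark.
#'
#' @param feature_sets character vector of feature families.
#' @param targets character vector of targets.
#' @param split_modes character vector of split protocols.
#' @param seed master seed (shared across cells).
#' @param ... forwarded to [run_pipeline()].
#' @return data.frame with one row per cell: `feature_set`, `target`,
#'   `split_mode`, `mae`, `scaled_mae`, `n_test`.
#' @export
compare_feature_sets <- function(feature_sets = c("electronic", "dice"),
                                 targets = c("em5050", "lifetime", "si"),
                                 split_modes = c("random", "grouped"),
                                 seed = 1, ...) {
  grid <- expand.grid(feature_set = feature_sets, target = targets,
                      split_mode = split_modes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- run_pipeline(target = grid$target[i],
                        feature_set = grid$feature_set[i],
                        split_mode = grid$split_mode[i], seed = seed, ...)
    data.frame(grid[i, ], mae = res$metrics$mae,
               scaled_mae = res$metrics$scaled_mae,
               n_test = length(res$split$test), row.names = NULL)
  })
  do.call(rbind, rows)
}
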