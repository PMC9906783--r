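test_that("latent distances match an exhaustive-sort kNN oracle", {
  set.seed(20)
  L <- matrix(rnorm(100 * 6), ncol = 6)
  Q <- matrix(rnorm(10 * 6), ncol = 6)
  d <- uq_distance(Q, L, k = 10)
  oracle <- apply(Q, 1, function(q) {
    all_d <- sort(apply(L, 1, function(t) sqrt(sum((t - q)^2))))
    mean(all_d[1:10])
  })
  expect_equal(d, oracle, tolerance = 1e-12)
  # coincident query has zero distance
  Lq <- rbind(L, matrix(rep(L[1, ], 12), ncol = 6, byrow = TRUE))
  expect_equal(uq_distance(L[1, ], Lq, k = 10), 0)
  # k = |training set| averages over every point
  expect_equal(uq_distance(Q[1, ], L, k = nrow(L)),
               mean(apply(L, 1, function(t) sqrt(sum((t - Q[1, ])^2)))))
  expect_error(uq_distance(Q, L[1:5, ], k = 10), "at least k")
})

test_that("cutoff calibration normalizes to the most distant reference", {
  # all-equal reference: normalized all 1.0, zero SD, cutoff 1.0
  cal <- calibrate_cutoff(rep(3.5, 8))
  expect_equal(cal$normalization, 3.5)
  expect_equal(cal$cutoff, 1.0)
  # hand-computed reference {1,2,3,4,10} -> normalized {0.1,...,1.0}
  z <- c(0.1, 0.2, 0.3, 0.4, 1.0)
  cal2 <- calibrate_cutoff(c(1, 2, 3, 4, 10))
  expect_equal(cal2$normalization, 10)
  expect_equal(cal2$cutoff, mean(z) + 2 * sd(z))
  # the largest normalized reference distance is 1 by construction
  expect_equal(max(c(1, 2, 3, 4, 10) / cal2$normalization), 1)
  expect_error(calibrate_cutoff(rep(0, 4)), "degenerate")
  # cap bounds the cutoff
  expect_equal(calibrate_cutoff(c(1, 2, 3, 4, 10), cap = 0.5)$cutoff, 0.5)
})

make_toy_ann <- function(seed = 30) {
  set.seed(seed)
  n <- 150
  X <- cbind(f1 = runif(n, 7.5, 9), f2 = runif(n, -0.4, -0.2))
  rownames(X) <- sprintf("r%03d", 1:n)
  y <- pmax(0.4 * X[, 1] + 2 * X[, 2] - 1, 0)
  m <- train_ann(X, y, train = 1:100, val = 101:125,
                 space = hyperparam_space(budget = 3L), seed = seed)
  list(model = m, X = X, y = y, test = 126:n)
}

test_that("latent embedding is consistent with the cached training latents", {
  tt <- make_toy_ann()
  emb <- latent_embed(tt$model, tt$X[1:125, ])
  expect_equal(emb, tt$model$latent_cache, tolerance = 1e-12)
  expect_identical(ncol(emb), tt$model$hyperparams$size)
  # identical inputs embed identically
  expect_equal(latent_embed(tt$model, tt$X[c(1, 1), ])[1, ],
               latent_embed(tt$model, tt$X[c(1, 1), ])[2, ])
  m_rf <- train_rf(tt$X, tt$y, train = 1:100)
  expect_error(latent_embed(m_rf, tt$X), "ANN")
})

test_that("error-vs-cutoff tables behave at the extremes and are monotone in retention", {
  tt <- make_toy_ann()
  Xte <- tt$X[tt$test, ]; yte <- tt$y[tt$test]
  tab <- error_vs_cutoff(tt$model, Xte, yte)
  expect_true(all(diff(tab$retained_fraction) >= 0))
  # cutoff at/above the max distance retains everything -> overall MAE
  expect_equal(tab$retained_fraction[nrow(tab)], 1)
  overall <- evaluate_model(tt$model, Xte, yte, y_range = 1)$mae
  expect_equal(tab$mae[nrow(tab)], overall, tolerance = 1e-12)
  # cutoff below the min distance leaves an empty, NA-flagged bin
  tab2 <- error_vs_cutoff(tt$model, Xte, yte, cutoffs = c(1e-9, 1))
  expect_identical(tab2$retained_fraction[1], 0)
  expect_true(is.na(tab2$mae[1]))
})

test_that("screening gates by all three models and tabulates extreme ligands", {
  set.seed(33)
  ds <- make_dataset(10, 6, seed = 33)
  X <- electronic_feature_matrix(ds$complexes, ds$electronics)
  sp <- make_random_split(ds$complexes$complex_id, seed = 33)
  models <- lapply(
    c(em5050 = "em5050_eV", lifetime = "lifetime_us",
      si = "spectral_integral_counts"),
    function(col) train_ann(X, stats::setNames(ds$complexes[[col]],
                                               ds$complexes$complex_id),
                            sp$train, sp$val,
                            space = hyperparam_space(budget = 2L), seed = 33))
  pols <- lapply(models, function(m) {
    d <- uq_distance(latent_embed(m, X[sp$test, ]), m$latent_cache)
    calibrate_cutoff(d)
  })
  cand <- ds$complexes[ds$complexes$complex_id %in% sp$test, 1:3]
  rep <- screen_complexes(cand, X[cand$complex_id, ], models, pols,
                          q_extreme = 0.1)
  expect_s3_class(rep, "screening_report")
  # overall acceptance is the intersection of the per-model gates
  tab <- rep$table
  expect_equal(tab$accepted,
               tab$accept_em5050 & tab$accept_lifetime & tab$accept_si)
  # zero cutoffs reject everything (training rows are not candidates here)
  pols0 <- lapply(pols, function(p) list(normalization = p$normalization,
                                         cutoff = 0))
  rep0 <- screen_complexes(cand, X[cand$complex_id, ], models, pols0)
  expect_length(rep0$accepted_ids, 0)
  # a candidate identical to a training complex passes every gate
  tr1 <- ds$complexes[ds$complexes$complex_id == sp$train[1], 1:3]
  rep1 <- screen_complexes(tr1, X[tr1$complex_id, , drop = FALSE],
                           models, pols)
  expect_true(rep1$table$accepted[1])
  # acceptance decisions do not depend on candidate ordering
  repR <- screen_complexes(cand[rev(seq_len(nrow(cand))), ],
                           X[rev(cand$complex_id), ], models, pols,
                           q_extreme = 0.1)
  expect_setequal(repR$accepted_ids, rep$accepted_ids)
  # enlarging any cutoff never shrinks the accepted set
  pols_wide <- pols
  pols_wide$em5050$cutoff <- pols$em5050$cutoff * 2
  rep_wide <- screen_complexes(cand, X[cand$complex_id, ], models, pols_wide)
  expect_true(all(rep$accepted_ids %in% rep_wide$accepted_ids))
})
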