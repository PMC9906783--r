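test_that("random splits have the documented sizes and are exhaustive", {
  ids <- sprintf("c%04d", 1:1380)
  sp <- make_random_split(ids, seed = 4)
  expect_length(sp$train, 966)
  expect_length(sp$val, 207)
  expect_length(sp$test, 207)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(make_random_split(ids, seed = 4), sp)
  expect_false(identical(make_random_split(ids, seed = 5)$test, sp$test))
  expect_error(make_random_split(c("a", "b")), "at least 3")
})

test_that("grouped splits quarantine complexes with held-out ligands", {
  lib <- gen_ligand_library(60, 23, seed = 2)
  cx <- enumerate_combinatorial(lib)
  held <- c("CN3", "CN17", "CN42", "NN5", "NN21")
  sp <- make_grouped_split(cx, held, seed = 1)
  # 1380 - 57*21 complexes contain at least one held-out ligand
  expect_length(sp$test, 1380 - 57 * 21)
  tv <- cx[cx$complex_id %in% c(sp$train, sp$val), ]
  expect_false(any(tv$cn_id %in% held | tv$nn_id %in% held))
  expect_setequal(c(sp$train, sp$val, sp$test), cx$complex_id)
  expect_error(make_grouped_split(cx, character(0)), "empty")
  expect_error(make_grouped_split(cx, unique(cx$cn_id)), "entire")
})

test_that("dissimilar-ligand selection matches a brute-force ranking", {
  lib <- small_library(6, 4, seed = 13)
  sel <- select_dissimilar_ligands(lib, 2, 1, nbits = 256)
  # brute-force oracle: exhaustive pairwise Dice means
  brute <- function(ligs, k) {
    fps <- lapply(ligs, morgan_fingerprint, radius = 3, nbits = 256)
    ms <- vapply(seq_along(fps), function(i)
      mean(vapply(setdiff(seq_along(fps), i), function(j)
        dice_similarity(fps[[i]], fps[[j]]), numeric(1))), numeric(1))
    names(ligs)[order(ms, names(ligs))][seq_len(k)]
  }
  expect_identical(sel, c(brute(lib$cn, 2), brute(lib$nn, 1)))
  # k = library size returns everything
  expect_setequal(select_dissimilar_ligands(lib, 6, 4, nbits = 128),
                  c(names(lib$cn), names(lib$nn)))
})

test_that("the dim filter applies only to emission-energy and lifetime tasks", {
  cx <- data.frame(complex_id = letters[1:4],
                   spectral_integral_counts = c(5e4, 2e5, 9e4, 1e5))
  expect_identical(filter_dim(cx, "em5050")$complex_id, c("b", "d"))
  expect_identical(filter_dim(cx, "lifetime")$complex_id, c("b", "d"))
  expect_identical(filter_dim(cx, "si"), cx)
  bright <- cx[cx$spectral_integral_counts >= 1e5, ]
  expect_identical(filter_dim(bright, "em5050"), bright)
})

test_that("the preprocessor standardizes, drops invariants and round-trips", {
  set.seed(9)
  X <- cbind(a = rnorm(30), b = runif(30), c = rep(2, 30))
  prep <- fit_preprocessor(X)
  Z <- apply_preprocessor(prep, X)
  expect_identical(colnames(Z), c("a", "b"))
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(invert_preprocessor(prep, Z), X[, 1:2], tolerance = 1e-12)
})

test_that("ridge recovers a noise-free linear map and floors predictions", {
  set.seed(10)
  n <- 120
  X <- cbind(x1 = runif(n, 7, 9), x2 = runif(n, -0.4, -0.2))
  rownames(X) <- sprintf("r%03d", 1:n)
  y <- 1 + 0.4 * X[, 1] - 2 * X[, 2]
  m <- train_ridge(X, y, train = 1:90, lambda = 1e-8)
  ev <- evaluate_model(m, X[91:n, ], y[91:n], y_range = diff(range(y)))
  expect_lt(ev$mae, 1e-6)
  # floored predictions on a shifted-negative target
  m2 <- train_ridge(X, y - 10, train = 1:90)
  expect_true(all(predict(m2, X) >= 0))
  # duplicate columns stay finite under regularization
  m3 <- train_ridge(cbind(X, X), y, train = 1:90, lambda = 1e-2)
  expect_true(all(is.finite(predict(m3, cbind(X, X)))))
})

test_that("scaled MAE is invariant to affine target rescaling", {
  set.seed(11)
  X <- matrix(rnorm(200), ncol = 2,
              dimnames = list(sprintf("r%02d", 1:100), c("a", "b")))
  y <- 2 + X[, 1]
  m <- train_ridge(X, y, train = 1:70)
  e1 <- evaluate_model(m, X[71:100, ], y[71:100], y_range = diff(range(y)))
  y2 <- 10 * y
  m2 <- train_ridge(X, y2, train = 1:70)
  e2 <- evaluate_model(m2, X[71:100, ], y2[71:100],
                       y_range = diff(range(y2)))
  expect_equal(e2$scaled_mae, e1$scaled_mae, tolerance = 1e-6)
  expect_equal(e2$mae, 10 * e1$mae, tolerance = 1e-6)
  expect_error(evaluate_model(m, X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("random-forest importances identify a planted single feature", {
  set.seed(12)
  n <- 300
  X <- cbind(cn_ip = runif(n, 7.5, 9), cn_homo = rnorm(n),
             nn_ip = runif(n, 7.3, 8.9), nn_ea = rnorm(n))
  rownames(X) <- sprintf("r%03d", 1:n)
  y <- 3 * X[, "cn_ip"] + rnorm(n, 0, 0.05)
  m <- train_rf(X, y, train = 1:n, seed = 1)
  imp <- rf_importances(m)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_identical(names(which.max(imp)), "cn_ip")
  agg <- aggregate_importance_by_ligand(imp)
  expect_equal(unname(sum(agg)), 1, tolerance = 1e-12)
  expect_gt(agg[["cn"]], agg[["nn"]])
})

test_that("the ANN trainer honors its contracts on simple data", {
  set.seed(13)
  n <- 200
  X <- cbind(f1 = runif(n), f2 = runif(n))
  rownames(X) <- sprintf("r%03d", 1:n)
  # constant target: predictions constant at the target value
  y_const <- rep(2.2, n)
  sp <- hyperparam_space(budget = 2L, maxit_choices = 100L)
  m <- train_ann(X, y_const, train = 1:140, val = 141:170, space = sp)
  expect_lt(evaluate_model(m, X[171:n, ], y_const[171:n],
                           y_range = 1)$mae, 0.05)
  # predictions are never negative even for a negative-shifted target
  y_neg <- -1 + 0.1 * X[, 1]
  m2 <- train_ann(X, pmax(y_neg, 0), train = 1:140, val = 141:170,
                  space = sp)
  expect_true(all(predict(m2, X) >= 0))
  # non-finite features are refused
  Xb <- X; Xb[1, 1] <- NA
  expect_error(train_ann(Xb, y_const, 1:140, 141:170, sp), "non-finite")
  # learnable smooth map reaches a low error at modest budget
  y_lin <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2]
  m3 <- train_ann(X, y_lin, train = 1:140, val = 141:170,
                  space = hyperparam_space(budget = 4L), seed = 2)
  expect_lt(evaluate_model(m3, X[171:n, ], y_lin[171:n],
                           y_range = 1)$mae, 0.02)
})

test_that("tree models beat ridge on curved maps and tie on linear ones", {
  set.seed(14)
  n <- 400
  X <- cbind(x = runif(n, -2, 2))
  rownames(X) <- sprintf("r%03d", 1:n)
  y_quad <- X[, 1]^2 + rnorm(n, 0, 0.02) + 5
  tr <- 1:300; te <- 301:n
  rng <- diff(range(y_quad))
  mae_rf <- evaluate_model(train_rf(X, y_quad, tr, seed = 1),
                           X[te, , drop = FALSE], y_quad[te], rng)$mae
  mae_ridge <- evaluate_model(train_ridge(X, y_quad, tr),
                              X[te, , drop = FALSE], y_quad[te], rng)$mae
  expect_lt(mae_rf, mae_ridge)
})
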