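test_that("node statistics match hand-computed values", {
  expect_equal(weighted_class_probs(c(1, 1, 0, 0)),
               c(p_a = 0.5, p_b = 0.5))
  expect_equal(weighted_class_probs(c(0.63, 0.37)),
               c(p_a = 0.5, p_b = 0.5))
  expect_equal(weighted_class_probs(0.63), c(p_a = 0.63, p_b = 0.37))
  # reach probabilities weight the average
  expect_equal(weighted_class_probs(c(1, 0), pi = c(0.75, 0.25)),
               c(p_a = 0.75, p_b = 0.25))
  expect_error(weighted_class_probs(c(1, 0), pi = c(0, 0)), "degenerate")

  expect_equal(modified_gini(1), 0)
  expect_equal(modified_gini(0.5), 0.5)
  expect_equal(modified_gini(0.63), 0.4662, tolerance = 1e-12)
})

test_that("split cost reduces to the fraction-weighted Gini on hard labels", {
  # perfect separation
  expect_equal(split_cost(c(1, 1), c(0, 0)), 0)
  # both sides same mix: cost equals parent impurity
  expect_equal(split_cost(c(1, 0), c(1, 0)), modified_gini(0.5))
  # split isolating one active from p_A = [1,1,0,0]
  expect_equal(split_cost(1, c(1, 0, 0)), 0.75 * oracle_gini(1 / 3),
               tolerance = 1e-12)
  expect_equal(split_cost(1, c(1, 0, 0)), 1 / 3, tolerance = 1e-12)
  # zero-mass side: cost falls back to parent impurity (split rejected)
  expect_equal(split_cost(c(1, 0), numeric(0)), modified_gini(0.5))
})

test_that("every fitted split equals the brute-force cost minimiser", {
  set.seed(101)
  n_checked <- 0
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    p <- sample(2:4, 1)
    x <- matrix(rbinom(n * p, 1, 0.5), n, p)
    py <- round(runif(n), 3)
    fit <- prf(x, py, n_trees = 1, bootstrap = FALSE, max_features = p,
               seed = rep)
    expect_true(oracle_check_tree(fit$trees[[1]], x, py))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 50)
})

test_that("split search honours the documented tie and stopping rules", {
  # duplicated informative feature: the tie breaks to the lowest feature id
  x <- cbind(noise = c(0, 1, 0, 1), b = c(0, 0, 1, 1), a = c(0, 0, 1, 1))
  fit <- prf(x, c(0, 0, 1, 1), n_trees = 1, bootstrap = FALSE,
             max_features = 3, seed = 1)
  expect_equal(fit$trees[[1]]$feature[1], 1L)  # 0-based id of column "b"
  # uninformative labels: no split strictly lowers the cost -> depth-0 tree
  fit2 <- prf(x, rep(0.5, 4), n_trees = 3, bootstrap = FALSE,
              max_features = 3, seed = 1)
  for (t in fit2$trees) {
    expect_equal(t$feature, -1L)
    expect_equal(t$p_a, 0.5)
  }
  pred <- predict(fit2, x)
  expect_equal(pred$prob_active, rep(0.5, 4))
})

test_that("separable hard labels are memorised; pure nodes predict exactly", {
  x <- cbind(a = c(0, 0, 0, 1, 1, 1), b = rbinom(6, 1, 0.5))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- prf_hard(x, y, n_trees = 30, max_features = 2, seed = 3,
                  bootstrap = FALSE)
  pred <- predict(fit, x)
  expect_equal(pred$prob_active, y, tolerance = 1e-12)
  # pure-class dataset: every prediction is 1 for that class
  pure <- prf_hard(x, rep(1, 6), n_trees = 5, seed = 1)
  expect_equal(predict(pure, x)$prob_active, rep(1, 6))
})

test_that("zero-sigma soft labels and hard mode build identical forests", {
  toy <- make_toy_dataset(seed = 9)
  soft0 <- prf(toy$x, delta_y(toy$observed, 5, 0), n_trees = 40, seed = 17)
  hard <- prf_hard(toy$x, toy$hard, n_trees = 40, seed = 17)
  expect_identical(soft0$trees, hard$trees)
  expect_equal(predict(soft0, toy$x)$prob_active,
               predict(hard, toy$x)$prob_active, tolerance = 1e-15)
})

test_that("fits are deterministic in the seed and tolerant of row shuffling", {
  toy <- make_toy_dataset(seed = 21)
  a <- prf(toy$x, toy$delta_y, n_trees = 20, seed = 5)
  b <- prf(toy$x, toy$delta_y, n_trees = 20, seed = 5)
  expect_identical(a$trees, b$trees)
  expect_identical(predict(a, toy$x), predict(b, toy$x))
  c <- prf(toy$x, toy$delta_y, n_trees = 20, seed = 6)
  expect_false(identical(a$trees, c$trees))
  # permutation invariance with bootstrap disabled
  perm <- sample(nrow(toy$x))
  d <- prf(toy$x, toy$delta_y, n_trees = 20, seed = 5, bootstrap = FALSE)
  e <- prf(toy$x[perm, ], toy$delta_y[perm], n_trees = 20, seed = 5,
           bootstrap = FALSE)
  expect_equal(predict(d, toy$x)$prob_active,
               predict(e, toy$x)$prob_active, tolerance = 1e-8)
})

test_that("fitting does not disturb the caller's RNG stream", {
  toy <- make_toy_dataset(seed = 2)
  set.seed(123)
  before <- .Random.seed
  invisible(prf(toy$x, toy$delta_y, n_trees = 5, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("predictions normalise and expose per-tree votes and dispersion", {
  toy <- make_toy_dataset(seed = 31)
  fit <- prf(toy$x, toy$delta_y, n_trees = 25, seed = 8)
  pred <- predict(fit, toy$x)
  expect_equal(pred$prob_active + pred$prob_inactive,
               rep(1, nrow(toy$x)), tolerance = 1e-9)
  tp <- attr(pred, "tree_probs")
  expect_equal(dim(tp), c(nrow(toy$x), 25))
  expect_equal(rowMeans(tp), pred$prob_active)
  expect_equal(rowMeans(tp >= 0.5), pred$vote_fraction)
  expect_true(all(pred$tree_sd >= 0))
})

test_that("feature ids align by name at prediction time", {
  toy <- make_toy_dataset(seed = 13)
  fit <- prf(toy$x, toy$delta_y, n_trees = 10, seed = 4)
  shuffled_cols <- toy$x[, rev(colnames(toy$x))]
  expect_equal(predict(fit, shuffled_cols)$prob_active,
               predict(fit, toy$x)$prob_active)
  expect_error(predict(fit, toy$x[, -1]), "configuration error")
})

test_that("keep_proba prunes low-mass branches and renormalises", {
  # hand-built depth-1 tree: leaf probabilities (0.8, 0.2) left, (0.1, 0.9)
  # right; feature uncertainty routes 0.96 of the mass left, 0.04 right
  tree <- list(feature = c(0L, -1L, -1L), threshold = c(0.5, 0.5, 0.5),
               left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
               p_a = c(0.5, 0.8, 0.1), p_b = c(0.5, 0.2, 0.9))
  model <- structure(list(trees = list(tree),
                          hyperparameters = list(keep_proba = 0.05),
                          feature_ids = NULL),
                     class = "prf")
  x <- matrix(0, 1, 1)
  dx <- 0.5 / qnorm(0.96)   # mass split 0.96 left / 0.04 right
  pruned <- predict(model, x, keep_proba = 0.05, dx = dx)
  expect_equal(pruned$prob_active, 0.8, tolerance = 1e-12)
  # without pruning both leaves contribute their mass
  full <- predict(model, x, keep_proba = 0, dx = dx)
  expect_equal(full$prob_active, 0.96 * 0.8 + 0.04 * 0.1, tolerance = 1e-9)
  expect_equal(full$prob_active + full$prob_inactive, 1, tolerance = 1e-12)
  # keep_proba larger than both branch masses: falls back to the larger one
  both <- predict(model, x, keep_proba = 0.99, dx = dx)
  expect_equal(both$prob_active, 0.8)
  # deterministic features reach exactly one leaf
  expect_equal(predict(model, matrix(1, 1, 1))$prob_active, 0.1)
})

test_that("identical feature rows produce prior-predicting depth-0 trees", {
  x <- matrix(1, 10, 3)
  y <- c(rep(1, 4), rep(0, 6))
  expect_warning(fit <- prf_hard(x, y, n_trees = 5, seed = 1),
                 "identical")
  expect_equal(predict(fit, x[1, , drop = FALSE])$prob_active, 0.4,
               tolerance = 0.2)  # bootstrap jitters the prior slightly
  fit2 <- suppressWarnings(prf_hard(x, y, n_trees = 5, seed = 1,
                                    bootstrap = FALSE))
  expect_equal(predict(fit2, x[1, , drop = FALSE])$prob_active, 0.4)
})

test_that("hyperparameters and labels are validated", {
  toy <- make_toy_dataset(n = 10, seed = 1)
  expect_error(prf(toy$x, toy$delta_y - 2), "\\[0, 1\\]")
  expect_error(prf(toy$x, toy$delta_y[-1]), "length")
  expect_error(prf(toy$x, toy$delta_y, keep_proba = 1), "keep_proba")
  expect_error(prf_hard(toy$x, toy$delta_y), "binary")
  expect_error(prf(toy$x + 2, toy$delta_y), "exactly 0 or 1")
})

test_that("serialization round-trips predictions bit-exactly", {
  toy <- make_toy_dataset(seed = 77)
  fit <- prf(toy$x, toy$delta_y, n_trees = 15, seed = 2,
             label_config = label_config(5, 0.3))
  path <- tempfile(fileext = ".rds")
  write_prf(fit, path)
  back <- read_prf(path)
  expect_identical(predict(back, toy$x), predict(fit, toy$x))
  expect_equal(back$label_config$sigma, 0.3)
  # refuses foreign files
  saveRDS(list(format = "other"), path)
  expect_error(read_prf(path), "not a prfbio model")
})
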