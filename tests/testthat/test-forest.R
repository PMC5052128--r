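two_feature_names <- c("f1", "f2")

# two well-separated clusters on feature 1
cluster_data <- function(n, seed) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x1 <- ifelse(y == 1, runif(n, 1, 2), runif(n, -1, 0))
  x2 <- runif(n, 0, 1)
  list(x = cbind(x1, x2), y = y)
}

test_that("a fresh forest is N bare leaves and predicts 0.5", {
  f <- forest_init(forest_config(n_trees = 20L), feature_names(FALSE))
  expect_length(f$trees, 20L)
  for (t in f$trees) {
    expect_length(t$feature, 1L)
    expect_true(is.na(t$feature))
    expect_equal(t$tot, 0)
  }
  p <- forest_predict(f, matrix(rnorm(26), 2, 13))
  expect_equal(p, c(0.5, 0.5))
})

test_that("lambda = 0 leaves the forest unchanged", {
  d <- cluster_data(100, 1)
  f0 <- forest_init(quick_forest(poisson_lambda = 0), two_feature_names)
  f1 <- forest_update(f0, d$x, d$y)
  for (k in seq_along(f1$trees)) {
    expect_equal(f1$trees[[k]]$tot, f0$trees[[k]]$tot)
    expect_equal(f1$trees[[k]]$feature, f0$trees[[k]]$feature)
  }
  expect_equal(forest_predict(f1, d$x), rep(0.5, 100))
})

test_that("online bagging replicates each sample Pois(1) times on average", {
  # one tree that never splits, so the root count records total replication
  cfg <- forest_config(n_trees = 1L, max_depth = 1L, poisson_lambda = 1,
                       min_samples_split = 1e9L, seed = 33L)
  f <- forest_init(cfg, two_feature_names)
  n <- 10000L
  f <- forest_update(f, matrix(rnorm(2 * n), n, 2), rep(0:1, n / 2))
  rate <- f$trees[[1]]$tot / n
  expect_gte(rate, 0.97); expect_lte(rate, 1.03)
})

test_that("separable clusters produce pure leaves", {
  d <- cluster_data(200, 5)
  f <- forest_init(forest_config(n_trees = 5L, seed = 2L), two_feature_names)
  f <- forest_update(f, d$x, d$y)
  held <- cluster_data(100, 6)
  p <- forest_predict(f, held$x)
  expect_true(all(p[held$y == 1] == 1))
  expect_true(all(p[held$y == 0] == 0))
})

test_that("prediction is the average of the per-tree leaf posteriors", {
  f <- forest_init(forest_config(n_trees = 2L, seed = 1L), two_feature_names)
  f$trees[[1]]$pos <- 1; f$trees[[1]]$tot <- 5    # posterior 0.2
  f$trees[[2]]$pos <- 4; f$trees[[2]]$tot <- 5    # posterior 0.8
  expect_equal(forest_predict(f, matrix(0, 1, 2)), 0.5)

  # N = 1: prediction equals that tree's posterior exactly
  f1 <- forest_init(forest_config(n_trees = 1L, seed = 1L), two_feature_names)
  f1$trees[[1]]$pos <- 3; f1$trees[[1]]$tot <- 4
  expect_equal(forest_predict(f1, matrix(0, 1, 2)), 0.75)
})

test_that("an all-positive stream predicts 1 everywhere", {
  f <- forest_init(quick_forest(seed = 4L), two_feature_names)
  f <- forest_update(f, matrix(rnorm(100), 50, 2), rep(1, 50))
  expect_equal(forest_predict(f, matrix(rnorm(20), 10, 2)), rep(1, 10))
})

test_that("posteriors are probabilities on arbitrary streams", {
  set.seed(9)
  f <- forest_init(quick_forest(seed = 9L), two_feature_names)
  for (b in 1:3) {
    x <- matrix(rnorm(60), 30, 2)
    f <- forest_update(f, x, rbinom(30, 1, 0.4))
    p <- forest_predict(f, matrix(rnorm(40), 20, 2))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("identical seeds give identical forests on identical streams", {
  d <- cluster_data(150, 3)
  p <- lapply(1:2, function(i) {
    f <- forest_init(forest_config(n_trees = 10L, seed = 77L),
                     two_feature_names)
    f <- forest_update(f, d$x[1:75, ], d$y[1:75])
    f <- forest_update(f, d$x[76:150, ], d$y[76:150])
    forest_predict(f, d$x)
  })
  expect_identical(p[[1]], p[[2]])
  # ... and the caller's RNG is untouched
  set.seed(123); before <- runif(1)
  f <- forest_init(forest_config(seed = 5L), two_feature_names)
  set.seed(123)
  f <- forest_update(f, d$x, d$y)
  expect_equal(runif(1), before)
})

test_that("held-out accuracy exceeds 0.95 on separable data", {
  d <- cluster_data(500, 10)
  f <- forest_init(forest_config(n_trees = 20L, max_depth = 10L, seed = 8L),
                   two_feature_names)
  f <- forest_update(f, d$x, d$y)
  held <- cluster_data(200, 11)
  acc <- mean((forest_predict(f, held$x) >= 0.5) == (held$y == 1))
  expect_gt(acc, 0.95)
})

test_that("more training data does not worsen held-out Brier score", {
  # noisy-but-learnable task, averaged over seeds
  gen <- function(n, seed) {
    set.seed(seed)
    y <- rbinom(n, 1, 0.5)
    x <- cbind(rnorm(n, y * 1.5, 1), rnorm(n))
    list(x = x, y = y)
  }
  brier <- matrix(0, 10, 2)
  for (s in 1:10) {
    f <- forest_init(forest_config(n_trees = 10L, seed = s),
                     two_feature_names)
    d1 <- gen(150, 100 + s); d2 <- gen(150, 200 + s)
    held <- gen(300, 300 + s)
    f1 <- forest_update(f, d1$x, d1$y)
    brier[s, 1] <- mean((forest_predict(f1, held$x) - held$y)^2)
    f2 <- forest_update(f1, d2$x, d2$y)
    brier[s, 2] <- mean((forest_predict(f2, held$x) - held$y)^2)
  }
  expect_lte(mean(brier[, 2]), mean(brier[, 1]) + 0.01)
})

test_that("a forest survives a JSON round trip", {
  d <- cluster_data(120, 14)
  f <- forest_init(forest_config(n_trees = 4L, seed = 3L), two_feature_names)
  f <- forest_update(f, d$x, d$y)
  path <- tempfile(fileext = ".json")
  forest_save(f, path)
  g <- forest_load(path)
  expect_equal(g$feature_names, f$feature_names)
  x <- cluster_data(40, 15)$x
  expect_equal(forest_predict(g, x), forest_predict(f, x))
})

test_that("contract violations are rejected", {
  f <- forest_init(quick_forest(), two_feature_names)
  expect_error(forest_update(f, matrix(0, 2, 3), c(0, 1)), "arity")
  expect_error(forest_update(f, matrix(0, 2, 2), c(0, 2)), "binary")
  expect_error(forest_update(f, matrix(0, 2, 2), c(0)), "match")
  expect_error(forest_predict(f, matrix(0, 2, 5)), "arity")
  expect_error(forest_config(n_trees = 0), "n_trees")
  expect_error(forest_config(poisson_lambda = -1), "poisson_lambda")
})
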