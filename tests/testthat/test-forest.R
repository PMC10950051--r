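test_that("curvature test matches the chi-square oracle on a separating feature", {
  y <- rep(c("a", "b"), each = 20)
  x <- c(rep(0, 20), rep(1, 20))
  p <- curvature_test(x, y)
  oracle <- chisq.test(matrix(c(20, 0, 0, 20), 2), correct = FALSE)$p.value
  expect_equal(p, oracle, tolerance = 1e-12)
  expect_lt(p, 1e-4)
})

test_that("curvature test returns 1 for uninformative predictors", {
  y <- rep(c("a", "b"), each = 10)
  expect_equal(curvature_test(rep(3, 20), y), 1)
  expect_equal(curvature_test(rep(NA_real_, 20), y), 1)
  expect_error(curvature_test(rnorm(5), rep("a", 5)), "2 classes")
})

test_that("curvature-test null p-values are uniform", {
  set.seed(55)
  ps <- replicate(1000, {
    curvature_test(runif(500), sample(rep(c("a", "b"), 250)))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("interaction test detects XOR structure individual tests miss", {
  set.seed(56)
  n <- 200
  x1 <- rbinom(n, 1, 0.5) + runif(n, -0.1, 0.1)
  x2 <- rbinom(n, 1, 0.5) + runif(n, -0.1, 0.1)
  y <- factor(xor(x1 > 0.5, x2 > 0.5))
  p_int <- interaction_curvature_test(x1, x2, y)
  p_ind <- min(curvature_test(x1, y), curvature_test(x2, y))
  expect_lt(p_int, 1e-10)
  expect_gt(p_ind, 0.01)
  expect_lt(p_int, p_ind / 100)
})

test_that("interaction test is null-calibrated and degenerates gracefully", {
  set.seed(57)
  ps <- replicate(600, {
    y <- sample(rep(c("a", "b"), 150))
    interaction_curvature_test(runif(300), runif(300), y)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # one constant predictor reduces to the single-variable curvature test
  set.seed(58)
  x <- runif(80)
  y <- factor(rep(c("a", "b"), 40))
  expect_equal(interaction_curvature_test(x, rep(1, 80), y),
               curvature_test(x, y), tolerance = 1e-12)
})

test_that("a perfectly separating feature yields a depth-1 tree with zero error", {
  d <- separable_fixture(n = 80)
  tr <- grow_tree(d, "y", forest_markers(d), min_leaf = 1, max_splits = 20)
  expect_identical(sum(tr$tree$is_leaf == 0L), 1L)
  expect_identical(tr$markers[tr$tree$var[1] + 1], "x1")
  expect_identical(predict(tr, d, type = "class"), d$y)
})

test_that("complete-data trees match an rpart CART oracle", {
  set.seed(60)
  for (i in 1:3) {
    n <- 100
    d <- tibble::tibble(x1 = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
    d$y <- factor(ifelse(d$x1 + rnorm(n, sd = 0.4) > 0, "a", "b"))
    mine <- grow_tree(d, "y", c("x1", "n1", "n2"), min_leaf = 7,
                      max_splits = 1)
    ref <- rpart::rpart(y ~ x1, data = d, method = "class",
                        control = rpart::rpart.control(
                          minbucket = 7, minsplit = 14, maxdepth = 1,
                          cp = 0, xval = 0))
    expect_identical(as.character(predict(mine, d, type = "class")),
                     as.character(predict(ref, d, type = "class")))
  }
})

test_that("surrogates route masked rows in agreement with complete data", {
  set.seed(61)
  n <- 300
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, sd = 0.25) # informative correlated surrogate
  d <- tibble::tibble(x1 = x1, x2 = x2, noise = rnorm(n),
                      y = factor(ifelse(x1 > 0, "a", "b")))
  tr <- grow_tree(d, "y", c("x1", "x2", "noise"), min_leaf = 5,
                  max_splits = 6)
  full <- predict(tr, d, type = "class")
  masked <- d
  masked$x1[sample(n, 60)] <- NA # 20% masked at predict time
  agree <- mean(predict(tr, masked, type = "class") == full)
  expect_gte(agree, 0.9)
})

test_that("a perfect surrogate routes masked rows identically", {
  set.seed(62)
  n <- 150
  x1 <- rnorm(n)
  d <- tibble::tibble(x1 = x1, x2 = x1, y = factor(ifelse(x1 > 0, "a", "b")))
  tr <- grow_tree(d, "y", c("x1", "x2"), min_leaf = 5, max_splits = 4)
  # the duplicate column must appear as an agreement-1 surrogate at the root
  expect_equal(tr$tree$surr_agreement[1], 1)
  full <- predict(tr, d, type = "class")
  masked <- d
  masked$x1[sample(n, 50)] <- NA
  expect_identical(predict(tr, masked, type = "class"), full)
})

test_that("rows with no usable values stop at the root and take the priors", {
  d <- separable_fixture(n = 60)
  tr <- grow_tree(d, "y", forest_markers(d), min_leaf = 1, max_splits = 10)
  allna <- d[1, ]
  allna[forest_markers(d)] <- NA_real_
  post <- predict(tr, allna)
  priors <- as.numeric(table(d$y)) / nrow(d)
  expect_equal(as.numeric(post), priors)
  # a complete row is routed exactly as without any mask logic
  expect_identical(predict(tr, d[5, ], type = "class"), d$y[5])
})

test_that("pruning never hurts validation risk and shrinks noise-fit trees", {
  set.seed(63)
  n <- 200
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                      y = factor(sample(rep(c("a", "b"), n / 2))))
  val <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                        y = factor(sample(rep(c("a", "b"), n / 2))))
  tr <- grow_tree(d, "y", c("x1", "x2", "x3"), min_leaf = 2, max_splits = 40)
  pr <- prune_tree(tr, val)
  n_nodes <- function(t) sum(t$tree$is_leaf == 0L)
  expect_lt(n_nodes(pr), n_nodes(tr))
  err <- function(t) mean(predict(t, val, type = "class") != val$y)
  expect_lte(err(pr), err(tr))

  # perfectly separable data: pruning is the identity
  ds <- separable_fixture(n = 100)
  trs <- grow_tree(ds, "y", forest_markers(ds), min_leaf = 1, max_splits = 10)
  prs <- prune_tree(trs, ds)
  expect_identical(prs$tree$is_leaf, trs$tree$is_leaf)
})

test_that("importance concentrates on predictive markers", {
  d <- separable_fixture(n = 120)
  f1 <- grow_forest(d, "y", forest_markers(d), method = "bag", n_cycles = 20,
                    min_leaf = 3, max_splits = 5, seed = 1)
  imp <- feature_importance(f1)
  expect_identical(imp$marker[which.max(imp$importance)], "x1")
  # single-feature forest holds all the mass
  fs <- grow_forest(d, "y", "x1", method = "bag", n_cycles = 10,
                    min_leaf = 3, max_splits = 3, seed = 2)
  is <- feature_importance(fs)
  expect_gt(is$importance[is$marker == "x1"], 0)

  # planted predictive marker beats pure noise 10x across seeds
  set.seed(64)
  wins <- sapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 120
    dd <- tibble::tibble(sig = rnorm(n), noise = rnorm(n))
    dd$y <- factor(ifelse(dd$sig + rnorm(n, sd = 0.3) > 0, "a", "b"))
    ff <- grow_forest(dd, "y", c("sig", "noise"), method = "bag",
                      n_cycles = 15, min_leaf = 5, max_splits = 4, seed = s)
    ii <- feature_importance(ff)
    ii$importance[ii$marker == "sig"] >
      10 * ii$importance[ii$marker == "noise"]
  })
  expect_true(all(wins))
})

test_that("trees and importances are invariant to monotone predictor transforms", {
  set.seed(65)
  n <- 150
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- factor(ifelse(d$x1 - d$x2 + rnorm(n, sd = 0.6) > 0, "a", "b"))
  d2 <- d
  d2$x1 <- exp(d$x1)         # strictly increasing
  d2$x2 <- d$x2^3 + 5 * d$x2 # strictly increasing
  f1 <- grow_forest(d, "y", c("x1", "x2"), method = "bag", n_cycles = 10,
                    min_leaf = 5, max_splits = 6, seed = 3)
  f2 <- grow_forest(d2, "y", c("x1", "x2"), method = "bag", n_cycles = 10,
                    min_leaf = 5, max_splits = 6, seed = 3)
  for (b in seq_along(f1$trees)) {
    expect_identical(f1$trees[[b]]$var, f2$trees[[b]]$var)
    expect_identical(f1$trees[[b]]$is_leaf, f2$trees[[b]]$is_leaf)
    expect_equal(f1$trees[[b]]$risk_reduction, f2$trees[[b]]$risk_reduction,
                 tolerance = 1e-12)
  }
  expect_equal(predict(f1, d), predict(f2, d2), tolerance = 1e-12)
  expect_equal(feature_importance(f1)$importance,
               feature_importance(f2)$importance, tolerance = 1e-12)
})

test_that("posteriors are proper for both aggregation methods", {
  d <- separable_fixture(n = 80)
  d$x1[sample(80, 10)] <- NA
  for (m in c("bag", "boost")) {
    f <- grow_forest(d, "y", forest_markers(d), method = m, n_cycles = 12,
                     learn_rate = 0.4, min_leaf = 3, max_splits = 4, seed = 4)
    post <- predict(f, d)
    expect_true(all(abs(rowSums(post) - 1) < 1e-12))
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("bagged consensus agrees with a reference ensemble on easy data", {
  set.seed(66)
  n <- 200
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- factor(ifelse(d$x1 + 0.7 * d$x2 + rnorm(n, sd = 0.25) > 0, "a", "b"))
  mine <- grow_forest(d, "y", c("x1", "x2", "x3"), method = "bag",
                      n_cycles = 100, min_leaf = 5, max_splits = 15,
                      prune = FALSE, seed = 5)
  ref <- randomForest::randomForest(y ~ x1 + x2 + x3, data = d, ntree = 300)
  agree <- mean(predict(mine, d, type = "class") == predict(ref, d))
  expect_gte(agree, 0.95)
})

test_that("forests are deterministic under a fixed seed", {
  d <- separable_fixture(n = 90)
  f1 <- grow_forest(d, "y", forest_markers(d), method = "boost", n_cycles = 15,
                    learn_rate = 0.5, min_leaf = 4, max_splits = 3, seed = 11)
  f2 <- grow_forest(d, "y", forest_markers(d), method = "boost", n_cycles = 15,
                    learn_rate = 0.5, min_leaf = 4, max_splits = 3, seed = 11)
  expect_identical(predict(f1, d), predict(f2, d))
  expect_identical(feature_importance(f1), feature_importance(f2))
})

test_that("sensitivity and specificity follow the confusion-matrix arithmetic", {
  truth <- c(rep("pos", 10), rep("neg", 10))
  pred <- c(rep("pos", 8), rep("neg", 2), rep("pos", 3), rep("neg", 7))
  expect_equal(sens_spec(pred, truth, "pos"),
               tibble::tibble(sensitivity = 0.8, specificity = 0.7))
  expect_equal(sens_spec(truth, truth, "pos"),
               tibble::tibble(sensitivity = 1, specificity = 1))
  expect_equal(sens_spec(rep("pos", 20), truth, "pos"),
               tibble::tibble(sensitivity = 1, specificity = 0))
  expect_error(sens_spec(pred, rep("pos", 20), "pos"), "absent")
})

test_that("forest JSON serialization round-trips the topology", {
  d <- separable_fixture(n = 60)
  tr <- grow_tree(d, "y", forest_markers(d), min_leaf = 2, max_splits = 5)
  js <- as_forest_json(tr)
  back <- jsonlite::fromJSON(js)
  expect_identical(back$kind, "tree")
  expect_equal(back$tree$var, tr$tree$var)
  expect_equal(back$tree$threshold, tr$tree$threshold, tolerance = 1e-12)
})
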