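#' Curvature test of predictor-class independence
#'
#' Bins a continuous predictor into quartiles of its non-missing values
#' (fewer bins when ties collapse the quartile edges) and tests independence
#' of the binned predictor and the class with a Pearson chi-square on the
#' non-missing rows. Used for split-variable selection: choosing the
#' predictor with the smallest p-value reduces the selection bias toward
#' many-valued predictors that plain impurity search suffers from. A
#' constant or all-missing predictor is uninformative and returns p = 1.
#'
#' @param x Numeric predictor with `NA` for missing.
#' @param y Class vector (factor or coercible).
#' @param w Optional non-negative case weights.
#' @return The chi-square upper-tail p-value.
#' @export
curvature_test <- function(x, y, w = NULL) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    abort_stage("curvature", "need >= 2 classes present")
  w <- w %||% rep(1, length(x))
  cpp_curvature_p(matrix(as.numeric(x), ncol = 1), 1L,
                  as.integer(y) - 1L, as.numeric(w), nlevels(y))
}

#' @rdname curvature_test
#' @param x1,x2 Predictor pair; rows with either missing are dropped and the
#'   test uses the joint quartile cells of the pair against the class.
#' @export
interaction_curvature_test <- function(x1, x2, y, w = NULL) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    abort_stage("curvature", "need >= 2 classes present")
  w <- w %||% rep(1, length(x1))
  cpp_interaction_p(cbind(as.numeric(x1), as.numeric(x2)), 1L, 2L,
                    as.integer(y) - 1L, as.numeric(w), nlevels(y))
}

# build the predictor matrix + class vector from a panel data frame
forest_design <- function(data, outcome, markers) {
  missing_cols <- setdiff(c(outcome, markers), names(data))
  if (length(missing_cols) > 0)
    abort_stage("forest", paste0("columns not in data: ",
                                 paste(missing_cols, collapse = ", ")))
  y <- as.factor(data[[outcome]])
  y <- droplevels(y)
  if (nlevels(y) < 2) abort_stage("forest", "outcome has a single class")
  X <- as.matrix(data[, markers, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = y)
}

#' Grow a single curvature-test classification tree
#'
#' At each node the split variable is the one minimizing the curvature-test
#' p-value (exact ties refined by the pairwise interaction test); the
#' threshold is the best Gini-gain cut over the variable's non-missing
#' values; and up to `n_surrogates` surrogate splits (backup rules on other
#' variables whose best cut agrees with the primary split on more than half
#' of the commonly observed rows) are stored to route observations whose
#' primary value is missing. An observation whose primary and surrogate
#' values are all missing stops at the node and takes its posterior.
#'
#' @param data Panel tibble.
#' @param outcome Name of the class column.
#' @param markers Predictor columns.
#' @param min_leaf Minimum observations per leaf.
#' @param max_splits Maximum number of branch nodes.
#' @param n_surrogates Maximum surrogates per node.
#' @param weights Optional case weights.
#' @return An object of class `curvature_tree`.
#' @export
grow_tree <- function(data, outcome, markers = panel_markers(data),
                      min_leaf = 1L, max_splits = nrow(data) - 1L,
                      n_surrogates = 5L, weights = NULL) {
  d <- forest_design(data, outcome, markers)
  if (nrow(d$X) < min_leaf) abort_stage("forest", "fewer rows than min_leaf")
  w <- weights %||% rep(1, nrow(d$X))
  fit <- cpp_grow_tree(d$X, as.integer(d$y) - 1L, as.numeric(w),
                       nlevels(d$y), as.integer(min_leaf),
                       as.integer(max_splits), as.integer(n_surrogates))
  structure(list(tree = fit, markers = markers, outcome = outcome,
                 classes = levels(d$y)),
            class = "curvature_tree")
}

#' @export
print.curvature_tree <- function(x, ...) {
  cat(sprintf("<curvature_tree> %d nodes (%d leaves), outcome '%s'\n",
              length(x$tree$var), sum(x$tree$is_leaf), x$outcome))
  invisible(x)
}

#' @export
predict.curvature_tree <- function(object, newdata, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$markers, drop = FALSE])
  storage.mode(X) <- "double"
  post <- cpp_predict_tree(object$tree, X)
  colnames(post) <- object$classes
  if (type == "class")
    return(factor(object$classes[max.col(post, ties.method = "first")],
                  levels = object$classes))
  post
}

#' Prune a fitted tree on a validation set
#'
#' Bottom-up collapse of every subtree whose replacement by a leaf does not
#' increase the misclassification count on the validation data; surrogates
#' of removed nodes are dropped. The pruned tree's validation risk is never
#' worse than the unpruned tree's.
#'
#' @param tree A `curvature_tree`.
#' @param validation Data frame with the outcome and marker columns.
#' @return The pruned `curvature_tree`.
#' @export
prune_tree <- function(tree, validation) {
  X <- as.matrix(validation[, tree$markers, drop = FALSE])
  storage.mode(X) <- "double"
  y <- factor(validation[[tree$outcome]], levels = tree$classes)
  if (any(is.na(y))) abort_stage("prune", "validation outcome has unknown classes")
  tree$tree <- cpp_prune_tree(tree$tree, X, as.integer(y) - 1L)
  tree
}

#' Fit a curvature-test tree ensemble
#'
#' Bagging fits each tree to a bootstrap resample (and, when `prune = TRUE`,
#' prunes it on its out-of-bag rows); the ensemble posterior is the mean of
#' the tree posteriors. Boosting is adaptive reweighting with shrinkage: each
#' tree is fitted to reweighted data, misclassified rows are up-weighted, and
#' the additive vote score is mapped to a posterior through the logistic
#' function (binary outcomes only).
#'
#' @inheritParams grow_tree
#' @param method `"bag"` or `"boost"`.
#' @param n_cycles Number of trees (learning cycles).
#' @param learn_rate Shrinkage in `(0, 1]`, boosting only.
#' @param prune Prune bagged trees on out-of-bag rows.
#' @param seed Optional seed for the resampling.
#' @return An object of class `curvature_forest`.
#' @export
grow_forest <- function(data, outcome, markers = panel_markers(data),
                        method = c("bag", "boost"), n_cycles = 100L,
                        learn_rate = 0.1, min_leaf = 1L,
                        max_splits = 10L, n_surrogates = 5L,
                        prune = FALSE, seed = NULL) {
  method <- match.arg(method)
  d <- forest_design(data, outcome, markers)
  n <- nrow(d$X)
  K <- nlevels(d$y)
  yi <- as.integer(d$y) - 1L
  if (method == "boost") {
    if (K != 2) abort_stage("forest", "boosting supports binary outcomes only")
    if (learn_rate <= 0 || learn_rate > 1)
      abort_stage("forest", "learn_rate must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", n_cycles)
  alphas <- numeric(n_cycles)
  if (method == "bag") {
    all_idx <- seq_len(n)
    for (b in seq_len(n_cycles)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- cpp_grow_tree(d$X[idx, , drop = FALSE], yi[idx],
                           rep(1, n), K, as.integer(min_leaf),
                           as.integer(max_splits), as.integer(n_surrogates))
      if (prune) {
        oob <- setdiff(all_idx, idx)
        if (length(oob) > 1)
          fit <- cpp_prune_tree(fit, d$X[oob, , drop = FALSE], yi[oob])
      }
      trees[[b]] <- fit
      alphas[b] <- 1
    }
  } else {
    w <- rep(1 / n, n)
    used <- 0L
    for (b in seq_len(n_cycles)) {
      fit <- cpp_grow_tree(d$X, yi, w, K, as.integer(min_leaf),
                           as.integer(max_splits), as.integer(n_surrogates))
      post <- cpp_predict_tree(fit, d$X)
      pred <- max.col(post, ties.method = "first") - 1L
      err <- sum(w[pred != yi])
      e <- min(max(err, 1e-6), 1 - 1e-6)
      alpha <- learn_rate * 0.5 * log((1 - e) / e)
      used <- used + 1L
      trees[[b]] <- fit
      alphas[b] <- alpha
      if (err <= 0 || alpha <= 0) break
      w <- w * exp(alpha * (pred != yi) * 2)
      w <- w / sum(w)
    }
    trees <- trees[seq_len(used)]
    alphas <- alphas[seq_len(used)]
  }
  structure(list(trees = trees, alphas = alphas, method = method,
                 n_cycles = length(trees), learn_rate = learn_rate,
                 min_leaf = as.integer(min_leaf),
                 max_splits = as.integer(max_splits),
                 markers = markers, outcome = outcome, classes = levels(d$y),
                 priors = as.numeric(table(d$y)) / n),
            class = "curvature_forest")
}

#' @export
print.curvature_forest <- function(x, ...) {
  cat(sprintf("<curvature_forest> %s, %d trees, outcome '%s' (%s)\n",
              x$method, x$n_cycles, x$outcome,
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' @export
predict.curvature_forest <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$markers, drop = FALSE])
  storage.mode(X) <- "double"
  K <- length(object$classes)
  if (object$method == "bag") {
    post <- cpp_bag_posterior(object$trees, X)
  } else {
    score <- cpp_boost_scores(object$trees, object$alphas, X)
    p1 <- 1 / (1 + exp(-2 * score))
    post <- cbind(1 - p1, p1)
  }
  colnames(post) <- object$classes
  if (type == "class")
    return(factor(object$classes[max.col(post, ties.method = "first")],
                  levels = object$classes))
  post
}

#' Split-gain feature importance
#'
#' For each marker, sums the (weighted Gini) risk reduction over all nodes
#' of all trees whose primary split uses that marker, divided by the number
#' of trees. Markers never split on get 0. Surrogate use does not contribute
#' (importance is primary-split gain).
#'
#' @param object A `curvature_forest` or `curvature_tree`.
#' @return A tibble with `marker` and `importance`, in marker order.
#' @export
feature_importance <- function(object) {
  trees <- if (inherits(object, "curvature_forest")) object$trees
           else list(object$tree)
  imp <- numeric(length(object$markers))
  for (tr in trees) {
    branch <- tr$is_leaf == 0L
    if (!any(branch)) next
    v <- tr$var[branch] + 1L
    rr <- tr$risk_reduction[branch]
    for (t in seq_along(v)) imp[v[t]] <- imp[v[t]] + rr[t]
  }
  tibble::tibble(marker = object$markers,
                 importance = imp / length(trees))
}

#' Sensitivity and specificity
#'
#' @param pred Predicted classes.
#' @param truth True classes; both classes must be present.
#' @param positive The positive class label.
#' @return A one-row tibble with `sensitivity` (TP / (TP + FN)) and
#'   `specificity` (TN / (TN + FP)).
#' @export
sens_spec <- function(pred, truth, positive) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  pos <- truth == positive
  if (!any(pos) || all(pos))
    abort_stage("sens_spec", "a class is absent from the truth vector")
  tibble::tibble(
    sensitivity = sum(pred == positive & pos) / sum(pos),
    specificity = sum(pred != positive & !pos) / sum(!pos))
}

#' Serialize a tree or forest to JSON
#'
#' Topology, thresholds, surrogates and posteriors in a documented schema.
#'
#' @param object A `curvature_tree` or `curvature_forest`.
#' @param path Optional file.
#' @return JSON string, invisibly if written to file.
#' @export
as_forest_json <- function(object, path = NULL) {
  strip <- function(tr) tr[c("var", "threshold", "left", "right", "is_leaf",
                             "posterior", "n_obs", "risk_reduction",
                             "surr_start", "surr_n", "surr_var",
                             "surr_threshold", "surr_dir", "surr_agreement",
                             "n_classes")]
  obj <- if (inherits(object, "curvature_tree")) {
    list(kind = "tree", markers = object$markers, outcome = object$outcome,
         classes = object$classes, tree = strip(object$tree))
  } else {
    list(kind = "forest", method = object$method, markers = object$markers,
         outcome = object$outcome, classes = object$classes,
         alphas = object$alphas, trees = lapply(object$trees, strip))
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
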