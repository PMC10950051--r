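#' Gaussian-process Bayesian minimization on the unit cube
#'
#' A compact seeded Bayesian optimizer: a Latin-hypercube initial design, a
#' Gaussian-process surrogate (squared-exponential kernel, fixed length
#' scale on the unit cube, small noise nugget) fitted to standardized
#' objective values, and an expected-improvement acquisition maximized over
#' a random candidate set. Designed for the handful of encoded forest
#' hyperparameters it tunes; it is not a general-purpose optimizer.
#'
#' @param objective Function of a length-`d` numeric vector in `[0, 1]^d`
#'   returning a scalar to minimize.
#' @param d Dimension of the search space.
#' @param iterations Total objective evaluations (>= 2).
#' @param seed Optional seed; fixed seed implies identical incumbents.
#' @param n_init Initial design size.
#' @param n_candidates Random acquisition candidates per iteration.
#' @param lengthscale GP kernel length scale on the unit cube.
#' @param noise Relative noise variance of the observations.
#' @return A list with `par` (best point), `value`, and `history`
#'   (tibble of evaluated points and values).
#' @export
bo_minimize <- function(objective, d, iterations, seed = NULL,
                        n_init = min(8L, max(2L, iterations - 1L)),
                        n_candidates = 256L, lengthscale = 0.25,
                        noise = 1e-2) {
  if (iterations < 2) abort_stage("bayes_opt", "iteration budget must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n_init <- min(n_init, iterations)
  X <- lhs::randomLHS(n_init, d)
  yv <- apply(X, 1, objective)
  kfun <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }
  while (nrow(X) < iterations) {
    mu <- mean(yv); sdy <- stats::sd(yv)
    ys <- if (sdy > 0) (yv - mu) / sdy else yv * 0
    Kmat <- kfun(X, X) + diag(noise + 1e-8, nrow(X))
    L <- chol(Kmat)
    alpha <- backsolve(L, backsolve(L, ys, transpose = TRUE))
    cand <- matrix(runif(n_candidates * d), n_candidates, d)
    Ks <- kfun(cand, X)
    pred <- as.numeric(Ks %*% alpha)
    v <- backsolve(L, t(Ks), transpose = TRUE)
    s2 <- pmax(1 - colSums(v^2), 1e-12)
    s <- sqrt(s2)
    best <- min(ys)
    z <- (best - pred) / s
    ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
    xnew <- cand[which.max(ei), , drop = FALSE]
    X <- rbind(X, xnew)
    yv <- c(yv, objective(as.numeric(xnew)))
  }
  i <- which.min(yv)
  list(par = as.numeric(X[i, ]), value = yv[i],
       history = tibble::tibble(iteration = seq_along(yv), value = yv,
                                point = lapply(seq_len(nrow(X)),
                                               function(r) as.numeric(X[r, ]))))
}

# map a unit-cube point to forest hyperparameters
decode_hyper <- function(u, n, config) {
  log_interp <- function(t, range) exp(log(range[1]) + t * log(range[2] / range[1]))
  msr <- config$max_splits_range %||% c(1, max(1, n - 1))
  mlmax <- config$min_leaf_max %||% max(2, floor(n / 4))
  list(method = if (u[1] < 0.5) "bag" else "boost",
       n_cycles = as.integer(round(log_interp(u[2], config$n_cycles_range))),
       learn_rate = log_interp(u[3], config$learn_rate_range),
       min_leaf = as.integer(round(log_interp(u[4], c(1, mlmax)))),
       max_splits = as.integer(round(log_interp(u[5], msr))))
}

#' Tune forest hyperparameters by Bayesian optimization
#'
#' Searches aggregation method (bag/boost), number of learning cycles,
#' learn rate, minimum leaf size and maximum number of splits. The objective
#' is the inner-k-fold cross-validated misclassification rate on the
#' supplied data. Fully seeded: the same seed, data and config give the same
#' incumbent.
#'
#' @param data Training data frame.
#' @param outcome Class column name.
#' @param markers Predictor columns.
#' @param config An [analysis_config()].
#' @param seed Seed for the optimizer and inner folds.
#' @return A list with `hyper` (decoded incumbent), `cv_error`, and the
#'   optimizer `history`.
#' @export
tune_forest <- function(data, outcome, markers, config = analysis_config(),
                        seed = config$seed) {
  d <- forest_design(data, outcome, markers)
  n <- nrow(data)
  seeds <- derive_seeds(seed, 2)
  fold <- make_folds(d$y, config$inner_cv_folds, seed = seeds[1])
  objective <- function(u) {
    h <- decode_hyper(u, n, config)
    err <- 0L
    for (f in sort(unique(fold))) {
      tr <- data[fold != f, , drop = FALSE]
      te <- data[fold == f, , drop = FALSE]
      if (length(unique(tr[[outcome]])) < 2) return(0.5)
      fit <- grow_forest(tr, outcome, markers, method = h$method,
                         n_cycles = h$n_cycles, learn_rate = h$learn_rate,
                         min_leaf = h$min_leaf, max_splits = h$max_splits,
                         n_surrogates = config$n_surrogates,
                         prune = config$prune, seed = seeds[2] + f)
      pred <- predict(fit, te, type = "class")
      err <- err + sum(pred != te[[outcome]])
    }
    err / n
  }
  res <- bo_minimize(objective, d = 5L, iterations = config$bo_iterations,
                     seed = seed)
  list(hyper = decode_hyper(res$par, n, config), cv_error = res$value,
       history = res$history)
}
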