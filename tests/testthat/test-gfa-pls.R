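test_that("LOF arithmetic and monotonicity", {
  expect_equal(lof(4.1, 10, 9, 1.0, 41), (4.1 / 41) / (1 - 19 / 41)^2)
  expect_equal(round(lof(4.1, 10, 9, 1.0, 41), 4), 0.3473)
  expect_equal(lof(0, 5, 4, 2, 41), 0)
  # for fixed LSE, M, d the penalty grows with the descriptor count
  vals <- vapply(1:9, function(p) lof(2, p + 1, p, 1.0, 41), numeric(1))
  expect_true(all(diff(vals) > 0))
  # p -> 0 limit
  expect_equal(lof(2, 3, 0, 1.0, 41), (2 / 41) / (1 - 3 / 41)^2)
  expect_error(lof(2, 30, 29, 1.0, 41), "infeasible")
})

test_that("full-component PLS coincides with least squares", {
  set.seed(2)
  for (p in c(2, 4, 6)) {
    X <- matrix(rnorm(30 * p), 30)
    colnames(X) <- paste0("v", seq_len(p))
    y <- drop(X %*% rnorm(p)) + rnorm(30, 0, 0.3)
    fit <- fit_pls(X, y, n_components = p)
    # normal-equations oracle
    Xi <- cbind(1, X)
    beta <- solve(crossprod(Xi), crossprod(Xi, y))
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 unname(drop(beta)), tolerance = 1e-8)
    expect_equal(fit$lse, sum((drop(Xi %*% beta) - y)^2), tolerance = 1e-8)
  }
})

test_that("single-descriptor PLS is the univariate regression line", {
  set.seed(3)
  x <- rnorm(20)
  y <- 2.5 * x + rnorm(20, 0, 0.2)
  X <- matrix(x, dimnames = list(NULL, "x"))
  fit <- fit_pls(X, y, 1)
  slope <- stats::cov(x, y) / stats::var(x)
  expect_equal(unname(fit$coefficients), slope, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
})

test_that("degenerate responses and columns are handled gracefully", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_pls(X, rep(4, 10), 2)
  expect_equal(unname(fit$coefficients), c(0, 0))
  expect_equal(fit$intercept, 4)
  # constant column gets a zero loading rather than an error
  X2 <- cbind(X, const = 1)
  y <- rnorm(10)
  fit2 <- fit_pls(X2, y, 3)
  expect_true(all(is.finite(fit2$coefficients)))
  expect_equal(unname(fit2$coefficients["const"]), 0, tolerance = 1e-8)
})

test_that("PLS agrees with an independent implementation at low rank", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  X <- matrix(rnorm(25 * 6), 25)
  colnames(X) <- paste0("v", 1:6)
  y <- drop(X %*% c(2, -1, 0.5, 0, 0, 1)) + rnorm(25, 0, 0.4)
  for (a in c(1, 3)) {
    ours <- fit_pls(X, y, a)
    ref <- mixOmics::pls(X, y, ncomp = a, scale = FALSE, mode = "regression")
    pred <- predict(ref, X)$predict[, 1, a]
    expect_equal(unname(ours$intercept + drop(X %*% ours$coefficients)),
                 unname(pred), tolerance = 1e-6)
  }
})

test_that("GA search is reproducible and beats enumeration on small pools", {
  set.seed(4)
  n <- 30
  X <- matrix(runif(n * 10), n)
  colnames(X) <- paste0("g", 1:10)
  y <- 6 + 3 * X[, 2] - 2 * X[, 7] + rnorm(n, 0, 0.15)
  cfg <- gfa_config(population_size = 30, n_crossovers = 1500,
                    max_terms = 3, seed = 99)
  r1 <- gfa_search(X, y, cfg)
  r2 <- gfa_search(X, y, cfg)
  expect_identical(lapply(r1, `[[`, "descriptor_keys"),
                   lapply(r2, `[[`, "descriptor_keys"))
  expect_true(all(diff(vapply(r1, `[[`, numeric(1), "lof")) >= 0))

  # exhaustive enumeration oracle over all subsets of size <= 3
  subsets <- unlist(lapply(1:3, function(k) {
    combn(colnames(X), k, simplify = FALSE)
  }), recursive = FALSE)
  lofs <- vapply(subsets, function(keys) {
    f <- fit_pls(X[, keys, drop = FALSE], y)
    lof(f$lse, length(keys) + 1, length(keys), cfg$smoothing_d, n)
  }, numeric(1))
  best <- subsets[[which.min(lofs)]]
  expect_setequal(r1[[1]]$descriptor_keys, best)
  expect_equal(r1[[1]]$lof, min(lofs), tolerance = 1e-12)
})

test_that("a single-descriptor pool returns the only possible model", {
  set.seed(5)
  X <- matrix(runif(20), 20, 1, dimnames = list(NULL, "only"))
  y <- 1.5 * X[, 1] + rnorm(20, 0, 0.1)
  r <- gfa_search(X, y, gfa_config(population_size = 5, n_crossovers = 5,
                                   max_terms = 1, seed = 1))
  expect_equal(length(r), 1L)
  expect_equal(r[[1]]$descriptor_keys, "only")
  ols <- coef(lm(y ~ X))
  expect_equal(unname(c(r[[1]]$intercept, r[[1]]$coefficients)),
               unname(ols), tolerance = 1e-8)
})

test_that("size sweep pins the term count and ranks by adjusted Q2", {
  set.seed(6)
  n <- 36
  X <- matrix(runif(n * 14), n)
  colnames(X) <- paste0("g", 1:14)
  y <- 7 + 4 * X[, 1] - 3 * X[, 4] + 2 * X[, 9] + rnorm(n, 0, 0.2)
  out <- size_sweep(X, y, gfa_config(population_size = 30,
                                     n_crossovers = 600, seed = 2),
                    sizes = c(3L, 4L))
  expect_equal(vapply(out, `[[`, integer(1), "size"), c(3L, 4L))
  expect_equal(lengths(lapply(out, function(s) s$candidate$descriptor_keys)),
               c(3L, 4L))
  for (s in out) {
    expect_equal(s$q2_adj, adjusted(s$q2, n, s$size), tolerance = 1e-12)
  }
  expect_error(size_sweep(X[, 0, drop = FALSE], y), "empty")
})

test_that("equations print in the published linear form", {
  m <- load_published_model("1B9")
  eq <- format_equation(m)
  expect_match(eq, "^pIC50 = 8.19 ", fixed = FALSE)
  expect_match(eq, "- 18.84 (2,11,4)(any)", fixed = TRUE)
  expect_match(eq, "+ 15.96 (1,13,1)(any)", fixed = TRUE)
  expect_match(eq, "- 20.98 (1,6,-2)(np)", fixed = TRUE)
})
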