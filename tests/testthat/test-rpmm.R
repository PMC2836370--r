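test_that("single-component fit recovers beta parameters (vs truth and MLE oracle)", {
  set.seed(2)
  draws <- matrix(rbeta(500, 5, 2), ncol = 1)
  fit <- fit_beta_mixture(draws, K = 1)
  # independent maximum-likelihood oracle
  oracle <- MASS::fitdistr(as.numeric(draws), "beta",
                           list(shape1 = 2, shape2 = 2))$estimate
  expect_equal(as.numeric(c(fit$a, fit$b)), unname(oracle), tolerance = 1e-4)
  # recovery of the generating parameters across seeds (15% relative error)
  errs <- sapply(1:10, function(s) {
    set.seed(100 + s)
    d <- matrix(rbeta(500, 5, 2), ncol = 1)
    f <- fit_beta_mixture(d, K = 1)
    max(abs(c(f$a / 5, f$b / 2) - 1))
  })
  expect_gt(mean(errs < 0.15), 0.7)
  expect_lt(median(errs), 0.15)
})

test_that("well-separated two-component data is recovered with hard assignment", {
  set.seed(5)
  n <- 20; J <- 30
  lab <- rep(1:2, each = 10)
  mu <- ifelse(outer(lab, rep(1, J)) == 1, 0.2, 0.8)
  X <- matrix(rbeta(n * J, mu * 30, (1 - mu) * 30), n, J)
  fit <- fit_beta_mixture(X, K = 2, seed = 3)
  hard <- apply(fit$resp, 1, which.max)
  expect_equal(length(unique(paste(hard, lab))), 2)  # perfect partition
  expect_true(all(apply(fit$resp, 1, max) > 0.99))
})

test_that("EM log-likelihood is non-decreasing on every fixture", {
  set.seed(6)
  for (i in 1:5) {
    X <- matrix(rbeta(25 * 15, runif(1, 1, 5), runif(1, 1, 5)), 25, 15)
    fit <- fit_beta_mixture(X, K = 2, seed = i, n_init = 2)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("homogeneous data yields a single class", {
  set.seed(8)
  X <- matrix(rbeta(30 * 50, 3, 3), 30, 50)
  rownames(X) <- paste0("S", 1:30)
  cl <- suppressWarnings(rpmm_fit(X, seed = 1))
  expect_equal(cl$n_leaves, 1L)
  expect_true(all(cl$leaf_class == 1L))
  expect_true(all(cl$root_side == "left"))
})

test_that("planted 4-class data is recovered with high adjusted Rand index", {
  d <- make_class_beta(n = 40, J = 100, K = 4, informative_frac = 0.4,
                       gap = 0.6, seed = 11)
  cl <- rpmm_fit(d$X, max_depth = 3, seed = 5)
  expect_equal(cl$n_leaves, 4L)
  expect_gte(mclust::adjustedRandIndex(cl$leaf_class, d$labels), 0.9)
  # root split separates two super-groups
  expect_equal(nlevels(droplevels(root_grouping(cl))), 2)
})

test_that("depth cap limits the number of classes", {
  d <- make_class_beta(n = 40, J = 100, K = 4, informative_frac = 0.4,
                       gap = 0.6, seed = 12)
  cl <- rpmm_fit(d$X, max_depth = 1, seed = 5)
  expect_lte(cl$n_leaves, 2L)
})

test_that("classing is invariant to sample order", {
  d <- make_class_beta(n = 24, J = 60, K = 2, informative_frac = 0.4,
                       gap = 0.6, seed = 13)
  cl1 <- rpmm_fit(d$X, seed = 9)
  set.seed(1)
  perm <- sample(nrow(d$X))
  cl2 <- rpmm_fit(d$X[perm, ], seed = 9)
  expect_identical(cl1$leaf_class[rownames(d$X)[perm]], cl2$leaf_class)
  expect_identical(as.character(cl1$root_side[rownames(d$X)[perm]]),
                   as.character(cl2$root_side))
})

test_that("accepted splits strictly decrease BIC", {
  d <- make_class_beta(n = 30, J = 50, K = 2, informative_frac = 0.4,
                       gap = 0.6, seed = 14)
  cl <- rpmm_fit(d$X, seed = 2)
  check <- function(node) {
    if (!node$split) return(invisible())
    expect_lt(node$bic2, node$bic1)
    check(node$children$left); check(node$children$right)
  }
  check(cl$tree)
})
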