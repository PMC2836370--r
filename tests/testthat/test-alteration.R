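test_that("Welch t matches the textbook formulas and handles degenerate units", {
  tb <- matrix(c(0.8, 0.9, 0.7), 1, dimnames = list("g1", NULL))
  nb <- matrix(c(0.1, 0.2, 0.15), 1, dimnames = list("g1", NULL))
  res <- suppressWarnings(methylation_alteration(tb, nb))
  x <- tb[1, ]; y <- nb[1, ]
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$mean_alteration, mean(x) - mean(y))
  expect_equal(sign(res$t), sign(res$mean_alteration))
  # identical groups: t = 0, p = 1
  same <- matrix(rep(0.5, 3), 1, dimnames = list("g1", NULL))
  r0 <- suppressWarnings(methylation_alteration(same, same))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # unequal means with zero variance -> excluded as degenerate
  a <- matrix(rep(0.8, 3), 1, dimnames = list("g1", NULL))
  b <- matrix(rep(0.2, 3), 1, dimnames = list("g1", NULL))
  rd <- suppressWarnings(methylation_alteration(a, b))
  expect_equal(rd$flag, "degenerate_zero_variance")
  expect_true(is.na(rd$p))
})

test_that("one-sample CN test against diploid matches the closed form", {
  v <- matrix(c(3, 3, 3, 2, 2, 2, 2, 2, 2), 1, dimnames = list("g1", NULL))
  res <- suppressWarnings(cn_alteration(v))
  m <- mean(v); s <- sd(v)
  expect_equal(res$t, (m - 2) / (s / 3), tolerance = 1e-12)
  expect_equal(res$t, 2, tolerance = 1e-12)
  expect_equal(res$mean_alteration, m - 2)
  dip <- matrix(rep(2, 5), 1, dimnames = list("g1", NULL))
  r0 <- suppressWarnings(cn_alteration(dip))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
})

test_that("null methylation comparison is calibrated near the 5% level", {
  set.seed(33)
  n_g <- 663
  tb <- matrix(rbeta(n_g * 19, 3, 3), n_g)
  nb <- matrix(rbeta(n_g * 11, 3, 3), n_g)
  rownames(tb) <- rownames(nb) <- paste0("g", 1:n_g)
  res <- methylation_alteration(tb, nb)
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.025)
  expect_lt(frac, 0.075)
})

test_that("planted amplifications are detected with high power at q < 0.05", {
  set.seed(34)
  n_g <- 300; n_t <- 19
  cn <- matrix(2 + rnorm(n_g * n_t, 0, 0.15), n_g)  # gene-mean CN noise
  amp <- 1:30
  cn[amp, ] <- cn[amp, ] + matrix(rbinom(30 * n_t, 1, 0.6) * 1.5, 30)
  rownames(cn) <- paste0("g", 1:n_g)
  res <- cn_alteration(cn)
  power <- mean(res$significant[amp])
  expect_gte(power, 0.8)
  fpr <- mean(res$significant[-amp])
  expect_lt(fpr, 0.05)
})

test_that("volcano tables are consistent and strata partition the tumors", {
  set.seed(35)
  n_g <- 60
  tumors <- sprintf("T%02d", 1:10)
  side <- rep(c("left", "right"), each = 5)
  tb <- matrix(rbeta(n_g * 10, 2, 2), n_g, dimnames = list(paste0("g", 1:n_g), tumors))
  nb <- matrix(rbeta(n_g * 6, 2, 2), n_g, dimnames = list(paste0("g", 1:n_g), paste0("N", 1:6)))
  # CNA only in left tumors
  cn <- matrix(2 + rnorm(n_g * 10, 0, 0.05), n_g, dimnames = dimnames(tb))
  cn[1:30, side == "left"] <- cn[1:30, side == "left"] + 1.5
  cl <- fake_classing(tumors, side)
  v <- stratified_volcano(tb, nb, cn, cl)
  expect_setequal(names(v$tables), c("all", "left", "right"))
  # -log10(p) consistency to 1e-12
  for (tab in v$tables) {
    ok <- !is.na(tab$p)
    expect_equal(tab$neg_log10_p[ok], -log10(tab$p[ok]), tolerance = 1e-12)
  }
  # left stratum carries (many) more CN significants than the right
  n_left <- sum(v$tables$left$significant[v$tables$left$type == "copy_number"])
  n_right <- sum(v$tables$right$significant[v$tables$right$type == "copy_number"])
  expect_gte(n_left, 5 * max(n_right, 1))
  # identical strata data give identical tables
  cl_same <- fake_classing(tumors, rep(c("left", "right"), 5))
  tb2 <- cbind(tb[, c(1, 3, 5, 7, 9)], tb[, c(1, 3, 5, 7, 9)])
  colnames(tb2) <- tumors
  cn2 <- cbind(cn[, c(1, 3, 5, 7, 9)], cn[, c(1, 3, 5, 7, 9)])
  colnames(cn2) <- tumors
  v2 <- stratified_volcano(tb2, nb, cn2, cl_same)
  expect_equal(v2$tables$left[, -3], v2$tables$right[, -3])  # all but stratum
})
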