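test_that("Hamming distances count mismatches and rescale missing loci", {
  s <- rbind(T1 = c(2, 2, 0, 4), T2 = c(2, 3, 0, 2), T3 = c(2, 2, 0, 4))
  d <- as.matrix(hamming_matrix(s))
  expect_equal(d["T1", "T2"], 2)
  expect_equal(d["T1", "T3"], 0)
  # oracle equivalence on random pairs
  set.seed(44)
  st <- matrix(sample(0:4, 15 * 50, TRUE), 15)
  rownames(st) <- paste0("T", 1:15)
  d2 <- as.matrix(hamming_matrix(st))
  for (i in 1:14) for (j in (i + 1):15) {
    expect_identical(d2[i, j], sum(st[i, ] != st[j, ]) * 1)
  }
  # pairwise-complete rescaling: 1 mismatch in 2 co-observed of 4 loci -> 2
  sm <- rbind(A = c(2, NA, 0, 4), B = c(3, 3, NA, 4))
  expect_equal(as.matrix(hamming_matrix(sm))["A", "B"], 1 * (4 / 2))
})

test_that("Hamming distance is a metric on complete state vectors", {
  set.seed(45)
  for (rep in 1:20) {
    st <- matrix(sample(0:4, 3 * 30, TRUE), 3)
    rownames(st) <- c("a", "b", "c")
    d <- as.matrix(hamming_matrix(st))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"])
  }
})

test_that("Ward clustering merges duplicates first and recovers planted blocks", {
  set.seed(46)
  st <- matrix(sample(0:4, 8 * 100, TRUE), 8)
  st[2, ] <- st[1, ]  # exact duplicates
  rownames(st) <- paste0("T", 1:8)
  hc <- ward_cluster(hamming_matrix(st))
  expect_equal(hc$height[1], 0)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
  # two planted blocks: within-block Hamming << between
  base1 <- sample(0:4, 200, TRUE); base2 <- sample(0:4, 200, TRUE)
  blocks <- rbind(
    t(replicate(4, { v <- base1; i <- sample(200, 5); v[i] <- (v[i] + 1) %% 5; v })),
    t(replicate(4, { v <- base2; i <- sample(200, 5); v[i] <- (v[i] + 1) %% 5; v })))
  rownames(blocks) <- paste0("T", 1:8)
  hc2 <- ward_cluster(hamming_matrix(blocks))
  expect_equal(unname(cutree(hc2, 2)), rep(1:2, each = 4))
  expect_true(all(diff(hc2$height) >= -1e-8))  # monotone merge heights
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("high/low dichotomization labels the heavier-burden cluster high", {
  set.seed(47)
  st <- rbind(matrix(sample(c(0, 1, 3, 4), 4 * 100, TRUE), 4),
              matrix(2L, 4, 100))
  st[5:8, 1:3] <- 3L  # slight noise in the diploid block
  rownames(st) <- paste0("T", 1:8)
  burden <- cn_burden(st)
  grp <- dichotomize_cna(ward_cluster(hamming_matrix(st)), burden)
  expect_s3_class(grp, "cna_grouping")
  expect_equal(unname(as.character(grp$label[1:4])), rep("high", 4))
  expect_gte(grp$group_means["high"], grp$group_means["low"])
  # permuting tumor order does not change the partition
  perm <- c(5, 1, 7, 3, 8, 2, 6, 4)
  grp2 <- dichotomize_cna(ward_cluster(hamming_matrix(st[perm, ])), burden[perm])
  expect_identical(as.character(grp$label[rownames(st)]),
                   as.character(grp2$label[rownames(st)]))
})

test_that("high/low grouping recovers the planted burden tiers", {
  tier_cfg <- function(seed) {
    simulation_config(n_cpg = 30, n_genes = 15, seed = seed)
  }
  hits <- sapply(1:20, function(s) {
    co <- simulate_cohort(tier_cfg(s))
    grp <- dichotomize_cna(ward_cluster(hamming_matrix(co$cn)),
                           cn_burden(co$cn))
    mean(as.character(grp$label) == co$truth$burden_tier[names(grp$label)])
  })
  expect_gte(mean(hits == 1), 0.9)
  # agreement with thresholding true burden at the planted mid-point
  agree <- sapply(1:20, function(s) {
    co <- simulate_cohort(tier_cfg(100 + s))
    grp <- dichotomize_cna(ward_cluster(hamming_matrix(co$cn)),
                           cn_burden(co$cn))
    mid <- mean(c(co$cfg$burden_high, co$cfg$burden_low))
    thr <- ifelse(co$truth$true_burden > mid, "high", "low")
    mean(as.character(grp$label[names(thr)]) == thr)
  })
  expect_gte(mean(agree == 1), 0.9)
})

test_that("LINE-1 group difference matches the Welch closed form", {
  l1 <- c(A = 50, B = 52, C = 64, D = 66)
  grp <- factor(c(A = "high", B = "high", C = "low", D = "low"),
                levels = c("high", "low"))
  res <- line1_group_difference(l1, grp)
  expect_equal(res$difference, -14)
  tt <- t.test(c(50, 52), c(64, 66))
  expect_equal(res$conf_int, unname(tt$conf.int), tolerance = 1e-12)
  # identical groups: difference 0, CI contains 0
  l0 <- c(A = 60, B = 61, C = 60, D = 61)
  r0 <- line1_group_difference(l0, grp)
  expect_equal(r0$difference, 0)
  expect_true(r0$conf_int[1] <= 0 && r0$conf_int[2] >= 0)
  # singleton group: point estimate only
  r1 <- line1_group_difference(l1[c("A", "C", "D")], grp[c("A", "C", "D")])
  expect_false(r1$ci_available)
})

test_that("heatmap orderings are permutations consistent with the classing", {
  d <- make_class_beta(n = 16, J = 60, K = 2, informative_frac = 0.4,
                       gap = 0.6, seed = 48)
  cl <- rpmm_fit(d$X, seed = 3)
  set.seed(48)
  st <- matrix(sample(0:4, 16 * 80, TRUE), 16)
  rownames(st) <- rownames(d$X)
  ords <- heatmap_orderings(d$X, st, cl)
  expect_setequal(ords$meth_order, rownames(d$X))
  expect_setequal(ords$cn_order, rownames(st))
  # class blocks are contiguous in the methylation ordering
  cls_seq <- cl$leaf_class[ords$meth_order]
  expect_equal(sum(diff(cls_seq) != 0), cl$n_leaves - 1)
})
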