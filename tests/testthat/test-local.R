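test_that("nearest-SNP matching obeys distance and tie rules", {
  cpg <- data.frame(chrom = "chr1", start = 100, locus = "cg1", gene = NA)
  snp <- data.frame(chrom = "chr1", start = c(90, 150), locus = c("a", "b"),
                    gene = NA)
  m <- match_loci(cpg, snp)
  expect_equal(m$snp, "a")
  expect_equal(m$distance, 10)
  # exact tie -> lower coordinate
  snp2 <- data.frame(chrom = "chr1", start = c(90, 110), locus = c("a", "b"),
                     gene = NA)
  expect_equal(match_loci(cpg, snp2)$snp, "a")
  # CpG on a chromosome without SNPs -> unmatched, flagged
  cpg2 <- data.frame(chrom = "chr9", start = 5, locus = "cg9", gene = NA)
  m2 <- match_loci(cpg2, snp)
  expect_true(is.na(m2$snp) && !m2$matched)
  # max_distance filter
  m3 <- match_loci(cpg, snp, max_distance = 5)
  expect_false(m3$matched)
})

test_that("matching equals the brute-force nearest-neighbor oracle", {
  set.seed(25)
  cpg <- data.frame(chrom = sample(paste0("chr", 1:4), 1000, TRUE),
                    start = sample.int(1e5, 1000, TRUE),
                    locus = paste0("cg", 1:1000), gene = NA)
  snp <- data.frame(chrom = sample(paste0("chr", 1:4), 800, TRUE),
                    start = sample.int(1e5, 800, TRUE),
                    locus = paste0("rs", 1:800), gene = NA)
  got <- match_loci(cpg, snp)
  got <- got[match(cpg$locus, got$cpg), ]
  oracle <- vapply(seq_len(nrow(cpg)), function(i) {
    cand <- snp[snp$chrom == cpg$chrom[i], ]
    d <- abs(cand$start - cpg$start[i])
    best <- d == min(d)
    cand$locus[best][which.min(cand$start[best])]
  }, character(1))
  expect_identical(got$snp, oracle)
})

test_that("gene aggregation averages promoter CpGs and gene SNPs", {
  beta <- matrix(c(0.2, 0.4, 0.9), 1, dimnames = list("S1", c("c1", "c2", "c3")))
  cn <- matrix(c(2, 4), 1, dimnames = list("S1", c("r1", "r2")))
  cpg_annot <- data.frame(chrom = "chr1", start = 1:3,
                          locus = c("c1", "c2", "c3"),
                          gene = c("G1", "G1", "G2"),
                          upstream_of_tss = c(1, 1, 0))
  snp_annot <- data.frame(chrom = "chr1", start = 1:2,
                          locus = c("r1", "r2"), gene = c("G1", "G1"))
  agg <- gene_aggregate(beta, cn, cpg_annot, snp_annot)
  expect_equal(unname(agg$meth["S1", "G1"]), 0.3)
  expect_false("G2" %in% colnames(agg$meth))  # only downstream CpG
  expect_equal(unname(agg$cn["S1", "G1"]), 3)
  expect_true("G2" %in% agg$excluded$gene)
})

test_that("gene aggregation equals a per-gene loop oracle on random fixtures", {
  set.seed(26)
  n <- 8; J <- 40
  genes <- sample(paste0("G", 1:10), J, TRUE)
  up <- rbinom(J, 1, 0.7)
  beta <- matrix(runif(n * J), n, dimnames = list(paste0("S", 1:n),
                                                  paste0("c", 1:J)))
  cpg_annot <- data.frame(chrom = "chr1", start = 1:J,
                          locus = colnames(beta), gene = genes,
                          upstream_of_tss = up)
  cn <- matrix(sample(0:4, n * J, TRUE), n,
               dimnames = list(paste0("S", 1:n), paste0("r", 1:J)))
  snp_annot <- data.frame(chrom = "chr1", start = 1:J,
                          locus = colnames(cn), gene = genes)
  agg <- gene_aggregate(beta, cn, cpg_annot, snp_annot)
  for (g in colnames(agg$meth)) {
    keep <- genes == g & up == 1
    expect_equal(agg$meth[, g], rowMeans(beta[, keep, drop = FALSE]),
                 ignore_attr = TRUE)
  }
  for (g in colnames(agg$cn)) {
    expect_equal(agg$cn[, g], rowMeans(cn[, genes == g, drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("correlation screen: exact r, permutation floor, degenerate flags", {
  x <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("u1", NULL))
  y <- matrix(c(2, 1, 4, 3, 5), 1, dimnames = list("u1", NULL))
  res <- correlation_screen(x, y, n_perm = 200, seed = 1)
  expect_equal(res$r, 0.8)
  expect_equal(res$r, unname(cor(x[1, ], y[1, ])), tolerance = 1e-12)
  # y = x exactly over 19 samples
  x19 <- matrix(rnorm(19), 1, dimnames = list("u", NULL))
  res2 <- correlation_screen(x19, x19, n_perm = 5000, seed = 2)
  expect_equal(res2$r, 1)
  expect_equal(res2$p, 1 / 5001)
  # constant vector excluded with a flag
  yc <- matrix(rep(0.5, 19), 1, dimnames = list("u", NULL))
  res3 <- correlation_screen(x19, yc, n_perm = 100, seed = 3)
  expect_true(is.na(res3$r) && res3$flag == "zero_variance")
  expect_error(correlation_screen(x19, x19, n_perm = 0), "n_perm")
})

test_that("permutation p is uniform on the achievable grid under the null", {
  set.seed(27)
  n_u <- 800
  x <- matrix(rnorm(n_u * 19), n_u)
  y <- matrix(rnorm(n_u * 19), n_u)
  res <- correlation_screen(x, y, n_perm = 999, seed = 5)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("q-values reduce to Benjamini-Hochberg at pi0 = 1 and are monotone", {
  expect_equal(qvalues(rep(1, 20)), rep(1, 20))
  set.seed(28)
  for (i in 1:20) {
    p <- runif(sample(20:200, 1))^sample(1:3, 1)
    q <- qvalues(p, pi0 = 1)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(diff(qvalues(p)[order(p)]) >= -1e-12))
  }
  expect_warning(qvalues(runif(5)), "pi0 = 1")
  expect_error(qvalues(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("significant units are filtered and ordered by p then |r|", {
  res <- data.frame(unit = letters[1:4], r = c(0.9, -0.95, 0.2, 0.5),
                    p = c(0.001, 0.001, 0.5, 0.01),
                    q = c(0.01, 0.01, 0.6, 0.04))
  out <- flag_significant(res, 0.05)
  expect_equal(out$unit, c("b", "a", "d"))
  expect_equal(nrow(flag_significant(res[0, ], 0.05)), 0)
})
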