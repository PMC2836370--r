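#' Match each CpG locus to its nearest same-chromosome SNP
#'
#' Nearest-coordinate matching (typically within 1 kb on a dense SNP array):
#' each CpG is paired with the SNP of minimal absolute coordinate distance on
#' the same chromosome; exact distance ties go to the lower coordinate.  CpGs
#' on chromosomes with no SNPs are returned unmatched (NA snp, flagged).
#'
#' @param cpg_annot,snp_annot annotation data.frames as from
#'   [read_annotation()] (columns chrom, start, locus).
#' @param max_distance drop pairs farther than this many bp (default
#'   unlimited).
#' @return data.frame with columns \code{cpg}, \code{snp}, \code{chrom},
#'   \code{distance}, \code{matched}.
#' @export
match_loci <- function(cpg_annot, snp_annot, max_distance = Inf) {
  out <- lapply(split(cpg_annot, cpg_annot$chrom), function(cp) {
    chr <- cp$chrom[1]
    sn <- snp_annot[snp_annot$chrom == chr, , drop = FALSE]
    if (nrow(sn) == 0L) {
      return(data.frame(cpg = cp$locus, snp = NA_character_, chrom = chr,
                        distance = NA_real_, matched = FALSE,
                        stringsAsFactors = FALSE))
    }
    sn <- sn[order(sn$start), , drop = FALSE]
    pos <- sn$start
    # candidate = insertion point and its left neighbor
    idx <- findInterval(cp$start, pos)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(pos))
    d_lo <- abs(cp$start - pos[lo])
    d_hi <- abs(cp$start - pos[hi])
    # ties (equal distance) go to the lower coordinate, i.e. the left candidate
    take_lo <- d_lo <= d_hi
    pick <- ifelse(take_lo, lo, hi)
    dist <- ifelse(take_lo, d_lo, d_hi)
    data.frame(cpg = cp$locus, snp = sn$locus[pick], chrom = chr,
               distance = dist, matched = dist <= max_distance,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$matched[is.na(res$snp)] <- FALSE
  res
}

#' Aggregate methylation and copy number to the gene level
#'
#' Gene-level methylation is the mean beta over the gene's promoter CpGs
#' (those flagged upstream of the TSS); genes with no promoter CpG are
#' excluded from the methylation table.  Gene-level copy number is the mean
#' state over all SNPs assigned to the gene; genes with no SNPs are excluded
#' from the CN table.
#'
#' @param beta samples-by-CpGs beta matrix (columns named by CpG locus id).
#' @param cn tumors-by-SNPs copy-number-state matrix (columns named by SNP id).
#' @param cpg_annot CpG annotation with columns locus, gene, upstream_of_tss.
#' @param snp_annot SNP annotation with columns locus, gene.
#' @return list with \code{meth} (samples x genes promoter methylation),
#'   \code{cn} (tumors x genes mean copy number), \code{excluded} (genes
#'   missing from either table, with reason).
#' @export
gene_aggregate <- function(beta, cn, cpg_annot, snp_annot) {
  stopifnot("upstream_of_tss" %in% names(cpg_annot))
  prom <- cpg_annot[!is.na(cpg_annot$gene) & cpg_annot$upstream_of_tss == 1 &
                      cpg_annot$locus %in% colnames(beta), , drop = FALSE]
  meth <- aggregate_cols(beta, prom$locus, prom$gene)
  snps <- snp_annot[!is.na(snp_annot$gene) &
                      snp_annot$locus %in% colnames(cn), , drop = FALSE]
  cng <- aggregate_cols(cn, snps$locus, snps$gene)
  all_genes <- unique(c(cpg_annot$gene, snp_annot$gene))
  all_genes <- all_genes[!is.na(all_genes)]
  no_prom <- setdiff(all_genes, colnames(meth))
  no_snp <- setdiff(all_genes, colnames(cng))
  excl <- data.frame(gene = c(no_prom, no_snp),
                     reason = rep(c("no_promoter_cpg", "no_snp"),
                                  c(length(no_prom), length(no_snp))),
                     stringsAsFactors = FALSE)
  list(meth = meth, cn = cng, excluded = excl)
}

# column-group means: samples x loci matrix -> samples x groups
aggregate_cols <- function(m, loci, groups) {
  sub <- m[, loci, drop = FALSE]
  g <- factor(groups)
  ind <- matrix(0, length(g), nlevels(g))
  ind[cbind(seq_along(g), as.integer(g))] <- 1
  counts <- colSums(ind)
  out <- sub %*% ind
  out <- sweep(out, 2, counts, "/")
  colnames(out) <- levels(g)
  # NA propagation: recompute affected columns with na.rm pairwise means
  if (anyNA(sub)) {
    for (k in seq_len(nlevels(g))) {
      cols <- which(g == levels(g)[k])
      if (anyNA(sub[, cols])) out[, k] <- rowMeans(sub[, cols, drop = FALSE],
                                                   na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
  }
  out
}

#' Pearson correlation screen with permutation p-values
#'
#' For each unit (locus or gene), computes the Pearson product-moment
#' correlation between matched methylation and copy-number values over tumors
#' and a two-sided permutation p-value: the methylation vector's sample order
#' is permuted (copy number held fixed) and
#' \eqn{p = (1 + \#\{|r_b| \ge |r_{obs}|\}) / (n_{perm} + 1)}.  A single
#' permutation schedule, drawn once from the seed, is shared across all units
#' so results are seed-stable and comparable between units.  Units with zero
#' variance in either vector, or fewer than 3 complete pairs, are excluded
#' with a flag.
#'
#' @param x_matrix units-by-samples matrix (copy number; held fixed).
#' @param y_matrix units-by-samples matrix (methylation; permuted), same
#'   columns.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed for the shared permutation schedule.
#' @param level label stored in the output ("locus" or "gene").
#' @return data.frame of class \code{"methcna_corr"}: columns \code{unit},
#'   \code{level}, \code{r}, \code{p}, \code{q}, \code{n}, \code{flag}.
#' @export
correlation_screen <- function(x_matrix, y_matrix, n_perm = 5000, seed = 1,
                               level = "locus") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  stopifnot(ncol(x_matrix) == ncol(y_matrix),
            nrow(x_matrix) == nrow(y_matrix))
  units <- rownames(x_matrix)
  if (is.null(units)) units <- paste0("u", seq_len(nrow(x_matrix)))
  n_s <- ncol(x_matrix)
  set.seed(stage_seed(seed, "local_perm"))
  perms <- vapply(seq_len(n_perm), function(b) sample.int(n_s), integer(n_s))

  n_u <- nrow(x_matrix)
  r <- rep(NA_real_, n_u); p <- rep(NA_real_, n_u)
  npairs <- integer(n_u); flag <- rep("", n_u)

  complete <- !is.na(x_matrix) & !is.na(y_matrix)
  all_complete <- rowSums(complete) == n_s
  sdx <- apply(x_matrix, 1, function(v) stats::sd(v, na.rm = TRUE))
  sdy <- apply(y_matrix, 1, function(v) stats::sd(v, na.rm = TRUE))

  zerovar <- !is.na(sdx) & !is.na(sdy) & (sdx == 0 | sdy == 0)
  toofew <- rowSums(complete) < 3
  flag[zerovar] <- "zero_variance"
  flag[toofew] <- "too_few_pairs"
  usable <- !zerovar & !toofew
  npairs <- rowSums(complete)

  # fast path: complete units, vectorized across units and permutations
  fast <- usable & all_complete
  if (any(fast)) {
    X <- x_matrix[fast, , drop = FALSE]
    Y <- y_matrix[fast, , drop = FALSE]
    Xs <- t(scale(t(X)))  # centered/scaled rows
    Ys <- t(scale(t(Y)))
    robs <- rowSums(Xs * Ys) / (n_s - 1)
    r[fast] <- robs
    count <- integer(sum(fast))
    for (b in seq_len(n_perm)) {
      rb <- rowSums(Xs * Ys[, perms[, b], drop = FALSE]) / (n_s - 1)
      count <- count + (abs(rb) >= abs(robs) - 1e-12)
    }
    p[fast] <- (1 + count) / (n_perm + 1)
  }
  # slow path: units with missing values (pairwise-complete within unit)
  slow <- which(usable & !all_complete)
  for (i in slow) {
    ok <- complete[i, ]
    x <- x_matrix[i, ok]; y <- y_matrix[i, ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      flag[i] <- "zero_variance"; next
    }
    robs <- stats::cor(x, y)
    m <- length(x)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      # restrict the shared schedule to the observed samples
      yb <- y[rank(perms[ok, b], ties.method = "first")]
      if (abs(stats::cor(x, yb)) >= abs(robs) - 1e-12) cnt <- cnt + 1L
    }
    r[i] <- robs
    p[i] <- (1 + cnt) / (n_perm + 1)
  }
  res <- data.frame(unit = units, level = level, r = r, p = p,
                    q = NA_real_, n = npairs, flag = flag,
                    stringsAsFactors = FALSE)
  ok <- !is.na(res$p)
  if (sum(ok) > 0) res$q[ok] <- qvalues(res$p[ok])
  class(res) <- c("methcna_corr", "data.frame")
  res
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the proportion of true nulls
#' \eqn{\pi_0} estimated on the grid \eqn{\lambda = 0.05, 0.10, \ldots, 0.95}
#' and extrapolated to \eqn{\lambda \to 1} with a cubic smoothing spline
#' (3 df), clamped to (0, 1].  With fewer than 10 p-values, \eqn{\pi_0} falls
#' back to 1 with a warning, which makes the result identical to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p vector of p-values in (0, 1].
#' @param pi0 optionally force \eqn{\pi_0} (e.g. 1 for plain BH).
#' @return q-values, same order as \code{p}; monotone non-decreasing in p.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10) {
      warning("fewer than 10 p-values; using pi0 = 1 (Benjamini-Hochberg)")
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o])
  pmin(q, 1)
}

#' Significant units of a correlation screen
#'
#' Units with q below the threshold, sorted by p ascending (ties by |r|
#' descending).
#'
#' @param results a [correlation_screen()] result (or any data.frame with
#'   columns p, q, r).
#' @param q_threshold significance threshold (default 0.05).
#' @return subset of \code{results}.
#' @export
flag_significant <- function(results, q_threshold = 0.05) {
  keep <- !is.na(results$q) & results$q < q_threshold
  out <- results[keep, , drop = FALSE]
  out[order(out$p, -abs(out$r)), , drop = FALSE]
}
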