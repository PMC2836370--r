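#' Pairwise Hamming distances between copy-number profiles
#'
#' d(i, j) is the number of loci at which the integer state vectors differ.
#' With missing states, the comparison is pairwise-complete and the count is
#' rescaled to the full locus number so distances stay comparable across
#' pairs; a pair with no co-observed loci is an error.
#'
#' @param states tumors-by-loci integer copy-number-state matrix.
#' @return a \code{dist} object over tumors.
#' @export
hamming_matrix <- function(states) {
  stopifnot(is.matrix(states), nrow(states) >= 2)
  n <- nrow(states); L <- ncol(states)
  d <- matrix(0, n, n, dimnames = list(rownames(states), rownames(states)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(states[i, ]) & !is.na(states[j, ])
      m <- sum(ok)
      if (m == 0) stop("tumor pair with zero co-observed loci: ", i, ",", j)
      d[i, j] <- d[j, i] <- sum(states[i, ok] != states[j, ok]) * (L / m)
    }
  }
  stats::as.dist(d)
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering by Ward's minimum-variance criterion, applying
#' the Lance-Williams recurrence to squared input distances (the "ward.D2"
#' convention), so it is well defined for non-Euclidean metrics such as
#' Hamming.
#'
#' @param dist_matrix a \code{dist} object or symmetric zero-diagonal matrix.
#' @param squared if FALSE (default) use the ward.D2 convention; TRUE applies
#'   the recurrence to the raw distances ("ward.D").
#' @return an \code{hclust} object.
#' @export
ward_cluster <- function(dist_matrix, squared = FALSE) {
  if (is.matrix(dist_matrix)) {
    if (!isSymmetric(unname(dist_matrix)) || any(diag(dist_matrix) != 0)) {
      stop("distance matrix must be symmetric with zero diagonal")
    }
    dist_matrix <- stats::as.dist(dist_matrix)
  }
  stats::hclust(dist_matrix, method = if (squared) "ward.D" else "ward.D2")
}

#' Dichotomize tumors into high/low CNA groups
#'
#' Cuts the copy-number dendrogram into two clusters and labels the cluster
#' with the larger mean burden "high".  If the mean burdens tie, the larger
#' cluster is labeled "low" with a warning.
#'
#' @param dend an \code{hclust} object over tumors (e.g. from
#'   [ward_cluster()] of [hamming_matrix()]).
#' @param burden named per-tumor burden vector (see [cn_burden()]).
#' @return list of class \code{"cna_grouping"}: \code{label} (named factor
#'   high/low), \code{group_means} (mean burden per group).
#' @export
dichotomize_cna <- function(dend, burden) {
  stopifnot(inherits(dend, "hclust"))
  cl <- stats::cutree(dend, k = 2)
  burden <- burden[names(cl)]
  m <- tapply(burden, cl, mean)
  if (m[1] == m[2]) {
    warning("equal mean burdens; labeling the larger cluster 'low'")
    sizes <- table(cl)
    low_id <- names(sizes)[which.max(sizes)]
  } else {
    low_id <- names(m)[which.min(m)]
  }
  lab <- factor(ifelse(as.character(cl) == low_id, "low", "high"),
                levels = c("high", "low"))
  names(lab) <- names(cl)
  gm <- tapply(burden, lab, mean)
  structure(list(label = lab, group_means = gm), class = "cna_grouping")
}

#' LINE-1 global-methylation difference between high and low CNA groups
#'
#' Point estimate mean(high) - mean(low) in percentage points of LINE-1
#' methylation, with a Welch-based two-sided confidence interval.  With fewer
#' than 2 values in a group only the point estimate is returned and the CI is
#' flagged unavailable.
#'
#' @param line1 named per-sample mean LINE-1 percent methylation (as from
#'   [line1_summary()]).
#' @param groups a \code{"cna_grouping"} or named factor of high/low labels.
#' @param conf_level confidence level (default 0.95).
#' @return list: \code{difference}, \code{conf_int} (length 2 or NULL),
#'   \code{conf_level}, \code{n} (per group), \code{ci_available}.
#' @export
line1_group_difference <- function(line1, groups, conf_level = 0.95) {
  if (inherits(groups, "cna_grouping")) groups <- groups$label
  common <- intersect(names(line1), names(groups))
  x <- line1[common][groups[common] == "high"]
  y <- line1[common][groups[common] == "low"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("need LINE-1 values in both groups")
  d <- mean(x) - mean(y)
  if (length(x) < 2 || length(y) < 2) {
    return(list(difference = d, conf_int = NULL, conf_level = conf_level,
                n = c(high = length(x), low = length(y)), ci_available = FALSE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  list(difference = d, conf_int = unname(tt$conf.int),
       conf_level = conf_level,
       n = c(high = length(x), low = length(y)), ci_available = TRUE)
}

#' Sample orderings for methylation and copy-number heatmaps
#'
#' Tumors are ordered for display: methylation by (RPMM leaf class, then
#' Ward/Euclidean leaf order within class); copy number by the CN dendrogram
#' leaf order.  Only orderings (and optionally plots) are produced; the
#' matrices themselves are not reshaped.
#'
#' @param beta samples-by-CpGs beta matrix (tumors only).
#' @param states tumors-by-loci copy-number-state matrix.
#' @param classing an [rpmm_fit()] result covering the tumors.
#' @param cn_dend \code{hclust} over tumors (from [ward_cluster()] on
#'   [hamming_matrix()]); computed if NULL.
#' @return list with \code{meth_order} and \code{cn_order} (character vectors
#'   of tumor ids) and \code{meth_table} (sample, class, side, position).
#' @export
heatmap_orderings <- function(beta, states, classing, cn_dend = NULL) {
  tumors <- rownames(beta)
  cls <- classing$leaf_class[tumors]
  meth_order <- character(0)
  for (k in sort(unique(cls))) {
    members <- tumors[cls == k]
    if (length(members) > 2) {
      d <- stats::dist(beta[members, , drop = FALSE])
      hc <- ward_cluster(d)
      members <- members[hc$order]
    }
    meth_order <- c(meth_order, members)
  }
  if (is.null(cn_dend)) cn_dend <- ward_cluster(hamming_matrix(states))
  cn_order <- rownames(states)[cn_dend$order]
  list(meth_order = meth_order, cn_order = cn_order,
       meth_table = data.frame(sample = meth_order,
                               class = classing$leaf_class[meth_order],
                               side = classing$root_side[meth_order],
                               position = seq_along(meth_order),
                               stringsAsFactors = FALSE, row.names = NULL))
}
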