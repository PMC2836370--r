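#' Tumor-versus-normal methylation alteration tests
#'
#' Per unit (gene or locus), a two-sided Welch two-sample t-test
#' (unequal variance, Satterthwaite degrees of freedom) compares tumor and
#' normal methylation; the mean alteration is mean(tumor) - mean(normal).
#' q-values are computed over the unit family.  Degenerate units (zero
#' variance in both groups) get t = 0, p = 1 when the means agree and are
#' excluded with a flag when they differ.
#'
#' @param tumor_beta units-by-tumors methylation matrix (rows = units).
#' @param normal_beta units-by-normals methylation matrix, same rows.
#' @param stratum label stored in the output (default "all").
#' @param q_threshold significance threshold for the \code{significant} flag.
#' @return data.frame: unit, type, stratum, mean_alteration, t, df, p, q,
#'   significant, flag.
#' @export
methylation_alteration <- function(tumor_beta, normal_beta, stratum = "all",
                                   q_threshold = 0.05) {
  stopifnot(nrow(tumor_beta) == nrow(normal_beta))
  units <- rownames(tumor_beta)
  if (is.null(units)) units <- paste0("u", seq_len(nrow(tumor_beta)))
  n_u <- nrow(tumor_beta)
  out <- data.frame(unit = units, type = "methylation", stratum = stratum,
                    mean_alteration = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, q = NA_real_, significant = FALSE,
                    flag = "", stringsAsFactors = FALSE)
  for (i in seq_len(n_u)) {
    x <- tumor_beta[i, ]; x <- x[!is.na(x)]
    y <- normal_beta[i, ]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) { out$flag[i] <- "too_few"; next }
    d <- mean(x) - mean(y)
    out$mean_alteration[i] <- d
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (d == 0) { out$t[i] <- 0; out$p[i] <- 1 }
      else out$flag[i] <- "degenerate_zero_variance"
      next
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    out$t[i] <- unname(tt$statistic)
    out$df[i] <- unname(tt$parameter)
    out$p[i] <- tt$p.value
  }
  finalize_alteration(out, q_threshold)
}

#' One-sample copy-number alteration tests against diploid
#'
#' Per unit, a one-sample t-test of gene-mean copy number against the normal
#' expectation of 2 copies; mean alteration is mean(CN) - 2.  Zero-variance
#' units at exactly 2 get t = 0, p = 1; zero variance off 2 is flagged
#' degenerate and excluded.
#'
#' @param cn_gene_matrix units-by-tumors mean copy-number matrix.
#' @param stratum label stored in the output.
#' @param q_threshold significance threshold.
#' @return data.frame as in [methylation_alteration()] with type
#'   "copy_number".
#' @export
cn_alteration <- function(cn_gene_matrix, stratum = "all", q_threshold = 0.05) {
  units <- rownames(cn_gene_matrix)
  if (is.null(units)) units <- paste0("u", seq_len(nrow(cn_gene_matrix)))
  n_u <- nrow(cn_gene_matrix)
  out <- data.frame(unit = units, type = "copy_number", stratum = stratum,
                    mean_alteration = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, q = NA_real_, significant = FALSE,
                    flag = "", stringsAsFactors = FALSE)
  for (i in seq_len(n_u)) {
    x <- cn_gene_matrix[i, ]; x <- x[!is.na(x)]
    if (length(x) < 2) { out$flag[i] <- "too_few"; next }
    d <- mean(x) - 2
    out$mean_alteration[i] <- d
    if (stats::sd(x) == 0) {
      if (d == 0) { out$t[i] <- 0; out$p[i] <- 1 }
      else out$flag[i] <- "degenerate_zero_variance"
      next
    }
    tt <- stats::t.test(x, mu = 2)
    out$t[i] <- unname(tt$statistic)
    out$df[i] <- unname(tt$parameter)
    out$p[i] <- tt$p.value
  }
  finalize_alteration(out, q_threshold)
}

finalize_alteration <- function(out, q_threshold) {
  ok <- !is.na(out$p)
  if (sum(ok) > 1) {
    out$q[ok] <- qvalues(pmax(out$p[ok], .Machine$double.xmin))
    out$significant[ok] <- out$q[ok] < q_threshold
  }
  out
}

#' Stratified volcano tables by RPMM left/right class
#'
#' Re-runs the methylation and copy-number alteration tests within each root
#' split stratum of the RPMM tree, and overall, producing volcano-plot tables
#' of mean alteration versus -log10 p.  Strata with fewer than 2 tumors are
#' skipped with a flag.  Multiple-testing families are per (alteration type x
#' stratum).
#'
#' @param tumor_beta,normal_beta units-by-samples methylation matrices.
#' @param cn_gene_matrix units-by-tumors copy-number matrix (tumor columns as
#'   in \code{tumor_beta}).
#' @param classing an [rpmm_fit()] result whose samples include the tumor
#'   columns.
#' @param q_threshold significance threshold.
#' @return list with \code{tables} (one data.frame per stratum, with
#'   \code{neg_log10_p}), \code{skipped} (character vector of skipped strata).
#' @export
stratified_volcano <- function(tumor_beta, normal_beta, cn_gene_matrix,
                               classing, q_threshold = 0.05) {
  sides <- root_grouping(classing)
  tumors <- colnames(tumor_beta)
  stopifnot(!is.null(tumors), all(tumors %in% names(sides)))
  strata <- list(all = tumors,
                 left = tumors[sides[tumors] == "left"],
                 right = tumors[sides[tumors] == "right"])
  tables <- list(); skipped <- character(0)
  for (s in names(strata)) {
    cols <- strata[[s]]
    if (length(cols) < 2) { skipped <- c(skipped, s); next }
    meth <- methylation_alteration(tumor_beta[, cols, drop = FALSE],
                                   normal_beta, stratum = s,
                                   q_threshold = q_threshold)
    cna <- cn_alteration(cn_gene_matrix[, cols, drop = FALSE], stratum = s,
                         q_threshold = q_threshold)
    tab <- rbind(meth, cna)
    tab$neg_log10_p <- -log10(tab$p)
    tables[[s]] <- tab
  }
  list(tables = tables, skipped = skipped)
}
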