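#' Compute methylation beta values from methylated/unmethylated signals
#'
#' The beta value at a CpG is estimated from the methylated (M) and
#' unmethylated (U) fluorescence intensities as
#' \deqn{\beta = \max(M, 0) / (|U| + |M| + 100),}
#' the standard GoldenGate/BeadStudio estimator.  The +100 offset stabilizes
#' low-intensity loci; negative M (background over-subtraction) is clamped to
#' zero in the numerator but still contributes |M| to the denominator, so the
#' result is always in [0, 1).
#'
#' @param M numeric vector/matrix of methylated-allele signals (may be negative).
#' @param U numeric vector/matrix of unmethylated-allele signals.
#' @return beta values, same shape as the inputs, each in [0, 1).
#' @examples
#' compute_beta(900, 0)    # 0.9
#' compute_beta(-50, 100)  # 0: negative M clamps to 0
#' @export
compute_beta <- function(M, U) {
  if (!is.numeric(M) || !is.numeric(U)) {
    stop("M and U must be numeric")
  }
  if (any(!is.finite(M)) || any(!is.finite(U))) {
    stop("non-finite signal values")
  }
  pmax(M, 0) / (abs(U) + abs(M) + 100)
}

#' Reconstruct M/U signal pairs from beta values
#'
#' Inverts the beta estimator for simulation purposes: given a target beta and
#' a total raw intensity M + U, solves for non-negative M and U such that
#' \code{compute_beta(M, U)} returns the target.  With M, U >= 0 the estimator
#' is beta = M / (M + U + 100), so M = beta * (total + 100) and U = total - M.
#' Betas too large to be representable at the given total intensity (i.e.
#' beta * (total + 100) > total) are clamped with a warning.
#'
#' @param beta numeric vector/matrix of target beta values in [0, 1).
#' @param total_intensity positive scalar, the raw intensity M + U per probe.
#' @return list with components \code{M} and \code{U}, same shape as \code{beta}.
#' @export
synthesize_signals <- function(beta, total_intensity = 10000) {
  if (!is.numeric(total_intensity) || length(total_intensity) != 1L ||
      !is.finite(total_intensity) || total_intensity <= 0) {
    stop("total_intensity must be a positive scalar")
  }
  if (any(beta < 0 | beta >= 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1)")
  }
  bmax <- total_intensity / (total_intensity + 100)
  if (any(beta > bmax, na.rm = TRUE)) {
    warning("some beta values exceed total_intensity/(total_intensity+100); clamped")
    beta <- pmin(beta, bmax)
  }
  M <- beta * (total_intensity + 100)
  U <- total_intensity - M
  list(M = M, U = U)
}

#' Summarize LINE-1 pyrosequencing records per sample
#'
#' Each pyrosequencing record carries percent methylation at four CpG
#' dinucleotides of the LINE-1 consensus; reactions are typically run in
#' triplicate.  The per-sample summary is the mean over the four CpGs within
#' each replicate, then the mean over replicates (unweighted, so the result
#' does not depend on replicate order).
#'
#' @param records data.frame with columns \code{sample}, \code{replicate}, and
#'   four CpG columns \code{cpg1..cpg4} holding percent methylation in [0, 100].
#' @return data.frame with columns \code{sample} and \code{line1} (mean percent
#'   methylation), one row per sample.
#' @export
line1_summary <- function(records) {
  cpg_cols <- paste0("cpg", 1:4)
  need <- c("sample", "replicate", cpg_cols)
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  vals <- as.matrix(records[, cpg_cols])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("CpG percent-methylation values must be finite numerics")
  }
  if (any(vals < 0 | vals > 100)) {
    stop("percent methylation must lie in [0, 100]")
  }
  rep_mean <- rowMeans(vals)
  agg <- tapply(rep_mean, as.character(records$sample), mean)
  data.frame(sample = names(agg), line1 = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}
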