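#' Kruskal-Wallis H statistic with midrank ties correction
#'
#' Rank-based between-group statistic
#' \deqn{H = \frac{12}{n(n+1)} \sum_g n_g (\bar r_g - \bar r)^2 / C}
#' where ranks are midranks and C is the usual ties correction
#' \eqn{1 - \sum (t^3 - t) / (n^3 - n)}.  Matches
#' \code{stats::kruskal.test}'s statistic; implemented directly so the
#' permutation test can evaluate it on precomputed ranks.
#'
#' @param values numeric vector (e.g. per-tumor copy-number burden).
#' @param groups group labels, any type coercible to factor; at least 2
#'   non-empty groups.
#' @return the H statistic (scalar).
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (length(values) != length(g)) stop("length mismatch")
  r <- rank(values)
  n <- length(r)
  kw_from_ranks(r, g, n)
}

# H from precomputed midranks (hot path of the permutation test).
kw_from_ranks <- function(r, g, n) {
  sums <- tapply(r, g, sum)
  sizes <- tabulate(g)
  H <- 12 / (n * (n + 1)) * sum(sums^2 / sizes) - 3 * (n + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C == 0) return(0)  # all values identical
  H / C
}

#' Permutation Kruskal-Wallis test of burden against methylation class
#'
#' Tests whether genome-wide copy-number burden (mean |CNS - 2|) differs by
#' methylation class by permuting class labels over tumors and recomputing the
#' Kruskal-Wallis H statistic.  The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{H_{perm} \ge H_{obs}\}) / (n_{perm} + 1)}, which never
#' returns 0 and has floor 1/(n_perm + 1).
#'
#' @param burden per-tumor burden vector.
#' @param classes class labels (same length/order as \code{burden}).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer RNG seed.
#' @return list of class \code{"methcna_global_test"}: \code{H}, \code{p},
#'   \code{n_perm}, \code{class_summary} (per-class n / median / mean burden).
#' @export
permutation_test_global <- function(burden, classes, n_perm = 10000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  g <- factor(classes)
  if (nlevels(g) < 2) stop("need at least 2 classes")
  n <- length(burden)
  stopifnot(length(g) == n)
  r <- rank(burden)
  H_obs <- kw_from_ranks(r, g, n)
  sizes <- tabulate(g)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  set.seed(stage_seed(seed, "global_perm"))
  # permuting labels is equivalent to permuting ranks; vectorized over
  # permutations via rank-sum matrix algebra
  G <- stats::model.matrix(~ g - 1)
  R_perm <- vapply(seq_len(n_perm), function(b) r[sample.int(n)], numeric(n))
  S <- crossprod(R_perm, G)                       # n_perm x K rank sums
  H_perm <- 12 / (n * (n + 1)) * as.numeric(S^2 %*% (1 / sizes)) - 3 * (n + 1)
  H_perm <- if (C > 0) H_perm / C else rep(0, n_perm)
  p <- (1 + sum(H_perm >= H_obs)) / (n_perm + 1)
  summ <- data.frame(
    class = levels(g), n = as.integer(sizes),
    median_burden = as.numeric(tapply(burden, g, stats::median)),
    mean_burden = as.numeric(tapply(burden, g, mean)),
    stringsAsFactors = FALSE)
  structure(list(H = H_obs, p = p, n_perm = as.integer(n_perm),
                 class_summary = summ),
            class = "methcna_global_test")
}

#' @export
print.methcna_global_test <- function(x, ...) {
  cat(sprintf("Permutation Kruskal-Wallis test: H = %.4f, p = %.4g (%d permutations)\n",
              x$H, x$p, x$n_perm))
  print(x$class_summary, row.names = FALSE)
  invisible(x)
}

#' Clinical covariate tests against high/low CNA grouping
#'
#' Association of the high/low copy-number-alteration grouping with clinical
#' covariates: Fisher's exact test for dichotomous stage (I/II vs III/IV) and
#' HPV16 status, Monte-Carlo Fisher (simulated p) for anatomic site (> 2
#' levels), and the Wilcoxon rank-sum test for age as a continuous variable.
#'
#' @param high_low factor/character of per-tumor "high"/"low" labels.
#' @param metadata data.frame with columns among \code{stage} (I-IV or
#'   already dichotomized), \code{site}, \code{hpv16}, \code{age}; rows in the
#'   same order as \code{high_low}.
#' @param n_mc Monte-Carlo replicates for the site test (default 1e5).
#' @param seed integer seed for the Monte-Carlo test.
#' @return data.frame with columns \code{covariate}, \code{test}, \code{p},
#'   \code{skipped}.
#' @export
covariate_tests <- function(high_low, metadata, n_mc = 100000, seed = 1) {
  hl <- factor(high_low)
  res <- list()
  add <- function(covariate, test, p, skipped = FALSE) {
    res[[length(res) + 1]] <<- data.frame(covariate = covariate, test = test,
                                          p = p, skipped = skipped,
                                          stringsAsFactors = FALSE)
  }
  two_level <- function(x, nm) {
    x <- factor(x)
    if (nlevels(x) < 2 || nlevels(droplevels(hl[!is.na(x)])) < 2) {
      add(nm, "fisher_exact", NA_real_, TRUE)
    } else {
      add(nm, "fisher_exact", stats::fisher.test(table(x, hl))$p.value)
    }
  }
  if ("stage" %in% names(metadata)) {
    st <- metadata$stage
    if (!all(st %in% c("I/II", "III/IV", NA))) {
      st <- ifelse(st %in% c("I", "II", 1, 2), "I/II", "III/IV")
    }
    two_level(st, "stage")
  }
  if ("hpv16" %in% names(metadata)) two_level(metadata$hpv16, "hpv16")
  if ("site" %in% names(metadata)) {
    site <- factor(metadata$site)
    if (nlevels(site) < 2) {
      add("site", "fisher_mc", NA_real_, TRUE)
    } else {
      set.seed(stage_seed(seed, "site_mc"))
      p <- stats::fisher.test(table(site, hl), simulate.p.value = TRUE,
                              B = n_mc)$p.value
      add("site", "fisher_mc", p)
    }
  }
  if ("age" %in% names(metadata)) {
    ok <- !is.na(metadata$age)
    if (nlevels(droplevels(hl[ok])) < 2) {
      add("age", "wilcoxon", NA_real_, TRUE)
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(metadata$age[ok] ~ droplevels(hl[ok]))$p.value)
      add("age", "wilcoxon", p)
    }
  }
  do.call(rbind, res)
}
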