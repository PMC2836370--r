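#' @keywords internal
clamp_beta <- function(X, eps = 1e-6) pmin(pmax(X, eps), 1 - eps)

# Parameter bounds for beta shape parameters: divergence guard.
.ab_lo <- 1e-4
.ab_hi <- 1e4

# Weighted beta MLE for all CpGs of one component at once, by Newton iteration
# on (a, b) with step halving, starting from (a0, b0).  Suff stats per CpG j:
#   Sw  — total responsibility-weighted sample weight (scalar, shared)
#   T1j — sum_i r_i w_i log x_ij ;  T2j — sum_i r_i w_i log(1 - x_ij)
# Objective: Sw*(lgamma(a+b)-lgamma(a)-lgamma(b)) + (a-1)*T1 + (b-1)*T2.
# Guaranteed non-decreasing in the objective, so the surrounding EM is monotone.
beta_mle_newton <- function(Sw, T1, T2, a0, b0, max_iter = 30, tol = 1e-8) {
  a <- pmin(pmax(a0, .ab_lo), .ab_hi)
  b <- pmin(pmax(b0, .ab_lo), .ab_hi)
  obj <- function(a, b, idx) {
    Sw * (lgamma(a + b) - lgamma(a) - lgamma(b)) +
      (a - 1) * T1[idx] + (b - 1) * T2[idx]
  }
  f <- obj(a, b, seq_along(a))
  for (it in seq_len(max_iter)) {
    dg_ab <- digamma(a + b)
    ga <- Sw * (dg_ab - digamma(a)) + T1
    gb <- Sw * (dg_ab - digamma(b)) + T2
    tg_ab <- trigamma(a + b)
    haa <- Sw * (tg_ab - trigamma(a))
    hbb <- Sw * (tg_ab - trigamma(b))
    hab <- Sw * tg_ab
    det <- haa * hbb - hab * hab
    # Newton direction for a maximum: -H^{-1} g
    da <- -(hbb * ga - hab * gb) / det
    db <- -(haa * gb - hab * ga) / det
    bad <- !is.finite(da) | !is.finite(db) | det <= 0 | haa >= 0
    da[bad] <- ga[bad] / pmax(Sw, 1e-12)  # gradient fallback
    db[bad] <- gb[bad] / pmax(Sw, 1e-12)
    step <- rep(1, length(a))
    an <- a; bn <- b; fn <- f
    active <- rep(TRUE, length(a))
    for (h in 1:25) {
      if (!any(active)) break
      idx <- which(active)
      an[idx] <- pmin(pmax(a[idx] + step[idx] * da[idx], .ab_lo), .ab_hi)
      bn[idx] <- pmin(pmax(b[idx] + step[idx] * db[idx], .ab_lo), .ab_hi)
      fn[idx] <- obj(an[idx], bn[idx], idx)
      worse <- active & (fn < f - 1e-12 | !is.finite(fn))
      an[worse] <- a[worse]; bn[worse] <- b[worse]; fn[worse] <- f[worse]
      step[worse] <- step[worse] / 2
      active <- worse
    }
    moved <- abs(fn - f)
    a <- an; b <- bn; f <- fn
    if (max(moved) < tol) break
  }
  list(a = a, b = b, obj = f)
}

# Weighted method-of-moments beta estimates (initialization only).
beta_mom <- function(X, w) {
  W <- sum(w)
  mu <- as.numeric(crossprod(w, X)) / W
  v <- as.numeric(crossprod(w, X^2)) / W - mu^2
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  v <- pmax(v, 1e-6)
  phi <- pmax(mu * (1 - mu) / v - 1, 0.1)
  list(a = pmin(pmax(mu * phi, .ab_lo), .ab_hi),
       b = pmin(pmax((1 - mu) * phi, .ab_lo), .ab_hi))
}

# Per-sample log beta density under component parameters (a, b): vectorized
# over CpGs via precomputed log(X) and log(1-X).
comp_logdens <- function(LX, L1X, a, b) {
  as.numeric(LX %*% (a - 1) + L1X %*% (b - 1)) +
    sum(lgamma(a + b) - lgamma(a) - lgamma(b))
}

#' Fit a weighted mixture of beta distributions to methylation profiles
#'
#' Each mixture component models CpGs as independent beta distributions; the
#' model is fit by weighted EM.  The M-step maximizes the weighted beta
#' log-likelihood per CpG by Newton iteration with step halving (initialized
#' by weighted method of moments), which keeps the observed-data
#' log-likelihood non-decreasing across EM iterations.  Restarts use
#' deterministic random-projection splits derived from the seed, so the fit
#' is invariant to sample order.
#'
#' @param X samples-by-CpGs beta matrix; values are clamped to
#'   [1e-6, 1 - 1e-6] before fitting.
#' @param weights per-sample non-negative weights (the RPMM recursion passes
#'   soft membership weights here).
#' @param K number of components (1 or 2).
#' @param seed integer controlling the restart projections.
#' @param n_init number of restarts for K = 2 (best log-likelihood kept).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param min_node_weight minimum effective (weighted) samples required.
#' @return list with \code{a}, \code{b} (K x J shape matrices), \code{mix}
#'   (component weights), \code{resp} (n x K responsibilities), \code{loglik},
#'   \code{loglik_trace}, or \code{NULL} when the node is degenerate.
#' @export
fit_beta_mixture <- function(X, weights = rep(1, nrow(X)), K = 2, seed = 1,
                             n_init = 5, tol = 1e-6, max_iter = 200,
                             min_node_weight = 2) {
  X <- clamp_beta(as.matrix(X))
  n <- nrow(X); J <- ncol(X)
  w <- as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0))
  W <- sum(w)
  if (W < min_node_weight || sum(w > 1e-8) < 2) return(NULL)
  LX <- log(X); L1X <- log1p(-X)

  run_em <- function(resp) {
    a <- matrix(0, K, J); b <- matrix(0, K, J)
    mix <- rep(1 / K, K)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    first <- TRUE
    for (iter in seq_len(max_iter)) {
      # M-step
      for (k in seq_len(K)) {
        rw <- resp[, k] * w
        Sw <- sum(rw)
        if (Sw < 1e-10) return(NULL)
        T1 <- as.numeric(crossprod(rw, LX))
        T2 <- as.numeric(crossprod(rw, L1X))
        init <- if (first) beta_mom(X, rw) else list(a = a[k, ], b = b[k, ])
        fit <- beta_mle_newton(Sw, T1, T2, init$a, init$b)
        a[k, ] <- fit$a; b[k, ] <- fit$b
        mix[k] <- Sw / W
      }
      first <- FALSE
      # E-step
      ld <- vapply(seq_len(K), function(k) comp_logdens(LX, L1X, a[k, ], b[k, ]),
                   numeric(n))
      ld <- matrix(ld, nrow = n)
      lw <- sweep(ld, 2, log(mix), "+")
      mx <- apply(lw, 1, max)
      lse <- mx + log(rowSums(exp(lw - mx)))
      resp <- exp(lw - lse)
      ll <- sum(w * lse)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(a = a, b = b, mix = mix, resp = resp, loglik = ll,
         loglik_trace = ll_trace)
  }

  if (K == 1) {
    return(run_em(matrix(1, n, 1)))
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    # order-invariant init: split on a deterministic random projection of the
    # CpG profiles (restart 1 uses the mean-methylation direction)
    v <- if (r == 1) rep(1, J) else sin(seq_len(J) * ((seed %% 977) + r * 13 + 0.5))
    s <- as.numeric(X %*% v)
    med <- stats::median(s[w > 1e-8])
    resp <- cbind(ifelse(s <= med, 0.9, 0.1), ifelse(s <= med, 0.1, 0.9))
    fit <- run_em(resp)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) return(NULL)
  # canonical component order: lower overall mean methylation first ("left")
  m1 <- sum(best$a[1, ] / (best$a[1, ] + best$b[1, ]))
  m2 <- sum(best$a[2, ] / (best$a[2, ] + best$b[2, ]))
  if (m2 < m1) {
    best$a <- best$a[2:1, , drop = FALSE]
    best$b <- best$b[2:1, , drop = FALSE]
    best$mix <- best$mix[2:1]
    best$resp <- best$resp[, 2:1, drop = FALSE]
  }
  best
}

#' Recursively partitioned beta-mixture clustering (RPMM)
#'
#' Builds a binary tree of 2-component beta-mixture splits over methylation
#' profiles.  At each node a 1-component and a 2-component weighted mixture
#' are fit; the split is accepted iff the 2-component BIC is lower and both
#' children retain at least \code{min_node_weight} effective samples.  Leaves
#' are methylation classes, numbered left to right from 1; the left child of
#' any split is the component with lower mean methylation.
#'
#' BIC counts 2 parameters per CpG per component plus K - 1 mixing weights,
#' with the total sample weight as the effective n.
#'
#' @param X samples-by-CpGs beta matrix.
#' @param max_depth maximum number of split levels (depth 1 = root split only).
#' @param min_node_weight minimum effective weight per child node.
#' @param seed integer; each node derives its own stream from the seed and its
#'   tree path, so results do not depend on sample order.
#' @param n_init EM restarts per node.
#' @param tol EM tolerance.
#' @return object of class \code{"rpmm_classing"}: list with \code{tree}
#'   (nested node list), \code{leaf_class} (integer class per sample),
#'   \code{root_side} (factor "left"/"right"), \code{n_leaves},
#'   \code{sample_ids}.
#' @export
rpmm_fit <- function(X, max_depth = 3, min_node_weight = 2, seed = 1,
                     n_init = 5, tol = 1e-6) {
  X <- clamp_beta(as.matrix(X))
  n <- nrow(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))

  build <- function(wts, depth, path) {
    node <- list(path = path, weight = sum(wts), split = FALSE)
    fit1 <- fit_beta_mixture(X, wts, K = 1, tol = tol,
                             min_node_weight = min_node_weight)
    node$fit1 <- fit1[c("a", "b", "loglik")]
    if (is.null(fit1)) return(node)
    if (depth >= max_depth || sum(wts > 1e-8) < 4) return(node)
    fit2 <- fit_beta_mixture(X, wts, K = 2,
                             seed = stage_seed(seed, paste0("rpmm", path)),
                             n_init = n_init, tol = tol,
                             min_node_weight = min_node_weight)
    if (is.null(fit2)) return(node)
    J <- ncol(X); W <- sum(wts)
    bic1 <- -2 * fit1$loglik + (2 * J) * log(W)
    bic2 <- -2 * fit2$loglik + (4 * J + 1) * log(W)
    wl <- wts * fit2$resp[, 1]
    wr <- wts * fit2$resp[, 2]
    if (bic2 < bic1 && sum(wl) >= min_node_weight && sum(wr) >= min_node_weight) {
      node$split <- TRUE
      node$bic1 <- bic1; node$bic2 <- bic2
      node$resp <- fit2$resp
      node$mix <- fit2$mix
      node$children <- list(left = build(wl, depth + 1, paste0(path, "L")),
                            right = build(wr, depth + 1, paste0(path, "R")))
    }
    node
  }

  root <- build(rep(1, n), 0, "r")

  # leaf numbering (left first) and hard sample assignment by cumulative
  # soft weight, ties toward the left
  leaf_counter <- 0L
  leaf_weights <- list()
  walk <- function(node, wts) {
    if (!node$split) {
      leaf_counter <<- leaf_counter + 1L
      leaf_weights[[leaf_counter]] <<- wts
      return(leaf_counter)
    }
    list(walk(node$children$left, wts * node$resp[, 1]),
         walk(node$children$right, wts * node$resp[, 2]))
  }
  walk(root, rep(1, n))
  LW <- do.call(cbind, leaf_weights)
  leaf_class <- apply(LW, 1, which.max)  # which.max takes first (leftmost) on ties

  if (root$split) {
    root_side <- ifelse(root$resp[, 1] >= root$resp[, 2], "left", "right")
  } else {
    warning("root split not accepted; all samples assigned to 'left'")
    root_side <- rep("left", n)
  }
  structure(list(tree = root, leaf_class = stats::setNames(as.integer(leaf_class), ids),
                 root_side = stats::setNames(factor(root_side, levels = c("left", "right")), ids),
                 n_leaves = leaf_counter, sample_ids = ids),
            class = "rpmm_classing")
}

#' Left/right grouping from the RPMM root split
#'
#' The two sample groups defined by the first (root) split of the RPMM tree:
#' each sample goes to the root child with the larger soft weight; exact ties
#' go left.  If the root split was not accepted, all samples are "left".
#'
#' @param classing an [rpmm_fit()] result.
#' @return named factor with levels "left" and "right".
#' @export
root_grouping <- function(classing) {
  stopifnot(inherits(classing, "rpmm_classing"))
  classing$root_side
}

#' @export
print.rpmm_classing <- function(x, ...) {
  cat("RPMM classing:", length(x$sample_ids), "samples,",
      x$n_leaves, "classes\n")
  print(table(class = x$leaf_class, side = x$root_side))
  invisible(x)
}
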