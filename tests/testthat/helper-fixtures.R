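# shared fixture builders (everything generated in code; no data files)

# reduced-scale cohort configuration for simulation-heavy tests
small_sim_config <- function(seed, kappa = 1, ...) {
  simulation_config(n_cpg = 60, n_genes = 30, n_snp = 500, n_chrom = 4,
                    kappa = kappa, seed = seed, ...)
}

# planted multi-class beta matrix with block-structured class means:
# every class pair differs by `gap` at 2/K of the informative CpGs
make_class_beta <- function(n, J, K, informative_frac = 0.4, gap = 0.6,
                            precision = 30, seed = 1) {
  set.seed(seed)
  lab <- rep_len(seq_len(K), n)
  n_inf <- round(informative_frac * J)
  block <- rep_len(seq_len(K), n_inf)
  lo <- (1 - gap) / 2; hi <- (1 + gap) / 2
  base <- stats::runif(J, 0.1, 0.9)
  X <- matrix(NA_real_, n, J)
  for (i in seq_len(n)) {
    mu <- base
    mu[seq_len(n_inf)] <- ifelse(block == lab[i], hi, lo)
    X[i, ] <- stats::rbeta(J, mu * precision, (1 - mu) * precision)
  }
  rownames(X) <- sprintf("S%02d", seq_len(n))
  list(X = X, labels = lab)
}

# brute-force Viterbi by exhaustive path enumeration (oracle; <= 10 loci)
viterbi_brute <- function(log_ratios, model) {
  n <- length(log_ratios)
  S <- length(model$states)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  em <- sapply(seq_len(S), function(s) {
    dnorm(log_ratios, model$means[s], model$sd, log = TRUE)
  })
  em <- matrix(em, nrow = n)
  logA <- log(model$transition)
  score <- apply(paths, 1, function(pth) {
    lp <- log(model$initial[pth[1]]) + em[1, pth[1]]
    if (n > 1) for (t in 2:n) {
      lp <- lp + logA[pth[t - 1], pth[t]] + em[t, pth[t]]
    }
    lp
  })
  model$states[paths[which.max(score), ]]
}

# path log-probability under the HMM (for the random-path dominance check)
path_logprob <- function(states, log_ratios, model) {
  idx <- match(states, model$states)
  lp <- log(model$initial[idx[1]]) +
    dnorm(log_ratios[1], model$means[idx[1]], model$sd, log = TRUE)
  if (length(states) > 1) for (t in 2:length(states)) {
    lp <- lp + log(model$transition[idx[t - 1], idx[t]]) +
      dnorm(log_ratios[t], model$means[idx[t]], model$sd, log = TRUE)
  }
  lp
}

# minimal rpmm_classing stand-in for stratification tests
fake_classing <- function(samples, side) {
  structure(list(tree = NULL,
                 leaf_class = stats::setNames(as.integer(factor(side)), samples),
                 root_side = stats::setNames(factor(side, levels = c("left", "right")),
                                             samples),
                 n_leaves = 2L, sample_ids = samples),
            class = "rpmm_classing")
}
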