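#' Construct a 5-state Gaussian copy-number HMM
#'
#' States are integer copy numbers 0..4.  Emission at state s is Gaussian with
#' mean log2(max(s, 0.5)/2) — the 0.5 floor avoids log2(0) for homozygous
#' deletions — and a shared standard deviation.  The transition matrix puts
#' \code{stay_prob} on the diagonal and splits the remainder uniformly over
#' the other four states.
#'
#' @param emission_sd shared emission standard deviation (> 0).
#' @param stay_prob self-transition probability, in (0, 1).
#' @param initial initial state distribution (length 5, sums to 1).
#' @return list of class \code{"cn_hmm_model"} with components \code{states},
#'   \code{means}, \code{sd}, \code{transition}, \code{initial}.
#' @export
cn_hmm_model <- function(emission_sd = 0.2, stay_prob = 0.98,
                         initial = c(0.02, 0.05, 0.86, 0.05, 0.02)) {
  if (emission_sd <= 0) stop("emission_sd must be positive")
  if (!(stay_prob > 0 && stay_prob < 1)) stop("stay_prob must be in (0,1)")
  if (length(initial) != 5L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8) {
    stop("initial must be a length-5 distribution")
  }
  states <- 0:4
  means <- log2(pmax(states, 0.5) / 2)
  trans <- matrix((1 - stay_prob) / 4, 5, 5)
  diag(trans) <- stay_prob
  structure(list(states = states, means = means, sd = emission_sd,
                 transition = trans, initial = initial),
            class = "cn_hmm_model")
}

# Preference order for tie-breaking: state closest to 2, then lower state.
state_preference <- function(states) order(abs(states - 2), states)

#' Viterbi decoding of copy-number states for one chromosome
#'
#' Returns the maximum-a-posteriori integer state path for a vector of log2
#' tumor/normal ratios.  Ties in path score are broken toward the state closer
#' to diploid (|s - 2| smaller), then toward the lower state.
#'
#' @param log_ratios numeric vector of log2 ratios along one chromosome.
#' @param model a [cn_hmm_model()].
#' @return integer vector of states in 0..4, same length as \code{log_ratios}.
#' @export
viterbi_states <- function(log_ratios, model = cn_hmm_model()) {
  if (!inherits(model, "cn_hmm_model")) stop("model must be a cn_hmm_model")
  n <- length(log_ratios)
  if (n == 0L) stop("empty chromosome")
  if (any(!is.finite(log_ratios))) stop("non-finite log ratio")
  S <- length(model$states)
  pref <- state_preference(model$states)  # indices in preference order
  logA <- log(model$transition)
  # emission log-densities: n x S
  em <- vapply(seq_len(S), function(s) {
    stats::dnorm(log_ratios, mean = model$means[s], sd = model$sd, log = TRUE)
  }, numeric(n))
  em <- matrix(em, nrow = n)
  delta <- matrix(-Inf, n, S)
  psi <- matrix(0L, n, S)
  delta[1, ] <- log(model$initial) + em[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (s in seq_len(S)) {
        cand <- delta[t - 1, ] + logA[, s]
        # argmax with preference-order tie-breaking
        best <- pref[which.max(cand[pref])]
        psi[t, s] <- best
        delta[t, s] <- cand[best] + em[t, s]
      }
    }
  }
  path <- integer(n)
  path[n] <- pref[which.max(delta[n, pref])]
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  model$states[path]
}

#' Call copy-number states for a tumors-by-loci log-ratio matrix
#'
#' Chromosomes are decoded independently per tumor with [viterbi_states()].
#'
#' @param log_ratios numeric matrix, tumors in rows, loci in columns (column
#'   order must follow genomic order within chromosome).
#' @param chrom character/integer vector assigning each column to a chromosome.
#' @param model a [cn_hmm_model()].
#' @param median_center if TRUE, subtract each tumor's median log ratio first
#'   (off by default).
#' @return integer copy-number-state matrix with the same dimnames.
#' @export
call_cn_states <- function(log_ratios, chrom, model = cn_hmm_model(),
                           median_center = FALSE) {
  stopifnot(is.matrix(log_ratios), length(chrom) == ncol(log_ratios))
  out <- matrix(NA_integer_, nrow(log_ratios), ncol(log_ratios),
                dimnames = dimnames(log_ratios))
  chr_idx <- split(seq_len(ncol(log_ratios)), chrom)
  for (i in seq_len(nrow(log_ratios))) {
    x <- log_ratios[i, ]
    if (median_center) x <- x - stats::median(x, na.rm = TRUE)
    for (idx in chr_idx) {
      out[i, idx] <- viterbi_states(x[idx], model)
    }
  }
  out
}

#' Per-tumor copy-number burden
#'
#' The burden of a tumor is the mean of |CNS - 2| over its loci, where CNS is
#' the integer copy-number state: 0 for a fully diploid genome, up to 2 for
#' states restricted to 0..4.  Missing loci are excluded pairwise.
#'
#' @param states integer copy-number-state matrix, tumors in rows.
#' @return named numeric vector of burdens, one per tumor.
#' @export
cn_burden <- function(states) {
  stopifnot(is.matrix(states))
  v <- states[!is.na(states)]
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("states must be non-negative integers")
  }
  b <- rowMeans(abs(states - 2), na.rm = TRUE)
  if (any(is.nan(b))) stop("tumor with all states missing")
  b
}
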