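#' Read a samples-by-loci (or loci-by-samples) numeric matrix from TSV
#'
#' The on-disk layout is: first column = row identifiers, header = column
#' identifiers, numeric body, missing cells written as \code{NA}.  The
#' \code{kind} argument selects validation: \code{beta} entries must lie in
#' [0, 1]; \code{cn_state} entries must be non-negative integers;
#' \code{log_ratio} and \code{signal_pair} are unconstrained reals.
#'
#' @param path path to a tab-separated file.
#' @param kind one of \code{"beta"}, \code{"cn_state"}, \code{"log_ratio"},
#'   \code{"signal_pair"}.
#' @return numeric matrix with dimnames taken from the file.
#' @export
read_matrix <- function(path, kind = c("beta", "cn_state", "log_ratio", "signal_pair")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicated column identifiers in ", path)
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v) && !is.logical(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v) & v != "NA")
      stop("non-numeric cell at row '", ids[bad[1]], "', column '",
           names(body)[j], "' in ", path)
    }
  }
  m <- as.matrix(body)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_matrix(m, kind)
  m
}

validate_matrix <- function(m, kind) {
  if (kind == "beta" && any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("beta values outside [0, 1]")
  }
  if (kind == "cn_state") {
    v <- m[!is.na(m)]
    if (any(v < 0) || any(v != round(v))) {
      stop("copy-number states must be non-negative integers")
    }
  }
  invisible(m)
}

#' Write a numeric matrix as TSV (inverse of [read_matrix])
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_name header label for the identifier column.
#' @export
write_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like locus annotation table
#'
#' Columns: \code{chrom}, \code{start} (0-based coordinate), \code{locus}
#' (locus id), \code{gene} (may be empty), and optionally
#' \code{upstream_of_tss} (0/1 flag, CpG annotations only).  Loci are returned
#' sorted by coordinate within chromosome; duplicate coordinates are allowed.
#'
#' @param path path to a tab-separated annotation file with a header row.
#' @return data.frame sorted by (chrom, start).
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA"))
  need <- c("chrom", "start", "locus")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns chrom, start, locus")
  }
  if (!is.numeric(df$start) || any(!is.finite(df$start))) {
    stop("start coordinates must be numeric")
  }
  if (any(df$start < 0)) stop("negative coordinate in annotation")
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  df$gene <- as.character(df$gene)
  df$gene[!is.na(df$gene) & df$gene == ""] <- NA_character_
  if ("upstream_of_tss" %in% names(df)) {
    if (!all(df$upstream_of_tss %in% c(0, 1, NA))) {
      stop("upstream_of_tss flag must be 0/1")
    }
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a locus annotation table (inverse of [read_annotation])
#' @param annot annotation data.frame.
#' @param path output path.
#' @export
write_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a validated analysis configuration
#'
#' Collects the paths and tuning parameters for [run_pipeline()].  Defaults
#' follow the analysis conventions: 5,000 permutations for the local
#' correlation screen, 10,000 for the global burden test, significance at
#' q < 0.05.
#'
#' @param paths named list of input paths (see [run_pipeline()]); may be empty
#'   when matrices are passed in memory.
#' @param seed integer RNG seed; every stochastic stage derives its own stream
#'   from it, so reruns are byte-identical.
#' @param n_perm_local permutations for the correlation screen (>= 1).
#' @param n_perm_global permutations for the global Kruskal-Wallis test (>= 1).
#' @param q_threshold significance threshold on the q-value, in (0, 1).
#' @param match_max_distance maximum CpG-SNP matching distance in bp
#'   (\code{Inf} = unlimited).
#' @param hmm_emission_sd,hmm_stay_prob Gaussian HMM emission sd and
#'   self-transition probability.
#' @param rpmm_max_depth,rpmm_min_node_weight,rpmm_tol RPMM recursion depth cap,
#'   minimum effective node weight, and EM convergence tolerance.
#' @return object of class \code{"methcna_config"} (a validated list).
#' @export
analysis_config <- function(paths = list(), seed = 1L,
                            n_perm_local = 5000L, n_perm_global = 10000L,
                            q_threshold = 0.05, match_max_distance = Inf,
                            hmm_emission_sd = 0.2, hmm_stay_prob = 0.98,
                            rpmm_max_depth = 3L, rpmm_min_node_weight = 2,
                            rpmm_tol = 1e-6) {
  stopifnot(is.list(paths))
  if (n_perm_local < 1 || n_perm_global < 1) {
    stop("permutation counts must be >= 1")
  }
  if (!(q_threshold > 0 && q_threshold < 1)) stop("q_threshold must be in (0,1)")
  if (hmm_emission_sd <= 0) stop("hmm_emission_sd must be positive")
  if (!(hmm_stay_prob > 0 && hmm_stay_prob < 1)) stop("hmm_stay_prob must be in (0,1)")
  if (rpmm_max_depth < 1 || rpmm_min_node_weight <= 0) {
    stop("invalid rpmm parameters")
  }
  cfg <- list(paths = paths, seed = as.integer(seed),
              n_perm_local = as.integer(n_perm_local),
              n_perm_global = as.integer(n_perm_global),
              q_threshold = q_threshold,
              match_max_distance = match_max_distance,
              hmm_emission_sd = hmm_emission_sd, hmm_stay_prob = hmm_stay_prob,
              rpmm_max_depth = as.integer(rpmm_max_depth),
              rpmm_min_node_weight = rpmm_min_node_weight,
              rpmm_tol = rpmm_tol)
  class(cfg) <- "methcna_config"
  cfg
}

#' Read an analysis configuration from YAML or JSON
#' @param path path to a .yaml/.yml or .json file whose keys match the
#'   arguments of [analysis_config()].
#' @return a \code{methcna_config} object.
#' @export
read_analysis_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be YAML or JSON")
  args <- lst[names(lst) %in% names(formals(analysis_config))]
  do.call(analysis_config, args)
}

# Derive a reproducible child seed for a named stage from the master seed.
# Keeps results stable under stage-level reruns and below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 97L + h) %% 2147483629)
}
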