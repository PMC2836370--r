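#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design the analysis is built for: 19 tumors and
#' 11 normal tissues, a GoldenGate-scale methylation panel (1,500 CpGs in the
#' promoter regions of 800 genes), a SNP copy-number array generated at
#' reduced scale (5,000 loci over 22 autosomes), K = 5 latent methylation
#' classes, and a two-tier burden coupling in which two classes carry high
#' genome-wide copy-number burden (0.5) and the rest stay near-diploid
#' (0.05).  \code{kappa} scales the class-to-burden coupling: 0 gives the
#' null (burden identically distributed across classes), 1 the full planted
#' effect.
#'
#' @param n_tumors,n_normals,n_cpg,n_genes,n_snp,n_chrom cohort dimensions.
#' @param K number of latent methylation classes.
#' @param informative_frac fraction of CpGs whose beta law depends on class.
#' @param kappa global methylation-class/burden coupling in [0, 1].
#' @param burden_high,burden_low target mean |CNS - 2| for the two tiers.
#' @param high_burden_classes classes assigned the high tier.
#' @param precision beta-distribution precision (a + b) at each CpG.
#' @param class_mean_low,class_mean_high the two class-informative beta means.
#' @param segment_mean_len mean copy-number segment length in loci
#'   (geometric).
#' @param altered_states,altered_state_probs states and probabilities for
#'   altered segments.
#' @param log_ratio_sd Gaussian noise sd on log2(state/2) (state 0 floored at
#'   0.5 inside the log).
#' @param n_line1 tumors with LINE-1 measurements.
#' @param line1_mean_high,line1_mean_low,line1_sd LINE-1 percent-methylation
#'   group means (high/low CNA) and between-sample sd.
#' @param seed integer RNG seed.
#' @return list of class \code{"methcna_sim_config"}.
#' @export
simulation_config <- function(n_tumors = 19, n_normals = 11, n_cpg = 1500,
                              n_genes = 800, n_snp = 5000, n_chrom = 22,
                              K = 5, informative_frac = 0.5, kappa = 1,
                              burden_high = 0.5, burden_low = 0.05,
                              high_burden_classes = c(1, 3),
                              precision = 40,
                              class_mean_low = 0.2, class_mean_high = 0.8,
                              segment_mean_len = 50,
                              altered_states = c(0, 1, 3, 4),
                              altered_state_probs = c(0.15, 0.35, 0.35, 0.15),
                              log_ratio_sd = 0.2,
                              n_line1 = 11, line1_mean_high = 52,
                              line1_mean_low = 65.2, line1_sd = 8,
                              seed = 1) {
  if (n_cpg < n_genes) stop("n_cpg must be >= n_genes")
  if (!(kappa >= 0 && kappa <= 1)) stop("kappa must be in [0, 1]")
  if (K < 1 || n_tumors < K) stop("need n_tumors >= K >= 1")
  max_burden <- sum(altered_state_probs * abs(altered_states - 2))
  if (burden_high > max_burden || burden_low > max_burden) {
    stop("infeasible coupling: target burden exceeds maximum achievable (",
         round(max_burden, 3), ") with the altered-state distribution")
  }
  cfg <- as.list(environment())
  cfg$max_burden <- max_burden
  class(cfg) <- "methcna_sim_config"
  cfg
}

#' Simulate a methylation + copy-number cohort with ground truth
#'
#' Generates a full synthetic cohort: tumor beta values drawn from
#' class-specific beta distributions at class-informative CpGs (one shared
#' beta law elsewhere), normals from a distinct normal-epithelium law;
#' per-chromosome segmental integer copy-number states with geometric segment
#' lengths whose altered-segment rate matches each tumor's class-tier burden
#' target; a matching noisy log2-ratio matrix; BED-like CpG/SNP annotations
#' with gene assignment and promoter (upstream-of-TSS) flags; sample
#' metadata; LINE-1 pyrosequencing triplicates whose group mean depends on
#' the tumor's burden tier; and a \code{truth} record for recovery tests.
#'
#' @param cfg a [simulation_config()].
#' @return list of class \code{"methcna_cohort"} with elements \code{beta}
#'   (samples x CpGs, tumors then normals), \code{cn} (tumors x SNPs),
#'   \code{log_ratio}, \code{cpg_annot}, \code{snp_annot}, \code{metadata},
#'   \code{line1} (replicate records), \code{truth}, \code{cfg}.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "methcna_sim_config"))
  set.seed(stage_seed(cfg$seed, "simulate"))
  tumors <- sprintf("T%02d", seq_len(cfg$n_tumors))
  normals <- sprintf("N%02d", seq_len(cfg$n_normals))
  cpgs <- sprintf("cg%05d", seq_len(cfg$n_cpg))
  snps <- sprintf("rs%05d", seq_len(cfg$n_snp))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  ## --- annotations -------------------------------------------------------
  gene_chrom <- rep(seq_len(cfg$n_chrom), length.out = cfg$n_genes)
  gene_per_chrom <- tabulate(gene_chrom, cfg$n_chrom)
  gene_tss <- unlist(lapply(seq_len(cfg$n_chrom), function(c) {
    seq_len(gene_per_chrom[c]) * 50000
  }))
  ord <- order(gene_chrom)
  gene_tab <- data.frame(gene = genes, chrom = paste0("chr", gene_chrom[ord]),
                         tss = gene_tss, stringsAsFactors = FALSE)
  # CpGs: one per gene, remainder spread over random genes
  cpg_gene_idx <- c(seq_len(cfg$n_genes),
                    sample.int(cfg$n_genes, cfg$n_cpg - cfg$n_genes,
                               replace = TRUE))
  upstream <- stats::rbinom(cfg$n_cpg, 1, 0.8)
  offset <- round(stats::runif(cfg$n_cpg, 50, 2000))
  cpg_start <- ifelse(upstream == 1, gene_tab$tss[cpg_gene_idx] - offset,
                      gene_tab$tss[cpg_gene_idx] + offset)
  cpg_annot <- data.frame(chrom = gene_tab$chrom[cpg_gene_idx],
                          start = pmax(cpg_start, 0), locus = cpgs,
                          gene = gene_tab$gene[cpg_gene_idx],
                          upstream_of_tss = upstream,
                          stringsAsFactors = FALSE)
  # SNPs: uniform along each chromosome; assigned to a gene when inside its
  # 20 kb body downstream of the TSS
  snp_chrom <- sort(rep(seq_len(cfg$n_chrom), length.out = cfg$n_snp))
  chrom_len <- (gene_per_chrom + 1) * 50000
  snp_start <- round(stats::runif(cfg$n_snp, 1, chrom_len[snp_chrom]))
  snp_gene <- rep(NA_character_, cfg$n_snp)
  for (c in seq_len(cfg$n_chrom)) {
    gi <- which(gene_tab$chrom == paste0("chr", c))
    si <- which(snp_chrom == c)
    hit <- findInterval(snp_start[si], gene_tab$tss[gi])
    inside <- hit >= 1 & (snp_start[si] - gene_tab$tss[gi][pmax(hit, 1)]) <= 20000
    snp_gene[si[inside]] <- gene_tab$gene[gi][hit[inside]]
  }
  snp_annot <- data.frame(chrom = paste0("chr", snp_chrom), start = snp_start,
                          locus = snps, gene = snp_gene,
                          stringsAsFactors = FALSE)
  # genomic sort order within chromosome (the CN segments follow this order)
  snp_annot <- snp_annot[order(snp_chrom, snp_start), , drop = FALSE]
  rownames(snp_annot) <- NULL
  cpg_annot <- cpg_annot[order(readr_chrom_num(cpg_annot$chrom),
                               cpg_annot$start), , drop = FALSE]
  rownames(cpg_annot) <- NULL

  ## --- methylation classes and beta matrix -------------------------------
  class_label <- sample(rep_len(seq_len(cfg$K), cfg$n_tumors))
  n_inf <- round(cfg$informative_frac * cfg$n_cpg)
  informative <- sort(sample.int(cfg$n_cpg, n_inf))
  # class-specific means at informative CpGs: block design — class k is
  # hypermethylated at its own block of informative CpGs and hypomethylated at
  # the other classes' blocks, so every class pair differs (gap
  # class_mean_high - class_mean_low) at 2/K of the informative CpGs
  block <- rep_len(seq_len(cfg$K), n_inf)
  class_means <- matrix(cfg$class_mean_low, cfg$K, n_inf)
  for (k in seq_len(cfg$K)) class_means[k, block == k] <- cfg$class_mean_high
  base_mean <- stats::runif(cfg$n_cpg, 0.1, 0.9)   # shared tumor law
  normal_mean <- stats::runif(cfg$n_cpg, 0.1, 0.9) # distinct normal law
  phi <- cfg$precision
  beta <- matrix(NA_real_, cfg$n_tumors + cfg$n_normals, cfg$n_cpg,
                 dimnames = list(c(tumors, normals), cpgs))
  for (i in seq_len(cfg$n_tumors)) {
    mu <- base_mean
    mu[informative] <- class_means[class_label[i], ]
    beta[i, ] <- stats::rbeta(cfg$n_cpg, mu * phi, (1 - mu) * phi)
  }
  for (i in seq_len(cfg$n_normals)) {
    beta[cfg$n_tumors + i, ] <- stats::rbeta(cfg$n_cpg, normal_mean * phi,
                                             (1 - normal_mean) * phi)
  }

  ## --- copy-number states ------------------------------------------------
  tier_target <- ifelse(class_label %in% cfg$high_burden_classes,
                        cfg$burden_high, cfg$burden_low)
  burden_target <- cfg$burden_low + cfg$kappa * (tier_target - cfg$burden_low)
  p_alt <- burden_target / cfg$max_burden
  if (any(p_alt > 1)) stop("infeasible coupling: required alteration rate > 1")
  chr_of_col <- readr_chrom_num(snp_annot$chrom)
  cn <- matrix(2L, cfg$n_tumors, cfg$n_snp,
               dimnames = list(tumors, snp_annot$locus))
  # shared segmental architecture: one segment grid per chromosome (geometric
  # lengths), each segment carrying a recurrence weight (hotspot propensity)
  # and a preferred direction (gain or loss), emulating the recurrent
  # arm/focal events of tumor genomes; tumors then alter segments with a rate
  # proportional to the hotspot weight, scaled to their burden target
  grid <- list()
  for (c in seq_len(cfg$n_chrom)) {
    idx <- which(chr_of_col == c)
    L <- length(idx)
    if (L == 0) next
    pos <- 1L
    while (pos <= L) {
      len <- min(stats::rgeom(1, 1 / cfg$segment_mean_len) + 1L, L - pos + 1L)
      grid[[length(grid) + 1]] <-
        data.frame(chrom = c, from = pos, to = pos + len - 1L, len = len,
                   weight = stats::rbeta(1, 0.5, 1.5),
                   gain = stats::runif(1) < 0.5)
      pos <- pos + len
    }
  }
  grid <- do.call(rbind, grid)
  losses <- cfg$altered_states < 2
  p_loss <- cfg$altered_state_probs[losses] / sum(cfg$altered_state_probs[losses])
  p_gain <- cfg$altered_state_probs[!losses] / sum(cfg$altered_state_probs[!losses])
  segments <- vector("list", cfg$n_tumors)
  names(segments) <- tumors
  chr_idx <- split(seq_len(cfg$n_snp), chr_of_col)
  # per-tumor scaling solved so the expected altered-locus fraction equals the
  # tumor's target rate despite hotspot saturation at probability 1
  calib_scale <- function(target) {
    if (target <= 0) return(0)
    f <- function(s) sum(grid$len * pmin(1, s * grid$weight)) / sum(grid$len) - target
    stats::uniroot(f, c(0, 1e6))$root
  }
  for (i in seq_len(cfg$n_tumors)) {
    p_seg <- pmin(1, calib_scale(p_alt[i]) * grid$weight)
    altered <- stats::runif(nrow(grid)) < p_seg
    st <- rep(2L, nrow(grid))
    n_gain <- sum(altered & grid$gain)
    n_loss <- sum(altered & !grid$gain)
    if (n_gain > 0) {
      st[altered & grid$gain] <- as.integer(
        sample(cfg$altered_states[!losses], n_gain, TRUE, prob = p_gain))
    }
    if (n_loss > 0) {
      st[altered & !grid$gain] <- as.integer(
        sample(cfg$altered_states[losses], n_loss, TRUE, prob = p_loss))
    }
    for (s in which(st != 2L)) {
      cols <- chr_idx[[as.character(grid$chrom[s])]][grid$from[s]:grid$to[s]]
      cn[i, cols] <- st[s]
    }
    segments[[i]] <- data.frame(chrom = paste0("chr", grid$chrom),
                                from = grid$from, to = grid$to, state = st)
  }
  log_ratio <- log2(pmax(cn, 0.5) / 2) +
    matrix(stats::rnorm(length(cn), 0, cfg$log_ratio_sd), nrow(cn))
  dimnames(log_ratio) <- dimnames(cn)

  ## --- LINE-1 and metadata ------------------------------------------------
  n_l1 <- min(cfg$n_line1, cfg$n_tumors)
  l1_samples <- tumors[seq_len(n_l1)]
  tier_high <- class_label %in% cfg$high_burden_classes & cfg$kappa > 0
  l1_mu <- ifelse(tier_high[seq_len(n_l1)], cfg$line1_mean_high,
                  cfg$line1_mean_low)
  l1_sample_mean <- stats::rnorm(n_l1, l1_mu, cfg$line1_sd)
  line1 <- do.call(rbind, lapply(seq_len(n_l1), function(i) {
    do.call(rbind, lapply(1:3, function(rep) {
      vals <- pmin(pmax(l1_sample_mean[i] + stats::rnorm(4, 0, 2), 0), 100)
      data.frame(sample = l1_samples[i], replicate = rep,
                 cpg1 = vals[1], cpg2 = vals[2], cpg3 = vals[3],
                 cpg4 = vals[4], stringsAsFactors = FALSE)
    }))
  }))
  metadata <- data.frame(
    sample = c(tumors, normals),
    tissue = rep(c("tumor", "normal"), c(cfg$n_tumors, cfg$n_normals)),
    age = round(stats::rnorm(cfg$n_tumors + cfg$n_normals, 60, 10)),
    sex = sample(c("M", "F"), cfg$n_tumors + cfg$n_normals, replace = TRUE),
    site = sample(c("oral", "pharynx", "larynx"),
                  cfg$n_tumors + cfg$n_normals, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"),
                   cfg$n_tumors + cfg$n_normals, replace = TRUE),
    hpv16 = sample(c("pos", "neg"), cfg$n_tumors + cfg$n_normals,
                   replace = TRUE, prob = c(0.3, 0.7)),
    stringsAsFactors = FALSE)

  truth <- list(class_label = stats::setNames(class_label, tumors),
                burden_tier = stats::setNames(
                  ifelse(tier_high, "high", "low"), tumors),
                burden_target = stats::setNames(burden_target, tumors),
                true_burden = cn_burden(cn),
                segments = segments,
                informative_cpgs = cpgs[informative],
                class_means = class_means,
                line1_group_means = c(high = cfg$line1_mean_high,
                                      low = cfg$line1_mean_low),
                planted_genes = character(0))
  structure(list(beta = beta, cn = cn, log_ratio = log_ratio,
                 cpg_annot = cpg_annot, snp_annot = snp_annot,
                 metadata = metadata, line1 = line1, truth = truth,
                 cfg = cfg),
            class = "methcna_cohort")
}

# "chr7" -> 7 (internal)
readr_chrom_num <- function(x) as.integer(sub("^chr", "", x))

#' Plant locally coupled genes into a simulated cohort
#'
#' For each selected gene a tumor-level latent Gaussian variable shifts both
#' the gene's promoter-CpG methylation and its SNP copy-number states, so the
#' expected gene-level Pearson correlation between promoter methylation and
#' mean copy number matches \code{target_r} in sign and approximate
#' magnitude.  The log-ratio matrix and truth burden are updated to stay
#' consistent with the modified states.  \code{target_r = 0} leaves the
#' cohort unchanged.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param genes gene ids to plant (must have >= 1 promoter CpG and >= 1 SNP).
#' @param target_r signed target correlation, |target_r| <= 1.
#' @param seed integer RNG seed.
#' @return the modified cohort; \code{truth$planted_genes} and
#'   \code{truth$planted_target_r} record the planting.
#' @export
plant_local_coupling <- function(cohort, genes, target_r, seed = 1) {
  stopifnot(inherits(cohort, "methcna_cohort"))
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  if (target_r == 0) {
    cohort$truth$planted_genes <- genes
    cohort$truth$planted_target_r <- 0
    return(cohort)
  }
  set.seed(stage_seed(seed, "plant"))
  tumors <- rownames(cohort$cn)
  n <- length(tumors)
  rho <- abs(target_r); s <- sign(target_r)
  for (g in genes) {
    prom <- cohort$cpg_annot$locus[!is.na(cohort$cpg_annot$gene) &
                                     cohort$cpg_annot$gene == g &
                                     cohort$cpg_annot$upstream_of_tss == 1]
    gsnps <- cohort$snp_annot$locus[!is.na(cohort$snp_annot$gene) &
                                      cohort$snp_annot$gene == g]
    if (length(prom) == 0 || length(gsnps) == 0) {
      stop("gene ", g, " lacks promoter CpGs or SNPs; cannot plant coupling")
    }
    z <- stats::rnorm(n)
    u <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    st <- as.integer(pmin(pmax(round(2 + 1.4 * z), 0), 4))
    cohort$cn[, gsnps] <- matrix(st, n, length(gsnps))
    cohort$log_ratio[, gsnps] <-
      log2(pmax(cohort$cn[, gsnps, drop = FALSE], 0.5) / 2) +
      matrix(stats::rnorm(n * length(gsnps), 0, cohort$cfg$log_ratio_sd), n)
    for (cp in prom) {
      b <- 0.5 + s * 0.18 * u + stats::rnorm(n, 0, 0.02)
      cohort$beta[tumors, cp] <- pmin(pmax(b, 0.01), 0.99)
    }
  }
  cohort$truth$true_burden <- cn_burden(cohort$cn)
  cohort$truth$planted_genes <- genes
  cohort$truth$planted_target_r <- target_r
  cohort
}
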