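#' Configuration for synthetic multi-center case cohorts
#'
#' Parameterizes the generative model used throughout the test-bench: an
#' ancestral population split into subpopulations whose allele frequencies
#' drift around ancestral values under the Balding-Nichols model (Beta with
#' parameters `p(1-F)/F`, `(1-p)(1-F)/F`), Hardy-Weinberg genotypes within
#' subpopulation, a logistic disease model with main effects and a planted
#' gene-gene interaction, center-specific ancestry mixes, symmetric batch
#' genotyping error, and imputation-style fractional dosages with call
#' probabilities.
#'
#' @param n_centers Number of study centers.
#' @param cases_per_center Cases sampled per center.
#' @param n_snps Number of SNPs (>= 2).
#' @param n_subpops Number of subpopulations.
#' @param fst Wright's fixation index in \[0, 1); 0 means no structure.
#' @param ancestral_mafs Per-SNP ancestral minor allele frequencies in
#'   (0, 0.5\]; recycled if scalar.
#' @param center_admixture `n_centers` x `n_subpops` matrix of subpopulation
#'   mixing proportions; rows must sum to 1. Default: uniform.
#' @param me_snp_index,partner_snp_index Column indices of the main-effect
#'   SNP and its interaction partner.
#' @param beta0 Baseline log-odds of disease (sets prevalence).
#' @param beta1,beta2 Main-effect log-odds ratios on the coded genotypes.
#' @param delta_interaction Interaction log-odds ratio (the planted signal).
#' @param coding_g1,coding_g2 Genetic model applied to the ME and partner
#'   SNP in the disease model (`"dominant"`, `"recessive"`, `"additive"`).
#' @param batch_error_rate Per-genotype probability of a miscall to a
#'   uniformly chosen other genotype, applied per center.
#' @param dosage_noise_sd SD of the fractional dosage noise (truncated to
#'   keep dosages in \[0, 2\]).
#' @param call_prob_floor Lower bound of the Uniform call probabilities.
#' @param pair_freq_corr Correlation (Gaussian copula) between the
#'   subpopulation allele frequencies of the ME and partner SNP; nonzero
#'   values plant population-level LD that violates the case-only
#'   independence assumption.
#' @param aao_params List with elements `mu`, `sd`, `a1`, `a2`, `a3`,
#'   `b_sex` for the age-at-onset model
#'   `y = mu + a1 c(G1) + a2 c(G2) + a3 c(G1)c(G2) + b_sex sex + noise`.
#' @param pop_size Population size for [simulate_population()]. Default
#'   scales the expected case yield to 1.5x the total demand.
#' @param seed RNG seed; all randomness derives from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_centers = 5L, cases_per_center = 1000L,
                       n_snps = 500L, n_subpops = 2L, fst = 0.01,
                       ancestral_mafs = 0.3, center_admixture = NULL,
                       me_snp_index = 1L, partner_snp_index = 2L,
                       beta0 = stats::qlogis(0.02), beta1 = log(1.15),
                       beta2 = log(1.1),
                       delta_interaction = log(1.8),
                       coding_g1 = "dominant", coding_g2 = "dominant",
                       batch_error_rate = 0, dosage_noise_sd = 0,
                       call_prob_floor = 0.85, pair_freq_corr = 0,
                       aao_params = list(mu = 60, sd = 10, a1 = 0, a2 = 0,
                                         a3 = 0, b_sex = 0),
                       pop_size = NULL, seed = 1L) {
  mafs <- rep_len(ancestral_mafs, n_snps)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("ancestral MAFs must lie in (0, 0.5]")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (is.null(center_admixture))
    center_admixture <- matrix(1 / n_subpops, n_centers, n_subpops)
  center_admixture <- as.matrix(center_admixture)
  stopifnot(nrow(center_admixture) == n_centers,
            ncol(center_admixture) == n_subpops)
  if (any(abs(rowSums(center_admixture) - 1) > 1e-12))
    stop("admixture rows must sum to 1")
  if (any(center_admixture < 0)) stop("admixture proportions must be >= 0")
  stopifnot(batch_error_rate >= 0, batch_error_rate <= 1,
            dosage_noise_sd >= 0,
            call_prob_floor >= 0, call_prob_floor <= 1,
            abs(pair_freq_corr) <= 1,
            me_snp_index >= 1, me_snp_index <= n_snps,
            partner_snp_index >= 1, partner_snp_index <= n_snps,
            me_snp_index != partner_snp_index)
  coding_g1 <- match.arg(coding_g1, c("dominant", "recessive", "additive"))
  coding_g2 <- match.arg(coding_g2, c("dominant", "recessive", "additive"))
  cfg <- list(n_centers = as.integer(n_centers),
              cases_per_center = as.integer(cases_per_center),
              n_snps = as.integer(n_snps), n_subpops = as.integer(n_subpops),
              fst = fst, ancestral_mafs = mafs,
              center_admixture = center_admixture,
              me_snp_index = as.integer(me_snp_index),
              partner_snp_index = as.integer(partner_snp_index),
              beta0 = beta0, beta1 = beta1, beta2 = beta2,
              delta_interaction = delta_interaction,
              coding_g1 = coding_g1, coding_g2 = coding_g2,
              batch_error_rate = batch_error_rate,
              dosage_noise_sd = dosage_noise_sd,
              call_prob_floor = call_prob_floor,
              pair_freq_corr = pair_freq_corr,
              aao_params = aao_params, pop_size = pop_size,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_centers, "centers x", x$cases_per_center,
      "cases,", x$n_snps, "SNPs,", x$n_subpops, "subpops (Fst =", x$fst,
      ")\n")
  cat("disease model: beta0 =", round(x$beta0, 3), " interaction OR =",
      round(exp(x$delta_interaction), 3),
      sprintf("(%s x %s)\n", x$coding_g1, x$coding_g2))
  invisible(x)
}

# default population size: expected yield 1.5x the total case demand
.default_pop_size <- function(config) {
  prev_guess <- stats::plogis(config$beta0 +
                                abs(config$beta1) + abs(config$beta2))
  need <- config$n_centers * config$cases_per_center
  as.integer(ceiling(1.5 * need / max(prev_guess, 1e-4)))
}

# Balding-Nichols subpopulation allele frequencies (n_subpops x n_snps).
# pair_freq_corr couples the ME/partner SNP deviates via a Gaussian copula.
.bn_frequencies <- function(config) {
  p <- config$ancestral_mafs
  k <- config$n_subpops
  if (config$fst == 0) {
    freq <- matrix(rep(p, each = k), k, config$n_snps)
  } else {
    a <- p * (1 - config$fst) / config$fst
    b <- (1 - p) * (1 - config$fst) / config$fst
    z <- matrix(stats::rnorm(k * config$n_snps), k, config$n_snps)
    if (config$pair_freq_corr != 0) {
      i <- config$me_snp_index; j <- config$partner_snp_index
      rho <- config$pair_freq_corr
      z[, j] <- rho * z[, i] + sqrt(1 - rho^2) * z[, j]
    }
    u <- stats::pnorm(z)
    freq <- t(stats::qbeta(t(u), a, b))
  }
  pmin(pmax(freq, 1e-4), 1 - 1e-4)
}

#' Simulate a structured population with disease status
#'
#' Draws subpopulation allele frequencies by the Balding-Nichols model,
#' genotypes in Hardy-Weinberg equilibrium within subpopulation, and disease
#' status from the logistic model
#' `logit P(D) = beta0 + beta1 c1(G1) + beta2 c2(G2) + delta c1(G1) c2(G2)`
#' where `c1`, `c2` apply the configured genetic codings to the ME and
#' partner SNP. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `genotype_dataset` of the whole population with integer
#'   dosages, subpopulation labels and affection flags.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- if (is.null(config$pop_size)) .default_pop_size(config) else config$pop_size
  freq <- .bn_frequencies(config)
  subpop <- sample.int(config$n_subpops, n, replace = TRUE)
  geno <- matrix(0L, n, config$n_snps)
  for (s in seq_len(config$n_subpops)) {
    idx <- which(subpop == s)
    if (!length(idx)) next
    geno[idx, ] <- matrix(
      stats::rbinom(length(idx) * config$n_snps, 2L,
                    rep(freq[s, ], each = length(idx))),
      length(idx), config$n_snps)
  }
  c1 <- encode_genotypes(geno[, config$me_snp_index], config$coding_g1)
  c2 <- encode_genotypes(geno[, config$partner_snp_index], config$coding_g2)
  eta <- config$beta0 + config$beta1 * c1 + config$beta2 * c2 +
    config$delta_interaction * c1 * c2
  affected <- stats::rbinom(n, 1L, stats::plogis(eta))
  snps <- .place_snps(config)
  samples <- data.frame(
    sample_id = sprintf("ind%06d", seq_len(n)),
    center = NA_character_, subpop = subpop, affected = affected,
    age_onset = NA_real_, sex = stats::rbinom(n, 1L, 0.5),
    stringsAsFactors = FALSE)
  ds <- genotype_dataset(samples, snps, geno, call_probs = NULL)
  attr(ds, "seed") <- config$seed
  attr(ds, "subpop_freqs") <- freq
  ds
}

# Place SNPs on GRCh37-style coordinates; the ME SNP goes to chr12q and the
# partner to chr12p so the cross-arm rule passes by default.
.place_snps <- function(config) {
  cen <- read_centromeres()
  lens <- utils::read.delim(system.file("extdata", "chrom_lengths_grch37.tsv",
                                        package = "coscreen", mustWork = TRUE))
  n <- config$n_snps
  chrom <- cen$chrom[1 + (seq_len(n) - 1) %% nrow(cen)]
  pos <- integer(n)
  for (i in seq_len(n)) {
    ci <- match(chrom[i], cen$chrom)
    len <- lens$length[match(chrom[i], lens$chrom)]
    # alternate deterministic p/q placement outside the gap
    if (i %% 2 == 0) pos[i] <- max(1L, as.integer(cen$start[ci] * 0.5)) +
        (i * 7919L) %% as.integer(cen$start[ci] * 0.4)
    else pos[i] <- as.integer(cen$end[ci] + (len - cen$end[ci]) * 0.3) +
        (i * 104729L) %% as.integer((len - cen$end[ci]) * 0.4)
  }
  chrom[config$me_snp_index] <- "chr12"; pos[config$me_snp_index] <- 40614434L
  chrom[config$partner_snp_index] <- "chr12"
  pos[config$partner_snp_index] <- 33539559L
  arm <- chrom_arm(chrom, pos, cen)
  data.frame(snp_id = sprintf("snp%05d", seq_len(n)), chrom = chrom,
             pos = pos, arm = arm, ref = "A", alt = "G", minor_allele = "G",
             maf = config$ancestral_mafs, stringsAsFactors = FALSE)
}

#' Sample cases into centers with batch artifacts
#'
#' Draws affected individuals from a simulated population into centers
#' according to each center's ancestry mix, then applies per-center batch
#' genotyping error (symmetric miscall to a uniformly chosen other
#' genotype), fractional imputation-style dosages, and Uniform call
#' probabilities. Deterministic given `config$seed`.
#'
#' @param population Output of [simulate_population()].
#' @param config The same [sim_config()].
#' @return A `genotype_dataset` of cases with center labels, fractional
#'   dosages, call probabilities, and an `age_onset` column from
#'   [simulate_aao()].
#' @export
sample_cases <- function(population, config) {
  stopifnot(inherits(population, "genotype_dataset"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  aff <- which(population$samples$affected == 1L)
  subpop <- population$samples$subpop
  pools <- lapply(seq_len(config$n_subpops), function(s) aff[subpop[aff] == s])
  # integer per-center/subpop quota via largest remainder
  quota <- matrix(0L, config$n_centers, config$n_subpops)
  for (i in seq_len(config$n_centers)) {
    raw <- config$center_admixture[i, ] * config$cases_per_center
    q <- floor(raw)
    rem <- config$cases_per_center - sum(q)
    if (rem > 0) {
      ord <- order(raw - q, decreasing = TRUE)
      q[ord[seq_len(rem)]] <- q[ord[seq_len(rem)]] + 1L
    }
    quota[i, ] <- as.integer(q)
  }
  need <- colSums(quota)
  have <- lengths(pools)
  if (any(need > have)) {
    s <- which(need > have)[1]
    stop(sprintf(paste0("insufficient cases: subpopulation %d has %d ",
                        "affected individuals but %d are required; ",
                        "increase pop_size or prevalence"),
                 s, have[s], need[s]))
  }
  pools <- lapply(pools, sample)  # permute once, then deal out
  taken <- integer(config$n_subpops)
  rows <- integer(0); centers <- character(0)
  for (i in seq_len(config$n_centers)) {
    for (s in seq_len(config$n_subpops)) {
      k <- quota[i, s]
      if (k == 0) next
      rows <- c(rows, pools[[s]][taken[s] + seq_len(k)])
      taken[s] <- taken[s] + k
      centers <- c(centers, rep(sprintf("center%02d", i), k))
    }
  }
  geno <- population$dosages[rows, , drop = FALSE]
  n <- nrow(geno); m <- ncol(geno)
  if (config$batch_error_rate > 0) {
    flip <- matrix(stats::runif(n * m) < config$batch_error_rate, n, m)
    shift <- matrix(sample(1:2, n * m, replace = TRUE), n, m)
    geno[flip] <- (geno[flip] + shift[flip]) %% 3
  }
  dos <- geno
  if (config$dosage_noise_sd > 0) {
    dos <- dos + matrix(stats::rnorm(n * m, 0, config$dosage_noise_sd), n, m)
    dos <- pmin(pmax(dos, 0), 2)
  }
  cp <- matrix(stats::runif(n * m, config$call_prob_floor, 1), n, m)
  samples <- population$samples[rows, , drop = FALSE]
  samples$center <- centers
  snps <- population$snps
  snps$maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
  cases <- genotype_dataset(samples, snps, dos, call_probs = cp)
  cases$samples$age_onset <- simulate_aao(cases, config)
  attr(cases, "seed") <- config$seed
  attr(cases, "true_rows") <- rows
  cases
}

#' Simulate age at onset for cases
#'
#' `y = mu + a1 c1(G1) + a2 c2(G2) + a3 c1(G1) c2(G2) + b_sex sex + noise`
#' with parameters from `config$aao_params` and codings from the disease
#' model. Uses the hard genotypes (rounded dosages) of the ME and partner
#' SNP.
#'
#' @param cases A case `genotype_dataset`.
#' @param config The [sim_config()].
#' @return Numeric vector of ages at onset (years).
#' @export
simulate_aao <- function(cases, config) {
  stopifnot(inherits(cases, "genotype_dataset"))
  p <- config$aao_params
  set.seed(config$seed + 2000L)
  g1 <- pmin(pmax(round(cases$dosages[, config$me_snp_index]), 0), 2)
  g2 <- pmin(pmax(round(cases$dosages[, config$partner_snp_index]), 0), 2)
  c1 <- encode_genotypes(g1, config$coding_g1)
  c2 <- encode_genotypes(g2, config$coding_g2)
  sex <- cases$samples$sex
  n <- nrow(cases$dosages)
  noise <- if (p$sd > 0) stats::rnorm(n, 0, p$sd) else 0
  p$mu + p$a1 * c1 + p$a2 * c2 + p$a3 * c1 * c2 + p$b_sex * sex + noise
}

#' Desk-scale demonstration configuration
#'
#' A small multi-center scenario sized so that one screening run finishes
#' in seconds while the planted interaction (OR 1.8, dominant x dominant,
#' MAF 0.3) is detectable at the Bonferroni-corrected genome-wide threshold
#' when the eight centers are pooled: 8 centers x 700 cases, 60 SNPs, two
#' evenly mixed subpopulations at Fst 0.01, baseline prevalence 2\%.
#'
#' @param seed RNG seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
demo_sim_config <- function(seed = 1L, ...) {
  args <- list(
    n_centers = 8L, cases_per_center = 700L, n_snps = 60L,
    n_subpops = 2L, fst = 0.01,
    ancestral_mafs = 0.3, beta0 = stats::qlogis(0.02),
    delta_interaction = log(1.8), seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Simulate a full multi-center case cohort
#'
#' Convenience wrapper: [simulate_population()] then [sample_cases()].
#'
#' @param config A [sim_config()].
#' @return List with elements `population` and `cases`.
#' @export
simulate_cohort <- function(config) {
  pop <- simulate_population(config)
  list(population = pop, cases = sample_cases(pop, config))
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$center_admixture <- apply(config$center_admixture, 1, as.numeric,
                              simplify = FALSE)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$center_admixture <- do.call(rbind, x$center_admixture)
  x$ancestral_mafs <- as.numeric(x$ancestral_mafs)
  do.call(sim_config, x)
}
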