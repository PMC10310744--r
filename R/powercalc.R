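#' Define an interaction-power scenario
#'
#' Parameterizes a power computation for a gene-gene interaction test under
#' a case-only (CO) or case-control (CC) design. Both SNPs are in
#' Hardy-Weinberg equilibrium and independent in the population; disease
#' risk follows the logistic model
#' `logit P(D) = b0 + ln(me_or1) g1 + ln(me_or2) g2 + ln(interaction_or) c(g1) c(g2)`
#' with per-allele (log-additive) main effects and the interaction on the
#' coded genotypes, with `b0` solved so that the population prevalence
#' matches `prevalence`.
#'
#' @param design `"CO"` or `"CC"`.
#' @param n_cases Number of cases.
#' @param n_controls Number of controls (CC only; default equal to
#'   `n_cases`).
#' @param maf1,maf2 Population minor allele frequencies in (0, 0.5\].
#' @param me_or1,me_or2 Per-allele main-effect disease odds ratios.
#' @param interaction_or Interaction odds ratio on the logit scale.
#' @param prevalence Population disease probability (default 0.005).
#' @param alpha Two-sided significance level.
#' @param coding Genetic model for the interaction term and the CO test:
#'   `"dominant"` (default), `"recessive"` or `"additive"`.
#' @return Object of class `power_scenario`.
#' @export
power_scenario <- function(design = c("CO", "CC"), n_cases, n_controls = NULL,
                           maf1 = 0.2, maf2 = 0.2, me_or1 = 1.25,
                           me_or2 = 1.25, interaction_or = 1.5,
                           prevalence = 0.005, alpha = 5.6e-10,
                           coding = "dominant") {
  design <- match.arg(design)
  coding <- match.arg(coding, c("dominant", "recessive", "additive"))
  stopifnot(maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5,
            me_or1 > 0, me_or2 > 0, interaction_or > 0,
            prevalence > 0, prevalence < 1, alpha > 0, alpha < 1,
            n_cases >= 1)
  if (is.null(n_controls)) n_controls <- n_cases
  structure(list(design = design, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), maf1 = maf1,
                 maf2 = maf2, me_or1 = me_or1, me_or2 = me_or2,
                 interaction_or = interaction_or, prevalence = prevalence,
                 alpha = alpha, coding = coding),
            class = "power_scenario")
}

.hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# Joint genotype grid with population probabilities, penetrances solved to
# the target prevalence, and the exact case/control distributions.
.scenario_dist <- function(s, interaction_or = s$interaction_or) {
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  pg <- .hwe_probs(s$maf1)[grid$g1 + 1] * .hwe_probs(s$maf2)[grid$g2 + 1]
  c1 <- encode_genotypes(grid$g1, s$coding)
  c2 <- encode_genotypes(grid$g2, s$coding)
  eta0 <- log(s$me_or1) * grid$g1 + log(s$me_or2) * grid$g2 +
    log(interaction_or) * c1 * c2
  f <- function(b0) sum(pg * stats::plogis(b0 + eta0)) - s$prevalence
  b0 <- stats::uniroot(f, c(-80, 80), tol = 1e-12)$root
  pd <- stats::plogis(b0 + eta0)
  p_case <- pg * pd
  if (sum(p_case) <= 0) stop("parameter combination makes P(case) = 0")
  list(grid = grid, pg = pg, pd = pd, b0 = b0,
       pi_case = p_case / sum(p_case),
       pi_ctrl = pg * (1 - pd) / sum(pg * (1 - pd)),
       x1 = c1, x2 = c2)
}

# collapse a 9-cell case distribution onto the coded 2x2
.collapse_2x2 <- function(pi, x1, x2) {
  tab <- tapply(pi, list(factor(x1, 0:1), factor(x2, 0:1)), sum)
  matrix(as.numeric(tab), 2, 2)
}

#' Analytic power of the case-only interaction test
#'
#' Computes the exact case genotype-pair distribution by Bayes' rule from
#' the population genotype distribution and the logistic disease model, then
#' the Wald noncentrality of the case-only interaction log-OR at
#' `n_cases`: power is `P(chisq_1(ncp) > chisq_1 quantile at 1 - alpha)`.
#' For binary codings the CO estimator is the log cross-product ratio of
#' the collapsed 2x2 case table with variance `sum(1/cell)/n`; for the
#' additive coding it is the linear-by-linear interaction coefficient of the
#' log-linear model fitted to the exact 3x3 case distribution, with its
#' Fisher-information variance. Deterministic.
#'
#' @param scenario A [power_scenario()] with `design = "CO"`.
#' @return Power in \[0, 1\].
#' @export
co_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  d <- .scenario_dist(scenario)
  if (scenario$coding %in% c("dominant", "recessive")) {
    tab <- .collapse_2x2(d$pi_case, d$x1, d$x2)
    if (any(tab <= 0)) stop("degenerate case table: empty exposure cell")
    delta <- log(tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1]))
    v <- sum(1 / tab) / scenario$n_cases
  } else {
    dat <- data.frame(y = d$pi_case, f1 = factor(d$grid$g1),
                      f2 = factor(d$grid$g2), xx = d$grid$g1 * d$grid$g2)
    fit <- suppressWarnings(stats::glm(y ~ f1 + f2 + xx,
                                       family = stats::poisson(),
                                       data = dat))
    delta <- stats::coef(fit)[["xx"]]
    v <- stats::vcov(fit)["xx", "xx"] / scenario$n_cases
  }
  ncp <- delta^2 / v
  stats::pchisq(stats::qchisq(1 - scenario$alpha, 1), df = 1, ncp = ncp,
                lower.tail = FALSE)
}

#' Analytic power of the case-control interaction test
#'
#' Wald power for the product-term coefficient of the prospective logistic
#' model `D ~ c(g1) + c(g2) + c(g1):c(g2)` fitted to the expected genotype
#' distribution of `n_cases` cases and `n_controls` controls drawn
#' retrospectively from the same disease model as [co_power()].
#'
#' @param scenario A [power_scenario()] with `design = "CC"`.
#' @return Power in \[0, 1\].
#' @export
cc_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  d <- .scenario_dist(scenario)
  n1 <- scenario$n_cases; n0 <- scenario$n_controls
  dat <- data.frame(
    D = rep(c(1, 0), each = 9),
    x1 = rep(d$x1, 2), x2 = rep(d$x2, 2),
    w = c(n1 * d$pi_case, n0 * d$pi_ctrl))
  dat <- dat[dat$w > 0, ]
  fit <- suppressWarnings(stats::glm(D ~ x1 * x2,
                                     family = stats::binomial(),
                                     weights = dat$w, data = dat))
  delta <- stats::coef(fit)[["x1:x2"]]
  v <- stats::vcov(fit)["x1:x2", "x1:x2"]
  ncp <- delta^2 / v
  stats::pchisq(stats::qchisq(1 - scenario$alpha, 1), df = 1, ncp = ncp,
                lower.tail = FALSE)
}

#' Power of a scenario under its own design
#'
#' @param scenario A [power_scenario()].
#' @return Power in \[0, 1\] from [co_power()] or [cc_power()].
#' @export
interaction_power <- function(scenario) {
  if (scenario$design == "CO") co_power(scenario) else cc_power(scenario)
}

#' Minimum detectable interaction OR on a grid
#'
#' Searches the interaction OR upward from 1.00 in steps of `grid_step` and
#' returns the smallest grid value whose analytic power reaches
#' `target_power`.
#'
#' @param scenario A [power_scenario()]; its `interaction_or` is ignored.
#' @param target_power Target power (default 0.8).
#' @param grid_step Grid resolution (default 0.05).
#' @param max_or Upper search bound (default 10).
#' @return The minimum detectable OR (a grid value).
#' @export
min_detectable_or <- function(scenario, target_power = 0.8,
                              grid_step = 0.05, max_or = 10) {
  stopifnot(target_power > scenario$alpha, target_power < 1)
  grid <- seq(1, max_or, by = grid_step)
  best <- NA_real_
  for (or in grid) {
    s <- scenario; s$interaction_or <- or
    pw <- interaction_power(s)
    if (pw >= target_power) return(or)
    best <- pw
  }
  stop(sprintf("no OR <= %.2f reaches power %.2f (max achieved %.3f)",
               max_or, target_power, best))
}

#' Monte-Carlo power of the interaction test
#'
#' Simulates replicate studies from the exact genotype distributions of the
#' scenario and counts the fraction in which the design's interaction test
#' rejects at `alpha`. CO replicates draw a multinomial case table and test
#' the collapsed 2x2 log cross-product ratio (or, for additive coding, the
#' linear-by-linear log-linear coefficient) by Wald; CC replicates draw
#' case and control tables and fit the prospective logistic product-term
#' model. Deterministic given `seed`.
#'
#' @param scenario A [power_scenario()].
#' @param reps Number of replicates (>= 100).
#' @param seed RNG seed.
#' @return List with `power`, binomial 99\% confidence bounds `ci_low`,
#'   `ci_high`, and `reps`.
#' @export
simulate_power <- function(scenario, reps = 2000, seed = 1L) {
  stopifnot(inherits(scenario, "power_scenario"), reps >= 100)
  set.seed(seed)
  d <- .scenario_dist(scenario)
  rejects <- 0L; used <- 0L
  if (scenario$design == "CO" &&
      scenario$coding %in% c("dominant", "recessive")) {
    p4 <- as.vector(.collapse_2x2(d$pi_case, d$x1, d$x2))
    cnt <- stats::rmultinom(reps, scenario$n_cases, p4)
    ok <- colSums(cnt == 0) == 0
    lor <- log(cnt[1, ] * cnt[4, ] / (cnt[2, ] * cnt[3, ]))
    se <- sqrt(colSums(1 / cnt))
    pv <- 2 * stats::pnorm(-abs(lor / se))
    rejects <- sum(pv[ok] < scenario$alpha)
    used <- sum(ok)
  } else if (scenario$design == "CO") {
    for (r in seq_len(reps)) {
      cnt <- stats::rmultinom(1, scenario$n_cases, d$pi_case)[, 1]
      dat <- data.frame(y = cnt, f1 = factor(d$grid$g1),
                        f2 = factor(d$grid$g2), xx = d$grid$g1 * d$grid$g2)
      fit <- try(suppressWarnings(
        stats::glm(y ~ f1 + f2 + xx, family = stats::poisson(),
                   data = dat)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      co <- summary(fit)$coefficients
      if (!"xx" %in% rownames(co)) next
      used <- used + 1L
      if (2 * stats::pnorm(-abs(co["xx", "z value"])) < scenario$alpha)
        rejects <- rejects + 1L
    }
  } else {
    for (r in seq_len(reps)) {
      cc <- stats::rmultinom(1, scenario$n_cases, d$pi_case)[, 1]
      ct <- stats::rmultinom(1, scenario$n_controls, d$pi_ctrl)[, 1]
      dat <- data.frame(D = rep(c(1, 0), each = 9),
                        x1 = rep(d$x1, 2), x2 = rep(d$x2, 2),
                        w = c(cc, ct))
      dat <- dat[dat$w > 0, ]
      fit <- try(suppressWarnings(
        stats::glm(D ~ x1 * x2, family = stats::binomial(),
                   weights = dat$w, data = dat)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      co <- summary(fit)$coefficients
      if (!"x1:x2" %in% rownames(co)) next
      est <- co["x1:x2", "Estimate"]
      if (abs(est) > 15) next
      used <- used + 1L
      if (2 * stats::pnorm(-abs(co["x1:x2", "z value"])) < scenario$alpha)
        rejects <- rejects + 1L
    }
  }
  if (used == 0L) stop("no usable replicates")
  phat <- rejects / used
  half <- 2.575829 * sqrt(phat * (1 - phat) / used)
  list(power = phat, ci_low = max(0, phat - half),
       ci_high = min(1, phat + half), reps = used)
}

#' Power-curve table over a grid of interaction ORs
#'
#' @param scenario A [power_scenario()].
#' @param or_grid Interaction ORs to evaluate.
#' @return `data.frame` with columns `interaction_or`, `power`.
#' @export
power_curve <- function(scenario, or_grid = seq(1, 3, by = 0.05)) {
  pw <- vapply(or_grid, function(or) {
    s <- scenario; s$interaction_or <- or
    interaction_power(s)
  }, numeric(1))
  data.frame(interaction_or = or_grid, power = pw)
}
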