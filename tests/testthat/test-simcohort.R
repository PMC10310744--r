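test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(ancestral_mafs = 0), "MAF")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(n_centers = 2, n_subpops = 2,
                          center_admixture = rbind(c(0.5, 0.4),
                                                   c(0.5, 0.5))),
               "sum to 1")
  # fst = 0 with several subpopulations is allowed (no drift)
  expect_s3_class(sim_config(fst = 0, n_subpops = 3), "sim_config")
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_centers = 2, cases_per_center = 50, n_snps = 10,
                    pop_size = 6000, beta0 = qlogis(0.1),
                    dosage_noise_sd = 0.1, batch_error_rate = 0.01,
                    seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$population$dosages, b$population$dosages)
  expect_identical(a$cases$dosages, b$cases$dosages)
  expect_identical(a$cases$call_probs, b$cases$call_probs)
  cfg2 <- cfg; cfg2$seed <- 8L
  c2 <- simulate_cohort(cfg2)
  expect_false(identical(a$cases$dosages, c2$cases$dosages))
})

test_that("without noise or batch error, case dosages are exact integers", {
  cfg <- sim_config(n_centers = 5, cases_per_center = 40, n_snps = 8,
                    pop_size = 15000, beta0 = qlogis(0.1),
                    batch_error_rate = 0, dosage_noise_sd = 0, seed = 3)
  cases <- simulate_cohort(cfg)$cases
  expect_true(all(cases$dosages == round(cases$dosages)))
  # center counts exactly as configured
  expect_equal(unname(table(cases$samples$center)),
               rep(40L, 5), ignore_attr = TRUE)
  expect_equal(nrow(cases$dosages), 200)
})

test_that("insufficient affected individuals raise a shortfall error", {
  cfg <- sim_config(n_centers = 2, cases_per_center = 5000, n_snps = 4,
                    pop_size = 2000, beta0 = qlogis(0.05), seed = 1)
  pop <- simulate_population(cfg)
  expect_error(sample_cases(pop, cfg), "insufficient cases")
})

test_that("under no structure and no interaction the pair is independent", {
  cfg <- sim_config(n_centers = 1, cases_per_center = 10, n_snps = 2,
                    n_subpops = 1, fst = 0, delta_interaction = 0,
                    beta1 = 0, beta2 = 0, pop_size = 20000,
                    batch_error_rate = 0, seed = 21)
  pop <- simulate_population(cfg)
  r <- cor(pop$dosages[, 1], pop$dosages[, 2])
  expect_lt(abs(r), 3 / sqrt(nrow(pop$dosages)))
})

test_that("crude case OR matches the analytic enumeration oracle", {
  # dominant x dominant, planted OR 1.8, MAF 0.3, ~1% baseline prevalence
  cfg <- sim_config(n_centers = 1, cases_per_center = 100, n_snps = 2,
                    n_subpops = 1, fst = 0, ancestral_mafs = 0.3,
                    beta0 = qlogis(0.01), beta1 = log(1.15),
                    beta2 = log(1.1), delta_interaction = log(1.8),
                    pop_size = 1000000, seed = 31)
  pop <- simulate_population(cfg)
  aff <- pop$samples$affected == 1
  g1 <- encode_genotypes(pop$dosages[aff, 1], "dominant")
  g2 <- encode_genotypes(pop$dosages[aff, 2], "dominant")
  tab <- table(g1, g2)
  observed_lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  oracle <- oracle_case_dist(0.3, 0.3, qlogis(0.01), log(1.15), log(1.1),
                             log(1.8))
  expect_lt(abs(exp(observed_lor) - exp(oracle$crude_log_or)), 0.1)
})

test_that("population-level LD planting inflates the case-only estimate", {
  # correlated subpopulation frequencies violate the independence
  # assumption and bias the case-only interaction OR upward
  est <- function(rho, seed) {
    cfg <- sim_config(n_centers = 1, cases_per_center = 2000, n_snps = 2,
                      n_subpops = 4, fst = 0.1, ancestral_mafs = 0.3,
                      beta0 = qlogis(0.05), delta_interaction = log(1.5),
                      pair_freq_corr = rho, pop_size = 80000, seed = seed)
    cases <- simulate_cohort(cfg)$cases
    g <- hard_call(cases$dosages, cases$call_probs, 0)
    fit_co(encode_genotypes(g[, 1], "dominant"),
           encode_genotypes(g[, 2], "dominant"))$delta1_hat
  }
  with_ld <- mean(vapply(1:6, function(s) est(0.95, s), numeric(1)))
  without <- mean(vapply(1:6, function(s) est(0, s + 100), numeric(1)))
  expect_gt(with_ld, without)
  expect_gt(with_ld, log(1.5))
})

test_that("age-at-onset model is exact without noise and recoverable with", {
  cfg <- sim_config(n_centers = 2, cases_per_center = 100, n_snps = 2,
                    pop_size = 30000, beta0 = qlogis(0.05),
                    aao_params = list(mu = 60, sd = 0, a1 = -1, a2 = 0.5,
                                      a3 = -2, b_sex = 1.5), seed = 12)
  cases <- simulate_cohort(cfg)$cases
  c1 <- encode_genotypes(round(cases$dosages[, 1]), cfg$coding_g1)
  c2 <- encode_genotypes(round(cases$dosages[, 2]), cfg$coding_g2)
  y_hat <- 60 - 1 * c1 + 0.5 * c2 - 2 * c1 * c2 +
    1.5 * cases$samples$sex
  expect_equal(cases$samples$age_onset, y_hat, tolerance = 1e-12)
  # fitted interaction recovers a3 = -2 on average with noise
  cfg$aao_params$sd <- 5
  ests <- vapply(1:20, function(s) {
    cfg$seed <- s
    cases <- simulate_cohort(cfg)$cases
    c1 <- encode_genotypes(round(cases$dosages[, 1]), "dominant")
    c2 <- encode_genotypes(round(cases$dosages[, 2]), "dominant")
    coef(lm(cases$samples$age_onset ~ c1 * c2 + cases$samples$sex))["c1:c2"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - (-2)), 0.5)
})

test_that("batch error perturbs the configured fraction of genotypes", {
  cfg <- sim_config(n_centers = 1, cases_per_center = 500, n_snps = 50,
                    pop_size = 40000, beta0 = qlogis(0.05),
                    batch_error_rate = 0.1, dosage_noise_sd = 0, seed = 9)
  pop <- simulate_population(cfg)
  cases <- sample_cases(pop, cfg)
  orig <- pop$dosages[attr(cases, "true_rows"), ]
  frac <- mean(cases$dosages != orig)
  expect_gt(frac, 0.07); expect_lt(frac, 0.13)
  # call probabilities live in [floor, 1]
  expect_true(all(cases$call_probs >= cfg$call_prob_floor))
  expect_true(all(cases$call_probs <= 1))
})

test_that("sim config YAML round-trips", {
  cfg <- sim_config(n_centers = 3, cases_per_center = 10, n_snps = 6,
                    center_admixture = rbind(c(0.7, 0.3), c(0.5, 0.5),
                                             c(0.2, 0.8)),
                    ancestral_mafs = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.25),
                    seed = 99)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$center_admixture, cfg$center_admixture,
               ignore_attr = TRUE)
  expect_equal(back$ancestral_mafs, cfg$ancestral_mafs)
  expect_equal(back$seed, cfg$seed)
})
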