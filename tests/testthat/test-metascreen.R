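test_that("DerSimonian-Laird pooling matches the hand arithmetic oracle", {
  est <- data.frame(center_id = c("a", "b"), delta1_hat = c(0.5, 0.7),
                    se = c(0.1, 0.1), converged = TRUE)
  m <- pool_estimates(est)
  # hand DL: w = 100 each, ybar = 0.6, Q = 2, tau2 = (2-1)/(200-100) = 0.01
  expect_equal(m$Q, 2.0, tolerance = 1e-9)
  expect_equal(m$tau2, 0.01, tolerance = 1e-9)
  expect_equal(m$pooled_log_or, 0.6, tolerance = 1e-9)
  expect_equal(m$pooled_se, sqrt(1 / (2 / 0.02)), tolerance = 1e-9)
  expect_equal(m$i2, 0.5, tolerance = 1e-9)
  # and the general oracle on random inputs
  set.seed(23)
  for (r in 1:10) {
    k <- sample(2:8, 1)
    y <- rnorm(k, 0.3, 0.4); se <- runif(k, 0.05, 0.5)
    got <- pool_estimates(data.frame(center_id = seq_len(k),
                                     delta1_hat = y, se = se,
                                     converged = TRUE))
    want <- oracle_dl(y, se)
    expect_equal(got$pooled_log_or, want$pooled, tolerance = 1e-9)
    expect_equal(got$pooled_se, want$se, tolerance = 1e-9)
    expect_equal(got$tau2, want$tau2, tolerance = 1e-9)
    expect_equal(got$i2, want$i2, tolerance = 1e-9)
  }
})

test_that("DL pooling agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(29)
  y <- rnorm(6, 0.4, 0.3); se <- runif(6, 0.08, 0.4)
  got <- pool_estimates(data.frame(center_id = 1:6, delta1_hat = y,
                                   se = se, converged = TRUE))
  ref <- metafor::rma(yi = y, sei = se, method = "DL", test = "z")
  expect_equal(got$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(got$pooled_se, ref$se, tolerance = 1e-8)
  expect_equal(got$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(got$p, ref$pval, tolerance = 1e-8)
})

test_that("single-center and homogeneous pools behave trivially", {
  one <- pool_estimates(data.frame(center_id = "a", delta1_hat = 0.3,
                                   se = 0.12, converged = TRUE))
  expect_equal(one$pooled_log_or, 0.3)
  expect_equal(one$pooled_se, 0.12)
  expect_equal(one$Q, 0); expect_equal(one$i2, 0)
  same <- pool_estimates(data.frame(center_id = 1:4,
                                    delta1_hat = rep(0.25, 4),
                                    se = rep(0.1, 4), converged = TRUE))
  expect_equal(same$pooled_log_or, 0.25)
  expect_equal(same$tau2, 0); expect_equal(same$i2, 0)
  # equal SEs: DL pooled estimate is the arithmetic mean of the log-ORs
  y <- c(0.1, 0.5, 0.3)
  eq <- pool_estimates(data.frame(center_id = 1:3, delta1_hat = y,
                                  se = rep(0.2, 3), converged = TRUE))
  expect_equal(eq$pooled_log_or, mean(y), tolerance = 1e-12)
  expect_error(pool_estimates(data.frame(center_id = 1,
                                         delta1_hat = NA_real_,
                                         se = NA_real_,
                                         converged = FALSE)),
               "no converged")
})

test_that("tau2 is zero whenever Q <= k - 1, and I2 stays in [0, 1]", {
  set.seed(37)
  for (r in 1:30) {
    k <- sample(2:10, 1)
    y <- rnorm(k, 0, 0.2); se <- runif(k, 0.1, 0.6)
    m <- pool_estimates(data.frame(center_id = 1:k, delta1_hat = y,
                                   se = se, converged = TRUE))
    expect_gte(m$Q, 0)
    expect_gte(m$i2, 0); expect_lte(m$i2, 1)
    if (m$Q <= k - 1) expect_equal(m$tau2, 0)
    expect_true(m$ci_low <= m$or && m$or <= m$ci_high)
  }
})

test_that("removing the most outlying center never increases Q", {
  set.seed(43)
  for (r in 1:10) {
    k <- sample(4:9, 1)
    y <- rnorm(k, 0.3, 0.5); se <- runif(k, 0.05, 0.3)
    df <- data.frame(center_id = 1:k, delta1_hat = y, se = se,
                     converged = TRUE)
    m <- pool_estimates(df)
    w <- 1 / se^2
    ybar <- sum(w * y) / sum(w)
    out <- which.max(w * (y - ybar)^2)
    m2 <- pool_estimates(df[-out, ])
    expect_lte(m2$Q, m$Q + 1e-12)
  }
})

test_that("stability filter excludes wide-CI and non-converged centers", {
  df <- data.frame(center_id = c("a", "b", "c", "d", "e", "f"),
                   delta1_hat = c(0.5, 0.55, 0.45, 0.6, 2.0, NA),
                   se = c(0.1, 0.11, 0.09, 0.12, 50, NA),
                   converged = c(rep(TRUE, 5), FALSE))
  sf <- stability_filter(df, ci_width_max = 4)
  expect_setequal(sf$kept$center_id, c("a", "b", "c", "d"))
  expect_setequal(sf$excluded$center_id, c("e", "f"))
  expect_match(sf$excluded$reason[sf$excluded$center_id == "e"],
               "CI width")
  ref <- pool_estimates(df[1:4, ])
  expect_equal(sf$meta$pooled_log_or, ref$pooled_log_or)
  # all within bounds: nothing excluded
  sf2 <- stability_filter(df[1:4, ], ci_width_max = 4)
  expect_equal(nrow(sf2$excluded), 0)
  # everything unstable: error
  expect_error(stability_filter(df[5:6, ], ci_width_max = 4), "no stable")
})

test_that("screen config computes the Bonferroni threshold from its parts", {
  cfg <- screen_config()
  expect_equal(cfg$final_threshold, 5e-8 / 90)
  expect_equal(signif(cfg$final_threshold, 2), 5.6e-10)
  cfg2 <- screen_config(genome_wide_p = 1e-6, n_me_snps = 10)
  expect_equal(cfg2$final_threshold, 1e-7)
})

test_that("two-stage bookkeeping keeps stage-2 entries out of final hits", {
  # two pairs: one strong everywhere, one moderate (passes stage 1 entry
  # but not the final threshold)
  mk <- function(me, pa, d1, se) {
    data.frame(me_snp = me, partner_snp = pa, model_g1 = "dominant",
               model_g2 = "dominant", center = sprintf("c%02d", 1:8),
               delta1_hat = d1, se = se, p = 2 * pnorm(-abs(d1 / se)),
               n = 1000, converged = TRUE, failure_reason = NA)
  }
  strong <- mk("me1", "p1", rep(0.8, 8), rep(0.08, 8))
  # three convincing centers, five null ones: clears the stage-2 entry
  # level via stage-1 selection but heterogeneity keeps it short of the
  # final threshold over all centers
  weak <- mk("me1", "p2", c(rep(0.25, 3), rep(0.02, 5)), rep(0.06, 8))
  res <- two_stage_screen(rbind(strong, weak), screen_config())
  expect_true("p1" %in% res$hits$partner_snp)
  expect_true("p2" %in% res$stage2$partner_snp)
  expect_false("p2" %in% res$hits$partner_snp)
  expect_true(all(res$hits$p < 5.6e-10))
})

test_that("forest data has one row per kept center plus a summary row", {
  df <- data.frame(center_id = c("a", "b", "c"),
                   delta1_hat = c(0.4, 0.5, 0.6), se = rep(0.1, 3),
                   converged = TRUE)
  m <- pool_estimates(df)
  fd <- forest_data(m, df)
  expect_equal(nrow(fd), 4)
  expect_equal(fd$type, c(rep("center", 3), "summary"))
  expect_equal(attr(fd, "Q"), m$Q)
  # single center: two rows with identical ORs
  one <- df[1, ]
  m1 <- pool_estimates(one)
  fd1 <- forest_data(m1, one)
  expect_equal(nrow(fd1), 2)
  expect_equal(fd1$or[1], fd1$or[2])
  # excluded centers never appear as rows
  ex <- data.frame(center_id = "z", reason = "not converged")
  fd2 <- forest_data(m, df, excluded = ex)
  expect_false("z" %in% fd2$label)
  expect_equal(attr(fd2, "excluded")$center_id, "z")
})
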