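make_aao_records <- function(n_per_center, centers, a3 = 0, sd = 5,
                             seed = 1, with_pcs = FALSE) {
  set.seed(seed)
  rows <- lapply(seq_len(centers), function(ce) {
    n <- n_per_center
    g1 <- rbinom(n, 1, 0.4); g2 <- rbinom(n, 1, 0.35)
    sex <- rbinom(n, 1, 0.5)
    y <- 62 - 1.2 * g1 + 0.4 * g2 + a3 * g1 * g2 + 1.1 * sex +
      rnorm(n, 0, sd)
    out <- data.frame(center = sprintf("c%02d", ce), y = y, g1 = g1,
                      g2 = g2, sex = sex)
    if (with_pcs) for (k in 1:3) out[[paste0("pc", k)]] <- rnorm(n)
    out
  })
  do.call(rbind, rows)
}

test_that("noise-free records reproduce the interaction coefficient exactly", {
  rec <- make_aao_records(60, 2, a3 = -2, sd = 0, seed = 2)
  res <- aao_interaction(rec)
  expect_equal(res$centers$estimate, rep(-2, 2), tolerance = 1e-10)
  expect_equal(res$meta$pooled_log_or, -2, tolerance = 1e-10)
})

test_that("interaction of -2 years is recovered on average", {
  ests <- vapply(1:25, function(s) {
    rec <- make_aao_records(200, 1, a3 = -2, sd = 5, seed = s)
    aao_interaction(rec)$meta$pooled_log_or
  }, numeric(1))
  expect_lt(abs(mean(ests) - (-2)), 0.5)
})

test_that("null age-at-onset interaction is calibrated at the 0.05 level", {
  ps <- vapply(1:100, function(s) {
    rec <- make_aao_records(150, 1, a3 = 0, sd = 6, seed = 1000 + s)
    aao_interaction(rec)$centers$p
  }, numeric(1))
  frac <- mean(ps < 0.05)
  # binomial 99% bounds around 0.05 with 100 replicates
  expect_gte(frac, 0.0); expect_lte(frac, 0.11)
})

test_that("a single center's meta row equals the center row", {
  rec <- make_aao_records(100, 1, a3 = -1.5, sd = 3, seed = 9)
  res <- aao_interaction(rec)
  expect_equal(res$meta$pooled_log_or, res$centers$estimate[1])
  expect_equal(res$meta$pooled_se, res$centers$se[1])
})

test_that("with sex and PCs at zero the fit equals plain two-way OLS", {
  rec <- make_aao_records(120, 1, a3 = -2, sd = 4, seed = 13)
  rec$sex <- 0
  res <- aao_interaction(rec)
  plain <- lm(y ~ g1 * g2, data = rec)
  expect_equal(res$centers$estimate, unname(coef(plain)["g1:g2"]),
               tolerance = 1e-10)
})

test_that("tiny or rank-deficient centers are skipped with a reason", {
  rec <- make_aao_records(100, 1, seed = 17)
  rec2 <- rbind(rec, data.frame(center = "tiny", y = c(60, 61), g1 = 0:1,
                                g2 = 0, sex = 0:1))
  res <- aao_interaction(rec2)
  expect_equal(res$skipped$center, "tiny")
  expect_equal(nrow(res$centers), 1)
  expect_error(aao_interaction(transform(rec, y = -y)), "positive")
})

test_that("the 4-down vs 3-up carrier table gives exact p = 1/35", {
  rec <- data.frame(
    individual = rep(1:7, each = 4),
    group = rep(c(rep("affected_carrier", 4), rep("unaffected_carrier", 3)),
                each = 4),
    day = rep(c("d70", "d70", "d90", "d90"), 7),
    value = c(rep(c(2.0, 2.2, 1.0, 1.1), 4),   # carriers: down (d70 > d90)
              rep(c(1.0, 1.1, 2.0, 2.2), 3)))  # unaffected: up
  res <- direction_fisher(rec)
  expect_equal(res$p, 1 / 35, tolerance = 1e-12)
  expect_equal(round(res$p, 2), 0.03)
  expect_equal(unname(res$table["affected_carrier", "down"]), 4)
})

test_that("the Fisher direction test matches hypergeometric enumeration", {
  # probability-mass ordering two-sided definition
  enum_fisher <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(m, k)
    probs <- dhyper(support, m, n, k)
    obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(19)
  for (r in 1:25) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    groups <- rep(c("a", "b"), rowSums(tab))
    dirs <- c(rep(c("down", "up"), tab[1, ]), rep(c("down", "up"), tab[2, ]))
    nind <- length(groups)
    rec <- data.frame(
      individual = rep(seq_len(nind), each = 2),
      group = rep(groups, each = 2),
      day = rep(c("d70", "d90"), nind),
      value = as.vector(vapply(dirs, function(d)
        if (d == "down") c(2, 1) else c(1, 2), numeric(2))))
    res <- direction_fisher(rec)
    expect_equal(res$p, enum_fisher(tab), tolerance = 1e-9)
  }
})

test_that("the direction test is symmetric in groups and directions", {
  mk <- function(groups, dirs) {
    nind <- length(groups)
    data.frame(individual = rep(seq_len(nind), each = 2),
               group = rep(groups, each = 2),
               day = rep(c("d70", "d90"), nind),
               value = as.vector(vapply(dirs, function(d)
                 if (d == "down") c(2, 1) else c(1, 2), numeric(2))))
  }
  groups <- c(rep("a", 5), rep("b", 4))
  dirs <- c("down", "down", "down", "up", "down", "up", "up", "down", "up")
  p1 <- direction_fisher(mk(groups, dirs))$p
  p2 <- direction_fisher(mk(ifelse(groups == "a", "b", "a"), dirs))$p
  p3 <- direction_fisher(mk(groups, ifelse(dirs == "down", "up", "down")))$p
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, p3, tolerance = 1e-12)
  # identical direction mix in both groups -> p = 1
  same <- mk(c("a", "a", "b", "b"), c("down", "up", "down", "up"))
  expect_equal(direction_fisher(same)$p, 1)
  # zero change demands a tie rule
  tie <- mk(c("a", "a", "b"), c("down", "up", "up"))
  tie$value[5:6] <- 1
  expect_error(direction_fisher(tie), "tie rule")
})

test_that("rank-sum comparison has the exact enumeration p for 3 vs 3", {
  # all 20 allocations of ranks {1..6} into two triples; only the two
  # extreme splits are as separated as a = {1,2,3}: p = 2/20 = 0.1
  expect_equal(group_compare(c(1, 2, 3), c(4, 5, 6)), 0.1,
               tolerance = 1e-12)
  expect_equal(group_compare(c(5, 6, 7), c(5, 6, 7)), 1)
})

test_that("equal-mean groups are declared different only rarely", {
  hits <- sum(vapply(1:100, function(s) {
    set.seed(300 + s)
    group_compare(rnorm(15, 1, 0.3), rnorm(12, 1, 0.3)) < 0.05
  }, logical(1)))
  expect_lte(hits, 7)
})

test_that("Pearson correlation matches the covariance-quotient arithmetic", {
  x <- c(1.2, 2.1, 2.9, 4.2, 5.1)
  y <- c(0.9, 2.2, 2.7, 4.4, 4.8)
  res <- expr_correlation(x, y)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, hand, tolerance = 1e-12)
  expect_equal(expr_correlation(x, 2 * x)$r, 1, tolerance = 1e-12)
  set.seed(23)
  big <- expr_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$r), 0.1)
  expect_error(expr_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(expr_correlation(1:2, 2:3), "at least 3")
})
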