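#' Age-at-onset interaction linear model with center meta-analysis
#'
#' Fits, per center, the ordinary least-squares model
#' `y = G1 + G2 + G1 x G2 + sex + PC1 + ... + PCk` with `y` the age at
#' onset, and pools the interaction coefficients across centers with the
#' same DerSimonian-Laird random-effects machinery as the case-only screen.
#' Centers with a rank-deficient design (or fewer than 8 records) are
#' skipped with a reason. No multiple-testing correction is applied: this is
#' a targeted supportive analysis at a nominal 0.05 level.
#'
#' @param records `data.frame` with columns `center`, `y` (age at onset,
#'   years), `g1`, `g2` (encoded genotypes), `sex` (0/1), and optionally
#'   `pc1` ... `pck` principal-component scores.
#' @param n_pcs Number of PC columns to use (default: all `pc*` columns
#'   present).
#' @return List of class `aao_result`: `centers` (per-center coefficient
#'   table), `skipped` (with reasons), `meta` (pooled `meta_result`, or
#'   `NULL` if no center could be fitted).
#' @export
aao_interaction <- function(records, n_pcs = NULL) {
  stopifnot(is.data.frame(records),
            all(c("center", "y", "g1", "g2", "sex") %in% names(records)))
  if (any(records$y <= 0, na.rm = TRUE))
    stop("age at onset must be positive")
  pc_cols <- grep("^pc[0-9]+$", names(records), value = TRUE)
  if (!is.null(n_pcs)) pc_cols <- utils::head(pc_cols, n_pcs)
  rows <- list(); skipped <- list()
  for (ce in unique(records$center)) {
    sub <- records[records$center == ce, , drop = FALSE]
    sub <- sub[stats::complete.cases(sub[, c("y", "g1", "g2", "sex",
                                             pc_cols)]), , drop = FALSE]
    npar <- 5L + length(pc_cols)
    if (nrow(sub) < max(8L, npar)) {
      skipped[[ce]] <- data.frame(center = ce,
                                  reason = sprintf("only %d usable records",
                                                   nrow(sub)))
      next
    }
    fml <- stats::as.formula(paste(
      c("y ~ g1 * g2 + sex", pc_cols), collapse = " + "))
    fit <- stats::lm(fml, data = sub)
    co <- suppressWarnings(summary(fit))$coefficients  # noise-free fits
    if (!"g1:g2" %in% rownames(co) ||
        any(is.na(stats::coef(fit)[c("g1", "g2", "g1:g2")]))) {
      skipped[[ce]] <- data.frame(center = ce,
                                  reason = "rank-deficient design")
      next
    }
    rows[[ce]] <- data.frame(center = ce,
                             estimate = co["g1:g2", "Estimate"],
                             se = co["g1:g2", "Std. Error"],
                             p = co["g1:g2", "Pr(>|t|)"],
                             n = nrow(sub), stringsAsFactors = FALSE)
  }
  centers <- do.call(rbind, rows)
  meta <- NULL
  if (!is.null(centers) && nrow(centers) > 0) {
    est <- data.frame(center_id = centers$center,
                      delta1_hat = centers$estimate, se = centers$se,
                      converged = TRUE)
    meta <- pool_estimates(est)
  }
  structure(list(centers = centers,
                 skipped = do.call(rbind, skipped), meta = meta),
            class = "aao_result")
}

#' @export
print.aao_result <- function(x, ...) {
  cat("age-at-onset interaction (per-center OLS + RE meta-analysis)\n")
  if (!is.null(x$centers)) print(x$centers, row.names = FALSE)
  if (!is.null(x$meta))
    cat(sprintf("pooled interaction: %.3f years (SE %.3f), p = %.3g\n",
                x$meta$pooled_log_or, x$meta$pooled_se, x$meta$p))
  invisible(x)
}

#' Fisher exact test on dichotomized expression changes
#'
#' Averages each individual's replicate expression values per day, computes
#' the change `mean(day A) - mean(day B)`, dichotomizes it by sign, and
#' tests the 2x2 group-by-direction table with a two-sided Fisher exact
#' test using probability-mass ordering (the sum of all tables whose point
#' hypergeometric probability does not exceed the observed one).
#'
#' @param records `data.frame` with columns `individual`, `group`, `day`,
#'   `value`; `day` must have exactly two levels (compared as first minus
#'   second after sorting, or in the order of a factor's levels).
#' @param groups Optional length-2 character vector selecting/ordering the
#'   groups compared.
#' @return List with the 2x2 `table` (groups x direction down/up), the
#'   per-individual `changes`, and the two-sided `p`.
#' @export
direction_fisher <- function(records, groups = NULL) {
  stopifnot(is.data.frame(records),
            all(c("individual", "group", "day", "value") %in% names(records)))
  days <- if (is.factor(records$day)) levels(droplevels(records$day))
          else sort(unique(records$day))
  if (length(days) != 2L) stop("exactly two days are required")
  agg <- stats::aggregate(value ~ individual + group + day, records, mean)
  wide <- stats::reshape(agg, idvar = c("individual", "group"),
                         timevar = "day", direction = "wide")
  ch <- wide[[paste0("value.", days[1])]] - wide[[paste0("value.", days[2])]]
  if (any(ch == 0))
    stop("zero expression change for individual(s) ",
         paste(wide$individual[ch == 0], collapse = ", "),
         ": an explicit tie rule is required")
  changes <- data.frame(individual = wide$individual, group = wide$group,
                        change = ch,
                        direction = ifelse(ch > 0, "down", "up"))
  # positive change = higher at the first day = downregulation over time
  if (is.null(groups)) groups <- unique(as.character(changes$group))
  if (length(groups) != 2L) stop("exactly two groups are required")
  changes <- changes[changes$group %in% groups, , drop = FALSE]
  tab <- table(factor(changes$group, groups),
               factor(changes$direction, c("down", "up")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, changes = changes, p = ft$p.value)
}

#' Two-group expression comparison (Wilcoxon rank-sum)
#'
#' Exact two-sided rank-sum p-value for small samples (25 or fewer values
#' in total, no ties), normal approximation with tie correction otherwise.
#'
#' @param values_a,values_b Numeric vectors, at least one value each.
#' @return Two-sided p-value.
#' @export
group_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = n <= 25 && !ties,
                       correct = TRUE))
  wt$p.value
}

#' Pearson correlation of paired expression values
#'
#' @param x,y Numeric vectors of equal length, at least 3 pairs.
#' @return List with `r`, two-sided `p`, and `n`.
#' @export
expr_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
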