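#' Screening protocol configuration
#'
#' Thresholds of the two-stage screening protocol. The final significance
#' threshold is the genome-wide level Bonferroni-corrected for the number of
#' ME SNPs: `final_threshold = genome_wide_p / n_me_snps` (5e-8 / 90 =
#' 5.6e-10 under the defaults). No correction is applied for the number of
#' genetic models tested.
#'
#' @param stage1_center_p Center-level p-value cutoff for entering the
#'   stage-1 meta-analysis (default 0.05).
#' @param stage2_entry_p Stage-1 pooled p-value below which a pair is
#'   re-pooled over all centers (default 5e-5).
#' @param genome_wide_p Genome-wide significance level (default 5e-8).
#' @param n_me_snps Number of ME SNPs screened (default 90).
#' @param top_per_center Number of lowest-p pairs extracted per ME SNP per
#'   center for the top-hit report (default 50).
#' @param report_top Number of lowest-p pooled associations reported per ME
#'   SNP (default 5).
#' @param ci_width_max Stability bound: maximal width of a center's 95\%
#'   confidence interval on the log-OR scale (default 4.0).
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(stage1_center_p = 0.05, stage2_entry_p = 5e-5,
                          genome_wide_p = 5e-8, n_me_snps = 90L,
                          top_per_center = 50L, report_top = 5L,
                          ci_width_max = 4.0) {
  structure(list(stage1_center_p = stage1_center_p,
                 stage2_entry_p = stage2_entry_p,
                 genome_wide_p = genome_wide_p,
                 n_me_snps = as.integer(n_me_snps),
                 final_threshold = genome_wide_p / n_me_snps,
                 top_per_center = as.integer(top_per_center),
                 report_top = as.integer(report_top),
                 ci_width_max = ci_width_max),
            class = "screen_config")
}

#' Random-effects pooling of center estimates (DerSimonian-Laird)
#'
#' Pools converged center-level interaction log-ORs with inverse-variance
#' weights under the DerSimonian-Laird random-effects model: the
#' between-center variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/se^2`, the pooled estimate uses weights
#' `1/(se^2 + tau2)`, and heterogeneity is summarized by Cochran's Q and
#' `I2 = max(0, (Q - (k - 1)) / Q)`. The pooled p-value is a two-sided
#' normal-approximation Wald test.
#'
#' @param estimates List of `center_estimate` objects, or a `data.frame`
#'   with columns `delta1_hat`, `se`, `converged` (and optionally
#'   `center_id`/`center`).
#' @return Object of class `meta_result`.
#' @export
pool_estimates <- function(estimates) {
  df <- .as_estimate_df(estimates)
  df <- df[df$converged & is.finite(df$delta1_hat) & is.finite(df$se), ,
           drop = FALSE]
  if (nrow(df) == 0L) stop("no converged center estimates to pool")
  y <- df$delta1_hat; se <- df$se; k <- length(y)
  w <- 1 / se^2
  ybar_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar_fe)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
          else 0
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * y) / sum(wr)
  pooled_se <- sqrt(1 / sum(wr))
  z <- pooled / pooled_se
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  structure(list(pooled_log_or = pooled, pooled_se = pooled_se,
                 or = exp(pooled),
                 ci_low = exp(pooled - 1.959964 * pooled_se),
                 ci_high = exp(pooled + 1.959964 * pooled_se),
                 p = 2 * stats::pnorm(-abs(z)),
                 tau2 = tau2, Q = Q,
                 q_p = if (k > 1) stats::pchisq(Q, k - 1, lower.tail = FALSE)
                       else NA_real_,
                 i2 = i2, k = k, centers = df$center_id),
            class = "meta_result")
}

.as_estimate_df <- function(estimates) {
  if (inherits(estimates, "center_estimate")) estimates <- list(estimates)
  if (is.data.frame(estimates)) {
    df <- estimates
    if (!"center_id" %in% names(df))
      df$center_id <- if ("center" %in% names(df)) df$center
                      else sprintf("center%02d", seq_len(nrow(df)))
  } else {
    df <- do.call(rbind, lapply(estimates, function(e)
      data.frame(center_id = e$center_id, delta1_hat = e$delta1_hat,
                 se = e$se, converged = e$converged,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("delta1_hat", "se", "converged") %in% names(df)))
  df
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("RE meta-analysis (k = %d): OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$k, x$or, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  tau2 = %.4f, Q = %.3f (p = %.3g), I2 = %.1f%%\n",
              x$tau2, x$Q, x$q_p, 100 * x$i2))
  invisible(x)
}

#' Stability filtering of center estimates
#'
#' Low minor-allele counts make center-level interaction estimates unstable;
#' such centers are recognizable by failed convergence or very wide
#' confidence intervals for the interaction OR. This filter iteratively
#' removes non-converged estimates and estimates whose 95\% CI width on the
#' log-OR scale exceeds `ci_width_max`, re-pooling until the kept set is
#' stable.
#'
#' @param estimates As in [pool_estimates()].
#' @param ci_width_max Maximal CI width on the log-OR scale (default 4.0,
#'   i.e. a ratio of about e^4 between the OR confidence bounds).
#' @return List with `kept` (data.frame), `excluded` (data.frame with a
#'   `reason` column), and `meta` (the pooled `meta_result` of the kept
#'   set).
#' @export
stability_filter <- function(estimates, ci_width_max = 4.0) {
  df <- .as_estimate_df(estimates)
  excluded <- df[0, ]; excluded$reason <- character(0)
  repeat {
    bad_conv <- !df$converged | !is.finite(df$delta1_hat) | !is.finite(df$se)
    width <- 2 * 1.959964 * df$se
    bad_wide <- !bad_conv & width > ci_width_max
    bad <- bad_conv | bad_wide
    if (!any(bad)) break
    ex <- df[bad, , drop = FALSE]
    ex$reason <- ifelse(bad_conv[bad], "not converged",
                        sprintf("log-OR CI width %.2f > %.2f",
                                width[bad], ci_width_max))
    excluded <- rbind(excluded, ex)
    df <- df[!bad, , drop = FALSE]
    if (nrow(df) == 0L)
      stop("no stable centers: all estimates excluded")
  }
  list(kept = df, excluded = excluded, meta = pool_estimates(df))
}

#' Two-stage case-only screening across centers
#'
#' Implements the screening protocol: stage 1 pools, for every (pair, model
#' combination), only the centers whose center-level p-value is below
#' `stage1_center_p`; pairs with stage-1 pooled p below `stage2_entry_p`
#' are re-pooled over all centers in stage 2; final hits are stage-2 results
#' below `final_threshold`. Independently, the `top_per_center` lowest-p
#' pairs per ME SNP per center are extracted, re-pooled over all centers,
#' and the `report_top` lowest pooled associations per ME SNP reported.
#' All pooling is stability-filtered. Ties in top-k selection are broken by
#' (p, |log-OR| descending, partner SNP id) for determinism.
#'
#' @param center_results Output of [run_center_fits()]: one row per
#'   (pair, model, center).
#' @param config A [screen_config()].
#' @return List of class `screen_result` with data.frames `stage1`,
#'   `stage2`, `hits`, `top_hits`, and the `config`.
#' @export
two_stage_screen <- function(center_results, config = screen_config()) {
  df <- center_results
  key <- interaction(df$me_snp, df$partner_snp, df$model_g1, df$model_g2,
                     drop = TRUE)
  groups <- split(df, key)
  meta_row <- function(sub, meta, stage) {
    data.frame(me_snp = sub$me_snp[1], partner_snp = sub$partner_snp[1],
               model_g1 = sub$model_g1[1], model_g2 = sub$model_g2[1],
               or = meta$or, ci_low = meta$ci_low, ci_high = meta$ci_high,
               log_or = meta$pooled_log_or, se = meta$pooled_se,
               p = meta$p, tau2 = meta$tau2, Q = meta$Q, i2 = meta$i2,
               k = meta$k, centers = paste(meta$centers, collapse = ","),
               stage = stage, stringsAsFactors = FALSE)
  }
  stage1 <- lapply(groups, function(sub) {
    s1 <- sub[!is.na(sub$p) & sub$p < config$stage1_center_p & sub$converged,
              , drop = FALSE]
    if (nrow(s1) == 0L) return(NULL)
    sf <- tryCatch(stability_filter(s1, config$ci_width_max),
                   error = function(e) NULL)
    if (is.null(sf)) return(NULL)
    meta_row(sub, sf$meta, "stage1")
  })
  stage1 <- do.call(rbind, stage1[!vapply(stage1, is.null, logical(1))])
  pool_all <- function(sub, stage) {
    sf <- tryCatch(stability_filter(sub, config$ci_width_max),
                   error = function(e) NULL)
    if (is.null(sf)) return(NULL)
    meta_row(sub, sf$meta, stage)
  }
  stage2 <- NULL
  if (!is.null(stage1) && nrow(stage1) > 0L) {
    enter <- stage1[stage1$p < config$stage2_entry_p, , drop = FALSE]
    if (nrow(enter) > 0L) {
      sel <- paste(df$me_snp, df$partner_snp, df$model_g1, df$model_g2) %in%
        paste(enter$me_snp, enter$partner_snp, enter$model_g1, enter$model_g2)
      g2 <- split(df[sel, , drop = FALSE],
                  droplevels(key[sel]))
      stage2 <- lapply(g2, pool_all, stage = "stage2")
      stage2 <- do.call(rbind, stage2[!vapply(stage2, is.null, logical(1))])
    }
  }
  hits <- if (!is.null(stage2))
    stage2[stage2$p < config$final_threshold, , drop = FALSE]
  else NULL
  # top-k per ME SNP per center pathway
  top_keys <- character(0)
  for (me in unique(df$me_snp)) {
    for (ce in unique(df$center)) {
      sub <- df[df$me_snp == me & df$center == ce & df$converged &
                  !is.na(df$p), , drop = FALSE]
      if (nrow(sub) == 0L) next
      ord <- order(sub$p, -abs(sub$delta1_hat), sub$partner_snp)
      sub <- sub[ord[seq_len(min(config$top_per_center, nrow(sub)))], ,
                 drop = FALSE]
      top_keys <- union(top_keys, paste(sub$me_snp, sub$partner_snp,
                                        sub$model_g1, sub$model_g2))
    }
  }
  top_hits <- NULL
  if (length(top_keys)) {
    sel <- paste(df$me_snp, df$partner_snp, df$model_g1, df$model_g2) %in%
      top_keys
    gt <- split(df[sel, , drop = FALSE], droplevels(key[sel]))
    pooled <- lapply(gt, pool_all, stage = "top")
    pooled <- do.call(rbind, pooled[!vapply(pooled, is.null, logical(1))])
    if (!is.null(pooled)) {
      top_hits <- do.call(rbind, lapply(split(pooled, pooled$me_snp),
        function(sub) {
          ord <- order(sub$p, -abs(sub$log_or), sub$partner_snp)
          sub[ord[seq_len(min(config$report_top, nrow(sub)))], ,
              drop = FALSE]
        }))
      rownames(top_hits) <- NULL
    }
  }
  empty <- function() data.frame()
  structure(list(stage1 = if (is.null(stage1)) empty() else stage1,
                 stage2 = if (is.null(stage2)) empty() else stage2,
                 hits = if (is.null(hits)) empty() else hits,
                 top_hits = if (is.null(top_hits)) empty() else top_hits,
                 config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("two-stage case-only screen\n")
  cat("  stage 1 pairs pooled:", nrow(x$stage1), "\n")
  cat("  stage 2 pairs re-pooled:", nrow(x$stage2), "\n")
  cat(sprintf("  final hits (p < %.3g): %d\n", x$config$final_threshold,
              nrow(x$hits)))
  if (nrow(x$hits)) {
    h <- x$hits[order(x$hits$p), ]
    for (i in seq_len(min(5, nrow(h))))
      cat(sprintf("    %s x %s (%s/%s): OR = %.2f, p = %.2g\n",
                  h$me_snp[i], h$partner_snp[i], h$model_g1[i],
                  h$model_g2[i], h$or[i], h$p[i]))
  }
  invisible(x)
}

#' Forest-plot table for one pooled pair
#'
#' @param meta A `meta_result`.
#' @param estimates The center estimates that entered pooling (list or
#'   data.frame as in [pool_estimates()]); excluded centers may be passed
#'   via `excluded` and are returned as an annex attribute, never as rows.
#' @param excluded Optional data.frame of excluded centers with reasons.
#' @return `data.frame` with one row per kept center plus a summary row
#'   (`type = "RE summary"`), annotated with Q, its p-value and I2;
#'   attribute `"excluded"` carries the exclusion annex.
#' @export
forest_data <- function(meta, estimates, excluded = NULL) {
  stopifnot(inherits(meta, "meta_result"))
  df <- .as_estimate_df(estimates)
  df <- df[df$converged, , drop = FALSE]
  rows <- data.frame(label = df$center_id, type = "center",
                     or = exp(df$delta1_hat),
                     ci_low = exp(df$delta1_hat - 1.959964 * df$se),
                     ci_high = exp(df$delta1_hat + 1.959964 * df$se),
                     stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(label = "RE summary", type = "summary",
                                 or = meta$or, ci_low = meta$ci_low,
                                 ci_high = meta$ci_high,
                                 stringsAsFactors = FALSE))
  attr(rows, "Q") <- meta$Q
  attr(rows, "q_p") <- meta$q_p
  attr(rows, "i2") <- meta$i2
  attr(rows, "excluded") <- excluded
  rows
}
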