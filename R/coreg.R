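#' Specification of the case-only regression model
#'
#' The case-only model regresses the binary-coded ME SNP genotype on the
#' coded partner SNP genotype among cases:
#' `logit P(G1 = 1) = delta0 + delta1 G2 (+ PC1 .. PCk)`.
#' The coefficient `delta1` estimates the interaction log-odds ratio under
#' population-level independence of the two SNPs.
#'
#' @param model_g1 Coding of the ME SNP: `"dominant"` or `"recessive"` (the
#'   response must be binary).
#' @param model_g2 Coding of the partner SNP: `"dominant"` or `"additive"`.
#' @param n_pcs Number of center-level principal components to adjust for
#'   (default 10).
#' @return Object of class `co_model_spec`.
#' @export
co_model_spec <- function(model_g1 = "dominant", model_g2 = "dominant",
                          n_pcs = 10L) {
  model_g1 <- match.arg(model_g1, c("dominant", "recessive"))
  model_g2 <- match.arg(model_g2, c("dominant", "additive"))
  structure(list(model_g1 = model_g1, model_g2 = model_g2,
                 n_pcs = as.integer(n_pcs)),
            class = "co_model_spec")
}

#' Center-level principal components of the dosage matrix
#'
#' Computes the top-k principal component scores of the centered,
#' unit-scaled dosage matrix of one center's cases, after dropping
#' zero-variance SNP columns. Component signs are fixed by making each
#' component's largest-magnitude loading positive, so results are fully
#' deterministic.
#'
#' @param dosages Samples-by-SNPs numeric matrix for one center.
#' @param k Number of components.
#' @return Samples-by-k score matrix (columns `PC1` ... `PCk`).
#' @export
center_pcs <- function(dosages, k) {
  stopifnot(is.matrix(dosages), k >= 1)
  if (nrow(dosages) < k + 1)
    stop("need at least k + 1 samples for ", k, " components")
  v <- apply(dosages, 2, stats::var)
  keep <- which(v > 0)
  if (!length(keep))
    stop("rank 0 after centering: all SNP columns are constant ",
         "(achievable rank 0)")
  x <- scale(dosages[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  pos <- pc$sdev > max(pc$sdev) * 1e-8
  rank <- sum(pos)
  if (k > rank)
    stop("k = ", k, " exceeds the achievable rank ", rank)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- x %*% rot
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Fit the case-only interaction regression for one center
#'
#' Maximum-likelihood logistic regression of the binary-coded ME genotype on
#' the coded partner genotype plus optional PC scores. Inference on
#' `delta1` (the coefficient on the partner genotype) is by two-sided Wald
#' test. Fits that fail to converge within 100 iterations, or whose
#' interaction coefficient exceeds 15 in absolute value (a practical
#' separation marker), are flagged non-converged and their estimates
#' withheld; instability is handled downstream by exclusion rather than by
#' penalized fitting.
#'
#' @param g1_binary Binary (0/1) coded ME genotypes with both classes
#'   present.
#' @param g2_encoded Coded partner genotypes; must be non-constant.
#' @param pcs Optional samples-by-k PC score matrix.
#' @param center_id Label carried into the result.
#' @return Object of class `center_estimate`: `center_id`, `delta1_hat`,
#'   `se`, `p`, `ci_low`/`ci_high` (OR scale), `n`, `converged`,
#'   `failure_reason`.
#' @export
fit_co <- function(g1_binary, g2_encoded, pcs = NULL, center_id = "center") {
  keep <- !is.na(g1_binary) & !is.na(g2_encoded)
  if (!is.null(pcs)) keep <- keep & stats::complete.cases(pcs)
  g1 <- g1_binary[keep]; g2 <- g2_encoded[keep]
  n <- length(g1)
  if (!all(g1 %in% 0:1)) stop("degenerate response: g1 must be binary 0/1")
  if (length(unique(g1)) < 2L)
    stop("degenerate response: only one G1 class present")
  if (length(unique(g2)) < 2L)
    stop("degenerate predictor: G2 is constant")
  X <- if (is.null(pcs)) data.frame(g2 = g2)
       else data.frame(g2 = g2, pcs[keep, , drop = FALSE])
  fit <- suppressWarnings(
    stats::glm(g1 ~ ., data = X, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  est <- co["g2", "Estimate"]; se <- co["g2", "Std. Error"]
  conv <- isTRUE(fit$converged) && is.finite(est) && is.finite(se) &&
    abs(est) <= 15
  reason <- if (conv) NA_character_
            else if (!isTRUE(fit$converged)) "no convergence in 100 iterations"
            else "separation (|log-OR| > 15)"
  if (!conv) est <- se <- NA_real_
  p <- if (conv) 2 * stats::pnorm(-abs(est / se)) else NA_real_
  structure(list(center_id = center_id, delta1_hat = est, se = se,
                 p = p,
                 ci_low = if (conv) exp(est - 1.959964 * se) else NA_real_,
                 ci_high = if (conv) exp(est + 1.959964 * se) else NA_real_,
                 n = n, converged = conv, failure_reason = reason),
            class = "center_estimate")
}

#' @export
print.center_estimate <- function(x, ...) {
  if (x$converged)
    cat(sprintf("%s: OR = %.3f [%.3f, %.3f], p = %.3g (n = %d)\n",
                x$center_id, exp(x$delta1_hat), x$ci_low, x$ci_high,
                x$p, x$n))
  else
    cat(sprintf("%s: not converged (%s, n = %d)\n", x$center_id,
                x$failure_reason, x$n))
  invisible(x)
}

#' Case-only fits for a batch of SNP pairs across centers
#'
#' Hard-calls genotypes, computes per-center PCs once, and fits the
#' case-only regression for every requested (ME SNP, partner SNP, model
#' combination) in every center.
#'
#' @param cases A case `genotype_dataset`.
#' @param pairs `data.frame` with columns `me_snp`, `partner_snp`,
#'   `model_g1`, `model_g2` (SNP ids).
#' @param n_pcs PCs per center (reduced to the achievable rank if needed).
#' @param call_threshold Imputation-probability threshold for hard calls.
#' @return `data.frame` with one row per (pair, model, center):
#'   estimates, standard errors, Wald p-values and convergence flags.
#' @export
run_center_fits <- function(cases, pairs, n_pcs = 10L, call_threshold = 0.8) {
  stopifnot(inherits(cases, "genotype_dataset"))
  geno <- hard_call(cases$dosages, cases$call_probs, call_threshold)
  centers <- unique(cases$samples$center)
  pcs_by_center <- lapply(centers, function(ce) {
    rows <- cases$samples$center == ce
    k <- n_pcs
    if (k > 0) {
      avail <- min(sum(rows) - 1L, ncol(cases$dosages))
      k <- min(k, avail)
      tryCatch(center_pcs(cases$dosages[rows, , drop = FALSE], k),
               error = function(e) NULL)
    } else NULL
  })
  names(pcs_by_center) <- centers
  out <- vector("list", nrow(pairs) * length(centers))
  r <- 0L
  for (i in seq_len(nrow(pairs))) {
    me <- match(pairs$me_snp[i], cases$snps$snp_id)
    pa <- match(pairs$partner_snp[i], cases$snps$snp_id)
    if (is.na(me) || is.na(pa))
      stop("unknown SNP id in pair list: ",
           pairs$me_snp[i], " / ", pairs$partner_snp[i])
    g1_all <- encode_genotypes(geno[, me], pairs$model_g1[i])
    g2_all <- encode_genotypes(geno[, pa], pairs$model_g2[i])
    for (ce in centers) {
      rows <- cases$samples$center == ce
      est <- tryCatch(
        fit_co(g1_all[rows], g2_all[rows], pcs_by_center[[ce]],
               center_id = ce),
        error = function(e)
          structure(list(center_id = ce, delta1_hat = NA_real_,
                         se = NA_real_, p = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, n = sum(rows),
                         converged = FALSE,
                         failure_reason = conditionMessage(e)),
                    class = "center_estimate"))
      r <- r + 1L
      out[[r]] <- data.frame(
        me_snp = pairs$me_snp[i], partner_snp = pairs$partner_snp[i],
        model_g1 = pairs$model_g1[i], model_g2 = pairs$model_g2[i],
        center = ce, delta1_hat = est$delta1_hat, se = est$se, p = est$p,
        n = est$n, converged = est$converged,
        failure_reason = est$failure_reason, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(r)])
}
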