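#' Haplotype-EM linkage disequilibrium between two SNPs
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' biallelic genotypes by expectation-maximization over the
#' double-heterozygote phase ambiguity, then derives the disequilibrium
#' coefficient `D = p_AB - p_A p_B`, the normalized `D' = |D| / D_max`, and
#' the squared allelic correlation `r2 = D^2 / (p_A p_a p_B p_b)`. The EM
#' is initialized at linkage equilibrium (products of allele frequencies)
#' and iterated until the log-likelihood changes by less than `tol`
#' (default 1e-10, cap 1000 iterations); the two-locus biallelic likelihood
#' is unimodal in practice so no restarts are used.
#'
#' @param g1,g2 Integer genotype vectors (minor-allele counts 0/1/2, `NA`
#'   allowed) of equal length.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Object of class `ld_result`: haplotype frequencies `hap_freq`
#'   (AB, Ab, aB, ab where A/B are the counted alleles), `d`, `d_prime`,
#'   `r2`, `n`, `em_iterations`, `loglik`, and the `loglik_trace`.
#' @export
em_haplotypes <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  stopifnot(length(g1) == length(g2))
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2))
    stop("genotypes must be 0, 1, 2 or NA")
  n <- length(g1)
  if (n == 0L) stop("no complete genotype pairs")
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L)
    stop("undefined LD: monomorphic SNP")
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  cnt <- matrix(as.numeric(cnt), 3, 3)  # rows g1, cols g2
  pA <- sum(g1) / (2 * n)  # frequency of counted allele at locus 1
  pB <- sum(g2) / (2 * n)
  # haplotypes: 1=AB, 2=Ab, 3=aB, 4=ab (A/B = counted alleles)
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  h <- pmax(h, 1e-12); h <- h / sum(h)
  loglik_of <- function(h) {
    pAB <- h[1]; pAb <- h[2]; paB <- h[3]; pab <- h[4]
    # P(genotype pair) under random union of haplotypes; rows g1+1, cols g2+1
    P <- matrix(0, 3, 3)
    P[3, 3] <- pAB^2;         P[3, 2] <- 2 * pAB * pAb; P[3, 1] <- pAb^2
    P[2, 3] <- 2 * pAB * paB; P[2, 1] <- 2 * pAb * pab
    P[2, 2] <- 2 * (pAB * pab + pAb * paB)
    P[1, 3] <- paB^2;         P[1, 2] <- 2 * paB * pab; P[1, 1] <- pab^2
    sum(cnt * log(pmax(P, 1e-300)))
  }
  trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pAB <- h[1]; pAb <- h[2]; paB <- h[3]; pab <- h[4]
    # expected haplotype counts
    eAB <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
    eAb <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
    eaB <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2]
    eab <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
    dh <- cnt[2, 2]
    if (dh > 0) {
      w <- pAB * pab / (pAB * pab + pAb * paB)
      eAB <- eAB + dh * w; eab <- eab + dh * w
      eAb <- eAb + dh * (1 - w); eaB <- eaB + dh * (1 - w)
    }
    h <- c(eAB, eAb, eaB, eab)
    h <- h / sum(h)
    ll <- loglik_of(h)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    if (iter >= max_iter) break
    ll_old <- ll
  }
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  d <- h[1] - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax > 0) abs(d) / dmax else 0
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(hap_freq = stats::setNames(h, c("AB", "Ab", "aB", "ab")),
                 d = d, d_prime = min(d_prime, 1), r2 = min(r2, 1),
                 n = n, em_iterations = iter, loglik = trace[length(trace)],
                 loglik_trace = trace),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD (n = %d): r2 = %.4f, D' = %.4f, D = %.5f (%d EM iter)\n",
              x$n, x$r2, x$d_prime, x$d, x$em_iterations))
  invisible(x)
}

#' Sample-size-weighted average LD across populations
#'
#' @param results List of `ld_result` objects, one per population.
#' @param n Sample sizes (weights); defaults to each result's own `n`.
#' @return List with weighted `r2`, `d_prime`, and total `n`.
#' @export
weighted_ld <- function(results, n = NULL) {
  if (inherits(results, "ld_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  if (is.null(n)) n <- vapply(results, `[[`, numeric(1), "n")
  stopifnot(length(n) == length(results), all(n > 0))
  w <- n / sum(n)
  list(r2 = sum(w * vapply(results, `[[`, numeric(1), "r2")),
       d_prime = sum(w * vapply(results, `[[`, numeric(1), "d_prime")),
       n = sum(n))
}

#' Pairwise LD of SNPs around a focal SNP
#'
#' Computes haplotype-EM r2 and D' between a focal SNP and every SNP within
#' a window on the same chromosome, the audit used to check the case-only
#' independence assumption in a reference population.
#'
#' @param ds A `genotype_dataset` (population sample).
#' @param focal_snp SNP id of the anchor.
#' @param window_bp Window half-width in base pairs (default 1e6).
#' @param call_threshold Hard-call threshold applied to dosages.
#' @return `data.frame` with `snp_id`, `chrom`, `pos`, `r2`, `d_prime`, `n`.
#' @export
ld_window <- function(ds, focal_snp, window_bp = 1e6, call_threshold = 0.8) {
  stopifnot(inherits(ds, "genotype_dataset"))
  fi <- match(focal_snp, ds$snps$snp_id)
  if (is.na(fi)) stop("unknown focal SNP: ", focal_snp)
  geno <- hard_call(ds$dosages, ds$call_probs, call_threshold)
  near <- which(ds$snps$chrom == ds$snps$chrom[fi] &
                  abs(ds$snps$pos - ds$snps$pos[fi]) <= window_bp &
                  seq_len(ncol(geno)) != fi)
  rows <- lapply(near, function(j) {
    res <- tryCatch(em_haplotypes(geno[, fi], geno[, j]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(snp_id = ds$snps$snp_id[j], chrom = ds$snps$chrom[j],
               pos = ds$snps$pos[j], r2 = res$r2, d_prime = res$d_prime,
               n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) data.frame() else out
}
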