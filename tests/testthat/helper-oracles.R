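# Shared fixtures and independent oracles used across the test files.

# Observed genotype counts of the lead SNP pair among all cases combined
# (rows: partner SNP genotypes TT/TG/GG; cols: ME SNP genotypes CC/CT/TT).
table1_counts <- matrix(c(7364, 2341, 207,
                          1581, 876, 107,
                          75, 72, 8),
                        nrow = 3, byrow = TRUE)

# expand a 3x3 count table into genotype vectors (g1 = columns, g2 = rows)
expand_table <- function(counts) {
  g1 <- rep(rep(0:2, 3), as.vector(t(counts)))
  g2 <- rep(rep(0:2, each = 3), as.vector(t(counts)))
  list(g1 = g1, g2 = g2)
}

# brute-force expected counts under independence: outer product of margins
outer_expected <- function(counts) {
  outer(rowSums(counts), colSums(counts)) / sum(counts)
}

# closed-form 2x2 logistic oracle: log cross-product ratio and Woolf SE
oracle_2x2 <- function(tab) {
  list(log_or = log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])),
       se = sqrt(sum(1 / tab)))
}

# hand DerSimonian-Laird arithmetic for a set of (y, se)
oracle_dl <- function(y, se) {
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  k <- length(y)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(pooled = sum(wr * y) / sum(wr), se = sqrt(1 / sum(wr)),
       Q = Q, tau2 = tau2, i2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0)
}

# exact case genotype-pair distribution for a two-SNP logistic disease model
# (HWE, independent loci); enumeration oracle for the simulator and power code
oracle_case_dist <- function(maf1, maf2, beta0, beta1, beta2, delta,
                             coding1 = "dominant", coding2 = "dominant") {
  hwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  code <- function(g, m) switch(m, dominant = as.numeric(g >= 1),
                                recessive = as.numeric(g == 2), additive = g)
  c1 <- code(grid$g1, coding1); c2 <- code(grid$g2, coding2)
  pg <- hwe(maf1)[grid$g1 + 1] * hwe(maf2)[grid$g2 + 1]
  pd <- plogis(beta0 + beta1 * c1 + beta2 * c2 + delta * c1 * c2)
  pi_case <- pg * pd / sum(pg * pd)
  tab <- tapply(pi_case, list(factor(c1, 0:1), factor(c2, 0:1)), sum)
  list(grid = grid, pi_case = pi_case, collapsed = matrix(tab, 2, 2),
       crude_log_or = log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])))
}

# direct haplotype counting when phase is unambiguous (no double
# heterozygotes): haplotype counts implied by each genotype pair
oracle_hap_count <- function(g1, g2) {
  stopifnot(!any(g1 == 1 & g2 == 1))
  n <- length(g1)
  hap <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in seq_len(n)) {
    a <- g1[i]; b <- g2[i]
    # each individual carries two haplotypes; with at most one heterozygous
    # locus the phase split is determined
    alle1 <- if (a == 1) c(1, 0) else rep(a / 2, 2)
    alle2 <- if (b == 1) c(1, 0) else rep(b / 2, 2)
    for (k in 1:2) {
      key <- paste0(if (alle1[k] == 1) "A" else "a",
                    if (alle2[k] == 1) "B" else "b")
      hap[key] <- hap[key] + 1
    }
  }
  hap / (2 * n)
}

# build a small multi-center case dataset directly from per-center 2x2
# exposure tables (dominant coding both SNPs); bypasses the simulator
cases_from_tables <- function(tables) {
  rows <- list()
  for (ce in names(tables)) {
    tab <- tables[[ce]]
    g1 <- rep(c(0, 0, 1, 1), as.vector(tab))
    g2 <- rep(c(0, 1, 0, 1), as.vector(tab))
    rows[[ce]] <- data.frame(center = ce, g1 = g1, g2 = g2)
  }
  do.call(rbind, rows)
}
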