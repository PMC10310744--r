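#' Hard-call genotypes from imputed dosages
#'
#' Converts fractional dosages to integer genotypes, setting genotypes with a
#' low imputation call probability to missing. A genotype is called as the
#' rounded dosage when its call probability is at least `threshold`, and `NA`
#' otherwise.
#'
#' @param dosages Numeric vector or matrix of dosages in \[0, 2\].
#' @param call_probs Numeric vector or matrix of call probabilities in
#'   \[0, 1\], same shape as `dosages`. May be `NULL`, in which case every
#'   dosage is called.
#' @param threshold Minimum call probability for a genotype to be retained
#'   (default 0.8). At `threshold = 0` hard-calling reduces to rounding; at
#'   `threshold = 1` only probability-1 genotypes survive.
#' @return Integer genotypes (0/1/2) with `NA` for filtered entries, same
#'   shape as `dosages`.
#' @export
hard_call <- function(dosages, call_probs = NULL, threshold = 0.8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  g <- round(dosages)
  g[g < 0] <- 0
  g[g > 2] <- 2
  if (!is.null(call_probs)) {
    if (length(call_probs) != length(dosages))
      stop("`call_probs` must have the same shape as `dosages`")
    g[call_probs < threshold] <- NA
  }
  storage.mode(g) <- "integer"
  g
}

#' Encode genotypes under a genetic model
#'
#' Maps minor-allele genotype counts (0/1/2) to the coded exposure used in
#' regression: dominant (carrier of the minor allele), recessive (homozygous
#' minor), or additive (allele count, identity). Missing genotypes propagate.
#'
#' @param genotypes Integer vector/matrix with values in \{0, 1, 2, NA\}.
#' @param model One of `"dominant"`, `"recessive"`, `"additive"`.
#' @return Numeric encoding with the same shape as `genotypes`.
#' @examples
#' encode_genotypes(c(0, 1, 2), "dominant")  # 0 1 1
#' encode_genotypes(c(0, 1, 2), "recessive") # 0 0 1
#' @export
encode_genotypes <- function(genotypes, model) {
  model <- match.arg(model, c("dominant", "recessive", "additive"))
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  switch(model,
    dominant  = as.numeric(genotypes >= 1),
    recessive = as.numeric(genotypes == 2),
    additive  = as.numeric(genotypes))
}

#' Read a centromere table
#'
#' Reads a BED-like, 0-based half-open table of centromere intervals
#' (columns `chrom`, `start`, `end`, `label`). The GRCh37 gap-track
#' centromeres for chr1-chr22 ship with the package.
#'
#' @param path Path to the TSV; defaults to the bundled GRCh37 table.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
read_centromeres <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "centromeres_grch37.tsv",
                        package = "coscreen", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
  tab
}

#' Chromosome arm of a position
#'
#' @param chrom Chromosome name(s) matching the centromere table.
#' @param pos 1-based position(s).
#' @param centromeres Centromere table from [read_centromeres()].
#' @return Character vector: `"p"`, `"q"`, or `NA` for positions falling
#'   inside the centromere gap (unplaceable).
#' @export
chrom_arm <- function(chrom, pos, centromeres = read_centromeres()) {
  idx <- match(chrom, centromeres$chrom)
  if (anyNA(idx)) stop("unknown chromosome(s): ",
                       paste(unique(chrom[is.na(idx)]), collapse = ", "))
  start <- centromeres$start[idx]  # 0-based half-open gap
  end <- centromeres$end[idx]
  ifelse(pos <= start, "p", ifelse(pos > end, "q", NA_character_))
}

#' Are two SNPs on different chromosome arms?
#'
#' The case-only design requires the paired SNPs to be uncorrelated in the
#' source population; restricting pairs to different chromosome arms removes
#' within-arm linkage disequilibrium as a source of spurious association.
#'
#' @param snp_a,snp_b Lists or one-row data.frames with elements `chrom` and
#'   `pos` (1-based).
#' @param centromeres Centromere table from [read_centromeres()].
#' @return `TRUE` if the SNPs lie on different chromosomes or on opposite
#'   arms of the same chromosome; `FALSE` if on the same arm; `NA` if either
#'   position falls inside the centromere gap (unplaceable, to be excluded).
#' @export
cross_arm_ok <- function(snp_a, snp_b, centromeres = read_centromeres()) {
  if (snp_a$chrom != snp_b$chrom) {
    # still flag unplaceable positions
    arms <- chrom_arm(c(snp_a$chrom, snp_b$chrom), c(snp_a$pos, snp_b$pos),
                      centromeres)
    if (anyNA(arms)) return(NA)
    return(TRUE)
  }
  arms <- chrom_arm(c(snp_a$chrom, snp_b$chrom), c(snp_a$pos, snp_b$pos),
                    centromeres)
  if (anyNA(arms)) return(NA)
  arms[1] != arms[2]
}

#' 3x3 genotype contingency table with independence-expected counts
#'
#' Cross-tabulates two genotype vectors (pairwise-complete), computes margins
#' from the cells, and the counts expected under independence
#' (`expected[i,j] = rowsum_i * colsum_j / N`). Rows index the second
#' (partner) SNP's genotypes, columns the first (main-effect) SNP's, so a
#' printed table reads partner-by-ME.
#'
#' @param g1 Integer genotypes (0/1/2, `NA` allowed) of the main-effect SNP.
#' @param g2 Integer genotypes of the partner SNP, same length.
#' @return Object of class `contingency_3x3`: list with `observed` and
#'   `expected` 3x3 matrices (rows = `g2`, columns = `g1`), `row_margins`,
#'   `col_margins`, `n`.
#' @export
contingency_table <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(g1) == 0L) stop("empty table after missingness filter")
  obs <- table(factor(g2, levels = 0:2), factor(g1, levels = 0:2))
  obs <- matrix(as.numeric(obs), 3, 3,
                dimnames = list(g2 = 0:2, g1 = 0:2))
  rm_ <- rowSums(obs); cm_ <- colSums(obs); n <- sum(obs)
  expected <- outer(rm_, cm_) / n
  dimnames(expected) <- dimnames(obs)
  structure(list(observed = obs, expected = expected,
                 row_margins = rm_, col_margins = cm_, n = n),
            class = "contingency_3x3")
}

#' @export
print.contingency_3x3 <- function(x, ...) {
  cat("3x3 genotype contingency table (n =", x$n, ")\n")
  cat("Observed (expected):\n")
  for (i in 1:3) {
    cat(sprintf("  %s\n", paste(sprintf("%6.0f (%8.2f)",
                                        x$observed[i, ], x$expected[i, ]),
                                collapse = "  ")))
  }
  invisible(x)
}

#' Crude odds ratio from a collapsed 3x3 table
#'
#' Collapses the 3x3 genotype table to 2x2 under a binary genetic model for
#' each SNP and returns the cross-product odds ratio.
#'
#' @param tab A `contingency_3x3` from [contingency_table()].
#' @param model_g1,model_g2 `"dominant"` or `"recessive"` collapse for the
#'   column (ME) and row (partner) SNP respectively.
#' @return List with the 2x2 `table` (rows: partner exposure 0/1, columns:
#'   ME exposure 0/1), `or`, `log_or`, and `se` (Woolf).
#' @export
crude_or <- function(tab, model_g1 = "dominant", model_g2 = "dominant") {
  stopifnot(inherits(tab, "contingency_3x3"))
  model_g1 <- match.arg(model_g1, c("dominant", "recessive"))
  model_g2 <- match.arg(model_g2, c("dominant", "recessive"))
  split_idx <- function(model) if (model == "dominant") list(1L, 2:3) else list(1:2, 3L)
  ci <- split_idx(model_g1)  # columns (g1)
  ri <- split_idx(model_g2)  # rows (g2)
  m <- matrix(c(sum(tab$observed[ri[[1]], ci[[1]]]),
                sum(tab$observed[ri[[1]], ci[[2]]]),
                sum(tab$observed[ri[[2]], ci[[1]]]),
                sum(tab$observed[ri[[2]], ci[[2]]])),
              2, 2, byrow = TRUE,
              dimnames = list(g2 = 0:1, g1 = 0:1))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(table = m, or = or, log_or = log(or), se = sqrt(sum(1 / m)))
}

#' Read a flat dosage TSV as a genotype dataset
#'
#' Expects columns `sample_id`, `center`, `affected`, `age_onset`, `sex`,
#' then one numeric dosage column per SNP, as written by
#' [write_cohort_tsv()]. SNP metadata is rebuilt from a companion SNP table
#' when given, otherwise left minimal.
#'
#' @param path TSV path.
#' @param snp_table Optional `data.frame` of SNP metadata with a `snp_id`
#'   column matching the dosage column names.
#' @return A `genotype_dataset`.
#' @export
read_dosage_tsv <- function(path, snp_table = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  meta_cols <- c("sample_id", "center", "affected", "age_onset", "sex")
  stopifnot(all(meta_cols %in% names(tab)))
  snp_cols <- setdiff(names(tab), meta_cols)
  dos <- as.matrix(tab[, snp_cols, drop = FALSE])
  rownames(dos) <- tab$sample_id
  if (is.null(snp_table))
    snp_table <- data.frame(snp_id = snp_cols, chrom = NA_character_,
                            pos = NA_integer_, arm = NA_character_,
                            stringsAsFactors = FALSE)
  genotype_dataset(samples = tab[, meta_cols], snps = snp_table,
                   dosages = dos, call_probs = NULL)
}

#' Read genotypes from a VCF into a genotype dataset
#'
#' Reads dosages from the `DS` FORMAT field (falling back to `GT` allele
#' counts) and per-genotype call probabilities from `GP` (maximum genotype
#' probability) when present. Center labels are recovered from the
#' `##SAMPLE_CENTER` header line written by [write_cohort_vcf()] if present,
#' otherwise set to a single center.
#'
#' @param path VCF path (plain or gzipped).
#' @return A `genotype_dataset`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ds <- NULL
  if ("DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(ds)) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(x) {
      vapply(strsplit(x, "[/|]"), function(a) sum(a != "0"), numeric(1))
    })
    ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  cp <- NULL
  if ("GP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    gp <- vcfR::extract.gt(v, element = "GP")
    cp <- apply(gp, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      max(as.numeric(strsplit(x, ",")[[1]]))
    })
  }
  dosages <- t(ds)  # samples x SNPs
  call_probs <- if (!is.null(cp)) t(cp) else NULL
  centers <- rep("center1", nrow(dosages))
  hdr <- grep("^##SAMPLE_CENTER=", v@meta, value = TRUE)
  if (length(hdr) == 1L) {
    map <- strsplit(sub("^##SAMPLE_CENTER=", "", hdr), ",")[[1]]
    kv <- do.call(rbind, strsplit(map, ":"))
    centers <- kv[match(rownames(dosages), kv[, 1]), 2]
  }
  snps <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = rownames(dosages), center = centers,
                        affected = 1L, age_onset = NA_real_, sex = NA_integer_,
                        stringsAsFactors = FALSE)
  genotype_dataset(samples = samples, snps = snps, dosages = dosages,
                   call_probs = call_probs)
}
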