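#' Construct a genotype dataset
#'
#' Container for a dosage matrix with per-sample metadata (center label,
#' affection status, age at onset, sex) and per-SNP metadata (position, arm,
#' minor allele, sample MAF). The raw material of the case-only screen.
#'
#' @param samples `data.frame` with at least `sample_id` and `center`;
#'   typically also `affected`, `age_onset`, `sex`, `subpop`.
#' @param snps `data.frame` with at least `snp_id`; typically `chrom`, `pos`,
#'   `arm`, `ref`, `alt`, `minor_allele`, `maf`.
#' @param dosages Numeric samples-by-SNPs matrix with values in \[0, 2\].
#' @param call_probs Optional samples-by-SNPs matrix of call probabilities
#'   in \[0, 1\].
#' @return Object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, snps, dosages, call_probs = NULL) {
  stopifnot(is.data.frame(samples), is.data.frame(snps), is.matrix(dosages))
  stopifnot(nrow(dosages) == nrow(samples), ncol(dosages) == nrow(snps))
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (!is.null(call_probs)) {
    stopifnot(all(dim(call_probs) == dim(dosages)))
    if (any(call_probs < 0 | call_probs > 1, na.rm = TRUE))
      stop("call probabilities must lie in [0, 1]")
  }
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- snps$snp_id
  if (!is.null(call_probs)) dimnames(call_probs) <- dimnames(dosages)
  structure(list(samples = samples, snps = snps, dosages = dosages,
                 call_probs = call_probs),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "SNPs\n")
  if ("center" %in% names(x$samples)) {
    tab <- table(x$samples$center)
    cat("centers:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  }
  if ("affected" %in% names(x$samples))
    cat("affected:", sum(x$samples$affected == 1), "/",
        nrow(x$samples), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Subset a genotype dataset by samples and/or SNPs
#'
#' @param ds A `genotype_dataset`.
#' @param samples Logical/integer index into rows (samples).
#' @param snps Logical/integer index into columns (SNPs).
#' @return The subsetted `genotype_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, snps = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(samples)) samples <- seq_len(nrow(ds$dosages))
  if (is.null(snps)) snps <- seq_len(ncol(ds$dosages))
  genotype_dataset(
    samples = ds$samples[samples, , drop = FALSE],
    snps = ds$snps[snps, , drop = FALSE],
    dosages = ds$dosages[samples, snps, drop = FALSE],
    call_probs = if (!is.null(ds$call_probs))
      ds$call_probs[samples, snps, drop = FALSE])
}

#' Write a cohort as a flat dosage TSV
#'
#' One row per sample: `sample_id`, `center`, `affected`, `age_onset`,
#' `sex`, then one dosage column per SNP. A `# seed:` comment line records
#' the generating seed when available.
#'
#' @param ds A `genotype_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  meta <- ds$samples[, intersect(c("sample_id", "center", "affected",
                                   "age_onset", "sex"), names(ds$samples)),
                     drop = FALSE]
  for (col in setdiff(c("affected", "age_onset", "sex"), names(meta)))
    meta[[col]] <- NA
  out <- cbind(meta[, c("sample_id", "center", "affected", "age_onset", "sex")],
               as.data.frame(ds$dosages, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(ds, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort as a VCF with DS and GP fields
#'
#' Emits a minimal VCF 4.2 with `GT:DS:GP` per genotype: `GT` is the rounded
#' dosage, `DS` the fractional dosage, and `GP` a genotype-probability triple
#' whose maximum equals the stored call probability. Center labels are
#' preserved in a `##SAMPLE_CENTER` header line.
#'
#' @param ds A `genotype_dataset`.
#' @param path Output path (`.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n_snp <- ncol(ds$dosages); n_samp <- nrow(ds$dosages)
  snps <- ds$snps
  ref <- if ("ref" %in% names(snps)) snps$ref else rep("A", n_snp)
  alt <- if ("alt" %in% names(snps)) snps$alt else rep("G", n_snp)
  chrom <- if ("chrom" %in% names(snps)) snps$chrom else rep("chr1", n_snp)
  pos <- if ("pos" %in% names(snps)) snps$pos else seq_len(n_snp)
  cp <- ds$call_probs
  if (is.null(cp)) cp <- matrix(1, n_samp, n_snp)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
            paste0("##FORMAT=<ID=GP,Number=G,Type=Float,",
                   "Description=\"Genotype probabilities\">"),
            paste0("##SAMPLE_CENTER=",
                   paste(ds$samples$sample_id, ds$samples$center,
                         sep = ":", collapse = ",")))
  seed <- attr(ds, "seed")
  if (!is.null(seed)) meta <- c(meta, sprintf("##simulation_seed=%d", seed))
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_snp), function(j) {
    g <- pmin(pmax(round(ds$dosages[, j]), 0), 2)
    p <- cp[, j]
    rest <- (1 - p) / 2
    gp <- matrix(rest, n_samp, 3)
    gp[cbind(seq_len(n_samp), g + 1)] <- p
    cells <- sprintf("%s:%.4g:%.4g,%.4g,%.4g",
                     gt_codes[g + 1], ds$dosages[, j],
                     gp[, 1], gp[, 2], gp[, 3])
    paste(c(chrom[j], pos[j], snps$snp_id[j], ref[j], alt[j], ".", "PASS",
            ".", "GT:DS:GP", cells), collapse = "\t")
  }, character(1))
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", ds$samples$sample_id), collapse = "\t")
  con <- gzfile(path, "w")
  writeLines(c(meta, header, body), con)
  close(con)
  invisible(path)
}
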