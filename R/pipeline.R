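#' Configuration of an end-to-end screening run
#'
#' @param sim A [sim_config()] to generate the input cohort, or `NULL` when
#'   reading genotypes from `input_path`.
#' @param input_path Path to a VCF or flat dosage TSV (used when `sim` is
#'   `NULL`).
#' @param me_snps Character vector of ME SNP ids (at least one). Default
#'   (with `sim`): the configured ME SNP.
#' @param model_combos `data.frame` with columns `model_g1`
#'   (dominant/recessive) and `model_g2` (dominant/additive); default all
#'   four combinations.
#' @param screen A [screen_config()].
#' @param n_pcs Principal components per center (default 10).
#' @param call_threshold Imputation-probability hard-call threshold
#'   (default 0.8).
#' @param early_onset Logical: restrict to cases with age at onset below
#'   `early_onset_cutoff` (PCs are recomputed within the subgroup).
#' @param early_onset_cutoff Years (default 50; must be positive).
#' @param out_dir Output directory for TSVs and the manifest; `NULL` skips
#'   writing.
#' @param seed Seed for any randomness (overrides `sim$seed` when `sim` is
#'   given).
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = NULL, input_path = NULL, me_snps = NULL,
                       model_combos = NULL, screen = screen_config(),
                       n_pcs = 10L, call_threshold = 0.8,
                       early_onset = FALSE, early_onset_cutoff = 50,
                       out_dir = NULL, seed = 1L) {
  if (is.null(sim) && is.null(input_path))
    stop("either `sim` or `input_path` must be given")
  if (early_onset_cutoff <= 0) stop("early-onset cutoff must be positive")
  if (is.null(model_combos))
    model_combos <- expand.grid(model_g1 = c("dominant", "recessive"),
                                model_g2 = c("dominant", "additive"),
                                stringsAsFactors = FALSE)
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, input_path = input_path, me_snps = me_snps,
                 model_combos = model_combos, screen = screen,
                 n_pcs = as.integer(n_pcs), call_threshold = call_threshold,
                 early_onset = early_onset,
                 early_onset_cutoff = early_onset_cutoff,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the case-only screen end to end
#'
#' Loads or simulates the case cohort, hard-calls genotypes, optionally
#' restricts to early-onset cases, enumerates all cross-arm (ME SNP,
#' partner SNP) pairs under the configured model combinations, fits the
#' per-center case-only regressions with PC adjustment, runs the two-stage
#' random-effects screen, and (optionally) writes `hits.tsv`, `forest.tsv`,
#' `locuszoom.tsv` and a JSON `manifest` that reconciles every exclusion.
#'
#' @param config A [run_config()].
#' @return List of class `run_result`: `screen` (a `screen_result`),
#'   `center_results`, `cases`, `manifest`, and output paths when written.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("coscreen")),
                   seed = config$seed,
                   thresholds = unclass(config$screen))
  if (!is.null(config$sim)) {
    sim <- config$sim
    cohort <- simulate_cohort(sim)
    cases <- cohort$cases
    manifest$input <- "simulated"
    me_snps <- config$me_snps
    if (is.null(me_snps)) me_snps <- cases$snps$snp_id[sim$me_snp_index]
  } else {
    cases <- if (grepl("\\.vcf(\\.gz)?$", config$input_path))
      read_genotypes_vcf(config$input_path)
    else read_dosage_tsv(config$input_path)
    manifest$input <- config$input_path
    me_snps <- config$me_snps
    if (is.null(me_snps)) stop("`me_snps` must be given for file input")
  }
  if (!all(me_snps %in% cases$snps$snp_id))
    stop("unknown ME SNP id(s): ",
         paste(setdiff(me_snps, cases$snps$snp_id), collapse = ", "))
  n_input <- nrow(cases$dosages)
  manifest$samples <- list(input = n_input, kept = n_input, excluded = 0L)
  if (config$early_onset) {
    keep <- !is.na(cases$samples$age_onset) &
      cases$samples$age_onset < config$early_onset_cutoff
    manifest$samples$kept <- sum(keep)
    manifest$samples$excluded <- n_input - sum(keep)
    manifest$samples$exclusion_reason <-
      sprintf("age at onset >= %g or missing", config$early_onset_cutoff)
    if (!any(keep))
      stop("empty subgroup: no cases with age at onset < ",
           config$early_onset_cutoff)
    cases <- subset_dataset(cases, samples = keep)
  }
  # enumerate cross-arm pairs
  cen <- read_centromeres()
  arms <- chrom_arm(cases$snps$chrom, cases$snps$pos, cen)
  pair_rows <- list(); excluded_pairs <- list()
  for (me in me_snps) {
    mi <- match(me, cases$snps$snp_id)
    for (pi in seq_len(nrow(cases$snps))) {
      if (pi == mi) next
      partner <- cases$snps$snp_id[pi]
      if (is.na(arms[mi]) || is.na(arms[pi])) {
        excluded_pairs[[length(excluded_pairs) + 1L]] <-
          data.frame(me_snp = me, partner_snp = partner,
                     reason = "unplaceable: inside centromere gap")
        next
      }
      same_arm <- cases$snps$chrom[mi] == cases$snps$chrom[pi] &&
        arms[mi] == arms[pi]
      if (same_arm) {
        excluded_pairs[[length(excluded_pairs) + 1L]] <-
          data.frame(me_snp = me, partner_snp = partner,
                     reason = "same chromosome arm")
        next
      }
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(me_snp = me, partner_snp = partner)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("zero eligible pairs after the cross-arm filter")
  manifest$pairs <- list(
    candidate = nrow(cases$snps) * length(me_snps) - length(me_snps),
    kept = nrow(pairs), excluded = length(excluded_pairs))
  pairs <- merge(pairs, config$model_combos)
  center_results <- run_center_fits(cases, pairs, n_pcs = config$n_pcs,
                                    call_threshold = config$call_threshold)
  screen <- two_stage_screen(center_results, config$screen)
  manifest$fits <- list(total = nrow(center_results),
                        converged = sum(center_results$converged),
                        not_converged = sum(!center_results$converged))
  manifest$results <- list(stage1 = nrow(screen$stage1),
                           stage2 = nrow(screen$stage2),
                           hits = nrow(screen$hits))
  out <- list(screen = screen, center_results = center_results,
              cases = cases, manifest = manifest,
              excluded_pairs = do.call(rbind, excluded_pairs))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      hits = file.path(config$out_dir, "hits.tsv"),
      forest = file.path(config$out_dir, "forest.tsv"),
      locuszoom = file.path(config$out_dir, "locuszoom.tsv"),
      manifest = file.path(config$out_dir, "manifest.json"))
    utils::write.table(screen$hits, paths$hits, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    forest <- .forest_for_hits(screen, center_results)
    utils::write.table(forest, paths$forest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lz <- .locuszoom_table(screen, cases)
    utils::write.table(lz, paths$locuszoom, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out$paths <- paths
  }
  class(out) <- "run_result"
  out
}

.forest_for_hits <- function(screen, center_results) {
  if (nrow(screen$hits) == 0L)
    return(data.frame(me_snp = character(0), partner_snp = character(0),
                      label = character(0), type = character(0),
                      or = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0)))
  rows <- lapply(seq_len(nrow(screen$hits)), function(i) {
    h <- screen$hits[i, ]
    sub <- center_results[
      center_results$me_snp == h$me_snp &
        center_results$partner_snp == h$partner_snp &
        center_results$model_g1 == h$model_g1 &
        center_results$model_g2 == h$model_g2, , drop = FALSE]
    sf <- stability_filter(sub)
    fd <- forest_data(sf$meta, sf$kept, sf$excluded)
    cbind(me_snp = h$me_snp, partner_snp = h$partner_snp,
          model_g1 = h$model_g1, model_g2 = h$model_g2, fd)
  })
  do.call(rbind, rows)
}

.locuszoom_table <- function(screen, cases) {
  if (nrow(screen$stage2) == 0L)
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), neg_log10_p = numeric(0)))
  best <- stats::aggregate(p ~ partner_snp, screen$stage2, min)
  idx <- match(best$partner_snp, cases$snps$snp_id)
  data.frame(snp_id = best$partner_snp, chrom = cases$snps$chrom[idx],
             pos = cases$snps$pos[idx], neg_log10_p = -log10(best$p))
}

#' @export
print.run_result <- function(x, ...) {
  cat("case-only screen run (seed", x$manifest$seed, ")\n")
  cat("  samples kept:", x$manifest$samples$kept, "/",
      x$manifest$samples$input, "\n")
  cat("  cross-arm pairs:", x$manifest$pairs$kept, "(excluded",
      x$manifest$pairs$excluded, ")\n")
  print(x$screen)
  invisible(x)
}
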