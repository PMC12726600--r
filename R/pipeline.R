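#' Pipeline configuration
#'
#' Collects every stage threshold of the analysis workflow with its standard
#' default: GP masking at 0.90, site missingness 0.10, sample missingness
#' 0.15, extreme-ratio thresholds 30/40/12 with the second family filtered at
#' half thresholds (scale 0.5), TDT MAF filter 0.15 and family-wise alpha
#' 0.05.
#'
#' @param sim a [sim_config()] describing the synthetic study (also carries
#'   the master seed).
#' @param n_offspring,penetrance,family_ids study design, see
#'   [simulate_study()].
#' @param platforms which platforms to analyse (`"array"`, `"imputed"`).
#' @param gp_threshold GP masking threshold for the imputed platform.
#' @param site_max_missing site-level missingness ceiling (array platform).
#' @param sample_max_missing sample-level missingness cutoff (>= removed).
#' @param ratio_thresholds a [filter_config()] for the anchor family.
#' @param family2_scale threshold scale for the later (smaller) families.
#' @param maf_min,alpha TDT settings.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_offspring = c(190L, 95L),
                            penetrance = list(c(0.50, 0.05), c(0.95, 0.55)),
                            family_ids = c("F1", "F2"),
                            platforms = c("array", "imputed"),
                            gp_threshold = 0.90,
                            site_max_missing = 0.10,
                            sample_max_missing = 0.15,
                            ratio_thresholds = filter_config(),
                            family2_scale = 0.5,
                            maf_min = 0.15,
                            alpha = 0.05) {
  stopifnot(inherits(sim, "sim_config"), inherits(ratio_thresholds, "filter_config"))
  structure(list(sim = sim, n_offspring = n_offspring,
                 penetrance = penetrance, family_ids = family_ids,
                 platforms = platforms,
                 gp_threshold = gp_threshold,
                 site_max_missing = site_max_missing,
                 sample_max_missing = sample_max_missing,
                 ratio_thresholds = ratio_thresholds,
                 family2_scale = family2_scale,
                 maf_min = maf_min, alpha = alpha),
            class = "pipeline_config")
}

# QC one platform across families: anchor-family site filtering + ratio
# filter, later families extracted on the anchor site list with parental
# masking at their own flagged sites, then merge, sample filter and TDT.
qc_and_tdt <- function(matrices, pedigrees, phenotypes, cfg,
                       gp_mask = FALSE, site_max_missing = NULL,
                       drop_monomorphic = TRUE) {
  log <- list()
  if (gp_mask)
    matrices <- lapply(matrices, mask_low_gp, threshold = cfg$gp_threshold)
  # anchor family QC
  mm <- mendel_mask(matrices[[1]], pedigrees[[1]])
  log$mendel_errors_family1 <- mm$n_errors
  sf <- site_filter(mm$matrix, max_missing_fraction = site_max_missing,
                    drop_monomorphic = drop_monomorphic)
  log$site_filter_removed <- sf$removed
  qc1 <- family_ratio_qc(sf$matrix, pedigrees[[1]], cfg$ratio_thresholds)
  keep <- qc1$decision == "retain"
  log$ratio_dropped_family1 <- sum(!keep)
  anchor <- subset_sites(sf$matrix, keep)
  qc_reports <- list(qc1)
  merged_in <- list(anchor)
  # later families: extract on anchor sites, flag, parent-mask
  if (length(matrices) > 1) {
    thr2 <- cfg$ratio_thresholds
    thr2$scale <- thr2$scale * cfg$family2_scale
    for (i in seq_along(matrices)[-1]) {
      m2 <- extract_sites(matrices[[i]], anchor$sites)
      qc2 <- family_ratio_qc(m2, pedigrees[[i]], thr2)
      flagged <- which(qc2$decision == "drop")
      log[[paste0("ratio_flagged_family", i)]] <- length(flagged)
      m2 <- mask_parents_for_flagged(m2, pedigrees[[i]], flagged)
      if (!is.null(m2$gp)) m2$gp <- NULL
      qc_reports[[i]] <- qc2
      merged_in[[i]] <- m2
    }
  }
  merged_in[[1]]$gp <- NULL
  merged <- merge_families(merged_in)
  smf <- sample_missingness_filter(merged, cfg$sample_max_missing)
  log$samples_excluded <- smf$excluded
  ped <- do.call(rbind, pedigrees)
  tdt <- run_tdt(smf$matrix, ped, phenotypes,
                 maf_min = cfg$maf_min, alpha = cfg$alpha)
  list(matrix = smf$matrix, tdt = tdt, qc_reports = qc_reports, log = log)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates the two-family study, then for each requested platform runs the
#' QC chain (GP masking for the imputed platform, Mendelian masking and site
#' filters on the anchor family, extreme-ratio filtering, extraction of later
#' families on the anchor site list, parental masking at their flagged sites,
#' family merging, sample-missingness exclusion) and the TDT; finally
#' compares the imputed call set against the array call set (when both are
#' present) and assembles the summary tables. Deterministic under the master
#' seed in `config$sim`.
#'
#' @param config a [pipeline_config()].
#' @return a result bundle: `study`, per-platform `array` / `imputed`
#'   elements (each with `matrix`, `tdt`, `qc_reports`, `log`), `accuracy`
#'   (imputed-vs-array [accuracy_report()]), `phenotype_summary`,
#'   `significant_summary` and `qtl_truth` (chromosome/position of the
#'   simulated risk locus).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_study(config$sim, n_offspring = config$n_offspring,
                          penetrance = config$penetrance,
                          family_ids = config$family_ids,
                          platforms = config$platforms)
  pedigrees <- lapply(study, function(x) x$family$pedigree)
  phenotypes <- do.call(rbind, lapply(study, function(x) x$family$phenotypes))
  out <- list(study = study)
  if ("array" %in% config$platforms)
    out$array <- qc_and_tdt(lapply(study, `[[`, "array"), pedigrees,
                            phenotypes, config,
                            site_max_missing = config$site_max_missing)
  if ("imputed" %in% config$platforms)
    out$imputed <- qc_and_tdt(lapply(study, `[[`, "imputed"), pedigrees,
                              phenotypes, config, gp_mask = TRUE)
  if (all(c("array", "imputed") %in% config$platforms)) {
    truth <- merge_families(lapply(study, `[[`, "array"))
    test <- merge_families(lapply(lapply(study, `[[`, "imputed"),
                                  mask_low_gp, threshold = config$gp_threshold))
    out$accuracy <- accuracy_report(truth, test)
  }
  pheno_cat <- do.call(rbind, lapply(study, function(x) {
    ph <- x$family$phenotypes
    ok <- !is.na(ph$code)
    data.frame(family = x$family$family_id,
               individual = ph$individual[ok],
               category = c("Female", "Male")[ph$code[ok]],
               stringsAsFactors = FALSE)
  }))
  out$phenotype_summary <- phenotype_summary(pheno_cat)
  runs <- Filter(Negate(is.null),
                 list(array = out$array$tdt, imputed = out$imputed$tdt))
  if (length(runs))
    out$significant_summary <- do.call(
      significant_snp_summary, c(unname(runs), list(labels = names(runs))))
  fo <- study[[1]]$family$founders
  out$qtl_truth <- list(chrom = fo$sites$chrom[fo$qtl_index],
                        pos = fo$sites$pos[fo$qtl_index])
  out
}

#' Per-family phenotype summary table
#'
#' Counts and one-decimal percentages of each phenotype category per family,
#' with a totals row, in the shape of a dissection-summary table.
#'
#' @param phenotypes data.frame with columns `family` and `category` (one row
#'   per individual; extra columns ignored). Categories may include, e.g.,
#'   Male, Female, Intersex, Immature.
#' @return data.frame `(family, category, count, percentage)` including a
#'   `"Total"` row per family.
#' @export
phenotype_summary <- function(phenotypes) {
  if (nrow(phenotypes) == 0) stop("empty phenotype input")
  out <- do.call(rbind, lapply(split(phenotypes, phenotypes$family), function(d) {
    tab <- table(d$category)
    data.frame(family = d$family[1],
               category = c(names(tab), "Total"),
               count = c(as.vector(tab), sum(tab)),
               percentage = round(c(100 * as.vector(tab) / sum(tab), 100), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-chromosome summary of significant SNPs
#'
#' Counts significant SNPs per chromosome for one or two TDT runs (e.g. two
#' genotyping platforms); with two runs a shared-SNP column reports sites
#' significant in both, matched on chromosome, position and alleles.
#'
#' @param run_a a `tdt_result` (or its `results` data.frame).
#' @param run_b optional second run.
#' @param labels column labels for the runs.
#' @return data.frame with one row per chromosome carrying at least one
#'   significant SNP (empty, with headers, when there is none).
#' @export
significant_snp_summary <- function(run_a, run_b = NULL,
                                    labels = c("run_a", "run_b")) {
  get_sig <- function(r) {
    d <- if (inherits(r, "tdt_result")) r$results else r
    d[d$significant, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  }
  sa <- get_sig(run_a)
  chroms <- unique(sa$chrom)
  if (is.null(run_b)) {
    out <- data.frame(chrom = chroms,
                      n = vapply(chroms, function(ch) sum(sa$chrom == ch), 0L))
    names(out)[2] <- labels[1]
    rownames(out) <- NULL
    return(out)
  }
  sb <- get_sig(run_b)
  chroms <- unique(c(chroms, sb$chrom))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  shared <- intersect(key(sa), key(sb))
  out <- data.frame(
    chrom = chroms,
    a = vapply(chroms, function(ch) sum(sa$chrom == ch), 0L),
    b = vapply(chroms, function(ch) sum(sb$chrom == ch), 0L),
    shared = vapply(chroms, function(ch)
      sum(startsWith(shared, paste0(ch, " "))), 0L))
  names(out)[2:3] <- labels
  rownames(out) <- NULL
  out
}
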