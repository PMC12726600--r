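#' Tabulate genotype matches and mismatches between two call sets
#'
#' Intersects the two matrices on shared samples and on shared sites with
#' identical ref/alt alleles (allele-mismatched shared sites are dropped with
#' a warning), drops pairs with a missing call on either side, and classifies
#' every remaining pair by the TRUTH genotype into the six discordance
#' counts: `e_rr`, `e_ra`, `e_aa` (mismatches at truth hom-ref, het, hom-alt)
#' and `m_rr`, `m_ra`, `m_aa` (matches).
#'
#' @param truth the reference call set (e.g. array genotypes), a
#'   [genotype_matrix()] or an integer genotype vector.
#' @param test the call set under evaluation (same type as `truth`).
#' @return an object of class `discordance_counts` (a named list of the six
#'   counts, with attribute `n_pairs`).
#' @export
tabulate_matches <- function(truth, test) {
  if (inherits(truth, "genotype_matrix")) {
    stopifnot(inherits(test, "genotype_matrix"))
    samples <- intersect(truth$sample_ids, test$sample_ids)
    kt <- site_keys(truth); ks <- site_keys(test)
    shared <- intersect(kt, ks)
    if (!length(samples) || !length(shared))
      stop("empty intersection of samples/sites")
    it <- match(shared, kt); is_ <- match(shared, ks)
    ok <- truth$sites$ref[it] == test$sites$ref[is_] &
      truth$sites$alt[it] == test$sites$alt[is_]
    if (any(!ok)) {
      warning(sum(!ok), " shared site(s) dropped for ref/alt mismatch")
      it <- it[ok]; is_ <- is_[ok]
    }
    if (!length(it)) stop("empty intersection of samples/sites")
    tv <- truth$geno[match(samples, truth$sample_ids), it, drop = FALSE]
    sv <- test$geno[match(samples, test$sample_ids), is_, drop = FALSE]
  } else {
    if (length(truth) != length(test))
      stop("truth and test vectors must have equal length")
    tv <- truth; sv <- test
  }
  keep <- !is.na(tv) & !is.na(sv)
  tv <- tv[keep]; sv <- sv[keep]
  if (!length(tv)) stop("no jointly non-missing genotype pairs")
  match_ <- tv == sv
  counts <- list(
    e_rr = sum(!match_ & tv == 0L), e_ra = sum(!match_ & tv == 1L),
    e_aa = sum(!match_ & tv == 2L),
    m_rr = sum(match_ & tv == 0L), m_ra = sum(match_ & tv == 1L),
    m_aa = sum(match_ & tv == 2L))
  structure(counts, n_pairs = length(tv), class = "discordance_counts")
}

#' Non-reference discordance (NRD)
#'
#' `NRD = 100 * (e_rr + e_ra + e_aa) / (e_rr + e_ra + e_aa + m_ra + m_aa)`.
#' Concordant homozygous-reference pairs (`m_rr`) are intentionally excluded
#' from the denominator, so the metric emphasizes errors at variant-carrying
#' genotypes. Undefined (returned as `NA` with a warning) when the
#' denominator is zero, i.e. with no non-reference evidence at all.
#'
#' @param counts a `discordance_counts` object or named list/vector with the
#'   six fields.
#' @return percentage in `[0, 100]`, or `NA` if undefined.
#' @export
nrd <- function(counts) {
  k <- as.list(counts)
  e <- k$e_rr + k$e_ra + k$e_aa
  den <- e + k$m_ra + k$m_aa
  if (den == 0) {
    warning("NRD undefined: no mismatches and no non-reference matches")
    return(NA_real_)
  }
  100 * e / den
}

#' Genotype concordance
#'
#' Percentage of genotype pairs identical between the two call sets, over all
#' jointly non-missing pairs.
#'
#' @inheritParams nrd
#' @return percentage in `[0, 100]`.
#' @export
concordance <- function(counts) {
  k <- as.list(counts)
  total <- k$e_rr + k$e_ra + k$e_aa + k$m_rr + k$m_ra + k$m_aa
  if (total == 0) stop("concordance undefined: zero genotype pairs")
  100 * (k$m_rr + k$m_ra + k$m_aa) / total
}

#' Squared correlation of alternative-allele dosages
#'
#' Square of the Pearson correlation between the ALT-allele dosages (0/1/2)
#' of the two call sets over jointly non-missing pairs, pooled across all
#' samples and sites (one global value). Invariant to a simultaneous allele
#' flip of both call sets.
#'
#' @param truth,test [genotype_matrix()] objects or integer genotype vectors.
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) if either side has
#'   zero variance or fewer than two pairs remain.
#' @export
dosage_r2 <- function(truth, test) {
  if (inherits(truth, "genotype_matrix")) {
    samples <- intersect(truth$sample_ids, test$sample_ids)
    shared <- intersect(site_keys(truth), site_keys(test))
    if (!length(samples) || !length(shared)) stop("empty intersection")
    tv <- truth$geno[match(samples, truth$sample_ids),
                     match(shared, site_keys(truth)), drop = FALSE]
    sv <- test$geno[match(samples, test$sample_ids),
                    match(shared, site_keys(test)), drop = FALSE]
  } else {
    tv <- truth; sv <- test
  }
  keep <- !is.na(tv) & !is.na(sv)
  tv <- as.numeric(tv[keep]); sv <- as.numeric(sv[keep])
  if (length(tv) < 2 || stats::var(tv) == 0 || stats::var(sv) == 0) {
    warning("dosage r2 undefined: fewer than 2 pairs or zero variance")
    return(NA_real_)
  }
  stats::cor(tv, sv)^2
}

#' Full accuracy report for an imputed call set against truth
#'
#' Computes concordance, NRD and dosage r-squared overall and, optionally,
#' within minor-allele-frequency bins (MAF taken from the truth call set).
#'
#' @param truth,test [genotype_matrix()] objects.
#' @param maf_bins optional vector of MAF bin edges (see [maf_bin_report()]).
#' @return a data.frame with one overall row (and one row per MAF bin when
#'   `maf_bins` is given): `stratum`, `n_pairs`, `concordance`, `nrd`, `r2`.
#' @export
accuracy_report <- function(truth, test, maf_bins = NULL) {
  one <- function(tr, te, label) {
    cts <- tabulate_matches(tr, te)
    data.frame(stratum = label, n_pairs = attr(cts, "n_pairs"),
               concordance = concordance(cts),
               nrd = suppressWarnings(nrd(cts)),
               r2 = suppressWarnings(dosage_r2(tr, te)),
               stringsAsFactors = FALSE)
  }
  out <- one(truth, test, "overall")
  if (!is.null(maf_bins)) {
    maf <- site_maf(truth)
    bin <- cut(maf, maf_bins, include.lowest = TRUE, right = TRUE)
    for (lv in levels(bin)) {
      j <- which(!is.na(bin) & bin == lv)
      if (!length(j)) next
      out <- rbind(out, one(subset_sites(truth, j),
                            extract_sites(test, truth$sites[j, , drop = FALSE]),
                            lv))
    }
  }
  out
}

#' Bin sites by minor allele frequency
#'
#' Sites are binned by MAF with closed right boundaries and the first
#' boundary inclusive, so with edges `c(0, 0.05, 0.5)` the first bin is
#' "MAF of 0.05 or less".
#'
#' @param x a [genotype_matrix()] or a numeric vector of per-site MAFs.
#' @param bin_edges increasing vector of bin edges (default `c(0, 0.05, 0.5)`).
#' @return data.frame `(bin, count, percentage)`; percentages sum to 100.
#' @export
maf_bin_report <- function(x, bin_edges = c(0, 0.05, 0.5)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin edges must be increasing")
  maf <- if (inherits(x, "genotype_matrix")) site_maf(x) else x
  maf <- maf[!is.na(maf)]
  bin <- cut(maf, bin_edges, include.lowest = TRUE, right = TRUE)
  counts <- as.vector(table(bin))
  data.frame(bin = levels(bin), count = counts,
             percentage = bin_percentages(counts),
             stringsAsFactors = FALSE)
}

#' Percentages of a count vector
#'
#' @param counts non-negative counts.
#' @return `100 * counts / sum(counts)`.
#' @export
bin_percentages <- function(counts) {
  if (sum(counts) == 0) stop("zero total count")
  100 * counts / sum(counts)
}

#' Compare two call-set panels
#'
#' Emits one row per panel plus an A-minus-B difference row for each column,
#' as used when benchmarking an updated haplotype reference panel against its
#' predecessor.
#'
#' @param stats_a,stats_b named lists with `n_snps`,
#'   `n_snps_gt10pct_missing` and `overall_missing_pct`.
#' @param labels row labels for the two panels.
#' @return data.frame with rows `labels[1]`, `labels[2]` and
#'   `"<A> - <B>"`.
#' @export
panel_comparison_report <- function(stats_a, stats_b,
                                    labels = c("A", "B")) {
  need <- c("n_snps", "n_snps_gt10pct_missing", "overall_missing_pct")
  for (s in list(stats_a, stats_b))
    if (!all(need %in% names(s))) stop("panel stats need fields: ",
                                       paste(need, collapse = ", "))
  a <- unlist(stats_a[need]); b <- unlist(stats_b[need])
  out <- rbind(a, b, a - b)
  rownames(out) <- NULL
  data.frame(panel = c(labels, paste(labels[1], "-", labels[2])),
             as.data.frame(out), stringsAsFactors = FALSE)
}

#' Transition/transversion ratio of a site list
#'
#' Transitions are A<->G and C<->T substitutions; everything else among
#' single-base ref/alt pairs is a transversion. Records whose ref or alt is
#' not a single base (indels) are excluded and counted.
#'
#' @param sites data.frame `(ref, alt)` or a [genotype_matrix()].
#' @return list with `ratio` (`NA` with a warning when there are zero
#'   transversions), `n_transitions`, `n_transversions`, `n_excluded`.
#' @export
tstv_ratio <- function(sites) {
  s <- if (inherits(sites, "genotype_matrix")) sites$sites else sites
  snp <- nchar(s$ref) == 1 & nchar(s$alt) == 1 &
    s$ref %in% c("A", "C", "G", "T") & s$alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!snp)
  pair <- paste0(pmin(s$ref[snp], s$alt[snp]), pmax(s$ref[snp], s$alt[snp]))
  n_ts <- sum(pair %in% c("AG", "CT"))
  n_tv <- sum(!(pair %in% c("AG", "CT")))
  ratio <- if (n_tv == 0) {
    warning("Ts/Tv undefined: zero transversions")
    NA_real_
  } else n_ts / n_tv
  list(ratio = ratio, n_transitions = n_ts, n_transversions = n_tv,
       n_excluded = n_excluded)
}
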