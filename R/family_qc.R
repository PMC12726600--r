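#' Thresholds for the extreme-genotype-ratio segregation filter
#'
#' At a site where both parents are heterozygous, every one of the three
#' offspring genotype classes must exceed `min_each_both_het`; where exactly
#' one parent is heterozygous, the het and major-homozygote classes must each
#' exceed `min_het_and_majhom_one_het` while the minor-homozygote class
#' (which Mendelian transmission forbids) must stay below
#' `max_minorhom_one_het`. `scale` multiplies all three constants, so a
#' smaller family can be filtered with, e.g., `scale = 0.5` (thresholds
#' reduced to half); inequalities stay strict.
#'
#' @param min_each_both_het,min_het_and_majhom_one_het,max_minorhom_one_het
#'   positive counts (defaults 30, 40, 12).
#' @param scale positive multiplier applied to all three thresholds.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_each_both_het = 30,
                          min_het_and_majhom_one_het = 40,
                          max_minorhom_one_het = 12,
                          scale = 1) {
  if (min_each_both_het <= 0 || min_het_and_majhom_one_het <= 0 ||
      max_minorhom_one_het <= 0 || scale <= 0)
    stop("thresholds and scale must be positive")
  structure(list(min_each_both_het = min_each_both_het,
                 min_het_and_majhom_one_het = min_het_and_majhom_one_het,
                 max_minorhom_one_het = max_minorhom_one_het,
                 scale = scale),
            class = "filter_config")
}

# 3x3x3 lookup: is offspring genotype o possible given parents s, d?
# (indices are code + 1). A parent's gametes: 0 -> {0}, 1 -> {0,1}, 2 -> {1}.
mendel_table <- function() {
  gametes <- list(0L, c(0L, 1L), 1L)
  tab <- array(FALSE, dim = c(3, 3, 3))
  for (s in 0:2) for (d in 0:2) for (o in 0:2)
    tab[s + 1, d + 1, o + 1] <-
      o %in% outer(gametes[[s + 1]], gametes[[d + 1]], "+")
  tab
}

#' Mask Mendelian-inconsistent offspring genotypes
#'
#' For every parent-parent-offspring trio and site where both parental
#' genotypes are non-missing, an offspring genotype impossible under
#' Mendelian transmission is set to missing. By default only the offspring
#' call is masked (parents are shared across all sibs, so masking them would
#' cascade); `scope = "trio"` masks all three. Idempotent: a second pass
#' finds zero errors.
#'
#' @param x a [genotype_matrix()].
#' @param pedigree data.frame `(family, individual, sire, dam)`; rows with a
#'   non-missing sire and dam define the trios. Parent ids must resolve
#'   against the matrix.
#' @param scope `"offspring"` (default) or `"trio"`.
#' @return list with `matrix` (masked) and `n_errors` (genotypes found
#'   Mendelian-inconsistent).
#' @export
mendel_mask <- function(x, pedigree, scope = c("offspring", "trio")) {
  stopifnot(inherits(x, "genotype_matrix"))
  scope <- match.arg(scope)
  tab <- mendel_table()
  off <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), , drop = FALSE]
  ids <- unique(c(off$individual, off$sire, off$dam))
  bad_ids <- setdiff(ids, x$sample_ids)
  if (length(bad_ids)) stop("pedigree ids not in matrix: ",
                            paste(bad_ids, collapse = ", "))
  n_err <- 0L
  for (i in seq_len(nrow(off))) {
    s <- x$geno[off$sire[i], ]
    d <- x$geno[off$dam[i], ]
    o <- x$geno[off$individual[i], ]
    known <- !is.na(s) & !is.na(d) & !is.na(o)
    bad <- known
    bad[known] <- !tab[cbind(s[known] + 1L, d[known] + 1L, o[known] + 1L)]
    if (any(bad)) {
      n_err <- n_err + sum(bad)
      x$geno[off$individual[i], bad] <- NA_integer_
      if (scope == "trio") {
        x$geno[off$sire[i], bad] <- NA_integer_
        x$geno[off$dam[i], bad] <- NA_integer_
      }
    }
  }
  list(matrix = x, n_errors = n_err)
}

#' Orient each site to its minor allele and tally offspring genotypes
#'
#' Determines, per site, which allele is the minor allele A1 among the given
#' samples (ties broken deterministically: the ALT allele is A1 when both
#' alleles are equally frequent) and tallies genotype classes
#' A1A1 / A1A2 / A2A2 over `count_samples`.
#'
#' @param x a [genotype_matrix()].
#' @param samples sample ids whose allele frequencies define the orientation
#'   (default: all samples).
#' @param count_samples sample ids tallied into the genotype counts
#'   (default: `samples`).
#' @param on_all_missing `"error"` (default) to fail on a site with no
#'   non-missing call among `samples`, or `"na"` to orient it to ALT and
#'   carry on (its counts are all zero).
#' @return list with `a1_is_alt` (logical per site), `a1_allele` /
#'   `a2_allele` (character per site) and `counts`, a data.frame
#'   `(n_A1A1, n_A1A2, n_A2A2, n_missing)`.
#' @export
orient_minor_allele <- function(x, samples = NULL, count_samples = samples,
                                on_all_missing = c("error", "na")) {
  stopifnot(inherits(x, "genotype_matrix"))
  on_all_missing <- match.arg(on_all_missing)
  if (is.null(samples)) samples <- x$sample_ids
  f <- alt_freq(x, samples)
  if (anyNA(f)) {
    if (on_all_missing == "error")
      stop("site(s) with all genotypes missing: ",
           paste(utils::head(site_keys(x)[is.na(f)], 3), collapse = ", "))
    f[is.na(f)] <- 0
  }
  a1_is_alt <- f <= 0.5
  if (is.null(count_samples)) count_samples <- samples
  g <- x$geno[match(count_samples, x$sample_ids), , drop = FALSE]
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  counts <- data.frame(
    n_A1A1 = ifelse(a1_is_alt, n2, n0),
    n_A1A2 = n1,
    n_A2A2 = ifelse(a1_is_alt, n0, n2),
    n_missing = colSums(is.na(g)))
  list(a1_is_alt = a1_is_alt,
       a1_allele = ifelse(a1_is_alt, x$sites$alt, x$sites$ref),
       a2_allele = ifelse(a1_is_alt, x$sites$ref, x$sites$alt),
       counts = counts)
}

# Genotype codes re-expressed as counts of the minor allele A1.
orient_dosage <- function(geno, a1_is_alt) {
  d <- geno
  flip <- !a1_is_alt
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  d
}

#' Classify the parental genotype configuration at a site
#'
#' @param sire_code,dam_code genotype codes (0/1/2/NA), vectorized.
#' @return character vector with values `both_het` (both parents
#'   heterozygous), `one_het` (exactly one), `other` (neither, both
#'   non-missing) or `unknown` (either parent missing).
#' @export
classify_parental_config <- function(sire_code, dam_code) {
  out <- rep("unknown", length(sire_code))
  known <- !is.na(sire_code) & !is.na(dam_code)
  nhet <- (sire_code == 1L) + (dam_code == 1L)
  out[known & nhet == 2L] <- "both_het"
  out[known & nhet == 1L] <- "one_het"
  out[known & nhet == 0L] <- "other"
  out
}

#' Extreme-genotype-ratio (segregation distortion) filter
#'
#' Applies the family-based segregation filter to minor-allele-oriented
#' offspring genotype counts. At both-parents-heterozygous sites, all three
#' genotype classes must exceed `min_each_both_het * scale`; at
#' one-parent-heterozygous sites, A1A2 and A2A2 must each exceed
#' `min_het_and_majhom_one_het * scale` while A1A1 must stay below
#' `max_minorhom_one_het * scale`. Sites with `other` or `unknown` parental
#' configuration pass unfiltered (no rule is defined for them; they are
#' policed by Mendelian masking and the monomorphism filter).
#'
#' @param counts data.frame of oriented counts as produced by
#'   [orient_minor_allele()] (columns `n_A1A1`, `n_A1A2`, `n_A2A2`).
#' @param config character vector of parental configurations from
#'   [classify_parental_config()].
#' @param thresholds a [filter_config()].
#' @return data.frame with `decision` (`"retain"`/`"drop"`) and `reason`
#'   (the violated rule, `NA` for retained sites).
#' @export
extreme_ratio_filter <- function(counts, config, thresholds = filter_config()) {
  stopifnot(inherits(thresholds, "filter_config"),
            nrow(counts) == length(config))
  sc <- thresholds$scale
  t_bh <- thresholds$min_each_both_het * sc
  t_oh <- thresholds$min_het_and_majhom_one_het * sc
  t_mh <- thresholds$max_minorhom_one_het * sc
  decision <- rep("retain", nrow(counts))
  reason <- rep(NA_character_, nrow(counts))
  bh <- config == "both_het"
  bad <- bh & !(counts$n_A1A1 > t_bh & counts$n_A1A2 > t_bh & counts$n_A2A2 > t_bh)
  decision[bad] <- "drop"
  reason[bad] <- "both_het_min_count"
  oh <- config == "one_het"
  bad_minor <- oh & counts$n_A1A1 >= t_mh
  bad_major <- oh & !bad_minor & !(counts$n_A1A2 > t_oh & counts$n_A2A2 > t_oh)
  decision[bad_minor | bad_major] <- "drop"
  reason[bad_minor] <- "one_het_minor_hom_excess"
  reason[bad_major] <- "one_het_min_count"
  data.frame(decision = decision, reason = reason, stringsAsFactors = FALSE)
}

#' Run the segregation filter for one family
#'
#' Convenience wrapper: orients alleles on the family's parents plus
#' offspring, tallies offspring genotypes, classifies the parental
#' configuration and applies [extreme_ratio_filter()].
#'
#' @param x a [genotype_matrix()] containing the family.
#' @param pedigree pedigree rows for this family.
#' @param thresholds a [filter_config()].
#' @return data.frame per site: `chrom`, `pos`, `config`, the oriented
#'   counts, `decision`, `reason`.
#' @export
family_ratio_qc <- function(x, pedigree, thresholds = filter_config()) {
  off <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), , drop = FALSE]
  sire <- unique(off$sire); dam <- unique(off$dam)
  if (length(sire) != 1 || length(dam) != 1)
    stop("family_ratio_qc expects a single full-sib family")
  fam_samples <- intersect(c(sire, dam, off$individual), x$sample_ids)
  om <- orient_minor_allele(x, samples = fam_samples,
                            count_samples = intersect(off$individual, x$sample_ids),
                            on_all_missing = "na")
  config <- classify_parental_config(x$geno[sire, ], x$geno[dam, ])
  dec <- extreme_ratio_filter(om$counts, config, thresholds)
  cbind(x$sites[, c("chrom", "pos")], config = config, om$counts, dec)
}

#' Mask parental genotypes of one family at flagged sites
#'
#' At each flagged site both parents of the family are set to missing,
#' which removes that family's trios from transmission counting there while
#' keeping the offspring genotypes (and the other family's evidence) intact.
#'
#' @param x a [genotype_matrix()].
#' @param pedigree pedigree rows identifying the family's sire and dam.
#' @param flagged_sites integer site indices, or character site keys
#'   (`"chrom:pos"`).
#' @return the masked `genotype_matrix`.
#' @export
mask_parents_for_flagged <- function(x, pedigree, flagged_sites) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.character(flagged_sites)) {
    j <- match(flagged_sites, site_keys(x))
    if (anyNA(j)) stop("unknown site(s): ",
                       paste(flagged_sites[is.na(j)], collapse = ", "))
  } else {
    j <- as.integer(flagged_sites)
    if (any(j < 1 | j > n_sites(x))) stop("site index out of range")
  }
  if (!length(j)) return(x)
  off <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), , drop = FALSE]
  parents <- unique(c(off$sire, off$dam))
  bad <- setdiff(parents, x$sample_ids)
  if (length(bad)) stop("parent ids not in matrix: ", paste(bad, collapse = ", "))
  x$geno[parents, j] <- NA_integer_
  x
}

#' Merge family genotype matrices onto the first family's site list
#'
#' The merged matrix carries the union of samples and exactly the first
#' matrix's sites (the anchor family's retained site list). Sites absent from
#' a later family are filled as missing for that family's samples; a shared
#' site whose ref/alt alleles disagree between inputs is an error.
#'
#' @param matrices list of [genotype_matrix()] objects with disjoint samples.
#' @return the merged `genotype_matrix` (without GP/GQ/DP annotations).
#' @export
merge_families <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  anchor <- matrices[[1]]
  keys <- site_keys(anchor)
  geno <- anchor$geno
  ids <- anchor$sample_ids
  for (m in matrices[-1]) {
    dup <- intersect(ids, m$sample_ids)
    if (length(dup)) stop("duplicated samples across families: ",
                          paste(dup, collapse = ", "))
    j <- match(keys, site_keys(m))
    shared <- which(!is.na(j))
    mism <- shared[anchor$sites$ref[shared] != m$sites$ref[j[shared]] |
                   anchor$sites$alt[shared] != m$sites$alt[j[shared]]]
    if (length(mism)) stop("ref/alt mismatch at shared site(s): ",
                           paste(keys[mism], collapse = ", "))
    g <- matrix(NA_integer_, n_samples(m), length(keys),
                dimnames = list(m$sample_ids, NULL))
    g[, shared] <- m$geno[, j[shared], drop = FALSE]
    geno <- rbind(geno, g)
    ids <- c(ids, m$sample_ids)
  }
  genotype_matrix(geno, anchor$sites, ids)
}

#' Extract a matrix onto a reference site list
#'
#' Subsets/expands a genotype matrix to exactly the given sites (matched on
#' chromosome and position); absent sites are filled as missing. Allele
#' disagreement at a matched site is an error.
#'
#' @param x a [genotype_matrix()].
#' @param sites reference sites data.frame `(chrom, pos, ref, alt)`.
#' @return a `genotype_matrix` on the reference sites.
#' @export
extract_sites <- function(x, sites) {
  keys <- site_keys(sites)
  j <- match(keys, site_keys(x))
  shared <- which(!is.na(j))
  mism <- shared[sites$ref[shared] != x$sites$ref[j[shared]] |
                 sites$alt[shared] != x$sites$alt[j[shared]]]
  if (length(mism)) stop("ref/alt mismatch at site(s): ",
                         paste(keys[mism], collapse = ", "))
  g <- matrix(NA_integer_, n_samples(x), length(keys),
              dimnames = list(x$sample_ids, NULL))
  g[, shared] <- x$geno[, j[shared], drop = FALSE]
  gp <- NULL
  if (!is.null(x$gp)) {
    gp <- array(NA_real_, c(n_samples(x), length(keys), 3L))
    gp[, shared, ] <- x$gp[, j[shared], , drop = FALSE]
  }
  genotype_matrix(g, sites, x$sample_ids, gp = gp)
}
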