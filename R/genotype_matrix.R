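#' Construct a genotype matrix
#'
#' The central container of the package: diploid biallelic genotypes for a set
#' of samples at a set of SNP sites, coded as counts of the ALT allele
#' (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing), with optional
#' genotype-posterior (GP) triplets and optional per-call GQ/DP annotations.
#'
#' @param geno integer matrix, samples x sites; entries in `{0, 1, 2, NA}`.
#'   Row names, if absent, are taken from `sample_ids`.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   describing the sites (one row per column of `geno`), sorted by
#'   `(chrom, pos)` within each chromosome.
#' @param sample_ids character vector of sample identifiers.
#' @param gp optional numeric array `n_samples x n_sites x 3` of genotype
#'   posteriors; each non-missing triplet must sum to 1 (within 2e-3, the
#'   precision of triplets serialized at 3 decimals in VCF).
#' @param gq,dp optional numeric matrices (samples x sites) of per-call
#'   genotype quality and depth.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, sample_ids = rownames(geno),
                            gp = NULL, gq = NULL, dp = NULL) {
  if (!is.matrix(geno)) stop("'geno' must be a matrix")
  storage.mode(geno) <- "integer"
  ok <- geno %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(geno)))
  if (length(sample_ids) != nrow(geno)) stop("'sample_ids' length != nrow(geno)")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) stop("'sites' needs columns chrom, pos, ref, alt")
  if (nrow(sites) != ncol(geno)) stop("nrow(sites) != ncol(geno)")
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1)) stop("site positions must be >= 1")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    split_pos <- split(sites$pos, factor(sites$chrom, levels = unique(sites$chrom)))
    if (any(vapply(split_pos, is.unsorted, logical(1))))
      stop("sites must be sorted by position within chromosome")
  }
  if (!is.null(gp)) {
    if (!is.array(gp) || length(dim(gp)) != 3 ||
        any(dim(gp)[1:2] != c(nrow(geno), ncol(geno))) || dim(gp)[3] != 3)
      stop("'gp' must be an n_samples x n_sites x 3 array")
    s <- gp[, , 1] + gp[, , 2] + gp[, , 3]
    # 2e-3 accommodates triplets serialized at 3 decimals in VCF
    if (any(abs(s[!is.na(s)] - 1) > 2e-3)) stop("GP triplets must sum to 1")
  }
  for (nm in c("gq", "dp")) {
    m <- get(nm)
    if (!is.null(m) && (!is.matrix(m) || any(dim(m) != dim(geno))))
      stop(sprintf("'%s' must be a matrix with the dimensions of 'geno'", nm))
  }
  rownames(geno) <- sample_ids
  structure(list(geno = geno, sites = sites, sample_ids = sample_ids,
                 gp = gp, gq = gq, dp = dp),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%s GP, %s GQ/DP)\n",
              n_samples(x), n_sites(x),
              if (is.null(x$gp)) "no" else "with",
              if (is.null(x$gq) && is.null(x$dp)) "no" else "with"))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param x a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_sites <- function(x) ncol(x$geno)

#' Site keys ("chrom:pos") of a genotype matrix
#' @param x a `genotype_matrix` or a sites data.frame
#' @return character vector
#' @export
site_keys <- function(x) {
  s <- if (inherits(x, "genotype_matrix")) x$sites else x
  paste(s$chrom, s$pos, sep = ":")
}

#' Subset a genotype matrix by samples or by site index
#'
#' @param x a `genotype_matrix`
#' @param ids sample identifiers to keep (in the given order)
#' @return a `genotype_matrix`
#' @export
subset_samples <- function(x, ids) {
  miss <- setdiff(ids, x$sample_ids)
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  i <- match(ids, x$sample_ids)
  genotype_matrix(x$geno[i, , drop = FALSE], x$sites, ids,
                  gp = if (!is.null(x$gp)) x$gp[i, , , drop = FALSE],
                  gq = if (!is.null(x$gq)) x$gq[i, , drop = FALSE],
                  dp = if (!is.null(x$dp)) x$dp[i, , drop = FALSE])
}

#' @rdname subset_samples
#' @param j site indices (integer or logical) to keep
#' @export
subset_sites <- function(x, j) {
  if (is.logical(j)) j <- which(j)
  genotype_matrix(x$geno[, j, drop = FALSE], x$sites[j, , drop = FALSE],
                  x$sample_ids,
                  gp = if (!is.null(x$gp)) x$gp[, j, , drop = FALSE],
                  gq = if (!is.null(x$gq)) x$gq[, j, drop = FALSE],
                  dp = if (!is.null(x$dp)) x$dp[, j, drop = FALSE])
}

#' Per-site ALT allele frequency and minor allele frequency
#'
#' Frequencies are computed over non-missing genotypes of the selected
#' samples. Sites with no non-missing call get `NA`.
#'
#' @param x a `genotype_matrix`
#' @param samples optional sample ids restricting the computation
#' @return numeric vector, one value per site
#' @export
alt_freq <- function(x, samples = NULL) {
  g <- x$geno
  if (!is.null(samples)) g <- g[match(samples, x$sample_ids), , drop = FALSE]
  n <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n)
  f[n == 0] <- NA_real_
  f
}

#' @rdname alt_freq
#' @export
site_maf <- function(x, samples = NULL) {
  f <- alt_freq(x, samples)
  pmin(f, 1 - f)
}
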