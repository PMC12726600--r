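#' Count transmissions of the minor allele to affected offspring
#'
#' Classic affected-only TDT counting. For each offspring with phenotype
#' code 2 and each site, every heterozygous non-missing parent contributes
#' one transmission when the trio genotype table resolves it:
#'
#' * one parent heterozygous, the other homozygous: the homozygote's
#'   contribution is forced, so the het parent's transmitted allele is the
#'   offspring genotype minus that forced allele;
#' * both parents heterozygous: an A1A1 offspring means two A1 transmissions
#'   (`b += 2`), an A2A2 offspring two A2 transmissions (`c += 2`), and a
#'   heterozygous offspring one of each (`b += 1, c += 1`).
#'
#' Trios with a missing genotype on any member contribute nothing at that
#' site. Counting transmissions from a het parent while the other parent is
#' missing would be biased: only homozygous offspring would be resolvable,
#' and their genotypes are correlated with which allele the het parent
#' transmitted. Mendelian-impossible trios (which should not survive
#' [mendel_mask()]) are skipped and tallied, with a warning.
#'
#' @param x a [genotype_matrix()] (the merged, QC'd analysis matrix).
#' @param pedigree pedigree data.frame; rows with non-missing sire and dam
#'   define the trios (several families may be pooled).
#' @param phenotypes data.frame `(individual, code)` with codes 1, 2 or `NA`.
#' @param a1_is_alt logical per site: orientation of the minor allele A1
#'   (from [orient_minor_allele()]). Default: orient on all samples of `x`.
#' @return list with `b` and `c` (numeric per site: A1 and A2 transmissions
#'   from heterozygous parents to affected offspring) and
#'   `n_mendel_skipped`.
#' @export
count_transmissions <- function(x, pedigree, phenotypes, a1_is_alt = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!all(phenotypes$code %in% c(1L, 2L, NA)))
    stop("phenotype codes must be 1, 2 or NA")
  if (is.null(a1_is_alt))
    a1_is_alt <- orient_minor_allele(x, on_all_missing = "na")$a1_is_alt
  d <- orient_dosage(x$geno, a1_is_alt)
  off <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), , drop = FALSE]
  code <- phenotypes$code[match(off$individual, phenotypes$individual)]
  off <- off[!is.na(code) & code == 2L, , drop = FALSE]
  # trios with members excluded from the matrix (e.g. by the sample
  # missingness filter) contribute nothing
  off <- off[off$individual %in% x$sample_ids &
               off$sire %in% x$sample_ids &
               off$dam %in% x$sample_ids, , drop = FALSE]
  S <- n_sites(x)
  b <- numeric(S); cc <- numeric(S); skipped <- 0L
  for (i in seq_len(nrow(off))) {
    s <- d[off$sire[i], ]
    m <- d[off$dam[i], ]
    o <- d[off$individual[i], ]
    ok <- !is.na(o)
    # both parents heterozygous
    bh <- ok & !is.na(s) & !is.na(m) & s == 1L & m == 1L
    b <- b + 2 * (bh & o == 2L) + (bh & o == 1L)
    cc <- cc + 2 * (bh & o == 0L) + (bh & o == 1L)
    # exactly one het parent, other homozygous: transmitted = o - forced
    for (p in list(c("s", "m"), c("m", "s"))) {
      het <- get(p[1]); other <- get(p[2])
      sel <- ok & !is.na(het) & het == 1L & !is.na(other) & other != 1L
      t_all <- o - other / 2L
      valid <- sel & (t_all == 0L | t_all == 1L)
      skipped <- skipped + sum(sel & !valid)
      b <- b + (valid & t_all == 1L)
      cc <- cc + (valid & t_all == 0L)
    }
  }
  if (skipped > 0)
    warning(skipped, " Mendelian-impossible trio genotype(s) skipped; ",
            "run mendel_mask() first")
  list(b = unname(b), c = unname(cc), n_mendel_skipped = skipped)
}

#' TDT chi-square statistic and p-value
#'
#' The transmission disequilibrium statistic `(b - c)^2 / (b + c)`, referred
#' to the upper tail of the chi-square distribution with one degree of
#' freedom (no continuity correction). Sites with `b + c = 0` carry no
#' transmission information and are returned as `NA` (untested), not as
#' `p = 1`.
#'
#' @param b,c transmission counts (vectorized).
#' @return list with `chi_square` and `p_value`.
#' @export
tdt_statistic <- function(b, c) {
  n <- b + c
  chi <- ifelse(n > 0, (b - c)^2 / n, NA_real_)
  p <- ifelse(n > 0, stats::pchisq(chi, df = 1, lower.tail = FALSE), NA_real_)
  list(chi_square = chi, p_value = p)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level, in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("'n_tests' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  alpha / n_tests
}

#' Run the transmission disequilibrium test over a genotype matrix
#'
#' Orients every site to its minor allele on the full analysis matrix, pools
#' transmission counts over all families in the pedigree, computes the TDT
#' statistic, applies the minor-allele-frequency filter to the results and
#' flags genome-wide significance at the Bonferroni threshold
#' `alpha / n_sites` (the denominator is the number of SNPs in the analysis
#' matrix). MAF is computed over all non-missing genotypes of the matrix
#' (parents and offspring).
#'
#' @param x the merged, QC'd [genotype_matrix()].
#' @param pedigree pooled pedigree data.frame.
#' @param phenotypes data.frame `(individual, code)`.
#' @param maf_min sites with MAF strictly below this are excluded from the
#'   reported results (default 0.15).
#' @param alpha family-wise significance level (default 0.05).
#' @return an object of class `tdt_result`: `results` (data.frame per tested,
#'   MAF-passing site: chrom, pos, ref, alt, a1, b, c, chi_square, p_value,
#'   maf, significant), `per_chromosome` (significant counts), `threshold`,
#'   `n_tests`, `n_untested`, `untested` (site keys with no informative
#'   transmissions), `n_maf_filtered` and `n_mendel_skipped`.
#' @export
run_tdt <- function(x, pedigree, phenotypes, maf_min = 0.15, alpha = 0.05) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (n_sites(x) == 0) stop("no sites to test")
  om <- orient_minor_allele(x, on_all_missing = "na")
  tc <- count_transmissions(x, pedigree, phenotypes, a1_is_alt = om$a1_is_alt)
  st <- tdt_statistic(tc$b, tc$c)
  maf <- site_maf(x)
  n_tests <- n_sites(x)
  thr <- bonferroni_threshold(alpha, n_tests)
  tested <- tc$b + tc$c > 0
  res <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    ref = x$sites$ref, alt = x$sites$alt,
                    a1 = om$a1_allele,
                    b = tc$b, c = tc$c,
                    chi_square = st$chi_square, p_value = st$p_value,
                    maf = maf, stringsAsFactors = FALSE)
  # sites are already sorted by (chromosome, position) by construction
  untested <- site_keys(x)[!tested]
  keep_maf <- !is.na(res$maf) & res$maf >= maf_min
  out <- res[tested & keep_maf, , drop = FALSE]
  out$significant <- out$p_value < thr
  per_chrom <- significant_per_chromosome(out)
  structure(list(results = out,
                 per_chromosome = per_chrom,
                 threshold = thr, n_tests = n_tests, alpha = alpha,
                 maf_min = maf_min,
                 n_untested = sum(!tested),
                 untested = untested,
                 n_maf_filtered = sum(tested & !keep_maf),
                 n_mendel_skipped = tc$n_mendel_skipped),
            class = "tdt_result")
}

significant_per_chromosome <- function(results) {
  if (nrow(results) == 0)
    return(data.frame(chrom = character(0), n_significant = integer(0)))
  agg <- stats::aggregate(significant ~ chrom, data = results, FUN = sum)
  names(agg) <- c("chrom", "n_significant")
  agg[order(factor(agg$chrom, levels = unique(results$chrom))), , drop = FALSE]
}

#' @export
print.tdt_result <- function(x, ...) {
  cat(sprintf("TDT: %d sites tested (of %d; %d untested, %d below MAF %.2f)\n",
              nrow(x$results), x$n_tests, x$n_untested, x$n_maf_filtered,
              x$maf_min))
  cat(sprintf("Bonferroni threshold %.3g; %d significant SNP(s)\n",
              x$threshold, sum(x$results$significant)))
  invisible(x)
}

#' Write a TDT result table
#'
#' Tab-separated results (gzip-capable via a `.gz` path).
#'
#' @param res a `tdt_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tdt_results <- function(res, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(res$results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
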