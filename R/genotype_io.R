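#' Read a VCF into a genotype matrix
#'
#' Parses GT (and optionally GP, GQ, DP) from a VCF 4.x file. Only biallelic
#' SNP records are kept; multi-allelic or indel records are skipped with a
#' message, or raise an error when `strict = TRUE`. Phase is discarded and
#' half-missing diploid calls (`./1`) are treated as fully missing.
#'
#' @param path a `.vcf` or `.vcf.gz` file with a GT FORMAT field.
#' @param want_posteriors if `TRUE`, the GP field is required and parsed.
#' @param strict if `TRUE`, non-biallelic-SNP records are an error instead of
#'   being skipped.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, want_posteriors = FALSE, strict = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keep <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "REF"] %in% c("A", "C", "G", "T") & fix[, "ALT"] %in% c("A", "C", "G", "T")
  if (any(!keep)) {
    if (strict) stop(sum(!keep), " non-biallelic-SNP record(s) in ", path)
    message("skipping ", sum(!keep), " non-biallelic-SNP record(s)")
    v <- v[keep, ]
    fix <- fix[keep, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("no GT field in ", path)
  code <- gt_to_code(gt)
  gp <- NULL
  if (want_posteriors) {
    gps <- vcfR::extract.gt(v, element = "GP")
    if (is.null(gps) || all(is.na(gps))) stop("GP field required but absent in ", path)
    gp <- parse_gp(gps)
  }
  num_field <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m) || all(is.na(m))) NULL else t(m)
  }
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  genotype_matrix(t(code), sites, colnames(gt), gp = gp,
                  gq = num_field("GQ"), dp = num_field("DP"))
}

# "0/1", "1|0" -> 1; any "." in the call -> NA
gt_to_code <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[g %in% c("0/0")] <- 0L
  code[g %in% c("0/1", "1/0")] <- 1L
  code[g %in% c("1/1")] <- 2L
  bad <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1")) & !grepl(".", g, fixed = TRUE)
  if (any(bad)) stop("unsupported GT value(s), e.g. ", g[bad][1])
  code
}

# "0.950,0.050,0.000" strings (variants x samples) -> samples x sites x 3
parse_gp <- function(gps) {
  nv <- nrow(gps); ns <- ncol(gps)
  v <- as.vector(gps)
  flat <- rep(NA_real_, 3L * nv * ns)
  nn <- which(!is.na(v))
  if (length(nn)) {
    parts <- strsplit(v[nn], ",", fixed = TRUE)
    if (any(lengths(parts) != 3L)) stop("malformed GP triplets")
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    if (anyNA(vals)) stop("malformed GP triplets")
    flat[rep((nn - 1L) * 3L, each = 3L) + rep(1:3, length(nn))] <- vals
  }
  a <- array(flat, dim = c(3L, nv, ns))
  aperm(a, c(3L, 2L, 1L))
}

#' Write a genotype matrix as VCF
#'
#' Emits a VCF 4.2 file with GT and, when present, GP (3 decimals), GQ and DP.
#' Paths ending in `.gz` are gzip-compressed. Reading the file back with
#' [read_genotypes()] reproduces the genotype codes, sites and sample order.
#'
#' @param x a [genotype_matrix()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return invisibly, `path`.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- n_samples(x); S <- n_sites(x)
  gt_str <- matrix("./.", n, S)
  for (cls in 0:2) gt_str[!is.na(x$geno) & x$geno == cls] <-
      c("0/0", "0/1", "1/1")[cls + 1L]
  fmt <- "GT"
  if (!is.null(x$gq)) {
    fmt <- paste0(fmt, ":GQ")
    gt_str <- paste(gt_str, ifelse(is.na(x$gq), ".", as.character(x$gq)), sep = ":")
  }
  if (!is.null(x$dp)) {
    fmt <- paste0(fmt, ":DP")
    gt_str <- paste(gt_str, ifelse(is.na(x$dp), ".", as.character(x$dp)), sep = ":")
  }
  if (!is.null(x$gp)) {
    fmt <- paste0(fmt, ":GP")
    gp_str <- sprintf("%.3f,%.3f,%.3f", x$gp[, , 1], x$gp[, , 2], x$gp[, , 3])
    gp_str[is.na(as.vector(x$gp[, , 1]))] <- "."
    gt_str <- paste(gt_str, gp_str, sep = ":")
  }
  gt_mat <- matrix(gt_str, n, S)
  fix <- cbind(CHROM = x$sites$chrom, POS = as.character(x$sites$pos), ID = ".",
               REF = x$sites$ref, ALT = x$sites$alt,
               QUAL = ".", FILTER = ".", INFO = ".")
  gt <- cbind(FORMAT = rep(fmt, S), t(gt_mat))
  colnames(gt) <- c("FORMAT", x$sample_ids)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            if (!is.null(x$gq)) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
            if (!is.null(x$dp)) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            if (!is.null(x$gp)) "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior probabilities\">")
  if (S == 0) {  # vcfR cannot serialize a record-less body; emit the header
    lines <- c(meta, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                             "FILTER", "INFO", "FORMAT", x$sample_ids),
                           collapse = "\t"))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con)
    close(con)
    return(invisible(path))
  }
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(v, file = path)
  } else {
    tmp <- tempfile(fileext = ".vcf.gz")
    on.exit(unlink(tmp))
    vcfR::write.vcf(v, file = tmp)
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), path)
    close(con)
  }
  invisible(path)
}

#' Mask low-confidence imputed genotypes
#'
#' Sets to missing every call whose maximal genotype-posterior (GP) element is
#' below `threshold`; all other calls are unchanged. Idempotent.
#'
#' @param x a [genotype_matrix()] with posteriors.
#' @param threshold posterior-probability cutoff (default 0.90; calls with
#'   max GP `< threshold` are masked).
#' @return the masked `genotype_matrix`.
#' @export
mask_low_gp <- function(x, threshold = 0.90) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(x$gp)) stop("no posteriors (GP) present")
  maxgp <- pmax(x$gp[, , 1], x$gp[, , 2], x$gp[, , 3])
  x$geno[!is.na(maxgp) & maxgp < threshold] <- NA_integer_
  x
}

#' Site-level quality filter
#'
#' Applies per-genotype GQ/DP masks first, then removes sites failing any
#' enabled site-level test: missingness fraction strictly greater than
#' `max_missing_fraction`, monomorphism (when `drop_monomorphic`), minor
#' allele frequency strictly below `min_maf` (boundary kept), or mean depth
#' above `max_mean_dp`. A removal log records the first failing rule per
#' removed site.
#'
#' @param x a [genotype_matrix()].
#' @param min_gq,min_dp per-genotype thresholds; calls below are set missing.
#'   Require the corresponding annotation to be present.
#' @param max_mean_dp site-level mean-depth ceiling (mean over non-missing
#'   depth values).
#' @param max_missing_fraction maximum tolerated fraction of missing
#'   genotypes per site (strict: a site is removed when its missingness
#'   exceeds this value).
#' @param min_maf minimum minor allele frequency (sites with MAF equal to the
#'   threshold are kept).
#' @param drop_monomorphic drop sites where every non-missing call carries
#'   the same allele.
#' @return list with `matrix` (the filtered `genotype_matrix`) and `removed`,
#'   a data.frame `(chrom, pos, rule)`.
#' @export
site_filter <- function(x, min_gq = NULL, min_dp = NULL, max_mean_dp = NULL,
                        max_missing_fraction = NULL, min_maf = NULL,
                        drop_monomorphic = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!is.null(min_gq)) {
    if (is.null(x$gq)) stop("min_gq set but no GQ annotation present")
    x$geno[!is.na(x$gq) & x$gq < min_gq] <- NA_integer_
  }
  if (!is.null(min_dp)) {
    if (is.null(x$dp)) stop("min_dp set but no DP annotation present")
    x$geno[!is.na(x$dp) & x$dp < min_dp] <- NA_integer_
  }
  S <- n_sites(x)
  rule <- rep(NA_character_, S)
  miss <- colMeans(is.na(x$geno))
  maf <- site_maf(x)
  if (!is.null(max_missing_fraction))
    rule[is.na(rule) & miss > max_missing_fraction] <- "missingness"
  if (drop_monomorphic)
    rule[is.na(rule) & (is.na(maf) | maf == 0)] <- "monomorphic"
  if (!is.null(min_maf))
    rule[is.na(rule) & !is.na(maf) & maf < min_maf] <- "low_maf"
  if (!is.null(max_mean_dp)) {
    if (is.null(x$dp)) stop("max_mean_dp set but no DP annotation present")
    mdp <- colMeans(x$dp, na.rm = TRUE)
    rule[is.na(rule) & !is.na(mdp) & mdp > max_mean_dp] <- "high_mean_depth"
  }
  removed <- data.frame(chrom = x$sites$chrom[!is.na(rule)],
                        pos = x$sites$pos[!is.na(rule)],
                        rule = rule[!is.na(rule)],
                        stringsAsFactors = FALSE)
  list(matrix = subset_sites(x, is.na(rule)), removed = removed)
}

#' Exclude samples with too many missing genotypes
#'
#' By default removes samples whose missing-genotype fraction is greater than
#' or equal to `max_missing_fraction` (the "15% or more" rule); with
#' `boundary = "gt"` the boundary itself is retained, which is the array
#' call-rate convention (see [array_call_rate_filter()]).
#'
#' @param x a [genotype_matrix()].
#' @param max_missing_fraction missingness threshold (default 0.15).
#' @param boundary `"gte"` (remove at the boundary) or `"gt"` (keep it).
#' @return list with `matrix` and `excluded` (character vector of sample ids).
#' @export
sample_missingness_filter <- function(x, max_missing_fraction = 0.15,
                                      boundary = c("gte", "gt")) {
  stopifnot(inherits(x, "genotype_matrix"))
  boundary <- match.arg(boundary)
  miss <- rowMeans(is.na(x$geno))
  out <- if (boundary == "gte") miss >= max_missing_fraction else miss > max_missing_fraction
  list(matrix = subset_samples(x, x$sample_ids[!out]),
       excluded = x$sample_ids[out])
}

#' @describeIn sample_missingness_filter preset for the array genotyping
#'   call-rate rule: samples with call rate strictly below 95% (missingness
#'   strictly above 5%) are removed.
#' @export
array_call_rate_filter <- function(x) {
  sample_missingness_filter(x, max_missing_fraction = 0.05, boundary = "gt")
}

#' Read / write pedigree and phenotype tables
#'
#' Pedigrees are tab-separated with columns `family`, `individual`, `sire`,
#' `dam` (unknown parents written as `0`); phenotype tables are tab-separated
#' `individual`, `code` with codes 1 (female/unaffected), 2 (male/affected)
#' and 0 for unknown (read back as `NA`).
#'
#' @param path file path.
#' @return `read_pedigree`: data.frame `(family, individual, sire, dam)` with
#'   `NA` for unknown parents; `read_phenotypes`: data.frame
#'   `(individual, code)`.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", stringsAsFactors = FALSE)
  d$sire[d$sire == "0"] <- NA
  d$dam[d$dam == "0"] <- NA
  d
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame as above.
#' @export
write_pedigree <- function(ped, path) {
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_pedigree
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  d$code <- as.integer(d$code)
  d$code[d$code == 0L] <- NA_integer_
  if (!all(d$code %in% c(1L, 2L, NA))) stop("phenotype codes must be 0, 1 or 2")
  d
}

#' @rdname read_pedigree
#' @param phe phenotype data.frame `(individual, code)`.
#' @export
write_phenotypes <- function(phe, path) {
  phe$code[is.na(phe$code)] <- 0L
  utils::write.table(phe, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
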