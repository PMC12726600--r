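#' Simulation configuration for synthetic full-sib families
#'
#' Bundles every tunable of the synthetic-data generator: genome shape,
#' sex-specific recombination, founder allele-frequency law, the sire-derived
#' risk locus and its penetrances, and the two observation platforms (a sparse
#' low-error "array" and a dense "imputed" call set with genotype posteriors).
#' Defaults describe the study conditions the package is built around: ten
#' chromosomes of 2,000 SNPs each (100 cM female map per chromosome, male
#' recombination at half the female rate), a U-shaped Beta(0.5, 0.5) founder
#' allele-frequency law, an array subset of ~55% of sites with 0.1% genotyping
#' error, and an imputed platform with heterozygote-enriched errors and
#' MAF-dependent posterior confidence.
#'
#' @param n_chromosomes number of chromosomes.
#' @param sites_per_chromosome SNP sites per chromosome (must be >= 1).
#' @param chromosome_length_cM_female female genetic map length per
#'   chromosome, in centimorgans.
#' @param male_recomb_factor ratio in `[0, 1]` scaling the male (paternal)
#'   recombination rate relative to the female map.
#' @param founder_maf_distribution founder ALT-allele-frequency law: either
#'   `list(type = "beta", shape1, shape2)` or `list(type = "point", value)`.
#' @param qtl_chromosome,qtl_position chromosome index and within-chromosome
#'   site index of the risk locus. The sire is made heterozygous there
#'   (risk allele = ALT on sire haplotype 1) so a sire-derived signal exists.
#' @param penetrance_carrier,penetrance_noncarrier probability that an
#'   offspring is coded 2 (affected / male) given it did or did not inherit
#'   the paternal risk haplotype.
#' @param array_site_fraction fraction of sites on the sparse array platform,
#'   in `(0, 1]`.
#' @param array_error_rate per-genotype symmetric error probability on the
#'   array platform.
#' @param array_missing_rate per-genotype missingness probability on the
#'   array platform.
#' @param imputed_error_model list with per-truth-class error probabilities
#'   `hom_ref`, `het`, `hom_alt` and `gp_concentration` (larger = more
#'   confident GP triplets; `Inf` = point mass on the emitted genotype).
#' @param tstv transition/transversion ratio used when drawing ref/alt
#'   allele pairs.
#' @param seed master seed; all stages derive independent substreams from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10L,
                       sites_per_chromosome = 2000L,
                       chromosome_length_cM_female = 100,
                       male_recomb_factor = 0.5,
                       founder_maf_distribution = list(type = "beta",
                                                       shape1 = 0.5,
                                                       shape2 = 0.5),
                       qtl_chromosome = 7L,
                       qtl_position = 1000L,
                       penetrance_carrier = 0.5,
                       penetrance_noncarrier = 0.05,
                       array_site_fraction = 0.55,
                       array_error_rate = 0.001,
                       array_missing_rate = 0.01,
                       imputed_error_model = list(hom_ref = 0.005,
                                                  het = 0.03,
                                                  hom_alt = 0.005,
                                                  gp_concentration = 30),
                       tstv = 1.03,
                       seed = 1L) {
  chk_count <- function(x, nm, min = 1L) {
    if (length(x) != 1 || is.na(x) || x < min || x != round(x))
      stop(sprintf("invalid '%s': must be an integer >= %d", nm, min))
  }
  chk_prob <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("invalid '%s': must be a probability in [0, 1]", nm))
  }
  chk_count(n_chromosomes, "n_chromosomes")
  chk_count(sites_per_chromosome, "sites_per_chromosome")
  if (chromosome_length_cM_female <= 0)
    stop("invalid 'chromosome_length_cM_female': must be > 0")
  chk_prob(male_recomb_factor, "male_recomb_factor")
  d <- founder_maf_distribution
  if (!is.list(d) || is.null(d$type) ||
      !(d$type %in% c("beta", "point")) ||
      (d$type == "beta" && (is.null(d$shape1) || is.null(d$shape2) ||
                            d$shape1 <= 0 || d$shape2 <= 0)) ||
      (d$type == "point" && (is.null(d$value) || d$value < 0 || d$value > 1)))
    stop("invalid 'founder_maf_distribution'")
  chk_count(qtl_chromosome, "qtl_chromosome")
  chk_count(qtl_position, "qtl_position")
  if (qtl_chromosome > n_chromosomes)
    stop("invalid 'qtl_chromosome': exceeds n_chromosomes")
  if (qtl_position > sites_per_chromosome)
    stop("invalid 'qtl_position': exceeds sites_per_chromosome")
  chk_prob(penetrance_carrier, "penetrance_carrier")
  chk_prob(penetrance_noncarrier, "penetrance_noncarrier")
  if (array_site_fraction <= 0 || array_site_fraction > 1)
    stop("invalid 'array_site_fraction': must be in (0, 1]")
  chk_prob(array_error_rate, "array_error_rate")
  chk_prob(array_missing_rate, "array_missing_rate")
  m <- imputed_error_model
  if (!is.list(m) || is.null(m$hom_ref) || is.null(m$het) || is.null(m$hom_alt) ||
      is.null(m$gp_concentration) ||
      any(unlist(m[c("hom_ref", "het", "hom_alt")]) < 0) ||
      any(unlist(m[c("hom_ref", "het", "hom_alt")]) > 1) ||
      m$gp_concentration <= 0)
    stop("invalid 'imputed_error_model'")
  if (tstv <= 0) stop("invalid 'tstv': must be > 0")
  chk_count(seed, "seed", min = 0L)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 sites_per_chromosome = as.integer(sites_per_chromosome),
                 chromosome_length_cM_female = chromosome_length_cM_female,
                 male_recomb_factor = male_recomb_factor,
                 founder_maf_distribution = d,
                 qtl_chromosome = as.integer(qtl_chromosome),
                 qtl_position = as.integer(qtl_position),
                 penetrance_carrier = penetrance_carrier,
                 penetrance_noncarrier = penetrance_noncarrier,
                 array_site_fraction = array_site_fraction,
                 array_error_rate = array_error_rate,
                 array_missing_rate = array_missing_rate,
                 imputed_error_model = m,
                 tstv = tstv,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic substream seed for a named stage. Keeps all derived seeds
# below 2^31 so they are valid R integer seeds.
stage_seed <- function(seed, stage, stream = 1L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 977 + h * 7919 + stream * 104729) %% 2147483629)
}

# Transition partner of a base; transversions pick one of the two others.
draw_alleles <- function(n, tstv) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  ref <- sample(bases, n, replace = TRUE)
  is_ts <- stats::runif(n) < tstv / (1 + tstv)
  alt <- character(n)
  alt[is_ts] <- transition[ref[is_ts]]
  for (b in bases) {
    i <- which(!is_ts & ref == b)
    if (length(i)) {
      tv <- setdiff(bases, c(b, transition[[b]]))
      alt[i] <- sample(tv, length(i), replace = TRUE)
    }
  }
  list(ref = ref, alt = alt)
}

#' Simulate founder haplotypes for one parent pair
#'
#' Builds the site map (chromosome, position, genetic position, alleles) and
#' draws four phased founder haplotypes (two per parent) with per-site ALT
#' frequencies from the configured founder allele-frequency law. The sire is
#' forced heterozygous at the risk locus, with the ALT allele (the risk
#' allele) on sire haplotype 1, so that a sire-derived association can
#' segregate.
#'
#' @param config a [sim_config()].
#' @param stream integer substream index (use a different value per family).
#' @return an object of class `founder_set`: the site table (with genetic
#'   positions in cM), `sire_haps` and `dam_haps` (2 x n_sites 0/1 matrices),
#'   the global QTL site index and the risk haplotype index.
#' @export
simulate_founders <- function(config, stream = 1L) {
  stopifnot(inherits(config, "sim_config"))
  # the site map (positions, alleles, founder allele frequencies) describes
  # the population's genome and is shared by every family under one seed
  set.seed(stage_seed(config$seed, "map", 1L))
  m <- config$sites_per_chromosome
  k <- config$n_chromosomes
  S <- m * k
  chrom <- rep(paste0("OmyA", seq_len(k)), each = m)
  pos <- rep.int(seq_len(m) * 10000L, k)
  cm <- rep.int((seq_len(m) - 0.5) / m * config$chromosome_length_cM_female, k)
  al <- draw_alleles(S, config$tstv)
  sites <- data.frame(chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
                      stringsAsFactors = FALSE)
  d <- config$founder_maf_distribution
  p <- if (d$type == "point") rep(d$value, S) else stats::rbeta(S, d$shape1, d$shape2)
  set.seed(stage_seed(config$seed, "founders", stream))
  haps <- matrix(stats::rbinom(4L * S, 1L, rep(p, each = 4L)), nrow = 4L)
  qtl_index <- (config$qtl_chromosome - 1L) * m + config$qtl_position
  haps[1L, qtl_index] <- 1L  # risk allele (ALT) on sire haplotype 1
  haps[2L, qtl_index] <- 0L
  structure(list(sites = sites, site_cm = cm,
                 chrom_index = rep(seq_len(k), each = m),
                 sire_haps = haps[1:2, , drop = FALSE],
                 dam_haps = haps[3:4, , drop = FALSE],
                 founder_freq = p,
                 qtl_index = qtl_index, risk_hap = 1L),
            class = "founder_set")
}

# One batch of n meioses from a phased parent (2 x S haplotypes).
# Crossover count per chromosome is Poisson(map_cM/100 * factor), crossover
# positions uniform on the chromosome (no interference). Returns the matrix
# of transmitted alleles (n x S) and the haplotype of origin at each site.
make_gametes <- function(haps, n, founders, length_cM, factor) {
  S <- ncol(haps)
  origin <- matrix(0L, n, S)
  mu <- length_cM / 100 * factor
  for (ch in unique(founders$chrom_index)) {
    idx <- which(founders$chrom_index == ch)
    cm <- founders$site_cm[idx]
    ks <- stats::rpois(n, mu)
    starts <- sample.int(2L, n, replace = TRUE)
    phase <- matrix(starts, n, length(idx))
    for (i in which(ks > 0L)) {
      x <- sort(stats::runif(ks[i], 0, length_cM))
      phase[i, ] <- 1L + (starts[i] - 1L + findInterval(cm, x)) %% 2L
    }
    origin[, idx] <- phase
  }
  alleles <- matrix(haps[cbind(as.vector(origin), rep(seq_len(S), each = n))],
                    n, S)
  list(alleles = alleles, origin = origin)
}

#' Simulate a full-sib family from founder haplotypes
#'
#' Each offspring is formed by one maternal and one paternal meiosis; the
#' paternal crossover rate is scaled by `male_recomb_factor` (reduced male
#' recombination). Offspring genotypes are Mendelian-consistent with the
#' parents by construction.
#'
#' @param founders a `founder_set` from [simulate_founders()].
#' @param n_offspring number of offspring (>= 1).
#' @param config the [sim_config()].
#' @param family_id family identifier used to build sample ids.
#' @param stream integer substream index.
#' @return an object of class `sim_family`: a `genotype_matrix` of the two
#'   parents plus offspring (`$geno`), the pedigree, per-offspring carrier
#'   flags for the paternal risk haplotype (`$qtl_carrier`), and the paternal
#'   haplotype-of-origin at the QTL.
#' @export
simulate_family <- function(founders, n_offspring, config,
                            family_id = "F1", stream = 1L) {
  stopifnot(inherits(founders, "founder_set"), inherits(config, "sim_config"))
  if (length(n_offspring) != 1 || is.na(n_offspring) || n_offspring < 1)
    stop("'n_offspring' must be >= 1")
  n <- as.integer(n_offspring)
  set.seed(stage_seed(config$seed, "family", stream))
  L <- config$chromosome_length_cM_female
  pat <- make_gametes(founders$sire_haps, n, founders, L, config$male_recomb_factor)
  mat <- make_gametes(founders$dam_haps, n, founders, L, 1)
  off_geno <- pat$alleles + mat$alleles
  sire_id <- paste0(family_id, "_sire")
  dam_id <- paste0(family_id, "_dam")
  off_ids <- sprintf("%s_o%03d", family_id, seq_len(n))
  geno <- rbind(colSums(founders$sire_haps), colSums(founders$dam_haps), off_geno)
  gm <- genotype_matrix(geno, founders$sites, c(sire_id, dam_id, off_ids))
  ped <- data.frame(family = family_id,
                    individual = c(sire_id, dam_id, off_ids),
                    sire = c(NA, NA, rep(sire_id, n)),
                    dam = c(NA, NA, rep(dam_id, n)),
                    stringsAsFactors = FALSE)
  carrier <- pat$origin[, founders$qtl_index] == founders$risk_hap
  names(carrier) <- off_ids
  structure(list(family_id = family_id, geno = gm, pedigree = ped,
                 founders = founders, offspring_ids = off_ids,
                 sire_id = sire_id, dam_id = dam_id,
                 qtl_carrier = carrier, phenotypes = NULL),
            class = "sim_family")
}

#' Attach a binary trait under a paternal-origin penetrance model
#'
#' Offspring that inherited the sire's risk haplotype at the QTL are coded 2
#' (affected / male) with probability `penetrance_carrier`, other offspring
#' with probability `penetrance_noncarrier`; everyone else is coded 1.
#' Parents get an unknown phenotype (`NA`).
#'
#' @param family a `sim_family`.
#' @param config the [sim_config()]; `penetrance_carrier` /
#'   `penetrance_noncarrier` can be overridden per call.
#' @param penetrance_carrier,penetrance_noncarrier optional overrides.
#' @param stream integer substream index.
#' @return the family with `$phenotypes` set to a data.frame
#'   `(individual, code)` with codes in `{1, 2, NA}`.
#' @export
attach_trait <- function(family, config,
                         penetrance_carrier = config$penetrance_carrier,
                         penetrance_noncarrier = config$penetrance_noncarrier,
                         stream = 1L) {
  stopifnot(inherits(family, "sim_family"), inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "trait", stream))
  pr <- ifelse(family$qtl_carrier, penetrance_carrier, penetrance_noncarrier)
  code <- 1L + stats::rbinom(length(pr), 1L, pr)
  family$phenotypes <- data.frame(
    individual = c(family$sire_id, family$dam_id, family$offspring_ids),
    code = c(NA_integer_, NA_integer_, code),
    stringsAsFactors = FALSE)
  family
}

#' Observe a family on the sparse array-like platform
#'
#' Draws the reproducible array site subset, applies a symmetric per-genotype
#' error (an erroneous call becomes one of the other two genotypes with equal
#' probability) and injects missingness.
#'
#' @param family a `sim_family`.
#' @param config the [sim_config()].
#' @param stream integer substream index.
#' @return a `genotype_matrix` on the array site subset (parents included).
#' @export
observe_array <- function(family, config, stream = 1L) {
  stopifnot(inherits(family, "sim_family"), inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "array-sites", 1L))  # shared across families
  S <- n_sites(family$geno)
  n_sub <- max(1L, round(config$array_site_fraction * S))
  idx <- sort(sample.int(S, n_sub))
  set.seed(stage_seed(config$seed, "array-obs", stream))
  gm <- subset_sites(family$geno, idx)
  g <- gm$geno
  N <- length(g)
  err <- stats::runif(N) < config$array_error_rate
  if (any(err)) {
    shift <- sample(1:2, sum(err), replace = TRUE)
    g[err] <- (g[err] + shift) %% 3L
  }
  g[stats::runif(N) < config$array_missing_rate] <- NA_integer_
  genotype_matrix(g, gm$sites, gm$sample_ids)
}

#' Observe a family on the dense imputed-like platform
#'
#' Emits a genotype at every site with per-truth-class error probabilities
#' (heterozygote-enriched by default; an erroneous het becomes one of the two
#' homozygotes, an erroneous homozygote usually becomes a het) plus a GP
#' triplet whose mass on the emitted genotype grows with the configured
#' concentration and with the site's minor allele frequency, so low-MAF sites
#' carry less confident posteriors. Triplets sum to 1 exactly and the maximal
#' GP is always the emitted genotype.
#'
#' @inheritParams observe_array
#' @return a `genotype_matrix` on all sites with a GP array.
#' @export
observe_imputed <- function(family, config, stream = 1L) {
  stopifnot(inherits(family, "sim_family"), inherits(config, "sim_config"))
  mod <- config$imputed_error_model
  set.seed(stage_seed(config$seed, "imputed-obs", stream))
  truth <- family$geno$geno
  n <- nrow(truth); S <- ncol(truth)
  err_rate <- c(mod$hom_ref, mod$het, mod$hom_alt)[truth + 1L]
  err <- stats::runif(length(truth)) < err_rate
  emitted <- truth
  if (any(err)) {
    t_err <- truth[err]
    u <- stats::runif(sum(err))
    new <- integer(sum(err))
    new[t_err == 1L] <- ifelse(u[t_err == 1L] < 0.5, 0L, 2L)
    new[t_err == 0L] <- ifelse(u[t_err == 0L] < 0.9, 1L, 2L)
    new[t_err == 2L] <- ifelse(u[t_err == 2L] < 0.9, 1L, 0L)
    emitted[err] <- new
  }
  maf <- site_maf(family$geno)
  maf[is.na(maf)] <- 0
  kappa <- mod$gp_concentration * (0.25 + 1.5 * maf)
  kappa_cell <- rep(kappa, each = n)
  if (is.infinite(mod$gp_concentration)) {
    gp_main <- rep(1, length(emitted))
  } else {
    gp_main <- 0.5 + 0.5 * stats::rbeta(length(emitted), kappa_cell, 1)
  }
  rem <- 1 - gp_main
  gp <- array(0, dim = c(n, S, 3L))
  for (cls in 0:2) {
    sel <- emitted == cls
    gp[, , cls + 1L][sel] <- gp_main[sel]
  }
  # remainder: hets split evenly between the homozygotes; homozygotes give
  # two thirds to the het and one third to the opposite homozygote
  sel <- emitted == 1L
  gp[, , 1L][sel] <- gp[, , 1L][sel] + rem[sel] / 2
  gp[, , 3L][sel] <- gp[, , 3L][sel] + rem[sel] / 2
  sel <- emitted == 0L
  gp[, , 2L][sel] <- gp[, , 2L][sel] + 2 * rem[sel] / 3
  gp[, , 3L][sel] <- gp[, , 3L][sel] + rem[sel] / 3
  sel <- emitted == 2L
  gp[, , 2L][sel] <- gp[, , 2L][sel] + 2 * rem[sel] / 3
  gp[, , 1L][sel] <- gp[, , 1L][sel] + rem[sel] / 3
  genotype_matrix(emitted, family$geno$sites, family$geno$sample_ids, gp = gp)
}

#' Build a truth/test genotype-vector fixture with prescribed match counts
#'
#' Constructs two genotype vectors whose pairwise tabulation reproduces the
#' given discordance counts exactly (mismatch targets are drawn among the two
#' wrong genotypes), with the pair order shuffled by `seed`.
#'
#' @param intended_counts named numeric vector or list with elements
#'   `e_rr, e_ra, e_aa, m_rr, m_ra, m_aa` (all >= 0, total > 0).
#' @param seed integer seed for the shuffle and mismatch targets.
#' @return an object of class `discordance_fixture` with `truth`, `test`
#'   and `intended_counts`.
#' @export
generate_discordance_fixture <- function(intended_counts, seed = 1L) {
  cn <- c("e_rr", "e_ra", "e_aa", "m_rr", "m_ra", "m_aa")
  k <- unlist(intended_counts)[cn]
  if (any(is.na(k)) || any(k < 0)) stop("counts must be named, non-negative: ",
                                        paste(cn, collapse = ", "))
  if (sum(k) == 0) stop("all-zero counts: fixture would be empty")
  set.seed(seed)
  truth <- c(rep(0L, k["e_rr"]), rep(1L, k["e_ra"]), rep(2L, k["e_aa"]),
             rep(0L, k["m_rr"]), rep(1L, k["m_ra"]), rep(2L, k["m_aa"]))
  wrong <- function(t) vapply(t, function(g) sample(setdiff(0:2, g), 1L), integer(1))
  n_e <- sum(k[1:3])
  test <- c(if (n_e > 0) wrong(truth[seq_len(n_e)]) else integer(0),
            truth[-seq_len(n_e)][seq_len(sum(k[4:6]))])
  if (n_e == 0) test <- truth
  o <- sample.int(length(truth))
  counts <- as.list(as.numeric(k))
  names(counts) <- cn
  structure(list(truth = truth[o], test = test[o],
                 intended_counts = structure(counts, class = "discordance_counts")),
            class = "discordance_fixture")
}

#' Simulate the full two-family study design
#'
#' Convenience wrapper generating both full-sib families with their own
#' founder sets, traits and platform observations. Defaults reflect the
#' study design the package targets: 190 and 95 genotyped offspring, the
#' second family heavily male-skewed.
#'
#' @param config a [sim_config()].
#' @param n_offspring integer vector of offspring counts, one per family.
#' @param penetrance list of `c(penetrance_carrier, penetrance_noncarrier)`
#'   per family.
#' @param family_ids family identifiers.
#' @param platforms character subset of `c("array", "imputed")` to observe.
#' @return list of per-family lists with elements `family` (a `sim_family`
#'   with phenotypes), `array` and/or `imputed` (`genotype_matrix`).
#' @export
simulate_study <- function(config,
                           n_offspring = c(190L, 95L),
                           penetrance = list(c(0.50, 0.05), c(0.95, 0.55)),
                           family_ids = c("F1", "F2"),
                           platforms = c("array", "imputed")) {
  stopifnot(inherits(config, "sim_config"),
            length(n_offspring) == length(family_ids),
            length(penetrance) == length(family_ids))
  out <- vector("list", length(family_ids))
  names(out) <- family_ids
  for (i in seq_along(family_ids)) {
    fo <- simulate_founders(config, stream = i)
    fam <- simulate_family(fo, n_offspring[i], config,
                           family_id = family_ids[i], stream = i)
    fam <- attach_trait(fam, config,
                        penetrance_carrier = penetrance[[i]][1],
                        penetrance_noncarrier = penetrance[[i]][2],
                        stream = i)
    res <- list(family = fam)
    if ("array" %in% platforms) res$array <- observe_array(fam, config, stream = i)
    if ("imputed" %in% platforms) res$imputed <- observe_imputed(fam, config, stream = i)
    out[[i]] <- res
  }
  out
}

#' Write a simulated study to disk
#'
#' Emits one VCF per family and platform (GT; GP for the imputed platform),
#' a tab-separated pedigree (`family`, `individual`, `sire`, `dam`; parents
#' coded `0`), a tab-separated phenotype table (`individual`, `code`) and the
#' configuration as YAML.
#'
#' @param study result of [simulate_study()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ped <- do.call(rbind, lapply(study, function(x) x$family$pedigree))
  phe <- do.call(rbind, lapply(study, function(x) x$family$phenotypes))
  f <- file.path(dir, "pedigree.tsv"); write_pedigree(ped, f); files <- c(files, f)
  f <- file.path(dir, "phenotypes.tsv"); write_phenotypes(phe, f); files <- c(files, f)
  for (id in names(study)) {
    for (pl in intersect(c("array", "imputed"), names(study[[id]]))) {
      f <- file.path(dir, sprintf("%s_%s.vcf.gz", id, pl))
      write_genotypes(study[[id]][[pl]], f)
      files <- c(files, f)
    }
  }
  f <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(config), f)
  files <- c(files, f)
  invisible(files)
}
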