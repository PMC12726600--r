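test_that("config validation reports the offending field", {
  expect_error(tiny_config(sites_per_chromosome = 0), "sites_per_chromosome")
  expect_error(tiny_config(male_recomb_factor = 1.5), "male_recomb_factor")
  expect_error(tiny_config(qtl_chromosome = 3), "qtl_chromosome")
  expect_error(tiny_config(qtl_position = 51), "qtl_position")
  expect_error(tiny_config(penetrance_carrier = -0.1), "penetrance_carrier")
  expect_error(tiny_config(array_site_fraction = 0), "array_site_fraction")
  expect_error(tiny_config(imputed_error_model = list(het = 0.1)),
               "imputed_error_model")
})

test_that("founder simulation is deterministic and honours the frequency law", {
  cfg <- tiny_config(founder_maf_distribution = list(type = "point", value = 0.5),
                     n_chromosomes = 4L, sites_per_chromosome = 500L,
                     qtl_position = 250L)
  f1 <- simulate_founders(cfg)
  f2 <- simulate_founders(cfg)
  expect_identical(f1, f2)
  # point mass at 0.5: mean allele frequency over sites ~ 0.5 (4 haplotypes
  # per site, 2000 sites -> SE of the mean ~ 0.0056)
  freqs <- colMeans(rbind(f1$sire_haps, f1$dam_haps))
  expect_lt(abs(mean(freqs) - 0.5), 3 * sqrt(0.25 / (4 * 2000)))
  # different stream, same map: sites identical, haplotypes differ
  f3 <- simulate_founders(cfg, stream = 2L)
  expect_identical(f1$sites, f3$sites)
  expect_false(identical(f1$dam_haps, f3$dam_haps))
  # sire forced heterozygous at the risk locus, ALT on haplotype 1
  expect_identical(f1$sire_haps[, f1$qtl_index], c(1L, 0L))
})

test_that("offspring are formed by meiosis and are Mendelian-consistent", {
  cfg <- tiny_config()
  fo <- simulate_founders(cfg)
  fam <- simulate_family(fo, 40, cfg)
  expect_error(simulate_family(fo, 0, cfg), "n_offspring")
  mm <- mendel_mask(fam$geno, fam$pedigree)
  expect_identical(mm$n_errors, 0L)
  # zero male recombination: every paternal gamete is one parental haplotype
  gam <- sibtdt:::make_gametes(fo$sire_haps, 30, fo,
                               cfg$chromosome_length_cM_female, 0)
  per_chrom <- split(seq_len(ncol(gam$origin)), fo$chrom_index)
  for (idx in per_chrom)
    expect_true(all(apply(gam$origin[, idx], 1, function(r) length(unique(r)) == 1)))
})

test_that("both parents homozygous reference forces homozygous offspring", {
  cfg <- tiny_config(founder_maf_distribution = list(type = "point", value = 0))
  fo <- simulate_founders(cfg)
  fam <- simulate_family(fo, 25, cfg)
  g <- fam$geno$geno[fam$offspring_ids, -fo$qtl_index]  # sire het at the QTL
  expect_true(all(g == 0L))
})

test_that("het x het offspring genotypes segregate 1:2:1", {
  cfg <- tiny_config(n_chromosomes = 1L, sites_per_chromosome = 3L,
                     qtl_position = 2L)
  fo <- simulate_founders(cfg)
  fo$sire_haps[, 1] <- c(1L, 0L)
  fo$dam_haps[, 1] <- c(1L, 0L)
  fam <- simulate_family(fo, 10000, cfg)
  g <- fam$geno$geno[fam$offspring_ids, 1]
  exp_n <- 10000 * c(0.25, 0.5, 0.25)
  sd_n <- sqrt(10000 * c(0.25, 0.5, 0.25) * (1 - c(0.25, 0.5, 0.25)))
  obs <- tabulate(g + 1L, 3L)
  expect_true(all(abs(obs - exp_n) < 3 * sd_n))
})

test_that("crossover counts per meiosis are Poisson(map length / 100)", {
  cfg <- tiny_config(n_chromosomes = 1L, sites_per_chromosome = 400L,
                     qtl_position = 200L, seed = 11L)
  fo <- simulate_founders(cfg)
  gam <- sibtdt:::make_gametes(fo$dam_haps, 2000, fo,
                               cfg$chromosome_length_cM_female, 1)
  # observed phase switches along the chromosome ~ crossover count (dense map)
  switches <- apply(gam$origin, 1, function(r) sum(diff(r) != 0))
  mu <- cfg$chromosome_length_cM_female / 100
  breaks <- c(-0.5, 0.5, 1.5, 2.5, Inf)
  obs <- table(cut(switches, breaks))
  p <- c(dpois(0:2, mu), ppois(2, mu, lower.tail = FALSE))
  gof <- chisq.test(as.vector(obs), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("trait attachment follows the paternal-origin penetrance model", {
  cfg <- tiny_config(n_chromosomes = 1L, sites_per_chromosome = 3L,
                     qtl_position = 2L)
  fo <- simulate_founders(cfg)
  fam <- simulate_family(fo, 200, cfg)
  # deterministic penetrance: phenotype 2 iff carrier
  f1 <- attach_trait(fam, cfg, penetrance_carrier = 1, penetrance_noncarrier = 0)
  codes <- f1$phenotypes$code[match(fam$offspring_ids, f1$phenotypes$individual)]
  expect_identical(codes == 2L, unname(fam$qtl_carrier))
  # binomial mixture: male fraction ~ 0.5*0.75 + 0.5*0.05 = 0.4
  f2 <- attach_trait(fam, cfg, penetrance_carrier = 0.75,
                     penetrance_noncarrier = 0.05)
  codes <- f2$phenotypes$code[match(fam$offspring_ids, f2$phenotypes$individual)]
  expect_lt(abs(mean(codes == 2L) - 0.4), 3 * sqrt(0.4 * 0.6 / 200))
})

test_that("equal penetrances break the carrier-phenotype association", {
  n_indep <- 0L
  for (seed in 1:20) {
    cfg <- tiny_config(n_chromosomes = 1L, sites_per_chromosome = 3L,
                       qtl_position = 2L, seed = seed)
    fam <- simulate_family(simulate_founders(cfg), 200, cfg)
    fam <- attach_trait(fam, cfg, penetrance_carrier = 0.4,
                        penetrance_noncarrier = 0.4)
    codes <- fam$phenotypes$code[match(fam$offspring_ids,
                                       fam$phenotypes$individual)]
    p <- suppressWarnings(
      chisq.test(table(fam$qtl_carrier, codes))$p.value)
    if (p > 0.01) n_indep <- n_indep + 1L
  }
  expect_gte(n_indep, 19L)
})

test_that("array observation: noiseless identity, error rate, subset size", {
  cfg <- tiny_config(array_site_fraction = 1, array_error_rate = 0,
                     array_missing_rate = 0)
  fam <- simulate_family(simulate_founders(cfg), 20, cfg)
  obs <- observe_array(fam, cfg)
  expect_identical(obs$geno, fam$geno$geno)
  # symmetric error: mismatch fraction ~ error rate
  cfg2 <- tiny_config(n_chromosomes = 2L, sites_per_chromosome = 1000L,
                      qtl_position = 500L, array_site_fraction = 1,
                      array_error_rate = 0.01, array_missing_rate = 0)
  fam2 <- simulate_family(simulate_founders(cfg2), 100, cfg2)
  obs2 <- observe_array(fam2, cfg2)
  frac <- mean(obs2$geno != fam2$geno$geno)
  n <- length(obs2$geno)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  # exact subset size from the site fraction
  cfg3 <- tiny_config(n_chromosomes = 2L, sites_per_chromosome = 12000L,
                      qtl_position = 600L, array_site_fraction = 22228 / 24000)
  fam3 <- simulate_family(simulate_founders(cfg3), 2, cfg3)
  expect_identical(n_sites(observe_array(fam3, cfg3)), 22228L)
})

test_that("imputed observation: GP contract, noiseless limit, het errors", {
  cfg <- tiny_config(imputed_error_model = list(hom_ref = 0, het = 0,
                                                hom_alt = 0,
                                                gp_concentration = Inf))
  fam <- simulate_family(simulate_founders(cfg), 20, cfg)
  obs <- observe_imputed(fam, cfg)
  expect_identical(obs$geno, fam$geno$geno)
  idx <- cbind(as.vector(row(obs$geno)), as.vector(col(obs$geno)),
               as.vector(obs$geno) + 1L)
  expect_true(all(obs$gp[idx] == 1))
  # GP normalisation and argmax-on-emitted under a noisy model
  cfg2 <- tiny_config(founder_maf_distribution = list(type = "point", value = 0.5),
                      n_chromosomes = 1L, sites_per_chromosome = 1000L,
                      qtl_position = 500L,
                      imputed_error_model = list(hom_ref = 0.005, het = 0.05,
                                                 hom_alt = 0.005,
                                                 gp_concentration = 10))
  fam2 <- simulate_family(simulate_founders(cfg2), 100, cfg2)
  obs2 <- observe_imputed(fam2, cfg2)
  sums <- obs2$gp[, , 1] + obs2$gp[, , 2] + obs2$gp[, , 3]
  expect_true(all(abs(sums - 1) < 1e-9))
  amax <- apply(obs2$gp, c(1, 2), which.max) - 1L
  expect_identical(unname(amax), unname(obs2$geno))
  # heterozygote error rate ~ 0.05
  het <- fam2$geno$geno == 1L
  frac <- mean(obs2$geno[het] != fam2$geno$geno[het])
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / sum(het)))
})

test_that("study simulation is byte-identical under one seed", {
  cfg <- tiny_config()
  s1 <- simulate_study(cfg, n_offspring = c(15L, 10L))
  s2 <- simulate_study(cfg, n_offspring = c(15L, 10L))
  expect_identical(s1, s2)
  # families share the site map but not founder haplotypes
  expect_identical(s1$F1$family$geno$sites, s1$F2$family$geno$sites)
  expect_false(identical(s1$F1$family$founders$dam_haps,
                         s1$F2$family$founders$dam_haps))
})

test_that("discordance fixtures reproduce their intended counts", {
  fx <- generate_discordance_fixture(
    c(e_rr = 1, e_ra = 1, e_aa = 0, m_rr = 0, m_ra = 5, m_aa = 3), seed = 3)
  tab <- tabulate_matches(fx$truth, fx$test)
  expect_equal(unclass(tab)[names(fx$intended_counts)],
               unclass(fx$intended_counts), ignore_attr = TRUE)
  expect_equal(nrd(tab), nrd(fx$intended_counts))
  # single-class fixture
  fx2 <- generate_discordance_fixture(
    c(e_rr = 0, e_ra = 0, e_aa = 0, m_rr = 3, m_ra = 0, m_aa = 0), seed = 1)
  expect_identical(fx2$truth, rep(0L, 3))
  expect_identical(fx2$test, rep(0L, 3))
  expect_error(generate_discordance_fixture(
    c(e_rr = 0, e_ra = 0, e_aa = 0, m_rr = 0, m_ra = 0, m_aa = 0)),
    "all-zero")
  # property: random fixtures round-trip exactly
  set.seed(99)
  for (i in 1:10) {
    k <- setNames(as.numeric(rpois(6, 5)), c("e_rr", "e_ra", "e_aa",
                                             "m_rr", "m_ra", "m_aa"))
    if (sum(k) == 0) k["m_ra"] <- 1
    fx <- generate_discordance_fixture(k, seed = i)
    expect_equal(unlist(unclass(tabulate_matches(fx$truth, fx$test))), k)
  }
})
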