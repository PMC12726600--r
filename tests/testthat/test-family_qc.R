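test_that("mendel_mask agrees with trio enumeration on all 27 genotype states", {
  states <- expand.grid(s = 0:2, d = 0:2, o = 0:2)
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    ts <- toy_trio_set(matrix(c(st$s, st$d, st$o), 3, 1), phen_codes = 1L)
    mm <- mendel_mask(ts$matrix, ts$pedigree)
    possible <- oracle_mendel_possible(st$s, st$d, st$o)
    expect_identical(unname(is.na(mm$matrix$geno[3, 1])), !possible,
                     label = sprintf("trio (%d,%d,%d)", st$s, st$d, st$o))
    expect_identical(mm$n_errors, as.integer(!possible))
    # parents untouched under the default scope
    expect_identical(mm$matrix$geno[1:2, 1], ts$matrix$geno[1:2, 1])
  }
})

test_that("mendel_mask is idempotent, scope-aware and skips missing parents", {
  # sire 0, dam 0, offspring 1: masked; sire 0, dam 2, offspring 1: kept
  ts <- toy_trio_set(rbind(c(0L, 0L), c(0L, 2L), c(1L, 1L)), phen_codes = 1L)
  mm <- mendel_mask(ts$matrix, ts$pedigree)
  expect_identical(unname(mm$matrix$geno[3, ]), c(NA, 1L))
  again <- mendel_mask(mm$matrix, ts$pedigree)
  expect_identical(again$n_errors, 0L)
  expect_identical(again$matrix$geno, mm$matrix$geno)
  # trio scope masks the parents too
  tr <- mendel_mask(ts$matrix, ts$pedigree, scope = "trio")
  expect_true(all(is.na(tr$matrix$geno[, 1])))
  # a missing parent genotype disables the check at that site
  g <- rbind(c(NA_integer_), c(0L), c(2L))
  ts2 <- toy_trio_set(g, phen_codes = 1L)
  expect_identical(mendel_mask(ts2$matrix, ts2$pedigree)$n_errors, 0L)
  # unresolvable pedigree ids are an error
  bad <- ts$pedigree
  bad$sire[3] <- "ghost"
  expect_error(mendel_mask(ts$matrix, bad), "ghost")
})

test_that("minor-allele orientation flips by frequency and breaks ties to ALT", {
  # codes {0:10, 1:5, 2:85}: ALT freq 0.875 so A1 = REF
  g <- matrix(c(rep(0L, 10), rep(1L, 5), rep(2L, 85)), ncol = 1)
  x <- toy_matrix(g)
  om <- orient_minor_allele(x)
  expect_false(om$a1_is_alt[1])
  expect_identical(om$a1_allele[1], x$sites$ref[1])
  expect_identical(om$counts$n_A1A1, 10)
  expect_identical(om$counts$n_A1A2, 5)
  expect_identical(om$counts$n_A2A2, 85)
  # frequency exactly 0.5: A1 = ALT
  g2 <- matrix(c(0L, 2L, 1L, 1L), ncol = 1)
  expect_true(orient_minor_allele(toy_matrix(g2))$a1_is_alt[1])
  # all-missing site errors unless tolerated
  g3 <- matrix(NA_integer_, 4, 1)
  expect_error(orient_minor_allele(toy_matrix(g3)), "missing")
  expect_true(orient_minor_allele(toy_matrix(g3),
                                  on_all_missing = "na")$a1_is_alt[1])
})

test_that("parental configurations classify by heterozygosity", {
  expect_identical(
    classify_parental_config(c(1L, 1L, 0L, 0L, NA, 2L),
                             c(1L, 0L, 2L, 0L, 1L, NA)),
    c("both_het", "one_het", "other", "other", "unknown", "unknown"))
})

test_that("extreme-ratio filter applies the 30/40/12 rules with scaling", {
  thr <- filter_config()
  cts <- function(a, b, c) data.frame(n_A1A1 = a, n_A1A2 = b, n_A2A2 = c)
  # both het: every class must exceed 30
  expect_identical(extreme_ratio_filter(cts(31, 31, 31), "both_het", thr)$decision,
                   "retain")
  expect_identical(extreme_ratio_filter(cts(30, 31, 31), "both_het", thr)$decision,
                   "drop")
  # one het: A1A2 and A2A2 above 40, A1A1 strictly below 12
  d <- extreme_ratio_filter(cts(12, 45, 50), "one_het", thr)
  expect_identical(d$decision, "drop")
  expect_identical(d$reason, "one_het_minor_hom_excess")
  expect_identical(extreme_ratio_filter(cts(11, 41, 41), "one_het", thr)$decision,
                   "retain")
  expect_identical(extreme_ratio_filter(cts(11, 40, 41), "one_het", thr)$decision,
                   "drop")
  # half thresholds (scale 0.5): limits become 15/20/6
  thr2 <- filter_config(scale = 0.5)
  expect_identical(extreme_ratio_filter(cts(5, 21, 26), "one_het", thr2)$decision,
                   "retain")
  expect_identical(extreme_ratio_filter(cts(16, 16, 16), "both_het", thr2)$decision,
                   "retain")
  # other/unknown configurations pass unfiltered
  expect_identical(extreme_ratio_filter(cts(0, 0, 500), "other", thr)$decision,
                   "retain")
  expect_identical(extreme_ratio_filter(cts(0, 0, 0), "unknown", thr)$decision,
                   "retain")
})

test_that("filter decisions depend only on counts, config and thresholds", {
  # sample order must not matter: shuffle offspring and re-derive counts
  cfg <- tiny_config(founder_maf_distribution = list(type = "point", value = 0.5))
  fam <- simulate_family(simulate_founders(cfg), 60, cfg)
  qc1 <- family_ratio_qc(fam$geno, fam$pedigree)
  perm <- c(1:2, 2 + sample(60))
  shuffled <- subset_samples(fam$geno, fam$geno$sample_ids[perm])
  qc2 <- family_ratio_qc(shuffled, fam$pedigree)
  expect_identical(qc1$decision, qc2$decision)
})

test_that("well-powered both-het sites are rarely dropped", {
  # 190 offspring at Mendelian 1:2:1 -> expected counts (47.5, 95, 47.5);
  # the > 30-per-class rule should drop well under 5% of such sites
  cfg <- tiny_config(n_chromosomes = 4L, sites_per_chromosome = 500L,
                     qtl_position = 250L,
                     founder_maf_distribution = list(type = "beta",
                                                     shape1 = 2, shape2 = 2))
  fam <- simulate_family(simulate_founders(cfg), 190, cfg)
  qc <- family_ratio_qc(fam$geno, fam$pedigree)
  f <- fam$founders$founder_freq
  bh <- qc$config == "both_het" & pmin(f, 1 - f) >= 0.3
  expect_gt(sum(bh), 100)
  expect_lt(mean(qc$decision[bh] == "drop"), 0.05)
})

test_that("parental masking removes exactly the family's parents at flagged sites", {
  ts <- toy_trio_set(matrix(1L, 12, 4), phen_codes = rep(2L, 10))
  m <- mask_parents_for_flagged(ts$matrix, ts$pedigree, 2L)
  expect_identical(sum(is.na(m$geno)), 2L)  # 2 parents x 1 site
  expect_true(all(is.na(m$geno[1:2, 2])))
  expect_identical(m$geno[3:12, ], ts$matrix$geno[3:12, ])
  # empty flag set is the identity
  expect_identical(mask_parents_for_flagged(ts$matrix, ts$pedigree, integer(0)),
                   ts$matrix)
  expect_error(mask_parents_for_flagged(ts$matrix, ts$pedigree, 99L), "range")
  expect_error(mask_parents_for_flagged(ts$matrix, ts$pedigree, "OmyA9:1"),
               "unknown site")
  # downstream: no informative transmissions from that family at the site
  tc <- count_transmissions(m, ts$pedigree, ts$phenotypes,
                            a1_is_alt = rep(TRUE, 4))
  expect_identical(tc$b[2] + tc$c[2], 0)
  expect_gt(tc$b[1] + tc$c[1], 0)
})

test_that("family merging anchors on the first family's sites", {
  s1 <- toy_matrix(matrix(0:2, 3, 4), sample_ids = c("a", "b", "c"))
  s2 <- toy_matrix(matrix(1L, 2, 4), sample_ids = c("d", "e"))
  m <- merge_families(list(s1, s2))
  expect_identical(n_samples(m), 5L)
  expect_identical(m$sites, s1$sites)
  # a family-1 site absent from family 2 is filled as missing
  s2b <- subset_sites(s2, c(1, 3, 4))
  m2 <- merge_families(list(s1, s2b))
  expect_true(all(is.na(m2$geno[4:5, 2])))
  expect_identical(m2$geno[4:5, c(1, 3, 4)], s2b$geno)
  # conflicting ALT allele at a shared site errors, naming the site
  s2c <- s2
  s2c$sites$alt[2] <- "C"
  expect_error(merge_families(list(s1, s2c)), site_keys(s1)[2], fixed = TRUE)
  # duplicated samples across families are rejected
  expect_error(merge_families(list(s1, s1)), "duplicated")
})
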