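---
title: "Family-based TDT and genotype-quality workflows in full-sib families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based TDT and genotype-quality workflows in full-sib families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibtdt)
```

## The analysis problem

Large full-sib families are the standard mapping unit in aquaculture
genetics: two parents and tens to hundreds of offspring, genotyped at
genome-wide SNPs on one or more platforms. `sibtdt` implements the analysis
chain for a binary trait in such families — for instance spontaneous sex
reversal in all-female (XX) salmonid lines, where offspring are coded
1 (female) or 2 (male) — together with the genotype-quality control that
family data both demands and makes possible, and the accuracy metrics used
to validate genotypes imputed from low-coverage whole-genome sequencing
(lcWGS) against SNP-array truth.

Everything operates on one container, the `genotype_matrix`: samples × sites
diploid genotypes coded 0/1/2 as ALT-allele counts, with optional
genotype-posterior (GP) triplets and per-call GQ/DP annotations, read from
and written to VCF.

## The transmission disequilibrium test

The TDT conditions on parental genotypes: at a biallelic site, each
heterozygous parent transmits one of its two alleles to each offspring, and
under the null of no linkage and no association the two alleles are
transmitted to *affected* offspring with equal probability, regardless of
population structure or the trait's base rate. Per site, `b` counts
transmissions of the minor allele A1 from heterozygous parents to affected
(code 2) offspring, `c` the transmissions of A2; the statistic

$$\chi^2 = \frac{(b - c)^2}{b + c}$$

is referred to the upper tail of the chi-square distribution with one degree
of freedom, without continuity correction. Transmissions are resolved from
the trio genotype table: with one heterozygous and one homozygous parent the
homozygote's contribution is forced, so the het parent's allele is the
offspring genotype minus it; with both parents heterozygous, a homozygous
offspring pins both transmissions while a heterozygous offspring contributes
one A1 and one A2. Trios with any missing member contribute nothing — note
that counting a lone heterozygous parent while the other parent is missing
would be ascertainment-biased, because only homozygous offspring would be
resolvable and their genotypes are correlated with the transmitted allele.
Sites with `b + c = 0` are reported as *untested* rather than as `p = 1`:
"no information" is not "no distortion".

Two result-level conventions follow common practice in this field:

* SNPs with minor allele frequency below 0.15 are excluded from the result
  table. The MAF denominator is every non-missing genotype in the merged
  analysis matrix (parents and offspring); the threshold exists because a
  full-sib family offers at most four founder haplotypes, so low-MAF sites
  carry little transmission information and unstable estimates.
* Genome-wide significance uses a Bonferroni threshold of
  `alpha / n_SNPs`, where `n_SNPs` is the number of SNPs in the analysis
  matrix (all retained sites, not only those with informative
  transmissions). This matches how the threshold is conventionally quoted
  for a genotyping panel, e.g. 0.05/22,228 ≈ 2.25e-6 for an array set and
  0.05/4,978,369 ≈ 1e-8 for an imputed set.

## Family-aware quality control

The QC chain exploits the pedigree:

1. **Mendelian masking** (`mendel_mask`): an offspring genotype impossible
   given two non-missing parents is set missing. Only the offspring call is
   masked by default — the parents are shared by every sib, so masking them
   would cascade across the family; `scope = "trio"` is available.
2. **Site filters** (`site_filter`): per-genotype GQ/DP masks first, then
   monomorphic sites and sites with missingness above 10% are removed, with
   a per-site removal log naming the violated rule.
3. **Minor-allele orientation** (`orient_minor_allele`): A1 is the less
   frequent allele among the family's parents and offspring; an exact 50/50
   tie deterministically assigns A1 to ALT.
4. **Extreme-genotype-ratio filter** (`extreme_ratio_filter`): segregation
   distortion beyond what Mendelian sampling explains signals genotyping
   artifacts (e.g. a parent miscalled heterozygous at a monomorphic site,
   which would otherwise fabricate strong spurious transmission signals).
   Where both parents are heterozygous, each offspring class must exceed 30;
   where exactly one parent is heterozygous, A1A2 and A2A2 must exceed 40
   while A1A1 (forbidden by transmission) must stay below 12. All three
   constants scale multiplicatively — a half-size family is filtered with
   `scale = 0.5` — and inequalities stay strict. Configurations with no
   stated rule (neither or unknown parents heterozygous) pass and are left
   to the Mendelian and monomorphism filters, rather than inventing
   thresholds.
5. **Anchored merging**: the first (largest) family's retained sites define
   the analysis site list; later families are extracted onto it, their
   flagged sites handled by masking both of *their* parents (removing those
   trios from the TDT) instead of dropping the site, so the anchor family's
   evidence is retained. Allele disagreement at a shared site is an error,
   not a silent strand flip.
6. **Sample exclusion**: samples with 15% or more missing genotypes are
   removed (boundary included). The array call-rate rule — call rate
   strictly below 95% — is the same operation with `boundary = "gt"`,
   exposed as `array_call_rate_filter()`.

`run_pipeline()` composes these stages in the order: read/simulate → GP
masking (imputed platform) → family-1 Mendelian masking and site filters →
family-1 ratio filter → family-2 extraction on family-1 sites → family-2
ratio flags → parental masking → merge → sample filter → TDT → reports.
GP masking precedes the polymorphism and ratio filters for imputed data
(mask-first): low-confidence calls should not influence filter statistics.

## Imputation accuracy metrics

Comparing an imputed call set against array truth over jointly non-missing
pairs at shared, allele-matched sites, classified by the *truth* genotype:

* **Concordance** = 100 · matches / all pairs.
* **NRD** = 100 · (e_rr + e_ra + e_aa) / (e_rr + e_ra + e_aa + m_ra + m_aa).
  Concordant homozygous-reference pairs are excluded from the denominator,
  so NRD is not inflated by the bulk of easy hom-ref calls; it is invariant
  to adding m_rr and always at least 100 − concordance when m_rr > 0.
* **Dosage r²**: one global squared Pearson correlation between ALT dosages
  over all pairs (matching the single value quoted per panel); per-MAF-bin
  stratification is available via `accuracy_report(maf_bins =)`.

MAF binning uses closed right boundaries with the first boundary inclusive,
so a bin edge at 0.05 means "MAF of 0.05 or less".

## What the simulator emulates

`sim_config()` + `simulate_study()` generate the study design the package is
built around; the defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| genome | 10 chromosomes × 2,000 SNPs | enough sites for stable filter/TDT behaviour at desk scale |
| female map length | 100 cM / chromosome | a typical salmonid chromosome |
| `male_recomb_factor` | 0.5 | reduced male recombination, as repeatedly observed in salmonids; paternal crossover counts are Poisson(L/100 × factor), uniform placement, no interference |
| founder allele-frequency law | Beta(0.5, 0.5) | U-shaped spectrum with an excess of rare variants, as seen genome-wide; a point mass is expressible for controlled experiments |
| Ts/Tv bias | 1.03 | the transition/transversion ratio observed in the motivating species' variant set |
| families | 190 + 95 offspring | two full-sib families, the second smaller and heavily male-skewed |
| trait model | single sire-derived risk haplotype; penetrance 0.50/0.05 (family 1), 0.95/0.55 (family 2) | expected male fractions 0.275 and 0.75 under the paternal-origin single-locus model, matching the skew the design targets; the sire is forced heterozygous at the risk locus (ALT on haplotype 1), since a sire-derived signal cannot segregate otherwise |
| array platform | ~55% of sites, 0.1% symmetric genotype error, 1% missingness | sparse, high-quality array |
| imputed platform | all sites; per-class errors 0.005/0.03/0.005 (hom-ref/het/hom-alt); GP concentration 30, scaled by 0.25 + 1.5·MAF | heterozygote-enriched errors and less confident posteriors at rare alleles, the characteristic lcWGS imputation error structure |

One master seed drives every stage through named substreams, so identical
configurations are byte-identical across runs, and the two families share
one site map (positions, alleles, founder frequencies) while drawing their
own founder haplotypes.

**What it does not emulate.** Founders are drawn independently per site (no
coalescent ancestry, no linkage disequilibrium between founder haplotypes
beyond what the family transmits); imputation errors are independent across
calls rather than haplotype-blocked; GP triplets are stylized (confidence
mass on the emitted genotype with a Beta-distributed remainder) rather than
the output of an imputation HMM; there is no genotyping batch structure.
Passing tests therefore demonstrate the correctness and calibration of the
*analysis* under a faithful family sampling model — not the field accuracy
of any particular imputation tool.

## Numerical and design choices

* Half-missing diploid VCF calls (`./1`) are treated as fully missing;
  phase is ignored throughout.
* "Posterior probability" of a call is the maximal element of its GP
  triplet; masking at 0.90 is idempotent. GP triplets are serialized at
  3 decimals, so the container accepts triplet sums within 2e-3 of 1 (the
  generator itself emits exact-sum triplets).
* MAF filter boundaries: sites with MAF exactly at the site-filter threshold
  are kept (`>=` semantics, matching the conventional `--maf` flag); the
  sample-missingness boundary is removed ("15% *or more*").
* Mismatch classification in the accuracy metrics is keyed on the truth
  (array) genotype.
* In `extreme_ratio_filter` the one-parent-het rule is applied symmetrically
  (it is not stated to differ by which parent is heterozygous), and
  thresholds compare non-missing tallies only.
* Ties, degenerate inputs and undefined metrics (zero NRD denominator, zero
  dosage variance, zero transversions) return `NA` with a warning rather
  than a fabricated value.

## Calibration checks and problem sizes

The test suite verifies, beyond unit behaviour:

* **Oracle equivalence** — Mendelian masking against enumeration of all 27
  trio genotype states; transmission counting against per-trio enumeration
  of consistent gamete pairs over all trio states × phenotypes; match
  tabulation against an exhaustive double loop on random fixtures.
* **Type-I error** — on a null family (equal penetrances) of 190 offspring
  genotyped at 7,000 single-site chromosomes (sites on separate chromosomes
  segregate independently, which the binomial envelope requires; linked
  sites within one family are strongly correlated), the fraction of
  p < 0.05 lies within the 99% binomial envelope of 0.05 over ≥ 5,000
  informative sites.
* **QTL recovery** — across 20 seeded two-family studies (5 chromosomes ×
  400 sites, risk locus mid-chromosome-3), the top SNP lies on the true
  chromosome below the Bonferroni threshold, and all genome-wide significant
  array SNPs lie on the QTL chromosome, in at least 18 of 20 runs. The
  imputed platform occasionally yields off-chromosome significant SNPs —
  an artifact of residual imputed-genotype errors that mirrors what
  imputed-data association scans report in practice.
* **Metric identities** — concordance/mismatch complementarity, m_rr
  invariance of NRD, NRD ≥ 100 − concordance, and allele-flip invariance of
  dosage r², on random fixtures.

These sizes (1,500–7,000 sites, 150–285 offspring) are the package's chosen
desk-scale study shapes; the acceptance script (`scripts/acceptance.R`) uses
a 5 × 1,000-site study for the accuracy metrics and 20 seeded 5 × 400-site
studies for recovery, all reproducible from a single `--seed`.

## Limitations

* Affected-only TDT: unaffected offspring never contribute, and no sib-TDT,
  exact-binomial or permutation variants are provided.
* No covariates, no polygenic background, no X/Y-specific handling — the
  intended designs are autosomal biallelic SNPs in XX families.
* Parental origin of transmissions is only resolvable in unambiguous trios;
  no haplotype phasing is attempted.
* The site filter handles biallelic SNPs only; multi-allelic records are
  skipped at import, not decomposed.
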