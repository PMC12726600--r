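# Small simulation configs and hand-built genotype matrices used across tests.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 2L, sites_per_chromosome = 50L,
                   qtl_chromosome = 1L, qtl_position = 25L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# sites table for n sites on one chromosome
toy_sites <- function(n, chrom = "OmyA1") {
  data.frame(chrom = rep_len(chrom, n), pos = seq_len(n) * 100L,
             ref = rep_len(c("A", "C", "G", "T"), n),
             alt = rep_len(c("G", "T", "A", "C"), n),
             stringsAsFactors = FALSE)
}

# genotype matrix from a samples x sites integer matrix (NA allowed)
toy_matrix <- function(g, sample_ids = NULL, ...) {
  g <- as.matrix(g)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(g)))
  genotype_matrix(g, toy_sites(ncol(g)), sample_ids, ...)
}

# one family (sire, dam, offspring...) as matrix + pedigree + phenotypes
toy_trio_set <- function(geno, phen_codes, family = "FAM") {
  n_off <- nrow(geno) - 2L
  ids <- c(paste0(family, "_sire"), paste0(family, "_dam"),
           sprintf("%s_o%02d", family, seq_len(n_off)))
  x <- toy_matrix(geno, sample_ids = ids)
  ped <- data.frame(family = family, individual = ids,
                    sire = c(NA, NA, rep(ids[1], n_off)),
                    dam = c(NA, NA, rep(ids[2], n_off)),
                    stringsAsFactors = FALSE)
  phe <- data.frame(individual = ids,
                    code = c(NA_integer_, NA_integer_, as.integer(phen_codes)),
                    stringsAsFactors = FALSE)
  list(matrix = x, pedigree = ped, phenotypes = phe)
}
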