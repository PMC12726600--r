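# Independent brute-force oracles.

# gametes a genotype can produce (counts of the A1/ALT allele)
oracle_gametes <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)

# is offspring genotype o possible given non-missing parents s, d?
oracle_mendel_possible <- function(s, d, o) {
  any(outer(oracle_gametes(s), oracle_gametes(d), "+") == o)
}

# TDT transmissions for one trio by enumeration of consistent gamete pairs:
# over all (u_s, u_d) with u_s + u_d = o, if the total number of A1 alleles
# transmitted by *heterozygous* parents is the same in every consistent
# assignment, that total is counted as b and the remaining het-parent
# transmissions as c; otherwise the trio is ambiguous and contributes nothing.
oracle_transmissions <- function(s, d, o, phen) {
  if (is.na(phen) || phen != 2L || is.na(s) || is.na(d) || is.na(o))
    return(c(b = 0, c = 0))
  pairs <- expand.grid(u_s = oracle_gametes(s), u_d = oracle_gametes(d))
  pairs <- pairs[pairs$u_s + pairs$u_d == o, , drop = FALSE]
  if (nrow(pairs) == 0) return(c(b = 0, c = 0))  # Mendelian-impossible
  n_het <- (s == 1L) + (d == 1L)
  if (n_het == 0) return(c(b = 0, c = 0))
  t_a1 <- pairs$u_s * (s == 1L) + pairs$u_d * (d == 1L)
  if (length(unique(t_a1)) > 1) return(c(b = 0, c = 0))  # ambiguous
  c(b = t_a1[1], c = n_het - t_a1[1])
}

# exhaustive pairwise tabulation of two genotype vectors
oracle_tabulate <- function(truth, test) {
  k <- c(e_rr = 0, e_ra = 0, e_aa = 0, m_rr = 0, m_ra = 0, m_aa = 0)
  for (i in seq_along(truth)) {
    t <- truth[i]; s <- test[i]
    if (is.na(t) || is.na(s)) next
    cls <- c("rr", "ra", "aa")[t + 1L]
    key <- paste0(if (t == s) "m_" else "e_", cls)
    k[key] <- k[key] + 1
  }
  k
}
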