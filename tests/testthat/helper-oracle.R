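# Exhaustive minimum-switch oracle, independent of the FMV walk.
#
# Enumerates every orientation assignment of the family's informative loci
# (which sire strand carries allele 0 at each locus) and returns the minimum
# total number of per-offspring strand changes consistent with the homozygous
# genotypes. Feasible only for small k (<= 16 informative loci).
min_switches_oracle <- function(G) {
  het <- find_sire_het_loci(G)
  H <- which(het)
  k <- length(H)
  if (k == 0L) return(0L)
  stopifnot(k <= 16L)
  X <- G[, H, drop = FALSE] / 2  # 0/1 at homozygous cells, 0.5 het, NA missing
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  total <- integer(nrow(combos))
  for (i in seq_len(nrow(G))) {
    idx <- which(!is.na(X[i, ]) & X[i, ] %in% c(0, 1))
    if (length(idx) < 2L) next
    S <- sweep(combos[, idx, drop = FALSE], 2L, X[i, idx],
               FUN = function(o, g) xor(o, g))
    total <- total + rowSums(S[, -1L, drop = FALSE] != S[, -ncol(S), drop = FALSE])
  }
  min(total)
}

# Swap genotype codes 0 <-> 2 at every marker (strand relabelling of the data).
swap_geno_codes <- function(G) {
  out <- 2L - G
  out[G == 1L] <- 1L
  dimnames(out) <- dimnames(G)
  out
}
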