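# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

null_sim_config <- function(seed = 1L, n_genes = 500L, dispersion = 0.05) {
  sim_config(n_genes = n_genes, dispersion = dispersion,
             frac_A_up = 0, frac_A_down = 0, frac_B_up = 0, frac_B_down = 0,
             frac_opposite_overlap = 0, frac_same_overlap = 0,
             frac_rescued = 0, seed = seed)
}

# tiny count_matrix with two genotypes, explicit values
toy_count_matrix <- function(counts, genotypes) {
  d <- data.frame(sample = colnames(counts), genotype = genotypes,
                  stringsAsFactors = FALSE)
  count_matrix(counts, d)
}

# brute-force BH step-up, the oracle for bh_adjust()
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- which(o == i)  # rank of p[i]
    adj[i] <- min(1, min(p[o][seq(j, n)] * n / seq(j, n)))
  }
  adj
}

# full 2^n enumeration of the signed-rank null, the oracle for
# signed_rank_test(); returns the two-sided p for observed differences d
signed_rank_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive nearest-TSS search, the oracle for annotate_peaks()
nearest_tss_brute <- function(regions, genes) {
  mid <- (regions$start + regions$end) %/% 2L
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cand <- genes[genes$chrom == regions$chrom[i], ]
    if (!nrow(cand)) { out[i] <- NA_character_; next }
    dd <- abs(mid[i] - cand$tss)
    best <- cand$gene[dd == min(dd)]
    out[i] <- sort(best)[1]
  }
  out
}
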