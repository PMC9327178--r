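# Shared fixtures: small, programmatically generated inputs.

# reduced MCMC schedule for desk-scale fits
mc_fast <- function(seed = 1, n_iter = 3000, burn_in = 500, thin = 5) {
  mcmc_control(n_iter, burn_in, thin, seed = seed)
}

# tiny toy OTU table with known structure (4 samples x 3 OTU)
toy_otu <- function() {
  m <- matrix(c(10, 0, 90,
                20, 5, 75,
                0, 0, 100,
                30, 0, 70), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("otu", 1:3)))
  storage.mode(m) <- "integer"
  m
}

# iid unrelated dosage panel (not a pedigree), p drawn per SNP
unrelated_panel <- function(n = 200, n_snps = 1000, seed = 1) {
  set.seed(seed)
  p <- runif(n_snps, 0.1, 0.5)
  Z <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(Z) <- paste0("a", seq_len(n))
  colnames(Z) <- paste0("snp", seq_len(n_snps))
  Z
}
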