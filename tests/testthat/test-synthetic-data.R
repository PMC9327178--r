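test_that("population design splits every full-sib pair across the diets", {
  d <- make_population_design(n_sires = 5, n_dams_per_sire = 4, seed = 1)
  expect_equal(nrow(d), 40)                      # 2 animals x 20 pairs
  split_ok <- tapply(d$diet, d$pair, function(x) setequal(x, c("CO", "HF")))
  expect_true(all(split_ok))
  expect_true(all(table(d$dam) == 2))            # each dam in exactly one pair
  expect_false(any(duplicated(d$animal_id)))
  # pens are nested in batch x diet
  pen_batch <- unique(d[, c("pen", "batch")])
  expect_false(any(duplicated(pen_batch$pen)))
})

test_that("gene dropping yields valid dosages and is reproducible", {
  d <- make_population_design(n_sires = 1, n_dams_per_sire = 1, seed = 2)
  Z <- simulate_genotypes(d, n_snps = 10, seed = 3)
  expect_equal(dim(Z), c(2, 10))
  expect_true(all(Z %in% 0:2))
  expect_identical(Z, simulate_genotypes(d, n_snps = 10, seed = 3))
  expect_error(simulate_genotypes(d[0, ], 10), "empty")
  expect_error(simulate_genotypes(d, 10, maf_range = c(0.2, 0.7)), "maf_range")
})

test_that("allele frequencies follow the binomial expectation at maf 0.5", {
  d <- make_population_design(n_sires = 50, n_dams_per_sire = 4, seed = 4)
  Z <- simulate_genotypes(d, n_snps = 400, maf_range = c(0.5, 0.5), seed = 5)
  # per-SNP mean dosage ~ 1; allele-frequency noise is driven by the founder
  # pool (2 alleles x 250 founders), inflated further by sib correlation
  se_founder <- sqrt(2 * 0.5 * 0.5 / 500)
  per_snp <- colMeans(Z)
  expect_lt(mean(abs(per_snp - 1) > 4 * 2 * se_founder), 0.05)
  expect_lt(abs(mean(per_snp) - 1), 0.02)
})

test_that("full sibs are more related than unrelated animals in the GRM", {
  d <- make_population_design(n_sires = 20, n_dams_per_sire = 3, seed = 6)
  Z <- simulate_genotypes(d, n_snps = 800, seed = 7)
  G <- unclass(build_grm(Z))
  sib <- unrel <- c()
  for (p in unique(d$pair)) {
    idx <- which(d$pair == p)
    sib <- c(sib, G[idx[1], idx[2]])
  }
  other_sire <- outer(d$sire, d$sire, "!=")
  unrel <- G[upper.tri(G) & other_sire]
  expect_gt(mean(sib), mean(unrel) + 0.3)   # ~0.5 vs ~0 expected
})

test_that("OTU tables have exact row sums and respond to the diet shift", {
  d <- make_population_design(n_sires = 10, n_dams_per_sire = 3, seed = 8)
  otu <- simulate_otu_table(d, n_otu = 50, depth = 2000, seed = 9)
  expect_true(all(rowSums(otu) == 2000))
  expect_error(simulate_otu_table(d, n_otu = 50, depth = 0), "depth")

  # diet_shift = 0: shifted set has equal mean relative abundance across diets
  otu0 <- simulate_otu_table(d, n_otu = 50, depth = 5000, diet_shift = 0,
                             seed = 10)
  sh <- attr(otu0, "shifted_otus")
  rel <- rowSums(otu0[, sh, drop = FALSE]) / 5000
  co <- rel[d$diet == "CO"]; hf <- rel[d$diet == "HF"]
  pooled_se <- sqrt(var(co) / length(co) + var(hf) / length(hf))
  expect_lt(abs(mean(co) - mean(hf)), 4 * pooled_se)

  # diet_shift > 0 raises the shifted set's share under HF
  otu1 <- simulate_otu_table(d, n_otu = 50, depth = 5000, diet_shift = 2,
                             seed = 10)
  rel1 <- rowSums(otu1[, attr(otu1, "shifted_otus"), drop = FALSE]) / 5000
  expect_gt(mean(rel1[d$diet == "HF"]), mean(rel1[d$diet == "CO"]))
})

test_that("a dominant OTU carries the majority of counts in every sample", {
  d <- make_population_design(n_sires = 5, n_dams_per_sire = 2, seed = 11)
  # seed chosen so the two baselines are far apart; no animal noise
  otu <- simulate_otu_table(d, n_otu = 2, depth = 10000,
                            log_abundance_sd = 4, animal_sd = 0,
                            diet_shift = 0, seed = 12)
  dominant <- which.max(colSums(otu))
  expect_true(all(otu[, dominant] > 5000))
})

test_that("phenotype generator honors the noise-free and pure-noise limits", {
  d <- make_population_design(n_sires = 15, n_dams_per_sire = 4, seed = 13)
  Z <- simulate_genotypes(d, n_snps = 400, seed = 14)
  otu <- simulate_otu_table(d, n_otu = 100, depth = 3000, seed = 15)

  # pure noise: var(y) ~ 1, y uncorrelated with kernel structure
  tr0 <- synthetic_truth(sigma2_u = 0, sigma2_m = 0, sigma2_e = 1,
                         pen_effect_sd = 0, mu = 0)
  sim0 <- simulate_phenotypes(Z, otu, tr0, d, seed = 16)
  y0 <- sim0$phenotypes$trait
  expect_lt(abs(var(y0) - 1), 3 * sqrt(2 / length(y0)) + 0.15)
  expect_lt(abs(cor(y0, unclass(sim0$G)[, 1])), 0.25)

  # noise-free genetic limit: y - mu lies in the column space of G
  tr1 <- synthetic_truth(sigma2_u = 1, sigma2_m = 0, sigma2_e = 0,
                         pen_effect_sd = 0, mu = 0)
  sim1 <- simulate_phenotypes(Z, otu, tr1, d, seed = 17)
  y1 <- sim1$phenotypes$trait
  eg <- eigen(unclass(sim1$G), symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values)
  U <- eg$vectors[, keep]
  proj <- U %*% crossprod(U, y1)
  expect_lt(max(abs(y1 - proj)), 1e-6)
  expect_equal(y1, as.numeric(sim1$u), tolerance = 1e-12)

  # mismatched animal sets rejected
  expect_error(simulate_phenotypes(Z[-1, ], otu, tr0, d), "identical")
})

test_that("generated variance components match the truth in expectation", {
  d <- make_population_design(n_sires = 42, n_dams_per_sire = 6, seed = 18)
  d <- d[d$pair <= 250, ]   # 500 animals
  Z <- simulate_genotypes(d, n_snps = 600, seed = 19)
  otu <- simulate_otu_table(d, n_otu = 150, depth = 3000, seed = 20)
  tr <- synthetic_truth(sigma2_u = 0.3, sigma2_m = 0.5, sigma2_e = 0.2)
  vars <- sapply(1:50, function(r) {
    s <- simulate_phenotypes(Z, otu, tr, d, seed = 100 + r)
    c(u = var(s$u), m = var(s$m), e = var(s$e))
  })
  mg <- mean(diag(simulate_phenotypes(Z, otu, tr, d, seed = 1)$G))
  mm <- mean(diag(simulate_phenotypes(Z, otu, tr, d, seed = 1)$M))
  # empirical variances track sigma2 * mean(diag K) within Monte-Carlo error
  expect_lt(abs(mean(vars["u", ]) - 0.3 * mg), 0.05)
  expect_lt(abs(mean(vars["m", ]) - 0.5 * mm), 0.05)
  expect_lt(abs(mean(vars["e", ]) - 0.2), 0.02)
})

test_that("RFI is an OLS residual orthogonal to its predictors", {
  # toy 6-animal table with a brute-force normal-equations oracle
  set.seed(21)
  tab <- data.frame(animal_id = paste0("a", 1:6),
                    ADG = c(0.8, 0.9, 1.0, 0.85, 0.95, 1.05),
                    lean_pct = c(58, 61, 60, 59, 62, 57),
                    carcass_yield = c(77, 79, 78, 80, 76, 78),
                    avg_metabolic_bw = c(88, 92, 95, 90, 93, 97))
  tab$DFI <- 0.5 + 2 * tab$ADG + 0.01 * tab$avg_metabolic_bw + rnorm(6, 0, 0.1)
  rfi <- compute_rfi(tab)
  X <- cbind(1, as.matrix(tab[, c("ADG", "lean_pct", "carcass_yield",
                                  "avg_metabolic_bw")]))
  beta <- solve(t(X) %*% X, t(X) %*% tab$DFI)
  oracle <- as.vector(tab$DFI - X %*% beta)
  expect_equal(unname(rfi), oracle, tolerance = 1e-8)
  expect_lt(abs(sum(rfi)), 1e-8)
  for (p in c("ADG", "lean_pct")) expect_lt(abs(sum(rfi * tab[[p]])), 1e-6)

  # exact linear combination -> all residuals zero
  tab$DFI <- 1 + 3 * tab$ADG - 0.2 * tab$lean_pct
  expect_lt(max(abs(compute_rfi(tab))), 1e-10)

  # collinear predictors -> error naming a column
  tab$dup <- tab$ADG
  expect_error(compute_rfi(tab, predictors = c("ADG", "dup")), "collinear")
})

test_that("simulate_dataset is deterministic and internally consistent", {
  s1 <- simulate_dataset(n_pairs = 15, n_snps = 120, n_otu = 60, seed = 22)
  s2 <- simulate_dataset(n_pairs = 15, n_snps = 120, n_otu = 60, seed = 22)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_equal(nrow(s1$phenotypes), 30)
  expect_true(all(c("DFI", "ADG", "RFI") %in% names(s1$phenotypes)))
  expect_lt(abs(sum(s1$phenotypes$RFI)), 1e-6)
})
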