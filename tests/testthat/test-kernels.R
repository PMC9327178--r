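test_that("log-abundance standardization matches hand computation", {
  # 3 animals x 2 OTU, natural log of count+1, column-standardized
  counts <- matrix(c(0, 7, 1,
                     3, 0, 8), nrow = 3,
                   dimnames = list(paste0("a", 1:3), c("o1", "o2")))
  S <- build_log_abundance(counts, sd_type = "population")
  L <- log(counts + 1)
  expected <- apply(L, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(S), unname(expected), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colMeans(S), c(o1 = 0, o2 = 0), tolerance = 1e-12)

  # two-point column: (0, e-1) -> log1p gives (0, 1) -> +/- 1 under
  # population SD, +/- sqrt(1/2) under sample SD
  two <- matrix(c(0, exp(1) - 1), ncol = 1,
                dimnames = list(c("a1", "a2"), "o1"))
  expect_equal(as.vector(build_log_abundance(two, "population")), c(-1, 1),
               tolerance = 1e-12)
  expect_equal(as.vector(build_log_abundance(two, "sample")),
               c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-12)
})

test_that("constant OTU columns are dropped with a warning", {
  counts <- cbind(toy_otu(), otuK = c(5L, 5L, 5L, 5L))
  expect_warning(S <- build_log_abundance(counts), "zero-variance")
  expect_false("otuK" %in% colnames(S))
  expect_equal(attr(S, "dropped"), "otuK")
  expect_error(build_log_abundance(counts[1, , drop = FALSE]), "2 animals")
})

test_that("microbial kernel equals brute-force SS^T / n", {
  set.seed(1)
  S <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("a", 1:3), NULL))
  M <- build_microbial_kernel(S)
  # independent entrywise computation
  brute <- matrix(0, 3, 3)
  for (j in 1:3) for (l in 1:3) brute[j, l] <- sum(S[j, ] * S[l, ]) / 4
  expect_equal(unclass(M), brute, ignore_attr = TRUE, tolerance = 1e-14)
  expect_equal(attr(M, "divisor"), 4)

  # duplicate animal rows give off-diagonal equal to the diagonal
  S2 <- rbind(a = S[1, ], b = S[1, ], c = S[2, ])
  M2 <- build_microbial_kernel(S2)
  expect_equal(M2["a", "b"], M2["a", "a"], tolerance = 1e-12)
  # orthogonal rows give zero off-diagonals
  S3 <- rbind(x = c(1, 0, 0, 0), y = c(0, 1, 0, 0))
  expect_equal(build_microbial_kernel(S3)["x", "y"], 0)
})

test_that("GRM matches hand-computed VanRaden construction on a toy", {
  Z <- matrix(c(0, 1, 2,
                1, 1, 0,
                2, 0, 1,
                1, 2, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("a", 1:4), paste0("s", 1:3)))
  G <- build_grm(Z)
  p <- colMeans(Z) / 2
  Zc <- sweep(Z, 2, 2 * p)
  expected <- (Zc %*% t(Zc)) / (2 * sum(p * (1 - p)))
  expect_equal(unclass(G), expected, ignore_attr = TRUE, tolerance = 1e-14)

  # duplicate genotypes ("identical twins"): G_jk equals G_jj
  Zt <- rbind(Z, a5 = Z["a1", ])
  Gt <- build_grm(Zt)
  expect_equal(Gt["a1", "a5"], Gt["a1", "a1"], tolerance = 1e-12)

  expect_error(build_grm(cbind(Z, mono = c(2, 2, 2, 2))), "monomorphic")
})

test_that("GRM mean diagonal is near 1 for an unrelated panel", {
  Z <- unrelated_panel(n = 200, n_snps = 1000, seed = 42)
  G <- build_grm(Z)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  expect_true(is_psd(G))
})

test_that("kernels are symmetric PSD and permutation-consistent", {
  sim <- simulate_dataset(n_pairs = 30, n_snps = 300, n_otu = 80, seed = 2)
  for (K in list(sim$G, sim$M)) {
    expect_true(is_psd(K))
    expect_equal(unclass(K), t(unclass(K)), tolerance = 1e-10)
  }
  # permuting input animals permutes kernel rows/cols consistently
  perm <- sample(nrow(sim$otu))
  S1 <- build_log_abundance(sim$otu)
  M1 <- build_microbial_kernel(S1)
  M2 <- build_microbial_kernel(build_log_abundance(sim$otu[perm, ]))
  expect_equal(unclass(M2), unclass(M1)[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("filter-then-build equals build-on-filtered columns", {
  sim <- simulate_dataset(n_pairs = 25, n_snps = 200, n_otu = 120, seed = 3)
  filt <- filter_otus(sim$otu, 2, 1e-4)
  M_filt <- build_microbial_kernel(build_log_abundance(filt))
  M_cols <- build_microbial_kernel(
    build_log_abundance(sim$otu[, colnames(filt), drop = FALSE]))
  expect_equal(unclass(M_filt), unclass(M_cols), tolerance = 1e-12)
})

test_that("diet-specific kernels have exact zero cross-diet blocks", {
  set.seed(7)
  F_ <- matrix(rnorm(4 * 6), 4, 6,
               dimnames = list(paste0("a", 1:4), NULL))
  diet <- c("CO", "HF", "CO", "HF")
  kk <- build_diet_specific_kernels(F_, diet, kind = "toy")
  co <- which(diet == "CO"); hf <- which(diet == "HF")
  expect_true(all(unclass(kk$specific)[co, hf] == 0))
  expect_true(all(unclass(kk$specific_by_diet$CO)[hf, hf] == 0))

  # within-diet block equals the kernel built from that diet alone
  own <- tcrossprod(F_[co, ]) / 6
  expect_equal(unclass(kk$specific_by_diet$CO)[co, co], own, tolerance = 1e-12)

  # brute-force block assembly oracle
  brute <- matrix(0, 4, 4)
  brute[co, co] <- tcrossprod(F_[co, ]) / 6
  brute[hf, hf] <- tcrossprod(F_[hf, ]) / 6
  expect_equal(unclass(kk$specific), brute, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(kk$main), tcrossprod(F_) / 6, ignore_attr = TRUE,
               tolerance = 1e-12)

  expect_error(build_diet_specific_kernels(F_, c("CO", "CO", "CO", "HF")),
               "at least 2")
})

test_that("kernel TSV round trip preserves the matrix", {
  G <- build_grm(unrelated_panel(n = 8, n_snps = 50, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel_tsv(G, path)
  G2 <- read_kernel_tsv(path, kind = "genomic")
  expect_equal(unclass(G2), unclass(G), tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(rownames(G2), rownames(G))
})
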