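test_that("rarefaction subsamples to exact depth without inventing counts", {
  otu <- rbind(s1 = c(3000L, 3000L),        # total 6000 < depth -> dropped
               s2 = c(6000L, 6000L),
               s3 = c(10000L, 0L))          # total exactly depth
  colnames(otu) <- c("o1", "o2")
  r <- rarefy(otu, depth = 10000, seed = 1)
  expect_equal(rownames(r), c("s2", "s3"))
  expect_true(all(rowSums(r) == 10000))
  expect_equal(attr(r, "report")$dropped_samples, "s1")
  expect_equal(r["s3", ], c(o1 = 10000L, o2 = 0L))   # full-total sample unchanged
  expect_true(all(r <= otu[c("s2", "s3"), ]))        # never exceeds originals
  expect_error(rarefy(otu, depth = 0), "positive")
})

test_that("rarefaction matches the hypergeometric expectation", {
  # (6000, 6000) subsampled to 10000: each OTU has mean 5000 and
  # SD sqrt(10000 * .5 * .5 * 2000/11999) ~ 20.4
  otu <- matrix(c(6000L, 6000L), 1, dimnames = list("s", c("o1", "o2")))
  draws <- vapply(1:20, function(i) rarefy(otu, 10000, seed = i)[1, 1],
                  integer(1))
  sd_hyper <- sqrt(10000 * 0.25 * (12000 - 10000) / (12000 - 1))
  expect_lt(abs(mean(draws) - 5000), 3 * sd_hyper / sqrt(20))
  # support preservation: an absent OTU stays absent
  otu2 <- matrix(c(12000L, 0L), 1, dimnames = list("s", c("o1", "o2")))
  expect_equal(unname(rarefy(otu2, 10000, seed = 1)[1, "o2"]), 0L)
})

test_that("OTU filtering applies strict prevalence and abundance thresholds", {
  # 10 samples; otuA present in exactly 5 -> dropped under min_samples = 5
  counts <- matrix(0L, 10, 3,
                   dimnames = list(paste0("s", 1:10), c("otuA", "otuB", "otuC")))
  counts[1:5, "otuA"] <- 100L
  counts[1:6, "otuB"] <- 100L
  counts[, "otuC"] <- 1000L
  f <- filter_otus(counts, min_samples_present = 5,
                   min_mean_abundance_fraction = 0)
  expect_false("otuA" %in% colnames(f))   # "more than five samples" is strict
  expect_true(all(c("otuB", "otuC") %in% colnames(f)))

  # no-op thresholds keep every OTU with any count
  f0 <- filter_otus(counts, 0, 0)
  expect_equal(colnames(f0), colnames(counts))
})

test_that("filtering matches a brute-force evaluation on a toy table", {
  otu <- toy_otu()   # 4 samples x 3 OTU
  spec_s <- 1; spec_f <- 0.05
  f <- filter_otus(otu, spec_s, spec_f)
  # independent brute-force evaluation of both criteria
  keep <- logical(ncol(otu))
  for (k in seq_len(ncol(otu))) {
    prev <- sum(otu[, k] > 0)
    mean_ab <- mean(otu[, k] / rowSums(otu))
    keep[k] <- (prev > spec_s) && (mean_ab > spec_f)
  }
  expect_equal(colnames(f), colnames(otu)[keep])
  expect_equal(attr(f, "report")$dropped_total, sum(!keep))
  expect_error(filter_otus(otu, 10, 0.9), "relax")
})

test_that("filtering is idempotent and monotone in the thresholds", {
  sim <- simulate_dataset(n_pairs = 20, n_snps = 100, n_otu = 150, seed = 4)
  once <- filter_otus(sim$otu, 3, 1e-4)
  twice <- filter_otus(once, 3, 1e-4)
  expect_equal(colnames(twice), colnames(once))
  expect_equal(unname(unclass(twice)), unname(unclass(once)),
               ignore_attr = TRUE)
  # stricter spec retains a subset
  stricter <- filter_otus(sim$otu, 6, 1e-3)
  expect_true(all(colnames(stricter) %in% colnames(once)))
})

test_that("genotype QC drops individuals, then SNPs, then imputes", {
  set.seed(9)
  Z <- unrelated_panel(n = 100, n_snps = 40, seed = 9)
  Z[, 1] <- 1L                                   # all-het: HWE P << 1e-6
  Z[, 2] <- 0L                                   # monomorphic: MAF 0
  Z[1, 3] <- NA                                  # one missing (cr 39/40) -> imputed
  Z[2, 4:40] <- NA                               # individual 2: call rate 3/40
  q <- qc_genotypes(Z, ind_call_rate = 0.95, snp_call_rate = 0.95,
                    min_maf = 0.05, hwe_alpha = 1e-6)
  rep <- attr(q, "report")
  expect_equal(rep$dropped_individuals, 1)
  expect_false("a2" %in% rownames(q))
  expect_false("snp1" %in% colnames(q))          # HWE failure
  expect_false("snp2" %in% colnames(q))          # MAF failure
  expect_false(anyNA(q))
  # imputed value is the column mean dosage = 2 * allele frequency
  obs <- Z[-c(1, 2), 3]
  expect_equal(q["a1", "snp3"], mean(obs), tolerance = 1e-12)
})

test_that("HWE chi-square test matches an independent oracle", {
  # all-heterozygous SNP, n = 100: expected (25, 50, 25), observed (0, 100, 0)
  p <- hwe_test(rep(1, 100))
  x2 <- (0 - 25)^2 / 25 + (100 - 50)^2 / 50 + (0 - 25)^2 / 25
  expect_equal(p, pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(p, 1e-6)
  # HWE-balanced SNP passes
  d <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  expect_gt(hwe_test(d), 0.99)
  # clean matrix survives QC untouched
  Zc <- matrix(rep(d, 3), ncol = 3,
               dimnames = list(paste0("a", 1:100), paste0("s", 1:3)))
  q <- qc_genotypes(Zc)
  expect_equal(dim(q), dim(Zc))
})
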