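#' Rarefy an OTU count table to a common depth
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose total is below
#' `depth` cannot be rarefied and are dropped; their ids are recorded in the
#' `report` attribute. A sample whose total equals `depth` is returned
#' unchanged.
#'
#' @param otu integer count matrix, samples x OTU.
#' @param depth target depth (the study design rarefies to 10,000 reads per
#'   sample).
#' @param seed integer seed for the subsampling.
#' @return rarefied count matrix with attributes `rarefied_depth` and
#'   `report` (list with `dropped_samples`).
#' @export
rarefy <- function(otu, depth = 10000, seed = 1) {
  if (depth <= 0) stop("depth must be a positive integer")
  otu <- as.matrix(otu)
  totals <- rowSums(otu)
  drop <- totals < depth
  kept <- otu[!drop, , drop = FALSE]
  set.seed(seed)
  out <- t(apply(kept, 1, function(counts) {
    tot <- sum(counts)
    if (tot == depth) return(counts)
    picked <- sample.int(tot, depth)                 # positions in the read pool
    pool_otu <- rep.int(seq_along(counts), counts)   # read -> OTU index
    tabulate(pool_otu[picked], nbins = length(counts))
  }))
  dimnames(out) <- dimnames(kept)
  storage.mode(out) <- "integer"
  attr(out, "rarefied_depth") <- as.integer(depth)
  attr(out, "report") <- list(dropped_samples = rownames(otu)[drop])
  out
}

#' Filter OTU on prevalence and mean relative abundance
#'
#' Retains OTU present (count > 0) in *more than* `min_samples_present`
#' samples AND with mean per-sample relative abundance *higher than*
#' `min_mean_abundance_fraction` (both comparisons strict). The study's three
#' editing scenarios are: no filtering; `> 5` samples and `> 0.001%`
#' (fraction 1e-5); `> 5` samples and `> 0.01%` (fraction 1e-4).
#'
#' @param otu count matrix, samples x OTU.
#' @param min_samples_present strict prevalence threshold (count of samples).
#' @param min_mean_abundance_fraction strict threshold on the mean across
#'   samples of per-sample relative abundance (counts / sample total).
#' @param abundance_mode `"per_sample_mean"` (default: mean of per-sample
#'   fractions) or `"global"` (OTU total / grand total).
#' @return filtered count matrix with attribute `report` giving per-criterion
#'   drop counts.
#' @export
filter_otus <- function(otu, min_samples_present = 5,
                        min_mean_abundance_fraction = 1e-5,
                        abundance_mode = c("per_sample_mean", "global")) {
  abundance_mode <- match.arg(abundance_mode)
  otu <- as.matrix(otu)
  if (ncol(otu) == 0 || nrow(otu) == 0) stop("empty OTU table")
  stopifnot(min_samples_present >= 0,
            min_mean_abundance_fraction >= 0, min_mean_abundance_fraction <= 1)

  prevalence <- colSums(otu > 0)
  totals <- rowSums(otu)
  if (abundance_mode == "per_sample_mean") {
    rel <- sweep(otu, 1, pmax(totals, 1), "/")
    mean_ab <- colMeans(rel)
  } else {
    mean_ab <- colSums(otu) / max(sum(totals), 1)
  }

  pass_prev <- prevalence > min_samples_present
  pass_ab <- mean_ab > min_mean_abundance_fraction
  keep <- pass_prev & pass_ab
  if (!any(keep)) stop("all OTU removed; relax min_samples_present or the abundance threshold")

  out <- otu[, keep, drop = FALSE]
  attr(out, "rarefied_depth") <- attr(otu, "rarefied_depth")
  attr(out, "report") <- list(
    n_input = ncol(otu), n_kept = sum(keep),
    dropped_prevalence = sum(!pass_prev),
    dropped_abundance = sum(!pass_ab),
    dropped_total = sum(!keep))
  out
}

#' Hardy-Weinberg equilibrium chi-square test for one SNP
#'
#' Goodness-of-fit test (1 df) of observed genotype counts against the
#' frequencies implied by the observed allele frequency.
#'
#' @param dosages vector of 0/1/2 dosages, `NA` allowed (excluded).
#' @return p-value; `NA` if fewer than 2 informative genotypes or monomorphic.
#' @export
hwe_test <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n <- length(d)
  if (n < 2) return(NA_real_)
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  q <- (2 * obs[3] + obs[2]) / (2 * n)   # frequency of the counted allele
  if (q <= 0 || q >= 1) return(NA_real_)
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  x2 <- sum((obs - expd)^2 / expd)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Quality control of a genotype matrix
#'
#' Applies, in order: (1) drop individuals with call rate below
#' `ind_call_rate`; (2) drop SNPs with call rate below `snp_call_rate`, minor
#' allele frequency below `min_maf`, or Hardy-Weinberg chi-square P below
#' `hwe_alpha`; (3) impute remaining missing dosages to twice the observed
#' allele frequency (column mean dosage), as required for GRM construction.
#' The defaults are the study's thresholds (95% call rates, MAF 5%,
#' HWE P < 1e-6).
#'
#' @param geno dosage matrix, animals x SNPs, entries in `{0,1,2,NA}`.
#' @param ind_call_rate minimum per-individual genotype call rate.
#' @param snp_call_rate minimum per-SNP call rate.
#' @param min_maf minimum minor allele frequency (strict `<` removal).
#' @param hwe_alpha HWE significance threshold (strict `<` removal).
#' @return imputed numeric dosage matrix with attribute `report` (counts
#'   dropped per rule).
#' @export
qc_genotypes <- function(geno, ind_call_rate = 0.95, snp_call_rate = 0.95,
                         min_maf = 0.05, hwe_alpha = 1e-6) {
  Z <- as.matrix(geno)
  bad <- !is.na(Z) & !(Z %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")

  ind_cr <- rowMeans(!is.na(Z))
  keep_ind <- ind_cr >= ind_call_rate
  Z <- Z[keep_ind, , drop = FALSE]
  if (nrow(Z) == 0) stop("no individuals survive the call-rate filter")

  snp_cr <- colMeans(!is.na(Z))
  p_hat <- colMeans(Z, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  hwe_p <- apply(Z, 2, hwe_test)

  fail_cr <- snp_cr < snp_call_rate
  fail_maf <- maf < min_maf
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  keep_snp <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep_snp)) stop("no SNPs survive QC")
  Z <- Z[, keep_snp, drop = FALSE]

  # mean imputation = 2 * allele frequency, per SNP
  for (j in which(colSums(is.na(Z)) > 0)) {
    Z[is.na(Z[, j]), j] <- mean(Z[, j], na.rm = TRUE)
  }

  attr(Z, "report") <- list(
    dropped_individuals = sum(!keep_ind),
    dropped_snp_call_rate = sum(fail_cr),
    dropped_snp_maf = sum(fail_maf),
    dropped_snp_hwe = sum(fail_hwe),
    n_individuals = nrow(Z), n_snps = ncol(Z))
  Z
}
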