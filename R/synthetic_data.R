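#' Build a full-sib, two-diet population design
#'
#' Emulates the study design: sires mated to several dams, each dam
#' contributing exactly one pair of full sibs, and within every pair one sib
#' assigned to the conventional (CO) diet and the other to the high-fiber
#' (HF) diet. Animals are grouped into batches and into pens nested within
#' batch and diet.
#'
#' @param n_sires number of sires.
#' @param n_dams_per_sire dams (= full-sib pairs) per sire.
#' @param pairs_per_batch full-sib pairs per batch.
#' @param pen_size animals per pen within a batch-diet group.
#' @param seed integer seed controlling the (arbitrary) within-pair diet
#'   assignment order.
#' @return data.frame with one row per offspring: `animal_id`, `sire`, `dam`,
#'   `pair`, `diet` (CO/HF), `batch`, `pen` (nested label `batch.diet.k`).
#' @export
make_population_design <- function(n_sires = 50, n_dams_per_sire = 6,
                                   pairs_per_batch = 25, pen_size = 14,
                                   seed = 1) {
  stopifnot(n_sires >= 1, n_dams_per_sire >= 1)
  set.seed(seed)
  n_pairs <- n_sires * n_dams_per_sire
  pair <- seq_len(n_pairs)
  sire <- rep(seq_len(n_sires), each = n_dams_per_sire)
  dam <- pair  # each dam appears in exactly one pair

  # one CO and one HF sib per pair; randomize which is listed first
  first_co <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
  design <- data.frame(
    animal_id = sprintf("id%04d_%s", rep(pair, each = 2),
                        as.vector(rbind(ifelse(first_co, "CO", "HF"),
                                        ifelse(first_co, "HF", "CO")))),
    sire = sprintf("s%03d", rep(sire, each = 2)),
    dam = sprintf("d%04d", rep(dam, each = 2)),
    pair = rep(pair, each = 2),
    diet = as.vector(rbind(ifelse(first_co, "CO", "HF"),
                           ifelse(first_co, "HF", "CO"))),
    stringsAsFactors = FALSE)

  design$batch <- sprintf("b%02d", (design$pair - 1) %/% pairs_per_batch + 1)
  # pens nested in batch x diet
  design$pen <- NA_character_
  for (b in unique(design$batch)) {
    for (dt in c("CO", "HF")) {
      idx <- which(design$batch == b & design$diet == dt)
      design$pen[idx] <- sprintf("%s.%s.p%d", b, dt,
                                 (seq_along(idx) - 1) %/% pen_size + 1)
    }
  }
  design
}

#' Simulate SNP dosages by Mendelian gene dropping
#'
#' Per-SNP allele frequencies are drawn uniformly from `maf_range`; founder
#' (sire/dam) genotypes are Binomial(2, p) and each offspring receives one
#' allele from each parent (heterozygous parents transmit either allele with
#' probability 1/2). SNPs are independent (no linkage disequilibrium), which
#' is sufficient for kernel-level analyses because the models only use the
#' genomic relationship matrix. Full sibs share on average half their alleles
#' identical-by-descent.
#'
#' @param design population design from [make_population_design()].
#' @param n_snps number of SNPs.
#' @param maf_range allele-frequency interval, subset of (0, 0.5].
#' @param missing_rate fraction of dosages set missing at random.
#' @param seed integer seed.
#' @return integer dosage matrix offspring x SNPs (rownames = animal ids),
#'   entries 0/1/2 with `NA` for missing.
#' @export
simulate_genotypes <- function(design, n_snps, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1) {
  if (nrow(design) == 0) stop("empty design")
  stopifnot(n_snps >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  set.seed(seed)
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])

  sires <- unique(design$sire)
  dams <- unique(design$dam)
  # founder genotypes stored as two haplotypes so transmission is by haplotype
  hap <- function(n) matrix(stats::rbinom(n * n_snps, 1, rep(p, each = n)),
                            nrow = n, byrow = FALSE)
  sire_h1 <- hap(length(sires)); sire_h2 <- hap(length(sires))
  dam_h1 <- hap(length(dams)); dam_h2 <- hap(length(dams))
  rownames(sire_h1) <- rownames(sire_h2) <- sires
  rownames(dam_h1) <- rownames(dam_h2) <- dams

  n_off <- nrow(design)
  Z <- matrix(0L, n_off, n_snps,
              dimnames = list(design$animal_id,
                              sprintf("snp%05d", seq_len(n_snps))))
  for (i in seq_len(n_off)) {
    s <- design$sire[i]; d <- design$dam[i]
    pick_s <- stats::rbinom(n_snps, 1, 0.5)
    pick_d <- stats::rbinom(n_snps, 1, 0.5)
    a1 <- ifelse(pick_s == 1, sire_h1[s, ], sire_h2[s, ])
    a2 <- ifelse(pick_d == 1, dam_h1[d, ], dam_h2[d, ])
    Z[i, ] <- as.integer(a1 + a2)
  }
  if (missing_rate > 0) {
    Z[matrix(stats::runif(length(Z)) < missing_rate, nrow(Z))] <- NA_integer_
  }
  Z
}

#' Simulate a rarefied OTU count table
#'
#' Latent per-animal log-abundances are an OTU baseline (normal on the log
#' scale across OTU, i.e. log-normal abundances), plus a diet shift applied
#' to a configurable subset of OTU for HF animals, plus per-animal noise.
#' Counts are drawn multinomially with exactly `depth` reads per sample, so
#' every row sum equals `depth` (the table is born rarefied).
#'
#' @param design population design (uses `animal_id` and `diet`).
#' @param n_otu number of OTU (>= 2).
#' @param depth reads per sample.
#' @param log_abundance_sd SD of the OTU baseline on the log scale; larger
#'   values give more skewed, sparser compositions.
#' @param diet_shift additive log-scale shift applied to the shifted OTU set
#'   for HF animals.
#' @param shift_fraction fraction of OTU in the diet-shifted set.
#' @param animal_sd SD of per-animal, per-OTU log-scale noise (drives
#'   between-animal microbiota variation).
#' @param seed integer seed.
#' @return integer count matrix animals x OTU with attributes
#'   `rarefied_depth` and `shifted_otus` (ids of the diet-responsive set).
#' @export
simulate_otu_table <- function(design, n_otu = 500, depth = 10000,
                               log_abundance_sd = 1.5, diet_shift = 1,
                               shift_fraction = 0.1, animal_sd = 1,
                               seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  stopifnot(n_otu >= 2)
  set.seed(seed)
  baseline <- stats::rnorm(n_otu, 0, log_abundance_sd)
  shifted <- seq_len(max(1, round(shift_fraction * n_otu)))
  otu_ids <- sprintf("otu%04d", seq_len(n_otu))

  n <- nrow(design)
  counts <- matrix(0L, n, n_otu, dimnames = list(design$animal_id, otu_ids))
  for (i in seq_len(n)) {
    eta <- baseline + stats::rnorm(n_otu, 0, animal_sd)
    if (design$diet[i] == "HF") eta[shifted] <- eta[shifted] + diet_shift
    pr <- exp(eta - max(eta))
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, pr))
  }
  attr(counts, "rarefied_depth") <- as.integer(depth)
  attr(counts, "shifted_otus") <- otu_ids[shifted]
  counts
}

#' Generating truth for synthetic phenotypes
#'
#' Holds the variance components used to generate phenotypes under
#' `y = Xb + Zu + Wm + e` with `u ~ N(0, G s2_u)`, `m ~ N(0, M s2_m)`,
#' `e ~ N(0, I s2_e)`. For diet-interaction scenarios, supply the main and
#' diet-specific components instead (`sigma2_u0`/`sigma2_uCO`/`sigma2_uHF`,
#' and likewise for `m`); the corresponding effect is then generated as
#' main-plus-specific draws from the interaction kernels, matching the
#' decomposition the interaction models fit.
#'
#' @param sigma2_u,sigma2_m,sigma2_e genetic, microbial, residual variances.
#' @param sigma2_u0,sigma2_uCO,sigma2_uHF main and diet-specific genetic
#'   variances (all three or none).
#' @param sigma2_m0,sigma2_mCO,sigma2_mHF main and diet-specific microbial
#'   variances (all three or none).
#' @param pen_effect_sd SD of the fixed pen-within-batch effects.
#' @param mu intercept.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(sigma2_u = 0.25, sigma2_m = 0.50, sigma2_e = 0.25,
                            sigma2_u0 = NULL, sigma2_uCO = NULL, sigma2_uHF = NULL,
                            sigma2_m0 = NULL, sigma2_mCO = NULL, sigma2_mHF = NULL,
                            pen_effect_sd = 0.5, mu = 10) {
  vals <- c(sigma2_u, sigma2_m, sigma2_e,
            sigma2_u0, sigma2_uCO, sigma2_uHF,
            sigma2_m0, sigma2_mCO, sigma2_mHF)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all variances must be finite and non-negative")
  }
  gx <- c(is.null(sigma2_u0), is.null(sigma2_uCO), is.null(sigma2_uHF))
  mx <- c(is.null(sigma2_m0), is.null(sigma2_mCO), is.null(sigma2_mHF))
  if (length(unique(gx)) > 1 || length(unique(mx)) > 1) {
    stop("supply all three interaction variances (main, CO, HF) or none")
  }
  structure(list(sigma2_u = sigma2_u, sigma2_m = sigma2_m, sigma2_e = sigma2_e,
                 sigma2_u0 = sigma2_u0, sigma2_uCO = sigma2_uCO,
                 sigma2_uHF = sigma2_uHF,
                 sigma2_m0 = sigma2_m0, sigma2_mCO = sigma2_mCO,
                 sigma2_mHF = sigma2_mHF,
                 pen_effect_sd = pen_effect_sd, mu = mu),
            class = "synthetic_truth")
}

# draw x ~ N(0, K * s2) through the eigendecomposition of K (PSD required).
# With normalize = TRUE the kernel is first scaled to unit mean diagonal over
# its support (animals with a nonzero diagonal entry), so that s2 is the
# phenotypic variance contributed per animal — this keeps the truth
# invariant h2 = s2_u / (s2_u + s2_m + s2_e) meaningful for kernels whose
# raw diagonal is not ~1 (e.g. the F F'/d interaction kernels).
draw_from_kernel <- function(K, s2, normalize = FALSE) {
  if (s2 == 0) return(rep(0, nrow(K)))
  if (!is_psd(K, tol = 1e-6)) stop("kernel is not positive semi-definite")
  K <- unclass(K)
  if (normalize) {
    dg <- diag(K)
    K <- K / mean(dg[dg > 1e-12])
  }
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  as.vector(eg$vectors %*% (sqrt(d * s2) * stats::rnorm(length(d))))
}

#' Simulate phenotypes from genotypes and an OTU table
#'
#' Builds the genomic and microbial kernels, draws the genetic, microbial and
#' residual effects at the variances in `truth`, adds fixed pen-within-batch
#' effects, and returns the phenotype table together with the true effect
#' vectors (the recovery targets for the fitted models). When `truth` carries
#' interaction components, `u` (and/or `m`) is generated as a main draw from
#' the full-panel kernel plus diet-specific draws from the block kernels.
#'
#' @param genotypes complete dosage matrix (monomorphic SNPs are dropped
#'   internally before kernel construction).
#' @param otu count matrix aligned to the same animals.
#' @param truth a [synthetic_truth()].
#' @param design population design providing diet/batch/pen columns.
#' @param trait name of the generated trait column.
#' @param seed integer seed.
#' @return list: `phenotypes` (data.frame `animal_id`, `diet`, `batch`,
#'   `pen`, trait), `u`, `m`, `e` (true effect vectors), `G`, `M`, `S`
#'   (kernels and log-abundance matrix), `pen_effects`, and `truth`.
#' @export
simulate_phenotypes <- function(genotypes, otu, truth, design,
                                trait = "trait", seed = 1) {
  Z <- as.matrix(genotypes)
  W <- as.matrix(otu)
  if (!identical(rownames(Z), rownames(W)) ||
      !identical(rownames(Z), design$animal_id)) {
    stop("genotype, OTU and design animal sets must be identical and in the same order")
  }
  set.seed(seed)
  poly <- apply(Z, 2, function(x) length(unique(x)) > 1)
  G <- build_grm(Z[, poly, drop = FALSE])
  S <- build_log_abundance(W)
  M <- build_microbial_kernel(S)
  n <- nrow(Z)

  if (!is.null(truth$sigma2_u0)) {
    gk <- build_diet_specific_kernels(center_dosages(Z[, poly, drop = FALSE]),
                                      design$diet, kind = "genomic")
    u <- draw_from_kernel(gk$main, truth$sigma2_u0, normalize = TRUE) +
      draw_from_kernel(gk$specific_by_diet$CO, truth$sigma2_uCO, normalize = TRUE) +
      draw_from_kernel(gk$specific_by_diet$HF, truth$sigma2_uHF, normalize = TRUE)
  } else {
    u <- draw_from_kernel(G, truth$sigma2_u)
  }
  if (!is.null(truth$sigma2_m0)) {
    mk <- build_diet_specific_kernels(S, design$diet, kind = "microbial")
    m <- draw_from_kernel(mk$main, truth$sigma2_m0, normalize = TRUE) +
      draw_from_kernel(mk$specific_by_diet$CO, truth$sigma2_mCO, normalize = TRUE) +
      draw_from_kernel(mk$specific_by_diet$HF, truth$sigma2_mHF, normalize = TRUE)
  } else {
    m <- draw_from_kernel(M, truth$sigma2_m)
  }
  e <- stats::rnorm(n, 0, sqrt(truth$sigma2_e))

  pens <- unique(design$pen)
  pen_eff <- stats::setNames(stats::rnorm(length(pens), 0, truth$pen_effect_sd),
                             pens)
  y <- truth$mu + pen_eff[design$pen] + u + m + e

  phen <- data.frame(animal_id = design$animal_id, diet = design$diet,
                     batch = design$batch, pen = design$pen,
                     stringsAsFactors = FALSE)
  phen[[trait]] <- as.numeric(y)
  names(u) <- names(m) <- names(e) <- design$animal_id

  list(phenotypes = phen, u = u, m = m, e = e, G = G, M = M, S = S,
       pen_effects = pen_eff, truth = truth)
}

#' Residual feed intake by multiple linear regression
#'
#' RFI is the residual of a single ordinary least-squares multiple regression
#' of feed intake on production traits (conventionally: daily feed intake on
#' average daily gain, lean meat percentage, carcass yield and average
#' metabolic body weight), pooled across both diets. Residuals sum to zero
#' over the fitted animals.
#'
#' @param phenotypes data.frame with `animal_id` and the trait columns.
#' @param response name of the regressed trait (e.g. `"DFI"`).
#' @param predictors character vector of predictor column names.
#' @return named numeric vector of residuals for animals with complete data,
#'   aligned by `animal_id`.
#' @export
compute_rfi <- function(phenotypes, response = "DFI",
                        predictors = c("ADG", "lean_pct", "carcass_yield",
                                       "avg_metabolic_bw")) {
  missing_cols <- setdiff(c(response, predictors), names(phenotypes))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  dat <- phenotypes[, c("animal_id", response, predictors)]
  dat <- dat[stats::complete.cases(dat), ]
  Xp <- as.matrix(dat[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, Xp))
  if (qrX$rank < ncol(Xp) + 1) {
    dropped <- c("(Intercept)", predictors)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient predictor matrix; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(stats::reformulate(predictors, response = response),
                   data = dat)
  stats::setNames(stats::residuals(fit), dat$animal_id)
}

#' Simulate a complete study dataset
#'
#' One call wiring the generator together: design, genotypes, OTU table,
#' phenotype with known variance-component truth, plus a battery of
#' production traits (DFI, ADG, lean meat percentage, carcass yield, average
#' metabolic body weight) from which residual feed intake can be computed.
#'
#' @param n_pairs number of full-sib pairs (animals = 2 x pairs).
#' @param n_snps,n_otu,depth generator sizes.
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @return list: `design`, `genotypes`, `otu`, and all elements of
#'   [simulate_phenotypes()] (phenotype table extended with production
#'   traits and `RFI`).
#' @export
simulate_dataset <- function(n_pairs = 300, n_snps = 2000, n_otu = 500,
                             depth = 10000, truth = synthetic_truth(),
                             seed = 1) {
  n_sires <- max(1L, round(n_pairs / 6))
  design <- make_population_design(n_sires = n_sires,
                                   n_dams_per_sire = ceiling(n_pairs / n_sires),
                                   seed = seed)
  design <- design[design$pair <= n_pairs, , drop = FALSE]
  geno <- simulate_genotypes(design, n_snps = n_snps, seed = seed + 1)
  otu <- simulate_otu_table(design, n_otu = n_otu, depth = depth,
                            seed = seed + 2)
  sim <- simulate_phenotypes(geno, otu, truth, design, seed = seed + 3)

  # correlated production traits for the RFI regression
  set.seed(seed + 4)
  n <- nrow(design)
  adg <- stats::rnorm(n, 0.9, 0.08)
  mbw <- 70 + 40 * adg + stats::rnorm(n, 0, 2)      # metabolic BW tracks growth
  lean <- stats::rnorm(n, 60, 2) - 5 * (adg - 0.9)
  cy <- stats::rnorm(n, 78, 1.5)
  dfi <- 0.3 + 2.2 * adg + 0.01 * mbw - 0.02 * (lean - 60) +
    stats::rnorm(n, 0, 0.12)
  sim$phenotypes$ADG <- adg
  sim$phenotypes$avg_metabolic_bw <- mbw
  sim$phenotypes$lean_pct <- lean
  sim$phenotypes$carcass_yield <- cy
  sim$phenotypes$DFI <- dfi
  rfi <- compute_rfi(sim$phenotypes)
  sim$phenotypes$RFI <- rfi[sim$phenotypes$animal_id]

  c(list(design = design, genotypes = geno, otu = otu), sim)
}
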