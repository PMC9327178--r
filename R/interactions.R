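#' Interaction correlation from main and diet-specific variances
#'
#' `r = s2_main / sqrt((s2_CO + s2_main) * (s2_HF + s2_main))`: the implied
#' correlation across diets of the total (main + specific) effect. Equals 1
#' when the diet-specific variances vanish and 0 when the main variance
#' vanishes; invariant to rescaling all three variances by a common factor.
#'
#' @param s2_main,s2_CO,s2_HF variances (vectors allowed, e.g. draws).
#' @return numeric correlation(s) in `[0, 1]`.
#' @export
interaction_correlation <- function(s2_main, s2_CO, s2_HF) {
  s2_main / sqrt((s2_CO + s2_main) * (s2_HF + s2_main))
}

#' Classify an interaction correlation against the 0.80 threshold
#'
#' Correlations *lower than* the threshold (strict) indicate an interaction
#' substantial enough that selection outcomes would differ between diets.
#'
#' @param r correlation in `[0, 1]`.
#' @param threshold decision threshold (default 0.80).
#' @return `"substantial_interaction"` or `"negligible"`.
#' @export
classify_interaction <- function(r, threshold = 0.80) {
  if (is.na(r) || r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (r < threshold) "substantial_interaction" else "negligible"
}

#' Fit a main-plus-diet-specific variance decomposition
#'
#' Fits `y = Xb + g0 + g1 + e` where `g0 ~ N(0, K_main s2_main)` is the
#' cross-diet main effect and `g1` is diet-specific with one variance per
#' diet block: `g1 ~ N(0, blockdiag(K_CO s2_CO, K_HF s2_HF))`, all kernels
#' sharing the same feature-count divisor. Implemented as a three-kernel
#' [fit_rkhs()] (main + two zero-padded block kernels), which is the same
#' likelihood. The interaction correlation is computed per retained draw and
#' then summarized; the correlation at the posterior means is also reported.
#'
#' @param phenotypes data.frame with `animal_id`, `diet`, the trait and
#'   fixed-effect columns; both diets must be present among phenotyped
#'   animals.
#' @param trait trait column name.
#' @param features centered feature matrix (animals x features) with animal
#'   ids as rownames: log-abundances `S` for the microbiota-by-diet model,
#'   `2p`-centered dosages for the genotype-by-diet model.
#' @param fixed fixed-effect columns.
#' @param divisor feature-count denominator (defaults to `ncol(features)`).
#' @param kind label stem (`"genomic"` or `"microbial"`).
#' @param threshold decision threshold for [classify_interaction()].
#' @param ... passed to [fit_rkhs()] (notably `mcmc`).
#' @return list of class `interaction_result`: posterior means/SDs of
#'   `sigma2_main`, `sigma2_CO`, `sigma2_HF`, `r_mean`/`r_sd` (posterior of
#'   draw-wise r), `r_at_means` (ratio of posterior means), `flag`, and the
#'   underlying `fit`.
#' @export
fit_diet_interaction <- function(phenotypes, trait, features,
                                 fixed = character(), divisor = NULL,
                                 kind = "feature", threshold = 0.80, ...) {
  keep <- !is.na(phenotypes[[trait]])
  dat <- phenotypes[keep, , drop = FALSE]
  diets <- unique(dat$diet)
  if (length(diets) < 2) stop("both diets must be represented among phenotyped animals")

  F_ <- as.matrix(features)
  if (is.null(rownames(F_)) || !all(dat$animal_id %in% rownames(F_))) {
    stop("feature matrix does not cover all phenotyped animals")
  }
  F_ <- F_[dat$animal_id, , drop = FALSE]
  if (is.null(divisor)) divisor <- ncol(F_)

  kk <- build_diet_specific_kernels(F_, dat$diet, divisor = divisor,
                                    kind = kind)
  kernels <- list(main = kk$main,
                  CO = kk$specific_by_diet[["CO"]],
                  HF = kk$specific_by_diet[["HF"]])
  fit <- fit_trait_model(dat, trait, kernels, fixed = fixed, ...)

  s2 <- fit$sigma2
  r_draws <- interaction_correlation(s2[, "main"], s2[, "CO"], s2[, "HF"])
  mu <- colMeans(s2)
  r_mean <- mean(r_draws)
  res <- list(
    sigma2_main = mu[["main"]], sigma2_CO = mu[["CO"]], sigma2_HF = mu[["HF"]],
    sd_main = stats::sd(s2[, "main"]), sd_CO = stats::sd(s2[, "CO"]),
    sd_HF = stats::sd(s2[, "HF"]),
    r_mean = r_mean, r_sd = stats::sd(r_draws),
    r_at_means = interaction_correlation(mu[["main"]], mu[["CO"]], mu[["HF"]]),
    flag = classify_interaction(min(max(r_mean, 0), 1), threshold),
    kind = kind, fit = fit)
  class(res) <- "interaction_result"
  res
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "<interaction_result> %s: s2_main=%.4f s2_CO=%.4f s2_HF=%.4f  r=%.3f (SD %.3f) [%s]\n",
    x$kind, x$sigma2_main, x$sigma2_CO, x$sigma2_HF, x$r_mean, x$r_sd, x$flag))
  invisible(x)
}

#' Genotype-by-diet interaction model
#'
#' Main-plus-diet-specific decomposition of the genetic variance; features
#' are the mean-centered SNP dosages and the divisor is the SNP count, so
#' the main kernel is `Z_c Z_c' / d` and each specific block
#' `Z_diet Z_diet' / d`.
#'
#' @param phenotypes,trait,fixed,... as in [fit_diet_interaction()].
#' @param genotypes complete (QC-imputed) dosage matrix with animal ids as
#'   rownames.
#' @return an `interaction_result`; `r_mean` is the genomic cross-diet
#'   correlation r_g.
#' @export
fit_gxd <- function(phenotypes, trait, genotypes, fixed = character(), ...) {
  Z <- as.matrix(genotypes)
  poly <- apply(Z, 2, function(x) length(unique(x)) > 1)
  Zc <- center_dosages(Z[, poly, drop = FALSE])
  fit_diet_interaction(phenotypes, trait, Zc, fixed = fixed,
                       divisor = ncol(Zc), kind = "genomic", ...)
}

#' Microbiota-by-diet interaction model
#'
#' Main-plus-diet-specific decomposition of the microbial variance; features
#' are the log-transformed standardized abundances and the divisor is the
#' OTU count, so the main kernel is `S S' / n` and each specific block
#' `S_diet S_diet' / n`.
#'
#' @param phenotypes,trait,fixed,... as in [fit_diet_interaction()].
#' @param otu rarefied/filtered count matrix (converted internally with
#'   [build_log_abundance()]), or pass a prebuilt `S` via `features`.
#' @param features optional log-abundance matrix overriding `otu`.
#' @return an `interaction_result`; `r_mean` is the microbial cross-diet
#'   correlation r_m.
#' @export
fit_mxd <- function(phenotypes, trait, otu = NULL, features = NULL,
                    fixed = character(), ...) {
  if (is.null(features)) {
    if (is.null(otu)) stop("supply otu counts or a log-abundance matrix")
    features <- build_log_abundance(otu)
  }
  fit_diet_interaction(phenotypes, trait, features, fixed = fixed,
                       divisor = ncol(features), kind = "microbial", ...)
}
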