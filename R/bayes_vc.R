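#' MCMC settings for the Gibbs sampler
#'
#' Defaults mirror the full analysis schedule: a single chain of 120,000
#' iterations, 20,000 discarded as burn-in, thinning of 20 (5,000 retained
#' draws). Reduced settings (e.g. 12,000 / 2,000 / 10) are appropriate for
#' desk-scale testing.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before retention.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 120000, burn_in = 20000, thin = 20,
                         seed = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_control")
}

#' Fit a Gaussian mixed model with kernel random effects by Gibbs sampling
#'
#' Fits `y = Xb + sum_i g_i + e` with `g_i ~ N(0, K_i s2_i)` and
#' `e ~ N(0, I s2_e)`, the Bayesian RKHS regression used for microbiability
#' and heritability estimation. One kernel (genomic G or microbial M) gives
#' the single-effect models; two kernels give the joint model with no
#' covariance between the random terms; three kernels (main + two diet
#' blocks) give the diet-interaction models.
#'
#' Priors: each variance gets a scaled-inverse-chi-square prior with
#' `prior_df` degrees of freedom and a scale set from the sample variance of
#' the phenotypes — the residual receives share `1 - prior_R2` and the kernel
#' terms split `prior_R2` evenly, each scale being
#' `var(y) * share * (df + 2) / df` so the prior mode sits at the
#' corresponding variance share. Fixed effects get independent N(0,
#' `fixed_prior_var`) priors (default 1e10, effectively flat).
#'
#' The sampler reparameterizes each random effect through the
#' eigendecomposition `K = U D U'` and samples the independent coordinates'
#' exact Gaussian full conditionals; this is mathematically equivalent to
#' sampling `g` directly. Eigenvalues below `eigen_tol * max(eigenvalue)` are
#' dropped (null directions of the kernel carry no signal).
#'
#' @param y numeric response vector (no missing values).
#' @param kernels named list of kernel matrices aligned to `y`.
#' @param X fixed-effect design matrix (defaults to an intercept).
#' @param prior_df prior degrees of freedom for every variance.
#' @param prior_R2 prior share of phenotypic variance assigned to the kernel
#'   terms jointly.
#' @param fixed_prior_var prior variance of fixed-effect coefficients.
#' @param mcmc an [mcmc_control()].
#' @param ridge optional non-negative constant added to each kernel diagonal
#'   before eigendecomposition (stabilizes near-singular kernels).
#' @param eigen_tol relative eigenvalue cutoff.
#' @return object of class `rkhs_fit`: `sigma2` (retained draws, one column
#'   per kernel plus `"residual"`), `beta` (retained fixed-effect draws),
#'   `effects` (posterior-mean random-effect vectors per term — the GEBV for
#'   a genomic term, the EMV for a microbial term), `y`, `X`, `kernels`,
#'   `mcmc`, `prior`.
#' @export
fit_rkhs <- function(y, kernels, X = NULL, prior_df = 5, prior_R2 = 0.5,
                     fixed_prior_var = 1e10, mcmc = mcmc_control(),
                     ridge = 0, eigen_tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing phenotypes: drop unphenotyped animals before fitting")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X rows must match length(y)")
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design matrix")
  if (!length(kernels)) stop("at least one kernel term is required")
  if (is.null(names(kernels)) || any(!nzchar(names(kernels)))) {
    names(kernels) <- paste0("K", seq_along(kernels))
  }

  eigs <- lapply(kernels, function(K) {
    K <- unclass(as.matrix(K))
    if (nrow(K) != n) stop("kernel/phenotype dimension mismatch")
    if (ridge > 0) diag(K) <- diag(K) + ridge
    eg <- eigen(K, symmetric = TRUE)
    keep <- eg$values > eigen_tol * max(eg$values)
    if (!any(keep)) stop("kernel has no positive eigenvalues")
    list(U = eg$vectors[, keep, drop = FALSE], d = eg$values[keep])
  })

  k <- length(kernels)
  vy <- stats::var(y)
  share_term <- prior_R2 / k
  S0_terms <- rep(vy * share_term * (prior_df + 2) / prior_df, k)
  S0_resid <- vy * (1 - prior_R2) * (prior_df + 2) / prior_df

  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  res <- gibbs_rkhs_cpp(y, X,
                        lapply(eigs, `[[`, "U"), lapply(eigs, `[[`, "d"),
                        prior_df, S0_terms, S0_resid, fixed_prior_var,
                        mcmc$n_iter, mcmc$burn_in, mcmc$thin)

  sigma2 <- res$sigma2
  colnames(sigma2) <- c(names(kernels), "residual")
  beta <- res$beta
  colnames(beta) <- colnames(X)
  effects <- stats::setNames(lapply(res$g_mean, as.numeric), names(kernels))
  for (i in seq_along(effects)) {
    ids <- rownames(as.matrix(kernels[[i]]))
    if (!is.null(ids)) names(effects[[i]]) <- ids
  }

  structure(list(sigma2 = sigma2, beta = beta, effects = effects,
                 y = y, X = X, kernels = lapply(kernels, unclass),
                 mcmc = mcmc,
                 prior = list(df = prior_df, R2 = prior_R2,
                              S0_terms = S0_terms, S0_resid = S0_resid,
                              fixed_prior_var = fixed_prior_var)),
            class = "rkhs_fit")
}

#' @export
print.rkhs_fit <- function(x, ...) {
  cat(sprintf("<rkhs_fit> n=%d, terms: %s; %d retained draws\n",
              length(x$y), paste(setdiff(colnames(x$sigma2), "residual"),
                                 collapse = " + "),
              nrow(x$sigma2)))
  print(round(colMeans(x$sigma2), 4))
  invisible(x)
}

hdi_normal <- function(mean, sd) c(lower = mean - 1.96 * sd,
                                   upper = mean + 1.96 * sd)

#' Posterior summary of a fitted model
#'
#' Posterior means and SDs over the retained draws, with 95% highest density
#' intervals approximated as mean +/- 1.96 SD (the convention used
#' throughout this analysis). Random-effect vectors are summarized by their
#' posterior means: the genomic effects are the GEBV, the microbial effects
#' the EMV.
#'
#' @param fit an [fit_rkhs()] result.
#' @return list of class `posterior_summary`: `variances` (data.frame with
#'   term, mean, sd, hdi bounds), `beta` (same layout), `effects`
#'   (posterior-mean vectors per term).
#' @export
posterior_summary <- function(fit) {
  if (!nrow(fit$sigma2)) stop("empty chain")
  sumdf <- function(draws) {
    mu <- colMeans(draws)
    sdv <- apply(draws, 2, stats::sd)
    data.frame(term = colnames(draws), mean = mu, sd = sdv,
               hdi_lower = mu - 1.96 * sdv, hdi_upper = mu + 1.96 * sdv,
               row.names = NULL)
  }
  structure(list(variances = sumdf(fit$sigma2), beta = sumdf(fit$beta),
                 effects = fit$effects),
            class = "posterior_summary")
}

#' Heritability / microbiability ratios from a fitted model
#'
#' Computes, per retained draw, the fraction of phenotypic variance assigned
#' to each kernel term: `ratio_i = s2_i / (sum_j s2_j + s2_e)`. With a single
#' genomic term this is `h2 = s2_u / (s2_u + s2_e)`; with a single microbial
#' term, `m2 = s2_m / (s2_m + s2_e)`; in the joint model both ratios use the
#' three-component denominator. Draw-wise ratios are then summarized (mean,
#' SD, HDI as mean +/- 1.96 SD).
#'
#' @param fit an [fit_rkhs()] result.
#' @param terms kernel terms to report (default: all). Requesting a term the
#'   model does not contain is an error.
#' @return data.frame: term, mean, sd, hdi_lower, hdi_upper, plus attribute
#'   `draws` (matrix of draw-wise ratios).
#' @export
variance_ratios <- function(fit, terms = NULL) {
  vc_names <- setdiff(colnames(fit$sigma2), "residual")
  if (is.null(terms)) terms <- vc_names
  missing <- setdiff(terms, vc_names)
  if (length(missing)) {
    stop("term(s) not in model: ", paste(missing, collapse = ", "))
  }
  total <- rowSums(fit$sigma2)
  draws <- fit$sigma2[, terms, drop = FALSE] / total
  mu <- colMeans(draws)
  sdv <- apply(draws, 2, stats::sd)
  out <- data.frame(term = terms, mean = mu, sd = sdv,
                    hdi_lower = mu - 1.96 * sdv, hdi_upper = mu + 1.96 * sdv,
                    row.names = NULL)
  attr(out, "draws") <- draws
  out
}

#' Bayesian information criterion at the posterior means
#'
#' `BIC = -2 log L + k log N`, where `L` is the marginal Gaussian likelihood
#' of the phenotypes with mean `X beta_hat` and covariance
#' `sum_i s2_i_hat K_i + s2_e_hat I` evaluated at the posterior means,
#' `k` counts the fixed-effect coefficients plus all variance parameters
#' (kernel terms and residual), and `N` is the number of phenotyped animals.
#' The model with the lowest BIC is preferred.
#'
#' @param fit an [fit_rkhs()] result.
#' @return numeric BIC with attributes `logLik` and `k`.
#' @export
compute_bic <- function(fit) {
  mu_s2 <- colMeans(fit$sigma2)
  n <- length(fit$y)
  V <- diag(mu_s2[["residual"]], n)
  for (nm in setdiff(names(mu_s2), "residual")) {
    V <- V + mu_s2[[nm]] * fit$kernels[[nm]]
  }
  ch <- tryCatch(chol(V), error = function(e) {
    stop("plug-in covariance is not positive definite; refit with a small diagonal ridge")
  })
  beta_hat <- colMeans(fit$beta)
  r <- fit$y - as.vector(fit$X %*% beta_hat)
  quad <- sum(backsolve(ch, r, transpose = TRUE)^2)
  logdet <- 2 * sum(log(diag(ch)))
  logL <- -0.5 * (n * log(2 * pi) + logdet + quad)
  k <- ncol(fit$X) + length(mu_s2)
  bic <- -2 * logL + k * log(n)
  attr(bic, "logLik") <- logL
  attr(bic, "k") <- k
  bic
}

#' Compare two posterior estimates through their HDIs
#'
#' Two estimates are flagged as significantly different iff their 95% HDIs
#' (mean +/- 1.96 SD) do not overlap.
#'
#' @param mean_a,sd_a,mean_b,sd_b posterior means and SDs.
#' @return logical: `TRUE` if significantly different.
#' @export
compare_estimates <- function(mean_a, sd_a, mean_b, sd_b) {
  if (anyNA(c(sd_a, sd_b))) stop("posterior SD missing")
  a <- hdi_normal(mean_a, sd_a)
  b <- hdi_normal(mean_b, sd_b)
  a["upper"] < b["lower"] || b["upper"] < a["lower"]
}

#' Write a chain or posterior summary as CSV
#'
#' The chain CSV has one row per retained draw (variance components then
#' fixed effects); the summary CSV is the `variances` table of
#' [posterior_summary()].
#'
#' @param fit an [fit_rkhs()] result.
#' @param path output file.
#' @export
write_chain_csv <- function(fit, path) {
  utils::write.csv(cbind(as.data.frame(fit$sigma2), as.data.frame(fit$beta)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
write_summary_csv <- function(fit, path) {
  utils::write.csv(posterior_summary(fit)$variances, path, row.names = FALSE)
  invisible(path)
}

#' Fit one trait with chosen kernel terms from a phenotype table
#'
#' Convenience wrapper: drops animals missing the trait, aligns the kernels
#' to the phenotyped animals by id, builds a reference-coded fixed-effect
#' design (intercept plus the given columns, factors dummy-coded dropping
#' the first level), verifies full rank, and calls [fit_rkhs()].
#'
#' @param phenotypes data.frame with `animal_id`, the trait and fixed-effect
#'   columns.
#' @param trait trait column name.
#' @param kernels named list of kernels with animal ids as dimnames.
#' @param fixed character vector of fixed-effect column names (may be empty).
#' @param ... passed to [fit_rkhs()] (prior settings, `mcmc`, `ridge`).
#' @return an `rkhs_fit` with an extra element `animal_ids`.
#' @export
fit_trait_model <- function(phenotypes, trait, kernels, fixed = character(),
                            ...) {
  if (!trait %in% names(phenotypes)) stop("trait column not found: ", trait)
  keep <- !is.na(phenotypes[[trait]])
  dat <- phenotypes[keep, , drop = FALSE]
  ids <- dat$animal_id

  kernels <- lapply(kernels, function(K) {
    K <- as.matrix(K)
    if (is.null(rownames(K)) || !all(ids %in% rownames(K))) {
      stop("kernel does not cover all phenotyped animals")
    }
    K[ids, ids]
  })

  if (length(fixed)) {
    miss <- setdiff(fixed, names(dat))
    if (length(miss)) stop("fixed-effect column(s) not found: ",
                           paste(miss, collapse = ", "))
    for (f in fixed) if (is.character(dat[[f]])) dat[[f]] <- factor(dat[[f]])
    X <- stats::model.matrix(stats::reformulate(fixed), dat)
    # drop aliased columns (e.g. a factor level emptied by trait missingness)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  } else {
    X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  }

  fit <- fit_rkhs(dat[[trait]], kernels, X = X, ...)
  fit$animal_ids <- ids
  fit
}
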