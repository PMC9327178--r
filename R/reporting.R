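#' Spearman rank correlation with a bootstrap confidence interval
#'
#' Point estimate is the Pearson correlation of average ranks (ties share
#' their average rank). The 95% CI is the 2.5/97.5 percentile interval of
#' the correlation over `n_boot` paired resamples with replacement.
#'
#' @param a,b numeric vectors over the same animals (aligned; if both are
#'   named the names must match).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @return list of class `rank_correlation`: `rho`, `ci_lower`, `ci_upper`,
#'   `n`, `n_boot`, `seed`.
#' @export
spearman_with_bootstrap <- function(a, b, n_boot = 1000, seed = 1) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!identical(sort(names(a)), sort(names(b)))) {
      stop("a and b must cover the same animals")
    }
    b <- b[names(a)]
  }
  n <- length(a)
  if (n < 3 || length(b) != n) stop("need >= 3 aligned pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  rho <- stats::cor(a, b, method = "spearman")
  set.seed(seed)
  boots <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(a[idx]) == 0 || stats::sd(b[idx]) == 0) NA_real_
    else stats::cor(a[idx], b[idx], method = "spearman")
  })
  boots <- boots[is.finite(boots)]
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(rho = rho,
                 ci_lower = min(ci[1], rho), ci_upper = max(ci[2], rho),
                 n = n, n_boot = n_boot, seed = seed),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f  95%% CI [%.3f, %.3f]  (n=%d, %d bootstrap reps)\n",
              x$rho, x$ci_lower, x$ci_upper, x$n, x$n_boot))
  invisible(x)
}

#' Rank models by BIC
#'
#' Lowest BIC is best. Labels follow the reporting convention used for the
#' three-model comparison: `c` = best (lowest BIC), `b` = worst (highest),
#' `a` = intermediate. Exact ties are reported in the `tie` column and
#' ranked in stable input order.
#'
#' @param bics named numeric vector of BIC values (>= 2 models).
#' @return data.frame in ascending BIC order: `model`, `bic`, `rank`,
#'   `label` (best/intermediate/worst), `letter`, `tie`.
#' @export
compare_models <- function(bics) {
  if (length(bics) < 2) stop("need at least 2 models")
  if (any(!is.finite(bics))) stop("non-finite BIC value(s)")
  if (is.null(names(bics))) names(bics) <- paste0("model", seq_along(bics))
  ord <- order(bics)
  out <- data.frame(model = names(bics)[ord], bic = unname(bics[ord]),
                    rank = seq_along(bics), stringsAsFactors = FALSE)
  out$label <- "intermediate"
  out$label[1] <- "best"
  out$label[nrow(out)] <- "worst"
  out$letter <- ifelse(out$label == "best", "c",
                       ifelse(out$label == "worst", "b", "a"))
  out$tie <- duplicated(out$bic) | duplicated(out$bic, fromLast = TRUE)
  out
}

#' Assemble study-style report tables
#'
#' Joins per-trait outputs from the fitting, ranking and interaction steps
#' into the report tables of a typical microbiability study: a variance-ratio
#' table (m2/h2 with posterior SDs per model and diet), a BIC comparison
#' table with best/intermediate/worst labels, a rank-correlation table and an
#' interaction table. A quantity absent for a model kind (e.g. h2 under the
#' microbiota-only model) is rendered as `NA`, never zero.
#'
#' @param ratios data.frame with columns `trait`, `diet`, `model`, `term`,
#'   `mean`, `sd` (from [variance_ratios()] runs).
#' @param bics data.frame with columns `trait`, `diet`, `model`, `bic`.
#' @param rank_correlations optional data.frame with columns `trait`, `diet`,
#'   `comparison`, `rho`, `ci_lower`, `ci_upper`.
#' @param interactions optional data.frame with columns `trait`, `kind`,
#'   `sigma2_main`, `sigma2_CO`, `sigma2_HF`, `r`, `r_sd`, `flag`.
#' @return list of class `report_tables` with elements `variance_ratios`
#'   (wide per trait x diet x model), `bic` (with labels), plus the optional
#'   tables passed through.
#' @export
build_summary_tables <- function(ratios, bics, rank_correlations = NULL,
                                 interactions = NULL) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table missing column(s): ",
                           paste(miss, collapse = ", "))
  }
  need(ratios, c("trait", "diet", "model", "term", "mean", "sd"), "ratios")
  need(bics, c("trait", "diet", "model", "bic"), "bic")

  traits_r <- sort(unique(ratios$trait))
  traits_b <- sort(unique(bics$trait))
  if (!identical(traits_r, traits_b)) {
    stop("trait sets differ between inputs: ratios has {",
         paste(traits_r, collapse = ","), "} but bic has {",
         paste(traits_b, collapse = ","), "}")
  }

  # wide variance-ratio table: one row per trait x diet, columns model.term
  ratios$key <- paste(ratios$model, ratios$term, sep = ".")
  cells <- unique(ratios$key)
  base <- unique(ratios[, c("trait", "diet")])
  for (k in cells) {
    sub <- ratios[ratios$key == k, ]
    idx <- match(paste(base$trait, base$diet),
                 paste(sub$trait, sub$diet))
    base[[paste0(k, "_mean")]] <- sub$mean[idx]
    base[[paste0(k, "_sd")]] <- sub$sd[idx]
  }

  bic_tab <- do.call(rbind, lapply(split(bics, bics[, c("trait", "diet")],
                                         drop = TRUE), function(g) {
    cmp <- compare_models(stats::setNames(g$bic, g$model))
    cmp$trait <- g$trait[1]; cmp$diet <- g$diet[1]
    cmp
  }))
  rownames(bic_tab) <- NULL

  structure(list(variance_ratios = base, bic = bic_tab,
                 rank_correlations = rank_correlations,
                 interactions = interactions),
            class = "report_tables")
}

#' Write report tables to CSV files
#'
#' @param tables a `report_tables` object.
#' @param dir output directory (created if needed).
#' @param seed,config_hash provenance recorded as a `#` comment header line
#'   in every file.
#' @return invisibly, the written file paths.
#' @export
write_report_tables <- function(tables, dir, seed = NA, config_hash = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab)) next
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# seed=%s config=%s", as.character(seed), config_hash),
               con)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
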