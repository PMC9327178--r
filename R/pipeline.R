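#' Run the full analysis pipeline
#'
#' Executes preprocessing, kernel construction, the three variance-component
#' models (microbiota-only, genomic-only, joint) per trait and diet,
#' breeding-value re-ranking, and the diet-interaction models, then
#' assembles report tables. Data are either simulated (config `simulate`) or
#' loaded from files (config `inputs` with `otu`, `genotypes`, `phenotypes`
#' paths). Any stage failure stops with the failing stage named. All
#' randomness flows from `config$seed`, so a rerun with the same config
#' reproduces every artifact.
#'
#' Config entries (all optional unless noted): `simulate` (list passed to
#' [simulate_dataset()]) or `inputs`; `trait`(s); `fixed` (fixed-effect
#' columns, default `"pen"`); `filter` (`min_samples_present`,
#' `min_mean_abundance_fraction`); `qc` (passed to [qc_genotypes()]); `mcmc`
#' (`n_iter`, `burn_in`, `thin`); `per_diet` (fit each diet separately,
#' default TRUE); `interactions` (fit GxD/MxD, default TRUE); `seed`;
#' `out_dir` (write CSV artifacts when set).
#'
#' @param config list, or path to a YAML file parsed with the yaml package.
#' @return list of class `pipeline_result`: `tables` (a `report_tables`),
#'   `fits`, `interactions`, `rank_correlations`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read config files")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    trait = "trait", fixed = "pen",
    filter = list(min_samples_present = 5, min_mean_abundance_fraction = 1e-5),
    qc = list(), mcmc = list(n_iter = 12000, burn_in = 2000, thin = 10),
    per_diet = TRUE, interactions = TRUE, seed = 1, out_dir = NULL
  ), config)

  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  dat <- stage("load", {
    if (!is.null(cfg$inputs)) {
      otu <- read_otu_table(cfg$inputs$otu,
                            format = cfg$inputs$otu_format %||% "tsv")
      geno <- read_genotypes(cfg$inputs$genotypes,
                             format = cfg$inputs$geno_format %||% "dosage")
      phen <- utils::read.csv(cfg$inputs$phenotypes,
                              stringsAsFactors = FALSE)
      list(otu = otu, genotypes = geno, phenotypes = phen)
    } else {
      sim_args <- cfg$simulate %||% list()
      truth_fields <- intersect(names(sim_args), names(formals(synthetic_truth)))
      truth <- do.call(synthetic_truth, sim_args[truth_fields])
      size_args <- sim_args[setdiff(names(sim_args), truth_fields)]
      do.call(simulate_dataset,
              c(size_args, list(truth = truth, seed = cfg$seed)))
    }
  })

  stage("validate", {
    if (!cfg$trait %in% names(dat$phenotypes)) {
      stop("trait column '", cfg$trait, "' missing from phenotype table")
    }
    miss_fx <- setdiff(cfg$fixed, names(dat$phenotypes))
    if (length(miss_fx)) stop("fixed-effect column(s) missing: ",
                              paste(miss_fx, collapse = ", "))
  })

  # id intersection across the three inputs, with a logged report
  common <- stage("align", {
    ids <- Reduce(intersect, list(rownames(dat$otu), rownames(dat$genotypes),
                                  dat$phenotypes$animal_id))
    if (length(ids) < 4) stop("fewer than 4 animals shared across inputs")
    n_drop <- length(unique(c(rownames(dat$otu), rownames(dat$genotypes),
                              dat$phenotypes$animal_id))) - length(ids)
    if (n_drop > 0) message(n_drop, " animal(s) dropped by id intersection")
    ids
  })
  otu <- dat$otu[common, , drop = FALSE]
  geno <- dat$genotypes[common, , drop = FALSE]
  phen <- dat$phenotypes[match(common, dat$phenotypes$animal_id), ,
                         drop = FALSE]

  pre <- stage("preprocess", {
    f <- filter_otus(otu, cfg$filter$min_samples_present,
                     cfg$filter$min_mean_abundance_fraction)
    q <- do.call(qc_genotypes, c(list(geno), cfg$qc))
    list(otu = f, geno = q)
  })

  mc <- mcmc_control(cfg$mcmc$n_iter %||% 12000, cfg$mcmc$burn_in %||% 2000,
                     cfg$mcmc$thin %||% 10, seed = cfg$seed)

  diets <- if (isTRUE(cfg$per_diet)) sort(unique(phen$diet)) else "both"
  fits <- list(); ratio_rows <- list(); bic_rows <- list(); rank_rows <- list()

  for (dt in diets) {
    sub <- if (dt == "both") rep(TRUE, nrow(phen)) else phen$diet == dt
    ids <- phen$animal_id[sub]
    S <- stage("kernels", build_log_abundance(pre$otu[ids, , drop = FALSE]))
    M <- build_microbial_kernel(S)
    G <- stage("kernels", {
      Zs <- pre$geno[ids, , drop = FALSE]
      poly <- apply(Zs, 2, function(x) length(unique(x)) > 1)
      build_grm(Zs[, poly, drop = FALSE])
    })
    psub <- phen[sub, , drop = FALSE]
    fx <- if (dt == "both") unique(c(cfg$fixed, "diet")) else cfg$fixed
    fx <- fx[vapply(fx, function(f) length(unique(psub[[f]])) > 1, TRUE)]

    model_kernels <- list(Micro = list(microbial = M),
                          Gen = list(genomic = G),
                          `Micro+Gen` = list(genomic = G, microbial = M))
    dfits <- list()
    for (mod in names(model_kernels)) {
      fit <- stage(paste0("fit_", mod), fit_trait_model(
        psub, cfg$trait, model_kernels[[mod]], fixed = fx, mcmc = mc))
      dfits[[mod]] <- fit
      vr <- variance_ratios(fit)
      vr$term <- ifelse(vr$term == "genomic", "h2", "m2")
      ratio_rows[[length(ratio_rows) + 1]] <-
        data.frame(trait = cfg$trait, diet = dt, model = mod,
                   term = vr$term, mean = vr$mean, sd = vr$sd)
      bic_rows[[length(bic_rows) + 1]] <-
        data.frame(trait = cfg$trait, diet = dt, model = mod,
                   bic = as.numeric(compute_bic(fit)))
    }
    fits[[dt]] <- dfits

    rc_gebv <- stage("rank_correlations", spearman_with_bootstrap(
      dfits$Gen$effects$genomic, dfits$`Micro+Gen`$effects$genomic,
      seed = cfg$seed))
    rc_emv <- spearman_with_bootstrap(
      dfits$Micro$effects$microbial, dfits$`Micro+Gen`$effects$microbial,
      seed = cfg$seed)
    rank_rows[[length(rank_rows) + 1]] <- data.frame(
      trait = cfg$trait, diet = dt,
      comparison = c("GEBV_Gen_vs_joint", "EMV_Micro_vs_joint"),
      rho = c(rc_gebv$rho, rc_emv$rho),
      ci_lower = c(rc_gebv$ci_lower, rc_emv$ci_lower),
      ci_upper = c(rc_gebv$ci_upper, rc_emv$ci_upper))
  }

  inter <- NULL; inter_tab <- NULL
  if (isTRUE(cfg$interactions) && length(unique(phen$diet)) == 2) {
    inter <- stage("interactions", {
      gxd <- fit_gxd(phen, cfg$trait, pre$geno, fixed = cfg$fixed, mcmc = mc)
      mxd <- fit_mxd(phen, cfg$trait, otu = pre$otu, fixed = cfg$fixed,
                     mcmc = mc)
      list(gxd = gxd, mxd = mxd)
    })
    inter_tab <- data.frame(
      trait = cfg$trait, kind = c("genomic", "microbial"),
      sigma2_main = c(inter$gxd$sigma2_main, inter$mxd$sigma2_main),
      sigma2_CO = c(inter$gxd$sigma2_CO, inter$mxd$sigma2_CO),
      sigma2_HF = c(inter$gxd$sigma2_HF, inter$mxd$sigma2_HF),
      r = c(inter$gxd$r_mean, inter$mxd$r_mean),
      r_sd = c(inter$gxd$r_sd, inter$mxd$r_sd),
      flag = c(inter$gxd$flag, inter$mxd$flag))
  }

  tables <- stage("report", build_summary_tables(
    do.call(rbind, ratio_rows), do.call(rbind, bic_rows),
    rank_correlations = do.call(rbind, rank_rows), interactions = inter_tab))

  if (!is.null(cfg$out_dir)) {
    write_report_tables(tables, cfg$out_dir, seed = cfg$seed)
  }

  structure(list(tables = tables, fits = fits, interactions = inter,
                 rank_correlations = do.call(rbind, rank_rows),
                 config = cfg),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
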