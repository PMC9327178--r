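#' Kernel (relationship matrix) objects
#'
#' A kernel is a symmetric positive semi-definite animal-by-animal similarity
#' matrix. Two kinds are central here: the microbial covariance matrix
#' \eqn{M = SS^T/n} built from log-transformed, per-OTU standardized
#' abundances (\eqn{n} = number of OTU), and the genomic relationship matrix
#' \eqn{G} built by VanRaden's first method from allele dosages
#' (\eqn{G = Z_c Z_c^T / (2\sum_k p_k(1-p_k))}). Diet-interaction models add
#' block-structured diet-specific kernels.
#'
#' Kernels are stored as a base matrix with row/column names equal to the
#' animal ids, plus attributes `kind` (e.g. `"microbial"`, `"genomic"`,
#' `"main"`, `"diet_specific"`) and `divisor` (the number of features the
#' cross-product was divided by).
#'
#' @param mat symmetric numeric matrix with animal ids as dimnames.
#' @param kind character label for the kernel's role.
#' @param divisor number of features (OTU or SNPs) used as denominator.
#' @return A matrix of class `mb_kernel`.
#' @export
new_kernel <- function(mat, kind = "generic", divisor = NA_integer_) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat))
  if (is.null(rownames(mat))) {
    rownames(mat) <- colnames(mat) <- paste0("a", seq_len(nrow(mat)))
  }
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) {
    stop("kernel matrix is not symmetric")
  }
  mat <- (mat + t(mat)) / 2
  structure(mat, kind = kind, divisor = divisor, class = c("mb_kernel", "matrix"))
}

#' @export
print.mb_kernel <- function(x, ...) {
  cat(sprintf("<mb_kernel> kind=%s, %d animals, divisor=%s, mean diag=%.3f\n",
              attr(x, "kind"), nrow(x), as.character(attr(x, "divisor")),
              mean(diag(x))))
  invisible(x)
}

#' Check positive semi-definiteness of a kernel
#'
#' A kernel passes if its smallest eigenvalue is no less than
#' `-tol * trace / n`, tolerating the round-off expected from cross-product
#' construction.
#'
#' @param K kernel matrix.
#' @param tol relative tolerance on the smallest eigenvalue.
#' @return `TRUE`/`FALSE`.
#' @export
is_psd <- function(K, tol = 1e-8) {
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * sum(diag(K)) / nrow(K)
}

#' Log-transform and standardize an OTU count table
#'
#' Computes `s_jk = (log(count_jk + 1) - mean_k) / sd_k`, the log-transformed
#' and per-OTU standardized abundance for animal `j` and OTU `k` (natural
#' logarithm, pseudocount 1). Columns with zero variance carry no
#' between-animal information and are dropped with a warning.
#'
#' @param otu integer count matrix, samples in rows, OTU in columns.
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by n-1)
#'   standard deviation. The resulting microbial kernel differs only by a
#'   constant factor `(n-1)/n` between the two conventions.
#' @return numeric matrix `S` (animals x retained OTU) with attribute
#'   `dropped` listing removed OTU ids.
#' @export
build_log_abundance <- function(otu, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  otu <- as.matrix(otu)
  if (nrow(otu) < 2) stop("need at least 2 animals to standardize abundances")
  L <- log(otu + 1)
  mu <- colMeans(L)
  cv <- colMeans(L^2) - mu^2           # population variance
  cv[cv < 0] <- 0
  if (sd_type == "sample") cv <- cv * nrow(L) / (nrow(L) - 1)
  keep <- sqrt(cv) > 1e-12
  if (!any(keep)) stop("all OTU columns have zero variance")
  if (any(!keep)) {
    warning(sprintf("dropping %d zero-variance OTU column(s)", sum(!keep)))
  }
  S <- sweep(L[, keep, drop = FALSE], 2, mu[keep], "-")
  S <- sweep(S, 2, sqrt(cv[keep]), "/")
  attr(S, "dropped") <- colnames(otu)[!keep]
  S
}

#' Build the microbial covariance matrix M = SS^T / n
#'
#' @param S log-abundance matrix from [build_log_abundance()]
#'   (animals x OTU).
#' @return an [new_kernel()] object of kind `"microbial"` with
#'   `divisor = ncol(S)`.
#' @export
build_microbial_kernel <- function(S) {
  S <- as.matrix(S)
  if (any(!is.finite(S))) stop("non-finite entries in log-abundance matrix")
  n_otu <- ncol(S)
  M <- tcrossprod(S) / n_otu
  new_kernel(M, kind = "microbial", divisor = n_otu)
}

#' Build the genomic relationship matrix (VanRaden method 1)
#'
#' Centers dosages by twice the observed allele frequency and normalizes the
#' cross-product: \eqn{G = Z_c Z_c^T / (2\sum_k p_k(1-p_k))}. Inputs must be
#' complete (QC-imputed) dosages in `[0, 2]`; monomorphic SNPs are rejected
#' because they contribute nothing and should have been removed by QC.
#'
#' @param geno dosage matrix, animals x SNPs, entries in `[0, 2]`, no missing.
#' @return an [new_kernel()] object of kind `"genomic"` with
#'   `divisor = ncol(geno)`.
#' @export
build_grm <- function(geno) {
  Z <- as.matrix(geno)
  if (anyNA(Z)) stop("missing dosages: impute during QC before building the GRM")
  p <- colMeans(Z) / 2
  if (any(p <= 0 | p >= 1)) {
    stop(sprintf("%d monomorphic SNP(s) present; remove them in QC first",
                 sum(p <= 0 | p >= 1)))
  }
  Zc <- sweep(Z, 2, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Zc) / denom
  new_kernel(G, kind = "genomic", divisor = ncol(Z))
}

#' Build main and diet-specific kernels for interaction models
#'
#' For the genotype-by-diet and microbiota-by-diet decompositions, the main
#' effect uses the full-panel kernel `F F^T / divisor` over all animals, and
#' the diet-specific effect uses block-diagonal kernels: within-diet
#' similarity blocks with exact zeros between animals on different diets,
#' divided by the same feature count. The per-diet variance scalars stay in
#' the model, not in the kernels.
#'
#' @param features centered feature matrix, animals x features: the
#'   log-abundance matrix `S` for microbial kernels, or `2p`-centered dosages
#'   for genomic kernels (use `center_dosages()`).
#' @param diet per-animal factor/character with exactly two levels
#'   (conventionally `"CO"` and `"HF"`), aligned with `rownames(features)`.
#' @param divisor denominator; defaults to `ncol(features)`.
#' @param kind label stem for the returned kernels.
#' @return list with elements `main` (full kernel), `specific` (block-diagonal
#'   kernel summing both blocks, for inspection) and `specific_by_diet`
#'   (named list of one zero-padded block kernel per diet, the form the
#'   interaction model fits with one variance each).
#' @export
build_diet_specific_kernels <- function(features, diet, divisor = NULL,
                                        kind = "feature") {
  F_ <- as.matrix(features)
  diet <- as.character(diet)
  if (length(diet) != nrow(F_)) stop("diet labels must match feature rows")
  levs <- sort(unique(diet))
  if (length(levs) != 2) stop("exactly two diet levels required")
  if (any(table(diet) < 2)) stop("each diet needs at least 2 animals")
  if (is.null(divisor)) divisor <- ncol(F_)

  ids <- rownames(F_)
  if (is.null(ids)) ids <- paste0("a", seq_len(nrow(F_)))
  main <- tcrossprod(F_) / divisor
  dimnames(main) <- list(ids, ids)

  blocks <- lapply(levs, function(lv) {
    B <- matrix(0, nrow(F_), nrow(F_), dimnames = list(ids, ids))
    idx <- which(diet == lv)
    B[idx, idx] <- tcrossprod(F_[idx, , drop = FALSE]) / divisor
    new_kernel(B, kind = paste0(kind, "_specific_", lv), divisor = divisor)
  })
  names(blocks) <- levs

  specific <- unclass(blocks[[1]]) + unclass(blocks[[2]])
  list(main = new_kernel(main, kind = paste0(kind, "_main"), divisor = divisor),
       specific = new_kernel(specific, kind = paste0(kind, "_specific"),
                             divisor = divisor),
       specific_by_diet = blocks)
}

#' Center a dosage matrix by twice the allele frequency
#'
#' Helper producing the `Z_c` features used by [build_diet_specific_kernels()]
#' for genomic interaction kernels; the full-panel cross-product of these
#' features divided by the SNP count is the (unnormalized-denominator) analog
#' of the GRM used in the interaction model's main term.
#'
#' @param geno complete dosage matrix, animals x SNPs.
#' @return centered numeric matrix of the same shape.
#' @export
center_dosages <- function(geno) {
  Z <- as.matrix(geno)
  if (anyNA(Z)) stop("missing dosages: impute during QC first")
  sweep(Z, 2, colMeans(Z), "-")
}

#' Write / read a kernel as TSV
#'
#' Plain-text round trip: a header row of animal ids, then one row per animal
#' with its id in the first column.
#'
#' @param K kernel matrix.
#' @param path output file.
#' @export
write_kernel_tsv <- function(K, path) {
  df <- data.frame(animal_id = rownames(K), unclass(K), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @param kind,divisor metadata restored on read (not stored in the TSV).
#' @export
read_kernel_tsv <- function(path, kind = "generic", divisor = NA_integer_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  new_kernel(mat, kind = kind, divisor = divisor)
}
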