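#' Read an OTU count table
#'
#' TSV layout: rows are samples, first column `sample_id`, remaining header
#' fields are OTU ids. BIOM files are read with the biomformat package
#' (observations = OTU are transposed to columns). Counts must be
#' non-negative integers; duplicate sample or OTU ids are rejected, naming
#' the offender.
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom"`.
#' @return integer count matrix samples x OTU.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required to read BIOM files")
    }
    bm <- biomformat::read_biom(path)
    counts <- t(as.matrix(biomformat::biom_data(bm)))  # samples x OTU
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- as.character(df[[1]])
  }
  dup_s <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_s)) stop("duplicate sample id: ", dup_s[1])
  dup_o <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_o)) stop("duplicate OTU id: ", dup_o[1])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Write an OTU count table
#'
#' @param otu count matrix samples x OTU.
#' @param path output file.
#' @param format `"tsv"` or `"biom"`.
#' @export
write_otu_table <- function(otu, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required to write BIOM files")
    }
    bm <- biomformat::make_biom(t(as.matrix(otu)))   # observations x samples
    biomformat::write_biom(bm, path)
  } else {
    df <- data.frame(sample_id = rownames(otu), as.matrix(otu),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

gt_to_dosage <- function(gt, locus) {
  if (is.na(gt) || gt %in% c("./.", ".|.", ".")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2 || !all(alleles %in% c("0", "1", "."))) {
    stop("malformed or non-diploid GT '", gt, "' at ", locus)
  }
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == "1")
}

#' Read a genotype matrix
#'
#' Dosage TSV layout: rows are animals, first column `animal_id`, remaining
#' header fields are SNP ids, entries 0/1/2 or NA. VCF files are read with
#' vcfR; only biallelic diploid records are used — multiallelic sites are
#' skipped and their count reported in the `skipped_multiallelic` attribute.
#' Haploid or malformed GT fields are an error naming the record.
#'
#' @param path input file.
#' @param format `"dosage"` or `"vcf"`.
#' @return numeric dosage matrix animals x SNPs with `NA` for missing.
#' @export
read_genotypes <- function(path, format = c("dosage", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    Z <- as.matrix(df[, -1, drop = FALSE])
    rownames(Z) <- as.character(df[[1]])
    bad <- which(!is.na(Z) & !(Z %in% c(0, 1, 2)), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("invalid dosage at animal '%s', SNP '%s'",
                   rownames(Z)[bad[1, 1]], colnames(Z)[bad[1, 2]]))
    }
    attr(Z, "skipped_multiallelic") <- 0L
    return(Z)
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  fx <- matrix(fx, ncol = ncol(fx), dimnames = dimnames(fx)) # drop vcfR class quirks
  multi <- grepl(",", fx[, "ALT"])
  if (any(multi)) message(sum(multi), " multiallelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fx <- fx[!multi, , drop = FALSE]
  ids <- fx[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fx[, "CHROM"], ":", fx[, "POS"])[
    is.na(ids) | ids == "."]
  Z <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
              dimnames = list(colnames(gt), ids))
  for (i in seq_len(nrow(gt))) {
    locus <- paste0(fx[i, "CHROM"], ":", fx[i, "POS"])
    Z[, i] <- vapply(gt[i, ], gt_to_dosage, integer(1), locus = locus)
  }
  attr(Z, "skipped_multiallelic") <- sum(multi)
  Z
}

#' Write genotypes as a dosage TSV
#'
#' @param geno dosage matrix animals x SNPs.
#' @param path output file.
#' @export
write_genotypes_dosage <- function(geno, path) {
  df <- data.frame(animal_id = rownames(geno), as.matrix(geno),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal biallelic VCF
#'
#' Emits a VCFv4.2 file with GT-only FORMAT, REF=A / ALT=B placeholder
#' alleles and one record per SNP on a synthetic chromosome. Dosage 0/1/2
#' maps to 0/0, 0/1, 1/1; `NA` to `./.`.
#'
#' @param geno dosage matrix animals x SNPs.
#' @param path output file (plain text).
#' @export
write_genotypes_vcf <- function(geno, path) {
  Z <- as.matrix(geno)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(Z)), collapse = "\t"))
  rows <- vapply(seq_len(ncol(Z)), function(j) {
    gts <- ifelse(is.na(Z[, j]), "./.", gt_code[as.character(Z[, j])])
    paste(c("1", j, colnames(Z)[j], "A", "B", ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write / read a generating-truth sidecar
#'
#' Simple `key=value` text file holding the non-null scalar fields of a
#' [synthetic_truth()] (machine-readable provenance for simulated datasets).
#'
#' @param truth a `synthetic_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  flat <- Filter(Negate(is.null), unclass(truth))
  writeLines(sprintf("%s=%.10g", names(flat), unlist(flat)), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(x[2]))
  names(vals) <- vapply(kv, `[[`, "", 1)
  do.call(synthetic_truth, vals)
}
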