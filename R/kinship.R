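#' Construct a kinship matrix object
#'
#' @param values Square symmetric numeric matrix of relatedness coefficients.
#' @param check_psd Verify positive semi-definiteness (smallest eigenvalue no
#'   less than -1e-8 times the largest). Default `TRUE`.
#'
#' @return An object of class `kinship_matrix` with fields `values`, `n`.
#' @export
kinship_matrix <- function(values, check_psd = TRUE) {
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) != ncol(values)) {
    abort("kinship must be a square numeric matrix.", class = "embai_format_error")
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-10) {
    warn(sprintf("kinship asymmetric by %.3g; symmetrizing as (K + t(K))/2.", asym))
    values <- (values + t(values)) / 2
  }
  if (check_psd) {
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      abort("kinship matrix is not positive semi-definite.",
            class = "embai_domain_error")
    }
  }
  structure(list(values = values, n = nrow(values)), class = "kinship_matrix")
}

as_kinship_matrix <- function(x) {
  if (inherits(x, "kinship_matrix")) x else kinship_matrix(x)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix> ", x$n, " x ", x$n,
      "; mean diagonal = ", sprintf("%.3f", mean(diag(x$values))), "\n", sep = "")
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: each dosage column is centered by twice its allele frequency,
#' \eqn{K = M M^T / (2 \sum_k p_k (1 - p_k))}. Under Hardy-Weinberg sampling
#' the diagonal averages 1.
#'
#' @param genotypes A [genotype_matrix()] (or bare dosage matrix) with no
#'   monomorphic column.
#'
#' @return A [kinship_matrix()].
#' @export
compute_grm <- function(genotypes) {
  genotypes <- as_genotype_matrix(genotypes)
  p <- colMeans(genotypes$dosages) / 2
  mono <- which(p == 0 | p == 1)
  if (length(mono) > 0L) {
    abort(paste0("monomorphic marker column(s): ",
                 paste(genotypes$marker_ids[utils::head(mono, 5)], collapse = ", "),
                 if (length(mono) > 5) " ..." else ""),
          class = "embai_domain_error")
  }
  M <- sweep(genotypes$dosages, 2, 2 * p)
  K <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2   # exact symmetry against BLAS roundoff
  kinship_matrix(K, check_psd = FALSE)   # PSD by construction (Gram matrix)
}

#' Read a kinship matrix from CSV
#'
#' Accepts a square numeric CSV with an optional header row and optional label
#' column. Asymmetry beyond 1e-10 is repaired by (K + K')/2 with a warning.
#'
#' @param path Path to the CSV file.
#' @return A [kinship_matrix()].
#' @export
read_kinship <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  # detect header row / label column: non-numeric first row or column
  first_row_num <- suppressWarnings(all(!is.na(as.numeric(unlist(raw[1, ])))))
  if (!first_row_num) raw <- raw[-1, , drop = FALSE]
  first_col_num <- suppressWarnings(all(!is.na(as.numeric(raw[[1]]))))
  if (!first_col_num) raw <- raw[, -1, drop = FALSE]
  suppressWarnings(vals <- vapply(raw, as.numeric, numeric(nrow(raw))))
  if (anyNA(vals)) {
    abort("kinship file contains non-numeric entries.", class = "embai_format_error")
  }
  vals <- as.matrix(vals)
  dimnames(vals) <- NULL
  if (nrow(vals) != ncol(vals)) {
    abort(sprintf("kinship file is %d x %d, not square.", nrow(vals), ncol(vals)),
          class = "embai_format_error")
  }
  kinship_matrix(vals)
}

#' Write a kinship matrix to CSV
#'
#' @param kinship A [kinship_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kinship, path) {
  kinship <- as_kinship_matrix(kinship)
  utils::write.table(kinship$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
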