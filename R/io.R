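#' Read a genotype matrix from file
#'
#' Two dialects are supported. `"csv"`: first column is the individual id,
#' header row holds marker ids, remaining cells are dosages 0/1/2.
#' `"plink_raw"`: PLINK `--recode A` output, whitespace-separated with header
#' `FID IID PAT MAT SEX PHENOTYPE <snp>_<allele> ...` and dosages 0/1/2 (`NA`
#' for missing). Missing dosages are imputed to the rounded column mean with a
#' message; columns over 20% missing are dropped with a warning.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"plink_raw"`.
#' @return A [genotype_matrix()]; individual ids kept as row names.
#' @export
read_genotypes <- function(path, format = c("csv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("genotype file not found: ", path), class = "embai_format_error")
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(df[[1]])
    dat <- df[, -1, drop = FALSE]
  } else {
    df <- readr::read_table(path, show_col_types = FALSE, progress = FALSE,
                            na = c("NA", "-9"))
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(df)[1:6])) {
      abort("not a PLINK RAW header (expected FID IID PAT MAT SEX PHENOTYPE ...).",
            class = "embai_format_error")
    }
    ids <- as.character(df$IID)
    dat <- df[, -(1:6), drop = FALSE]
    names(dat) <- sub("_[ACGTacgt0-9]+$", "", names(dat))
  }
  dos <- as.matrix(dat)
  if (!is.numeric(dos)) {
    bad <- which(!vapply(dat, is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(dat[[bad]]))) &
                      !is.na(dat[[bad]]))[1]
    abort(sprintf("non-numeric dosage in column '%s' (data row %s).",
                  names(dat)[bad], badrow %||% "?"),
          class = "embai_format_error")
  }
  # drop heavily missing columns, impute the rest to rounded column means
  miss_frac <- colMeans(is.na(dos))
  drop_cols <- which(miss_frac > 0.2)
  if (length(drop_cols) > 0L) {
    warn(sprintf("dropping %d marker column(s) with > 20%% missing dosages.",
                 length(drop_cols)))
    dos <- dos[, -drop_cols, drop = FALSE]
  }
  n_imputed <- sum(is.na(dos))
  if (n_imputed > 0L) {
    message(sprintf("imputed %d missing dosage(s) to rounded column means.",
                    n_imputed))
    for (k in which(colSums(is.na(dos)) > 0L)) {
      fill <- round(mean(dos[, k], na.rm = TRUE))
      dos[is.na(dos[, k]), k] <- min(max(fill, 0), 2)
    }
  }
  rownames(dos) <- ids
  genotype_matrix(dos)
}

#' Write a genotype matrix to file
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @param format `"csv"` (id column + marker header) or `"plink_raw"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, format = c("csv", "plink_raw")) {
  format <- match.arg(format)
  genotypes <- as_genotype_matrix(genotypes)
  ids <- rownames(genotypes$dosages) %||% paste0("ind", seq_len(genotypes$n))
  if (format == "csv") {
    df <- data.frame(id = ids, genotypes$dosages, check.names = FALSE)
    readr::write_csv(df, path, progress = FALSE)
  } else {
    df <- data.frame(
      FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
      genotypes$dosages, check.names = FALSE
    )
    names(df)[-(1:6)] <- paste0(genotypes$marker_ids, "_A")
    readr::write_delim(df, path, delim = " ", progress = FALSE)
  }
  invisible(path)
}

#' Read phenotypes from a two-column TSV
#'
#' Column 1: individual id; remaining column(s): one numeric trait each.
#'
#' @param path Input path.
#' @return A tibble with an `id` column and one column per trait.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("phenotype file not found: ", path), class = "embai_format_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) {
    abort("phenotype file needs an id column and at least one trait column.",
          class = "embai_format_error")
  }
  if (!all(vapply(df[-1], is.numeric, logical(1)))) {
    abort("trait columns must be numeric.", class = "embai_format_error")
  }
  names(df)[1] <- "id"
  df
}

#' Write phenotypes as TSV
#'
#' @param y Numeric trait vector or tibble from [read_phenotypes()].
#' @param path Output path.
#' @param ids Individual ids (defaults to 1..n) when `y` is a bare vector.
#' @param trait Trait column name when `y` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(y, path, ids = NULL, trait = "y") {
  if (!is.data.frame(y)) {
    y <- tibble(id = ids %||% seq_along(y), value = as.numeric(y))
    names(y)[2] <- trait
  }
  readr::write_tsv(y, path, progress = FALSE)
  invisible(path)
}

#' Write a fit report (marker effects + run metadata)
#'
#' Writes `<stem>_effects.tsv` (marker_id, gamma_hat, sigma_k2_hat and, for
#' the spike-and-slab fit, inclusion) and `<stem>_meta.tsv` (method, lambda_g,
#' sigma2, iterations, convergence, prior settings).
#'
#' @param fit An `embai_fit`.
#' @param stem Output path stem.
#' @return The effects path, invisibly.
#' @export
write_fit_report <- function(fit, stem) {
  stopifnot(inherits(fit, "embai_fit"))
  eff <- tidy(fit)
  readr::write_tsv(eff, paste0(stem, "_effects.tsv"), progress = FALSE)
  readr::write_tsv(glance(fit), paste0(stem, "_meta.tsv"), progress = FALSE)
  invisible(paste0(stem, "_effects.tsv"))
}

#' Write the simulation truth sidecar
#'
#' Records QTN indices and effects plus the variance settings and seed of a
#' scenario as a TSV pair readable without the package.
#'
#' @param scenario A `sim_scenario`.
#' @param stem Output path stem; writes `<stem>_qtn.tsv` and
#'   `<stem>_settings.tsv`.
#' @return `stem`, invisibly.
#' @export
write_scenario <- function(scenario, stem) {
  stopifnot(inherits(scenario, "sim_scenario"))
  readr::write_tsv(
    tibble(qtn_index = scenario$qtn_indices, effect = scenario$qtn_effects),
    paste0(stem, "_qtn.tsv"), progress = FALSE
  )
  readr::write_tsv(
    tibble(
      experiment = scenario$experiment, n = scenario$n, q = scenario$q,
      mu = scenario$mu, sigma2_e = scenario$sigma2_e,
      background_multiplier = scenario$background_multiplier,
      seed = scenario$seed
    ),
    paste0(stem, "_settings.tsv"), progress = FALSE
  )
  invisible(stem)
}
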