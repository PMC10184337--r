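#' Covariate regimes for methylation pre-adjustment
#'
#' Three named covariate sets drive the analyses: `set1` is the full set
#' (cell proportions, technical covariates, smoking variables, age,
#' age-squared, sex); `set2` drops the smoking variables (used when smoking
#' status is the target phenotype); `set3` drops age and age-squared (used
#' for age-acceleration phenotypes, which are age-adjusted by construction).
#'
#' @param name One of `"set1"`, `"set2"`, `"set3"`.
#' @param samples A [sample_table()]; used to enumerate the cell and
#'   technical covariate columns present.
#' @return List with elements `name` and `included` (column names).
#' @export
covariate_set <- function(name = c("set1", "set2", "set3"), samples) {
  name <- match.arg(name)
  cells <- grep("^cell_", names(samples), value = TRUE)
  tech <- grep("^tech_", names(samples), value = TRUE)
  smoking <- intersect(c("smoking_status", "pack_years"), names(samples))
  base <- c(cells, tech, "sex")
  included <- switch(name,
                     set1 = c(base, smoking, "age", "age2"),
                     set2 = c(base, "age", "age2"),
                     set3 = c(base, smoking))
  list(name = name, included = included)
}

# Design matrix for a covariate set; age2 derived from age. Drops one cell
# proportion column if all are present (they sum to 1).
covariate_design <- function(samples, included) {
  cells <- grep("^cell_", included, value = TRUE)
  if (length(cells) >= 2) {
    tot <- rowSums(samples[cells])
    if (all(abs(tot - 1) < 1e-8)) included <- setdiff(included, cells[1])
  }
  cols <- lapply(included, function(v) {
    if (v == "age2") samples$age^2 else samples[[v]]
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", included)
  X
}

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  z <- x - mean(x)
  s2 <- mean(z^2)
  if (s2 == 0) return(0)
  mean(z^3) / s2^1.5
}

#' Prepare a phenotype for association testing
#'
#' Applies the protocol's phenotype pipeline: a log10 transform for
#' positive, skewed traits; a single-pass 4-SD outlier rule (mean and SD
#' computed once, post-transform, never recomputed after removal); and
#' least-squares residualization on the supplied covariates. Missing values
#' are dropped for this phenotype only.
#'
#' @param raw Numeric phenotype vector, named by sample id (missing values
#'   allowed).
#' @param samples A [sample_table()] aligned with `raw`.
#' @param cov_names Covariate columns to residualize on. The default (NULL)
#'   uses the technical covariate columns only, mirroring the protocol's
#'   asymmetry: biological covariates are removed from the methylation side,
#'   while the phenotype is adjusted only for structural/technical effects.
#' @param skew_threshold Absolute skewness above which a positive trait is
#'   log10-transformed.
#' @param sd_limit Outlier cutoff in standard deviations (default 4).
#' @return List of class `adjusted_phenotype`: `values` (named residuals,
#'   NA for dropped samples), `transform_applied`, `n_outliers_removed`,
#'   `n_used`.
#' @export
prepare_phenotype <- function(raw, samples, cov_names = NULL,
                              skew_threshold = 1.0, sd_limit = 4) {
  if (is.null(cov_names))
    cov_names <- grep("^tech_", names(samples), value = TRUE)
  if (is.null(names(raw))) names(raw) <- samples$sample_id
  ok <- !is.na(raw)
  if (sum(ok) < 30) stop("fewer than 30 non-missing phenotype values")
  x <- raw
  if (stats::sd(x[ok]) == 0) stop("constant phenotype")
  transform_applied <- "none"
  if (abs(sample_skewness(x[ok])) > skew_threshold && all(x[ok] > 0)) {
    x <- log10(x)
    transform_applied <- "log10"
  }
  mu <- mean(x[ok])
  sdev <- stats::sd(x[ok])
  outlier <- ok & abs(x - mu) > sd_limit * sdev
  keep <- ok & !outlier
  X <- covariate_design(samples, cov_names)
  fit <- stats::lm.fit(X[keep, , drop = FALSE], x[keep])
  values <- rep(NA_real_, length(raw))
  names(values) <- names(raw)
  values[keep] <- fit$residuals
  structure(list(values = values,
                 transform_applied = transform_applied,
                 n_outliers_removed = sum(outlier),
                 n_used = sum(keep)),
            class = "adjusted_phenotype")
}

#' @export
print.adjusted_phenotype <- function(x, ...) {
  cat("adjusted_phenotype: n =", x$n_used, "| transform =",
      x$transform_applied, "| outliers removed =", x$n_outliers_removed,
      "\n")
  invisible(x)
}

#' Residualize a methylation matrix on a covariate set
#'
#' Per-CpG least-squares residuals of M values on the covariate design.
#' Residualization is idempotent and leaves any CpG exactly equal to zero if
#' it lies in the covariate column space.
#'
#' @param mat A `meth_matrix` (typically on the M scale).
#' @param samples A [sample_table()] whose rows match the matrix samples.
#' @param cov_set A [covariate_set()], or a name passed to it.
#' @return A `meth_matrix` with scale `"residual"`, tagged with the
#'   covariate set name.
#' @export
residualize_methylation <- function(mat, samples, cov_set = "set1") {
  if (is.character(cov_set)) cov_set <- covariate_set(cov_set, samples)
  samples <- samples[match(rownames(mat), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("samples table does not cover all matrix samples")
  X <- covariate_design(samples, cov_set$included)
  if (anyNA(X)) stop("covariate columns must be complete for all samples")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- unclass(mat) - X %*% qr.coef(qrX, unclass(mat))
  meth_matrix(res, scale = "residual", cov_set = cov_set$name)
}
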