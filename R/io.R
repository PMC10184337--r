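#' Read a methylation matrix from delimited text
#'
#' Expects a header row of CpG ids and a first column of sample ids;
#' tab- or comma-delimited. Values are validated against the declared scale:
#' beta matrices must lie in \[0,1\], and no missing cells are allowed on any
#' scale.
#'
#' @param path File path.
#' @param scale Declared scale of the stored values (see [meth_matrix()]).
#' @param sep Field separator (default tab).
#' @return A `meth_matrix`.
#' @export
read_methylation_matrix <- function(path, scale = c("beta", "m", "residual"),
                                    sep = "\t") {
  scale <- match.arg(scale)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed header: need sample id column plus ",
                         "at least one CpG column in ", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop("non-numeric cell at row '", ids[bad], "', column '",
           names(vals)[j], "' in ", path)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  meth_matrix(m, scale = scale)
}

#' Write a methylation matrix as delimited text
#'
#' Inverse of [read_methylation_matrix()]; full double precision is kept so
#' the round trip preserves values.
#'
#' @param mat A `meth_matrix`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_methylation_matrix <- function(mat, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(mat), unclass(mat),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write sample tables and CpG annotation
#'
#' Plain TSV with a header. The annotation uses a BED-like column layout
#' (chromosome, position, cpg_id, poe_class, region_class, clock flags).
#'
#' @param path File path.
#' @return A `sample_table` or `cpg_annotation`.
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' @rdname read_sample_table
#' @param st A `sample_table` to write.
#' @export
write_sample_table <- function(st, path) {
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_table
#' @export
read_cpg_annotation <- function(path) {
  cpg_annotation(utils::read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE))
}

#' @rdname read_sample_table
#' @param ann A `cpg_annotation` to write.
#' @export
write_cpg_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert beta values to M values
#'
#' M = log2(b / (1 - b)) after clipping b into \[epsilon, 1 - epsilon\] so the
#' logit stays finite at the boundaries. The transform is strictly increasing
#' on (0,1) and antisymmetric about 0.5.
#'
#' @param mat A `meth_matrix` on the beta scale (or a bare numeric
#'   matrix/vector of betas).
#' @param epsilon Clipping constant in (0, 0.5); default 1e-6, which leaves
#'   interior values essentially untouched.
#' @return M values in the same shape; a `meth_matrix` with scale "m" when
#'   the input was one.
#' @export
beta_to_m <- function(mat, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must lie in (0, 0.5)")
  is_mm <- inherits(mat, "meth_matrix")
  if (is_mm && meth_scale(mat) != "beta")
    stop("beta_to_m requires a beta-scale matrix, got scale = ",
         meth_scale(mat))
  b <- pmin(pmax(unclass(mat), epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  if (is_mm) meth_matrix(m, scale = "m") else m
}

#' @rdname beta_to_m
#' @param m M values to map back to the beta scale.
#' @export
m_to_beta <- function(m, epsilon = 1e-6) {
  is_mm <- inherits(m, "meth_matrix")
  if (is_mm && meth_scale(m) != "m")
    stop("m_to_beta requires an m-scale matrix")
  b <- 2^unclass(m) / (1 + 2^unclass(m))
  if (is_mm) meth_matrix(b, scale = "beta") else b
}
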