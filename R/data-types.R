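#' Construct a methylation matrix
#'
#' Container for array methylation values with a declared scale. Rows are
#' samples, columns are CpG sites; this orientation is fixed throughout the
#' package to avoid silent transposition errors.
#'
#' @param values Numeric matrix (samples x CpGs) with row names (sample ids)
#'   and column names (CpG ids).
#' @param scale One of `"beta"` (methylation proportions in \[0,1\]), `"m"`
#'   (logit2-transformed betas) or `"residual"` (covariate-adjusted values).
#' @param cov_set Optional covariate-set tag carried by residual matrices
#'   (see [covariate_set()]).
#' @return An object of class `meth_matrix`: the matrix with `scale` and
#'   `cov_set` attributes.
#' @export
meth_matrix <- function(values, scale = c("beta", "m", "residual"),
                        cov_set = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x CpGs)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids as rownames and CpG ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate CpG ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing methylation value at sample '", rownames(values)[bad[1]],
         "', CpG '", colnames(values)[bad[2]],
         "': missing values are not allowed after ingestion")
  }
  if (scale == "beta") {
    out <- which(values < 0 | values > 1, arr.ind = TRUE)
    if (nrow(out) > 0)
      stop("beta value outside [0,1] at sample '",
           rownames(values)[out[1, 1]], "', CpG '",
           colnames(values)[out[1, 2]], "' (value = ",
           format(values[out[1, , drop = FALSE]]), ")")
  }
  structure(values, scale = scale, cov_set = cov_set, class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", nrow(x), "samples x", ncol(x), "CpGs, scale =",
      attr(x, "scale"))
  if (!is.null(attr(x, "cov_set"))) cat(", cov_set =", attr(x, "cov_set"))
  cat("\n")
  invisible(x)
}

#' @export
`[.meth_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     cov_set = attr(x, "cov_set"), class = "meth_matrix")
  out
}

meth_scale <- function(x) attr(x, "scale")

sample_ids <- function(x) rownames(x)
cpg_ids <- function(x) colnames(x)

#' Validate a CpG annotation table
#'
#' The annotation carries, per CpG, genomic position (1-based bp), POE class,
#' CpG-island region class and epigenetic-clock memberships. The
#' (chromosome, position) pair defines the genomic order used by the circular
#' permutation; ties are broken by CpG id.
#'
#' @param ann Data frame with columns `cpg_id`, `chromosome`, `position`,
#'   `poe_class` (one of atypical/typical/none); optional `region_class`
#'   (island/shore/shelf/open_sea/other) and logical clock membership columns
#'   `horvath`, `hannum`, `phenoage`, `dnamtl`.
#' @return The validated data frame (class `cpg_annotation`).
#' @export
cpg_annotation <- function(ann) {
  req <- c("cpg_id", "chromosome", "position", "poe_class")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$cpg_id))
    stop("duplicate cpg_id in annotation")
  if (any(ann$position < 0)) stop("negative position in annotation")
  ok <- ann$poe_class %in% c("atypical", "typical", "none")
  if (!all(ok))
    stop("invalid poe_class value(s): ",
         paste(unique(ann$poe_class[!ok]), collapse = ", "))
  if (!"region_class" %in% names(ann)) ann$region_class <- "other"
  for (clk in c("horvath", "hannum", "phenoage", "dnamtl"))
    if (!clk %in% names(ann)) ann[[clk]] <- FALSE
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  class(ann) <- c("cpg_annotation", "data.frame")
  ann
}

#' Genomic order of annotated CpGs
#'
#' Orders CpGs lexicographically by chromosome label then position, ties
#' broken by CpG id. This total order defines the ring used by
#' [circular_permutation_test()].
#'
#' @param ann A [cpg_annotation()] table.
#' @return Character vector of CpG ids in genomic order.
#' @export
genomic_order <- function(ann) {
  ann$cpg_id[order(ann$chromosome, ann$position, ann$cpg_id)]
}

#' Validate a sample table
#'
#' @param st Data frame with columns `sample_id`, `age`, `sex`, six cell
#'   proportion columns (prefixed `cell_`), technical covariates (prefixed
#'   `tech_`), `smoking_status`, `pack_years`, and phenotype columns
#'   (prefixed `pheno_`, missing values allowed).
#' @return The validated data frame (class `sample_table`).
#' @export
sample_table <- function(st) {
  req <- c("sample_id", "age", "sex", "smoking_status", "pack_years")
  miss <- setdiff(req, names(st))
  if (length(miss) > 0)
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(st$sample_id)) stop("duplicate sample_id")
  if (any(st$age < 0, na.rm = TRUE)) stop("negative age")
  cells <- grep("^cell_", names(st), value = TRUE)
  for (cc in cells)
    if (any(st[[cc]] < 0 | st[[cc]] > 1, na.rm = TRUE))
      stop("cell proportion outside [0,1] in column ", cc)
  st <- as.data.frame(st, stringsAsFactors = FALSE)
  class(st) <- c("sample_table", "data.frame")
  st
}

#' Names of phenotype columns in a sample table
#' @param st A [sample_table()].
#' @return Character vector of phenotype ids (without the `pheno_` prefix).
#' @export
phenotype_ids <- function(st) {
  sub("^pheno_", "", grep("^pheno_", names(st), value = TRUE))
}

#' Pipeline configuration
#'
#' All tunable thresholds of the analysis pipeline with their defaults.
#' Defaults encode the standard analysis protocol: FDR q = 0.05, minimum
#' module size 8, 10-kb pruning windows, module overlap thresholds 60% and
#' 90%, PC retention by SS loading > 1 and > 5% variance explained, network
#' edge threshold |r| > 0.4, 10,000 permutations, and six age bins spanning
#' 18-94 years.
#'
#' @param fdr_q FDR threshold for discovery/replication.
#' @param bonferroni_alpha Family-wise alpha for Bonferroni-controlled scans.
#' @param soft_power_override Optional integer; bypasses scale-free power
#'   selection (the protocol value for POE methylome networks is 3).
#' @param min_module_size Smallest number of CpGs forming a module.
#' @param prune_window_bp Window size for index-CpG pruning.
#' @param overlap_primary Primary module match threshold (strictly greater).
#' @param overlap_secondary Secondary match threshold (strictly greater).
#' @param pc_ss_loading_min Minimum SS loading for a retained module PC.
#' @param pc_var_explained_min Minimum variance fraction for a retained PC.
#' @param edge_threshold |r| threshold for connectivity graph edges
#'   (strictly greater).
#' @param n_permutations Number of circular permutations.
#' @param age_bins Matrix or list of inclusive \[low, high\] age ranges,
#'   non-overlapping and ordered.
#' @param epsilon Clipping constant for logit and entropy transforms.
#' @param skew_threshold Absolute skewness above which positive phenotypes
#'   are log10-transformed.
#' @param cut_height Static branch-cut height on the topological-overlap
#'   dissimilarity dendrogram.
#' @param dedup_r_threshold |r| at or above which associated CpGs are
#'   counted once in normalized association counts.
#' @param seed Integer seed; the pipeline is a pure function of
#'   (inputs, config, seed).
#' @return A list of class `poe_config`.
#' @export
poe_config <- function(fdr_q = 0.05,
                       bonferroni_alpha = 0.05,
                       soft_power_override = NULL,
                       min_module_size = 8,
                       prune_window_bp = 10000,
                       overlap_primary = 0.60,
                       overlap_secondary = 0.90,
                       pc_ss_loading_min = 1.0,
                       pc_var_explained_min = 0.05,
                       edge_threshold = 0.4,
                       n_permutations = 10000,
                       age_bins = default_age_bins(),
                       epsilon = 1e-6,
                       skew_threshold = 1.0,
                       cut_height = 0.995,
                       dedup_r_threshold = 0.5,
                       seed = 1L) {
  cfg <- list(fdr_q = fdr_q, bonferroni_alpha = bonferroni_alpha,
              soft_power_override = soft_power_override,
              min_module_size = as.integer(min_module_size),
              prune_window_bp = as.integer(prune_window_bp),
              overlap_primary = overlap_primary,
              overlap_secondary = overlap_secondary,
              pc_ss_loading_min = pc_ss_loading_min,
              pc_var_explained_min = pc_var_explained_min,
              edge_threshold = edge_threshold,
              n_permutations = as.integer(n_permutations),
              age_bins = as_age_bins(age_bins),
              epsilon = epsilon,
              skew_threshold = skew_threshold,
              cut_height = cut_height,
              dedup_r_threshold = dedup_r_threshold,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "poe_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$bonferroni_alpha > 0, cfg$bonferroni_alpha < 1,
            cfg$min_module_size >= 2,
            cfg$prune_window_bp >= 1,
            cfg$overlap_primary >= 0, cfg$overlap_primary <= 1,
            cfg$overlap_secondary >= 0, cfg$overlap_secondary <= 1,
            cfg$edge_threshold >= 0, cfg$edge_threshold <= 1,
            cfg$n_permutations >= 1,
            cfg$epsilon > 0, cfg$epsilon < 0.5,
            cfg$cut_height > 0, cfg$cut_height <= 1)
  bins <- cfg$age_bins
  if (nrow(bins) == 0) stop("age_bins must contain at least one bin")
  if (any(bins[, 2] < bins[, 1])) stop("age bin with high < low")
  if (nrow(bins) > 1) {
    if (any(bins[-1, 1] <= bins[-nrow(bins), 2]))
      stop("age bins must be non-overlapping and ordered")
  }
  invisible(cfg)
}

as_age_bins <- function(x) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  if (is.null(x) || length(x) == 0) x <- matrix(numeric(0), 0, 2)
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("age_bins must have two columns (low, high)")
  colnames(x) <- c("low", "high")
  if (nrow(x) > 0) rownames(x) <- paste0(x[, 1], "-", x[, 2])
  x
}

#' Default six age bins (years, inclusive)
#' @return A 6x2 matrix of bin bounds: 18-27, 28-37, 38-46, 47-56, 57-65,
#'   66-94.
#' @export
default_age_bins <- function() {
  as_age_bins(rbind(c(18, 27), c(28, 37), c(38, 46),
                    c(47, 56), c(57, 65), c(66, 94)))
}

#' Read a pipeline configuration from YAML
#'
#' Field names in the YAML file mirror the arguments of [poe_config()]
#' exactly; absent fields take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `poe_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(poe_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(poe_config, raw)
}
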