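#' Unsigned soft-thresholded adjacency and topological overlap
#'
#' Adjacency is `|r|^power` on pairwise Pearson correlations (unsigned
#' network, diagonal zero). The topological overlap measure (TOM) between
#' nodes i and j counts their shared neighbourhood:
#' \eqn{TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) / (\min(k_i, k_j) + 1 -
#' a_{ij})}, giving a similarity in \[0,1\] used as the clustering metric.
#'
#' @param residuals Matrix (samples x CpGs) of adjusted methylation.
#' @param power Soft-thresholding power.
#' @return For `adjacency_matrix`, the CpG x CpG adjacency; for
#'   `tom_similarity`, the TOM matrix.
#' @export
adjacency_matrix <- function(residuals, power) {
  a <- abs(stats::cor(unclass(residuals)))^power
  diag(a) <- 0
  a
}

#' @rdname adjacency_matrix
#' @export
tom_similarity <- function(residuals, power) {
  a <- adjacency_matrix(residuals, power)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Scale-free topology fit and soft power selection
#'
#' For each candidate power, node connectivities `k_i = sum_j a_ij` are
#' binned and the log10 frequency of each bin regressed on the log10 mean
#' connectivity; the (slope-signed) R-squared of this line measures
#' scale-free fit. Returns the smallest power reaching `r2_target`,
#' otherwise the R-squared-maximizing power. An explicit override (the
#' protocol default for POE methylome networks is 3) bypasses the search.
#'
#' @param residuals Matrix (samples x CpGs); at least 20 CpGs.
#' @param powers Candidate integer powers.
#' @param r2_target Scale-free fit target (default 0.85, the WGCNA convention).
#' @param override Optional integer returned as-is.
#' @param n_bins Connectivity bins for the fit.
#' @return List with `power`, `fit_table` (power, r_squared, slope,
#'   mean_k).
#' @export
pick_soft_threshold <- function(residuals, powers = 1:20, r2_target = 0.85,
                                override = NULL, n_bins = 10) {
  if (!is.null(override)) {
    return(list(power = as.integer(override), fit_table = NULL))
  }
  if (ncol(residuals) < 20)
    stop("need at least 20 CpGs to estimate a soft threshold")
  absr <- abs(stats::cor(unclass(residuals)))
  if (any(!is.finite(absr)))
    stop("degenerate correlation matrix (constant CpG?)")
  diag(absr) <- 0
  rows <- lapply(powers, function(pw) {
    k <- rowSums(absr^pw)
    ft <- scale_free_fit(k, n_bins)
    data.frame(power = pw, r_squared = ft$r2, slope = ft$slope,
               mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  signed <- tab$r_squared * as.numeric(tab$slope < 0)
  hit <- which(signed >= r2_target)
  power <- if (length(hit) > 0) tab$power[hit[1]]
           else tab$power[which.max(signed)]
  list(power = as.integer(power), fit_table = tab)
}

# log-log regression of binned connectivity frequency; slope sign retained
# so only decreasing (scale-free-like) degree distributions can pass.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 5) return(list(r2 = 0, slope = 0))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = 0))
  x <- log10(mk[keep])
  y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Detect co-methylation modules
#'
#' Builds the unsigned soft-thresholded network, converts it to topological
#' overlap dissimilarity (1 - TOM), clusters with average-linkage
#' hierarchical clustering and applies a static branch cut; branches with at
#' least `min_size` CpGs become modules, the remainder stay unassigned.
#'
#' @param residuals Matrix (samples x CpGs).
#' @param power Soft-thresholding power.
#' @param min_size Minimum module size (default 8).
#' @param cut_height Static cut height on 1 - TOM (default 0.995).
#' @return List of modules, each `list(module_id, cpg_ids, power_used)`,
#'   ordered by decreasing size; attribute `unassigned` holds leftover CpG
#'   ids.
#' @export
detect_modules <- function(residuals, power, min_size = 8,
                           cut_height = 0.995) {
  stopifnot(power >= 1)
  tom <- tom_similarity(residuals, power)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  labels <- stats::cutree(hc, h = cut_height)
  ids <- colnames(residuals)
  groups <- split(ids, labels)
  groups <- groups[order(-lengths(groups),
                         vapply(groups, min, character(1)))]
  big <- groups[lengths(groups) >= min_size]
  mods <- lapply(seq_along(big), function(i) {
    list(module_id = paste0("m", i), cpg_ids = unname(big[[i]]),
         power_used = as.integer(power))
  })
  attr(mods, "unassigned") <- unname(unlist(groups[lengths(groups) <
                                                     min_size]))
  mods
}

#' Recursive pruning and soft-power estimation
#'
#' Implements the recursive construction: (1) pick a (typically high) power
#' on the current CpG set and detect tightly connected modules; (2) within
#' each module, tile the genome into fixed windows
#' (`floor(position / window_bp)` per chromosome) and keep only the index
#' CpG per window — the member with the highest summed |r| with the other
#' module CpGs, ties broken by smaller genomic position; (3) repeat until an
#' iteration removes nothing; (4) re-estimate the power on the retained set;
#' (5) build the final network on ALL CpGs with that power.
#'
#' @param residuals Matrix (samples x CpGs) for one POE group.
#' @param annotation A [cpg_annotation()] covering all CpGs.
#' @param config A [poe_config()] (supplies window size, minimum module
#'   size, cut height and any soft-power override).
#' @param max_iter Non-termination guard (default 50).
#' @return List with `power` (final), `modules` (final module list),
#'   `retained_cpgs`, `n_iterations`.
#' @export
recursive_prune_and_power <- function(residuals, annotation,
                                      config = poe_config(),
                                      max_iter = 50) {
  ids <- colnames(residuals)
  miss <- setdiff(ids, annotation$cpg_id)
  if (length(miss) > 0)
    stop("annotation missing position for: ", paste(miss, collapse = ", "))
  current <- ids
  for (it in seq_len(max_iter)) {
    pw <- pick_soft_threshold(residuals[, current, drop = FALSE],
                              override = config$soft_power_override)$power
    mods <- detect_modules(residuals[, current, drop = FALSE], pw,
                           min_size = config$min_module_size,
                           cut_height = config$cut_height)
    removed <- character(0)
    for (m in mods)
      removed <- c(removed,
                   prune_module_windows(residuals, annotation, m$cpg_ids,
                                        config$prune_window_bp))
    if (length(removed) == 0) {
      final_pw <- pick_soft_threshold(residuals[, current, drop = FALSE],
                                      override = config$soft_power_override)$power
      return(list(power = final_pw,
                  modules = detect_modules(residuals, final_pw,
                                           min_size = config$min_module_size,
                                           cut_height = config$cut_height),
                  retained_cpgs = current, n_iterations = it))
    }
    current <- setdiff(current, removed)
  }
  stop("recursive pruning failed to converge within ", max_iter,
       " iterations")
}

# Returns the CpGs pruned from one module: all non-index CpGs of windows
# holding two or more module members.
prune_module_windows <- function(residuals, annotation, cpg_ids,
                                 window_bp) {
  ann <- annotation[match(cpg_ids, annotation$cpg_id), , drop = FALSE]
  win <- paste0(ann$chromosome, ":", ann$position %/% window_bp)
  absr <- abs(stats::cor(unclass(residuals)[, cpg_ids, drop = FALSE]))
  diag(absr) <- 0
  conn <- rowSums(absr)
  removed <- character(0)
  for (w in unique(win[duplicated(win)])) {
    members <- which(win == w)
    best <- members[order(-conn[members], ann$position[members])][1]
    removed <- c(removed, cpg_ids[setdiff(members, best)])
  }
  removed
}

#' Match modules across discovery and replication datasets
#'
#' Pairs are ranked by overlap rate (|intersection| / |union|, symmetric)
#' in descending order and accepted greedily while the rate is strictly
#' greater than `overlap_primary`, each acceptance consuming both modules.
#' Remaining replication modules may attach to a discovery module when the
#' secondary rate (|intersection| / |replication module|, asymmetric)
#' strictly exceeds `overlap_secondary`; several replication modules may
#' attach to one discovery module this way. Matched pairs are the
#' "consistent modules"; their intersections are the constituent CpGs used
#' downstream.
#'
#' @param discovery,replication Module lists from [detect_modules()].
#' @param config A [poe_config()] (supplies the two thresholds).
#' @return List of consistent modules, each `list(discovery_module_id,
#'   replication_module_id, shared_cpg_ids, overlap_rate, match_type)`.
#' @export
match_modules <- function(discovery, replication, config = poe_config()) {
  if (length(discovery) == 0 || length(replication) == 0) return(list())
  pairs <- expand.grid(d = seq_along(discovery),
                       r = seq_along(replication))
  pairs$rate <- mapply(function(d, r) {
    a <- discovery[[d]]$cpg_ids
    b <- replication[[r]]$cpg_ids
    length(intersect(a, b)) / length(union(a, b))
  }, pairs$d, pairs$r)
  did <- vapply(discovery, `[[`, "", "module_id")
  rid <- vapply(replication, `[[`, "", "module_id")
  pairs <- pairs[order(-pairs$rate, did[pairs$d], rid[pairs$r]), ,
                 drop = FALSE]
  used_d <- used_r <- logical(0)
  out <- list()
  taken_d <- rep(FALSE, length(discovery))
  taken_r <- rep(FALSE, length(replication))
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$d[i]; r <- pairs$r[i]
    if (pairs$rate[i] <= config$overlap_primary) break
    if (taken_d[d] || taken_r[r]) next
    taken_d[d] <- taken_r[r] <- TRUE
    out[[length(out) + 1]] <- list(
      discovery_module_id = did[d], replication_module_id = rid[r],
      shared_cpg_ids = intersect(discovery[[d]]$cpg_ids,
                                 replication[[r]]$cpg_ids),
      overlap_rate = pairs$rate[i], match_type = "primary")
  }
  for (r in which(!taken_r)) {
    b <- replication[[r]]$cpg_ids
    sec <- vapply(discovery, function(m)
      length(intersect(m$cpg_ids, b)) / length(b), 0)
    best <- order(-sec, did)[1]
    if (sec[best] > config$overlap_secondary) {
      out[[length(out) + 1]] <- list(
        discovery_module_id = did[best], replication_module_id = rid[r],
        shared_cpg_ids = intersect(discovery[[best]]$cpg_ids, b),
        overlap_rate = sec[best], match_type = "secondary")
    }
  }
  out
}

#' Principal components of a consistent module
#'
#' PCA of the constituent CpGs' (standardized) residuals over the training
#' samples. Components are retained when their SS loading — the sum of
#' squared loadings after scaling the loading vector by the component's
#' singular value, i.e. the eigenvalue of the correlation matrix — exceeds
#' `ss_loading_min` (a Kaiser-style rule) AND the explained variance
#' fraction exceeds `var_explained_min`. The stored centring/scaling and
#' rotation define a projection formula applicable to any sample set.
#'
#' @param residuals Matrix (samples x CpGs) on the appropriate covariate
#'   regime.
#' @param cpg_ids Constituent CpGs of the module.
#' @param training_samples Sample ids used to estimate the PCA.
#' @param ss_loading_min,var_explained_min Retention thresholds.
#' @param standardize Standardize CpGs to unit variance (default TRUE,
#'   correlation-matrix PCA).
#' @return Object of class `module_pc_model`: rotation, center, scale,
#'   ss_loading, explained_fraction, retained indices, cpg_ids,
#'   training_sample_ids.
#' @export
fit_module_pca <- function(residuals, cpg_ids,
                           training_samples = rownames(residuals),
                           ss_loading_min = 1.0, var_explained_min = 0.05,
                           standardize = TRUE) {
  x <- unclass(residuals)[training_samples, cpg_ids, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant CpG column(s): ",
         paste(cpg_ids[sds == 0], collapse = ", "))
  if (length(training_samples) <= length(cpg_ids))
    warning("fewer training samples than CpGs; PCA will be rank-deficient")
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ss <- pc$sdev^2                       # eigenvalues = SS of scaled loadings
  expl <- ss / sum(ss)
  retained <- which(ss > ss_loading_min & expl > var_explained_min)
  structure(list(rotation = pc$rotation, center = pc$center,
                 scale = if (standardize) pc$scale else FALSE,
                 ss_loading = ss, explained_fraction = expl,
                 retained = retained, cpg_ids = cpg_ids,
                 training_sample_ids = training_samples),
            class = "module_pc_model")
}

#' @export
print.module_pc_model <- function(x, ...) {
  cat("module_pc_model:", length(x$cpg_ids), "CpGs,",
      length(x$retained), "retained PC(s) of", length(x$ss_loading), "\n")
  if (length(x$retained) > 0)
    cat("  retained:",
        paste0("PC", x$retained, " (", round(100 * x$explained_fraction[
          x$retained], 1), "%)", collapse = ", "), "\n")
  invisible(x)
}

#' Project module PCs onto samples
#'
#' Applies the training-set centring/scaling and rotation to new samples;
#' projecting the training samples reproduces their PCA scores exactly.
#'
#' @param model A `module_pc_model`.
#' @param residuals Matrix (samples x CpGs) containing all constituent
#'   CpGs.
#' @param retained_only Return only retained components (default TRUE).
#' @return Score matrix (samples x components).
#' @export
project_module_pcs <- function(model, residuals, retained_only = TRUE) {
  miss <- setdiff(model$cpg_ids, colnames(residuals))
  if (length(miss) > 0)
    stop("missing constituent CpG(s): ", paste(miss, collapse = ", "))
  x <- unclass(residuals)[, model$cpg_ids, drop = FALSE]
  x <- scale(x, center = model$center, scale = model$scale)
  scores <- x %*% model$rotation
  if (retained_only) scores <- scores[, model$retained, drop = FALSE]
  scores
}

#' Associate module PC scores with a phenotype
#'
#' Simple regression of the pre-adjusted phenotype on each PC score
#' (`y_p = w_pc b_pc`), one test per retained component.
#'
#' @param scores Score matrix (samples x PCs) with sample id rownames.
#' @param y Named adjusted phenotype vector (NAs dropped).
#' @param feature_prefix Prefix for feature ids (e.g. the module id).
#' @param phenotype_id,stage Tags copied to the output.
#' @return Data frame of association records (model = "module_pc").
#' @export
associate_module_pcs <- function(scores, y, feature_prefix = "m",
                                 phenotype_id = "y", stage = "discovery") {
  ids <- intersect(rownames(scores), names(y)[!is.na(y)])
  out <- lapply(seq_len(ncol(scores)), function(j) {
    fit <- stats::lm(y[ids] ~ scores[ids, j])
    cf <- summary(fit)$coefficients
    data.frame(feature_id = paste0(feature_prefix, "_", colnames(scores)[j]),
               phenotype_id = phenotype_id, model = "module_pc",
               stage = stage, beta = cf[2, 1], se = cf[2, 2], p = cf[2, 4],
               n = length(ids), variance_ratio = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
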