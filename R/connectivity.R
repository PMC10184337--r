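#' Assign samples to age bins
#'
#' Deterministic assignment by inclusive \[low, high\] ranges; out-of-range
#' ages are unassigned (NA) with a message.
#'
#' @param samples A [sample_table()].
#' @param bins Age bin matrix (see [default_age_bins()]).
#' @return Factor of bin labels aligned with samples (levels in bin order).
#' @export
stratify_ages <- function(samples, bins = default_age_bins()) {
  lab <- rep(NA_character_, nrow(samples))
  for (b in seq_len(nrow(bins)))
    lab[samples$age >= bins[b, 1] & samples$age <= bins[b, 2]] <-
      rownames(bins)[b]
  n_out <- sum(is.na(lab) & !is.na(samples$age))
  if (n_out > 0)
    message(n_out, " sample(s) outside the age bin range left unassigned")
  factor(lab, levels = rownames(bins))
}

#' Within-module connectivity per age bin
#'
#' Pairwise Pearson correlations of the module's CpGs computed separately
#' within each age bin's samples. Connectivity analyses use methylation
#' adjusted for cell proportions, sex, technical and smoking covariates but
#' NOT for age (the age signal is the object of study).
#'
#' @param residuals Matrix (samples x CpGs), age not pre-corrected.
#' @param cpg_ids Module CpGs (k of them; k(k-1)/2 pairs).
#' @param samples A [sample_table()] covering the matrix samples.
#' @param bins Age bin matrix.
#' @param min_n Bins with fewer samples trigger a warning ( < 3 drops the
#'   bin).
#' @return Object of class `connectivity_profile`: `pairs` (data frame
#'   cpg_a, cpg_b), `corr` and `abs_corr` (pairs x bins), `n_per_bin`,
#'   `cpg_ids`.
#' @export
module_connectivity_by_age <- function(residuals, cpg_ids, samples,
                                       bins = default_age_bins(),
                                       min_n = 30) {
  samples <- samples[match(rownames(residuals), samples$sample_id), ,
                     drop = FALSE]
  lab <- stratify_ages(samples, bins)
  k <- length(cpg_ids)
  if (k < 2) stop("need at least 2 CpGs for a connectivity profile")
  ut <- which(upper.tri(diag(k)), arr.ind = TRUE)
  pairs <- data.frame(cpg_a = cpg_ids[ut[, 1]], cpg_b = cpg_ids[ut[, 2]],
                      stringsAsFactors = FALSE)
  corr <- matrix(NA_real_, nrow(pairs), nrow(bins),
                 dimnames = list(NULL, rownames(bins)))
  n_per_bin <- integer(nrow(bins))
  names(n_per_bin) <- rownames(bins)
  for (b in rownames(bins)) {
    rows <- which(lab == b)
    n_per_bin[b] <- length(rows)
    if (length(rows) < 3) {
      warning("age bin ", b, " has ", length(rows),
              " samples; dropped from the profile")
      next
    }
    if (length(rows) < min_n)
      warning("age bin ", b, " has only ", length(rows), " samples")
    cm <- stats::cor(unclass(residuals)[rows, cpg_ids, drop = FALSE])
    corr[, b] <- cm[ut]
  }
  keep <- !apply(corr, 2, function(col) all(is.na(col)))
  structure(list(pairs = pairs, corr = corr[, keep, drop = FALSE],
                 abs_corr = abs(corr[, keep, drop = FALSE]),
                 n_per_bin = n_per_bin[keep],
                 bin_mids = rowMeans(bins)[keep], cpg_ids = cpg_ids),
            class = "connectivity_profile")
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat("connectivity_profile:", length(x$cpg_ids), "CpGs,",
      nrow(x$pairs), "pairs,", ncol(x$corr), "age bins\n")
  cat("  mean |r| per bin:",
      paste(colnames(x$abs_corr),
            format(colMeans(x$abs_corr), digits = 3), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

#' Paired connectivity shift between two age bins
#'
#' Two-sided Wilcoxon signed-rank test on the per-pair |r| values of the
#' two bins: each CpG pair contributes one paired observation, so the test
#' asks whether connectivity as a whole moved between the age groups.
#'
#' @param profile A `connectivity_profile`.
#' @param bin_a,bin_b Bin labels.
#' @param paired Set FALSE for an unpaired rank-sum variant.
#' @return `htest` object from [stats::wilcox.test()].
#' @export
test_connectivity_shift <- function(profile, bin_a, bin_b, paired = TRUE) {
  a <- profile$abs_corr[, bin_a]
  b <- profile$abs_corr[, bin_b]
  if (all(a == b)) {
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          method = "Wilcoxon signed rank test (degenerate)",
                          alternative = "two.sided",
                          data.name = paste(bin_a, "vs", bin_b)),
                     class = "htest"))
  }
  suppressWarnings(stats::wilcox.test(a, b, paired = paired))
}

#' Linear connectivity trend across age bins
#'
#' Regresses the per-bin mean |r| on the bin midpoints (age in years) and
#' tests the slope. The bin is the unit of evidence: within one bin the
#' pair-level |r| estimates of a co-methylated module move together
#' (they share CpGs and latent factors), so pair-level paired tests
#' overstate evidence for a shift, while this bin-level trend test stays
#' calibrated and still has ample power for real age trends.
#'
#' @param profile A `connectivity_profile` with at least 3 bins.
#' @return List with `slope` (|r| units per year), `se`, `p`.
#' @export
test_connectivity_trend <- function(profile) {
  if (ncol(profile$abs_corr) < 3)
    stop("need at least 3 age bins for a trend test")
  m <- colMeans(profile$abs_corr)
  mids <- profile$bin_mids
  cf <- summary(stats::lm(m ~ mids))$coefficients
  list(slope = cf[2, 1], se = cf[2, 2], p = cf[2, 4])
}

#' Variance of |connectivity| across age bins (Brown-Forsythe Levene test)
#'
#' Median-centred Levene test of whether the dispersion of per-pair |r|
#' differs across age bins.
#'
#' @param profile A `connectivity_profile`.
#' @return List with `statistic`, `p`, `df`.
#' @export
test_connectivity_variance <- function(profile) {
  if (ncol(profile$abs_corr) < 2) stop("need at least 2 age bins")
  vals <- as.vector(profile$abs_corr)
  grp <- factor(rep(colnames(profile$abs_corr),
                    each = nrow(profile$abs_corr)))
  if (stats::sd(vals) == 0)
    return(list(statistic = 0, p = 1, df = c(nlevels(grp) - 1,
                                             length(vals) - nlevels(grp))))
  lt <- car::leveneTest(vals, grp, center = stats::median)
  list(statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]))
}

#' Cluster connectivity trajectories
#'
#' Hierarchical clustering (Ward linkage, Euclidean distance) of each CpG
#' pair's |r|-across-bins vector, cut into `k` clusters. Cluster labels are
#' assigned by ascending mean(last bin - first bin), so "c1" is the
#' flattest and the last cluster the most steeply increasing — matching the
#' flat / modestly increasing / sharply increasing taxonomy.
#'
#' @param profile A `connectivity_profile`.
#' @param k Number of clusters (default 3).
#' @return Integer-free character vector of labels ("c1".."ck") per pair,
#'   plus attribute `slopes` (per-cluster mean last-minus-first change).
#' @export
cluster_trajectories <- function(profile, k = 3) {
  x <- profile$abs_corr
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(x)) stop("k exceeds the number of CpG pairs")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  delta <- x[, ncol(x)] - x[, 1]
  slope <- tapply(delta, raw, mean)
  ord <- order(slope)
  relabel <- match(raw, as.integer(names(slope))[ord])
  out <- paste0("c", relabel)
  attr(out, "slopes") <- stats::setNames(slope[ord], paste0("c", seq_len(k)))
  out
}

#' Hub CpGs by degree centrality in one age bin
#'
#' Builds the within-module graph keeping edges with |r| strictly greater
#' than `edge_threshold` in the chosen bin, computes per-CpG degree, and
#' ranks hubs by degree with summed |r| as the tie-break.
#'
#' @param profile A `connectivity_profile`.
#' @param bin Bin label (default: the last/oldest bin, where connectivity
#'   is strongest).
#' @param edge_threshold Edge cutoff (strictly greater; default 0.4).
#' @param n_hubs Number of top hubs to report (default 5).
#' @return List with `degree` (named per CpG), `strength` (summed |r| over
#'   edges), `hubs` (top ids), `edges` (data frame cpg_a, cpg_b, r).
#' @export
hub_centrality <- function(profile, bin = NULL, edge_threshold = 0.4,
                           n_hubs = 5) {
  if (is.null(bin)) bin <- colnames(profile$abs_corr)[ncol(profile$abs_corr)]
  if (!bin %in% colnames(profile$abs_corr)) stop("unknown bin: ", bin)
  ar <- profile$abs_corr[, bin]
  sel <- ar > edge_threshold
  edges <- cbind(profile$pairs[sel, , drop = FALSE],
                 r = profile$corr[sel, bin])
  degree <- stats::setNames(numeric(length(profile$cpg_ids)),
                            profile$cpg_ids)
  strength <- degree
  for (i in which(sel)) {
    a <- profile$pairs$cpg_a[i]; b <- profile$pairs$cpg_b[i]
    degree[a] <- degree[a] + 1; degree[b] <- degree[b] + 1
    strength[a] <- strength[a] + ar[i]; strength[b] <- strength[b] + ar[i]
  }
  ord <- order(-degree, -strength, names(degree))
  list(degree = degree, strength = strength,
       hubs = names(degree)[ord][seq_len(min(n_hubs, length(degree)))],
       edges = edges)
}

#' Per-CpG radiated connectivity shift between extreme age bins
#'
#' For each CpG, the paired signed-rank test on |r| of all pairs containing
#' that CpG between the youngest and oldest bins, Bonferroni-adjusted over
#' the module's CpGs. Identifies the CpGs whose radiating connections
#' strengthen with age.
#'
#' @param profile A `connectivity_profile`.
#' @param bin_young,bin_old Bin labels (defaults: first and last).
#' @return Data frame (cpg, n_pairs, median_young, median_old, p,
#'   p_bonferroni); CpGs with a single pair get NA p with a warning.
#' @export
per_cpg_radiated_shift <- function(profile, bin_young = NULL,
                                   bin_old = NULL) {
  cols <- colnames(profile$abs_corr)
  if (is.null(bin_young)) bin_young <- cols[1]
  if (is.null(bin_old)) bin_old <- cols[length(cols)]
  rows <- lapply(profile$cpg_ids, function(cg) {
    sel <- profile$pairs$cpg_a == cg | profile$pairs$cpg_b == cg
    a <- profile$abs_corr[sel, bin_young]
    b <- profile$abs_corr[sel, bin_old]
    p <- if (sum(sel) < 2) {
      warning("CpG ", cg, " contributes a single pair; test degenerate")
      NA_real_
    } else suppressWarnings(stats::wilcox.test(a, b,
                                               paired = TRUE)$p.value)
    data.frame(cpg = cg, n_pairs = sum(sel),
               median_young = stats::median(a), median_old = stats::median(b),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * length(profile$cpg_ids), 1)
  out
}

#' Age-stratified association
#'
#' Fits the CpG-outcome (or PC score) regression independently within each
#' age bin; bins below `min_n` samples are skipped with a warning.
#'
#' @param feature Named numeric feature (CpG M values/residuals or PC
#'   score).
#' @param phenotype Named raw phenotype.
#' @param samples A [sample_table()].
#' @param bins Age bin matrix.
#' @param phenotype_class Covariate rule selector (see
#'   [fit_cpg_outcome()]); `"none"` fits feature ~ phenotype only.
#' @param min_n Minimum per-bin sample count (default 30).
#' @return Data frame (bin, n, beta, se, p).
#' @export
age_stratified_association <- function(feature, phenotype, samples,
                                       bins = default_age_bins(),
                                       phenotype_class = "standard",
                                       min_n = 30) {
  lab <- stratify_ages(samples, bins)
  rows <- list()
  for (b in rownames(bins)) {
    ids <- samples$sample_id[!is.na(lab) & lab == b]
    ids <- intersect(ids, names(feature))
    ids <- ids[!is.na(phenotype[ids]) & !is.na(feature[ids])]
    if (length(ids) < min_n) {
      warning("age bin ", b, " has ", length(ids),
              " usable samples; skipped")
      next
    }
    f <- if (phenotype_class == "none") {
      fit <- stats::lm(feature[ids] ~ phenotype[ids])
      cf <- summary(fit)$coefficients
      list(beta = cf[2, 1], se = cf[2, 2], p = cf[2, 4], n = length(ids))
    } else {
      sub <- samples[match(ids, samples$sample_id), , drop = FALSE]
      fit_cpg_outcome(feature[ids], phenotype[ids], sub,
                      phenotype_class = phenotype_class)
    }
    rows[[b]] <- data.frame(bin = b, n = f$n, beta = f$beta, se = f$se,
                            p = f$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Feature-by-age interaction test
#'
#' Regression `phenotype ~ covariates + feature + age + feature:age` with
#' feature and age centred before forming the product, reporting the
#' interaction term. Centring leaves the interaction coefficient invariant
#' under shifts of age.
#'
#' @param feature Named numeric feature values.
#' @param phenotype Named phenotype values.
#' @param samples A [sample_table()].
#' @param covariates Covariate column names (default sex plus cell and
#'   technical columns; age enters explicitly).
#' @return List with `beta`, `se`, `p` for the interaction term and the
#'   full coefficient table.
#' @export
interaction_test <- function(feature, phenotype, samples,
                             covariates = NULL) {
  if (is.null(covariates))
    covariates <- c(grep("^cell_", names(samples), value = TRUE),
                    grep("^tech_", names(samples), value = TRUE), "sex")
  ids <- samples$sample_id
  ids <- ids[!is.na(phenotype[ids]) & !is.na(feature[ids])]
  sub <- samples[match(ids, samples$sample_id), , drop = FALSE]
  X <- covariate_design(sub, covariates)
  fc <- feature[ids] - mean(feature[ids])
  ac <- sub$age - mean(sub$age)
  X <- cbind(X, feature = fc, age = ac, feature_x_age = fc * ac)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear predictors in interaction model: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  fit <- stats::lm.fit(X, phenotype[ids])
  df <- length(ids) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  xtxi <- chol2inv(qr.R(qrX))
  se_all <- sqrt(sigma2 * diag(xtxi))
  names(se_all) <- colnames(X)[qrX$pivot]
  b <- fit$coefficients["feature_x_age"]
  se <- se_all["feature_x_age"]
  list(beta = unname(b), se = unname(se),
       p = 2 * stats::pt(-abs(b / se), df),
       coefficients = fit$coefficients, n = length(ids))
}
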