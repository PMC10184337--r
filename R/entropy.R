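#' Methylation Shannon entropy
#'
#' Per-sample, per-CpG binary Shannon entropy of the beta value:
#' \eqn{E(m) = -m \log_2 m - (1-m) \log_2(1-m)}, in bits, after clipping m
#' into \[epsilon, 1-epsilon\]. Entropy is symmetric about 0.5, where it
#' attains its unique maximum of 1; extreme methylation (m near 0 or 1)
#' carries almost no entropy. Rising entropy with age quantifies epigenetic
#' drift — loss of methylation information.
#'
#' @param mat A `meth_matrix` on the beta scale (or bare numeric values).
#' @param epsilon Clipping constant (default 1e-6).
#' @return Entropy values in \[0,1\], same shape as the input.
#' @export
shannon_entropy <- function(mat, epsilon = 1e-6) {
  if (inherits(mat, "meth_matrix") && meth_scale(mat) != "beta")
    stop("shannon_entropy requires beta-scale values, got scale = ",
         meth_scale(mat))
  m <- pmin(pmax(unclass(mat), epsilon), 1 - epsilon)
  e <- -m * log2(m) - (1 - m) * log2(1 - m)
  if (is.matrix(e)) dimnames(e) <- dimnames(unclass(mat))
  e
}

#' Compare entropy between CpG sets
#'
#' The comparison unit is the per-CpG mean entropy across samples (CpGs as
#' observations). Every pair of sets is compared with a two-sided Wilcoxon
#' rank-sum test, BH-adjusted across comparisons. Overlapping sets are
#' allowed but flagged.
#'
#' @param entropy Entropy matrix (samples x CpGs) from [shannon_entropy()].
#' @param sets Named list of CpG id vectors.
#' @return Data frame (set_a, set_b, mean_a, mean_b, statistic, p, p_bh,
#'   overlapping).
#' @export
compare_entropy_groups <- function(entropy, sets) {
  if (length(sets) < 2) stop("need at least 2 CpG sets")
  if (any(lengths(sets) == 0)) stop("empty CpG set")
  means <- lapply(sets, function(ids) colMeans(entropy[, ids, drop = FALSE]))
  cmb <- utils::combn(names(sets), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    ov <- length(intersect(sets[[a]], sets[[b]])) > 0
    wt <- if (identical(sort(sets[[a]]), sort(sets[[b]])))
      list(statistic = NA_real_, p.value = 1)
    else suppressWarnings(stats::wilcox.test(means[[a]], means[[b]]))
    data.frame(set_a = a, set_b = b,
               mean_a = mean(means[[a]]), mean_b = mean(means[[b]]),
               statistic = unname(wt$statistic[1]), p = wt$p.value,
               overlapping = ov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Entropy drift with age
#'
#' Regresses per-sample mean entropy over a CpG set on age, giving the
#' drift slope in bits/year. With `cpg_set_b` supplied, the slope
#' difference between the two sets is tested via a set-by-age interaction
#' in a stacked regression.
#'
#' @param entropy Entropy matrix (samples x CpGs).
#' @param samples A [sample_table()] with `age`.
#' @param cpg_set CpG ids of the set of interest.
#' @param cpg_set_b Optional second set for a slope contrast.
#' @return List with `slope` (bits/year), `se`, `p`; and, when two sets are
#'   given, `slope_b`, `interaction` (list beta/se/p for the slope
#'   difference, set A minus set B).
#' @export
entropy_age_drift <- function(entropy, samples, cpg_set, cpg_set_b = NULL) {
  age <- samples$age[match(rownames(entropy), samples$sample_id)]
  if (anyNA(age)) stop("age missing for some samples")
  ent_a <- rowMeans(entropy[, cpg_set, drop = FALSE])
  fit <- stats::lm(ent_a ~ age)
  cf <- summary(fit)$coefficients
  out <- list(slope = cf[2, 1], se = cf[2, 2], p = cf[2, 4])
  if (!is.null(cpg_set_b)) {
    ent_b <- rowMeans(entropy[, cpg_set_b, drop = FALSE])
    fb <- summary(stats::lm(ent_b ~ age))$coefficients
    y <- c(ent_a, ent_b)
    grp <- rep(c(1, 0), each = length(age))   # 1 = set A
    aa <- rep(age, 2)
    fi <- summary(stats::lm(y ~ aa * grp))$coefficients
    out$slope_b <- fb[2, 1]
    out$interaction <- list(beta = fi["aa:grp", 1], se = fi["aa:grp", 2],
                            p = fi["aa:grp", 4])
  }
  out
}
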