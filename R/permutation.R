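#' Mean absolute cross-correlation between two CpG sets
#'
#' The connectivity statistic of the clock permutation test: the mean of
#' |Pearson r| over all pairs (a, b) with a in `set_a`, b in `set_b`,
#' excluding self-pairs (a CpG can belong to both sets).
#'
#' @param residuals Matrix (samples x CpGs).
#' @param set_a,set_b CpG id vectors (non-empty, present in the matrix).
#' @return Scalar mean |r|.
#' @export
mean_abs_cross_correlation <- function(residuals, set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) stop("empty CpG set")
  miss <- setdiff(c(set_a, set_b), colnames(residuals))
  if (length(miss) > 0)
    stop("CpG(s) absent from matrix: ", paste(miss, collapse = ", "))
  cc <- abs(stats::cor(unclass(residuals)[, set_a, drop = FALSE],
                       unclass(residuals)[, set_b, drop = FALSE]))
  self <- outer(set_a, set_b, "==")
  n_pairs <- length(cc) - sum(self)
  if (n_pairs == 0)
    stop("no cross pairs left after excluding self-pairs")
  (sum(cc) - sum(cc[self])) / n_pairs
}

#' Circular permutation test of POE-clock connectivity
#'
#' Tests whether a CpG group (e.g. the atypical POE set) is more connected
#' to a fixed clock CpG set than position-matched random sets. All
#' methylome CpGs are ordered by (chromosome, position) into a ring; the
#' group's membership mask is rotated by a uniformly drawn offset in
#' \[1, N-1\] for each permutation, and the CpGs under the rotated mask form
#' the random set. Rotation preserves the mask's run structure exactly —
#' consecutive CpGs stay consecutive — so the random sets keep the true
#' set's internal spatial/correlation structure. The one-sided permutation
#' p is (#\{null >= observed\} + 1) / (n_permutations + 1).
#'
#' @param residuals Matrix (samples x CpGs) covering the whole (synthetic)
#'   methylome.
#' @param annotation A [cpg_annotation()] defining genomic order for every
#'   matrix CpG.
#' @param group_set CpG ids of the POE group.
#' @param clock_set CpG ids of the clock.
#' @param n_permutations Number of rotations (default 10000).
#' @param seed Integer seed for the offsets.
#' @return Object of class `permutation_result`: `observed`, `null_values`,
#'   `p`, `n_permutations`, `seed`.
#' @export
circular_permutation_test <- function(residuals, annotation, group_set,
                                      clock_set, n_permutations = 10000,
                                      seed = 1L) {
  if (n_permutations < 100)
    warning("fewer than 100 permutations; p resolution is coarse")
  ord <- genomic_order(annotation)
  miss <- setdiff(colnames(residuals), ord)
  if (length(miss) > 0)
    stop("annotation lacks genomic order for: ",
         paste(miss, collapse = ", "))
  ord <- ord[ord %in% colnames(residuals)]
  n <- length(ord)
  mask_pos <- match(group_set, ord)
  if (anyNA(mask_pos)) stop("group_set CpG(s) missing from the methylome")

  # |r| between every methylome CpG and the clock set, computed once; a
  # rotated set's statistic is then a sum over precomputed rows, with the
  # unit diagonal of any self-pair removed.
  cc <- abs(stats::cor(unclass(residuals)[, ord, drop = FALSE],
                       unclass(residuals)[, clock_set, drop = FALSE]))
  row_sum <- rowSums(cc)
  is_clock <- stats::setNames(ord %in% clock_set, ord)
  stat_for <- function(pos) {
    ids <- ord[pos]
    selfs <- ids[is_clock[ids]]
    tot <- sum(row_sum[pos]) - sum(cc[cbind(match(selfs, ord),
                                            match(selfs, clock_set))])
    np <- length(pos) * length(clock_set) - length(selfs)
    tot / np
  }
  observed <- stat_for(mask_pos)
  set.seed(seed)
  offsets <- sample.int(n - 1, n_permutations, replace = TRUE)
  null_values <- vapply(offsets, function(off)
    stat_for((mask_pos - 1 + off) %% n + 1), 0)
  p <- (sum(null_values >= observed) + 1) / (n_permutations + 1)
  structure(list(observed = observed, null_values = null_values, p = p,
                 n_permutations = n_permutations, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("circular permutation test:\n")
  cat("  observed mean |r| =", format(x$observed, digits = 4), "\n")
  cat("  null mean (sd)    =", format(mean(x$null_values), digits = 4),
      "(", format(stats::sd(x$null_values), digits = 3), ")\n")
  cat("  one-sided p       =", format(x$p, digits = 4), " (",
      x$n_permutations, "rotations )\n")
  invisible(x)
}
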