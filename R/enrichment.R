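#' Compare POE association signal against the rest of the methylome
#'
#' Two-sided Wilcoxon rank-sum test comparing the -log10 p values of one
#' POE group's CpG-phenotype associations against those of all non-POE
#' CpGs for the same phenotype. Being rank-based, the result is invariant
#' to any monotone transform of the p values; -log10 p is used so a
#' positive location shift means stronger POE associations. The location
#' shift is the Hodges-Lehmann estimate.
#'
#' @param mwas_records Data frame of association records for ONE phenotype
#'   covering the whole methylome (columns `feature_id`, `p`).
#' @param annotation A [cpg_annotation()].
#' @param group `"atypical"` or `"typical"`.
#' @param n_tests Number of (phenotype x group) comparisons in the family,
#'   for Bonferroni adjustment (default 1).
#' @return Data frame row: group, n_group, n_rest, statistic,
#'   location_shift, p, p_bonferroni.
#' @export
compare_poe_vs_rest <- function(mwas_records, annotation,
                                group = c("atypical", "typical"),
                                n_tests = 1) {
  group <- match.arg(group)
  cls <- annotation$poe_class[match(mwas_records$feature_id,
                                    annotation$cpg_id)]
  ok <- !is.na(mwas_records$p)
  in_group <- ok & cls == group
  rest <- ok & cls == "none"
  if (sum(in_group) == 0) stop("no records for group ", group)
  if (sum(in_group) < 10 || sum(rest) < 10)
    warning("fewer than 10 CpGs in a compared set")
  x <- -log10(mwas_records$p[in_group])
  y <- -log10(mwas_records$p[rest])
  wt <- suppressWarnings(stats::wilcox.test(x, y, conf.int = TRUE))
  data.frame(group = group, n_group = sum(in_group), n_rest = sum(rest),
             statistic = unname(wt$statistic),
             location_shift = unname(wt$estimate),
             p = wt$p.value,
             p_bonferroni = min(wt$p.value * n_tests, 1),
             stringsAsFactors = FALSE)
}

#' Correlation-deduplicated association counts
#'
#' Counts associated CpGs per (phenotype, POE group) treating correlated
#' CpGs as one signal: associated CpGs are clustered by single linkage on
#' |Pearson r| >= `r_threshold` and clusters are counted, then the count is
#' normalized by the group's total size in the annotation.
#'
#' @param records High-confidence association records (columns
#'   `feature_id`, `phenotype_id`).
#' @param annotation A [cpg_annotation()].
#' @param residuals Matrix with all associated CpGs (for the correlations).
#' @param r_threshold Dedup threshold (default 0.5).
#' @return Data frame (phenotype_id, group, n_raw, n_dedup,
#'   normalized_count).
#' @export
normalized_association_counts <- function(records, annotation, residuals,
                                          r_threshold = 0.5) {
  if (nrow(records) == 0)
    return(data.frame(phenotype_id = character(0), group = character(0),
                      n_raw = integer(0), n_dedup = integer(0),
                      normalized_count = numeric(0)))
  cls <- annotation$poe_class[match(records$feature_id, annotation$cpg_id)]
  group_sizes <- table(annotation$poe_class)
  rows <- list()
  for (ph in sort(unique(records$phenotype_id))) {
    for (g in c("atypical", "typical")) {
      cpgs <- sort(unique(records$feature_id[records$phenotype_id == ph &
                                               cls == g]))
      if (length(cpgs) == 0) next
      n_dedup <- count_correlation_clusters(residuals, cpgs, r_threshold)
      rows[[length(rows) + 1]] <- data.frame(
        phenotype_id = ph, group = g, n_raw = length(cpgs),
        n_dedup = n_dedup,
        normalized_count = n_dedup / as.numeric(group_sizes[g]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# single-linkage clusters joining CpGs with |r| >= threshold; the count is
# invariant to input order.
count_correlation_clusters <- function(residuals, cpgs, r_threshold) {
  if (length(cpgs) == 1) return(1L)
  absr <- abs(stats::cor(unclass(residuals)[, cpgs, drop = FALSE]))
  hc <- stats::hclust(stats::as.dist(1 - absr), method = "single")
  # heights strictly below 1 - threshold + eps merge; cutree at the
  # threshold keeps |r| >= r_threshold in one cluster
  length(unique(stats::cutree(hc, h = 1 - r_threshold)))
}

#' Functional-region enrichment of associated CpGs
#'
#' Per region class, a 2x2 Fisher exact test of (associated vs not) x
#' (in region vs not) within the background set, BH-adjusted across
#' regions.
#'
#' @param associated CpG ids of the associated set.
#' @param background CpG ids of the background (must contain the associated
#'   set).
#' @param annotation A [cpg_annotation()] with `region_class`.
#' @return Data frame (region, n_assoc_in, n_assoc_out, n_bg_in, n_bg_out,
#'   odds_ratio, p, p_bh). Empty associated set gives zero rows.
#' @export
region_enrichment <- function(associated, background, annotation) {
  if (!all(associated %in% background))
    stop("background must contain the associated set")
  if (length(associated) == 0)
    return(data.frame(region = character(0), odds_ratio = numeric(0),
                      p = numeric(0), p_bh = numeric(0)))
  reg <- stats::setNames(annotation$region_class, annotation$cpg_id)
  regions <- sort(unique(reg[background]))
  rest <- setdiff(background, associated)
  rows <- lapply(regions, function(rc) {
    a_in <- sum(reg[associated] == rc)
    a_out <- length(associated) - a_in
    r_in <- sum(reg[rest] == rc)
    r_out <- length(rest) - r_in
    ft <- stats::fisher.test(matrix(c(a_in, a_out, r_in, r_out), 2,
                                    byrow = TRUE))
    data.frame(region = rc, n_assoc_in = a_in, n_assoc_out = a_out,
               n_bg_in = r_in, n_bg_out = r_out,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
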