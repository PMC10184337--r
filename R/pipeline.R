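#' Read a cohort bundle from disk
#'
#' Reads the TSV formats written by [write_cohort()].
#'
#' @param dir Directory holding `methylation.tsv`, `samples.tsv`,
#'   `annotation.tsv`.
#' @param scale Scale of the stored methylation values.
#' @return A `poe_cohort` (without simulation truth).
#' @export
read_cohort <- function(dir, scale = "beta") {
  meth <- read_methylation_matrix(file.path(dir, "methylation.tsv"), scale)
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  ann <- read_cpg_annotation(file.path(dir, "annotation.tsv"))
  structure(list(meth = meth, samples = samples, annotation = ann,
                 truth = NULL,
                 phenotype_info = default_phenotype_info(samples)),
            class = "poe_cohort")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full POE phenome-wide analysis pipeline
#'
#' Executes every stage in order — adjustment, single-CpG EWAS
#' (discovery/replication/validation), enrichment versus the rest of the
#' methylome, co-methylation module construction/matching and module-PC
#' scans, age-stratified connectivity dynamics, Shannon entropy
#' comparisons and drift, and the clock circular-permutation test — and
#' writes one TSV per stage plus a machine-readable run log. Outputs are a
#' pure function of (inputs, config, seed).
#'
#' @param config A [poe_config()].
#' @param inputs Either a list with `poe_cohort` elements `discovery` and
#'   `replication`, a list of two directory paths (`discovery`,
#'   `replication`) to load with [read_cohort()], or a synthetic spec
#'   `list(n_samples =, n_cpgs =, truth =)` simulated with
#'   [simulate_pair()] under the config seed.
#' @param out_dir Output directory for stage tables and the run log.
#' @return List of class `poe_pipeline_result` with all stage outputs.
#' @export
run_full_pipeline <- function(config = poe_config(), inputs, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "inputs"
  result <- tryCatch(
    run_pipeline_stages(config, inputs, out_dir),
    error = function(e) {
      stop("pipeline failed in stage [", attr(e, "poe_stage") %||%
             "unknown", "]: ", conditionMessage(e), call. = FALSE)
    })
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    attr(e, "poe_stage") <- name
    stop(e)
  })
}

run_pipeline_stages <- function(config, inputs, out_dir) {
  pair <- with_stage("inputs", resolve_inputs(config, inputs))
  disc <- pair$discovery
  repl <- pair$replication

  ewas <- with_stage("ewas",
    discovery_replication_workflow(disc, repl, config))
  write_tsv(ewas$records[, c("feature_id", "phenotype_id", "model",
                             "stage", "beta", "se", "p",
                             "significant_fdr")],
            file.path(out_dir, "ewas_associations.tsv"))
  write_tsv(ewas$high_confidence,
            file.path(out_dir, "ewas_high_confidence.tsv"))

  enr <- with_stage("enrichment",
    enrichment_stage(disc, ewas, config))
  write_tsv(enr$comparison, file.path(out_dir, "enrichment_poe_vs_rest.tsv"))
  write_tsv(enr$counts, file.path(out_dir, "enrichment_counts.tsv"))
  write_tsv(enr$regions, file.path(out_dir, "enrichment_regions.tsv"))

  com <- with_stage("comethylation",
    comethylation_stage(disc, repl, ewas, config))
  write_tsv(com$membership, file.path(out_dir, "module_membership.tsv"))
  write_tsv(com$consistent, file.path(out_dir, "consistent_modules.tsv"))
  write_tsv(com$pc_records, file.path(out_dir, "module_pc_associations.tsv"))

  conn <- with_stage("connectivity",
    connectivity_stage(disc, com, ewas, config))
  write_tsv(conn$profile_table, file.path(out_dir, "connectivity_bins.tsv"))
  write_tsv(conn$tests, file.path(out_dir, "connectivity_tests.tsv"))

  ent <- with_stage("entropy", entropy_stage(disc, config))
  write_tsv(ent$comparisons, file.path(out_dir, "entropy_comparisons.tsv"))
  write_tsv(ent$drift, file.path(out_dir, "entropy_drift.tsv"))

  perm <- with_stage("clock_permutation",
    permutation_stage(disc, ewas, config))
  write_tsv(perm$summary, file.path(out_dir, "clock_permutation.tsv"))

  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("poemeth")),
              config = config_as_list(config),
              n_samples = c(discovery = nrow(disc$meth),
                            replication = nrow(repl$meth)),
              n_cpgs = ncol(disc$meth),
              n_high_confidence = nrow(ewas$high_confidence))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(ewas = ewas, enrichment = enr, comethylation = com,
                 connectivity = conn, entropy = ent, permutation = perm,
                 log = log, out_dir = out_dir),
            class = "poe_pipeline_result")
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$age_bins <- apply(config$age_bins, 1, function(r)
    list(low = r[[1]], high = r[[2]]), simplify = FALSE)
  out
}

resolve_inputs <- function(config, inputs) {
  if (!is.null(inputs$discovery) && inherits(inputs$discovery,
                                             "poe_cohort")) {
    return(inputs)
  }
  if (!is.null(inputs$discovery) && is.character(inputs$discovery)) {
    return(list(discovery = read_cohort(inputs$discovery),
                replication = read_cohort(inputs$replication)))
  }
  if (!is.null(inputs$n_samples)) {
    truth <- inputs$truth %||% simulation_truth()
    return(simulate_pair(inputs$n_samples, inputs$n_cpgs, truth, config,
                         seed = config$seed))
  }
  stop("inputs must supply cohorts, directories, or a synthetic spec")
}

#' @export
print.poe_pipeline_result <- function(x, ...) {
  cat("poe_pipeline_result (outputs in ", x$out_dir, ")\n", sep = "")
  cat("  high-confidence CpG-phenotype pairs:",
      nrow(x$ewas$high_confidence), "\n")
  cat("  consistent modules:", nrow(x$comethylation$consistent), "\n")
  cat("  clock permutation tests:", nrow(x$permutation$summary), "\n")
  invisible(x)
}

# ---- stage helpers ---------------------------------------------------------

enrichment_stage <- function(disc, ewas, config) {
  hc <- ewas$high_confidence
  phenos <- sort(unique(hc$phenotype_id))
  pinfo <- disc$phenotype_info
  prep <- ewas$prepared$discovery
  comparison <- NULL
  if (length(phenos) > 0) {
    n_tests <- length(phenos) * 2
    rows <- list()
    for (ph in phenos) {
      cls <- pinfo$class[match(ph, pinfo$phenotype_id)]
      mwas <- moa_scan(prep$adjusted_phenotypes[[ph]],
                       prep$residuals$set1, prep$orm,
                       phenotype_id = ph)
      for (g in c("atypical", "typical")) {
        r <- compare_poe_vs_rest(mwas, disc$annotation, g, n_tests)
        r$phenotype_id <- ph
        rows[[length(rows) + 1]] <- r
      }
    }
    comparison <- do.call(rbind, rows)
  } else {
    comparison <- data.frame(group = character(0),
                             phenotype_id = character(0),
                             statistic = numeric(0), p = numeric(0))
  }
  counts <- normalized_association_counts(hc, disc$annotation,
                                          prep$residuals$set1,
                                          config$dedup_r_threshold)
  regions <- region_stage(hc, disc$annotation)
  list(comparison = comparison, counts = counts, regions = regions)
}

region_stage <- function(hc, annotation) {
  rows <- list()
  cls <- stats::setNames(annotation$poe_class, annotation$cpg_id)
  for (ph in sort(unique(hc$phenotype_id))) {
    for (g in c("atypical", "typical")) {
      assoc <- unique(hc$feature_id[hc$phenotype_id == ph &
                                      cls[hc$feature_id] == g])
      if (length(assoc) == 0) next
      bg <- annotation$cpg_id[annotation$poe_class == g]
      re <- region_enrichment(assoc, bg, annotation)
      if (nrow(re) == 0) next
      re$phenotype_id <- ph
      re$group <- g
      rows[[length(rows) + 1]] <- re
    }
  }
  if (length(rows) == 0)
    return(data.frame(region = character(0), phenotype_id = character(0)))
  do.call(rbind, rows)
}

comethylation_stage <- function(disc, repl, ewas, config) {
  pinfo <- disc$phenotype_info
  membership <- list()
  consistent <- list()
  pc_records <- list()
  models <- list()
  for (g in c("atypical", "typical")) {
    cpgs <- disc$annotation$cpg_id[disc$annotation$poe_class == g]
    if (length(cpgs) < config$min_module_size) next
    res_d <- ewas$prepared$discovery$residuals$set1[, cpgs, drop = FALSE]
    res_r <- ewas$prepared$replication$residuals$set1[, cpgs, drop = FALSE]
    rd <- recursive_prune_and_power(res_d, disc$annotation, config)
    rr <- recursive_prune_and_power(res_r, repl$annotation, config)
    for (m in rd$modules)
      membership[[length(membership) + 1]] <- data.frame(
        cpg_id = m$cpg_ids, module_id = paste0(g, "_", m$module_id),
        group = g, dataset = "discovery", power = m$power_used,
        stringsAsFactors = FALSE)
    for (m in rr$modules)
      membership[[length(membership) + 1]] <- data.frame(
        cpg_id = m$cpg_ids, module_id = paste0(g, "_", m$module_id),
        group = g, dataset = "replication", power = m$power_used,
        stringsAsFactors = FALSE)
    cm <- match_modules(rd$modules, rr$modules, config)
    for (i in seq_along(cm)) {
      mod <- cm[[i]]
      mod_id <- paste0(g, "_cm", i)
      consistent[[length(consistent) + 1]] <- data.frame(
        consistent_id = mod_id,
        discovery_module_id = paste0(g, "_", mod$discovery_module_id),
        replication_module_id = paste0(g, "_", mod$replication_module_id),
        n_constituent = length(mod$shared_cpg_ids),
        overlap_rate = mod$overlap_rate, match_type = mod$match_type,
        group = g, cpg_ids = paste(sort(mod$shared_cpg_ids),
                                   collapse = ","),
        stringsAsFactors = FALSE)
      models[[mod_id]] <- list(group = g, cpg_ids = mod$shared_cpg_ids)
    }
  }
  # module-PC phenome scan: PCs trained on discovery, projected to both
  phenos <- intersect(phenotype_ids(disc$samples),
                      phenotype_ids(repl$samples))
  disc_recs <- list()
  scores_cache <- list()
  for (mod_id in names(models)) {
    cpg <- models[[mod_id]]$cpg_ids
    if (length(cpg) < 2) next
    for (set in c("set1", "set2", "set3")) {
      res_d <- ewas$prepared$discovery$residuals[[set]]
      res_r <- ewas$prepared$replication$residuals[[set]]
      if (!all(cpg %in% colnames(res_d))) next
      pcm <- fit_module_pca(res_d, cpg,
                            ss_loading_min = config$pc_ss_loading_min,
                            var_explained_min = config$pc_var_explained_min)
      if (length(pcm$retained) == 0) next
      scores_cache[[paste(mod_id, set, "discovery")]] <-
        project_module_pcs(pcm, res_d)
      scores_cache[[paste(mod_id, set, "replication")]] <-
        project_module_pcs(pcm, res_r)
    }
  }
  scan_pcs <- function(stage) {
    prep <- ewas$prepared[[stage]]
    recs <- list()
    for (mod_id in names(models)) {
      for (ph in phenos) {
        cls <- pinfo$class[match(ph, pinfo$phenotype_id)]
        set <- residual_set_for(cls)
        sc <- scores_cache[[paste(mod_id, set, stage)]]
        if (is.null(sc)) next
        recs[[length(recs) + 1]] <- associate_module_pcs(
          sc, prep$adjusted_phenotypes[[ph]],
          feature_prefix = mod_id, phenotype_id = ph, stage = stage)
      }
    }
    if (length(recs) == 0) return(NULL)
    do.call(rbind, recs)
  }
  dr <- scan_pcs("discovery")
  pc_out <- NULL
  if (!is.null(dr)) {
    dr$significant_bonferroni <- dr$p < config$bonferroni_alpha / nrow(dr)
    surv <- dr[dr$significant_bonferroni, c("feature_id", "phenotype_id")]
    rr <- scan_pcs("replication")
    rr <- rr[paste(rr$feature_id, rr$phenotype_id) %in%
               paste(surv$feature_id, surv$phenotype_id), , drop = FALSE]
    if (nrow(rr) > 0)
      rr$significant_bonferroni <- rr$p < config$bonferroni_alpha / nrow(rr)
    pc_out <- rbind(dr, rr)
  }
  list(membership = if (length(membership)) do.call(rbind, membership)
                    else data.frame(),
       consistent = if (length(consistent)) do.call(rbind, consistent)
                    else data.frame(),
       pc_records = pc_out %||% data.frame(),
       models = models)
}

connectivity_stage <- function(disc, com, ewas, config) {
  pinfo <- disc$phenotype_info
  aging_phenos <- pinfo$phenotype_id[pinfo$class == "age_accel"]
  pc <- com$pc_records
  aging_mods <- character(0)
  if (is.data.frame(pc) && nrow(pc) > 0) {
    repl_hits <- pc[pc$stage == "replication" & pc$significant_bonferroni &
                      pc$phenotype_id %in% aging_phenos, , drop = FALSE]
    aging_mods <- unique(sub("_PC[0-9]+$", "", repl_hits$feature_id))
  }
  if (length(aging_mods) == 0) aging_mods <- names(com$models)
  res <- ewas$prepared$discovery$residuals$set3   # age NOT pre-corrected
  prof_rows <- list()
  test_rows <- list()
  for (mod_id in aging_mods) {
    cpg <- com$models[[mod_id]]$cpg_ids
    if (length(cpg) < 3) next
    prof <- module_connectivity_by_age(res[, cpg, drop = FALSE],
                                       cpg, disc$samples, config$age_bins)
    for (b in colnames(prof$abs_corr))
      prof_rows[[length(prof_rows) + 1]] <- data.frame(
        module = mod_id, bin = b, n = prof$n_per_bin[b],
        mean_abs_r = mean(prof$abs_corr[, b]),
        var_abs_r = stats::var(prof$abs_corr[, b]),
        stringsAsFactors = FALSE)
    bins <- colnames(prof$abs_corr)
    sh <- test_connectivity_shift(prof, bins[1], bins[length(bins)])
    tr <- test_connectivity_trend(prof)
    lv <- test_connectivity_variance(prof)
    hubs <- hub_centrality(prof, edge_threshold = config$edge_threshold)
    test_rows[[length(test_rows) + 1]] <- data.frame(
      module = mod_id,
      shift_p = sh$p.value, trend_slope = tr$slope, trend_p = tr$p,
      levene_p = lv$p,
      hubs = paste(hubs$hubs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(profile_table = if (length(prof_rows)) do.call(rbind, prof_rows)
                       else data.frame(),
       tests = if (length(test_rows)) do.call(rbind, test_rows)
               else data.frame(),
       modules_analysed = aging_mods)
}

entropy_stage <- function(disc, config) {
  ent <- shannon_entropy(disc$meth, config$epsilon)
  ann <- disc$annotation
  clock_cols <- clock_names()
  sets <- list(
    atypical = ann$cpg_id[ann$poe_class == "atypical"],
    typical = ann$cpg_id[ann$poe_class == "typical"],
    clock = ann$cpg_id[rowSums(as.matrix(ann[clock_cols])) > 0],
    rest = ann$cpg_id[ann$poe_class == "none" &
                        rowSums(as.matrix(ann[clock_cols])) == 0])
  sets <- sets[lengths(sets) > 0]
  comparisons <- compare_entropy_groups(ent, sets)
  drift_rows <- lapply(names(sets), function(nm) {
    d <- entropy_age_drift(ent, disc$samples, sets[[nm]])
    data.frame(set = nm, slope_bits_per_year = d$slope, se = d$se,
               p = d$p, stringsAsFactors = FALSE)
  })
  drift <- do.call(rbind, drift_rows)
  if (all(c("atypical", "rest") %in% names(sets))) {
    d <- entropy_age_drift(ent, disc$samples, sets$atypical, sets$rest)
    drift$slope_diff_vs_rest <- NA_real_
    drift$slope_diff_p <- NA_real_
    i <- match("atypical", drift$set)
    drift$slope_diff_vs_rest[i] <- d$interaction$beta
    drift$slope_diff_p[i] <- d$interaction$p
  }
  list(comparisons = comparisons, drift = drift, entropy = ent)
}

permutation_stage <- function(disc, ewas, config) {
  ann <- disc$annotation
  res <- ewas$prepared$discovery$residuals$set1
  set.seed(config$seed + 1L)
  seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  rows <- list()
  results <- list()
  i <- 0L
  for (clk in clock_names()) {
    clock_set <- ann$cpg_id[ann[[clk]]]
    if (length(clock_set) == 0) next
    for (g in c("atypical", "typical")) {
      i <- i + 1L
      grp <- ann$cpg_id[ann$poe_class == g]
      pr <- circular_permutation_test(res, ann, grp, clock_set,
                                      config$n_permutations, seeds[i])
      rows[[length(rows) + 1]] <- data.frame(
        clock = clk, group = g, observed = pr$observed,
        null_mean = mean(pr$null_values), p = pr$p,
        n_permutations = pr$n_permutations, stringsAsFactors = FALSE)
      results[[paste(clk, g, sep = "_")]] <- pr
    }
  }
  list(summary = do.call(rbind, rows), results = results)
}
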