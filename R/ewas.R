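#' Build an omic relationship matrix (ORM)
#'
#' The ORM summarizes epigenetic similarity between samples:
#' \eqn{ORM_{jk} = (1/M) \sum_i z_{ij} z_{ik}} where \eqn{z} holds per-probe
#' standardized values (mean 0, SD 1 over samples). It plays the role of a
#' genomic relationship matrix in the mixed-model association fit, absorbing
#' global methylation correlation between samples.
#'
#' @param mat A `meth_matrix` (typically covariate-adjusted residuals).
#' @param probe_ids Optional subset of probes to use (default: all).
#' @return Object of class `poe_orm`: list with `values` (n x n symmetric
#'   matrix), `sample_ids`, `n_probes_used`.
#' @export
build_orm <- function(mat, probe_ids = NULL) {
  v <- unclass(mat)
  if (!is.null(probe_ids)) v <- v[, probe_ids, drop = FALSE]
  if (ncol(v) < 2) stop("need at least 2 probes to build an ORM")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance probe(s) excluded from ORM")
    v <- v[, sds > 0, drop = FALSE]
  }
  # population-SD standardization, so each probe contributes mean square 1
  # and the ORM diagonal averages exactly 1
  z <- scale(v, center = TRUE, scale = FALSE)
  z <- sweep(z, 2, sqrt(colMeans(z^2)), "/")
  orm <- tcrossprod(z) / ncol(z)
  dimnames(orm) <- list(rownames(v), rownames(v))
  structure(list(values = orm, sample_ids = rownames(v),
                 n_probes_used = ncol(z)),
            class = "poe_orm")
}

#' @export
print.poe_orm <- function(x, ...) {
  cat("poe_orm:", length(x$sample_ids), "samples, built from",
      x$n_probes_used, "probes; mean diagonal =",
      format(mean(diag(x$values)), digits = 4), "\n")
  invisible(x)
}

#' Eigendecompose an ORM for repeated mixed-model fits
#'
#' The REML fit rotates the model into the ORM eigenbasis once; reuse this
#' object across probes and phenotypes sharing the same sample set.
#'
#' @param orm A `poe_orm`.
#' @param sample_ids Optional subset of samples.
#' @return Object of class `poe_orm_eigen` with `U` (eigenvectors), `d`
#'   (eigenvalues, clipped at 0), `sample_ids`.
#' @export
orm_eigen <- function(orm, sample_ids = NULL) {
  v <- orm$values
  if (!is.null(sample_ids)) v <- v[sample_ids, sample_ids, drop = FALSE]
  e <- eigen(v, symmetric = TRUE)
  structure(list(U = e$vectors, d = pmax(e$values, 0),
                 sample_ids = rownames(v)),
            class = "poe_orm_eigen")
}

# Restricted log-likelihood (up to a constant) of the rotated model
# y ~ N(Xb, sigma2 * (ratio * D + I)), profiled over b and sigma2.
reml_ll <- function(ratio, yt, Xt, d, np) {
  v <- ratio * d + 1
  sv <- sqrt(v)
  Xw <- Xt / sv
  yw <- yt / sv
  xtx <- crossprod(Xw)
  R <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  b <- backsolve(R, forwardsolve(t(R), crossprod(Xw, yw)))
  rss <- sum((yw - Xw %*% b)^2)
  if (rss <= 0) return(Inf)
  -0.5 * (np * log(rss / np) + sum(log(v)) + 2 * sum(log(diag(R))))
}

moa_solve <- function(ratio, yt, Xt, d, np) {
  v <- ratio * d + 1
  sv <- sqrt(v)
  Xw <- Xt / sv
  yw <- yt / sv
  xtx <- crossprod(Xw)
  xtxi <- solve(xtx)
  b <- xtxi %*% crossprod(Xw, yw)
  rss <- sum((yw - Xw %*% b)^2)
  sigma2e <- rss / np
  se <- sqrt(sigma2e * diag(xtxi))
  list(b = drop(b), se = se, sigma2e = sigma2e)
}

#' Mixed-model omic association fit for a single probe
#'
#' Fits \eqn{y = w b_m + g + e} with \eqn{cov(g) = \sigma^2_g \cdot ORM} and
#' \eqn{cov(e) = \sigma^2_e I}: the target CpG enters as a fixed effect and
#' the ORM as a random effect absorbing global epigenetic structure. The
#' variance ratio \eqn{\sigma^2_g/\sigma^2_e} is estimated by REML through a
#' one-time eigendecomposition of the ORM and a bracketed scalar search on
#' the log scale over \[1e-6, 1e6\]; the zero-ratio boundary is evaluated
#' exactly, where the fit reduces to ordinary least squares. The fixed
#' effect is tested with a Wald z statistic.
#'
#' @param y Named numeric phenotype (pre-adjusted; NAs dropped).
#' @param probe Named numeric CpG values (pre-adjusted residuals).
#' @param orm A `poe_orm` or `poe_orm_eigen` covering the samples.
#' @param ratio Optional fixed variance ratio (skips REML; `0` gives the
#'   exact OLS limit).
#' @param min_overlap Minimum sample overlap (default 50).
#' @return Object of class `moa_fit`: list with `beta`, `se`, `p`,
#'   `variance_ratio`, `sigma2_g`, `sigma2_e`, `n`, `converged`.
#' @export
fit_moa <- function(y, probe, orm, ratio = NULL, min_overlap = 50) {
  ids <- intersect(names(y)[!is.na(y)], names(probe)[!is.na(probe)])
  ids <- intersect(ids, orm_sample_ids(orm))
  if (length(ids) < min_overlap)
    stop("sample overlap between phenotype, probe and ORM is ",
         length(ids), " (< ", min_overlap, ")")
  eg <- if (inherits(orm, "poe_orm_eigen")) {
    if (!setequal(ids, eg_ids <- orm$sample_ids))
      stop("precomputed ORM eigendecomposition does not match the ",
           "phenotype/probe sample overlap; pass the `poe_orm` or rebuild ",
           "with orm_eigen(orm, sample_ids)")
    orm
  } else orm_eigen(orm, ids)
  ids <- eg$sample_ids
  yt <- crossprod(eg$U, y[ids])
  Xt <- crossprod(eg$U, cbind(1, probe[ids]))
  moa_fit_rotated(yt, Xt, eg$d, ratio = ratio)
}

orm_sample_ids <- function(orm) orm$sample_ids

# Core fit on the rotated scale (shared by fit_moa and moa_scan).
moa_fit_rotated <- function(yt, Xt, d, ratio = NULL) {
  n <- length(yt)
  np <- n - ncol(Xt)
  converged <- TRUE
  if (is.null(ratio)) {
    opt <- stats::optimize(function(lr) reml_ll(10^lr, yt, Xt, d, np),
                           lower = -6, upper = 6, maximum = TRUE,
                           tol = 1e-9)
    ll0 <- reml_ll(0, yt, Xt, d, np)
    if (!is.finite(opt$objective) && !is.finite(ll0)) {
      return(structure(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                            variance_ratio = NA_real_, sigma2_g = NA_real_,
                            sigma2_e = NA_real_, n = n, converged = FALSE),
                       class = "moa_fit"))
    }
    ratio <- if (ll0 >= opt$objective) 0 else 10^opt$maximum
  }
  sol <- moa_solve(ratio, yt, Xt, d, np)
  beta <- sol$b[2]
  se <- sol$se[2]
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(beta = beta, se = se, p = p, variance_ratio = ratio,
                 sigma2_g = ratio * sol$sigma2e, sigma2_e = sol$sigma2e,
                 n = n, converged = converged),
            class = "moa_fit")
}

#' @export
print.moa_fit <- function(x, ...) {
  cat("MOA fit (n =", x$n, ")\n")
  cat("  beta =", format(x$beta, digits = 5),
      " se =", format(x$se, digits = 5),
      " p =", format(x$p, digits = 4), "\n")
  cat("  variance ratio (sigma2_g / sigma2_e) =",
      format(x$variance_ratio, digits = 5), "\n")
  invisible(x)
}

#' @export
coef.moa_fit <- function(object, ...) c(beta = object$beta)

#' MOA scan of many probes against one phenotype
#'
#' Eigendecomposes the ORM once on the phenotype's complete samples and fits
#' every probe.
#'
#' @param y Named phenotype vector (NAs dropped).
#' @param probes `meth_matrix` of residuals (samples x CpGs).
#' @param orm A `poe_orm`.
#' @param probe_ids Probes to test (default: all columns).
#' @param phenotype_id,stage Tags copied into the output.
#' @return Data frame of association records (one row per probe) with
#'   columns feature_id, phenotype_id, model, stage, beta, se, p, n,
#'   variance_ratio.
#' @export
moa_scan <- function(y, probes, orm, probe_ids = colnames(probes),
                     phenotype_id = "y", stage = "discovery") {
  ids <- intersect(names(y)[!is.na(y)],
                   intersect(rownames(probes), orm_sample_ids(orm)))
  eg <- orm_eigen(orm, ids)
  yt <- crossprod(eg$U, y[eg$sample_ids])
  P <- unclass(probes)[eg$sample_ids, probe_ids, drop = FALSE]
  Pt <- crossprod(eg$U, P)
  ones <- crossprod(eg$U, rep(1, length(ids)))
  out <- lapply(seq_along(probe_ids), function(j) {
    f <- moa_fit_rotated(yt, cbind(ones, Pt[, j]), eg$d)
    data.frame(feature_id = probe_ids[j], phenotype_id = phenotype_id,
               model = "moa", stage = stage, beta = f$beta, se = f$se,
               p = f$p, n = f$n, variance_ratio = f$variance_ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fixed-effect CpG-outcome model
#'
#' The validation model: methylation of the target CpG as the dependent
#' variable, the raw phenotype as the predictor of interest, with the
#' methylation-related covariates fitted jointly. Covariate rules follow the
#' protocol: age and age-squared are dropped for age-acceleration
#' phenotypes; smoking variables are dropped when smoking status is the
#' target. The phenotype coefficient is tested against a t reference with
#' residual degrees of freedom.
#'
#' @param y_m Named CpG values (M scale or technical residuals).
#' @param phenotype Named raw phenotype values (NAs dropped).
#' @param samples A [sample_table()].
#' @param phenotype_class One of "standard", "age_accel", "smoking".
#' @param extra Optional named list/data.frame of extra covariate columns
#'   (used by [conditional_association()]).
#' @return List of class `cpg_outcome_fit` with `beta`, `se`, `p`, `n`, plus
#'   the phenotype/feature tags if supplied.
#' @export
fit_cpg_outcome <- function(y_m, phenotype, samples,
                            phenotype_class = "standard", extra = NULL) {
  cov_names <- switch(phenotype_class,
                      standard = covariate_set("set1", samples)$included,
                      age_accel = covariate_set("set3", samples)$included,
                      smoking = covariate_set("set2", samples)$included,
                      stop("unknown phenotype_class: ", phenotype_class))
  samples <- samples[match(names(y_m), samples$sample_id), , drop = FALSE]
  X <- covariate_design(samples, cov_names)
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    X <- cbind(X, as.matrix(extra))
  }
  keep <- !is.na(phenotype[names(y_m)]) & stats::complete.cases(X)
  X <- cbind(X, phenotype = phenotype[names(y_m)])[keep, , drop = FALSE]
  yv <- y_m[keep]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear predictor(s) in CpG-outcome model: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, yv)
  df <- length(yv) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  xtxi <- chol2inv(qr.R(qrX))
  se_all <- sqrt(sigma2 * diag(xtxi))
  names(se_all) <- colnames(X)[qrX$pivot]
  b <- fit$coefficients["phenotype"]
  se <- se_all["phenotype"]
  p <- 2 * stats::pt(-abs(b / se), df)
  structure(list(beta = unname(b), se = unname(se), p = unname(p),
                 n = length(yv), df = df),
            class = "cpg_outcome_fit")
}

#' Benjamini-Hochberg FDR flags
#'
#' Standard step-up rule at level `q`. Flags are monotone in p: whenever a
#' larger p value is rejected, every smaller one is too.
#'
#' @param pvals Numeric p values in (0, 1\].
#' @param q FDR level.
#' @return List with `flags` (logical, aligned with input), `threshold`
#'   (largest rejected p, or NA if none).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p values must lie in (0, 1] with no missing values")
  flags <- stats::p.adjust(pvals, method = "BH") <= q
  list(flags = flags,
       threshold = if (any(flags)) max(pvals[flags]) else NA_real_)
}

#' Discovery/replication/validation association workflow
#'
#' Stage 1 runs the MOA model over every POE-CpG x phenotype pair in the
#' discovery cohort and keeps FDR survivors; stage 2 re-tests the survivors
#' in the replication cohort with FDR over that restricted set; stage 3
#' validates stage-2 survivors with the CpG-outcome model in both cohorts
#' (FDR within each). Pairs passing all filters are the high-confidence
#' associations.
#'
#' @param discovery,replication `poe_cohort` bundles (or equivalent lists
#'   with `meth`, `samples`, `annotation`, `phenotype_info`).
#' @param config A [poe_config()].
#' @param phenotypes Phenotype ids to scan (default: all shared).
#' @param poe_cpgs CpG ids to test (default: all POE-annotated CpGs).
#' @return List of class `poe_ewas` with `records` (all stages bound
#'   together, with `significant_fdr` flags), `high_confidence` (subset),
#'   `n_tests` per stage, and the per-cohort prepared inputs (invisibly
#'   reused by downstream stages).
#' @export
discovery_replication_workflow <- function(discovery, replication,
                                           config = poe_config(),
                                           phenotypes = NULL,
                                           poe_cpgs = NULL) {
  pinfo <- discovery$phenotype_info
  if (is.null(phenotypes))
    phenotypes <- intersect(phenotype_ids(discovery$samples),
                            phenotype_ids(replication$samples))
  if (is.null(poe_cpgs))
    poe_cpgs <- discovery$annotation$cpg_id[
      discovery$annotation$poe_class != "none"]

  prep <- lapply(list(discovery = discovery, replication = replication),
                 prepare_cohort, config = config)

  scan_stage <- function(stage, pairs) {
    ph_list <- split(pairs, pairs$phenotype_id)
    recs <- lapply(names(ph_list), function(ph) {
      cls <- pinfo$class[match(ph, pinfo$phenotype_id)]
      pc <- prep[[stage]]
      moa_scan(pc$adjusted_phenotypes[[ph]],
               pc$residuals[[residual_set_for(cls)]],
               pc$orm, probe_ids = ph_list[[ph]]$feature_id,
               phenotype_id = ph, stage = stage)
    })
    do.call(rbind, recs)
  }

  all_pairs <- expand.grid(feature_id = poe_cpgs, phenotype_id = phenotypes,
                           stringsAsFactors = FALSE)
  disc <- scan_stage("discovery", all_pairs)
  ok <- !is.na(disc$p)
  disc$significant_fdr <- FALSE
  disc$significant_fdr[ok] <- bh_fdr(disc$p[ok], config$fdr_q)$flags
  s1 <- disc[disc$significant_fdr, c("feature_id", "phenotype_id")]

  if (nrow(s1) > 0) {
    repl <- scan_stage("replication", s1)
    ok <- !is.na(repl$p)
    repl$significant_fdr <- FALSE
    repl$significant_fdr[ok] <- bh_fdr(repl$p[ok], config$fdr_q)$flags
    s2 <- repl[repl$significant_fdr, c("feature_id", "phenotype_id")]
  } else {
    repl <- disc[0, ]
    s2 <- s1
  }

  outcome_stage <- function(stage, pairs) {
    if (nrow(pairs) == 0) return(NULL)
    pc <- prep[[stage]]
    cohort <- if (stage == "discovery") discovery else replication
    out <- lapply(seq_len(nrow(pairs)), function(i) {
      ph <- pairs$phenotype_id[i]
      cls <- pinfo$class[match(ph, pinfo$phenotype_id)]
      ym <- unclass(pc$m_values)[, pairs$feature_id[i]]
      f <- fit_cpg_outcome(ym, pc$raw_phenotypes[[ph]], cohort$samples,
                           phenotype_class = cls)
      data.frame(feature_id = pairs$feature_id[i], phenotype_id = ph,
                 model = "cpg_outcome", stage = stage, beta = f$beta,
                 se = f$se, p = f$p, n = f$n, variance_ratio = NA_real_,
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, out)
    recs$significant_fdr <- bh_fdr(recs$p, config$fdr_q)$flags
    recs
  }
  oc_disc <- outcome_stage("discovery", s2)
  oc_repl <- outcome_stage("replication", s2)

  hc <- s2
  if (nrow(hc) > 0 && !is.null(oc_disc)) {
    key <- function(d) paste(d$feature_id, d$phenotype_id)
    pass <- key(oc_disc)[oc_disc$significant_fdr]
    pass <- intersect(pass, key(oc_repl)[oc_repl$significant_fdr])
    hc <- s2[key(s2) %in% pass, , drop = FALSE]
  }
  records <- rbind(disc, repl, oc_disc, oc_repl)
  structure(list(records = records, high_confidence = hc,
                 n_tests = c(discovery = nrow(disc),
                             replication = nrow(repl),
                             outcome = if (is.null(oc_disc)) 0L
                                       else nrow(oc_disc)),
                 prepared = prep),
            class = "poe_ewas")
}

#' @export
print.poe_ewas <- function(x, ...) {
  cat("poe_ewas workflow:\n")
  cat("  discovery tests:      ", x$n_tests["discovery"], "\n")
  cat("  replicated survivors: ", x$n_tests["replication"], "\n")
  cat("  high-confidence pairs:", nrow(x$high_confidence), "\n")
  invisible(x)
}

residual_set_for <- function(phenotype_class) {
  switch(phenotype_class,
         age_accel = "set3", smoking = "set2", "set1")
}

# Shared per-cohort preparation: M values, the three residual regimes on
# POE CpGs (set1 on all CpGs, for the ORM and methylome-wide scans),
# the ORM, and adjusted/raw phenotypes.
prepare_cohort <- function(cohort, config = poe_config()) {
  m <- beta_to_m(cohort$meth, config$epsilon)
  poe <- cohort$annotation$cpg_id[cohort$annotation$poe_class != "none"]
  res1 <- residualize_methylation(m, cohort$samples, "set1")
  res <- list(set1 = res1,
              set2 = residualize_methylation(m[, poe], cohort$samples,
                                             "set2"),
              set3 = residualize_methylation(m[, poe], cohort$samples,
                                             "set3"))
  orm <- build_orm(res1)
  raw <- list()
  adj <- list()
  for (ph in phenotype_ids(cohort$samples)) {
    v <- cohort$samples[[paste0("pheno_", ph)]]
    names(v) <- cohort$samples$sample_id
    raw[[ph]] <- v
    adj[[ph]] <- prepare_phenotype(v, cohort$samples,
                                   skew_threshold = config$skew_threshold)$values
  }
  list(m_values = m, residuals = res, orm = orm,
       raw_phenotypes = raw, adjusted_phenotypes = adj)
}

#' Conditional association refit
#'
#' Refits the CpG-outcome model with an extra covariate (e.g., a putative
#' mediator such as maternal smoking behind a parental-smoking signal) and
#' reports the updated phenotype effect.
#'
#' @inheritParams fit_cpg_outcome
#' @param extra_covariate Named numeric vector (aligned by sample id).
#' @return A `cpg_outcome_fit` tagged `conditional`.
#' @export
conditional_association <- function(y_m, phenotype, samples,
                                    phenotype_class = "standard",
                                    extra_covariate) {
  if (is.null(names(extra_covariate)))
    stop("extra_covariate must be named by sample id")
  f <- fit_cpg_outcome(y_m, phenotype, samples, phenotype_class,
                       extra = data.frame(
                         conditional = extra_covariate[names(y_m)]))
  f$conditional <- TRUE
  f
}
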