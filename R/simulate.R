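#' Ground-truth specification for the synthetic cohort generator
#'
#' Defines the statistical structure planted in simulated cohorts: blocks of
#' co-methylated CpGs (optionally with within-block correlation rising with
#' age), CpG-phenotype effects of known variance explained, per-class
#' baseline methylation dispersion (which sets Shannon entropy differences
#' between POE classes), per-class epigenetic drift rates, and the latent
#' coupling between epigenetic-clock CpGs and the atypical POE factor.
#'
#' The defaults are the generator's study conditions: two atypical modules
#' (one whose within-module correlation rises from 0.15 at age 18 towards
#' 0.30 at age 94, one densely correlated at 0.6) and one typical module at
#' 0.6; planted CpG effects explaining 2.5% of phenotype variance; atypical
#' CpGs centred near beta 0.5 (high entropy) versus typical CpGs near the
#' extremes (low entropy); atypical baselines drifting towards 0.5 fastest
#' with age; clock/atypical factor correlation 0.5.
#'
#' @param modules Data frame with columns `module`, `group`
#'   (atypical/typical), `size`, `base_correlation`, `age_slope`
#'   (correlation units per year of age above 18).
#' @param effects Data frame with columns `phenotype`, `n_cpgs`, `group`,
#'   `variance_explained`: each phenotype row plants `n_cpgs` mutually
#'   correlated CpGs sharing a latent with the phenotype.
#' @param module_effects Data frame `module`, `phenotype`,
#'   `variance_explained`: phenotype variance driven by a module's shared
#'   factor.
#' @param n_atypical,n_typical Number of POE CpGs per class.
#' @param n_clock_cpgs Clock CpGs per clock (four clocks), drawn from the
#'   non-POE methylome.
#' @param n_clock_overlap Atypical POE CpGs additionally labelled as members
#'   of each clock (CpGs can belong to both a POE class and a clock).
#' @param clock_coupling Correlation between the clock latent factor and the
#'   atypical-POE latent factor.
#' @param factor_share Variance share of the global atypical / clock latent
#'   factors in their member CpGs.
#' @param baseline_logit Named list of functions drawing per-CpG baseline
#'   logits for classes `atypical`, `typical`, `none`, `clock`.
#' @param drift_per_year Named vector: fractional shrinkage of the baseline
#'   logit towards 0 per year of age (epigenetic drift towards beta 0.5).
#' @param sigma_logit Latent-signal standard deviation on the logit scale.
#' @param cov_effect_sd,cov_effect_prob Standard deviation of covariate
#'   coefficients on unstructured CpGs and the fraction of such CpGs hit per
#'   covariate; set `cov_effect_sd = 0` for a covariate-free null.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(
    modules = data.frame(
      module = c("atyp_aging", "atyp_dense", "typ_1"),
      group = c("atypical", "atypical", "typical"),
      size = c(20L, 20L, 20L),
      base_correlation = c(0.15, 0.60, 0.60),
      age_slope = c((0.30 - 0.15) / (94 - 18), 0, 0),
      stringsAsFactors = FALSE),
    effects = data.frame(
      phenotype = c("dnamtl_accel", "intelligence", "maternal_smoking"),
      n_cpgs = c(3L, 2L, 2L),
      group = c("atypical", "atypical", "atypical"),
      variance_explained = c(0.025, 0.025, 0.025),
      stringsAsFactors = FALSE),
    module_effects = data.frame(
      module = c("atyp_aging", "atyp_aging"),
      phenotype = c("dnamtl_accel", "phenoage_accel"),
      variance_explained = c(0.06, 0.04),
      stringsAsFactors = FALSE),
    n_atypical = 70L,
    n_typical = 88L,
    n_clock_cpgs = 23L,
    n_clock_overlap = 2L,
    clock_coupling = 0.5,
    factor_share = 0.3,
    baseline_logit = NULL,
    drift_per_year = c(atypical = 0.006, typical = 0.001, none = 0.0015),
    sigma_logit = 0.5,
    cov_effect_sd = 0.25,
    cov_effect_prob = 0.3) {
  if (is.null(baseline_logit)) {
    # atypical: intermediate methylation (high entropy, room to drift);
    # typical: near-extreme (imprinted-like, low entropy); bulk methylome:
    # mostly extreme with an intermediate minority; clock CpGs in between.
    baseline_logit <- list(
      atypical = function(n) sample(c(-1, 1), n, replace = TRUE) *
        stats::rnorm(n, 1.2, 0.35),
      typical = function(n) sample(c(-1, 1), n, replace = TRUE) *
        stats::rnorm(n, 2.2, 0.4),
      none = function(n) {
        extreme <- stats::runif(n) < 0.7
        ifelse(extreme,
               sample(c(-1, 1), n, replace = TRUE) * stats::rnorm(n, 2.5, 0.5),
               stats::rnorm(n, 0, 1))
      },
      clock = function(n) sample(c(-1, 1), n, replace = TRUE) *
        stats::rnorm(n, 1.5, 0.4))
  }
  if (any(modules$base_correlation > 0.95))
    stop("infeasible base correlation target (> 0.95)")
  if (any(modules$base_correlation < 0)) stop("negative correlation target")
  if (any(effects$variance_explained <= 0 | effects$variance_explained >= 1))
    stop("variance_explained must lie in (0,1)")
  stopifnot(clock_coupling >= -1, clock_coupling <= 1,
            factor_share > 0, factor_share < 1)
  structure(list(modules = modules, effects = effects,
                 module_effects = module_effects,
                 n_atypical = as.integer(n_atypical),
                 n_typical = as.integer(n_typical),
                 n_clock_cpgs = as.integer(n_clock_cpgs),
                 n_clock_overlap = as.integer(n_clock_overlap),
                 clock_coupling = clock_coupling,
                 factor_share = factor_share,
                 baseline_logit = baseline_logit,
                 drift_per_year = drift_per_year,
                 sigma_logit = sigma_logit,
                 cov_effect_sd = cov_effect_sd,
                 cov_effect_prob = cov_effect_prob),
            class = "simulation_truth")
}

clock_names <- function() c("horvath", "hannum", "phenoage", "dnamtl")

# Assign CpG ids to classes, modules, planted effects, clocks and genomic
# coordinates. Done once per cohort pair so discovery and replication share
# identical annotation and planted structure.
assign_truth <- function(n_cpgs, truth) {
  need <- truth$n_atypical + truth$n_typical +
    4L * truth$n_clock_cpgs
  if (n_cpgs < need + 10L)
    stop("n_cpgs = ", n_cpgs, " too small for planted structure (need >= ",
         need + 10L, ")")
  msz <- sum(truth$modules$size)
  n_eff <- sum(truth$effects$n_cpgs)
  if (truth$n_atypical + truth$n_typical < msz + n_eff)
    stop("POE group sizes too small for planted modules and effects")

  cpg_id <- sprintf("cg%07d", sample.int(9999999L, n_cpgs))
  chromosome <- paste0("chr", sample.int(22L, n_cpgs, replace = TRUE))
  position <- integer(n_cpgs)
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    position[idx] <- sort(sample.int(2e7L, length(idx)))
  }
  poe_class <- rep("none", n_cpgs)
  pool <- sample.int(n_cpgs)                 # random genomic placement
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  atypical <- take(truth$n_atypical)
  typical <- take(truth$n_typical)
  poe_class[atypical] <- "atypical"
  poe_class[typical] <- "typical"

  # modules and planted-effect CpGs are disjoint subsets of their group
  grp_pool <- list(atypical = atypical, typical = typical)
  take_grp <- function(g, k) {
    out <- grp_pool[[g]][seq_len(k)]
    grp_pool[[g]] <<- grp_pool[[g]][-seq_len(k)]
    out
  }
  module_cpgs <- list()
  for (i in seq_len(nrow(truth$modules)))
    module_cpgs[[truth$modules$module[i]]] <-
      take_grp(truth$modules$group[i], truth$modules$size[i])
  effect_cpgs <- list()
  for (i in seq_len(nrow(truth$effects)))
    effect_cpgs[[truth$effects$phenotype[i]]] <-
      take_grp(truth$effects$group[i], truth$effects$n_cpgs[i])

  clock_sets <- list()
  clock_mat <- matrix(FALSE, n_cpgs, 4,
                      dimnames = list(NULL, clock_names()))
  # remaining atypical CpGs load the global atypical factor; a few of them
  # are also clock members (POE/clock overlap)
  global_atypical <- grp_pool$atypical
  for (clk in clock_names()) {
    own <- take(truth$n_clock_cpgs)
    ovl <- global_atypical[sample.int(length(global_atypical),
                                      truth$n_clock_overlap)]
    clock_mat[c(own, ovl), clk] <- TRUE
    clock_sets[[clk]] <- c(own, ovl)
  }
  ann <- cpg_annotation(data.frame(
    cpg_id = cpg_id, chromosome = chromosome, position = position,
    poe_class = poe_class,
    region_class = sample(c("island", "shore", "shelf", "open_sea"),
                          n_cpgs, replace = TRUE,
                          prob = c(0.30, 0.25, 0.10, 0.35)),
    clock_mat, stringsAsFactors = FALSE))
  list(annotation = ann,
       module_cpgs = lapply(module_cpgs, function(i) cpg_id[i]),
       effect_cpgs = lapply(effect_cpgs, function(i) cpg_id[i]),
       clock_sets = lapply(clock_sets, function(i) cpg_id[i]),
       global_atypical = cpg_id[global_atypical],
       clock_only = lapply(clock_sets, function(i)
         cpg_id[setdiff(i, global_atypical)]))
}

# Draw covariates and phenotypes for one cohort. Latent phenotype factors
# (shared with planted CpGs / module factors) are returned for reuse in the
# methylation draw.
draw_samples <- function(n, truth, config, batch_tag) {
  bins <- config$age_bins
  widths <- bins[, 2] - bins[, 1]
  bin_of <- sample.int(nrow(bins), n, replace = TRUE,
                       prob = widths / sum(widths))
  age <- bins[bin_of, 1] + stats::runif(n) * widths[bin_of]
  sex <- stats::rbinom(n, 1, 0.5)
  # blood cell mixture (B, NK, monocytes, granulocytes, CD4T, CD8T)
  alpha <- c(cell_b = 5, cell_nk = 4, cell_mono = 8, cell_gran = 55,
             cell_cd4t = 18, cell_cd8t = 10)
  cells <- sapply(alpha, function(a) stats::rgamma(n, shape = a))
  cells <- cells / rowSums(cells)
  tech1 <- stats::rnorm(n)
  tech2 <- stats::rnorm(n)
  agestd <- as.numeric(scale(age))

  smk_latent <- 0.25 * agestd + stats::rnorm(n)
  smoking_status <- as.integer(cut(smk_latent,
                                   stats::quantile(smk_latent,
                                                   c(0, 0.5, 0.75, 1)),
                                   include.lowest = TRUE)) - 1L
  pack_years <- ifelse(smoking_status > 0,
                       stats::rexp(n, 1 / 8) * smoking_status, 0)

  # one latent per phenotype carrying planted effects; module factors drawn
  # here so phenotypes can load them
  factors <- list()
  for (m in truth$modules$module) factors[[m]] <- stats::rnorm(n)
  f_atypical <- stats::rnorm(n)
  # one latent per clock, each correlated clock_coupling with the atypical
  # factor; clocks are related to each other only through that factor
  f_clock <- lapply(stats::setNames(nm = clock_names()), function(clk)
    truth$clock_coupling * f_atypical +
      sqrt(1 - truth$clock_coupling^2) * stats::rnorm(n))
  eff_latent <- list()
  for (ph in truth$effects$phenotype) eff_latent[[ph]] <- stats::rnorm(n)

  pheno_part <- function(ph) {
    v <- numeric(n)
    used <- 0
    i <- match(ph, truth$effects$phenotype)
    if (!is.na(i)) {
      s <- sqrt(truth$effects$variance_explained[i])
      v <- v + sqrt(s) * eff_latent[[ph]]
      used <- used + s
    }
    me <- truth$module_effects[truth$module_effects$phenotype == ph, ,
                               drop = FALSE]
    for (j in seq_len(nrow(me))) {
      v <- v + sqrt(me$variance_explained[j]) * factors[[me$module[j]]]
      used <- used + me$variance_explained[j]
    }
    list(v = v, used = used)
  }
  mk_pheno <- function(ph, cov_part, cov_share) {
    p <- pheno_part(ph)
    resid_share <- 1 - cov_share - p$used
    if (resid_share <= 0) stop("phenotype variance budget exceeded for ", ph)
    cov_part + p$v + sqrt(resid_share) * stats::rnorm(n)
  }

  pheno <- data.frame(
    pheno_dnamtl_accel = mk_pheno("dnamtl_accel", 0, 0),
    pheno_phenoage_accel = mk_pheno("phenoage_accel", 0, 0),
    pheno_smoking_status = as.numeric(smoking_status),
    pheno_intelligence = mk_pheno("intelligence", -0.3 * agestd, 0.09),
    pheno_maternal_smoking = mk_pheno("maternal_smoking",
                                      0.15 * smk_latent, 0.15^2 * 2),
    pheno_bmi = NA_real_)
  # BMI: positively skewed on the natural scale (log-normal shape)
  pheno$pheno_bmi <- exp(stats::rnorm(n, 0, 0.35) + 0.10 * agestd) * 9 + 16
  # sprinkle missing phenotype values (never in methylation)
  for (ph in c("pheno_intelligence", "pheno_maternal_smoking", "pheno_bmi"))
    pheno[[ph]][sample.int(n, max(1L, round(0.02 * n)))] <- NA_real_

  st <- sample_table(data.frame(
    sample_id = sprintf("%s_s%05d", batch_tag, seq_len(n)),
    age = age, sex = sex, cells,
    tech_1 = tech1, tech_2 = tech2,
    smoking_status = smoking_status, pack_years = pack_years,
    pheno, stringsAsFactors = FALSE))
  list(samples = st, factors = factors, f_atypical = f_atypical,
       f_clock = f_clock, eff_latent = eff_latent, agestd = agestd,
       smkstd = as.numeric(scale(smoking_status)))
}

# Latent Gaussian methylation signal for all CpGs of one cohort, mapped to
# beta values through a logistic transform around per-CpG baselines.
draw_methylation <- function(drawn, asn, truth, config) {
  st <- drawn$samples
  n <- nrow(st)
  ann <- asn$annotation
  p <- nrow(ann)
  age <- st$age
  x <- matrix(stats::rnorm(n * p), n, p)     # idiosyncratic noise

  cellstd <- as.numeric(scale(st$cell_gran))
  sexstd <- as.numeric(scale(st$sex))
  covs <- cbind(sexstd, cellstd, drawn$smkstd,
                as.numeric(scale(st$tech_1)))

  idx <- function(ids) match(ids, ann$cpg_id)
  structured <- rep(FALSE, p)

  for (i in seq_len(nrow(truth$modules))) {
    m <- truth$modules$module[i]
    j <- idx(asn$module_cpgs[[m]])
    rho <- pmin(pmax(truth$modules$base_correlation[i] +
                       truth$modules$age_slope[i] * (age - min(config$age_bins)),
                     0), 0.95)
    l <- sqrt(rho)
    x[, j] <- l * drawn$factors[[m]] + sqrt(1 - rho) * x[, j]
    structured[j] <- TRUE
  }
  fs <- truth$factor_share
  for (i in seq_len(nrow(truth$effects))) {
    ph <- truth$effects$phenotype[i]
    j <- idx(asn$effect_cpgs[[ph]])
    s <- sqrt(truth$effects$variance_explained[i])
    # effect CpGs also ride the global atypical factor (they belong to the
    # atypical class, whose CpGs co-fluctuate beyond the planted modules)
    x[, j] <- sqrt(s) * drawn$eff_latent[[ph]] +
      sqrt(fs) * drawn$f_atypical + sqrt(1 - s - fs) * x[, j]
    structured[j] <- TRUE
  }
  ga <- idx(asn$global_atypical)
  x[, ga] <- sqrt(fs) * drawn$f_atypical + sqrt(1 - fs) * x[, ga]
  structured[ga] <- TRUE
  co <- integer(0)
  for (clk in clock_names()) {
    jc <- idx(asn$clock_only[[clk]])
    x[, jc] <- sqrt(fs) * drawn$f_clock[[clk]] + sqrt(1 - fs) * x[, jc]
    structured[jc] <- TRUE
    co <- c(co, jc)
  }

  # modest covariate effects on a subset of unstructured CpGs, so the
  # adjustment stage has real work to do
  free <- which(!structured)
  bcov <- matrix(0, p, ncol(covs))
  hit <- matrix(stats::runif(length(free) * ncol(covs)) < truth$cov_effect_prob,
                length(free), ncol(covs))
  bcov[free, ] <- hit * matrix(stats::rnorm(length(free) * ncol(covs),
                                            0, truth$cov_effect_sd),
                               length(free), ncol(covs))
  x <- x + covs %*% t(bcov)

  # per-CpG baselines by class; baseline logit shrinks towards 0 with age
  # (epigenetic drift towards beta 0.5, fastest for the atypical class)
  mu <- numeric(p)
  is_clock_only <- seq_len(p) %in% co
  for (cl in c("atypical", "typical", "none")) {
    j <- which(ann$poe_class == cl & !is_clock_only)
    mu[j] <- truth$baseline_logit[[cl]](length(j))
  }
  mu[co] <- truth$baseline_logit$clock(length(co))
  drift <- truth$drift_per_year[ann$poe_class]
  shrink <- outer(age - 18, drift, function(a, d) pmax(1 - a * d, 0))
  logit <- shrink * matrix(mu, n, p, byrow = TRUE) + truth$sigma_logit * x
  beta <- 1 / (1 + 2^(-logit))
  dimnames(beta) <- list(st$sample_id, ann$cpg_id)
  meth_matrix(beta, scale = "beta")
}

#' Simulate one synthetic cohort
#'
#' Draws a cohort of beta-valued methylation with the planted structure in
#' `truth`: co-methylation blocks (including age-strengthening ones),
#' CpG-phenotype effects, covariate-driven variation, class-specific
#' baseline dispersion and drift, and clock/POE factor coupling. Ages are
#' uniform over the union of the configured age bins. The latent Gaussian
#' signal is mapped to betas with a logistic transform around per-CpG
#' baselines, so planted correlations survive the transform approximately.
#'
#' @param n_samples Number of samples.
#' @param n_cpgs Number of CpGs (must accommodate the planted structure).
#' @param truth A [simulation_truth()].
#' @param config A [poe_config()].
#' @param seed Integer seed.
#' @param batch_tag Prefix for sample ids.
#' @return A list (class `poe_cohort`) with elements `meth` (beta
#'   `meth_matrix`), `samples`, `annotation`, `truth` (realized CpG
#'   assignments), `phenotype_info` and `seed`.
#' @export
simulate_cohort <- function(n_samples, n_cpgs, truth = simulation_truth(),
                            config = poe_config(), seed = 1L,
                            batch_tag = "b1") {
  set.seed(seed)
  asn <- assign_truth(n_cpgs, truth)
  simulate_with_assignment(n_samples, asn, truth, config, batch_tag, seed)
}

simulate_with_assignment <- function(n_samples, asn, truth, config,
                                     batch_tag, seed) {
  drawn <- draw_samples(n_samples, truth, config, batch_tag)
  meth <- draw_methylation(drawn, asn, truth, config)
  realized <- c(truth,
                list(module_cpgs = asn$module_cpgs,
                     effect_cpgs = asn$effect_cpgs,
                     clock_sets = asn$clock_sets,
                     global_atypical = asn$global_atypical))
  class(realized) <- "simulation_truth"
  structure(list(meth = meth, samples = drawn$samples,
                 annotation = asn$annotation, truth = realized,
                 phenotype_info = default_phenotype_info(drawn$samples),
                 seed = seed),
            class = "poe_cohort")
}

#' @export
print.poe_cohort <- function(x, ...) {
  cat("poe_cohort:", nrow(x$meth), "samples x", ncol(x$meth), "CpGs;",
      sum(x$annotation$poe_class == "atypical"), "atypical /",
      sum(x$annotation$poe_class == "typical"), "typical POE CpGs;",
      length(phenotype_ids(x$samples)), "phenotypes\n")
  invisible(x)
}

#' Phenotype metadata for covariate-rule handling
#'
#' Classifies phenotype columns so that association models can apply the
#' protocol's covariate rules: age and age-squared are not adjusted for when
#' the phenotype is an age-acceleration measure, and smoking covariates are
#' not adjusted for when the phenotype is smoking status.
#'
#' @param samples A [sample_table()].
#' @return Data frame with columns `phenotype_id` and `class`
#'   (standard / age_accel / smoking).
#' @export
default_phenotype_info <- function(samples) {
  ids <- phenotype_ids(samples)
  cls <- ifelse(grepl("_accel$", ids), "age_accel",
                ifelse(ids == "smoking_status", "smoking", "standard"))
  data.frame(phenotype_id = ids, class = cls, stringsAsFactors = FALSE)
}

#' Simulate a discovery/replication cohort pair
#'
#' Two independent draws from the same generative model: the planted CpG
#' assignments, annotation and truth are shared, while samples are drawn
#' with distinct recorded sub-seeds.
#'
#' @inheritParams simulate_cohort
#' @param n_samples Samples per batch (scalar or length-2 vector).
#' @return List with elements `discovery` and `replication`, each a
#'   `poe_cohort`.
#' @export
simulate_pair <- function(n_samples, n_cpgs, truth = simulation_truth(),
                          config = poe_config(), seed = 1L) {
  if (length(n_samples) == 1) n_samples <- rep(n_samples, 2)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  set.seed(sub[1])
  asn <- assign_truth(n_cpgs, truth)
  set.seed(sub[2])
  disc <- simulate_with_assignment(n_samples[1], asn, truth, config,
                                   "disc", sub[2])
  set.seed(sub[3])
  repl <- simulate_with_assignment(n_samples[2], asn, truth, config,
                                   "repl", sub[3])
  list(discovery = disc, replication = repl)
}

#' Write a simulated cohort to disk
#'
#' Writes the TSV formats the readers consume, plus the realized truth as
#' JSON.
#'
#' @param cohort A `poe_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_methylation_matrix(cohort$meth, file.path(dir, "methylation.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_cpg_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  truth <- unclass(cohort$truth)
  truth$baseline_logit <- NULL               # closures are not serializable
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
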