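test_that("ORM matches the standardized cross-product definition", {
  # two samples, one probe: standardization forces [[1,-1],[-1,1]] up to
  # the 2-probe minimum, so use a second identical-information probe
  m <- matrix(c(0, 1, 0, 1), 2, 2,
              dimnames = list(c("s1", "s2"), c("cg1", "cg2")))
  orm <- build_orm(meth_matrix(m, "m"))
  expect_equal(unname(orm$values),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2) * 2, tolerance = 1e-12)

  # brute-force oracle on a 5x4 toy (population-SD standardization)
  set.seed(5)
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("cg", 1:4)))
  orm2 <- build_orm(meth_matrix(x, "m"))
  z <- apply(x, 2, function(col)
    (col - mean(col)) / sqrt(mean((col - mean(col))^2)))
  expect_equal(unname(orm2$values), unname(z %*% t(z) / 4),
               tolerance = 1e-12)
  expect_equal(orm2$n_probes_used, 4L)

  # diagonal mean is exactly 1 by construction
  big <- rand_meth(50, 400, seed = 6)
  orm3 <- build_orm(beta_to_m(big))
  expect_equal(mean(diag(orm3$values)), 1, tolerance = 1e-12)

  # zero-variance probe excluded with warning
  xz <- cbind(x, cg5 = rep(1, 5))
  expect_warning(o <- build_orm(meth_matrix(xz, "m")), "zero-variance")
  expect_equal(o$n_probes_used, 4L)
})

test_that("MOA at the zero-ratio boundary equals OLS exactly", {
  set.seed(7)
  n <- 200
  Z <- matrix(rnorm(n * 100), n, 100,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("cg%03d", 1:100)))
  orm <- build_orm(meth_matrix(Z, "residual"))
  w <- Z[, 1]
  y <- setNames(0.3 * w + rnorm(n), rownames(Z))
  f <- fit_moa(y, w, orm, ratio = 0)
  ols <- summary(lm(y ~ w))$coefficients
  expect_equal(f$beta, ols[2, 1], tolerance = 1e-10)
  expect_equal(f$se, ols[2, 2], tolerance = 1e-10)
  expect_equal(f$p, 2 * pnorm(-abs(ols[2, 3])), tolerance = 1e-10)
  # and whenever REML lands on the boundary the same identity holds
  fr <- fit_moa(y, w, orm)
  if (fr$variance_ratio == 0) expect_equal(fr$beta, ols[2, 1],
                                           tolerance = 1e-10)
})

test_that("REML recovers a planted variance ratio and beats a ratio grid", {
  set.seed(8)
  n <- 400
  Z <- matrix(rnorm(n * 200), n, 200,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("cg%03d", 1:200)))
  orm <- build_orm(meth_matrix(Z, "residual"))
  eg <- poemeth:::orm_eigen(orm)
  ratios <- replicate(8, {
    g <- eg$U %*% (sqrt(eg$d) * rnorm(n))
    y <- setNames(drop(0.2 * Z[, 1] + g + rnorm(n)), rownames(Z))
    fit_moa(y, Z[, 1], orm)$variance_ratio
  })
  expect_equal(median(ratios), 1, tolerance = 0.5)

  # optimization sanity: returned optimum at least as good as a dense grid
  g <- eg$U %*% (sqrt(eg$d) * rnorm(n))
  y <- setNames(drop(g + rnorm(n)), rownames(Z))
  f <- fit_moa(y, Z[, 2], orm)
  yt <- crossprod(eg$U, y)
  Xt <- crossprod(eg$U, cbind(1, Z[, 2]))
  ll_opt <- poemeth:::reml_ll(f$variance_ratio, yt, Xt, eg$d, n - 2)
  grid <- 10^seq(-6, 6, length.out = 50)
  ll_grid <- vapply(grid, poemeth:::reml_ll, 0, yt = yt, Xt = Xt,
                    d = eg$d, np = n - 2)
  expect_gte(ll_opt, max(ll_grid) - 1e-6)
})

test_that("perfect linear relationship drives MOA p to zero", {
  set.seed(9)
  n <- 120
  Z <- matrix(rnorm(n * 60), n, 60,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("cg%02d", 1:60)))
  orm <- build_orm(meth_matrix(Z, "residual"))
  y <- setNames(3 * Z[, 4], rownames(Z))
  f <- fit_moa(y, Z[, 4], orm)
  expect_equal(f$beta, 3, tolerance = 1e-6)
  expect_lt(f$p, 1e-12)
})

test_that("CpG-outcome model matches a hand-computed regression", {
  st <- toy_samples(120, seed = 10)
  set.seed(10)
  ph <- rnorm(120); names(ph) <- st$sample_id
  ym <- 0.5 * ph + rnorm(120); names(ym) <- st$sample_id
  f <- fit_cpg_outcome(ym, ph, st, "standard")
  # normal-equations oracle with the same design
  X <- poemeth:::covariate_design(st, covariate_set("set1", st)$included)
  X <- cbind(X, ph)
  bh <- solve(t(X) %*% X, t(X) %*% ym)
  expect_equal(f$beta, unname(bh[nrow(bh), 1]), tolerance = 1e-10)
  resid <- ym - X %*% bh
  s2 <- sum(resid^2) / (120 - ncol(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[ncol(X), ncol(X)])
  expect_equal(f$se, se, tolerance = 1e-10)
  expect_equal(f$p, 2 * pt(-abs(f$beta / f$se), 120 - ncol(X)),
               tolerance = 1e-12)

  # collinearity is reported
  st2 <- st
  phc <- st2$tech_1; names(phc) <- st2$sample_id
  expect_error(fit_cpg_outcome(ym, phc, st2, "standard"), "collinear")
})

test_that("covariate rules drop age for age-acceleration phenotypes", {
  st <- toy_samples(200, seed = 11)
  set.seed(11)
  # methylation strongly age-driven; phenotype = pure age signal
  ym <- 0.05 * st$age + rnorm(200, 0, 0.1); names(ym) <- st$sample_id
  ph <- st$age + rnorm(200); names(ph) <- st$sample_id
  f_std <- fit_cpg_outcome(ym, ph, st, "standard")   # age adjusted away
  f_acc <- fit_cpg_outcome(ym, ph, st, "age_accel")  # age kept in play
  expect_gt(f_std$p, 1e-4)
  expect_lt(f_acc$p, 1e-10)
})

test_that("BH flags equal the brute-force step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.9), q = 0.05)
  expect_identical(r$flags, c(TRUE, TRUE, FALSE))
  expect_equal(r$threshold, 0.02)
  expect_identical(bh_fdr(rep(1, 5), 0.05)$flags, rep(FALSE, 5))
  expect_error(bh_fdr(numeric(0)), "empty")

  set.seed(12)
  for (i in 1:100) {
    m <- sample(1:500, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    flags <- bh_fdr(p, q)$flags
    expect_identical(flags, brute_force_bh(p, q))
    # monotone in p
    if (any(flags)) expect_true(all(p[flags] <= max(p[flags])))
  }
})

test_that("workflow recovers planted effects and filters unreplicated ones", {
  pair <- shared_pair()
  wf <- discovery_replication_workflow(pair$discovery, pair$replication)
  hc <- paste(wf$high_confidence$feature_id, wf$high_confidence$phenotype_id)
  planted <- pair$discovery$truth$effect_cpgs
  hits <- sum(paste(planted$dnamtl_accel, "dnamtl_accel") %in% hc,
              paste(planted$intelligence, "intelligence") %in% hc,
              paste(planted$maternal_smoking, "maternal_smoking") %in% hc)
  expect_gte(hits, 2)   # power at n=500 and R2=0.025 is moderate
  # every high-confidence pair was FDR-significant at every stage
  rec <- wf$records
  for (i in seq_len(nrow(wf$high_confidence))) {
    sub <- rec[rec$feature_id == wf$high_confidence$feature_id[i] &
                 rec$phenotype_id == wf$high_confidence$phenotype_id[i], ]
    expect_true(all(sub$significant_fdr))
    expect_setequal(unique(sub$stage), c("discovery", "replication"))
  }
})

test_that("empty stage-1 survivor set returns an empty result quietly", {
  pair <- shared_pair()
  cfg <- poe_config(fdr_q = 1e-12)
  wf <- discovery_replication_workflow(pair$discovery, pair$replication,
                                       cfg,
                                       phenotypes = "bmi")
  expect_equal(nrow(wf$high_confidence), 0L)
})

test_that("conditional association behaves under null and mediator", {
  st <- toy_samples(400, seed = 13)
  set.seed(13)
  mediator <- rnorm(400)
  ph <- mediator + rnorm(400, 0, 0.5)
  ym <- 0.5 * mediator + rnorm(400, 0, 0.8)
  names(ph) <- names(ym) <- st$sample_id
  med <- setNames(mediator, st$sample_id)
  base <- fit_cpg_outcome(ym, ph, st, "standard")
  expect_lt(base$p, 1e-6)
  cond <- conditional_association(ym, ph, st, "standard", med)
  expect_gt(cond$p, 0.01)  # signal explained by the mediator
  # independent extra covariate barely moves the estimate
  indep <- setNames(rnorm(400), st$sample_id)
  cond2 <- conditional_association(ym, ph, st, "standard", indep)
  expect_lt(abs(cond2$beta - base$beta), 2 * base$se)
  # conditioning on the phenotype itself is collinear
  expect_error(conditional_association(ym, ph, st, "standard", ph),
               "collinear")
})
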