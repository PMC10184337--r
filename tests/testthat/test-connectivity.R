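ramp_profile_fixture <- function(n_per_bin = 200, k = 8, base = 0.15,
                                 top = 0.30, seed = 60, flat = FALSE) {
  set.seed(seed)
  bins <- default_age_bins()
  ages <- unlist(lapply(seq_len(nrow(bins)), function(b)
    runif(n_per_bin, bins[b, 1], bins[b, 2])))
  n <- length(ages)
  rho <- if (flat) rep(base, n) else base + (top - base) *
    (ages - 18) / (94 - 18)
  f <- rnorm(n)
  x <- matrix(rnorm(n * k), n, k)
  x <- sqrt(rho) * f + sqrt(1 - rho) * x
  dimnames(x) <- list(sprintf("s%05d", 1:n), sprintf("cg%02d", 1:k))
  st <- toy_samples(n, seed = seed + 1)
  st$age <- ages
  st$sample_id <- rownames(x)
  list(x = x, samples = st, bins = bins)
}

test_that("age stratification respects printed bin boundaries", {
  st <- toy_samples(6)
  st$age <- c(27, 28, 94, 17, 18, 66)
  lab <- as.character(suppressMessages(stratify_ages(st)))
  expect_equal(lab, c("18-27", "28-37", "66-94", NA, "18-27", "66-94"))
})

test_that("connectivity profile has k(k-1)/2 pairs and tracks the ramp", {
  fx <- ramp_profile_fixture(n_per_bin = 300, k = 4)
  prof <- module_connectivity_by_age(fx$x, colnames(fx$x), fx$samples,
                                     fx$bins)
  expect_equal(nrow(prof$pairs), 6L)
  expect_equal(ncol(prof$abs_corr), 6L)

  fx2 <- ramp_profile_fixture(n_per_bin = 300, k = 10, seed = 61)
  prof2 <- module_connectivity_by_age(fx2$x, colnames(fx2$x), fx2$samples,
                                      fx2$bins)
  mids <- rowMeans(fx2$bins)
  m <- colMeans(prof2$abs_corr)
  slope <- coef(lm(m ~ mids))[2]
  truth_slope <- (0.30 - 0.15) / (94 - 18)
  expect_lt(abs(unname(slope) - truth_slope), 0.35 * truth_slope)
  expect_gt(m[6], m[1])
})

test_that("flat modules show no monotone connectivity trend", {
  ps <- sapply(1:5, function(i) {
    fx <- ramp_profile_fixture(n_per_bin = 150, k = 8, seed = 600 + i,
                               flat = TRUE)
    prof <- module_connectivity_by_age(fx$x, colnames(fx$x), fx$samples,
                                       fx$bins)
    test_connectivity_trend(prof)$p
  })
  expect_gt(sum(ps > 0.01), 3)   # mostly non-significant

  # while a rising module shows a clear positive bin-level trend
  fx <- ramp_profile_fixture(n_per_bin = 150, k = 8, seed = 599)
  prof <- module_connectivity_by_age(fx$x, colnames(fx$x), fx$samples,
                                     fx$bins)
  tr <- test_connectivity_trend(prof)
  expect_gt(tr$slope, 0)
  expect_lt(tr$p, 0.05)
})

test_that("paired shift test matches exact signed-rank enumeration", {
  fx <- ramp_profile_fixture(n_per_bin = 80, k = 4, seed = 62)
  prof <- module_connectivity_by_age(fx$x, colnames(fx$x), fx$samples,
                                     fx$bins)
  # identical bins: degenerate, p = 1
  prof0 <- prof
  prof0$abs_corr[, "66-94"] <- prof0$abs_corr[, "18-27"]
  expect_equal(test_connectivity_shift(prof0, "18-27", "66-94")$p.value, 1)

  # 8-pair toy against full enumeration
  set.seed(63)
  a <- runif(8, 0.1, 0.5)
  b <- a + runif(8, -0.1, 0.3)
  toy <- list(pairs = data.frame(cpg_a = paste0("x", 1:8),
                                 cpg_b = paste0("y", 1:8)),
              abs_corr = cbind(young = a, old = b),
              cpg_ids = c(paste0("x", 1:8), paste0("y", 1:8)))
  class(toy) <- "connectivity_profile"
  got <- test_connectivity_shift(toy, "young", "old")
  oracle <- brute_force_signed_rank(a, b)
  expect_equal(unname(got$statistic), oracle$V)
  expect_equal(got$p.value, oracle$p, tolerance = 1e-10)

  # every pair larger in the old bin: the minimal two-sided p is 2/2^n
  b2 <- a + runif(8, 0.02, 0.2)
  toy$abs_corr <- cbind(young = a, old = b2)
  got2 <- test_connectivity_shift(toy, "young", "old")
  expect_equal(got2$p.value, 2 / 2^8, tolerance = 1e-10)
})

test_that("Levene variance test reacts to dispersion changes only", {
  # two bins with identical values: between-group spread is exactly zero
  set.seed(641)
  v <- abs(rnorm(50, 0.3, 0.08))
  toy <- list(abs_corr = cbind(b1 = v, b2 = v))
  class(toy) <- "connectivity_profile"
  lv <- test_connectivity_variance(toy)
  expect_equal(lv$statistic, 0, tolerance = 1e-12)

  set.seed(64)
  base <- rnorm(60, 0.3, 0.05)
  toy2 <- list(abs_corr = cbind(b1 = base,
                                b2 = 0.3 + (rnorm(60, 0, 0.05)) * 3))
  class(toy2) <- "connectivity_profile"
  expect_lt(test_connectivity_variance(toy2)$p, 0.01)

  # null calibration: equal dispersion gives roughly uniform p
  ps <- sapply(1:40, function(i) {
    set.seed(640 + i)
    t0 <- list(abs_corr = cbind(b1 = rnorm(50, 0.3, 0.05),
                                b2 = rnorm(50, 0.3, 0.05)))
    class(t0) <- "connectivity_profile"
    test_connectivity_variance(t0)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("trajectory clustering recovers three slope regimes", {
  set.seed(65)
  n_per <- 40
  mk_traj <- function(start, slope, noise = 0.01)
    t(replicate(n_per, start + slope * (0:5) / 5 + rnorm(6, 0, noise)))
  x <- rbind(mk_traj(0.2, 0), mk_traj(0.2, 0.1), mk_traj(0.2, 0.3))
  truth <- rep(1:3, each = n_per)
  prof <- list(abs_corr = x,
               pairs = data.frame(cpg_a = paste0("a", 1:nrow(x)),
                                  cpg_b = paste0("b", 1:nrow(x))))
  colnames(prof$abs_corr) <- paste0("bin", 1:6)
  class(prof) <- "connectivity_profile"
  cl <- cluster_trajectories(prof, k = 3)
  expect_gte(adjusted_rand(cl, truth), 0.8)
  # labels ordered by increasing slope
  expect_equal(names(which.min(attr(cl, "slopes"))), "c1")
  # invariance to pair order
  perm <- sample(nrow(x))
  prof2 <- prof
  prof2$abs_corr <- x[perm, ]
  cl2 <- cluster_trajectories(prof2, k = 3)
  expect_gte(adjusted_rand(cl2, cl[perm]), 0.999)
  expect_error(cluster_trajectories(prof, k = nrow(x) + 1), "exceeds")
})

test_that("hub centrality counts strict-threshold edges", {
  # star: one CpG correlated with 6 others, others mutually uncorrelated
  cpgs <- paste0("cg", 0:6)
  pairs <- t(combn(cpgs, 2))
  r <- ifelse(pairs[, 1] == "cg0" | pairs[, 2] == "cg0", 0.8, 0.01)
  prof <- list(pairs = data.frame(cpg_a = pairs[, 1], cpg_b = pairs[, 2]),
               corr = cbind(old = r), abs_corr = cbind(old = abs(r)),
               cpg_ids = cpgs)
  class(prof) <- "connectivity_profile"
  hub <- hub_centrality(prof, "old", edge_threshold = 0.4)
  expect_equal(unname(hub$degree["cg0"]), 6)
  expect_true(all(hub$degree[-1] == 1))
  expect_equal(hub$hubs[1], "cg0")

  # boundary: |r| exactly 0.4 produces no edge
  prof$corr[] <- 0.4
  prof$abs_corr[] <- 0.4
  hub2 <- hub_centrality(prof, "old", edge_threshold = 0.4)
  expect_true(all(hub2$degree == 0))

  # brute-force degrees on a random profile
  set.seed(66)
  r3 <- runif(nrow(pairs), 0, 1)
  prof$corr[] <- r3
  prof$abs_corr[] <- r3
  hub3 <- hub_centrality(prof, "old", edge_threshold = 0.5)
  for (cg in cpgs) {
    manual <- sum((pairs[, 1] == cg | pairs[, 2] == cg) & r3 > 0.5)
    expect_equal(unname(hub3$degree[cg]), manual)
  }
})

test_that("per-CpG radiated shift separates hub-like from flat CpGs", {
  set.seed(67)
  bins <- default_age_bins()
  n_per <- 250
  ages <- unlist(lapply(seq_len(nrow(bins)), function(b)
    runif(n_per, bins[b, 1], bins[b, 2])))
  n <- length(ages)
  k <- 10
  # CpG 1 has age-growing loading; others static moderate loading
  f <- rnorm(n)
  x <- matrix(rnorm(n * k), n, k)
  l1 <- sqrt(0.05 + 0.55 * (ages - 18) / 76)
  x[, 1] <- l1 * f + sqrt(1 - l1^2) * x[, 1]
  for (j in 2:k) x[, j] <- sqrt(0.3) * f + sqrt(0.7) * x[, j]
  dimnames(x) <- list(sprintf("s%05d", 1:n), sprintf("cg%02d", 1:k))
  st <- toy_samples(n, seed = 68)
  st$age <- ages; st$sample_id <- rownames(x)
  prof <- module_connectivity_by_age(x, colnames(x), st, bins)
  out <- per_cpg_radiated_shift(prof)
  expect_lt(out$p_bonferroni[out$cpg == "cg01"], 0.05)
  expect_gt(min(out$p_bonferroni[out$cpg != "cg01"]), 0.05)
})

test_that("age-stratified association localizes an old-age effect", {
  set.seed(69)
  st <- toy_samples(1200, seed = 69)
  old <- st$age >= 57
  feature <- rnorm(1200)
  ph <- ifelse(old, 0.6 * feature, 0) + rnorm(1200)
  names(feature) <- names(ph) <- st$sample_id
  out <- age_stratified_association(feature, ph, st,
                                    phenotype_class = "none")
  expect_true(all(out$p[out$bin %in% c("57-65", "66-94")] < 1e-3))
  expect_true(all(out$p[out$bin %in% c("18-27", "28-37")] > 0.01))
})

test_that("interaction test recovers a product effect, centred invariantly", {
  set.seed(70)
  st <- toy_samples(800, seed = 70)
  feature <- rnorm(800); names(feature) <- st$sample_id
  ac <- st$age - mean(st$age)
  fc <- feature - mean(feature)
  ph <- 0.5 * fc + 0.02 * ac + 0.01 * fc * ac + rnorm(800, 0, 0.5)
  names(ph) <- st$sample_id
  it <- interaction_test(feature, ph, st)
  expect_lt(abs(it$beta - 0.01), 2 * it$se)
  expect_lt(it$p, 0.01)
  # shifting age leaves the interaction coefficient unchanged
  st2 <- st; st2$age <- st$age + 50
  it2 <- interaction_test(feature, ph, st2)
  expect_equal(it2$beta, it$beta, tolerance = 1e-8)
  # additive phenotype: interaction null
  ph0 <- 0.5 * fc + 0.02 * ac + rnorm(800, 0, 0.5); names(ph0) <- st$sample_id
  expect_gt(interaction_test(feature, ph0, st)$p, 0.001)
})
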