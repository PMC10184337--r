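planted_blocks_fixture <- function(n, seed, n_noise = 60, rho = 0.6,
                                   block = 20) {
  set.seed(seed)
  p <- 2 * block + n_noise
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1:block] <- sqrt(rho) * f1 + sqrt(1 - rho) * x[, 1:block]
  x[, block + 1:block] <- sqrt(rho) * f2 +
    sqrt(1 - rho) * x[, block + 1:block]
  dimnames(x) <- list(sprintf("s%04d", 1:n), sprintf("cg%03d", 1:p))
  list(x = x, truth = list(b1 = colnames(x)[1:block],
                           b2 = colnames(x)[block + 1:block]))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

test_that("power-1 adjacency is |correlation| and override bypasses search", {
  fx <- planted_blocks_fixture(200, seed = 40)
  a <- adjacency_matrix(fx$x, 1)
  cc <- abs(cor(fx$x)); diag(cc) <- 0
  expect_equal(a, cc, tolerance = 1e-12)
  expect_equal(pick_soft_threshold(fx$x, override = 3)$power, 3L)
})

test_that("scale-free fit statistics match an independent recomputation", {
  fx <- planted_blocks_fixture(150, seed = 41, n_noise = 10, block = 10)
  ps <- pick_soft_threshold(fx$x)
  absr <- abs(cor(fx$x)); diag(absr) <- 0
  for (pw in c(2, 5, 9)) {
    k <- rowSums(absr^pw)
    br <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- tapply(k, bin, length); mk <- tapply(k, bin, mean)
    keep <- !is.na(freq)
    fit <- summary(lm(log10(freq[keep]) ~ log10(mk[keep])))
    expect_equal(ps$fit_table$r_squared[ps$fit_table$power == pw],
                 fit$r.squared, tolerance = 1e-10)
  }
})

test_that("planted blocks are recovered and sub-threshold blocks are not", {
  fx <- planted_blocks_fixture(1000, seed = 42)
  pw <- pick_soft_threshold(fx$x)$power
  mods <- detect_modules(fx$x, pw)
  expect_length(mods, 2L)
  best <- sapply(fx$truth, function(b)
    max(sapply(mods, function(m) jaccard(m$cpg_ids, b))))
  expect_true(all(best >= 0.9))

  # a 5-CpG block is below the minimum size of 8
  set.seed(43)
  f <- rnorm(500)
  y <- matrix(rnorm(500 * 45), 500, 45)
  y[, 1:5] <- sqrt(0.7) * f + sqrt(0.3) * y[, 1:5]
  dimnames(y) <- list(sprintf("s%03d", 1:500), sprintf("cg%02d", 1:45))
  mods2 <- detect_modules(y, 6, min_size = 8)
  expect_length(mods2, 0L)
  expect_true(all(paste0("cg0", 1:5) %in% attr(mods2, "unassigned")))
})

test_that("pure noise rarely produces modules", {
  hits <- sapply(1:5, function(i) {
    set.seed(400 + i)
    x <- matrix(rnorm(500 * 60), 500, 60,
                dimnames = list(NULL, sprintf("cg%02d", 1:60)))
    rownames(x) <- sprintf("s%03d", 1:500)
    length(detect_modules(x, 6))
  })
  expect_lte(sum(hits > 0), 1)
})

test_that("module detection depends on data only through correlations", {
  fx <- planted_blocks_fixture(300, seed = 44)
  mods <- detect_modules(fx$x, 6)
  perm <- sample(nrow(fx$x))
  mods_p <- detect_modules(fx$x[perm, ], 6)
  expect_identical(lapply(mods, `[[`, "cpg_ids"),
                   lapply(mods_p, `[[`, "cpg_ids"))
})

test_that("10-kb window pruning keeps exactly the index CpG", {
  set.seed(45)
  n <- 300
  f <- rnorm(n)
  x <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("s%03d", 1:n), c("cgA", "cgB", "cgC")))
  # cgB most connected to the others
  x[, 1] <- sqrt(0.5) * f + sqrt(0.5) * x[, 1]
  x[, 2] <- sqrt(0.9) * f + sqrt(0.1) * x[, 2]
  x[, 3] <- sqrt(0.5) * f + sqrt(0.5) * x[, 3]
  ann <- cpg_annotation(data.frame(
    cpg_id = c("cgA", "cgB", "cgC"), chromosome = "chr1",
    position = c(100, 5000, 9000), poe_class = "atypical"))
  removed <- poemeth:::prune_module_windows(x, ann, colnames(x), 10000)
  expect_setequal(removed, c("cgA", "cgC"))

  # 9,999 and 10,000 fall in different windows (floor division)
  ann2 <- cpg_annotation(data.frame(
    cpg_id = c("cgA", "cgB"), chromosome = "chr1",
    position = c(9999, 10000), poe_class = "atypical"))
  expect_length(
    poemeth:::prune_module_windows(x[, 1:2], ann2, c("cgA", "cgB"), 10000),
    0L)
})

test_that("recursion is a fixed point when no module CpGs share a window", {
  fx <- planted_blocks_fixture(400, seed = 46)
  ann <- cpg_annotation(data.frame(
    cpg_id = colnames(fx$x),
    chromosome = rep(paste0("chr", 1:10), length.out = ncol(fx$x)),
    position = seq(1e5, by = 1e5, length.out = ncol(fx$x)),
    poe_class = "atypical"))
  out <- recursive_prune_and_power(fx$x, ann, poe_config())
  expect_equal(out$n_iterations, 1L)
  expect_setequal(out$retained_cpgs, colnames(fx$x))
})

test_that("recursive pruning collapses same-window triplets", {
  set.seed(47)
  n <- 500
  # three cis triplets, each triplet within one 10-kb window, all part of
  # one correlated module, plus independent trans CpGs to reach the
  # soft-threshold minimum
  f <- rnorm(n)
  p_cis <- 9
  x <- matrix(rnorm(n * 29), n, 29)
  load <- c(rep(0.85, p_cis), rep(0.6, 6))   # triplets + 6 trans members
  for (j in 1:15) x[, j] <- sqrt(load[j]) * f + sqrt(1 - load[j]) * x[, j]
  ids <- c(sprintf("cis%02d", 1:9), sprintf("trans%02d", 1:6),
           sprintf("noise%02d", 1:14))
  dimnames(x) <- list(sprintf("s%03d", 1:n), ids)
  ann <- cpg_annotation(data.frame(
    cpg_id = ids,
    chromosome = c(rep(c("chr1", "chr2", "chr3"), each = 3),
                   rep("chr4", 6), rep(paste0("chr", 5:18), 1)),
    position = c(rep(c(1000, 4000, 8000), 3), seq(2e4, by = 2e4,
                                                  length.out = 20)),
    poe_class = "atypical"))
  cfg <- poe_config(soft_power_override = 3)
  out <- recursive_prune_and_power(x, ann, cfg)
  expect_lte(out$n_iterations, 3L)
  # exactly one survivor per cis window
  for (ch in c("chr1", "chr2", "chr3")) {
    surv <- intersect(out$retained_cpgs,
                      ann$cpg_id[ann$chromosome == ch])
    expect_length(surv, 1L)
  }
  expect_true(all(sprintf("trans%02d", 1:6) %in% out$retained_cpgs))
})

test_that("module matching applies strict overlap thresholds", {
  mk <- function(id, cpgs) list(module_id = id, cpg_ids = cpgs,
                                power_used = 3L)
  cfg <- poe_config()
  # overlap 6/10 = 0.6 is NOT higher than 60%, so no primary match; the
  # fully-nested replication module still attaches through the secondary
  # rule (6/6 = 1 > 90%)
  d <- list(mk("m1", paste0("cg", 1:10)))
  r <- list(mk("m1", paste0("cg", 1:6)))
  cm0 <- match_modules(d, r, cfg)
  expect_false(any(vapply(cm0, `[[`, "", "match_type") == "primary"))
  expect_equal(vapply(cm0, `[[`, "", "match_type"), "secondary")
  # identical modules match at rate 1
  r2 <- list(mk("m1", paste0("cg", 1:10)))
  cm <- match_modules(d, r2, cfg)
  expect_length(cm, 1L)
  expect_equal(cm[[1]]$overlap_rate, 1)
  expect_equal(cm[[1]]$match_type, "primary")
  # secondary: 9/10 inside = 0.9 NOT matched; 10/10 matched
  dbig <- list(mk("m1", paste0("cg", 1:40)))
  r3 <- list(mk("m1", c(paste0("cg", 1:9), "other")))
  expect_length(match_modules(dbig, r3, cfg), 0L)
  r4 <- list(mk("m1", paste0("cg", 5:14)))
  cm2 <- match_modules(dbig, r4, cfg)
  expect_length(cm2, 1L)
  expect_equal(cm2[[1]]$match_type, "secondary")
  expect_equal(cm2[[1]]$overlap_rate, 1)   # secondary rate
})

test_that("module matching is invariant to input ordering", {
  mk <- function(id, cpgs) list(module_id = id, cpg_ids = cpgs,
                                power_used = 3L)
  d <- list(mk("mA", paste0("a", 1:12)), mk("mB", paste0("b", 1:10)),
            mk("mC", c(paste0("a", 1:4), paste0("c", 1:8))))
  r <- list(mk("m1", paste0("a", 1:11)), mk("m2", paste0("b", 2:10)),
            mk("m3", paste0("c", 1:8)))
  cfg <- poe_config()
  key <- function(cm) sort(vapply(cm, function(m)
    paste(m$discovery_module_id, m$replication_module_id,
          round(m$overlap_rate, 10)), ""))
  base <- key(match_modules(d, r, cfg))
  expect_identical(key(match_modules(rev(d), rev(r), cfg)), base)
  expect_identical(key(match_modules(d[c(2, 3, 1)], r[c(3, 1, 2)], cfg)),
                   base)
})

test_that("planted two-batch modules become primary consistent modules", {
  pair <- shared_pair()
  prep <- shared_prepared()
  ann <- pair$discovery$annotation
  cpgs <- ann$cpg_id[ann$poe_class == "atypical"]
  cfg <- poe_config(soft_power_override = 3)
  rd <- recursive_prune_and_power(
    prep$discovery$residuals$set1[, cpgs], ann, cfg)
  rr <- recursive_prune_and_power(
    prep$replication$residuals$set1[, cpgs], ann, cfg)
  cm <- match_modules(rd$modules, rr$modules, cfg)
  truth <- pair$discovery$truth$module_cpgs
  for (tm in c("atyp_aging", "atyp_dense")) {
    best <- max(vapply(cm, function(m)
      jaccard(m$shared_cpg_ids, truth[[tm]]), 0))
    expect_gte(best, 0.6)
  }
  expect_true(all(vapply(cm, `[[`, 0, "overlap_rate") > 0.6))
})

test_that("module PCA retains Kaiser-style components and projects back", {
  set.seed(48)
  n <- 200
  f <- rnorm(n)
  x <- cbind(cg1 = f + rnorm(n, 0, 1e-4), cg2 = f + rnorm(n, 0, 1e-4),
             cg3 = rnorm(n))
  rownames(x) <- sprintf("s%03d", 1:n)
  pcm <- fit_module_pca(x, c("cg1", "cg2"))
  expect_equal(pcm$explained_fraction[1], 1, tolerance = 1e-4)
  expect_identical(pcm$retained, 1L)
  expect_equal(sum(pcm$explained_fraction), 1, tolerance = 1e-12)

  # eigen-oracle on 3 CpGs
  set.seed(49)
  y <- matrix(rnorm(600), 200, 3,
              dimnames = list(sprintf("s%03d", 1:200), c("a", "b", "c")))
  y[, 2] <- 0.6 * y[, 1] + 0.8 * y[, 2]
  pcm3 <- fit_module_pca(y, c("a", "b", "c"), var_explained_min = 0)
  ev <- eigen(cor(y))
  expect_equal(unname(pcm3$ss_loading), ev$values, tolerance = 1e-10)
  expect_equal(abs(unname(pcm3$rotation)), abs(ev$vectors),
               tolerance = 1e-8)

  # projection reproduces training scores; the mean sample maps to 0
  sc <- project_module_pcs(pcm3, y, retained_only = FALSE)
  pr <- prcomp(y, center = TRUE, scale. = TRUE)
  expect_equal(unname(sc), unname(pr$x), tolerance = 1e-10)
  mean_sample <- matrix(colMeans(y), 1, dimnames = list("mu", colnames(y)))
  expect_equal(max(abs(project_module_pcs(pcm3, mean_sample,
                                          retained_only = FALSE))), 0,
               tolerance = 1e-10)
  expect_error(fit_module_pca(cbind(x, cg4 = rep(1, n)),
                              c("cg1", "cg4")), "constant")
  expect_error(project_module_pcs(pcm3, y[, 1:2]), "missing constituent")
})

test_that("held-out projection variance matches the training eigenvalue", {
  set.seed(50)
  n <- 4000
  f <- rnorm(n)
  x <- sapply(1:6, function(i) sqrt(0.5) * f + sqrt(0.5) * rnorm(n))
  colnames(x) <- paste0("cg", 1:6)
  rownames(x) <- sprintf("s%04d", 1:n)
  train <- rownames(x)[1:2000]
  pcm <- fit_module_pca(x, colnames(x), training_samples = train)
  held <- project_module_pcs(pcm, x[2001:4000, ])
  expect_equal(var(held[, 1]), pcm$ss_loading[1], tolerance = 0.1)
})

test_that("module PC associations recover a planted factor-phenotype link", {
  pair <- shared_pair()
  prep <- shared_prepared()
  truth <- pair$discovery$truth
  cpgs <- truth$module_cpgs$atyp_aging
  recs <- lapply(c("discovery", "replication"), function(stg) {
    res <- prep[[stg]]$residuals$set3
    pcm <- fit_module_pca(res, cpgs)
    sc <- project_module_pcs(pcm, res)
    associate_module_pcs(sc, prep[[stg]]$adjusted_phenotypes$dnamtl_accel,
                         feature_prefix = "aging", stage = stg)
  })
  for (r in recs) expect_lt(r$p[r$feature_id == "aging_PC1"], 1e-4)
  # orthogonalized score shows no association
  res <- prep$discovery$residuals$set3
  pcm <- fit_module_pca(res, cpgs)
  sc <- project_module_pcs(pcm, res)
  y <- prep$discovery$adjusted_phenotypes$dnamtl_accel
  ids <- intersect(rownames(sc), names(y)[!is.na(y)])
  s1 <- sc[ids, 1]
  s_orth <- unname(resid(lm(s1 ~ y[ids])))
  sco <- matrix(s_orth, ncol = 1,
                dimnames = list(ids, "PC1"))
  r0 <- associate_module_pcs(sco, y, feature_prefix = "orth")
  expect_gt(r0$p, 0.9)
})
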