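# Shared fixtures and independent oracles used across test files.

# memoized medium-sized cohort pair so several test files can reuse it
.fixture_env <- new.env(parent = emptyenv())

shared_pair <- function() {
  if (is.null(.fixture_env$pair)) {
    .fixture_env$pair <- simulate_pair(500, 700, seed = 20260922)
  }
  .fixture_env$pair
}

shared_prepared <- function() {
  if (is.null(.fixture_env$prep)) {
    pair <- shared_pair()
    .fixture_env$prep <- lapply(pair, poemeth:::prepare_cohort)
  }
  .fixture_env$prep
}

rand_meth <- function(n, p, seed = 1, prefix = "s") {
  set.seed(seed)
  m <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                              sprintf("cg%03d", seq_len(p))))
  meth_matrix(m, scale = "beta")
}

toy_samples <- function(n, seed = 1) {
  set.seed(seed)
  cells <- matrix(rgamma(n * 6, 5), n, 6)
  cells <- cells / rowSums(cells)
  colnames(cells) <- paste0("cell_", c("b", "nk", "mono", "gran", "cd4t",
                                       "cd8t"))
  sample_table(data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    age = runif(n, 18, 94), sex = rbinom(n, 1, 0.5), cells,
    tech_1 = rnorm(n), tech_2 = rnorm(n),
    smoking_status = sample(0:2, n, replace = TRUE),
    pack_years = rexp(n), stringsAsFactors = FALSE))
}

# brute-force BH step-up: largest k with p_(k) <= k q / m; reject all
# p <= p_(k)
brute_force_bh <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  k <- which(s <= seq_len(m) * q / m)
  if (length(k) == 0) return(rep(FALSE, m))
  p <= s[max(k)]
}

# exact signed-rank statistic and two-sided p by full enumeration (zero
# differences dropped, mean ranks for ties)
brute_force_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p <- mean(vs >= v)
  p2 <- min(2 * min(p, mean(vs <= v)), 1)
  list(V = v, p = p2)
}

# hypergeometric two-sided Fisher p by enumeration over all tables with the
# given margins (probability-based two-sided rule, as fisher.test uses)
brute_force_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# invert binary entropy on [0, 0.5] so tests can plant exact bits/year
# drift in entropy space
inverse_entropy <- function(e) {
  vapply(e, function(ei) {
    if (ei >= 1) return(0.5)
    if (ei <= 0) return(1e-9)
    stats::uniroot(function(b) -b * log2(b) - (1 - b) * log2(1 - b) - ei,
                   c(1e-12, 0.5), tol = 1e-12)$root
  }, 0)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
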