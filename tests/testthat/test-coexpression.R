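test_that("median-of-ratios normalization behaves like a size-factor VST substitute", {
  set.seed(8)
  counts <- matrix(rnbinom(200 * 4, mu = 500, size = 20), 200, 4,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  counts[, 2] <- counts[, 1]                      # identical samples
  nr <- normalize_counts(counts[, 1:2])
  expect_equal(nr$size_factors, c(1, 1), tolerance = 1e-12)
  expect_equal(nr$normalized[, 1], nr$normalized[, 2])
  # doubling a sample's counts doubles its size factor and leaves the
  # transformed values nearly unchanged at large counts
  doubled <- cbind(counts, d = 2L * counts[, 1])
  nd <- normalize_counts(doubled)
  expect_equal(nd$size_factors[[5]] / nd$size_factors[[1]], 2,
               tolerance = 1e-12)
  expect_equal(nd$normalized[, 5], nd$normalized[, 1], tolerance = 1e-2,
               ignore_attr = TRUE)
  # constant gene, equal size factors -> constant transformed row
  const <- matrix(100, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  expect_equal(unname(apply(normalize_counts(const)$normalized, 1, var)),
               rep(0, 3))
  expect_error(normalize_counts(cbind(counts, z = 0L)), "all-zero")
})

test_that("size factors agree with DESeq2's median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  counts <- matrix(rnbinom(300 * 6, mu = 300, size = 10), 300, 6)
  sf <- median_ratio_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(sf, unname(ref), tolerance = 1e-8)
})

test_that("bicor matches its analytic identities and resists outliers", {
  set.seed(10)
  x <- rnorm(50)
  expect_equal(bicor(x, 2 * x + 1), 1)
  expect_equal(bicor(x, -x), -1)
  expect_error(bicor(x, x[-1]), "equal length")
  # zero-MAD vector falls back to Pearson normalization
  y <- rnorm(50)
  z <- c(rep(1, 48), 2, 3)   # MAD 0, variance > 0
  expect_equal(bicor(z, y), bicor_matrix(rbind(z, y))[1, 2])
  # robustness: with one gross outlier appended, bicor stays closer to the
  # outlier-free Pearson than contaminated Pearson does
  wins <- 0
  for (rep in 1:100) {
    a <- rnorm(30); b <- 0.6 * a + rnorm(30, 0, 0.5)
    clean <- cor(a, b)
    a2 <- c(a, 10); b2 <- c(b, -10)
    if (abs(bicor(a2, b2) - clean) < abs(cor(a2, b2) - clean)) wins <- wins + 1
  }
  expect_gt(wins, 90)
  # bicor_matrix equals pairwise bicor
  m <- matrix(rnorm(5 * 40), 5, dimnames = list(paste0("g", 1:5), NULL))
  bm <- bicor_matrix(m)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(bm[i, j], bicor(m[i, ], m[j, ]), tolerance = 1e-12)
  }
})

test_that("signed adjacency maps correlations into [0,1] monotonically", {
  expect_equal(signed_adjacency(matrix(1, 1, 1), 12)[1, 1], 1)
  a <- signed_adjacency(rbind(c(1, -1), c(-1, 1)), 12)
  expect_equal(a[1, 2], 0)
  expect_equal(signed_adjacency(matrix(c(1, 0, 0, 1), 2), 12)[1, 2],
               2.44140625e-4)
  grid <- seq(-1, 1, by = 0.05)
  vals <- ((1 + grid) / 2)^12
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("TOM equals its brute-force definition on small instances", {
  set.seed(12)
  for (n in c(5, 12, 20)) {
    x <- matrix(rnorm(n * 30), n, dimnames = list(paste0("g", 1:n), NULL))
    adj <- signed_adjacency(bicor_matrix(x), 6)
    tom <- tom_similarity(adj)
    expect_equal(tom, oracle_tom(adj), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(isSymmetric(unname(tom)))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("scale-free fit reports signed R-squared and flags degenerate nets", {
  blocks <- simulate_blocks(n_blocks = 3, block_size = 30, n_samples = 50,
                            rho = 0.7, n_background = 30, seed = 2)
  fit <- scale_free_fit(bicor_matrix(blocks$x), beta_grid = c(2, 6, 12))
  expect_true(all(is.na(fit$r_squared) |
                    (fit$r_squared >= -1 & fit$r_squared <= 1)))
  expect_true(all(fit$mean_connectivity > 0))
  expect_true(all(diff(fit$mean_connectivity) < 0))  # higher beta, sparser
  # equal-weight complete graph has no degree spread
  deg <- scale_free_fit(matrix(0.5, 60, 60) + diag(60) * 0.5,
                        beta_grid = 6)
  expect_true(is.na(deg$r_squared))
})

test_that("planted blocks are recovered as modules; undersized input stays unassigned", {
  blocks <- simulate_blocks(n_blocks = 2, block_size = 60, n_samples = 60,
                            rho = 0.8, seed = 4)
  det <- detect_modules(blocks$x, network_config(min_module_size = 50))
  ari <- adjusted_rand_index(det$modules[names(blocks$truth)], blocks$truth)
  expect_gte(ari, 0.8)
  expect_equal(length(det$sizes), 2L)
  # 40 correlated genes under a min size of 50: all module 0
  small <- simulate_blocks(n_blocks = 1, block_size = 40, n_samples = 50,
                           rho = 0.8, seed = 5)
  expect_warning(
    det0 <- detect_modules(small$x, network_config(min_module_size = 50)),
    "fewer genes")
  expect_true(all(det0$modules == 0))
})

test_that("eigengenes are unit-norm first singular vectors oriented with the module", {
  # identical profiles: eigengene is the shared z-scored profile
  prof <- sin(seq_len(40))
  x <- matrix(rep(prof, each = 6), 6, byrow = FALSE,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:40)))
  x <- x + 0                     # identical rows
  mods <- setNames(rep(1L, 6), rownames(x))
  eig <- compute_eigengenes(x, mods)
  e <- eig$eigengenes[, "ME1"]
  expect_equal(sqrt(sum(e^2)), 1, tolerance = 1e-12)
  zprof <- as.numeric(scale(prof))
  expect_equal(e, zprof / sqrt(sum(zprof^2)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(eig$membership$correlation, rep(1, 6), tolerance = 1e-8)
  # planted one-factor module: eigengene tracks the latent factor
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    f <- rnorm(50)
    m <- t(vapply(1:20, function(i) f + rnorm(50, 0, 0.3), numeric(50)))
    rownames(m) <- paste0("g", 1:20); colnames(m) <- paste0("s", 1:50)
    e2 <- compute_eigengenes(m, setNames(rep(1L, 20), rownames(m)))
    if (abs(cor(e2$eigengenes[, 1], f)) >= 0.9) hits <- hits + 1
  }
  expect_equal(hits, 10L)
  # first-singular-vector optimality: no random unit vector explains more
  set.seed(77)
  z <- t(scale(t(m)))
  var_along <- function(v) sum((z %*% v)^2)
  best <- var_along(e2$eigengenes[, 1])
  rand <- replicate(100, {
    v <- rnorm(50); var_along(v / sqrt(sum(v^2)))
  })
  expect_true(all(rand <= best + 1e-8))
})
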