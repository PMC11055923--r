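test_that("Spearman matrix: monotone invariance and hand-ranked value", {
  set.seed(1)
  x <- rnorm(30)
  m <- cbind(x = x, ex = exp(x), neg = -x)
  cm <- spearmanMatrix(m)
  expect_equal(cm$r["x", "ex"], 1)
  expect_equal(cm$r["x", "neg"], -1)
  expect_equal(diag(cm$r), c(x = 1, ex = 1, neg = 1))
  expect_true(isSymmetric(cm$r))
  cm2 <- spearmanMatrix(cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3)))
  expect_equal(cm2$r["a", "b"], 0.6)
  expect_error(spearmanMatrix(cbind(1:3, 3:1)), "4 observations")
  expect_error(spearmanMatrix(cbind(a = 1:5, flat = rep(2, 5))), "flat")
})

test_that("sign-independent distance identities and Euclidean bound", {
  x <- c(1, -2, 3)
  expect_equal(signIndependentDist(x, -x), 0)
  expect_equal(signIndependentDist(x, x), 0)
  expect_equal(signIndependentDist(c(1, 0), c(0, 1)), sqrt(2))
  expect_error(signIndependentDist(1:3, 1:4), "length mismatch")
  set.seed(2)
  for (i in 1:50) {
    a <- rnorm(10); b <- rnorm(10)
    dsi <- signIndependentDist(a, b)
    deu <- sqrt(sum((a - b)^2))
    expect_lte(dsi, deu + 1e-12)
    if (sum(a * b) >= 0) expect_equal(dsi, deu)
  }
})

test_that("Ward linkage matches a brute-force Lance-Williams oracle", {
  pts <- matrix(c(0, 1, 10), 1)  # 1-D points as columns
  colnames(pts) <- c("p0", "p1", "p10")
  tree <- wardLinkage(pts, metric = "euclidean")
  orc <- oracleWard(dist(c(0, 1, 10)))
  expect_equal(tree$hclust$height, orc$heights, tolerance = 1e-12)
  expect_setequal(tree$hclust$merge[1, ], orc$merges[1, ])
  # first merge pairs the two closest points at their distance
  expect_equal(tree$hclust$height[1], 1)
  # larger random instance against the oracle
  set.seed(3)
  m <- matrix(rnorm(8 * 12), 12)
  tr <- wardLinkage(m)
  or2 <- oracleWard(dist(t(m)))
  expect_equal(tr$hclust$height, or2$heights, tolerance = 1e-9)
  # identical points merge at height zero
  dup <- cbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  expect_equal(wardLinkage(dup)$hclust$height[1], 0)
  # a variable and its negation are merged first under the sign-independent metric
  v <- rnorm(20)
  m2 <- cbind(v = v, negv = -v, other = rnorm(20) + 3)
  tsi <- wardLinkage(m2, metric = "sign_independent")
  expect_equal(tsi$hclust$height[1], 0)
  expect_setequal(tsi$hclust$merge[1, ], c(-1, -2))
})

test_that("Ward heights are monotone and cuts are nested", {
  set.seed(4)
  m <- matrix(rnorm(15 * 30), 30)
  tree <- wardLinkage(m)
  expect_true(all(diff(tree$hclust$height) >= -1e-12))
  prev <- cutClusters(tree, 2)$labels
  for (k in 3:6) {
    cur <- cutClusters(tree, k)$labels
    # nested: items sharing a cluster at k share one at k-1
    for (cl in unique(cur)) {
      expect_equal(length(unique(prev[cur == cl])), 1L)
    }
    prev <- cur
  }
})

test_that("cophenetic coefficient: ultrametric exactness and 3-point oracle", {
  # 3 points with d = (1, 5, 6); Ward merges {1,2} at 1, then 3 at
  # sqrt((2/3)*25 + (2/3)*36 - (1/3)*1)
  d <- stats::as.dist(matrix(c(0, 1, 5, 1, 0, 6, 5, 6, 0), 3))
  tree <- wardLinkage(d, metric = "precomputed")
  h2 <- sqrt((2 / 3) * 25 + (2 / 3) * 36 - (1 / 3) * 1)
  expect_equal(tree$hclust$height, c(1, h2), tolerance = 1e-12)
  coph <- c(1, h2, h2)          # tree-implied pairwise distances
  oracle <- cor(coph, c(1, 5, 6))
  expect_equal(copheneticCoefficient(tree), oracle, tolerance = 1e-12)
  expect_gte(copheneticCoefficient(tree), -1)
  expect_lte(copheneticCoefficient(tree), 1)
  # ultrametric input is reproduced exactly
  du <- stats::as.dist(matrix(c(0, 1, 4, 4,
                                1, 0, 4, 4,
                                4, 4, 0, 2,
                                4, 4, 2, 0), 4))
  treeU <- wardLinkage(du, metric = "precomputed")
  # heights may rescale under Ward, but a perfect hierarchy keeps r = 1 for
  # single linkage; for Ward assert near-perfect rank agreement instead
  expect_gte(copheneticCoefficient(treeU), 0.99)
})

test_that("cutClusters spans k = 1..n and recovers separated groups", {
  pts <- matrix(c(0, 1, 10, 11), 1)
  colnames(pts) <- paste0("p", 1:4)
  tree <- wardLinkage(pts)
  expect_equal(unname(unique(cutClusters(tree, 1)$labels)), 1L)
  expect_equal(length(unique(cutClusters(tree, 4)$labels)), 4L)
  two <- cutClusters(tree, 2)$labels
  expect_equal(two[["p1"]], two[["p2"]])
  expect_equal(two[["p3"]], two[["p4"]])
  expect_false(two[["p1"]] == two[["p3"]])
  expect_error(cutClusters(tree, 0), "out of range")
  expect_error(cutClusters(tree, 5), "out of range")
})

test_that("label separation chi-squared reflects alignment", {
  perfect <- labelSeparationTest(rep(1:2, each = 10),
                                 rep(c("sus", "res"), each = 10))
  expect_equal(perfect$chi2, 20)
  expect_lt(perfect$p, 0.001)
  balanced <- labelSeparationTest(rep(1:2, 10), rep(c("a", "b"), each = 10))
  expect_equal(balanced$chi2, 0)
})

test_that("clustering reliability: no resampling variability at fraction 1", {
  sim <- generateBattery(defaultBatteryConfig(seed = 31))
  Z <- zscores(sim$battery)
  val <- variableInfo(sim$battery)$valence
  out <- clusteringReliability(Z, val, fraction = 1, n_iter = 5, seed = 1)
  expect_equal(length(unique(out$p_values)), 1L)
  expect_equal(out$n_iter, 5)
  expect_true(out$fraction_significant %in% c(0, 1))
})

test_that("clustering reliability separates planted from shuffled data", {
  sim <- generateBattery(defaultBatteryConfig(seed = 32))
  Z <- zscores(sim$battery)
  val <- variableInfo(sim$battery)$valence
  obs <- clusteringReliability(Z, val, n_iter = 60, seed = 2)
  nul <- clusteringReliability(Z, val, n_iter = 60, seed = 2, shuffle = TRUE)
  expect_gte(obs$fraction_significant, 0.5)
  expect_lte(nul$fraction_significant, 0.10)
  # variables axis works too
  vax <- clusteringReliability(Z, val, n_iter = 40, axis = "variables",
                               seed = 3)
  expect_gte(vax$fraction_significant, 0.5)
})

test_that("factor analysis recovers planted block structure", {
  # two orthogonal factors with disjoint loadings
  set.seed(5)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(sapply(1:4, function(i) 0.8 * f1 + 0.5 * rnorm(n)),
             sapply(1:4, function(i) 0.8 * f2 + 0.5 * rnorm(n)))
  colnames(X) <- paste0("v", 1:8)
  fs <- fitFactorModel(X, 2)
  block <- apply(abs(fs$loadings), 1, which.max)
  expect_equal(length(unique(block[1:4])), 1L)
  expect_equal(length(unique(block[5:8])), 1L)
  expect_false(block[1] == block[5])
  # rotation leaves communalities unchanged
  fr <- fitFactorModel(X, 2, rotation = "none")
  expect_equal(sort(fs$communalities), sort(fr$communalities),
               tolerance = 1e-6, ignore_attr = TRUE)
  # loadings reproduce the reduced correlation matrix on exact-factor data
  R <- cor(X)
  fitR <- fs$loadings %*% t(fs$loadings) + diag(fs$uniquenesses)
  expect_lt(max(abs(R - fitR)), 0.05)
})

test_that("seven factors on the 8-test battery are test-dominated", {
  cfg <- noiseConfig(n_ns = 100, n_is = 100, lambda_test = 1,
                     lambda_sus = 0.4)
  sim <- generateBattery(cfg, seed = 6)
  Z <- zscores(sim$battery)
  tests <- variableInfo(sim$battery)$test
  fs <- fitFactorModel(Z, 7)
  dominated <- apply(fs$loadings, 2, function(l) {
    big <- which(abs(l) > 0.4)
    length(big) > 0 && length(unique(tests[big])) == 1
  })
  expect_gte(sum(dominated), 6)
})

test_that("principal-axis fallback is available and sane", {
  set.seed(7)
  R <- cor(matrix(rnorm(200 * 6), 200))
  pa <- StressBattery:::.principalAxis(R, 2)
  expect_equal(dim(pa$loadings), c(6L, 2L))
  expect_true(all(rowSums(pa$loadings^2) <= 1 + 1e-8))
})
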