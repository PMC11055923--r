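test_that("best-of-restarts k-means: planted blobs and closed forms", {
  set.seed(1)
  blob <- rbind(matrix(rnorm(40, 0, 0.5), 20), matrix(rnorm(40, 6, 0.5), 20))
  fit <- kmeansRestarts(blob, 2, n_restarts = 20, seed = 2)
  expect_equal(length(unique(fit$labels[1:20])), 1L)
  expect_equal(length(unique(fit$labels[21:40])), 1L)
  expect_false(fit$labels[1] == fit$labels[21])
  # k = 1: inertia is the total SS around the grand centroid
  one <- kmeansRestarts(blob, 1, seed = 3)
  expect_equal(one$inertia,
               sum(sweep(blob, 2, colMeans(blob))^2), tolerance = 1e-10)
  # k = n: zero inertia
  full <- kmeansRestarts(blob[1:6, ], 6, n_restarts = 5, seed = 4)
  expect_equal(full$inertia, 0, tolerance = 1e-12)
  # more restarts never increase the best inertia
  few <- kmeansRestarts(blob, 3, n_restarts = 1, seed = 5)
  many <- kmeansRestarts(blob, 3, n_restarts = 50, seed = 5)
  expect_lte(many$inertia, few$inertia + 1e-12)
  # determinism
  expect_identical(kmeansRestarts(blob, 2, n_restarts = 10, seed = 6)$labels,
                   kmeansRestarts(blob, 2, n_restarts = 10, seed = 6)$labels)
  expect_error(kmeansRestarts(blob, 0), "out of range")
})

test_that("silhouette: hand example, conventions, and library cross-check", {
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  lab <- c(1, 1, 2, 2)
  s <- silhouetteValues(X, lab)
  # point 0: a = 1, b = (100 + 121)/2 = 110.5 with squared Euclidean
  expect_equal(s$values[1], 109.5 / 110.5, tolerance = 1e-10)
  expect_equal(round(s$values[1], 4), 0.9910)
  # identical points split across clusters: s = 0, flagged
  same <- silhouetteValues(matrix(1, 4, 2), c(1, 1, 2, 2))
  expect_equal(same$values, rep(0, 4))
  expect_true(all(same$flagged))
  # singleton convention s = 1, flagged
  sing <- silhouetteValues(matrix(c(0, 1, 10), 3, 1), c(1, 1, 2))
  expect_equal(sing$values[3], 1)
  expect_true(sing$flagged[3])
  expect_error(silhouetteValues(X, rep(1, 4)), "k >= 2")
  # Euclidean option agrees with cluster::silhouette on a clean case
  set.seed(2)
  Y <- rbind(matrix(rnorm(30), 15), matrix(rnorm(30, 8), 15))
  lab2 <- rep(1:2, each = 15)
  ours <- silhouetteValues(Y, lab2, distance = "euclidean")
  ref <- cluster::silhouette(lab2, dist(Y))[, "sil_width"]
  expect_equal(ours$values, unname(ref), tolerance = 1e-10)
  expect_gt(silhouetteValues(Y, lab2)$mean, 0.9)
})

test_that("helplessness classification follows the higher-failures rule", {
  vals <- matrix(c(0, 10, 0, 10), 2,
                 dimnames = list(NULL, c("sb_escape_failures",
                                         "sb_mean_latency")))
  bat <- toyBattery(vals, group = c("NS", "IS"))
  out <- classifyHelplessness(bat, k_range = 2, n_restarts = 5, seed = 1)
  expect_equal(unname(out$labels), c("NH", "H"))
  expect_equal(out$k, 2L)
  # invariance to affine rescaling of the inputs
  vals2 <- vals; vals2[, 1] <- vals2[, 1] * 100 + 7; vals2[, 2] <- vals2[, 2] / 3
  colnames(vals2) <- colnames(vals)
  out2 <- classifyHelplessness(toyBattery(vals2, group = c("NS", "IS")),
                               k_range = 2, n_restarts = 5, seed = 1)
  expect_equal(out2$labels, out$labels)
  # degenerate identical rats
  flat <- matrix(1, 3, 2, dimnames = list(NULL, colnames(vals)))
  expect_error(classifyHelplessness(toyBattery(flat, group = c("NS", "NS", "IS"))),
               "degenerate")
  # missing variables
  bad <- toyBattery(matrix(rnorm(4), 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(classifyHelplessness(bad), "lacks")
})

test_that("helplessness recovery on the planted generator is high", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    sim <- generateBattery(defaultBatteryConfig(seed = 300 + s))
    out <- classifyHelplessness(sim$battery, n_restarts = 50, seed = s)
    hits <- hits + sum(out$labels == sim$truth$helpless)
    total <- total + length(out$labels)
  }
  expect_gte(hits / total, 0.9)
})

test_that("selectK: silhouette optimum, semi-supervised rule, edge cases", {
  set.seed(3)
  blob3 <- rbind(matrix(rnorm(40, 0, 0.7), 20),
                 matrix(rnorm(40, 6, 0.7), 20),
                 matrix(rnorm(40, 12, 0.7), 20))
  sil <- selectK(blob3, 2:7, n_restarts = 20, seed = 4)
  expect_equal(sil$k, 3)
  # groups aligned with one blob: semi-supervised also lands on 3
  g <- rep(c("A", "A", "B"), each = 20)
  semi <- selectK(blob3, 2:7, mode = "semi_supervised", groups = g,
                  n_restarts = 20, seed = 4)
  expect_equal(semi$k, 3)
  # groups independent of structure: explicit no-selection
  set.seed(5)
  noise <- matrix(rnorm(45 * 5), 45)
  gr <- rep(c("A", "B"), length.out = 45)
  ns <- selectK(noise, 2:7, mode = "semi_supervised", groups = gr,
                n_restarts = 20, seed = 1)
  expect_true(is.na(ns$k))
  expect_equal(nrow(ns$diagnostics), 6)
  # singleton k_range
  expect_equal(selectK(blob3, 2, n_restarts = 10, seed = 6)$k, 2)
  expect_error(selectK(blob3, 2:7, mode = "semi_supervised"), "groups")
})

test_that("hierarchical profiles: planted split, singletons, nesting", {
  cfg <- defaultBatteryConfig(seed = 0)
  sim <- generateBattery(cfg, seed = 310)
  Z <- zscores(sim$battery)
  hp <- hierProfiles(Z, 2)
  # the 2-cut should align with the planted helpless split
  agree <- max(mean((hp$assignment$labels == 1) ==
                      (sim$truth$helpless == "H")),
               mean((hp$assignment$labels == 2) ==
                      (sim$truth$helpless == "H")))
  expect_gte(agree, 0.8)
  n <- nrow(Z)
  expect_equal(length(unique(hierProfiles(Z, n)$assignment$labels)), n)
  k7 <- hierProfiles(Z, 7)$assignment$labels
  k6 <- hierProfiles(Z, 6)$assignment$labels
  for (cl in unique(k7)) {
    expect_equal(length(unique(k6[k7 == cl])), 1L)
  }
})

test_that("hierarchy scan flags group discrimination across cut levels", {
  sim <- generateBattery(defaultBatteryConfig(seed = 311))
  Z <- zscores(sim$battery)
  grp <- groupLabels(sim$battery)
  tree <- hierProfiles(Z, 2)$tree
  scan <- hierarchyScan(tree, grp, k_range = 2:7)
  expect_equal(scan$k, 2:7)
  expect_true(all(scan$p[!scan$degenerate] <= 1))
  expect_lt(scan$p[1], 0.05)  # planted group shift at the top split
  # k = n yields a legal (if weak) table or a flagged degenerate row
  big <- hierarchyScan(tree, grp, k_range = nrow(Z))
  expect_equal(nrow(big), 1L)
})

test_that("cluster profiles summarize Z means, SEM and composition", {
  sim <- generateBattery(defaultBatteryConfig(seed = 312))
  Z <- zscores(sim$battery)
  grp <- groupLabels(sim$battery)
  # single cluster: profile is the (zero) column means
  single <- clusterProfiles(Z, rep(1L, nrow(Z)), grp)
  expect_lt(max(abs(single$mean)), 1e-10)
  expect_equal(single$sizes, nrow(Z))
  expect_equal(sum(single$composition), nrow(Z))
  # singleton cluster: SEM missing
  lab <- c(1L, rep(2L, nrow(Z) - 1))
  prof <- clusterProfiles(Z, lab)
  expect_true(all(is.na(prof$sem[1, ])))
  expect_false(anyNA(prof$sem[2, ]))
  # planted susceptible profile cluster: positive mean on susceptibility
  # variables, negative on resilience variables
  info <- variableInfo(sim$battery)
  # planted cluster 2 carries the susceptible-like offset pattern
  cl <- sim$truth$cluster
  profT <- clusterProfiles(Z, cl)
  susRow <- profT$mean["cluster2", info$valence == "susceptibility"]
  resRow <- profT$mean["cluster2", info$valence == "resilience"]
  expect_gt(mean(susRow), 0.25)
  expect_lt(mean(resRow), -0.25)
})

test_that("cluster correspondence: identity, relabeling, random baseline", {
  a <- sample(1:6, 45, TRUE)
  expect_equal(clusterCorrespondence(a, a)$agreement, 1)
  relab <- c(3L, 1L, 6L, 2L, 4L, 5L)[a]
  expect_equal(clusterCorrespondence(a, relab)$agreement, 1)
  set.seed(6)
  ag <- replicate(15, clusterCorrespondence(sample(1:6, 45, TRUE),
                                            sample(1:6, 45, TRUE))$agreement)
  expect_gt(mean(ag), 1 / 6)      # matching optimizes above chance
  expect_lt(mean(ag), 0.55)       # but stays far from real correspondence
  expect_error(clusterCorrespondence(1:5, 1:4), "different items")
  # jaccard and table shape
  cc <- clusterCorrespondence(rep(1:2, each = 10), rep(c(1, 2), each = 10))
  expect_equal(cc$matching$jaccard, c(1, 1))
})
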