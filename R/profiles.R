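#' Best-of-restarts k-means
#'
#' Lloyd's algorithm with the squared-Euclidean objective, initial centroids
#' drawn uniformly from the observations, repeated `n_restarts` times;
#' returns the restart with the lowest within-cluster sum of squares.
#' Restarts that collapse to an empty cluster are re-drawn. Deterministic
#' given `seed`.
#'
#' @param X observations-by-features numeric matrix.
#' @param k number of clusters, 1 <= k <= n.
#' @param n_restarts number of random restarts.
#' @param seed integer seed.
#' @param iter_max Lloyd iterations per restart.
#' @return list of class `ClusterAssignment`: `labels`, `k`, `centers`,
#'   `inertia` (total within-cluster sum of squares), `silhouette` (filled
#'   by [silhouetteValues()] when k >= 2), `method`.
#' @export
kmeansRestarts <- function(X, k, n_restarts = 100, seed = NULL,
                           iter_max = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k out of range", call. = FALSE)
  withSeed(seed, {
    if (k == 1) {
      ctr <- matrix(colMeans(X), 1)
      inertia <- sum(sweep(X, 2, ctr)^2)
      return(structure(list(labels = setNames(rep(1L, n), rownames(X)),
                            k = 1L, centers = ctr, inertia = inertia,
                            silhouette = NULL, method = "kmeans"),
                       class = "ClusterAssignment"))
    }
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- NULL
      for (attempt in 1:50) {  # re-seed centroids on empty-cluster failures
        init <- X[sample.int(n, k), , drop = FALSE]
        fit <- tryCatch(
          suppressWarnings(kmeans(X, centers = init, iter.max = iter_max,
                                  algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed to converge on any restart",
                            call. = FALSE)
    sil <- if (k >= 2) silhouetteValues(X, best$cluster)$values else NULL
    structure(list(labels = setNames(best$cluster, rownames(X)), k = as.integer(k),
                   centers = best$centers, inertia = best$tot.withinss,
                   silhouette = sil, method = "kmeans"),
              class = "ClusterAssignment")
  })
}

#' Silhouette values
#'
#' Standard per-item silhouette `s_i = (b_i - a_i)/max(a_i, b_i)` with
#' `a_i` the mean distance to the item's own cluster and `b_i` the mean
#' distance to the nearest other cluster. The default distance is squared
#' Euclidean, consistent with the k-means objective; plain Euclidean is
#' available. Conventions for degenerate cases: items in singleton clusters
#' get `s = 1` (flagged), and items with `a = b = 0` (exactly duplicated
#' points split across clusters) get `s = 0` (flagged).
#'
#' @param X observations-by-features matrix.
#' @param labels per-item cluster ids (k >= 2, every cluster nonempty).
#' @param distance `"squared_euclidean"` or `"euclidean"`.
#' @return list: `values` (per item), `mean`, `flagged` (logical per item).
#' @export
silhouetteValues <- function(X, labels,
                             distance = c("squared_euclidean", "euclidean")) {
  distance <- match.arg(distance)
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2) stop("silhouette requires k >= 2", call. = FALSE)
  D <- as.matrix(dist(X))
  if (distance == "squared_euclidean") D <- D^2
  n <- nrow(X)
  s <- numeric(n)
  flagged <- logical(n)
  sizes <- tabulate(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[own] == 1L) { s[i] <- 1; flagged[i] <- TRUE; next }
    a <- sum(D[i, labels == own]) / (sizes[own] - 1)
    b <- min(vapply(setdiff(seq_len(k), own),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    if (a == 0 && b == 0) { s[i] <- 0; flagged[i] <- TRUE; next }
    s[i] <- (b - a) / max(a, b)
  }
  list(values = s, mean = mean(s), flagged = flagged)
}

#' Classify helpless (H) versus non-helpless (NH) rats
#'
#' K-means clustering of rats on the two Z-scored shuttle-box escape
#' measures (number of escape failures and mean escape latency), with the
#' cluster count chosen by mean silhouette over `k_range` (the expected
#' optimum is 2). The cluster with the higher mean escape-failure count is
#' labeled H. Z-scoring makes the classification invariant to affine
#' rescaling of the two inputs.
#'
#' @param battery a [BehavioralBattery-class] containing the two variables.
#' @param failures_var,latency_var variable names.
#' @param k_range candidate cluster numbers for the silhouette scan.
#' @param n_restarts,seed passed to [kmeansRestarts()].
#' @return list: `labels` (named "H"/"NH" per rat), `k`, `assignment`
#'   (the underlying `ClusterAssignment`), `mean_silhouette`.
#' @export
classifyHelplessness <- function(battery,
                                 failures_var = "sb_escape_failures",
                                 latency_var = "sb_mean_latency",
                                 k_range = 2:4, n_restarts = 100,
                                 seed = NULL) {
  vals <- batteryValues(battery)
  miss <- setdiff(c(failures_var, latency_var), colnames(vals))
  if (length(miss)) {
    stop("battery lacks variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sub <- vals[, c(failures_var, latency_var), drop = FALSE]
  if (any(apply(sub, 2, sd) == 0)) {
    stop("degenerate input: constant escape measure(s)", call. = FALSE)
  }
  Zsub <- zscores(sub)
  withSeed(seed, {
    fits <- lapply(k_range, function(k)
      kmeansRestarts(Zsub, k, n_restarts = n_restarts))
    msil <- vapply(fits, function(f) mean(f$silhouette), numeric(1))
    bestIdx <- which.max(msil)
    fit <- fits[[bestIdx]]
    clMeanFail <- tapply(vals[, failures_var], fit$labels, mean)
    hCluster <- as.integer(names(which.max(clMeanFail)))
    labels <- ifelse(fit$labels == hCluster, "H", "NH")
    list(labels = setNames(labels, rownames(vals)), k = fit$k,
         assignment = fit, mean_silhouette = msil[bestIdx],
         silhouette_by_k = setNames(msil, k_range))
  })
}

#' Select the number of clusters
#'
#' Mode `"silhouette"` returns the `k` in `k_range` maximizing the mean
#' silhouette of [kmeansRestarts()]. Mode `"semi_supervised"` additionally
#' requires discrimination of a known two-class grouping: among the
#' candidates whose mean silhouette is within `delta` of the maximum, it
#' returns the *largest* k whose clusters-by-groups chi-squared is
#' significant at `alpha`; if none qualifies the result records
#' `k = NA` (explicit no-selection).
#'
#' @param X observations-by-features matrix.
#' @param k_range candidate cluster counts (within `[2, n-1]`).
#' @param mode `"silhouette"` or `"semi_supervised"`.
#' @param groups per-observation class labels (required for
#'   `"semi_supervised"`).
#' @param delta silhouette tolerance defining the top candidates.
#' @param alpha significance level for the group-discrimination test.
#' @param n_restarts,seed passed to [kmeansRestarts()].
#' @return list: `k` (selected, or NA), `diagnostics` data.frame
#'   (`k, mean_silhouette, chi2_p`), `assignments` (list of
#'   `ClusterAssignment` per candidate k).
#' @export
selectK <- function(X, k_range = 2:7,
                    mode = c("silhouette", "semi_supervised"), groups = NULL,
                    delta = 0.02, alpha = 0.05, n_restarts = 100,
                    seed = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(X) - 1]
  if (!length(k_range)) stop("empty k_range", call. = FALSE)
  if (mode == "semi_supervised" && is.null(groups)) {
    stop("semi_supervised mode requires `groups`", call. = FALSE)
  }
  withSeed(seed, {
    fits <- lapply(k_range, function(k)
      kmeansRestarts(X, k, n_restarts = n_restarts))
    msil <- vapply(fits, function(f) mean(f$silhouette), numeric(1))
    chiP <- rep(NA_real_, length(k_range))
    if (!is.null(groups)) {
      chiP <- vapply(seq_along(fits), function(i) {
        tryCatch(labelSeparationTest(fits[[i]], groups)$p,
                 error = function(e) NA_real_)
      }, numeric(1))
    }
    diag <- data.frame(k = k_range, mean_silhouette = msil, chi2_p = chiP)
    k <- if (mode == "silhouette") {
      k_range[which.max(msil)]
    } else {
      top <- k_range[msil >= max(msil) - delta]
      ok <- top[!is.na(chiP[match(top, k_range)]) &
                  chiP[match(top, k_range)] < alpha]
      if (length(ok)) max(ok) else NA_integer_
    }
    list(k = k, diagnostics = diag, assignments = setNames(fits, k_range))
  })
}

#' Hierarchical profile clustering of rats
#'
#' Ward tree on Euclidean distances between rats' Z-score profiles, cut at
#' `k`. A thin composition of [wardLinkage()] (over rats, i.e. rows) and
#' [cutClusters()].
#'
#' @param Z rats-by-variables Z-scored matrix.
#' @param k number of clusters.
#' @return list: `assignment` (a `ClusterAssignment`), `tree`
#'   (a `LinkageTree` over rats).
#' @export
hierProfiles <- function(Z, k) {
  tree <- wardLinkage(t(as.matrix(Z)), metric = "euclidean")
  list(assignment = cutClusters(tree, k), tree = tree)
}

#' Chi-squared scan over clustering hierarchies
#'
#' Cuts a rats tree at every `k` in `k_range` and tests each cut's
#' clusters-by-groups association.
#'
#' @param tree a `LinkageTree` over rats (e.g. from [hierProfiles()]).
#' @param groups per-rat class labels.
#' @param k_range cluster counts to scan.
#' @return data.frame: `k, chi2, df, p` (NA rows where the table
#'   degenerates, flagged in `degenerate`).
#' @export
hierarchyScan <- function(tree, groups, k_range = 2:7) {
  res <- lapply(k_range, function(k) {
    out <- tryCatch({
      ct <- labelSeparationTest(cutClusters(tree, k), groups)
      data.frame(k = k, chi2 = ct$chi2, df = ct$df, p = ct$p,
                 degenerate = FALSE)
    }, error = function(e) {
      data.frame(k = k, chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                 degenerate = TRUE)
    })
    out
  })
  do.call(rbind, res)
}

#' Per-cluster behavioral profiles
#'
#' Mean Z score and SEM per variable within each cluster, cluster sizes and
#' group composition — the numeric content of a cluster-profile panel.
#' SEM is NA for singleton clusters.
#'
#' @param Z rats-by-variables Z-scored matrix.
#' @param assignment `ClusterAssignment` (or bare cluster id vector) over
#'   the rats.
#' @param groups optional per-rat group labels for the composition table.
#' @return list of class `ClusterProfile`: `mean` and `sem`
#'   (clusters-by-variables matrices), `sizes`, `composition` (clusters by
#'   groups, or NULL).
#' @export
clusterProfiles <- function(Z, assignment, groups = NULL) {
  Z <- as.matrix(Z)
  cl <- if (inherits(assignment, "ClusterAssignment")) assignment$labels
        else assignment
  if (length(cl) != nrow(Z)) stop("assignment does not match rows", call. = FALSE)
  ks <- sort(unique(cl))
  mu <- t(vapply(ks, function(k) colMeans(Z[cl == k, , drop = FALSE]),
                 numeric(ncol(Z))))
  sem <- t(vapply(ks, function(k) {
    sub <- Z[cl == k, , drop = FALSE]
    if (nrow(sub) < 2) rep(NA_real_, ncol(Z))
    else apply(sub, 2, sd) / sqrt(nrow(sub))
  }, numeric(ncol(Z))))
  dimnames(mu) <- dimnames(sem) <- list(paste0("cluster", ks), colnames(Z))
  comp <- if (!is.null(groups)) table(cluster = cl, group = groups) else NULL
  structure(list(mean = mu, sem = sem,
                 sizes = as.integer(table(cl)), composition = comp),
            class = "ClusterProfile")
}

#' @export
print.ClusterProfile <- function(x, ...) {
  cat(sprintf("Cluster profiles: %d clusters, sizes %s\n",
              nrow(x$mean), paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Correspondence between two cluster assignments
#'
#' Cross-tabulates two assignments over the same items, finds the
#' one-to-one cluster matching maximizing the total overlap (exhaustive
#' over permutations of the smaller side, feasible for the k <= 8 regime
#' used here), and reports per-matched-pair Jaccard indices and the overall
#' agreement (matched overlap / n). Invariant to cluster relabeling.
#'
#' @param a,b `ClusterAssignment`s (or bare label vectors) over the same
#'   items.
#' @return list: `table` (contingency), `matching` (data.frame `a, b,
#'   overlap, jaccard`), `agreement`.
#' @export
clusterCorrespondence <- function(a, b) {
  la <- if (inherits(a, "ClusterAssignment")) a$labels else a
  lb <- if (inherits(b, "ClusterAssignment")) b$labels else b
  if (length(la) != length(lb)) stop("assignments cover different items",
                                     call. = FALSE)
  if (!is.null(names(la)) && !is.null(names(lb)) &&
      !identical(names(la), names(lb))) {
    stop("assignments cover different items", call. = FALSE)
  }
  tab <- table(a = la, b = lb)
  ka <- nrow(tab); kb <- ncol(tab)
  swap <- ka > kb
  m <- if (swap) t(tab) else tab
  perms <- .permutations(ncol(m))
  best <- NULL; bestSum <- -1
  for (p in perms) {
    cols <- p[seq_len(nrow(m))]
    s <- sum(m[cbind(seq_len(nrow(m)), cols)])
    if (s > bestSum) { bestSum <- s; best <- cols }
  }
  rows <- rownames(m)[seq_len(nrow(m))]
  cols <- colnames(m)[best]
  jac <- vapply(seq_along(rows), function(i) {
    ov <- m[i, best[i]]
    ov / (sum(m[i, ]) + sum(m[, best[i]]) - ov)
  }, numeric(1))
  matching <- if (swap) {
    data.frame(a = cols, b = rows, overlap = m[cbind(seq_along(rows), best)],
               jaccard = jac, stringsAsFactors = FALSE)
  } else {
    data.frame(a = rows, b = cols, overlap = m[cbind(seq_along(rows), best)],
               jaccard = jac, stringsAsFactors = FALSE)
  }
  list(table = tab, matching = matching,
       agreement = bestSum / length(la))
}

# all permutations of 1..n (n <= 8 here)
.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
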