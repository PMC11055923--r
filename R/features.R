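#' Pairwise Spearman correlation matrix with p values
#'
#' Spearman rho (mid-ranks for ties) between every pair of columns, with
#' two-sided p values from [stats::cor.test()].
#'
#' @param Z numeric matrix (rats by variables), >= 4 rows, no constant
#'   columns.
#' @return list of class `CorrelationMatrix` with symmetric matrices `r`
#'   and `p`.
#' @export
spearmanMatrix <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 4) stop("need at least 4 observations", call. = FALSE)
  sds <- apply(Z, 2, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(Z)[sds == 0], collapse = ", "), call. = FALSE)
  }
  P <- ncol(Z)
  r <- cor(Z, method = "spearman")
  p <- matrix(0, P, P, dimnames = dimnames(r))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      pv <- suppressWarnings(
        cor.test(Z[, i], Z[, j], method = "spearman", exact = FALSE))$p.value
      p[i, j] <- p[j, i] <- pv
    }
  }
  structure(list(r = r, p = p), class = "CorrelationMatrix")
}

#' Sign-independent Euclidean distance
#'
#' `min(||x - y||, ||x + y||)`: the distance between two Z-scored variable
#' vectors ignoring the sign of their association, so a variable and its
#' negation are at distance zero. Used to cluster variables by strength of
#' (anti-)covariation, e.g. when grouping variables by test membership.
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar.
#' @examples
#' signIndependentDist(c(1, 0), c(0, 1))  # sqrt(2)
#' @export
signIndependentDist <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  min(sqrt(sum((x - y)^2)), sqrt(sum((x + y)^2)))
}

#' Pairwise sign-independent distances
#'
#' @param m numeric matrix; distances between *columns* (variables).
#' @return a `dist` object over the columns of `m`.
#' @export
signIndependentDistMatrix <- function(m) {
  m <- as.matrix(m)
  P <- ncol(m)
  d <- matrix(0, P, P, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      d[i, j] <- d[j, i] <- signIndependentDist(m[, i], m[, j])
    }
  }
  stats::as.dist(d)
}

#' Ward agglomerative clustering
#'
#' Ward minimum-variance linkage (Lance-Williams update on squared
#' dissimilarities, heights reported on the dissimilarity scale, i.e.
#' `hclust(method = "ward.D2")`). Items are the *columns* of `items` for
#' metrics `"euclidean"` and `"sign_independent"`; pass a precomputed `dist`
#' with `metric = "precomputed"`. For the sign-independent metric the
#' Lance-Williams update is applied as if the dissimilarities were
#' Euclidean (an approximation, since that metric is not embeddable).
#' Tie-breaking is deterministic (lowest index pair first, as in hclust).
#'
#' @param items numeric matrix (observations by items) or a `dist`.
#' @param metric `"euclidean"`, `"sign_independent"` or `"precomputed"`.
#' @return list of class `LinkageTree`: `hclust` (the stats::hclust object),
#'   `merges` (n-1 x 3 matrix: the two merged nodes in hclust convention and
#'   the merge height), `labels`, `metric`, `dist` (the dissimilarities
#'   used).
#' @export
wardLinkage <- function(items, metric = c("euclidean", "sign_independent",
                                          "precomputed")) {
  metric <- match.arg(metric)
  d <- switch(metric,
    euclidean = dist(t(as.matrix(items))),
    sign_independent = signIndependentDistMatrix(items),
    precomputed = {
      if (!inherits(items, "dist")) items <- stats::as.dist(as.matrix(items))
      items
    })
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (attr(d, "Size") < 2) stop("need at least 2 items", call. = FALSE)
  hc <- hclust(d, method = "ward.D2")
  structure(list(hclust = hc,
                 merges = cbind(hc$merge, height = hc$height),
                 labels = hc$labels, metric = metric, dist = d),
            class = "LinkageTree")
}

#' @export
print.LinkageTree <- function(x, ...) {
  cat(sprintf("Ward linkage tree: %d leaves (%s metric), max height %.3f\n",
              length(x$hclust$order), x$metric, max(x$hclust$height)))
  invisible(x)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the cophenetic distances implied by a linkage
#' tree and the original pairwise dissimilarities; values near 1 indicate
#' the dendrogram faithfully represents the input distances.
#'
#' @param tree a `LinkageTree` from [wardLinkage()].
#' @param d optional original dissimilarities (`dist`); defaults to the ones
#'   the tree was built from.
#' @return single numeric correlation in `[-1, 1]`.
#' @export
copheneticCoefficient <- function(tree, d = NULL) {
  if (is.null(d)) d <- tree$dist
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (attr(d, "Size") < 3) stop("need at least 3 items", call. = FALSE)
  cph <- cophenetic(tree$hclust)
  cor(as.vector(cph), as.vector(d))
}

#' Cut a linkage tree into k clusters
#'
#' Cuts below the k-1 tallest merges, yielding exactly `k` clusters.
#'
#' @param tree a `LinkageTree`.
#' @param k number of clusters, 1 <= k <= n.
#' @return list of class `ClusterAssignment`: `labels` (named integer
#'   vector), `k`, `method`.
#' @export
cutClusters <- function(tree, k) {
  n <- length(tree$hclust$order)
  if (k < 1 || k > n) stop("k out of range", call. = FALSE)
  labels <- cutree(tree$hclust, k = k)
  structure(list(labels = labels, k = k, method = "hierarchical/ward",
                 silhouette = NULL),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("%s clustering: k = %d, sizes %s\n", x$method, x$k,
              paste(table(x$labels), collapse = "/")))
  if (!is.null(x$silhouette)) {
    cat(sprintf("  mean silhouette = %.3f\n", mean(x$silhouette)))
  }
  invisible(x)
}

#' Chi-squared test of clusters against known classes
#'
#' Cross-tabulates a cluster assignment with a categorical label (e.g.
#' variable valence, or rat group) and applies [chisqAssociation()].
#'
#' @param assignment a `ClusterAssignment` (or bare vector of cluster ids).
#' @param labels per-item categorical labels.
#' @return a `ContingencyResult`.
#' @export
labelSeparationTest <- function(assignment, labels) {
  cl <- if (inherits(assignment, "ClusterAssignment")) assignment$labels
        else assignment
  if (length(cl) != length(labels)) stop("length mismatch", call. = FALSE)
  chisqAssociation(table(cluster = cl, class = labels))
}

#' Subsampling permutation reliability of valence feature clustering
#'
#' Repeats the feature-clustering pipeline (Ward tree over variables, cut at
#' 2, chi-squared of cluster vs. label) on random subsets of the data —
#' `fraction` of the rats (`axis = "observations"`) or of the variables
#' (`axis = "variables"`) per iteration — and reports the fraction of
#' iterations whose separation test is significant at `alpha`. Running the
#' same procedure on a column-shuffled copy of the data (null_kind
#' `"shuffled"`) calibrates the null: covariance is destroyed, so the
#' separation should almost never be significant.
#'
#' Iterations whose subsampled table degenerates (a cluster or label class
#' absent) are counted as non-significant (conservative).
#'
#' @param Z rats-by-variables Z-scored matrix.
#' @param labels per-variable class labels (e.g. valence).
#' @param fraction subsample fraction.
#' @param axis `"observations"` or `"variables"`.
#' @param n_iter iterations.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param metric clustering metric, see [wardLinkage()].
#' @param shuffle run on a shuffled copy of `Z` (the null) instead.
#' @return list of class `PermutationSummary`: `n_iter`,
#'   `fraction_significant`, `alpha`, `null_kind`, `p_values`, `n_skipped`.
#' @export
clusteringReliability <- function(Z, labels, fraction = 0.7,
                                  axis = c("observations", "variables"),
                                  n_iter = 100, alpha = 0.05, seed = NULL,
                                  metric = "euclidean", shuffle = FALSE) {
  axis <- match.arg(axis)
  Z <- as.matrix(Z)
  stopifnot(length(labels) == ncol(Z), n_iter >= 1)
  withSeed(seed, {
    pvals <- rep(NA_real_, n_iter)
    nskip <- 0L
    for (it in seq_len(n_iter)) {
      # a fresh shuffle per iteration, so the null summary estimates the
      # false-positive rate rather than the behavior of one random dataset
      Zit <- if (shuffle) shuffleData(Z) else Z
      sub <- subsampleData(Zit, fraction = fraction, axis = axis)
      m <- sub$data
      labs <- if (axis == "variables") labels[sub$index] else labels
      p <- tryCatch({
        keep <- apply(m, 2, sd) > 0
        m2 <- m[, keep, drop = FALSE]
        labs2 <- labs[keep]
        tree <- wardLinkage(m2, metric = metric)
        cut2 <- cutClusters(tree, 2)
        labelSeparationTest(cut2, labs2)$p
      }, error = function(e) NA_real_)
      if (is.na(p)) nskip <- nskip + 1L
      pvals[it] <- p
    }
    frac <- sum(!is.na(pvals) & pvals < alpha) / n_iter
    structure(list(n_iter = n_iter, fraction_significant = frac,
                   alpha = alpha,
                   null_kind = if (shuffle) "shuffled" else "subsample",
                   p_values = pvals, n_skipped = nskip),
              class = "PermutationSummary")
  })
}

#' @export
print.PermutationSummary <- function(x, ...) {
  cat(sprintf("%s permutation: %.2f%% of %d iterations significant at alpha = %g\n",
              x$null_kind, 100 * x$fraction_significant, x$n_iter, x$alpha))
  invisible(x)
}

#' Common factor analysis with varimax rotation
#'
#' Maximum-likelihood common-factor model via [stats::factanal()] with
#' iterative pairwise varimax rotation; on non-convergence, falls back to
#' principal-axis factoring (iterated communalities on the reduced
#' correlation matrix) followed by [stats::varimax()]. Uniquenesses at the
#' optimizer's lower bound are flagged as Heywood cases. Rotation is
#' orthogonal, so per-variable communalities are unchanged by it.
#'
#' @param Z rats-by-variables matrix (standardized internally).
#' @param n_factors number of factors, < number of variables.
#' @param rotation `"varimax"` or `"none"`.
#' @return list of class `FactorSolution`: `loadings` (variables x factors),
#'   `uniquenesses`, `communalities`, `rotation`, `method`, `heywood`
#'   (logical per variable), `converged`.
#' @export
fitFactorModel <- function(Z, n_factors, rotation = c("varimax", "none")) {
  rotation <- match.arg(rotation)
  Z <- as.matrix(Z)
  if (n_factors >= ncol(Z)) stop("n_factors must be < number of variables",
                                 call. = FALSE)
  ml <- tryCatch(
    factanal(Z, factors = n_factors, rotation = rotation,
             control = list(nstart = 3)),
    error = function(e) NULL)
  if (!is.null(ml)) {
    L <- matrix(as.numeric(ml$loadings), ncol = n_factors,
                dimnames = list(colnames(Z),
                                paste0("F", seq_len(n_factors))))
    uniq <- ml$uniquenesses
    method <- "ml"
    converged <- TRUE
  } else {
    pa <- .principalAxis(cor(Z), n_factors)
    L <- pa$loadings
    if (rotation == "varimax" && n_factors > 1) {
      L <- stats::varimax(L, normalize = FALSE)$loadings
      L <- matrix(as.numeric(L), ncol = n_factors,
                  dimnames = list(colnames(Z),
                                  paste0("F", seq_len(n_factors))))
    }
    uniq <- 1 - rowSums(L^2)
    method <- "principal-axis"
    converged <- pa$converged
  }
  uniq <- pmax(uniq, 0)
  structure(list(loadings = L, uniquenesses = uniq,
                 communalities = 1 - uniq, rotation = rotation,
                 method = method,
                 heywood = uniq <= 0.005 + 1e-12, converged = converged),
            class = "FactorSolution")
}

# Iterated principal-axis factoring on a correlation matrix.
.principalAxis <- function(R, k, max_iter = 200, tol = 1e-6) {
  h2 <- 1 - 1 / diag(solve(R))  # SMC start
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    eg <- eigen(Rr, symmetric = TRUE)
    val <- pmax(eg$values[seq_len(k)], 0)
    L <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(val), k)
    h2new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2new - h2)) < tol) { h2 <- h2new; converged <- TRUE; break }
    h2 <- h2new
  }
  dimnames(L) <- list(rownames(R), paste0("F", seq_len(k)))
  list(loadings = L, converged = converged)
}

#' @export
print.FactorSolution <- function(x, ...) {
  cat(sprintf("%d-factor solution (%s extraction, %s rotation)\n",
              ncol(x$loadings), x$method, x$rotation))
  if (any(x$heywood)) {
    cat("  Heywood-flagged variables:",
        paste(names(which(x$heywood)), collapse = ", "), "\n")
  }
  invisible(x)
}
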