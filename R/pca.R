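#' Principal component analysis via SVD
#'
#' PCA of a column-centered matrix through singular value decomposition.
#' Components are ordered by decreasing explained variance and signed so
#' that each component's largest-magnitude coefficient is positive (a fixed
#' convention making coefficient tables reproducible; SVD signs are
#' otherwise arbitrary). Rank-deficient input is allowed: trailing
#' components carry 0% variance.
#'
#' @param Z rats-by-variables numeric matrix (typically Z-scored). Centered
#'   internally; not rescaled.
#' @return list of class `PCAResult`: `coefficients` (variables x
#'   components, orthonormal), `scores` (rats x components), `sdev`,
#'   `explained_pct`, `sign_convention`.
#' @export
pcaFit <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2) stop("need at least 2 observations", call. = FALSE)
  sds <- apply(Z, 2, sd)
  if (any(sds == 0)) stop("constant column(s) in PCA input", call. = FALSE)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  sv <- svd(Zc)
  ncomp <- ncol(Z)
  coef <- sv$v
  d <- sv$d
  if (length(d) < ncomp) {  # wide case: pad (not expected for n > P)
    coef <- cbind(coef, matrix(0, ncomp, ncomp - ncol(coef)))
    d <- c(d, rep(0, ncomp - length(d)))
  }
  # sign convention: largest |coefficient| entry positive
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(coef[, j]))
    if (coef[i, j] < 0) coef[, j] <- -coef[, j]
  }
  scores <- Zc %*% coef
  vars <- d^2 / (nrow(Z) - 1)
  expl <- 100 * vars / sum(vars)
  dimnames(coef) <- list(colnames(Z), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(Z), paste0("PC", seq_len(ncomp)))
  structure(list(coefficients = coef, scores = scores,
                 sdev = sqrt(vars), explained_pct = expl,
                 sign_convention = "largest-coefficient-positive",
                 center = attr(Zc, "scaled:center")),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  k <- min(5L, length(x$explained_pct))
  cat("PCA:", paste(sprintf("PC%d %.2f%%", seq_len(k), x$explained_pct[seq_len(k)]),
                    collapse = ", "),
      if (length(x$explained_pct) > k) "..." else "", "\n")
  invisible(x)
}

#' Shuffled-data null for PCA explained variance
#'
#' Repeatedly column-shuffles the data (destroying covariance, preserving
#' marginals), recomputes the PCA, and flags the observed components whose
#' explained-variance percentage exceeds the null's `prob` quantile — the
#' permutation analogue of parallel analysis.
#'
#' @param Z rats-by-variables matrix.
#' @param n_iter number of shuffles (>= 100 recommended).
#' @param seed integer seed.
#' @param prob null quantile (default 0.95).
#' @return list: `observed_pct`, `null_quantile`, `flagged` (logical per
#'   component), `null_pct` (n_iter x components matrix).
#' @export
pcaShuffledNull <- function(Z, n_iter = 100, seed = NULL, prob = 0.95) {
  Z <- as.matrix(Z)
  obs <- pcaFit(Z)$explained_pct
  withSeed(seed, {
    nullPct <- matrix(NA_real_, n_iter, length(obs))
    for (it in seq_len(n_iter)) {
      nullPct[it, ] <- pcaFit(shuffleData(Z))$explained_pct
    }
    qs <- apply(nullPct, 2, quantile, probs = prob)
    list(observed_pct = obs, null_quantile = qs, flagged = obs > qs,
         null_pct = nullPct, prob = prob)
  })
}

#' Split-data reliability of principal components
#'
#' Per iteration, subsamples `fraction` of the rats, recomputes the PCA, and
#' matches every full-data component to the subsample component with the
#' highest absolute Pearson correlation — coefficients compared over all
#' variables, scores over the shared rats. Reports the median of these
#' per-iteration maxima for each component. For the null, each iteration
#' instead draws a fresh column-shuffled copy of the data before
#' subsampling, and its components are matched against the same observed
#' full-data components: the null medians estimate how similar the
#' components of covariance-free data look by chance.
#'
#' @param Z rats-by-variables matrix.
#' @param fraction subsample fraction of rats.
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param n_components how many leading full-data components to track
#'   (default all).
#' @param with_null also compute the shuffled-data null medians.
#' @return list of class `PCReliability`: `coeff_median`, `score_median`,
#'   and when `with_null` the same for the shuffled data
#'   (`coeff_median_shuffled`, `score_median_shuffled`).
#' @export
pcaReliability <- function(Z, fraction = 0.7, n_iter = 100, seed = NULL,
                           n_components = NULL, with_null = TRUE) {
  Z <- as.matrix(Z)
  if (is.null(n_components)) n_components <- ncol(Z)
  full <- pcaFit(Z)
  run <- function(shuffle) {
    coefMax <- matrix(NA_real_, n_iter, n_components)
    scoreMax <- matrix(NA_real_, n_iter, n_components)
    for (it in seq_len(n_iter)) {
      mat <- if (shuffle) shuffleData(Z) else Z
      sub <- subsampleData(mat, fraction = fraction, axis = "observations")
      part <- tryCatch(pcaFit(sub$data), error = function(e) NULL)
      if (is.null(part)) next
      cc <- abs(cor(full$coefficients[, seq_len(n_components), drop = FALSE],
                    part$coefficients))
      sc <- abs(cor(full$scores[sub$index, seq_len(n_components), drop = FALSE],
                    part$scores))
      coefMax[it, ] <- apply(cc, 1, max, na.rm = TRUE)
      scoreMax[it, ] <- apply(sc, 1, max, na.rm = TRUE)
    }
    list(coeff = apply(coefMax, 2, median, na.rm = TRUE),
         score = apply(scoreMax, 2, median, na.rm = TRUE))
  }
  withSeed(seed, {
    obs <- run(shuffle = FALSE)
    out <- list(coeff_median = obs$coeff, score_median = obs$score,
                fraction = fraction, n_iter = n_iter)
    if (with_null) {
      nul <- run(shuffle = TRUE)
      out$coeff_median_shuffled <- nul$coeff
      out$score_median_shuffled <- nul$score
    }
    structure(out, class = "PCReliability")
  })
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of each
#' column on all the others. Values above `threshold` (default 1.1, a
#' deliberately strict screen for choosing near-independent representative
#' variables) are flagged; perfect collinearity yields `Inf`.
#'
#' @param Z rats-by-variables matrix with more rows than columns.
#' @param threshold flag level.
#' @return data.frame: `variable`, `vif`, `flagged`.
#' @export
vifScores <- function(Z, threshold = 1.1) {
  Z <- as.matrix(Z)
  if (nrow(Z) <= ncol(Z)) stop("need more observations than variables",
                               call. = FALSE)
  P <- ncol(Z)
  if (P < 2) stop("need at least 2 variables", call. = FALSE)
  vif <- vapply(seq_len(P), function(j) {
    fit <- lm(Z[, j] ~ Z[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # warns on perfect fits
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  nm <- colnames(Z)
  if (is.null(nm)) nm <- paste0("V", seq_len(P))
  data.frame(variable = nm, vif = vif, flagged = vif > threshold,
             stringsAsFactors = FALSE)
}

#' Per-component group comparison of PC scores
#'
#' Applies [compareGroups()] (auto route by default) to every component's
#' scores, contrasting the two groups.
#'
#' @param scores rats-by-components score matrix.
#' @param groups per-rat group labels (exactly two levels).
#' @param route passed to [compareGroups()].
#' @return data.frame: component, statistic, route, p.
#' @export
pcGroupComparison <- function(scores, groups, route = "auto") {
  scores <- as.matrix(scores)
  g <- as.character(groups)
  lv <- unique(g)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  res <- lapply(seq_len(ncol(scores)), function(j) {
    cmp <- compareGroups(scores[g == lv[1L], j], scores[g == lv[2L], j],
                         route = route)
    data.frame(component = colnames(scores)[j] %||% paste0("PC", j),
               statistic = cmp$statistic, route = cmp$route, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-class linear discriminant with pooled covariance; pseudo-inverse when
# the pooled covariance is singular. Returns a prediction function.
.ldaTrain <- function(X, y) {
  lv <- sort(unique(y))
  X1 <- X[y == lv[1L], , drop = FALSE]
  X2 <- X[y == lv[2L], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  S1 <- if (n1 > 1) (n1 - 1) * cov(X1) else matrix(0, ncol(X), ncol(X))
  S2 <- if (n2 > 1) (n2 - 1) * cov(X2) else matrix(0, ncol(X), ncol(X))
  Sp <- (S1 + S2) / (n1 + n2 - 2)
  Si <- tryCatch(solve(Sp), error = function(e) MASS::ginv(Sp))
  w <- Si %*% (m2 - m1)
  # threshold includes the log prior odds (training proportions)
  c0 <- as.numeric(t(w) %*% (m1 + m2) / 2) - log(n2 / n1)
  function(Xn) {
    proj <- as.numeric(as.matrix(Xn) %*% w)
    ifelse(proj > c0, lv[2L], lv[1L])
  }
}

#' Cross-validated LDA accuracy on cumulative PC sets
#'
#' For each cumulative component set (PC1..k, k in `ks`), estimates the mean
#' test accuracy of a two-class linear discriminant (pooled covariance, no
#' shrinkage; pseudo-inverse if singular) over `n_iter` random
#' unstratified train/test splits (`train_frac` training fraction; a split
#' is redrawn if a class is absent from the training set). The identical
#' procedure on a column-shuffled copy of the scores gives the null
#' accuracies, and the permutation p value for each set is
#' `(1 + #\{null iterations >= observed mean\}) / (n_iter + 1)`.
#'
#' @param scores rats-by-components PC score matrix.
#' @param labels two-class per-rat labels (e.g. H/NH).
#' @param ks cumulative set sizes (default `2:ncol(scores)`; `1` allowed).
#' @param n_iter train/test iterations per set.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list of class `LDAEvaluation` with data.frame `results`
#'   (`k, accuracy, accuracy_shuffled, p`) and the per-iteration accuracy
#'   matrices.
#' @export
ldaCumulativeAccuracy <- function(scores, labels, ks = NULL, n_iter = 1000,
                                  train_frac = 0.7, seed = NULL) {
  X <- as.matrix(scores)
  y <- as.character(labels)
  if (length(unique(y)) != 2) stop("labels must have exactly two classes",
                                   call. = FALSE)
  if (min(table(y)) < 2) stop("both classes need >= 2 members", call. = FALSE)
  if (is.null(ks)) ks <- 2:ncol(X)
  ks <- ks[ks >= 1 & ks <= ncol(X)]
  n <- nrow(X)
  ntrain <- roundHalfUp(train_frac * n)
  iterAccuracy <- function(Xk, it_seed_offset = 0) {
    acc <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      repeat {
        tr <- sample.int(n, ntrain)
        if (length(unique(y[tr])) == 2) break
      }
      pred <- .ldaTrain(Xk[tr, , drop = FALSE], y[tr])
      te <- setdiff(seq_len(n), tr)
      acc[it] <- mean(pred(Xk[te, , drop = FALSE]) == y[te])
    }
    acc
  }
  withSeed(seed, {
    Xshuf <- shuffleData(X)
    obsAcc <- matrix(NA_real_, n_iter, length(ks))
    nullAcc <- matrix(NA_real_, n_iter, length(ks))
    for (i in seq_along(ks)) {
      k <- ks[i]
      obsAcc[, i] <- iterAccuracy(X[, seq_len(k), drop = FALSE])
      nullAcc[, i] <- iterAccuracy(Xshuf[, seq_len(k), drop = FALSE])
    }
    res <- data.frame(
      k = ks,
      accuracy = colMeans(obsAcc),
      accuracy_shuffled = colMeans(nullAcc),
      p = vapply(seq_along(ks), function(i) {
        (1 + sum(nullAcc[, i] >= mean(obsAcc[, i]))) / (n_iter + 1)
      }, numeric(1)))
    structure(list(results = res, accuracy_iters = obsAcc,
                   null_iters = nullAcc, n_iter = n_iter,
                   train_frac = train_frac),
              class = "LDAEvaluation")
  })
}

#' @export
print.LDAEvaluation <- function(x, ...) {
  cat("LDA on cumulative PC sets:\n")
  print(x$results, row.names = FALSE, digits = 3)
  invisible(x)
}
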