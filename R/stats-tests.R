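#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the standardized sample `(x - mean)/sd` against the
#' standard normal. With `lilliefors = TRUE` the Lilliefors correction for
#' estimated parameters is applied instead (via [nortest::lillie.test()]);
#' the plain KS p value is conservative when mean and SD are fitted, which
#' is acceptable for routing between parametric and non-parametric group
#' comparisons.
#'
#' @param x numeric sample, n >= 4.
#' @param lilliefors use the Lilliefors-corrected test.
#' @return list with `statistic`, `p`, `method` (class `TestResult`).
#' @export
ksNormality <- function(x, lilliefors = FALSE) {
  x <- as.numeric(na.omit(x))
  if (length(x) < 4) stop("ksNormality requires n >= 4", call. = FALSE)
  if (sd(x) == 0) stop("constant sample", call. = FALSE)
  if (lilliefors) {
    kt <- nortest::lillie.test(x)
    res <- list(statistic = unname(kt$statistic), df = NA_real_,
                p = kt$p.value, method = "Lilliefors KS")
  } else {
    kt <- suppressWarnings(ks.test((x - mean(x)) / sd(x), "pnorm"))
    res <- list(statistic = unname(kt$statistic), df = NA_real_,
                p = kt$p.value, method = "one-sample KS vs N(0,1)")
  }
  structure(res, class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n", x$method, x$statistic, x$p))
  invisible(x)
}

#' Two-group comparison with normality routing
#'
#' Compares two independent samples. Route `"t"` is Student's two-sample
#' t-test (pooled variance, df = nx + ny - 2). Route `"ranksum"` is the
#' Wilcoxon rank-sum test; the reported `statistic` is the rank sum of the
#' first sample, with the Mann-Whitney `U` alongside, and the p value uses
#' exact enumeration when `min(n) <= 10` and there are no ties, otherwise
#' the tie-corrected normal approximation with continuity correction. Route
#' `"auto"` (default) uses the t-test when both groups pass [ksNormality()]
#' at `alpha_normal`, and the rank-sum test otherwise (groups smaller than 4
#' are treated as passing).
#'
#' @param x,y numeric samples.
#' @param route `"auto"`, `"t"` or `"ranksum"`.
#' @param alpha_normal normality-screen level for the auto route.
#' @return `TestResult` list: `statistic`, `df`, `p`, `method`, `route`,
#'   plus `U` for the rank-sum route.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6), route = "ranksum")$statistic  # 6
#' @export
compareGroups <- function(x, y, route = c("auto", "t", "ranksum"),
                          alpha_normal = 0.05) {
  route <- match.arg(route)
  x <- as.numeric(na.omit(x)); y <- as.numeric(na.omit(y))
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (route == "auto") {
    normalOk <- function(v) {
      if (length(v) < 4 || sd(v) == 0) return(TRUE)
      ksNormality(v)$p > alpha_normal
    }
    route <- if (normalOk(x) && normalOk(y)) "t" else "ranksum"
  }
  if (route == "t") {
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      res <- list(statistic = 0, df = length(x) + length(y) - 2, p = 1,
                  method = "Student t (pooled)", route = "t")
      return(structure(res, class = "TestResult"))
    }
    tt <- t.test(x, y, var.equal = TRUE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, method = "Student t (pooled)", route = "t")
  } else {
    nx <- length(x)
    hasTies <- anyDuplicated(c(x, y)) > 0
    exact <- min(nx, length(y)) <= 10 && !hasTies
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    U <- unname(wt$statistic)              # Mann-Whitney U of the first sample
    W1 <- U + nx * (nx + 1) / 2            # rank sum of the first sample
    res <- list(statistic = W1, df = NA_real_, p = wt$p.value,
                method = if (exact) "Wilcoxon rank-sum (exact)"
                         else "Wilcoxon rank-sum (normal approx.)",
                route = "ranksum", U = U)
  }
  structure(res, class = "TestResult")
}

#' Levene test for equality of variances (mean-centered)
#'
#' One-way ANOVA on absolute deviations from the respective group means.
#'
#' @param x,y numeric samples, each n >= 2.
#' @return `TestResult` with the F statistic (`W`), df pair and p value.
#' @export
leveneVariance <- function(x, y) {
  x <- as.numeric(na.omit(x)); y <- as.numeric(na.omit(y))
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  d <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (sd(d) == 0) {
    res <- list(statistic = 0, df = c(1, length(d) - 2), p = 1,
                method = "Levene (mean-centered)")
    return(structure(res, class = "TestResult"))
  }
  fit <- anova(lm(d ~ g))
  structure(list(statistic = fit$`F value`[1L],
                 df = c(fit$Df[1L], fit$Df[2L]),
                 p = fit$`Pr(>F)`[1L],
                 method = "Levene (mean-centered)"),
            class = "TestResult")
}

#' Pearson chi-squared test of association
#'
#' Pearson chi-squared on a contingency table of counts, without continuity
#' correction, df = (r-1)(c-1). Errors on zero marginals (expected counts
#' must all be positive).
#'
#' @param table integer matrix of observed counts.
#' @return list of class `ContingencyResult`: `observed`, `expected`,
#'   `chi2`, `df`, `p`.
#' @examples
#' # helpless/non-helpless vs shocked/non-shocked worked example
#' chisqAssociation(matrix(c(20, 8, 3, 14), 2))$chi2  # 12.2443
#' @export
chisqAssociation <- function(table) {
  tab <- as.matrix(table)
  .assertCount(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column marginal", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(observed = tab, expected = ct$expected,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("chi-squared = %.4f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Cohen's kappa for two label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two equally
#' long categorical sequences (e.g. second-by-second behavioral event codes
#' from two raters), with expected agreement from the marginal label
#' frequencies. When both raters are constant and identical (`p_e = 1`)
#' kappa is defined as 1.
#'
#' @param a,b vectors of labels, equal length.
#' @return single numeric kappa in `[-1, 1]`.
#' @examples
#' cohensKappa(rep(c("x", "y"), c(25, 25)),
#'             rep(c("x", "y", "x", "y"), c(20, 5, 10, 15)))  # 0.4
#' @export
cohensKappa <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have equal length", call. = FALSE)
  a <- as.character(a); b <- as.character(b)
  labs <- sort(unique(c(a, b)))
  tab <- table(factor(a, labs), factor(b, labs))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' ICC(2,1): two-way random effects, single measure, absolute agreement
#'
#' Intraclass correlation of absolute agreement from the two-way ANOVA mean
#' squares of a complete subjects-by-raters matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` subjects, `k` raters, row (subject), column (rater) and residual
#' mean squares. Systematic rater offsets lower the coefficient (absolute
#' agreement, not consistency). Values at or below 0 indicate no
#' between-subject variance beyond noise and are returned as computed.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns.
#' @return single numeric value (<= 1).
#' @export
iccAbsolute <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings must be complete", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  rowM <- rowMeans(m); colM <- colMeans(m); grand <- mean(m)
  SSR <- k * sum((rowM - grand)^2)
  SSC <- n * sum((colM - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (denom == 0) return(1)  # all cells identical
  (MSR - MSE) / denom
}

#' Pearson correlation
#'
#' Sample Pearson correlation between two non-constant vectors (n >= 3).
#'
#' @param x,y numeric vectors.
#' @return single numeric correlation.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)
  cor(x, y)
}

#' Univariate battery comparison table
#'
#' Applies [compareGroups()] (auto route) and [leveneVariance()] to every
#' variable of a battery, contrasting the NS and IS groups — the standard
#' per-variable summary table of a battery experiment.
#'
#' @param battery a [BehavioralBattery-class].
#' @return data.frame: variable, test, valence, statistic, route, p,
#'   levene_W, levene_p.
#' @export
univariateBattery <- function(battery) {
  vals <- batteryValues(battery)
  grp <- groupLabels(battery)
  info <- variableInfo(battery)
  res <- lapply(seq_len(ncol(vals)), function(j) {
    x <- vals[grp == "NS", j]; y <- vals[grp == "IS", j]
    cmp <- compareGroups(x, y)
    lev <- leveneVariance(x, y)
    data.frame(variable = colnames(vals)[j], test = info$test[j],
               valence = info$valence[j], statistic = cmp$statistic,
               route = cmp$route, p = cmp$p,
               levene_W = lev$statistic, levene_p = lev$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
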