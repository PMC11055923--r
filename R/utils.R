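#' @importFrom stats aov anova chisq.test cor cor.test cov cutree dist hclust
#'   kmeans ks.test lm median na.omit p.adjust pnorm prcomp predict pt qnorm
#'   quantile rbinom rnorm runif sd setNames t.test var wilcox.test cophenetic
#'   rmultinom
#' @importFrom utils read.delim write.table head modifyList
NULL

# Run expr with a temporary RNG state seeded at `seed`, restoring the caller's
# state afterwards. All stochastic operations in the package go through this,
# so a function's randomness never leaks into (or depends on) global state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single integer or NULL", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive independent per-stage seeds from a master seed
#'
#' A deterministic counter-based scheme: stage i receives
#' `(master + 7919 * i) mod (2^31 - 1)`. Changing one stage's seed therefore
#' never perturbs another stage's stream, and all derived seeds stay within
#' the 32-bit integer range `set.seed()` accepts.
#'
#' @param master single integer master seed.
#' @param n number of stage seeds to derive.
#' @param labels optional character labels for the stages.
#' @return named integer vector of length `n`.
#' @export
stageSeeds <- function(master, n, labels = NULL) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  s <- as.integer((as.numeric(master) + 7919 * seq_len(n)) %% 2147483647)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    names(s) <- labels
  }
  s
}

# Round half up (positive inputs). Used for subsample sizes.
roundHalfUp <- function(x) floor(x + 0.5)

# Pearson chi-squared without continuity correction, with guards shared by
# every clusters-x-classes test in the package.
.assertCount <- function(x) {
  if (!all(x >= 0) || any(abs(x - round(x)) > 1e-8)) {
    stop("contingency table must contain non-negative integer counts",
         call. = FALSE)
  }
}
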