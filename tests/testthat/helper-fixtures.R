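# Small builders shared across the suite. Everything is generated in code;
# no fixture files.

# Minimal two-variable shuttle-box battery with arbitrary extra variables.
toyBattery <- function(values, group = NULL) {
  values <- as.matrix(values)
  if (is.null(group)) group <- rep(c("NS", "IS"), length.out = nrow(values))
  meta <- data.frame(
    name = colnames(values),
    test = rep(c("SB", "OF", "FST", "EPM"), length.out = ncol(values)),
    valence = rep(c("susceptibility", "resilience"), length.out = ncol(values)),
    units = "a.u.")
  BehavioralBattery(values, group = group, meta = meta)
}

# A no-structure config: pure noise plus optional test factors.
noiseConfig <- function(n_ns = 1000, n_is = 1000, lambda_test = 0,
                        lambda_sus = 0, ...) {
  defaultBatteryConfig(n_ns = n_ns, n_is = n_is, lambda_test = lambda_test,
                       lambda_sus = lambda_sus, delta_h = 0,
                       delta_helpless = 0, pi_h_is = 0, pi_h_ns = 0,
                       n_profile_clusters = 1, ...)
}

# Independent Lance-Williams Ward implementation (heights on the distance
# scale, i.e. the ward.D2 convention) used as a brute-force linkage oracle.
oracleWard <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  active <- seq_len(n)
  sizes <- rep(1, n)
  id <- -seq_len(n)          # hclust node convention
  merges <- matrix(0, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(active)[-length(active)]) {
      for (j in (i + 1):length(active)) {
        if (D2[active[i], active[j]] < bestD) {
          bestD <- D2[active[i], active[j]]; best <- c(i, j)
        }
      }
    }
    a <- active[best[1]]; b <- active[best[2]]
    heights[step] <- sqrt(bestD)
    merges[step, ] <- sort(c(id[a], id[b]))
    na <- sizes[a]; nb <- sizes[b]
    for (k in active) {
      if (k == a || k == b) next
      nk <- sizes[k]
      D2[a, k] <- D2[k, a] <-
        ((na + nk) * D2[a, k] + (nb + nk) * D2[b, k] - nk * bestD) /
        (na + nb + nk)
    }
    sizes[a] <- na + nb
    id[a] <- step
    active <- setdiff(active, b)
  }
  list(merges = merges, heights = heights)
}

# Two vectors with an exact sample correlation r (via Gram-Schmidt).
exactCorrPair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  e <- e - mean(e)
  e <- e - x * sum(e * x) / sum(x * x)
  e <- e / sd(e)
  y <- r * x + sqrt(1 - r^2) * e
  cbind(x = x, y = y)
}
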