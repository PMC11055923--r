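#' Default synthetic battery configuration
#'
#' Returns the configuration of the synthetic behavioral battery generator,
#' mirroring the study scale the analyses are designed for: 22 no-shock (NS)
#' and 23 inescapable-shock (IS) rats measured on 26 variables across the 8
#' battery tests (OF, FST, SIT, EPM, NOR, PPI, SPT, SB).
#'
#' The generative model for rat \eqn{i}, variable \eqn{v} of test \eqn{t} is
#' \deqn{x_{iv} = \lambda_{test} f_{it} + s_v \lambda_{sus} u_i + m_{c(i),v}
#'   + \delta_{SB}\,[H_i, v \in SB_{sus}] + \epsilon_{iv}}
#' with per-test factors \eqn{f_{it} \sim N(0,1)} (strong intra-test, weak
#' inter-test correlation), a latent susceptibility axis
#' \eqn{u_i \sim N(0,1) + \delta_H H_i} loading on every variable with
#' valence-dependent sign \eqn{s_v} (+1 susceptibility, −1 resilience), a
#' latent helpless flag \eqn{H_i} drawn with group-specific probability, an
#' additional helplessness signature \eqn{\delta_{SB}} on the shuttle-box
#' susceptibility variables (emulating the clearly bimodal escape-failure
#' distribution of helpless rats), cluster-specific mean offsets
#' \eqn{m_{c,v}} planting multivariate profile clusters on valence-designated
#' variable blocks, and i.i.d. Gaussian noise.
#'
#' @param n_ns,n_is group sizes.
#' @param lambda_test intra-test factor loading.
#' @param lambda_sus susceptibility-axis loading.
#' @param delta_h susceptibility-axis shift (SD units) for latent-helpless rats.
#' @param delta_helpless extra mean shift on shuttle-box susceptibility
#'   variables for latent-helpless rats.
#' @param pi_h_is,pi_h_ns probability of the latent helpless state per group.
#' @param n_profile_clusters number of planted multivariate profile clusters
#'   (cluster 1 is a neutral baseline; further clusters alternate
#'   susceptible-like and resilient-like offset patterns).
#' @param profile_effect magnitude of the cluster offsets.
#' @param cluster_probs_ns,cluster_probs_is per-group cluster membership
#'   probabilities (length `n_profile_clusters`); defaults concentrate the
#'   susceptible-like cluster in the shocked group.
#' @param noise_sd residual standard deviation.
#' @param variables data.frame `name,test,valence,units` describing the
#'   battery; default is a 26-variable layout over the 8 tests.
#' @param seed integer seed stored in the config.
#' @return a list of class `SyntheticConfig`.
#' @seealso [generateBattery()]
#' @export
defaultBatteryConfig <- function(n_ns = 22, n_is = 23,
                                 lambda_test = 1.0, lambda_sus = 0.9,
                                 delta_h = 2.0, delta_helpless = 3.0,
                                 pi_h_is = 0.87, pi_h_ns = 0.36,
                                 n_profile_clusters = 3, profile_effect = 0.8,
                                 cluster_probs_ns = NULL,
                                 cluster_probs_is = NULL,
                                 noise_sd = 1.0,
                                 variables = defaultBatteryVariables(),
                                 seed = 1L) {
  if (is.null(cluster_probs_ns)) {
    cluster_probs_ns <- .defaultClusterProbs(n_profile_clusters, shocked = FALSE)
  }
  if (is.null(cluster_probs_is)) {
    cluster_probs_is <- .defaultClusterProbs(n_profile_clusters, shocked = TRUE)
  }
  cfg <- list(n_ns = n_ns, n_is = n_is, lambda_test = lambda_test,
              lambda_sus = lambda_sus, delta_h = delta_h,
              delta_helpless = delta_helpless,
              pi_h_is = pi_h_is, pi_h_ns = pi_h_ns,
              n_profile_clusters = n_profile_clusters,
              profile_effect = profile_effect,
              cluster_probs_ns = cluster_probs_ns,
              cluster_probs_is = cluster_probs_is,
              noise_sd = noise_sd, variables = variables, seed = seed)
  class(cfg) <- "SyntheticConfig"
  .validateConfig(cfg)
  cfg
}

# Baseline-heavy membership; susceptible-like clusters (even indices >= 2)
# enriched in IS, resilient-like (odd indices >= 3) enriched in NS.
.defaultClusterProbs <- function(k, shocked) {
  if (k == 1L) return(1)
  p <- rep(0.1, k)
  p[1L] <- 0.5
  extra <- 0.4
  idx <- 2:k
  susLike <- idx[idx %% 2L == 0L]
  resLike <- idx[idx %% 2L == 1L]
  fav <- if (shocked) susLike else resLike
  if (length(fav)) p[fav] <- p[fav] + extra / length(fav) else p[1L] <- p[1L] + extra
  p / sum(p)
}

#' Default 26-variable battery layout
#'
#' One row per behavioral variable: 3 open-field, 3 forced-swim, 3 social
#' interaction, 3 elevated-plus-maze, 2 novel-object, 4 startle/PPI, 4
#' sucrose-preference and 4 shuttle-box measures, each labeled with its
#' resilience/susceptibility valence.
#'
#' @return data.frame with columns `name,test,valence,units`.
#' @export
defaultBatteryVariables <- function() {
  data.frame(
    name = c("of_total_distance", "of_center_time", "of_rearing",
             "fst_immobility", "fst_climbing", "fst_swimming",
             "sit_social_pref_ratio", "sit_interaction_time", "sit_corner_ratio",
             "epm_open_arms", "epm_closed_arms", "epm_risk_assessment",
             "nor_discrimination_st", "nor_discrimination_lt",
             "ppi_startle_amplitude", "ppi_habituation_pct",
             "ppi_pct_77", "ppi_pct_83",
             "spt_pref_d1", "spt_pref_d2", "spt_pref_d3", "spt_pref_avg",
             "sb_escape_failures", "sb_latency_fr1", "sb_latency_fr2",
             "sb_mean_latency"),
    test = c(rep("OF", 3), rep("FST", 3), rep("SIT", 3), rep("EPM", 3),
             rep("NOR", 2), rep("PPI", 4), rep("SPT", 4), rep("SB", 4)),
    valence = c("resilience", "resilience", "resilience",
                "susceptibility", "resilience", "resilience",
                "resilience", "resilience", "susceptibility",
                "resilience", "susceptibility", "resilience",
                "resilience", "resilience",
                "susceptibility", "resilience", "resilience", "resilience",
                "resilience", "resilience", "resilience", "resilience",
                "susceptibility", "susceptibility", "susceptibility",
                "susceptibility"),
    units = "a.u.",
    stringsAsFactors = FALSE
  )
}

.validateConfig <- function(cfg) {
  with(cfg, {
    if (n_ns < 1 || n_is < 1) stop("group sizes must be positive", call. = FALSE)
    if (any(c(pi_h_is, pi_h_ns) < 0) || any(c(pi_h_is, pi_h_ns) > 1)) {
      stop("helpless proportions must be in [0, 1]", call. = FALSE)
    }
    if (noise_sd <= 0 && lambda_test == 0 && lambda_sus == 0) {
      stop("configuration implies non-positive variable variance", call. = FALSE)
    }
    if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
    if (length(cluster_probs_ns) != n_profile_clusters ||
        length(cluster_probs_is) != n_profile_clusters) {
      stop("cluster probabilities must have length n_profile_clusters",
           call. = FALSE)
    }
    if (any(cluster_probs_ns < 0) || any(cluster_probs_is < 0)) {
      stop("cluster probabilities must be non-negative", call. = FALSE)
    }
  })
  invisible(cfg)
}

# Signed valence vector: +1 susceptibility, -1 resilience.
.valenceSign <- function(valence) ifelse(valence == "susceptibility", 1, -1)

# k x P matrix of planted cluster mean offsets. Cluster 1 is the baseline;
# cluster j > 1 applies +/- profile_effect along the signed valence vector
# (even j susceptible-like, odd j resilient-like), magnitudes growing by
# pair so additional clusters remain distinguishable.
.clusterOffsets <- function(cfg) {
  sgn <- .valenceSign(cfg$variables$valence)
  k <- cfg$n_profile_clusters
  off <- matrix(0, nrow = k, ncol = length(sgn))
  if (k >= 2) {
    for (j in 2:k) {
      dir <- if (j %% 2L == 0L) 1 else -1
      magn <- cfg$profile_effect * ceiling((j - 1) / 2)
      off[j, ] <- dir * magn * sgn
    }
  }
  off
}

#' Generate a synthetic behavioral battery
#'
#' Draws one dataset from the generative model described in
#' [defaultBatteryConfig()], together with its ground truth (latent
#' susceptibility score, helpless flag and profile-cluster membership per
#' rat). Fully reproducible from `seed`.
#'
#' @param config a `SyntheticConfig`, e.g. from [defaultBatteryConfig()].
#' @param seed overrides `config$seed` when given.
#' @return list with elements `battery` (a [BehavioralBattery-class]) and
#'   `truth` (data.frame `rat_id, group, susceptibility, helpless, cluster`).
#' @examples
#' sim <- generateBattery(defaultBatteryConfig(seed = 7))
#' table(sim$truth$group, sim$truth$helpless)
#' @export
generateBattery <- function(config = defaultBatteryConfig(), seed = NULL) {
  .validateConfig(config)
  if (is.null(seed)) seed <- config$seed
  vars <- config$variables
  P <- nrow(vars)
  n <- config$n_ns + config$n_is
  group <- c(rep("NS", config$n_ns), rep("IS", config$n_is))
  tests <- unique(vars$test)
  sgn <- .valenceSign(vars$valence)
  sbSus <- vars$test == "SB" & vars$valence == "susceptibility"
  withSeed(seed, {
    piH <- ifelse(group == "IS", config$pi_h_is, config$pi_h_ns)
    helpless <- runif(n) < piH
    s <- rnorm(n) + config$delta_h * helpless
    f <- matrix(rnorm(n * length(tests)), n, length(tests),
                dimnames = list(NULL, tests))
    cl <- integer(n)
    for (i in seq_len(n)) {
      p <- if (group[i] == "IS") config$cluster_probs_is else config$cluster_probs_ns
      cl[i] <- sample.int(config$n_profile_clusters, 1L, prob = p)
    }
    off <- .clusterOffsets(config)
    x <- config$lambda_test * f[, vars$test, drop = FALSE] +
      outer(s, sgn * config$lambda_sus) +
      off[cl, , drop = FALSE] +
      outer(as.numeric(helpless), as.numeric(sbSus) * config$delta_helpless) +
      matrix(rnorm(n * P, sd = config$noise_sd), n, P)
    colnames(x) <- vars$name
    rownames(x) <- sprintf("rat%02d", seq_len(n))
    battery <- BehavioralBattery(x, group = group, meta = vars)
    truth <- data.frame(rat_id = rownames(x), group = group,
                        susceptibility = s,
                        helpless = ifelse(helpless, "H", "NH"),
                        cluster = cl, stringsAsFactors = FALSE)
    list(battery = battery, truth = truth)
  })
}

#' Closed-form covariance of the generator (no mixtures)
#'
#' For a configuration with a single profile cluster and helpless probability
#' zero, the population covariance of the generated variables is
#' `lambda_test^2 B + lambda_sus^2 v v' + noise_sd^2 I`, with `B` the
#' same-test indicator matrix and `v` the signed valence vector. Used to
#' verify the generator against its own model.
#'
#' @param config a `SyntheticConfig`.
#' @return P x P covariance matrix.
#' @export
generatorCovariance <- function(config) {
  vars <- config$variables
  B <- outer(vars$test, vars$test, "==") * 1
  v <- .valenceSign(vars$valence)
  cv <- config$lambda_test^2 * B + config$lambda_sus^2 * outer(v, v) +
    diag(config$noise_sd^2, nrow(vars))
  dimnames(cv) <- list(vars$name, vars$name)
  cv
}

#' Shuffle a data matrix to destroy covariance
#'
#' Default unit `"column"` permutes every column independently across rows:
#' all inter-variable covariance is destroyed while each variable's marginal
#' distribution is preserved exactly — the null used throughout the
#' shuffled-data comparisons. Unit `"rows"` instead applies one common row
#' permutation (covariance intact, row identities scrambled), the
#' label-shuffle alternative.
#'
#' @param Z numeric matrix (rats by variables).
#' @param seed integer seed.
#' @param unit `"column"` (independent per-column permutation) or `"rows"`.
#' @return matrix of the same dimension.
#' @export
shuffleData <- function(Z, seed = NULL, unit = c("column", "rows")) {
  unit <- match.arg(unit)
  Z <- as.matrix(Z)
  withSeed(seed, {
    if (unit == "column") {
      out <- vapply(seq_len(ncol(Z)),
                    function(j) Z[sample.int(nrow(Z)), j],
                    numeric(nrow(Z)))
      out <- matrix(out, nrow = nrow(Z), dimnames = dimnames(Z))
      out
    } else {
      Z[sample.int(nrow(Z)), , drop = FALSE]
    }
  })
}

#' Subsample rows or columns without replacement
#'
#' Draws `round(fraction * size)` (half rounds up) rows (`"observations"`) or
#' columns (`"variables"`) uniformly without replacement.
#'
#' @param x numeric matrix.
#' @param fraction fraction in (0, 1].
#' @param axis subsample rats (`"observations"`) or variables (`"variables"`).
#' @param seed integer seed.
#' @return list with `data` (the subset) and `index` (selected positions, in
#'   original order).
#' @export
subsampleData <- function(x, fraction = 0.7,
                          axis = c("observations", "variables"), seed = NULL) {
  axis <- match.arg(axis)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  x <- as.matrix(x)
  total <- if (axis == "observations") nrow(x) else ncol(x)
  size <- roundHalfUp(fraction * total)
  if (size < 2) stop("subsample would have fewer than 2 elements", call. = FALSE)
  withSeed(seed, {
    idx <- sort(sample.int(total, size))
    data <- if (axis == "observations") x[idx, , drop = FALSE]
            else x[, idx, drop = FALSE]
    list(data = data, index = idx)
  })
}
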