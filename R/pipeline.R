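#' Read a pipeline run configuration from YAML
#'
#' Reads a YAML file and merges it over [defaultRunConfig()].
#'
#' @param path path to a YAML config.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(defaultRunConfig(), user)
  .validateRunConfig(cfg)
  cfg
}

#' Default pipeline run configuration
#'
#' Study-scale iteration counts: 1e4 feature-reliability iterations,
#' 1000 LDA train/test splits, 1e4 k-means restarts. `fast = TRUE` reduces
#' these to exploratory sizes (200 / 200 / 100).
#'
#' @param seed master seed (per-stage seeds are derived via [stageSeeds()]).
#' @param fast use reduced iteration counts.
#' @return a `RunConfig` list.
#' @export
defaultRunConfig <- function(seed = 1L, fast = FALSE) {
  list(
    values_path = NULL, meta_path = NULL,   # set these, or simulate:
    simulate = TRUE,
    seed = seed,
    alpha = 0.05,
    fraction = 0.7,
    n_iter_reliability = if (fast) 200L else 10000L,
    n_iter_lda = if (fast) 200L else 1000L,
    n_iter_pca_null = if (fast) 100L else 1000L,
    n_restarts_kmeans = if (fast) 100L else 10000L,
    k_range_profiles = 2:7,
    representative_vars = c("of_total_distance", "fst_immobility",
                            "sit_social_pref_ratio", "epm_open_arms",
                            "spt_pref_avg", "sb_escape_failures"),
    stage_seeds = NULL,  # named list overriding individual derived seeds
    out_dir = NULL
  )
}

.validateRunConfig <- function(cfg) {
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$values_path) || is.null(cfg$meta_path)) {
      stop("config error: either simulate=TRUE or both values_path and meta_path",
           call. = FALSE)
    }
    if (!file.exists(cfg$values_path)) {
      stop("config error: values_path does not exist: ", cfg$values_path,
           call. = FALSE)
    }
    if (!file.exists(cfg$meta_path)) {
      stop("config error: meta_path does not exist: ", cfg$meta_path,
           call. = FALSE)
    }
  }
  for (f in c("n_iter_reliability", "n_iter_lda", "n_iter_pca_null",
              "n_restarts_kmeans")) {
    if (cfg[[f]] < 1) stop("config error: ", f, " must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full battery analysis pipeline
#'
#' Executes the complete analysis in the order of the study design:
#' univariate battery statistics, helplessness classification, feature
#' structure (correlations, valence clustering, permutation reliability),
#' PCA (shuffled null, representative-variable VIF screen, per-PC group
#' tests, LDA on cumulative PCs) and individual profile clustering
#' (hierarchy scan, semi-supervised k-means, cluster profiles and
#' cross-algorithm correspondence). When `cfg$out_dir` is set, each stage's
#' tables are written as TSV/JSON plus a JSON run manifest. All stochastic
#' stages use independent seeds derived from `cfg$seed`, so rerunning an
#' identical config reproduces every output bit-identically.
#'
#' @param cfg a `RunConfig` from [defaultRunConfig()] / [readRunConfig()].
#' @return a list of class `RunReport` with one element per stage plus
#'   `manifest`.
#' @export
runPipeline <- function(cfg = defaultRunConfig()) {
  .validateRunConfig(cfg)
  t0 <- Sys.time()
  seeds <- stageSeeds(cfg$seed, 7,
                      labels = c("simulate", "helpless", "features",
                                 "pca_null", "lda", "profiles", "reliability"))
  if (!is.null(cfg$stage_seeds)) {
    for (nm in names(cfg$stage_seeds)) seeds[[nm]] <- cfg$stage_seeds[[nm]]
  }
  battery <- if (isTRUE(cfg$simulate)) {
    generateBattery(defaultBatteryConfig(seed = seeds[["simulate"]]))$battery
  } else {
    readBattery(cfg$values_path, cfg$meta_path)
  }
  Z <- zscores(battery)
  info <- variableInfo(battery)
  grp <- groupLabels(battery)

  univariate <- univariateBattery(battery)

  helpless <- classifyHelplessness(battery,
                                   n_restarts = cfg$n_restarts_kmeans,
                                   seed = seeds[["helpless"]])
  helplessLabels(battery) <- helpless$labels
  hnChi <- chisqAssociation(table(hn = helpless$labels, group = grp))

  corr <- spearmanMatrix(Z)
  valTree <- wardLinkage(Z, metric = "euclidean")
  valCut <- cutClusters(valTree, 2)
  valChi <- labelSeparationTest(valCut, info$valence)
  testTree <- wardLinkage(Z, metric = "sign_independent")
  features <- list(
    correlation = corr,
    valence_tree = valTree, valence_chi2 = valChi,
    valence_cophenetic = copheneticCoefficient(valTree),
    test_tree = testTree,
    test_cophenetic = copheneticCoefficient(testTree),
    reliability_obs = clusteringReliability(
      Z, info$valence, fraction = cfg$fraction, axis = "observations",
      n_iter = cfg$n_iter_reliability, alpha = cfg$alpha,
      seed = seeds[["reliability"]]),
    reliability_shuffled = clusteringReliability(
      Z, info$valence, fraction = cfg$fraction, axis = "observations",
      n_iter = cfg$n_iter_reliability, alpha = cfg$alpha,
      seed = seeds[["reliability"]], shuffle = TRUE))

  pcaRes <- pcaFit(Z)
  pcaNull <- pcaShuffledNull(Z, n_iter = cfg$n_iter_pca_null,
                             seed = seeds[["pca_null"]])
  repVars <- intersect(cfg$representative_vars, colnames(Z))
  vif <- if (length(repVars) >= 2) vifScores(Z[, repVars, drop = FALSE]) else NULL
  groupTests <- pcGroupComparison(pcaRes$scores, grp)
  lda <- ldaCumulativeAccuracy(pcaRes$scores, helpless$labels,
                               n_iter = cfg$n_iter_lda,
                               seed = seeds[["lda"]])
  pca <- list(fit = pcaRes, null = pcaNull, vif = vif,
              group_tests = groupTests, lda = lda)

  hp <- hierProfiles(Z, max(cfg$k_range_profiles))
  scan <- hierarchyScan(hp$tree, grp, k_range = cfg$k_range_profiles)
  sel <- selectK(Z, k_range = cfg$k_range_profiles, mode = "semi_supervised",
                 groups = grp, n_restarts = cfg$n_restarts_kmeans,
                 seed = seeds[["profiles"]])
  kmK <- if (is.na(sel$k)) sel$diagnostics$k[which.max(sel$diagnostics$mean_silhouette)]
         else sel$k
  km <- sel$assignments[[as.character(kmK)]]
  profiles <- list(
    tree = hp$tree, hierarchy_scan = scan,
    hier_assignment = hp$assignment,
    hier_profiles = clusterProfiles(Z, hp$assignment, grp),
    profile_cophenetic = copheneticCoefficient(hp$tree),
    k_selection = sel[c("k", "diagnostics")],
    kmeans_assignment = km,
    kmeans_profiles = clusterProfiles(Z, km, grp),
    # compare the two algorithms at the same granularity
    correspondence = clusterCorrespondence(cutClusters(hp$tree, kmK), km))

  manifest <- list(
    package_version = as.character(utils::packageVersion("StressBattery")),
    r_version = R.version.string,
    seed = cfg$seed, stage_seeds = as.list(seeds),
    parameters = cfg[c("alpha", "fraction", "n_iter_reliability",
                       "n_iter_lda", "n_iter_pca_null",
                       "n_restarts_kmeans")],
    n_rats = ncol(battery), n_variables = nrow(battery),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  report <- structure(list(battery = battery, univariate = univariate,
                           helplessness = c(helpless["labels"], helpless["k"],
                                            list(chi2 = hnChi)),
                           features = features, pca = pca,
                           profiles = profiles, manifest = manifest),
                      class = "RunReport")
  if (!is.null(cfg$out_dir)) .writeReport(report, cfg$out_dir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Battery analysis run:\n")
  cat(sprintf("  %d rats x %d variables\n", x$manifest$n_rats,
              x$manifest$n_variables))
  cat(sprintf("  helplessness: k = %d, chi2 = %.4f (p = %.4g)\n",
              x$helplessness$k, x$helplessness$chi2$chi2,
              x$helplessness$chi2$p))
  cat(sprintf("  valence clustering chi2 = %.4f (p = %.4g)\n",
              x$features$valence_chi2$chi2, x$features$valence_chi2$p))
  cat(sprintf("  PCA: PC1-3 = %.2f/%.2f/%.2f%%, %d component(s) above null\n",
              x$pca$fit$explained_pct[1], x$pca$fit$explained_pct[2],
              x$pca$fit$explained_pct[3], sum(x$pca$null$flagged)))
  cat(sprintf("  k-means k = %s, hierarchical correspondence = %.2f\n",
              x$profiles$k_selection$k, x$profiles$correspondence$agreement))
  invisible(x)
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

.writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .writeTSV(report$univariate, file.path(dir, "univariate.tsv"))
  .writeTSV(data.frame(rat_id = names(report$helplessness$labels),
                       hn = report$helplessness$labels),
            file.path(dir, "helplessness.tsv"))
  rmat <- report$features$correlation$r
  .writeTSV(data.frame(variable = rownames(rmat), rmat, check.names = FALSE),
            file.path(dir, "spearman.tsv"))
  hc <- report$features$valence_tree$hclust
  .writeTSV(data.frame(node_a = hc$merge[, 1], node_b = hc$merge[, 2],
                       height = hc$height),
            file.path(dir, "valence_linkage.tsv"))
  jsonlite::write_json(
    list(observed = report$features$reliability_obs$fraction_significant,
         shuffled = report$features$reliability_shuffled$fraction_significant,
         n_iter = report$features$reliability_obs$n_iter,
         alpha = report$features$reliability_obs$alpha),
    file.path(dir, "reliability.json"), auto_unbox = TRUE, digits = NA)
  co <- report$pca$fit$coefficients
  .writeTSV(data.frame(variable = rownames(co), co, check.names = FALSE),
            file.path(dir, "pca_coefficients.tsv"))
  sc <- report$pca$fit$scores
  .writeTSV(data.frame(rat_id = rownames(sc), sc, check.names = FALSE),
            file.path(dir, "pca_scores.tsv"))
  jsonlite::write_json(
    list(explained_pct = report$pca$fit$explained_pct,
         null_quantile = report$pca$null$null_quantile,
         flagged = report$pca$null$flagged),
    file.path(dir, "pca_explained.json"), digits = NA)
  if (!is.null(report$pca$vif)) {
    .writeTSV(report$pca$vif, file.path(dir, "vif.tsv"))
  }
  .writeTSV(report$pca$lda$results, file.path(dir, "lda_accuracy.tsv"))
  .writeTSV(data.frame(rat_id = names(report$profiles$hier_assignment$labels),
                       hier = report$profiles$hier_assignment$labels,
                       kmeans = report$profiles$kmeans_assignment$labels),
            file.path(dir, "profile_assignments.tsv"))
  .writeTSV(report$profiles$hierarchy_scan, file.path(dir, "hierarchy_scan.tsv"))
  pm <- report$profiles$hier_profiles$mean
  .writeTSV(data.frame(cluster = rownames(pm), pm, check.names = FALSE),
            file.path(dir, "hier_profile_means.tsv"))
  jsonlite::write_json(report$profiles$correspondence$matching,
                       file.path(dir, "correspondence.json"), digits = NA)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
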