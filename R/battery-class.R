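#' BehavioralBattery: a rats-by-variables behavioral test battery
#'
#' S4 container for a behavioral test battery, extending
#' [SummarizedExperiment::SummarizedExperiment]. Following the
#' SummarizedExperiment convention, behavioral variables are rows (features)
#' and rats are columns (samples). `rowData` holds the per-variable metadata
#' (`test` membership, resilience/susceptibility `valence`, `units`);
#' `colData` holds the per-rat `group` label (`NS` no-shock / `IS`
#' inescapable-shock) and, once computed, the helpless/non-helpless label
#' `hn`.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @aliases BehavioralBattery
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass BehavioralBattery
setClass("BehavioralBattery", contains = "SummarizedExperiment")

.BATTERY_TESTS <- c("OF", "FST", "SIT", "EPM", "NOR", "PPI", "SPT", "SB")
.VALENCES <- c("resilience", "susceptibility")

setValidity("BehavioralBattery", function(object) {
  msg <- character()
  if (!"values" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'values' is required")
  } else {
    v <- SummarizedExperiment::assay(object, "values")
    if (!is.numeric(v)) msg <- c(msg, "assay 'values' must be numeric")
    if (anyNA(v)) msg <- c(msg, "assay 'values' must not contain missing values")
  }
  rd <- SummarizedExperiment::rowData(object)
  for (fld in c("test", "valence")) {
    if (!fld %in% colnames(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", fld))
  }
  if ("test" %in% colnames(rd) && !all(rd$test %in% .BATTERY_TESTS)) {
    msg <- c(msg, sprintf("rowData$test must be one of %s",
                          paste(.BATTERY_TESTS, collapse = ", ")))
  }
  if ("valence" %in% colnames(rd) && !all(rd$valence %in% .VALENCES)) {
    msg <- c(msg, "rowData$valence must be 'resilience' or 'susceptibility'")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData lacks 'group'")
  } else if (!all(cd$group %in% c("NS", "IS"))) {
    msg <- c(msg, "colData$group must be 'NS' or 'IS'")
  }
  if ("hn" %in% colnames(cd) && !all(is.na(cd$hn) | cd$hn %in% c("H", "NH"))) {
    msg <- c(msg, "colData$hn must be 'H' or 'NH'")
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "variable names must be unique")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "rat ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a BehavioralBattery
#'
#' @param values numeric matrix, rats in rows and variables in columns (the
#'   orientation of the on-disk format); transposed internally to the
#'   features-by-samples layout.
#' @param group character/factor of per-rat group labels, `"NS"` or `"IS"`.
#' @param meta data.frame of per-variable metadata with columns `name`,
#'   `test`, `valence` and optionally `units`; one row per column of
#'   `values`, matched by name.
#' @param hn optional per-rat helpless label (`"H"`/`"NH"`).
#' @return a validated [BehavioralBattery-class] object.
#' @examples
#' sim <- generateBattery(defaultBatteryConfig(seed = 1))
#' sim$battery
#' @export
BehavioralBattery <- function(values, group, meta, hn = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (is.null(colnames(values))) stop("`values` must have variable names", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("rat%02d", seq_len(nrow(values)))
  }
  meta <- as.data.frame(meta)
  if (!all(c("name", "test", "valence") %in% colnames(meta))) {
    stop("`meta` needs columns name, test, valence", call. = FALSE)
  }
  missingMeta <- setdiff(colnames(values), meta$name)
  if (length(missingMeta)) {
    stop("metadata missing for variable(s): ",
         paste(missingMeta, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(values), meta$name), , drop = FALSE]
  if (!"units" %in% colnames(meta)) meta$units <- NA_character_
  if (length(group) != nrow(values)) {
    stop("`group` must have one label per rat", call. = FALSE)
  }
  cd <- S4Vectors::DataFrame(group = as.character(group),
                             row.names = rownames(values))
  if (!is.null(hn)) cd$hn <- as.character(hn)
  rd <- S4Vectors::DataFrame(test = meta$test, valence = meta$valence,
                             units = meta$units, row.names = meta$name)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)), rowData = rd, colData = cd)
  methods::new("BehavioralBattery", se)
}

#' @describeIn BehavioralBattery rats-by-variables numeric matrix of raw values.
#' @param x,object a `BehavioralBattery`.
#' @export
batteryValues <- function(x) t(SummarizedExperiment::assay(x, "values"))

#' @describeIn BehavioralBattery per-rat group labels (`NS`/`IS`).
#' @export
groupLabels <- function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$group), colnames(x))
}

#' @describeIn BehavioralBattery per-variable metadata as a data.frame.
#' @export
variableInfo <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(name = rownames(x), test = rd$test, valence = rd$valence,
             units = rd$units, row.names = NULL)
}

#' @describeIn BehavioralBattery per-rat helpless/non-helpless labels, or
#'   `NULL` if not yet assigned.
#' @export
helplessLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"hn" %in% colnames(cd)) return(NULL)
  setNames(as.character(cd$hn), colnames(x))
}

#' @describeIn BehavioralBattery assign helpless labels.
#' @param value character vector of `"H"`/`"NH"`, one per rat.
#' @export
`helplessLabels<-` <- function(x, value) {
  stopifnot(length(value) == ncol(x))
  SummarizedExperiment::colData(x)$hn <- as.character(value)
  methods::validObject(x)
  x
}

setMethod("show", "BehavioralBattery", function(object) {
  grp <- table(SummarizedExperiment::colData(object)$group)
  cat(sprintf("BehavioralBattery: %d rats x %d variables\n",
              ncol(object), nrow(object)))
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  cat("  tests:", paste(unique(SummarizedExperiment::rowData(object)$test),
                        collapse = ", "), "\n")
  hn <- helplessLabels(object)
  if (!is.null(hn)) {
    tb <- table(hn)
    cat("  helplessness:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Column-wise Z-scoring
#'
#' Standardizes every variable over all rats (both groups pooled): subtract
#' the column mean and divide by the sample standard deviation (n−1
#' denominator). The per-column centers and scales used are attached as
#' attributes `center` and `scale` so the transform is reproducible.
#'
#' @param x a [BehavioralBattery-class] or a rats-by-variables numeric matrix.
#' @return rats-by-variables matrix of Z scores with provenance attributes.
#' @examples
#' z <- zscores(matrix(c(1, 2, 3, 4, 6, 8), ncol = 2))
#' colMeans(z)  # ~ 0
#' @export
zscores <- function(x) {
  m <- if (methods::is(x, "BehavioralBattery")) batteryValues(x) else as.matrix(x)
  if (anyNA(m)) stop("input contains missing values", call. = FALSE)
  sds <- apply(m, 2, sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  if (length(degenerate)) {
    nm <- colnames(m)[degenerate]
    if (is.null(nm)) nm <- as.character(degenerate)
    stop("zero-variance variable(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  ctr <- colMeans(m)
  z <- sweep(sweep(m, 2, ctr), 2, sds, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- sds
  z
}
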