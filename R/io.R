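.readTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a behavioral battery from values + metadata files
#'
#' The values file (CSV or TSV, by extension) has one row per rat: first
#' column `rat_id`, second column `group` (`NS`/`IS`), remaining columns the
#' numeric behavioral variables. The metadata file has columns
#' `name,test,valence,units`, one row per variable. Column order of the
#' values file is authoritative; metadata rows are matched by name.
#'
#' @param values_path path to the values table.
#' @param meta_path path to the variable metadata table.
#' @param drop_incomplete drop rats with any missing value instead of
#'   erroring (the default rejects missing data at load).
#' @return a [BehavioralBattery-class].
#' @seealso [writeBattery()]
#' @export
readBattery <- function(values_path, meta_path, drop_incomplete = FALSE) {
  vals <- .readTable(values_path)
  if (ncol(vals) < 3L) {
    stop("values file needs rat_id, group and at least one variable column",
         call. = FALSE)
  }
  meta <- .readTable(meta_path)
  if (!all(c("name", "test", "valence") %in% colnames(meta))) {
    stop("metadata file must have columns name, test, valence", call. = FALSE)
  }
  ids <- as.character(vals[[1L]])
  group <- as.character(vals[[2L]])
  m <- vals[, -(1:2), drop = FALSE]
  for (j in seq_along(m)) {
    col <- m[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "")
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     col[bad[1L]], bad[1L], colnames(m)[j]), call. = FALSE)
      }
      m[[j]] <- num
    }
  }
  m <- as.matrix(m)
  rownames(m) <- ids
  if (anyNA(m)) {
    if (drop_incomplete) {
      keep <- stats::complete.cases(m)
      m <- m[keep, , drop = FALSE]
      group <- group[keep]
    } else {
      stop("missing values in values file; set drop_incomplete=TRUE to drop rats",
           call. = FALSE)
    }
  }
  BehavioralBattery(m, group = group, meta = meta)
}

#' Write a behavioral battery to values + metadata files
#'
#' Inverse of [readBattery()]: values as `rat_id,group,<variables...>`,
#' metadata as `name,test,valence,units`. Format (CSV/TSV) follows the file
#' extension.
#'
#' @param battery a [BehavioralBattery-class].
#' @param values_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
writeBattery <- function(battery, values_path, meta_path) {
  sep <- if (grepl("\\.csv$", values_path, ignore.case = TRUE)) "," else "\t"
  m <- batteryValues(battery)
  # 17 significant digits so doubles survive the text round trip exactly
  mtxt <- matrix(formatC(m, digits = 17, format = "g"), nrow(m),
                 dimnames = dimnames(m))
  vals <- data.frame(rat_id = colnames(battery),
                     group = groupLabels(battery),
                     mtxt, check.names = FALSE)
  write.table(vals, values_path, sep = sep, row.names = FALSE, quote = FALSE)
  sep2 <- if (grepl("\\.csv$", meta_path, ignore.case = TRUE)) "," else "\t"
  write.table(variableInfo(battery), meta_path, sep = sep2,
              row.names = FALSE, quote = FALSE)
  invisible(c(values_path, meta_path))
}

#' Derived behavioral indices from raw test quantities
#'
#' Computes the battery's standard composite indices from raw counts and
#' durations, exactly as defined for each test:
#' \itemize{
#'   \item sucrose preference \% = `100 * SI / (SI + WI)` (SI sucrose intake,
#'     WI water intake, ml);
#'   \item novel-object discrimination index = `TN / (TF + TN)` (new / familiar
#'     object exploration time, s);
#'   \item social preference ratio = `OC / EC` (occupied- / empty-cage
#'     interaction time, s);
#'   \item startle habituation \% = `100 - 100 * HAB1 / HAB0` (late / early
#'     startle amplitude);
#'   \item prepulse inhibition \% = `100 - 100 * PPP / P` (prepulse+pulse
#'     amplitude over pulse-alone amplitude).
#' }
#' Only the indices whose inputs are supplied are returned.
#'
#' @param SI,WI sucrose and water intake (ml).
#' @param TN,TF new and familiar object exploration time (s).
#' @param OC,EC occupied- and empty-cage interaction time (s).
#' @param HAB0,HAB1 startle amplitude in the first and last habituation block.
#' @param PPP,P startle amplitude in prepulse+pulse and pulse-alone trials.
#' @return named list of the computable indices.
#' @examples
#' deriveTestIndices(SI = 12, WI = 12)  # sucrose preference 50
#' @export
deriveTestIndices <- function(SI = NULL, WI = NULL, TN = NULL, TF = NULL,
                              OC = NULL, EC = NULL, HAB0 = NULL, HAB1 = NULL,
                              PPP = NULL, P = NULL) {
  chkNonNeg <- function(...) {
    vals <- c(...)
    if (any(vals < 0)) stop("raw test quantities must be non-negative",
                            call. = FALSE)
  }
  chkDenom <- function(d, what) {
    if (any(d <= 0)) stop(sprintf("zero or negative denominator in %s", what),
                          call. = FALSE)
  }
  out <- list()
  if (!is.null(SI) && !is.null(WI)) {
    chkNonNeg(SI, WI); chkDenom(SI + WI, "sucrose preference")
    out$sucrose_preference_pct <- 100 * SI / (SI + WI)
  }
  if (!is.null(TN) && !is.null(TF)) {
    chkNonNeg(TN, TF); chkDenom(TF + TN, "discrimination index")
    out$discrimination_index <- TN / (TF + TN)
  }
  if (!is.null(OC) && !is.null(EC)) {
    chkNonNeg(OC, EC); chkDenom(EC, "social preference ratio")
    out$social_preference_ratio <- OC / EC
  }
  if (!is.null(HAB0) && !is.null(HAB1)) {
    chkNonNeg(HAB0, HAB1); chkDenom(HAB0, "startle habituation")
    out$habituation_pct <- 100 - 100 * HAB1 / HAB0
  }
  if (!is.null(PPP) && !is.null(P)) {
    chkNonNeg(PPP, P); chkDenom(P, "prepulse inhibition")
    out$ppi_pct <- 100 - 100 * PPP / P
  }
  if (!length(out)) stop("no complete index inputs supplied", call. = FALSE)
  out
}
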