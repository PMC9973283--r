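# Derived clinical quantities: HOMA indices, OGTT areas, ADA glycemic
# classification, coefficients of variation, and the standardized matrix
# that feeds k-medoids stratification.

#' Homeostatic model assessment indices
#'
#' HOMA-IR = glucose_0 * insulin_0 / 22.5; HOMA-IS = 22.5 / (glucose_0 *
#' insulin_0); HOMA-beta = 20 * insulin_0 / (glucose_0 - 3.5), undefined
#' (NA) when fasting glucose is at or below 3.5 mmol/L.
#'
#' @param glucose_0 Fasting glucose, mmol/L (> 0).
#' @param insulin_0 Fasting insulin, uU/mL (> 0).
#' @return Data frame with columns `homa_ir`, `homa_is`, `homa_beta`.
#' @export
homa_indices <- function(glucose_0, insulin_0) {
  ok_g <- is.na(glucose_0) | glucose_0 > 0
  ok_i <- is.na(insulin_0) | insulin_0 > 0
  if (!all(ok_g)) stop("glucose_0 must be positive")
  if (!all(ok_i)) stop("insulin_0 must be positive")
  gi <- glucose_0 * insulin_0
  homa_ir <- gi / 22.5
  homa_is <- 22.5 / gi
  homa_beta <- ifelse(!is.na(glucose_0) & glucose_0 > 3.5,
                      20 * insulin_0 / (glucose_0 - 3.5), NA_real_)
  data.frame(homa_ir = homa_ir, homa_is = homa_is, homa_beta = homa_beta)
}

#' Trapezoidal area under an OGTT curve
#'
#' @param values Numeric matrix or data frame, one row per participant,
#'   columns at the sampling minutes; or a single numeric vector.
#' @param minutes Sampling times in minutes (default 0, 30, 60, 120, 180).
#' @return Area in concentration x min; `NA` where any time point is missing.
#' @export
ogtt_auc <- function(values, minutes = c(0, 30, 60, 120, 180)) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(minutes))
  if (any(values < 0, na.rm = TRUE)) stop("concentrations must be nonnegative")
  dt <- diff(minutes)
  mids <- (values[, -1, drop = FALSE] + values[, -ncol(values), drop = FALSE]) / 2
  auc <- as.vector(mids %*% dt)
  auc[!stats::complete.cases(values)] <- NA_real_
  auc
}

#' ADA glycemic classification
#'
#' Classifies each participant as T2D, CGI, IFG, IGT or NGT from fasting and
#' 2-h OGTT glucose and HbA1c. Thresholds follow the ADA criteria (fasting
#' 5.6 / 7.0 mmol/L, 2-h 7.8 / 11.1 mmol/L, HbA1c 6.5 %) and can be
#' overridden.
#'
#' @param glucose_0,glucose_120 mmol/L; both required per participant.
#' @param hba1c Percent; optional (`NA` treated as non-diabetic on that
#'   criterion).
#' @param thresholds Named list overriding `ifg_lo`, `dm_fasting`, `igt_lo`,
#'   `dm_2h`, `dm_hba1c`.
#' @return Factor with levels NGT, IFG, IGT, CGI, T2D; `NA` where a required
#'   input is missing.
#' @export
ada_classify <- function(glucose_0, glucose_120, hba1c = NA_real_,
                         thresholds = list()) {
  th <- utils::modifyList(list(ifg_lo = 5.6, dm_fasting = 7.0,
                               igt_lo = 7.8, dm_2h = 11.1, dm_hba1c = 6.5),
                          thresholds)
  n <- max(length(glucose_0), length(glucose_120), length(hba1c))
  glucose_0 <- rep_len(glucose_0, n)
  glucose_120 <- rep_len(glucose_120, n)
  hba1c <- rep_len(hba1c, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(glucose_0) & !is.na(glucose_120)
  t2d <- ok & (glucose_0 >= th$dm_fasting | glucose_120 >= th$dm_2h |
                 (!is.na(hba1c) & hba1c >= th$dm_hba1c))
  ifg <- ok & !t2d & glucose_0 >= th$ifg_lo & glucose_0 < th$dm_fasting
  igt <- ok & !t2d & glucose_120 >= th$igt_lo & glucose_120 < th$dm_2h
  out[t2d] <- "T2D"
  out[ifg & igt] <- "CGI"
  out[ifg & !igt] <- "IFG"
  out[!ifg & igt] <- "IGT"
  out[ok & !t2d & !ifg & !igt] <- "NGT"
  factor(out, levels = c("NGT", "IFG", "IGT", "CGI", "T2D"))
}

#' Coefficients of variation per variable and group
#'
#' CV = sample SD (n-1 denominator) / mean, computed per (variable, group);
#' `NA` when a group has fewer than two non-missing values or a nonpositive
#' mean.
#'
#' @param table Data frame of clinical measurements.
#' @param classes Group label per row (e.g. the ADA class).
#' @param variables Columns to profile; defaults to all numeric columns.
#' @return Matrix, variables x groups, of CVs.
#' @export
cv_by_group <- function(table, classes, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  classes <- factor(classes)
  out <- matrix(NA_real_, length(variables), nlevels(classes),
                dimnames = list(variables, levels(classes)))
  for (v in variables) {
    x <- table[[v]]
    for (g in levels(classes)) {
      xs <- x[!is.na(x) & !is.na(classes) & classes == g]
      if (length(xs) >= 2 && mean(xs) > 0) {
        out[v, g] <- stats::sd(xs) / mean(xs)
      }
    }
  }
  out
}

#' Compute all derived clinical metrics
#'
#' Appends HOMA indices, OGTT glucose/insulin areas (five-point 0-180 min,
#' and the four-point 0-120 min variant `*_auc_0_120` for cohorts without
#' 3-h sampling), waist-to-hip ratio and the ADA class to a clinical table.
#'
#' @param table A `clinical_table`.
#' @return The table with derived columns appended.
#' @export
derive_metrics <- function(table) {
  g_cols <- paste0("glucose_", c(0, 30, 60, 120, 180))
  i_cols <- paste0("insulin_", c(0, 30, 60, 120, 180))
  out <- table
  h <- homa_indices(table$glucose_0, table$insulin_0)
  out$homa_ir <- h$homa_ir
  out$homa_is <- h$homa_is
  out$homa_beta <- h$homa_beta
  have5 <- function(cols) all(cols %in% names(table))
  if (have5(g_cols)) {
    out$glucose_auc <- ogtt_auc(table[, g_cols])
  }
  if (have5(i_cols)) {
    out$insulin_auc <- ogtt_auc(table[, i_cols])
  }
  g4 <- paste0("glucose_", c(0, 30, 60, 120))
  i4 <- paste0("insulin_", c(0, 30, 60, 120))
  if (all(g4 %in% names(table))) {
    out$glucose_auc_0_120 <- ogtt_auc(table[, g4], minutes = c(0, 30, 60, 120))
  }
  if (all(i4 %in% names(table))) {
    out$insulin_auc_0_120 <- ogtt_auc(table[, i4], minutes = c(0, 30, 60, 120))
  }
  if (all(c("waist", "hip") %in% names(table))) {
    out$whr <- table$waist / table$hip
  }
  if (all(c("glucose_0", "glucose_120") %in% names(table))) {
    out$ada_class <- ada_classify(table$glucose_0, table$glucose_120,
                                  if ("hba1c" %in% names(table)) table$hba1c else NA)
  }
  out
}

#' Standardized stratification matrix with outlier exclusion
#'
#' Complete cases on the stratification variables are z-scored per variable;
#' rows with any |z| at or above `outlier_z` are excluded and the retained
#' rows re-standardized. By default this is a single exclusion pass (the
#' re-standardized matrix may contain new marginal outliers); with
#' `iterate = TRUE` the exclude/re-standardize cycle runs to a fixed point.
#'
#' @param table A `clinical_table`.
#' @param variables Stratification variable names (default the 16 canonical
#'   ones).
#' @param outlier_z Exclusion threshold on |z| (default 5).
#' @param iterate Iterate exclusion to a fixed point (default `FALSE`).
#' @param min_rows Minimum retained rows (default 40, twice the top of the
#'   default k range).
#' @return A `strat_matrix`: list with `z` (retained rows x variables),
#'   `center`, `scale` (the retained-set means/SDs on the raw scale),
#'   `excluded` (data frame id/reason).
#' @export
build_stratification_matrix <- function(table, variables = STRAT_VARIABLES,
                                        outlier_z = 5, iterate = FALSE,
                                        min_rows = 40L) {
  miss_v <- setdiff(variables, names(table))
  if (length(miss_v)) stop("missing stratification variables: ",
                           paste(miss_v, collapse = ", "))
  x <- as.matrix(table[, variables])
  rownames(x) <- table$participant_id
  cc <- stats::complete.cases(x)
  excluded <- data.frame(participant_id = rownames(x)[!cc],
                         reason = rep("missing", sum(!cc)))
  x <- x[cc, , drop = FALSE]
  repeat {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance stratification variable(s): ",
           paste(variables[sds == 0], collapse = ", "))
    }
    z <- scale(x)
    out_rows <- apply(abs(z) >= outlier_z, 1, any)
    if (any(out_rows)) {
      excluded <- rbind(excluded,
                        data.frame(participant_id = rownames(x)[out_rows],
                                   reason = rep("outlier", sum(out_rows))))
      x <- x[!out_rows, , drop = FALSE]
      if (!iterate) {  # single pass: re-standardize once and stop
        z <- scale(x)
        break
      }
    } else break
  }
  if (nrow(x) < min_rows) {
    stop("only ", nrow(x), " rows retained; need at least ", min_rows)
  }
  structure(list(z = z[, , drop = FALSE],
                 center = attr(z, "scaled:center"),
                 scale = attr(z, "scaled:scale"),
                 excluded = excluded),
            class = "strat_matrix")
}

#' @export
print.strat_matrix <- function(x, ...) {
  cat("strat_matrix:", nrow(x$z), "participants x", ncol(x$z),
      "standardized variables;", nrow(x$excluded), "excluded\n")
  invisible(x)
}
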