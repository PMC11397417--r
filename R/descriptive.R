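#' Descriptive summary of a measurement series
#'
#' Reports n, min, max, mean, median, sample SD (n-1), SE = SD/sqrt(n) and
#' the coefficient of variation CV = 100 SD / mean, the statistics used for
#' the per-variable survey summaries (SD whiskers, SE box, median line).
#'
#' @param values Numeric vector (no NAs).
#' @param variable Variable name carried into the output.
#' @return One-row data.frame with columns variable, n, min, max, mean,
#'   median, sd, se, cv_percent, cv_defined.
#' @export
summarize_values <- function(values, variable = "x") {
  if (length(values) == 0L) stop("empty input for '", variable, "'")
  if (anyNA(values)) stop("NA values in '", variable, "'")
  n <- length(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  se <- if (n >= 2) s / sqrt(n) else NA_real_
  m <- mean(values)
  cv_defined <- n >= 2 && !(m == 0 && s > 0)
  cv <- if (!cv_defined || n < 2) NA_real_ else 100 * s / m
  data.frame(variable = variable, n = n,
             min = min(values), max = max(values),
             mean = m, median = stats::median(values),
             sd = s, se = se, cv_percent = cv, cv_defined = cv_defined,
             stringsAsFactors = FALSE)
}

#' Descriptive summaries for a whole table
#'
#' @param table A \code{\link{measurement_table}}.
#' @param by \code{"overall"} (one row per variable) or \code{"region"}
#'   (one row per region x variable).
#' @param panel Optional \code{\link{variable_panel}} restricting variables.
#' @return Data.frame of stacked \code{\link{summarize_values}} rows (with a
#'   \code{region} column when \code{by = "region"}).
#' @export
describe_table <- function(table, by = c("overall", "region"), panel = NULL) {
  by <- match.arg(by)
  vars <- if (is.null(panel)) measurement_vars(table) else panel$members
  check_complete(table, vars, "describe")
  if (by == "overall") {
    do.call(rbind, lapply(vars, function(v)
      summarize_values(table[[v]], v)))
  } else {
    out <- list()
    for (r in unique(table$region)) {
      sub <- table[table$region == r, , drop = FALSE]
      rows <- do.call(rbind, lapply(vars, function(v)
        summarize_values(sub[[v]], v)))
      rows <- cbind(region = r, rows, stringsAsFactors = FALSE)
      out[[r]] <- rows
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
}

# Any variable used by a stage must be complete for that stage.
check_complete <- function(table, vars, stage) {
  for (v in vars) {
    if (anyNA(table[[v]])) {
      stop("stage '", stage, "' requires complete data but variable '", v,
           "' has missing values")
    }
  }
  invisible(TRUE)
}

#' Sugar-acid ratio
#'
#' Total polysaccharide divided by total acid, computed per replicate
#' (before any averaging): a mean of ratios is not a ratio of means, and the
#' indicator is defined at the sample level.
#'
#' @param total_polysaccharide Numeric vector, percent.
#' @param total_acid Numeric vector, percent, strictly positive.
#' @return Elementwise quotient (dimensionless).
#' @export
sugar_acid_ratio <- function(total_polysaccharide, total_acid) {
  if (any(total_acid <= 0)) {
    stop("total_acid must be strictly positive to form the sugar-acid ratio")
  }
  total_polysaccharide / total_acid
}

#' Fit a linear calibration line
#'
#' Ordinary least squares of instrument response on standard concentration,
#' as used for HPLC quantitation of L-malic acid and AA-2\eqn{\beta}G.
#'
#' @param concentrations Standard concentrations (mg/mL), >= 3 distinct.
#' @param responses Instrument responses (e.g. peak areas).
#' @param analyte Analyte name.
#' @return An object of class \code{calibration_line} with slope, intercept,
#'   r_squared and valid_range (the span of the standards).
#' @export
fit_calibration <- function(concentrations, responses, analyte = "analyte") {
  if (length(concentrations) < 3L || length(responses) != length(concentrations)) {
    stop("calibration requires >= 3 (concentration, response) pairs")
  }
  if (stats::var(concentrations) == 0) {
    stop("calibration concentrations have zero variance")
  }
  fit <- stats::lm(responses ~ concentrations)
  structure(list(analyte = analyte,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = unname(stats::cor(concentrations, responses)^2),
                 valid_range = range(concentrations)),
            class = "calibration_line")
}

#' Construct a calibration line from published coefficients
#'
#' @param slope,intercept Line coefficients (response = slope x conc + int).
#' @param valid_range Length-2 numeric, low < high (mg/mL).
#' @param r_squared Optional published coefficient of determination.
#' @param analyte Analyte name.
#' @return A \code{calibration_line}.
#' @export
calibration_line <- function(slope, intercept, valid_range,
                             r_squared = NA_real_, analyte = "analyte") {
  stopifnot(length(valid_range) == 2L, valid_range[1] < valid_range[2])
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]")
  }
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = r_squared, valid_range = valid_range),
            class = "calibration_line")
}

#' Inverse-predict concentration from a calibration line
#'
#' @param line A \code{calibration_line}.
#' @param response Observed instrument response(s).
#' @return Data.frame with \code{concentration} (mg/mL) and
#'   \code{extrapolated} (outside the line's valid range).
#' @export
quantify <- function(line, response) {
  stopifnot(inherits(line, "calibration_line"))
  if (line$slope == 0) stop("zero slope: concentration is unidentifiable")
  conc <- (response - line$intercept) / line$slope
  data.frame(concentration = conc,
             extrapolated = conc < line$valid_range[1] |
                            conc > line$valid_range[2])
}
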