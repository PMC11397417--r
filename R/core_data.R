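#' Define a named panel of variables
#'
#' A panel groups the columns of a measurement table by role: the mineral
#' elements assayed by ICP-MS, or the phytochemical quality indicators
#' (total polysaccharide, total acid, sugar-acid ratio, total polyphenols,
#' L-malic acid, AA-2\eqn{\beta}G).
#'
#' @param name Panel name (e.g. \code{"minerals"}).
#' @param members Character vector of distinct variable names, in order.
#' @param role Either \code{"mineral"} or \code{"quality"}.
#' @return An object of class \code{variable_panel}.
#' @export
variable_panel <- function(name, members, role = c("mineral", "quality")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L)
  members <- as.character(members)
  if (length(members) == 0L) stop("panel '", name, "' has no members")
  if (anyDuplicated(members)) {
    stop("panel '", name, "' has duplicated members: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  structure(list(name = name, members = members, role = role),
            class = "variable_panel")
}

#' @export
print.variable_panel <- function(x, ...) {
  cat("<variable_panel> ", x$name, " (", x$role, "): ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default mineral-element panel
#'
#' The eight elements of the study design: K, Ca, Zn, Mg, Cu, Fe, Se, Mn.
#' @return A \code{\link{variable_panel}}.
#' @export
mineral_panel <- function() {
  variable_panel("minerals",
                 c("K", "Ca", "Zn", "Mg", "Cu", "Fe", "Se", "Mn"),
                 role = "mineral")
}

#' Default quality-indicator panel
#'
#' The six quality and medicinal indicators: total polysaccharide, total acid,
#' sugar-acid ratio, total polyphenols, L-malic acid and AA-2\eqn{\beta}G.
#' @return A \code{\link{variable_panel}}.
#' @export
quality_panel <- function() {
  variable_panel("quality",
                 c("total_polysaccharide", "total_acid", "sugar_acid_ratio",
                   "total_polyphenols", "l_malic_acid", "aa2bg"),
                 role = "quality")
}

#' Default measurement units, as opaque labels
#'
#' Units are carried as labels and never converted (source tables are not
#' internally consistent about mineral scales, so no conversion is safe).
#' @return Named character vector variable -> unit.
#' @export
default_units <- function() {
  c(K = "g/kg", Ca = "g/kg", Zn = "ug/kg", Mg = "ug/kg", Cu = "ug/kg",
    Fe = "ug/kg", Se = "ug/kg", Mn = "ug/kg",
    total_polysaccharide = "%", total_acid = "%", sugar_acid_ratio = "ratio",
    total_polyphenols = "%", l_malic_acid = "%", aa2bg = "%")
}

#' Construct and validate a measurement table
#'
#' The universal input of the pipeline: one row per biological replicate
#' (tree-level sample), with a region code, a species label and one numeric
#' column per measured variable.
#'
#' @param df A data.frame with columns \code{sample_id}, \code{region},
#'   \code{species} and numeric measurement columns.
#' @param units Optional named character vector variable -> unit label.
#' @param panels Optional list of \code{\link{variable_panel}}s that must be
#'   present in the table.
#' @return \code{df} with class \code{measurement_table} and a \code{units}
#'   attribute.
#' @export
measurement_table <- function(df, units = NULL, panels = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("sample_id", "region", "species")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  vars <- setdiff(names(df), required)
  if (!is.null(panels)) {
    for (p in panels) {
      absent <- setdiff(p$members, vars)
      if (length(absent)) {
        stop("panel '", p$name, "' variable(s) absent from table: ",
             paste(absent, collapse = ", "))
      }
    }
  }
  if (nrow(df) == 0L) stop("measurement table has no rows")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (any(is.na(df$region)) || any(df$region == "")) {
    stop("every row must have a region")
  }
  if (any(is.na(df$species)) || any(df$species == "")) {
    stop("every row must have a species")
  }
  if (is.null(units)) units <- rep("", length(vars))
  units <- units[vars]
  names(units) <- vars
  units[is.na(units)] <- ""
  for (v in vars) {
    col <- df[[v]]
    if (!is.numeric(col)) stop("column '", v, "' is not numeric")
    bad <- which(!is.na(col) & col < 0)
    if (length(bad)) {
      stop("negative value for '", v, "' at row ", bad[1L],
           " (concentrations and percentages must be >= 0)")
    }
    if (identical(unname(units[v]), "%")) {
      over <- which(!is.na(col) & col > 100)
      if (length(over)) {
        stop("percentage '", v, "' exceeds 100 at row ", over[1L])
      }
    }
  }
  df$sample_id <- as.character(df$sample_id)
  df$region <- as.character(df$region)
  df$species <- as.character(df$species)
  attr(df, "units") <- units
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' @export
print.measurement_table <- function(x, ...) {
  vars <- measurement_vars(x)
  cat("<measurement_table> ", nrow(x), " rows, ",
      length(unique(x$region)), " regions, ", length(vars), " variables\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Variable (measurement) columns of a table
#' @param table A \code{measurement_table}.
#' @return Character vector of measurement column names.
#' @export
measurement_vars <- function(table) {
  setdiff(names(table), c("sample_id", "region", "species"))
}

#' Units attribute of a table
#' @param table A \code{measurement_table}.
#' @return Named character vector variable -> unit (possibly "").
#' @export
measurement_units <- function(table) {
  u <- attr(table, "units")
  if (is.null(u)) {
    u <- stats::setNames(rep("", length(measurement_vars(table))),
                         measurement_vars(table))
  }
  u
}

# Split "name (unit)" headers into name + unit; returns list(names, units).
parse_unit_headers <- function(headers) {
  m <- regmatches(headers, regexec("^(.*?)\\s*\\(([^()]*)\\)\\s*$", headers))
  nm <- headers
  un <- rep("", length(headers))
  for (i in seq_along(headers)) {
    if (length(m[[i]]) == 3L) {
      nm[i] <- m[[i]][2L]
      un[i] <- m[[i]][3L]
    }
  }
  list(names = nm, units = stats::setNames(un, nm))
}

#' Read a measurement table from CSV
#'
#' Comma-separated, UTF-8, "." decimal, first row header. Units may be
#' embedded in headers as \code{"K (g/kg)"}. A \code{sample_id} column is
#' generated from row order when absent. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param panels Optional list of \code{\link{variable_panel}}s to validate
#'   against.
#' @return A \code{\link{measurement_table}}.
#' @export
read_measurements <- function(path, panels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty file: ", path)
  ph <- parse_unit_headers(names(df))
  names(df) <- ph$names
  if (!("sample_id" %in% names(df))) {
    df$sample_id <- sprintf("S%03d", seq_len(nrow(df)))
  }
  vars <- setdiff(names(df), c("sample_id", "region", "species"))
  for (v in vars) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", raw[bad[1L]], "' in column '", v,
           "', row ", bad[1L])
    }
    num[raw == ""] <- NA_real_
    df[[v]] <- num
  }
  measurement_table(df, units = ph$units, panels = panels)
}

#' Write a measurement (or result) table to CSV
#'
#' Units are re-embedded in headers as \code{"name (unit)"} so that
#' \code{read_measurements(write_table(t))} reproduces \code{t}'s values to
#' full precision.
#'
#' @param table A \code{measurement_table} or plain data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(table, path) {
  df <- as.data.frame(table)
  # full precision so that read(write(t)) is the identity at value level
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "", sprintf("%.17g", df[[j]]))
    }
  }
  if (inherits(table, "measurement_table")) {
    u <- measurement_units(table)
    hdr <- names(df)
    for (i in seq_along(hdr)) {
      un <- u[hdr[i]]
      if (!is.na(un) && nzchar(un)) hdr[i] <- paste0(hdr[i], " (", un, ")")
    }
    names(df) <- hdr
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' Aggregate replicates to region level
#'
#' Collapses a replicate-level table to one row per region (the scale at
#' which scoring and PCA operate by default). The species label is carried
#' through when unanimous within a region; otherwise it is set to
#' \code{"mixed"} with a warning. Idempotent on already-aggregated tables.
#'
#' @param table A \code{\link{measurement_table}}.
#' @param statistic Aggregation statistic; only \code{"mean"} is supported.
#' @return A region-level \code{measurement_table} (sample_id = region code).
#' @export
aggregate_regions <- function(table, statistic = "mean") {
  statistic <- match.arg(statistic, "mean")
  vars <- measurement_vars(table)
  regions <- unique(table$region)
  out <- data.frame(sample_id = regions, region = regions,
                    species = NA_character_, stringsAsFactors = FALSE)
  for (v in vars) {
    out[[v]] <- vapply(regions, function(r) {
      mean(table[[v]][table$region == r])
    }, numeric(1))
  }
  mixed <- character(0)
  out$species <- vapply(regions, function(r) {
    sp <- unique(table$species[table$region == r])
    if (length(sp) > 1L) {
      mixed <<- c(mixed, r)
      "mixed"
    } else sp
  }, character(1))
  if (length(mixed)) {
    warning("mixed species within region(s) ", paste(mixed, collapse = ", "),
            "; species set to 'mixed'")
  }
  measurement_table(out, units = measurement_units(table))
}
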