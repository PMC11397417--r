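# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards. All package randomness flows through this.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Repair a correlation matrix to the nearest positive semi-definite one
#'
#' Eigenvalues below \code{eps} are clipped to \code{eps}, the matrix is
#' rebuilt and its diagonal renormalized to 1. Deterministic.
#'
#' @param mat Symmetric matrix with unit diagonal, entries in [-1, 1].
#' @param eps Clipping floor for eigenvalues (default 1e-8).
#' @return A positive semi-definite correlation matrix.
#' @export
nearest_psd_correlation <- function(mat, eps = 1e-8) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-12) stop("correlation matrix not symmetric")
  if (any(abs(diag(mat) - 1) > 1e-12)) stop("correlation diagonal must be 1")
  if (any(mat < -1 - 1e-12 | mat > 1 + 1e-12)) {
    stop("correlation entries must lie in [-1, 1]")
  }
  e <- eigen(mat, symmetric = TRUE)
  if (min(e$values) >= eps) return(mat)
  vals <- pmax(e$values, eps)
  m <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  dimnames(m) <- dimnames(mat)
  (m + t(m)) / 2
}

# Region-mean ranges (low, high) reported for the twelve-region survey.
default_mean_ranges <- function() {
  list(
    K = c(3.89, 5.44), Ca = c(0.89, 2.32), Zn = c(31.11, 102.15),
    Mg = c(4.27, 10.23), Cu = c(4.22, 13.52), Fe = c(0.53, 2.03),
    Se = c(0.63, 2.16), Mn = c(0.24, 0.73),
    total_polysaccharide = c(16.35, 38.50), total_acid = c(0.81, 3.34),
    sugar_acid_ratio = c(7.21, 31.69), total_polyphenols = c(1.27, 3.81),
    l_malic_acid = c(0.65, 2.13), aa2bg = c(1.56, 4.55)
  )
}

# Per-variable coefficients of variation (%) reported for the survey.
default_cvs <- function() {
  c(K = 5.82, Ca = 18.43, Zn = 32.95, Mg = 20.22, Cu = 27.03, Fe = 31.55,
    Se = 31.88, Mn = 22.05,
    total_polysaccharide = 17.37, total_acid = 32.50, sugar_acid_ratio = 49.50,
    total_polyphenols = 23.14, l_malic_acid = 28.06, aa2bg = 23.03)
}

# Reported pairwise Pearson correlations seeded into the target structure.
default_correlation_seeds <- function() {
  list(
    list("K", "Mg", -0.48), list("K", "Mn", 0.29),
    list("Ca", "Zn", 0.42), list("Ca", "Mg", 0.51),
    list("Ca", "Fe", -0.56), list("Ca", "Mn", -0.37),
    list("Zn", "Se", 0.72),
    list("Mg", "Cu", -0.33), list("Mg", "Mn", -0.46),
    list("Cu", "Fe", -0.59), list("Fe", "Mn", 0.43),
    list("Se", "Mn", -0.55),
    list("total_polysaccharide", "sugar_acid_ratio", 0.32),
    list("total_acid", "sugar_acid_ratio", -0.86),
    list("total_acid", "total_polyphenols", 0.70),
    list("total_acid", "l_malic_acid", 0.31),
    list("total_acid", "aa2bg", 0.83),
    list("sugar_acid_ratio", "total_polyphenols", -0.48),
    list("sugar_acid_ratio", "l_malic_acid", -0.30),
    list("sugar_acid_ratio", "aa2bg", -0.71),
    list("total_polyphenols", "l_malic_acid", 0.59),
    list("total_polyphenols", "aa2bg", 0.47)
  )
}

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the study design: 12 production regions with 4 tree-level
#' replicates each, 8 mineral elements plus 6 quality indicators, region-mean
#' ranges and per-variable CVs matching the survey's reported summaries, and a
#' replicate-level target correlation seeded from the reported pairwise
#' Pearson values (repaired to positive semi-definite).
#'
#' @param n_regions Number of regions (default 12).
#' @param n_replicates Replicates per region (default 4).
#' @param panels List of \code{\link{variable_panel}}s (default minerals +
#'   quality).
#' @param region_mean_ranges Named list variable -> c(low, high).
#' @param within_region_cv Named numeric, CV in percent per variable.
#' @param target_correlation Optional correlation matrix over all variables;
#'   defaults to identity seeded with the reported pairwise values.
#' @param noise Noise model: \code{"gaussian"} (mean x (1 + CV/100 z)) or
#'   \code{"lognormal"}.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_regions = 12, n_replicates = 4,
                              panels = list(mineral_panel(), quality_panel()),
                              region_mean_ranges = default_mean_ranges(),
                              within_region_cv = default_cvs(),
                              target_correlation = NULL,
                              noise = c("gaussian", "lognormal"),
                              seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_regions >= 1, n_replicates >= 1)
  vars <- unlist(lapply(panels, `[[`, "members"))
  if (anyDuplicated(vars)) stop("panels share variable names")
  miss <- setdiff(vars, names(region_mean_ranges))
  if (length(miss)) stop("no mean range for: ", paste(miss, collapse = ", "))
  miss <- setdiff(vars, names(within_region_cv))
  if (length(miss)) stop("no CV for: ", paste(miss, collapse = ", "))
  if (any(within_region_cv[vars] < 0)) stop("CVs must be >= 0")
  p <- length(vars)
  if (is.null(target_correlation)) {
    target_correlation <- diag(p)
    dimnames(target_correlation) <- list(vars, vars)
    for (s in default_correlation_seeds()) {
      if (s[[1]] %in% vars && s[[2]] %in% vars) {
        target_correlation[s[[1]], s[[2]]] <- s[[3]]
        target_correlation[s[[2]], s[[1]]] <- s[[3]]
      }
    }
  }
  target_correlation <- target_correlation[vars, vars, drop = FALSE]
  target_correlation <- nearest_psd_correlation(target_correlation)
  structure(list(n_regions = n_regions, n_replicates = n_replicates,
                 panels = panels, variables = vars,
                 region_mean_ranges = region_mean_ranges[vars],
                 within_region_cv = within_region_cv[vars],
                 target_correlation = target_correlation,
                 noise = noise, seed = as.integer(seed)),
            class = "simulation_config")
}

region_codes <- function(n) paste0("M", seq_len(n))

# Build the replicate-level table around a matrix of planted region means.
simulate_replicates <- function(config, region_means, cvs = NULL) {
  vars <- config$variables
  if (is.null(cvs)) cvs <- config$within_region_cv
  n_rep <- config$n_replicates
  n_reg <- config$n_regions
  L <- chol(config$target_correlation + diag(1e-10, length(vars)))
  rows <- vector("list", n_reg)
  for (r in seq_len(n_reg)) {
    z <- matrix(stats::rnorm(n_rep * length(vars)), nrow = n_rep) %*% L
    colnames(z) <- vars
    vals <- matrix(NA_real_, n_rep, length(vars),
                   dimnames = list(NULL, vars))
    for (j in seq_along(vars)) {
      mu <- region_means[r, vars[j]]
      cv <- cvs[[vars[j]]] / 100
      vals[, j] <- switch(config$noise,
        gaussian = mu * (1 + cv * z[, j]),
        lognormal = {
          sigma <- sqrt(log1p(cv^2))
          mu * exp(sigma * z[, j] - sigma^2 / 2)
        })
    }
    vals[vals <= 0] <- 1e-6
    rows[[r]] <- vals
  }
  vals <- do.call(rbind, rows)
  regions <- rep(region_codes(n_reg), each = n_rep)
  df <- data.frame(
    sample_id = sprintf("%s_rep%d", regions, rep(seq_len(n_rep), n_reg)),
    region = regions,
    species = "Malus toringoides",
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(vals))
  # cap simulated percentages at 100 so the table validates
  u <- default_units()[config$variables]
  u[is.na(u)] <- ""
  for (j in which(u == "%")) df[[config$variables[j]]] <-
    pmin(df[[config$variables[j]]], 100)
  measurement_table(df, units = u)
}

quality_members <- function(config) {
  for (p in config$panels) if (p$role == "quality") return(p$members)
  character(0)
}

# Composite criterion declared for planted truth: mean z-score of the
# quality-panel region means, ordered descending (ties by region code).
composite_order <- function(region_means, quality_vars) {
  if (length(quality_vars) == 0) return(NULL)
  z <- scale(region_means[, quality_vars, drop = FALSE])
  if (any(!is.finite(z))) return(NULL)
  comp <- rowMeans(z)
  rownames(region_means)[order(-comp, rownames(region_means))]
}

#' Generate a synthetic multi-region study
#'
#' Region means are drawn uniformly within each variable's configured range;
#' replicate values are the region mean times \code{(1 + CV/100 z)} with
#' \code{z} correlated standard normals (via a triangular factor of the
#' target correlation), floored at a small positive epsilon.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list with \code{table} (a \code{\link{measurement_table}}) and
#'   \code{truth} (planted region means, declared composite ordering, seed).
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_private_seed(config$seed, {
    vars <- config$variables
    region_means <- matrix(
      NA_real_, config$n_regions, length(vars),
      dimnames = list(region_codes(config$n_regions), vars))
    for (j in seq_along(vars)) {
      rg <- config$region_mean_ranges[[vars[j]]]
      region_means[, j] <- stats::runif(config$n_regions, rg[1], rg[2])
    }
    table <- simulate_replicates(config, region_means)
    truth <- structure(
      list(region_means = region_means,
           true_order = composite_order(region_means, quality_members(config)),
           order_defined = TRUE, seed = config$seed),
      class = "planted_truth")
    list(table = table, truth = truth)
  })
}

#' Generate a study with a planted region ordering
#'
#' Quality-indicator region means are placed on an equally spaced, monotone
#' grid across each variable's configured range, so the quality composite
#' increases strictly with rank. The within-region noise SD of each quality
#' variable is derived as (per-step mean gap) / \code{effect_size}, making
#' \code{effect_size} the exact signal-to-noise ratio of one rank step.
#' Mineral means remain uniform draws. \code{effect_size = 0} plants no
#' gradient and declares the ordering undefined.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param effect_size Non-negative real, standard deviations per rank step.
#' @return As \code{\link{generate_study}}; \code{truth$true_order} is the
#'   planted ordering (best region first) or NULL when undefined.
#' @export
plant_ordering <- function(config = simulation_config(), effect_size) {
  stopifnot(inherits(config, "simulation_config"), effect_size >= 0)
  with_private_seed(config$seed + 1L, {
    vars <- config$variables
    qvars <- quality_members(config)
    n_reg <- config$n_regions
    region_means <- matrix(NA_real_, n_reg, length(vars),
                           dimnames = list(region_codes(n_reg), vars))
    cvs <- as.list(config$within_region_cv)
    for (j in seq_along(vars)) {
      rg <- config$region_mean_ranges[[vars[j]]]
      v <- vars[j]
      if (effect_size > 0 && v %in% qvars && n_reg > 1) {
        region_means[, j] <- seq(rg[1], rg[2], length.out = n_reg)
        step <- (rg[2] - rg[1]) / (n_reg - 1)
        mid <- mean(rg)
        cvs[[v]] <- 100 * (step / effect_size) / mid
      } else {
        region_means[, j] <- stats::runif(n_reg, rg[1], rg[2])
      }
    }
    table <- simulate_replicates(config, region_means, cvs = cvs)
    defined <- effect_size > 0 && length(qvars) > 0 && n_reg > 1
    truth <- structure(
      list(region_means = region_means,
           true_order = if (defined)
             rev(region_codes(n_reg)) else NULL,
           order_defined = defined, seed = config$seed),
      class = "planted_truth")
    list(table = table, truth = truth)
  })
}
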