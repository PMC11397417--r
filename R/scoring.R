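#' Component scores H_k from standardized indicators
#'
#' H_rk = sum_j Z_rj w_jk: each region's score on component k is the linear
#' combination of its standardized indicator values with the component-score
#' coefficients — exactly the structure of the published H_1..H_3 formulas.
#'
#' @param z A \code{\link{standardize}} result.
#' @param model A \code{\link{pca_correlation}} model fitted on the same
#'   variables in the same order.
#' @param k Number of components to score.
#' @return Matrix regions x k of component scores.
#' @export
component_scores <- function(z, model, k) {
  stopifnot(inherits(z, "ztable"), inherits(model, "pca_model"))
  if (!identical(z$variables, model$variables)) {
    stop("variable order of the z-table does not match the PCA model")
  }
  if (k < 1 || k > model$n_variables) stop("k must be in 1..", model$n_variables)
  h <- z$z %*% model$csc[, seq_len(k), drop = FALSE]
  colnames(h) <- paste0("H", seq_len(k))
  h
}

#' Variance-contribution weights for the composite score
#'
#' weight_i = v_i / sum_{j <= k} v_j with the unrounded variance
#' contributions; weights sum to 1. With \code{rounded = TRUE} the
#' contributions are first rounded to two decimals of weight (reproducing a
#' published formula like 0.63/0.27/0.10 literally, without renormalizing).
#'
#' @param model A \code{pca_model}.
#' @param k Number of retained components.
#' @param rounded Use two-decimal rounded weights (not renormalized).
#' @return Numeric weight vector of length k.
#' @export
composite_weights <- function(model, k, rounded = FALSE) {
  stopifnot(inherits(model, "pca_model"))
  if (k < 1) stop("k must be >= 1")
  v <- model$variability_percent[seq_len(k)]
  w <- v / sum(v)
  if (rounded) w <- round(w, 2)
  w
}

#' Comprehensive score H_0
#'
#' h0_r = sum_k weight_k H_rk.
#'
#' @param h Matrix regions x components of component scores.
#' @param weights Weight vector, length = ncol(h).
#' @return Numeric vector of comprehensive scores, named by region.
#' @export
composite_score <- function(h, weights) {
  h <- as.matrix(h)
  if (ncol(h) != length(weights)) {
    stop("weights length (", length(weights), ") != score columns (",
         ncol(h), ")")
  }
  drop(h %*% weights)
}

#' Rank regions by comprehensive score
#'
#' Descending order; ties broken deterministically by region code and
#' flagged.
#'
#' @param h0 Named numeric vector of comprehensive scores.
#' @param regions Optional region names (defaults to \code{names(h0)}).
#' @return Data.frame with rank, region, h0, tied.
#' @export
rank_regions <- function(h0, regions = names(h0)) {
  if (any(!is.finite(h0))) stop("non-finite comprehensive score")
  if (is.null(regions)) stop("region names required")
  ord <- order(-h0, regions)
  tied <- duplicated(h0[ord]) | duplicated(h0[ord], fromLast = TRUE)
  data.frame(rank = seq_along(h0), region = regions[ord],
             h0 = unname(h0[ord]), tied = tied,
             stringsAsFactors = FALSE)
}

#' Comprehensive quality evaluation of a multi-region study
#'
#' End-to-end procedure: aggregate replicates to region means, standardize
#' the quality panel, correlation-matrix PCA, retain k components, compute
#' component scores H_k, weight them by their variance contributions and
#' rank regions by the comprehensive score H_0.
#'
#' @param table A replicate- or region-level \code{\link{measurement_table}}.
#' @param panel Indicator panel (default \code{\link{quality_panel}()}).
#' @param retain Retention rule, a list such as \code{list(rule = "fixed_k",
#'   k = 3)} — see \code{\link{retain_components}}.
#' @param aggregate Aggregate to region means first (default TRUE; the scale
#'   at which one score per region is defined).
#' @param rounded_weights Use two-decimal weights (see
#'   \code{\link{composite_weights}}).
#' @return An object of class \code{composite_scores}: regions, h (score
#'   matrix), weights, h0, ranking, eigen_table (PCA summary), model, checks
#'   (score-variance identity diagnostics).
#' @export
evaluate_quality <- function(table, panel = quality_panel(),
                             retain = list(rule = "fixed_k", k = 3),
                             aggregate = TRUE, rounded_weights = FALSE) {
  if (aggregate) table <- aggregate_regions(table)
  z <- standardize(table, panel)
  model <- pca_correlation(z)
  k <- retain_components(model, rule = retain$rule, k = retain$k,
                         threshold = retain$threshold)
  h <- component_scores(z, model, k)
  w <- composite_weights(model, k, rounded = rounded_weights)
  h0 <- stats::setNames(composite_score(h, w), z$regions)
  ranking <- rank_regions(h0)
  eigen_table <- data.frame(
    component = paste0("PC", seq_len(model$n_variables)),
    eigenvalue = model$eigenvalues,
    variability_percent = model$variability_percent,
    cumulative_percent = model$cumulative_percent)
  checks <- list(
    score_means = colMeans(h),
    score_variance_minus_eigenvalue =
      apply(h, 2, stats::var) - model$eigenvalues[seq_len(k)],
    weights_sum = sum(w))
  structure(list(regions = z$regions, h = h, weights = w, h0 = h0,
                 ranking = ranking, eigen_table = eigen_table,
                 model = model, k = k, checks = checks),
            class = "composite_scores")
}

#' @export
print.composite_scores <- function(x, ...) {
  cat("Comprehensive quality scores (", x$k, " components; weights ",
      paste(sprintf("%.3f", x$weights), collapse = "/"), ")\n", sep = "")
  tab <- cbind(as.data.frame(round(x$h, 3)), H0 = round(x$h0, 3))
  print(tab)
  cat("Ranking:", paste(x$ranking$region, collapse = " > "), "\n")
  invisible(x)
}
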