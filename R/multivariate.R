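#' Column-standardize a region-level table
#'
#' Z-scores each panel variable (mean 0, sample SD 1, n-1 denominator),
#' retaining center and scale for inverse transforms. This is the Z_1..Z_p
#' input of the component-score formulas.
#'
#' @param table A region-level \code{\link{measurement_table}} (>= 2 rows).
#' @param panel A \code{\link{variable_panel}} or character vector.
#' @return An object of class \code{ztable}: list(z, regions, variables,
#'   center, scale).
#' @export
standardize <- function(table, panel) {
  vars <- if (inherits(panel, "variable_panel")) panel$members else panel
  check_complete(table, vars, "standardize")
  if (nrow(table) < 2L) stop("standardization needs >= 2 rows")
  x <- as.matrix(as.data.frame(table)[vars])
  rownames(x) <- table$region
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- vars[scl == 0]
  if (length(zero)) {
    stop("zero-variance variable(s): ", paste(zero, collapse = ", "))
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(z = z, regions = rownames(x), variables = vars,
                 center = ctr, scale = scl),
            class = "ztable")
}

#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the sample correlation matrix of the standardized
#' columns. Components are ordered by descending eigenvalue; each eigenvector
#' is oriented so its largest-|loading| entry is positive. Factor loadings
#' are a_jk = e_jk sqrt(lambda_k); component-score coefficients (the weights
#' applied to Z_j in the H_k formulas) are w_jk = a_jk / sqrt(lambda_k), i.e.
#' the eigenvector entries themselves. Variance contributions are
#' v_k = 100 lambda_k / p.
#'
#' @param z A \code{\link{standardize}} result.
#' @return An object of class \code{pca_model}: eigenvalues, eigenvectors,
#'   loadings, csc, variability_percent, cumulative_percent, n_variables.
#' @export
pca_correlation <- function(z) {
  stopifnot(inherits(z, "ztable"))
  if (any(!is.finite(z$z))) stop("non-finite values in standardized input")
  R <- stats::cor(z$z)
  e <- eigen(R, symmetric = TRUE)
  vals <- e$values
  vals[vals < 1e-12] <- 0
  vecs <- e$vectors
  p <- ncol(R)
  for (k in seq_len(p)) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  dimnames(vecs) <- list(z$variables, paste0("PC", seq_len(p)))
  loadings <- sweep(vecs, 2, sqrt(vals), "*")
  csc <- vecs
  v <- 100 * vals / p
  structure(list(eigenvalues = vals, eigenvectors = vecs,
                 loadings = loadings, csc = csc,
                 variability_percent = v, cumulative_percent = cumsum(v),
                 n_variables = p, variables = z$variables,
                 correlation = R),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("Correlation-matrix PCA on", x$n_variables, "variables\n")
  tab <- rbind(Eigenvalue = x$eigenvalues,
               `Variability (%)` = x$variability_percent,
               `Cumulative (%)` = x$cumulative_percent)
  colnames(tab) <- colnames(x$loadings)
  print(round(tab, 3))
  invisible(x)
}

#' Variance contributions of a PCA model
#'
#' @param model A \code{\link{pca_correlation}} result.
#' @return List with \code{variability_percent} (100 lambda_k / p) and
#'   \code{cumulative_percent}.
#' @export
variance_contributions <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  list(variability_percent = model$variability_percent,
       cumulative_percent = model$cumulative_percent)
}

#' Choose how many components to retain
#'
#' @param model A \code{pca_model}.
#' @param rule \code{"fixed_k"}, \code{"cumulative_threshold"} or
#'   \code{"kaiser"} (eigenvalue > 1).
#' @param k Number of components for \code{"fixed_k"}.
#' @param threshold Cumulative fraction (0-1) or percent for
#'   \code{"cumulative_threshold"}.
#' @return Integer number of retained components.
#' @export
retain_components <- function(model,
                              rule = c("fixed_k", "cumulative_threshold",
                                       "kaiser"),
                              k = NULL, threshold = NULL) {
  rule <- match.arg(rule)
  p <- model$n_variables
  switch(rule,
    fixed_k = {
      if (is.null(k) || k < 1 || k > p) stop("k must be in 1..", p)
      as.integer(k)
    },
    cumulative_threshold = {
      if (is.null(threshold)) stop("threshold required")
      if (threshold <= 1) threshold <- 100 * threshold
      as.integer(which(model$cumulative_percent >= threshold)[1L])
    },
    kaiser = as.integer(sum(model$eigenvalues > 1)))
}

#' Agglomerative hierarchical clustering (complete linkage, Euclidean)
#'
#' Wraps the standard agglomerative algorithm (complete linkage is monotone,
#' so merge heights are non-decreasing). Accepts either a numeric matrix of
#' row profiles or a precomputed \code{dist}.
#'
#' @param x Numeric matrix with rownames, or a \code{dist}.
#' @param metric Distance metric for matrix input (\code{"euclidean"}).
#' @param linkage Linkage method (\code{"complete"}).
#' @return An \code{hclust} object (metric recorded in \code{$dist.method}).
#' @export
hcluster <- function(x, metric = "euclidean", linkage = "complete") {
  metric <- match.arg(metric, "euclidean")
  linkage <- match.arg(linkage, "complete")
  d <- if (inherits(x, "dist")) x else {
    if (any(!is.finite(as.matrix(x)))) stop("non-finite values in input")
    stats::dist(as.matrix(x), method = metric)
  }
  if (any(!is.finite(d))) stop("non-finite distances")
  if (attr(d, "Size") < 2L) stop("clustering needs >= 2 rows")
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into k clusters
#'
#' Labels are canonicalized by first appearance in the table's row order
#' (cluster 1 contains the first row).
#'
#' @param dendrogram An \code{hclust} object.
#' @param k Number of clusters, 1 <= k <= leaves.
#' @return Named integer vector region/row -> cluster label.
#' @export
cut_clusters <- function(dendrogram, k) {
  n_leaves <- length(dendrogram$order)
  if (k < 1 || k > n_leaves) stop("k must be in 1..", n_leaves)
  raw <- stats::cutree(dendrogram, k = k)
  first <- unique(raw)
  relabel <- stats::setNames(seq_along(first), first)
  out <- relabel[as.character(raw)]
  names(out) <- names(raw)
  out
}
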