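#' One-way fixed-effects ANOVA
#'
#' Classical between/within decomposition of one variable across region
#' groups: F = MS_between / MS_within with p from the F distribution.
#'
#' @param table A \code{\link{measurement_table}}.
#' @param variable Name of the measurement column to test.
#' @param group Grouping column (default \code{"region"}).
#' @return An object of class \code{anova_result} with f_stat, df_between,
#'   df_within, p_value, mse (within-group mean square), group_means,
#'   group_ns, and a \code{degenerate} flag when all values are identical.
#' @export
one_way_anova <- function(table, variable, group = "region") {
  check_complete(table, variable, "compare")
  y <- table[[variable]]
  g <- as.character(table[[group]])
  ns <- table(g)
  if (length(ns) < 2L) stop("ANOVA requires >= 2 groups")
  if (any(ns < 2L)) {
    stop("group(s) with < 2 replicates: ",
         paste(names(ns)[ns < 2], collapse = ", "))
  }
  means <- tapply(y, g, mean)
  N <- length(y)
  k <- length(ns)
  ssb <- sum(ns * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  df_b <- k - 1L
  df_w <- N - k
  msb <- ssb / df_b
  mse <- ssw / df_w
  degenerate <- ssw == 0 && ssb == 0
  f <- if (degenerate) NA_real_ else if (ssw == 0) Inf else msb / mse
  p <- if (degenerate) NA_real_ else
    if (is.infinite(f)) 0 else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(variable = variable, f_stat = f,
                 df_between = df_b, df_within = df_w, p_value = p, mse = mse,
                 group_means = means[order(names(means))],
                 group_ns = ns[order(names(ns))],
                 degenerate = degenerate),
            class = "anova_result")
}

# Duncan critical range for means p ranks apart: R_p = q(alpha_p, p, df) *
# sqrt(MSE / n_h), with protection level alpha_p = 1 - (1 - alpha)^(p - 1)
# and q the studentized-range quantile.
duncan_critical_range <- function(alpha, p, df, mse, n_h) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  q <- stats::qtukey(1 - alpha_p, nmeans = p, df = df)
  if (!is.finite(q)) stop("studentized-range quantile unavailable (df = ", df, ")")
  q * sqrt(mse / n_h)
}

# Pairwise non-significance under Duncan's step-down rule on means sorted in
# descending order: a span is non-significant if its range fails R_p or it is
# contained in a larger non-significant span. Returns a logical matrix
# (TRUE = not significantly different) over the sorted means.
duncan_nonsig_matrix <- function(means_sorted, ns_sorted, mse, df, alpha) {
  k <- length(means_sorted)
  nonsig <- diag(TRUE, k)
  if (k < 2L) return(nonsig)
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (nonsig[i, j]) next  # already absorbed by a wider span
      n_h <- 2 / (1 / ns_sorted[i] + 1 / ns_sorted[j])
      rp <- duncan_critical_range(alpha, span, df, mse, n_h)
      if (abs(means_sorted[i] - means_sorted[j]) <= rp) {
        nonsig[i:j, i:j] <- TRUE  # protection: sub-ranges inherit
      }
    }
  }
  nonsig
}

# Compact letter display from an interval-closed non-significance matrix:
# letters are the maximal non-significant spans (insert-and-absorb), assigned
# a, b, c, ... in order of descending means.
letters_from_nonsig <- function(nonsig) {
  k <- nrow(nonsig)
  spans <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    spans[[i]] <- c(i, j)
  }
  # absorb spans contained in an earlier (wider) one
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (h in seq_len(k)) {
      if (h != i && keep[h] &&
          spans[[h]][1] <= spans[[i]][1] && spans[[i]][2] <= spans[[h]][2] &&
          !(spans[[h]][1] == spans[[i]][1] && spans[[h]][2] == spans[[i]][2])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  maximal <- unique(spans[keep])
  out <- character(k)
  for (s in seq_along(maximal)) {
    rng <- maximal[[s]]
    idx <- rng[1]:rng[2]
    out[idx] <- paste0(out[idx], letters[s])
  }
  out
}

#' Duncan's new multiple range test with compact letters
#'
#' Sorts group means descending and declares means p ranks apart different
#' when their gap exceeds R_p = q(alpha_p, p, df_within) sqrt(MSE / n_h),
#' where alpha_p = 1 - (1 - alpha)^(p-1) is Duncan's protection level, q the
#' studentized-range quantile and n_h the harmonic mean of the two group
#' sizes. Non-significant spans share lowercase letters (a, b, ... in order
#' of descending means), the convention of the survey's box plots.
#'
#' @param anova An \code{\link{one_way_anova}} result.
#' @param alpha Significance level (default 0.05).
#' @return An object of class \code{letter_display}: a data.frame with
#'   columns group, mean, n, letters, ordered by descending mean.
#' @export
duncan_mrt <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_result"))
  if (anova$df_within < 1L) stop("df_within must be >= 1")
  means <- anova$group_means
  ns <- anova$group_ns[names(means)]
  ord <- order(-means, names(means))
  ms <- means[ord]
  nonsig <- duncan_nonsig_matrix(unname(ms), unname(ns[ord]),
                                 anova$mse, anova$df_within, alpha)
  lets <- letters_from_nonsig(nonsig)
  out <- data.frame(group = names(ms), mean = unname(ms),
                    n = unname(as.integer(ns[ord])), letters = lets,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(variable = anova$variable, alpha = alpha, entries = out,
                 nonsig = nonsig),
            class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  cat("Duncan MRT letters for", x$variable, "(alpha =", x$alpha, ")\n")
  print(x$entries, ...)
  invisible(x)
}

p_to_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise Pearson correlation matrix with significance stars
#'
#' Two-tailed p-values from t = r sqrt((n-2)/(1-r^2)); stars at the 0.05 /
#' 0.01 / 0.001 thresholds (no multiple-testing correction by default,
#' matching the survey's presentation; \code{adjust = "holm"} is available).
#'
#' @param table A \code{\link{measurement_table}}.
#' @param panel A \code{\link{variable_panel}} (or character vector of
#'   variable names).
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return An object of class \code{correlation_result} with matrices r, p
#'   and stars.
#' @export
pearson_matrix <- function(table, panel, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  vars <- if (inherits(panel, "variable_panel")) panel$members else panel
  check_complete(table, vars, "correlate")
  n <- nrow(table)
  if (n < 3L) stop("need >= 3 complete observations")
  x <- as.matrix(as.data.frame(table)[vars])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance variable(s): ",
            paste(vars[sds == 0], collapse = ", "), "; r set to NA")
  }
  r <- suppressWarnings(stats::cor(x))
  r[, sds == 0] <- NA
  r[sds == 0, ] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  if (adjust == "holm") {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = "holm")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  stars <- matrix(p_to_stars(p), nrow(p), dimnames = dimnames(p))
  diag(stars) <- ""
  structure(list(variables = vars, n = n, r = r, p = p, stars = stars,
                 adjust = adjust),
            class = "correlation_result")
}

#' Distance matrix over table rows
#'
#' Euclidean distance on (optionally z-scored) panel columns, or Bray-Curtis
#' dissimilarity d_ij = sum|x_i - x_j| / sum(x_i + x_j) for non-negative
#' panels.
#'
#' @param table A \code{\link{measurement_table}}.
#' @param panel A \code{\link{variable_panel}} or character vector.
#' @param metric \code{"euclidean"} or \code{"bray_curtis"}.
#' @param standardize Z-score columns first (Euclidean only).
#' @return A \code{dist} object labelled by sample_id (or region).
#' @export
distance_matrix <- function(table, panel,
                            metric = c("euclidean", "bray_curtis"),
                            standardize = FALSE) {
  metric <- match.arg(metric)
  vars <- if (inherits(panel, "variable_panel")) panel$members else panel
  check_complete(table, vars, "distance")
  x <- as.matrix(as.data.frame(table)[vars])
  rownames(x) <- if (!is.null(table$sample_id)) table$sample_id else
    table$region
  if (metric == "euclidean") {
    if (standardize) x <- scale(x)
    return(stats::dist(x, method = "euclidean"))
  }
  if (any(x < 0)) stop("Bray-Curtis requires non-negative values")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else
        sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  stats::as.dist(d)
}

#' Mantel permutation test of association between two distance matrices
#'
#' The observed statistic is the Pearson correlation of the off-diagonal
#' entries; the null distribution is built by jointly permuting the rows and
#' columns of the second matrix. One-tailed positive alternative with
#' p = (1 + #\{r_perm >= r_obs\}) / (n_permutations + 1).
#'
#' @param d_a,d_b \code{dist} objects or symmetric matrices of equal size
#'   (>= 4 objects).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed (mandatory; the test is deterministic given it).
#' @return An object of class \code{mantel_result}.
#' @export
mantel_test <- function(d_a, d_b, n_permutations = 999, seed) {
  if (missing(seed)) stop("mantel_test requires an explicit seed")
  ma <- as.matrix(d_a)
  mb <- as.matrix(d_b)
  if (!all(dim(ma) == dim(mb))) stop("distance matrices differ in size")
  n <- nrow(ma)
  if (n < 4L) stop("Mantel test needs >= 4 objects")
  if (max(abs(ma - t(ma))) > 1e-12 || max(abs(mb - t(mb))) > 1e-12 ||
      any(abs(diag(ma)) > 1e-12) || any(abs(diag(mb)) > 1e-12)) {
    stop("inputs must be symmetric with zero diagonal")
  }
  ut <- upper.tri(ma)
  va <- ma[ut]
  if (stats::sd(va) == 0 || stats::sd(mb[ut]) == 0) {
    stop("constant distance matrix: Mantel r undefined")
  }
  r_obs <- stats::cor(va, mb[ut])
  count <- with_private_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      perm <- sample.int(n)
      stats::cor(va, mb[perm, perm][ut]) >= r_obs
    }, logical(1)))
  })
  structure(list(r_obs = r_obs,
                 p_value = (1 + count) / (n_permutations + 1),
                 n_permutations = n_permutations,
                 metric_a = attr(d_a, "method"), metric_b = attr(d_b, "method"),
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$r_obs, x$p_value, x$n_permutations))
  invisible(x)
}
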