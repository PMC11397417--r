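test_that("standardize produces valid z-scores and is idempotent", {
  tab <- table_from_means(matrix(c(1, 3), 2, 1,
                                 dimnames = list(c("M1", "M2"), "x")))
  z <- standardize(tab, "x")
  expect_equal(as.numeric(z$z), c(-0.7071, 0.7071), tolerance = 1e-4)

  sim <- aggregate_regions(generate_study(simulation_config(seed = 13))$table)
  z2 <- standardize(sim, quality_panel())
  expect_true(all(abs(colMeans(z2$z)) < 1e-10))
  expect_true(all(abs(apply(z2$z, 2, sd) - 1) < 1e-10))

  # standardizing an already-standardized table changes nothing
  ztab <- table_from_means(z2$z)
  z3 <- standardize(ztab, quality_panel())
  expect_equal(z3$z, z2$z, tolerance = 1e-12)

  const <- table_from_means(matrix(c(1, 1, 2, 3), 2, 2,
                                   dimnames = list(c("M1", "M2"),
                                                   c("a", "b"))))
  expect_error(standardize(const, c("a", "b")), "zero-variance.*a")
})

test_that("correlation PCA matches closed forms and prcomp oracle", {
  # p = 2 with correlation r: eigenvalues are 1 +/- r
  set.seed(31)
  n <- 400
  u <- rnorm(n)
  x1 <- u + rnorm(n)
  x2 <- u + rnorm(n)
  tab <- table_from_means(cbind(a = x1, b = x2))
  tab$region <- paste0("R", seq_len(n))  # unique regions
  tab$sample_id <- tab$region
  z <- standardize(tab, c("a", "b"))
  model <- pca_correlation(z)
  r <- cor(x1, x2)
  expect_equal(sort(model$eigenvalues), sort(c(1 - r, 1 + r)))

  # prcomp on scaled data gives the same eigenvalues
  ref <- prcomp(cbind(x1, x2), scale. = TRUE)
  expect_equal(model$eigenvalues, ref$sdev^2 * (n - 1) / (n - 1),
               tolerance = 1e-10)

  # independent columns at large n: eigenvalues near 1
  iso <- table_from_means(matrix(rnorm(4000), 1000, 4,
                                 dimnames = list(paste0("R", 1:1000),
                                                 letters[1:4])))
  mi <- pca_correlation(standardize(iso, letters[1:4]))
  expect_true(all(abs(mi$eigenvalues - 1) < 0.25))

  # invariants on the quality-panel model of a synthetic study
  agg <- aggregate_regions(generate_study(simulation_config(seed = 5))$table)
  zq <- standardize(agg, quality_panel())
  mq <- pca_correlation(zq)
  p <- mq$n_variables
  expect_equal(sum(mq$eigenvalues), p, tolerance = 1e-8)
  expect_equal(mq$eigenvectors %*% diag(mq$eigenvalues) %*%
                 t(mq$eigenvectors), mq$correlation, tolerance = 1e-8)
  expect_equal(crossprod(mq$eigenvectors), diag(p), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(colSums(mq$loadings^2), unname(mq$eigenvalues),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sweep(mq$csc, 2, sqrt(mq$eigenvalues), "*"), mq$loadings,
               tolerance = 1e-10)
  # sign convention: largest-|loading| entry positive in every component
  for (k in seq_len(p)) {
    expect_gt(mq$loadings[which.max(abs(mq$loadings[, k])), k], 0)
  }
  # scores have mean 0 and variance lambda_k
  h <- zq$z %*% mq$csc
  expect_true(all(abs(colMeans(h)) < 1e-10))
  expect_equal(apply(h, 2, var), mq$eigenvalues, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("variance contributions and retention rules", {
  agg <- aggregate_regions(generate_study(simulation_config(seed = 5))$table)
  m <- pca_correlation(standardize(agg, quality_panel()))
  vc <- variance_contributions(m)
  expect_equal(vc$variability_percent, 100 * m$eigenvalues / 6)
  expect_equal(vc$cumulative_percent[6], 100, tolerance = 1e-8)

  # rules applied to the published eigenvalue table
  ref <- reference_survey()
  fake <- m
  fake$eigenvalues <- c(ref$eigenvalues, 0.25, 0.15, 0.01)
  fake$variability_percent <- 100 * fake$eigenvalues / 6
  fake$cumulative_percent <- cumsum(fake$variability_percent)
  expect_equal(retain_components(fake, "kaiser"), 2L)
  expect_equal(retain_components(fake, "cumulative_threshold",
                                 threshold = 0.90), 3L)
  expect_equal(retain_components(fake, "fixed_k", k = 3), 3L)
  expect_error(retain_components(fake, "fixed_k", k = 7), "1..6")
})

test_that("complete-linkage clustering matches a hand trace", {
  x <- matrix(c(0, 1, 4, 10), 4, 1,
              dimnames = list(c("p1", "p2", "p3", "p4"), NULL))
  hc <- hcluster(x)
  expect_equal(hc$height, c(1, 4, 10))
  cl2 <- cut_clusters(hc, 2)
  expect_equal(unname(cl2), c(1, 1, 1, 2))
  expect_equal(cut_clusters(hc, 1), setNames(rep(1L, 4), rownames(x)),
               ignore_attr = TRUE)
  expect_equal(length(unique(cut_clusters(hc, 4))), 4L)
  expect_error(cut_clusters(hc, 5), "1..4")

  y <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  cl <- cut_clusters(hcluster(y), 2)
  expect_equal(unname(cl), c(1, 1, 2))

  # heights are non-decreasing; row permutation only relabels
  set.seed(17)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("M", 1:10), NULL))
  h1 <- hcluster(m)
  expect_true(all(diff(h1$height) >= -1e-12))
  perm <- sample(10)
  h2 <- hcluster(m[perm, ])
  c1 <- cut_clusters(h1, 3)
  c2 <- cut_clusters(h2, 3)
  expect_true(all(outer(c1, c1, "==") ==
                    outer(c2[names(c1)], c2[names(c1)], "==")))
})

test_that("planted three-archetype structure is recovered at k = 3", {
  # one extreme outlier region, one two-region group, the remaining nine
  set.seed(23)
  base <- matrix(rnorm(12 * 8, sd = 0.3), 12, 8,
                 dimnames = list(paste0("M", 1:12), mineral_panel()$members))
  base["M4", ] <- base["M4", ] + c(8, 8, 8, 8, -6, -6, -6, -6)
  base[c("M9", "M12"), ] <- base[c("M9", "M12"), ] +
    matrix(rep(c(-5, 4, -5, 4, 5, 5, 4, -4), each = 2), 2)
  cl <- cut_clusters(hcluster(base), 3)
  expect_equal(length(unique(cl)), 3L)
  expect_equal(unname(cl["M9"]), unname(cl["M12"]))
  expect_false(cl["M4"] == cl["M9"])
  expect_equal(length(unique(cl[setdiff(rownames(base),
                                        c("M4", "M9", "M12"))])), 1L)
})
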