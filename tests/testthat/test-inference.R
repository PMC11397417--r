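# plain data.frame: ANOVA inputs in these tests are centered normals, which
# the measurement_table validator would reject as negative concentrations
anova_table <- function(y, g) {
  data.frame(sample_id = seq_along(y), region = g, species = "sp", v = y)
}

test_that("one-way ANOVA matches the classical decomposition and lm oracle", {
  tab <- anova_table(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  a <- one_way_anova(tab, "v")
  expect_equal(a$f_stat, 0)
  expect_equal(a$p_value, 1)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)

  tab2 <- anova_table(c(0, 0, 1e-9, 0, 10, 10, 10, 10 + 1e-9),
                      rep(c("A", "B"), each = 4))
  expect_lt(one_way_anova(tab2, "v")$p_value, 1e-6)

  set.seed(21)
  for (i in 1:5) {
    y <- rnorm(24)
    g <- rep(paste0("G", 1:6), each = 4)
    ours <- one_way_anova(anova_table(y, g), "v")
    ref <- anova(lm(y ~ g))
    expect_equal(ours$f_stat, ref$`F value`[1])
    expect_equal(ours$p_value, ref$`Pr(>F)`[1])
    expect_equal(ours$mse, ref$`Mean Sq`[2])
  }

  expect_error(one_way_anova(anova_table(1:3, c("A", "A", "B")), "v"),
               "< 2 replicates")
  deg <- one_way_anova(anova_table(rep(1, 6), rep(c("A", "B"), 3)), "v")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$f_stat))
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(314)
  n_sims <- 2000
  rej <- 0L
  g <- rep(paste0("G", 1:6), each = 4)
  for (i in seq_len(n_sims)) {
    a <- one_way_anova(anova_table(rnorm(24), g), "v")
    if (a$p_value < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_sims
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("Duncan letters agree with the brute-force R_p oracle", {
  # all means equal -> single letter
  tab <- anova_table(c(1, 2, 1, 2, 1, 2) + 0.001 * rnorm(6),
                     rep(c("A", "B", "C"), each = 2))
  set.seed(1)
  eq <- duncan_mrt(one_way_anova(
    anova_table(rep(c(1, 2), 3), rep(c("A", "B", "C"), each = 2)), "v"))
  expect_equal(eq$entries$letters, rep("a", 3))

  # far-separated group is isolated
  y <- c(0.0, 0.02, 0.1, 0.12, 50, 50.02)
  far <- duncan_mrt(one_way_anova(
    anova_table(y, rep(c("A", "B", "C"), each = 2)), "v"))
  expect_false(any(grepl(far$entries$letters[1],
                         far$entries$letters[2:3], fixed = TRUE)))

  # randomized equivalence with the oracle across 2..6 groups
  set.seed(77)
  for (k in 2:6) {
    for (rep_i in 1:40) {
      n_per <- sample(2:5, k, replace = TRUE)
      g <- rep(paste0("G", seq_len(k)), n_per)
      # mix of null and separated configurations
      mu <- sample(c(0, 0, 0.5, 1, 3), k, replace = TRUE)
      y <- rnorm(length(g), mean = mu[match(g, paste0("G", seq_len(k)))])
      an <- one_way_anova(anova_table(y, g), "v")
      ld <- duncan_mrt(an, alpha = 0.05)
      orc <- oracle_duncan(an$group_means, an$group_ns, an$mse,
                           an$df_within, 0.05)
      expect_identical(shared_letter_matrix(ld), orc$nonsig,
                       label = sprintf("k=%d rep=%d", k, rep_i))
    }
  }
})

test_that("Duncan letter displays are minimal", {
  # dropping any letter from any group must break the shared-letter <->
  # non-significance equivalence
  set.seed(123)
  for (rep_i in 1:10) {
    g <- rep(paste0("G", 1:5), each = 3)
    y <- rnorm(15, mean = rep(c(0, 0.5, 1, 1.5, 4), each = 3))
    ld <- duncan_mrt(one_way_anova(anova_table(y, g), "v"))
    target <- shared_letter_matrix(ld)
    lets <- strsplit(ld$entries$letters, "")
    for (i in seq_along(lets)) {
      for (l in lets[[i]]) {
        mod <- lets
        mod[[i]] <- setdiff(mod[[i]], l)
        if (length(mod[[i]]) == 0) next  # breaks the >= 1 letter invariant
        shared <- outer(seq_along(mod), seq_along(mod), Vectorize(function(a, b)
          length(intersect(mod[[a]], mod[[b]])) > 0))
        diag(shared) <- TRUE
        expect_false(identical(shared, target))
      }
    }
  }
})

test_that("Duncan whole-null family error equals its protection level", {
  # under a complete null with k groups any-disjoint-letters happens exactly
  # when the widest range test rejects, with level 1 - (1 - alpha)^(k - 1)
  set.seed(2024)
  k <- 6
  n_sims <- 400
  g <- rep(paste0("G", seq_len(k)), each = 4)
  any_sep <- 0L
  for (i in seq_len(n_sims)) {
    ld <- duncan_mrt(one_way_anova(anova_table(rnorm(k * 4), g), "v"))
    m <- shared_letter_matrix(ld)
    if (!all(m)) any_sep <- any_sep + 1L
  }
  level <- 1 - 0.95^(k - 1)
  mc_se <- sqrt(level * (1 - level) / n_sims)
  expect_lt(abs(any_sep / n_sims - level), 3.5 * mc_se)
})

test_that("pearson_matrix matches closed forms and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5, 6, 8, 9, 11, 14)
  set.seed(61)
  tab <- data.frame(sample_id = 1:10, region = "M1", species = "sp",
                    a = x, b = 2 * x + 3, c = rnorm(10))
  cr <- pearson_matrix(tab, c("a", "b", "c"))
  expect_equal(cr$r["a", "b"], 1)
  expect_equal(cr$stars["a", "b"], "***")
  expect_true(isSymmetric(cr$r))
  expect_equal(diag(cr$r), c(a = 1, b = 1, c = 1))

  # closed-form 2x2 and exact t-distribution p
  r <- cr$r["a", "c"]
  expect_equal(r, cor(x, tab$c))
  tt <- r * sqrt(8 / (1 - r^2))
  expect_equal(cr$p["a", "c"], 2 * pt(abs(tt), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(cr$stars[cr$p < 0.001 & row(cr$p) != col(cr$p)][1],
               "***", ignore_attr = TRUE)

  tabz <- tab
  tabz$c <- 5
  expect_warning(crz <- pearson_matrix(tabz, c("a", "b", "c")),
                 "zero-variance")
  expect_true(all(is.na(crz$r[, "c"])))

  # null correlation shrinks with n
  set.seed(8)
  big <- data.frame(sample_id = 1:10000, region = "M1", species = "sp",
                    u = rnorm(10000), v = rnorm(10000))
  expect_lt(abs(pearson_matrix(big, c("u", "v"))$r["u", "v"]), 0.05)

  # holm adjustment only increases p-values
  crh <- pearson_matrix(tab, c("a", "b", "c"), adjust = "holm")
  expect_true(all(crh$p >= cr$p - 1e-15))
})

test_that("distance_matrix computes Euclidean and Bray-Curtis correctly", {
  tab <- measurement_table(data.frame(
    sample_id = c("r1", "r2"), region = c("A", "B"), species = "sp",
    x = c(0, 3), y = c(0, 0)))
  expect_equal(as.numeric(distance_matrix(tab, c("x", "y"), "euclidean")), 3)

  bc <- measurement_table(data.frame(
    sample_id = c("r1", "r2"), region = c("A", "B"), species = "sp",
    x = c(1, 0), y = c(0, 1)))
  expect_equal(as.numeric(distance_matrix(bc, c("x", "y"), "bray_curtis")), 1)

  same <- measurement_table(data.frame(
    sample_id = c("r1", "r2"), region = c("A", "B"), species = "sp",
    x = c(2, 2), y = c(5, 5)))
  expect_equal(as.numeric(distance_matrix(same, c("x", "y"), "bray_curtis")), 0)
  expect_equal(as.numeric(distance_matrix(same, c("x", "y"), "euclidean")), 0)

  neg <- data.frame(sample_id = c("r1", "r2"), region = c("A", "B"),
                    species = "sp", x = c(-1, 2))
  expect_error(distance_matrix(neg, "x", "bray_curtis"), "non-negative")

  # oracle: vegan::vegdist on the synthetic study
  skip_if_not_installed("vegan")
  agg <- aggregate_regions(generate_study(simulation_config(seed = 9))$table)
  ours <- distance_matrix(agg, mineral_panel(), "bray_curtis")
  ref <- vegan::vegdist(as.matrix(as.data.frame(agg)[mineral_panel()$members]),
                        method = "bray")
  expect_equal(as.numeric(ours), as.numeric(ref), tolerance = 1e-12)
})

test_that("mantel_test statistic, identity case and determinism", {
  set.seed(55)
  x <- matrix(rnorm(24), 8)
  y <- matrix(rnorm(24), 8)
  da <- dist(x)
  db <- dist(y)
  mt <- mantel_test(da, db, n_permutations = 199, seed = 10)
  expect_equal(mt$r_obs, cor(as.numeric(da), as.numeric(db)))
  expect_identical(mantel_test(da, db, 199, seed = 10)$p_value, mt$p_value)

  ident <- mantel_test(da, da, n_permutations = 999, seed = 3)
  expect_equal(ident$r_obs, 1)
  expect_equal(ident$p_value, 1 / 1000)

  # joint relabeling leaves r_obs unchanged (p invariant in distribution)
  perm <- sample(8)
  da2 <- as.dist(as.matrix(da)[perm, perm])
  db2 <- as.dist(as.matrix(db)[perm, perm])
  expect_equal(mantel_test(da2, db2, 99, seed = 1)$r_obs, mt$r_obs)

  expect_error(mantel_test(dist(x), dist(matrix(rnorm(10), 5)), 99, 1),
               "size")
  expect_error(mantel_test(dist(matrix(0, 5, 2)), dist(matrix(rnorm(10), 5)),
                           99, 1), "constant")
  expect_error(mantel_test(da, db, 99), "seed")

  skip_if_not_installed("vegan")
  ref <- vegan::mantel(da, db, permutations = 99)
  expect_equal(mt$r_obs, unname(ref$statistic))
})

test_that("mantel_test null p-values are near-uniform", {
  set.seed(404)
  n_reps <- 300
  ps <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    da <- dist(matrix(rnorm(20), 10))
    db <- dist(matrix(rnorm(20), 10))
    ps[i] <- mantel_test(da, db, n_permutations = 99, seed = i)$p_value
  }
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
  expect_lt(abs(mean(ps) - 0.5), 0.06)
})

test_that("a planted shared gradient is detected by the Mantel test", {
  # regions ordered along a gradient expressed in both minerals and
  # polysaccharide: association should be significant
  set.seed(66)
  grad <- seq(0, 1, length.out = 12)
  m <- cbind(K = 4 + grad + rnorm(12, sd = 0.05),
             Ca = 1 + 2 * grad + rnorm(12, sd = 0.05),
             total_polysaccharide = 20 + 10 * grad + rnorm(12, sd = 0.3))
  rownames(m) <- paste0("M", 1:12)
  tab <- table_from_means(m)
  da <- distance_matrix(tab, c("K", "Ca"), "bray_curtis")
  db <- distance_matrix(tab, "total_polysaccharide", "euclidean")
  mt <- mantel_test(da, db, n_permutations = 999, seed = 12)
  expect_lt(mt$p_value, 0.05)
  expect_gt(mt$r_obs, 0)
})
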