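#' Assemble a run configuration
#'
#' @param input Path to a replicate-level CSV, or NULL to simulate.
#' @param simulate A \code{\link{simulation_config}} when \code{input} is
#'   NULL.
#' @param stages Stages to run, in dependency order; any of
#'   \code{"describe"}, \code{"compare"}, \code{"correlate"},
#'   \code{"mantel"}, \code{"cluster"}, \code{"pca"}, \code{"score"}.
#' @param alpha Significance level for Duncan letters.
#' @param permutations Mantel permutations.
#' @param k Clusters for the cluster stage.
#' @param retain Component-retention rule for scoring (list, see
#'   \code{\link{retain_components}}).
#' @param seed Integer seed; required when any stochastic stage (simulate,
#'   mantel) is enabled.
#' @param out_dir Output directory.
#' @return A \code{run_config} list.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       stages = c("describe", "compare", "correlate",
                                  "mantel", "cluster", "pca", "score"),
                       alpha = 0.05, permutations = 999, k = 3,
                       retain = list(rule = "fixed_k", k = 3),
                       seed = NULL, out_dir = tempfile("phytoscore_run_")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(input) && is.null(simulate)) {
    stop("provide an input CSV or a simulation config")
  }
  if ((is.null(input) || "mantel" %in% stages) && is.null(seed)) {
    stop("a seed is required when a stochastic stage is enabled")
  }
  structure(list(input = input, simulate = simulate, stages = stages,
                 alpha = alpha, permutations = permutations, k = k,
                 retain = retain, seed = seed, out_dir = out_dir),
            class = "run_config")
}

write_stage_csv <- function(df, out_dir, name, manifest) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(manifest, name)
}

#' Run the full pipeline
#'
#' Executes the selected stages in dependency order (describe, compare,
#' correlate, mantel, cluster, pca, score), writing one CSV per output plus a
#' JSON MANIFEST recording stage parameters, the seed and completeness. On a
#' stage failure, partial outputs are retained and the MANIFEST marks the
#' run incomplete.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list of in-memory stage results; side effect: files
#'   under \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  results <- list()
  status <- "complete"
  err <- NULL
  panels <- list(mineral_panel(), quality_panel())

  tryCatch({
    if (!is.null(config$input)) {
      table <- read_measurements(config$input)
    } else {
      sim <- generate_study(config$simulate)
      table <- sim$table
      results$truth <- sim$truth
      write_table(table, file.path(config$out_dir, "simulated_table.csv"))
      manifest <- c(manifest, "simulated_table.csv")
      jsonlite::write_json(
        list(region_means = as.data.frame(sim$truth$region_means),
             true_order = sim$truth$true_order, seed = sim$truth$seed),
        file.path(config$out_dir, "truth.json"), digits = NA)
      manifest <- c(manifest, "truth.json")
    }
    have <- measurement_vars(table)
    panels <- Filter(function(p) all(p$members %in% have), panels)
    if (!length(panels)) stop("no complete panel found in the input table")

    for (stage in config$stages) {
      if (stage == "describe") {
        manifest <- write_stage_csv(describe_table(table, "overall"),
                                    config$out_dir, "describe_overall.csv",
                                    manifest)
        manifest <- write_stage_csv(describe_table(table, "region"),
                                    config$out_dir, "describe_region.csv",
                                    manifest)
      } else if (stage == "compare") {
        rows <- list()
        for (v in have) {
          an <- one_way_anova(table, v)
          ld <- duncan_mrt(an, alpha = config$alpha)
          rows[[v]] <- cbind(variable = v, ld$entries,
                             f_stat = an$f_stat, p_value = an$p_value)
        }
        results$compare <- do.call(rbind, c(rows, make.row.names = FALSE))
        manifest <- write_stage_csv(results$compare, config$out_dir,
                                    "compare_letters.csv", manifest)
      } else if (stage == "correlate") {
        for (p in panels) {
          cr <- pearson_matrix(table, p)
          manifest <- write_stage_csv(
            data.frame(variable = rownames(cr$r), as.data.frame(cr$r)),
            config$out_dir, paste0("correlation_r_", p$name, ".csv"), manifest)
          manifest <- write_stage_csv(
            data.frame(variable = rownames(cr$p), as.data.frame(cr$p)),
            config$out_dir, paste0("correlation_p_", p$name, ".csv"), manifest)
          results[[paste0("correlate_", p$name)]] <- cr
        }
      } else if (stage == "mantel") {
        minp <- Filter(function(p) p$role == "mineral", panels)
        qp <- Filter(function(p) p$role == "quality", panels)
        if (length(minp) && length(qp)) {
          agg <- aggregate_regions(table)
          da <- distance_matrix(agg, minp[[1]], metric = "bray_curtis")
          rows <- list()
          for (v in qp[[1]]$members) {
            db <- distance_matrix(agg, v, metric = "euclidean")
            mt <- mantel_test(da, db, n_permutations = config$permutations,
                              seed = config$seed)
            rows[[v]] <- data.frame(variable = v, r = mt$r_obs,
                                    p_value = mt$p_value,
                                    permutations = mt$n_permutations)
          }
          results$mantel <- do.call(rbind, c(rows, make.row.names = FALSE))
          manifest <- write_stage_csv(results$mantel, config$out_dir,
                                      "mantel.csv", manifest)
        }
      } else if (stage == "cluster") {
        agg <- aggregate_regions(table)
        for (p in panels) {
          z <- standardize(agg, p)
          hc <- hcluster(z$z)
          cl <- cut_clusters(hc, config$k)
          manifest <- write_stage_csv(
            data.frame(region = names(cl), cluster = unname(cl)),
            config$out_dir, paste0("clusters_", p$name, ".csv"), manifest)
          manifest <- write_stage_csv(
            data.frame(step = seq_along(hc$height), height = hc$height,
                       merge1 = hc$merge[, 1], merge2 = hc$merge[, 2]),
            config$out_dir, paste0("merges_", p$name, ".csv"), manifest)
        }
      } else if (stage == "pca") {
        agg <- aggregate_regions(table)
        for (p in panels) {
          model <- pca_correlation(standardize(agg, p))
          manifest <- write_stage_csv(
            data.frame(component = colnames(model$loadings),
                       eigenvalue = model$eigenvalues,
                       variability_percent = model$variability_percent,
                       cumulative_percent = model$cumulative_percent),
            config$out_dir, paste0("pca_eigen_", p$name, ".csv"), manifest)
          manifest <- write_stage_csv(
            data.frame(variable = rownames(model$loadings),
                       as.data.frame(model$loadings)),
            config$out_dir, paste0("pca_loadings_", p$name, ".csv"), manifest)
          manifest <- write_stage_csv(
            data.frame(variable = rownames(model$csc),
                       as.data.frame(model$csc)),
            config$out_dir, paste0("pca_csc_", p$name, ".csv"), manifest)
          results[[paste0("pca_", p$name)]] <- model
        }
      } else if (stage == "score") {
        qp <- Filter(function(p) p$role == "quality", panels)
        if (length(qp)) {
          cs <- evaluate_quality(table, qp[[1]], retain = config$retain)
          results$score <- cs
          manifest <- write_stage_csv(cs$eigen_table, config$out_dir,
                                      "eigen.csv", manifest)
          manifest <- write_stage_csv(
            data.frame(region = cs$regions, as.data.frame(cs$h),
                       H0 = unname(cs$h0)),
            config$out_dir, "scores.csv", manifest)
          manifest <- write_stage_csv(cs$ranking, config$out_dir,
                                      "ranking.csv", manifest)
        }
      }
    }
  }, error = function(e) {
    status <<- "failed"
    err <<- conditionMessage(e)
  })

  jsonlite::write_json(
    list(status = status, error = err, files = manifest,
         stages = config$stages,
         parameters = list(alpha = config$alpha,
                           permutations = config$permutations,
                           k = config$k, retain = config$retain),
         seed = config$seed),
    file.path(config$out_dir, "MANIFEST.json"), auto_unbox = TRUE, null = "null")
  if (status == "failed") stop("pipeline failed: ", err)
  invisible(results)
}
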