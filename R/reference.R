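#' Published reference results for the twelve-region survey
#'
#' The published multivariate results of the twelve-region E'seguo quality
#' survey this pipeline is modelled on, keyed in as structured fixtures for
#' internal-consistency checks: the eigenvalue/variance table, factor
#' loadings and component-score coefficients of the quality-indicator PCA,
#' and the per-region component scores H_1..H_3 with comprehensive score H_0.
#' The raw replicate measurements were never released, so these summary
#' tables are the only published quantities the pipeline can be checked
#' against directly.
#'
#' @return A list with elements \code{eigenvalues}, \code{variability_percent},
#'   \code{cumulative_percent}, \code{loadings} (6 x 3), \code{csc} (6 x 3),
#'   \code{scores} (12 x 4 data.frame: H1, H2, H3, H0 by region) and
#'   \code{ranking} (character vector, best region first).
#' @export
reference_survey <- function() {
  vars <- quality_panel()$members
  pcs <- c("PC1", "PC2", "PC3")
  loadings <- matrix(c(
     0.041,  0.906,  0.386,
     0.963, -0.124,  0.172,
    -0.888,  0.333,  0.097,
     0.865,  0.389,  0.070,
     0.590,  0.566, -0.560,
     0.848, -0.345,  0.206), ncol = 3, byrow = TRUE,
    dimnames = list(vars, pcs))
  csc <- matrix(c(
     0.022,  0.730,  0.521,
     0.512, -0.100,  0.233,
    -0.472,  0.269,  0.131,
     0.460,  0.314,  0.094,
     0.314,  0.456, -0.756,
     0.451, -0.279,  0.278), ncol = 3, byrow = TRUE,
    dimnames = list(vars, pcs))
  scores <- data.frame(
    region = paste0("M", 1:12),
    H1 = c(-0.415, -0.498, 1.276, -0.572, -3.073, 0.362,
           1.870, -3.601, 0.342, 2.922, 0.050, 1.336),
    H2 = c(1.213, 0.537, -0.387, -3.020, 0.282, 2.166,
           -0.698, 0.054, 0.173, 0.415, -0.642, -0.092),
    H3 = c(-0.936, -1.358, -0.077, -0.134, -0.273, 0.774,
           -0.109, 0.739, 0.586, 0.472, 1.008, -0.692),
    H0 = c(-0.021, -0.299, 0.689, -1.199, -1.882, 0.896,
           0.974, -2.177, 0.320, 1.997, -0.046, 0.747),
    stringsAsFactors = FALSE)
  list(
    eigenvalues = c(3.533, 1.538, 0.549),
    variability_percent = c(58.880, 25.628, 9.147),
    cumulative_percent = c(58.880, 84.508, 93.655),
    loadings = loadings,
    csc = csc,
    scores = scores,
    ranking = c("M10", "M7", "M6", "M12", "M3", "M9",
                "M1", "M11", "M2", "M4", "M5", "M8"))
}

#' Published HPLC calibration lines
#'
#' The two published standard curves (peak area vs concentration in mg/mL)
#' for the survey's medicinal markers, as \code{\link{calibration_line}}
#' objects for inverse prediction.
#'
#' @return Named list of \code{calibration_line}s for \code{l_malic_acid}
#'   and \code{aa2bg}.
#' @export
reference_calibration <- function() {
  list(
    l_malic_acid = calibration_line(17.734, -3.4596, c(0.626, 1.565),
                                    r_squared = 0.9990,
                                    analyte = "l_malic_acid"),
    aa2bg = calibration_line(395.97, 2.2132, c(0.031, 0.760),
                             r_squared = 0.9991, analyte = "aa2bg"))
}
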