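#' Published six-descriptor NET-inhibitor model fixture
#'
#' Returns, exactly as printed, the constants of a published GA-MLR model of
#' norepinephrine-transporter (NET) inhibition: the six-descriptor linear
#' equation, the standardized-coefficient/contribution table, the descriptor
#' correlation matrix with its quoted VIF/t/p columns, the Y-randomization
#' table, the descriptive statistics of the 36/14 activity partitions, and
#' the headline fit statistics. These are regression-test anchors: the
#' underlying 50-compound descriptor matrix was never published, so the
#' fixture supports internal-consistency checks, not refitting.
#'
#' @return A list of class `published_model_fixture` with elements:
#' \describe{
#'   \item{model}{`mlr_model` with the printed coefficients and intercept.}
#'   \item{table1}{descriptive statistics of the training/test activities.}
#'   \item{table2}{descriptor name/type/standardized coefficient/percent.}
#'   \item{table4_correlations}{6x6 symmetric Pearson matrix, unit diagonal.}
#'   \item{table4_quality}{the VIF, t-statistic and p-value columns as
#'     printed alongside the matrix.}
#'   \item{table5}{Y-randomization table: original row, 10 random rows, and
#'     the printed averages and cRp2.}
#'   \item{stats}{headline statistics: n_train, r2, r2_adjusted, q2_loo,
#'     n_test, r2_test (the section value 0.5832 and the checklist value
#'     0.5850 are both kept).}
#' }
#' @examples
#' fx <- published_model_fixture()
#' fx$model$coefficients[["GGI10"]]   # -5.147
#' @export
published_model_fixture <- function() {
  nm <- c("ALogP", "AATS7i", "ATSC3p", "IC2", "GGI10", "RDF75u")
  coefs <- c(ALogP = 2.788, AATS7i = 3.382, ATSC3p = 3.782,
             IC2 = 2.234, GGI10 = -5.147, RDF75u = 3.728)
  model <- new_mlr_model(intercept = 0.989, coefficients = coefs,
                         n_train = 36L)

  table1 <- data.frame(
    statistic = c("n", "standard_error", "median", "standard_deviation",
                  "sample_variance", "kurtosis", "skewness", "range",
                  "minimum", "maximum", "mean"),
    training = c(36, 0.185, 7.054, 1.108, 1.227, -0.632, 0.229, 4.439,
                 5.084, 9.523, 6.940),
    test = c(14, 0.296, 7.497, 1.106, 1.223, 2.677, -1.264, 4.436,
             4.500, 8.936, 7.394))

  table2 <- data.frame(
    descriptor = nm,
    type = c("2D", "2D", "2D", "2D", "2D", "3D"),
    std_coef = c(0.513, 0.500, 0.631, 0.383, -1.061, 0.756),
    percent = c(13.3, 13.0, 16.4, 10.0, 27.6, 19.7))

  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  lower <- list(
    AATS7i = c(ALogP = -0.3321),
    ATSC3p = c(ALogP = -0.2592, AATS7i = -0.2991),
    IC2    = c(ALogP = -0.2742, AATS7i = 0.0487, ATSC3p = 0.0765),
    GGI10  = c(ALogP = -0.2382, AATS7i = 0.0921, ATSC3p = -0.1711,
               IC2 = 0.5005),
    RDF75u = c(ALogP = -0.2940, AATS7i = 0.2215, ATSC3p = -0.1337,
               IC2 = 0.4759, GGI10 = 0.6377))
  for (r in names(lower)) for (cc in names(lower[[r]])) {
    R[r, cc] <- lower[[r]][[cc]]
    R[cc, r] <- lower[[r]][[cc]]
  }

  table4_quality <- data.frame(
    descriptor = nm,
    vif = c(1.5021, 1.4789, 1.4376, 1.4177, 4.5022, 4.3800),
    t = c(7.5604, 7.4649, 9.4970, 5.8502, -9.5663, 6.7912),
    p = c(2.47e-08, 3.16e-08, 2.1e-10, 2.4e-06, 1.79e-10, 1.87e-07))

  table5 <- list(
    original = c(R = 0.9545, R2 = 0.9111, Q2 = 0.8702),
    random = data.frame(
      model = paste0("Random ", 1:10),
      R  = c(0.4197, 0.3402, 0.3943, 0.4690, 0.4408,
             0.1560, 0.3589, 0.3237, 0.3323, 0.3646),
      R2 = c(0.1762, 0.1157, 0.1555, 0.2199, 0.1943,
             0.0243, 0.1288, 0.1048, 0.1104, 0.1329),
      Q2 = c(-0.2759, -0.4558, -0.3333, -0.2220, -0.1861,
             -0.6456, -0.3166, -0.3536, -0.4357, -0.3307)),
    average_r = 0.3599, average_r2 = 0.1363, average_q2 = -0.3555,
    crp2 = 0.8439)

  stats <- list(n_train = 36L, r2 = 0.9156, r2_adjusted = 0.8982,
                q2_loo = 0.8755, n_test = 14L,
                r2_test_section = 0.5832, r2_test_checklist = 0.5850)

  structure(list(model = model, table1 = table1, table2 = table2,
                 table4_correlations = R, table4_quality = table4_quality,
                 table5 = table5, stats = stats),
            class = "published_model_fixture")
}

#' Checksum of the published fixture
#'
#' Sum of every numeric constant in the fixture, used by the regression
#' suite to guard the printed values against accidental edits.
#'
#' @param fx a [published_model_fixture()].
#' @return A single double.
#' @export
fixture_checksum <- function(fx = published_model_fixture()) {
  num <- function(x) {
    if (is.list(x) && !is.data.frame(x)) return(sum(vapply(x, num, 0)))
    if (is.data.frame(x)) return(sum(vapply(x[vapply(x, is.numeric, TRUE)],
                                            sum, 0)))
    if (is.numeric(x)) return(sum(x))
    0
  }
  num(list(fx$model$intercept, fx$model$coefficients, fx$table1, fx$table2,
           fx$table4_correlations, fx$table4_quality,
           fx$table5, fx$stats))
}
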