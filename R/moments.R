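# Second moments of the selective advantage and of the long-term
# contributions per path.

#' Variance of the selective advantage per path
#'
#' A parent's selective advantage is its own breeding-value deviation plus
#' the mean deviation of its mates. For the sire paths the mate term is the
#' variance of a mean of `N_DS/N_SS` (resp. `N_DD/N_SD`) dams; for the dam
#' paths it is the full variance of the single mated sire. Post-selection
#' variances carry the truncation shrinkage `(1 - k r2)` and a finite-sample
#' factor `(1 - 1/N)` for measuring deviations from an estimated category
#' mean; mate-mean covariances across paths are zero under random mating.
#'
#' @param genetics A [genetic_inputs()].
#' @param regime A [build_regime()].
#' @param N Parent numbers per path.
#' @return Named numeric vector `sigma2_s` of advantage variances.
#' @export
advantage_variances <- function(genetics, regime, N) {
  k <- regime$k
  s2m <- genetics$sigma2_m; s2f <- genetics$sigma2_f
  r2m <- genetics$r2_m;     r2f <- genetics$r2_f
  N <- as.numeric(N)
  v <- c(
    SS = s2m * (1 - k[1] * r2m) * (1 - 1 / N[1]) +
         s2f / (N[3] / N[1]) * (1 - k[3] * r2f) * (1 - 1 / N[1]),
    SD = s2m * (1 - k[2] * r2m) * (1 - 1 / N[2]) +
         s2f / (N[4] / N[2]) * (1 - k[4] * r2f) * (1 - 1 / N[2]),
    DS = s2f * (1 - k[3] * r2f) * (1 - 1 / N[3]) +
         s2m * (1 - k[1] * r2m) * (1 - 1 / N[1]),
    DD = s2f * (1 - k[4] * r2f) * (1 - 1 / N[4]) +
         s2m * (1 - k[2] * r2m) * (1 - 1 / N[2])
  )
  v
}

#' Expected squared long-term contribution per path
#'
#' `E(u^2_x) = alpha_x^2 + beta_x^2 sigma2_s,x`: the squared contribution of
#' an average parent plus the contribution spread induced by regression on
#' the selective advantage.
#'
#' @param alpha,beta Per-path vectors from the contribution solution.
#' @param var_s Advantage variances from [advantage_variances()].
#' @return Named numeric vector `E(u^2)`.
#' @export
squared_contributions <- function(alpha, beta, var_s) {
  structure(as.numeric(alpha)^2 + as.numeric(beta)^2 * as.numeric(var_s),
            names = PATHS)
}

#' Cross moments of contributions between the nested path pairs
#'
#' Because every SS sire is also an SD sire (and every DS dam also a DD dam),
#' the quadratic form for deltaF needs the cross moments
#' `E(u_SD u_SS)` and `E(u_DS u_DD)`. Each is the product of average
#' contributions, plus the product of slopes times the shared own-breeding-
#' value variance component, plus a term from the difference in category
#' means, `E(Abar_SS - Abar_SD) = (i_SS - i_SD) sigma_A,m` (and its female
#' analogue), which is nonzero because the elite path is selected more
#' intensely.
#'
#' @param alpha,beta Per-path vectors from the contribution solution.
#' @param genetics A [genetic_inputs()].
#' @param regime A [build_regime()].
#' @param N Parent numbers per path.
#' @return Named list with `cov_SD_SS`, `cov_DS_DD`, `mean_diff_m`,
#'   `mean_diff_f`.
#' @export
cross_contributions <- function(alpha, beta, genetics, regime, N) {
  k <- regime$k; i <- regime$i
  N <- as.numeric(N)
  mean_diff_m <- (i[1] - i[2]) * sqrt(genetics$sigma2_m)
  mean_diff_f <- (i[3] - i[4]) * sqrt(genetics$sigma2_f)
  shared_m <- genetics$sigma2_m * (1 - k[1] * genetics$r2_m) * (1 - 1 / N[1])
  shared_f <- genetics$sigma2_f * (1 - k[3] * genetics$r2_f) * (1 - 1 / N[3])
  list(
    cov_SD_SS = alpha[["SD"]] * alpha[["SS"]] +
      beta[["SD"]] * beta[["SS"]] * shared_m +
      alpha[["SS"]] * beta[["SD"]] * mean_diff_m,
    cov_DS_DD = alpha[["DS"]] * alpha[["DD"]] +
      beta[["DS"]] * beta[["DD"]] * shared_f +
      alpha[["DS"]] * beta[["DD"]] * mean_diff_f,
    mean_diff_m = mean_diff_m,
    mean_diff_f = mean_diff_f
  )
}

#' All second moments for a scenario
#'
#' @param solution A [solve_contributions()] result.
#' @param scenario A [breeding_scenario()].
#' @param genetics A [genetic_inputs()].
#' @return Object of class `advantage_moments`: list with `var_s`, `Eu2`,
#'   `cov_SD_SS`, `cov_DS_DD`, `mean_diff_m`, `mean_diff_f`.
#' @export
advantage_moments <- function(solution, scenario, genetics) {
  var_s <- advantage_variances(genetics, solution$regime, scenario$N)
  Eu2 <- squared_contributions(solution$alpha, solution$beta, var_s)
  cross <- cross_contributions(solution$alpha, solution$beta, genetics,
                               solution$regime, scenario$N)
  structure(c(list(var_s = var_s, Eu2 = Eu2), cross),
            class = "advantage_moments")
}
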