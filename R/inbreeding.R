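# Assembly of the rate of inbreeding, effective population size, per-path
# accounting shares, and the family-size (Poisson-deviation) correction.

#' Rate of inbreeding under selection
#'
#' Evaluates `deltaF = (1/2) 1' N0 U0 1`, where the diagonal of `N0` holds
#' the parent numbers in the order SD, SS, DD, DS and `U0` holds the expected
#' squared contributions with the sub-diagonal cross moments
#' `2 E(u_SD u_SS)` and `2 E(u_DD u_DS)` that arise because the SS sires are
#' nested within SD and the DS dams within DD. Expanded:
#' `deltaF = 1/2 [ N_SD E(u2_SD) + N_SS (E(u2_SS) + 2 E(u_SD u_SS))
#'               + N_DD E(u2_DD) + N_DS (E(u2_DS) + 2 E(u_DD u_DS)) ]`.
#'
#' @param moments An [advantage_moments()] object.
#' @param alpha Per-path average contributions (unused in the quadratic form
#'   itself, accepted for interface completeness).
#' @param N Parent numbers per path.
#' @return `deltaF` per generation (dimensionless, positive).
#' @export
delta_f <- function(moments, alpha = NULL, N) {
  Eu2 <- moments$Eu2
  N <- as.numeric(N)
  0.5 * (N[2] * Eu2[["SD"]] +
         N[1] * (Eu2[["SS"]] + 2 * moments$cov_SD_SS) +
         N[4] * Eu2[["DD"]] +
         N[3] * (Eu2[["DS"]] + 2 * moments$cov_DS_DD))
}

#' Rate of inbreeding ignoring selection
#'
#' With all contribution slopes at zero the quadratic form collapses to the
#' classical four-path closed form
#' `deltaF = (1/32) (1/N_SS + 3/N_SD + 1/N_DS + 3/N_DD)`.
#'
#' @param N Parent numbers per path.
#' @return `deltaF` per generation.
#' @examples
#' delta_f_no_selection(c(20, 50, 100, 7000)) # 0.00376
#' @export
delta_f_no_selection <- function(N) {
  stopifnot(is.numeric(N), length(N) == 4L)
  if (any(N < 1)) stop("parent numbers must be >= 1")
  N <- as.numeric(N)
  (1 / 32) * (1 / N[1] + 3 / N[2] + 1 / N[3] + 3 / N[4])
}

#' Effective population size
#'
#' @param deltaF Positive rate of inbreeding per generation.
#' @return `Ne = 1 / (2 deltaF)`.
#' @export
effective_population_size <- function(deltaF) {
  if (!is.numeric(deltaF) || any(deltaF <= 0))
    stop("deltaF must be positive")
  1 / (2 * deltaF)
}

#' Per-path accounting shares of the rate of inbreeding
#'
#' Splits `deltaF` into the fractions accounted for by each path. The cross
#' moment between the nested pairs is shared: SS takes
#' `N_SS (E(u2_SS) + E(u_SD u_SS)) / 2`, SD takes
#' `N_SD E(u2_SD)/2 + N_SS E(u_SD u_SS)/2`, and the female paths likewise.
#' This partition is exact, so the shares sum to one by construction; a
#' renormalization guard is kept and the residual recorded as an attribute.
#'
#' @param moments An [advantage_moments()] object.
#' @param alpha Accepted for interface completeness.
#' @param N Parent numbers per path.
#' @param deltaF The value from [delta_f()] for the same scenario.
#' @return Named numeric vector of four fractions summing to 1, with
#'   attribute `residual` (pre-normalization departure of the sum from 1).
#' @export
accounting_shares <- function(moments, alpha = NULL, N, deltaF) {
  Eu2 <- moments$Eu2
  N <- as.numeric(N)
  raw <- c(
    SS = 0.5 * N[1] * (Eu2[["SS"]] + moments$cov_SD_SS),
    SD = 0.5 * N[2] * Eu2[["SD"]] + 0.5 * N[1] * moments$cov_SD_SS,
    DS = 0.5 * N[3] * (Eu2[["DS"]] + moments$cov_DS_DD),
    DD = 0.5 * N[4] * Eu2[["DD"]] + 0.5 * N[3] * moments$cov_DS_DD
  ) / deltaF
  residual <- sum(raw) - 1
  shares <- if (abs(residual) > 1e-9) raw / sum(raw) else raw
  attr(shares, "residual") <- residual
  shares
}

#' Family-size deviation-from-Poisson correction
#'
#' The contribution framework assumes independent Poisson numbers of
#' selected offspring per family. With a fixed number `f` of candidates per
#' family each selected with probability `q`, the selected count is binomial
#' with variance `f q (1 - q)` instead of Poisson `f q`, a deviation of
#' `-f q^2` per family. The per-path correction is
#' `delta_y = -sum_x f_y q_x^2 E[(u*_xy)^2]`, where `u*_xy = alpha_x +
#' beta_x pi_xy s_y` is the contribution of a category-x selected offspring
#' given its parent's advantage and the expectation is over
#' `s_y ~ N(0, sigma2_s,y)`; x runs over the two offspring categories of the
#' sex bred by path y. Family sizes are `(N_DS/N_SS) fmds` for SS sires,
#' `(N_DD/N_SD) ffdd` for SD sires, `fmds` for DS dams and `ffdd` for DD
#' dams (a DS dam's daughters are accounted through her DD role). The
#' aggregate adjustment to `deltaF` is `(1/8) sum_y N_y delta_y`, small and
#' negative.
#'
#' @param solution A [solve_contributions()] result.
#' @param moments An [advantage_moments()] object.
#' @param scenario A [breeding_scenario()] (supplies family sizes).
#' @param regime A [build_regime()]; defaults to the solution's regime.
#' @return List with `delta` (per-path corrections) and `aggregate`
#'   (`(1/8) sum N_y delta_y`, on the deltaF scale).
#' @export
poisson_deviation_correction <- function(solution, moments, scenario,
                                         regime = solution$regime) {
  fam <- scenario$family_sizes
  if (any(is.na(fam))) stop("family sizes fmds, ffds, ffdd are required")
  N <- as.numeric(scenario$N)
  f_y <- c(SS = N[3] / N[1] * fam[["fmds"]],
           SD = N[4] / N[2] * fam[["ffdd"]],
           DS = fam[["fmds"]],
           DD = fam[["ffdd"]])
  q <- scenario$p
  alpha <- solution$alpha; beta <- solution$beta; Pi <- solution$Pi
  var_s <- moments$var_s
  delta <- numeric(4)
  for (y in 1:4) {
    xs <- if (y %in% c(1, 3)) c(1, 2) else c(3, 4)  # offspring sex bred by y
    Eu_star2 <- alpha[xs]^2 + beta[xs]^2 * Pi[cbind(xs, y)]^2 * var_s[y]
    delta[y] <- -sum(f_y[y] * q[xs]^2 * Eu_star2)
  }
  names(delta) <- PATHS
  list(delta = delta, aggregate = sum(N * delta) / 8)
}

#' Predict the rate of inbreeding for a four-path scenario
#'
#' Runs the full deterministic chain: selection regime, contribution
#' solution, advantage moments, the rate of inbreeding with and without
#' selection, effective population size, per-path accounting shares, and the
#' family-size correction. The headline `deltaF` is the uncorrected value
#' (the correction is orders of magnitude smaller); set
#' `with_correction = TRUE` to use the corrected value as `deltaF`.
#'
#' @param scenario A [breeding_scenario()].
#' @param genetics A [genetic_inputs()].
#' @param with_correction Logical; report `deltaF` including the family-size
#'   correction (default `FALSE`).
#' @return Object of class `inbreeding_report`.
#' @examples
#' sc <- breeding_scenario(c(20, 50, 100, 7000), c(0.05, 0.125, 0.01, 0.70))
#' ge <- genetic_inputs(0.2200, 0.2367, 0.4164, 0.4577)
#' predict_inbreeding(sc, ge)
#' @export
predict_inbreeding <- function(scenario, genetics, with_correction = FALSE) {
  check_intensity_assumptions(scenario)
  solution <- solve_contributions(scenario, genetics)
  moments <- advantage_moments(solution, scenario, genetics)
  dF <- delta_f(moments, solution$alpha, scenario$N)
  dF0 <- delta_f_no_selection(scenario$N)
  corr <- poisson_deviation_correction(solution, moments, scenario)
  dF_corr <- dF + corr$aggregate
  headline <- if (with_correction) dF_corr else dF
  structure(
    list(scenario = scenario, genetics = genetics,
         regime = solution$regime, solution = solution, moments = moments,
         deltaF_selection = dF,
         deltaF_no_selection = dF0,
         deltaF_corrected = dF_corr,
         deltaF = headline,
         Ne = effective_population_size(headline),
         Ne_no_selection = effective_population_size(dF0),
         accounting_shares = accounting_shares(moments, solution$alpha,
                                               scenario$N, dF),
         delta_corrections = corr$delta,
         correction_aggregate = corr$aggregate,
         with_correction = with_correction),
    class = "inbreeding_report"
  )
}

#' @export
print.inbreeding_report <- function(x, ...) {
  cat("Four-path rate of inbreeding\n")
  cat("  parents (SS-SD-DS-DD):", paste(x$scenario$N, collapse = "-"), "\n")
  cat("  proportions retained :", paste(format(x$scenario$p), collapse = "-"), "\n")
  cat(sprintf("  deltaF (selection)   : %.5f   Ne = %.1f\n",
              x$deltaF_selection, effective_population_size(x$deltaF_selection)))
  cat(sprintf("  deltaF (no selection): %.5f   Ne = %.1f\n",
              x$deltaF_no_selection, x$Ne_no_selection))
  cat(sprintf("  family-size corr.    : %+.3f x 1e-4 (corrected deltaF %.5f)\n",
              1e4 * x$correction_aggregate, x$deltaF_corrected))
  sh <- x$accounting_shares
  cat("  accounting shares    :",
      paste(sprintf("%s %.3f", PATHS, sh), collapse = "  "), "\n")
  invisible(x)
}
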