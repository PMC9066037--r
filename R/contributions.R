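# Long-term genetic contributions: gene-flow matrix, average contributions
# alpha, the regression matrices Pi and Lambda, and the contribution slopes
# beta obtained from the linear system (I - Pi'/2) N beta = Lambda'/2 (1/4)1.

# Permitted (offspring x, parent y) cells: male offspring (rows SS, SD) have
# their sire in SS and their dam in DS; female offspring (rows DS, DD) have
# their sire in SD and their dam in DD.
path_cells <- cbind(
  x = c(1L, 2L, 1L, 2L, 3L, 4L, 3L, 4L),
  y = c(1L, 1L, 3L, 3L, 2L, 2L, 4L, 4L)
)

#' Gene-flow matrix of the four-path scheme
#'
#' Constant 4x4 matrix giving the parental origin of the genes of selected
#' offspring: rows are offspring categories, columns parent categories, in
#' SS, SD, DS, DD order. Sons (rows SS and SD) receive half their genes from
#' SS sires and half from DS dams; daughters (rows DS and DD) half from SD
#' sires and half from DD dams. Its left eigenvector with eigenvalue 1,
#' normalized to sum to 1, is (1/4, 1/4, 1/4, 1/4): in the long run each
#' path contributes a quarter of the genes.
#'
#' @return A 4x4 numeric matrix with dimnames `PATHS` x `PATHS`.
#' @export
gene_flow_matrix <- function() {
  G <- matrix(0, 4, 4, dimnames = list(PATHS, PATHS))
  G["SS", c("SS", "DS")] <- 0.5
  G["SD", c("SS", "DS")] <- 0.5
  G["DS", c("SD", "DD")] <- 0.5
  G["DD", c("SD", "DD")] <- 0.5
  G
}

#' Expected contribution of an average parent per path
#'
#' From the unit left eigenvector of the gene-flow matrix, a path's parents
#' jointly contribute a quarter of the genes of distant descendants, so an
#' average parent in path x contributes `alpha_x = 1/(4 N_x)`.
#'
#' @param N Parent numbers per path (length four, SS, SD, DS, DD order).
#' @return Named numeric vector `alpha`.
#' @export
alpha_vector <- function(N) {
  stopifnot(is.numeric(N), length(N) == 4L)
  if (any(N <= 0)) stop("parent numbers must be positive")
  structure(1 / (4 * as.numeric(N)), names = PATHS)
}

#' Regression matrix of offspring selective advantage on parental advantage
#'
#' Element `pi[x, y]` is the regression coefficient of the selective
#' advantage of a selected offspring in category x on the selective advantage
#' of its parent in category y. Under the linear transmission model the
#' covariance of an offspring's breeding value with its parent's selective
#' advantage equals half the advantage variance of the parent category, so
#' the no-selection regression is exactly 1/2; truncation-selecting the
#' offspring on a GEBV with reliability r2 shrinks it by `(1 - k_x r2)`:
#' `pi[x, y] = (1 - k_x r2_x) / 2`, with `r2_x` the reliability in the
#' offspring's sex. Cells outside the eight permitted parent-offspring
#' combinations are exactly zero.
#'
#' @param regime A [build_regime()] object.
#' @param genetics A [genetic_inputs()] object.
#' @param scenario A [breeding_scenario()] (kept for interface symmetry; the
#'   elements do not depend on parent numbers).
#' @return 4x4 numeric matrix, rows offspring, columns parents.
#' @export
pi_matrix <- function(regime, genetics, scenario = NULL) {
  r2 <- path_r2(genetics)
  Pi <- matrix(0, 4, 4, dimnames = list(PATHS, PATHS))
  Pi[path_cells] <- 0.5 * (1 - regime$k[path_cells[, "x"]] * r2[path_cells[, "x"]])
  Pi
}

#' Regression matrix of selected-offspring numbers on parental advantage
#'
#' Element `lambda[x, y]` carries the selection-induced dependence of the
#' number of category-x selected offspring on the advantage of their
#' category-y parent, expressed per expected selected offspring:
#' `lambda[x, y] = i_x r_x / (2 sigma_A,x)`, where `i_x` is the selection
#' intensity of path x and `r_x`, `sigma_A,x` are the GEBV accuracy and
#' genetic standard deviation of the candidate cohort of x's sex. A unit
#' increase in parental advantage raises a candidate's GEBV mean by
#' `r2_x / 2`, and hence its selection probability by
#' `i_x p_x r2_x / (2 r_x sigma_A,x)`; the raw count regression for a
#' category-y parent is therefore `(N_x / N_y) * lambda[x, y]`. Expressed
#' per expected offspring, the elements are independent of parent numbers,
#' which is what makes `N_x beta_x` invariant to jointly rescaling all
#' parent numbers. Unselected paths (`i = 0`) have zero rows.
#'
#' @inheritParams pi_matrix
#' @return 4x4 numeric matrix, rows offspring, columns parents.
#' @export
lambda_matrix <- function(regime, genetics, scenario = NULL) {
  r <- sqrt(path_r2(genetics))
  sigma <- sqrt(path_sigma2(genetics))
  La <- matrix(0, 4, 4, dimnames = list(PATHS, PATHS))
  xs <- path_cells[, "x"]
  La[path_cells] <- regime$i[xs] * r[xs] / (2 * sigma[xs])
  La
}

#' Solve for the contribution slopes beta
#'
#' Solves the linear system
#' `N beta = (I - Pi'/2)^{-1} (Lambda'/2) (1/4, 1/4, 1/4, 1/4)'`
#' for the per-path regression slopes of the long-term contribution on the
#' selective advantage. The right-hand side is free of parent numbers, so
#' `N_x beta_x` is invariant to scaling all parent numbers jointly and
#' `beta_x` itself is inversely proportional to `N_x`.
#'
#' @param Pi,Lambda 4x4 matrices from [pi_matrix()] and [lambda_matrix()].
#' @param N Parent numbers per path.
#' @return Named numeric vector `beta`.
#' @export
solve_beta <- function(Pi, Lambda, N) {
  A <- diag(4) - 0.5 * t(Pi)
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12)
    stop("contribution system (I - Pi'/2) is numerically singular ",
         "(rcond = ", format(rc), "); check k * r2 < 1 on every path")
  Nbeta <- solve(A, 0.5 * t(Lambda) %*% rep(0.25, 4))
  structure(as.numeric(Nbeta) / as.numeric(N), names = PATHS)
}

#' Full contribution solution for a scenario
#'
#' Convenience wrapper assembling the gene-flow matrix, alpha, Pi, Lambda
#' and beta for a scenario.
#'
#' @param scenario A [breeding_scenario()].
#' @param genetics A [genetic_inputs()].
#' @param regime Optionally a precomputed [build_regime()]; defaults to the
#'   regime implied by `scenario$p`.
#' @return Object of class `contribution_solution`: list with `G`, `alpha`,
#'   `Pi`, `Lambda`, `beta`, and the `regime` used.
#' @export
solve_contributions <- function(scenario, genetics, regime = build_regime(scenario$p)) {
  Pi <- pi_matrix(regime, genetics, scenario)
  La <- lambda_matrix(regime, genetics, scenario)
  structure(
    list(G = gene_flow_matrix(),
         alpha = alpha_vector(scenario$N),
         Pi = Pi, Lambda = La,
         beta = solve_beta(Pi, La, scenario$N),
         regime = regime),
    class = "contribution_solution"
  )
}

#' @export
print.contribution_solution <- function(x, digits = 4, ...) {
  cat("Long-term contribution solution\n")
  cat("  alpha:", paste(sprintf("%s=%.3g", PATHS, x$alpha), collapse = "  "), "\n")
  cat("  beta :", paste(sprintf("%s=%.3g", PATHS, x$beta), collapse = "  "), "\n")
  invisible(x)
}
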