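#' Define a four-path breeding scenario
#'
#' A scenario fixes the numbers of selected parents and the retained
#' proportions for the four paths, together with the family-size parameters
#' used for the family-size (Poisson-deviation) correction and by the
#' stochastic simulator: `fmds` and `ffds` are the numbers of male and female
#' candidates per dam of sons (DS), `ffdd` the number of female candidates
#' per dam of daughters (DD). Sires of sons are a subset of sires of
#' daughters, and dams of sons a subset of dams of daughters, so
#' `N_SS <= N_SD` and `N_DS <= N_DD`.
#'
#' @param N Positive integer vector of four parent numbers (SS, SD, DS, DD).
#' @param p Numeric vector of four retained proportions in (0, 1].
#' @param fmds Male candidates per DS dam (default 4).
#' @param ffds Female candidates per DS dam (default 4).
#' @param ffdd Female candidates per DD dam (default 1.4).
#' @return Object of class `breeding_scenario`.
#' @examples
#' breeding_scenario(N = c(20, 50, 100, 7000), p = c(0.05, 0.125, 0.01, 0.70))
#' @export
breeding_scenario <- function(N, p, fmds = 4, ffds = 4, ffdd = 1.4) {
  stopifnot(is.numeric(N), length(N) == 4L, is.numeric(p), length(p) == 4L)
  if (any(N < 1) || any(N != round(N)))
    stop("parent numbers must be positive integers")
  if (N[1] > N[2])
    stop("N_SS must not exceed N_SD (sires of sons are a subset of sires of daughters)")
  if (N[3] > N[4])
    stop("N_DS must not exceed N_DD (dams of sons are a subset of dams of daughters)")
  if (any(c(fmds, ffds, ffdd) <= 0))
    stop("family sizes fmds, ffds, ffdd must be positive")
  N <- as.numeric(N)
  names(N) <- names(p) <- PATHS
  structure(
    list(N = N, p = as.numeric(p),
         family_sizes = c(fmds = fmds, ffds = ffds, ffdd = ffdd)),
    class = "breeding_scenario"
  )
}

#' @export
print.breeding_scenario <- function(x, ...) {
  cat("Four-path breeding scenario\n")
  cat("  parents (SS-SD-DS-DD): ", paste(x$N, collapse = "-"), "\n")
  cat("  retained proportions : ", paste(format(x$p), collapse = "-"), "\n")
  cat("  family sizes         :  fmds =", x$family_sizes["fmds"],
      " ffds =", x$family_sizes["ffds"], " ffdd =", x$family_sizes["ffdd"], "\n")
  invisible(x)
}

#' Equilibrium genetic inputs by sex
#'
#' The deterministic prediction runs on equilibrium quantities: the additive
#' genetic variances of the male and female candidate populations after
#' repeated selection has driven the gametic-phase disequilibrium to its
#' asymptote, and the corresponding equilibrium reliabilities of the GEBV
#' used as the selection criterion. These are inputs here, typically obtained
#' from a deterministic recursion of variances under selection, or measured
#' from simulation output.
#'
#' @param sigma2_m,sigma2_f Equilibrium additive-genetic variance of the
#'   male / female candidate population (trait units squared).
#' @param r2_m,r2_f Equilibrium squared accuracy (reliability) of the GEBV
#'   in males / females, in `[0, 1]`.
#' @return Object of class `genetic_inputs`.
#' @examples
#' genetic_inputs(sigma2_m = 0.22, sigma2_f = 0.2367, r2_m = 0.4164, r2_f = 0.4577)
#' @export
genetic_inputs <- function(sigma2_m, sigma2_f, r2_m, r2_f) {
  stopifnot(length(sigma2_m) == 1L, length(sigma2_f) == 1L,
            length(r2_m) == 1L, length(r2_f) == 1L)
  if (sigma2_m <= 0 || sigma2_f <= 0)
    stop("genetic variances must be positive")
  if (r2_m < 0 || r2_m > 1 || r2_f < 0 || r2_f > 1)
    stop("reliabilities must lie in [0, 1]")
  structure(list(sigma2_m = sigma2_m, sigma2_f = sigma2_f,
                 r2_m = r2_m, r2_f = r2_f),
            class = "genetic_inputs")
}

#' @export
print.genetic_inputs <- function(x, ...) {
  cat("Equilibrium genetic inputs\n")
  cat(sprintf("  male  : sigma2_A = %.4f, GEBV reliability = %.4f\n",
              x$sigma2_m, x$r2_m))
  cat(sprintf("  female: sigma2_A = %.4f, GEBV reliability = %.4f\n",
              x$sigma2_f, x$r2_f))
  invisible(x)
}

# Per-path equilibrium variance / reliability / sd of the candidate cohort a
# path selects from (male for SS, SD; female for DS, DD), in path order.
path_sigma2 <- function(genetics)
  c(genetics$sigma2_m, genetics$sigma2_m, genetics$sigma2_f, genetics$sigma2_f)
path_r2 <- function(genetics)
  c(genetics$r2_m, genetics$r2_m, genetics$r2_f, genetics$r2_f)

# Warn when truncation-theory intensities are questionable: very few selected
# parents drawn from multi-candidate families call for an order-statistics
# (finite-family) intensity adjustment this package does not apply.
check_intensity_assumptions <- function(scenario) {
  fam <- scenario$family_sizes
  per_family <- c(SS = unname(scenario$N["DS"] / scenario$N["SS"] * fam["fmds"]),
                  SD = unname(scenario$N["DD"] / scenario$N["SD"] * fam["ffdd"]),
                  DS = unname(fam["fmds"]), DD = unname(fam["ffdd"]))
  few <- scenario$N < 20 & per_family > 1 & scenario$p < 1
  if (any(few))
    warning("path(s) ", paste(PATHS[few], collapse = ", "),
            " select fewer than 20 parents from multi-candidate families; ",
            "infinite-population selection intensities may be biased upward",
            call. = FALSE)
  invisible(scenario)
}
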