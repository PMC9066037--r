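#' Selection paths
#'
#' The four classical selection paths of a closed breeding nucleus, in the
#' fixed order used for every 4x4 matrix in the package: sires of sons (SS),
#' sires of daughters (SD), dams of sons (DS) and dams of daughters (DD).
#'
#' @format Character vector of length four.
#' @export
PATHS <- c("SS", "SD", "DS", "DD")

# Sex of the candidates competing for each path (SS/SD select among male
# candidates, DS/DD among female candidates).
path_sex <- c(SS = "male", SD = "male", DS = "female", DD = "female")

#' Selection intensity and truncation point for upper-tail truncation
#'
#' For a standard-normal selection criterion, retaining the best fraction
#' `p` of candidates truncates at the upper-tail quantile `t` with tail mass
#' `p`, and the mean of the retained fraction is the selection intensity
#' `i = phi(t)/p`. `p = 1` (no selection) gives `i = 0` with `t = -Inf`.
#'
#' @param p Proportion of candidates retained, in (0, 1].
#' @return Named list with `i` (intensity, standard-deviation units) and
#'   `t` (truncation point, standard-deviation units).
#' @examples
#' selection_intensity(0.5)$i # 2 * dnorm(0) = 0.7979
#' @export
selection_intensity <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("selection proportion must be a single number in (0, 1], got ",
         deparse(substitute(p)), " = ", format(p))
  if (p == 1)
    return(list(i = 0, t = -Inf))
  t <- stats::qnorm(p, lower.tail = FALSE)
  list(i = stats::dnorm(t) / p, t = t)
}

#' Variance reduction coefficient of truncation selection
#'
#' Truncation selection reduces the variance of the criterion among the
#' selected by the factor `1 - k`, with `k = i (i - t)`. `k = 0` when there
#' is no selection and approaches 1 under extreme selection.
#'
#' @param i Selection intensity from [selection_intensity()].
#' @param t Truncation point from [selection_intensity()].
#' @return Dimensionless `k` in `[0, 1)`.
#' @export
variance_reduction <- function(i, t) {
  if (i == 0) return(0)
  i * (i - t)
}

#' Assemble the per-path selection regime
#'
#' Computes the per-path selection intensity, truncation point, and variance
#' reduction coefficient from the four retained proportions. Paths with
#' `p = 1` get `i = k = 0` exactly, which is also how an unselected DD path
#' should be encoded.
#'
#' @param proportions Numeric vector of four proportions in (0, 1], in
#'   SS, SD, DS, DD order (names, if present, are checked).
#' @return Object of class `selection_regime`: a data frame with one row per
#'   path and columns `path`, `p`, `i`, `t`, `k`.
#' @examples
#' build_regime(c(0.05, 0.125, 0.01, 0.70))
#' @export
build_regime <- function(proportions) {
  stopifnot(is.numeric(proportions), length(proportions) == 4L)
  if (!is.null(names(proportions)) && !identical(names(proportions), PATHS))
    stop("proportions must be given in SS, SD, DS, DD order")
  it <- lapply(proportions, selection_intensity)
  regime <- data.frame(
    path = PATHS,
    p = as.numeric(proportions),
    i = vapply(it, `[[`, numeric(1), "i"),
    t = vapply(it, `[[`, numeric(1), "t"),
    stringsAsFactors = FALSE
  )
  regime$k <- mapply(variance_reduction, regime$i, regime$t)
  class(regime) <- c("selection_regime", "data.frame")
  regime
}

#' @export
print.selection_regime <- function(x, digits = 4, ...) {
  cat("Four-path selection regime (upper-tail truncation):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
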