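# Stochastic four-path breeding simulator.
#
# Discrete generations; truncation selection on GEBV within each sex; the
# SS sires are the top subset of the SD sires and the DS dams the top subset
# of the DD dams; random (balanced) mating; exact pedigree inbreeding via
# the tabular relationship-matrix recursion restricted to the selected
# parents of each generation. The simulator is the independent Monte-Carlo
# check for the analytic regressions (Pi, Lambda), the advantage variances,
# and the realized rate of inbreeding.

# Candidate counts per dam. "poisson": independent Poisson counts with the
# configured mean, the reproductive model the uncorrected deltaF prediction
# assumes. "fixed": deterministic counts (floor(f) everywhere plus one extra
# candidate for a random subset of dams, hitting the fractional total), the
# model behind the binomial family-size correction.
family_counts <- function(n, f, model = "poisson") {
  if (n == 0L) return(integer(0))
  if (model == "poisson") return(stats::rpois(n, f))
  base <- floor(f)
  cnt <- rep.int(base, n)
  extra <- round(n * (f - base))
  if (extra > 0) cnt[sample.int(n, extra)] <- base + 1L
  cnt
}

#' Simulate a four-path breeding program
#'
#' Simulates `replicates` independent populations for `generations` discrete
#' generations. Founders are unrelated with breeding values drawn at the
#' base-generation variances in `genetics`; GEBV are modeled as the true
#' breeding value plus independent noise sized so that the base-generation
#' squared accuracy equals the stated reliability (reliability 0 gives a
#' criterion of pure noise). Selection-induced gametic-phase disequilibrium
#' then drives the candidate variances and realized reliabilities to their
#' own equilibrium over the burn-in generations; the post-burn-in candidate
#' cohorts are measured and reported, and those measured equilibria are what
#' should be fed to the deterministic chain when comparing against this
#' simulator.
#'
#' Each generation, every DS dam is mated to one SS sire (balanced at
#' random) and produces `fmds` male candidates, and every DD dam is mated to
#' one SD sire and produces `ffds` (DS dams) or `ffdd` (remaining dams)
#' female candidates. Candidates' breeding values are the parent average
#' plus a Mendelian term with variance `(1/2) sigma2_A0 (1 - Fbar_parents)`.
#' The top `N_SD` males and `N_DD` females by GEBV become the next parents,
#' with the top `N_SS` and `N_DS` flagged as the elite subsets. Inbreeding
#' is exact: the relationship matrix among parents is propagated by the
#' tabular method and each candidate's F is half the parental relationship.
#'
#' @param scenario A [breeding_scenario()]. Candidate numbers are implied by
#'   `N` and the family sizes; an error names the first path whose candidates
#'   cannot supply the required parents.
#' @param genetics A [genetic_inputs()] interpreted as base-generation
#'   (generation-0) variances and reliabilities.
#' @param generations Number of generations (>= 5).
#' @param replicates Number of independent replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param burn_in Generations discarded before measuring (default 5).
#' @param family_size_model `"poisson"` (default) draws each dam's candidate
#'   count from a Poisson distribution with the configured mean, the
#'   reproductive model the uncorrected deltaF prediction assumes;
#'   `"fixed"` breeds deterministic candidate counts, the model behind the
#'   binomial family-size correction.
#' @param keep_pedigree Keep the 3-column pedigree of replicate 1.
#' @return Object of class `fourpath_sim`: per-generation mean inbreeding
#'   `F_t` (replicates x generations matrix), `realized_deltaF` per
#'   replicate, measured `equilibrium` genetics, realized selection
#'   proportions, and the parent-offspring records used by
#'   [empirical_regressions()].
#' @export
simulate_breeding <- function(scenario, genetics, generations = 15,
                              replicates = 1, seed = 1, burn_in = 5,
                              family_size_model = c("poisson", "fixed"),
                              keep_pedigree = FALSE) {
  stopifnot(generations >= 5, replicates >= 1, burn_in >= 1,
            burn_in < generations)
  family_size_model <- match.arg(family_size_model)
  N <- scenario$N
  fam <- scenario$family_sizes
  nS <- as.integer(N["SD"]); nD <- as.integer(N["DD"])
  nSS <- as.integer(N["SS"]); nDS <- as.integer(N["DS"])
  if (nDS < nSS) stop("infeasible scenario: path SS needs N_SS <= N_DS son-matings")
  n_males <- nDS * fam[["fmds"]]
  n_females <- nDS * fam[["ffds"]] + (nD - nDS) * fam[["ffdd"]]
  if (floor(n_males) < nS)
    stop("infeasible scenario: path SD requires ", nS,
         " sires but only ", floor(n_males), " male candidates")
  if (floor(n_females) < nD)
    stop("infeasible scenario: path DD requires ", nD,
         " dams but only ", floor(n_females), " female candidates")
  set.seed(seed)
  s2m0 <- genetics$sigma2_m; s2f0 <- genetics$sigma2_f
  r2m0 <- genetics$r2_m;     r2f0 <- genetics$r2_f
  s2A0 <- (s2m0 + s2f0) / 2
  sd_em <- if (r2m0 > 0) sqrt(s2m0 * (1 - r2m0) / r2m0) else NA_real_
  sd_ef <- if (r2f0 > 0) sqrt(s2f0 * (1 - r2f0) / r2f0) else NA_real_

  Ft <- matrix(NA_real_, replicates, generations)
  dF_rep <- numeric(replicates)
  eq_acc <- matrix(0, 0, 4, dimnames = list(NULL, c("vm", "vf", "r2m", "r2f")))
  pi_rec <- vector("list", replicates)
  la_rec <- vector("list", replicates)
  s_rec <- vector("list", replicates)
  pedigree <- NULL

  for (rep in seq_len(replicates)) {
    # founders: sires then dams, unrelated, sorted by GEBV within sex
    A_par <- c(stats::rnorm(nS, 0, sqrt(s2m0)), stats::rnorm(nD, 0, sqrt(s2f0)))
    gm <- if (r2m0 > 0) A_par[1:nS] + stats::rnorm(nS, 0, sd_em) else stats::rnorm(nS)
    gf <- if (r2f0 > 0) A_par[nS + 1:nD] + stats::rnorm(nD, 0, sd_ef) else stats::rnorm(nD)
    A_par[1:nS] <- A_par[1:nS][order(gm, decreasing = TRUE)]
    A_par[nS + 1:nD] <- A_par[nS + 1:nD][order(gf, decreasing = TRUE)]
    F_par <- rep(0, nS + nD)
    A_pp <- diag(nS + nD)
    prev_s <- NULL      # parent advantages from the previous mating
    links <- NULL       # parentage of the current parents
    do_ped <- keep_pedigree && rep == 1L
    if (do_ped) {
      ped <- matrix(0L, nS + nD, 3)
      ped[, 1] <- seq_len(nS + nD)
      par_ids <- seq_len(nS + nD)
      next_id <- nS + nD + 1L
    }
    pi_g <- list(); la_g <- list(); s_g <- list()

    for (g in seq_len(generations)) {
      # --- mating assignment (balanced at random) ---
      son_sire <- sample(rep_len(seq_len(nSS), nDS))          # per DS dam
      dtr_sire <- sample(rep_len(seq_len(nS), nD))            # per DD dam
      # --- selective advantages of current parents ---
      A_s <- A_par[1:nS]; A_d <- A_par[nS + 1:nD]
      mSS <- mean(A_s[1:nSS]); mSD <- mean(A_s)
      mDS <- mean(A_d[1:nDS]); mDD <- mean(A_d)
      mateDS <- vapply(seq_len(nSS),
                       function(j) mean(A_d[which(son_sire == j)]), 0)
      mateDD <- vapply(seq_len(nS),
                       function(j) mean(A_d[which(dtr_sire == j)]), 0)
      s_now <- list(
        SS = (A_s[1:nSS] - mSS) + (mateDS - mDS),
        SD = (A_s - mSD) + (mateDD - mDD),
        DS = (A_d[1:nDS] - mDS) + (A_s[son_sire] - mSS),
        DD = (A_d - mDD) + (A_s[dtr_sire] - mSD)
      )
      # --- records pairing current parents (selected offspring) with the
      #     previous generation's parents ---
      if (!is.null(prev_s) && g > burn_in + 1) {
        off_cat <- list(SS = 1:nSS, SD = 1:nS,
                        DS = nS + 1:nDS, DD = nS + 1:nD)
        for (x in 1:4) {
          idx <- off_cat[[x]]
          local_idx <- if (x <= 2) idx else idx - nS
          so <- s_now[[x]][seq_along(idx)]
          sire_p <- links$sire[idx]; dam_p <- links$dam[idx]
          if (x <= 2) {  # male offspring: sire in SS, dam in DS
            sp_sire <- prev_s$SS[sire_p]; sp_dam <- prev_s$DS[dam_p - nS]
            ys <- c(1L, 3L)
          } else {       # female offspring: sire in SD, dam in DD
            sp_sire <- prev_s$SD[sire_p]; sp_dam <- prev_s$DD[dam_p - nS]
            ys <- c(2L, 4L)
          }
          pi_g[[length(pi_g) + 1L]] <- cbind(x = x, y = ys[1], sp = sp_sire,
                                             so = so, par = g * 1e5 + sire_p)
          pi_g[[length(pi_g) + 1L]] <- cbind(x = x, y = ys[2], sp = sp_dam,
                                             so = so, par = g * 1e5 + dam_p)
          # selected-offspring counts per previous parent
          if (x <= 2) {
            cnt_s <- tabulate(sire_p, nbins = nSS)
            cnt_d <- tabulate(dam_p - nS, nbins = nDS)
            la_g[[length(la_g) + 1L]] <- cbind(x = x, y = 1L, sp = prev_s$SS, n = cnt_s)
            la_g[[length(la_g) + 1L]] <- cbind(x = x, y = 3L, sp = prev_s$DS, n = cnt_d)
          } else {
            cnt_s <- tabulate(sire_p, nbins = nS)
            cnt_d <- tabulate(dam_p - nS, nbins = nD)
            la_g[[length(la_g) + 1L]] <- cbind(x = x, y = 2L, sp = prev_s$SD, n = cnt_s)
            la_g[[length(la_g) + 1L]] <- cbind(x = x, y = 4L, sp = prev_s$DD, n = cnt_d)
          }
        }
      }
      if (g > burn_in)
        for (x in 1:4)
          s_g[[length(s_g) + 1L]] <- cbind(x = x, s = s_now[[x]])
      # --- breed candidates ---
      son_dam <- rep(seq_len(nDS),
                     times = family_counts(nDS, fam[["fmds"]], family_size_model))
      son_sir <- son_sire[son_dam]
      dtr_cnt <- c(family_counts(nDS, fam[["ffds"]], family_size_model),
                   family_counts(nD - nDS, fam[["ffdd"]], family_size_model))
      dtr_dam <- rep(seq_len(nD), times = dtr_cnt)
      dtr_sir <- dtr_sire[dtr_dam]
      cs <- c(son_sir, dtr_sir)                 # sire index (1..nS)
      cd <- nS + c(son_dam, dtr_dam)            # dam index (nS+1..nS+nD)
      nm <- length(son_dam); nf <- length(dtr_dam)
      if (nm < nS) stop("infeasible generation: path SD requires ", nS,
                        " sires but only ", nm, " male candidates were born")
      if (nf < nD) stop("infeasible generation: path DD requires ", nD,
                        " dams but only ", nf, " female candidates were born")
      Fo <- 0.5 * A_pp[cbind(cs, cd)]
      mend_sd <- sqrt(pmax(0, 0.5 * s2A0 * (1 - 0.5 * (F_par[cs] + F_par[cd]))))
      A_o <- 0.5 * (A_par[cs] + A_par[cd]) + stats::rnorm(nm + nf, 0, mend_sd)
      Am <- A_o[1:nm]; Af <- A_o[nm + 1:nf]
      gebv_m <- if (r2m0 > 0) Am + stats::rnorm(nm, 0, sd_em) else stats::rnorm(nm)
      gebv_f <- if (r2f0 > 0) Af + stats::rnorm(nf, 0, sd_ef) else stats::rnorm(nf)
      Ft[rep, g] <- mean(Fo)
      if (g > burn_in)
        eq_acc <- rbind(eq_acc, c(stats::var(Am), stats::var(Af),
                                  if (r2m0 > 0) stats::cor(gebv_m, Am)^2 else 0,
                                  if (r2f0 > 0) stats::cor(gebv_f, Af)^2 else 0))
      # --- truncation selection on GEBV, elite subsets first ---
      sel_m <- order(gebv_m, decreasing = TRUE)[1:nS]
      sel_f <- nm + order(gebv_f, decreasing = TRUE)[1:nD]
      sel <- c(sel_m, sel_f)
      # --- propagate the relationship matrix to the selected parents ---
      n_old <- nS + nD
      M <- matrix(0, n_old, n_old)
      M[cbind(seq_len(n_old), cs[sel])] <- 0.5
      M[cbind(seq_len(n_old), cd[sel])] <- 0.5
      A_new <- M %*% A_pp %*% t(M)
      diag(A_new) <- 1 + Fo[sel]
      if (do_ped) {
        ids <- next_id:(next_id + nm + nf - 1L)
        ped <- rbind(ped, cbind(ids, par_ids[cs], par_ids[cd]))
        par_ids <- ids[sel]
        next_id <- next_id + nm + nf
      }
      prev_s <- s_now
      links <- list(sire = cs[sel], dam = cd[sel] - 0L)
      A_pp <- A_new
      F_par <- Fo[sel]
      A_par <- A_o[sel]
    }
    tt <- burn_in:generations
    fit <- stats::lm.fit(cbind(1, tt), log(1 - Ft[rep, tt]))
    dF_rep[rep] <- 1 - exp(fit$coefficients[2])
    pi_rec[[rep]] <- if (length(pi_g)) cbind(rep = rep, do.call(rbind, pi_g))
    la_rec[[rep]] <- if (length(la_g)) cbind(rep = rep, do.call(rbind, la_g))
    s_rec[[rep]] <- if (length(s_g)) cbind(rep = rep, do.call(rbind, s_g))
    if (do_ped) pedigree <- ped
  }
  eqm <- colMeans(eq_acc)
  structure(
    list(scenario = scenario, genetics = genetics,
         generations = generations, burn_in = burn_in,
         replicates = replicates, seed = seed,
         F_t = Ft, realized_deltaF = dF_rep,
         equilibrium = genetic_inputs(eqm[["vm"]], eqm[["vf"]],
                                      max(eqm[["r2m"]], 0),
                                      max(eqm[["r2f"]], 0)),
         realized_p = c(SS = nSS / n_males, SD = nS / n_males,
                        DS = nDS / n_females, DD = nD / n_females),
         pi_records = do.call(rbind, pi_rec),
         lambda_records = do.call(rbind, la_rec),
         s_records = do.call(rbind, s_rec),
         pedigree = pedigree),
    class = "fourpath_sim"
  )
}

#' @export
print.fourpath_sim <- function(x, ...) {
  cat("Four-path breeding simulation\n")
  cat("  replicates:", x$replicates, " generations:", x$generations,
      "(burn-in", x$burn_in, ")\n")
  cat(sprintf("  realized deltaF: %.5f (MC se %.5f)\n",
              mean(x$realized_deltaF),
              stats::sd(x$realized_deltaF) / sqrt(x$replicates)))
  cat(sprintf("  final mean F: %.4f\n", mean(x$F_t[, x$generations])))
  invisible(x)
}

# per-replicate OLS slope of y on x
.rep_slope <- function(d, xcol, ycol) {
  sp <- d[, xcol]
  if (stats::var(sp) == 0) return(NA_real_)
  stats::cov(sp, d[, ycol]) / stats::var(sp)
}

#' Empirical regression estimates from a simulation
#'
#' Estimates, per permitted parent-offspring cell, the OLS regression of the
#' selective advantage of selected offspring on the parental advantage
#' (empirical counterpart of [pi_matrix()]), the regression of
#' selected-offspring counts on the parental advantage (count-scale
#' counterpart of [lambda_matrix()]: compare against
#' `(N_x / N_y) lambda[x, y]`), and the per-path variances of the selective
#' advantage. Estimates are means over replicates with Monte-Carlo standard
#' errors across replicates.
#'
#' @param sim A [simulate_breeding()] result with more than one replicate.
#' @return List with 4x4 matrices `Pi_hat`, `Pi_se`, `Lambda_count_hat`,
#'   `Lambda_count_se`, vectors `var_s_hat`, `var_s_se`, and `n_records`
#'   per cell.
#' @export
empirical_regressions <- function(sim) {
  if (is.null(sim$pi_records))
    stop("simulation has no records; run with generations > burn_in + 1")
  R <- sim$replicates
  Pi_hat <- Pi_se <- La_hat <- La_se <- nrec <- matrix(NA_real_, 4, 4,
                                                       dimnames = list(PATHS, PATHS))
  for (m in seq_len(nrow(path_cells))) {
    x <- path_cells[m, "x"]; y <- path_cells[m, "y"]
    dp <- sim$pi_records[sim$pi_records[, "x"] == x & sim$pi_records[, "y"] == y, , drop = FALSE]
    dl <- sim$lambda_records[sim$lambda_records[, "x"] == x & sim$lambda_records[, "y"] == y, , drop = FALSE]
    sl_p <- vapply(seq_len(R), function(r) {
      d <- dp[dp[, "rep"] == r, , drop = FALSE]
      # one point per parent (mean offspring advantage): parents with many
      # selected offspring must not be overweighted, since the analytic
      # pi is the conditional regression given the parent's advantage
      sp <- tapply(d[, "sp"], d[, "par"], `[`, 1L)
      so <- tapply(d[, "so"], d[, "par"], mean)
      .rep_slope(cbind(sp = sp, so = so), "sp", "so")
    }, 0)
    sl_l <- vapply(seq_len(R), function(r)
      .rep_slope(dl[dl[, "rep"] == r, , drop = FALSE], "sp", "n"), 0)
    Pi_hat[x, y] <- mean(sl_p, na.rm = TRUE)
    La_hat[x, y] <- mean(sl_l, na.rm = TRUE)
    if (R > 1) {
      Pi_se[x, y] <- stats::sd(sl_p, na.rm = TRUE) / sqrt(sum(!is.na(sl_p)))
      La_se[x, y] <- stats::sd(sl_l, na.rm = TRUE) / sqrt(sum(!is.na(sl_l)))
    }
    nrec[x, y] <- nrow(dp)
  }
  if (any(nrec[path_cells] < 1e4))
    warning("fewer than 10^4 records in some cells; ",
            "confidence intervals will be wide", call. = FALSE)
  vs_hat <- vs_se <- structure(numeric(4), names = PATHS)
  for (x in 1:4) {
    d <- sim$s_records[sim$s_records[, "x"] == x, , drop = FALSE]
    v <- vapply(seq_len(R), function(r) stats::var(d[d[, "rep"] == r, "s"]), 0)
    vs_hat[x] <- mean(v)
    vs_se[x] <- if (R > 1) stats::sd(v) / sqrt(R) else NA_real_
  }
  list(Pi_hat = Pi_hat, Pi_se = Pi_se,
       Lambda_count_hat = La_hat, Lambda_count_se = La_se,
       var_s_hat = vs_hat, var_s_se = vs_se, n_records = nrec)
}

#' Write a simulated pedigree as a 3-column text file
#'
#' @param sim A [simulate_breeding()] result run with
#'   `keep_pedigree = TRUE`.
#' @param file Output path; tab-separated columns `id`, `sire`, `dam`
#'   (0 = unknown founder parent).
#' @return The path, invisibly.
#' @export
write_pedigree <- function(sim, file) {
  if (is.null(sim$pedigree))
    stop("simulation was run without keep_pedigree = TRUE")
  ped <- sim$pedigree
  colnames(ped) <- c("id", "sire", "dam")
  utils::write.table(ped, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
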