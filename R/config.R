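# Scenario configuration files, report generation, and the
# analytic-versus-simulation validation harness.

#' Path to the bundled example scenario grid
#'
#' A YAML grid covering three trait settings (single-trait selection at
#' heritability 0.3 and 0.1, and two-trait index selection with equal
#' weights), two proportion settings and three parent-number settings, with
#' the matching equilibrium variances and reliabilities per trait and
#' proportion setting.
#'
#' @return File path of `example_grid.yaml`.
#' @export
fourpath_example_config <- function() {
  system.file("extdata", "example_grid.yaml", package = "fourpath",
              mustWork = TRUE)
}

#' Read a scenario configuration
#'
#' Two layouts are supported. A *grid* layout with `trait_settings`
#' (each carrying per-proportion-setting equilibrium genetics),
#' `proportion_settings` and `parent_settings`, expanded into their cross
#' product; or an explicit `scenarios:` list whose entries each carry `name`,
#' `N`, `p` and a `genetics` block. `family_sizes` applies to all scenarios.
#'
#' @param path YAML file path.
#' @return List of scenario specifications, each with `name`, `trait`,
#'   `scenario` ([breeding_scenario()]) and `genetics` ([genetic_inputs()]).
#' @export
read_scenario_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse config '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(cfg$version)) stop("config missing 'version' field")
  fam <- cfg$family_sizes %||% list(fmds = 4, ffds = 4, ffdd = 1.4)
  mk_scn <- function(N, p) breeding_scenario(
    N = as.numeric(N), p = as.numeric(p),
    fmds = fam$fmds, ffds = fam$ffds, ffdd = fam$ffdd)
  mk_gen <- function(g) genetic_inputs(g$sigma2_m, g$sigma2_f, g$r2_m, g$r2_f)
  out <- list()
  if (!is.null(cfg$scenarios)) {
    for (sc in cfg$scenarios) {
      for (f in c("N", "p", "genetics"))
        if (is.null(sc[[f]])) stop("scenario '", sc$name %||% "?",
                                   "' missing field '", f, "'")
      out[[length(out) + 1L]] <- list(
        name = sc$name %||% paste(sc$N, collapse = "-"),
        trait = sc$trait %||% NA_character_,
        scenario = mk_scn(sc$N, sc$p), genetics = mk_gen(sc$genetics))
    }
    return(out)
  }
  for (f in c("trait_settings", "proportion_settings", "parent_settings"))
    if (is.null(cfg[[f]])) stop("grid config missing field '", f, "'")
  for (ts in cfg$trait_settings) {
    for (p in cfg$proportion_settings) {
      eq <- NULL
      for (e in ts$equilibrium)
        if (isTRUE(all.equal(as.numeric(e$proportions), as.numeric(p))))
          eq <- e
      if (is.null(eq))
        stop("trait setting '", ts$name,
             "' has no equilibrium entry for proportions ",
             paste(p, collapse = "-"))
      for (N in cfg$parent_settings)
        out[[length(out) + 1L]] <- list(
          name = paste0(ts$name, " | ", paste(p, collapse = "-"), " | ",
                        paste(N, collapse = "-")),
          trait = ts$name,
          scenario = mk_scn(N, p), genetics = mk_gen(eq))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run every scenario of a configuration and tabulate the predictions
#'
#' For each scenario the full deterministic chain is run and one report row
#' emitted: the rate of inbreeding with and without selection (full
#' precision plus a 3-significant-figure printing column), effective
#' population sizes, expected squared contributions per path (x 1e-4),
#' accounting shares, and the aggregate family-size correction (x 1e-4).
#'
#' @param config A file path or the list from [read_scenario_config()].
#' @param out_dir Optional directory; writes `predictions.csv` there.
#' @param with_correction Use the corrected deltaF as the headline value.
#' @return The report as a data frame (zero rows for an empty scenario list).
#' @export
run_scenarios <- function(config, out_dir = NULL, with_correction = FALSE) {
  scns <- if (is.character(config)) read_scenario_config(config) else config
  rows <- lapply(scns, function(sc) {
    rpt <- predict_inbreeding(sc$scenario, sc$genetics,
                              with_correction = with_correction)
    data.frame(
      name = sc$name, trait = sc$trait,
      N = paste(sc$scenario$N, collapse = "-"),
      p = paste(sc$scenario$p, collapse = "-"),
      deltaF = rpt$deltaF_selection,
      deltaF_printed = signif(rpt$deltaF_selection, 3),
      deltaF_no_selection = rpt$deltaF_no_selection,
      deltaF_no_selection_printed = signif(rpt$deltaF_no_selection, 3),
      Ne = rpt$Ne, Ne_no_selection = rpt$Ne_no_selection,
      Eu2_SS_e4 = 1e4 * rpt$moments$Eu2[["SS"]],
      Eu2_SD_e4 = 1e4 * rpt$moments$Eu2[["SD"]],
      Eu2_DS_e4 = 1e4 * rpt$moments$Eu2[["DS"]],
      Eu2_DD_e4 = 1e4 * rpt$moments$Eu2[["DD"]],
      share_SS = rpt$accounting_shares[["SS"]],
      share_SD = rpt$accounting_shares[["SD"]],
      share_DS = rpt$accounting_shares[["DS"]],
      share_DD = rpt$accounting_shares[["DD"]],
      correction_e4 = 1e4 * rpt$correction_aggregate,
      stringsAsFactors = FALSE
    )
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  report
}

#' Compare a simulation against the analytic prediction
#'
#' Computes the analytic deltaF from the simulation's *measured* equilibrium
#' genetics and realized selection proportions, and checks whether the 95
#' percent Monte-Carlo interval of the mean realized deltaF covers it.
#'
#' @param sim A [simulate_breeding()] result.
#' @param prediction Optional precomputed analytic deltaF; by default it is
#'   derived from the simulation's measured equilibrium.
#' @return List with `analytic`, `realized`, `se`, `ci` (95 percent interval
#'   for the mean), and logical `pass`.
#' @export
compare_sim_prediction <- function(sim, prediction = NULL) {
  if (is.null(prediction)) {
    scn <- sim$scenario
    scn_eff <- breeding_scenario(scn$N, as.numeric(sim$realized_p),
                                 fmds = scn$family_sizes[["fmds"]],
                                 ffds = scn$family_sizes[["ffds"]],
                                 ffdd = scn$family_sizes[["ffdd"]])
    prediction <- suppressWarnings(
      predict_inbreeding(scn_eff, sim$equilibrium)$deltaF_selection)
  }
  m <- mean(sim$realized_deltaF)
  se <- stats::sd(sim$realized_deltaF) / sqrt(sim$replicates)
  ci <- m + c(-1, 1) * stats::qt(0.975, sim$replicates - 1) * se
  list(analytic = prediction, realized = m, se = se, ci = ci,
       pass = prediction >= ci[1] && prediction <= ci[2])
}

#' Validate configured scenarios against the stochastic simulator
#'
#' Runs the simulator for each scenario in the configuration and reports the
#' analytic prediction, the realized deltaF with its Monte-Carlo interval,
#' and a pass flag per scenario. Intended for desk-scale scenarios; the
#' simulator cost grows with the candidate numbers.
#'
#' @param config File path or list from [read_scenario_config()].
#' @param generations,replicates,burn_in,seed Passed to
#'   [simulate_breeding()].
#' @return Data frame with one row per scenario.
#' @export
validate_against_simulation <- function(config, generations = 15,
                                        replicates = 50, burn_in = 5,
                                        seed = 1) {
  scns <- if (is.character(config)) read_scenario_config(config) else config
  rows <- lapply(seq_along(scns), function(j) {
    sc <- scns[[j]]
    sim <- simulate_breeding(sc$scenario, sc$genetics,
                             generations = generations,
                             replicates = replicates, burn_in = burn_in,
                             seed = seed + j)
    cmp <- compare_sim_prediction(sim)
    data.frame(name = sc$name, analytic = cmp$analytic,
               realized = cmp$realized, se = cmp$se,
               ci_lo = cmp$ci[1], ci_hi = cmp$ci[2], pass = cmp$pass,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else data.frame(name = character(0))
}
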