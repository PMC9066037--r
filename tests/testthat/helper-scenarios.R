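# Shared fixtures: the worked scenarios (equilibrium inputs per trait and
# proportion setting) and the desk-scale oracle scenario for simulation.

scn_small <- function(p = c(0.05, 0.125, 0.01, 0.70))
  breeding_scenario(c(20, 50, 100, 7000), p)
scn_mid <- function(p = c(0.05, 0.125, 0.01, 0.70))
  breeding_scenario(c(40, 100, 200, 14000), p)
scn_large <- function(p = c(0.05, 0.125, 0.01, 0.70))
  breeding_scenario(c(60, 150, 300, 21000), p)

# equilibrium genetic inputs: trait setting x proportion setting
gen_h03_5 <- function() genetic_inputs(0.2200, 0.2367, 0.4164, 0.4577)
gen_h03_1 <- function() genetic_inputs(0.2190, 0.2365, 0.4138, 0.4571)
gen_h01_5 <- function() genetic_inputs(0.0774, 0.0806, 0.3329, 0.3590)
gen_idx_5 <- function() genetic_inputs(0.4040, 0.4225, 0.3861, 0.4015)

# reduced scenario for the simulation oracle: proportions as realized by the
# candidate numbers (males = 80 * 2.5 = 200, females = 400 * 2 = 800)
oracle_scenario <- function()
  breeding_scenario(c(20, 40, 80, 400), c(0.10, 0.20, 0.10, 0.50),
                    fmds = 2.5, ffds = 2, ffdd = 2)
oracle_genetics <- function() genetic_inputs(0.3, 0.3, 0.5, 0.5)

# the full-replication oracle run is shared between acceptance blocks
oracle_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_breeding(oracle_scenario(), oracle_genetics(),
                                  generations = 20, replicates = 100,
                                  seed = 11)
    cache
  }
})

# agreement with a printed table value to within 0.5 percent (about one
# unit in the third significant figure)
expect_printed <- function(x, printed) {
  expect_lt(abs(x / printed - 1), 0.005)
}
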