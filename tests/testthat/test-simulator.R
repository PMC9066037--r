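# Simulator mechanics: reproducibility, pedigree consistency, feasibility.
# Statistical agreement with the analytic chain is exercised by the
# acceptance suite at full replication.

tiny_scn <- function() breeding_scenario(c(10, 20, 40, 200),
                                         c(0.125, 0.25, 0.10, 0.50),
                                         fmds = 2, ffds = 2, ffdd = 2)

test_that("identical seeds reproduce the simulation exactly", {
  a <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 8,
                         replicates = 2, seed = 99)
  b <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 8,
                         replicates = 2, seed = 99)
  expect_identical(a$F_t, b$F_t)
  expect_identical(a$realized_deltaF, b$realized_deltaF)
  expect_identical(a$pi_records, b$pi_records)
  c <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 8,
                         replicates = 2, seed = 100)
  expect_false(identical(a$F_t, c$F_t))
})

test_that("mean inbreeding is nondecreasing and starts near zero", {
  sim <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 10,
                           replicates = 3, seed = 7)
  expect_equal(sim$F_t[, 1], rep(0, 3))  # founders unrelated
  for (r in 1:3)
    expect_true(all(diff(sim$F_t[r, ]) > -1e-12))
  expect_true(all(sim$realized_deltaF > 0))
})

test_that("infeasible scenarios are rejected with the path named", {
  scn <- breeding_scenario(c(10, 100, 40, 200), c(0.1, 0.5, 0.1, 0.5),
                           fmds = 2, ffds = 2, ffdd = 2)
  expect_error(
    simulate_breeding(scn, oracle_genetics(), generations = 8, seed = 1),
    "path SD")
  scn2 <- breeding_scenario(c(10, 20, 40, 500), c(0.1, 0.5, 0.1, 0.9),
                            fmds = 2, ffds = 1, ffdd = 0.5)
  expect_error(
    simulate_breeding(scn2, oracle_genetics(), generations = 8, seed = 1,
                      family_size_model = "fixed"),
    "path DD")
})

test_that("pedigree export is consistent", {
  sim <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 6,
                           replicates = 1, seed = 3, keep_pedigree = TRUE)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  write_pedigree(sim, f)
  ped <- read.table(f, header = TRUE)
  expect_identical(names(ped), c("id", "sire", "dam"))
  expect_true(all(ped$sire < ped$id | ped$sire == 0))
  expect_true(all(ped$dam < ped$id | ped$dam == 0))
  founders <- ped$sire == 0
  expect_equal(sum(founders), 220)  # N_SD + N_DD
  sim2 <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 6,
                            replicates = 1, seed = 3)
  expect_error(write_pedigree(sim2, f), "keep_pedigree")
})

test_that("fixed family sizes depress deltaF relative to Poisson", {
  # fixed candidate counts remove family-size variance, which is what the
  # negative deviation-from-Poisson correction quantifies
  sp <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 12,
                          replicates = 25, seed = 17)
  sf <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 12,
                          replicates = 25, seed = 17,
                          family_size_model = "fixed")
  expect_lt(mean(sf$realized_deltaF), mean(sp$realized_deltaF))
})

test_that("empirical regressions have the permitted sparsity and warn when thin", {
  sim <- simulate_breeding(tiny_scn(), oracle_genetics(), generations = 10,
                           replicates = 3, seed = 21)
  expect_warning(er <- empirical_regressions(sim), "records")
  allowed <- matrix(FALSE, 4, 4)
  allowed[cbind(c(1, 2, 1, 2, 3, 4, 3, 4), c(1, 1, 3, 3, 2, 2, 4, 4))] <- TRUE
  expect_true(all(is.na(er$Pi_hat[!allowed])))
  expect_true(all(is.finite(er$Pi_hat[allowed])))
  expect_true(all(is.finite(er$var_s_hat)))
  expect_true(all(er$Lambda_count_hat[allowed] > 0))
})
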