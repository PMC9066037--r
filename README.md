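# fourpath

Deterministic prediction of the rate of inbreeding (ΔF) and effective
population size (N_E = 1/(2ΔF)) for discrete-generation breeding programs
that truncation-select parents on genomically enhanced breeding values
(GEBV) along the four classical paths of animal breeding: sires of sons
(SS), sires of daughters (SD), dams of sons (DS) and dams of daughters
(DD), with SS ⊆ SD and DS ⊆ DD. The widely used four-path formula of Gowe,

    ΔF = (1/32) (1/N_SS + 3/N_SD + 1/N_DS + 3/N_DD),

ignores selection and underestimates ΔF by roughly 40 % under realistic
dairy-style selection pressure. `fourpath` predicts ΔF *with* selection,
which matters to anyone designing a breeding scheme that must hold
inbreeding to an acceptable level while selecting hard.

## The model

The prediction is built on expected long-term genetic contributions. The
contribution of parent *i* in path *x* is modeled as linear in its
selective advantage *s* (its breeding-value deviation plus that of its
mates):

    u_i,x = alpha_x + beta_x * s_i,x,      alpha_x = 1/(4 N_x),

where alpha comes from the unit left eigenvector of the 4×4 gene-flow
matrix **G** (each path ultimately contributes a quarter of the genes), and
the slopes beta solve

    N beta = (I - Pi'/2)^(-1) (Lambda'/2) (1/4, 1/4, 1/4, 1/4)',

with **Pi** the regressions of offspring selective advantage on parental
advantage, `pi[x,y] = (1 - k_x r²_x)/2`, and **Lambda** the
selection-induced regressions of selected-offspring numbers on parental
advantage, `lambda[x,y] = i_x r_x / (2 sigma_A,x)` per expected offspring.
Here `i_x`, `k_x` are the truncation-selection intensity and
variance-reduction coefficient of path *x* and `r²_x`, `sigma²_A,x` the
equilibrium GEBV reliability and genetic variance of the candidate cohort
of that path's sex. The rate of inbreeding is half a weighted sum of
expected squared contributions,

    E(ΔF) = 1/2 * 1' N0 U0 1,

where U0 carries E(u²_x) = alpha_x² + beta_x² sigma²_s,x per path plus the
cross moments E(u_SD u_SS) and E(u_DD u_DS) that arise because the elite
sires (dams) serve in both male (female) paths. A correction for the
deviation of selected family sizes from Poisson variance (binomial family
model) is available; it is orders of magnitude smaller than ΔF.

All predictions run on *equilibrium* variances and reliabilities (after
selection-induced gametic-phase disequilibrium has stabilized), which are
inputs. A stochastic four-path simulator with exact pedigree inbreeding
(tabular relationship matrix) is included as an independent Monte-Carlo
check of every analytic component.

## Worked example

Twenty sires of sons selected from the top 5 % of male candidates, 50
sires of daughters (12.5 %), 100 dams of sons (1 %), 7000 dams of
daughters (70 %), single-trait selection with heritability 0.3 at its
equilibrium variances and reliabilities:

```r
library(fourpath)
sc <- breeding_scenario(N = c(20, 50, 100, 7000),
                        p = c(0.05, 0.125, 0.01, 0.70))
ge <- genetic_inputs(sigma2_m = 0.2200, sigma2_f = 0.2367,
                     r2_m = 0.4164, r2_f = 0.4577)
predict_inbreeding(sc, ge)
#> Four-path rate of inbreeding
#>   parents (SS-SD-DS-DD): 20-50-100-7000
#>   proportions retained : 0.050-0.125-0.010-0.700
#>   deltaF (selection)   : 0.00614   Ne = 81.5
#>   deltaF (no selection): 0.00376   Ne = 132.9
#>   family-size corr.    : -0.871 x 1e-4 (corrected deltaF 0.00605)
#>   accounting shares    : SS 0.573  SD 0.322  DS 0.101  DD 0.004
```

Ignoring selection would report N_E ≈ 133 when the selected population
behaves like one of 81: selection concentrates long-term contributions in
the heavily selected male paths (SS and SD jointly account for ~90 % of
ΔF), and the family-size correction is negligible next to that. Per-path
selection regimes (`build_regime`), contribution solutions
(`solve_contributions`) and all intermediate moments are exposed.

A bundled grid of 18 scenario predictions (three trait settings, two
proportion settings, three parent-number settings, each row carrying its
no-selection reference):

```r
run_scenarios(fourpath_example_config(), out_dir = "out")
```

or from the shell: `exec/fourpath tables --out out`. The simulator:

```r
sc <- breeding_scenario(c(20, 40, 80, 400), c(0.10, 0.20, 0.10, 0.50),
                        fmds = 2.5, ffds = 2, ffdd = 2)
sim <- simulate_breeding(sc, genetic_inputs(0.3, 0.3, 0.5, 0.5),
                         generations = 20, replicates = 100, seed = 11)
compare_sim_prediction(sim)   # analytic deltaF vs realized, with 95% MC CI
```

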