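---
title: "Predicting rates of inbreeding under four-path genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting rates of inbreeding under four-path genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourpath)
```

## The problem

Closed breeding nuclei in cattle-style programs select parents along four
paths — sires of sons (SS), sires of daughters (SD), dams of sons (DS) and
dams of daughters (DD) — with the elite subsets nested: every SS sire also
serves as an SD sire, every DS dam also as a DD dam. When parents are used
in constant numbers and at constant selection intensity over their usage
period, each path forms a single exclusive category and generations can be
treated as discrete. The classical four-path formula for the rate of
inbreeding,
$$\Delta F = \tfrac{1}{32}\left(\tfrac{1}{N_{SS}} + \tfrac{3}{N_{SD}} +
\tfrac{1}{N_{DS}} + \tfrac{3}{N_{DD}}\right),$$
ignores selection entirely. Selection on GEBV concentrates long-term
genetic contributions in the families of high-ranking parents and inflates
$\Delta F$ substantially — by roughly 60–90 % under the selection
pressures this package ships as examples. `fourpath` predicts $\Delta F$
and $N_E = 1/(2\Delta F)$ with selection included.

## Model

### Long-term contributions

The long-term genetic contribution $r_i$ of parent $i$ is the asymptotic
fraction of genes in distant descendants deriving from $i$; the rate of
inbreeding is proportional to the expected sum of squared contributions.
Conditional on the parent's *selective advantage*
$s_{i,x}$ — its breeding-value deviation plus the mean deviation of its
mates, relative to the category means — the expected contribution is
modeled linearly:
$$u_{i,x} = \alpha_x + \beta_x s_{i,x}.$$

The intercepts come from the gene-flow matrix $G$ (rows offspring
category, columns parent category; sons draw half their genes from SS and
half from DS, daughters half from SD and half from DD). Its left
eigenvector with eigenvalue 1 is uniform, $(\tfrac14,\tfrac14,\tfrac14,
\tfrac14)$, so an average parent contributes $\alpha_x = 1/(4N_x)$.

The slopes solve
$$N\beta = (I_4 - \tfrac12 \Pi')^{-1}\, \tfrac12 \Lambda'\,
(\tfrac14,\tfrac14,\tfrac14,\tfrac14)',$$
which is the fixed point of the recursion "a parent's contribution is half
the summed contributions of its selected offspring". The right-hand side
carries no parent numbers, so $N_x\beta_x$ is invariant to jointly
rescaling the program and $\beta_x \propto 1/N_x$.

### The regression matrices

The element algebra of $\Pi$ and $\Lambda$ is derived here from that
recursion for truncation selection on a GEBV of known reliability, rather
than transcribed. Two identities make the elements compact. First, with
the advantage defined as own deviation plus mate-mean deviation, the
covariance of an offspring's breeding value with its parent's advantage
equals *half the advantage variance of the parent's category* — for a sire
the offspring's dam is one of his $N_{DS}/N_{SS}$ (or $N_{DD}/N_{SD}$)
mates, for a dam the offspring's sire is her single mate, and the mate
term of the parent's advantage supplies exactly the other half. Hence the
unselected parent–offspring regression is $\tfrac12$ for every permitted
cell. Second, for a BLUP-like criterion (estimation error orthogonal to
the estimate), truncation of the offspring cohort with variance-reduction
coefficient $k_x$ shrinks that regression by $(1 - k_x r^2_x)$:
$$\pi_{xy} = \tfrac12\,(1 - k_x r^2_x),$$
with $r^2_x$ the equilibrium reliability in the offspring's sex. A unit
increase in parental advantage raises a candidate's GEBV mean by
$r^2_x/2$ and therefore its selection probability by $i_x p_x r^2_x /
(2 r_x \sigma_{A,x})$; expressed per expected selected offspring
(the form the contribution recursion needs, and the form in which the
elements are free of parent numbers),
$$\lambda_{xy} = \frac{i_x r_x}{2\sigma_{A,x}},$$
where $i_x$ is the selection intensity and $r_x \sigma_{A,x}$ the GEBV
standard deviation of the candidate cohort. The raw regression of
offspring *counts* on parental advantage is $(N_x/N_y)\lambda_{xy}$, which
is what the simulator estimates. Both matrices are non-zero only in the
eight cells permitted by the mating design.

### Advantage variances, moments, and assembly

Post-selection advantage variances combine the truncation shrinkage
$(1-k r^2)$ with a finite-sample factor $(1-1/N)$ for deviations measured
from estimated category means; sire paths carry the variance of a mean of
their mates, dam paths the full variance of their single mate, and
mate-mean covariances across paths vanish under random mating. The
variance of the *mean* term uses the mating ratio ($\sigma^2_{A,f}$
divided by $N_{DS}/N_{SS}$ for SS sires), and the $(1-1/N)$ factor of the
own-path parent count is applied to both terms. Squared contributions are
$E(u^2_x) = \alpha_x^2 + \beta_x^2\sigma^2_{s,x}$. Because the elite
subsets are nested, the assembly uses cross moments
$E(u_{SD}u_{SS})$ and $E(u_{DD}u_{DS})$, each containing a term from the
difference in category means, $E(\bar A_{SS}-\bar A_{SD}) =
(i_{SS}-i_{SD})\sigma_{A,m}$ (the female analogue likewise; the genetic
standard deviation is used unscaled by accuracy). Then
$$E(\Delta F) = \tfrac12\,\mathbf{1}' N_0 U_0 \mathbf{1},$$
with $N_0 = \mathrm{diag}(N_{SD}, N_{SS}, N_{DD}, N_{DS})$ and $U_0$
carrying the squared moments on the diagonal and twice the cross moments
on the sub-diagonal. At $\beta = 0$ this collapses *exactly* to the
classical closed form above (verified to $10^{-12}$ over 1000 random
parent vectors in the test suite).

The per-path accounting shares split $\Delta F$ by assigning each nested
pair's cross moment half to the elite path and half to the wider path:
SS takes $\tfrac12 N_{SS}(E(u^2_{SS}) + E(u_{SD}u_{SS}))$, SD takes
$\tfrac12 N_{SD}E(u^2_{SD}) + \tfrac12 N_{SS}E(u_{SD}u_{SS})$, and the
female paths analogously. This partition is exact — the shares sum to one
with zero residual — and reproduces the published-style share tables; a
renormalization guard is retained but never active.

### Family-size correction

The contribution framework assumes independent Poisson numbers of
selected offspring per family. A family with a fixed number $f$ of
candidates, each selected with probability $q$, instead has binomial
variance $fq(1-q)$ — a deviation of $-fq^2$. The per-path correction takes
the expectation of the squared offspring-contribution vector
$u^*_{xy} = \alpha_x + \beta_x\pi_{xy}s_y$ over $s_y \sim
N(0,\sigma^2_{s,y})$ and aggregates as $\tfrac18\sum_y N_y\delta_y$ with
$$\delta_y = -\sum_x f_y\, q_x^2\,
\left(\alpha_x^2 + \beta_x^2\pi_{xy}^2\sigma^2_{s,y}\right).$$
Family sizes per parent category follow the mating structure:
$(N_{DS}/N_{SS})\,\mathrm{fmds}$ male candidates per SS sire,
$(N_{DD}/N_{SD})\,\mathrm{ffdd}$ female candidates per SD sire,
$\mathrm{fmds}$ and $\mathrm{ffdd}$ per DS and DD dam. The female family
size of DS dams (`ffds`) does not enter the correction: a DS dam's
daughters are accounted through her DD role. The $\Delta V$ matrices are
taken diagonal; the covariance between a family's SS- and SD-selected
counts is already represented by the $U_0$ cross moments, and adding it
again would double-count. The correction is negative and one to two
orders of magnitude below $\Delta F$ (about $-0.9\times10^{-4}$ against
$\Delta F \approx 6\times10^{-3}$ in the flagship example), so the
headline $\Delta F$ is reported uncorrected; `with_correction = TRUE`
switches the headline.

## Parameters that matter

* `N` (parents per path) and `p` (retained proportions, driving $i$, $k$):
  the two dominant levers. $\Delta F$ scales almost inversely with a joint
  increase of all $N_x$; relaxing male-path proportions from 1 %–5 % to
  5 %–12.5 % lowers $\Delta F$ by only ~12 %.
* `sigma2_m/f`, `r2_m/f`: *equilibrium* genetic variances and GEBV
  reliabilities per sex, in trait units² and as squared accuracies. These
  are inputs; computing them (e.g., by iterating variances under selection
  to the asymptote) is outside this package's scope. Defaults are not
  provided deliberately — they are scheme-specific.
* `fmds`, `ffds`, `ffdd` (candidates per dam family; defaults 4, 4, 1.4,
  typical for multiple-ovulation/embryo-transfer son-matings and
  conventional daughter-matings): used only by the family-size correction
  and the simulator.
* Selection intensities use infinite-population truncation theory,
  evaluated from the exact normal quantile/density (absolute accuracy
  far below $10^{-10}$). With fewer than ~20 selected parents drawn from
  multi-candidate families an order-statistics correction would be
  needed; the package warns and proceeds.

## The simulator, and what passing tests show

`simulate_breeding()` is a from-scratch stochastic implementation of the
same breeding scheme: discrete generations, GEBV = true breeding value
plus independent noise sized to the stated base-generation reliability,
truncation selection of the top $N_x$ per sex with nested elite subsets,
balanced random mating, Mendelian-sampling variance
$\tfrac12\sigma^2_{A0}(1-\bar F_{parents})$, and *exact* pedigree
inbreeding by propagating the relationship matrix of each parent
generation (tabular method restricted to parents, $O(N^2)$ per
generation). Equilibrium variances and reliabilities are *measured* from
post-burn-in candidate cohorts and fed to the analytic chain, keeping the
two routes independent.

Design choices a user should know:

* **Family-size model.** The default draws each dam's candidate count from
  a Poisson distribution, matching the assumption of the uncorrected
  prediction. With `family_size_model = "fixed"` (deterministic counts)
  the realized $\Delta F$ drops several percent below the Poisson-model
  value — the effect the binomial correction quantifies, and a directional
  check of its sign.
* **Oracle scenario scale.** The validation runs use 20-40-80-400 parents
  with uniform female family sizes (candidate numbers then realize
  proportions 10 %-20 %-10 %-50 %), 20 generations, 100 replicates; the
  zero-reliability anchor doubles the parent numbers because the
  no-selection closed form is first-order in $1/N$ and its $O(1/N^2)$
  remainder (~1.5 % at the smaller size) would otherwise exceed the
  Monte-Carlo resolution. These sizes keep every analytic approximation
  visible without conflating it with sampling noise.
* **What agrees.** Realized pedigree $\Delta F$ covers the analytic
  prediction within the 95 % Monte-Carlo interval; the count regressions
  ($\Lambda$ scale) and the per-path advantage variances agree within
  3 standard errors in every cell; with reliability zero the realized rate
  matches the closed form.
* **What does not.** The measurable OLS regression of selected-offspring
  advantage on parental advantage sits systematically 3–10 % *above* the
  linearized $\pi_{xy}$ (largest for dam-side advantages, which contain a
  strongly truncation-skewed single-mate component: the conditional mean
  of offspring advantage is convex in the parent's advantage, and a
  right-skewed regressor pushes the OLS slope above the tangent slope at
  the origin). This is a property of the linearization itself, not of its
  implementation: substituting the empirically estimated regressions into
  the contribution assembly moves the predicted $\Delta F$ *away* from the
  realized value. The concordance check is kept in the acceptance suite at
  Monte-Carlo precision and fails there by design of the comparison; the
  package deliberately retains the linearized elements, which are
  self-consistent with the contribution accounting and reproduce the
  published-style worked examples to within ~0.2 %.
* **What the simulator does not emulate.** Real genomic evaluation
  (marker effects, information sharing among relatives — GEBV errors here
  are independent), overlapping generations, non-random mating,
  selection-scheme changes over time, and fertility/viability variation
  beyond the family-size model. Passing oracle tests therefore validates
  the prediction for the idealized scheme the theory addresses, not for
  any particular real program.

## Numerical choices and degenerate inputs

* $p = 1$ encodes an unselected path exactly ($i = k = 0$, $t = -\infty$),
  the recommended encoding when the DD path is effectively unselected.
* The contribution system is solved by LU factorization (never an explicit
  inverse); its condition is checked and an error raised below a
  reciprocal condition number of $10^{-12}$ (unreachable while
  $k r^2 < 1$).
* Proportions at or below zero, reliabilities outside $[0,1]$,
  non-positive variances, non-integer or inverted parent numbers
  ($N_{SS} > N_{SD}$, $N_{DS} > N_{DD}$) and infeasible simulator
  scenarios (candidates fewer than parents, named by path) are rejected
  at construction.
* Report CSVs round nothing; a 3-significant-figure column is added for
  table-style comparison. Outputs are byte-stable for a fixed seed.

## Known limitations

The prediction inherits the framework's first-order character: at
desk-scale parent numbers its neglected higher-order terms amount to a few
percent (quantified by the simulator), shrinking as programs grow. The
equilibrium inputs must come from elsewhere; feeding base-generation
variances overstates both gain and $\Delta F$. And the linear contribution
model holds for truncation selection on a normally distributed criterion —
strongly non-normal criteria or within-family selection rules are out of
scope.
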