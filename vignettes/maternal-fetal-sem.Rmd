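---
title: "Partitioning maternal and fetal genetic effects with latent-genotype SEM"
author: "dyadsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning maternal and fetal genetic effects with latent-genotype SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A genetic variant associated with a perinatal phenotype such as birthweight
can act through the individual's own genome (a *fetal* effect, coefficient
$f$), through the mother's genome via the intrauterine environment (a
*maternal* effect, coefficient $m$), or both. Because a mother transmits
half her alleles to her child, the two genotypes are correlated at 0.5, and
the simple regressions used in most genetic studies confound the two
routes: regressing an individual's phenotype on their own dosage estimates
$f + m/2$, and regressing their offspring's phenotype on the same dosage
estimates $m + f/2$. Separating $m$ from $f$ normally requires genotypes in
both generations, which few cohorts have.

`dyadsem` implements a structural equation model that needs genotypes in
only one generation. For each genotyped individual we may observe their own
phenotype ($BW$), their offspring's phenotype ($BW_O$), or both, alongside
their dosage ($SNP$). The genotype of the individual's mother ($G_G$) and
of their offspring ($G_O$) are *latent* variables, tied to the observed
dosage by Mendelian transmission paths fixed at $1/2$, with all three
genotype variables constrained to a common variance $\Phi$.

## The model

Path tracing through the latent genotypes gives the implied moments of the
observed vector $(BW, BW_O, SNP)$:

$$
\begin{aligned}
\operatorname{Var}(BW) &= \Phi(m^2+f^2+mf) + \sigma^2_\varepsilon, \qquad
\operatorname{Var}(BW_O) = \Phi(m^2+f^2+mf) + \sigma^2_{\varepsilon_O},\\
\operatorname{Var}(SNP) &= \Phi, \qquad
\operatorname{Cov}(BW, SNP) = \Phi\!\left(f + \tfrac{m}{2}\right), \qquad
\operatorname{Cov}(BW_O, SNP) = \Phi\!\left(m + \tfrac{f}{2}\right),\\
\operatorname{Cov}(BW, BW_O) &= \Phi\!\left(\tfrac{m^2+f^2}{2} +
  \tfrac{5}{4}mf\right) + \rho .
\end{aligned}
$$

$\rho$ is the covariance between the two phenotype residuals and absorbs
everything mothers and offspring share beyond the modelled locus (polygenic
background, environment). The residual variances
$\sigma^2_\varepsilon, \sigma^2_{\varepsilon_O}$ and the three means are
free; the transmission paths are fixed by Mendelian inheritance and are
never estimated.

Estimation is full-information maximum likelihood over *observation
patterns*: individuals with both phenotypes contribute a trivariate normal
density, individuals with only their own phenotype or only their
offspring's contribute the corresponding bivariate marginal. The same
objective can be evaluated from raw records (`neg2_loglik_raw`) or from
per-pattern sample means and maximum-likelihood covariances
(`neg2_loglik_cov`); the two are algebraically identical, and the
covariance route is roughly two orders of magnitude faster, which is what
makes replicate-heavy power studies practical. Cohorts that cannot share
raw data enter through `summary_stats_to_group`, which rebuilds the
two-variable sufficient statistics of an unconditional association analysis
from its effect-allele frequency, slope, phenotype variance and sample
size; all groups in a joint fit must code dosage on the same scale, since
they share $\Phi$.

With complete data the full model is just-identified (nine free parameters
against nine observed moments), so the maximum-likelihood estimates solve
the moment equations in closed form; the test suite uses that algebraic
solution as an independent check on the optimizer.

## Tests

Wald tests of each free path use $(\hat\theta/\mathrm{SE})^2$ on
$\chi^2_1$. Likelihood-ratio tests compare the full model with a variant in
which one path (df = 1) or both paths (the 2-degrees-of-freedom omnibus
test of any SNP effect) are fixed at zero. Wald is the default reported
test: across the simulation harness the two disagree negligibly, and Wald
needs a single fit. `heterogeneity_i2` provides the fixed-effect Cochran
$Q$ / $I^2$ comparison used to contrast an SEM estimate with an external
conditional-regression estimate of the same effect.

## What the simulator emulates

`simulate_dyads` generates mother–offspring dyads the way the estimator
assumes the world works, so that every dataset carries its own truth:

* **Genotypes.** Grand-maternal genotypes from Hardy–Weinberg at allele
  frequency $p$; one allele transmitted uniformly at random per meiosis;
  fathers in both generations drawn from Hardy–Weinberg and discarded.
  Dosages are standardized, so $\Phi \approx 1$ in simulations.
* **Phenotypes.** $BW = m\,G_G + f\,SNP + \beta_U U + \varepsilon$ and
  $BW_O = m\,SNP + f\,G_O + \beta_U U + \varepsilon_O$, with $U$ a shared
  standard-normal confounder. The default loading $\beta_U = 0.5$ on both
  phenotypes makes the true residual covariance $\rho = 0.25$, a
  mother–offspring phenotype correlation in the range reported for
  birthweight. Residual variances are chosen so both phenotypes have unit
  variance asymptotically.
* **Effect sizes** are specified as signed fractions of phenotypic variance
  (`v_fetal = 4e-4` means 0.04%); the working coefficient is the signed
  square root ($\pm 0.02$), matching how single-variant effects on
  birthweight are usually reported. Defaults cover the grid used throughout:
  $p \in \{0.5, 0.9, 0.99\}$, fetal fractions $\{0, 0.02\%, 0.04\%\}$,
  maternal fractions $\{0, 0.01\%, 0.02\%\}$, both signs.
* **Measurement error.** Classical additive noise calibrated by the $R^2$
  of degraded-on-true regression (so $R^2 = 0.25$ triples the error
  variance relative to the signal), and optional rounding of the offspring
  phenotype to the nearest unit on its standardized scale — about six
  occupied categories, emulating birthweight recalled to the nearest pound.
  The exact category boundaries of real recalled birthweight are not
  reproduced; the rounding is an emulation of that coarseness.
* **Missingness.** Four completely-at-random designs on 30 000 families:
  (i) half own-phenotype-only, (ii) half offspring-only, (iii) half
  complete plus a quarter of each single-phenotype group, (iv) no family
  with both phenotypes. Under (iv) the likelihood never touches
  $\operatorname{Cov}(BW, BW_O)$, so $\rho$ is structurally inestimable and
  is dropped from the parameter vector.

What the simulator does **not** emulate: gestational age, sex differences,
informative (non-random) missingness, assortative mating, paternal effects,
non-normal phenotypes, genotyping or imputation error. Passing tests
therefore show the estimator behaves as designed under its own assumptions,
not that those assumptions hold in any particular cohort.

## Numerical choices

* Variances are optimized on the log scale (positivity by construction);
  $m$, $f$, $\rho$ and the means are unconstrained, with positive
  definiteness of the implied covariance checked at every objective
  evaluation (`Inf` inside the optimizer, an explicit invalid-parameter
  condition at the user surface).
* Starting values solve the moment equations
  ($\hat f_0 = (4c_1 - 2c_2)/3$, $\hat m_0 = (4c_2 - 2c_1)/3$ with
  $c_1 = \widehat{\operatorname{Cov}}(BW,SNP)/\hat\Phi$,
  $c_2 = \widehat{\operatorname{Cov}}(BW_O,SNP)/\hat\Phi$), so on complete
  data BFGS starts essentially at the optimum.
* If a fit fails to converge or its Hessian is singular, up to `restarts`
  (default 10) jittered restarts are attempted and the best converged fit
  returned — the retry-on-failure behaviour low-frequency variants need.
* Standard errors come from the inverse of a central finite-difference
  Hessian of the negative log-likelihood, step $10^{-4}$ on each working
  coordinate.
* Likelihood-ratio statistics are floored at zero: with finite optimizer
  tolerance a reduced model can come out a hair "better". Comparing a model
  with itself is allowed and returns a degenerate df = 0 test with p = 1.
* Replicate $r$ of a scenario is seeded with `seed + r`, so any replicate
  can be regenerated in isolation and identical configurations are
  bit-reproducible.

## The Monte-Carlo harness

`run_scenario` simulates, degrades, masks, fits the requested model
variants and aggregates: rejection rates at $\alpha = 0.05$ per test, mean
estimates, bias with a 95% CI, mean reported SEs, and the convergence rate
(results are flagged below 90%; non-converged replicates are excluded and
counted). `run_grid` crosses scenario settings and `format_results_table`
emits a long-format TSV with one row per scenario and path.

Problem sizes: a full-scale characterization of this design calls for
about 10 000 replicates of 30 000 dyads per scenario. The package's own
test suite and acceptance script use the same 30 000-dyad replicates but
300–1000 replicates per scenario — enough
that a rate known to be $P$ carries a Monte-Carlo standard error of
$\sqrt{P(1-P)/R}$ of one to two percentage points, which is the tolerance
the tests use (three such SEs). The moment-oracle checks use $10^6$–$10^7$
simulated families. The one quantity that genuinely needs the full $10^4$
replicates is the small residual maternal-effect bias (about $-0.0003$)
under the no-overlap missingness design; the desk-scale test bounds it by
3% of the true effect plus three Monte-Carlo SEs and notes that resolving
the value itself is a long run of `run_scenario` away.

## Known limitations

* Identification of $m$ and $f$ separately requires phenotype information
  from both generations somewhere in the joint data; a lone
  own-phenotype-only cohort identifies only $f + m/2$.
* Low minor allele frequencies (below ~5%) make the objective surface
  harder; restarts mitigate but do not remove this.
* The model assumes multivariate normality of the phenotypes given the
  genotype, additivity at the locus, and no maternal–fetal genotype
  interaction; it estimates maternal and fetal effects only — paternal
  effects would require genotyped fathers with phenotyped offspring.
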