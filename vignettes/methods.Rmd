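---
title: "Models and methods behind gulldemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gulldemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gulldemog)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and the reasoning
behind the numerical and design choices. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## The estimation problem

Colonial waterbirds marked as fledglings and re-observed visually over
years yield one 0/1 encounter history per bird. Two facts shape
everything downstream:

1. **Age is known exactly.** Every bird is marked at fledging, so age at
   occasion $j$ for a bird first detected at occasion $c$ is $j - c$.
   Age-structured survival and resighting come "for free" from the cohort
   layout, with no age-uncertainty machinery.
2. **Permanent emigration is invisible.** A bird that settles in another
   colony is never seen again, indistinguishably from death. All survival
   parameters are therefore *apparent (local) survival*: true survival
   times site fidelity. The synthetic generator makes this explicit by
   simulating emigration as a separate permanent removal whose effect is
   only ever observable through depressed apparent survival.

## Cormack–Jolly–Seber machinery

Histories are reduced to cohort m-arrays: for each (colony, marking
cohort, release occasion $i$) stratum, the number released $R_i$
(first markings plus re-releases of birds detected at $i$), the counts
$m_{ij}$ first re-encountered at each later occasion $j$, and the number
never seen again. Conditional on release, the cell probability is

$$\pi_{ij} = \Big(\prod_{k=i}^{j-1}\varphi_{a(k),k}\Big)
             \Big(\prod_{k=i+1}^{j-1}(1-p_{a(k),k})\Big)\, p_{a(j),j},$$

with indices resolved per age class and year by the model structure, and
the never-seen cell takes the remaining mass. The deviance is $-2\log$ of
the product multinomial with the (model-independent) multinomial
coefficients dropped; the tests verify on random small instances that
this equals a per-individual likelihood computed independently with the
$\chi_i$ (never-seen-again) recursion.

**Model grammar.** `a(...)` declares contiguous age classes ending in an
open class; `t`, `col` and covariate names are effects; `.` compiles to a
full interaction, `+` to an additive term, and `/` separates independent
per-age-class blocks. Each block becomes an R model formula over the
*feasible* parameter cells (group × age class × year) given the cohorts
actually present; the block design matrix is reduced to a full-column-rank
basis by pivoted QR, so the nominal parameter count already reflects
cells that the cohort geometry cannot reach. Covariates are standardized
to zero mean and unit population standard deviation before binding, so
slopes are comparable across covariates of different units.

**Fitting.** The logit link keeps all probabilities in (0,1). The
deviance gradient is computed analytically (reverse cumulative sums of
cell weights scattered onto design rows), and optimization is BFGS with
seeded multi-start — the first start at logit(0.5), the rest standard
normal draws; the default of 5 starts guards against the mild
multimodality constrained CMR likelihoods can show, and simulation-scale
callers may reduce it (the likelihood at study scale is, in our tests,
unimodal in practice). Convergence is declared when the gradient norm
falls below $10^{-8}$ (relative); otherwise the fit is flagged, never
silently accepted.

**Estimable parameters and AICc.** The reported parameter count `np` is
the numerical rank of the deviance Hessian at the optimum (singular
values below $10^{-6}$ of the largest dropped). This automatically
captures the terminal $\varphi_{T-1} \times p_T$ confounding of the fully
time-dependent model. AICc uses
$\mathrm{Dev} + 2\,np + 2\,np(np+1)/(n_{\mathrm{eff}} - np - 1)$ with
$n_{\mathrm{eff}}$ = the total number of observations (initial captures
plus resights). That convention is not universal — some software uses
releases — but it is the one that reproduces the published AICc
arithmetic of the tables this package's acceptance suite checks
(e.g. $4026.82 + 66 + 2244/2421 = 4093.75$), so it is the default;
`n_eff` can be overridden.

**ANODEV.** A covariate test compares three nested fits sharing the
resighting structure: the focal parameter constant, driven by the
covariate, and fully time-dependent. $F$ is the mean-square ratio of
deviance explained by the covariate to residual temporal deviance, with
degrees of freedom from the supplied parameter counts (not re-derived
from rank: published tables count parameters structurally). The
convention for building the reference pair mirrors the covariate's
structural form: an interactive per-class covariate is replaced by
interactive per-class time, an additive shared covariate by additive
time. $r^2$ is the explained fraction of temporal deviance. Slightly
negative numerators from optimizer noise are clipped to zero with a
warning; inverted reference models are an error.

## Goodness-of-fit

The classic contingency decomposition: at each occasion, TEST3.SR and
TEST3.Sm contrast newly vs previously marked birds (transience/marking
effects); TEST2.CT and TEST2.CL contrast birds seen vs not seen at the
occasion among those known alive (trap-dependence). Tables are
Pearson-tested after merging rows/columns whose expected count falls
below 2 toward their neighbours; tables that cannot reach a valid 2×2
are flagged degenerate (df 0) and excluded from the global sum. Only
chi-square forms are computed — the directional z variants do not feed
the global statistic.

One subtlety matters in age-structured studies: on pooled multi-cohort
data, TEST3 reads a *modeled* age effect (first-year survival below adult
survival) as transience and rejects, although the general model fits.
Computing the components within each marking cohort — where all birds
share an age — removes that artifact, at the price of making TEST3
degenerate. Both modes are exposed (`by_cohort`); the pipeline uses the
cohort-wise mode because its general models carry age structure, while
the calibration property (type-I error within [0.02, 0.09] on CJS-true
simulations) and the transience power property are established on the
pooled mode, each in the world where it is the right test.

## Count-based growth

Annual growth is $\lambda_t = N_{t+1}/N_t$ for consecutive-year pairs
only. The stochastic growth rate regresses
$y_i = \log(N_{i+1}/N_i)/\sqrt{\tau_i}$ on $x_i = \sqrt{\tau_i}$ without
intercept over successive census pairs with elapsed time $\tau_i$, which
handles census gaps exactly: $\hat\mu$ is the slope, $\hat\sigma^2$ the
residual mean square, $\lambda_s = e^{\hat\mu}$ with CI
$\exp(\hat\mu \pm t_{\alpha/2,\,q-1}\,SE(\hat\mu))$. We report the
median-growth convention $e^{\hat\mu}$ by default; the lognormal-mean
variant $e^{\hat\mu + \hat\sigma^2/2}$ sits behind an option because
published regional estimates in this literature are consistent with the
$\mu$-based interval. A CI lower limit below 1 is reported as a flag
("decline cannot be ruled out"), never as a point conclusion. When
summing regional censuses into one series, years missing from any region
default to census gaps (`require_all = TRUE`), since partially-summed
years would masquerade as crashes; both behaviours are exposed.

## Projection and immigration

The stage matrix is female-based with a pre-breeding census: stages are
pre-breeders of ages 1..k−1 plus breeders, where k is the terminal
recruitment age. A pre-breeder of age $a$ survives with adult survival
and recruits with the age-$(a{+}1)$ recruitment probability; breeders
survive with adult survival and contribute
$\text{sex ratio} \times f \times \varphi_1$ female fledglings that
survive their first year into the age-1 stage. The recruitment schedule
is an explicit input because the source estimates for this species come
from a different population and are not reproduced here; the default
(ages 2–5, probabilities 0.25/0.5/0.75/1) encodes the delayed accession
typical of gulls and is a placeholder, not an estimate. Note a
consequence the tests freeze: with fecundity 2, survival 1 everywhere and
recruitment at age 2, the two-stage matrix is [[0,1],[1,1]] and grows at
the golden ratio — "two chicks per pair" is *not* replacement when the
parents also survive. Asymptotic growth is the dominant eigenvalue
(checked against power iteration); the bounding property
$\varphi_{ad} \le \lambda \le \varphi_{ad} + \text{sr}\cdot f \cdot
\varphi_1$ holds for any schedule with terminal age ≤ 5.

The immigration correction divides the observed number of marked
immigrants by the marking fraction at the origin and the resighting
probability at the destination; it assumes immigrants are resighted with
the same probability as residents and that the marking fraction is known
without error.

## The synthetic worlds, and what a green test establishes

The generator simulates exactly the structure the estimators assume:
Bernoulli survival per age/interval, Bernoulli detection per occasion,
permanent emigration folded into apparent survival, lognormal census
noise, truncated-normal productivity on [0, 1.9] fledglings per nest
(the observed range in this study system, from complete failure to 1.9).
Study-scale presets mark 3303 fledglings over 13 cohorts of 14 occasions
(first-year survival 0.78, adult 0.83) and 1662 over 8 cohorts of 11
occasions (0.38, 0.76) — the published point estimates of the two
colonies — with age-structured resighting defaults (0.10/0.20 and
0.27/0.42) solved once from the expected-observation-count identity so
the simulated data volume matches the reported ~5042 and ~2455
observations; real annual resighting probabilities varied over time, and
these constants do not emulate that.

What the synthetic worlds deliberately lack: temporal covariation between
colonies, individual heterogeneity, trap-dependence, observation error in
censuses, and any dispersal structure beyond permanent emigration. A
green recovery test therefore establishes the *estimators'* correctness
under their own assumptions (no bias at study scale, calibrated
uncertainty), not robustness to the violations real data contain. The
published model-based vs count-based growth comparison is out of reach at
desk scale — it needs the annual vital-rate series and external
recruitment estimates that are not printed — so eigen-projection
correctness is established by oracle and monotonicity properties instead.

## Numerical choices

* Logit link everywhere; probabilities never clamp (cell probabilities
  are clamped only inside logs at 1e-300 to avoid -Inf in degenerate
  corners).
* Ties in model selection tables break toward fewer parameters.
* Covariate gap-filling uses the monotone (Fritsch–Carlson) piecewise
  cubic Hermite spline, which reproduces linear stretches exactly and
  never overshoots locally monotone data; boundary gaps are an error
  because extrapolation has no support in an annual covariate.
* Standardization uses the population (denominator n) standard deviation
  and is idempotent.
* All simulation randomness flows through a single seeded generator per
  call, with the caller's RNG state restored afterwards.
* The m-array builder treats a detection at the final occasion as a
  release with no multinomial cells, so the conservation identity
  $R_i = \sum_j m_{ij} + \text{never}_i$ holds for all interior strata.
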