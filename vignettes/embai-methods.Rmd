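---
title: "Two-stage genomic selection with polygenic-background whitening and EM-BayesA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage genomic selection with polygenic-background whitening and EM-BayesA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Genomic selection predicts the genetic merit of individuals — the genomic
estimated breeding value (GEBV) — from genome-wide marker dosages rather than
from a handful of individually significant loci. The data model is the mixed
linear model

$$y = W\alpha + Z\gamma + u + \varepsilon,$$

where $y$ is the phenotype of $n$ individuals, $W$ a design of $c$ fixed
covariates (at least an intercept), $Z$ the $n \times q$ allele-dosage matrix
(0/1/2), $\gamma$ the vector of marker effects treated as random,
$u \sim MVN(0, \sigma_g^2 K)$ a polygenic background with known relatedness
matrix $K$, and $\varepsilon \sim N(0, \sigma^2 I_n)$. With variance ratios
$\lambda_\gamma = \sigma_\gamma^2/\sigma^2$ and
$\lambda_g = \sigma_g^2/\sigma^2$,
$\mathrm{var}(y) = \sigma^2(\lambda_\gamma ZZ^T + \lambda_g K + I_n)$.

The package fits this model in two stages.

**Stage one — whitening.** Because most markers are unlinked to the trait,
$\lambda_\gamma$ is held at zero and $\lambda_g$ is estimated by restricted
maximum likelihood on the reduced model $y = W\alpha + u + \varepsilon$
(`estimate_lambda_g()`). After one eigendecomposition of $K$, every candidate
$\lambda_g$ costs $O(n)$, so a bounded 1-D search over
$\log_{10}\lambda_g \in [-5, 5]$ suffices; the boundary solution
$\hat\lambda_g = 0$ is checked explicitly. The positive definite matrix
$B = \hat\lambda_g K + I_n = Q \Lambda Q^T$ then yields the symmetric
inverse square root $C = Q\Lambda^{-1/2}Q^T$ (`build_whitening()`), and
$y_c = Cy$, $W_c = CW$, $Z_c = CZ$ turn the correlated noise $u +
\varepsilon$ into an iid residual (`apply_whitening()`).

**Stage two — EM for BayesA.** On the whitened data each marker effect has
its own variance with a scaled inverse chi-square prior,
$\gamma_k \sim N(0, \sigma_k^2)$, $\sigma_k^2 \sim \chi^{-2}(\nu, S)$. The
E-step replaces $\sigma_k^2$ by its conditional posterior expectation
$(\hat\gamma_k^2 + S)/(\nu + 1)$; the M-step maximizes the log-posterior
coordinate-wise: a Gauss–Seidel sweep of single-marker ridge updates
$\hat\gamma_k = z_k^T r_k / (z_k^Tz_k + \sigma^2/\hat\sigma_k^2)$ on an
incrementally maintained residual ($O(nq)$ per sweep, implemented in C++),
followed by the covariate and residual-variance updates. `fit_embai()`
composes both stages; `fit_emba()` is stage two alone on raw data.

Marker effects are unchanged by the linear transform, so GEBVs are computed
on the original dosage scale, $\widehat{GEBV} = Z\hat\gamma$
(`predict_gebv()`). The polygenic component is treated as corrected-away
noise and is not added back; on the simulations this package targets, the
in-sample phenotype–GEBV correlations are near 1 either way, so the simpler
contract was chosen.

### The recorded objective

The E-step divisor $(\nu+1)$ arises from the conditional expectation of the
precision, $E[1/\sigma_k^2] = (\nu+1)/(\hat\gamma_k^2+S)$, which is not the
per-marker argmax of the joint log-posterior (that would divide by
$\nu + 3$). Consequently the joint posterior with the E-step values plugged
in is *not* monotone along the iteration — small decreases are provable and
observed. What EM theory does guarantee to ascend is the marginal
log-posterior with the marker variances integrated out,

$$-\tfrac{n}{2}\log\sigma^2 - \frac{\|r\|^2}{2\sigma^2}
  - \tfrac{\nu+1}{2}\sum_k \log(\hat\gamma_k^2 + S),$$

whose stationary points are exactly the EM fixed points. This is the
objective recorded in `log_posterior_trace` and asserted non-decreasing in
the tests; it is also what the brute-force oracle in the test suite
maximizes directly.

## Priors and tuning parameters

* `nu` (default 4): prior degrees of freedom of the marker-variance prior.
* `scale` (default: data-sized): prior scale $S$. By default
  $S = (\nu+1)\, r^2\, \mathrm{var}(y) / \sum_k \mathrm{var}(z_k)$ with
  $r^2 = 0.5$, the convention of the Bayesian whole-genome regression
  packages this model family comes from: the prior attributes half the
  phenotypic variance to the markers a priori. This choice matters: the EM
  has a degenerate fixed point at $\gamma = 0$, and with a fixed tiny scale
  (say $S = 0.01$ against $\mathrm{var}(y) \approx 60$) the shrinkage
  $\sigma^2/\sigma_k^2$ is so strong at the start that no effect can escape
  it — the algorithm provably stalls at the null solution. A fixed numeric
  `scale` remains available for small, well-scaled problems.
* `max_iter` (default 200) and `tol` (default 1e-6): the sweep stops when
  the largest marker-effect change falls below `tol * (1 + max|gamma|)`.
  On the simulation designs below, convergence typically takes 10–130
  sweeps.
* `pi_init` (default 0.05) and `estimate_pi` (default off) for the
  spike-and-slab baseline; see below.

## Baseline fitters

All baselines share the input contract and report schema of the main fitter
and can optionally run after the whitening stage (`whiten = TRUE`).

* `fit_emrr()` — Bayesian ridge: one shared marker variance. The EM here is
  the genuine random-effect EM: the E-step carries each effect's conditional
  posterior variance $v_k$, and the M-steps use
  $E[\gamma_k^2] = \hat\gamma_k^2 + v_k$ plus the matching correction in the
  residual-variance update. The naive plug-in update
  $(\sum\hat\gamma_k^2 + S)/(q+\nu)$, by contrast, collapses the shared
  variance on real signal (the shrunk $\hat\gamma_k^2$ systematically
  underestimate $E[\gamma_k^2]$) and was rejected.
* `fit_emml()` — Gaussian maximum likelihood: the equivalent-GBLUP marginal
  likelihood with covariance $\sigma_\gamma^2 ZZ^T + \sigma^2 I$, maximized
  over the variance ratio on the eigenbasis of $ZZ^T$; effects recovered as
  the posterior mean. emRR and emML estimate the same model family and
  track each other closely, which the tests assert.
* `fit_embc()` — spike-and-slab: the conditional-slab variational EM for
  Bayesian variable selection (Bernoulli inclusion posterior per marker,
  conditional Gaussian slab, shared slab variance). Every update is an exact
  coordinate maximum of one evaluable ELBO, so its trace is monotone by
  construction, and at $\pi = 1$ the arithmetic reduces exactly to emRR.
  Estimating $\pi$ as the mean inclusion probability is supported but off
  by default: under a dense polygenic background, where effectively every
  marker tags some signal, the estimated proportion drifts to a degenerate
  boundary. A fixed prior inclusion probability is the standard remedy.
* `fit_emen()` — elastic net: deliberately not implemented in this release
  (unreliable on $p \gg n$ marker data); it signals a typed
  not-implemented condition so dispatch stays uniform.

## What the simulator emulates

`simulate_genotypes()` draws independent markers under Hardy–Weinberg
equilibrium with allele frequencies uniform on [0.1, 0.5];
`make_scenario_one_qtn()` places a single causal locus on marker 98 with
heritability 0.1, and `make_scenario_multi_qtn()` draws 50 causal loci among
markers with MAF > 0.3 carrying a total phenotypic variance share of 0.5.
The population mean is 10, the residual variance 10, and the polygenic
background is $\sigma_g^2 = m\,\sigma_e^2$ with $m \in \{2, 5, 10\}$ —
"$m$ times" is anchored on the residual variance, the only fixed variance
in the design; this reading is kept as a configuration knob. The QTN
heritability is taken as
$\sigma^2_{QTN}/(\sigma^2_{QTN} + \sigma_g^2 + \sigma_e^2)$, the standard
narrow-sense share, which degenerates correctly when $\sigma_g^2 = 0$;
effect sizes are solved from the *realized* marker variances so the
intended variance share is met exactly in sample. The polygenic term is
drawn through the VanRaden factorisation of the GRM of the simulated
markers themselves ($u = Mb$ with iid normal $b$), which gives exactly the
covariance $\sigma_g^2\,GRM$ without decomposing $K$, and keeps the
generative kinship identical to the kinship used in fitting.

What the simulator does **not** emulate: linkage disequilibrium (markers
are independent), dominance and epistasis, minor-allele-frequency spectra
of real panels, genotyping error or missingness, and population structure
beyond what the random GRM induces. Passing tests therefore demonstrate
correct behaviour under the stated generative model, not performance on
structured real data.

## Numerical choices

* Eigenvalues of $B$ are floored at 1e-10 (with a warning) against
  roundoff; $K$ is validated PSD with tolerance $-10^{-8}\cdot\lambda_{max}$.
* `estimate_lambda_g()` guards against a likelihood plateau: sparse
  major-effect loci, which the reduced model omits, occasionally make the
  restricted likelihood rise into a flat shelf extending to the upper
  search bound (the gain from the shoulder to $\lambda = 10^5$ is about
  one log-likelihood unit). Any estimate on the shelf over-whitens — it
  models the iid environmental component away and slows the stage-two EM —
  while being statistically indistinguishable from the shoulder. Whenever
  the upper bound's restricted log-likelihood comes within 1.0 units of
  the optimum, the smallest $\lambda$ within 1.0 units of the supremum is
  taken instead. Well-identified interior optima are never touched.
* A flat kinship spectrum (e.g. $K = I$) makes $\lambda_g$ and $\sigma^2$
  jointly unidentifiable; the estimator returns $\hat\lambda_g = 0$ with a
  warning, which reduces the two-stage fit to plain EM-BayesA.
* The shared-variance fitters initialize $\sigma_\gamma^2$ at
  $0.5\,\mathrm{var}(y)/\sum_k \mathrm{var}(z_k)$ — the prior-mode
  initialization sits inside the basin of the degenerate null fixed point.
* The residual variance is floored at 1e-12 (warning) when a $q \gg n$ fit
  becomes numerically exact, which is the expected in-sample behaviour of
  adaptive-shrinkage fitters at these dimensions.
* Replicate seeds in `run_benchmark()` are derived from the master seed and
  the cell coordinates by an integer mixing function, so per-cell results do
  not depend on grid ordering.

## Problem sizes used by the tests

The packaged checks reproduce the simulation study at reduced replication,
chosen as the smallest designs at which the compared quantities are stable:
the scenario grid uses $n \in \{1000, 2000\}$ by background multipliers
$\{2, 5\}$ with $q = 10{,}000$ and 10 replicates per cell for the AUC
comparisons; the single-QTN correlation check uses $n = 2000$, $m = 2$,
10 replicates; variance-ratio recovery uses $n = 2000$ with a GRM built
from 2000 markers (the marker count only sets the GRM's precision) and 20
replicates; the brute-force posterior oracle runs at $n \le 10$,
$q \le 3$. Property-style invariants (trace ascent, whitening identity,
permutation invariance, AUC against the exhaustive pairwise oracle) run on
small instances throughout the unit tests.

## Known limitations

* Single trait only; multi-trait selection is out of scope.
* The in-sample evaluation protocol mirrors the simulation study the
  package reproduces; cross-validated accuracy on real panels is a
  different (and harder) target.
* VCF input is deliberately unsupported; dosage CSV and PLINK RAW cover the
  intended workflows.
* emBC's inclusion probabilities are variational approximations; they rank
  markers well but are not calibrated posterior probabilities.
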