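---
title: "Residue-based LFER analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-based LFER analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rblfer)
```

## The model

Multiprobe experiments on a two-state exchanging polypeptide — EXSY or
relaxation-dispersion NMR, or hydrogen/deuterium exchange — yield, for each
residue $i$, an equilibrium constant $K_i$ and forward/backward rate
constants $k_i$ and $k'_i$ of the exchange
$\mathrm{A} \rightleftharpoons \mathrm{B}$, tied together by
$K_i = k_i / k'_i$. A residue-based linear free energy relationship
(rbLFER) is a linear trend across residues in the REFER
(rate-equilibrium free energy relationship) plot,

$$\log_{10} k_i = \rho\,\log_{10} K_i + c,$$

whose slope $\rho$ measures the similarity of the transition state to the
final ground state; interpretable slopes lie in $[0, 1]$ for the forward
direction and, because $\log k' = \log k - \log K$, in $[-1, 0]$ for the
backward direction. Unlike a Hammett or Brønsted series, the points come
from different residues of one polypeptide, not from chemical
perturbations, so the two axes are *not* independent: the triadic
constraint can manufacture linearity out of noise. The package therefore
always pairs the REFER regression with an analysis of the
$(\log k', \log k)$ scatter, which is immune to that artifact.

All logarithms in the package are base 10. Slopes, $R^2$, correlation
coefficients and the flatness statistic are base-invariant; intercepts and
offsets are reported in decades, matching the pH/decade conventions of the
hydrogen-exchange model.

## REFER regression and line classification

`fit_refer()` runs ordinary least squares of $\log k$ and of $\log k'$ on
$\log K$ (vertical residuals, $\log K$ as abscissa — the convention under
which plotted least-squares lines are defined, and the one that preserves
the exact identity $\rho_f - \rho_b = 1$). Measurement uncertainties are
carried as error bars in plots but do not weight the fit by default;
`weighted = TRUE` opts in and breaks the exact identity.

Each direction is classified independently by `classify_slope()`: with a
two-sided Pearson correlation p-value below `alpha` (default 0.05, the
conventional level; configurable) the line is drawn, solid if the slope is
in the interpretable band and dashed otherwise; an insignificant
correlation draws no line. When the two directions disagree on
significance, each keeps its own class. Below `min_n = 4` residues a line
is always drawn near-perfectly, so the fit refuses to run; a zero-variance
abscissa returns an explicit no-fit result rather than an error, since it
is a property of the dataset, not a usage mistake.

## Scatter geometry: ellipse, flatness, taxonomy

Because $R^2$ in the REFER plot can be high for spurious reasons, the
$(\log k', \log k)$ cloud is summarized by a 95% confidence ellipse:
eigen-decomposition of the sample covariance ($n-1$ denominator), with
semi-axes $\sqrt{\lambda_i\,\chi^2_{2,0.95}}$
($\chi^2_{2,0.95} \approx 5.99$). The chi-square scaling treats the
estimated covariance as known; at typical residue counts (15–70) the
small-sample F alternative differs by under 10% and the level is
configurable. Flatness is $f = 1 - b/a$: 0 for an isotropic cloud, 1 for a
perfectly collinear one, invariant under translation, rotation and uniform
scaling.

`classify_kk_type()` assigns the taxonomy: significant negative
correlation is type N (the hallmark of a genuine rbLFER, forcing
$\rho_f \in (0,1)$); significant positive correlation is P or P′ according
to whether $\log k'$ or $\log k$ has the larger sample variance (ties go
to P); an insignificant correlation with flatness at or above 0.6 and the
long axis within 20° of a coordinate axis is V or H; anything else is nr
(no relation). The 0.6 / 20° cutoffs operationalize "flattened shape" —
no numeric thresholds exist in the literature for these labels — and were
chosen once so that idealized V/H/nr cartoons classify correctly; both are
exposed as arguments.

One convention deserves emphasis. Type labels here follow the slope
signature: **V** means $\log k$ is essentially constant while $\log k'$
spreads, which drives the REFER slopes to $\rho_f \to 0$ and
$\rho_b \to -1$; **H** is the mirror case ($\rho_f \to 1$,
$\rho_b \to 0$). "Vertical" refers to the appearance of the cloud when
$\log k'$ is drawn on the vertical axis, which is how `plot()` renders a
`kk_class` object. Function inputs remain $(\log k', \log k)$ pairs.

## Robust outlier detection

Collectively deviating residues (e.g. a transiently translocated helix
whose broken hydrogen bonds accelerate exchange) are found by iteratively
reweighted least squares with Tukey bisquare weights, tuning constant
4.685 (95% Gaussian efficiency), residual scale $\mathrm{median}|r|/0.6745$
recomputed each iteration, and residuals inflated by
$1/\sqrt{1-h_{ii}}$ using the leverage of the fixed design — the
convention of the widely used `fitlm`-style robust linear model, so that
weights are comparable with analyses performed in that environment. The
leverage adjustment is toggleable. The start is OLS, so the whole
procedure is deterministic; convergence is declared when coefficients move
less than $10^{-8}$ (relative), capped at 100 iterations.

A residue is flagged when its weight drops below 0.5 — the midpoint of the
weight range, configurable — in *either* the forward or the backward fit
(outlying residues perturb both lines, and the OR rule is the conservative
screen). `refit_without_outliers()` then redraws the OLS lines on the
retained residues and reports the outliers' mean signed vertical offset
from each line in decades plus the implied multiplicative rate factor
$10^{\Delta}$; the offset is reported as a factor rather than an additive
rate because an additive value depends on the absolute intercept. A
second, parallel line (slope pinned to the refit line) through the
outliers operationalizes the "almost parallel second line" picture of a
collective motion.

With Gaussian noise the 0.5 cutoff sits near 2.5–3.3 robust scales, so on
a clean dataset of ~30–40 residues a marginal false flag appears in a few
percent of realizations; this is a property of the liberal cutoff, not a
defect, and users screening for collective blocks should read the weights
(`$forward$weights`) rather than the binary flag alone.

## Hydrogen-exchange kinetics

The two-process model is
$\mathrm{NH(closed)} \underset{k_{cl}}{\overset{k_{op}}{\rightleftharpoons}}
\mathrm{NH(open)} \xrightarrow{k_{int}} \mathrm{ND(exchanged)}$, with the
steady-state (Linderstrøm-Lang) observed rate
$k_{obs} = k_{op} k_{int}/(k_{op} + k_{cl} + k_{int})$. The EX1 limit
($k_{int} \gg k_{cl}$) gives $k_{obs} \to k_{op}$; the EX2 limit
($k_{int} \ll k_{cl}$) gives $k_{obs} \to (k_{op}/k_{cl})\,k_{int}$.
Regime labels use a one-decade ratio ($R = 10$) as the conventional
reading of "$\gg$/$\ll$"; `hx_exact_slow_rate()` provides the exact
slow-phase eigenvalue of the kinetic matrix, used as an internal oracle —
the steady-state form is accurate to well under 1% whenever
$k_{op} \le 0.01\,k_{cl}$, the folded-protein regime the approximation
assumes.

The intrinsic rate model is single-term base catalysis,
$k_{int} = k_{ref}\,10^{\mathrm{pH} - \mathrm{pH}_{ref}}$, one decade per
pH unit; sequence-dependent intrinsic-rate tables are out of scope but a
per-residue `kint_table` override slots in wherever a $k_{int}$ model is
accepted.

`fit_hx_rates()` estimates $(k_{op}, k_{cl})$ per residue by nonlinear
least squares on the *occupancies* (the measured quantity; fitting
log-rates would distort the error model), with both rates pH-independent
by assumption. Optimization runs on $\log_{10}$ parameters bounded to
$[10^{-6}, 10^{8}]\,\mathrm{s}^{-1}$ (a physically generous box), started
from the best point of a 13×13 log-spaced grid to avoid the flat
far-field. A single parameter pair is fit jointly across all pulse
durations by default (`share_pulses = TRUE`), reproducing the pooling used
when rates are assumed unchanged across labeling windows; per-pulse fits
are available.

Identifiability is probed at the optimum on the occupancy scale: if
shifting both rates one decade at fixed ratio changes no predicted
occupancy by more than 0.005 — half a percent, below any realistic
measurement precision — the data are EX2-limited and only
$K_{op} = k_{op}/k_{cl}$ is estimable (refit directly as the
one-parameter EX2 model); if shifting $k_{cl}$ alone is similarly
invisible, the data are EX1-limited and only $k_{op}$ is reported.
Residues whose occupancies never leave 1 (full protection) or 0 return an
explicit status instead of numbers. Standard errors come from the
Gauss–Newton Jacobian at the optimum; for `ex2_limited`/`ex1_limited`
fits only the estimable quantity carries an error.

## The synthetic-data generators

Three generators produce every input the pipeline consumes, each
deterministic for a given seed (Mersenne-Twister, seeded locally; the
caller's RNG stream is never touched).

**LFER ensembles** (`generate_lfer_ensemble()`): $\log K$ uniform over
`logK_center ± logK_spread` (default spread 1 decade, the dispersion
typical of residue-resolved datasets; a normal option exists), then
$\log k = \rho\,\log K + c + \varepsilon$ with
$\varepsilon \sim N(0, \sigma)$, default $\sigma = 0.05$ decades — a
realistic per-residue uncertainty for well-measured NMR rate constants —
and $\log k' = \log k - \log K$, so the triad holds exactly by
construction. Noise enters $\log k$ only, mirroring how the three measured
quantities are mutually constrained. An optional contiguous residue block
receives a collective offset $\Delta$ on $\log k$, emulating a
collectively moving structural element.

**Fake linearity** (`simulate_fake_linearity()`): all residues share
single true $k$ and $k'$ values; per-residue scatter is pure measurement
error, drawn uniformly on the *rates themselves* over 3–7 and 8–12 (the
ranges are arbitrary by construction; a log-uniform option exists for
sensitivity checks). Each of `n_reps = 30` replicates per residue is kept,
and the aggregate reports per-residue mean, SD and standard error of the
mean — both SD and SE, since published error bars mix the two
conventions; at 30 repeats their ratio is exactly
$\sqrt{30} \approx 5.5$. The expected diagnosis is an nr scatter with a
deceptively linear REFER plot whose forward slope concentrates near
$\mathrm{Var}(\log k)/(\mathrm{Var}(\log k)+\mathrm{Var}(\log k'))$.

**HX occupancies** (`generate_hx_dataset()`): the forward model above on
a pH ladder (default 6–11 in unit steps) and pulse schedule (default 0.05
and 0.2 s, chosen so that rates of order $1$–$10^3\,\mathrm{s}^{-1}$
traverse the informative occupancy range), plus Gaussian noise clipped to
$[0, 1]$.

What the generators do *not* emulate: NMR observables themselves (peak
intensities, relaxation rates) and their state-specific biases,
heteroscedastic or correlated per-residue errors, proline/exchange-
incompetent residues, and back-exchange. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
error model, not robustness to every bias a real measurement can carry.

## Problem sizes and numerical checks

The shipped checks use sizes chosen to make Monte-Carlo error negligible
relative to the tolerances tested: 1000 random ensembles for the
slope-difference identity ($\le 10^{-10}$) and the type-N slope-band
property; 2000 replicates of the fake-linearity construction against a
$10^5$-draw brute-force oracle of the same construction; $10^5$
bivariate-normal draws for ellipse coverage (94.5–95.5%) and flatness
against the closed form $1 - \sqrt{\lambda_2/\lambda_1}$; 50 replicate HX
fits at 2% occupancy noise (median relative error under 15%, with exact
recovery to 1% in the noiseless case). The collective-offset recovery
check uses 7 of 40 residues shifted by one decade, roughly 20 robust
scales at the default noise, where exact set recovery is expected.

## Known limitations

* The significance gate, flatness threshold and angle tolerance are
  operationalizations of visual judgments; datasets near a boundary can
  change label under small threshold changes, and the classification
  should be read together with the printed $r$, $f$ and angle.
* The EX2-limited detector keys on a 0.005 occupancy effect; data with
  noise far above that can be flagged identifiable while being, in
  practice, poorly constrained — the reported standard errors carry that
  information.
* Source-table uncertainties are stored verbatim; whether they are
  standard errors or standard deviations is left to the caller.
* Three-state exchange is out of scope: P/P′ scatters are reported as
  such, not refit with richer models.
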