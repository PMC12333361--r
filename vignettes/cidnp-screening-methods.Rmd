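---
title: "Methods: feature-based screening of steady-state photo-CIDNP enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based screening of steady-state photo-CIDNP enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidnpscreen)
```

## The problem

Steady-state photo-CIDNP enhancement of a proton site arises from several
entangled pathways — geminate radical-pair recombination, F-pair
re-encounters, polarization transfer, relaxation during irradiation — and no
closed-form expression predicts it. What *is* cheap to compute is a set of
molecular features that govern the individual steps: the electron-donating
ability of the target (ionization potential, nucleophilicity index, the
frontier-orbital gap against the dye), the triplet–singlet mixing terms of
the spin-correlated radical pair (hyperfine coupling `a_iso`, g-factor
difference `delta_g`, and their combination `q_value`), the radical
localization (`fukui`), and the dye–target stacking propensity (`log_p`).
This package provides the machinery to relate those eight features to
measured site-specific signal-to-noise enhancements (SNE): site ranking,
mechanism assignment, hierarchical statistics, and repeated-random-split
machine learning, plus a synthetic library generator so the whole chain is
testable without measurements.

## Core quantities

**Condensed nucleophilic Fukui index.** For atomic partial charges
$q_k(N)$ and $q_k(N-1)$ of the neutral and one-electron-oxidized molecule,
$f^-_k = q_k(N-1) - q_k(N)$. Summed over atoms this is exactly the one
removed electron, which `charge_table()` enforces to $10^{-6}$ e. Two
conventions were open:

* *Condensation onto heavy atoms.* Hydrogen charges are folded into their
  bonded heavy atom before differencing, and a proton site inherits the value
  of its bearing heavy atom. This is the standard condensed-Fukui practice;
  the alternative (per-hydrogen values) is recoverable by passing no
  hydrogen map.
* *Charge scheme.* The arithmetic is population-scheme-agnostic; Hirshfeld
  charges are the expected input but nothing checks or requires that.

**Geminate polarization probability.**
$Q = \tfrac{1}{12}\,|a_{iso}|^2\,|g_D - g_M|\,\frac{\mu_B}{\hbar}B_0$, with
$a_{iso}$ supplied in MHz and converted to angular frequency internally, and
CODATA constants fixed in `physical_constants()`. $Q$ is exactly quadratic
in $a_{iso}$ and linear in $|\Delta g|$ and $B_0$; the tests assert these
scaling laws exactly. Radical-pair lifetime terms (contact distance,
diffusion) are deliberately omitted — the rapid-diffusion limit. Raw values
at 14.1 T are of order $10^{21}$ rad$^3$s$^{-3}$, so tables store
$Q/10^{21}$ by default (`q_scale` in the config); this pure rescaling is
metadata and affects no standardized analysis.

**Kaptein net-effect rule.** $\Gamma_{net} = \mu\,\varepsilon\,
\mathrm{sign}(\Delta g)\,\mathrm{sign}(a_{iso})$ predicts absorptive (+1) or
emissive (−1) polarization. Defaults $\mu = +1$ (triplet precursor, the
standard for xanthene dyes) and $\varepsilon = +1$ (polarization observed on
the regenerated diamagnetic target, a recombination product) are
config-overridable, as is the $\Delta g$ sign convention
($g_{dye} - g_{radical}$), because published bookkeeping varies. For
molecules that can form their radical by either electron transfer (ET) or
proton-coupled electron transfer (PCET) — hydroxyl-substituted aromatics —
both candidate radicals are scored by per-site sign agreement with
observation; the winner's $g$ and $a_{iso}$ are installed before feature
assembly. Exact agreement ties are reported as `ambiguous`, never broken
silently: a tie means the data cannot discriminate the mechanisms.

## Statistics layer

Features live at three natural levels (series, molecule, site), so trends
against SNE are fitted at three coarse-grainings: all sites, the maximal-SNE
site per molecule, and the maximal-SNE site per (family, series) group.
Electron-transfer-related features (IP, N, LUMO–HOMO) get a quadratic form —
the Marcus picture of electron-transfer rates is parabolic in the driving
force — the others a linear one. P-values are the overall F-test, reported
raw; only the Tukey HSD post-hoc comparisons carry a multiplicity
adjustment.

PCA is computed on z-scored features (correlation-matrix PCA). This was an
open choice, but with features spanning eV, MHz and dimensionless indices a
covariance-matrix PCA would be dominated by whichever unit happens to be
numerically largest, so standardization is the only defensible default; it
is switchable (`standardize = FALSE`). Constant columns cannot be z-scored
and are dropped with a warning rather than erroring, since degenerate
synthetic tables are legitimate test inputs. By default PCA uses all sites;
a `level` argument switches to the coarse-grained views.

## Machine-learning layer

**Classification.** SNE classes are low (< 40), medium, and high (> 90);
boundary values fall in the medium class (the strict inequalities on either
side leave boundaries unassigned; closed-medium is the symmetric choice).
Because small-data splits dominate variance, a multinomial logistic model is
refit over many independent stratified random splits (70/30 by default) and
test predictions accumulate into a cumulative confusion matrix,
row-normalized by true class. A small weight decay ($10^{-4}$) keeps the fit
finite under complete class separation. Importances are mean absolute
standardized coefficients, normalized to sum 1. The default of $10^4$ runs
makes the Monte-Carlo standard error of each matrix entry a fraction of a
percentage point at this data size; more runs are config-reachable but only
shrink an already negligible error.

**Regression.** Five model families — k-NN, gradient-boosted trees
(xgboost), random forest (ranger), ridge (glmnet), RBF support-vector
regression (e1071) — are evaluated over repeated 60/20/20
train/validation/test splits: standardization fitted on train, a small fixed
hyperparameter grid tuned on validation (k ∈ {3,5,7}; depth ∈ {2,3} ×
rounds ∈ {50,100}; mtry ∈ {2,4}; λ ∈ {10⁻³…1}; cost ∈ {1,10}), scoring on
test only. The composite score is mean test R² (coefficient of
determination), with RMSE and MAE alongside — the score definition is this
package's own documented choice and is flagged as such in reports. Note that
for *independent* prediction/observation pairs the coefficient of
determination converges to −1, not 0; the squared Pearson correlation
(also reported) is the quantity that vanishes under independence.
Importances are native gain (xgboost) or impurity (ranger) for tree models
and test-fold permutation importance otherwise; both are normalized so runs
and models are comparable. The gradient-boosted tree family here is
xgboost's; reports name the implementation used.

## Synthetic library generator

`generate_library()` emulates the hierarchical structure the analysis
assumes, with 27 indole, 5 amino-acid and 8 phenol derivatives by default:

| parameter | default | what it encodes |
|---|---|---|
| `sites_range` | 3–7 | observable protons per molecule |
| `fukui_dirichlet_alpha` | 1.2 | site Fukui indices on the simplex, mildly concentrated |
| `kappa`, `sigma_a` | 90 MHz, 8 MHz | a_iso = κ·f⁻ + noise: strong but imperfect hyperfine–Fukui coupling |
| `ip_optimum`, `marcus_lambda` | 7.5 eV, 0.6 eV⁻² | quadratic (Marcus-like) enhancement dependence on IP |
| `mol_scale_meanlog/sdlog` | log 150, 0.8 | lognormal molecule-level enhancement scale |
| `sne_noise_sdlog` | 0.25 | multiplicative site-level noise (SNE is a positive ratio quantity) |
| `detection_floor` | 0.5 | sub-threshold sites clip to a small positive SNE |
| `concordance` | 0.925 | probability the max-SNE site is the max-Fukui site |
| `series_attenuation` | N → 0.2 | suppressed amino-indole series (positive charge hinders electron transfer) |

The molecule scale was fixed at log 150 so that the default library's SNE
marginal reproduces a realistic low-dominated class structure (roughly
77/15/8% low/medium/high across seeds) while keeping every class populated;
nucleophilicity is drawn anticorrelated with IP and the orbital gap
positively correlated with it, as frontier-orbital theory implies.

Concordance is planted *structurally*: each molecule draws
Bernoulli(`concordance`), and SNE values are swapped between two sites to
make or break the argmax agreement. The parameter is therefore an exact
per-molecule hit probability, giving the binomial oracle the recovery tests
need. Two caveats follow. First, with the default 0.925 a 40-molecule
library has mean hit count 37.0 with SD ≈ 1.7. Second, the detection floor
can tie several sites at the floor value; argmax ties are conservatively
counted as misses, so observed hit rates sit a few tenths of a percent below
the planted concordance.

`generate_class_structured()` instead fixes the SNE class counts exactly
(default 143/40/7 over 190 sites — the strongly imbalanced situation the
classifier must cope with) and shifts every feature's class mean by
`separation` SDs between adjacent classes: 0 gives chance-level features,
10 gives effectively perfect separability. The mechanism benchmark gives
each molecule ET and PCET candidates sharing the hyperfine sign pattern but
with g-factors on opposite sides of the dye's; their Kaptein predictions are
then exactly opposite, which is the regime in which the net-effect rule can
discriminate mechanisms at all. With 5 sites and a 10% sign-flip rate,
recovery is the probability that a Binomial(5, 0.9) exceeds half its sites,
≈ 0.99. If instead the candidates' hyperfine patterns were independent, the
wrong candidate would agree with the observations at rate ½ and no decision
rule could exceed ≈ 88% recovery at this size — an upper bound worth
remembering when interpreting real assignments from few sites.

What the generator does *not* emulate: real quantum-chemical feature values
(only plausible magnitudes and correlations), spectral artifacts,
emissive/absorptive phases (all SNE are absolute values), inter-feature
structure beyond the planted correlations, and any dependence between sites
beyond the Fukui simplex constraint. Green tests on synthetic data therefore
validate the *machinery* — estimators, invariants, planted-truth recovery —
not the chemistry of any particular compound library.

## Numerical and edge-case choices

* Units fix at the I/O boundary: eV, MHz, Tesla; conversion happens once,
  inside `geminate_polarization_q()`.
* Negative `a_iso` is preserved (Kaptein rules need the sign); only its
  magnitude enters Q.
* Argmax ties in site ranking count as misses and are flagged — conservative,
  and a tie in measured SNE usually signals a detection-floor artifact.
* Validation is report-only and idempotent; loading rejects rows with
  missing required fields and lists them rather than failing wholesale.
* CSV output formats doubles with 17 significant digits so a write → read
  round trip is exact.
* All stochastic stages derive child seeds from the single config seed via
  a deterministic hash, so any run is reproducible from its config alone.

## Problem sizes in the test suite

The suite exercises: 1000 random charge tables for the Fukui oracle; a
6 × 4 × 6 grid for the Q oracle; all 16 Kaptein sign combinations plus 500
benchmark molecules; 2000 replicate 40-molecule libraries for argmax
recovery; 10³–10⁴ split repetitions for the classifier (10⁴ matches the
point where Monte-Carlo error is far below a percentage point); 20
repetitions of a 10-run gradient-boosted regression for importance
recovery; and 500/1000 replicates for p-value uniformity and ANOVA type-I
calibration. These sizes put every Monte-Carlo standard error well inside
the asserted tolerances while keeping the suite fast.

## Known limitations

* The feature set is ingested, not computed: no quantum chemistry is run,
  so garbage features give garbage predictions with no warning beyond
  schema validation.
* The mechanism assignment uses only net-effect signs; multiplet effects
  and kinetic modeling of proton transfer are out of scope.
* Regression scores on realistic synthetic libraries are modest (R² ≈ 0.2–0.4)
  because molecule-level lognormal variance is irreducible from site
  features alone — a faithful property of the screening problem, not a bug.
* With seven members in the high-SNE class, per-class confusion entries for
  that class carry the largest Monte-Carlo and split-protocol uncertainty;
  interpret them with the reported supports in hand.
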