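# cidnpscreen

Feature-based screening of steady-state photo-CIDNP enhancement.

Photochemically induced dynamic nuclear polarization (photo-CIDNP) boosts NMR
sensitivity through light-driven radical-pair chemistry between a photoactive
dye (e.g. fluorescein) and a target molecule. There is no closed-form theory
for the *steady-state* signal-to-noise enhancement (SNE), so promising targets
are normally found by experimental screening. `cidnpscreen` implements an
*in silico* alternative for libraries of indole, amino-acid and phenol
derivatives: it connects eight readily computable molecular features to
site-specific SNE through site ranking, hierarchical statistics, and repeated
random-split machine learning.

The eight features, one row per proton site:

| feature | level | meaning |
|---|---|---|
| `ip` | molecule | ionization potential (eV) |
| `nucleophilicity` | molecule | nucleophilicity index *N* (eV) |
| `lumo_homo` | molecule | E_LUMO(dye) − E_HOMO(target) (eV) |
| `delta_g` | molecule | \|g_D − g_M\| of the radical pair |
| `a_iso` | site | isotropic hyperfine coupling (MHz) |
| `fukui` | site | condensed nucleophilic Fukui index f⁻ |
| `q_value` | site | geminate polarization probability *Q* |
| `log_p` | series | octanol–water partition coefficient |

Core quantities authored here:

- **Condensed Fukui index** f⁻_k = q_k(N−1) − q_k(N) from atomic charge
  tables of the neutral and one-electron-oxidized states, with hydrogen
  charges folded into their bonded heavy atoms. Over all atoms Σ f⁻ = 1.
- **Geminate polarization probability**
  Q = (1/12) |a_iso|² |g_D − g_M| (μ_B/ħ) B₀, the field- and
  coupling-dependent part of the geminate polarization of a
  spin-correlated radical pair.
- **Kaptein net-effect rule** Γ_net = μ · ε · sign(Δg) · sign(a_iso), used to
  decide per molecule whether the radical forms by electron transfer (ET) or
  proton-coupled electron transfer (PCET): the candidate radical whose
  predicted polarization phases match the observed ones is installed before
  feature assembly.
- **Repeated random-split evaluation**: a multinomial logistic classifier of
  low/medium/high SNE classes accumulated into a cumulative confusion matrix
  over many stratified splits, and a regression suite (k-NN, gradient-boosted
  trees, random forest, ridge, SVR) with per-model feature importances.

A synthetic compound-library generator with planted ground truth (Fukui-led
site effect, Marcus-like quadratic IP dependence, multiplicative lognormal
noise, planted argmax concordance) makes every stage testable end to end
without measured data.

## Worked example

```r
library(cidnpscreen)

cfg <- pipeline_config(random_seed = 1)
lib <- generate_library(generator_params(seed = 1), cfg)
lib$table
#> <feature_table> 203 sites, 40 molecules, 3 families

argmax_hit_rate(lib$table, "fukui")
#> <hit_rate_result> fukui: 36/40 molecules (90.0%), 95% CI [0.763, 0.972]

run_pca(lib$table, n_components = 3)
#> <pca_result>
#>   cumulative variance: PC1-1: 0.401, PC1-2: 0.705, PC1-3: 0.859
```

The hit rate says that in 36 of the 40 molecules the site with the largest
nucleophilic Fukui index is also the site with the largest SNE — the
generator plants this concordance with probability 0.925 per molecule, so a
40-molecule draw typically yields 36–38 hits. The PCA line says two principal
components of the z-scored 8-feature space carry ~70% of its variance, three
~86%.

Classification on a 190-site table with a 143/40/7 low/medium/high class
imbalance, and regression on the library above:

```r
cs <- generate_class_structured(generator_params(seed = 1))
cc <- repeated_split_classification(cs, n_runs = 1000, seed = 1)
round(diag(cc$matrix), 2)     # per-class fraction of correct predictions
#>    low medium   high
#>   0.99   0.94   0.69

reports <- repeated_split_regression(lib$table, n_runs = 20, seed = 1)
reports[[1]]
#> <evaluation_report> random forest (ranger): composite R2 = 0.235 (RMSE 31.26, MAE 19.63) over 20 runs
#>   top importances: fukui=0.21, a_iso=0.17, q_value=0.17
```

The rare high class is hardest (7 protons, so a test fold holds only one or
two of them), and the regression R² is bounded by the molecule-level
lognormal noise the generator plants on top of the Fukui-led site effect.

The whole chain, with CSV outputs and a run manifest:

```r
run_pipeline(cfg, stages = c("simulate", "validate", "rank", "stats",
                             "classify", "regress"),
             out_dir = "cidnp_out")
```

or from a shell via the thin wrapper
`Rscript inst/scripts/cidnp-screen.R all --seed 1 --out cidnp_out`.

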