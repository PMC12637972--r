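# cellcompete

Stochastic models of stem-cell competition under chronic low-dose-rate
irradiation.

Whether very low dose rates of ionizing radiation pose a cancer risk is
contested, and one proposed protective mechanism is *stem-cell
competition*: damaged stem cells with lower fitness are eliminated from the
stem-cell pool by their intact neighbors before their lineage can expand.
`cellcompete` is for modellers and radiation biologists who want to ask,
quantitatively: given a set of cell-cell interaction costs, a pool size and
a dose rate, does competition suppress or promote the accumulation of
damaged cells - and does spatial structure change the answer?

## The model

A pool of `N` stem cells holds two types, intact (`I`) and damaged (`D`).
Radiation converts intact cells irreversibly at rate `λ` (expected
successful track hits per cell per cell cycle). Turnover is a Moran
process: each elementary step one cell divides (uniformly at random) and
one is eliminated with probability proportional to its *cost* - inverse
fitness - given by a 2×2 matrix `(C_I←I, C_I←D, C_D←I, C_D←D)` of pairwise
interaction costs. With `k` damaged cells, expected costs are the
partner-frequency averages

    F_k = [C_I←I (N−k−1) + C_I←D k] / (N−1)
    G_k = [C_D←I (N−k)   + C_D←D (k−1)] / (N−1)

and the damaged count rises or falls by one with probabilities

    P(k→k+1) = (k/N) · (N−k) F_k / [(N−k) F_k + k G_k]
    P(k→k−1) = ((N−k)/N) · k G_k / [(N−k) F_k + k G_k]

The observable is `T_abs`, the mean number of cell cycles until damaged
cells occupy the whole pool. At very low dose rates

    T_abs ≈ 1 / (N λ π1),   π1 = 1 / (1 + Σ_j Π_{k≤j} G_k/F_k)

where `π1` is the fixation probability of a single damaged cell. A lattice
variant puts the cells on a periodic `L × L` torus with Moore (8-site)
neighborhoods, local cost evaluation, and local replacement. See the
methods vignette (`vignettes/competition-model.Rmd`) for the full account.

## Worked example

```r
library(cellcompete)

cm <- cost_matrix(1, 1.5, 1.16, 0.8)  # C_I←I, C_I←D, C_D←I, C_D←D
regime(cm)
#> [1] "positive_frequency_dependent"

sweep <- run_dose_rate_sweep(
  cost_matrices = list(neutral = cost_matrix(), mixed = cm),
  lam_grid = c(0.001, 0.1), n = 20, reps = 1000, seed = 42)
sweep[, c("scenario", "lam", "mean_t_abs", "se_t_abs",
          "t_abs_exact", "t_abs_approx", "ratio_sim_approx")]
#>  scenario   lam mean_t_abs se_t_abs t_abs_exact t_abs_approx ratio_sim_approx
#>   neutral 0.001     994.32  30.7837     1018.72     1000.000           0.9943
#>   neutral 0.100      19.08   0.3443       19.04       10.000           1.9084
#>     mixed 0.001     665.36  21.0619      631.13      626.486           1.0621
#>     mixed 0.100      10.59   0.1512       10.74        6.265           1.6904
```

Each row pairs the simulated mean occupation time (with its standard error
over 1000 replicates) with the exact Markov-chain value and the low-dose
approximation. At `λ = 0.001` the simulation/approximation ratio is ~1, so
the closed form is trustworthy; at `λ = 0.1` it is not (ratio ~1.9). The
mixed matrix shortens `T_abs` relative to neutral at `N = 20`: here
competition *promotes* damage accumulation. Whether it does depends on pool
size:

```r
study <- run_pool_size_study(cost_matrix(1, 1.5, 1.2, 0.5),
                             n_grid = c(2, 4, 8, 16, 64, 1000, 1e5))
study
#> Pool-size study (positive_frequency_dependent cost matrix)
#> shape: convex_down | decreases from n=2 to 3: TRUE | increasing at n=1e5: TRUE
#>        n log_t_abs_norm   t_abs_norm
#> 1      2     -0.1053605 9.000000e-01
#> 2      4     -0.2424356 7.847143e-01
#> ...
#> 6   1000     12.6591120 3.146172e+05
#> 7 100000   1520.0826577          Inf
```

`t_abs_norm` is `T_abs` normalized to 1 for the neutral matrix: below 1,
accumulation is promoted; above 1, suppressed. For this matrix the profile
is convex down - small pools accumulate damage *faster* than neutral while
large pools are protected (by `N = 1000`, some 10^5-fold; the log column
stays finite where the ratio overflows). `run_shape_diagram()` maps these
labels over the cost plane, and `run_lattice_comparison()` contrasts the
well-mixed and lattice models at matched pool sizes.

A command-line front end covering the same runners ships in
`inst/scripts/cellcompete`:

```sh
Rscript inst/scripts/cellcompete dosimetry
Rscript inst/scripts/cellcompete dose-sweep --n 20 --reps 1000 --seed 1 --out sweep.csv
```

The `dosimetry` subcommand converts an occupational exposure (default: the
20 mGy/year worker limit over 250 8-hour days, 1 mGy elemental dose) into
the model's `λ`, printing `λ = 0.08` hits per cell per 24-h cell cycle.

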