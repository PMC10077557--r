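# uvabc

Classification of UV–Vis absorption spectra with an improved adaptive
artificial bee colony (IAABC) optimised neural network.

`uvabc` is aimed at chemometric classification of solutes whose UV
fingerprints overlap — here NaCl, NaOH, β-phenylethylamine (PEA) and
their seven mixtures (0–60 % m/m PEA). Spectra on the 190–400 nm grid
(1 nm steps) are compressed by PCA to a few score vectors, and a small
feed-forward network (tansig hidden layer, logsig outputs) assigns the
class. The network's weights and thresholds are trained either by
back-propagation with momentum (`traingdm`-style) or by the bee-colony
metaheuristic that is the package's core.

## The optimiser

The standard artificial bee colony keeps `N` honey sources
(candidate solutions) and cycles through employed, onlooker and scout
phases with greedy selection; the employed move is
`ν_ij = x_ij + r (x_ij − x_kj)` with `r ~ U(−1, 1)`. The improved
variant replaces the employed move by

    ν_ij = x_ij + ω(c) · r · (x_ij − x_kj) + s · (x_ij − x_kj) · L_j(t)

with a cycle-decaying inertia weight `ω(c)` (linear from 1.05 to 0.15)
and a heavy-tailed Levy mutation `L_j(t)` (Mantegna's algorithm,
β = 1.5) scaled by the colony's local spread. Fitness is
`fit = 1/(1+f)` for `f ≥ 0`, selection is roulette-wheel, stagnant
sources (more than `limit = 100` failed trials) are re-seeded
uniformly, and runs stop at the precision goal 1e-6 or `MaxCycle`.
Performance is compared on the Griewank benchmark
`f(x) = 1 + Σ x_i²/4000 − Π cos(x_i/√i)` (global minimum `f(0) = 0`).

The full evaluation suite — confusion matrix (rows = actual),
per-class Recall %, Precision %, F-Score (0–1), Accuracy %, and
RMSEP / REP % / R² on class codes — plus a synthetic Beer–Lambert
spectrum generator (Gaussian bands at 197, 202, 210/258 nm) make the
pipeline exercisable end to end without instrument data.

## Worked example

```r
library(uvabc)

data  <- generate_dataset(classes = "mixtures", n_per_class = 30, seed = 1)
model <- train_classifier(data$train, trainer = "iaabc", pca_k = 3, seed = 1,
                          colony = colony_config(max_cycles = 500))
evaluate_classifier(model, data$test)
```

which prints:

```
Confusion matrix (rows = actual, columns = predicted)
      predicted
actual 0 10 20 30 40 50 60
    0  5  5  0  0  0  0  0
    10 2  8  0  0  0  0  0
    20 0  0  9  1  0  0  0
    30 0  0  3  7  0  0  0
    40 0  0  0  0 10  0  0
    50 0  0  0  0  0 10  0
    60 0  0  0  0  0  0 10

Per-class metrics (Recall %, Precision %, F-Score, Accuracy %):
  class recall precision f_score accuracy
1     0     50     71.43  0.5882    84.29
2    10     80     61.54  0.6957    84.29
...
Regression metrics on class codes:
   rmsep rep_percent r_squared
1 0.3964        9.91    0.9607
```

Reading this: all misclassification sits in the adjacent low-PEA
classes (0 vs 10 % m/m, 20 vs 30 % m/m), whose 258 nm PEA shoulder is
weak or absent — the high-PEA classes are recognised perfectly.
Overall accuracy is 84.3 %, RMSEP on the class codes 1–7 is 0.40 and
REP is 9.9 % of the mean class code.

A benchmark comparison of the two optimiser variants:

```r
tr <- dplyr::bind_rows(
  run_benchmark("iaabc", runs = 30, seed = 1, config = colony_config(max_cycles = 300)),
  run_benchmark("abc",   runs = 30, seed = 1, config = colony_config(max_cycles = 300))
)
dplyr::summarise(dplyr::group_by(tr, variant),
  median_best = median(best_objective[cycle == max(cycle)]))
```

A command line front end with `simulate`, `train`, `classify`,
`evaluate` and `benchmark` subcommands is installed as
`exec/uvclassify.R`.

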