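# whalenet

Whale-optimization-tuned convolutional ensembles for three-class medical
image classification.

## The problem

Classifying gynecological MR images into Normal / Benign / Malignant with
small, patient-grouped datasets is dominated by hyperparameter choices:
learning rate, batch size, dropout, dense width, optimizer family,
activation, weight decay, and — for a from-scratch CNN — the per-block
filter counts. Grid search is unaffordable when every probe is a model
training, and manual tuning does not reproduce. `whalenet` is for
researchers who want that tuning automated, seeded, and auditable end to
end: it drives the search with the Whale Optimization Algorithm (WOA), a
population metaheuristic that needs no gradients of the tuning objective,
and combines the tuned classifiers with a soft-voting ensemble.

## The method

Candidate configurations live in the unit cube `[0,1]^d` (d = 8 for
transfer heads, 11 for the from-scratch "lightweight vision model") and
are decoded dimension-wise, e.g. learning rate `10^(-5+3x)`, batch size
`int(16 + 112x)`, optimizer `round(2x) -> {Adam, SGD, RMSprop}`. Each
WOA whale is one configuration; its fitness is the validation loss
`L_val(θ; X)` after short partial training (10 epochs by default). The
population updates per iteration by encircling the best position
`X(t+1) = X* − A·|C·X* − X|`, exploring toward a random whale when
`|A| ≥ 1`, or the logarithmic spiral `X(t+1) = |X* − X|·e^{bl}·cos(2πl) + X*`,
with the coefficient magnitude `a` decaying linearly from 2 to 0.

The best configuration per family is then trained fully; member
probabilities are averaged with equal weights, `p̄_k = (1/M) Σ_m p_k^(m)`,
and the label is `argmax_k p̄_k`. Evaluation is one-vs-rest per class
(precision, sensitivity, specificity, F1), an unweighted macro "Overall"
row, accuracy = trace/N, and Wald intervals
`100·(μ̂ ± 1.96·sqrt(μ̂(1−μ̂)/n))`.

Everything runs on a bundled synthetic three-class cohort generator
(patients, three imaging planes, a tunable class-separation dial, and a
`kauh_like` preset with per-class totals 497/699/618), so the whole
pipeline is testable on one CPU with no downloads. See
`vignettes/whalenet-methods.Rmd` for the full model description, the
design decisions, and what the synthetic conditions do and do not show.

## Worked example

```r
library(whalenet)

# decode a whale position into a training configuration
sp <- search_space("lvm")
decode_hyperparameters(rep(0.5, 11), sp)
#> <whale_hyperparameters> family: lvm
#>   learning_rate  0.000316228
#>   batch_size     72
#>   dropout_rate   0.3
#>   dense_units    288
#>   optimizer      SGD
#>   activation     LeakyReLU
#>   weight_decay   0.0000316228
#>   momentum       0.725
#>   conv1_filters  40
#>   conv2_filters  80
#>   conv3_filters  160

# minimize a test function with the optimizer
run <- woa_optimize(function(x) sum((x - 0.5)^2), d = 5,
                    woa_config(n_whales = 5, max_iterations = 10, seed = 7))
run
#> <woa_run> 5 whales, 10 iteration(s), 55 evaluations
#>   best fitness: 0.0469117

# per-class metrics of a 3x3 test confusion matrix (70 images per class)
counts <- read.csv(system.file("extdata",
                   "reference_confusion_ucm_synthetic.csv",
                   package = "whalenet"), check.names = FALSE)
per_class_metrics(as_confusion_matrix(counts[, -1], counts$true_class))
#> <metrics_table> n = 210, accuracy = 88.57%
#>      class precision sensitivity specificity    f1
#>     Benign     88.06       84.29       94.29 86.13
#>  Malignant     90.14       91.43       95.00 90.78
#>     Normal     87.50       90.00       93.57 88.73
#>    Overall     88.57       88.57       94.29 88.55

# Wald confidence interval for 166 correct out of 210
accuracy_ci(166, 210)
#> accuracy 79.05% (n = 210), 95%-CI (73.54, 84.55)
```

The accuracy is the trace of the matrix over 210; the Overall row is the
unweighted macro mean of the three class rows; the interval is the
normal approximation for a proportion at z = 1.96.

A full pipeline run (synthesize → split → WOA search per family → final
training → predict → soft-vote → report) is one call,

```r
cfg <- run_config(out_dir = "run1", seed = 42)
report <- run_all(cfg)
```

or, from a shell, the staged CLI:

```sh
Rscript inst/cli/whalenet.R run-all --seed 42 --out run1
Rscript inst/cli/whalenet.R report --seed 42 --out run1   # re-run one stage
```

Each stage writes plain CSV/YAML/PNG artifacts under the output
directory (`convergence_<model>.csv`, `fitness_ledger_<model>.csv`,
`best_config_<model>.yaml`, `proba_<model>_test.csv`,
`metrics_<model>_test.csv`, `ci_table_test.csv`, ...) and is
independently re-runnable; a missing upstream artifact aborts with the
name of the producing command.

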