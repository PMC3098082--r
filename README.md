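# gsbench

Automated model selection over gene-selection procedures for two-class
expression data.

## The problem

Selecting the genes that discriminate two sample classes (tumor vs.
normal, responder vs. non-responder) is a standard route to diagnostic
biomarker panels, but no single selection recipe wins on every dataset:
the best choice of ranking statistic, gene count, feature encoding and
classifier is an empirical property of each matrix. gsbench makes that
choice systematically. It enumerates a grid of up to 60 complete
*gene-selection procedures* per gene-count k — every combination of

| dimension | options |
|---|---|
| ranking statistic | Welch t-test, Wilcoxon rank-sum, information gain (MDL discretization) |
| expression pattern | all genes, up-regulated only, down-regulated only |
| feature encoding | raw values, MDL-discretized intervals |
| feature-vector addition | off, on (sum the k same-direction genes into one composite feature; up/down patterns only) |
| classifier | SVM (RBF), random forest |

— estimates every procedure's generalization error with the **.632+
bootstrap**, re-running the entire selection pipeline inside each
bootstrap replicate so the estimate is free of selection bias, and
reports the procedures with the smallest error at the smallest k,
together with the gene panels they select on the full data.

The estimator blends the resubstitution error err̄ and the leave-one-out
bootstrap error err⁽¹⁾ with a data-driven weight:

    err¹′ = min(err⁽¹⁾, γ)                        γ = Σ_c p_c (1 − q_c)
    R     = (err¹′ − err̄) / (γ − err̄)            clipped to [0, 1]
    ŵ     = 0.632 / (1 − 0.368 R)
    Err.632+ = (1 − ŵ) · err̄ + ŵ · err¹′

where γ is the no-information rate from the observed class proportions
p and the predicted-class proportions q. ŵ ranges from 0.632 (no
overfitting) to 1 (maximal overfitting), so the estimate always lies
between err̄ and err¹′.

## Worked example

```r
library(gsbench)

# a synthetic two-class study: 300 genes, 15 + 15 samples,
# 10 up- and 10 down-regulated informative genes at effect size 2
sim <- generate_dataset(simulation_config(n_genes = 300, n1 = 15, n2 = 15,
                                          n_up = 10, n_down = 10,
                                          effect_size = 2, seed = 42))

specs  <- enumerate_procedures(methods = c("wilcoxon", "infogain"),
                               k_grid = c(5, 10))   # 80 procedures
report <- run_grid(specs, sim$dataset, bootstrap_plan(B = 50, master_seed = 7))
print(report)
#> GridReport: 80 procedures on 300 genes x 30 samples
#> best (err632plus=0, k=10):
#>   wilcoxon/up/k=10/disc=on/fva=on/svm

print(rank_results(report)[[1]])
#> wilcoxon/up/k=10/disc=on/fva=on/svm
#>   err632plus=0.0000 (err_bar=0.0000, err1=0.0000, gamma=0.5000, w=0.632)
#>   genes: g0003, g0001, g0004, g0007, g0009, g0006, g0008, g0002, ...

head(grid_table(report)[, c("fs_method", "pattern", "k", "discretize",
                            "fva", "classifier", "err632plus")], 5)
#>   fs_method pattern  k discretize   fva classifier  err632plus
#> 1  wilcoxon      up 10       TRUE  TRUE        svm 0.000000000
#> 2  wilcoxon      up 10      FALSE  TRUE        svm 0.002641434
#> 3  wilcoxon   total 10      FALSE FALSE        svm 0.003564007
#> 4  wilcoxon    down  5      FALSE  TRUE        svm 0.003958519
#> 5  wilcoxon      up 10      FALSE FALSE        svm 0.004475897
```

Reading the output: the grid's best procedure ranks genes by the
Wilcoxon statistic among up-regulated genes, keeps the top 10, sums them
into one discretized composite feature and classifies with the SVM; its
.632+ bootstrap error is 0 (err̄ = err⁽¹⁾ = 0, so ŵ stays at 0.632),
against a no-information rate γ = 0.5 for these balanced classes. The
gene list is the panel that procedure selects on the full data — the
reportable biomarker candidate set. `write_report(report, "results/")`
writes the full grid as `grid.tsv`, the tied-best subset as `best.tsv`,
a machine-readable `report.json`, and a run log.

Real datasets enter through `read_dataset("matrix.tsv")` — tab-delimited
text, sample ids in row 1, a `class` label row, one gene per row (or a
separate two-column label file). A command-line front end wraps the same
functions:

```sh
Rscript inst/cli/gsbench.R simulate --genes 2000 --n1 30 --n2 30 --up 20 \
        --down 20 --effect 2 --seed 7 --out sim/
Rscript inst/cli/gsbench.R run --input sim/matrix.tsv --k 10,20,50 \
        --bootstrap 100 --seed 17 --workers 4 --out results/
Rscript inst/cli/gsbench.R report results/report.json --top 10
```

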