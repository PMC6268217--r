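# vsmvi

Best-subset descriptor selection for multiple-linear-regression QSAR
models, built around a pool-based **variable-interaction search (VSMVI)**
scored by leave-multiple-out Monte-Carlo cross-validation, together with
the model-quality apparatus a regulatory-grade QSAR workflow needs:
descriptor preselection, LOO/LMO cross-validation, y-randomization
chance-correlation testing, and a leverage-based applicability domain with
Williams-plot outlier classification.

## Who this is for

QSAR modellers who start from a large table of computed molecular
descriptors (e.g. an E-Dragon export: one row per compound, one numeric
column per descriptor) and a measured activity such as logRBA (log10
relative binding affinity to the estrogen receptor), and who want a small,
interpretable MLR model whose descriptors were chosen by an explicit,
reproducible search rather than a stochastic heuristic.

## The method

An exhaustive all-subsets scan over m descriptors at subset size k costs
C(m, k) model evaluations — C(53, 5) = 2,869,685 already for a modest
pool. VSMVI exploits variable interaction instead: a good k-descriptor
subset extends a good (k−1)-descriptor subset by one variable. The search

1. scans sizes 1..Na (default 3) **exhaustively**, keeping the best `Ns`
   (default 1000) subsets per size in a fixed-capacity pool ranked by a
   stop criterion SC — the mean LMOCV q²;
2. for each larger size, combines every pool subset with every absent
   descriptor (at most `Ns × m` candidates — 53,000 instead of millions),
   deduplicates, and refills the pool under the SC_min replacement rule.

Two gates avoid wasting cross-validation effort: a candidate is skipped if
any internal pairwise descriptor correlation reaches `r_int` (default
0.9), or if its training r² falls below a size-dependent floor `r_cri`
(0.1 for one descriptor, growing with size). Model size is then chosen
from the q̄² curve: the smallest size whose relative gain going one size up
drops below 5%.

Model quality uses the standard definitions: r² and RMSE (denominator n)
on the training set; per-split q² about the validation-set mean and RMSEV
for two-fold MCCV, with means and SDs over N splits; external q² about the
test-set mean; F = (r²/p)/((1−r²)/(n−p−1)); c r²p = r·sqrt(r² − r̄²ᵣ)
against the mean r̄²ᵣ of y-scrambled refits; leverage h = x(X'X)⁻¹x' with
control value h* = 3k/n and a 2.5-SD standardized-residual cut for the
Williams plot.

## Worked example

```r
library(vsmvi)

sim <- generate_qsar_dataset(n = 60, m = 40, seed = 7)   # 4 planted descriptors
res <- run_vsmvi(sim$train, vsmvi_config(vm = 4, seed = 42))
res
#> <vsmvi_result> sizes 1..4 over 40 descriptors
#>  size      stage generated scored pool_size   best_sc
#>     1 exhaustive        40      4         4 0.2571837
#>     2 exhaustive       780    102       102 0.6327150
#>     3 exhaustive      9880   1148      1000 0.7901998
#>     4  extension     37000   3540      1000 0.9746798

best_subset(res, 4)$names
#> [1] "D001" "D002" "D003" "D004"     # the planted subset
sim$truth$true_names
#> [1] "D001" "D002" "D003" "D004"
```

The trace reads as follows: at size 3 all C(40,3) = 9,880 triples were
generated but only 1,148 cleared the correlation and r² gates and were
cross-validated; at size 4 the extension stage generated 37,000 candidates
(the Ns × m bound less in-pool variables), and the best four-descriptor
subset reached a mean two-fold-MCCV q² of 0.975. A full analysis —
preselection, search, final model with LOOCV/MCCV, y-randomization and
the Williams-plot domain — is one call:

```r
report <- run_pipeline(run_config(
  simulate = list(n = 60, m = 20, true_indices = 1:3,
                  true_coefficients = c(1.2, -1.0, 0.8), n_test = 10),
  search = list(vm = 4), output = "report.json", seed = 5))
report$model$subset
#> [1] "D001" "D002" "D003"
```

A command-line wrapper with `simulate`, `preprocess`, `search`,
`validate`, `domain` and `run` subcommands is installed at
`inst/cli/vsmvi.R` (`Rscript $(Rscript -e 'cat(system.file("cli/vsmvi.R", package="vsmvi"))') run --config cfg.yaml`).

## Further reading

The methods vignette (`vignettes/vsmvi-methods.Rmd`) documents the model
assumptions, every tunable parameter with its default and rationale, the
numerical choices in the compiled search core, what the synthetic fixtures
do and do not emulate, and known limitations.
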