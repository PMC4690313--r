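# forestscreen

Feature screening for ultrahigh-dimensional continuous phenotypes —
the `n = 200`, `p = 100,000` regime of genome-wide association studies,
where per-feature ranking must replace full model fitting and where
causal variants with weak *marginal* but strong *interactive*
(epistasis-like) or nonlinear effects are exactly the ones a naive
marginal screen loses.

The package ranks every feature by one of six measures behind a single
fitting function:

| method  | measure |
|---------|---------|
| `sis`   | componentwise correlation learning, `w = |t(Xs) y|` on the standardized matrix (equivalently, absolute Pearson correlation) |
| `isis`  | iterated SIS: regress the response on the features selected so far, re-screen the rest against the residuals |
| `ccsis` | expected squared conditional correlation `E[rho^2(x_j, y | u)]` given a covariate `u`, via Gaussian-kernel local moment estimates |
| `iccsis`| the iterated variant of `ccsis` |
| `dcsis` | sample distance correlation (double-centered V-statistic), a model-free dependence measure |
| `rf`    | out-of-bag permutation variable importance (PVIM) from a regression random forest grown from scratch in compiled code |

For tree `t` with out-of-bag set `B_t`, the forest's per-tree
importance of feature `j` is

    PVIM_t(j) = [ sum_{i in B_t}(y_i - yhat*_ti)^2 - sum_{i in B_t}(y_i - yhat_ti)^2 ] / |B_t|

with `yhat*` the predictions after permuting `x_j` within `B_t`; the
screening score averages this over trees, so a feature the forest
relies on — marginally or through interactions — earns a positive
importance.  A non-negative node-impurity importance
(`impurity_importance()`) is exposed alongside for robustness
comparisons.

The package also ships the four-design simulation benchmark used to
compare the six screens (AR(1)-correlated Gaussian features, linear /
quadratic / product responses, optionally with functional coefficients
driven by a uniform covariate), the standard evaluation criteria
(average causal ranks `R_j`, minimum model size `M` and its quantiles,
selection powers `p_j` / `p_a` within candidate budgets `d`), and
delimited-text readers plus a Manhattan-style importance table for real
genotype/phenotype data.  A thin command-line front end
(`inst/cli/forestscreen.R`) wraps the same functions as
`simulate | screen | evaluate | benchmark | manhattan` subcommands.

## Worked example

One replicate of the benchmark's first design
(`y = 0.5 x1 + 0.8 x2 + x3 + 2 x4 x5 + e`, the first five of 1000
correlated features causal), screened by the forest:

```r
library(forestscreen)
design <- sim_design("sim1", n = 200, p = 1000, rho = 0.4)
rep1   <- generate_replicate(design, seed = 42)
scr    <- screen_features(rep1$X, rep1$y, method = "rf",
                          control = forest_control(seed = 7))
scr
#> Feature screening by RF (n = 200, p = 1000)
#>   candidate-set size d = 16
#> Feature ranking (rf), p = 1000
#>  rank feature      score
#>     1      x3 1.98209728
#>     2      x2 1.11985872
#>     3      x5 0.43780641
#>     4      x4 0.20992657
#>     5      x1 0.11353175
#>     6    x377 0.03669738
#> ... and 990 more features
summary(scr, causal = 1:5)
#> ranks of the causal features:
#> x1 x2 x3 x4 x5
#>  5  2  1  4  3
#> minimum model size M = 5
```

All five causal features — including the pure-interaction pair
`x4, x5`, which have *zero* marginal effect — land in the top five, so
the minimum model size `M` is 5: a screen keeping only 5 of 1000
candidates would retain every causal feature.  The candidate budget
rule `suggested_d(200)` gives the conventional sizes `16 32 48`.
Aggregating such rankings over replicates with
`screening_criteria()` / `run_benchmark()` reproduces the comparative
study; see the vignette in `vignettes/forest-screening.Rmd` for the
model details, parameter choices, and known limitations (in
particular, the heavy tail of *mean* causal ranks under signed-PVIM
ranking).

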