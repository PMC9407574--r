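# ctmi

Entropy-based discovery of **summary causal graphs** from multivariate time
series.

Given a panel of jointly observed series (gene-expression programs, brain
regions, monitoring metrics, ...), `ctmi` infers which series cause which,
collapsing all lagged effects between two series into a single directed
edge.  It is aimed at analysts who have regularly sampled multivariate
series — possibly at different sampling rates — and want a constraint-based
causal structure rather than pairwise association scores.

## The measure and the algorithms

The core quantity is the **causal temporal mutual information** between
series $X^p$ and $X^q$:

$$
\mathrm{CTMI}(X^p;X^q)=\max_{(\lambda_{pq},\lambda_{qp},\gamma)}
I\!\left(X^{(p;\lambda_{pq})}_{t};\,X^{(q;\lambda_{qp})}_{t+\gamma}\,\middle|\,
X^{(p;1)}_{t-1},\,X^{(q;1)}_{t+\gamma-1}\right)
$$

— the mutual information between *window embeddings* of the two series,
maximized over window sizes and lag, conditioned on the one-step past of
both series so that autocorrelation alone cannot create dependence.  A
conditional variant minimizes over the placement of conditioning windows of
other series.  Estimation is k-nearest-neighbour (digamma form, supremum
distance); independence decisions use a local permutation test whose null
re-maximizes each permuted replicate across candidate lags, matching the
maximization in the statistic.

Two learners build on the measure:

* `pctmi()` — assumes no hidden common causes; PC-stable-style skeleton with
  CTMI tests, then collider/propagation rules plus two entropy-reduction
  rules that orient edges from the optimal lag (or, at lag zero, from the
  asymmetry of the optimal windows).  All lagged relations come out
  oriented.
* `fcitmi()` — allows hidden common causes; adds Possible-Dsep removals and
  the FCI rule set, returning a partial ancestral graph where arrowheads at
  both edge ends flag a latent confounder.

A structural-equation benchmark generator (`generate_panel()`,
`builtin_structures()`), sampling-rate decimation (`decimate()`) and a
directed-edge F1 scorer (`f1_directed()`, `run_benchmark()`) close the loop
from simulation to evaluation.

## Worked example

```r
library(ctmi)

spec <- builtin_structures()$fork          # X1 -> X2, X1 -> X3, lag 1
sim  <- generate_panel(spec, n_time = 1000, seed = 42)

g <- pctmi(sim$panel,
           space = search_space(gamma_max = 5),
           cfg   = estimator_config(k = 10, B = 50, alpha = 0.05, seed = 42))
tidy(g)
#> # A tibble: 2 × 5
#>   from  to    mark_from mark_to type
#>   <chr> <chr> <chr>     <chr>   <chr>
#> 1 X1    X2    tail      arrow   directed
#> 2 X1    X3    tail      arrow   directed

attr(g, "stats")
#> # A tibble: 2 × 7
#>   p     q     value gamma_bar lambda_pq lambda_qp p_value
#>   <chr> <chr> <dbl>     <int>     <int>     <int>   <dbl>
#> 1 X1    X2    0.774         3         6         5       0
#> 2 X1    X3    0.141         1         1         1       0

f1_directed(g, sim$truth)
#> [1] 1
```

`tidy(g)` lists the inferred edges with their endpoint marks; the common
cause X1 is recovered and both edges are oriented out of it.  The `stats`
attribute carries, per surviving edge, the measure value in nats, the
optimal lag (`gamma_bar` > 0: X1 leads), the optimal window sizes, and the
permutation p-value (0 = the observed statistic exceeded all permutation
replicates).  `f1_directed()` scores directed edges against the
generating truth, ignoring self-loops; here recovery is perfect.

Single measures are available directly:

```r
r <- ctmi(sim$panel, "X1", "X2", search_space(5), estimator_config(seed = 1))
glance(r)   # value (nats), optimal lag and windows, sample size
```

A thin command-line front end ships in `inst/cli/ctmi`
(`ctmi discover --input panel.csv ...`, `ctmi benchmark --structure fork`).

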