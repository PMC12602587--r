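# isingselect

Ising model estimation for binary data that were **selected on a minimum
sum score of the modelled variables** — the standard situation in
psychological network studies that recruit on symptom severity and then
model the associations between those same symptoms.

Selecting cases with sum score $s = \sum_i y_i \ge k$ conditions on a
common effect (collider) of all modelled variables. In the Ising model

$$\Pr(Y = y) = \frac{1}{Z}\exp\Big(\sum_i \tau_i y_i
  + \sum_{i<j} \omega_{ij}\, y_i y_j\Big), \qquad y \in \{0,1\}^m,$$

this Berkson-type selection attenuates positive edges and can turn
absent or weak edges negative, and the distortion does not shrink with
sample size. `isingselect` estimates the *unselected* population model
from the selected data by two corrections:

* **Multivariate maximum likelihood** with the truncated partition
  function $Z^{(k)} = \sum_{y:\,s \ge k} \exp(\cdot)$ in place of $Z$:
  the likelihood of the sum-score-conditioned distribution, maximised
  exactly (Newton with enumerated moments), with information-matrix
  standard errors and one-pass Wald pruning.
* **Nodewise pseudo-likelihood** (plain logistic with AND-rule
  significance thresholding, or lasso with EBIC model selection): under
  selection at $s \ge k$, a case whose *other* variables sum to $k-1$
  logically forces the predicted variable to 1 and carries likelihood 1,
  so those cases are removed from each regression.

The package also ships exact seeded samplers from the full and the
conditioned distribution, the four network-recovery metrics (total edge
weight error, sensitivity, specificity, proportion of spurious negative
edges), a deterministic 9-node data-generating network, a factorial
simulation harness, JSON/CSV serialization, and a command-line interface
(`inst/cli/isingselect.R`).

## Worked example

Generate the 9-node symptom-network fixture, draw 5,000 cases that pass
a cutoff of 5 symptoms, and compare corrected with uncorrected
estimation:

```r
library(isingselect)

net <- make_true_network(seed = 1)
summary(net)
#> Ising model with 9 nodes
#>   edges present: 29 / 36 (density 0.81)
#>   mean present-edge weight: 0.610
#>   threshold range: [-2.974, -1.048]

y <- ising_sample(net, n = 5000, k = 5, seed = 42)   # post-selection n
corrected <- ising_fit(y, k = 5, method = "multivariate")
usual     <- ising_fit(y, k = 5, method = "multivariate", corrected = FALSE)
corrected
#> Ising fit (multivariate, selection-corrected), n = 5000, m = 9, cutoff k = 5
#>   edges included: 26 / 36
#>   log-likelihood: -20969.37

str(recovery_metrics(net, corrected))
#> List of 4
#>  $ total_edge_weight_error: num 2.95
#>  $ sensitivity            : num 0.897
#>  $ specificity            : num 1
#>  $ prop_spurious_negative : num 0

str(recovery_metrics(net, usual))
#> List of 4
#>  $ total_edge_weight_error: num 20.3
#>  $ sensitivity            : num 0.31
#>  $ specificity            : num 0
#>  $ prop_spurious_negative : num 0.306
```

On the same selected sample, the corrected fit recovers the network
almost perfectly (90% of true edges found, no false or negative edges,
small total weight error), while estimation as usual misses two thirds
of the edges, estimates a negative edge in almost a third of all pairs,
and carries a large weight error that reflects bias, not noise —
collecting more cases would not repair it.

The full corrected-vs-uncorrected comparison across sample sizes,
cutoffs and all three estimators is available as
`run_study(make_true_network(seed = 1), ...)`; see the vignette in
`vignettes/selection-bias-correction.Rmd` for the model, the estimators'
tuning parameters, and the design of the simulation study.

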