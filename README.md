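# grapherr — graphical multiple testing with generalized error rates

Clinical trials increasingly test many structured hypotheses at once —
multiple doses, endpoints, time points, subgroups — and encode the testing
strategy as a weighted directed graph: node weights are fractions of the
overall significance level, and edges propagate a rejected hypothesis'
level onward.  The classical graphical approach controls the familywise
error rate (FWER), which becomes punishingly strict as the family grows.
`grapherr` extends the graphical machinery to *generalized* error rates
for exploratory settings:

* **k-FWER** — the probability of `k` or more false rejections,
  `P(V ≥ k) ≤ α`;
* **FDP tail** — the probability that the false discovery proportion
  exceeds a bound, `P(V / max(R, 1) > γ) ≤ α`;
* **FDR bounds** implied by FDP control (`2α` asymptotically,
  `α(1 − γ) + γ` in finite samples).

For each rate there are two routes.  *Augmented* procedures run the
Bonferroni-based graphical FWER shortcut at level `α` and then continue it
on the updated graph at a relaxed level `δ`, taking up to `k − 1` (or `D`,
the largest integer with `D/(D + |R|) ≤ γ`) extra rejections in the order
`argmin p_i / w_i(I)`.  *Generalized* stepdown procedures instead account
for up to `k − 1` possibly-false earlier rejections by minimising the
intersection weights `w_i(I ∪ J)` over all subsets `J` of the rejected set
of size `k − 1`.  Both come with adjusted-p-value formulations where they
exist, entangled (multi-graph) versions with an r-of-n gatekeeper builder,
weighted parametric (min-p) thresholds `c_J w_j(J) α` under a known
multivariate normal dependence, and a trial simulator for operating
characteristics.

## A worked example

Four hypotheses: two dose-versus-placebo comparisons on a primary endpoint
(`H1`, `H2`, half the level each) gatekeeping the matching secondary
comparisons (`H3`, `H4`).  Control the FDP at `γ = 0.5` with `α = .05`,
continuing augmentation at `δ = 0.5`:

```r
library(grapherr)
g <- example_graph("diabetes")
p <- example_pvalues("diabetes-b")   # (.01, .015, .02, .024)
res <- graph_test(g, p, "aug-fdp", alpha = 0.05, gamma = 0.5, delta = 0.5)
summary(res)
#> Graphical multiple testing procedure: aug-fdp
#> alpha = 0.05, gamma = 0.5, delta = 0.5
#> Rejected (4): H1, H2, H3, H4
#>
#> Rejection trace:
#>  hypothesis     p threshold     stage
#>          H1 0.010     0.025      base
#>          H2 0.015     0.025      base
#>          H3 0.020     0.125 augmented
#>          H4 0.024     0.125 augmented
```

The base stage is the FWER shortcut: `H1` and `H2` fall at their local
thresholds `w_i · α = 0.025`.  With two base rejections and `γ = 0.5`, the
augmentation budget is `D = 2`, and the continuation at `δ = 0.5` rejects
the two secondaries at thresholds `w_i(I) · δ = 0.125` — rejections a
plain FWER analysis would not make.  The price is stated by the FDR
bounds:

```r
fdr_bounds(0.05, 0.3)
#> $asymptotic        0.1
#> $lehmann_romano    0.335
#> $smaller           "asymptotic"
#> $lr_beats_asymptotic FALSE
```

Entangled gatekeeping, e.g. "test the secondary once 6 of 9 primaries are
rejected":

```r
eg <- build_r_of_n_gatekeeper(9, 6, "H10")   # 84 Holm components, c = 1/84
entangled_weights(eg, paste0("H", 1:6))      # gate just opened
#>        H7        H8        H9       H10
#> 0.3293651 0.3293651 0.3293651 0.0119048   # = 83/252 and 1/84
```

A thin command-line wrapper over the same functions lives at
`inst/cli/grapherr.R` (subcommands `test`, `adjust`, `weights`,
`fdr-bound`, `build-gatekeeper`, `fixtures`); see `?run_cli`.

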