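---
title: "Graphical testing with generalized error rates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphical testing with generalized error rates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapherr)
```

## The testing model

A family of null hypotheses $H_1,\dots,H_m$ is tested with p-values
$p_1,\dots,p_m$, assumed valid for the true nulls ($P(p_i \le u) \le u$).
The testing strategy is encoded as a weighted directed graph: node weights
$w_i(M)$ are fractions of the overall level $\alpha$ initially allocated to
each hypothesis, and an edge weight $g_{ij}$ is the fraction of $H_i$'s
level handed to $H_j$ when $H_i$ is rejected.  The graph must satisfy
$0 \le g_{ij} \le 1$, $g_{ii}=0$, $\sum_j g_{ij} \le 1$, $w_i \ge 0$ and
$\sum_i w_i \le 1$.  Removing a rejected node $j$ updates

$$w_l \leftarrow w_l + w_j g_{jl}, \qquad
  g_{lk} \leftarrow \frac{g_{lk} + g_{lj}g_{jk}}{1 - g_{lj}g_{jl}},$$

with the convention that the updated edge is 0 when $g_{lj}g_{jl}=1$.
Iterating removals yields the intersection-hypothesis weights $w_j(J)$ for
any subset $J$; they do not depend on the removal order and satisfy the
monotonicity property $w_j(J) \le w_j(J')$ for $J' \subseteq J$.  The
familywise error rate (FWER) shortcut rejects any active $H_j$ with
$p_j \le w_j(I)\,\alpha$ and repeats; its adjusted p-values are running
maxima of the ratios $p_j/w_j(I)$ along the removal sequence.

## Generalized error rates

Beyond the FWER, the package controls

* the **k-FWER**, $P(V \ge k) \le \alpha$ with $V$ the number of false
  rejections;
* the **FDP tail**, $P\bigl(V/\max(R,1) > \gamma\bigr) \le \alpha$; and
* reports the two **FDR bounds** implied by FDP control: the asymptotic
  $2\alpha$ and the finite-sample $\alpha(1-\gamma)+\gamma$.  (Different
  sections of the source literature print the latter in two inconsistent
  forms; the package uses $\alpha(1-\gamma)+\gamma$, the form consistent
  with the underlying Lehmann–Romano result.)

Two routes are implemented for each rate.

**Augmented procedures** run the FWER shortcut at $\alpha$ and then simply
continue it on the updated graph at a relaxed level $\delta$, taking up to
$k-1$ extra rejections (k-FWER) or up to
$D = \max\{d : d/(d+|R|) \le \gamma\}$ extra rejections (FDP), selecting
$\arg\min_i p_i/w_i(I)$ at each step.  $D$ is computed once from the
stage-1 count and deliberately not recomputed as augmented rejections
accrue.  $\delta$ may exceed $\alpha$; $\delta = \infty$ takes every
available free rejection.  Data-dependent-$\delta$ ("adjusted")
formulations threshold the adjusted p-values and then take the smallest
remaining ones.  Ties among equal adjusted values are broken by the
shortcut's removal sequence and then by index: the removal sequence is
exactly the order in which the $\delta=\infty$ continuation rejects, so
this tie-break makes the two formulations coincide, which pure
smallest-index tie-breaking does not.

**Generalized (stepdown) procedures** account for $k-1$ possibly-false
earlier rejections: after rejecting $R = \{i : p_i \le w_i(M)k\alpha\}$,
any remaining $H_i$ is rejected when
$p_i \le \min_{J \subseteq R, |J|=k-1} w_i(I \cup J)\, k\alpha$, the
minimum taken by exact enumeration of the $\binom{|R|}{k-1}$ subsets
(refused above $10^6$ subsets; streamlined large-$m$ approximations are out
of scope).  When the procedure stops with fewer than $k-1$ rejections, a
free-rejection subprocedure may continue the FWER shortcut at $\delta$
up to a total of $k-1$.  The FDP version runs rounds $k_j = 1,2,\dots$
and stops as soon as $|R_j| < k_j/\gamma - 1$ (strict, as stated), capped
at $k_j = m$; $\gamma = 0$ is defined as the $k=1$ (FWER) round.  A
structural weakness of the stepdown route is inherited from its
definition: a hypothesis with fewer than $k$ donor edges can never have
its threshold raised above $w_j(M)k\alpha$ in step (iv), so level does not
propagate effectively through hierarchical graphs — visible in the
case-study tables, and the reason the augmented route is generally
preferable at trial scale.

## Entangled graphs and gatekeeping

An entangled graph mixes $L$ component strategies over the same hypotheses
with coefficients $c_l$, $\sum c_l = 1$; rejections propagate within each
component independently and the working weight of $H_j$ is
$\sum_l c_l w_j^{(l)}(I)$.  This gives the procedure memory of where
rejected level originated.  The r-of-n gatekeeper ("test the secondary
family once any $r$ of $n$ primaries fall") is built as one component per
size-$r$ subset, each component performing Holm on its subset and handing
the full level to a Holm split over the secondary family once the subset
is exhausted.

That component semantics is *not* representable as a regular transition
graph: with two primaries $A, B$ and secondary $S$, Holm requires
$g_{AB} = 1$, which forces $g_{AS} = 0$ and (by the $0/0$ convention)
leaves no route to $S$ after both rejections.  The literature works
around this with infinitesimal $\varepsilon$-edges; these are deliberately
not implemented (a symbolic-weight machinery for a limit that is known in
closed form).  Instead gatekeeper components are small rule objects whose
weights are exact rationals, and the generic entangled machinery accepts
plain graphs and rule components interchangeably.  A closed-form
evaluation of the gatekeeper weights,

$$w_{\text{prim}} = \binom{n}{r}^{-1}\sum_j \binom{u-1}{j}
  \binom{n-u}{r-1-j}\frac{1}{1+j},\qquad
  w_{\text{sec}} = \binom{n-u}{r}\Big/\binom{n}{r},$$

with $u$ unrejected primaries, is provided and cross-checked against the
component enumeration in the tests — the enumeration is the
implementation, the closed form the oracle.  The augmented procedures swap
the entangled engine in for both stages; the generalized procedures use
the entangled weights through the same subset-minimisation (the entangled
weighting also satisfies the monotonicity condition, which is all the
stepdown needs).

## Weighted parametric tests

When the test statistics are jointly normal with known correlation, the
weighted Bonferroni threshold can be inflated to $c_J w_j(J)\alpha$, where
$c_J$ is the largest constant with
$P\bigl(\bigcup_{j \in J}\{p_j \le c_J w_j(J)\alpha\}\bigr) = \alpha$.
The union probability is evaluated as one minus a multivariate normal
rectangle probability (deterministic Miwa quadrature up to dimension 19 on
non-singular correlations, seeded quasi–Monte Carlo otherwise, perfect
exchangeable correlation handled in closed form), and $c_J$ is found by
bisection on $[1, 1/(\alpha\max_j w_j)]$ to $10^{-6}$.  Zero-weight
hypotheses contribute no rejection event.  $c_J = 1$ at the Bonferroni
end; it grows with positive exchangeable correlation, reaching
$1/\max_j w_j$ at perfect correlation.  The scaled weights
$c_J w_j(J)$ need not be monotone in $J$ even when the raw weights are,
so the parametric shortcut first enumerates all subsets (default
$m \le 10$) and refuses with a diagnostic if the condition fails rather
than silently repairing the weighting; repair schemes and adjusted
p-values for parametric tests are out of scope.

## Case-study fixtures

The package ships the four graphs its worked examples and tests use.  Two
of them had to be reconstructed, because the original publications define
them only in figures:

* **diabetes** (4 hypotheses): fixed to weights $(1/2, 1/2, 0, 0)$ with
  $g_{13} = g_{24} = 1/2$ and all other entries zero — the minimal graph
  consistent with every constraint the worked examples impose.  The
  unassigned half of each primary row makes the fixture conservative.
* **pharmacodynamic** (15 dose-by-time contrasts $T_iD_j$): the shipped
  serpentine topology (top dose cascading toward earlier times while
  dropping level to the middle dose; the middle dose feeding forward to
  the latest time, crossing to the lowest dose, and cascading back) was
  identified by a constraint search: it reproduces, exactly, all 24
  published rejection sets across both initial weightings
  ($1/3$ on $T_4D_3, T_5D_2, T_5D_3$, and uniform $1/15$), procedures,
  and parameter values, several of which sit within ten percent of a
  decision boundary — strong evidence, though not proof, that it matches
  the published figure.  The study level is taken as $\alpha = .05$ (used
  by every worked example; the case study itself does not restate it).
* **atmosphere** (3 primaries, 2 secondary families): reconstructed the
  same way; the borderline rejection of one secondary at threshold
  $\tfrac{1}{8}(.025) = .003125$ against $p = .0031$ pins the
  quarter-level edges from the second primary.  Exact within-family
  "Holm then exit" routing is not graph-representable without
  $\varepsilon$-edges, so the secondary families use half-to-sibling /
  half-to-exit edges, which reproduce every published outcome.

These are documented as figure-derived reconstructions, not
transcriptions.

## The simulator

`simulation_scenario()` emulates a two-arm multi-endpoint trial: the
observed per-endpoint mean vectors are multivariate normal,
$\bar X_G \sim N(\mu_G, \Sigma_G)$,
$\Sigma_G = \mathrm{diag}(\sigma_G/\sqrt{n_G})\Sigma(\rho)
\mathrm{diag}(\sigma_G/\sqrt{n_G})$ with exchangeable correlation, and the
per-endpoint statistic is the standardized mean difference.  The source
material defers the variance estimator to external software; here the
per-arm sample variances are drawn from their scaled $\chi^2$
distributions and the statistic is referred to a t distribution with
Welch–Satterthwaite degrees of freedom, with a switch to plain
z-statistics using the true variances.  Independent normal "extra"
statistics model secondary endpoints.  Replicates are deterministic in
`(seed, replicate_index)`.  What the generator does *not* emulate:
non-normal endpoints, unequal or estimated correlation structures, missing
data, and interim analyses — passing error-control tests here shows
correctness of the procedures under the stated normal model, not
robustness on real trial data.

The packaged `prerelax_synthetic_scenario()` is a synthetic stand-in for
the proof-of-concept heart-failure study driving the 6-of-9 gatekeeper
example: nine endpoints with standardized effects
$(0.55, 0.50, 0.40, 0.45, 0.50, 1.0, 1.0, 0.35, 0)$ at $n = 40$ per arm
and $\rho = 0.3$ — six clearly efficacious endpoints, as in the trial —
with the ninth exactly null at mean $0.07$ in both arms and a secondary
statistic distributed $N(3,1)$, both as stated in the source.  The true
endpoint means and standard errors live in supplementary material that is
not redistributable, so simulated operating characteristics are
qualitatively comparable to the published table (power orderings, type-I
control) but not numerically.

## Numerical choices

* Validation tolerance $10^{-9}$; propagated-weight equality $10^{-12}$.
* Threshold comparisons use plain $\le$: a p-value exactly on its
  threshold rejects.
* Selection inside every shortcut: $\arg\min p_i/w_i(I)$, ratio $+\infty$
  at zero weight (zero-weight hypotheses with $p = 0$ rank first, since
  they satisfy any threshold), ties to the smallest index.  The final
  FWER rejection set is order-invariant regardless.
* `augmentation_count()` evaluates its integer maximisation with an
  epsilon guard and verifies the boundary by direct comparison, so
  rational boundaries like $\gamma|R|/(1-\gamma) = 2$ are exact.
* Adjusted p-values are capped at 1; permanently unreachable hypotheses
  (zero weight, no incoming mass) receive exactly 1.
* Sub-stochastic transition rows are accepted silently; lost level is
  conservative.
* Graph files round-trip through JSON/YAML at 17 significant digits,
  which is lossless for doubles.

## Problem sizes

The test-suite simulations use $2{,}000$ replications for the per-module
Monte-Carlo checks and $10^4$ replications for the consolidated
error-control suite on the four-hypothesis fixture (bounds are asserted
with three binomial standard errors, which is valid at any replication
count); the gatekeeper power comparison uses $800$ replications of the
ten-hypothesis entangled procedure.  These sizes were chosen so the whole
suite completes in a few minutes on a single core while leaving the
Monte-Carlo error an order of magnitude below the effects being asserted.

## Known limitations

* Adjusted p-values exist for the FWER shortcut only; deriving them for
  the augmented and generalized procedures is an open problem in the
  methodology itself.
* The generalized stepdown is exact brute force over
  $\binom{|R|}{k-1}$ subsets and is intended for trial-sized $m$.
* Group-sequential designs, $\varepsilon$-edges, partially known joint
  distributions (conservative $c_J$ bounds), and direct FDR-controlling
  procedures are out of scope.
* Serialisation covers plain graphs and entangled graphs with plain
  components; rule-based gatekeeper components are rebuilt from
  `build_r_of_n_gatekeeper(n, r, ...)` rather than stored.
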