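---
title: "Typicality inference and majority-rule error rates for small samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typicality inference and majority-rule error rates for small samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(typicality)
```

## The problem

Studies on scarce subjects — non-human primates are the canonical case —
often test only one to three animals and then wish to say something about
the population. This package quantifies exactly what such small samples
support. The central parameter is the **typicality** (elsewhere called
prevalence) $\gamma$ of a qualitative outcome: the probability that a
randomly drawn member of the population shows it. Two inferential devices
are implemented:

1. **Conjunction analysis**: from $N$ individually significant subjects out
   of $M$ tested, an exact lower confidence bound $\gamma_c$ on typicality.
2. **The N-out-of-M majority rule**: declare whichever outcome a strict
   majority of subjects shows to be the population's representative
   outcome, and ask how often that declaration is wrong.

Everything is closed-form binomial arithmetic; a seeded Monte Carlo layer
verifies each analytic quantity empirically.

## The model

### From typicality to significant tests

Each of $M$ subjects carries the outcome with probability $\gamma$. A
per-subject statistical test is significant with probability $\beta$ (the
sensitivity) in carriers and $\alpha$ (the false-positive rate) in
non-carriers, so a test is significant with probability

$$p \;=\; \gamma\beta + (1-\gamma)\alpha \;=\; \alpha + (\beta-\alpha)\gamma,
\qquad \gamma \;=\; \frac{p-\alpha}{\beta-\alpha}.$$

The map is strictly increasing only when $\alpha < \beta$, which the
package enforces. `p_from_gamma()` and `gamma_from_p()` implement the pair;
a property test checks that they round-trip to $10^{-12}$.

### The exact bound on p and the bound on typicality

The count of significant subjects is $N \sim \mathrm{Binomial}(M, p)$.
`lower_bound_p()` computes the exact equal-tailed (Clopper–Pearson) lower
bound: the value of $p$ at which the upper-tail probability
$P(X \ge N)$ equals the allotted tail mass — $(1-\text{level})/2$ for a
two-sided interval, $1-\text{level}$ for a one-sided lower bound — with
$p_L = 0$ at $N = 0$ by the standard convention. Numerically the bound is
the beta quantile $\mathrm{qbeta}(\text{tail}, N, M-N+1)$; the test suite
verifies it against an independent bisection on the binomial tail to
$10^{-9}$ for every tally up to $M = 10$. Exact inversion was chosen over
mid-p or approximate intervals because it reproduces every cell of the
published reference tables; approximate belts would not.

`gamma_lower_bound()` then maps $p_L$ through the inverse mixture and clips
to $[0,1]$:

$$\gamma_c \;=\; \max\!\left(0, \min\!\left(1,
  \frac{p_L - \alpha}{\beta - \alpha}\right)\right).$$

The raw (unclipped) value is kept alongside a `clipped` flag: negative raw
values are what produce the zero entries in the reference tables for small
$N$, and raw values above 1 arise whenever $\beta < 1$ — which is why the
bound is only meaningful under the conservative assumption $\beta = 1$. A
sample non-significant under $\beta < 1$ could always be a false negative,
so lowering $\beta$ inflates $\gamma_c$ without limit; the package accepts
$\beta < 1$ for sensitivity exploration (`gamma_sensitivity()`,
`run_report("fig3d")`) but warns.

```{r gammac}
gamma_lower_bound(2, 3, sided = "one.sided")
```

Even with all of 2-oo-3 logic in its favour, two significant animals out of
three support a one-sided 95% lower bound of only about 9% typicality —
far below the 50% needed to call the outcome typical of a majority.

### The majority rule and its error rates

For an outcome distribution $(\pi_1, \pi_2, \dots)$ with the representative
outcome first (it must be the strict modal outcome; the total outlier
probability is $\omega = 1 - \pi_1$), a sample of $M$ subjects is classified
by the strict-majority threshold $t = \lfloor M/2\rfloor + 1$:

* **correct** if the representative's count reaches $t$,
* **incorrect** if any outlier type's count reaches $t$ (probability
  $\delta$),
* **inconclusive** otherwise.

At most one outcome can reach a strict majority, so the events are disjoint
and each rate is a binomial upper tail: `rule_rates()` computes
$\delta = \sum_{j \ge 2} P(X_j \ge t)$ with $X_j \sim
\mathrm{Binomial}(M, \pi_j)$. `enumerate_exact()` re-derives the same rates
by brute-force enumeration of all $K^M$ ordered assignments (guarded at
$10^7$); the suite requires agreement to $10^{-12}$ on 100 seeded random
distributions with $K \le 5$, $M \le 7$.

For a single outlier type, $\delta(\omega) = 3\omega^2 - 2\omega^3$ for the
2-oo-3 rule and $\delta = \omega$ for 1-oo-1. The curve is steep:

```{r delta}
delta_curve(3, c(0.10, 0.13, 0.14, 0.20))
typicality_threshold(3, 0.05)
```

$\delta$ crosses the conventional 5% error rate just above $\omega = 13\%$
(`omega_threshold(3, 0.05)` gives the continuous root 0.1354), so the
2-oo-3 rule keeps an acceptable error rate only when the representative
outcome's typicality is at least **87%** — at which point testing beyond a
single animal adds little. The benefit of 2-oo-3 over 1-oo-1,
`delta_difference()`, peaks near $\omega = 0.211$ and vanishes at both
extremes.

The even-$M$ generalization uses the same strict-majority threshold (ties
are inconclusive); that choice keeps the majority events disjoint for every
$M$, and reduces to the published $M = 1, 3$ cases.

### Hypothesis tests

`typicality_pvalue()` tests a hypothesized typicality $\gamma_0$ with the
upper-tail probability $P(X \ge N \mid M, p_0)$, $p_0 = \alpha +
(\beta-\alpha)\gamma_0$. $\gamma_0 = 0.5$ is the majority-null hypothesis
(1-oo-1 p-value $0.525$), $\gamma_0 = 0$ the global-null hypothesis
(1-oo-1 p-value $\alpha = 0.05$: a single significant animal already
rejects "the effect exists in no animal"). The $N = M$ diagonals follow the
closed forms $0.525^M$ and $0.05^M$ exactly. The upper-tail convention is
deliberate: a lower-tail reading ("$N$ or less") appears in some prose
descriptions of this test but is inconsistent with every published table
value, so the package implements the tail that reproduces the tables and
documents the discrepancy here.

## Monte Carlo verification

The `simulate` layer re-derives each analytic quantity empirically:
`simulate_rule()` draws subject outcomes and classifies them with the same
`classify_sample()` used by the enumeration oracle;
`simulate_significance()` draws carrier status and per-subject test
outcomes (animals within replicate, replicates outer, one `set.seed(seed)`
per run, so results are bit-reproducible); `coverage_check()` verifies that
$\gamma_c \le \gamma$ in at least the nominal fraction of replicates —
exact intervals are conservative, so empirical coverage sits at or above
the level. Stochastic checks accept within 4 binomial standard errors of
the analytic value, which keeps the false-alarm rate of the test suite
negligible while still detecting real defects; the suite uses
$2\times10^5$ replicates for rates and $5\times10^4$–$10^5$ for coverage,
sizes at which the 4-SE band is a fraction of a percentage point.

What the simulator emulates is exactly the model above: exchangeable
subjects, a fixed outcome distribution, independent per-subject tests with
known $\alpha$ and $\beta$. Real data violate parts of this — tests differ
between labs, $\beta$ is unknown and below 1, outcomes may not be
independent across subjects reared or recorded together — so passing
simulations validate the arithmetic, not those assumptions.

## Numerical choices

* Exact bounds via the beta-quantile identity, cross-checked by bisection
  (agreement $10^{-9}$).
* `omega_threshold()` bisects to an $\omega$ tolerance of $10^{-10}$; the
  target must lie strictly between 0 and the curve's value at
  $\omega = 0.5$.
* Outcome distributions must sum to 1 within $10^{-12}$ and have a strict
  modal representative; $\omega \ge 0.5$ is rejected on the single-outlier
  curve so the representative stays modal.
* Table emission rounds half-up — percentages to 0.1 point, p-values to 4
  decimals, switching to 3 half-up significant digits below $10^{-4}$ —
  which reproduces the published tables cell-for-cell, with one caveat:
  two published global-null cells ($M=7$ and $M=8$ at $N=4$) were
  evidently truncated rather than rounded (printed .0001/.0003 against
  exact .000194/.000372), so table-equivalence tests compare within one
  unit in the last printed digit.
* Degenerate inputs: $N = 0$ gives $p_L = 0$ and $\gamma_c = 0$; $N = M$
  gives $p_U = 1$; a one-sided interval has upper limit 1 by convention
  and refuses to report an "upper bound".

## Reports

`run_report()` (and the `exec/typ` command-line wrapper) emits the four
reference tables and the figure data series as CSV or JSON, as data rather
than rendered plots. Defaults are $\alpha = 0.05$, $\beta = 1$, level
0.95, $M \le 10$; the sensitivity-versus-$\beta$ series fixes
$\alpha = 0.01$. Percentages are emitted on the percent scale.

## Limitations

The inference is about one qualitative outcome at a time; compound
requirements (several tests per animal, replication of full result
patterns) only lower effective sensitivity — e.g. three tests each at
$\beta = 0.9$ give $0.9^3 \approx 0.73$ jointly — and are outside the
package's operations. Upper bounds on typicality are computed internally
for confidence belts but deliberately not tabulated: the conservative,
reportable quantity is the lower bound.
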