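# typicality

Statistical inference about the population **typicality** (prevalence) of a
qualitative outcome from per-subject test results in small samples — the
"would you agree if N is three?" problem of non-human-primate and other
scarce-subject research, where studies traditionally test one to three
animals and wish to draw a conclusion about the population.

## What it computes

Let γ be the typicality of an outcome: the probability that a randomly
drawn member of the population shows it. An imperfect per-subject test
(false-positive rate α, sensitivity β) is significant with probability

    p = α + (β − α) γ

so from N individually significant subjects out of M tested, an exact
equal-tailed (Clopper–Pearson) lower confidence bound p_L on p maps to a
lower confidence bound on typicality

    γ_c = clip[ (p_L − α) / (β − α) ].

The package provides:

* `lower_bound_p()` / `upper_bound_p()` — exact binomial confidence
  bounds, one- and two-sided;
* `gamma_lower_bound()`, `gamma_table()`, `gamma_sensitivity()` — the
  typicality bound γ_c, full reference tables up to M = 10, and its
  sensitivity to α and β;
* `rule_rates()`, `delta_curve()`, `omega_threshold()`,
  `typicality_threshold()`, `enumerate_exact()` — analytic
  correct (π) / incorrect (δ) / inconclusive rates of the N-out-of-M
  strict-majority decision rule for arbitrary outcome distributions, the
  single-outlier error curve δ(ω) = 3ω² − 2ω³ (2-oo-3), threshold
  solving, and a brute-force enumeration oracle;
* `typicality_pvalue()`, `pvalue_table()` — one-sided binomial-tail tests
  of the majority-null (γ = 0.5) and global-null (γ = 0) hypotheses;
* `simulate_rule()`, `simulate_significance()`, `coverage_check()` —
  seeded Monte Carlo verification of every analytic quantity;
* `run_report()` and the `exec/typ` command-line wrapper — the four
  reference tables and figure data series as CSV/JSON.

## Worked example

Two of three tested animals show the effect. What does that support?

```r
library(typicality)

gamma_lower_bound(2, 3, sided = "one.sided")
#> Lower bound on typicality (one-sided 95% interval)
#>   2 of 3 subjects significant; alpha = 0.05, beta = 1
#>   p lower bound: 0.13535
#>   gamma_c: 9.0%
```

Even one-sided, the 95% lower bound on typicality is 9%: the data are
compatible with the outcome being present in as little as a tenth of the
population, far below the 50% needed to call it typical of a majority.

How error-prone is the 2-oo-3 majority rule itself?

```r
rule_rates(c(0.9, 0.1), 3)   # one outlier type at omega = 10%
#> Analytic decision rates of the 2-oo-3 majority rule
#>   correct (pi):       0.9720
#>   incorrect (delta):  0.0280
#>   inconclusive:       0.0000

typicality_threshold(3, 0.05)
#> [1] 87
```

δ is 2.8% at ω = 10% but rises steeply (10.4% at ω = 20%); keeping δ ≤ 5%
requires the representative outcome's typicality to be at least 87% — high
enough that testing beyond a single animal settles little. The Monte Carlo
layer confirms the arithmetic:

```r
simulate_rule(c(0.9, 0.1), 3, n_reps = 2e5, seed = 1)
#> Empirical decision rates of the 2-oo-3 majority rule (200000 replicates)
#>   correct (pi):       0.9728
#>   incorrect (delta):  0.0272
#>   inconclusive:       0.0000
```

Reference tables (here the one-sided γ_c table, percent):

```r
run_report("table2")[1:3, 1:4]
#>   M N0 N1   N2
#> 1 1  0  0   NA
#> 2 2  0  0 18.3
#> 3 3  0  0  9.0
```

From the shell: `Rscript exec/typ gammac --n 2 --m 3 --sided one`,
`Rscript exec/typ tables --which 2 --output table2.csv --format csv`.

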