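# wsrsite

Staged multi-criteria site selection for emergency medical facilities.

When a public-health emergency overloads a city's hospitals, large-space
public buildings — gymnasiums, exhibition centres — are converted into
temporary mass-care facilities (Fangcang-style shelter hospitals).
Choosing *which* buildings is a multi-criteria decision problem whose
criteria are of fundamentally different kinds, and `wsrsite` implements
the Wuli–Shili–Renli (WSR) staged screening methodology that treats
each kind on its own terms:

1. **Wuli (hard constraints).** Objective physical requirements — e.g.
   a greening clearance of at least 20 m from the surroundings — are
   applied as conjunctive pass/fail filters with a full exclusion audit
   trail.
2. **Shili (objective ranking).** Survivors are scored on quantifiable
   criteria (accessibility, distance to designated hospitals, space
   scale), min–max normalised, weighted by the entropy weight method

   *p*<sub>ij</sub> = *f*<sub>ij</sub> / Σ<sub>i</sub> *f*<sub>ij</sub>,  
   *e*<sub>j</sub> = −(1/ln *m*) Σ<sub>i</sub> *p*<sub>ij</sub> ln *p*<sub>ij</sub>,  
   *w*<sub>j</sub> = (1 − *e*<sub>j</sub>) / Σ<sub>j</sub> (1 − *e*<sub>j</sub>),

   and ranked by TOPSIS closeness *E* = *d*⁻ / (*d*⁺ + *d*⁻) to the
   per-criterion ideals; the top fraction (default 50 %, ceiling, ties
   kept) moves on.
3. **Renli (subjective ranking).** Experts judge the finalists on a
   seven-term linguistic scale (VL … VH) mapped to trapezoidal interval
   type-2 fuzzy sets. Criterion weights come from the linear Best-Worst
   Method (min ξ s.t. |*w*<sub>B</sub> − *a*<sub>Bj</sub>*w*<sub>j</sub>| ≤ ξ,
   |*w*<sub>j</sub> − *a*<sub>jW</sub>*w*<sub>W</sub>| ≤ ξ, Σ*w* = 1).
   Judgments are normalised, weighted, defuzzified by the ranking value
   Rank(ṽ) = ΣM<sub>p</sub> − ¼ΣS<sub>q</sub> + ΣH<sub>w</sub> over both
   trapezoids, and ranked by fuzzy TOPSIS closeness, with Shili
   closeness breaking exact ties.

Criterion calculators (gravity-model accessibility Σ *M*/*D*,
nearest-designated-hospital distance, bed-equivalent space scale), a
weight-perturbation sensitivity harness, a seeded synthetic case
generator with a known ground-truth ordering, and a command-line driver
round out the package. The methods vignette
(`vignettes/wsr-site-selection-methods.Rmd`) documents every modelling
convention and open-reading decision.

## Worked example

```r
library(wsrsite)

case <- generate_case(synthetic_spec(n_facilities = 12, seed = 7,
                                     wuli_fail_fraction = 0.25))
report <- run_pipeline(case$matrix, case$renli,
                       c(operability = 0.4, recovery = 0.1,
                         operational_effect = 0.2,
                         implementation_efficiency = 0.3))
report
#> <staged_report>
#>   initial:    12 candidates
#>   post-wuli:  9 survivors (3 excluded)
#>   post-shili: 5 retained of 9 ranked
#>   final:      5 ranked; best = Synthetic facility 01
```

Twelve synthetic candidates enter; three fall below the 20 m greening
threshold and are excluded with per-violation audit rows
(`report$wuli$exclusions`); entropy-weighted TOPSIS ranks the nine
survivors and retains the top five (`report$shili$weights` holds the
data-driven weights); fuzzy TOPSIS orders the finalists:

```r
head(report$renli$ranking[order(report$renli$ranking$rank),
                          c("id", "name", "closeness", "rank")], 4)
#>     id                  name closeness rank
#>  fac01 Synthetic facility 01 1.0000000    1
#>  fac08 Synthetic facility 08 1.0000000    2
#>  fac10 Synthetic facility 10 0.3976084    3
#>  fac02 Synthetic facility 02 0.0000000    4
```

`fac01` and `fac08` received identical linguistic judgments (closeness
1 at the fuzzy ideal); the tie is broken in favour of `fac01` by its
higher Shili closeness — the staged methodology's tie rule. Closeness
1/0 means a row coincides with the positive/negative ideal on every
criterion.

The published Shanghai case tables ship as fixtures:

```r
sh <- shanghai_case()
retain_top_fraction(sh$shili_ranking, 0.5)$members$id  # the 11 finalists
```

plus a clearly-labelled synthetic reconstruction of the (unpublished)
expert judgment table, `shanghai_renli_judgments()` — see its help page
for exactly what that fixture can and cannot demonstrate.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "wsr-siteselect.R", package = "wsrsite"))')" \
  run --config config.yaml --out results/
```

Subcommands: `run`, `wuli`, `shili`, `bwm`, `renli`, `sensitivity`,
`simulate`. Exit codes: 0 ok, 2 validation error, 3 degenerate data.

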