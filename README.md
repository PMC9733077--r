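# securesum

Secure summation and distributed biostatistics for multi-centre studies,
without a trusted third party.

Multi-institution medical research routinely needs pooled quantities —
case counts of a rare disease across hospitals, a pooled mean and standard
deviation of a lab value, a chi-square test over a multi-site contingency
table — while data protection law forbids sharing the site-level values
that go into them. `securesum` implements the cryptographic core that makes
this possible with nothing but message exchange between the sites:
**full-threshold additive arithmetic secret sharing** over the finite ring
ℤ(2¹²⁷ − 1), wrapped in a two-round store-and-forward protocol and a layer
that composes secure sums into standard statistics.

## The method

To contribute a secret value *x*, a party encodes it as a fixed-point
residue ⌊*x* · 10⁶⌋ mod *p* with *p* = 2¹²⁷ − 1 (negative values map to
*p* − |·|), then splits it into *n* additive shares

    s_1, …, s_{n−1} ~ Uniform[0, p),   s_n = x − (s_1 + … + s_{n−1}) mod p,

one per participant. Any strict subset of shares is jointly uniform and
therefore carries no information about *x* — the scheme stays private even
if *n* − 1 parties collude. Because shares add component-wise, a pooled sum
needs only two communication rounds:

1. **Input sharing** — every party sends one share vector to every other
   party and keeps one; each party then locally sums the shares it holds.
2. **Output reconstruction** — every party broadcasts its local sum; adding
   all broadcasts modulo *p* yields Σᵢ xᵢ, identically at every site.

Each participant sends and receives 2·(*n* − 1) messages, so one "cycle"
costs 2·*n*·(*n* − 1) deliveries in total. A finite state machine
(`CREATED → INITIAL_SENDING → INITIAL_RECEIVING → RESULT_SENDING →
RESULT_RECEIVING → FINISHED`) guards every session, messages travel as
checksummed, Base64-encoded, size-limited text envelopes over a pluggable
bus (in-memory, or one mailbox directory per party for multi-process runs),
and sessions can be saved and resumed at any point.

Statistics beyond plain sums are expressed as *cycle plans* — sequences of
secure sums with local pre-processing in between: frequency tables,
chi-square tests, quartiles of ordinal data and the Wilcoxon rank-sum test
need one cycle; pooled standard deviation and one-way ANOVA (with the
two-group t-test as a special case) need two; Pearson correlation needs
three. All any party ever learns are the planned global sums of each cycle.

## Worked example

Three sites pool two variables; nobody reveals their own column:

```r
library(securesum)

out <- run_secure_sum(
  list("a@site" = c(cases = 12,  controls = 100),
       "b@site" = c(cases = 7,   controls = 250),
       "c@site" = c(cases = 3.5, controls = 40)),
  rng = insecure_seeded_rng(1)   # reproducible demo; omit for real use
)
out$result
#>   variable   sum exact
#> 1    cases  22.5  22.5
#> 2 controls 390.0   390
out$bus_stats$envelopes_sent
#> [1] 12                         # 2 * 3 * (3 - 1) deliveries
```

`sum` is the pooled total each site reconstructs (22.5 cases, 390
controls); `exact` is the same number as an exact fixed-point decimal. A
distributed statistic runs the same protocol once per cycle:

```r
res <- run_plan(plan_sd(),
                list("a@site" = c(1, 2, 3, 4),
                     "b@site" = c(2, 3, 7, 4, 2, 2),
                     "c@site" = c(5, 5.5)),
                rng = insecure_seeded_rng(1))
res
#> <stat_result> SD after 2 secure-sum cycle(s)
#>   sd: 1.772582
#>   mean: 3.375
#>   n: 12
```

The pooled sample SD (1.77) equals `sd()` of the concatenated values to
within the 10⁻⁶ fixed-point grid, but no site saw another site's data —
only the global mean (cycle 1) and the global squared-deviation sum
(cycle 2) were ever reconstructed.

For a real deployment each party runs its own process against a shared
mailbox directory via the CLI in `inst/cli/securesum`
(`create` / `join` / `step` / `result`, plus `stats` and `bench`); see the
vignette for the message formats and the study configuration file.

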