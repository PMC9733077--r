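---
title: "Secure summation and distributed statistics: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure summation and distributed statistics: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(securesum)
```

## The protocol and its security model

`securesum` computes pooled sums of named variables across $n \ge 3$
parties so that no party learns another party's inputs. The primitive is
additive arithmetic secret sharing over the finite ring
$\mathbb{Z}_p$ with $p = 2^{127}-1$: a secret residue $x$ is split into

$$s_1,\dots,s_{n-1} \sim \mathrm{Uniform}[0,p), \qquad
  s_n = x - \sum_{i<n} s_i \bmod p,$$

so that $\sum_i s_i \equiv x \pmod p$. Because every strict subset of the
shares is jointly uniform regardless of $x$, the scheme is
*full-threshold*: it leaks nothing even if $n-1$ parties pool their
knowledge. Only addition is used, and additions compose share-wise without
interaction, so one pooled sum ("cycle") needs exactly two communication
rounds — input sharing, then reconstruction of the broadcast local sums —
and each party sends and receives $2(n-1)$ messages.

The adversary model is honest-but-curious: parties follow the protocol but
may try to infer others' inputs. The package does **not** authenticate
participants and does not protect result integrity — a party (or a
man-in-the-middle on the transport) could corrupt the *output*, but never
learn the *inputs*. Checksums on every envelope detect accidental
corruption only.

A small worked check of the share algebra in a test ring:

```{r}
cfg <- ring_config(11, 1)                      # tiny ring for illustration
sh <- make_shares("7", 3, cfg, rng = stub_rng(c(4, 9)))
sh                                             # two uniform draws + remainder
reconstruct(sh, cfg)
```

## Fixed-point encoding

Ring arithmetic is exact integer arithmetic, so decimal inputs are encoded
as scaled integers: with the default scale $10^6$, a value $x$ becomes
$x \cdot 10^6 \bmod p$, negatives mapping to $p - |x \cdot 10^6|$. The
representable window is $\pm (p-1)/2$ ring units, about $\pm 8.5\times
10^{31}$ at scale $10^6$ — comfortably beyond single-precision magnitudes
for any realistic number of parties.

Two deliberate strictness rules follow from the requirement that pooled
sums be bit-identical at every site:

* **Excess precision is an error, not a rounding.** A value with more than
  six fractional digits is rejected; silently rounding would make pooled
  sums depend on which party rounded what. The distributed-statistics layer
  is the one place where rounding is legitimate (see below) and it does so
  explicitly.
* **Exact decimal parsing.** Values can be supplied as decimal strings,
  which are parsed digit-by-digit with no binary floating-point
  intermediate; numeric input is accepted when it sits exactly on the
  fixed-point grid within double precision ($|x \cdot 10^6| \le 2^{53}$).

The 127-bit arithmetic itself is implemented in C++ on `unsigned __int128`
(sums of two residues below $2^{127}$ cannot overflow $2^{128}$, so a
single conditional subtraction reduces them); ring elements cross the R
boundary as canonical decimal strings.

## Randomness

Share uniformity *is* the security argument, so the default randomness
source reads the OS entropy pool and de-biases by rejection sampling
(accepted draws are exactly uniform on $[0, p)$). Two alternatives exist
for testing only and are named accordingly: `insecure_seeded_rng()`
(reproducible Mersenne-Twister bytes) and `stub_rng()` (a preset
sequence, used to enumerate *every* possible sharing in a small test ring
and verify the subset-uniformity property exactly rather than
statistically). Test rings with moduli 7, 11 and 13 are first-class
configurations for this reason; the default ring is always $2^{127}-1$.

## Protocol engine

A finite state machine guards each party's session:

```
CREATED -> INITIAL_SENDING -> INITIAL_RECEIVING
        -> RESULT_SENDING  -> RESULT_RECEIVING -> FINISHED
```

with `ABORTED` reachable from any non-final state and every other
transition refused. Design choices where more than one reasonable option
existed:

* **Roster order is protocol state.** The initiator's participant list
  fixes sender indices; its digest travels in every envelope, so messages
  from a diverging study definition are rejected before any share is
  recorded.
* **The dealer keeps the remainder share.** The $n-1$ *transmitted* round-1
  shares are then pure uniform draws, independent of the secret — nothing
  derived from a party's input ever leaves it in round 1.
* **Duplicates:** redelivery of an identical envelope is a no-op
  (store-and-forward buses may redeliver); a *conflicting* duplicate from
  the same sender is a hard protocol error.
* **Strict rounds, buffering caller.** A round-2 envelope arriving while a
  party still collects round-1 shares is refused by the session; the
  bus-facing drivers (the in-process runner and the CLI) buffer and
  redeliver it after advancing. This keeps the session's invariants simple
  and auditable.
* **Persistence at any time.** Sessions serialize to versioned JSON
  between, not only after, transitions. Secrets and shares are stored as
  held in memory — unencrypted; at-rest protection is delegated to file
  permissions, matching the local-state model of a desktop deployment.

## Message bus

Envelopes are deterministic 8-line ASCII blocks: version banner,
Base64-encoded header fields, Base64-encoded JSON payload, and a CRC-32
checksum over everything above it. CRC-32 was chosen because the goal is
integrity against accidental corruption, not authenticity; any single-byte
change is detected (verified over random corruption trials in the test
suite). The wire dialect is the package's own and is versioned; no
compatibility with any other tool's serialization is claimed.

Transports: an in-memory bus (tests, benchmarks, single-process
demonstrations) and a filesystem mailbox — one directory per address, one
plain-text file per chunk, atomic rename on publish — over which
independent processes complete studies. An e-mail transport would slot
behind the same two-function interface (`bus_send`/`bus_poll`) but is not
implemented. Messages larger than the configurable limit (default 10 MiB,
a conservative mail-server cap) are split into chunks with a fixed
128-byte header budget; chunk sets reassemble order-independently and
never mix across envelope identifiers. Corrupt mailbox entries are
warned about, skipped and retained under a `.corrupt` suffix.

## Distributed statistics

Each statistic is a `cycle_plan`: per-cycle variable lists fixed a priori,
a local-input rule per party, and a finalizer over the pooled sums. Cycle
counts are structural: frequency, chi-square, quartiles, Wilcoxon and mean
need 1; SD and ANOVA need 2; correlation needs 3. Between cycles no extra
message type exists — the pooled sums of a finished cycle are already
public to every party, so each party derives the global means locally.

Conventions chosen where the method family admits variants:

* **SD / ANOVA denominators:** sample ($N-1$, and $N-k$ within groups),
  consistent with the t-test; `plan_sd()` exposes a population option.
* **Quartiles:** discrete inverse-CDF (smallest class whose cumulative
  relative frequency reaches the target), i.e. quantile type 1 — ordinal
  classes admit no interpolation.
* **Wilcoxon:** midranks for ties, normal approximation with tie-corrected
  variance, no continuity correction by default (flag available). The
  grouped-data $U$ equals the raw-data statistic exactly.
* **Counts stay exact.** Class frequencies and record counts are integers;
  on the $10^{-6}$ grid they encode and pool without error, so count-based
  methods agree with their centralized counterparts *exactly*.
* **Derived interval inputs are rounded explicitly.** Local sums, squared
  deviations and cross-products are rounded onto the fixed-point grid
  before encoding; with $P$ parties this perturbs a pooled intermediate by
  at most $P \cdot 5\times10^{-7}$, which propagates to well below the
  $10^{-6}$ agreement the tests assert for means, SDs, $F$, $t$ and $r$.
* **p-values are not computed.** Finalizers return statistics and degrees
  of freedom; mapping them to p-values is a local one-liner
  (`pchisq`, `pnorm`, `pf`, `pt`) the caller can apply.

Degenerate inputs fail loudly with classed errors: empty pooled
distributions, zero contingency margins, pooled counts below 2, zero
variance in correlation, undersized groups in ANOVA.

```{r}
res <- run_plan(plan_mean(),
                list("a@x" = c(1, 2), "b@x" = c(3, 4), "c@x" = 5),
                rng = insecure_seeded_rng(1))
res$statistics$mean
res$pooled          # the only values any party ever sees reconstructed
```

Running a plan always drives the full two-round protocol per cycle — the
in-process runner is a scheduler around real sessions and a real bus,
never a computational shortcut — so the disclosure surface measured in
tests is the deployed one.

## Synthetic studies and what the tests do (and do not) show

`generate_study(n, v, seed)` emulates the structure of a large automated
study: `v` variables named by 10 random letters and values spanning
single-precision magnitudes, sampled uniform-in-exponent as a
7-significant-digit mantissa times $10^e$, $e \in [-6, 23]$, bounded to
$\pm 10^{30}$ so pooled sums of up to 20 parties stay inside the signed
window. Every value sits exactly on the fixed-point grid, and ground-truth
pooled sums come from exact non-modular 128-bit decimal summation — an
independent code path from the ring arithmetic it validates.

What the generator does *not* emulate: real transport latency and
failures, concurrent processes (benchmarks schedule all parties in one
process over the in-memory bus), adversarial message tampering, and the
skewed, correlated distributions of real clinical variables. Passing
benchmarks therefore demonstrate protocol correctness, message-count laws
and throughput structure — not wall-clock performance of a networked
deployment, which is dominated by the mail infrastructure.

Problem sizes used in the shipped test suite were chosen to keep a full
run in the low minutes on one core: protocol property tests use $n \in
[3, 8]$ parties and up to 50 variables; statistic-versus-oracle
equivalence runs 50 randomized trials per method with up to 200 values per
party; the scaling harness verifies the $2n(n-1)$ message law up to
$n = 20$ and one large cell (20 parties, 10{,}000 variables) end to end.

## Known limitations

* Addition is the only ring operation; multiplication sub-protocols,
  Boolean circuits and vertically partitioned correlation are out of scope.
* No participant authentication and no output-privacy mechanism
  (e.g. differential privacy): the pooled sums themselves are disclosed by
  design, and multi-cycle statistics disclose more intermediates than a
  tailored single protocol would. Whether those global sums are safe to
  reveal must be judged per study.
* The two-round cycle assumes all $n$ parties stay available; a party that
  never sends leaves the others waiting (the state machine makes this
  visible, and sessions can be aborted and saved, but there is no
  automatic recovery).
* Share generation security rests entirely on the OS entropy source; the
  seeded generator exists for reproducibility and is insecure by
  construction.
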