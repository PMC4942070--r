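---
title: "Exact operating characteristics of A+B dose-escalation designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact operating characteristics of A+B dose-escalation designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The A+B design and its state space

An A+B design is specified by five integers $\{A, B, C, D, E\}$ and a
de-escalation indicator. At each dose level $d_j$ a first cohort of $A$
patients is treated and the number of dose-limiting toxicities (DLTs)
$x$ observed:

* $x \le C-1$: escalate to $d_{j+1}$;
* $C \le x \le D$: treat a second cohort of $B$ at $d_j$; escalate
  afterwards iff the total DLT count among all $A+B$ patients is at most
  $E$;
* otherwise escalation stops.

Without de-escalation, a stop at $d_j$ declares $d_{j-1}$ the MTD (no
MTD if $j = 1$). With de-escalation, the doses below the stopping dose
are revisited in descending order: a dose already holding $A+B$ patients
is declared the MTD iff its total DLTs are $\le E$; a dose holding only
$A$ patients first receives $B$ more; if every dose is exhausted the
trial ends with no MTD. Escalation beyond the top dose ends the trial
with every dose tolerated. Escalation moves exactly one level up and
de-escalation exactly one level down; the de-escalation phase never
re-escalates, and no dose ever receives more than $A+B$ patients. The
classical 3+3 design is $\{3,3,1,1,1\}$ without de-escalation.

Patient outcomes are modelled as independent Bernoulli draws with
dose-specific true DLT probability $p_j$; a cohort's DLT count is
therefore binomial. Because the rules are deterministic functions of
those counts, a trial realisation is fully described by its *pathway* —
the ordered sequence of (dose, cohort size, DLT count) — and the
probability of a pathway is the product of its cohorts' binomial pmf
terms. `enumerate_pathways()` walks the decision tree depth-first,
branching on every DLT count $0,\dots,$ cohort size at every reachable
state, so the resulting pathway set is exhaustive and mutually exclusive
and its probabilities sum to one up to floating-point rounding (the
tests require $10^{-12}$). No branch is pruned, however improbable: all
operating characteristics are finite sums, exact in double precision.
The scales involved are small (hundreds to a few thousand pathways for
typical designs over 4–6 doses), so probabilities are far from
underflow and no log-space arithmetic is needed.

## Scenario operating characteristics

All quantities below are expectations over the pathway distribution
$\Pr(\omega)$; `operating_characteristics()` computes them in one pass.

**Sample-size distribution.** $\Pr(N = n)$ aggregates pathway
probability by total enrolment, giving the full distribution rather
than only a mean.

**Experimentation percentages.** For dose $j$, $100\,E[n_j(\omega) /
N(\omega)]$ — the expected *within-trial* proportion of patients treated
at $d_j$. Since each trial's proportions sum to one, the percentages sum
to 100. This pathway-weighted definition differs from the
ratio-of-expectations approximation $E[n_j]/E[N]$, which over-weights
long trials that escalate far; the package computes the exact version
(the tests assert the two differ and that only the exact one reproduces
the reference tables).

**MTD recommendation.** $100 \Pr(\text{MTD} = d_j)$ per dose, alongside
two no-MTD categories: stopping with no safe dose
(`none_too_toxic`) and escalating past the top dose with every dose
tolerated (`all_tolerated`). How a program labels the latter is a
genuine reporting choice; `mtd_distribution()` reports it separately by
default and offers folding it into the top dose or into the no-MTD
category. Without de-escalation an interior stop always selects the
next-lower dose, so the top dose is never selected outright — its
recommendation mass can come only from the folded category.

**ETL.** The expected true DLT probability at the declared MTD,
conditional on one being declared:
$\sum_j p_j \Pr(\text{MTD}=d_j) / \sum_j \Pr(\text{MTD}=d_j)$. The
default counts full escalation past the top dose as declaring the top
dose (`fold_all_tolerated = TRUE`): a trial that tolerates every dose
has, in effect, identified its highest dose as tolerable, and the
conditional expectation is then defined whenever any trial ends with a
declared dose. Cross-checks against the reference examples confirmed
this is the convention the published values follow; the strictly
interior-selection variant remains available.

**EOTR.** The expected proportion of patients experiencing a DLT. Two
natural definitions exist because $N$ is random: the ratio of
expectations $E[\text{DLTs}]/E[N]$ (the long-run DLT rate across many
identical trials) and the per-trial mean $E[\text{DLTs}/N]$. They
differ by a few tenths of a percentage point for typical designs.
`eotr()` defaults to the ratio of expectations — again the convention
the reference values follow — and exposes `method = "per_trial"`.

**Interval summaries.** Per-dose experimentation and recommendation
percentages are also aggregated over doses whose true $p_j$ falls in
$[0,0.2], (0.2,0.4], (0.4,0.6], (0.6,0.8], (0.8,1]$. Every interval is
closed on the right, so a boundary value such as $p_j = 0.4$ belongs to
the lower interval; binning uses a $10^{-9}$ guard so that values like
$0.8/0.2$ are not pushed across a boundary by floating-point error.

## Design operating characteristics

**Terminal MTD data states.** The data observable at the selected MTD
are limited by the rules themselves: without de-escalation,
$(x, A)$ for $x \le C-1$ or $(y, A+B)$ for $C \le y \le \min(E, D+B)$;
with de-escalation always $(y, A+B)$ with $y \le \min(E, D+B)$. For the
3+3 these are 0/3 and 1/6 (without), 0/6 and 1/6 (with).

**Confidence intervals.** For each terminal state the package reports
the exact Clopper-Pearson interval (beta quantiles; lower limit 0 at
$x=0$, upper limit 1 at $x=n$) and, as a second method, the Wilson score
interval. The Wilson interval was chosen as the companion because it is
the standard non-exact counterpart with good coverage at these tiny
sample sizes; it is labelled in every output so users who want only the
exact interval can ignore it.

**Escalation probability and tipping point.** The probability of
escalating from a dose with true DLT probability $p$ is
$$\pi(p) = \sum_{x=0}^{C-1}\binom{A}{x}p^x(1-p)^{A-x} +
\sum_{x=C}^{D}\binom{A}{x}p^x(1-p)^{A-x}
\sum_{y=0}^{E-x}\binom{B}{y}p^y(1-p)^{B-y},$$
continuous and non-increasing with $\pi(0)=1$. The *tipping point* is
the root of $\pi(p)=\tfrac12$ on $(0,1)$, located by bracketing
root-finding (`uniroot`, tolerance $10^{-10}$) and reported to 3
decimals. For the degenerate family $D = A,\ E = A+B$ the design
escalates with certainty at every $p$, so the tipping point is reported
as undefined rather than an arbitrary root. Doses above the tipping
point are unlikely MTDs: without de-escalation the *modal trial
outcome*, when it is a dose selection at all, is a dose with
$p \le$ tipping point (conditioning on selection alone the claim can
fail — with a highly toxic dose 1 the modal *selection* may be dose 1
while most trials end with no MTD — so the property tests compare dose
selections against the no-MTD outcome categories); with de-escalation
at most half the selection mass can lie above the tipping point. Both
properties are exercised over randomized design/scenario sweeps in the
test suite.

## The Monte-Carlo oracle

`simulate_trial()` and `estimate_ocs()` form an independent stochastic
twin of the exact engine: cohort DLT counts are binomial draws and all
decisions go through the same `stage1_decision()` / `stage2_decision()` /
`determine_mtd()` functions, so the simulator and enumerator cannot
drift apart silently. The tests replay simulated pathways through the
enumeration (every simulated trial must be an enumerated pathway with
matching probability and outcome) and require every exact operating
characteristic to lie within four standard errors of its empirical
estimate — at 100,000 simulations for the headline example and at
6,000–8,000 for the quicker randomized checks. Randomness is controlled
by an explicit seed argument; no global state is assumed beyond R's RNG.

What the simulator does *not* emulate is real-trial complications:
patient heterogeneity, within-cohort correlation, incomplete or delayed
toxicity observation, deviations from the escalation rules. Agreement
between engine and simulator validates the combinatorics and
probability arithmetic, not the clinical realism of the binomial model.

## Numerical and reporting conventions

* Probability sums are checked to $10^{-12}$; percentage
  normalisations to $10^{-9}$.
* Presentation rounding is *half away from zero* (29.75 → 29.8), the
  convention of the reference tables, implemented in
  `round_half_away()` with a few-ulp guard for values stored just under
  a tie; percentages print to 1 decimal, probabilities to 3, confidence
  limits to 2 decimals of a percent.
* DLT-rate support points are pooled by their value as exact rationals
  (1/3 and 2/6 are one atom), keyed via 15-significant-digit formatting.
* `ab_design()` rejects violations of $1 \le C \le D \le A$,
  $B \ge 1$, $0 \le E \le A+B$; it warns — legally but suspiciously —
  when $E < C$ (an expanded dose can then never be escalated from) and
  for non-monotone toxicity scenarios.
* Reports round exactly as the CSV exports do, so the rendered numbers
  and the exported tables agree cell for cell.

## Problem sizes in the test suite

The randomized property sweeps use designs with $A \le 4$, $B \le 4$
over 2–4 doses, where enumerations finish in milliseconds and the
independent brute-force oracle (a second, deliberately simple
implementation kept in the test helpers) is feasible; the four worked
examples span 91–2,314 pathways. These sizes were chosen as
representative of real phase I designs, which rarely exceed 6 cohorts
of 6 over 10 doses.

## Limitations

* Only the $\{A,B,C,D,E\}$ + de-escalation rule family is covered: no
  dose skipping, accelerated titration, or model-based comparators.
* Confidence intervals are the standard fixed-sample ones and are not
  adjusted for the sequential stopping rule.
* The binomial model assumes exchangeable patients and fully observed
  binary toxicity.
* ETL is undefined (an error / `NA`) for scenarios in which no trial
  ever declares an MTD, e.g. certain toxicity at dose 1.
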