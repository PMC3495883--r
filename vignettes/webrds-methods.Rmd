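---
title: "Methods: simulating and analysing web-based respondent-driven sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing web-based respondent-driven sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webrds)
```

## The problem

Hidden populations — here, the motivating case is internet-using men who have
sex with men in a setting where same-sex relationships are stigmatized — have
no sampling frame, so conventional probability surveys cannot reach them.
Respondent-driven sampling (RDS) replaces the frame with the population's own
social network: a handful of purposively chosen *seeds* complete the survey
and each participant may invite a small number of peers (here, up to four
electronic invitations), producing referral chains that, after enough waves,
forget where they started. In the web-based variant (webRDS) the entire
process — invitations, the questionnaire, incentives — runs online, which
makes recruitment fast and cheap but also makes fraudulent and duplicate
submissions easy, so screening and sensitivity analysis become part of the
estimator's job.

`webrds` implements this whole workflow as testable code: a synthetic
population and recruitment simulator (no real data ship with the package), a
cleaning module with progressively stricter inclusion criteria, the RDS-II
estimator with network-size imputation, and the Markov-chain equilibrium
diagnostics used to argue that estimates do not depend on the seeds.

## The estimator

A long-run referral process on a connected network includes individuals
approximately in proportion to their degree $d_i$ (their personal network
size). RDS-II (Volz–Heckathorn) corrects this size bias by weighting each
respondent by $1/d_i$:

$$\hat p_A \;=\; \frac{\sum_{i \in A} d_i^{-1}}{\sum_{i} d_i^{-1}},
\qquad
\hat{\bar x} \;=\; \frac{\sum_i x_i d_i^{-1}}{\sum_i d_i^{-1}},
\qquad
\hat d \;=\; \frac{n}{\sum_i d_i^{-1}}.$$

$\hat d$, the harmonic mean of the reported degrees, estimates the
*population's arithmetic* mean degree under degree-proportional inclusion;
the package uses it both as a summary ("average personal network size") and
to impute degrees for respondents who declined the network-size question.
Within `rdsII()`, imputation always precedes estimation and uses only the
included records' non-missing values. A reported degree of zero is treated as
missing: $1/d$ is undefined at zero and anyone recruited through the network
has at least one in-scope contact. Refusals on categorical analysis variables
form their own `"(no answer)"` category; refusals on numeric variables are
dropped pairwise. The package deliberately reports no confidence intervals:
there is no consensus variance estimator for RDS designs, and pretending to
one would be worse than abstaining.

Two exact properties anchor the test suite: the estimates are invariant to
rescaling all degrees by a constant, and they collapse to the raw sample
statistics when all degrees are equal. The substantive property — that
inverse-degree weighting removes the bias that raw proportions suffer when an
attribute correlates with degree — is checked against an independent oracle:
a stationary simple random walk on a known graph, whose visit distribution is
exactly degree-proportional, the regime in which RDS-II is unbiased.

## The synthetic study

No data were deposited with the study this design follows, so the package's
generator *is* the study population for every test. It emulates:

* **Network.** A configuration-model graph (default 2,000 individuals,
  Poisson(8) degrees) built by stub matching with rejection of self-loops and
  multi-edges. Leftover stubs that cannot be matched after the retry rounds
  are placed by degree-preserving edge swaps, so small regular graphs come out
  exactly regular.
* **Homophily.** During matching, a proposed edge whose endpoints differ on a
  trait with homophily coefficient $h$ is accepted with probability $1-h$;
  $h=0$ makes the trait independent of the ties, and the same-category edge
  fraction grows monotonically with $h$. Provinces are one more categorical
  attribute: eight provinces, the two metropolitan ones holding 70% of the
  population, with $h = 0.90$. That value was calibrated once, on the
  generator itself, so that roughly 30% of ties (and hence of recruitment
  events) cross provinces — the level of geographic mixing the study design
  treats as evidence against isolated sub-networks.
* **Recruitment.** Discrete waves, 20 seeds, up to 4 invitations each, each
  participant inviting a uniform random subset of still-unsampled neighbours.
  Participation is voluntary and modelled as a per-person willingness drawn
  once (probability 0.35): someone who declines stays out even if re-invited
  later through another tie. The alternative — a fresh coin flip per
  invitation — lets chains re-invite decliners until they accept, which
  saturates the entire population; the per-person reading reproduces the
  local-saturation die-out characteristic of real chain-referral samples,
  where chains stop because neighbourhoods are exhausted, not the population.
  With the defaults this yields samples of a few hundred participants and
  chains commonly deeper than ten waves. The real design's 7-day invitation
  window and reminder messages play no analytical role and are not modelled;
  submission timestamps simply increase along each chain.
* **Submissions.** One record per participant with phone/e-mail/chat and IP
  tokens, completion duration, stated age (18–40, centred near 22, echoing a
  young online population), education, income, province, 6-month partner
  count, and the reported 7-day network size: Poisson noise around 0.7 of the
  true degree, with 10% refusal. Invalid records are injected at configurable
  rates (defaults: 3% underage, 7% duplicated contact token, 10% shared IP,
  2% fast completion), and the injected flags are kept as bookkeeping so the
  cleaning module can be validated record-for-record. Honest records never
  state an age below 18, a completion under 4 minutes or "no education", so a
  zero-injection run is clean by construction and every flag traces back to
  an injection.

What the generator does *not* emulate — real contact-token formats and typos,
bot behaviour beyond the listed screens, seasonal recruitment dynamics,
incentive choices, message forwarding — bounds what green tests mean: they
validate the estimator, the screens and the diagnostics under controlled
conditions, not the ecological realism of any particular field study.

## Cleaning and inclusion levels

Screens follow the field's practice for web surveys: stated age below 18; a
contact token (normalized: trimmed, lower-cased, phone numbers reduced to
digits) already registered by a chronologically earlier record; a repeated IP
token; completion under 3 minutes; no education; more than 1,000 partners in
six months. "Previously registered" is read chronologically by submission
timestamp (ties broken by id), so the earliest bearer of a token is never
flagged. Inclusion levels nest: L0 (non-seeds with valid age), L1 (minus
duplicate contacts — the cleaned sample and the default analysis set), L2
(minus duplicate IPs, which may be legitimate shared connections), L3 (minus
the softer suspicion screens). Seeds are always excluded, as is customary in
RDS analysis. `sensitivity_report()` recomputes every estimate at every level
and reports the maximum absolute difference against L0; excluded records'
retained descendants are re-parented to their nearest retained ancestor by
`reattach_orphans()` — a diagnostic repair only, since RDS-II ignores tree
structure.

## Equilibrium diagnostics

For each variable, recruitment events define a recruiter-category ×
recruit-category count matrix, row-normalized into a transition matrix $P$.
The diagnostic asks how many waves a first-order Markov chain on $P$ needs
before every category is within a 2% *relative* difference of the stationary
composition $\pi$ (solved by the leading eigenvector of $P^\top$, polished by
power iteration to a residual below $10^{-10}$). Design choices a reader
should know:

* **Worst-case starts.** `waves_to_equilibrium()` defaults to the maximum
  over all degenerate starting compositions, the faithful reading of
  seed-independence (any seed composition is a mixture of degenerate starts,
  so it can only converge faster); a specific start, e.g. the observed seed
  composition, can be supplied instead.
* **State space.** Categories never observed as recruiters are excluded from
  the chain (their rows cannot be normalized) and reported alongside the
  matrix; events into excluded categories are dropped.
* **Degenerate chains.** Reducible or periodic matrices, and stationary
  distributions with zero entries (the relative criterion is undefined
  there), raise errors naming the offending states; `equilibrium_report()`
  converts these to per-variable notes instead of aborting. Periodicity is
  detected by the BFS-level gcd method on the positive-support digraph.
* **Numeric variables** are binned (`bin_numeric()`, bin edges in the
  pipeline config) before Markov analysis, which is inherently categorical.

Two empirical stability checks complement the Markov criterion:
`running_composition()` recomputes sample and RDS-II compositions on growing
prefixes of the time-ordered sample (the final point equals the full-sample
estimate exactly), and `last_k_comparison()` contrasts the full sample with
the last $k$ respondents (default 200).

The two-state closed form $P^n - \Pi = \lambda^n (I - \Pi)$ with
$\lambda = P_{11} + P_{22} - 1$ gives an independent oracle for
`waves_to_equilibrium()`; the worked matrix
$P = \begin{pmatrix} 0.8 & 0.2 \\ 0.3 & 0.7 \end{pmatrix}$ has
$\pi = (0.6, 0.4)$, $\lambda = 0.5$, and needs 7 waves at the 2% criterion.

## Numerical and scale choices

Determinism is a contract: every simulation function takes an integer seed,
the pipeline derives per-stage substreams from one master seed, and identical
configuration plus seed reproduce byte-identical CSV/JSON artifacts (hashes
are written to a manifest). Problem sizes in the test suite — populations of
a few hundred to 2,000, 50 random-walk replicates of 500 draws, $10^5$-step
walks for stationarity checks — were chosen as the smallest sizes at which
the Monte-Carlo assertions are comfortably stable under their fixed seeds;
the stationarity check uses batch-means standard errors, which absorb the
walk's autocorrelation. Equality assertions on proportions use tolerances of
$10^{-9}$ or tighter; $\pi P = \pi$ is enforced at $10^{-10}$.

## Limitations

RDS-II's unbiasedness needs degree-proportional inclusion, accurately
reported degrees, and sampling with replacement — all violated to some degree
by any finite chain-referral study, including the simulated one (sampling
here is without replacement, degrees are noisy, and chains branch rather
than walk). These violations are the point of the diagnostics rather than
something the package corrects: no design-effect or variance machinery is
included, cross-province mixing is a qualitative argument, and the
equilibrium criterion says the chain *would* forget its seeds under the
fitted first-order model, not that the sample is a probability sample.
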