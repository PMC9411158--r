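---
title: "Predicting disease comorbidity from shared mode-of-action proteins"
author: "comoa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disease comorbidity from shared mode-of-action proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comoa)
```

## The model

Two diseases are clinically comorbid when they co-occur in one individual
more often than chance.  `comoa` predicts comorbidity from molecular
information alone: if the drugs that work for disease A and the drugs that
work for disease B converge on the same protein targets, the two diseases
plausibly share molecular drivers, and shared drivers are a mechanism for
comorbidity.  The pipeline has four stages.

**1. Efficacious-drug partition.**  For each indication the raw scores of a
probe-drug library are standardised,

$$z_d = \frac{\mathrm{raw}_d - \overline{\mathrm{raw}}}{\sigma_{\mathrm{raw}}},$$

with $\sigma$ the *population* standard deviation: the library is the whole
population of drugs being ranked, not a sample from a larger one.  Drugs
with $z_d \ge 1.65$ (boundary inclusive) form the efficacious set $N_1$;
the rest form $N_2$.  The cutoff 1.65 corresponds to a one-sided normal
tail of about 0.05, so the partition is deliberately loose — it always
nominates some drugs, with known statistical confidence, even for poorly
scored indications.

**2. MOA protein inference.**  For each protein $T$, with $N_1^T$ and
$N_2^T$ the numbers of binding drugs in the two partitions, the relative
risk

$$RR(D, T) = \frac{N_1^T / N_1}{N_2^T / N_2}$$

measures how much more likely an efficacious drug is to bind $T$ than a
background drug ($RR = 0$ when no drug binds $T$ at all; $RR = \infty$ when
only efficacious drugs do).  Significance comes from a one-sided Fisher
exact test on the corresponding 2×2 table; proteins with $p < 0.05$ that
survive the tissue filter form the disease's mode-of-action (MOA) set.
The tissue filter removes a candidate only on positive evidence of
absence: at least one expression record in a disease-related tissue, every
such record "not detected", and none of them "uncertain".  Proteins never
assayed in the related tissues are retained — absence of evidence is not
evidence of absence.  q-values over each disease's protein family are
computed and stored for ranking, but set membership uses the raw p-value;
the q-scope is per disease because MOA ranking is a within-disease
operation.

**3. Pair scoring.**  For diseases with MOA sets of sizes $N_{D1}$,
$N_{D2}$ sharing $N_s$ proteins, the comorbidity score is the Jaccard
index

$$J = \frac{N_s}{N_{D1} + N_{D2} - N_s},$$

and its significance is the hypergeometric tail $P(X \ge N_s)$ for a
random $N_{D2}$-subset of the $N_t$-protein universe intersecting a fixed
$N_{D1}$-set.  All $n(n-1)/2$ unordered pairs are enumerated (self-pairs
excluded) and FDR is controlled once across the whole family; pairs with
$q < 0.05$ are called significant.  A pathogenic gene list can be
substituted for one of the diseases (`genesetQuery()`): it is treated as a
pseudo-disease and ranked against every profile with the same machinery.

**4. Enrichment and pathways.**  For a focal disease, the top
$k \le 100$ comorbidities (q ascending, J descending, partner id as the
deterministic tie-break) are pooled.  A protein $T$ in the focal MOA set
accumulates, over pooled comorbidities that also carry $T$, the weight

$$w = \min(1, -\alpha \ln p_{T,D}), \qquad \alpha = 0.025,$$

where $p_{T,D}$ is the *comorbid* disease's MOA p-value for $T$.  The
logarithm is natural: saturation at $w = 1$ then happens exactly at
$p = e^{-1/\alpha} = e^{-40} \approx 4.2 \times 10^{-18}$, which pins down
the base, and the implied p-value of a total weight $W$ is $e^{-W/\alpha}$
on the *unnormalized* sum for the same consistency reason.  The score
$W/k$ is compared against a strict 0.01 threshold — one saturated
comorbidity in a hundred.  The top enriched proteins feed a one-sided
hypergeometric over-representation test against user-supplied GMT gene
sets over the protein universe.  This ORA is a declared surrogate for
web-service pathway analysis: it is the standard test a practitioner would
run locally, not a re-implementation of any service's internal statistic.

## Benchmarking against claims data

Clinical co-occurrence counts $(n_A, n_B, n_{AB})$ over a cohort of
$n_{tot}$ patients give

$$\log RR = \ln \frac{n_{AB}/n_{tot}}{(n_A/n_{tot})(n_B/n_{tot})}, \qquad
\varphi = \frac{n_{AB} n_{tot} - n_A n_B}
               {\sqrt{n_A n_B (n_{tot}-n_A)(n_{tot}-n_B)}}.$$

The log base is natural; labels are sign-based so the choice affects scale
only (and $\mathrm{sign}(\varphi) = \mathrm{sign}(\log RR)$ algebraically,
which the suite verifies by sweep).  A pair is a true positive when
$\log RR > 0$ and predicted positive when $q < 0.05$.  The benchmark
reports recall and precision (percent), Pearson correlations of $J$ with
$\log RR$ and $\varphi$, AUROC (Mann–Whitney rank statistic, ties counted
half) and AUPRC (step-wise summation over tied-score blocks), with $J$ as
the continuous ranking variable.  Records with $n_{AB} = 0$ are excluded
($\log RR$ undefined), as are *easy pairs*: pairs whose efficacious drug
sets overlap by more than 0.9 under $|A \cap B|/\sqrt{|A||B|}$, whose
comorbidity is trivially implied rather than predicted.

Two permutation nulls re-run the whole pipeline on perturbed inputs:
reassigning whole target sets among drugs (drug–protein) or whole score
rows among drugs (drug–disease), each a uniform random bijection so the
marginal structure is preserved exactly.  Per metric the null mean and sd
over `n_permutations = 100` seeded runs give
$z = (\mathrm{obs} - \mu_0)/\sigma_0$ and a one-sided upper-tail normal p.
Sidedness is deliberate: a two-sided p would not reproduce the arithmetic
of published permutation rows of this form.  Runs in which a metric is
undefined (for example a constant J-score vector after permutation, where
a correlation does not exist) are recorded as NA and dropped from that
metric's null, with the count of defined runs reported.

**A known divergence.**  In the original formulation of the drug–protein
test, the upstream indication predictor is re-applied after permuting the
target map, which leaves residual disease–protein signal and makes that
null visibly milder than the drug–disease null.  The upstream predictor is
out of scope here, so both permutations propagate through this package's
own pipeline only — and inside this pipeline they destroy the
disease-to-protein link symmetrically.  Consequently the package does
*not* promise an ordering between the two nulls' recall; what it verifies
is that both destroy the planted signal (the observed J–log RR correlation
sits many null standard deviations above either null).

## The synthetic world

`generateWorld()` builds a complete, deterministic test bed from a seed:
planted per-disease protein modules, a drug library whose target sets are
biased toward disease modules, raw scores
$\delta \cdot |t_d \cap M_D| / |t_d| + \mathcal{N}(0, \sigma^2)$, claims
counts with planted relative risk, a uniform-random tissue table, and a
GMT collection of the planted modules plus decoys.

The defaults are the package's standard study conditions: 300 drugs, 2000
proteins, 40 diseases, module size 25, $\delta = 3$ against unit noise,
8 planted comorbid pairs sharing exactly half their modules, a cohort of
$10^6$ patients with prevalence uniform in (0.01, 0.05) and planted
relative risk 5.  The free design choices — 25 targets per drug with 80%
drawn from the drug's dedicated disease module, drugs dedicated
round-robin — emulate a probe library developed against disease-relevant
targets and were fixed by a power calculation before any test ran: with
~7.5 dedicated drugs per disease, a module protein is covered by ~6 of
them, enough drugs land in the efficacious partition that the one-sided
Fisher test recovers the protein at $p < 0.05$ with high probability.
The test suite verifies, at seed 1, MOA recall of planted modules ≥ 90%
and an AUROC ≥ 0.9 for separating planted from unplanted pairs.

What the generator deliberately does not emulate: realistic pharmacology
(target counts, promiscuity distributions), correlated score noise across
indications, ontology structure among diseases, or histologically coherent
tissue expression (levels are uniform-random draws).  Passing tests
therefore demonstrate that the statistical machinery recovers planted
signal under controlled conditions, not that predictions on real
predictor outputs reach any particular accuracy.

## Numerical choices

- p-values are clamped to $10^{-320}$ before any logarithm, so enrichment
  weights stay finite down to the smallest representable p.
- Hypergeometric, binomial and normal tails are evaluated in log-gamma /
  log space (`phyper`, `pbinom`, `pnorm`), exact to machine precision;
  the suite cross-checks them against direct combinatorial enumeration
  for every feasible table with $N \le 60$ and against an independent
  `erfc` evaluation.
- q-values use the Storey estimator with the $\lambda$ grid
  $0.05, 0.10, \dots, 0.95$ and a cubic smoothing spline (df = 3)
  evaluated at $\lambda = 0.95$; with fewer than 100 p-values, or a
  $\hat\pi_0$ outside (0, 1], it falls back to Benjamini–Hochberg
  ($\pi_0 = 1$), which keeps small families well defined.
- Degenerate inputs have documented conventions: an all-zero Fisher table
  returns p = 1; a pair with an empty MOA profile carries J = 0, p = 1;
  the Jaccard index of two empty sets is 0; an indication with zero score
  variance or an empty efficacious partition yields an empty profile with
  a warning rather than an error.
- All rankings break ties deterministically (J descending, then
  lexicographic identifier), so every output is byte-stable for a fixed
  seed.
- Network analytics use unweighted shortest paths.  Closeness is the
  number of reachable nodes divided by the sum of hop distances (within
  the node's component; 0 for isolates) rather than any library's
  normalised variant; betweenness uses standard equal-split counting over
  equally short paths.

## Problem sizes in the test suite

The suite runs the full default world (40 diseases, 780 pairs) once and
both permutation nulls at 100 runs each; property sweeps use
$10^4$ count quadruples, exhaustive tables to $N = 60$, and Monte-Carlo
overlap nulls of $10^5$ draws on 20 small instances.  These sizes were
chosen so the statistical assertions have real power while the whole
suite stays comfortably interactive.

## Limitations

- Upstream predictions (drug indication scores, drug–target maps) are
  inputs; the package neither produces nor audits them, and garbage in
  means garbage out.
- Identifiers are opaque strings: no ontology mapping, no isoform
  handling.  Whether the universe counts genes or isoforms is decided by
  the universe file the user supplies.
- The pathway test ignores pathway topology and hierarchy.
- Comorbidity here is population-level sharing of molecular drivers; it
  can nominate pairs (e.g. sex-specific disease pairs) that cannot
  co-occur in one individual.
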