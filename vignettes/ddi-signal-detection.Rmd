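---
title: "Methods: frequency-statistical DDI signal detection for a rare adverse event"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-statistical DDI signal detection for a rare adverse event}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdpddi)
```

## The problem and the data model

Torsades de pointes (TdP) is a rare, potentially fatal ventricular
arrhythmia that is frequently drug-induced, and frequently the product of
*combinations* of QT-prolonging drugs rather than any single agent.
Spontaneous reporting systems (FAERS and its analogues) are the main
post-marketing window onto such events: each report lists the drugs a
patient received, each with a role code (PS primary suspect, SS secondary
suspect, C concomitant, I interacting), the adverse-event preferred terms
(PTs), and reporter demographics. `tdpddi` treats a report as exactly that
tuple; PTs are opaque strings (no MedDRA hierarchy), one report is one
case, and cross-report deduplication is assumed to have happened upstream.

Counting conventions, fixed once and used everywhere:

* a report's exposure set is its **deduplicated** drug-name set (a drug
  listed under two role codes counts once); names are normalized by
  trimming, whitespace collapsing and case-folding only — trade-name to
  generic mapping is out of scope by design, though a user-supplied synonym
  table is honored by `read_reports()`;
* by default every role code counts as exposure; `restrict_to_role()`
  supports subset analyses (e.g. role I only);
* reports with no drug entry carry no exposure information and are
  excluded from every contingency denominator *N*;
* a case is any report listing the target PT (`mark_cases()`, default
  `10044066`).

## The four models and their shared substrate

All pair statistics are computed from the 4×2 table $n_{ijk}$
($i$: drug-1 exposure, $j$: drug-2 exposure, $k$: event), produced
sparsely by `eligible_pairs()`: candidate pairs are generated only from
drugs co-occurring within case reports (any pair with $n_{111} \ge 1$
co-occurs in a case report, so the sparse scan is exhaustive), after a
drug-level screen keeping drugs present in at least `min_drug_cases` case
reports. Both thresholds default to 3, the conventional minimum-case rule
for this family of screens; both are configuration, not constants.

**No-interaction baseline.** The expected co-exposed event proportion
$g_{11}$ is built from shrunk stratum proportions
$g_{ij} = (n_{ij1}+0.5)/(n_{ij+}+0.5)$ (the +0.5 guarantees positivity in
empty-event strata). The default combination rule is additive on
$h(f) = 1/(1-f)$:

$$\frac{1}{1-g_{11}} = \frac{1}{1-g_{10}} + \frac{1}{1-g_{01}} - \frac{1}{1-g_{00}},$$

the interaction-surveillance baseline of the shrinkage observed-to-expected
literature. For rare events ($f \ll 1$) it reduces to the risk-additive
prediction $g_{11} \approx g_{10}+g_{01}-g_{00}$ while remaining bounded
in $[0,1)$ for any input. When the right-hand side is $\le 1$ (possible
only when the background stratum is riskier than both single-drug strata)
the baseline falls back to $\max(g_{10}, g_{01})$ and says so
(`fallback_used`). Two alternative variants are selectable throughout
(`variant=` in `no_interaction_baseline()`, `run_all_models()`,
`run_pipeline()`): `reciprocal`, additive on $1/f$, and `max`. The
reciprocal variant is provided because this family of methods circulates
in several algebraic forms; note that it is qualitatively different — for
two drugs with individual relative risks $r_1, r_2$ it is undefined
whenever $1/r_1 + 1/r_2 \le 1$ (e.g. two 3-fold-risk drugs), always
falling back to `max` there, which makes purely multiplicative joint risks
look like interactions. The default was chosen precisely because it does
not have that pathology and reproduces the Ω model's documented
conservatism; swapping variants is a one-argument change and the variant
used is recorded in the run manifest.

**Ω shrinkage measure.** $\Omega = \log_2\frac{n_{111}+0.5}{E_{111}+0.5}$
with $E_{111} = g_{11} n_{11+}$, and the closed-form lower credibility
bound $\Omega_{025} = \Omega - 3.3\,n_{111}^{-1/2} - 2\,n_{111}^{-3/4}$.
Signal: $\Omega_{025} > 0$ and $n_{111} \ge 3$. The +0.5 shrinkage always
pulls $\Omega$ toward zero relative to the raw ratio, and $\Omega_{025}$
is monotone in $n_{111}$ at fixed expectation (both property-tested).

**Signed Yates chi-square.** One-sample test of the co-exposed split
$(n_{111}, n_{110})$ against $(E_{111}, n_{11+}-E_{111})$ — the *same*
baseline as Ω — with continuity term $\max(|n_{111}-E_{111}|-0.5,\,0)$,
reported as a signed square root so the $\chi > 2$ criterion is one-sided
for excess risk. Requires $0 < E_{111} < n_{11+}$; otherwise the pair is
not evaluable under this model.

**Combination risk ratio.** PRRs of the co-exposed and single-drug strata
against the neither-drug reference stratum, with
$CRR = PRR_{combo}/\max(PRR_{10}, PRR_{01})$ isolating risk beyond the
stronger single drug, and a Yates chi-square of
$[[n_{111}, n_{110}],[n_{001}, n_{000}]]$. A +0.5 continuity correction is
applied to the ratio-defining cells only when the reference stratum has
zero events. Signal: $PRR_{combo} > 2$, $\chi^2 > 4$, $CRR > 2$,
$n_{111} \ge 3$.

**Additive model.** The interaction contrast
$p_{11}-p_{10}-p_{01}+p_{00}$ on raw (unshrunk) proportions, flagged when
strictly positive. Deliberately no variance term: this is the criterion as
used in this screening tradition, and its over-detection (half of all
truly null pairs sit above zero; purely multiplicative joint risks always
do) is a *feature being studied*, not a defect to repair.

**Three-valued flags and consensus.** Each model returns flagged / not
flagged / not evaluable (`NA`), the last when a required stratum is empty
or an expectation degenerate; a consensus signal requires all four models
evaluable and positive. Strict inequalities are evaluated exactly as
written, with no epsilon: the thresholds (0, 2, 4) sit far above
floating-point error for counts below $10^8$.

**Single-drug ROR.** $(a d)/(b c)$ with Haldane–Anscombe +0.5 on all four
cells when any cell is zero, log-normal 95% CI, signal at ROR > 2, CI
lower bound > 1, $a \ge 3$.

**Agreement.** For each of the six model pairs, flags are compared over
the pairs evaluable under *both* models (complete-case per model pair;
exclusion counts reported). $\kappa = (p_o-p_e)/(1-p_e)$ with the
large-sample CI $\kappa \pm 1.96\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$, plus the
proportionate agreements $P_{pos} = 2a/(2a+b+c)$,
$P_{neg} = 2d/(2d+b+c)$. The CI is the standard normal approximation,
unclipped (it may exceed 1, as published upper bounds in this literature
do); interpretation bands are slight/fair/moderate/substantial/excellent.

**Verification.** Detected pairs (all-four consensus by default; `any`
relaxes) are labeled by compendium indexing status
(Lexicomp-style X/D/C/B classes, Drugs.com-style Major/Moderate/Minor —
vocabularies validated, never ordered). A **negative DDI** is a pair
indexed by *both* sources, evaluable under all four models with
$n_{111} \ge 3$, and flagged by none: evaluability is required because
"not detected" is meaningless for pairs never assessable. Funnel counts
partition the detected set exactly (asserted on every run).

**Demographics.** Case counts by sex, age band (0–19, 20–39, 40–59,
60–79, ≥80, unknown; lower bound inclusive), worst outcome per report
(death > life-threatening > disability > hospitalization > required
intervention > other > unknown — one severity per case so the column sums
to the case total), reporter type and country, with percentages rounded
half-up to one decimal (display-style rounding; `percentage()`), plus
derived older-than-60 and nonprofessional (consumer + lawyer) rows.

## The synthetic-report generator

`generate_reports()` emulates the features of a spontaneous-reporting
database that the statistics actually react to:

1. per-drug exposures drawn independently from marginal probabilities,
   then a co-prescription boost: for each designated pair with exactly one
   member present, the partner is added with probability `corx_boost`
   (correlated co-prescription without correlated risk);
2. event probability
   $\min(0.99,\; b \prod_{\text{exposed}} r_d \prod_{\text{co-exposed pairs}} m_p)$
   — multiplicative single-drug risk multipliers $r_d$ and an explicit
   interaction multiplier $m_p$ ($m_p = 1$: no interaction, the joint risk
   is exactly multiplicative; $m_p < 1$: antagonism). Keeping single-drug
   and interaction effects separate is what lets tests target each model's
   intended null: "both drugs risky, no interaction" is representable
   exactly;
3. cases receive the target PT (sometimes plus a background PT),
   non-cases background PTs; one random exposed drug is coded PS, the
   rest C, and co-exposed designated pairs on case reports are recoded I
   with probability 0.5, so role-restricted analyses have material;
4. demographics from configurable categoricals whose defaults follow the
   published case profile of TdP reporting (55.7% female, 93/7
   professional/nonprofessional reporter mix, 41% US);
5. draws with no exposed drug are discarded (drug-less spontaneous
   reports do not exist), and the whole stream is reproducible from one
   seed.

`expected_event_prevalence()` returns the exact conditional expectation of
the event rate under this model (factorizing over independent drug
blocks), used as a binomial oracle in the tests.

What the generator does **not** emulate: duplicate reports, reporting
trends over time, notoriety biases, missing-not-at-random demographics,
trade-name aliasing, and higher-order (3+ drug) interactions. Passing
tests therefore demonstrate that the statistics and plumbing behave as
specified on data whose generating process is known — not that signals
from real reporting data are causal, which no disproportionality method
can establish.

## The published benchmark

`benchmark_default()` is the fixed configuration used by the acceptance
tests and `scripts/acceptance.R`: 200,000 draws, baseline event
probability $5\times10^{-3}$, 60 drugs with log-spaced exposure
probabilities in $[0.002, 0.05]$, and four kinds of planted ground truth
(all pairs with boost 0.3): 5 synergy pairs (inert drugs, $m=8$), 5
no-synergy risk pairs (both members $r=3$, $m=1$), 5 pure co-prescription
pairs (all multipliers 1), and one antagonistic negative-DDI control
(both members $r=3$, $m=0.4$) indexed by both sources in the matching
`benchmark_reference()` table.

Design choices that were genuinely open, and how they were fixed:

* **Exposure tiers.** Exposure probabilities are assigned to blocks
  deterministically rather than at random: risk pairs at the low end
  (specialist high-risk drugs are prescribed rarely), synergy pairs
  mid-range, the negative-DDI control at the high end (the
  amiodarone/sotalol analogue: widely used antiarrhythmics). This keeps
  each planted phenomenon in the count regime where it is diagnostic —
  no-synergy pairs at $n_{111} \approx 10\!-\!25$ where the Ω bound should
  hold them back, the control at $n_{111} \approx 100$ where "flagged by
  nothing" is sampling-robust.
* **Why the negative-DDI control is antagonistic.** A no-interaction pair
  of risky drugs is *correctly* flagged by the CRR and (usually) additive
  models, because its joint risk is multiplicative; a pair that no model
  flags while being compendium-indexed — the alert-fatigue phenomenon —
  requires joint reporting at or below the additive prediction, i.e.
  $m < (r_1 + r_2 - 1)/(r_1 r_2)$. $m = 0.4$ sits safely below that bound
  (≈ 0.56 at $r_1=r_2=3$).
* **Why co-prescription null pairs exist.** The additive model's
  over-detection operates on pairs with no risk elevation at all; without
  co-prescribed null pairs reaching $n_{111} \ge 3$ there would be nothing
  for it to over-detect at this scale.

Desk-scale operating characteristics worth knowing: with $n_{111}$ mostly
in the tens, the Ω credibility penalty is large, so Ω flags markedly fewer
pairs than the chi-square criterion and the Ω-vs-chi κ, while the largest
of the κ's involving Ω, is not near 1 as it is at database scale where
$n_{111}$ is big enough for the two shared-baseline criteria to coincide.
Problem sizes throughout (200,000-draw benchmark; 200–260-report,
30–35-drug oracle fixtures with 100 repetitions) were chosen as the
smallest at which every planted phenomenon is sampling-robust.

## Degenerate inputs and determinism

Empty collections, all-false case flags, absent drugs, empty strata,
constant raters and empty reference files all return well-defined empty or
not-evaluable results rather than errors (errors are reserved for schema
violations, unknown vocabulary values and conflicting demographics).
Unordered pairs are canonicalized by lexicographic sort of normalized
names; every statistic is invariant under the swap (property-tested).
`run_pipeline()` records thresholds, formula variants, input hashes and
the seed in a YAML manifest; re-running with the same manifest inputs
reproduces byte-identical outputs, and the sensitivity re-analysis
(excluding nonprofessional reporters) re-runs the identical configuration
on the filtered collection.

## Limitations

The limitations of the method travel with the package: signals are
statistical associations in biased, incomplete reporting data, not causal
claims; confounding by co-prescription produces consensus signals for
innocent bystander pairs (visible even in the README example); trade-name
aliasing inflates pair counts unless a synonym table is supplied; and the
additive model's criterion guarantees over-detection by construction. The
agreement CI uses the standard large-sample approximation, which is one of
several in circulation; point estimates are the comparable quantities.
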