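---
title: "Stratified ADE screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified ADE screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adescreen)
```

## The problem

Spontaneous reporting systems (SRS) such as JADER or FAERS accumulate
voluntary reports of suspected drug–adverse-event pairs. Disproportionality
statistics — here the proportional reporting ratio (PRR) used by the MHRA —
flag a drug–event pair when the event is reported disproportionately often
among reports mentioning the drug. Patient background matters: a drug may be
risky specifically in patients with impaired kidney or liver function, because
both organs shape drug elimination. Conditioning on a primary disease,
however, multiplies the number of 2×2 tables to build, which is why a cheap
first-pass screen is attractive.

`adescreen` implements that screen as association-rule (AR) mining over
report-level transactions. Each report is a transaction whose items are its
drugs, its primary-disease history terms, and its adverse-event preferred
terms. For the rule *A ∩ B → C* (drug A, disease stratum B, event C) it
computes, from the count vector of the triple:

* support(C) = `n_+1 / n_++` — event prevalence over the **whole** database;
* confidence = `n_AB1 / n_AB+` — event rate among A-exposed reports in B;
* **lift** = confidence / support(C), 1 under independence;
* **conviction** = (1 − support(C)) / (1 − confidence), 1 under independence
  and +∞ when confidence is 1.

The conventional comparator is the stratified PRR with Yates-corrected χ²,
computed **inside** stratum B only:

* PRR = `(n_AB1/n_AB+) / (n_B1/n_B+)`;
* χ² = `N (|n_AB1·n_B2 − n_AB2·n_B1| − N/2)² / (n_AB+·n_B+·(n_AB1+n_B1)·(n_AB2+n_B2))`,
  `N = n_AB+ + n_B+`.

Note the asymmetry, which is deliberate and kept: the AR baseline spans the
whole report universe, while the PRR baseline is stratum-restricted. Both
baselines are carried in one `triple_counts` row so each statistic uses its
own.

Signal criteria are taken as printed in the pharmacovigilance literature and
are *not* symmetric in strictness:

* AR signal: rule count `n_AB1` ≥ 3 (non-strict) **and** lift > 1 **and**
  conviction > 1 (both strict — lift exactly 1 is independence, not a signal);
* PRR signal: rule count ≥ 3 **and** PRR ≥ 2 **and** χ² ≥ 4 (all non-strict,
  so a triple at exactly (3, 2.0, 4.0) is a signal).

## Counting rules and numerical choices

* The counting unit is the report: an item listed twice in one report counts
  once. Published pair totals are read as counts of distinct pair *types*,
  which keeps support(C) well defined.
* Candidate generation is apriori-pruned: a drug or event whose own support
  inside the stratum is below the rule-count floor can never head a frequent
  triple, so its co-occurrences are never scanned. The mined output is
  provably identical to exhaustive enumeration (tested, bitwise).
* Conviction at confidence 1 is +∞ and counts as "above any threshold"; the
  source material is silent on this division by zero, and +∞ is the standard
  limit reading.
* χ² tables whose continuity correction `N/2` exceeds `|n_AB1·n_B2 −
  n_AB2·n_B1|` are clamped to 0 rather than squared into a spurious positive
  — the same convention as `stats::chisq.test(correct = TRUE)`, which serves
  as the independent oracle in the tests.
* PRR with an empty comparator (`n_B1 = 0`, or no unexposed stratum reports)
  is *undefined*: it becomes `NA` with a warning, is never a signal, and is
  excluded from ROC and regression rather than replaced by a sentinel.
* Signal intensity is `log10(PRR) + log10(χ²)`. Base 10 is a convention: a
  different base rescales the regression slope but leaves R² and the slope's
  sign unchanged, so every acceptance property is base-invariant.
* All statistics are computed in double precision with no rounding before
  threshold comparison.

## The evaluation protocol

Taking the PRR signal set as reference — a methodological comparator treated
*as if* true, explicitly not biological truth — the AR detector is scored per
stratum with sensitivity, specificity, Youden's index, PPV and NPV over the
candidate universe (every triple with `n_AB1` ≥ 1 by default; configurable).
The ROC sweeps the decision threshold over the lift value after applying the
rule-count ≥ 3 gate (triples below the gate can never be AR signals, so they
are not rankable candidates; conviction ranking is available behind
`roc_score`). AUC is trapezoidal, which the tests prove equal to the
Mann–Whitney pairwise-concordance estimate with ties counted ½, to 1e-12.
The correlation of the two signal scales is an OLS fit of `log10(lift)` on
`log10(PRR) + log10(χ²)`, restricted to triples where all three quantities
are positive and finite. No optimal cut-off is estimated.

## The synthetic world

Real SRS extracts and the MedDRA/SMQ term lists that define disease strata
are licensed and cannot ship here, so every end-to-end claim is made on a
synthetic world with known ground truth. The generator draws, per report,
each drug and each history term independently with its catalog probability;
each event fires with its baseline probability unless the report carries an
injected triple's drug and history term, in which case the baseline is
multiplied by that triple's relative risk ρ (largest applicable ρ wins).
Independence everywhere except the injected triples is the minimal structure
both detectors assume; drug–drug and event–event correlation, age/sex
confounding, reporting bias and underreporting dynamics are deliberately out
of scope.

The packaged default (`default_sim_config()`) mirrors a deduplicated
oral-route national-SRS extract at one-tenth scale, and its values were
chosen once, before the concordance tests were run:

* 18,000 reports (one tenth of ≈180k analyzable cases);
* two single-term disease strata, "kidney injury" at 10% prevalence and
  "liver injury" at 12.5% — the kidney/liver case fractions of such
  extracts — plus three common comorbidity terms as background noise;
* 40 drugs and 50 event preferred terms with log-spaced marginal
  probabilities (0.002–0.10 and 0.001–0.020): SRS item frequencies are
  heavily long-tailed, and that sparsity is what makes most candidate
  triples rare and both detectors' count gate meaningful;
* 5% of the drug × stratum × event triples injected, ρ drawn uniformly from
  the integers 2..10 (so ρ = 10 exists exactly, for the recovery property).

What a green concordance test establishes: on data satisfying the two
detectors' shared assumptions, AR screening with (count ≥ 3, lift > 1,
conviction > 1) recovers essentially every PRR signal (sensitivity ≈ 1),
keeps Youden's index above 0.8, ranks PRR signals with AUC above 0.9, and
its lift scale correlates with the PRR intensity scale (positive slope,
R² ≥ 0.5) — the same qualitative picture as the full-scale published
comparison. What it does not establish: behaviour under confounding,
correlated reporting, or real term vocabularies; and AR's excess signals
(the ≈13–16% of null candidate triples it flags, versus ≈2–4% for PRR)
are hypotheses, not detections of truth — on null-only simulations that AR
flag rate is monitored in the tests with a documented 0.25 ceiling.

## Design choices where the design was open

* **Dedup rule**: the case-identifier column is the key; the first
  occurrence in file order wins. Real extracts version their cases; a
  follow-up-aware dedup belongs to the data owner, not this screen.
* **Drug roles**: suspect and concomitant drugs are both counted by default
  (`role_allow = NULL`), with an allow-list override, since the published
  choice is unstated. Route filtering defaults to the oral allow-list.
* **Candidate universe** for specificity/NPV: all triples with `n_AB1` ≥ 1,
  configurable via `universe_min_count`, since the published denominator is
  not defined.
* **ROC ranking variable**: lift (the AR quantity actually thresholded);
  conviction available behind a flag, as the published thresholding variable
  for the curve is unstated.
* **Regression orientation**: `log10(lift)` as response, intensity as
  regressor; R² and the slope's sign — the only properties asserted — are
  orientation- and base-invariant.
* **Term matching** is exact string equality after whitespace trimming; no
  MedDRA hierarchy, narrow/broad SMQ scopes, or translation (out of scope,
  term lists are user-supplied).

## Limitations

Only single-drug antecedents and single-event consequents are mined; the
reference detector is itself a screen, so all agreement metrics compare two
hypotheses, not a hypothesis with truth; and the synthetic world's
independence assumptions make it a correctness harness, not an
epidemiological simulator.
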