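---
title: "Methods: disproportionality, PCA and clustering of GI-ulcer signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, PCA and clustering of GI-ulcer signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gisignal)
```

## The data model

Spontaneous-report databases in the FAERS quarterly format distribute each
report across linked `$`-delimited tables; this package consumes DEMO
(demographics), DRUG (drug mentions with routes) and REAC (event mentions
as MedDRA preferred terms, PTs), joined on the report id. Two cleaning
conventions matter and are applied by `merge_and_deduplicate()`:

* **Case versioning.** A case may be re-submitted in revised form; revisions
  share a case id and carry a larger report id. Only the numerically
  greatest report id per case is kept. The database does not document its
  deduplication key, so this standard versioning convention is the
  package's choice; it is deterministic and matches how the quarterly files
  are organized.
* **Mention collapsing.** Within a report, repeated (drug, route) rows and
  repeated PT rows are collapsed to sets, so a drug or event counts once
  per report regardless of how many lines mention it.

The analysis table is then restricted to cases with at least one orally
administered drug. The restriction is *report-scoped* (a case qualifies if
any mention is oral, and keeps all its mentions) because the underlying
inclusion criterion is about cases, not mentions; a mention-scoped variant
is available via `filter_oral(mention_level = TRUE)` for sensitivity
analysis. Drug names are standardized to generics through a user-supplied
mapping file (`read_name_map()`); the commercial curation used on the full
database is not redistributable, so unmapped names either pass through
lower-cased or are dropped, and are always logged. Ages are converted to
years from the quarterly unit codes (YR, MON, WK, DY, HR, DEC); a missing
unit is assumed to be years with a warning, and unparseable or negative
values become missing. Drug role codes (suspect/concomitant) are read but
do not restrict exposure: exposure is defined by the drug being mentioned
in the report.

## The disproportionality model

For an index drug D and event PT set E, reports are cross-classified as

|              | event        | no event |
|--------------|--------------|----------|
| D mentioned  | a            | b        |
| D absent     | c            | d        |

and the reporting odds ratio is ROR = (a/b)/(c/d) — a *reporting*
association measure, not an incidence ratio, since spontaneous databases
have no denominator of users. Conventions, each with its rationale:

* **Haldane correction** (+0.5 to all four cells) is applied before the ROR
  and its interval so that estimates stay finite with zero cells. It is
  *not* applied before the Fisher test, which is undefined on non-integer
  cells; at stratum scale (cells of 10⁴–10⁷) the correction moves the third
  decimal of nothing, so the two conventions are observationally
  indistinguishable on the large tables and the choice only matters for
  sparse pairs.
* **Woolf interval**: exp(lnROR ± z·√(1/a+1/b+1/c+1/d)), z = qnorm(0.975) ≈
  1.959964. This reproduces the published stratum intervals to all printed
  decimals.
* **Fisher two-sided p**: the minimum-likelihood convention — the sum over
  the hypergeometric support of all point probabilities not exceeding the
  observed one, with 1 + 1e−7 relative slack, matching the dominant
  software convention. Probabilities are evaluated with log-gamma and
  summed in log space. For support sizes above `max_support` (default 10⁶,
  which already covers full-database margins) a Haldane-corrected Wald test
  on the log odds ratio is substituted and flagged in the result; the
  threshold is configurable for sensitivity analysis because the exact
  convention used at scale by commercial statistics packages is not
  published.
* **−log₁₀ p is capped at 308**, the point at which double-precision
  p-values underflow; p = 0 maps to the cap.
* **Volcano labeling**: lnROR ≥ 1 and −log₁₀ p ≥ 1.3 (p < 0.05).

One orientation subtlety is worth recording. In the published stratum
table, recomputation from the printed counts shows that the ROR of 0.947
corresponds to the *female*-index orientation and 0.774 to the
*under-70*-index orientation — the reciprocal of what the row order
suggests. The stratum API therefore takes an explicit index group, and
`demographic_report()` emits both orientations. The printed age-stratum
ROR also appears to be truncated rather than rounded: the counts give
0.7746, which rounds to 0.775; the interval (0.766–0.784) reproduces
exactly.

## Cohort selection

Events: PTs from the GI-ulcer catalog with ≥1000 reports (inclusive
threshold). The shipped catalog carries the 21 terms that pass this screen
in the full database; the licensed 83-term standardized query cannot be
distributed, so the catalog accepts a user term file. Drugs: total report
count strictly >1000 *and* at least one pair p < 0.05. Sites: upper GI is
oral cavity through duodenum, lower GI jejunum through anus, terms without
anatomical wording are `not_classified`. The shipped site map classifies
13 terms upper, 3 lower, 5 not classified; "Peptic ulcer" (anatomically
gastric/duodenal) is mapped upper and "Intestinal ulcer" (ambiguous between
small and large bowel) not classified — both are judgment calls on the
anatomical rule and overridable via the catalog file.

## PCA and clustering

The selected events × drugs lnROR matrix (events as observations, drugs as
variables — drugs get loadings, events get scores) is decomposed by PCA on
the *correlation* matrix, i.e. each drug column standardized; this makes
the result invariant to per-drug scale and means eigenvalues sum to the
number of drugs. Percent variance is 100·λᵢ/p with p the number of drugs,
even when there are fewer events than drugs (the omitted eigenvalues are
exactly zero). Scores are standardized to unit variance; loadings are the
correlations between components and drug columns (bounded by 1). Because
eigenvector signs are arbitrary, each retained component is flipped so its
largest-|loading| drug loads positively — a pure reporting convention that
makes runs byte-reproducible. Three components are retained by default,
matching the three interpreted axes (overall risk, severity, injury site);
`n_retain` is configurable.

Per-event scores on a chosen component are compared between upper and
lower site groups with a two-sample t-test, pooled-variance Student form by
default (the source analysis says only "t-test"; Welch is a switch). Drugs
are then clustered on their retained loading rows with Ward's
minimum-variance linkage (`ward.D2` on Euclidean distances, the
squared-Euclidean update). The published rule for the cluster count — "the
point at which the slope of the distance graph increases rapidly" — is
operationalized as the k (2..k_max) maximizing the ratio of successive
top-down merge heights, ties toward smaller k, with k = 1 and a warning
when all heights are equal. This formalization is the package's
own interpretation of the verbal rule; it is validated by exact recovery of
planted structure rather than taken as the only possible reading.

## The synthetic generator

`generate_reports()` draws, per report, independent Bernoulli drug
exposures x and then each event independently with probability
plogis(base_logit + Σ β·x); β is the injected log odds ratio matrix
(optionally low-rank, β = u·vᵀ). With a single exposure and no other
covariates the marginal ROR equals exp(β) exactly, which is what the
recovery tests exploit. Demographics (56% female / 37% male / 7% unknown,
ages 60% Uniform(20,69) / 30% Uniform(70,95) / 10% missing — both matching
the broad composition of large spontaneous-report databases), duplicate
case versions, and non-oral routes are layered on top at configured rates
and do not feed back into the event model.

What the generator deliberately does **not** emulate: drug co-prescription
correlation, event-event dependence beyond shared drug effects,
reporting-dynamics biases (notoriety, Weber, masking), dose, and
indication. Passing tests therefore demonstrate correctness of the
*computations* under a clean reporting model, not robustness to the
reporting biases of real spontaneous data.

Three canonical designs (`scenario_null()`, `scenario_recovery()` /
`scenario_single_signal()`, `scenario_planted_clusters()`) fix the study
conditions used across the tests and the analysis workflow: a 30×10 null
design at 50,000 reports for type-I error (nominal 5%) and Woolf coverage
(nominal 95%); a 12×12 diagonal-β design (each event driven by exactly one
drug, so the marginal ROR is exactly exp(β) and error is pure sampling
noise) at 20k/80k/320k reports for consistency; and a 12-drug/9-event
three-block design (β = 1.6, 60,000 reports, duplicates and non-oral routes
on) that the full pipeline must recover blind — which it does with
adjusted Rand index 1 and an elbow-selected k of 3.

## Numerical and degenerate-input choices

* All-zero contingency tables Haldane-correct to a symmetric table with
  ROR exactly 1; correcting twice is an error, as is Fisher on corrected
  cells or a Woolf interval with a zero cell.
* The Fisher implementation is checked against full enumeration on every
  2×2 table with margins ≤ 40 (about half a million tables) to 10⁻¹²
  relative error, and against `stats::fisher.test` on random tables.
* Zero-variance drug columns make the correlation undefined and are a hard
  error naming the drug, rather than being silently dropped.
* Cluster labels are renumbered by decreasing cluster size (ties by first
  member name) so labelings are comparable across runs.
* All randomness flows from the single seed in the simulation config; the
  generator restores the caller's RNG state.

## Limitations

Beyond the generator simplifications above: the ROR is not an absolute
risk and pairs are not multiplicity-corrected (the selection rule uses raw
p < 0.05, as in the source analysis — with 10⁸-scale report counts the
Fisher p-values underflow for genuine signals, so correction would not
change selections materially); the shipped 21-term catalog is a subset of
the licensed terminology; and name normalization is exact-match only, so
the quality of a real-data run depends on the supplied mapping file.
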