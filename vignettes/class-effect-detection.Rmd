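---
title: "Detecting drug-class adverse event effects from literature co-mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drug-class adverse event effects from literature co-mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Some adverse drug events (ADEs) are properties of a whole pharmacologic
class — myopathy with statins, tendon injury with fluoroquinolones — while
others belong to individual drugs within a class. Telling the two apart
matters: a class effect changes prescribing decisions for every member,
including members with little direct evidence. classfx implements a
literature-based workflow for making that distinction at scale:

1. extract per-article drug and ADE mentions from indexed citation records,
2. normalize drug terms to ingredients and aggregate them into ATC-style
   classes; aggregate ADE terms to second-level hierarchy classes,
3. compute disproportionality signals (PRR) at drug and class resolution,
4. for each (drug class, ADE) pair, partition the members' log-PRRs into
   two clusters and test whether the cluster means differ — if they do not
   (or only one cluster exists), all members contribute to the signal and
   the pair is called a class effect.

```{r}
library(classfx)
```

## Extraction model

The input is a corpus of citation records: an article identifier plus
(descriptor, qualifier-set) annotations, the information structure of
MEDLINE's MeSH indexing, serialized as JSON-lines. A descriptor counts as a
**drug mention** when it maps to a known ingredient and carries a drug-role
qualifier (default `"AE"`, *adverse effects*). It counts as an **ADE
mention** when it is a known manifestation term and either carries a
manifestation-role qualifier (default `"CI"`, *chemically induced*) or is
inherently indicative of an adverse event (e.g. a drug-induced liver injury
heading), regardless of qualifiers. Both qualifier sets and the inherent
list are configurable in `extraction_rules()`.

Within an article, every drug mention is paired with every ADE mention (the
standard co-mention convention; the indexing does not link specific drugs
to specific manifestations). Descriptors unknown to both vocabularies are
ignored rather than rejected, since real indexing is dominated by headings
irrelevant to pharmacovigilance.

## Terminology normalization

Drug terms resolve to ingredients through a term table followed by the
precise-ingredient map (salts and esters resolve to their active moiety:
a valproic-acid term resolves to the valproate ingredient). The map is
transitively closed at load time, and cycles are construction errors. Class
membership is the union over all of an ingredient's codes — a drug coded
both systemically and topically (ofloxacin-style) is a member of both
classes — and is deduplicated by ingredient, never by code.

ADE terms carry dot-separated tree numbers; each is truncated to its first
two components, and the term owning that prefix is the ADE class (terms
under `C05.651` roll up to the muscular-diseases class). A term with
several tree numbers contributes to all of its second-level classes; a term
already at the second level (or above) aggregates to itself.

Classes with fewer than `min_members = 4` observed member ingredients are
dropped: with fewer members, a within-class homogeneity comparison is not
meaningful. The threshold is exposed as configuration.

## Signal model

All counting happens over the **analysis universe**: articles with at least
one drug mention and at least one ADE mention. The universe definition is a
package design choice — it makes every 2×2 table a true partition of one
fixed population and excludes articles that could never contribute to a
co-mention cell. For a row entity (drug, or "any member of the class") and
a column event (ADE term, or "any term of the ADE class"):

| | with event | without event |
|---|---|---|
| articles mentioning the drug (class) | a | b |
| articles not mentioning it | c | d |

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$$

When `b` or `c` is zero, 0.5 is added to all four cells first (the usual
zero-cell correction). Signals are computed for every pair co-occurring in
at least one article (`a >= 1`); pairs that never co-occur get the neutral
PRR of 1, which appears as `ln 1 = 0` when a dense matrix is materialized.
All transforms use the natural log. An article mentioning several members
of a class counts once in the class row; an article mentioning both a
member and a non-member still counts in the row (the predicate is "any
member present").

Only the PRR is implemented; the surrounding machinery (universe,
contingency tables, scans, matrices) is agnostic to the disproportionality
score, so replacing `prr()` is a local change.

## The class-effect decision

For an eligible (class, ADE) pair the members' log-PRRs are partitioned
into k = 2 clusters and the cluster means compared with Welch's t-test
(unequal variances). The verdict is:

* `class_effect_single_cluster` — fewer than two distinct values; the
  cluster is homogeneous by construction;
* `class_effect_homogeneous` — two clusters, p > α (default 0.05): no
  evidence the members split into subgroups;
* `heterogeneous` — two clusters with significantly different means: the
  class signal is driven by a subset of members.

**Eligibility.** A pair is only judged when *every* member has at least one
co-occurrence with the ADE. When some members have no evidence at all,
absence of evidence cannot be distinguished from evidence of absence, so
the pair is excluded rather than classified.

**Clustering.** `split_two()` is a deterministic, size-constrained optimal
1-D two-means: values are sorted and every contiguous split with both sides
of size ≥ 2 is scored by total within-cluster sum of squares. For
one-dimensional data the optimal two-means partition is always an interval
split, so this equals exhaustive search over all two-partitions under the
size constraint (a property the test suite verifies by brute force up to
n = 8). Two reasons for this choice over Lloyd-style k-means with random
starts: it is reproducible without a seed, and the size constraint
guarantees both clusters can support a variance estimate, so Welch's test
is always defined. On the published SSRI example the unconstrained
within-SS optimum would isolate fluoxetine (4.25) alone; the constrained
optimum is {fluoxetine, fluvoxamine} versus the rest, which matches the
published partition and yields the published p-value:

```{r}
ssri <- c(fluoxetine = 4.25, fluvoxamine = 3.85, sertraline = 3.68,
          citalopram = 3.57, paroxetine = 3.77, escitalopram = 3.57)
classify_pair("N06AB", "sexual_dysfunctions", ssri)
```

A Lloyd-mode (`method = "kmeans"`) is provided for comparison; when it
returns a singleton cluster the pair falls back to the single-cluster
verdict because no variance estimate exists.

**Numerical edges.** The single-cluster rule is operationalized as "fewer
than two distinct values" (exact equality; a near-equality tolerance would
be another free parameter and is left to the caller via rounding if
wanted). If both clusters have zero variance, Welch's statistic is
undefined and the test degenerates to p = 1 for equal means and p = 0
otherwise. Ties in the split score resolve to the smallest split index.
No multiple-testing correction is applied across a scan; the verdict table
records α and the absence of correction in its attributes.

## Heat-map exploration

Three resolutions support visual drill-down: all drug classes × ADE classes
(class-level PRR), the drugs of one class × ADE classes, and those drugs ×
individual ADE terms (drug-level PRR). Axes are clustered with Euclidean
distance and complete linkage (`stats::hclust`); leaf order is fixed by a
deterministic traversal that visits the subtree containing the smaller
original index first, so exports are platform-stable. The exported TSV of
the permuted matrix is the testable artifact; PNG rendering (red → yellow →
white, low to high) is a convenience. A complete elevated column in a
drill-down is the visual signature of a class effect; an incomplete column
marks a subset effect; isolated spots mark individual drug properties.
`prr_min` focuses a drill-down on columns whose maximum PRR reaches a
floor (10 is a practical starting point).

## The synthetic-data generator

`generate_corpus()` emulates the statistical structure the signal model
assumes: article-level co-mentions with per-drug ADE risks. Per article it
samples a drug count (default: one drug 70%, two drugs 30%), samples drugs
uniformly, annotates them with the `AE` qualifier, then includes each ADE
term with probability `baseline_ade_prob × max(RR over the article's
drugs)` capped at 1, annotated with `CI`. Planted effects raise the RR of
all terms of one ADE class for every member of a class (fraction 1, a class
effect) or a leading subset (a subset effect). The vocabularies exercise
the normalization machinery by construction: a seeded quarter of
ingredients get precise-ingredient aliases used in half their mentions, one
drug carries codes in two classes, and qualifier-less distractor headings
appear in half the articles.

Defaults — 5 classes × 6 members, 6 ADE classes × 3 terms, 50,000 articles,
baseline ADE-term probability 0.05 — were chosen once so that per-pair
co-occurrence counts land in the hundreds, the regime disproportionality
statistics are meant for, while a full end-to-end run stays in seconds.
The tests and the acceptance script use these defaults; parameter-recovery
checks run 20 seeded replicates at 50,000 articles each.

What the generator does **not** emulate: literature biases (case-report
skew, publication lag), correlated indexing noise, protective effects as a
default (RR < 1 is accepted but not planted by default), and the size and
structure of the real ATC/MeSH/RxNorm terminologies. Passing tests on this
generator show the machinery is correct under the model's own assumptions;
they do not validate the model against real MEDLINE behaviour.

One consequence of the risk model worth knowing when reading drill-down
matrices: a per-term relative risk of 10 does not produce log-PRR ≈ ln 10
at ADE-class resolution. The class event ("any of the class's terms") has a
high baseline, the universe conditions on having some ADE mention, and the
comparator population contains the other elevated members, all of which
compress the observed ratio — a uniform RR = 10 plant lands near log-PRR
0.8 under the defaults, still far clear of the ≈ 0 background.

## Known limitations

The most important one is statistical and belongs to the method itself:
the two clusters compared by Welch's test are *chosen to maximize their
separation*. Under a perfectly homogeneous class (all members sharing one
true PRR plus sampling noise), the selected split is significant far more
often than the nominal α — the acceptance checks measure a heterogeneous
rate of roughly half on null data, and the effect is scale-invariant in
the noise, so larger corpora do not remove it. In practice this makes the
procedure conservative *toward declaring class effects*: a "heterogeneous"
verdict is weaker evidence than its p-value suggests, while `class_effect`
verdicts (obtained despite the selection bias) are correspondingly strong.
Subset effects with a genuine gap are detected essentially always. Users
who need a calibrated homogeneity test should treat the verdict as a
screening flag and follow up with a selection-aware procedure; the verdict
table exposes the cluster means, sizes and p-values for exactly that
purpose.

Other limitations: co-mention is not causation — the PRR measures indexing
disproportionality, not risk; eligibility (every member must have evidence)
skews the judged pairs toward well-studied classes; and the pipeline trusts
its terminology tables, so coverage gaps in term → ingredient or tree-number
maps silently shrink the analysis rather than erroring.
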