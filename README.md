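# classfx

Drug-class adverse event signal detection from literature co-mentions.

Pharmacovigilance usually asks "is this drug associated with this adverse
event?". classfx asks the class-level question: is an adverse drug event
(ADE) a property of a whole pharmacologic class — like statin myopathy or
fluoroquinolone tendinopathy — or of individual members only? It is aimed
at drug-safety researchers working with MeSH-indexed citation records
(MEDLINE-style indexing) and table-driven terminologies (ATC-style drug
classes, RxNorm-style ingredient normalization, MeSH-style ADE trees).

## Method

From each indexed article, drug mentions (descriptors mapping to an
ingredient and carrying an *adverse effects* qualifier) and ADE mentions
(manifestation terms carrying a *chemically induced* qualifier, or
inherently ADE-indicative headings) are extracted and cross-paired. Over
the universe of articles with both mention kinds, each (drug or drug class,
ADE or ADE class) pair gets a 2×2 contingency table — articles mentioning
the row entity versus not, with the column event versus without — and the
proportional reporting ratio

    PRR = (a / (a + b)) / (c / (c + d))

with the 0.5 zero-cell correction when `b` or `c` is zero, and neutral
PRR = 1 for pairs that never co-occur. Drug classes need at least 4
observed members; ADE terms roll up to the second level of their hierarchy.

For each eligible (class, ADE) pair — eligible meaning *every* member has
co-occurrence evidence — the members' natural-log PRRs are partitioned into
k = 2 clusters by a deterministic size-constrained optimal 1-D two-means
(both clusters ≥ 2), and the cluster means are compared with Welch's
t-test. One cluster, or two clusters whose means do not differ at α = 0.05,
is a **class effect**; two significantly different clusters mean the signal
is **heterogeneous** — driven by a subset of members. Clustered heat-map
matrices at three resolutions (class × ADE class, drugs × ADE classes,
drugs × ADEs) support visual drill-down; a seeded synthetic-corpus
generator with planted effects makes the whole pipeline testable offline.

## Worked example

Generate a 50,000-article corpus with a planted uniform class effect
(class `CLS03`, ADE class `ADC01`, relative risk 10 for all 6 members) and
a planted subset effect (`CLS04` × `ADC02`, RR 10 for 2 of 6 members), then
run the pipeline:

```r
library(classfx)

cfg <- synthetic_config(
  n_articles = 50000,
  planted_effects = data.frame(
    class_id = c("CLS03", "CLS04"), ade_class_id = c("ADC01", "ADC02"),
    relative_risk = 10, affected_member_fraction = c(1, 2/6)),
  seed = 42)
vocab <- generate_vocabularies(cfg)
gen <- generate_corpus(cfg, vocab)

mentions <- extract_mentions(gen$corpus, extraction_rules(),
                             vocab$drug_vocab, vocab$ade_vocab)
universe <- build_universe(mentions)
members <- eligible_classes(universe$ingredients, vocab$drug_vocab)
drug_recs <- signal_scan(universe, "drug_x_ade_class",
                         ade_vocab = vocab$ade_vocab)
verdicts <- class_effect_scan(eligible_pairs(members, drug_recs),
                              drug_recs, members)
subset(verdicts, class_id %in% c("CLS03", "CLS04") &
         ade_id %in% c("ADC01", "ADC02"))[
  , c("class_id", "ade_id", "n_members", "p_value", "verdict")]
```

```
   class_id ade_id n_members      p_value                  verdict
13    CLS03  ADC01         6 6.925234e-02 class_effect_homogeneous
14    CLS03  ADC02         6 3.747596e-02            heterogeneous
19    CLS04  ADC01         6 1.256835e-04            heterogeneous
20    CLS04  ADC02         6 2.208751e-06            heterogeneous
```

The planted class effect (`CLS03`/`ADC01`) is called a class effect
(p = 0.069 > 0.05: the two clusters found among the member log-PRRs are not
significantly separated, so all members contribute to the signal), and the
planted subset effect (`CLS04`/`ADC02`) is called heterogeneous
(p = 2.2e-06). The null pair `CLS03`/`ADC02` at p = 0.037 illustrates a
real property of the procedure: because the two compared clusters are
*selected* for maximal separation, the test is anti-conservative on
homogeneous data, and heterogeneous verdicts occur well above the nominal
α on null pairs (see the vignette's limitations section before interpreting
a lone heterogeneous verdict).

The classic published example — the SSRI class against sexual dysfunctions,
with member log-PRRs fluoxetine 4.25, fluvoxamine 3.85, sertraline 3.68,
citalopram 3.57, paroxetine 3.77, escitalopram 3.57:

```r
ssri <- c(fluoxetine = 4.25, fluvoxamine = 3.85, sertraline = 3.68,
          citalopram = 3.57, paroxetine = 3.77, escitalopram = 3.57)
classify_pair("N06AB", "sexual_dysfunctions", ssri)
```

```
<classfx_class_effect> N06AB ~ sexual_dysfunctions
  members: fluoxetine=4.250, fluvoxamine=3.850, sertraline=3.680, citalopram=3.570, paroxetine=3.770, escitalopram=3.570
  clusters: {sertraline, citalopram, paroxetine, escitalopram} | {fluoxetine, fluvoxamine}
  Welch t = -1.956, dof = 1.12, p = 0.2797 (alpha = 0.05)
  verdict: class_effect_homogeneous
```

{fluoxetine, fluvoxamine} versus the rest, p rounds to 0.28, class effect.

A full file-based run (corpus JSON-lines + terminology TSVs in, pair/signal/
verdict/heat-map tables + JSON manifest out) is one call:
`run_pipeline(run_config(...))`, or `inst/cli/classfx run --config run.yaml`
from a shell. `inst/cli/classfx` also exposes `simulate`, `extract`,
`signal`, `class-effect` and `heatmap` subcommands.

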