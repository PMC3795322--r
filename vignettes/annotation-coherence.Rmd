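---
title: "Measuring and extending family annotation coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and extending family annotation coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goherence)
```

## The problem

Automated protein annotation transfers terms conservatively: when a
function cannot be predicted specifically enough, a generic ancestor term
is assigned instead. Inside a curated protein family — a set expected to
share function — this produces a mix of specific and generic annotations
that makes the family look less functionally coherent than it is, and it
hides an opportunity: the specifically annotated members are exactly the
evidence one needs to extend annotation to the rest.

`goherence` implements (i) coherence metrics that quantify this state,
(ii) an enrichment-filtered, semi-automatic pipeline that pairs each
specific term's *support set* with the *candidate* proteins that lack it,
and (iii) a flow-graph visualization of where a family's proteins sit in
the ontology.

## Model and assumptions

**True-path propagation.** Every computation runs on the ancestor closure
of the asserted annotations: an annotation to a term implies annotation to
all its ancestors. Propagation restarts from the direct annotations, so it
is idempotent, and propagated annotations inherit the evidence code of
their source while keeping a non-direct flag (the flow graph uses that
flag to distinguish gray, labelled direct-term nodes from white inherited
ones).

**Traversal relations.** By default only `is_a` edges are traversed.
`part_of` can be included via the `relations` argument; `regulates`-style
relations are parsed but never traversed, because they may cross ontology
aspects while the frequency model underlying the metrics is strictly
within-aspect. Whether `part_of` should contribute to propagation is a
genuine modelling choice; we default to the stricter `is_a`-only reading
and expose the switch.

**Information content.** For corpus annotation probability $f(t)$,
$IC(t) = -\log_2 f(t)$ (bits), normalized by the maximum IC over annotated
terms so the rarest term scores exactly 1. The reference corpus defaults
to the loaded corpus itself; a broader background (a GOA-like corpus) can
be supplied via `stats =` wherever IC is consumed, and is what makes
normalized IC values comparable across analyses.

**Family metrics and their term scope.** With freq_fam(term) the fraction
of annotated family proteins carrying a term after propagation,

$$\mathrm{GOscore} = \max_t\,[\,\mathrm{freq}(t)\cdot IC_{norm}(t)\,],
\qquad
\mathrm{GOoccurrence} = \mathrm{avg}_t\,[\,\mathrm{freq}(t)\,].$$

The aggregation scope is the family's *distinct directly asserted terms*,
excluding aspect roots, with frequencies counted after propagation. This
is the only scope under which the metrics behave as intended: averaging
over all propagated ancestors would dilute the penalty of missing specific
terms, while counting only direct occurrences would penalize proteins
whose specific annotation *implies* the generic term. In the degenerate
case of a corpus annotated only at the aspect root, the root itself is
scoped (GOoccurrence 1), since there is nothing else to measure. GOscore
ties are broken deterministically: higher normalized IC, then
lexicographic term id.

**Family size.** Reported size is the number of family proteins with at
least one *direct* annotation in the analysed aspect (default: molecular
function). Unannotated members never enter denominators.

**Restricted coherence.** `restricted_go_occurrence()` recomputes the mean
over scoped terms inside a focus lineage (focus term plus descendants).
This is the appropriate reading for families of multifunctional proteins
whose secondary functional modules contribute rare off-lineage terms; the
restriction must not empty the scope (that is an error naming the focus).
Multifunctional families remain the metric's known blind spot: when
several functions are unevenly shared, a single scalar cannot separate
incompleteness from genuine multi-functionality, and the restricted
variant is the only remedy offered.

## Enrichment filtering

Step 1 of the pipeline tests each scoped term for over-representation with
the one-sided hypergeometric tail (equivalently the one-sided Fisher exact
test) on propagated counts, and corrects with Benjamini–Yekutieli at
α = 0.01. Choices worth making explicit:

* correction is applied *per family*, across that family's scoped term
  list (cross-family correction would mix families of very different term
  counts); BH and no correction are available behind the `correction`
  switch, and BY is never below BH on the same input.
* significance is the strict inequality `p_adj < alpha`.
* the background defaults, at the command-line level, to the union of all
  loaded families' proteins; library calls take the background corpus
  explicitly. The builtin scenarios place their filler proteins in a
  `FILLER` pseudo-family so both conventions coincide there.

## The extension pipeline

For every relevant (enriched, rule-filtered) term, the support set is the
family proteins already carrying it and the candidates are the annotated
family proteins lacking it. When a focus term is configured, the candidate
pool is additionally restricted to carriers of the focus term — proteins
already on the right functional lineage. Proposals are emitted only when
there is at least one candidate and the support reaches `min_support`
(default 10, a configuration knob: a handful of sequences cannot seed a
useful classifier training corpus, while a few dozen can).

Proposals are *emitted, not applied*: the methodology is semi-automatic
and the decision to assert a term is delegated to external, sequence-based
classifiers (multiple alignments, PSSMs, HMMs, SVMs), which are out of
scope here — the package exports the support-set accessions for exactly
that purpose. `apply_extension()` performs the explicit apply step with a
distinguishing evidence code, and `coherence_differential()` reports the
GOoccurrence before and after a hypothetical extension; the "after" value
is a full recomputation on the extended corpus, so it can never fall below
the "before" value.

## Flow graphs

`build_flow_graph()` induces the subgraph of terms annotating at least one
family protein. Edges are oriented from generic to specific and carry the
child term's protein count; because annotation counts only shrink walking
downward, edge thickness (linearly proportional, thinnest edge = width 1
in the DOT export) gives an immediate picture of where annotation
specificity is lost. When a term has several included parents the same
count is drawn on each incoming edge — the available information does not
define a split of the flow. Transitively implied edges are omitted by
default (`reduce = FALSE` restores them).

## Synthetic scenarios

The generators in `make_scenario()` reproduce, with exact counts rather
than sampling, the annotation structure of characteristic
polysaccharide-lyase families:

| scenario | family side | background fillers |
|---|---|---|
| PL22 | 29 proteins: 22 on the specific term, 7 on its ancestor | 971 off-branch proteins |
| PL5  | 37 proteins sharing one specific term | 963 off-branch proteins |
| PL4  | 43 proteins, 25 on the generic lyase term, specific off-lineage term on 7 | 957 proteins, 700 carrying the ubiquitous catalytic term, 13 the calcium term |
| PL3  | 228 proteins on one dominant term, 6 off-lineage terms on ≤ 2 each | 9,772 proteins carrying the off-lineage noise terms |
| PL8  | 184 proteins, five leaf terms at supports 31/4/2/1/1 under a generic term with 180 carriers | 69,816 proteins carrying the generic lyase and metal-binding terms |

Filler sizes are part of each scenario's definition. They are chosen at a
realistic corpus scale relative to the contrast being modelled: ubiquitous
terms (catalytic activity, metal ion binding, generic lyase activity) are
made common in the background so they fail the significance filter, while
family-exclusive terms remain rare. PL8's background is the largest
because detecting a single-protein, family-exclusive term under BY at
α = 0.01 is only possible against a corpus of tens of thousands of
proteins — the same reason such terms are detectable against a GOA-scale
corpus but not against a small one.

What the scenarios deliberately do **not** emulate: the real GO topology
(thousands of terms, deep multi-parent paths), evidence-code heterogeneity,
inter-family overlap, and the absolute IC / p-value magnitudes of any
particular annotation snapshot. Tests passing on these fixtures therefore
validate the algebra and the behaviour of the pipeline (counts,
monotonicities, significance patterns, differentials), not any particular
real-world score value.

`random_dag_corpus()` complements them with seeded random DAG corpora for
property-style tests (propagation idempotence and closure, frequency and
IC monotonicity, score-oracle equivalence).

## Numerical and interface choices

* Report tables round scores to 3 decimals; enrichment p-values print with
  2 significant digits in scientific notation. Library functions always
  return full precision.
* Duplicate (protein, term) annotations collapse to one record holding the
  union of evidence codes.
* `NOT`-qualified GAF rows are excluded; other qualifier semantics are out
  of scope. Annotations to unknown or obsolete terms drop with a warning;
  alternate ids map silently (with a notice) to primary ids.
* Evidence filtering (e.g. excluding IEA) is available but off by default.
* All orderings (proposals, enrichment rows, argmax ties) are fully
  specified, so the pipeline is deterministic for a fixed configuration.
* Problem sizes in the shipped test suite follow the scenarios above
  (corpora up to 70,000 proteins; property suites over 10–100 seeded
  trials), which keeps the full suite within a few minutes on one CPU.

## Limitations

Beyond the multifunctionality caveat above: the metrics are deliberately
simple baselines, not calibrated statistics — they carry no uncertainty
and should not drive fully automated extension; the candidate lists are
upper bounds awaiting classifier confirmation; and cross-aspect analysis
(combining molecular function with process/component evidence) is not
attempted.
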