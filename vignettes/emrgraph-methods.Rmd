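---
title: "From EMR tables to patient graphs and HinSAGE outcome prediction"
author: "emrgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From EMR tables to patient graphs and HinSAGE outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrgraph)
```

## The problem

Electronic medical records (EMR) arrive as a bundle of relational tables —
demographics, diagnoses, laboratory results, echocardiography, physical
measurements, medications, surgeries, visits, smoking status — linked only
by an anonymized patient identifier. `emrgraph` converts such a bundle
into two graph views of an angina (ICD-10 I20) admission cohort and uses
them to predict a binary five-year composite cardiovascular outcome
(death, myocardial infarction, stroke or heart failure after the index
admission):

1. a **patient-centric heterogeneous property graph** — ten node types and
   nine relation types arranged as one star per patient — for querying and
   visualisation, with Cypher bulk-import and GraphML exporters; and
2. a **bipartite attributed graph** — a patient partition and a diagnosis
   partition with fixed-length feature vectors, one outcome-labelled edge
   per patient — on which a from-scratch heterogeneous GraphSAGE
   (**HinSAGE**) model performs supervised link-attribute inference.

Because real cardiology EMR extracts are not redistributable, the package
ships a synthetic generator that emulates the statistical and structural
conditions such a cohort presents, so the whole pipeline is testable
end-to-end without any data access.

## The synthetic cohort generator

`generateEmr()` draws, per patient: demographics (ages centred near 61 ±
11 years), an index admission uniform over the 2000--2016 window, latent
laboratory/echo/physical values with per-record measurement noise, ICD-10
codes from a fixed 200-code pool with Zipf-profile frequencies, and
records in all eight auxiliary tables. Three design points matter:

* **Outcome mechanism.** The five-year composite event is drawn from a
  logistic model in age and a subset of standardized latent features
  (`lab_blood`, `echo_EF`, `phys_SBP`); the intercept is calibrated by
  root-finding so that, among patients who survive cohort filtering, the
  event probability equals `event_prevalence` (default 1/12, giving the
  characteristic >10:1 negative:positive imbalance). Positives are
  therefore older by construction, and risk is strictly increasing in age
  whenever `age_effect > 0`.
* **Filter fodder.** Configurable fractions of patients are
  outpatient-only (default 0.15) or carry a pre-index MI/stroke/heart
  failure event (default 0.10), so the inclusion/exclusion flow has real
  work to do.
* **Follow-up window.** First events are placed uniformly within 0--5
  years (for label-1 patients) or 5--8 years (at rate `late_event_rate`),
  so both label classes occur at the five-year horizon.

What the generator does **not** emulate: real marginal feature
distributions (they are placeholders with plausible clinical centres),
ICD-10 co-occurrence structure, visit-by-visit disease progression, or
informative missingness. Passing tests therefore demonstrate that the
machinery — filtering, graph construction, learning, evaluation — behaves
correctly under controlled conditions; they say nothing about clinical
performance on real data.

## Cohort selection and labelling

`selectCohort()` keeps patients with at least one index-code (I20)
diagnosis on an inpatient or emergency encounter inside the admission
window — outpatient-only patients drop out — anchors each at the earliest
qualifying admission, and removes anyone with an MI/stroke/heart-failure
event strictly before index. `labelOutcome()` sets `outcome = 1` iff a
composite event falls strictly after index and within `horizon_days`.

Three decisions the data model leaves open were fixed as follows:

* **Five years = 1826 days** (365.25 × 5, rounded).
* **The index day does not count as follow-up**: "followed by" is read as
  strictly after, so an event at offset 0 yields label 0, and a composite
  event before index in an included patient raises a consistency error
  rather than being silently relabelled.
* **Stroke is part of the composite** by default. The composite event set
  is configurable (`event_types`), since reasonable definitions with and
  without stroke exist; the default follows the four-event definition
  used throughout the package.

Per-patient summaries attached to the cohort take the **latest value at
or before index** per named measure, with ties on the date broken by
value order so results are independent of row order.

## The property graph

`buildPropertyGraph()` produces one `Person` node per patient, one node
per *populated auxiliary record group* (not per raw row), and one `Event`
node carrying the outcome — ten labels in all — with nine relation labels
(`HAS_DIAGNOSIS`, `HAS_LAB`, ..., `EXPERIENCED_EVENT`) determined by the
tail node's label. Aggregating a record group into a single node keeps
the star small and the journey readable; numeric groups aggregate to the
latest-before-index value per measure, list-like groups (diagnoses,
medications, surgeries) to sorted distinct code/name lists. Every node
carries both the patient-ID property and a graph-internal integer id.

The star shape is enforced by the class validity: no edge joins two
non-person nodes, every non-person node hangs off exactly one person.
Queries (`queryPatients()`) are conjunctive filters across the star with
an explicit `DISTINCT`-style deduplication flag.

`exportCypher()` writes uniqueness constraints (one per node label),
look-up indexes on the patient-ID attribute, typed-header CSV data files
and `LOAD CSV` creation statements batched so no transaction exceeds
`batch_size` rows; `parseCypherExport()` re-reads exactly that dialect,
which gives a lossless round trip that the tests fuzz. Double-precision
properties are serialized with 17 significant digits so round trips are
exact. `exportGraphML()` hands the same graph to generic viewers via
igraph.

## The bipartite graph

Printed structural facts force the default construction: a cohort of N
patients yields 2N nodes and N edges, i.e. one diagnosis-profile node and
exactly one outcome-carrying edge per patient (`per_patient` mode). A
`shared_diagnosis` mode collapsing identical profiles is provided for the
multigraph reading. Node ids get `p_`/`d_` prefixes, making cross-partition
id collisions impossible.

Patient features (12 by default): age at index, sex, smoking level, three
laboratory summaries, two echocardiography summaries, two physical
summaries, visit and medication counts. Missing continuous values are
median-imputed (an all-missing column falls back to 0, its median after
centering) with optional missingness indicators; z-scoring uses
train-split statistics reusable on held-out data, and zero-variance
columns get unit scale. Diagnosis features (147 by default): indicators
of the 146 most frequent three-character ICD-10 codes (ties broken by
code order; the list is padded from the fixed pool if the data carry
fewer codes, so the width is constant) plus one residual column counting
distinct unmapped codes — so row sums equal each patient's distinct code
count. The outcome lives only on the edge: it is the training target and
is never an input feature.

## The HinSAGE model

For node $v$ of type $t(v)$ with sampled neighbourhood $S(v)$, one layer
computes

$$ h_v^{(k)} = \sigma\!\left(\Big[\,W^{t(v),k}_{\mathrm{self}}
h_v^{(k-1)} \;\Vert\; W^{t(v),k}_{\mathrm{neigh}} \cdot
\mathrm{mean}_{u \in S(v)} h_u^{(k-1)}\Big] + b^{t(v),k}\right), $$

with ReLU on the hidden layer, a linear final layer, and row-wise L2
normalization of the final embeddings; $h^{(0)}$ are the raw node
features. In a bipartite graph the neighbour type is determined by the
self type, so per-type weight matrices realise the heterogeneity. An
edge's probability is a logistic link head on the concatenation (or
Hadamard product) of its endpoint embeddings, trained with binary
cross-entropy by minibatch Adam; the gradients are hand-derived and are
verified against finite differences and against an independently coded
dense full-neighbourhood aggregator in the tests.

Sampling: each layer draws `num_samples[k]` neighbours per node —
without replacement when the degree allows, with replacement otherwise;
in the default per-patient graph every node has degree 1, so sampling
simply repeats the single neighbour (expected behaviour, not a bug). An
isolated node (possible in `shared_diagnosis` mode) aggregates a
zero-feature sentinel. `exhaustive = TRUE` disables sampling and is the
oracle-test mode.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| layers / hidden sizes | 2 / (32, 32) | two-hop star; halves concatenate, so sizes must be even |
| `num_samples` | (8, 4) | conventional two-layer budget; degree-1 graphs repeat the neighbour |
| optimizer / rate | Adam, 5e-3 | with L2-normalized embeddings the logit scale is bounded and gradients shrink; at 1e-3 thirty epochs leave the loss at the base-rate entropy, at 5e-3 they converge |
| epochs / batch | 30 / 200 | 30-epoch histories are the reporting convention here |
| split | 0.8, stratified | prevalence ~1/12 makes unstratified splits fragile |
| link operator | concat | keeps endpoint roles distinct |
| accuracy threshold | 0.5 | binary reporting convention |

A known representational limit, documented deliberately: because the
final embeddings are L2-normalized, the link logit is bounded by the head
weight norm, and a *hard threshold* rule on one feature is learned as a
strong ranking (training AUROC ≈ 0.94 on a separable task) rather than a
near-perfect 0.5-threshold classification — the unnormalized ANN baseline
sharpens further on the same inputs. On smooth logistic outcomes this
does not bind: the model reaches the feature-information ceiling set by a
logistic-regression oracle in the tests.

## Evaluation

AUROC uses the Mann--Whitney rank formulation with ties counted one half;
AUPRC is stepwise average precision over distinct score thresholds. Both
are checked against brute-force enumeration oracles. Confidence
intervals are stratified percentile bootstrap (positives and negatives
resampled separately, 1000 resamples, seeded) — stratification means no
resample can lose a class, and coverage is verified by Monte Carlo
against a binormal score model with known true AUROC. Baselines share
features, split and seed: a 500-tree random forest, an L2-regularized
logistic regression (ridge, small fixed penalty), and a two-hidden-layer
(32, 32, ReLU) sigmoid-output network trained with the same Adam/BCE
machinery as the graph model. `compareReport()` renders the model ×
AUROC/AUPRC (95% CI) table, ROC curves and the true/predicted outcome
distribution at the 0.5 threshold.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `runPipeline()` fans a
single global seed out to per-stage seeds (seed + stage index) and writes
a manifest with content hashes, so reruns are bit-identical for CSV
artifacts. The test suite exercises the structural claims at full
printed scale (a 53,841-patient bipartite build) and the statistical
properties at sizes chosen to keep the suite brisk while leaving the
checked bands many standard errors wide: cohort calibration at 50,000
generated patients, model property suites on ~5,000-patient cohorts with
a deliberately strong injected feature signal (age log-odds 0.12 per
year; ±2.5 SD log-odds on two latent features, +1.5 on a third — chosen
so the feature-information ceiling sits near AUROC 0.88, comfortably
above the 0.80 recovery bar), metric oracles on enumerable cases, and
bootstrap coverage over 200 replicates at n = 500.

## Limitations

* Synthetic data validates machinery, not clinical utility; the real
  per-feature distributions and code structure of a hospital extract are
  absent by design.
* The Cypher parser reads only the dialect the exporter emits; it is a
  round-trip tool, not a Cypher implementation.
* The property graph aggregates each record group to one node per
  patient; visit-level temporal modelling is out of scope.
* No significance testing between models is performed; the report gives
  per-model interval estimates only.
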