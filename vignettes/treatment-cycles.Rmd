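---
title: "Treatment cycles: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment cycles: models, indices and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treatcycles)
```

## The model

A hospital stay record says that a patient, within one *case* (treatment
episode), occupied one *nursing organizational unit* — a ward or facility
such as a paediatric intensive care unit — from an acquisition date to an
outgoing date. From the ordered stay records of a case we build a
**treatment cycle**: a directed graph `G = (V, E, f_V, f_E)` whose vertices
are the distinct unit codes visited in the case and whose edges are the
relocations between consecutive, differing units. The vertex labelling
`f_V` is injective within a graph — a revisited unit maps back onto the same
vertex, which is exactly what lets a returning patient close a directed
cycle. The edge label is a day count: for a transition from a stay of
duration `d_s` to a stay of duration `d_t`,

```
f_E = |d_t - d_s| + 1 ,
```

so every weight is a positive whole number of days and two equal-length
stays give weight 1. In the canonical two-stay example (one day on FRY4,
then six days on FRH1) the single edge gets weight `|6 - 1| + 1 = 6`.

Three modelling decisions are worth stating explicitly because the
construction rule alone does not force them:

* **No self-loops.** Consecutive records on the same unit are read as a
  continued stay, not a transition; edges represent relocations *between*
  units.
* **Simple graphs with multiplicities.** A directed transition repeated
  within a case (or across joined cases) keeps one edge; an integer
  `multiplicity` attribute counts occurrences and the weight of the first
  occurrence is kept. The record-level counts remain available to the
  frequency analysis, which deliberately does *not* go through the
  collapsed edges.
* **Joined graphs.** All case graphs of one patient can be merged by
  graph-theoretical union (vertices merged by unit code, edge sets unioned,
  multiplicities summed). The union of a patient's single-unit cases on
  different wards is a multi-vertex graph with no edges — disconnected, and
  deliberately so. Where the same edge occurs in several cases with
  different weights, the weight of the chronologically earliest case is
  kept; nothing downstream depends on merged weights, so any fixed
  convention works, and "earliest" is reproducible from the data alone.

Temporal order within a case is acquisition date, then outgoing date, then
original file order. Overlapping stays (next acquisition before previous
outgoing) occur in real exports; they are accepted, ordered by acquisition
date, and counted per case in `n_overlaps` so they can be audited rather
than silently reinterpreted.

## Structural classification

Each graph falls in exactly one category:

* `empty` — no edges (no relocation; the majority of cases),
* `cyclic` — contains a directed cycle (some walk starts and terminates on
  the same unit),
* `linear_2` / `linear_long` — a directed path: unique start vertex with a
  single outgoing edge, unique end vertex with a single incoming edge,
  intermediate vertices with one of each; two vertices versus more,
* `other` — acyclic but not a path. Individual case graphs can never land
  here (a case is a chain of consecutive transitions), but joined graphs
  can: branching unions, and edgeless multi-vertex unions.

Connectivity is *weak* connectivity of the underlying undirected graph,
with isolated vertices forcing "disconnected". Strong connectivity would be
the wrong notion here — it would call every linear graph disconnected.
Connectivity is only tabulated for graphs with more than one vertex, since
a single-vertex graph is trivially connected and carries no transfer
information.

One accounting subtlety: per graph, `empty` means "no edges", so a joined
graph with several vertices and no edges is `empty` *and* has `|V| > 1`. In
the cohort summary, whose category rows are meant to partition the
multi-vertex graphs, such graphs are counted in the `other` row. Both
invariants — `connected + disconnected = multi-vertex` and
`linear_2 + linear_long + cyclic + other = multi-vertex` — are asserted at
summary time, on every run.

## Structural indices

Two index families map each graph to a real number.

**Wiener index.** `W(G) = 1/2 * sum_ij d(v_i, v_j)` over all ordered vertex
pairs, where `d` is the shortest-path **hop count**: the day weights are
labels, not lengths, and a topological distance index should not change
because one stay was longer. Distances are computed on the underlying
undirected graph: on a directed path `d(end, start)` is undefined, yet
linear graphs are precisely the ones this cohort ranks, so the undirected
reading is the only one that gives finite values on the graphs of interest.
Disconnected graphs sum reachable pairs only and carry a `disconnected`
flag rather than an infinite value. For an undirected path on `n` vertices
`W = n(n^2 - 1)/6`, which the test suite checks against an independent
all-pairs BFS for `n = 2..10`.

**Randić connectivity index.** `R(G) = sum over edges (k_i * k_j)^(-1/2)`
with `k` the vertex degree. For directed graphs the package evaluates the
same summation over the directed edge set once with in-degrees and once
with out-degrees and averages:

```
R_fin(G) = ( R_in(G) + R_out(G) ) / 2 .
```

On a directed cycle of `n` units every degree is 1 and `R_fin = n`. On a
directed path the start vertex has in-degree 0 and the end vertex
out-degree 0, so the corresponding terms are formally undefined; the
package has such zero-product edges contribute 0. This is a choice, not a
theorem — but it is the only convention under which `R_fin` is finite on
linear graphs, and linear graphs dominate every realistic cohort, so any
convention that breaks on them would make the index useless here. The
identity `R_fin = (R_in + R_out)/2` is asserted to machine precision on
1,000 random digraphs in the test suite.

Extremal search (`find_extremal()`) excludes empty graphs, where every
index is trivially zero; ties are all reported, in cohort order, so the
first row per extreme is a deterministic representative.

## Frequency analysis

Two counting rules, intentionally different:

* **Units** are counted once per graph, over the graphs of a chosen
  structural class (default: cyclic). The question is "in how many of these
  patterns does ward X participate", not "how many nights".
* **Transitions** are counted at record level over all consecutive
  differing-unit pairs in all cases, so a transfer performed three times
  counts three times even though the graph keeps one edge. Transfer volume
  is a workload quantity; collapsing repeats would understate it.

Ranking ties are broken lexicographically so output is deterministic.

## The synthetic cohort generator

There is no public stay-record data set to ship, so `generate_cohort()`
draws one with the statistical shape of a nine-year single-centre
paediatric diabetes cohort, and emits ground-truth labels alongside. The
defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 298 | study-scale cohort |
| cases per patient | `1 + Geom(0.246)`, capped at 15 | mean 4.06, about 1,200 cases |
| records per case | 1: 0.870, 2: 0.105, 3: 0.013, 4: 0.008, 5: 0.004 | about 13% of case graphs non-empty, most with a single relocation |
| `revisit_prob` | 0.03 | directed cycles are rare (a handful per cohort) |
| `home_unit_prob` | 0.8 | a homogeneous-diagnosis cohort is sticky to one specialised ward |
| stay duration | geometric-shaped on 0–14 d | short paediatric stays, same-day discharges possible |
| start window | 2005–2013 | nine calendar years |
| transfer bias | mass from KIPI (ICU) onto the wards | stabilise-then-transfer pattern |

Within a case, dates never overlap (each acquisition is at or after the
previous outgoing date), which sidesteps the ordering ambiguity that real
exports can show. Ground truth is derived from the planted unit sequence:
one record → empty; all-distinct units → linear; any revisit → cyclic. The
generator never plants a branching case, because a single case is a walk —
branching can only arise through patient-level unions.

What the generator does *not* emulate: per-patient heterogeneity in case
counts beyond the geometric law, seasonal admission patterns, and — most
importantly — the full dependence structure between a patient's cases.
Real cohorts concentrate non-empty cases in few patients and reuse wards
across cases more than independence allows, so the *joined*-graph marginals
(how many unions are single-vertex, how many disconnected) are emulated
only qualitatively; the per-patient case histogram needed to calibrate them
is not derivable from cohort totals. Passing tests therefore demonstrate
correctness of the machinery and calibration of the case-level structure,
not distributional fidelity of the joined population.

## Numerical and degenerate-input choices

* Dates parse with an explicit format (`DD.MM.YYYY` by default, flaggable),
  and invalid rows are collected with row numbers, never silently dropped.
  Duplicate identical rows are kept, with a warning, as possible
  re-admissions.
* `Inf` marks unreachable vertex pairs in `shortest_path_distance()`;
  the Wiener index instead skips unreachable pairs and raises a flag,
  since a sum with `Inf` would erase all other information.
* Empty edge sets short-circuit every index to 0.
* All randomness flows through a single integer seed
  (`withr::with_seed`), making cohorts byte-reproducible.

## Problem sizes in the test suite

The suite exercises full study-scale cohorts (298 patients, roughly 1,200
cases) for the recovery and summary-invariant checks — ten seeds in the
deepest test — and smaller cohorts of 15–60 patients where only mechanics
are under test. Exhaustive classifier/oracle agreement runs over all 64
simple digraphs on three vertices plus 150 random digraphs on up to six;
the Randić identity is checked on 1,000 random digraphs.

## Known limitations

* The classifier's `other` bucket is not subdivided; a branching joined
  union and an edgeless one are not distinguished in the summary table.
* Merged edge weights in joined graphs follow the earliest-case
  convention; analyses that ever come to depend on joined weights should
  revisit it.
* The undirected reading of Wiener distances and the contribute-0
  convention for zero in-/out-degrees in the directed Randić index are
  documented choices; alternative conventions would change index values on
  paths and should not be compared across packages without checking.
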