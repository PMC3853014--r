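---
title: "Designing polyepitope T-cell antigens with polyepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing polyepitope T-cell antigens with polyepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyepi)
```

## The design model

A polyepitope antigen is a single artificial protein carrying many CTL
epitopes. Three processing steps decide whether each embedded epitope is
presented on MHC class I, and each is sequence-dependent in a way the
designer controls:

* **C-terminal liberation.** The proteasome (constitutively) or the
  immunoproteasome (under inflammatory cytokines) must cleave exactly at
  the epitope's C-terminus. `polyepi` ranks cleavage at a scissile bond on
  an 11-level efficiency scale — rank 1 the most efficient site, rank 11
  the least — read from a degenerate-motif pattern table over a context
  window around the bond.
* **TAP transport.** The liberated precursor is pumped into the ER by TAP.
  Peptide affinity for TAP is modelled additively, with the first three
  N-terminal residues and the C-terminal residue as the contributing
  positions. Since ER aminopeptidases trim N-terminal extensions, an
  inefficient TAP binder can be rescued by prepending up to three flanking
  residues without changing the mature epitope.
* **Junctional epitopes.** Concatenation creates peptides spanning the
  junction that existed in neither source antigen. Any such peptide that
  binds an HLA allele of the target population is an off-target
  immunogenicity risk and is penalized in proportion to its predicted
  affinity and the allele's genotypic frequency.

For an ordered pair of (flanked) epitopes and a candidate spacer `ss` the
package evaluates

$$W = \sum_{HLA} rank_{HLA}\,freq_{HLA} + len(ss)
  + 0.5\,\min(rank_{pr}, rank_{impr}) + 0.05\,(4 - \overline{rank}_{HLA})
  + 0.05\,N_{eps} + 0.05\,N_{HLA} + 0.25\,rank_{pr} + 0.25\,rank_{impr}$$

with junctional binders ranked 0–3 from predicted pIC50 (closed lower
bounds at 6.3, 7.3 and 8.3; rank 0 windows are discarded). The spacer of
minimal $W$ wins. The pairs then form a complete weighted digraph and the
construct is the minimum-weight open Hamiltonian path.

### The mean-rank term

As written, the $0.05\,(4 - \overline{rank}_{HLA})$ term *decreases* $W$
as junctional binders get stronger, opposing every other junctional
penalty. We keep the algebra verbatim whenever a junction has at least one
predicted binder, but define the term as 0 for a hit-free junction (rather
than the literal $0.05 \times 4 = 0.2$), so that "no junctional epitopes"
is always the best attainable case. The literal behaviour is available via
`design_config(hitfree_mean_term = "verbatim")`. With hits present the
term is a small correction (at most 0.15 between extremes) and never
reorders candidates against the dominant frequency-weighted sum in
practice.

### Admissibility and the disallowed weight

Criterion (ii) of spacer selection — an efficient cleavage site at the
first epitope's C-terminus — is the only hard requirement, so a candidate
is *admissible* when `min(rank_pr, rank_impr)` is at or below
`cleavage_allow_threshold` (default 7, the midpoint-or-better of the 1–11
scale). `best_junction()` minimizes $W$ over admissible candidates only;
if none exists the pair is disallowed and its graph edge carries the fixed
weight 5000, four orders of magnitude above typical allowed weights
(usually below 10), so any path through it is dominated by any path
avoiding it while the graph stays complete and every solver remains total.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `tap_threshold` | self-calibrated | TAP matrix score units | no universal cutoff exists across matrices; when unset, the median TAP score of the input epitope set is used (and logged), so the weaker half of the set is flanked |
| `max_flank` | 3 | residues | longer extensions risk creating new epitopes and are not needed for TAP rescue |
| `junction_lengths` | 9, 10 | residues | dominant class-I ligand lengths; configurable for 8/11-mer panels |
| `cleavage_allow_threshold` | 7 | rank, 1–11 | ranks past the midpoint mean inefficient liberation |
| `disallowed_weight` | 5000 | W units | sentinel weight for inadmissible pairings |
| `hitfree_mean_term` | "zero" | policy | see above |
| GA: pop 80, 500 generations, OX crossover 0.9, swap mutation 0.02/gene, tournament 2, elitism 1 | — | — | solves every n ≤ 7 benchmark graph to the exhaustive optimum in seconds; seed mandatory for reproducibility |
| `redundancy` | 1 | epitopes/allele | set-multicover target for the coverage module |

## Flank search

`select_flank()` searches all $20 + 400 + 8000$ flanks of length 1–3
exhaustively and returns the **shortest** flank reaching the threshold
(within that length: highest score, then lexicographic — determinism for
testing). If the threshold is unreachable it returns the highest-scoring
candidate overall, with the empty flank included in the pool, so the
flanked score never falls below the unflanked score. Exhaustive rather
than greedy per-position search: 8 420 four-term sums are vectorized and
effectively free, and greedy per-position construction can miss coupled
optima.

## Cleavage pattern tables

The context window is P4–P2′ (4 residues upstream of the bond, 2
downstream) — the minimal span the proteasomal-motif literature uses — and
is a declared, configurable property of the parameter file, not a
constant. Each pattern constrains a subset of window slots with residue
sets (`.` = unconstrained); specificity is the number of constrained
slots, the most specific match wins, ties go to file order, and unmatched
contexts take the table's declared default rank, so every context resolves
deterministically. Window slots falling outside the sequence match only
unconstrained pattern slots. The 11 rank classes' boundaries live entirely
in the parameter file: the bundled tables are synthetic fixtures (clearly
labelled in their headers and manifest), and users supply
literature-derived tables in the same format for real designs.

## Solvers

* `solve_exhaustive()` scans all $n!$ orderings (refused above $n = 8$;
  40 320 path sums are instant, beyond that the GA is the intended tool)
  and breaks ties lexicographically on the id sequence.
* `solve_greedy()` is multi-start nearest-neighbour: from *every* start
  node, repeatedly follow the cheapest outgoing edge; return the best of
  the $n$ paths. Deterministic, and never worse than single-start. It is
  reserved for nondegenerate motifs; with a degenerate motif the pipeline
  downgrades to the GA with a warning rather than erroring.
* `solve_ga()` is a permutation-encoded genetic algorithm (order
  crossover, per-gene swap mutation, tournament selection, elitism 1). A
  fixed seed gives bit-identical results. Defaults (population 80,
  500 generations) reach the exhaustive optimum on essentially all random
  n ≤ 7 benchmark graphs; the test suite asserts ≥ 19/20.

The path is open (no return edge): the designed object is a protein
sequence, not a tour.

## T-helper and coverage modules

`select_fragments()` evaluates **all** windows of length 20–40, counts
distinct 9-mer T-helper cores and the class-II alleles they cover, and
ranks windows by allele breadth first (the goal is restriction by a
maximal repertoire of class-II allomorphs), then hit count, then shorter
length, then earlier start. Accepted cores may not overlap — overlap
policy and the ranking tuple are package choices, as is leaving fragment
order unoptimized (junction weights between long fragments are dominated
by their fixed termini; `join_fragments()` reuses the full ranking
machinery per junction with the di-basic `[KR][KR]` cathepsin motif).
Each accepted core is extended by exactly five residues per side, clamped
at the antigen termini.

`select_minimal_set()` is greedy set-multicover (pick the epitope covering
the most not-yet-r-times-covered alleles; ties by summed genotypic
frequency of newly covered alleles, then id). Greedy rather than exact:
it is the standard approximation with the classical $1 + \ln d$ guarantee,
and an exhaustive subset scan guards small cases in the tests. Infeasible
repertoires return `complete = FALSE` rather than erroring — a design aid
should report partial coverage.

## What the synthetic generator emulates — and what it does not

`build_fixtures()` / `make_fixtures()` produce structurally faithful
parameter sets: a TAP matrix with normally distributed contributions, rank
tables with one planted efficient-cleavage residue (P1′ = `G` by default,
rank 1) against an inefficient default, per-allele class-I PSSMs (lengths
9 and 10) whose intercepts put random junctional windows near the 6.3
binder threshold, class-II matrices, and a frequency table. The planted
structure makes the expected optimum *known by construction*: the single
good residue is the provably minimal-W spacer for every pair, which the
tests recover end to end.

What passing these tests shows: the search machinery — flank search,
candidate enumeration, W arithmetic, admissibility, graph construction,
all three solvers — is correct against independent oracles. What it does
not show: that designs under the synthetic tables are immunologically
meaningful. Real designs require experimentally derived TAP, cleavage and
MHC parameters; the file formats exist precisely so those can be dropped
in unchanged. Synthetic junctional "epitopes" are also statistically
homogeneous, unlike real proteome-biased peptide space.

## Numerical and degenerate-input choices

* W comparisons use exact doubles; spacer ties break by length then
  lexicographic order, path ties lexicographically on ids — every result
  is reproducible to the byte.
* Duplicate input epitopes collapse (merged allele lists, warning);
  unknown alleles score frequency 0 with a warning rather than erroring,
  since population frequency tables are chronically incomplete.
* Empty MHC panels, hit-free junctions, single-node graphs, single
  fragments and infeasible repertoires all return well-defined degenerate
  results, never errors.
* Problem sizes in the test suite — 6-epitope designs, 720-permutation
  enumerations, 50 random junction fixtures, 20 random solver graphs,
  $2^{10}$ coverage subsets — were chosen so the full suite completes in a
  few minutes while still exercising every tie-break and boundary.

## Known limitations

* The reference pIC50 predictor is a position-specific scoring matrix;
  allele panels trained with modern neural predictors can be substituted
  only by exporting them to PSSM form, which loses pairwise effects.
* Cleavage ranking is table-driven; it cannot express long-range sequence
  context beyond the declared window.
* The graph is built serially; for 40–50 epitopes junction evaluation
  dominates runtime (hours, as expected for ~2 500 pairs × up to 213
  candidates each) and would benefit from parallel evaluation.
* Signal/targeting sequences (ubiquitin, LAMP-1) are biological options
  outside the package's scope; append them to the rendered sequence if
  needed.
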