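# polyepi

Rational design of polyepitope T-cell antigens in R.

## The problem

Polyepitope vaccines concatenate many CTL (CD8+) epitopes into one
artificial protein. Whether each epitope is actually presented depends on
the residues around it: the proteasome (or immunoproteasome) must cut
precisely at the epitope's C-terminus, the liberated precursor must be
pumped into the ER by TAP — an affinity dominated by the first three
N-terminal residues and the C-terminal one — and the junctions between
epitopes must not themselves create new, unintended ("junctional") HLA
binders. Epitope order and short inter-epitope spacers control all three.

`polyepi` automates this design:

1. **TAP flanking.** Each epitope is scored with an additive TAP model
   (`N1 + N2 + N3 + C` contributions). Inefficient binders get the shortest
   N-terminal flank (up to 3 residues, exhaustively searched over all
   20 + 400 + 8000 candidates) that reaches the efficiency threshold;
   ERAP trimming in the ER later removes the extension.
2. **Spacer selection.** For every ordered epitope pair, the direct
   junction and every prefix product of a spacer motif (e.g. `ADLVKV`
   tests A, AD, ADL, ADLV, ADLVK, ADLVKV; degenerate motifs like
   `[ARSP][DLIT][LGA][VKA]` expand to all 213 combinations) is scored by
   the ranking function

   ```
   W = Σ_HLA rank_HLA × freq_HLA + len(ss)
     + 0.5 × min(rank_pr, rank_impr) + 0.05 × (4 − mean rank_HLA)
     + 0.05 × N_eps + 0.05 × N_HLA + 0.25 × rank_pr + 0.25 × rank_impr
   ```

   where `rank_pr`/`rank_impr` rank proteasomal/immunoproteasomal cleavage
   at the first epitope's C-terminus on a 1–11 efficiency scale (1 best),
   junctional binders are ranked 1/2/3 at pIC50 thresholds 6.3 / 7.3 / 8.3
   and weighted by HLA genotypic frequency, and `N_eps`, `N_HLA` count
   junctional hits and affected alleles. The minimal-W admissible spacer
   wins; pairs with no admissible spacer are *disallowed*.
3. **Ordering.** The pairs form a complete weighted digraph (disallowed
   edges weigh 5000, allowed ones rarely exceed 10). The construct is the
   minimum-weight Hamiltonian path, found exactly (n ≤ 8), by multi-start
   greedy nearest-neighbour (nondegenerate motifs), or by a
   permutation-encoded genetic algorithm.

It also selects T-helper-rich 20–40 aa antigen fragments (extended ±5
residues, joined through cathepsin-cleavable `[KR][KR]` spacers) and
minimal epitope sets covering an HLA repertoire with redundancy
(greedy set-multicover).

All scoring models — TAP matrix, cleavage rank tables, per-allele MHC
PSSMs, HLA frequencies — are pluggable plain-text parameter files. The
bundled generators emit clearly labelled *synthetic* fixtures with planted
structure for testing; drop in literature-derived tables for real designs.

## Worked example

```r
library(polyepi)

fx  <- build_fixtures(fixture_spec(seed = 42, n_epitopes = 6, n_alleles = 3))
d   <- design_polyepitope(fx$epitopes, fx$motif, fx$tap,
                          fx$cleavage_pr, fx$cleavage_impr,
                          fx$panel, fx$freqs,
                          config = design_config(), solver = "exhaustive")
d
#> <polyepitope_design> 6 epitopes, total weight 14.380 (exhaustive solver)
#>   order:    e5 -> e4 -> e2 -> e1 -> e3 -> e6
#>   sequence: TFWGGCYDCGLGTFEVPFECVDTGWRDKEFPFYGTMEVTRHEFQGCIDALMRIEGKFATHEPLK

tidy(d)[, c("from", "to", "ss", "rank_pr", "rank_impr", "n_eps", "n_hla", "w")]
#> # A tibble: 5 × 8
#>   from  to    ss    rank_pr rank_impr n_eps n_hla     w
#> 1 e5    e4    G           1         1     6     2  3.29
#> 2 e4    e2    G           1         1     2     1  2.68
#> 3 e2    e1    G           1         1     3     2  2.90
#> 4 e1    e3    G           1         1     6     2  3.14
#> 5 e3    e6    G           1         1     1     1  2.37
```

Every junction carries the selected spacer (here the fixture's planted
rank-1 cleavage residue `G`), its cleavage ranks (1 = most efficient), the
junctional-epitope counts and its weight W; the optimal order minimizes
the summed W. `glance(d)` gives a one-row summary, `autoplot(d)` the
junction-weight profile, and `write_design(d, "run")` emits FASTA +
junction TSV + run summary. The same pipeline is scriptable from a shell
via `inst/cli/polyepi.R` (`design`, `thelper`, `cover`, `fixtures`
subcommands).

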