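# aldhtools

Sequence-level characterization of aldehyde dehydrogenase (ALDH) gene
superfamilies in plants, for genome annotators and gene-family curators. The
package covers the standard desk-scale workflow used to describe an ALDH
superfamily once candidate sequences are in hand:

- **AGNC classification and naming.** The ALDH Gene Nomenclature Committee
  criteria place a protein in an existing family when it is more than 40%
  identical to a named reference, and in that reference's subfamily above
  60%; below 40% it founds a new family. `assign_family()` /
  `classify_queries()` implement this as best-hit assignment against a
  reference panel and propose systematic names of the form
  `<prefix>ALDH<family><subfamily letter><member>` (e.g. `OsALDH2B5`).
- **Global alignment.** `nw_align()` computes optimal Needleman–Wunsch/Gotoh
  alignments with affine gaps (a gap of length *L* costs
  `open + L * ext`), default BLOSUM62 with pairwise penalties 10/0.1;
  `progressive_msa()` builds a minimal guide-tree progressive multiple
  alignment (10/0.5 merge penalties).
- **Active-site motifs and cofactor preference.** `compile_pattern()` /
  `scan_motifs()` form a PROSITE-syntax engine for the catalytic Cys and Glu
  site motifs, reporting anchored residue positions;
  `cofactor_call()` applies a residue-charge rule at the E195-equivalent
  position: an all-uncharged site neighborhood (A, V, L, I, T, C) calls
  NADP⁺-preferring, a charged E/K at or near the site calls NAD⁺-preferring,
  and an arginine at the site calls a dual/switching enzyme.
- **Phylogeny.** `pdistance()` + `nj_tree()` build neighbor-joining trees
  from p-distances; `bootstrap_support()` resamples alignment columns and
  scores bipartitions; `write_newick()` serializes trees with supports.
- **Transposon structure and dating.** `find_tsd()` and `find_tir()` detect
  target-site duplications and terminal inverted repeats;
  `date_ltr_pair()` estimates a retroelement's insertion age from the
  divergence of its two LTRs, `T = K / (2r)` with the Jukes–Cantor
  correction `K = -(3/4) ln(1 - (4/3) d)` and a default rate
  `r = 1.3e-8` substitutions/site/year.
- **Synthetic data with ground truth.** `simulate_families()`,
  `plant_motif()`, `evolve_on_tree()` and `simulate_ltr_element()` generate
  seeded inputs at controlled identity, with planted motifs, known trees and
  known insertion ages, so every stage can be validated against truth.

A packaged 21-gene rice ALDH annotation table (`aldh_table1()`) carries the
revised superfamily nomenclature with loci, CDS lengths, protein lengths and
molecular weights, and is used for internal-consistency and summary checks.

## Worked example

```r
library(aldhtools)

# summarize the packaged superfamily table
summarize_superfamily(aldh_table1())
#> Superfamily: 21 genes in 10 families
#>   multi-member: 2:5, 3:5, 10:2, 12:2, 18:2
#>   single-member families: 5, 6, 7, 11, 22
#>   two largest families together: 10 genes

# classify synthetic queries against a reference panel
fam <- simulate_families(n_families = 2, members_per_family = 3,
                         seq_length = 300, within_identity = 0.7, seed = 1)
panel <- reference_panel(setNames(fam$records[c("F1M1", "F2M1")],
                                  c("ALDH2A1", "ALDH3A1")))
classify_queries(fam$records["F1M2"], panel)[, 1:6]
#>   query_id proposed_name family subfamily member best_identity
#> 1     F1M2     OsALDH2A2      2         A      2     0.6633333

# date a simulated LTR retroelement inserted 0.43 million years ago
sim <- simulate_ltr_element(ltr_length = 2000, age_my = 0.43, seed = 5)
l5 <- substring(sim$seq, sim$element$ltr5["start"], sim$element$ltr5["end"])
l3 <- substring(sim$seq, sim$element$ltr3["start"], sim$element$ltr3["end"])
date_ltr_pair(l5, l3)
#> LTR dating (JC): d_raw 0.01300, K 0.01311 subs/site, r 1.3e-08 /site/yr -> T 0.504 MY
```

The summary reads directly off the packaged table: 21 genes across ten
families, five families with multiple members, and families 2 and 3 together
holding ten genes (~50% of the superfamily). The classification line shows
the query joining family 2, subfamily A as its second member at 66%
identity. The dating line reports the full chain — raw LTR mismatch
fraction, corrected substitutions per site, the rate assumed, and the age
estimate (a single 2-kb element carries Monte-Carlo error of roughly
±0.09 MY at this age; averaging replicates recovers 0.43 MY closely).

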