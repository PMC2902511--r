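---
title: "Methods: classifying, scanning and dating an ALDH superfamily"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying, scanning and dating an ALDH superfamily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldhtools)
```

Aldehyde dehydrogenases (ALDHs) are NAD(P)⁺-dependent enzymes that oxidize
reactive aldehydes to carboxylic acids; plants carry them in families with
roles in stress tolerance, proline metabolism (P5CS/P5CDH), betaine
synthesis (BADH) and non-phosphorylating glycolysis (GAPN). This vignette
explains the models and procedures behind each stage of the package, the
parameters that matter, and what the synthetic-data validation does and does
not establish.

## Identity-based classification

The AGNC criteria define the superfamily's structure by pairwise percent
identity against previously named sequences: strictly more than 40% identity
to a named reference places a query in that family, strictly more than 60%
in that subfamily, and below 40% the query founds a new family. Three design
points deserve note.

**The identity denominator is genuinely underdetermined.** "Percent
identity" needs a denominator, and the nomenclature criteria never fix one.
The package defaults to the shorter input sequence — the most permissive
common convention for family assignment, and well behaved for fragments —
with `aligned_columns` and `alignment_length` selectable. The choice moves
borderline calls, so every classification output records it.

**Best-hit assignment, not clustering.** The criteria are phrased against
"previously identified" sequences, so `assign_family()` compares the query
to each panel entry and uses the single best hit. Ties across families are
broken toward the lower family number, with a warning. Member ordinals for
accepted names continue from the panel's maximum within the subfamily, in
input order, so batch runs are reproducible; a query whose sequence is
identical to a panel entry keeps that entry's name, making re-classification
of the panel idempotent.

**Strict thresholds.** "More than 40%" is implemented as `> 0.40`, not
`>= 0.40`; a query at exactly the boundary founds a new group. Tests pin
this at 0.39/0.40/0.41 and 0.61 using constructed sequence pairs whose
optimal alignment is provably gap-free (every substituted position uses a
BLOSUM62-positive partner residue), so the realized identity is exact.

## Alignment

`nw_align()` is a standard global affine-gap (Gotoh) aligner. A gap of
length $L$ costs $g_o + L\,g_e$; the defaults are BLOSUM62 with
$g_o = 10, g_e = 0.1$ for pairwise comparisons and $g_e = 0.5$ for multiple-
alignment merges — the classic ClustalW-style parameterization for protein
family work. The Gonnet matrix is not distributed with Biostrings, so
BLOSUM62 is the documented default and the matrix name travels with every
scheme. Tracebacks break score ties deterministically (diagonal, then gap in
the second sequence, then gap in the first), so alignments are bit-stable
across runs. A `semi_global` flag makes terminal gaps free for fragment
comparisons.

The engine aligns *profiles* (per-column residue frequency vectors) in
compiled code; a pairwise alignment is the two-singleton special case. This
lets `progressive_msa()` merge sub-alignments profile-against-profile in the
join order of a neighbor-joining guide tree built from pairwise identity
distances. The MSA is intentionally minimal — no iterative refinement, no
position-specific penalties — because downstream consumers (p-distances,
column bootstrap) need a reasonable columnar alignment, not a
ClustalW-bit-compatible one. Two sequences degenerate exactly to
`nw_align()`; all-gap columns cannot occur by construction.

Correctness is checked two independent ways: exhaustive enumeration of every
gapped pairing for all length combinations up to 5×5, and score agreement
with Biostrings' independent dynamic-programming implementation (to ~1e-4;
Biostrings quantizes fractional gap penalties internally).

## Active-site motifs and cofactor calls

The catalytic machinery of an ALDH is a cysteine nucleophile and a glutamate
general base. The package ships a PROSITE-syntax engine
(`compile_pattern()`, `scan_motifs()`): elements separated by `-`, residue
sets `[...]`, negated sets `{...}`, wildcards `x`, repeat counts `(n)` /
`(n,m)`, and terminal anchors `<`/`>`. Each pattern may designate an anchor
element (the catalytic residue); all elements before the anchor must be
fixed-length so the anchor's offset in a match is unambiguous. The scanner
reports one hit per matching start position (overlapping by default), with
1-based coordinates. The bundled pattern file is labelled a *synthetic
stand-in*: PS00070 and PS00687 identify the canonical ALDH cysteine and
glutamate active-site entries, but pattern strings drift across PROSITE
revisions, so production use should load strings from a current release via
`read_pattern_config()`. The test suite validates the engine against a
brute-force matcher on randomly generated patterns, not against any
particular database release.

Cofactor preference follows a residue-charge rule at the position equivalent
to E195 of the family-2 reference numbering. `map_reference_position()`
carries the reference coordinate through a global alignment (returning
"unmapped" when the site falls in a deletion), and `classify_cofactor()`
applies, in order of precedence: arginine at the site → dual/switching;
E or K at or near the site → NAD⁺-preferring; site and flanking window all
within {A, V, L, I, T, C} → NADP⁺-preferring; otherwise unresolved. Three
points are deliberate: the site residue dominates the window (the
dual/switching group is defined solely by the site arginine); the charged
set defaults to E and K, following the three-group convention as it is
usually stated, even though lysine is positively charged — a strictly
acidic set is one argument away (`charged = c("E", "D")`); and the window
half-width defaults to $k = 2$ because "adjacent residues" is otherwise
unquantified. `unresolved` is a value, not an error: the rule is total.

`catalytic_pair_geometry()` reports the primary-sequence separation of the
Cys and Glu anchors (e.g. 90 residues for a pair at 271/361) and classes
pairs as separated or adjacent; with several hits per residue it uses the
leftmost of each, and a missing anchor yields an incomplete report rather
than an error.

## Phylogeny

Distances are uncorrected p-distances over an MSA — the minimal,
assumption-free choice for protein family trees, and the easiest to test —
with pairwise or complete gap deletion; the distance function is a natural
extension point for model-corrected alternatives. `nj_tree()` is a standard
Saitou–Nei agglomeration on the Q criterion, with two contracts the stock
implementations do not give: ties in Q are broken by the lexicographically
smallest pair of cluster labels (determinism), and negative branch-length
estimates are clamped to zero with the deficit moved to the sister edge so
the pair's summed length is preserved. On additive matrices the algorithm is
exact; tests verify topology and all leaf-to-leaf path lengths for 4–8 taxa
and cross-check topology against ape's independent implementation.

`bootstrap_support()` resamples alignment columns with replacement, rebuilds
the p-distance/NJ tree per replicate, and scores each internal edge of the
full-data tree by the percentage of replicates containing its bipartition.
Replicate $b$ reseeds the generator with `seed + b`, so any subset of
replicates reruns identically. Replicates in which some pair loses all
comparable columns are dropped from the denominator with a warning.
Supports attach to the tree as node labels and round-trip through Newick.
Reproducing any particular published plant-ALDH tree would require the
exact sequence set and aligner build behind it; clade-recovery properties
are instead exercised on sequences evolved along known trees, where a
4-taxon topology with a long internal branch draws ≥95% support at 100
replicates.

## Transposon structure and LTR dating

MITEs and other DNA transposons leave two structural signatures that were
originally curated by hand: a short direct repeat (target-site duplication,
TSD) flanking the insertion, and terminal inverted repeats (TIRs).
`find_tsd()` searches for the longest suffix-of-left-flank =
prefix-of-right-flank repeat within a mismatch budget; `find_tir()` for the
longest prefix matching the reverse-complement of the suffix. Both prefer
longer repeats, then fewer mismatches, and treat `N` as matching nothing.
One consequence worth knowing: a base just inside a true repeat matches its
partner by chance with probability 1/4, so a detected TIR may extend a
planted one by a base or two — detection is assessed as "contains the
planted repeat", which is the scientifically meaningful event.

LTR retroelements insert with two identical long terminal repeats; each then
accumulates substitutions independently, so the divergence between them
clocks the insertion. `ltr_divergence()` aligns the two LTRs globally and
counts mismatches over ungapped columns (indel columns excluded — standard
dating practice, and no indel treatment is specified in the source);
`jc_correct()` applies $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}d)$; and
`insertion_age()` returns $T = K/(2r)$ in million years. No universal
substitution rate exists for this calculation, so the default is
$1.3\times10^{-8}$ substitutions/site/year — a widely used figure for rice
intergenic DNA — with a Kimura two-parameter correction available as an
alternative, and every output records the full
$(d_{\text{raw}}, K, r, T)$ chain so any published rate can be substituted
after the fact. The validation condition dates elements simulated at
0.43 MY under that rate; recovering it is a parameter-recovery result,
conditional on the rate, not a rate estimate.

## Synthetic data: what it emulates, and what it does not

All generators are seeded and deterministic, and every downstream test reads
only generator truth. Substitutions are sampled through the conditional
channel "change with probability $p$, uniform over the $k-1$ alternatives",
with $p$ from the generalized Jukes–Cantor formula
$p = \tfrac{k-1}{k}(1 - e^{-\frac{k}{k-1}d})$ for expected distance $d$.
That channel *is* the JC transition matrix at distance $d$, so draws compose
across branches and two independently mutated copies of an ancestor sit at
exactly the JC-expected divergence of $2d$ — which is what makes the
family-identity calibration (`simulate_families()` solves
$(1-p)^2 + p^2/(k-1) = \text{identity}$ for $p$) and the dating recovery
unbiased by construction rather than approximately.

What the simulations do **not** emulate: indel evolution (simulated families
are alignment-free by construction, so the MSA stage is easier on synthetic
data than on real proteins), rate heterogeneity across sites, codon
structure, base/residue compositional bias, and nested or truncated
transposon insertions. Passing tests therefore demonstrate correctness of
the algorithms under their own model assumptions, not robustness to every
feature of real genomic data.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to give tight Monte-Carlo bounds at
desk scale: 300-residue proteins for classification margins (binomial s.d.
≈ 0.028 on identity, against a 0.22 margin to the family threshold),
500–600-column alignments for bootstrap recovery, 1000-bp LTRs × 200
replicates for dating (standard error ≈ 0.01 MY on a 0.43-MY target), and
exhaustive alignment enumeration up to 5×5 residues. Distance matrices must
be symmetric to 1e-8 and non-negative; NJ branch lengths are written with 12
significant digits, so Newick round-trips are stable to well below 1e-9.
Degenerate inputs are errors, not silent results: empty sequences, gapless
column sets under complete deletion, saturated divergences
($d \ge 0.75$ under JC), and pairs with no comparable columns all fail
loudly.

The table fixture deserves one footnote: its molecular weights are carried
as annotation metadata and are not recomputable without the underlying
protein sequences; the consistency checks cover the CDS/protein
length arithmetic (`n_aa = cds_bp/3 - 1`, the stop codon included in the CDS
length), locus uniqueness, and the summary counts.
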