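---
title: "Dissecting synonymous and nonsynonymous signal in protein-coding supermatrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting synonymous and nonsynonymous signal in protein-coding supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenkit)
```

## The problem

Deep-level phylogenies built from concatenated protein-coding nucleotide
alignments mix two very different historical signals. Nonsynonymous
substitutions change the encoded protein; they accumulate slowly and are the
signal of interest at ancient divergences. Synonymous substitutions are
invisible to the protein; they accumulate quickly, saturate, and — crucially
— their stationary base composition drifts between lineages. Two unrelated
lineages that have converged on, say, GC-rich third codon positions will
attract each other in any analysis that treats all sites under a single
stationary composition. The cure examined here is not a new model but a
*character recoding*: remove the synonymous signal from the data before the
analysis ever sees it.

`degenkit` implements that machinery: degen1 codon degeneration, the
character-set constructions that isolate or exclude synonymous change,
seeded subsampling, bipartition-level support accounting, a per-gene utility
statistic, base-composition diagnostics, indel screening, and a simulator
that generates data with all of these contrasts planted and known.

## degen1 coding

Every codon is replaced by the maximally degenerate IUPAC codon of its
synonymous family: `CAT` and `CAC` (His) both become `CAY`; all six leucine
codons become `YTN`; all six arginine codons `MGN`; the serine split is
preserved (`TCN` vs `AGY`) because no single-nucleotide change interconverts
the two clusters. After recoding, two sequences differ only where a
nonsynonymous difference exists; within-family differences have been erased.

Families are derived from the genetic code, not hard-coded: an amino acid's
codons are partitioned into connected components under single-nucleotide
interchange. That construction reproduces the published coding exactly —
leucine and arginine remain single six-codon families (their blocks are
bridged by first-position changes) while serine splits into Ser1 (TCN) and
Ser2 (AGY). The over-degeneration this implies (`YTN` also covers
Phe `TTY`; `MGN` also covers Ser2) is deliberate and kept bit-compatible
with the published behaviour.

```{r degen-examples}
degen1_codon("CAT")
degen1_codon("TTA")
degen1_codon("AGA")
classify_codon("AGT")
```

Choices the source material leaves open, decided here:

* **Stop codons** map to `NNN` with a warning. In-frame nuclear coding data
  should be stop-free, so a stop is treated as an artifact, not a state.
* **Gap- or `?`-containing codons** map to `NNN`.
* **Ambiguous codons** are resolved by enumeration: if every IUPAC
  resolution degenerates to the same codon (e.g. `YTR`, all Leu), that codon
  is emitted; a codon that is *already* a degen1 output (`CAY`, `YTN`, …) is
  a fixed point; anything else becomes `NNN`. The fixed-point clause is what
  makes the mapping idempotent over its own output alphabet — without it,
  re-degenerating `YTN` would enumerate Phe resolutions and collapse to
  `NNN`. Conservatism is preserved: no rule ever invents a nonsynonymous
  difference.

## Character sets

With the global reading frame (column $c$ has codon position
$((c-1) \bmod 3) + 1$), the package constructs the standard subsets:

* `nt1`, `nt2`, `nt3` — codon-position subsets; a partition of all columns.
* `LRall1` / `noLRall1` — the nt1 columns that do / do not potentially
  encode leucine or arginine in *any* taxon. Leu and Arg are the only amino
  acids with synonymous variation at the first position, so `LRall1` is
  where first-position synonymous change can hide. Membership uses "any
  taxon, any ambiguity resolution"; codons containing `-`, `?` or `N` do
  not trigger it (an unknown is not evidence of an L/R residue).
* `noLRall1nt2` = `noLRall1` + `nt2` (almost purely nonsynonymous) and
  `LRall1nt3` = `LRall1` + `nt3` (enriched for synonymous change). By
  construction they reconstitute the full matrix.
* `nt3_4foldsynon` — one column per codon: the third position, kept only
  where the codon belongs to a strictly fourfold family (Ala, Gly, Pro,
  Thr, Val), everything else `N`. Change here is purely synonymous.

Internally all column indices are 1-based inclusive — the R idiom — and
NEXUS I/O converts to and from that format's 1-based ranges (including the
step notation `a-b\3`). If an exclusion mask removes part of a codon, the
surviving columns are set to `N` in every taxon rather than silently
re-framed: their codon identity is gone and degeneracy-aware operations must
not reinterpret them. Per-column codon positions travel with every slice, so
a broken frame is detected rather than assumed away.

The `*_degen1` named sets are computed by degenerating the full matrix first
and slicing second. The result equals slice-then-degenerate on whole-codon
slices (degeneration is codon-local), but the degenerate-first order also
covers slices, like `nt3`, that carry no codon context of their own.

## Rate bins

Gene fragments carry a nonsynonymous-rate ranking (1 = fastest). Binning
into *k* groups keeps fragments contiguous in rank and chooses the split
points that minimise the maximum deviation of bin character counts from
`total/k`, ties resolved toward earlier splits. The published bin
memberships are reproducible through the explicit `breaks` override, since
the original splitting algorithm is not recorded anywhere.

## Subsampling

`shuffle_columns()` applies one Fisher–Yates permutation from a seeded
generator — distribution-identical to repeated reshuffling, and auditable
because the seed is recorded. `complementary_split()` cuts the shuffled
matrix into consecutive blocks of sizes $\lfloor f_i n \rfloor$ (remainder
to the last block): disjoint, jointly exhaustive, reproducible from
`(seed, fractions, replicate_id)` alone.

## Support accounting

Trees are reduced to informative bipartitions (both sides ≥ 2 leaves,
unrooted semantics); bootstrap percentages ride along from node labels.
Against a reference topology:

* reference "nodes" are its bipartitions with support ≥ 80% (all of them if
  the reference carries no supports);
* a candidate bipartition with support ≥ 80% that matches a reference node
  is *strongly supporting*;
* one with support ≥ 50% matching no reference node is *conflicting*, and
  *strongly conflicting* at ≥ 80%.

Matching is bipartition identity after restriction to the shared taxon set —
not mere compatibility — because on a fixed taxon set a non-matching
informative split of a binary tree necessarily contradicts some reference
clade. Restriction can merge two reference clades into one split (e.g. `AB`
and `CD` both become `AB|CD` on four shared taxa); merged splits keep the
maximum support. All thresholds are arguments: 80 ("strong"), 50
(reportable), 75 (single-gene).

## Per-gene utility

$$U = \frac{G}{L \times 10^{-3}} \times \frac{T}{T - m}$$

with $G$ the number of reference nodes the gene recovers at BP ≥ 75, $L$
the fragment length in nucleotides, $m$ the number of taxa missing from the
fragment and $T$ the total taxon count (default 80). A taxon counts as
missing iff its fragment row is entirely missing symbols (`?`, `-`, `N`) —
the taxon-count formulation governs, not a per-cell fraction.
`fit_utility_trend()` is ordinary least squares of utility on rate with
coefficient standard errors.

```{r utility}
utility(10, 1000, 16)
```

## Composition diagnostics

Per-taxon A/C/G/T percentages are computed over determinate bases only;
Euclidean distances between those 4-vectors are on the *percent* scale
(two taxa of pure, different composition are
$\sqrt{2}\times 100 \approx 141.4$ apart). The clustering diagram is UPGMA
(average-linkage) by default — the conventional display for composition
heterogeneity — with neighbor joining available. On `nt3_4foldsynon` input
the masked `N` cells drop out exactly like missing data, so the diagram
reflects synonymous-site composition and nothing else.

## Indel screening

Only `-` is a gap; `?` is missing data and never forms an event. Maximal
gap runs per taxon per fragment with identical bounds merge into one event;
the quality filter keeps events shared by ≥ 2 taxa whose interval is not
partially overlapped by any other taxon's run ("no staggered ends,
identical lengths"), with no requirement on flanking sequence identity.
The published screen of this kind involved manual judgment of alignment
quality that a mechanical filter cannot fully encode, so on real data the
per-event table is emitted for audit rather than trusted blindly.

## The simulator

`simulate_alignment()` evolves codons along a user tree with an amino-acid
replacement process (rate 1 per unit branch length, uniform replacement)
layered over a within-family synonymous process (rate
`syn_rate_multiplier`). Whenever a codon is redrawn it is sampled from the
amino acid's family with weights given by the receiving lineage's target
third-position composition — taxon groups in `nt3_bias` acquire the
compositional attraction that makes synonymous signal misleading. Families
use the same Ser1/Ser2 split as the recoder, so synonymous redraws never
cross the TCN/AGY boundary and stops never arise.

This is deliberately *not* a mutation–selection codon model: it creates
exactly the contrasts the toolkit must detect (synonymous vs nonsynonymous
rate, compositional bias, missing taxa, planted indels) with all randomness
flowing from one seed. What passing tests on simulated data do **not**
establish: behaviour under selection-driven codon usage, rate variation
across sites, alignment error beyond the planted indels, or realistic
ambiguity-code density.

The mechanism demonstration in the test suite uses a balanced 8-taxon tree,
4 fragments × 120 codons, synonymous rate 20× nonsynonymous, and two bias
groups at 96% GC vs 96% AT third positions — sizes chosen so the whole
suite runs in seconds while the effect sizes are unambiguous:

```{r mechanism, eval = FALSE}
sp <- sim_spec(tree, n_fragments = 4, n_codons = 120,
               syn_rate_multiplier = 20, nt3_bias = bias_groups, seed = 11)
m <- simulate_alignment(sp)
# composition of fourfold third positions clusters by bias group...
composition_tree(euclidean_matrix(base_composition(fourfold_synon_matrix(m))))
# ...while degen1 distances rank-correlate with true tree path lengths
```

## Numerical conventions and limitations

* Ties in UPGMA merge order follow input order (first pair); the dendrogram
  is deterministic for a fixed distance matrix.
* `rate_bins()` enumerates all contiguous splits (cheap for ≤ 3 bins over
  tens of fragments); ties go to the earlier split.
* A fragment whose length is not divisible by 3, or whose columns are not
  whole codons in the global frame, is rejected at construction.
* The NEXUS reader handles sequential and interleaved DATA/CHARACTERS
  blocks, CHARSET and EXSET statements; it does not implement MrBayes
  dialect commands, and the writer emits sequential format only.
* Bipartition counts treat a candidate bipartition lacking a support value
  as unreportable (absent is not zero).
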