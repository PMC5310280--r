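---
title: "Scaffolding draft genomes with a core-gene organizational framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding draft genomes with a core-gene organizational framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Within a bacterial species, single-copy core genes keep their local order:
long runs of them are collinear in every strain, while the runs themselves
— syntenic *segments* — translocate and invert between strains, often
symmetrically around the origin–terminus axis of replication. `coreframe`
treats this conserved structure, rather than any single reference
sequence, as the coordinate system for scaffolding a draft assembly.

Formally, each reference genome is reduced to a circular signed
permutation of its core genes (sign = coding strand, order = start
coordinate, one sequence per replicon). A signed adjacency $(a, b)$ is
*conserved* when every reference carries $\dots, a, b, \dots$ or
$\dots, -b, -a, \dots$ consecutively, wrapping around circular replicons.
Because conservation is demanded in all genomes simultaneously, the
conserved adjacencies form identical disjoint paths (or cycles) in every
genome; their maximal runs are the framework segments $S_1 \dots S_k$.
Runs shorter than `min_seg_len` (default 2 — the smallest run that still
carries order information; lowering the cutoff recovers more genes at the
price of less reliable segments) drop out of the framework. Each reference
is then a signed circular permutation of segments, canonicalized up to
rotation and reflection-with-sign-flip so that the arbitrary deposition
origin and strand of a reference cannot split one architecture into two.

This operationalizes "conserved consecutive order" as conservation of
every internal signed adjacency plus maximality. It is the weakest
definition consistent with strict consecutiveness, and the package's test
suite checks it against exhaustive enumeration of maximal conserved runs
on thousands of random signed permutations.

## From segments to scaffold strings

Core genes are located on the target's contigs from alignment files (PSL
or BLAST tabular) or with a built-in substitution-tolerant matcher. A gene
keeps its single best placement (identity × query coverage, defaults
0.90/0.80, conventional for intra-species core genes); a gene whose top
two placements tie within 1% is discarded — genes that do not map uniquely
cannot index anything. Contigs inherit maximal oriented runs of segment
gene indexes; gaps inside a run are tolerated (an internal deletion in the
target widens the estimated gap rather than invalidating the contig), and
a contig claiming irreconcilable gene ranges of one segment is demoted to
ambiguous. Contigs sharing a segment chain in gene-index order; a contig
spanning two segments (an *overbridge*) fuses their chains into one
scaffold string, and a contig spanning a circular reference's origin is
recognized as the wrap-bridge of a single-segment circle.

Gap lengths between within-string neighbours are the median inter-gene
distance across the references for the intervening genes, minus the
contig sequence already flanking the junction; replicons are treated as
circular, with the replicon extent approximated by its furthest gene end
(wrap-adjacent gaps are therefore underestimated by at most one intergenic
spacer and clamp at zero). When contigs exactly tile a reference this
arithmetic is exact, which is what makes byte-identical reconstruction
possible.

## Local scaffolding with paired-end links

Contig ends are head/tail vertices. A read pair links two ends when both
mates map to different contigs, each within a window $W$ of an end and
pointing off it (forward mate → tail, reverse mate → head); $W$ defaults
to the mean insert size estimated from intra-contig pairs (fallback
500 bp). Counts below or equal to the cut-off (default 5, strictly
greater-than) are discarded as systematic noise. Each surviving edge is
classified against the strings: *consistent* (it joins the facing ends of
string neighbours), *conflicting* (it contradicts a string placement), or
*uninformative* (at least one endpoint is unindexed or a string terminus).
Confidence is

$$c(i,j) = a \cdot \mathrm{permutation}(i,j) + (1-a) \cdot \mathrm{link}(i,j)$$

with consistent edges fixed at 1, conflicting at 0, and uninformative
edges blended with $\mathrm{permutation} = 0$ and
$\mathrm{link}(i,j) = \min(1, n_{ij}/L_{sat})$. The weight $a$ (default
0.5) and the saturation count $L_{sat}$ (default 10) are exposed in the
configuration; the saturating ramp keeps $c \in [0,1]$ and decouples the
noise cut-off from the scale of the link term. The fixed 1/0 values take
precedence over the blended form for consistent/conflicting edges — the
two prescriptions disagree for consistent-but-weakly-linked edges, and
framework consistency is treated as normative.

Resolution is greedy and deterministic: first, chains of up to four
unindexed contigs whose end-to-end links bridge a within-string gap are
inserted into it (this is how repetitive contigs, invisible to the
framework, are recovered; a repeat — read depth ≥ 1.5× the median with
two or more disjoint strong edges — may be inserted into several gaps);
second, remaining edges are processed by descending confidence (ties:
higher count, then endpoint ids) and attached only while both endpoints
are free. Cycles are broken at their weakest attachment. Framework-
confirmed adjacencies are never displaced by uninformative edges.

## Choosing the guide and emitting the pseudo-genome

Every junction between oriented segments that the assembled strings
witness — via an overbridge contig or via a link-supported join of two
segment-bearing strings — is a constraint: a reference pattern lacking any
witnessed adjacency is removed. Link-supported joins are included among
the witnesses deliberately: a physically joined string must embed
contiguously in whatever pattern guides the layout, and without this rule
a target rearrangement whose junction happens to lack an overbridge contig
would be missed. The most prevalent surviving pattern guides the layout;
prevalence ties break toward the pattern whose supporting genome set
contains the lexicographically first genome id, so adding an unrelated
genome cannot silently flip the winner. An empty surviving set is reported
as a novel arrangement — no pseudo-genome is forced.

Each segment-bearing string must embed as a contiguous arc of the guide
circle, forward or reflected; an arc matching several positions is an
error (ambiguous embedding), not a guess, except for a full-circle arc,
where every rotation is the same genome. Strings are laid around the
circle in arc order; inter-string gaps get reference-estimated N runs
(floor 100, cap 10 kb — within-string gaps have no floor and may be zero),
and junctions created only by the guide are listed as unverified, the
software counterpart of confirming weakly supported joins by PCR.
Unplaced contigs are emitted as leftovers, never dropped silently.

## The synthetic-data generator

`simulate_pangenome()` emulates the regime the method is built for: a
panel of references carrying the same core genes (default 200, lengths
300–600 bp, intergenic spacers 40–120 bp — compact toy genomes of about
100 kb that keep a realistic gene density while holding twenty end-to-end
runs to minutes; the vignette-scale defaults are the package's choice of
problem size) partitioned into segments that shuffle freely or flip
symmetrically; dispensable genes present in proper subsets of genomes at
genome-specific positions; a target drawn from the panel's architectures
or constructed outside them; uniform fragmentation into contigs (≥300 bp,
default 39 breaks, mirroring the scale of a typical short-read draft);
and a 2×100 bp paired-end library with normal insert (500 ± 50), a 0.02
per-base substitution rate and deep coverage (default 100×). All
randomness flows from one integer seed; the same seed reproduces the
simulation byte for byte.

The generator knows each read's origin, so tests consume an exact truth
SAM instead of running a mapper; production users supply a real mapper's
SAM. Reads carry substitutions only — no indels, no quality-score realism,
no GC bias — and the target shares its gene sequences with the references
(divergence enters through read error, not gene sequence). Passing tests
therefore demonstrate the combinatorial machinery — segment extraction,
indexing, link resolution, guide selection — under clean mappings; they do
not certify robustness to mapper artefacts, indel-rich sequence, or
paralog confusion in real data.

In novel mode the generator keeps every block adjacency that is conserved
across all references intact, because such adjacencies merge into a single
identified segment and an architecture violating them would be undefined
at segment granularity.

## The evaluator

Coverage is the summed length of all placed contigs over the true genome
length (percent); *falsely located* is the length of contigs placed at the
wrong locus or orientation. Correctness is judged per scaffold by a
dominant-diagonal vote: truth positions are ranked among placed contigs
only, so a contig the output omits neither shifts downstream placements
nor counts as an error; each contig with truth-matching orientation votes,
weighted by length, for the circular offset between its truth rank and its
scaffold index, and the winning offset defines correct placement (both
scaffold readings are tried). Junction errors are output adjacencies that
are not true adjacencies among placed contigs: orientation mismatches are
inversions, short same-direction skips (≤5 ranks) indels, the rest
relocations. Corrected N50 is recomputed after breaking scaffolds at every
error junction. The classification is an approximation of alignment-based
error tallies, but it is deterministic and needs no aligner.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; AGP output is 1-based
  inclusive per the AGP 2.1 specification.
* Segment numbering and canonical orientation follow the
  lexicographically first genome; a fully conserved circular order is
  rotated to start at its lexicographically smallest gene id. Both choices
  exist only to make output deterministic.
* Tie-breaks throughout (best-hit selection, edge ordering, chain
  numbering) resolve by count first, then lexicographic identifiers.
* Twelve-column tabular hits carry no query length; coverage then needs a
  13th `qlen` column or an explicit length vector, and degrades to 1 with
  a warning otherwise.
* Degenerate inputs degrade softly: an empty cluster table is a warning,
  a gene with tied best hits is dropped, a contig with contradictory
  segment claims is demoted to ambiguous and reported, zero witnessed
  junctions constrain nothing.

## Known limitations

Multi-replicon targets are not assembled into multiple circles — plasmid
contigs end in the leftovers. Gap estimates ignore insert-size evidence by
design (the reference median heuristic is used instead). Repeat reuse is
limited to gap insertion; a repeat cannot serve as a string terminus
bridge twice. The guide embeds each string at a unique position or errors;
targets whose architecture repeats an arc pattern therefore fail loudly
rather than being placed arbitrarily.
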