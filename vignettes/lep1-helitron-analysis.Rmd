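---
title: "Detecting non-autonomous Lep1 Helitrons and scoring horizontal transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-autonomous Lep1 Helitrons and scoring horizontal transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Helitrons are class-II transposons that replicate by a rolling-circle
mechanism. Unlike cut-and-paste DNA transposons they carry no terminal
inverted repeats and create no target-site duplication (TSD) on insertion,
which makes them hard to find by generic repeat detectors. They do, however,
leave a consistent structural signature:

* a `TC` dinucleotide at the 5' terminus;
* a `CTRR` motif (R = A/G) near the 3' end and a `CTRY` tetramer
  (Y = C/T) at the 3' terminus itself;
* a short palindromic sequence of about 16--20 bp near the 3' terminus that
  can fold into a hairpin;
* insertion precisely between a host `A` and `T`, so the upstream host flank
  ends `...A` and the downstream flank begins `T...`, with no TSD.

The Lep1 family is a small (134-bp core) non-autonomous Helitron first
described from lepidopteran genomes. Individual copies consist of the
conserved core plus a species-specific *acquired sequence* appended at the
3' end, terminating in the CTRR motif. Because acquired sequences show
little similarity between species while the core is highly conserved, the
family is a sensitive probe for horizontal transfer (HT): finding
near-identical copies (including acquired regions) in hosts that diverged
hundreds of millions of years ago — parasitoid wasps, their bracoviruses,
microsporidian parasites, and their lepidopteran hosts — is incompatible
with vertical inheritance at neutral rates.

`lepscan` implements the complete desk-side workflow around this argument:
candidate detection, structural annotation, identity measurement, tree
building with bootstrap, in-silico insertion-polymorphism assessment, and
quantitative HT scoring, together with a synthetic-genome generator that
makes every stage verifiable against known ground truth.

## Detection and annotation

### Candidate search

`find_candidates()` is a seed-and-extend search: exact 11-mer seeds from
the query (both strands) are located in the subject, clustered into loci,
and each locus is verified by an optimal affine-gap Smith--Waterman
alignment. Hits are kept when identity over gap-free aligned columns is at
least 0.70 **and** the alignment spans strictly more than 100 columns —
the classical screening filter for this family. Both thresholds are
arguments. Two conventions the original screening procedure leaves open
are fixed here and exposed:

* *gapped columns count toward the length filter* (the literal reading of
  "over > 100 bp" on alignment length);
* the per-hit identity denominator excludes gap columns, matching the
  family's "similarity excluding indels" convention used everywhere else.

A seed size of 11 keeps the search sensitive at 70 % identity for matches
of 100 bp and longer: a 100-bp match at 70 % identity still contains an
intact 11-mer with high probability, and every reported locus is re-scored
by the full dynamic program, so seeding affects speed, never scores.

### Alignment engine

All pairwise alignment (local, global, and "fit" — one sequence fully
aligned inside the other) runs in compiled code with affine gaps. The gap
convention is: a gap run of length $L$ costs `gap_open` $+ L \cdot$
`gap_extend` (defaults $-2$ and $-1$; match $+1$, mismatch $-1$). Matching
is IUPAC-aware: two symbols match when their degeneracy sets intersect, so
a consensus `R` matches `A` or `G`. Traceback is deterministic (diagonal
preferred, then vertical, then horizontal; among tied local optima the
lowest subject end coordinate wins). These conventions are mirrored by the
plain-R oracles the test suite compares against.

### Boundary refinement and hallmark calls

Homology hits rarely land exactly on element boundaries. `refine_boundaries()`
searches within ±30 bp of each hit end for the junction context the
rolling-circle mechanism predicts: a start where `TC` is preceded by host
`A`, and an end where a `CTRY` is followed by host `T`. The ±30 window is a
design choice: hits produced by a 134-bp core query cannot miss the true
boundary by more than a few tens of bases, and a wider window only invites
spurious context matches. An end with no such context keeps the raw hit
boundary, and the corresponding hallmark flag simply ends up false.

`annotate_element()` then evaluates, on the refined element:

* the terminal motifs (`detect_termini()`);
* the subterminal hairpin (`find_hairpin()`): an exhaustive inverted-repeat
  scan of the last 50 bp with arms of 6--12 bp, loops of 2--8 bp and at
  most one arm mismatch. These defaults are chosen so that a perfect
  16--20 bp palindrome (8--10 bp arms around a small loop) passes; the
  reported repeat maximises arm length, then minimises mismatches, then
  lies closest to the 3' terminus. Note that with one tolerated mismatch
  the reported arm can extend a written perfect palindrome by one
  position; the detector and the brute-force enumerator agree exactly, by
  construction of the ranking;
* the A^T junction (`check_at_junction()`), reported as undetermined when a
  contig edge removes a flank;
* a TSD screen (`detect_tsd()`) for duplications of 4--10 bp — typical
  class-II TSD lengths; a detected duplication argues against a Helitron;
* the core/acquired partition (`delineate_acquired()`): the core is the
  element span covered by a fit alignment of the core consensus (consensus
  fully aligned, element end gaps free). This is one defensible reading of
  how full-length elements are partitioned when core homology decays
  gradually; it is deterministic and end-gap-free on the element side. The
  CTRR motif must fall within the last 15 bp of the acquired region — "at
  the 3' end" made concrete and configurable. In short acquired tails the
  terminal CTRY and the CTRR may overlap; the overlap is allowed.

An element is called **full length** when it has the 5'-TC terminus, a
3'-CTRY terminus, a determinable A^T junction that holds, and no TSD.
Elements with undetermined junctions (contig edges) keep their annotation
but are excluded from the full-length set, mirroring conservative manual
curation.

## Identity, trees and support

Similarity between copies is always *identity excluding indels*: matches
divided by the number of columns carrying a residue in both rows. This is
the convention used for family-level comparisons (e.g. copies vs their
consensus), and `pairwise_identity_matrix()` applies it over global
alignments.

`progressive_msa()` re-implements progressive alignment: a 6-mer-count
guide tree by UPGMA (`stats::hclust`, average linkage), profiles merged by
global affine profile--profile alignment. It is deliberately simple — no
iterative refinement — because the sequences involved are short (190--450
bp) and closely related; the test suite bounds its sum-of-pairs score
against an exhaustive three-sequence dynamic program.

Distances come from pairwise deletion of gapped columns (not complete
deletion): these elements differ mostly by indel-rich acquired regions, and
complete deletion would discard most of the signal. Both the raw
p-distance and the Tamura--Nei (1993) correction are available; TN93 is
the closed form from purine-transition, pyrimidine-transition and
transversion proportions with base frequencies estimated from the pair,
raising an explicit "saturated" error when a logarithm argument becomes
non-positive. Maximum-likelihood tree inference is out of scope: the TN93
model enters through its distance, used with neighbor joining.

`neighbor_joining()` is the Saitou--Nei agglomeration with the standard Q
criterion, deterministic tie-breaking, and negative branch lengths clamped
to zero with the deficit moved to the sister edge (the standard remedy;
additive matrices are recovered exactly and never trigger it).
`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate, and reports for each internal bipartition
of the point-estimate tree the percentage of replicates containing it;
1000 replicates is the default. `to_newick()` hides supports below 50 %,
the conventional display threshold.

## Insertion polymorphism and horizontal transfer

`build_chimeric_query()` joins ~100 bp of host flank from each side of an
insertion into a ~200-bp junction query. `classify_site()` aligns the two
halves to a target independently and calls the site:

* **empty** — both halves land contiguously (gap below the insertion
  threshold, junction fuzz within ±10 bp of alignment slop);
* **occupied** — both halves hit on the same strand with an intervening
  gap of at least 50 bp, reported as the insert length estimate;
* **absent** — anything else (a half missing, below 50 aligned bases, or
  below 70 % identity).

The 50-bp minimum flank hit operationalises what was originally a manual
inspection; it is a parameter.

HT evidence is scored explicitly rather than qualitatively.
`expected_vertical_identity(T, r)` is the Jukes--Cantor expectation for two
lineages separated for $T$ years at neutral rate $r$ per site per year per
lineage: $1 - \frac{3}{4}\bigl(1 - e^{-8rT/3}\bigr)$, saturating at 25 %.
`flag_ht()` flags a pair when observed identity exceeds this expectation by
more than a margin (default 0.10). The default rate $2\times10^{-9}$ is a
conventional neutral metazoan value; both parameters are explicit and any
conclusion should be reported together with the values used. At the
canonical deep comparison — hosts separated 325 My — the expectation is
38.3 % identity, so the 90 %+ identities seen across such host pairs
exceed it by a wide margin under any defensible rate.

`dollo_loss_count()` formalises the "patchy distribution" argument: under a
single-gain model with the gain at the most recent common ancestor of the
carriers, it returns the minimum number of loss events explaining a
presence/absence pattern on the host tree. Implausibly many required
losses, together with identity in excess of the vertical expectation and
phylogenetic incongruence (`robinson_foulds()` between element and host
trees), are the three quantitative legs of the HT case.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated against:

* background genomes are i.i.d. with GC = 0.35 (an insect-like, AT-rich
  regime; AT-richness matters because it supplies A^T insertion sites);
* the founder element is the 134-bp core plus a 65-bp acquired tail
  carrying a perfect 8-bp-arm/4-bp-loop hairpin ending at least 6 bp before
  the terminus, a CTRR within the last 15 bp, and the terminal CTRY — the
  canonical full-length geometry of this family (the shipped default core
  is a deterministic synthetic stand-in, `core_consensus_synthetic.fasta`;
  it is *not* the published consensus and is labelled accordingly);
* per-copy divergence defaults to 2 % substitutions, reproducing the
  within-family regime of a recently active family (copy-to-consensus
  identities of 95--100 % with a median near 98 %); recovery experiments
  use 10 %;
* copies insert precisely between a host `A` and `T` with no TSD, at least
  150 bp apart;
* by default, mutation *protects the hallmark motif positions* (terminal
  TC/CTRY, CTRR, hairpin arms). Real copies of this family almost always
  retain their structural hallmarks — the motifs are what transposition
  requires — so a generator of hallmark-complete copies holds them fixed
  while the rest of the copy diverges. Set `protect_hallmarks = FALSE` for
  fully neutral divergence.

`simulate_clade()` evolves an element down a rooted host tree with branch
lengths in substitutions/site, converting each branch length to a per-site
substitution probability via the Jukes--Cantor map
$p = \frac{3}{4}(1 - e^{-4d/3})$, which makes realised element divergence
compose exactly additively along paths. Clade simulation does **not**
protect hallmarks — branch lengths must be honored exactly for the
distance arithmetic. A horizontal transfer copies the donor lineage's
element state at a chosen point on the donor's terminal branch into the
recipient's terminal branch; the donor branch is simulated in two segments
so the transferred state is the donor's actual state at the transfer
moment.

What the generator does *not* emulate: chimeric and nested insertions,
tandem arrays, heterogeneous substitution processes, selection on the
acquired region, and assembly artefacts. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
performance on arbitrary real assemblies — on real data the thresholds
(identity, window sizes, flank requirements) are the knobs that absorb
this gap.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GenBank-style 1-based
  inclusive locations convert on ingest, with reversed pairs (`371-171`)
  read as minus-strand features.
* Lower-case input and `U` normalise to upper-case `T`; invalid residues
  are parse errors naming the offending line.
* Local alignments with no positive-scoring cell return an empty alignment
  with score 0 rather than an error; callers treat this as "no hit".
* Alignments bridging two nearby loci through long gap runs are split at
  gap runs of 40+ columns before filtering, so tandem plants are reported
  as separate hits.
* Consensus building: per column the majority non-gap residue wins if it
  is a unique maximum with frequency ≥ 0.5; ties become the IUPAC code of
  the tied set (determinism plus information preservation rather than
  arbitrary choice); columns gapped in more than half the rows are
  dropped.
* TN93 on saturated pairs errors rather than returning `NaN`; the NJ and
  bootstrap layers never see non-finite distances.
* `detect_tsd()` on flanks shorter than the maximum k tests what is
  available and warns.

## Problem sizes

The shipped experiments are sized for a single desk CPU: recovery runs use
100 planted copies in a 400-kb genome (~15 s), bootstrap checks 1000
replicates of a 10-taxon, 200-column alignment (~4 s), NJ recovery 50
random additive trees of 4--8 taxa, Dollo validation every presence
pattern on 6- and 8-leaf trees, and HT flagging 10--20 seeded replicates of
a 6-taxon clade with a 445-bp element. The HT experiment uses the longer
(445-bp) element class precisely because identity noise scales as
$\sqrt{p(1-p)/L}$: at $L = 445$ the true transfer pair clears the flagging
threshold by several standard errors while unrelated pairs stay several
below it, so the expected outcome is exact flagging in every replicate.

## Limitations

* Detection is homology-based: a family absent from the query set is
  invisible (no de novo repeat discovery, no helicase-domain search for
  autonomous partners).
* The HT score is an explicit-parameter screen, not a statistical test; no
  likelihood ratio across tree topologies and no transfer dating is
  attempted.
* The progressive aligner has no refinement stage; for hundreds of long,
  highly diverged sequences a dedicated aligner will do better. Identity
  values can differ by a percentage point or two from those produced by
  other aligners' default parameters; comparisons across tools should fix
  the aligner.
* `dollo_loss_count()` requires a rooted host tree and conditions on the
  gain at the carriers' MRCA.
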