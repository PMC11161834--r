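---
title: "circsat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circsat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system being modelled

Expanded non-B DNA microsatellites — hairpin-forming (CAG) repeats,
G-quadruplex (G4) and triplex (H-DNA) tracts, AT-rich (ATTCT) repeats —
stall replication forks and suffer double-strand breaks.  Repair by
break-induced replication (BIR) is error-prone and template-switch-prone,
and at an engineered ectopic site (ES) it releases extrachromosomal
circular DNAs (eccDNAs) assembled from noncontiguous "template-switch
domains" joined at short sequence homologies.  Inverse PCR (iPCR) with
head-to-head primers amplifies only circular templates; long circular-
consensus (ccs) sequencing of the products yields concatemeric reads, each
a tandem string of PCR-product monomers.

`circsat` implements the computational side of that experiment as a tested
pipeline:

1. **decatenation** — split ccs reads into monomers at approximate primer
   occurrences, orientation-normalize, enforce ES specificity, deduplicate;
2. **segmentation** — align monomers to a hybrid reference (ES contig +
   host contigs) with an internal seed-and-extend aligner and chain local
   alignments into ordered template-switch domains;
3. **junction analysis** — measure microhomology overlap (or nontemplated
   insertion) at every junction, identify the circle-closing junction and
   its mediating repeat, and test overlap distributions for nonrandomness;
4. **mutation quantitation** — per-position pileups over domains, the
   per-generation rate table (rows A–H), per-kb deletion metrics, the
   2 mutations/kb read threshold, and 96-channel trinucleotide substitution
   signatures.

Because the deposited sequencing data are not required for any of the
package's checks, a first-class **simulator** generates ectopic sites,
eccDNA structures with engineered junction homologies, per-generation
mutagenesis and concatemer reads, with complete ground truth.

## The synthetic ectopic site

`ectopic_site()` assembles, in order: left flank, a 48-bp FRT recombinase
site, an upstream reporter (dTomato surrogate), a 311-bp Alu-like repeat
ending in a d(T)29 tail, a 1.2-kb replication-origin cassette, the two
outward-facing 24-mer iPCR primer sites separated by a 150-bp unamplified
gap, the microsatellite insert ((CAG)102 = 306 bp, (ATTCT)47 = 235 bp, a
five-consensus G4 tract, or a homopurine mirror repeat), a second identical
Alu, a downstream reporter (eGFP surrogate), a selection minigene, a second
identical FRT and a right flank — about 4.7 kb in all.  The repeated FRT
and Alu copies are the homologies that mediate circularization.  Filler
sequence is seeded-random; the bases flanking each repeat copy are pinned
to differ between copies, so the maximal shared homology at a repeat pair
equals the repeat length exactly (48 for FRT, 311 for Alu).

`default_reference()` adds two host-chromosome surrogates (2.5 kb each):
one carrying a full Alu copy (nonallelic Alu homology) and one of unique
sequence.  It also *plants* pairs of shared o-mers with divergent flanks —
intra-site pairs of 2/5/6/10/14 bp and ES-to-donor pairs of 43/64/101 bp —
and records their coordinates, so eccDNA models with exact intended
junction microhomologies can be constructed (`demo_ecc_model()`,
`nonallelic_ecc_model()`).  These lengths reproduce the short intra-site
versus long nonallelic overlap contrast seen in the study system.  Host
contigs are desk-scale surrogates, not genome-scale chromosomes; the
aligner makes no whole-genome indexing claims.

## The eccDNA and read models

An `eccdna_model()` is an ordered ring of reference domains; junction `j`
joins domain `j` to `j+1`, the last junction closing the circle.  Each
junction carries an intended overlap `o`: the generator verifies that the
upstream domain's `o`-suffix equals the downstream domain's `o`-prefix
(rejecting unrealizable requests) and realizes the shared bases once.

Mutagenesis follows the per-generation rate model used for the published
quantitation: for each event class the count on a molecule is Poisson with
mean rate × length × generations, positions uniform; deletion and
insertion tract lengths are geometric on {1, 2, …} with means taken from
the published D = C/B and G = F/E ratios (`mutation_model_from_rates()`).
Insertions are random bases, with a configurable tandem-duplication
fraction.  Colliding deletions are truncated; mutations falling inside a
deleted tract are recorded as masked.  Generation counts default to the
published culture spans (≈200 for the hairpin/AT presets, ≈150 for the
G4/triplex presets).

`simulate_ipcr_reads()` extracts the amplicon (forward-primer start, around
the circle, to the reverse-primer end; the inter-primer gap is excluded),
concatenates 1–8 monomer copies per read, reverse-complements half the
reads, and injects substitution errors at the ccs-scale default of
0.1 errors/kb (below the 0.2 errors/kb control bound).  A small
`spanning_fraction` (default 0.02) of reads instead concatenates full
circle copies — the rolling-circle artifact that reads through the gap; the
gap is simulated as known ES sequence, matching what those artifact reads
show in practice.  `simulate_population()` draws an independent mutation
set per molecule and, like real iPCR, skips molecules whose primer sites
no longer match within the edit tolerance.

The monomer-count distribution over 1..8 and the amplicon-length bias of
the polymerase are not known quantities; the defaults (a decreasing
distribution with mean ≈ 2.4, no length bias) are configurable choices,
not inferences.

## Decatenation

Primer occurrences are found by semi-global edit-distance DP (unit costs)
at `max_edits = 2` by default: at a ccs error rate below 0.2/kb, three or
more errors in a 24-mer are vanishingly rare, and primers shorter than
15 bp are rejected outright as ambiguity-prone.  Monomer termini are the
forward-primer starts on the read's consistent strand; reads with
inconsistent interleaved orientations are excluded and counted, as are
terminal fragments lacking a primer pair (they are discarded, not
rescued).  Monomers are reverse-complemented as needed so the forward
primer sits at the 5′ end; normalization is idempotent.

The specificity filter requires `k = 6` bases of exact ES sequence
immediately 3′ of each primer (the documented removal rule for nonspecific
PCR products); the comparison is strict, with zero mismatches allowed.
Deduplication is exact sequence identity after normalization — not
clustering — mirroring the removal of identical PCR copies; the first
occurrence by (read id, monomer index) is kept.  A consequence worth
noting when validating against simulations: deduplication removes
unmutated copies *en masse*, so rate estimates on deduplicated error-free
populations are only unbiased when essentially every molecule carries at
least one mutation (true at the published rates, where a molecule carries
≈14 expected events).

## The segment aligner and chainer

The internal aligner is deliberately minimal but exact about edit
operations, which the downstream quantitation requires:

* exact 15-mer seeds over both strands, with k-mers occurring more than 16
  times masked (repeat control; microsatellite interiors are bridged, not
  seeded);
* seeds clustered per contig/strand by diagonal (tolerance 200 bp, which
  bounds the cumulative indel length bridged within one segment) and query
  gap (≤ 400 bp, covering masked repeat interiors);
* banded global alignment per cluster with affine costs — match 0,
  mismatch 4, gap open 4, gap extend 1 — producing run-length `=`/`X`/`I`/`D`
  operations.  Affine costs keep one mutational event as one CIGAR run;
  the mismatch cost is set above the gap-open cost so that indels inside
  tandem repeats are represented as gaps rather than mismatch runs (with
  cheap mismatches, a deletion inside (CAG)n can be re-expressed as a run
  of substitutions, which corrupts event counts);
* each cluster alignment is trimmed to its maximal-scoring contiguous run
  subsequence (match +1, mismatch −2, indel −(4+length)); a cluster whose
  best window still falls below the identity floor is split at its widest
  seed gap and re-aligned recursively (incidental near-diagonal homology
  can otherwise drag two distinct loci into one low-quality alignment);
* ends are then extended maximally while bases match exactly, which is
  what makes junction-overlap measurement exact on error-free data.

Default filters: aligned query span ≥ 30 bp, identity ≥ 0.8 (both
configurable; the source workflow's aligner settings are not stated, and
external SAM/PAF alignments can be imported instead via
`read_sam_segments()`/`read_paf()`).

`chain_domains()` selects the maximal-score query-colinear subset of a
monomer's alignments by dynamic programming.  Adjacent selected segments
may overlap on the query by up to 300 bp — the microhomology allowance,
matching the observed up-to-≈300-bp overlap homologies (note the 311-bp
identical Alu pair *exceeds* this allowance by design: a circle closed
through full-Alu homology is reported as a single domain, which is also
the only consistent reading of such a molecule).  Equal-score chains
resolve to fewer junctions, then leftmost target start, then leftmost
query start; the DP is exact for this order and is tested against
exhaustive enumeration.

## Junction microhomology

Overlap is measured in **reference space**: starting from the two mapped
segments adjacent in the chain, extend the upstream alignment rightward
and the downstream alignment leftward while read bases continue to match
each locus's reference continuation.  The overlap is the read window
covered by both extensions — the shared homology of the two donor loci,
realized once in the read; if the extensions leave read bases matching
neither flank, those bases are a nontemplated insertion.  Overlap and
insertion are mutually exclusive per junction by construction.  The
measurement is exact on error-free data (a brute-force oracle over all
extension lengths is part of the test suite) and tolerant to ±1 bp near
sequencing errors.

The circle-closing junction of an orientation-normalized monomer is the
junction following the ES domain of maximal downstream reach (largest
target end among domains with a successor): the forward-primer extension
walks downstream until the sealed circle boundary and the chain then wraps
back toward reverse-primer territory.  The junction's mediating repeat is
the annotated FRT or Alu feature covering more than half of the overlap
window (ties and sub-majority coverage fall back to "other"), with a
sub-annotation for windows inside the Alu d(T)29 tail.

`test_nonrandom()` compares an observed overlap-length distribution with a
seeded random array.  The published analysis used a t-test against a
random number array whose distribution is unstated; here the null is
explicit — uniform integers on [0, max observed overlap], size-matched,
seed 1729 by default — and a permutation p-value for the difference in
means is reported alongside the t statistic as the recommended primary
result (the t-test is flagged inapplicable in zero-variance degenerate
cases, where the permutation result still stands).  Type-I calibration at
the 0.05 level is verified over 1,000 null replicates in the test suite.

## Mutation quantitation

Pileups walk the chained domains' edit operations: a deletion event is one
maximal run of contiguous deleted reference bases, counted once at its
start column; an insertion event is one contiguous inserted string
anchored between two reference positions; each read's mismatch counts
once per column.  Rates divide event totals by `aligned_bp` ×
`generations`, where `aligned_bp` is the total reference bases covered by
template-switch domains over all analyzed monomers after deduplication —
the natural reading of quantitation "within template switching domains"
(bases inside junction overlaps are covered by both flanking domains and
count in both, a ≈1% effect at the observed overlap lengths).  Rows D and
G are the ratios C/B and F/E, NA when their denominators are zero, and row
H is computed literally as A + C + F per its definition; the published
table's printed H does not equal A + C + F in several columns, so both the
computed value and the identity are reported and no agreement with the
printed H is forced.  Per-kb deletion metrics (deleted bases/kb, deletion
events/kb) carry no generation normalization.  The 2 mutations/kb
threshold uses per-read denominators for the removal decision and pooled
denominators for the recomputed rates.

Signatures fold every substitution to the pyrimidine-centred convention
(G>A at context NGN becomes C>T at the reverse-complement context) into 96
channels — 6 substitution classes × 16 flanking-base contexts — plus the
6-class and 16-context marginals used for bar plots; edge and N-context
calls are skipped and counted.

## What the simulator does and does not emulate

Emulated: the ES feature inventory and repeat structure; template-switch
domains joined at exact engineered microhomologies in both orientations
and across contigs; Poisson per-generation mutagenesis at published rates
with geometric tract lengths; concatemer reads with strand randomization,
ccs-scale substitution errors and rolling-circle gap-spanning reads;
iPCR's selection against primer-disrupted molecules.

Not emulated: replication-fork biochemistry, chromatin, or drug/knockdown
mechanisms (conditions are only parameter sets); polymerase-specific
substitution spectra (injected mismatches are uniform over alternates, so
signature tests exercise bookkeeping, not biology); sequence-dependent
error hotspots in ccs reads; amplicon-length amplification bias; diverged
(rather than identical) Alu copies, except where a test constructs them
explicitly.  Passing tests therefore demonstrate correctness of the
measurement machinery under the stated generative model, not performance
on real libraries — for real data the import path for external aligner
output exists precisely because aligner parity matters there.

## Problem sizes and numerical choices

The test suite runs at desk scale by choice: the parameter-recovery check
simulates ≈5,600 molecules (≥5,000 amplifiable monomers, ≈17 Mb aligned)
and requires each input rate back within 15% (ratios within 10%); the
oracle-equivalence battery uses 1,000 randomized junction fixtures and 150
random chain instances with ≤6 segments; calibration uses 1,000 null
replicates at n = 150 with 499 permutations.  Determinism is enforced
end-to-end: every stochastic routine takes a seed, restores the caller's
RNG state, and byte-identical outputs under equal seeds are tested.

Known limitations: event placement inside long tandem repeats is
inherently ambiguous (counts are preserved by the affine model, positions
only up to the repeat's ambiguity window); measured junction overlaps can
exceed the intended value by chance matches when fixtures are not
flank-pinned; domains shorter than the 30-bp floor or with < 15 bp of
unique anchor sequence are not recovered; and rate estimates on
deduplicated populations are biased upward when a non-negligible fraction
of molecules is mutation-free (see Decatenation above).
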