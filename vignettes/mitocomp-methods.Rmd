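---
title: "Methods: comparative mitogenome analysis with mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome analysis with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitocomp` analyses a trio of closely related plant mitochondrial
genomes on the fixed rooted topology `((C,S),D)`. This vignette explains
the models and procedures behind each stage, the parameters that matter,
what the bundled simulator does and does not emulate, and the design
choices taken where the design was genuinely open.

## Pairwise comparison

Local similarity search is delegated to the NCBI `blastn` binary (word
size 11, low-complexity filtering off), so the seed-and-extend contract
is the classic one: any interval pair whose mismatch density is within
the identity threshold and which contains one exact 11-mer seed is
examined. Percent identity is matches divided by alignment columns, gap
columns included — the conventional definition for this tool family.
Hits are filtered at identity ≥ 0.85 and length ≥ 90 bp by default; both
are exposed everywhere they are used.

Circular chromosomes are compared by concatenation-doubling the subject
and deduplicating hits modulo its length. This makes block coverage
invariant to where a circular-mapping chromosome happens to be
linearised; the simulator deliberately emits each genome at a random
(recorded) rotation so that this tolerance is exercised.

Hits are chained into collinear blocks by dynamic programming under
monotone-coordinate and uniform-strand constraints. The chain score is
anchored matching bp minus 0.01 per gap bp; inter-anchor gaps are capped
at `max_gap` = 1,000 bp, chosen as the granularity at which
organelle-scale rearrangements should interrupt synteny rather than be
absorbed into it (configurable). Chains are extracted best-first, ties
broken by leftmost query coordinate, so output is deterministic. A
one-to-one filter then drops lower-scoring chains that mostly re-cover
query or subject span already claimed by a better chain. This mirrors
locally-collinear-block synteny: the extra copy of a duplicated segment
falls outside block coverage and correctly surfaces as a non-alignable
region, which is what lets the classifier call it an intragenomic
duplication.

Non-alignable regions are the complement of block coverage, merged
across covered islands shorter than `merge_slack` = 50 bp and filtered
at `min_region_len` = 90 bp — the hit-recording threshold reused, since
the upstream analysis this emulates states no separate cutoff. Minus
strand blocks above 1 kb are reported as inversions; adjacent
minus-strand blocks separated by under 5 kb in both genomes are merged
first, because an insertion or deletion inside one large inversion
splits its anchor chain while remaining a single rearrangement.

## Chloroplast transfer detection

The mitogenome is searched against its own chloroplast genome and
qualifying hits are collapsed to a union on the mitochondrial axis.
Totals are computed on the union, not the sum of hits, so overlapping
hits are never double-counted; per-region rows still report each merged
region's span. One copy of the chloroplast inverted repeat (the largest
inverted self-duplication ≥ 8 kb) is removed before searching, as is
conventional when quantifying transferred content; a flag restores
full-length behaviour.

Transferred gene copies are located by projecting the chloroplast CDS
annotation through each hit's gapped alignment — annotation is an input,
not something the package re-derives. A copy is *intact* when it covers
at least 95% of the reference CDS with no net frame-disrupting indel and
no internal stop; otherwise the first disqualifying lesion in reference
coordinate order is reported, with precedence frameshift <
premature stop < truncation when coincident. The 95% coverage threshold
and the precedence order are package decisions; the biology fixes the
lesion classes but not the bookkeeping.

## Origin classification

Every base of every non-alignable region is attributed to exactly one of
six origins with fixed precedence CP > ID > GL > PH > NU > ND:

1. **CP** — the base is covered by a qualifying chloroplast hit.
2. **ID** — the own mitogenome carries at least two qualifying copies and
   strictly more than the pair partner.
3. **GL** — absent in the partner but present in the third mitogenome
   (gain on a shared stem or loss in the partner; direction is then
   polarised by exhaustive two-state parsimony on the tree, ties
   reported as ambiguous).
4. **PH** — the best external-collection hit is to a distant-taxon
   mitochondrial sequence and outscores any close-taxon hit by a 1.1×
   margin. The margin is a package decision standing in for a
   qualitative "higher hit score" criterion.
5. **NU** — covered by a hit to the own nuclear genome. Such bases also
   sit in a mitogenome, so the direction is annotated as probable
   mitochondrion-to-nucleus transfer; directionality is a note, not a
   category change.
6. **ND** — the residue.

Per-base precedence guarantees the invariant asserted on every call:
category bp sum exactly to the region length. Removing the external
collection can only move PH bases into ND, never into CP/ID/GL — the
cascade is evaluated in order.

## Repeats and recombination

Dispersed repeats are enumerated as *exact* maximal repeated segments
(≥ 30 bp, direct and inverted), found as runs of shared k-mers along
diagonals; circularity is handled by doubling plus modular
deduplication, including removal of truncated images of origin-crossing
copies. Exactness is a deliberate choice: it admits a transparent
quadratic oracle (per-diagonal `rle` scan) against which the enumeration
is tested, at the cost that a near-identical repeat family appears as
several exact units. Repeat units are then selected greedily
longest-first, masking copies already ≥ 90% claimed — emulating the
masking behaviour of the standard organelle repeat finder. Repeat
content is the union of all copies over genome length (union vs sum is
not standard anywhere; union avoids double-counting overlaps and is
declared in output headers).

The recombination assay counts a long read only if it spans one repeat
copy entirely plus ≥ 100 bp of unique flank on both sides; each flank is
aligned against the four junction conformations (two parental, two
recombinant; for inverted repeats the recombinant junctions carry
reverse-complemented flanks), the best-scoring pair assigns the
conformation, and ties are discarded. The 100 bp flank default is a
package decision; the method this follows does not state its exact
flank. Frequency is recombinant over total spanning reads, undefined
(NA) at zero spanning reads, and the assay refuses repeat pairs whose
copies sit closer than two flanks.

## Distances and the clock

Mismatch columns in the block alignments become substitution records
(position on the anchor genome, transition/transversion class, CDS /
intron / intergenic context, codon effect via the standard genetic
code); gap runs become indels. Kimura's two-parameter distance
`-½·ln(1−2P−Q) − ¼·ln(1−2Q)` is used for noncoding divergence and
raises a saturation error when a logarithm argument is non-positive
rather than returning NaN.

Synonymous/nonsynonymous rates use modified Nei–Gojobori counting:
sites are counted with a transition weight (`ts_weight`, default 1,
i.e. one third of random changes are transitions — consistent with the
observed transversion excess in very close mitogenome pairs);
differences are averaged over all shortest substitution pathways with
the same weighting, pathways through stop codons excluded when any
stop-free pathway exists, and changes *to* stop codons counted as
nonsynonymous. Each class is then K2P-corrected with its own transition
and transversion proportions. The exact variant implemented by legacy
GUI software is not recoverable in detail; the weighting is exposed and
the counting is pinned to a brute-force pathway-enumeration oracle in
the tests.

The clock is deliberately the pairwise convention: rate = calibration
distance / calibration time, estimated time = query distance / rate,
with **no factor two**. Reproducing the published arithmetic first was
the priority (1.33×10⁻³ against 6.28×10⁻² at 88 Ma gives 1.86 Ma, and
1.33×10⁻³ over 1.86 Ma prints as 7.15×10⁻¹⁰ per site per year); a
`per_lineage` flag reports the distance/2T convention, which halves the
rate and leaves the estimated time unchanged.

## Recurrent transfer: breakpoint, trees, fixation

A recurrent transfer overwrites part of an existing transferred region,
leaving a chimera: chloroplast-identical on one side of a breakpoint,
mitochondrial on the other. The scan works on an alignment of the
region from several species, one or more chloroplast counterparts, and
the query copy. *Diagnostic* columns are those where the chloroplast
state differs from the mitochondrial consensus (majority over the
non-query mitochondrial rows, ties resolved alphabetically for
determinism); columns containing gaps are excluded from scoring and
reported separately. Every inter-column boundary and both orientations
are scored — the number of diagnostic sites agreeing with the
chloroplast on one side plus those agreeing with the consensus on the
other — and the maximising boundary is returned, leftmost on ties.
Because the score is flat between consecutive diagnostic sites, the
boundary is only localisable to the local diagnostic-site spacing; the
no-chimera verdict (all-chloroplast or all-mitochondrial) is returned
whenever no interior split beats the best single-segment score. A
single breakpoint is assumed throughout; multi-breakpoint mosaics are
out of scope.

Verification trees are neighbor-joining on K2P distances with
nonparametric bootstrap (default 1,000 replicates, seeded), one tree per
partition. NJ replaces a full maximum-likelihood search deliberately:
the quantity of interest is the clustering pattern — the query joining
the chloroplast clade in the overwritten partition and the mitochondrial
clade in the remainder — not likelihoods, and NJ on these shallow,
signal-rich alignments recovers it with high support while staying
fast and fully deterministic given the seed. Partitions shorter than 50
columns are refused.

The fixation survey scans each individual's copy and calls it a carrier
when it receives a chimera verdict whose boundary lies within 5
diagnostic sites (the default tolerance window) of the template
boundary, then reports per-population carrier counts, per-population
fixation and species-wide fixation.

## The simulator and what passing tests mean

`simulate_genomes()` evolves one ancestor down `((C,S),D)`. Defaults
encode the study conditions the package targets: terminal branches of
1.55×10⁻⁴ noncoding substitutions/site (≈ 3×10⁻⁴ between the close
pair), a stem and D branch giving ≈ 4.45×10⁻³ to the outgroup species,
coding sites three-fold slower, indels of 1–8 bp at 0.5 events per
substitution, transitions weighted 1 against each transversion (one
third transitions, matching the observed transversion excess), a 5.1 kb
ancestral chloroplast transfer 2.4% diverged from its donor (≈ 123
diagnostic sites), an additional 8 kb young transfer on the D branch, a
2.7 kb gain, 2 kb losses and duplication, a 15 kb inversion, dispersed
repeat pairs, and a recurrent-transfer template overwriting the first
3.3 kb of the ancestral transfer, carried by one third of sampled
individuals (5 of 15). The default ancestor is 60 kb — a reduced-scale
genome that preserves the absolute event sizes and divergences above
while keeping examples and routine test runs quick; multi-seed property
checks use a further-reduced 25 kb ancestor whose event sizes are kept
above the chaining gap so that every event still interrupts synteny.
All coordinates are tracked through every subsequent edit, so ledger
intervals always map onto the emitted sequences, and the three genomes
are emitted linearised at one shared, ledgered rotation locus.

Placement of events is exact rather than rejection-sampled: an event is
placed uniformly over the intervals where it fits without splitting any
tracked feature, and placement fails with a named error only when no
such interval exists. Losses are planted at the root as tracked targets
and deleted on their designated branch, so the retained copies in sister
genomes carry ledger coordinates; substitutions are suppressed inside
loss targets so ledger substitution arithmetic stays exact. The
inversion may contain tracked features wholly (they are remapped and
strand-flipped) but its boundaries never split one.

The simulator emulates structure, not realism, and passing tests should
be read accordingly. It does not model: rearrangement beyond one
inversion; recombination-driven multipartite genome structures;
realistic long-read error profiles (uniform errors only); selection on
coding sequence beyond a uniform rate factor; within-population
diversity in the fixation survey (carriers differ from non-carriers
only by the overwrite); or chloroplast genome evolution after the
transfer (donor divergence is applied once, at insertion). Recovery
rates measured on these simulations therefore demonstrate correctness
of the algorithms under their stated models, not expected performance
on arbitrary real data.

## Numerical and degenerate-input conventions

* Intervals are 1-based closed everywhere — internally (the
  IRanges/Bioconductor convention) and in every exported file, each of
  which declares the convention in a header comment.
* Deterministic tie-breaks throughout: leftmost query coordinate in
  chaining, leftmost boundary in the breakpoint scan, alphabetical
  consensus ties, coordinate order in greedy repeat selection.
* Degenerate inputs fail loudly: empty chloroplast genome, saturation
  in K2P, zero synonymous sites, zero diagnostic columns, partitions
  under 50 columns, repeat copies closer than two flanks, out-of-bounds
  regions and GFF features.
* `run_pipeline()` halts on the first failing stage with the stage name;
  outputs end with an md5 manifest, and reruns with identical inputs and
  seed are checksum-identical. Stages are recomputed on every run; no
  caching layer is maintained, as a full reduced-scale run takes seconds.

## Problem sizes used by the checks

Routine tests run on the 60 kb default trio and constructed sequences of
1–10 kb. The statistical acceptance checks use: twenty seeded 25 kb
trios for origin-classification recovery (≥ 90% of planted-event bp) and
breakpoint localisation; ten seeded pairs of 10⁴ codons for Ka/Ks
recovery under a known dN/dS (the mean over seeds must sit within 10%);
about 250 spanning reads for recombination-frequency recovery against a
99% binomial interval; and one reduced-scale end-to-end determinism run.
These sizes are the package's chosen benchmark conditions and are stated
here so the measured rates can be interpreted.

## Known limitations

* Block granularity depends on `blastn` hit structure plus the chaining
  parameters, not on a progressive aligner; region counts on real
  accessions can differ by a block or two from aligner-based synteny,
  which is why accession-level checks carry tolerances.
* The PH/NU arms depend entirely on the supplied reference panel; with
  a sparse external collection, horizontally transferred sequence ends
  up in ND (never in CP/ID/GL).
* Near-identical repeat families are reported as multiple exact units
  rather than merged inexact families.
* The breakpoint model is single-boundary; a second overwrite inside the
  same region would be mis-localised rather than detected as two.
* Ks on extremely close pairs rests on a handful of events; the package
  reports the distance but confidence intervals are out of scope.
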