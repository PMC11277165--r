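---
title: "Structural haplotyping of the honey bee COI-COII intergenic region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural haplotyping of the honey bee COI-COII intergenic region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The marker and the problem

The non-coding region between the cytochrome c oxidase subunit I and II
genes of the *Apis mellifera* mitochondrial genome (spanning the tRNA-leu
gene) is hypervariable in both sequence and length. Its length variation is
structural: an optional P element — present as the full P form, or as the
shorter P0 or P1 derivatives — followed by one to three tandem copies of the
~0.2 kb Q element. The P-variant diagnoses the maternal evolutionary
lineage: P0/P1 mark the African A lineage, the full P the West-European M
lineage, and absence of any P element the East-European C lineage. Copy
number of Q then splits each lineage into structure classes (P0Q, P0QQ,
P0QQQ, PQ, PQQ, Q, ...), and point variation within a class defines named
haplotypes (A1, A74, A74c, M4r, C2_d, ...).

`coicoii` implements the full desk-side workflow for this marker: reading
E2/H2 amplicon FASTA, orienting and quality-filtering records, decomposing
each amplicon into its structural elements, calling the lineage, simulating
the classical DraI PCR-RFLP typing in silico, collapsing sequences into
haplotypes with catalog-anchored nomenclature, re-coding alignment gaps so
network software counts indels instead of masking them, and building one
median-joining network per structure class.

## Structure annotation

Annotation is a greedy left-to-right tiling. At each cursor position every
reference unit (tRNA-leu stub, P, P0, P1, Q, COII stub) is aligned
semi-globally — the unit global, end gaps free on the amplicon side — inside
a local window, and the best-scoring unit wins:

* **Identity** is matches / aligned length including internal gaps. This
  matters: with matches / reference-length, a deletion derivative (P0) would
  score 100% against its parent (P), because the aligner bridges the deleted
  block with a free pattern gap.
* **min_identity = 0.75** accepts a unit match. Intra-lineage divergence in
  this region is far below 25%, while cross-unit identities in the synthetic
  library sit near the random-sequence baseline (~0.5), so the threshold has
  a wide safety margin on both sides. It is config-overridable for real
  libraries.
* **Ambiguity margin 0.02 between P-variants**: if the two best P-variant
  identities are closer than 2%, the record is flagged ambiguous-P; the
  winner still drives the lineage call, but the near-tie stays visible in
  the warnings column. P0 and P1 differ from P by deletions, so near-ties
  indicate a genuinely borderline amplicon.
* Unmatched gaps under 10 bp between units are tolerated and logged; longer
  unmatched stretches are reported as annotation warnings. When a primer
  pair is supplied, tiling runs on the interior between the primer sites, so
  primer-bearing flanks never count as unmatched sequence.
* Alignment scoring is fixed at match +1 / mismatch −1 / gap open −4 / gap
  extend −1 everywhere. At the divergence levels of this marker the results
  are insensitive to the exact scores; fixing them makes every output
  bit-reproducible.

A record in which no Q unit can be found is structurally unresolvable; it is
flagged `UNRESOLVED` and excluded from haplotyping rather than failing the
run. The lineage call itself is a total function of the structure string
(`P0*`/`P1*` → A, `P*` → M, `Q*` → C).

## In-silico DraI test

The DraI assay digests the E2/H2 PCR product with the blunt cutter DraI
(TTTAAA, cut after position 3). The digestion model is linear (a PCR
product, not the circular genome); every occurrence of the recognition
string on the top strand counts (TTTAAA is its own reverse complement, so
top-strand scanning is complete), N never matches, cut coordinates are
deduplicated, and fragments always sum to the amplicon length — an assertion
checked on every call. Fragments are reported 5′→3′, with a
descending-sorted view mimicking gel band order. Fragment patterns are not
mapped to published DraI haplotype names: the marker literature itself
concludes that sequencing is required to resolve haplotypes fully, and this
package follows the sequence-first route.

## Haplotype collapse and nomenclature

Within one structure class, records are aligned by anchoring each structural
unit occurrence to its library reference and concatenating the per-unit
blocks; insertion columns are merged across records at the same reference
offset and left-justified. This "unit-anchored" scheme sidesteps full
multiple alignment: columns are defined by the reference, so the result is
deterministic and independent of record order.

Haplotypes are groups of identical aligned rows. Rows containing N never
merge with anything that is not byte-identical — an N could hide a real
difference — and are flagged low-confidence.

Nomenclature follows the lineage-letter + number + lowercase-suffix
convention used for this marker:

1. an exact catalog match keeps its name (`known`);
2. a group within 2 SNPs (configurable) of a same-lineage catalog entry,
   with no indel difference, takes that entry's base name plus the next
   unused suffix in a–z order (`renamed_alias`) — a base name with no
   suffix occupies no suffix, so after A74, A74a, A74b the next variant is
   A74c;
3. anything else opens the next number in the lineage series (`novel`).

New entries join the catalog with provenance `this_run`, so re-running the
same data against the updated catalog is idempotent. Where rules 2 and 3
disagree only because of an indel difference inside the SNP margin, the
assignment carries an explicit note. The prime mark in published names
(A77′) is preserved as an opaque character; generated names never contain
it. The rule thresholds codify the renaming practice observed in the
literature for this marker (suffix variants at one or two nucleotides);
because the historical precedence rules are not fully published, the
thresholds are configuration, not constants.

## Indel re-coding and median-joining networks

Popular network software masks alignment columns with more than 5% missing
data, which in this marker deletes the entire P element (absent in C-lineage
sequences) and the missing Q copies. The re-coding step prevents that: in
every column containing gaps, the gap state is replaced by one fixed
surrogate base — deterministically the alphabetically first base in
{A,C,G,T} absent from the column's observed bases. A column observing all
four bases alongside gaps cannot be re-coded and raises an error naming the
column (it cannot occur in unit-anchored alignments of this marker at
realistic diversity). Each gap column is re-coded independently, so a 2 bp
indel counts 2 toward distance; rows containing N are excluded (no surrogate
is defined for missing data) and logged. The re-coded Hamming distance then
equals SNP differences plus indel-column differences of the gapped original,
exactly — a property the test suite checks against an independent
column-walking oracle.

Median-joining networks are built per structure class, never mixed: the
classes differ in length by whole units, and cross-class "distances" would
be dominated by arbitrary gap handling.

The construction follows the classical scheme: (1) the epsilon-relaxed
minimum spanning network over the current node set (an edge of weight *w*
joins when its endpoints are not connected by pairs at distance below
*w* − ε; ε = 0, the default, gives the union of all minimum spanning
trees); (2) quasi-medians of connected triplets (per-column majority;
columns where all three states differ contribute the triplet members'
states, capped at 4 such columns before falling back to the three
parent-copy resolutions); (3) the median that most reduces the **total
cost** is added and the process iterates; (4) median nodes of degree ≤ 2
whose removal does not increase cost are pruned.

Total cost is defined as the minimum-spanning-tree cost over the network's
node set (observed plus medians). Under this definition the cost of the
final network never exceeds the MST cost of the observed haplotypes —
medians are only ever accepted when they strictly reduce it. The sum of
*all* edges of an ε = 0 spanning network is not a usable cost criterion:
with tied distances the union of minimum spanning trees holds every tied
edge and its edge sum exceeds the MST cost, so a cost bound stated on the
edge sum would be violated by the spanning step itself.

All tie-breaks (candidate choice, edge enumeration) are lexicographic on
node sequence, so networks are bit-identical across runs. Median nodes are
labeled mv1, mv2, ... in insertion order. Networks export to GraphML (with
frequency and population-composition node attributes) and to a NEXUS
network block.

## The synthetic-data generator

The generator exists so that every stage is testable without external
downloads; it emulates amplicon populations, not coalescent genealogies.

* **Unit library**: random founder sequences per seed; defaults TRNA_LEU
  68 bp, P 67 bp, Q 196 bp, COII stub 55 bp. P0 is a strict 15 bp central
  deletion of P. P1 is derived from P by one single-base deletion plus
  seeded substitutions that push P/P1 identity to ≤ 0.9: a pure one-indel
  derivative would sit at ~0.985 identity to P, inside the annotator's
  0.02 ambiguity margin, making every P/P1 call ambiguous by construction.
  The deletion is placed centrally so that both flanks anchor the alignment;
  an end-adjacent deletion lets the aligner prefer a contiguous mismatching
  placement and distorts identities. All lengths are declared testing
  approximations (the real unit sequences are supplied by the user's own
  library for real data) and are configurable.
* **Populations**: per group, founder haplotypes are derived from the
  composed architecture by planting three substitutions each at disjoint
  positions inside the structural units — so founders are pairwise ≥ 3 SNPs
  apart and the 1–2-SNP suffix rule cannot merge them. Records are drawn
  either by exact per-haplotype counts or by weights (with every haplotype
  seeded at least once when record count allows). Noise: i.i.d. per-base
  substitutions (default rate 0.005) and at most one 1–3 bp indel per
  record (default probability 0.02), never inside a primer site. One global
  seeded stream per generation call, consumed in a documented order
  (founders, then record draws, then per-record noise), so outputs are
  byte-identical per seed and the truth table's mutation logs replay every
  emitted sequence exactly.
* The bundled survey-shaped composition (`algeria_population_spec()`)
  plants 68 records as 24 P0Q / 42 P0QQ / 2 P0QQQ with 5/18/1 haplotypes per
  structure and exact counts (the dominant P0QQ haplotype at 16/68 ≈ 23.5%,
  the dominant P0Q haplotype at 7/68 ≈ 10.3%) — a frequency profile
  realistic for an all-A-lineage Algerian drone sample of that size.

What passing tests on this generator do **not** show: robustness to
chromatogram artefacts, heteroplasmy, primer-slippage chimeras, or unit
sequences diverging far from a user library — real data features the
generator deliberately does not model. Structure recovery figures quoted by
the test suite (100% noise-free, ≥ 99% at 0.5% substitutions over 1000
records) are statements about this noise model.

## Numerical and design choices

* Coordinates are 0-based, half-open throughout; sequences are always
  stored on the + (E2-first) orientation after orientation.
* Primer matching allows 2 mismatches and no indels (Sanger-grade primer
  sites); QC defaults are min length 300 bp and at most 2% N. Surveys of this marker
  typically discard poor-quality traces without publishing numeric criteria,
  so these defaults are declared, not inferred, and are config-overridable.
* Problem sizes used by the test suite and the acceptance script — 1000
  random amplicons for the digestion oracle, 1000 records for noisy
  recovery, 100 gapped alignments for re-coding, the 68-record bundled
  composition — were chosen as the smallest sizes at which the checked
  rates are statistically meaningful.
* The per-sequence indel model applies at most one indel per record: at
  Sanger amplicon scale multiple real indels per read are rare, and a
  single-indel model keeps mutation logs trivially replayable.
* `haplotype_records()` processes structure classes in lexicographic order
  and groups in (size, sequence) order, so catalog growth — and therefore
  every assigned name — is deterministic.

## Known limitations

* Sub-lineages (e.g. the African Z sub-lineage) are not structural calls;
  they remain catalog metadata.
* The catalog ships with names, structures and accessions of the deposited
  novel haplotypes only; their sequences are fetched online on demand and
  are not bundled.
* The unit-anchored alignment covers the structural units; bases in
  tolerated inter-unit gaps (< 10 bp, logged) do not enter the haplotype
  alignment.
* No contig assembly, chromatogram processing, FASTQ qualities, partial
  digestion, or gel-mobility simulation.
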