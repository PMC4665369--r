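---
title: "Assessing mitochondrial 16S rRNA variants by heterologous inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing mitochondrial 16S rRNA variants by heterologous inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthia)
```

## The problem

Mutations of the two mitochondrially encoded rRNAs are hard to interpret.
The mitochondrial translation machinery cannot be manipulated genetically the
way bacterial ribosomes can, so direct biochemical evidence for or against a
disruptive effect exists for only a handful of variants. Heterologous
inferential analysis (HIA) works around this: because the core fold of rRNA
is conserved across all domains of life, a human large-subunit (16S, gene
*MT-RNR2*) variant can be assessed from what is known about the equivalent
residue in bacterial, archaeal, eukaryotic-cytoplasmic and mitochondrial
ribosomes — mutagenesis phenotypes, structural roles, conservation — once
that equivalence has been established on superimposed three-dimensional
structures.

`mthia` implements this workflow end to end: population-rarity filtering of
candidate variants, coordinate mapping between mtDNA and rRNA numbering,
structural-context operations (contacts, base pairs, glycosidic
conformation, superposition, residue equivalence), a conservation index,
and the deterministic classification rubric, together with synthetic
generators that give every stage inputs with known ground truth.

## Variant labels and coordinate mapping

mt-rRNA variants are reported in two numbering systems: rCRS mtDNA
coordinates ("m.2680T > C") and 1-based residue indices within the 16S rRNA
("1010U > C"). Within the gene span the two differ by one constant offset.
`calibrate_mapper()` derives that offset from any table that carries both
numberings and refuses to calibrate when rows disagree; on the packaged
64-variant table the unique offset is 1670, giving the gene span
m.1671–3229 (residues 1–1559).

The rCRS carries a placeholder base (`N`) at m.3107 inside the gene. The
mapper treats numbering as strictly positional — no skip — because the
constant offset holds on fixture rows above m.3107; reference FASTA files
must therefore retain the N.

The label parser accepts the dialect mixture found in practice:
substitutions in either numbering, `del`/`Ins`/`dup` events, homopolymer
run-length changes ("449 3T > 4T", stored as their own event kind rather
than normalized to an insertion, since the affected run edge is not
identifiable from the label), en-dash or hyphen ranges, the "≥" glyph that
sometimes replaces ">", and a stray leading reference base occasionally
printed before the position. Alleles are stored in the RNA alphabet with
the original dialect recorded.

## Rarity filtering

The filter retains a variant only when it is genuinely rare in the
population: at most 15 appearances in total (the threshold is an argument)
and none of them "novel", i.e. outside the sequences attributable to the
sources that reported the variant. Source attribution — in the original
workflow a manual literature check — is mechanized as a provenance tag per
sequence id (`known_reporting_source` vs `population`).

Alignment of each population sequence to the reference is global
Needleman–Wunsch with affine gaps (match +1, mismatch −1, gap open −5, gap
extend −1), delegated to `Biostrings::pairwiseAlignment()`. Variant
extraction left-normalizes indels (an indel inside a repeat is reported at
the repeat's leftmost position) so counting is invariant to where the
aligner happens to place a gap; columns containing `N` call nothing, and
ambiguity codes other than N are rejected at ingest.

Desk-scale note: correctness tests run on synthetic populations of 100
sequences over a 2 kb reference segment standing in for the 16S gene —
population size and reference length are generator arguments, and nothing
in the filter depends on them.

## Structural context

Structures are tibbles of atoms (chain, residue, atom name, Å coordinates).
PDB and mmCIF parsing is delegated to bio3d; only the first model is used
and alternate locations resolve to the highest occupancy (ties: first
listed). Minimal deterministic PDB/mmCIF writers support synthetic models
and round-trip tests.

**Contacts.** `find_contacts()` reports heavy-atom pairs strictly below the
cutoff (default 3 Å, matching the reporting convention for atom-to-atom
distances; a single parameter, not a second code path, covers looser
inspection such as 4 Å bridge checks), excluding intra-residue pairs and
the covalent O3′(i)–P(i+1) backbone link.

**Base pairs.** Detection is geometric, in the spirit of standard RNA
annotators: candidate hydrogen bonds are donor–acceptor heavy-atom pairs at
2.4–3.4 Å between base polar atoms; paired bases must be near-coplanar
(plane-normal angle < 35°) and unstaggered (< 2.0 Å separation along the
mean normal); canonical and wobble assignments additionally require ≥ 2
hydrogen bonds and a C1′–C1′ distance of 8.0–11.5 Å. The stagger criterion
is part of this package's detector design: in an idealized coplanar helix,
stacked neighbours can satisfy distance and angle criteria alone, and
vertical stagger is the standard discriminator. All thresholds are
arguments (`pair_criteria()`).

Classification reads the hydrogen-bonded edges (Watson–Crick, Hoogsteen,
sugar — a purine donating N7 is using its Hoogsteen edge, N3/O2′ its sugar
edge) and the relative glycosidic orientation, approximated by the sign of
the dot product of the two C1′→N glycosidic vectors (positive = cis).
WC/WC cis pairs split into `cis_watson_crick` (A:U, G:C) and `wobble`
(G·U, A·C); WC/Hoogsteen trans is `reverse_hoogsteen`; sugar/Hoogsteen is
`sheared`; everything else, including lone ribose-to-base contacts, is
`other_noncanonical`.

**Glycosidic conformation.** χ is O4′–C1′–N9–C4 for purines and
O4′–C1′–N1–C2 for pyrimidines; `syn` iff χ ∈ [−90°, +90°], the conventional
boundary. Missing atoms yield `undetermined_conformation` rather than an
error.

**Superposition.** `superpose_structures()` is a Kabsch least-squares fit
over an explicit atom pairing, followed by iterative pruning: pairs with
post-fit distance above the cutoff (default 2 Å) are dropped and the fit
repeated until stable, mirroring interactive-viewer behaviour. The rotation
is always proper (det = +1); fewer than three surviving pairs is an error.
Explicit pairings keep tests deterministic; for real structures
`pairing_from_sequences()` derives a C1′ pairing from a global alignment of
the chain sequences. `map_equivalent_residue()` then assigns cross-structure
residue equivalences by the nearest C1′ within 4 Å after superposition —
the operation that underlies the "bacterial equivalent" annotations.

## Conservation

The conservation index lives on a 0–2 scale with 2.000 reserved for
universal, gap-free conservation. The package computes
`cv = (2 − H)(1 − g)` where `H` is the Shannon entropy (bits, 0·log 0 ≡ 0)
of the non-gap base frequencies and `g` the gap fraction; a fully gapped
column scores 0. This definition is adopted because it reproduces the
published ceiling (2.000) and ordering of values; reproducing non-extremal
published values exactly would require the original cross-kingdom alignment
corpus, which is out of scope. The scoring function is a pluggable argument
so an alternative definition can be swapped in without touching callers.

Interaction conservation across sources is rendered by
`conservation_code()`: a `C` followed by one glyph per source in the fixed
order bacterial, eukaryotic, archaeal, mammalian-mitochondrial,
yeast-mitochondrial — the source letter when the interaction is observed,
`+` when unmodelled but all partners present, `−` when a partner is absent,
`?` when absent despite present partners; with no observed source the
leading `C` is dropped.

## The classification rubric

Seven categories describe disruptive potential: **P** (proven — direct
biochemical evidence in the mitochondrial system), **E** / **N**
(expectedly disruptive / certainly not — direct heterologous mutagenesis at
the residue or its pairing partner), **L** / **U** (likely / unlikely —
indirect heterologous evidence only), **NEE** (nothing argues either way),
**und** (not placeable on the high-resolution structure, or no heterologous
data to extrapolate from). `classify_evidence()` evaluates a fixed priority
cascade: P first — direct homologous biochemistry outranks any inference,
which is how the one proven variant is treated even though heterologous
data at its site are indirect — then placeability/data existence (und),
then direct (E/N) over indirect (L/U) evidence, else NEE. The cascade is
total and deterministic; the tests enumerate the complete profile space
(48 valid combinations) against an independently written case-by-case
oracle.

The packaged table transcribes the 64 curated variants with their
equivalences and evidence profiles. Profiles follow the published
narrative: the proven variant carries the direct-biochemistry flag, the
four expectedly-disruptive variants direct heterologous disruption support,
the twelve likely and six unlikely variants indirect support in the
respective direction, the five undetermined variants are not placeable, and
the remaining 36 rows carry the evidence-free profile. Printed
irregularities (stray leading bases in two m. labels, a `?` partner cell,
one row with unlettered bacterial cells, one row whose bacterial-equivalent
cell reads like a partner entry) are preserved verbatim and flagged in a
`note` column rather than silently corrected.

## Synthetic data: what it emulates and what it does not

The generators provide ground truth, not realism:

* `gen_population()` plants variants at exact appearance counts in
  otherwise identical copies of a reference — no mutational spectrum, no
  phylogenetic structure, no sequencing error. Passing tests show the
  aligner/caller/counter recover planted truth, not that they are robust to
  messy real genomes.
* `gen_duplex()` builds idealized A-form duplexes (twist 32.7°/residue,
  rise 2.81 Å/residue) from standard planar base-frame templates, with a
  reduced atom set (base atoms, C1′, O4′ — enough for every detector
  criterion and χ). Real structures bend, twist irregularly, and carry full
  backbones; the detector thresholds are chosen for those too, but the
  exact-recovery guarantee is only demonstrated on ideal geometry.
  Noncanonical pair geometries (wobble by an in-plane shift derived from
  the canonical frame; reverse-Hoogsteen and sheared by a small
  deterministic least-squares placement of the partner base against the
  target hydrogen-bond distances) satisfy the classifier's criteria by
  construction.
* `gen_column()` realizes compositions exactly via largest-remainder
  rounding; `gen_evidence_profiles()` enumerates the finite profile space.

All generators are deterministic under a seed, and planted truth is
attached to the generated object (the `"pairs"` attribute of a duplex, the
`"truth"` attribute of a population) so tests never re-derive it.

## Numerical choices and degenerate inputs

* Superposition uses SVD with a sign correction, so reflections are never
  returned; identical models give rmsd 0 to machine precision.
* Pruning convergence is "no pair removed this iteration"; retained-pair
  count is non-increasing and the final rmsd is never above the unpruned
  fit's rmsd on the same retained set.
* The expected rmsd under i.i.d. Gaussian coordinate noise of sd σ is
  σ√3; the test suite checks agreement within 10 % at σ = 0.3 Å over ~500
  atom pairs.
* Contact and hydrogen-bond windows are half-open exactly as documented:
  a pair at exactly 3.0 Å is *not* a contact under a 3 Å cutoff.
* Homopolymer labels that change base identity, duplication ranges that
  disagree with their unit, substitutions with identical alleles, and
  positions outside the gene span are all refused with typed errors.

## Problem sizes

The test suite and the acceptance script run entirely on packaged or
generated data: the 64-row curated table, populations of up to 100
sequences over 800–2000 nt references, 50 random duplexes of 4–30 bp, and
1,000 random alignment columns. These sizes were chosen as the smallest
that exercise every code path and property convincingly; every operation
scales to larger inputs by argument. Validation against external deposited
ribosome structures (tens of thousands of atoms) is supported by the same
functions via `pairing_from_sequences()` but requires downloading those
structures, so it is not part of the packaged checks.

## Known limitations

* The rubric classifies evidence profiles; building a profile from the
  literature remains expert curation, shipped as data.
* The conservation index is one member of a family of (2 − entropy)-style
  scores; published values computed on other alignment corpora will differ
  away from the extremes.
* Base-pair classification covers the five classes above, not the full
  12-family geometric nomenclature; cis Hoogsteen pairs, for instance,
  report as `other_noncanonical`.
* Peptide-exit-tunnel membership is an annotation column, not a computed
  property.
* The cis/trans discriminator is a dot-product heuristic that is reliable
  for near-planar pairs; strongly non-planar pairs may need the full
  edge-frame treatment of dedicated annotators.
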