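---
title: "Methods: a signature-driven census of LuxI/LuxR quorum-sensing circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a signature-driven census of LuxI/LuxR quorum-sensing circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxcensus)
```

## The problem

In acyl-homoserine-lactone (AHL) quorum sensing, a LuxI-family synthase
produces the diffusible signal and a LuxR-family regulator binds it through
an N-terminal autoinducer-binding domain and acts on DNA through a
C-terminal helix-turn-helix. Genomes carry these genes in several
arrangements with different biological readings: the canonical adjacent
*luxI/R* pair (a complete circuit), *luxR* solos (listeners without a
cognate synthase), *luxI* solos (speakers without a cognate receiver), and
tandem-duplicated regulator loci (*luxR-luxR-luxI*) whose partners can be
highly diverged. `luxcensus` turns annotated genomes into a reproducible
census of these arrangements.

The package deliberately consumes *annotation products* — protein FASTA,
GFF3 coordinates, and protein-domain hit tables from hmmscan (domtblout) or
InterProScan (TSV) — rather than running gene callers or domain scanners
itself. Counts can therefore shift with the upstream gene caller; that is a
property of any annotation-based census and is documented rather than
hidden.

## Authentication: the two-tier signature rule

Candidate proteins are shortlisted by a Pfam profile-HMM prefilter: a hit
to the autoinducer-binding domain (PF03472, regulators) or the autoinducer
synthase domain (PF00765, synthases) with e-value strictly below `1e-5`.
The strict inequality is intentional: a hit at exactly `1e-5` is dropped.
The per-domain independent e-value (domtblout `i-Evalue`) is used, because
the prefilter is a per-domain criterion. When input comes from InterProScan
without usable e-values the prefilter is advisory and authentication rests
entirely on the second tier.

The second tier is a set-membership completeness test on InterPro
signatures. An authentic LuxR homolog must carry all four of IPR005143
(autoinducer binding), IPR016032 (response-regulator C-terminal effector),
IPR011991 (winged helix-turn-helix) and IPR000792 (LuxR C-terminal); an
authentic LuxI homolog must carry both IPR001690 and IPR018311. A protein
with a non-empty proper subset of the LuxR set is `LUXR_LIKE_INCOMPLETE`;
when the missing signature is the N-terminal autoinducer-binding one while
the C-terminal LuxR signature is present, the verdict additionally flags a
suspected N-terminal truncation — the footprint of a regulator relic next
to a *luxI* solo. Signature hits repeated across protein regions count
once; the rule is set membership, not hit counting.

Degenerate input — a protein complete for both rule sets — does not occur
in real data we know of; it is reported with *both* verdicts and a
`dual_role` flag rather than silently resolved, and the arrangement caller
treats it in the regulator role with a warning.

## Arrangement calling

"Close proximity" is quantified by a configurable policy: cognate members
must lie on the same contig, at most 3 intervening genes apart and at most
5,000 bp apart (both limits must hold). These defaults are calibrated so
that a regulator four genes downstream of a *luxI/R* pair remains a solo,
matching how such a case is treated in the literature this package
operationalizes.

Double loci (two same-strand regulators within policy of each other plus a
synthase within policy of either) take precedence over canonical pairs;
otherwise the middle regulator of a *luxR-luxR-luxI* trio would be stolen
as a pair partner. Within those precedence rules the assignment maximizes,
lexicographically, the number of double loci and then of canonical pairs,
preferring smaller total intergenic distance (and then smaller start
coordinates) among optima. We chose an exact per-contig search over a pure
nearest-first greedy because greedy pairing is provably suboptimal on
crossing proximity windows (R1 … I1 … R2 … I2 with R1–I2 out of range:
greedy takes R2–I1 and strands two solos where two pairs exist); the exact
search restores the intended "as many circuits as the geometry supports"
reading and is what the exhaustive-search property test asserts. Lux genes
per contig are few in practice, so the search is cheap; contigs with more
than 14 lux genes fall back to a documented greedy.

Every call records the strand relations of its members (tandem /
convergent / divergent) rather than enforcing any of them: published
descriptions of the double arrangement use "tandem" for the regulator pair
and "convergent" in figure legends, and we compute both relations instead
of guessing a single intended constraint. LuxI solos additionally record
the intergenic distance to the nearest upstream gene (relative to the
solo's own strand) — upstream non-coding stretches beyond ~800 bp are an
argument against a decayed pair — and whether an immediately adjacent gene
is `LUXR_LIKE_INCOMPLETE`.

A conservation law is asserted on every run: the number of authentic
regulators equals `2·doubles + pairs + luxR solos`, and synthases equal
`doubles + pairs + luxI solos`.

## Neighborhood topology typing

For each double locus the products of up to 8 genes downstream of the
synthase (reading away from the regulator pair) are normalized through a
case-insensitive synonym map (`"hypothetical protein"` → wildcard `X`,
phytanoyl dioxygenase → `phyH`, and so on) and matched against a catalog,
longest pattern first. The shipped catalog pre-populates only the fully
characterized topology `T` = `phyH, X, virB1, virB2, virB3`; the published
variants T1–T6 are defined only in a figure, so their gene content is not
guessed — users encode variants in a YAML catalog from their own
inspection. Anything unmatched is `UNTYPED`.

## Residue analysis in reference numbering

Candidate regulators are mapped onto TraR numbering by global
Needleman–Wunsch alignment (BLOSUM62; affine gaps, a gap of length
L costs 10 + L). Pairwise alignment — rather than the multiple alignment a
figure-oriented analysis would use — keeps numbering deterministic and
dependency-free; an `alignment` argument accepts externally aligned rows
(e.g. two rows of an MSA) for users who prefer that route. The regulator
map carries the invariant autoinducer-binding sites W57, Y61, D70, W85 and
DNA-binding sites E178, L182, G188; a Y61W substitution raises the PAB-like
flag (the hallmark of plant-associated-bacteria LuxR solos). The synthase
(TraI-numbered) map ships with an empty, fill-in site list: the ten
synthase-active residues are defined in structural literature we do not
transcribe from a figure.

The packaged TraR/TraI reference sequences are deterministic *synthetic
stand-ins*, labelled as such in their fixture files: random-but-frozen
sequences constructed to carry the expected residues at the numbered
positions. The analysis consumes only the numbering and expected residues,
so any user can substitute the biological references by editing the YAML
fixtures; the engineered-substitution tests and examples are unaffected by
the stand-in choice.

## Identity matrices

Percent identity is computed over the same global alignment engine:
100 × identical pairs / columns where both sequences have a residue
(default), or / full alignment length (`full_length` mode, always ≤ the
default; exposed because published identity-matrix tools differ in gap
handling and the upstream choice is not documented). `group_summary()`
contrasts within-locus partner identity against cross-locus same-slot
identity; because the published "same group" wording is ambiguous between
those two readings, the grouping is an explicit input and both statistics
are returned.

## The synthetic-genome generator

The generator is first-class, tested code: it emulates a multi-contig
annotated draft genome with planted arrangements, matching domain-hit
tables and machine-readable truth labels, so the full pipeline is
exercisable end-to-end without downloads.

Fixed study conditions (chosen once, documented here):

* Gene lengths uniform in 750–900 bp; intra-block intergenic gaps 50–200 bp
  (lux operon spacing); background gaps 50–400 bp.
* Planted blocks are separated by 6,000 bp spacers, beyond the default
  5,000 bp policy radius, so two planted arrangements can never merge.
* True signature hits draw e-values log-uniform in `[1e-50, 1e-6]`; decoy
  prefilter hits draw log-uniform in `[1e-4, 1]` — both straddle the `1e-5`
  cut from the correct side.
* Decoy background genes (probability `decoy_rate`) receive either a
  sub-threshold prefilter domain or one-to-two regulator signatures — never
  a complete set, so a correct classifier must never authenticate them.
* Planted proteins start from packaged seed sequences (synthetic LuxR- and
  LuxI-family stand-ins ~30% diverged from the reference stand-ins, with
  the invariant sites held fixed) and are diverged by per-residue
  substitution at `mutation_rate`; substitution is uniform over the 19
  alternative residues, length-preserving, with no indels.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: realistic nucleotide evolution, indels and frameshift
relics, operon structure, annotation noise in coordinates, and domain
scanners' partial-hit behavior on genuinely truncated proteins (truncated
regulators are planted with a clean signature subset instead). Planted
truth recovery therefore validates the *logic* of the rule engine and the
arrangement caller, not the upstream annotation stack.

## Numerical and degenerate-input choices

* Coordinates stay 1-based inclusive (GFF3 convention) end-to-end; the
  intergenic gap between genes is `start_right − end_left − 1`, clamped at
  0 for overlapping genes.
* Alignment tie-breaks are delegated to one fixed engine configuration;
  scores are checked against an independent brute-force DP in the tests,
  so any engine change that altered scores would be caught.
* Identity of a gapless identical pair is exactly 100 by construction (the
  diagonal is set, not computed, avoiding float drift).
* Empty inputs produce empty, well-typed tables; report files are emitted
  with stable sort keys so reruns are byte-identical.
* Problem sizes in the shipped tests and scripts (50 random bundles for
  truth recovery, 200 random pairs for the alignment oracle, 12-genome
  analysis cohort) were chosen as the smallest sizes at which the
  stochastic properties are stable.

## Known limitations

* The census is only as good as its annotation inputs; genomes annotated
  with different gene callers can shift counts (same-contig policy also
  means heavily fragmented assemblies under-call pairs).
* Topology variants beyond `T` must be user-supplied.
* The synthase site list ships empty pending transcription from the
  structural literature.
* The packaged 62-genome census table is a transcription of a printed
  table whose internal inconsistencies (documented in
  `inst/extdata/table3_notes.md`) are preserved, not resolved.
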