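# luxcensus

Genome-wide census of LuxI/LuxR quorum-sensing gene circuits in annotated
bacterial genomes.

## The problem

Gram-negative bacteria coordinate density-dependent behaviour through
N-acyl homoserine lactone (AHL) quorum sensing: a LuxI-family synthase
produces the AHL signal, and a LuxR-family transcriptional regulator —
N-terminal autoinducer-binding domain, C-terminal helix-turn-helix — binds
it and reprograms transcription. Beyond the canonical adjacent *luxI/R*
pair, genomes carry *luxR* solos (receivers with no cognate synthase),
*luxI* solos (senders with no cognate receiver) and tandem-duplicated
regulator loci (*luxR-luxR-luxI*) whose partners can be deeply diverged.
Mapping which genomes carry which arrangements is the first step in any
comparative study of a family's signalling capacity; `luxcensus` makes that
census reproducible for anyone with standard annotation products in hand.

## What it computes

From a per-genome bundle — protein FASTA, GFF3 coordinates, and domain-hit
tables (HMMER3 `domtblout` or InterProScan TSV):

1. **Authentication** (two-tier rule): Pfam prefilter at e-value < 1e-5 on
   the autoinducer-binding (PF03472) / synthase (PF00765) domains, then an
   InterPro completeness test — LuxR requires all of {IPR005143, IPR016032,
   IPR011991, IPR000792}; LuxI requires {IPR001690, IPR018311}. Partial
   LuxR signature sets yield `LUXR_LIKE_INCOMPLETE`, with an N-terminal
   truncation flag when the autoinducer-binding signature is the one
   missing.
2. **Arrangement calling** under a proximity policy (same contig, ≤ 3
   intervening genes, ≤ 5 kb): `double_luxR_luxI` (doubles take precedence),
   `canonical_pair`, `luxR_solo`, `luxI_solo`, with strand relations,
   upstream intergenic distance for luxI solos, and adjacent
   truncated-regulator flags. The counts always satisfy
   #LuxR = 2·doubles + pairs + luxR solos and
   #LuxI = doubles + pairs + luxI solos.
3. **Neighborhood topology typing** of double loci against a catalog
   (shipped: topology `T` = *phyH*, hypothetical, *virB1*, *virB2*, *virB3*).
4. **Residue profiling** in TraR numbering via global Needleman–Wunsch
   alignment (BLOSUM62, affine gaps): conservation at W57, Y61, D70, W85
   (autoinducer binding) and E178, L182, G188 (DNA binding); Y61W raises
   the PAB-like (plant-associated-bacteria solo) flag.
5. **Pairwise percent-identity matrices** and within-locus vs cross-locus
   partner identity for double-LuxR sets.
6. **Census tables**: per-genome rows and per-genus rollups; a packaged
   transcription of the published 62-genome sphingomonad census ships as a
   fixture.

A synthetic-genome generator plants all of the above arrangements (plus
decoy regulators and truncated relics) with truth labels, so the whole
pipeline is testable end-to-end with no downloads.

## Worked example

```r
library(luxcensus)

cfg <- synthetic_config(
  n_contigs = 1, n_background_genes = 3,
  arrangements = tibble::tibble(category = "double_luxR_luxI",
                                topology = "T", contig = 1L),
  mutation_rate = 0.1, seed = 17)
b <- generate_bundle(cfg)
cen <- run_census(b$genes, b$proteins, b$hits)
cen
#> Census of synthG: 0 canonical pair(s), 1 double(s) [T], 0 luxI solo(s), 0 luxR solo(s)
cen$calls[, c("category", "gene_ids", "strands", "topology_label")]
#> # A tibble: 1 × 4
#>   category         gene_ids                               strands topology_label
#>   <chr>            <chr>                                  <chr>   <chr>
#> 1 double_luxR_luxI synthG_g0002;synthG_g0003;synthG_g0004 +;+;-   T
```

The call says: one convergent double locus — two tandem (+/+) regulators
followed by a convergent (−) synthase — whose downstream neighborhood
matched the full `T` pattern. Residue-profile the first regulator (its
sequence was diverged from the seed at `mutation_rate = 0.1`, so one
invariant site happened to be hit):

```r
reg <- b$proteins[b$proteins$gene_id == "synthG_g0002", ]
check_conserved_sites(reg, site_map_trar())
#> Substitution report for synthG_g0002 vs TraR
#>   7 site(s): 6 conserved, 1 substituted, 0 missing
#>   substitutions: W85K
```

A W85K call means the residue aligned to TraR position 85 — one of the
four autoinducer-binding invariants — is a lysine in this regulator, an
argument against normal AHL binding.

The analysis workflow in `analysis/01_simulate.R` … `05_table3.R` runs the
same machinery over a 12-genome simulated cohort and over the packaged
62-genome census fixture, writing tables under `results/`; for example
`05_table3.R` prints:

```
Family census: 62 genomes; 40 with >=1 luxR, 33 with >=1 luxI; per genus
(with lux / total): Novosphingobium 7/11, Sphingobium 18/24,
Sphingomonas 11/22, Sphingopyxis 4/5
```

— i.e. 40 of the 62 family genomes carry at least one authenticated
regulator and 33 at least one synthase.

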