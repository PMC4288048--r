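# Notes on the packaged family census fixture

`table3_sphingomonads.tsv` transcribes, verbatim, the published per-genome
rows of the 62-genome sphingomonad lux census (40 genomes with at least one
lux homolog; 22 lux-free genomes appear only through the genus totals in
`table3_genus_totals.tsv`).  Topology labels in `double_topologies` are the
printed neighborhood variant labels (T1-T6).

Known internal inconsistencies of the printed source, deliberately NOT
reconciled here (the fixture reports what the table rows say):

- The abstract counts "13 Sphingobium and one Sphingomonas" genomes with
  the tandem double-regulator arrangement; the table rows give 11
  Sphingobium and 2 Sphingomonas (MM1, SKA58).
- The results text says 33 genomes contain "at least 1 putative canonical
  luxI/R homolog pair"; the table rows give 26 genomes with a canonical
  pair.  33 is the number of genomes with at least one luxI by the table's
  arithmetic, matching the abstract's luxI count.
- The abstract names Sphingobium yanoikuyae B1 as carrying seven luxR-
  homologous ORFs; the B1 table row (2 canonical, 1 luxR solo) accounts for
  3, while the ATCC 51230 row (2 canonical, 1 luxI solo, 5 luxR solos)
  accounts for 7 regulators.
- The abstract names three genomes with four luxI (SYK6, S. japonicum,
  S. lactosutens); by table arithmetic these rows carry 3 luxI each.

Row and genus-total arithmetic that DOES check out, and that the rollup
tests assert: 40 genomes with >=1 luxR; 33 with >=1 luxI; genus headers
7/11, 18/24, 11/22, 4/5; per-genus category genome counts [6,0,0,3],
[11,11,8,12], [5,2,0,7], [4,0,0,0]; 2 unpaired luxI in strain KK22.
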