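#!/usr/bin/env Rscript
# Profile every authenticated regulator from the census against the
# TraR-numbered invariant sites (autoinducer binding: W57, Y61, D70, W85;
# DNA binding: E178, L182, G188) and tabulate conservation, substitutions
# and PAB-like (Y61W) flags.

suppressMessages(library(luxcensus))

manifest <- read.delim("results/simulated/manifest.tsv")
verdicts <- read.delim("results/census/verdicts.tsv")
out <- "results/residues"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

m <- site_map_trar()
rows <- NULL; flags <- 0L
for (k in seq_len(nrow(manifest))) {
  prots <- read_fasta(file.path(manifest$dir[k], "proteins.faa"))
  lr <- verdicts$gene_id[verdicts$verdict == "AUTHENTIC_LUXR" &
                           verdicts$gene_id %in% prots$gene_id]
  for (g in lr) {
    rep <- check_conserved_sites(prots[prots$gene_id == g, ], m)
    flags <- flags + rep$pab_like_flag
    rows <- rbind(rows, data.frame(gene_id = g, rep$sites,
                                   pab_like = rep$pab_like_flag))
  }
}
write.table(rows, file.path(out, "site_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_prot <- length(unique(rows$gene_id))
message(sprintf(
  "Profiled %d regulators at %d TraR-numbered sites: %.1f%% site-calls conserved, %d substituted, %d in gaps; %d PAB-like (Y61W) flag(s)",
  n_prot, nrow(m$sites),
  100 * mean(rows$status == "conserved"),
  sum(rows$status == "substituted"), sum(rows$status == "missing"), flags))
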