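#!/usr/bin/env Rscript
# Cross-references DMR-associated genes with the differential-expression
# table and relates 24-nt siRNA loci to gene/TE metagene zones and to
# hyper- vs hypomethylated DMRs (the RdDM-motivated summaries).

suppressMessages({library(methscape); library(data.table)})
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

a <- read_count_table("results/sim/counts_stage1.tsv")
b <- read_count_table("results/sim/counts_stage2.tsv")
genes <- read_features("results/sim/genes.bed")
tes <- read_features("results/sim/tes.bed")
expr <- fread("results/sim/expression.tsv")
sirna <- read_features("results/sim/sirna.bed")
sirna[, length := end - start + 1L]

dmrs <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(cx)
  call_dmrs(a, b, cx)), use.names = TRUE)
assoc <- associate_dmrs(dmrs, genes)

deg <- dmr_deg_intersection(assoc, expr)
fwrite(deg$counts, "results/tables/dmr_deg_counts.tsv", sep = "\t")
if (nrow(deg$venn)) fwrite(deg$venn, "results/tables/dmr_deg_venn.tsv",
                           sep = "\t")
cat("DMR-related DEGs per context:\n"); print(deg$counts)

pg <- sirna_positional_abundance(sirna, genes)
fwrite(pg, "results/tables/sirna_gene_profile.tsv", sep = "\t")
pt <- sirna_positional_abundance(sirna, tes)
fwrite(pt, "results/tables/sirna_te_profile.tsv", sep = "\t")
dens <- pg[, .(loci = sum(n_loci)), by = zone]
cat("24-nt siRNA loci by gene zone:",
    paste(sprintf("%s %d", dens$zone, dens$loci), collapse = ", "), "\n")

ov <- sirna_dmr_overlap(sirna, dmrs)
fwrite(ov, "results/tables/sirna_dmr_overlap.tsv", sep = "\t")
cat("siRNA loci inside DMRs (direction x context):\n")
print(dcast(ov, direction ~ context, value.var = "n_loci"))
cat("the simulation places a fraction of siRNA loci inside spiked DMRs,",
    "so DMR cells exceed the uniform background expectation\n")
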