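#!/usr/bin/env Rscript
# Genome-scale methylome summaries for each stage: per-context methylated-site
# fractions, coverage by chromosome and TE class, methylation-level
# histograms, and 9-bp neighbourhood composition of C vs mC populations.

suppressMessages({library(methscape); library(data.table)})
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

sites <- read_cytosine_report("results/sim/cytosine_report.tsv")
tes <- read_features("results/sim/tes.bed")
stages <- c("stage1", "stage2")

for (st in stages) {
  ct <- read_count_table(sprintf("results/sim/counts_%s.tsv", st))

  gf <- global_fractions(ct)
  fwrite(gf, sprintf("results/tables/global_fractions_%s.tsv", st), sep = "\t")
  cat(sprintf("[%s] mC fractions (covered denominators): %s\n", st,
              paste(sprintf("%s %.2f%%", gf$context, 100 * gf$frac_covered),
                    collapse = ", ")))

  cov <- coverage_summary(ct, tes, class_col = "te_class")
  fwrite(cov, sprintf("results/tables/coverage_summary_%s.tsv", st), sep = "\t")

  hist_tab <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(cx) {
    h <- level_histogram(ct, cx)
    data.table(context = cx, bin_lo = head(h$bin_edges, -1),
               bin_hi = tail(h$bin_edges, -1), proportion = h$proportions)
  }))
  fwrite(hist_tab, sprintf("results/tables/level_histograms_%s.tsv", st),
         sep = "\t")
  chh <- hist_tab[context == "CHH"]
  cat(sprintf("[%s] mCHH mass in (0.1,0.4]: %.1f%%; mCG mass >0.9: %.1f%%\n",
              st, 100 * chh[bin_lo >= 0.1 & bin_hi <= 0.4, sum(proportion)],
              100 * hist_tab[context == "CG" & bin_lo == 0.9, proportion]))

  ctn <- merge(ct, sites[, .(chrom, pos, strand, neighborhood)],
               by = c("chrom", "pos", "strand"))
  comp <- neighborhood_composition(ctn, "CHH")
  compdt <- rbindlist(lapply(c("C", "mC"), function(pop)
    data.table(population = pop, base = rownames(comp[[pop]]),
               as.data.table(comp[[pop]]))))
  fwrite(compdt, sprintf("results/tables/chh_neighborhood_%s.tsv", st),
         sep = "\t")
}
cat("written: results/tables/{global_fractions,coverage_summary,",
    "level_histograms,chh_neighborhood}_<stage>.tsv\n", sep = "")
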