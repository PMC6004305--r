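#!/usr/bin/env Rscript
# Builds the simulated WGBS study: a 200-kb two-chromosome genome with gene
# and TE annotations, two developmental stages whose methylomes share a
# baseline (mCG/CG 0.81, mCHG/CHG 0.64, mCHH/CHH 0.05) with stage-specific
# spiked DMRs, per-stage count tables at ~27x depth, an expression table and
# 24-nt siRNA loci. Everything downstream reads from results/sim/.

suppressMessages(library(methscape))

cfg <- sim_config(seed = 1L, expression_coupling = TRUE)
bundle <- simulate_bundle(cfg, "results/sim", reads = FALSE)

cat("genome:", sum(Biostrings::width(bundle$genome)), "bp over",
    length(bundle$genome), "chromosomes\n")
cat("annotations:", nrow(bundle$genes), "genes,", nrow(bundle$tes), "TEs\n")
cat("cytosine sites:", nrow(bundle$sites), " (",
    sum(!is.na(bundle$sites$context)), "with defined context)\n")
cat("spiked DMRs:", nrow(bundle$truth$spikes), "(",
    paste(capture.output(print(table(bundle$truth$spikes$context)))[2],
          collapse = " "), ")\n")
cat("stages:", paste(cfg$stages, collapse = ", "),
    "| mean depth stage1:",
    round(mean(bundle$counts$stage1$n_meth + bundle$counts$stage1$n_unmeth), 2),
    "\n")
cat("files under results/sim/:", paste(basename(unlist(bundle$paths)),
                                       collapse = ", "), "\n")
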