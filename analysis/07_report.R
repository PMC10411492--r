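#!/usr/bin/env Rscript
# Stage 7: collate the stage outputs into one plain-text report.

fmt <- function(...) cat(sprintf(...), sep = "")
sink("results/report.txt", split = TRUE)

fmt("chromosome-aware gene-conflict analysis: run report\n")
fmt("==================================================\n\n")

qc <- read.delim("results/qc_report.tsv")
kept <- readLines("results/qc_kept_loci.txt")
fmt("QC: %d loci retained; %d filter actions\n", length(kept), nrow(qc))
for (r in names(table(qc$rule)))
  fmt("  %-18s %d\n", r, sum(qc$rule == r))

ls <- jsonlite::read_json("results/linkage_summary.json")
fmt("\nlinkage: male X vs female X p = %.3g (effect %.2f log2)\n",
    ls$male_x_vs_female_x$p, ls$male_x_vs_female_x$effect)
fmt("         male X vs male A   p = %.3g (effect %.2f log2)\n",
    ls$male_x_vs_male_a$p, ls$male_x_vs_male_a$effect)
fmt("         classification accuracy %.3f, Jaccard %.3f\n",
    ls$accuracy, ls$jaccard)

reg <- read.delim("results/signal_regimes.tsv")
fmt("\nper-edge signal regimes (X bin relative to autosomal bin):\n")
for (i in seq_len(nrow(reg)))
  fmt("  %-6s %-34s %-20s (A %.4f, X %.4f nats/bp)\n", reg$data[i],
      substr(reg$edge[i], 1, 34), reg$regime[i], reg$median_A[i],
      reg$median_X[i])

gc <- read.delim("results/grove_composition.tsv")
fmt("\ngroves:\n")
for (i in seq_len(nrow(gc)))
  fmt("  grove %d: %d loci, %d X-linked (%.1f%%)\n", gc$grove[i],
      gc$n_loci[i], gc$n_X[i], gc$pct_X[i])

sink()
cat("\nreport written to results/report.txt\n")
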