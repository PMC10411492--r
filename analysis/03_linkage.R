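#!/usr/bin/env Rscript
# Stage 3: confirm X-linkage from read depth of sexed samples.
#
# After per-sample autosomal-median normalization, male depth at X loci
# should sit near half the female depth (hemizygous X). Rank-sum tests
# compare male-X vs female-X and male-X vs male-autosome per-locus
# medians; each locus also gets a log2 male:female score and a
# predicted_X / predicted_A call at the -0.5 boundary.

suppressMessages(library(phyloconflict))
cov <- read_coverage("results/fixture/coverage")

res <- group_depth_test(cov)
print(res)

scores <- per_locus_linkage_score(cov)
write.table(scores, "results/linkage_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- cov$linkage
pred_x <- scores$locus[scores$predicted == "predicted_X"]
truth_x <- names(truth)[truth == "X"]
acc <- mean((scores$locus %in% pred_x) == (scores$locus %in% truth_x))
jac <- length(intersect(pred_x, truth_x)) / length(union(pred_x, truth_x))
cat(sprintf("classification vs reference labels: accuracy %.3f, Jaccard %.3f\n",
            acc, jac))

jsonlite::write_json(list(
  male_x_vs_female_x = res$male_x_vs_female_x,
  male_x_vs_male_a = res$male_x_vs_male_a,
  accuracy = acc, jaccard = jac),
  "results/linkage_summary.json", auto_unbox = TRUE, digits = NA)
cat("scores: results/linkage_scores.tsv\n")
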