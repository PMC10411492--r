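#!/usr/bin/env Rscript
# Stage 6: ordinate the analysis topologies in RF tree space.
#
# At desk scale the "analysis trees" are the species tree plus a medoid
# gene tree per grove (the gene tree with the smallest summed weighted-RF
# distance to its grove mates) -- the same kind of between-analysis
# ordination used to compare topologies from different data subsets.

suppressMessages(library(phyloconflict))
fixdir <- "results/fixture"
species_tree <- read_newick(file.path(fixdir, "species_tree.nwk"))
genetrees <- read_newick(file.path(fixdir, "genetrees.nwk"))
asg <- read.delim("results/grove_assignment.tsv")

trees <- list(reference = ape::unroot(species_tree))
for (g in sort(unique(asg$grove))) {
  ids <- asg$locus[asg$grove == g]
  sub <- genetrees[ids]
  d <- tree_distance_matrix(sub, support_collapse = NULL)
  medoid <- ids[which.min(rowSums(d))]
  trees[[paste0("grove", g)]] <- genetrees[[medoid]]
}

ts <- topology_space(trees)
co <- ts$coords[, seq_len(min(2, ncol(ts$coords))), drop = FALSE]
colnames(co) <- paste0("axis", seq_len(ncol(co)))
out <- data.frame(analysis = rownames(co), co, row.names = NULL)
write.table(out, "results/treespace_coords.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(axis = seq_along(ts$eigenvalues),
                       eigenvalue = ts$eigenvalues),
            "results/treespace_screeplot.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(out)
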