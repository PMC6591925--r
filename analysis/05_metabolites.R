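#!/usr/bin/env Rscript
# Stage 5: fecal bile-acid proportion analysis.
#
# Expresses each bile acid as a proportion of the sample's total BA level,
# sums proportions by class (primary / secondary / conjugated primary) and
# compares both individual metabolites and class totals between groups.

library(bsbtools)

outdir <- "results/metabolites"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

lev_df <- read.delim("results/simulated/metabolite_levels.tsv",
                     check.names = FALSE)
levels <- as.matrix(lev_df[, -1])
rownames(levels) <- lev_df[[1]]
metadata <- read.delim("results/simulated/metadata.tsv")

props <- to_proportions(levels)
write.table(data.frame(metabolite = rownames(props), signif(props, 6),
                       check.names = FALSE),
            file.path(outdir, "proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cp <- class_proportions(props)
grp <- metadata$group[match(cp$sample_id, metadata$sample_id)]
message("mean secondary-BA proportion per group:")
sec <- tapply(cp$secondary_total, grp, mean)
message(paste(" ", names(sec), "=", signif(sec, 3), collapse = "\n"))

cmp <- compare_metabolites(props, metadata)
write.table(cmp$per_metabolite,
            file.path(outdir, "metabolite_comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cmp$per_class, file.path(outdir, "class_comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cls <- cmp$per_class
message("class-level comparisons:")
for (k in seq_len(nrow(cls))) {
  message(sprintf("  %s %s vs %s: mean %.3f vs %.3f, p = %.2g %s",
                  cls$name[k], cls$group1[k], cls$group2[k], cls$mean1[k],
                  cls$mean2[k], cls$p_value[k], cls$stars[k]))
}
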