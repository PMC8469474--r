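#!/usr/bin/env Rscript
# Levins' habitat niche breadth per community class and layer: per-sample
# community breadths, paired topsoil-vs-subsoil t-tests per class, and a
# Tukey compact letter display across overall / abundant / rare classes.

library(soilbeta)
seed <- 20260919L

table <- read_otu_table("results/data/otu_table.tsv")
md <- read_metadata("results/data/metadata.tsv", "results/data/group_map.tsv")
md <- md[match(rownames(table), md$sample_id), ]
table <- rarefy(table, min(rowSums(table)), seed = seed)
table <- table[, colSums(table) > 0]
part <- partition_by_abundance(table)
classes <- list(overall = colnames(table), abundant = part$abundant_ids,
                rare = part$rare_ids)

vals <- list()
for (layer in c("topsoil", "subsoil")) {
  t0 <- table[md$sample_id[md$layer == layer], ]
  t0 <- t0[, colSums(t0) > 0]
  for (cl in names(classes)) {
    sb <- sample_breadths(t0, classes[[cl]])
    vals[[paste(layer, cl)]] <- data.frame(
      site = md$site_id[match(names(sb), md$sample_id)], layer = layer,
      class = cl, value = unname(sb))
  }
}
breadths <- do.call(rbind, vals)
breadths <- breadths[!is.na(breadths$value), ]
cmp <- compare_breadths(breadths)
print(cmp)
write.table(breadths, "results/niche_breadth_samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(merge(cmp$classes, cmp$paired, by = "class"),
            "results/niche_breadth_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
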