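#!/usr/bin/env Rscript
# Stage 4: cluster the persistent responders on their temporal profiles
# (per-condition replicate means over the mesoderm + ES time courses,
# 1 - Pearson correlation, average linkage) and split the tree at the root.
# The arm with the stronger ES-cell response is group 1 (ectopic endoderm
# program, Dex-responsive in ES too); the other arm is group 2 (precocious
# cardiac program, DKO-mesoderm-specific).

library(methgate)

out_dir <- "results/clustering"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
norm <- read_expression("results/expression/gene_expression_normalized.tsv",
                        "results/expression/design.tsv")
pers <- read_gene_set("results/responders/persistent_responders.txt")

prof <- condition_profiles(norm$exprs, norm$design, pers$members)
tree <- average_linkage_cluster(pearson_distance(prof))
write_newick(tree, file.path(out_dir, "persistent_tree.nwk"))
writeLines(tree$labels[tree$order], file.path(out_dir, "heatmap_row_order.txt"))

d <- norm$design
es_fit <- fit_moderated_t(norm$exprs, contrast_spec(
  d$sample_id[d$context == "ES" & d$genotype == "DKO" &
                d$treatment == "DexM" & d$time_h == 72],
  d$sample_id[d$context == "ES" & d$genotype == "DKO" &
                d$treatment == "DexP" & d$time_h == 72],
  label = "ES_DKO_response_72h"))
es <- setNames(es_fit$table$log2fc, es_fit$table$gene)
sp <- split_groups(tree, es)
assign_tab <- data.frame(
  gene = names(sp$cut), cluster = as.integer(sp$cut),
  group = ifelse(names(sp$cut) %in% sp$group1$members, "group1", "group2"),
  es_log2fc = round(es[names(sp$cut)], 4))
write.table(assign_tab, file.path(out_dir, "cluster_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("clustered %d persistent responders: group1 %d (mean ES lfc %.2f), group2 %d (%.2f)\n",
            length(pers), length(sp$group1),
            mean(es[sp$group1$members]), length(sp$group2),
            mean(es[sp$group2$members])))
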