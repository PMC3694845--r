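#!/usr/bin/env Rscript
# Stage 3: the Venn cascade. Three "up in induced DKO mesoderm" 2-fold
# selections — vs induced WT (i), vs uninduced DKO (ii), vs the DKO t=0
# baseline (iii) — are intersected at 72 h and 24 h; the triple overlap is
# the hyper-responsive set, the 24h/72h overlap the persistent responders.
# The short-term experiment gives the 3 h immediate responders and their
# overlap with the persistent set.

library(methgate)

out_dir <- "results/responders"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
norm <- read_expression("results/expression/gene_expression_normalized.tsv",
                        "results/expression/design.tsv")

h72 <- extract_hyper_responsive(norm$exprs, norm$design, 72)
h24 <- extract_hyper_responsive(norm$exprs, norm$design, 24)
pers <- persistent_responders(h24$genes, h72$genes)

venn_tab <- data.frame(region = names(h72$venn$counts),
                       count_72h = as.integer(h72$venn$counts),
                       count_24h = as.integer(h24$venn$counts))
write.table(venn_tab, file.path(out_dir, "venn_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gene_set(h72$genes, file.path(out_dir, "hyper_responsive_72h.txt"))
write_gene_set(h24$genes, file.path(out_dir, "hyper_responsive_24h.txt"))
write_gene_set(pers, file.path(out_dir, "persistent_responders.txt"))
for (nm in names(h72$venn$regions))
  write_gene_set(h72$venn$regions[[nm]],
                 file.path(out_dir, sprintf("venn72_%s.txt", nm)))

cat("Venn region counts (72 h / 24 h):\n")
print(venn_tab, row.names = FALSE)
cat(sprintf("hyper-responsive: %d @72h, %d @24h; persistent overlap %d\n",
            length(h72$genes), length(h24$genes), length(pers)))

im <- read_expression("results/data/expression_immediate.tsv",
                      "results/data/design_immediate.tsv")
probe_map <- read.table("results/data/probe_map.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
genes_im <- merge_probes_to_genes(quantile_normalize(im$exprs), probe_map)
immediate <- immediate_responders(genes_im, im$design)
overlap <- intersect(immediate$members, pers$members)
write_gene_set(immediate, file.path(out_dir, "immediate_responders_3h.txt"))
write_gene_set(overlap, file.path(out_dir, "immediate_and_persistent.txt"))
cat(sprintf("immediate responders at 3 h: %d; of these %d are persistent\n",
            length(immediate), length(overlap)))
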