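#!/usr/bin/env Rscript
# Stage 7: collate the stage outputs into one machine-readable summary and
# score the recovered gene sets against the planted truth written by stage 1.

library(methgate)

truth <- read.table("results/data/planted_truth.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
read_set <- function(p) read_gene_set(p)$members
h72 <- read_set("results/responders/hyper_responsive_72h.txt")
h24 <- read_set("results/responders/hyper_responsive_24h.txt")
pers <- read_set("results/responders/persistent_responders.txt")
imm <- read_set("results/responders/immediate_responders_3h.txt")
ovl <- read_set("results/responders/immediate_and_persistent.txt")
assign_tab <- read.table("results/clustering/cluster_assignments.tsv",
                         header = TRUE, sep = "\t", stringsAsFactors = FALSE)
cmp_tab <- read.table("results/expression/comparison_counts.tsv",
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
peaks <- read_bed("results/chip/peaks.bed")
links <- read.table("results/chip/peak_gene_links.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
meth <- read.table("results/bisulfite/comparison.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)

planted <- truth$gene[truth$archetype %in% c("group1_endoderm",
                                             "group2_cardiac")]
universe <- truth$gene
score <- recovery_stats(pers, planted, universe)

summary <- list(
  gene_sets = list(hyper_72h = length(h72), hyper_24h = length(h24),
                   persistent = length(pers), immediate_3h = length(imm),
                   immediate_and_persistent = length(ovl)),
  recovery_vs_truth = list(sensitivity = score$sensitivity,
                           specificity = score$specificity),
  group_split = as.list(table(assign_tab$group)),
  comparison_counts = cmp_tab[, c("comparison", "up_2fold", "down_2fold",
                                  "up_4fold", "down_4fold")],
  peaks = list(n_peaks = nrow(peaks), n_links = nrow(links)),
  methylation = as.list(meth[1, c("percent_wt", "percent_dko", "delta",
                                  "fisher_p")])
)
dir.create("results", showWarnings = FALSE)
jsonlite::write_json(summary, "results/summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, dataframe = "rows")
cat("persistent responders:", length(pers),
    sprintf("(sensitivity %.3f, specificity %.3f vs planted truth)\n",
            score$sensitivity, score$specificity))
cat("wrote results/summary.json\n")
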