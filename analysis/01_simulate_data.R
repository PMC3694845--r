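#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input for the analysis and write it to
# disk in the plain-text formats the rest of the workflow reads back:
# probe-level expression (main time course + short-term 0-3 h experiment)
# with design sidecars and the probe->gene map, ChIP tag tracks with a gene
# annotation (BED), summit-centered peak-window sequences, and bisulfite
# clone reads (FASTA) for a WT/DKO region pair.

library(methgate)

seed <- as.integer(Sys.getenv("METHGATE_SEED", "1"))
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
cfg <- pipeline_config(seed = seed)

## expression ---------------------------------------------------------------
tc <- simulate_timecourse_expression(cfg$sim, "timecourse")
im <- simulate_timecourse_expression(cfg$sim, "immediate")
write_expression(tc$exprs, tc$design,
                 file.path(data_dir, "expression_timecourse.tsv"),
                 file.path(data_dir, "design_timecourse.tsv"))
write_expression(im$exprs, im$design,
                 file.path(data_dir, "expression_immediate.tsv"),
                 file.path(data_dir, "design_immediate.tsv"))
write.table(tc$probe_map, file.path(data_dir, "probe_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tc$truth, file.path(data_dir, "planted_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("expression: %d probes x %d samples (+ %d short-term samples)\n",
            nrow(tc$exprs), ncol(tc$exprs), ncol(im$exprs)))
cat("planted archetypes:\n")
print(table(tc$truth$archetype))

## ChIP tracks --------------------------------------------------------------
specs <- methgate:::pipeline_chip_specs(cfg)
dko <- simulate_chip_tags(specs$dko)
wt <- simulate_chip_tags(specs$wt)
write_tag_track(dko$experiment, file.path(data_dir, "chip_dko_experiment.txt"))
write_tag_track(dko$background, file.path(data_dir, "chip_dko_background.txt"))
write_tag_track(wt$experiment, file.path(data_dir, "chip_wt_experiment.txt"))
write_bed(dko$annotation, file.path(data_dir, "gene_annotation.bed"))
seqs <- simulate_peak_sequences(specs$dko, n_windows = 200,
                                width = cfg$window_width, motif = cfg$motif)
write_fasta(seqs, file.path(data_dir, "peak_windows.fasta"))
cat(sprintf("ChIP: %d planted peaks (%d DKO-specific), %d + %d tags\n",
            nrow(specs$dko$planted_peaks), sum(specs$dko_specific),
            length(dko$experiment), length(dko$background)))

## bisulfite clones ---------------------------------------------------------
region <- methgate:::pipeline_bisulfite_region(seed + 30L)
write_fasta(stats::setNames(region$sequence, region$name),
            file.path(data_dir, "bisulfite_region.fasta"))
for (g in c("wt", "dko")) {
  p <- if (g == "wt") cfg$meth_prob_wt else cfg$meth_prob_dko
  off <- if (g == "wt") 31L else 32L
  clones <- simulate_bisulfite_clones(bisulfite_sim_spec(
    region$sequence, p, seed = seed + off))
  write_fasta(clones$reads, file.path(data_dir, sprintf("clones_%s.fasta", g)))
}
cat(sprintf("bisulfite: region with %d CpGs, 24 clones per genotype\n",
            length(region$cpg_positions)))
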