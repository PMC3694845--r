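#' Full pipeline configuration
#'
#' Bundles every stage threshold (all named, none hard-coded downstream)
#' with the synthetic-data specifications. Thresholds default to the values
#' used throughout this analysis: fold-change cuts 2 and 4 with p < 0.01,
#' KDE bandwidth 30 bp with candidate threshold 5.0 and background
#' enrichment 3.0, 5 kb peak-to-gene distance, and bisulfite QC at 95%
#' conversion / 90% identity.
#'
#' @param seed master seed; every stage's randomness derives from it.
#' @param n_genes,noise_sd,effect_log2fc forwarded to [sim_config()].
#' @param fc_primary,fc_strong linear fold-change cuts (2 and 4).
#' @param p_max p-value cut.
#' @param bandwidth,candidate_threshold,enrichment_threshold peak-calling
#'   parameters.
#' @param max_distance peak-to-gene association bound, bp.
#' @param central_bin,window_width central motif-enrichment geometry, bp.
#' @param motif IUPAC consensus scanned in peak windows.
#' @param min_conversion,min_identity bisulfite clone QC thresholds.
#' @param meth_prob_wt,meth_prob_dko planted per-CpG methylation
#'   probabilities for the two genotypes.
#' @param out_dir optional directory for stage artifacts and the JSON
#'   summary; `NULL` keeps everything in memory.
#' @param ... further arguments forwarded to [sim_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_genes = 1000, noise_sd = 0.25,
                            effect_log2fc = 2.0,
                            fc_primary = 2, fc_strong = 4, p_max = 0.01,
                            bandwidth = 30, candidate_threshold = 5.0,
                            enrichment_threshold = 3.0, max_distance = 5000,
                            central_bin = 100, window_width = 500,
                            motif = "WGATAR",
                            min_conversion = 0.95, min_identity = 0.90,
                            meth_prob_wt = 0.9, meth_prob_dko = 0.1,
                            out_dir = NULL, ...) {
  stopifnot(fc_primary > 1, fc_strong > 1, p_max > 0, bandwidth > 0,
            candidate_threshold > 0, enrichment_threshold > 0,
            max_distance > 0, min_conversion > 0, min_identity > 0)
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    sim = sim_config(n_genes = n_genes, noise_sd = noise_sd,
                     effect_log2fc = effect_log2fc, seed = seed, ...),
    fc_primary = fc_primary, fc_strong = fc_strong, p_max = p_max,
    bandwidth = bandwidth, candidate_threshold = candidate_threshold,
    enrichment_threshold = enrichment_threshold,
    max_distance = max_distance,
    central_bin = central_bin, window_width = window_width, motif = motif,
    min_conversion = min_conversion, min_identity = min_identity,
    meth_prob_wt = meth_prob_wt, meth_prob_dko = meth_prob_dko,
    out_dir = out_dir
  ), class = "pipeline_config")
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

# planted ChIP layout used by the pipeline: six enriched regions, half
# DKO-specific and half shared with the WT track
pipeline_chip_specs <- function(config) {
  centers <- c(20000, 50000, 80000, 110000, 140000, 170000)
  all_peaks <- data.frame(center = centers, width = 400, enrichment = 10)
  dko_specific <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  list(
    dko = chip_sim_spec(planted_peaks = all_peaks, seed = config$seed + 10L),
    wt = chip_sim_spec(planted_peaks = all_peaks[!dko_specific, ],
                       seed = config$seed + 11L),
    dko_specific = dko_specific
  )
}

# deterministic synthetic bisulfite region: random backbone with CpGs
# guaranteed by construction
pipeline_bisulfite_region <- function(seed, length_bp = 150, n_cpg = 10) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
  at <- round(seq(10, length_bp - 10, length.out = n_cpg))
  for (pos in at) { s[pos] <- "C"; s[pos + 1] <- "G" }
  # remove incidental CpGs elsewhere so planted probabilities map 1:1
  for (i in seq_len(length_bp - 1)) {
    if (s[i] == "C" && s[i + 1] == "G" && !(i %in% at)) s[i + 1] <- "A"
  }
  reference_region("synthetic_region", paste(s, collapse = ""))
}

#' Sensitivity/specificity of a recovered gene set against planted truth
#'
#' @param recovered [gene_set()] or character vector.
#' @param truth_positive character vector of planted positive genes.
#' @param universe all genes under consideration.
#' @return list: `sensitivity`, `specificity`, `tp`, `fp`, `fn`, `tn`.
#' @export
recovery_stats <- function(recovered, truth_positive, universe) {
  rec <- intersect(set_members(recovered), universe)
  pos <- intersect(truth_positive, universe)
  neg <- setdiff(universe, pos)
  tp <- length(intersect(rec, pos)); fp <- length(intersect(rec, neg))
  fn <- length(pos) - tp; tn <- length(neg) - fp
  list(sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
       specificity = if (length(neg)) tn / length(neg) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Run the whole synthetic analysis pipeline
#'
#' Simulates the expression, ChIP and bisulfite inputs, then executes every
#' stage in order: quantile normalization, probe-to-gene merging, the
#' four pairwise 72 h comparisons (up/down counts at 2- and 4-fold), the
#' three-way hyper-responsive Venn cascades at 72 h and 24 h, their
#' persistent intersection, the 3 h immediate responders and their overlap
#' with the persistent set, temporal clustering with the group 1 / group 2
#' split, KDE peak calling with differential (DKO-specific) selection,
#' peak-to-gene association, central motif enrichment, and bisulfite
#' methylation profiling of a WT-vs-DKO region pair. Fully deterministic
#' given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with a machine-readable
#'   `summary` (see [summarize_counts()]) and the per-stage objects. When
#'   `config$out_dir` is set, gene lists, Venn counts, peaks (BED), links
#'   (TSV), the dendrogram (Newick), methylation calls (TSV) and
#'   `summary.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  sim_tc <- with_stage("simulate_expression",
                       simulate_timecourse_expression(config$sim, "timecourse"))
  sim_im <- with_stage("simulate_expression_immediate",
                       simulate_timecourse_expression(config$sim, "immediate"))

  genes_tc <- with_stage("normalize_merge", {
    merge_probes_to_genes(quantile_normalize(sim_tc$exprs), sim_tc$probe_map)
  })
  genes_im <- with_stage("normalize_merge_immediate", {
    merge_probes_to_genes(quantile_normalize(sim_im$exprs), sim_im$probe_map)
  })

  comparisons <- with_stage("pairwise_comparisons", {
    d <- sim_tc$design
    pairs <- list(
      WT_DexM_vs_DKO_DexM = list(c("WT", "DexM"), c("DKO", "DexM")),
      WT_DexP_vs_DKO_DexP = list(c("WT", "DexP"), c("DKO", "DexP")),
      WT_DexM_vs_WT_DexP = list(c("WT", "DexM"), c("WT", "DexP")),
      DKO_DexM_vs_DKO_DexP = list(c("DKO", "DexM"), c("DKO", "DexP"))
    )
    lapply(names(pairs), function(nm) {
      p <- pairs[[nm]]
      ct <- contrast_spec(
        design_samples(d, "mesoderm", p[[1]][1], p[[1]][2], 72),
        design_samples(d, "mesoderm", p[[2]][1], p[[2]][2], 72),
        label = nm)
      fit <- fit_moderated_t(genes_tc, ct)
      list(label = nm, fit = fit,
           up2 = select_de_genes(fit, config$fc_primary, config$p_max, "up"),
           down2 = select_de_genes(fit, config$fc_primary, config$p_max, "down"),
           up4 = select_de_genes(fit, config$fc_strong, config$p_max, "up"),
           down4 = select_de_genes(fit, config$fc_strong, config$p_max, "down"))
    }) |> setNames(names(pairs))
  })

  hyper72 <- with_stage("extract_hyper_responsive_72h",
    extract_hyper_responsive(genes_tc, sim_tc$design, 72,
                             config$fc_primary, config$p_max))
  hyper24 <- with_stage("extract_hyper_responsive_24h",
    extract_hyper_responsive(genes_tc, sim_tc$design, 24,
                             config$fc_primary, config$p_max))
  persistent <- persistent_responders(hyper24$genes, hyper72$genes)

  immediate <- with_stage("immediate_responders",
    immediate_responders(genes_im, sim_im$design, config$fc_primary,
                         config$p_max))
  immediate_overlap <- gene_set(
    intersect(immediate$members, persistent$members),
    label = "immediate_and_persistent")

  clustering <- with_stage("clustering", {
    if (length(persistent) < 2) {
      NULL
    } else {
      prof <- condition_profiles(genes_tc, sim_tc$design, persistent$members)
      tree <- average_linkage_cluster(pearson_distance(prof))
      es_fit <- fit_moderated_t(genes_tc, contrast_spec(
        design_samples(sim_tc$design, "ES", "DKO", "DexM", 72),
        design_samples(sim_tc$design, "ES", "DKO", "DexP", 72),
        label = "ES_DKO_DexM_vs_DexP_72h"))
      es_response <- setNames(es_fit$table$log2fc, es_fit$table$gene)
      split <- split_groups(tree, es_response)
      list(tree = tree, split = split, profiles = prof)
    }
  })

  chip <- with_stage("chip_peaks", {
    specs <- pipeline_chip_specs(config)
    dko_sim <- simulate_chip_tags(specs$dko)
    wt_sim <- simulate_chip_tags(specs$wt)
    peaks <- call_peaks(dko_sim$experiment, dko_sim$background,
                        specs$dko$chrom_length, config$candidate_threshold,
                        config$enrichment_threshold, config$bandwidth,
                        chrom = specs$dko$chrom)
    dko_specific <- differential_peaks(peaks, dko_sim$experiment,
                                       wt_sim$experiment,
                                       specs$dko$chrom_length,
                                       config$enrichment_threshold,
                                       config$bandwidth)
    links <- associate_peaks_to_genes(peaks, dko_sim$annotation,
                                      config$max_distance)
    seqs <- simulate_peak_sequences(specs$dko, n_windows = 200,
                                    width = config$window_width,
                                    motif = config$motif)
    motif_stats <- central_motif_enrichment(seqs, config$motif,
                                            config$central_bin)
    list(dko_sim = dko_sim, wt_sim = wt_sim, peaks = peaks,
         dko_specific = dko_specific, links = links,
         motif = motif_stats, specs = specs)
  })

  meth <- with_stage("bisulfite", {
    region <- pipeline_bisulfite_region(config$seed + 30L)
    wt_spec <- bisulfite_sim_spec(region$sequence, config$meth_prob_wt,
                                  seed = config$seed + 31L)
    dko_spec <- bisulfite_sim_spec(region$sequence, config$meth_prob_dko,
                                   seed = config$seed + 32L)
    wt_cl <- simulate_bisulfite_clones(wt_spec)
    dko_cl <- simulate_bisulfite_clones(dko_spec)
    wt_prof <- call_methylation(region, wt_cl$reads, config$min_conversion,
                                config$min_identity)
    dko_prof <- call_methylation(region, dko_cl$reads, config$min_conversion,
                                 config$min_identity)
    list(region = region, wt = wt_prof, dko = dko_prof,
         comparison = compare_profiles(wt_prof, dko_prof))
  })

  result <- structure(list(
    config = config, truth = sim_tc$truth,
    genes_tc = genes_tc, genes_im = genes_im,
    design_tc = sim_tc$design, design_im = sim_im$design,
    comparisons = comparisons,
    hyper72 = hyper72, hyper24 = hyper24, persistent = persistent,
    immediate = immediate, immediate_overlap = immediate_overlap,
    clustering = clustering, chip = chip, meth = meth
  ), class = "pipeline_result")
  result$summary <- summarize_counts(result)

  if (!is.null(config$out_dir))
    with_stage("write_artifacts", write_pipeline_artifacts(result))
  result
}

#' Machine-readable pipeline summary
#'
#' Tabulates every gene-set count the pipeline produces (the synthetic
#' analogues of the pairwise up/down tallies, the 72 h and 24 h Venn
#' cascades, the persistent and immediate sets and their overlap, the
#' group 1 / group 2 split), the peak/link counts, the central motif
#' statistic and the methylation percentages.
#'
#' @param result a `pipeline_result`.
#' @return nested list, JSON-serializable.
#' @export
summarize_counts <- function(result) {
  cmp <- lapply(result$comparisons, function(x) list(
    up_2fold = length(x$up2), down_2fold = length(x$down2),
    up_4fold = length(x$up4), down_4fold = length(x$down4)))
  venn_counts <- function(h) as.list(c(h$venn$counts,
                                       union_size = h$venn$union_size,
                                       setNames(as.integer(h$venn$totals),
                                                paste0("total_", names(h$venn$totals)))))
  truth <- result$truth
  planted <- as.list(table(truth$archetype))
  split <- result$clustering$split
  list(
    seed = result$config$seed,
    n_genes = nrow(result$genes_tc),
    planted_archetypes = planted,
    planted_immediate = as.list(table(truth$immediate)),
    comparisons_72h = cmp,
    venn_72h = venn_counts(result$hyper72),
    venn_24h = venn_counts(result$hyper24),
    hyper_responsive_72h = length(result$hyper72$genes),
    hyper_responsive_24h = length(result$hyper24$genes),
    persistent_responders = length(result$persistent),
    immediate_responders_3h = length(result$immediate),
    immediate_and_persistent = length(result$immediate_overlap),
    group1_size = if (is.null(split)) 0L else length(split$group1),
    group2_size = if (is.null(split)) 0L else length(split$group2),
    n_peaks = nrow(result$chip$peaks),
    n_dko_specific_peaks = nrow(result$chip$dko_specific),
    n_peak_gene_links = nrow(result$chip$links),
    motif_bin_sites = result$chip$motif$bin_sites,
    motif_total_sites = result$chip$motif$total_sites,
    motif_p = result$chip$motif$p,
    percent_methylated_wt = result$meth$wt$percent_methylated,
    percent_methylated_dko = result$meth$dko$percent_methylated,
    methylation_delta = result$meth$comparison$delta_percent,
    methylation_p = result$meth$comparison$p
  )
}

write_pipeline_artifacts <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_set(result$hyper72$genes, file.path(dir, "hyper_responsive_72h.txt"))
  write_gene_set(result$hyper24$genes, file.path(dir, "hyper_responsive_24h.txt"))
  write_gene_set(result$persistent, file.path(dir, "persistent_responders.txt"))
  write_gene_set(result$immediate, file.path(dir, "immediate_responders_3h.txt"))
  for (nm in names(result$hyper72$venn$regions)) {
    write_gene_set(result$hyper72$venn$regions[[nm]],
                   file.path(dir, sprintf("venn72_%s.txt", nm)))
  }
  venn_tab <- data.frame(region = names(result$hyper72$venn$counts),
                         count_72h = as.integer(result$hyper72$venn$counts),
                         count_24h = as.integer(result$hyper24$venn$counts))
  write.table(venn_tab, file.path(dir, "venn_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$clustering)) {
    write_newick(result$clustering$tree, file.path(dir, "persistent_tree.nwk"))
    assign_tab <- data.frame(gene = names(result$clustering$split$cut),
                             cluster = as.integer(result$clustering$split$cut))
    assign_tab$group <- ifelse(assign_tab$gene %in%
                                 result$clustering$split$group1$members,
                               "group1", "group2")
    write.table(assign_tab, file.path(dir, "cluster_assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(result$clustering$tree$labels[result$clustering$tree$order],
               file.path(dir, "heatmap_row_order.txt"))
  }
  write_bed(result$chip$peaks, file.path(dir, "peaks.bed"))
  write_bed(result$chip$dko_specific, file.path(dir, "dko_specific_peaks.bed"))
  write.table(result$chip$links, file.path(dir, "peak_gene_links.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("wt", "dko")) {
    prof <- result$meth[[nm]]
    write.table(data.frame(clone = rownames(prof$calls), prof$calls,
                           check.names = FALSE),
                file.path(dir, sprintf("methylation_calls_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(render_lollipop(prof),
               file.path(dir, sprintf("lollipop_%s.txt", nm)))
  }
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Planted-truth recovery of the responder-extraction cascade
#'
#' One complete extraction run (simulate, normalize, merge, cascade at both
#' time points, persistent intersection) scored against the planted
#' archetypes; the positives are the group 1 + group 2 genes.
#'
#' @param config a [pipeline_config()] (only the expression arm is used).
#' @return list with `recovery` (per-set [recovery_stats()]) and set sizes.
#' @export
evaluate_recovery <- function(config) {
  sim <- simulate_timecourse_expression(config$sim, "timecourse")
  genes <- merge_probes_to_genes(quantile_normalize(sim$exprs), sim$probe_map)
  h72 <- extract_hyper_responsive(genes, sim$design, 72, config$fc_primary,
                                  config$p_max)
  h24 <- extract_hyper_responsive(genes, sim$design, 24, config$fc_primary,
                                  config$p_max)
  pers <- persistent_responders(h24$genes, h72$genes)
  truth_pos <- sim$truth$gene[sim$truth$archetype %in%
                                c("group1_endoderm", "group2_cardiac")]
  universe <- rownames(genes)
  list(
    recovery = list(
      h72 = recovery_stats(h72$genes, truth_pos, universe),
      h24 = recovery_stats(h24$genes, truth_pos, universe),
      persistent = recovery_stats(pers, truth_pos, universe)),
    sizes = c(h72 = length(h72$genes), h24 = length(h24$genes),
              persistent = length(pers), planted = length(truth_pos))
  )
}
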