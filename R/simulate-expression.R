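#' Configuration for the synthetic expression time course
#'
#' Describes a two-genotype (WT vs Dnmt3a/Dnmt3b-null "DKO"), two-context
#' (ES cells vs Flk1+ mesoderm) dexamethasone-induction microarray design
#' with planted gene archetypes. Time grids and replicate structure follow
#' the study design this package models: mesoderm sampled at 0, 12, 24, 36,
#' 48 and 72 h (triplicates at 0 h and for Dex+ samples, duplicates
#' otherwise) and ES cells at 0, 3, 6, 12, 24, 48 and 72 h in duplicate.
#'
#' Archetypes and their planted behaviour:
#' \describe{
#'   \item{group1_endoderm}{responds to Dex in ES cells of both genotypes and
#'     in DKO mesoderm, but not in WT mesoderm (ectopic endoderm program).}
#'   \item{group2_cardiac}{responds to Dex only in DKO mesoderm (precocious
#'     cardiac program).}
#'   \item{methylation_sensitive}{constitutively higher in all DKO samples by
#'     \code{constitutive_log2fc}, independent of Dex and time.}
#'   \item{wt_and_dko_responder}{responds to Dex in both genotypes and both
#'     contexts (methylation-independent responder).}
#'   \item{non_responder}{flat.}
#' }
#'
#' Dex effects ramp linearly from zero at t = 0 to the full
#' \code{effect_log2fc} at 24 h and plateau thereafter. A subset of
#' group1/group2 genes is additionally flagged "immediate" (full effect from
#' 1 h), and a subset of non-responders carries a transient immediate pulse
#' (full by 1 h, decayed by 12 h) visible only in the dedicated short-term
#' design; defaults give 64 immediate genes of which 15 are also persistent
#' hyper-responders at `n_genes = 1000`.
#'
#' @param n_genes number of simulated genes.
#' @param probes_per_gene probes measuring each gene (merged downstream).
#' @param archetype_fractions named fractions over the five archetypes;
#'   must sum to 1.
#' @param effect_log2fc planted Dex-response effect size, log2 units.
#' @param constitutive_log2fc planted constitutive DKO shift for
#'   methylation-sensitive genes, log2 units.
#' @param noise_sd per-probe Gaussian noise sd on the log2 scale; 0 gives
#'   the noiseless limit.
#' @param immediate_persistent_frac fraction of genes planted as immediate
#'   *and* persistent responders (drawn from group1/group2).
#' @param immediate_transient_frac fraction planted as immediate-only
#'   (transient pulse on non-responders).
#' @param unmapped_probe_frac extra probes carrying no gene symbol, as a
#'   fraction of mapped probes (exercises symbol filtering).
#' @param baseline_mean,baseline_sd distribution of baseline log2 intensity
#'   for constitutively expressed (non-responder) genes.
#' @param inducible_baseline_mean,inducible_baseline_sd baseline distribution
#'   for genes carrying planted effects (methylation-silenced and
#'   factor-inducible genes start near background intensity, so their
#'   induced values land in the dense mid-range of the array distribution).
#' @param timepoints_mesoderm,timepoints_es sampling times in hours.
#' @param reps_anchor replicates for mesoderm 0 h and mesoderm Dex+ samples.
#' @param reps_other replicates for all other samples.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       probes_per_gene = 3,
                       archetype_fractions = c(group1_endoderm = 0.025,
                                               group2_cardiac = 0.02,
                                               methylation_sensitive = 0.04,
                                               wt_and_dko_responder = 0.015,
                                               non_responder = 0.9),
                       effect_log2fc = 2.0,
                       constitutive_log2fc = 3.0,
                       noise_sd = 0.25,
                       immediate_persistent_frac = 0.015,
                       immediate_transient_frac = 0.049,
                       unmapped_probe_frac = 0.02,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       inducible_baseline_mean = 5.5,
                       inducible_baseline_sd = 0.75,
                       timepoints_mesoderm = c(0, 12, 24, 36, 48, 72),
                       timepoints_es = c(0, 3, 6, 12, 24, 48, 72),
                       reps_anchor = 3,
                       reps_other = 2,
                       seed = 1L) {
  archetypes <- c("group1_endoderm", "group2_cardiac", "methylation_sensitive",
                  "wt_and_dko_responder", "non_responder")
  if (!all(archetypes %in% names(archetype_fractions)))
    stop("archetype_fractions must name all of: ",
         paste(archetypes, collapse = ", "))
  archetype_fractions <- archetype_fractions[archetypes]
  if (abs(sum(archetype_fractions) - 1) > 1e-8)
    stop("archetype fractions must sum to 1 (got ",
         format(sum(archetype_fractions)), ")")
  if (n_genes < 1 || probes_per_gene < 1)
    stop("n_genes and probes_per_gene must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (reps_anchor < 2 || reps_other < 2)
    stop("replicate counts must be >= 2")
  structure(list(
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    archetype_fractions = archetype_fractions,
    effect_log2fc = effect_log2fc,
    constitutive_log2fc = constitutive_log2fc,
    noise_sd = noise_sd,
    immediate_persistent_frac = immediate_persistent_frac,
    immediate_transient_frac = immediate_transient_frac,
    unmapped_probe_frac = unmapped_probe_frac,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    inducible_baseline_mean = inducible_baseline_mean,
    inducible_baseline_sd = inducible_baseline_sd,
    timepoints_mesoderm = timepoints_mesoderm,
    timepoints_es = timepoints_es,
    reps_anchor = as.integer(reps_anchor),
    reps_other = as.integer(reps_other),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Planted per-gene ground truth
#'
#' Deterministic given `config$seed`; shared by the main time-course and the
#' short-term (0-3 h) designs so that overlap statistics against truth are
#' meaningful.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene`, `archetype`,
#'   `immediate` (one of `"none"`, `"persistent"`, `"transient"`) and
#'   `baseline` (log2 intensity).
#' @export
simulate_gene_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  counts <- round(config$archetype_fractions * n)
  # remainder absorbed by non_responder so labels cover every gene exactly
  counts["non_responder"] <- n - sum(counts[names(counts) != "non_responder"])
  if (counts["non_responder"] < 0)
    stop("archetype fractions leave no room for non-responders")
  set.seed(config$seed)
  archetype <- sample(rep(names(counts), counts))
  gene <- sprintf("gene%04d", seq_len(n))
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)

  immediate <- rep("none", n)
  hyper <- which(archetype %in% c("group1_endoderm", "group2_cardiac"))
  n_ip <- min(round(config$immediate_persistent_frac * n), length(hyper))
  if (n_ip > 0)
    immediate[sample(hyper, n_ip)] <- "persistent"
  flat <- which(archetype == "non_responder")
  n_it <- min(round(config$immediate_transient_frac * n), length(flat))
  if (n_it > 0)
    immediate[sample(flat, n_it)] <- "transient"

  # genes carrying planted effects start near background intensity:
  # methylation-silenced genes are repressed in WT and inducible genes are
  # off before activation, so their shifted values stay in the dense
  # mid-range of the intensity distribution
  inducible <- archetype != "non_responder" | immediate == "transient"
  baseline[inducible] <- rnorm(sum(inducible), config$inducible_baseline_mean,
                               config$inducible_baseline_sd)
  data.frame(gene = gene, archetype = archetype, immediate = immediate,
             baseline = baseline, stringsAsFactors = FALSE)
}

#' Sample design tables for the simulated experiments
#'
#' @param config a [sim_config()].
#' @param experiment `"timecourse"` for the full 0-72 h two-context design,
#'   `"immediate"` for the short-term mesoderm design (0, 1, 2, 3 h, Dex+
#'   duplicates against a 0 h baseline).
#' @return data.frame with columns `sample_id`, `context`, `genotype`,
#'   `treatment` (`"DexP"`, `"DexM"` or `"none"` at t = 0), `time_h`,
#'   `replicate`.
#' @export
simulate_design <- function(config, experiment = c("timecourse", "immediate")) {
  experiment <- match.arg(experiment)
  rows <- list()
  add <- function(context, genotype, treatment, time_h, n_rep) {
    data.frame(context = context, genotype = genotype, treatment = treatment,
               time_h = time_h, replicate = seq_len(n_rep),
               stringsAsFactors = FALSE)
  }
  if (experiment == "timecourse") {
    for (g in c("WT", "DKO")) {
      rows[[length(rows) + 1L]] <- add("mesoderm", g, "none", 0, config$reps_anchor)
      for (t in setdiff(config$timepoints_mesoderm, 0)) {
        rows[[length(rows) + 1L]] <- add("mesoderm", g, "DexP", t, config$reps_anchor)
        rows[[length(rows) + 1L]] <- add("mesoderm", g, "DexM", t, config$reps_other)
      }
      rows[[length(rows) + 1L]] <- add("ES", g, "none", 0, config$reps_other)
      for (t in setdiff(config$timepoints_es, 0)) {
        rows[[length(rows) + 1L]] <- add("ES", g, "DexP", t, config$reps_other)
        rows[[length(rows) + 1L]] <- add("ES", g, "DexM", t, config$reps_other)
      }
    }
  } else {
    for (g in c("WT", "DKO")) {
      rows[[length(rows) + 1L]] <- add("mesoderm", g, "none", 0, config$reps_other)
      for (t in c(1, 2, 3)) {
        rows[[length(rows) + 1L]] <- add("mesoderm", g, "DexP", t, config$reps_other)
      }
    }
  }
  design <- do.call(rbind, rows)
  design$sample_id <- sprintf("%s_%s_%s_%gh_r%d", design$context,
                              design$genotype, design$treatment,
                              design$time_h, design$replicate)
  design[, c("sample_id", "context", "genotype", "treatment", "time_h",
             "replicate")]
}

# Fraction of the full Dex effect realized at time t (hours).
# Persistent responses ramp linearly to the plateau at 24 h; immediate
# responses are full from 1 h; transient pulses are full at 1-3 h and decay
# to zero by 12 h.
response_ramp <- function(time_h, kind = c("persistent", "immediate", "transient")) {
  kind <- match.arg(kind)
  t <- as.numeric(time_h)
  switch(kind,
    persistent = pmin(t, 24) / 24,
    immediate  = pmin(t, 1),
    transient  = ifelse(t <= 3, pmin(t, 1), pmax(0, (12 - t) / 9))
  )
}

# Planted log2 effects of every gene in one sample (no noise), vectorized
# over genes.
planted_effect <- function(truth, design_row, config) {
  ctx <- design_row$context; gt <- design_row$genotype
  tr <- design_row$treatment; t <- design_row$time_h
  eff <- numeric(nrow(truth))
  if (gt == "DKO")
    eff[truth$archetype == "methylation_sensitive"] <-
      config$constitutive_log2fc
  if (tr == "DexP") {
    responds <-
      (truth$archetype == "group1_endoderm" &
         (ctx == "ES" | (ctx == "mesoderm" & gt == "DKO"))) |
      (truth$archetype == "group2_cardiac" & ctx == "mesoderm" & gt == "DKO") |
      (truth$archetype == "wt_and_dko_responder")
    kind_immediate <- truth$immediate == "persistent"
    eff[responds & kind_immediate] <- eff[responds & kind_immediate] +
      config$effect_log2fc * response_ramp(t, "immediate")
    eff[responds & !kind_immediate] <- eff[responds & !kind_immediate] +
      config$effect_log2fc * response_ramp(t, "persistent")
    if (ctx == "mesoderm" && gt == "DKO") {
      pulse <- truth$archetype == "non_responder" &
        truth$immediate == "transient"
      eff[pulse] <- eff[pulse] + config$effect_log2fc *
        response_ramp(t, "transient")
    }
  }
  eff
}

#' Simulate a probe-level expression time course with planted truth
#'
#' Generates a log2 probe-intensity matrix for the full two-context
#' Dex-induction design (or the short-term 0-3 h design), together with the
#' probe-to-gene map and the planted per-gene truth. Probes of a gene share
#' the gene signal and receive independent Gaussian noise; a configurable
#' fraction of additional probes carries no gene symbol.
#'
#' @param config a [sim_config()].
#' @param experiment `"timecourse"` or `"immediate"` (see [simulate_design()]).
#' @return list with elements `exprs` (matrix, probes x samples), `design`
#'   (data.frame), `probe_map` (data.frame `probe_id`, `gene`; `NA` gene for
#'   unmapped probes) and `truth` (see [simulate_gene_truth()]).
#' @export
simulate_timecourse_expression <- function(config,
                                           experiment = c("timecourse", "immediate")) {
  stopifnot(inherits(config, "sim_config"))
  experiment <- match.arg(experiment)
  truth <- simulate_gene_truth(config)
  design <- simulate_design(config, experiment)
  n <- config$n_genes
  ppg <- config$probes_per_gene

  # gene x sample planted signal
  signal <- matrix(truth$baseline, nrow = n, ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    signal[, j] <- signal[, j] + planted_effect(truth, design[j, ], config)
  }

  probe_gene_idx <- rep(seq_len(n), each = ppg)
  probe_id <- sprintf("probe_%04d_%d", probe_gene_idx, rep(seq_len(ppg), n))
  n_unmapped <- round(config$unmapped_probe_frac * n * ppg)
  # different substream per experiment so the two designs get independent
  # noise, while truth above is seeded identically
  set.seed(config$seed + ifelse(experiment == "timecourse", 1000L, 2000L))
  exprs <- signal[probe_gene_idx, , drop = FALSE]
  if (n_unmapped > 0) {
    unmapped_base <- rnorm(n_unmapped, config$baseline_mean, config$baseline_sd)
    exprs <- rbind(exprs, matrix(unmapped_base, n_unmapped, nrow(design)))
    probe_id <- c(probe_id, sprintf("probe_unmapped_%03d", seq_len(n_unmapped)))
    probe_gene_idx <- c(probe_gene_idx, rep(NA_integer_, n_unmapped))
  }
  if (config$noise_sd > 0)
    exprs <- exprs + matrix(rnorm(length(exprs), 0, config$noise_sd),
                            nrow(exprs), ncol(exprs))
  dimnames(exprs) <- list(probe_id, design$sample_id)
  probe_map <- data.frame(probe_id = probe_id,
                          gene = ifelse(is.na(probe_gene_idx), NA_character_,
                                        truth$gene[probe_gene_idx]),
                          stringsAsFactors = FALSE)
  list(exprs = exprs, design = design, probe_map = probe_map, truth = truth)
}
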