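#' Named gene set
#'
#' @param members character vector of gene symbols (deduplicated).
#' @param label set name.
#' @return list of class `gene_set` with elements `label`, `members`.
#' @export
gene_set <- function(members, label = "set") {
  structure(list(label = label,
                 members = sort(unique(as.character(members)))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s'> %d genes\n", x$label, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

# accept gene_set or plain character
set_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else sort(unique(as.character(x)))
}

#' Three-set Venn partition
#'
#' Decomposes three gene sets into the seven disjoint intersection regions
#' plus per-set totals, as in the fold-change Venn cascades used to define
#' hyper-responsive genes.
#'
#' @param a,b,c [gene_set()]s or character vectors.
#' @return list of class `venn_partition`: `regions` (named list of member
#'   vectors for `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`),
#'   `counts` (named integer), `totals` (per input set), `union_size`.
#' @export
three_way_venn <- function(a, b, c) {
  A <- set_members(a); B <- set_members(b); C <- set_members(c)
  abc <- intersect(intersect(A, B), C)
  ab <- setdiff(intersect(A, B), abc)
  ac <- setdiff(intersect(A, C), abc)
  bc <- setdiff(intersect(B, C), abc)
  a_only <- setdiff(A, union(B, C))
  b_only <- setdiff(B, union(A, C))
  c_only <- setdiff(C, union(A, B))
  regions <- list(a_only = a_only, b_only = b_only, c_only = c_only,
                  ab = ab, ac = ac, bc = bc, abc = abc)
  structure(list(
    regions = regions,
    counts = vapply(regions, length, integer(1)),
    totals = c(a = length(A), b = length(B), c = length(C)),
    union_size = length(union(union(A, B), C))
  ), class = "venn_partition")
}

# sample ids in the design matching a condition; errors name the group
design_samples <- function(design, context, genotype, treatment, time_h,
                           required = TRUE) {
  sel <- design$context == context & design$genotype == genotype &
    design$treatment == treatment & design$time_h == time_h
  ids <- design$sample_id[sel]
  if (required && length(ids) < 2)
    stop(sprintf("design lacks >=2 samples for group [%s %s %s %g h]",
                 context, genotype, treatment, time_h))
  ids
}

#' Extract hyper-responsive genes via the three-way fold-change cascade
#'
#' Builds three "up in induced DKO" differential-expression sets at one
#' mesoderm time point and intersects them. A gene is hyper-responsive when
#' it is (i) higher in induced DKO than induced WT, (ii) higher in induced
#' than uninduced DKO at the same time, and (iii) higher in induced DKO than
#' the DKO baseline at t = 0 (pre-induction, just after Flk1+ sorting).
#' Constitutively derepressed (methylation-sensitive) genes drop out through
#' (ii) and (iii); methylation-independent responders drop out through (i).
#'
#' @param x gene-level log2 matrix.
#' @param design sample design table (see [simulate_design()]).
#' @param time_h mesoderm time point (72 or 24 in the reference design).
#' @param fc_fold,p_max selection cuts passed to [select_de_genes()].
#' @return list of class `hyper_responsive`: `genes` (the triple-intersection
#'   [gene_set()]), `venn` ([three_way_venn()] partition), `sets` (the three
#'   input up-sets), `contrasts` (the three `contrast_result`s), `time_h`.
#' @export
extract_hyper_responsive <- function(x, design, time_h, fc_fold = 2,
                                     p_max = 0.01) {
  dko_dexp <- design_samples(design, "mesoderm", "DKO", "DexP", time_h)
  contrasts <- list(
    wt_vs_dko = contrast_spec(
      design_samples(design, "mesoderm", "WT", "DexP", time_h), dko_dexp,
      label = sprintf("WT_DexP_vs_DKO_DexP_%gh", time_h)),
    dexm_vs_dexp = contrast_spec(
      design_samples(design, "mesoderm", "DKO", "DexM", time_h), dko_dexp,
      label = sprintf("DKO_DexM_vs_DKO_DexP_%gh", time_h)),
    t0_vs_dexp = contrast_spec(
      design_samples(design, "mesoderm", "DKO", "none", 0), dko_dexp,
      label = sprintf("DKO_0h_vs_DKO_DexP_%gh", time_h))
  )
  fits <- lapply(contrasts, function(ct) fit_moderated_t(x, ct))
  sets <- lapply(fits, select_de_genes, fc_fold = fc_fold, p_max = p_max,
                 direction = "up")
  venn <- three_way_venn(sets[[1]], sets[[2]], sets[[3]])
  structure(list(
    genes = gene_set(venn$regions$abc,
                     label = sprintf("hyper_responsive_%gh", time_h)),
    venn = venn, sets = sets, contrasts = fits, time_h = time_h
  ), class = "hyper_responsive")
}

#' Persistent responders: intersection of two time points
#'
#' @param set_24h,set_72h [gene_set()]s from [extract_hyper_responsive()] at
#'   24 h and 72 h.
#' @return [gene_set()] of genes responding at both times.
#' @export
persistent_responders <- function(set_24h, set_72h) {
  gene_set(intersect(set_members(set_24h), set_members(set_72h)),
           label = "persistent_responders")
}

#' Immediate responders in the short-term design
#'
#' Genes up more than `fc_fold`-fold (p < `p_max`) in induced DKO mesoderm
#' at 3 h relative to the DKO 0 h baseline.
#'
#' @param x gene-level log2 matrix from the short-term design.
#' @param design its design table.
#' @param fc_fold,p_max selection cuts.
#' @return [gene_set()].
#' @export
immediate_responders <- function(x, design, fc_fold = 2, p_max = 0.01) {
  ct <- contrast_spec(
    design_samples(design, "mesoderm", "DKO", "none", 0),
    design_samples(design, "mesoderm", "DKO", "DexP", 3),
    label = "DKO_0h_vs_DKO_DexP_3h")
  fit <- fit_moderated_t(x, ct)
  out <- select_de_genes(fit, fc_fold = fc_fold, p_max = p_max,
                         direction = "up")
  out$label <- "immediate_responders_3h"
  out
}
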