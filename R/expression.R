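#' Quantile normalization
#'
#' Forces every column of a log2 intensity matrix onto the same empirical
#' distribution: the mean of the sorted columns. Ties within a column
#' receive the mean of the reference values at their tied ranks, so equal
#' inputs map to equal outputs.
#'
#' @param x numeric matrix (probes or genes x samples), all values finite.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 1) stop("matrix must have at least one column")
  if (!all(is.finite(x))) stop("matrix contains non-finite values")
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    o <- order(col)
    v <- numeric(length(col))
    if (anyDuplicated(col)) {
      # tie groups share the mean of the reference values at their ranks
      sorted <- col[o]
      grp <- cumsum(c(TRUE, diff(sorted) != 0))
      v[o] <- (rowsum(ref, grp) / tabulate(grp))[grp]
    } else {
      v[o] <- ref
    }
    out[, j] <- v
  }
  out
}

#' Merge probe-level values to gene level
#'
#' Collapses probes measuring the same gene to their arithmetic mean (log2
#' scale), per sample. Probes without a gene symbol (`NA` or empty) are
#' dropped, mirroring analyses restricted to annotated genes.
#'
#' @param x probe-level matrix (rownames = probe ids).
#' @param probe_map data.frame with columns `probe_id`, `gene`.
#' @return gene-level matrix, rows ordered by gene symbol.
#' @export
merge_probes_to_genes <- function(x, probe_map) {
  x <- as.matrix(x)
  if (is.null(probe_map) || nrow(probe_map) == 0)
    stop("probe_map is empty")
  stopifnot(all(c("probe_id", "gene") %in% names(probe_map)))
  gene <- probe_map$gene[match(rownames(x), probe_map$probe_id)]
  keep <- !is.na(gene) & gene != ""
  if (!any(keep)) stop("no probe maps to a gene symbol")
  x <- x[keep, , drop = FALSE]
  gene <- gene[keep]
  sums <- rowsum(x, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Specify a two-group contrast
#'
#' @param group_a,group_b character vectors of sample ids (column names);
#'   group B minus group A is the reported direction, so "up" means higher
#'   in `group_b`.
#' @param label human-readable contrast name.
#' @return list of class `contrast_spec`.
#' @export
contrast_spec <- function(group_a, group_b, label = "contrast") {
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)) > 0)
    stop("contrast groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each contrast group needs >= 2 samples")
  structure(list(group_a = group_a, group_b = group_b, label = label),
            class = "contrast_spec")
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# following the standard empirical-Bayes moment-matching recipe.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

# Moment-match a scaled-F prior to the observed gene-wise variances:
# log s2 has mean log(s0^2) + digamma(d0/2) - log(d0/2) (shifted by the
# sampling component) and excess variance trigamma(d0/2) beyond the
# sampling trigamma(d/2). Returns list(d0, s0_sq).
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) return(list(d0 = Inf, s0_sq = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess dispersion: variances are exchangeable, prior df infinite;
    # the common posterior variance is the mean observed variance
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-test for one two-group contrast
#'
#' Computes per-gene log2 fold changes and pooled two-group variances, shrinks
#' the variances toward a moment-matched scaled-F prior (prior df `d0`, prior
#' variance `s0_sq` estimated from the distribution of log variances via the
#' digamma/trigamma moment equations), and tests each gene with a Student t
#' on `d0 + d` degrees of freedom.
#'
#' When the moment equations imply infinite prior df (no excess variance
#' dispersion), every gene uses the common posterior variance `mean(s2)`.
#' In the degenerate noiseless case where that posterior variance is zero,
#' the statistic is `+/-Inf` and p is 0 for any nonzero fold change
#' (1 for a zero fold change).
#'
#' @param x gene-level log2 matrix with column names matching the contrast.
#' @param contrast a [contrast_spec()].
#' @return list of class `contrast_result`: `table` (data.frame `gene`,
#'   `log2fc`, `s2_g`, `t_mod`, `p`), hyperparameters `d0`, `s0_sq`,
#'   residual df `d`, group sizes and `label`.
#' @export
fit_moderated_t <- function(x, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  x <- as.matrix(x)
  missing_a <- setdiff(contrast$group_a, colnames(x))
  missing_b <- setdiff(contrast$group_b, colnames(x))
  if (length(missing_a) || length(missing_b))
    stop("samples absent from matrix: ",
         paste(c(missing_a, missing_b), collapse = ", "))
  A <- x[, contrast$group_a, drop = FALSE]
  B <- x[, contrast$group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  d <- na + nb - 2
  ma <- rowMeans(A); mb <- rowMeans(B)
  log2fc <- mb - ma
  rss <- rowSums((A - ma)^2) + rowSums((B - mb)^2)
  s2 <- rss / d

  if (all(s2 == 0)) {
    warning("all gene variances are zero; falling back to d0 = Inf")
    prior <- list(d0 = Inf, s0_sq = 0)
  } else {
    prior <- fit_variance_prior(s2, d)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log2fc / se, sign(log2fc) * Inf)
  t_mod[se == 0 & log2fc == 0] <- 0
  p <- 2 * pt(-abs(t_mod), df = df_total)  # t = +/-Inf -> p = 0; t = 0 -> p = 1
  structure(list(
    table = data.frame(gene = rownames(x), log2fc = log2fc, s2_g = s2,
                       t_mod = t_mod, p = p, row.names = NULL,
                       stringsAsFactors = FALSE),
    d0 = d0, s0_sq = s0_sq, d = d, n_a = na, n_b = nb,
    label = contrast$label
  ), class = "contrast_result")
}

#' Select differentially expressed genes by fold change and p-value
#'
#' Keeps genes with `p < p_max` and a signed linear fold change strictly
#' greater than `fc_fold` in the requested direction (i.e.
#' `|log2fc| > log2(fc_fold)` with matching sign). A gene at exactly the
#' fold cut is excluded.
#'
#' @param result a [fit_moderated_t()] result.
#' @param fc_fold linear fold-change cut (> 1), typically 2 or 4.
#' @param p_max p-value cut (default 0.01).
#' @param direction `"up"` (higher in group B) or `"down"`.
#' @return a [gene_set()].
#' @export
select_de_genes <- function(result, fc_fold = 2, p_max = 0.01,
                            direction = c("up", "down")) {
  stopifnot(inherits(result, "contrast_result"))
  if (!is.numeric(fc_fold) || fc_fold <= 1) stop("fc_fold must be > 1")
  direction <- match.arg(direction)
  tab <- result$table
  cut <- log2(fc_fold)
  keep <- tab$p < p_max &
    if (direction == "up") tab$log2fc > cut else tab$log2fc < -cut
  gene_set(tab$gene[keep],
           label = sprintf("%s_%s_fc%g", result$label, direction, fc_fold))
}
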