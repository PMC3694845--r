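#' Per-condition mean expression profiles
#'
#' Averages replicates within each design cell (context, genotype,
#' treatment, time) to build the gene x condition profile matrix used for
#' temporal clustering; conditions are ordered mesoderm before ES, then by
#' genotype, treatment and time.
#'
#' @param x gene-level log2 matrix.
#' @param design sample design table.
#' @param genes optional subset of rownames.
#' @return numeric matrix, genes x conditions.
#' @export
condition_profiles <- function(x, design, genes = NULL) {
  x <- as.matrix(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
      stop("genes absent from matrix: ", paste(head(missing, 5), collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  key <- interaction(design$context, design$genotype, design$treatment,
                     design$time_h, drop = TRUE, sep = "|")
  ord <- order(match(design$context, c("mesoderm", "ES")), design$genotype,
               design$treatment, design$time_h)
  key_levels <- unique(as.character(key[ord]))
  prof <- sapply(key_levels, function(k) {
    ids <- design$sample_id[as.character(key) == k]
    rowMeans(x[, ids, drop = FALSE])
  })
  colnames(prof) <- gsub("\\|", "_", key_levels)
  prof
}

#' Pearson correlation distance
#'
#' `d(i, j) = 1 - r(i, j)` over profile rows, in `[0, 2]`; the metric used
#' for temporal-profile clustering. Genes with zero variance across
#' conditions have no defined correlation and are rejected by name.
#'
#' @param profiles numeric matrix, genes x conditions (>= 2 conditions).
#' @return symmetric distance matrix with zero diagonal.
#' @export
pearson_distance <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("need >= 2 conditions per gene")
  v <- apply(profiles, 1, var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- rownames(profiles)[v == 0 | !is.finite(v)]
    stop("zero-variance profile(s): ", paste(head(bad, 5), collapse = ", "))
  }
  d <- 1 - cor(t(profiles))
  d <- (d + t(d)) / 2          # kill asymmetric rounding noise
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Repeatedly merges the closest pair of clusters; the distance from a
#' merged cluster to any other is the size-weighted mean of its members'
#' distances (equivalently, the mean over all cross-pairs of the original
#' metric). Ties are broken toward the pair containing the lowest original
#' leaf index (then the lowest index of the partner), making the tree
#' deterministic and invariant to input order up to relabeling. Merge
#' heights are checked for monotonicity and a warning is raised on any
#' inversion (average linkage is not guaranteed reducible on arbitrary
#' dissimilarities).
#'
#' @param d symmetric distance matrix with dimnames (n >= 2).
#' @return an object of class `hclust` (usable with [stats::cutree()] and
#'   convertible via [ape::as.phylo()]).
#' @export
average_linkage_cluster <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need >= 2 leaves to cluster")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  cur <- d
  id <- -seq_len(n)            # hclust convention: negative = leaf
  size <- rep(1L, n)
  minleaf <- seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (s in seq_len(n - 1)) {
    m <- nrow(cur)
    dmin <- min(cur[upper.tri(cur)])
    idx <- which(cur == dmin & upper.tri(cur), arr.ind = TRUE)
    # tie rule: lowest contained leaf index first, then the partner's
    lo <- pmin(minleaf[idx[, 1]], minleaf[idx[, 2]])
    hi <- pmax(minleaf[idx[, 1]], minleaf[idx[, 2]])
    pick <- order(lo, hi)[1]
    i <- min(idx[pick, ]); j <- max(idx[pick, ])

    merge[s, ] <- sort_merge_pair(id[i], id[j])
    height[s] <- dmin
    newd <- (size[i] * cur[i, ] + size[j] * cur[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    id <- c(id[keep], s)
    size <- c(size[keep], size[i] + size[j])
    minleaf <- c(minleaf[keep], min(minleaf[i], minleaf[j]))
  }
  if (any(diff(height) < -1e-10))
    warning("non-monotone merge heights (average-linkage inversion)")
  out <- list(merge = merge, height = height,
              order = hclust_leaf_order(merge), labels = labels,
              method = "average", dist.method = "pearson",
              call = match.call())
  class(out) <- "hclust"
  out
}

# hclust orders a merge row as (smaller, larger) with leaves (negative)
# before internal nodes
sort_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) c(min(a, b), max(a, b))
  else if (a < 0) c(a, b)
  else if (b < 0) c(b, a)
  else c(min(a, b), max(a, b))
}

# leaf order by depth-first traversal of the merge tree
hclust_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Split a response-gene tree into group 1 / group 2
#'
#' Cuts the dendrogram into its two root clusters and labels the cluster
#' with the higher mean ES-cell response as group 1 (the arm that also
#' responds in ES cells, i.e. the ectopic endoderm-program genes); the
#' other arm is group 2. On an exact tie the cluster containing the first
#' input gene becomes group 1 and a warning is raised.
#'
#' @param tree an `hclust` from [average_linkage_cluster()].
#' @param es_response named numeric: per-gene log2 fold change of induced
#'   vs uninduced ES cells (e.g. at 72 h); names must cover the tree leaves.
#' @return list with [gene_set()]s `group1`, `group2` and the cluster
#'   assignment vector `cut`.
#' @export
split_groups <- function(tree, es_response) {
  stopifnot(inherits(tree, "hclust"))
  if (length(tree$labels) < 2) stop("degenerate tree: fewer than 2 leaves")
  cut <- cutree(tree, k = 2)
  missing <- setdiff(names(cut), names(es_response))
  if (length(missing))
    stop("es_response missing genes: ", paste(head(missing, 5), collapse = ", "))
  m1 <- mean(es_response[names(cut)[cut == 1]])
  m2 <- mean(es_response[names(cut)[cut == 2]])
  if (m1 == m2) {
    warning("ES response tie between clusters; labeling by first leaf")
    g1 <- cut[tree$labels[1]]
  } else {
    g1 <- if (m1 > m2) 1L else 2L
  }
  list(group1 = gene_set(names(cut)[cut == g1], label = "group1"),
       group2 = gene_set(names(cut)[cut != g1], label = "group2"),
       cut = cut)
}
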