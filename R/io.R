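#' Write / read an expression matrix with its design sidecar
#'
#' Matrices travel as TSV with a leading id column and one column per
#' sample; the design is a sibling TSV keyed by `sample_id`.
#'
#' @param x numeric matrix with dimnames.
#' @param design per-sample annotation data.frame (`sample_id` first).
#' @param values_path,design_path output file paths.
#' @return invisibly, the paths.
#' @export
write_expression <- function(x, design, values_path, design_path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(values_path, design_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(values_path, design_path) {
  df <- read.table(values_path, sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  design <- read.table(design_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  list(exprs = x, design = design)
}

#' Write / read a gene set as one-symbol-per-line text
#'
#' @param x a [gene_set()] or character vector.
#' @param path file path.
#' @export
write_gene_set <- function(x, path) {
  writeLines(set_members(x), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @param label label for the set read back.
#' @export
read_gene_set <- function(path, label = basename(path)) {
  gene_set(readLines(path), label = label)
}

#' Write / read a tag track (one integer position per line)
#'
#' @param positions integer tag positions.
#' @param path file path.
#' @export
write_tag_track <- function(positions, path) {
  writeLines(format(as.integer(positions), scientific = FALSE, trim = TRUE),
             path)
  invisible(path)
}

#' @rdname write_tag_track
#' @export
read_tag_track <- function(path) {
  as.integer(readLines(path))
}

#' Read a BED interval file (0-based, half-open)
#'
#' Minimal three-plus-column BED with strict validation; malformed lines
#' are rejected with their line number.
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `name` (name defaults to
#'   `region_<i>` when absent).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 3) stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start)
      stop(sprintf("malformed BED line %d: bad interval [%s, %s)", i, f[2], f[3]))
    out[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                           name = if (length(f) >= 4) f[4] else
                             sprintf("region_%d", i),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write intervals as BED (optionally BED6 for peaks)
#'
#' Peak data.frames (with `enrichment`) are written as BED6 with
#' `score = round(100 * enrichment)` and `.` strand; plain annotations as
#' BED4.
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `enrichment`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(x)) x$name else
    sprintf("peak_%d", seq_len(nrow(x)))
  if ("enrichment" %in% names(x)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", x$chrom, x$start, x$end, name,
                     as.integer(round(100 * x$enrichment)))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end, name)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read FASTA sequences
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(ss))) names(ss) <- sprintf("seq%d", seq_along(ss))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Export a dendrogram as Newick
#'
#' @param tree an `hclust` from [average_linkage_cluster()].
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
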