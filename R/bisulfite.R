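#' Reference region for bisulfite analysis
#'
#' @param name region name.
#' @param sequence DNA string (A/C/G/T, upper case).
#' @return list of class `reference_region` with `name`, `sequence` and
#'   `cpg_positions` (0-based offsets of the C of every CpG).
#' @export
reference_region <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence)) stop("sequence must be A/C/G/T only")
  cpg <- cpg_offsets(sequence)
  structure(list(name = name, sequence = sequence, cpg_positions = cpg),
            class = "reference_region")
}

# 0-based offsets of CpG cytosines
cpg_offsets <- function(sequence) {
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits - 1L)
}

#' Align a bisulfite clone read to its reference region
#'
#' Global alignment (match +1, mismatch -1, gap -2) with reference C vs
#' read T scored as a match, so fully converted and fully methylated reads
#' both align at 100% identity. Identity is the matched fraction of
#' alignment columns; clones below `min_identity` are flagged unalignable.
#'
#' @param reference a [reference_region()].
#' @param read clone sequence (DNA string).
#' @param min_identity identity floor (default 0.90).
#' @return list: `aligned_ref`, `aligned_read` (gapped strings), `score`,
#'   `identity`, `alignable`.
#' @export
align_clone <- function(reference, read, min_identity = 0.90) {
  stopifnot(inherits(reference, "reference_region"))
  read <- toupper(as.character(read))
  ratio <- nchar(read) / nchar(reference$sequence)
  if (ratio < 0.5 || ratio > 1.5)
    stop("read length outside 50-150% of the reference")
  aln <- nw_bisulfite_align(reference$sequence, read)
  aln$alignable <- aln$identity >= min_identity
  aln
}

# read base aligned to each reference position (NA for gaps), from the
# gapped alignment strings
read_base_at_ref <- function(aligned_ref, aligned_read) {
  ra <- strsplit(aligned_ref, "")[[1]]
  rd <- strsplit(aligned_read, "")[[1]]
  keep <- ra != "-"
  out <- rd[keep]
  out[out == "-"] <- NA_character_
  out
}

#' Call per-CpG methylation across bisulfite clones
#'
#' Aligns every clone to the reference, reads each CpG cytosine as
#' methylated (C), unmethylated (T) or missing (gap/other), and computes a
#' per-clone conversion rate from the non-CpG cytosines (fraction read as
#' T). Clones failing the identity or conversion QC are excluded with a
#' reason. The headline percentage pools all non-missing CpG calls of the
#' included clones.
#'
#' @param reference a [reference_region()] with at least one CpG.
#' @param reads character vector (or `DNAStringSet`) of clone sequences.
#' @param min_conversion minimum non-CpG conversion rate (default 0.95).
#' @param min_identity minimum alignment identity (default 0.90).
#' @return list of class `methylation_profile`: `region`, `calls` (clones x
#'   CpGs matrix of 1/0/NA), `conversion_rate` (per clone),
#'   `included` (logical per clone), `excluded_clones` (data.frame `clone`,
#'   `reason`), `percent_methylated`, counts `n_methylated`,
#'   `n_unmethylated`.
#' @export
call_methylation <- function(reference, reads, min_conversion = 0.95,
                             min_identity = 0.90) {
  stopifnot(inherits(reference, "reference_region"))
  if (length(reference$cpg_positions) == 0)
    stop("reference region contains no CpG")
  reads <- as.character(reads)
  if (length(reads) < 1) stop("no clone reads supplied")
  ref_chars <- strsplit(reference$sequence, "")[[1]]
  cpg_idx <- reference$cpg_positions + 1L
  noncpg_c <- setdiff(which(ref_chars == "C"), cpg_idx)

  n_cl <- length(reads)
  calls <- matrix(NA_integer_, n_cl, length(cpg_idx),
                  dimnames = list(sprintf("clone%02d", seq_len(n_cl)),
                                  sprintf("CpG_%d", reference$cpg_positions)))
  conv <- rep(NA_real_, n_cl)
  identity <- rep(NA_real_, n_cl)
  reasons <- character(0); bad_clones <- character(0)
  for (i in seq_len(n_cl)) {
    aln <- align_clone(reference, reads[i], min_identity)
    identity[i] <- aln$identity
    at_ref <- read_base_at_ref(aln$aligned_ref, aln$aligned_read)
    if (length(noncpg_c) > 0) {
      bases <- at_ref[noncpg_c]
      informative <- bases %in% c("C", "T")
      conv[i] <- if (any(informative))
        mean(bases[informative] == "T") else NA_real_
    } else conv[i] <- 1
    cg <- at_ref[cpg_idx]
    calls[i, ] <- ifelse(cg == "C", 1L, ifelse(cg == "T", 0L, NA_integer_))
    if (!aln$alignable) {
      bad_clones <- c(bad_clones, rownames(calls)[i])
      reasons <- c(reasons, sprintf("identity %.3f < %.2f", aln$identity,
                                    min_identity))
    } else if (!is.na(conv[i]) && conv[i] < min_conversion) {
      bad_clones <- c(bad_clones, rownames(calls)[i])
      reasons <- c(reasons, sprintf("conversion %.3f < %.2f", conv[i],
                                    min_conversion))
    }
  }
  included <- !(rownames(calls) %in% bad_clones)
  inc_calls <- calls[included, , drop = FALSE]
  n_meth <- sum(inc_calls == 1L, na.rm = TRUE)
  n_unmeth <- sum(inc_calls == 0L, na.rm = TRUE)
  pct <- if (n_meth + n_unmeth > 0) 100 * n_meth / (n_meth + n_unmeth)
         else NA_real_
  structure(list(region = reference$name, calls = calls,
                 conversion_rate = conv, identity = identity,
                 included = included,
                 excluded_clones = data.frame(clone = bad_clones,
                                              reason = reasons,
                                              stringsAsFactors = FALSE),
                 percent_methylated = pct,
                 n_methylated = n_meth, n_unmethylated = n_unmeth),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("<methylation_profile '%s'> %d/%d clones included, %.1f%% methylated\n",
              x$region, sum(x$included), length(x$included),
              x$percent_methylated))
  invisible(x)
}

#' Text lollipop rendering of a methylation profile
#'
#' One row per clone: filled circles are methylated CpGs, open circles
#' unmethylated, dots missing calls; excluded clones are marked.
#'
#' @param profile a [call_methylation()] result.
#' @return character vector, one element per clone (invisibly printed).
#' @export
render_lollipop <- function(profile) {
  stopifnot(inherits(profile, "methylation_profile"))
  glyph <- function(v) paste(ifelse(is.na(v), ".",
                                    ifelse(v == 1L, "●", "○")),
                             collapse = " ")
  lines <- vapply(seq_len(nrow(profile$calls)), function(i) {
    sprintf("%s %s%s", rownames(profile$calls)[i], glyph(profile$calls[i, ]),
            if (profile$included[i]) "" else "  [excluded]")
  }, character(1))
  lines
}

#' Compare two methylation profiles of the same region
#'
#' Reports the percentage difference and a two-sided Fisher's exact test on
#' the pooled methylated/unmethylated 2x2 table. (The underlying study
#' reports no test for methylation differences; the Fisher test is this
#' package's addition.)
#'
#' @param a,b [call_methylation()] profiles for the same region.
#' @return list: `delta_percent` (`a` minus `b`), `p`, and the 2x2 `table`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "methylation_profile"),
            inherits(b, "methylation_profile"))
  if (!identical(a$region, b$region))
    stop("profiles are from different regions")
  ca <- c(a$n_methylated, a$n_unmethylated)
  cb <- c(b$n_methylated, b$n_unmethylated)
  if (sum(ca) == 0 || sum(cb) == 0) stop("empty profile")
  tab <- rbind(a = ca, b = cb)
  colnames(tab) <- c("methylated", "unmethylated")
  p <- fisher.test(tab)$p.value
  list(delta_percent = a$percent_methylated - b$percent_methylated,
       p = min(p, 1), table = tab)
}
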