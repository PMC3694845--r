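#' Kernel-density tag track
#'
#' Smooths integer tag positions into an expected-tags-per-bp density,
#' evaluated at every bp of the chromosome, using a Gaussian kernel
#' (default bandwidth 30 bp, the value used for transcription-factor
#' ChIP-seq in this pipeline). The discretized kernel is renormalized to
#' unit mass and counts are reflected at the chromosome boundaries, so the
#' density integrates to the tag count essentially exactly.
#'
#' @param positions integer tag positions (0-based bp), in `[0, chrom_length)`.
#' @param chrom_length chromosome length, bp.
#' @param bandwidth Gaussian kernel sd, bp.
#' @return numeric vector of length `chrom_length`; element `i` is the
#'   density at bp `i - 1` (tags per bp).
#' @export
kde_density <- function(positions, chrom_length, bandwidth = 30) {
  if (length(positions) < 1) stop("empty tag track")
  positions <- as.numeric(positions)
  if (any(positions < 0) || any(positions >= chrom_length))
    stop("tag positions outside chromosome bounds")
  L <- as.integer(chrom_length)
  R <- as.integer(ceiling(6 * bandwidth))
  if (L <= R) stop("chromosome too short for the requested bandwidth")
  counts <- tabulate(floor(positions) + 1L, nbins = L)
  k <- dnorm(seq(-R, R), 0, bandwidth)
  k <- k / sum(k)
  padded <- c(counts[R:1], counts, counts[L:(L - R + 1L)])
  sm <- stats::filter(padded, k, sides = 2)
  as.numeric(sm[(R + 1L):(R + L)])
}

#' Call enriched peaks from experiment and background tag tracks
#'
#' Candidate regions are maximal runs where the experiment density reaches
#' `candidate_threshold` times its genome-wide mean. A candidate becomes a
#' peak when, after scaling the background track to the experiment's total
#' tag count (and flooring the background density at its genome-wide mean
#' to avoid empty-background blowups), the experiment/background density
#' ratio at the candidate's summit reaches `enrichment_threshold`. The
#' summit is the argmax of the experiment density within the region.
#'
#' @param experiment,background integer tag position vectors.
#' @param chrom_length chromosome length, bp.
#' @param candidate_threshold fold over mean experiment density (default 5).
#' @param enrichment_threshold experiment/background ratio at the summit
#'   (default 3).
#' @param bandwidth KDE bandwidth, bp (default 30).
#' @param chrom chromosome name for the output.
#' @return data.frame of peaks: `chrom`, `start`, `end` (0-based,
#'   half-open), `summit` (bp), `score` (experiment density at summit,
#'   tags/bp), `enrichment` (summit density ratio).
#' @export
call_peaks <- function(experiment, background, chrom_length,
                       candidate_threshold = 5.0, enrichment_threshold = 3.0,
                       bandwidth = 30, chrom = "chrS") {
  if (length(background) < 1) stop("background track has no tags")
  if (length(experiment) < 1) stop("experiment track has no tags")
  L <- as.integer(chrom_length)
  dens_e <- kde_density(experiment, L, bandwidth)
  dens_b <- kde_density(background, L, bandwidth)
  ne <- length(experiment); nb <- length(background)
  scale <- ne / nb
  dens_b_scaled <- dens_b * scale
  floor_b <- ne / L                      # scaled genome-mean background
  mean_e <- ne / L
  above <- dens_e >= candidate_threshold * mean_e
  if (!any(above)) return(empty_peaks(chrom))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  rows <- lapply(cand, function(r) {
    i0 <- starts[r]; i1 <- ends[r]
    seg <- dens_e[i0:i1]
    summit_idx <- i0 + which.max(seg) - 1L      # leftmost argmax
    enr <- dens_e[summit_idx] / max(dens_b_scaled[summit_idx], floor_b)
    if (enr < enrichment_threshold) return(NULL)
    data.frame(chrom = chrom, start = i0 - 1L, end = i1,
               summit = summit_idx - 1L, score = dens_e[summit_idx],
               enrichment = enr, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_peaks(chrom))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_peaks <- function(chrom) {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             summit = integer(0), score = numeric(0), enrichment = numeric(0),
             stringsAsFactors = FALSE)
}

#' Retain peaks enriched in one track over another
#'
#' Differential (e.g. DKO-specific) peak selection: a called peak is kept
#' when the target/reference density ratio at its summit, with both tracks
#' scaled to equal totals and the reference floored at its genome-wide
#' mean, reaches `enrichment_threshold`.
#'
#' @param peaks data.frame from [call_peaks()] on the target track.
#' @param target,reference integer tag position vectors.
#' @param chrom_length chromosome length, bp.
#' @param enrichment_threshold summit density ratio cut (default 3).
#' @param bandwidth KDE bandwidth, bp.
#' @return the retained subset of `peaks` with an added
#'   `differential_enrichment` column.
#' @export
differential_peaks <- function(peaks, target, reference, chrom_length,
                               enrichment_threshold = 3.0, bandwidth = 30) {
  if (nrow(peaks) == 0) {
    peaks$differential_enrichment <- numeric(0)
    return(peaks)
  }
  L <- as.integer(chrom_length)
  dens_t <- kde_density(target, L, bandwidth)
  dens_r <- kde_density(reference, L, bandwidth) *
    (length(target) / length(reference))
  floor_r <- length(target) / L
  at <- peaks$summit + 1L
  ratio <- dens_t[at] / pmax(dens_r[at], floor_r)
  out <- peaks[ratio >= enrichment_threshold, , drop = FALSE]
  out$differential_enrichment <- ratio[ratio >= enrichment_threshold]
  rownames(out) <- NULL
  out
}

#' Associate peaks with their nearest gene within a distance bound
#'
#' For each peak, finds the gene interval with the smallest gap (0 when
#' overlapping; ties broken by the smaller gene start) and emits a link when
#' the gap is at most `max_distance` (default 5 kb). Coordinates are
#' 0-based half-open throughout, so a peak ending at `e` and a gene
#' starting at `s` are `s - e` bp apart.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (plus any other
#'   columns, carried through).
#' @param annotation BED-like data.frame: `chrom`, `start`, `end`, `name`.
#' @param max_distance maximum gap, bp (default 5000).
#' @return data.frame of links: peak coordinates, `gene`, `gene_start`,
#'   `gene_end`, `distance`.
#' @export
associate_peaks_to_genes <- function(peaks, annotation, max_distance = 5000) {
  if (is.null(annotation) || nrow(annotation) == 0)
    stop("annotation is empty")
  if (nrow(peaks) == 0)
    return(data.frame(chrom = character(0), peak_start = integer(0),
                      peak_end = integer(0), gene = character(0),
                      gene_start = integer(0), gene_end = integer(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  gg <- gr <- GenomicRanges::GRanges(annotation$chrom,
                                     IRanges::IRanges(annotation$start + 1L,
                                                      annotation$end))
  links <- lapply(seq_len(nrow(peaks)), function(i) {
    d <- GenomicRanges::distance(rep(pg[i], length(gg)), gg)
    d[is.na(d)] <- Inf                       # different chromosome
    dmin <- min(d)
    if (!is.finite(dmin) || dmin > max_distance) return(NULL)
    tied <- which(d == dmin)
    j <- tied[order(annotation$start[tied])][1]
    data.frame(chrom = peaks$chrom[i], peak_start = peaks$start[i],
               peak_end = peaks$end[i], gene = annotation$name[j],
               gene_start = annotation$start[j], gene_end = annotation$end[j],
               distance = as.integer(dmin), stringsAsFactors = FALSE)
  })
  links <- links[!vapply(links, is.null, logical(1))]
  if (length(links) == 0)
    return(data.frame(chrom = character(0), peak_start = integer(0),
                      peak_end = integer(0), gene = character(0),
                      gene_start = integer(0), gene_end = integer(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, links)
  rownames(out) <- NULL
  out
}

#' Central motif enrichment in summit-centered windows
#'
#' For each equal-length window centered on a peak summit, finds the best
#' match to an IUPAC consensus on either strand (best = match center
#' closest to the window center; remaining ties resolved leftmost). Counts
#' the sequences whose best match falls in a central bin and tests central
#' concentration with a one-sided binomial tail against the uniform
#' expectation `q = central_bin / (window - motif + 1)`.
#'
#' @param sequences `Biostrings::DNAStringSet` (or character vector) of
#'   equal-length windows.
#' @param motif IUPAC consensus (default `WGATAR`, the canonical GATA site).
#' @param central_bin central bin width, bp (default 100).
#' @return list: `bin_sites`, `total_sites`, `n_sequences`, `q`, `p`.
#' @export
central_motif_enrichment <- function(sequences, motif = "WGATAR",
                                     central_bin = 100) {
  seqs <- Biostrings::DNAStringSet(sequences)
  W <- unique(Biostrings::width(seqs))
  if (length(W) != 1) stop("windows must all have the same length")
  m <- nchar(motif)
  if (central_bin > W) stop("central bin wider than the window")
  searchable <- W - m + 1
  q <- central_bin / searchable
  wc <- (W + 1) / 2                       # 1-based window center
  fwd <- Biostrings::vmatchPattern(motif, seqs, fixed = FALSE)
  rev <- Biostrings::vmatchPattern(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif))),
    seqs, fixed = FALSE)
  best_off <- vapply(seq_along(seqs), function(i) {
    starts <- c(IRanges::start(fwd[[i]]), IRanges::start(rev[[i]]))
    if (length(starts) == 0) return(NA_real_)
    centers <- starts + (m - 1) / 2
    off <- abs(centers - wc)
    min_off <- min(off)
    min_off
  }, numeric(1))
  total_sites <- sum(!is.na(best_off))
  bin_sites <- sum(best_off[!is.na(best_off)] <= central_bin / 2)
  p <- if (total_sites == 0) 1 else
    pbinom(bin_sites - 1, total_sites, q, lower.tail = FALSE)
  list(bin_sites = as.integer(bin_sites), total_sites = as.integer(total_sites),
       n_sequences = length(seqs), q = q, p = p)
}
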