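#' Specification for a synthetic ChIP tag track
#'
#' One synthetic chromosome carrying uniform background tags plus planted
#' enriched regions. Excess tags inside a planted peak are placed as a
#' truncated Gaussian around the center (sd = width/8, emulating
#' fragment-midpoint scatter around a point-source binding site), so each
#' planted peak has a sharply defined summit. `enrichment` is the planted
#' summit-density fold over background — the same quantity the peak caller
#' thresholds — so the excess tag count is Poisson with mean
#' `(enrichment - 1) * background_density * sqrt(2 pi) * sd`.
#'
#' @param chrom_length chromosome length, bp.
#' @param n_background_tags expected/drawn number of background tags.
#' @param planted_peaks data.frame with columns `center`, `width`,
#'   `enrichment` (summit density fold over background; 1 = no enrichment).
#'   May be empty.
#' @param motif_placement fraction of peak-window sequences carrying the
#'   consensus motif at their center (used by [simulate_peak_sequences()]).
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return list of class `chip_sim_spec`.
#' @export
chip_sim_spec <- function(chrom_length = 200000,
                          n_background_tags = 20000,
                          planted_peaks = data.frame(center = numeric(),
                                                     width = numeric(),
                                                     enrichment = numeric()),
                          motif_placement = 0.6,
                          chrom = "chrS",
                          seed = 1L) {
  if (chrom_length <= 0) stop("chrom_length must be positive")
  if (nrow(planted_peaks) > 0) {
    stopifnot(all(c("center", "width", "enrichment") %in% names(planted_peaks)))
    if (any(planted_peaks$enrichment <= 0)) stop("enrichment must be > 0")
    lo <- planted_peaks$center - planted_peaks$width / 2
    hi <- planted_peaks$center + planted_peaks$width / 2
    if (any(lo < 0) || any(hi > chrom_length))
      stop("planted peak extends outside the chromosome")
  }
  if (motif_placement < 0 || motif_placement > 1)
    stop("motif_placement must be in [0, 1]")
  structure(list(chrom_length = as.integer(chrom_length),
                 n_background_tags = as.integer(n_background_tags),
                 planted_peaks = planted_peaks,
                 motif_placement = motif_placement,
                 chrom = chrom, seed = as.integer(seed)),
            class = "chip_sim_spec")
}

#' Simulate experiment/background ChIP tag tracks with a gene annotation
#'
#' Background tags are uniform on `[0, chrom_length)`. The experiment track
#' receives its own uniform draw at the background rate plus, inside each
#' planted peak, a Poisson number of excess tags at the stated fold
#' enrichment. Gene intervals are laid down at known offsets from the
#' planted peaks (one gene 1 kb downstream of each peak, one overlapping
#' gene for every third peak) plus distant decoys, so peak-to-gene
#' association can be validated against construction.
#'
#' @param spec a [chip_sim_spec()].
#' @return list with integer tag vectors `experiment`, `background`,
#'   data.frame `annotation` (BED-like: `chrom`, `start`, `end`, `name`),
#'   and `spec`.
#' @export
simulate_chip_tags <- function(spec) {
  stopifnot(inherits(spec, "chip_sim_spec"))
  set.seed(spec$seed)
  L <- spec$chrom_length
  bg_rate <- spec$n_background_tags / L
  background <- sort(floor(runif(spec$n_background_tags, 0, L)))
  experiment <- floor(runif(spec$n_background_tags, 0, L))
  pk <- spec$planted_peaks
  if (nrow(pk) > 0) {
    for (i in seq_len(nrow(pk))) {
      sdp <- pk$width[i] / 8
      # excess mass giving the planted summit-density fold over background
      excess <- (pk$enrichment[i] - 1) * bg_rate * sqrt(2 * pi) * sdp
      n_extra <- if (excess > 0) rpois(1, excess) else 0L
      if (n_extra > 0) {
        pos <- rnorm(n_extra, pk$center[i], sdp)
        # truncate to the planted interval by resampling
        bad <- which(abs(pos - pk$center[i]) > pk$width[i] / 2)
        while (length(bad) > 0) {
          pos[bad] <- rnorm(length(bad), pk$center[i], sdp)
          bad <- bad[abs(pos[bad] - pk$center[i]) > pk$width[i] / 2]
        }
        experiment <- c(experiment, floor(pos))
      }
    }
  }
  experiment <- sort(pmin(pmax(experiment, 0), L - 1))

  ann <- list()
  if (nrow(pk) > 0) {
    for (i in seq_len(nrow(pk))) {
      pe <- round(pk$center[i] + pk$width[i] / 2)
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = spec$chrom, start = pe + 1000, end = pe + 3000,
        name = sprintf("near_gene_%02d", i), stringsAsFactors = FALSE)
      if (i %% 3 == 0) {
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = spec$chrom, start = round(pk$center[i]) - 500,
          end = round(pk$center[i]) + 500,
          name = sprintf("overlap_gene_%02d", i), stringsAsFactors = FALSE)
      }
    }
  }
  # distant decoys, far (> 10 kb) from every planted peak
  decoy_starts <- round(seq(0.05, 0.95, length.out = 4) * L)
  if (nrow(pk) > 0) {
    far <- vapply(decoy_starts, function(s)
      all(abs(s - pk$center) > 10000 + pk$width / 2), logical(1))
    decoy_starts <- decoy_starts[far]
  }
  for (k in seq_along(decoy_starts)) {
    ann[[length(ann) + 1L]] <- data.frame(
      chrom = spec$chrom, start = decoy_starts[k],
      end = decoy_starts[k] + 2000,
      name = sprintf("decoy_gene_%02d", k), stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann)
  annotation <- annotation[annotation$start >= 0 & annotation$end <= L, ]
  annotation <- annotation[order(annotation$start), ]
  rownames(annotation) <- NULL
  list(experiment = experiment, background = background,
       annotation = annotation, spec = spec)
}

#' Simulate peak-window sequences for central motif enrichment
#'
#' Random-uniform DNA windows of fixed width; a `motif_placement` fraction
#' carries one instance of the consensus (IUPAC codes resolved uniformly)
#' centered in the window, emulating summit-centered ChIP peak sequences.
#'
#' @param spec a [chip_sim_spec()] (supplies `motif_placement` and seed).
#' @param n_windows number of sequences.
#' @param width window width, bp.
#' @param motif IUPAC consensus planted at the center.
#' @return `Biostrings::DNAStringSet` of length `n_windows`.
#' @export
simulate_peak_sequences <- function(spec, n_windows = 200, width = 500,
                                    motif = "WGATAR") {
  stopifnot(inherits(spec, "chip_sim_spec"))
  set.seed(spec$seed + 500L)
  bases <- c("A", "C", "G", "T")
  iupac <- Biostrings::IUPAC_CODE_MAP
  seqs <- vapply(seq_len(n_windows), function(i) {
    s <- sample(bases, width, replace = TRUE)
    if (runif(1) < spec$motif_placement) {
      inst <- vapply(strsplit(motif, "")[[1]], function(code) {
        opts <- strsplit(iupac[[code]], "")[[1]]
        sample(opts, 1)
      }, character(1))
      m <- length(inst)
      at <- floor((width - m) / 2) + 1   # motif centered in the window
      s[at:(at + m - 1)] <- inst
    }
    paste(s, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}
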