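#' Specification for synthetic bisulfite clone reads
#'
#' @param region_sequence DNA string containing at least one CpG.
#' @param per_cpg_meth_prob methylation probability per CpG (recycled to the
#'   number of CpGs in the region), each in `[0, 1]`.
#' @param n_clones clones to sequence (default 24, the panel size the
#'   pipeline emulates).
#' @param conversion_failure_rate probability that a non-CpG (unmethylated)
#'   cytosine escapes conversion and is read as C (default 0.005).
#' @param sequencing_error_rate per-base probability of a uniform random
#'   substitution after conversion (default 0).
#' @param seed integer seed.
#' @return list of class `bisulfite_sim_spec`.
#' @export
bisulfite_sim_spec <- function(region_sequence,
                               per_cpg_meth_prob,
                               n_clones = 24,
                               conversion_failure_rate = 0.005,
                               sequencing_error_rate = 0,
                               seed = 1L) {
  region_sequence <- toupper(as.character(region_sequence))
  cpg <- cpg_offsets(region_sequence)
  if (length(cpg) == 0) stop("region contains no CpG")
  p <- rep(per_cpg_meth_prob, length.out = length(cpg))
  if (any(p < 0 | p > 1)) stop("methylation probabilities must be in [0, 1]")
  if (conversion_failure_rate < 0 || conversion_failure_rate > 1 ||
      sequencing_error_rate < 0 || sequencing_error_rate > 1)
    stop("rates must be probabilities")
  if (n_clones < 1) stop("n_clones must be >= 1")
  structure(list(region_sequence = region_sequence,
                 cpg_positions = cpg,
                 per_cpg_meth_prob = p,
                 n_clones = as.integer(n_clones),
                 conversion_failure_rate = conversion_failure_rate,
                 sequencing_error_rate = sequencing_error_rate,
                 seed = as.integer(seed)),
            class = "bisulfite_sim_spec")
}

#' Simulate bisulfite-converted clone reads
#'
#' For each clone, every CpG cytosine is retained as C with its per-CpG
#' methylation probability and otherwise converted to T; every non-CpG
#' cytosine is converted to T except with `conversion_failure_rate`;
#' optional uniform sequencing errors are applied afterwards. Reads model
#' the top strand of the PCR product only.
#'
#' @param spec a [bisulfite_sim_spec()].
#' @return list: `reads` (character vector, one per clone, named), `truth`
#'   (clones x CpGs 0/1 matrix of planted methylation states), `spec`.
#' @export
simulate_bisulfite_clones <- function(spec) {
  stopifnot(inherits(spec, "bisulfite_sim_spec"))
  set.seed(spec$seed)
  ref <- strsplit(spec$region_sequence, "")[[1]]
  cpg_idx <- spec$cpg_positions + 1L
  noncpg_c <- setdiff(which(ref == "C"), cpg_idx)
  bases <- c("A", "C", "G", "T")
  truth <- matrix(0L, spec$n_clones, length(cpg_idx),
                  dimnames = list(sprintf("clone%02d", seq_len(spec$n_clones)),
                                  sprintf("CpG_%d", spec$cpg_positions)))
  reads <- vapply(seq_len(spec$n_clones), function(i) {
    s <- ref
    meth <- rbinom(length(cpg_idx), 1, spec$per_cpg_meth_prob)
    truth[i, ] <<- meth
    s[cpg_idx[meth == 0L]] <- "T"
    if (length(noncpg_c) > 0) {
      escaped <- rbinom(length(noncpg_c), 1, spec$conversion_failure_rate)
      s[noncpg_c[escaped == 0L]] <- "T"
    }
    if (spec$sequencing_error_rate > 0) {
      err <- which(rbinom(length(s), 1, spec$sequencing_error_rate) == 1L)
      for (k in err) s[k] <- sample(setdiff(bases, s[k]), 1)
    }
    paste(s, collapse = "")
  }, character(1))
  names(reads) <- rownames(truth)
  list(reads = reads, truth = truth, spec = spec)
}
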