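# Independent oracles used by the tests. Each re-derives a quantity by a
# different route than the package implementation (brute force, direct
# enumeration, closed form), so agreement is evidence rather than tautology.

# small default simulation: fast fixtures with every archetype represented
tiny_config <- function(noise_sd = 0, seed = 1L, n_genes = 120, ...) {
  sim_config(n_genes = n_genes, probes_per_gene = 2, noise_sd = noise_sd,
             seed = seed, ...)
}

# brute-force UPGMA: explicit member lists, cross-pair means recomputed from
# the original distance matrix at every step; same tie rule as the package
# (lowest contained leaf index, then the partner's lowest index)
brute_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  cluster_dist <- function(a, b) mean(D[a, b])
  for (s in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- cluster_dist(clusters[[i]], clusters[[j]])
      key <- c(dij, min(min(clusters[[i]]), min(clusters[[j]])),
               max(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) ||
          key[1] < best$key[1] - 1e-15 ||
          (abs(key[1] - best$key[1]) <= 1e-15 &&
             (key[2] < best$key[2] ||
                (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    a <- ids[i]; b <- ids[j]
    merges[s, ] <- if (a < 0 && b < 0) c(min(a, b), max(a, b))
      else if (a < 0) c(a, b) else if (b < 0) c(b, a) else c(min(a, b), max(a, b))
    heights[s] <- best$key[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- s
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merges, height = heights)
}

# brute-force peak-gene association: all-pairs minimal gap in half-open
# 0-based coordinates
brute_links <- function(peaks, annotation, max_distance = 5000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    gaps <- vapply(seq_len(nrow(annotation)), function(j) {
      if (peaks$chrom[i] != annotation$chrom[j]) return(Inf)
      ps <- peaks$start[i]; pe <- peaks$end[i]
      gs <- annotation$start[j]; ge <- annotation$end[j]
      if (pe <= gs) gs - pe else if (ge <= ps) ps - ge else 0
    }, numeric(1))
    dmin <- min(gaps)
    if (dmin > max_distance) next
    tied <- which(gaps == dmin)
    j <- tied[order(annotation$start[tied])][1]
    out[[length(out) + 1L]] <- data.frame(
      peak = i, gene = annotation$name[j], distance = dmin)
  }
  do.call(rbind, out)
}

# independent solve of the variance-prior moment equations: uniroot on the
# trigamma equation instead of Newton inversion
oracle_variance_prior <- function(s2, d) {
  z <- log(s2[s2 > 0])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (evar <= 0) return(list(d0 = Inf, s0_sq = mean(s2)))
  f <- function(x) trigamma(x) - evar
  half_d0 <- uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-14)$root
  list(d0 = 2 * half_d0,
       s0_sq = exp(mean(e) + digamma(half_d0) - log(half_d0)))
}

# two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# reference Needleman-Wunsch in plain R with the bisulfite scoring
# (same contract as the compiled version, independently written)
oracle_nw <- function(ref, read, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(ref, "")[[1]]; b <- strsplit(read, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)
  S[, 1] <- (0:n) * gap; P[, 1] <- 1L
  S[1, ] <- (0:m) * gap; P[1, ] <- 2L
  P[1, 1] <- 0L
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    is_match <- a[i - 1] == b[j - 1] || (a[i - 1] == "C" && b[j - 1] == "T")
    sc <- c(S[i - 1, j - 1] + if (is_match) match else mismatch,
            S[i - 1, j] + gap, S[i, j - 1] + gap)
    P[i, j] <- which.max(sc) - 1L      # ties: diag > up > left
    S[i, j] <- max(sc)
  }
  i <- n + 1; j <- m + 1; aref <- character(0); aread <- character(0)
  while (i > 1 || j > 1) {
    ptr <- if (i == 1) 2L else if (j == 1) 1L else P[i, j]
    if (ptr == 0L) { aref <- c(a[i - 1], aref); aread <- c(b[j - 1], aread); i <- i - 1; j <- j - 1 }
    else if (ptr == 1L) { aref <- c(a[i - 1], aref); aread <- c("-", aread); i <- i - 1 }
    else { aref <- c("-", aref); aread <- c(b[j - 1], aread); j <- j - 1 }
  }
  matches <- sum(aref != "-" & aread != "-" &
                   (aref == aread | (aref == "C" & aread == "T")))
  list(aligned_ref = paste(aref, collapse = ""),
       aligned_read = paste(aread, collapse = ""),
       score = S[n + 1, m + 1], identity = matches / length(aref))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
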