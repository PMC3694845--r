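test_that("KDE places kernel mass where tags are and conserves total mass", {
  L <- 5000
  d1 <- kde_density(2500, L, bandwidth = 30)
  expect_equal(which.max(d1) - 1, 2500)
  expect_equal(d1[2501], dnorm(0, 0, 30), tolerance = 1e-6)
  expect_lt(abs(sum(d1) - 1), 1e-6)
  # symmetric pair -> symmetric density about the midpoint
  d2 <- kde_density(c(2400, 2600), L, bandwidth = 30)
  expect_equal(d2[2401], d2[2601], tolerance = 1e-12)
  expect_equal(d2[2301], d2[2701], tolerance = 1e-12)
  expect_lt(abs(sum(d2) - 2), 1e-6)
  expect_error(kde_density(numeric(0), L), "empty")
  expect_error(kde_density(c(10, 6000), L), "bounds")
})

test_that("KDE mass is conserved even with tags at the chromosome edges", {
  set.seed(19)
  for (trial in 1:5) {
    pos <- c(0, 1, 2, floor(runif(500, 0, 10000)), 9997, 9998, 9999)
    dens <- kde_density(pos, 10000, bandwidth = 30)
    expect_lt(abs(sum(dens) - length(pos)), 1e-6)
  }
})

test_that("uniform tags give a flat density at the expected rate on average", {
  # 1000 tags on 100 kb: per-seed KDE values fluctuate strongly (only ~1 tag
  # per bandwidth), so the law-of-large-numbers claim is checked on the
  # seed-averaged density at interior positions against its sampling SE
  L <- 100000; n <- 1000; h <- 30; n_seeds <- 20
  probe <- seq(5000, 95000, by = 5000)
  acc <- matrix(0, n_seeds, length(probe))
  for (s in 1:n_seeds) {
    set.seed(s)
    dens <- kde_density(floor(runif(n, 0, L)), L, bandwidth = h)
    acc[s, ] <- dens[probe + 1]
  }
  se_point <- sqrt((n / L) / (2 * sqrt(pi) * h))   # kernel-variance formula
  se_mean <- se_point / sqrt(n_seeds)
  expect_true(all(abs(colMeans(acc) - n / L) < 5 * se_mean))
  expect_lt(abs(mean(acc) - n / L), 4 * se_mean / sqrt(length(probe)))
})

test_that("identical experiment and background yield no peaks", {
  set.seed(5)
  tags <- floor(runif(3000, 0, 50000))
  p <- call_peaks(tags, tags, 50000)
  expect_equal(nrow(p), 0)
  expect_error(call_peaks(tags, integer(0), 50000), "background")
})

test_that("planted enrichment above threshold is called; below is not", {
  hits <- 0; misses <- 0; offs <- numeric(0)
  for (s in 1:5) {
    sp10 <- chip_sim_spec(planted_peaks = data.frame(
      center = 1e5, width = 400, enrichment = 10), seed = s)
    sp2 <- chip_sim_spec(planted_peaks = data.frame(
      center = 1e5, width = 400, enrichment = 2), seed = s)
    x10 <- simulate_chip_tags(sp10); x2 <- simulate_chip_tags(sp2)
    p10 <- call_peaks(x10$experiment, x10$background, sp10$chrom_length)
    p2 <- call_peaks(x2$experiment, x2$background, sp2$chrom_length)
    hits <- hits + (nrow(p10) == 1)
    misses <- misses + nrow(p2)
    if (nrow(p10) == 1) offs <- c(offs, abs(p10$summit - 1e5))
  }
  expect_equal(hits, 5)
  expect_equal(misses, 0)
  expect_true(all(offs <= 30))
})

test_that("null ChIP simulation is statistically flat and deterministic", {
  ks_ok <- 0
  for (s in 1:20) {
    sp <- chip_sim_spec(planted_peaks = data.frame(
      center = 1e5, width = 400, enrichment = 1), seed = s)
    x <- simulate_chip_tags(sp)
    pv <- suppressWarnings(ks.test(x$experiment, x$background)$p.value)
    ks_ok <- ks_ok + (pv > 0.01)
  }
  expect_gte(ks_ok, 18)
  sp <- chip_sim_spec(seed = 77)
  expect_identical(simulate_chip_tags(sp)$experiment,
                   simulate_chip_tags(sp)$experiment)
  expect_error(chip_sim_spec(chrom_length = 0), "positive")
  expect_error(chip_sim_spec(planted_peaks = data.frame(
    center = 100, width = 400, enrichment = 2)), "outside")
})

test_that("peak calling is invariant to tag order", {
  sp <- chip_sim_spec(planted_peaks = data.frame(
    center = 5e4, width = 400, enrichment = 10), chrom_length = 1e5,
    n_background_tags = 4000, seed = 3)
  x <- simulate_chip_tags(sp)
  set.seed(1)
  p1 <- call_peaks(x$experiment, x$background, sp$chrom_length)
  p2 <- call_peaks(sample(x$experiment), sample(x$background), sp$chrom_length)
  expect_equal(p1, p2)
})

test_that("differential peaks keep target-specific signal only", {
  sp_both <- chip_sim_spec(planted_peaks = data.frame(
    center = c(3e4, 7e4), width = 400, enrichment = 10), chrom_length = 1e5,
    n_background_tags = 4000, seed = 8)
  sp_shared <- chip_sim_spec(planted_peaks = data.frame(
    center = 7e4, width = 400, enrichment = 10), chrom_length = 1e5,
    n_background_tags = 4000, seed = 9)
  target <- simulate_chip_tags(sp_both)
  reference <- simulate_chip_tags(sp_shared)
  peaks <- call_peaks(target$experiment, target$background, 1e5)
  expect_equal(nrow(peaks), 2)
  diffp <- differential_peaks(peaks, target$experiment, reference$experiment, 1e5)
  expect_equal(nrow(diffp), 1)
  expect_lt(abs(diffp$summit - 3e4), 200)    # the target-only peak survives
  # self-comparison always empties the list
  expect_equal(nrow(differential_peaks(peaks, target$experiment,
                                       target$experiment, 1e5)), 0)
})

test_that("peak-gene association handles overlap, boundary, and ties", {
  genes <- data.frame(chrom = "chrS",
                      start = c(1000, 20000, 40000),
                      end = c(2000, 21000, 41000),
                      name = c("inside", "far_gene", "edge_gene"))
  peaks <- data.frame(chrom = "chrS",
                      start = c(1200, 5000, 34999, 33999),
                      end = c(1300, 5100, 35001, 34999))
  links <- associate_peaks_to_genes(peaks, genes, max_distance = 5000)
  # overlapping peak -> distance 0
  expect_equal(links$distance[links$peak_start == 1200], 0)
  expect_equal(links$gene[links$peak_start == 1200], "inside")
  # 4,999 bp before a gene start is linked; 5,001 bp is not
  expect_true(34999 %in% links$peak_start[links$gene == "edge_gene"])
  expect_equal(links$distance[links$peak_start == 34999], 4999)
  expect_false(33999 %in% links$peak_start)
  expect_error(associate_peaks_to_genes(peaks, genes[0, ]), "empty")
})

test_that("association equals the brute-force all-pairs oracle", {
  set.seed(55)
  for (trial in 1:5) {
    genes <- data.frame(chrom = "chrS",
                        start = sort(sample(seq(0, 90000, 100), 5)))
    genes$end <- genes$start + sample(500:3000, 5, TRUE)
    genes$name <- sprintf("gene%d", 1:5)
    peaks <- data.frame(chrom = "chrS",
                        start = sample(seq(0, 95000, 50), 10))
    peaks$end <- peaks$start + sample(100:400, 10, TRUE)
    links <- associate_peaks_to_genes(peaks, genes, 5000)
    oracle <- brute_links(peaks, genes, 5000)
    if (is.null(oracle)) {
      expect_equal(nrow(links), 0)
    } else {
      expect_equal(nrow(links), nrow(oracle))
      expect_equal(links$gene, oracle$gene)
      expect_equal(links$distance, oracle$distance)
    }
  }
})

test_that("BED files round-trip bit-stably and reject malformed lines", {
  genes <- data.frame(chrom = "chrS", start = c(10L, 500L), end = c(200L, 900L),
                      name = c("g1", "g2"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_bed(genes, path)
  first <- readLines(path)
  back <- read_bed(path)
  expect_equal(back, genes)
  write_bed(back, path)
  expect_identical(readLines(path), first)
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chrS\t10\t200\tok", "chrS\t300"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines(c("chrS\t10\t200\tok", "chrS\t900\t300\tbad"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("central motif enrichment detects forced and absent placements", {
  set.seed(61)
  w <- 200
  # motif at every window center
  centered <- vapply(1:30, function(i) {
    s <- sample(c("A", "C", "G", "T"), w, TRUE,
                prob = c(0.2, 0.3, 0.3, 0.2))
    s[98:103] <- c("A", "G", "A", "T", "A", "A")   # WGATAR instance
    paste(s, collapse = "")
  }, character(1))
  res <- central_motif_enrichment(centered, "WGATAR", central_bin = 20)
  expect_equal(res$bin_sites, res$total_sites)
  q <- 20 / (w - 6 + 1)
  expect_equal(res$p, q^res$total_sites, tolerance = 1e-9)
  # no match anywhere -> total 0, p = 1 by convention
  none <- strrep("C", w)
  res0 <- central_motif_enrichment(rep(none, 5), "WGATAR", central_bin = 20)
  expect_equal(res0$total_sites, 0)
  expect_equal(res0$p, 1)
  expect_error(central_motif_enrichment(centered, "WGATAR", central_bin = 500),
               "wider")
})

test_that("motif matches on the reverse strand are found", {
  w <- 101
  s <- strrep("C", w)
  # plant only the reverse complement of AGATAA (= TTATCT) at the center
  substr(s, 48, 53) <- "TTATCT"
  res <- central_motif_enrichment(s, "WGATAR", central_bin = 10)
  expect_equal(res$total_sites, 1)
  expect_equal(res$bin_sites, 1)
})

test_that("uniformly placed motifs show no central concentration", {
  set.seed(71)
  w <- 500; nwin <- 500; q <- 0.2
  bin <- round(q * (w - 6 + 1))
  frac <- replicate(10, {
    seqs <- vapply(1:nwin, function(i) {
      s <- rep("C", w)
      at <- sample(w - 6, 1)
      s[at:(at + 5)] <- c("A", "G", "A", "T", "A", "A")
      paste(s, collapse = "")
    }, character(1))
    r <- central_motif_enrichment(seqs, "WGATAR", central_bin = bin)
    c(frac = r$bin_sites / r$total_sites, p = r$p)
  })
  expect_true(all(abs(frac["frac", ] - q) < 0.06))
  expect_gte(sum(frac["p", ] > 0.01), 9)
})
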