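ref_seq <- "ACGGTACGTTCACGTTAACGGTCCACGTA"  # several CpGs, several non-CpG Cs

test_that("reference regions locate exactly their CpG cytosines", {
  r <- reference_region("toy", ref_seq)
  chars <- strsplit(ref_seq, "")[[1]]
  expected <- which(chars == "C" & c(chars[-1], "") == "G") - 1L
  expect_identical(r$cpg_positions, expected)
  expect_error(reference_region("bad", "ACGX"), "A/C/G/T")
})

test_that("converted and methylated reads align at full identity", {
  r <- reference_region("toy", ref_seq)
  chars <- strsplit(ref_seq, "")[[1]]
  converted <- chars
  converted[converted == "C"] <- "T"                # full conversion
  a1 <- align_clone(r, paste(converted, collapse = ""))
  expect_equal(a1$identity, 1)
  expect_false(grepl("-", a1$aligned_read))
  retained <- chars
  noncpg <- setdiff(which(chars == "C"), r$cpg_positions + 1L)
  retained[noncpg] <- "T"                           # CpG Cs kept
  a2 <- align_clone(r, paste(retained, collapse = ""))
  expect_equal(a2$identity, 1)
  expect_error(align_clone(r, "ACG"), "50-150%")
})

test_that("alignment equals an independent dynamic-programming oracle", {
  set.seed(91)
  r30 <- random_dna(30)
  # one internal deletion
  del <- paste0(substr(r30, 1, 11), substr(r30, 13, 30))
  mine <- nw_bisulfite_align(r30, del)
  oracle <- oracle_nw(r30, del)
  expect_equal(mine$score, oracle$score)
  expect_equal(mine$aligned_ref, oracle$aligned_ref)
  expect_equal(mine$aligned_read, oracle$aligned_read)
  expect_equal(mine$identity, oracle$identity, tolerance = 1e-12)
  expect_equal(lengths(regmatches(mine$aligned_read,
                                  gregexpr("-", mine$aligned_read))), 1L)
  # random mutated/indel reads agree too
  for (trial in 1:10) {
    ref <- random_dna(40)
    read <- strsplit(ref, "")[[1]]
    k <- sample(40, 4)
    read[k] <- sample(c("A", "C", "G", "T"), 4, TRUE)
    if (trial %% 2 == 0) read <- read[-sample(40, 2)]
    read <- paste(read, collapse = "")
    mine <- nw_bisulfite_align(ref, read)
    oracle <- oracle_nw(ref, read)
    expect_equal(mine$score, oracle$score)
    expect_equal(mine$identity, oracle$identity, tolerance = 1e-12)
  }
})

test_that("methylation calls count forced outcomes correctly", {
  r <- reference_region("toy", ref_seq)
  chars <- strsplit(ref_seq, "")[[1]]
  noncpg <- setdiff(which(chars == "C"), r$cpg_positions + 1L)
  all_meth <- chars; all_meth[noncpg] <- "T"
  all_unmeth <- chars; all_unmeth[chars == "C"] <- "T"
  p_full <- call_methylation(r, rep(paste(all_meth, collapse = ""), 24))
  expect_equal(p_full$percent_methylated, 100)
  expect_true(all(p_full$included))
  p_none <- call_methylation(r, rep(paste(all_unmeth, collapse = ""), 24))
  expect_equal(p_none$percent_methylated, 0)
  expect_error(call_methylation(reference_region("nocpg", "ATTA"), "ATTA"),
               "no CpG")
})

test_that("the pooled percentage is methylated / (methylated + unmethylated)", {
  # 4 clones x 5 CpGs with 7 methylated calls -> 35%
  seqc <- "TTCGACGTTCGTTTCGATTTTACGTT"     # 5 CpGs, no other C
  r <- reference_region("five", seqc)
  expect_equal(length(r$cpg_positions), 5)
  make_read <- function(keep) {
    chars <- strsplit(seqc, "")[[1]]
    conv <- r$cpg_positions + 1L
    chars[conv[!seq_along(conv) %in% keep]] <- "T"
    paste(chars, collapse = "")
  }
  reads <- c(make_read(1:3), make_read(1:2), make_read(1:2), make_read(integer(0)))
  prof <- call_methylation(r, reads)
  expect_equal(prof$n_methylated, 7)
  expect_equal(prof$percent_methylated, 35)
})

test_that("clones failing conversion QC are excluded with reasons", {
  set.seed(7)
  # many non-CpG Cs so a 20% failure rate is unambiguous
  backbone <- paste(rep("CAT", 40), collapse = "")
  region <- paste0("ACGT", backbone, "ACGT")
  spec <- bisulfite_sim_spec(region, per_cpg_meth_prob = 0.5,
                             conversion_failure_rate = 0.2, seed = 5)
  sim <- simulate_bisulfite_clones(spec)
  r <- reference_region("qc", region)
  prof <- call_methylation(r, sim$reads, min_conversion = 0.95)
  expect_false(any(prof$included))
  expect_true(all(grepl("conversion", prof$excluded_clones$reason)))
  # and a clean simulation keeps everyone
  clean <- simulate_bisulfite_clones(bisulfite_sim_spec(
    region, 0.5, conversion_failure_rate = 0, seed = 5))
  prof2 <- call_methylation(r, clean$reads, min_conversion = 0.95)
  expect_true(all(prof2$included))
  expect_true(prof2$percent_methylated >= 0 && prof2$percent_methylated <= 100)
})

test_that("degraded reads are flagged unalignable", {
  r <- reference_region("toy", ref_seq)
  garbage <- paste(rep("G", nchar(ref_seq)), collapse = "")
  prof <- call_methylation(r, c(garbage))
  expect_false(any(prof$included))
  expect_true(any(grepl("identity", prof$excluded_clones$reason)))
  expect_true(is.na(prof$percent_methylated))
})

test_that("simulated clones realize forced and stochastic methylation", {
  region <- paste0(strrep("TTTTTTTTCG", 10), "TT")
  r <- reference_region("ten", region)
  expect_equal(length(r$cpg_positions), 10)
  # all methylated, no failures: CpG Cs retained, other Cs converted
  all1 <- simulate_bisulfite_clones(bisulfite_sim_spec(
    region, 1.0, conversion_failure_rate = 0, seed = 2))
  prof1 <- call_methylation(r, all1$reads)
  expect_equal(prof1$percent_methylated, 100)
  chars <- strsplit(all1$reads[[1]], "")[[1]]
  expect_true(all(chars[r$cpg_positions + 1L] == "C"))
  ref_chars <- strsplit(region, "")[[1]]
  noncpg <- setdiff(which(ref_chars == "C"), r$cpg_positions + 1L)
  expect_true(all(chars[noncpg] == "T"))
  # all unmethylated: reads equal the fully converted reference
  all0 <- simulate_bisulfite_clones(bisulfite_sim_spec(
    region, 0.0, conversion_failure_rate = 0, seed = 2))
  converted <- ref_chars; converted[converted == "C"] <- "T"
  expect_true(all(all0$reads == paste(converted, collapse = "")))
  # p = 0.5, 24 clones, 10 CpGs: binomial sampling bound
  half <- simulate_bisulfite_clones(bisulfite_sim_spec(
    region, 0.5, conversion_failure_rate = 0, seed = 3))
  prof <- call_methylation(r, half$reads)
  expect_lt(abs(prof$percent_methylated - 50),
            3 * sqrt(0.25 / 240) * 100)
  # determinism
  again <- simulate_bisulfite_clones(bisulfite_sim_spec(
    region, 0.5, conversion_failure_rate = 0, seed = 3))
  expect_identical(half$reads, again$reads)
})

test_that("percentage converges to the planted probability at many clones", {
  region <- paste0(strrep("TTTTTTTTCG", 10), "TT")
  r <- reference_region("ten", region)
  p_true <- 0.3
  sim <- simulate_bisulfite_clones(bisulfite_sim_spec(
    region, p_true, n_clones = 500, conversion_failure_rate = 0, seed = 11))
  prof <- call_methylation(r, sim$reads)
  se <- sqrt(p_true * (1 - p_true) / (500 * 10)) * 100
  expect_lt(abs(prof$percent_methylated - 100 * p_true), 3 * se)
  expect_true(prof$percent_methylated >= 0 && prof$percent_methylated <= 100)
})

test_that("profile comparison is symmetric and matches the hypergeometric oracle", {
  region <- "TTCGATTCGATTTTTTTTCGTT"
  r <- reference_region("cmp", region)
  mk <- function(p, seed) {
    sim <- simulate_bisulfite_clones(bisulfite_sim_spec(
      region, p, n_clones = 80, conversion_failure_rate = 0, seed = seed))
    call_methylation(r, sim$reads)
  }
  a <- mk(0.9, 1); b <- mk(0.1, 2)
  cmp <- compare_profiles(a, b)
  expect_lt(cmp$p, 1e-10)
  expect_equal(cmp$p, oracle_fisher_p(cmp$table), tolerance = 1e-9)
  swapped <- compare_profiles(b, a)
  expect_equal(swapped$delta_percent, -cmp$delta_percent)
  expect_equal(swapped$p, cmp$p, tolerance = 1e-12)
  same <- compare_profiles(a, a)
  expect_equal(same$delta_percent, 0)
  expect_equal(same$p, 1)
})

test_that("clone reads round-trip through FASTA", {
  region <- "TTCGATTCGATTTTTTTTCGTT"
  sim <- simulate_bisulfite_clones(bisulfite_sim_spec(region, 0.5, seed = 4))
  path <- tempfile(fileext = ".fasta")
  write_fasta(sim$reads, path)
  back <- read_fasta(path)
  expect_identical(back, sim$reads)
})
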