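# Generators: determinism, distributional contracts, truth-annotation
# round-trips and cross-module consistency with the design models.

test_that("repeat libraries are reproducible and respect the length range", {
  lib <- generate_repeat_library(5, c(500, 3000), seed = 1)
  expect_length(lib, 5)
  expect_true(all(nchar(lib) >= 500 & nchar(lib) <= 3000))
  expect_true(all(grepl("^[ACGT]+$", lib)))
  expect_identical(lib, generate_repeat_library(5, c(500, 3000), seed = 1))
  expect_false(any(lib == generate_repeat_library(5, c(500, 3000), seed = 2)))
  expect_error(generate_repeat_library(3, c(100, 50)), "range")
})

test_that("generated genomes reach the requested repeat fraction", {
  lib <- generate_repeat_library(6, c(500, 2500), seed = 3)
  g <- generate_genome(2e5, lib, 0.7, identity_range = c(80, 99), seed = 7)
  tr <- g$truth_repeats
  expect_true(all(tr$start >= 0 & tr$end <= g$length))
  expect_true(all(tr$identity >= 78 & tr$identity <= 100))
  covered <- logical(g$length)
  for (i in seq_len(nrow(tr))) covered[(tr$start[i] + 1):tr$end[i]] <- TRUE
  expect_gte(mean(covered), 0.70)
  # no repeats requested: pure random background
  g0 <- generate_genome(10000, seed = 8)
  expect_equal(nrow(g0$truth_repeats), 0)
  expect_error(generate_genome(1000, lib, 1.0), "\\[0, 1\\)")
  expect_error(generate_genome(1000, NULL, 0.5), "library")
})

test_that("planted copies realise their target identity (alignment oracle)", {
  lib <- generate_repeat_library(1, c(1000, 1000), seed = 4)
  g <- generate_genome(30000, lib, 0.10, identity_range = c(85, 85), seed = 9)
  tr <- g$truth_repeats
  expect_gt(nrow(tr), 0)
  for (i in seq_len(min(3, nrow(tr)))) {
    copy <- substr(g$sequence, tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") copy <- reverse_complement(copy)
    # substitution-only copies keep length, so column-wise comparison is the
    # exact alignment identity
    a <- strsplit(copy, "")[[1]]; b <- strsplit(lib[[1]], "")[[1]]
    ham_id <- 100 * mean(a == b)
    expect_lt(abs(ham_id - 85), 2)
    expect_lt(abs(tr$identity[i] - 85), 2)
    expect_equal(ham_id, tr$identity[i])
    # local alignment agrees up to end-clipping of mismatch-rich termini
    sw <- smith_waterman_oracle(copy, lib[[1]])
    expect_lt(abs(sw$identity - ham_id), 3)
  }
})

test_that("fosmid pools honour bounds, determinism and the insert-length mean", {
  g <- generate_genome(2e5, seed = 10)
  vec <- fixture_vector()
  p <- sample_fosmid_pool(g, 100, vector = vec, seed = 11)
  expect_equal(nrow(p$clones), 100)
  expect_true(all(p$clones$insert_length >= 27000 &
                  p$clones$insert_length <= 47000))
  expect_true(all(p$clones$end <= g$length))
  expect_identical(p$clones, sample_fosmid_pool(g, 100, vector = vec,
                                                seed = 11)$clones)
  expect_error(sample_fosmid_pool(g, 0), "positive")
  expect_error(sample_fosmid_pool(g, 5, length_bounds = c(27000, 3e5)),
               "exceed")
  # empirical insert mean over 1e4 draws within 1% of the configured mean
  big <- sample_fosmid_pool(generate_genome(1e5, seed = 1), 1e4,
                            seed = 12, keep_sequence = FALSE)
  expect_lt(abs(mean(big$clones$insert_length) - 40000) / 40000, 0.01)
})

test_that("observed pairwise insert overlaps match the design model", {
  g <- random_dna(2e7, seed = 13)
  counts <- vapply(1:60, function(s) {
    p <- sample_fosmid_pool(g, 1000, seed = s, keep_sequence = FALSE)
    count_overlapping_pairs(p$clones$start, p$clones$end)
  }, 0L)
  expected <- choose(1000, 2) * pairwise_overlap_probability(40000, 2e7)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("ideal contigs carry outward vector flanks on intact clones", {
  g <- generate_genome(1e5, seed = 14)
  vec <- fixture_vector()
  p <- sample_fosmid_pool(g, 3, vector = vec, seed = 15)
  ctg <- ideal_pool_contigs(p, seed = 16)
  info <- ctg$info
  expect_equal(nrow(info), 3)
  expect_true(all(info$left_flank >= 20 & info$left_flank <= 100))
  expect_equal(info$length,
               p$clones$insert_length + info$left_flank + info$right_flank)
  # left edge is the vector 3' end, right edge the vector 5' start
  for (i in 1:3) {
    s <- ctg$seq[[i]]
    expect_equal(substr(s, 1, info$left_flank[i]),
                 substr(vec, nchar(vec) - info$left_flank[i] + 1, nchar(vec)))
    expect_equal(substr(s, nchar(s) - info$right_flank[i] + 1, nchar(s)),
                 substr(vec, 1, info$right_flank[i]))
  }
  # zero flank: no vector sequence at all
  ctg0 <- ideal_pool_contigs(p, vector_flank = 0)
  expect_equal(unname(nchar(ctg0$seq)), p$clones$insert_length)
})

test_that("break_model=at_repeats splits inserts and flanks only true ends", {
  vec <- fixture_vector()
  gseq <- random_dna(60000, seed = 17)
  truth <- data.frame(start = c(20000, 30000), end = c(21000, 31500),
                      repeat_id = "repfam_01", identity = c(99, 99),
                      strand = "+", stringsAsFactors = FALSE)
  g <- manual_genome(gseq, truth)
  p <- manual_pool(g, 5000, 45000, vector = vec)
  ctg <- ideal_pool_contigs(p, vector_flank = 50, break_model = "at_repeats",
                            identity_break_threshold = 95, genome = g)
  expect_equal(nrow(ctg$info), 3)
  expect_equal(ctg$info$left_flank, c(50L, 0L, 0L))
  expect_equal(ctg$info$right_flank, c(0L, 0L, 50L))
  expect_equal(unname(nchar(ctg$seq)),
               c(15000 + 50, 9000, 13500 + 50))
  # below the identity threshold nothing breaks
  ctg2 <- ideal_pool_contigs(p, vector_flank = 50, break_model = "at_repeats",
                             identity_break_threshold = 99.5, genome = g)
  expect_equal(nrow(ctg2$info), 1)
  # minus-strand clone: same pieces, mirrored order
  pm <- manual_pool(g, 5000, 45000, strand = "-", vector = vec)
  cm <- ideal_pool_contigs(pm, vector_flank = 50, break_model = "at_repeats",
                           identity_break_threshold = 95, genome = g)
  expect_equal(unname(nchar(cm$seq)), c(13500 + 50, 9000, 15000 + 50))
})

test_that("error-free reads are exact substrings of the clone circle", {
  g <- generate_genome(5e4, seed = 18)
  vec <- fixture_vector()
  p <- sample_fosmid_pool(g, 1, vector = vec, seed = 19)
  rs <- simulate_pool_reads(p, depth = 1, error_rate = 0, seed = 20)
  circ2 <- strrep(clone_circles(p)[[1]], 2)
  expect_true(all(vapply(rs$read1, grepl, TRUE, x = circ2, fixed = TRUE)))
  expect_true(all(vapply(reverse_complement(rs$read2), grepl, TRUE,
                         x = circ2, fixed = TRUE)))
})

test_that("simulated base output and contaminant fractions meet their targets", {
  g <- generate_genome(1e5, seed = 21)
  vec <- fixture_vector()
  # vector-carrying pool: provenance covers insert/vector/junction and the
  # base output tracks depth x clone length
  pv <- sample_fosmid_pool(g, 4, vector = vec, seed = 22)
  rv <- simulate_pool_reads(pv, depth = 40, seed = 26)
  Sv <- sum(nchar(clone_circles(pv)))
  expect_true(all(c("insert", "vector", "junction") %in% rv$label))
  expect_lt(abs(200 * nrow(rv) - 40 * Sv) / (40 * Sv), 0.01)
  # vector reads arise in proportion to the vector share of the circle
  vshare <- 4 * nchar(vec) / Sv
  expect_lt(abs(mean(rv$label == "vector") - vshare), 0.01)

  # insert-only pool with injected contaminants (vector injected as a
  # labelled contaminant, so provenance fractions are exact targets)
  p <- sample_fosmid_pool(g, 4, vector = NULL, seed = 22)
  refs <- list(ecoli = random_dna(30000, seed = 23),
               mitochondrion = random_dna(20000, seed = 24),
               chloroplast = random_dna(15000, seed = 25),
               vector = vec)
  fr <- c(ecoli = 0.029, mitochondrion = 0.018, chloroplast = 0.0002,
          vector = 0.052)
  rs <- simulate_pool_reads(p, depth = 40, seed = 26, contaminant_refs = refs,
                            contaminant_fractions = fr)
  S <- sum(nchar(clone_circles(p)))
  n_total <- round(40 * S / 200)
  pool_bases <- 200 * sum(rs$label == "insert")
  expect_lt(abs(pool_bases - 200 * (n_total - sum(round(fr * n_total)))) /
            (40 * S), 0.01)
  for (lab in names(fr)) {
    obs <- sum(rs$label == lab)
    se <- sqrt(n_total * fr[[lab]] * (1 - fr[[lab]]))
    expect_lt(abs(obs - fr[[lab]] * n_total), 3 * se + 1)
  }
  expect_error(simulate_pool_reads(p, contaminant_refs = refs,
                                   contaminant_fractions = c(ecoli = 1.2)),
               "sum")
})

test_that("subsampling keeps pairs intact at the requested rate", {
  g <- generate_genome(5e4, seed = 27)
  p <- sample_fosmid_pool(g, 1, vector = fixture_vector(), seed = 28)
  rs <- simulate_pool_reads(p, depth = 10, seed = 29)
  expect_identical(subsample_reads(rs, 1.0, seed = 1)$id, rs$id)
  half <- subsample_reads(rs, 0.5, seed = 2)
  expect_equal(nrow(half), round(0.5 * nrow(rs)))
  expect_true(all(half$id %in% rs$id))
  # bernoulli mode at a target depth: retained fraction within 3 binomial SE
  d <- attr(rs, "depth")
  bern <- subsample_reads(rs, target_depth = d / 4, mode = "bernoulli",
                          seed = 3)
  pfrac <- nrow(bern) / nrow(rs)
  se <- sqrt(0.25 * 0.75 / nrow(rs))
  expect_lt(abs(pfrac - 0.25), 3 * se)
  expect_error(subsample_reads(rs, 1.5), "\\(0, 1\\]")
})

test_that("truth annotations round-trip through BED", {
  lib <- generate_repeat_library(3, c(400, 900), seed = 30)
  g <- generate_genome(5e4, lib, 0.2, seed = 31)
  p <- sample_fosmid_pool(g, 5, seed = 32, length_mean = 10000,
                          length_sd = 1000, length_bounds = c(8000, 12000),
                          keep_sequence = FALSE)
  bed1 <- withr::local_tempfile(fileext = ".bed")
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_repeat_bed(g, bed1)
  back <- read_repeat_bed(bed1)
  expect_equal(back$start, g$truth_repeats$start)
  expect_equal(back$end, g$truth_repeats$end)
  expect_equal(back$repeat_id, g$truth_repeats$repeat_id)
  expect_equal(back$identity, g$truth_repeats$identity, tolerance = 1e-6)
  write_insert_bed(p, bed2)
  ib <- read_insert_bed(bed2)
  expect_equal(ib$start, p$clones$start)
  expect_equal(ib$end, p$clones$end)
  expect_equal(ib$strand, p$clones$strand)
})

test_that("FASTA and paired FASTQ output round-trips sequences", {
  g <- generate_genome(20000, seed = 33)
  p <- sample_fosmid_pool(g, 2, vector = fixture_vector(), seed = 34,
                          length_mean = 5000, length_sd = 300,
                          length_bounds = c(4000, 6000))
  rs <- simulate_pool_reads(p, depth = 2, seed = 35)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(p$inserts, fa)
  expect_identical(read_fasta(fa), p$inserts)
  pre <- withr::local_tempfile()
  paths <- write_reads_fastq(rs, pre)
  back <- read_reads_fastq(paste0(pre, "_1.fastq"), paste0(pre, "_2.fastq"))
  expect_equal(back$read1, rs$read1)
  expect_equal(back$read2, rs$read2)
  expect_equal(back$id, rs$id)
})
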