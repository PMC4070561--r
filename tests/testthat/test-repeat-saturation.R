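# Repeat mapping statistics, saturation analysis and assembly metrics.

test_that("repeat mapping finds planted copies and respects the 78% cutoff", {
  lib <- generate_repeat_library(1, c(800, 800), seed = 80)
  set.seed(81)
  copy85 <- mutate_seq_r(lib[[1]], 0.15)
  copy70 <- mutate_seq_r(lib[[1]], 0.30)
  contigs <- c(with85 = paste0(random_dna(3000), copy85, random_dna(3000)),
               with70 = paste0(random_dna(3000), copy70, random_dna(3000)))
  h <- map_repeats(contigs, lib)
  expect_gt(sum(h$sseqid == "with85"), 0)
  expect_equal(sum(h$sseqid == "with70"), 0)
  expect_true(all(h$pident > 78))
  expect_error(map_repeats(contigs, character(0)), "non-empty")
})

test_that("random contigs rarely produce spurious repeat hits", {
  lib <- generate_repeat_library(5, c(500, 3000), seed = 82)
  set.seed(83)
  contigs <- setNames(vapply(1:100, function(i) random_dna(10000), ""),
                      paste0("rnd", 1:100))
  h <- map_repeats(contigs, lib)
  expect_lt(length(unique(h$sseqid)) / 100, 0.01)
})

test_that("repeat statistics compute exact ratios and the interior rule", {
  lens <- c(c1 = 5000L, c2 = 5000L, c3 = 4000L)
  hits <- data.frame(
    qseqid = "repfam_01",
    sseqid = c("c1", "c1", "c2", "c2", "c2", "c2"),
    pident = 90, length = 200, mismatch = 0, gapopen = 0,
    qstart = 1, qend = 200,
    sstart = c(1, 2000, 4801, 300, 11, 4992),
    send   = c(200, 2199, 5000, 101, 210, 4793),
    stringsAsFactors = FALSE)
  st <- repeat_statistics(hits, lens)
  expect_equal(st$total_hits, 6)
  expect_equal(st$mean_hits_per_contig * st$n_contigs, 6)
  expect_equal(st$zero_hit_fraction, 1 / 3)
  # interior: c1 at 2000, the minus-strand mid-c2 hit, and the hit starting
  # exactly end_margin bases in; flush hits and the one 8 bases from the
  # right end are unresolved
  expect_equal(st$resolved_fraction, 3 / 6)
  flush <- hits[c(1, 3), ]
  expect_equal(repeat_statistics(flush, lens)$resolved_fraction, 0)
  expect_error(repeat_statistics(hits, integer(0)), "empty")
})

test_that("count-based repeat summaries reproduce published-table arithmetic", {
  s <- repeat_load_summary(40559402, 13090107, 457)
  expect_equal(s$mean_hits_per_contig, 3.1)
  expect_equal(s$contigs_per_pool, 28643)
})

test_that("repeats in intact clones are mostly resolved", {
  lib <- generate_repeat_library(4, c(500, 1500), seed = 84)
  g <- generate_genome(3e5, lib, 0.4, seed = 85)
  p <- sample_fosmid_pool(g, 6, vector = fixture_vector(), seed = 86)
  ctg <- ideal_pool_contigs(p, seed = 87)
  st <- repeat_statistics(map_repeats(ctg$seq, lib), ctg$seq)
  expect_gt(st$resolved_fraction, 0.6)
  expect_gt(st$mean_hits_per_contig, 1)
})

test_that("saturation masking claims each marker once", {
  ref <- c(genome = random_dna(2e5, seed = 88))
  set.seed(89)
  mk <- function(a, b) setNames(substring(ref, a, b), sprintf("c%d_%d", a, b))
  poolA <- c(mk(1, 50000), mk(100001, 140000))
  poolB <- c(mk(50001, 100000))
  sat <- saturation_curve(list(A = poolA, A2 = poolA, B = poolB), ref,
                          seed = 1)
  expect_equal(sat$new_markers[sat$pool == "A2"], 0)
  first <- sat[match(c("A", "B"), sat$pool), ]
  # disjoint pools contribute additively
  expect_equal(sum(sat$novel_length), sat$cumulative_matched_length[3])
  expect_true(all(sat$cumulative_matched_length <= 2e5))
  expect_true(all(diff(sat$cumulative_matched_length) >= 0))
})

test_that("pool order changes the path but not the final matched length", {
  ref <- c(genome = random_dna(1e5, seed = 90))
  set.seed(91)
  pools <- lapply(1:4, function(i) {
    s <- sample(1:60000, 1)
    setNames(substring(ref, s, s + 39999), paste0("p", i))
  })
  finals <- vapply(1:4, function(sd) {
    sat <- saturation_curve(pools, ref, seed = sd)
    sat$cumulative_matched_length[nrow(sat)]
  }, 0)
  expect_equal(length(unique(finals)), 1)
})

test_that("saturation filters contigs, alignment lengths and identities", {
  ref <- c(genome = random_dna(5e4, seed = 92))
  set.seed(93)
  pools <- list(p = c(
    long = substring(ref, 1001, 6000),          # passes everything
    short_ctg = substring(ref, 20001, 20900),   # contig <= 1000, dropped
    diverged = mutate_seq_r(substring(ref, 30001, 35000), 0.05)))  # <99% id
  sat <- saturation_curve(pools, ref, seed = 1)
  # only the long clean contig claims markers: interior of [1001, 6000]
  expect_equal(sat$new_markers, 9)
  expect_equal(sat$pool_contig_length, 5000 + 5000)  # diverged still counts
})

test_that("assembly efficiency divides by expected pool content", {
  eff <- assembly_efficiency(c(6000, 4000, 12000), 5000, n = 1,
                             mean_insert = 40000)
  expect_equal(eff$efficiency, 0.45)
  eff3 <- assembly_efficiency(c(6000, 4000, 12000), c(5000, 10000, 20000),
                              n = 1, mean_insert = 40000)
  expect_true(all(diff(eff3$efficiency) <= 0))
  expect_equal(eff3$efficiency[3], 0)
  expect_error(assembly_efficiency(1000, 500, n = 0, mean_insert = 1),
               "positive")
})

test_that("intact large pools reach near-unit efficiency at 20 kb", {
  g <- generate_genome(2e6, seed = 94)
  p <- sample_fosmid_pool(g, 500, vector = fixture_vector(), seed = 95)
  ctg <- ideal_pool_contigs(p, seed = 96)
  eff <- assembly_efficiency(ctg$seq, 20000, n = 500, mean_insert = 40000)
  expect_gt(eff$efficiency, 0.99)
  expect_lt(eff$efficiency, 1.05)
})

test_that("coverage distribution counts contigs at or above each depth", {
  expect_equal(coverage_distribution(rep(20, 5), 10)$fraction, 1)
  expect_equal(coverage_distribution(c(5, 15), 10)$fraction, 0.5)
  expect_error(coverage_distribution(numeric(0)), "empty")
  expect_error(coverage_distribution(c(-1, 2)), ">= 0")
})

test_that("simulated deep pools keep nearly all contigs above 10x", {
  g <- generate_genome(1e5, seed = 97)
  vec <- fixture_vector()
  p <- sample_fosmid_pool(g, 2, vector = vec, seed = 98,
                          length_mean = 30000, length_sd = 1000,
                          length_bounds = c(27000, 33000))
  ctg <- ideal_pool_contigs(p, seed = 99)
  rs <- simulate_pool_reads(p, depth = 75, seed = 100)
  reads <- setNames(c(rs$read1, rs$read2), paste0(rep(rs$id, 2), "/",
                                                  rep(1:2, each = nrow(rs))))
  hits <- local_align(reads, ctg$seq, k = 15, min_identity = 90,
                      min_length = 80)
  depth <- contig_mean_depth(hits, ctg$seq)
  cd <- coverage_distribution(depth, 10)
  expect_gte(cd$fraction, 0.95)
  expect_gt(min(depth), 50)
})
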