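# Vector-end detection, proper-contig classification, trimming and
# junction-based clone counting on constructed and simulated clones.

test_that("terminal vector fragments are found and distance-filtered", {
  vec <- fixture_vector()
  set.seed(40)
  insert <- random_dna(35000)
  contig <- paste0(substr(vec, nchar(vec) - 45, nchar(vec)), insert,
                   substr(vec, 1, 46))
  h <- find_vector_end_hits(c(ctg = contig), vec)
  expect_equal(nrow(h), 2)
  expect_setequal(h$fragment_length, c(46, 46))
  expect_setequal(h$terminus, c("START", "END"))
  expect_setequal(h$side, c("LEFT", "RIGHT"))
  expect_true(all(h$outside_bases == 0))

  # fragment 12 bp from the contig end: outside bases exceed the slack
  c2 <- paste0(random_dna(12), substr(vec, nchar(vec) - 45, nchar(vec)),
               random_dna(30000))
  expect_equal(nrow(find_vector_end_hits(c(ctg = c2), vec)), 0)
  # 10 bp outside is still accepted
  c3 <- paste0(random_dna(10), substr(vec, nchar(vec) - 45, nchar(vec)),
               random_dna(30000))
  h3 <- find_vector_end_hits(c(ctg = c3), vec)
  expect_equal(nrow(h3), 1)
  expect_equal(h3$outside_bases, 10)

  expect_equal(nrow(find_vector_end_hits(c(ctg = random_dna(5000)), vec)), 0)
  expect_error(find_vector_end_hits(c(ctg = contig), "ACGT"), "shorter")
})

test_that("classification separates proper, partial and none", {
  vec <- fixture_vector()
  set.seed(41)
  mk <- function(insert_len, left = TRUE, right = TRUE, swap = FALSE) {
    ins <- random_dna(insert_len)
    lf <- substr(vec, nchar(vec) - 45, nchar(vec))   # vector END
    rf <- substr(vec, 1, 46)                          # vector START
    if (swap) { tmp <- lf; lf <- rf; rf <- tmp }
    paste0(if (left) lf else "", ins, if (right) rf else "")
  }
  contigs <- c(proper = mk(35000),
               out_of_range = mk(12000),
               partial = mk(30000, left = FALSE),
               wrong_orient = mk(35000, swap = TRUE),
               none = random_dna(30000))
  h <- find_vector_end_hits(contigs, vec)
  cls <- classify_contigs(h, contigs)
  expect_equal(cls$class[cls$contig_id == "proper"], "proper")
  expect_true(cls$in_expected_range[cls$contig_id == "proper"])
  expect_equal(cls$class[cls$contig_id == "out_of_range"], "proper")
  expect_false(cls$in_expected_range[cls$contig_id == "out_of_range"])
  expect_equal(cls$class[cls$contig_id == "partial"], "partial")
  expect_equal(cls$class[cls$contig_id == "wrong_orient"], "partial")
  expect_equal(cls$class[cls$contig_id == "none"], "none")
  # reverse-complemented proper contig stays proper
  hrc <- find_vector_end_hits(c(rc = reverse_complement(contigs[["proper"]])),
                              vec)
  expect_equal(classify_contig(35092, hrc)$class, "proper")
})

test_that("trimming removes the max of hit extent and the 30 bp floor", {
  vec <- fixture_vector()
  set.seed(42)
  ins <- random_dna(30000)
  c46 <- paste0(substr(vec, nchar(vec) - 45, nchar(vec)), ins)
  h46 <- find_vector_end_hits(c(ctg = c46), vec)
  t46 <- trim_vector_ends(c46, h46)
  expect_equal(t46$trimmed_left, 46)
  expect_equal(t46$seq, ins)

  c22 <- paste0(ins, substr(vec, 1, 22))
  h22 <- find_vector_end_hits(c(ctg = c22), vec)
  expect_equal(h22$fragment_length, 22)
  t22 <- trim_vector_ends(c22, h22)
  expect_equal(t22$trimmed_right, 30)  # min_trim dominates
  expect_equal(nchar(t22$seq), 30000 + 22 - 30)

  none <- trim_vector_ends(ins, h46[0, ])
  expect_equal(none$seq, ins)
  # idempotence: no hits remain after trimming
  expect_equal(nrow(find_vector_end_hits(c(t = t46$seq), vec)), 0)
  expect_equal(nrow(find_vector_end_hits(c(t = t22$seq), vec)), 0)
  # trimming can collapse a vector-only scrap
  scrap <- substr(vec, nchar(vec) - 39, nchar(vec))
  hs <- find_vector_end_hits(c(s = scrap), vec)
  expect_true(trim_vector_ends(scrap, hs)$collapsed)
})

test_that("intact ideal contigs all classify proper and trim idempotently", {
  g <- generate_genome(2e5, seed = 43)
  vec <- fixture_vector()
  p <- sample_fosmid_pool(g, 8, vector = vec, seed = 44)
  ctg <- ideal_pool_contigs(p, seed = 45)
  h <- find_vector_end_hits(ctg$seq, vec)
  cls <- classify_contigs(h, ctg$seq)
  expect_true(all(cls$class == "proper"))
  expect_true(all(cls$in_expected_range))
  expect_equal(cls$insert_length_estimate[match(ctg$info$contig_id,
                                                cls$contig_id)],
               p$clones$insert_length)
})

test_that("broken assemblies carry vector hits only on outermost pieces", {
  vec <- fixture_vector()
  gseq <- random_dna(60000, seed = 46)
  truth <- data.frame(start = c(20000, 30000), end = c(21000, 31500),
                      repeat_id = "repfam_01", identity = c(99, 99),
                      strand = "+", stringsAsFactors = FALSE)
  g <- manual_genome(gseq, truth)
  p <- manual_pool(g, 5000, 45000, vector = vec)
  ctg <- ideal_pool_contigs(p, vector_flank = 50, break_model = "at_repeats",
                            identity_break_threshold = 95, genome = g)
  h <- find_vector_end_hits(ctg$seq, vec)
  cls <- classify_contigs(h, ctg$seq)
  expect_setequal(cls$class[cls$contig_id %in%
                            ctg$info$contig_id[ctg$info$piece == 2]], "none")
  outer <- ctg$info$contig_id[ctg$info$piece != 2]
  expect_true(all(cls$class[cls$contig_id %in% outer] == "partial"))
})

test_that("junction reads are detected with their thresholds", {
  vec <- fixture_vector()
  set.seed(47)
  ins <- random_dna(1000)
  r_start <- paste0(substr(ins, 971, 1000), substr(vec, 1, 70))
  r_end <- paste0(substr(vec, nchar(vec) - 59, nchar(vec)), substr(ins, 1, 40))
  r_vec <- substr(vec, 1001, 1100)
  r_thin <- paste0(substr(ins, 901, 990), substr(vec, 1, 10))  # 10 < m
  j <- detect_junction_reads(c(a = r_start, b = r_end, c = r_vec,
                               d = r_thin,
                               e = reverse_complement(r_start)), vec)
  expect_equal(sort(j$read_id), c("a", "b", "e"))
  expect_equal(j$terminus[j$read_id == "a"], "START")
  expect_equal(j$flank[j$read_id == "a"], substr(ins, 981, 1000))
  expect_equal(j$terminus[j$read_id == "b"], "END")
  expect_equal(j$flank[j$read_id == "b"], substr(ins, 1, 20))
  # orientation-normalised: the reverse-complemented read gives the same flank
  expect_equal(j$flank[j$read_id == "e"], j$flank[j$read_id == "a"])
  # one tolerated substitution in the vector-side segment
  r_mut <- r_start
  substr(r_mut, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r_mut, 50, 50))[1]
  expect_equal(nrow(detect_junction_reads(c(m = r_mut), vec)), 1)
})

test_that("a clean single clone yields exactly two flanks and estimate 1", {
  g <- generate_genome(5e4, seed = 48)
  vec <- fixture_vector()
  p <- sample_fosmid_pool(g, 1, vector = vec, seed = 49)
  rs <- simulate_pool_reads(p, depth = 50, error_rate = 0, seed = 50)
  j <- detect_junction_reads(rs, vec)
  expect_equal(length(unique(j$flank[j$terminus == "START"])), 1)
  expect_equal(length(unique(j$flank[j$terminus == "END"])), 1)
  est <- estimate_clone_count(j, target = 1)
  expect_equal(est$estimate, 1)
  expect_equal(est$ratio_percent, 100)
})

test_that("the clone-count estimate ignores read order and duplication", {
  g <- generate_genome(1e5, seed = 51)
  vec <- fixture_vector()
  p <- sample_fosmid_pool(g, 6, vector = vec, seed = 52)
  rs <- simulate_pool_reads(p, depth = 40, seed = 53)
  j <- detect_junction_reads(rs, vec)
  base <- estimate_clone_count(j)$estimate
  set.seed(54)
  perm <- j[sample(nrow(j)), ]
  expect_equal(estimate_clone_count(perm)$estimate, base)
  dup <- rbind(j, j[sample(nrow(j), 50, replace = TRUE), ])
  expect_equal(estimate_clone_count(dup)$estimate, base)
  expect_warning(e0 <- estimate_clone_count(j[0, ]), "no junction")
  expect_equal(e0$estimate, 0)
})

test_that("low-depth pools drop clones (negative bias, never overcounting)", {
  g <- generate_genome(2e6, seed = 55)
  vec <- fixture_vector()
  ests <- vapply(1:8, function(s) {
    p <- sample_fosmid_pool(g, 50, vector = vec, seed = 500 + s)
    rs <- simulate_pool_reads(p, depth = 3, seed = 600 + s)
    estimate_clone_count(detect_junction_reads(rs, vec))$estimate
  }, 0L)
  expect_true(all(ests <= 50))
  expect_lt(mean(ests), 50)  # Poisson zero-coverage dropout at junctions
})

test_that("summary percentages reproduce report arithmetic", {
  s <- vector_end_summary(1071614, 83855, 1694, 1516)
  expect_equal(s$pct_with_end, 7.8)
  expect_equal(s$pct_proper, 89.5)
})
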