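# Shared fixtures, built in code. The mutator is deliberately independent of
# the package's compiled mutator so it can serve as part of test oracles.

mutate_seq_r <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# insert small indels (1-3 bp) at random positions
indel_seq_r <- function(seq, n_indels) {
  for (i in seq_len(n_indels)) {
    pos <- sample.int(nchar(seq) - 5, 1)
    len <- sample(1:3, 1)
    if (runif(1) < 0.5) {
      seq <- paste0(substr(seq, 1, pos), substr(seq, pos + len + 1, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, pos), random_dna(len),
                    substr(seq, pos + 1, nchar(seq)))
    }
  }
  seq
}

fixture_vector <- function(len = 2000, seed = 4242) random_dna(len, seed = seed)

# hand-built genome with repeats at known coordinates
manual_genome <- function(sequence, truth) {
  structure(list(sequence = sequence, truth_repeats = truth,
                 length = nchar(sequence), seed = NA_integer_),
            class = "synthetic_genome")
}

# hand-built single-clone pool over an explicit insert interval
manual_pool <- function(genome, start, end, strand = "+", vector = NULL,
                        pool_id = "manual") {
  gseq <- if (inherits(genome, "synthetic_genome")) genome$sequence else genome
  ins <- substr(gseq, start + 1, end)
  if (strand == "-") ins <- reverse_complement(ins)
  clones <- data.frame(clone_id = paste0(pool_id, "_c0001"), start = start,
                       end = end, strand = strand,
                       insert_length = end - start, stringsAsFactors = FALSE)
  structure(list(pool_id = pool_id, target_size = 1L, vector = vector,
                 clones = clones,
                 inserts = setNames(ins, clones$clone_id)),
            class = "fosmid_pool")
}

count_overlapping_pairs <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  n <- length(starts)
  total <- 0L
  j <- 1L
  for (i in seq_len(n)) {
    # count later intervals starting before this one ends
    k <- i + 1L
    while (k <= n && starts[k] < ends[i]) {
      total <- total + 1L
      k <- k + 1L
    }
  }
  total
}
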