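# Synthetic data generation: repeat libraries, repeat-rich genomes, fosmid
# pools, idealised per-clone contigs and paired-end read sets with
# contaminant injection. Every generator is a pure function of its inputs
# and seed. Coordinates are 0-based half-open internally; BED output follows
# the same convention.

#' Generate a synthetic repeat library
#'
#' Random consensus sequences standing in for a curated repeat-family
#' library. Family ids are `repfam_01`, `repfam_02`, ...; consensus lengths
#' are drawn uniformly from `length_range`.
#'
#' @param n_families Number of families (>= 1).
#' @param length_range Two-element integer range of consensus lengths.
#' @param seed Optional integer seed.
#' @return Named character vector of consensus sequences.
#' @export
#' @examples
#' lib <- generate_repeat_library(5, c(500, 3000), seed = 1)
#' nchar(lib)
generate_repeat_library <- function(n_families, length_range = c(500, 3000),
                                    seed = NULL) {
  check_positive(n_families = n_families)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 1) {
    stop("`length_range` must be a non-empty increasing range", call. = FALSE)
  }
  local_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_families,
                   replace = TRUE)
    out <- vapply(lens, function(l) random_dna_cpp(as.integer(l)), "")
    names(out) <- sprintf("repfam_%02d", seq_len(n_families))
    out
  })
}

#' Generate a synthetic genome with planted repeat copies
#'
#' Builds a uniform-random background and plants mutated copies of repeat
#' consensus sequences (random family, random strand, per-base substitution
#' tuned to a target identity drawn from `identity_range`) until at least
#' `repeat_fraction` of the bases are repeat-derived. Placement prefers
#' non-overlapping positions (bounded rejection sampling) and falls back to
#' overlapping placement when the genome gets crowded; the truth table
#' records every planted copy with its realised identity against the
#' consensus.
#'
#' @param length Genome length in bases.
#' @param library Repeat library from [generate_repeat_library()]; may be
#'   `NULL` when `repeat_fraction = 0`.
#' @param repeat_fraction Target repeat-derived fraction of bases, in `[0, 1)`.
#' @param identity_range Percent-identity range for planted copies,
#'   within `[78, 100]` (default `c(80, 99)`).
#' @param seed Optional integer seed.
#' @return A `synthetic_genome`: list with `sequence` (character),
#'   `truth_repeats` (data.frame `start`, `end` 0-based half-open,
#'   `repeat_id`, `identity`, `strand`), `length` and `seed`.
#' @export
#' @examples
#' lib <- generate_repeat_library(3, c(300, 800), seed = 1)
#' g <- generate_genome(50000, lib, 0.3, seed = 2)
#' sum(g$truth_repeats$end - g$truth_repeats$start) / g$length
generate_genome <- function(length, library = NULL, repeat_fraction = 0,
                            identity_range = c(80, 99), seed = NULL) {
  check_positive(length = length)
  if (repeat_fraction < 0 || repeat_fraction >= 1) {
    stop("`repeat_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (repeat_fraction > 0 && (is.null(library) || length(library) == 0)) {
    stop("a non-empty `library` is required when `repeat_fraction` > 0",
         call. = FALSE)
  }
  if (identity_range[1] < 78 || identity_range[2] > 100 ||
      identity_range[1] > identity_range[2]) {
    stop("`identity_range` must be within [78, 100]", call. = FALSE)
  }
  local_seed(seed, {
    glen <- as.integer(length)
    seq_chr <- random_dna_cpp(glen)
    truth <- data.frame(start = integer(), end = integer(),
                        repeat_id = character(), identity = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
    if (repeat_fraction > 0) {
      chars <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
      covered <- logical(glen)
      target <- repeat_fraction * glen
      fam_names <- names(library)
      max_iter <- ceiling(target / min(nchar(library))) * 20 + 100
      rows <- vector("list", 0)
      iter <- 0
      while (sum(covered) < target && iter < max_iter) {
        iter <- iter + 1
        fam <- sample(fam_names, 1)
        cons <- library[[fam]]
        tid <- runif(1, identity_range[1], identity_range[2])
        mut <- mutate_seq_cpp(cons, (100 - tid) / 100)
        copy <- mut$seq
        clen <- nchar(copy)
        if (clen > glen) next
        strand <- sample(c("+", "-"), 1)
        if (strand == "-") copy <- revcomp_cpp(copy)[[1]]
        s0 <- NA_integer_
        for (try in 1:50) {
          cand <- sample.int(glen - clen + 1, 1) - 1L
          if (!any(covered[(cand + 1):(cand + clen)])) { s0 <- cand; break }
        }
        if (is.na(s0)) s0 <- sample.int(glen - clen + 1, 1) - 1L
        chars[(s0 + 1):(s0 + clen)] <- strsplit(copy, "", fixed = TRUE)[[1]]
        covered[(s0 + 1):(s0 + clen)] <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          start = s0, end = s0 + clen, repeat_id = fam,
          identity = 100 * (clen - mut$n_sub) / clen, strand = strand,
          stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, c(list(truth), rows))
      truth <- truth[order(truth$start, truth$end), , drop = FALSE]
      rownames(truth) <- NULL
      seq_chr <- paste(chars, collapse = "")
    }
    structure(list(sequence = seq_chr, truth_repeats = truth,
                   length = glen, seed = seed),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d bp, %d planted repeat copies (%.1f%% of bases)\n",
              x$length, nrow(x$truth_repeats),
              100 * sum(x$truth_repeats$end - x$truth_repeats$start) / x$length))
  invisible(x)
}

genome_sequence <- function(genome) {
  if (inherits(genome, "synthetic_genome")) genome$sequence
  else as.character(genome)
}

# Truncated-normal draws by rejection.
rtrunc_norm <- function(n, mean, sd, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  round(out[seq_len(n)])
}

#' Sample a fosmid pool from a genome
#'
#' Draws `n` inserts with uniform random start, truncated-normal length
#' (default mean 40 kb, SD 3 kb on 27-47 kb, mirroring a pulsed-field gel
#' cut between the 30 kb and 50 kb markers) and random strand, and joins each
#' to the vector into a circular clone (vector followed by insert). With
#' `vector = NULL` the clone circle is the bare insert, a convenience for
#' screening scenarios where vector reads are injected separately.
#'
#' @param genome A `synthetic_genome` or a single character sequence.
#' @param n Number of clones (>= 1).
#' @param length_mean,length_sd Insert length distribution in bases.
#' @param length_bounds Two-element insert length bounds; must fit in the
#'   genome.
#' @param vector Vector sequence (character), or `NULL`.
#' @param seed Optional integer seed.
#' @param pool_id Pool identifier used in clone names.
#' @param keep_sequence Extract insert sequences (set `FALSE` for
#'   coordinate-only studies).
#' @return A `fosmid_pool`: list with `pool_id`, `target_size`, `vector`,
#'   `clones` (data.frame `clone_id`, `start`, `end` 0-based half-open,
#'   `strand`, `insert_length`) and `inserts` (named character or `NULL`).
#' @export
#' @examples
#' g <- generate_genome(2e5, seed = 1)
#' p <- sample_fosmid_pool(g, 3, 40000, 3000, c(27000, 47000),
#'                         vector = random_dna(8000, seed = 9), seed = 2)
#' p$clones
sample_fosmid_pool <- function(genome, n, length_mean = 40000,
                               length_sd = 3000,
                               length_bounds = c(27000, 47000),
                               vector = NULL, seed = NULL,
                               pool_id = "pool1", keep_sequence = TRUE) {
  check_positive(n = n)
  gseq <- genome_sequence(genome)
  glen <- nchar(gseq)
  if (length_bounds[2] > glen) {
    stop("`length_bounds` exceed the genome length", call. = FALSE)
  }
  if (!is.null(vector)) vector <- as.character(vector)
  local_seed(seed, {
    lens <- rtrunc_norm(n, length_mean, length_sd, length_bounds)
    starts <- vapply(lens, function(l) sample.int(glen - l + 1, 1) - 1L, 1L)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    clones <- data.frame(
      clone_id = sprintf("%s_c%04d", pool_id, seq_len(n)),
      start = starts, end = starts + lens, strand = strands,
      insert_length = lens, stringsAsFactors = FALSE)
    inserts <- NULL
    if (keep_sequence) {
      inserts <- substring(gseq, starts + 1, starts + lens)
      minus <- strands == "-"
      if (any(minus)) inserts[minus] <- revcomp_cpp(inserts[minus])
      names(inserts) <- clones$clone_id
    }
    structure(list(pool_id = pool_id, target_size = as.integer(n),
                   vector = vector, clones = clones, inserts = inserts),
              class = "fosmid_pool")
  })
}

#' @export
print.fosmid_pool <- function(x, ...) {
  cat(sprintf("fosmid pool '%s': %d clones, vector %s bp, insert lengths %d-%d\n",
              x$pool_id, nrow(x$clones),
              if (is.null(x$vector)) "0" else format(nchar(x$vector)),
              min(x$clones$insert_length), max(x$clones$insert_length)))
  invisible(x)
}

#' Circular clone sequences of a pool
#'
#' Each clone linearised at the vector start: vector followed by insert.
#'
#' @param pool A `fosmid_pool` with sequences.
#' @return Named character vector, one circle per clone.
#' @export
clone_circles <- function(pool) {
  stopifnot(inherits(pool, "fosmid_pool"))
  if (is.null(pool$inserts)) {
    stop("pool was sampled with `keep_sequence = FALSE`", call. = FALSE)
  }
  circ <- if (is.null(pool$vector)) pool$inserts
          else paste0(pool$vector, pool$inserts)
  names(circ) <- pool$clones$clone_id
  circ
}

#' Idealised per-clone contigs
#'
#' Emulates a perfect assembly of each clone. With `break_model = "none"`
#' each clone yields one contig: a fragment of the vector 3' end, the insert,
#' and a fragment of the vector 5' start (the two flanks that remain when the
#' circular clone is cut within the vector). Flank lengths are drawn
#' uniformly from 20-100 bp per end unless `vector_flank` fixes them. With
#' `break_model = "at_repeats"` inserts are additionally split at planted
#' repeat copies whose realised identity is at least
#' `identity_break_threshold`, emulating assembly breaks; vector flanks are
#' attached only at true clone ends.
#'
#' @param pool A `fosmid_pool`.
#' @param vector_flank Fixed flank length in bases, or `NULL` to draw
#'   uniformly from 20-100 bp per end; 0 disables flanks.
#' @param break_model `"none"` or `"at_repeats"`.
#' @param identity_break_threshold Percent identity at or above which a
#'   planted repeat breaks the assembly (default 95).
#' @param genome The `synthetic_genome` the pool was sampled from; required
#'   for `break_model = "at_repeats"`.
#' @param seed Optional integer seed (used for flank draws).
#' @return An `fp_contigs`: list with `seq` (named character) and `info`
#'   (data.frame `contig_id`, `clone_id`, `piece`, `left_flank`,
#'   `right_flank`, `length`).
#' @export
ideal_pool_contigs <- function(pool, vector_flank = NULL,
                               break_model = c("none", "at_repeats"),
                               identity_break_threshold = 95,
                               genome = NULL, seed = NULL) {
  stopifnot(inherits(pool, "fosmid_pool"))
  break_model <- match.arg(break_model)
  if (!is.null(vector_flank) && vector_flank < 0) {
    stop("`vector_flank` must be >= 0", call. = FALSE)
  }
  if (break_model == "at_repeats" && !inherits(genome, "synthetic_genome")) {
    stop("`genome` (a synthetic_genome) is required for break_model = 'at_repeats'",
         call. = FALSE)
  }
  vec <- pool$vector
  vlen <- if (is.null(vec)) 0L else nchar(vec)
  n <- nrow(pool$clones)
  local_seed(seed, {
    flanks_l <- flanks_r <- integer(n)
    if (vlen > 0) {
      if (is.null(vector_flank)) {
        flanks_l <- sample(20:100, n, replace = TRUE)
        flanks_r <- sample(20:100, n, replace = TRUE)
      } else {
        flanks_l[] <- flanks_r[] <- as.integer(min(vector_flank, vlen))
      }
    }
    seqs <- character(0); info <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- pool$clones[i, ]
      ins <- pool$inserts[[i]]
      # segments of the insert in insert coordinates (0-based half-open)
      segs <- cbind(0L, cl$insert_length)
      if (break_model == "at_repeats") {
        tr <- genome$truth_repeats
        tr <- tr[tr$identity >= identity_break_threshold &
                 tr$end > cl$start & tr$start < cl$end, , drop = FALSE]
        if (nrow(tr) > 0) {
          rs <- pmax(tr$start, cl$start) - cl$start
          re <- pmin(tr$end, cl$end) - cl$start
          if (cl$strand == "-") {
            tmp <- cl$insert_length - re
            re <- cl$insert_length - rs
            rs <- tmp
          }
          o <- order(rs)
          rs <- rs[o]; re <- re[o]
          # merge, then complement within [0, insert_length)
          ms <- rs[1]; me <- re[1]; brk <- list()
          for (j in seq_along(rs)[-1]) {
            if (rs[j] <= me) me <- max(me, re[j])
            else { brk[[length(brk) + 1]] <- c(ms, me); ms <- rs[j]; me <- re[j] }
          }
          brk[[length(brk) + 1]] <- c(ms, me)
          bnd <- do.call(rbind, brk)
          starts <- c(0L, bnd[, 2]); ends <- c(bnd[, 1], cl$insert_length)
          keep <- ends > starts
          segs <- cbind(starts[keep], ends[keep])
        }
      }
      if (nrow(segs) == 0) next
      piece_seqs <- substring(ins, segs[, 1] + 1, segs[, 2])
      at_left <- segs[, 1] == 0L
      at_right <- segs[, 2] == cl$insert_length
      lf <- ifelse(at_left & vlen > 0, flanks_l[i], 0L)
      rf <- ifelse(at_right & vlen > 0, flanks_r[i], 0L)
      for (j in seq_len(nrow(segs))) {
        s <- piece_seqs[j]
        if (lf[j] > 0) s <- paste0(substr(vec, vlen - lf[j] + 1, vlen), s)
        if (rf[j] > 0) s <- paste0(s, substr(vec, 1, rf[j]))
        piece_seqs[j] <- s
      }
      ids <- sprintf("%s_ctg%d", cl$clone_id, seq_len(nrow(segs)))
      names(piece_seqs) <- ids
      seqs <- c(seqs, piece_seqs)
      info[[i]] <- data.frame(contig_id = ids, clone_id = cl$clone_id,
                              piece = seq_len(nrow(segs)),
                              left_flank = as.integer(lf),
                              right_flank = as.integer(rf),
                              length = nchar(piece_seqs),
                              stringsAsFactors = FALSE)
    }
    structure(list(seq = seqs, info = do.call(rbind, info)),
              class = "fp_contigs")
  })
}

covers_boundary <- function(start, flen, len, b) {
  # fragment [start, start+flen) on a circle of length `len`; boundary b sits
  # between bases b-1 and b (mod len)
  off1 <- (b - 1 - start) %% len
  off2 <- (b - start) %% len
  off1 < flen & off2 < flen
}

#' Simulate paired-end reads from a pool with contaminant injection
#'
#' Fragments are drawn uniformly from each circular clone sequence (clones
#' weighted by length), so vector/insert junction-spanning chimeric pairs
#' arise naturally; 2 x `read_length` mates are cut from the fragment ends
#' with per-base substitution errors. Contaminant pairs replace pool pairs
#' at the requested per-label fractions (total pair count preserved), drawn
#' uniformly from the labelled linear references. Pair provenance is
#' recorded as `insert`, `vector`, `junction`, or the contaminant label.
#'
#' @param pool A `fosmid_pool` with sequences.
#' @param depth Target fold-coverage over the pool's total clone length.
#' @param read_length Read length in bases (default 100).
#' @param fragment_mean,fragment_sd Fragment length distribution
#'   (default 300 +- 30).
#' @param error_rate Per-base substitution rate (default 0.001).
#' @param contaminant_refs Named character vector/list of contaminant
#'   reference sequences.
#' @param contaminant_fractions Named fractions (must sum to < 1) of pairs
#'   drawn from each contaminant label.
#' @param seed Optional integer seed.
#' @return A `read_set` data.frame with columns `id`, `read1`, `read2`,
#'   `label`, and attributes `read_length`, `fragment_mean`, `fragment_sd`,
#'   `depth` (realised pool depth) and `quality_char`.
#' @export
simulate_pool_reads <- function(pool, depth = 75, read_length = 100,
                                fragment_mean = 300, fragment_sd = 30,
                                error_rate = 0.001,
                                contaminant_refs = NULL,
                                contaminant_fractions = NULL, seed = NULL) {
  stopifnot(inherits(pool, "fosmid_pool"))
  check_positive(depth = depth, read_length = read_length)
  fracs <- contaminant_fractions
  if (!is.null(fracs)) {
    if (is.null(names(fracs)) || any(!names(fracs) %in% names(contaminant_refs))) {
      stop("every contaminant fraction needs a matching labelled reference",
           call. = FALSE)
    }
    if (sum(fracs) >= 1) stop("contaminant fractions must sum to < 1", call. = FALSE)
  }
  if (read_length > fragment_mean - 2 * fragment_sd) {
    warning("read_length exceeds fragment_mean - 2*fragment_sd; mates will overlap heavily")
  }
  circles <- clone_circles(pool)
  S <- sum(nchar(circles))
  vlen <- if (is.null(pool$vector)) 0L else nchar(pool$vector)
  n_total <- as.integer(round(depth * S / (2 * read_length)))
  n_cont <- if (is.null(fracs)) integer(0)
            else setNames(as.integer(round(fracs * n_total)), names(fracs))
  n_pool <- n_total - sum(n_cont)
  if (n_pool < 0) stop("contaminant fractions leave no pool reads", call. = FALSE)
  local_seed(seed, {
    sim <- sim_reads_cpp(unname(circles), TRUE, n_pool, as.integer(read_length),
                         fragment_mean, fragment_sd, error_rate)
    clen <- nchar(circles)[sim$tidx]
    lab <- rep("insert", n_pool)
    if (vlen > 0) {
      j0 <- covers_boundary(sim$frag_start, sim$frag_len, clen, 0L)
      jV <- covers_boundary(sim$frag_start, sim$frag_len, clen, vlen)
      invec <- sim$frag_start < vlen & (sim$frag_start + sim$frag_len) <= vlen
      lab[invec] <- "vector"
      lab[j0 | jV] <- "junction"
    }
    r1 <- sim$read1; r2 <- sim$read2
    for (cl in names(n_cont)) {
      if (n_cont[[cl]] == 0) next
      refs <- as_seq_vector(contaminant_refs[[cl]])
      cs <- sim_reads_cpp(unname(refs), FALSE, n_cont[[cl]],
                          as.integer(read_length), fragment_mean, fragment_sd,
                          error_rate)
      r1 <- c(r1, cs$read1); r2 <- c(r2, cs$read2)
      lab <- c(lab, rep(cl, n_cont[[cl]]))
    }
    out <- data.frame(id = paste0(pool$pool_id, "_r", seq_along(r1)),
                      read1 = r1, read2 = r2, label = lab,
                      stringsAsFactors = FALSE)
    structure(out, class = c("read_set", "data.frame"),
              read_length = as.integer(read_length),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              depth = 2 * read_length * n_pool / S, quality_char = "I")
  })
}

#' Subsample read pairs
#'
#' Pair-wise sampling (mates are never split): `"exact"` keeps exactly
#' `round(fraction * n)` pairs, `"bernoulli"` keeps each pair independently
#' with probability `fraction`. `target_depth` derives the fraction from the
#' read set's realised depth.
#'
#' @param reads A `read_set`.
#' @param fraction Fraction of pairs to keep, in `(0, 1]`.
#' @param target_depth Alternative to `fraction`: desired fold-coverage.
#' @param mode `"exact"` or `"bernoulli"`.
#' @param seed Optional integer seed.
#' @return A `read_set` with updated `depth` attribute.
#' @export
subsample_reads <- function(reads, fraction = NULL, target_depth = NULL,
                            mode = c("exact", "bernoulli"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(reads, "read_set"))
  if (is.null(fraction)) {
    if (is.null(target_depth)) stop("give `fraction` or `target_depth`", call. = FALSE)
    cur <- attr(reads, "depth")
    if (is.null(cur)) stop("read set carries no depth attribute", call. = FALSE)
    fraction <- target_depth / cur
  }
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(reads)
  keep <- local_seed(seed, {
    if (mode == "exact") sort(sample.int(n, round(fraction * n)))
    else which(runif(n) < fraction)
  })
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(reads)
  for (a in c("read_length", "fragment_mean", "fragment_sd", "quality_char")) {
    attr(out, a) <- attrs[[a]]
  }
  attr(out, "depth") <- attrs$depth * length(keep) / n
  class(out) <- c("read_set", "data.frame")
  out
}
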