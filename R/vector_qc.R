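# Vector-end QC: terminal vector fragments on contigs, proper-contig
# classification, vector trimming, and clone-count estimation from
# vector/insert junction reads.
#
# Geometry: a clone circle is vector followed by insert, so a fully
# assembled insert read in forward orientation carries a fragment of the
# vector 3' terminus (END) at its left edge and of the 5' terminus (START)
# at its right edge, both facing outward.

#' Detect vector-terminus fragments at contig ends
#'
#' Aligns the first and last `terminal_window` bases of the vector (the
#' START and END termini) against the contigs and keeps hits that lie at a
#' contig end: at most `end_slack` contig bases may fall outside the hit
#' (between the hit and the nearer contig end) and the matched fragment must
#' be at least `min_hit` bases.
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param vector Vector sequence (single character string).
#' @param terminal_window Vector terminus window in bases (default 200).
#' @param end_slack Maximum contig bases outside the hit (default 10).
#' @param min_hit Minimum fragment length in bases (default 20).
#' @param min_identity Minimum percent identity for the underlying
#'   alignment (default 90).
#' @return A `data.frame` with one row per accepted hit: `contig_id`,
#'   `terminus` (START/END), `side` (LEFT/RIGHT), `orientation`
#'   (forward/reverse), `fragment_length`, `outside_bases`, `sstart`,
#'   `send`, `pident`.
#' @export
find_vector_end_hits <- function(contigs, vector, terminal_window = 200,
                                 end_slack = 10, min_hit = 20,
                                 min_identity = 90) {
  contigs <- as_seq_vector(contigs, "contig")
  vector <- as.character(vector)
  if (nchar(vector) < terminal_window) {
    stop("vector is shorter than `terminal_window`", call. = FALSE)
  }
  vlen <- nchar(vector)
  queries <- c(vstart = substr(vector, 1, terminal_window),
               vend = substr(vector, vlen - terminal_window + 1, vlen))
  hits <- local_align(queries, contigs, k = 11, min_identity = min_identity,
                      min_length = max(11, min_hit))
  empty <- data.frame(contig_id = character(), terminus = character(),
                      side = character(), orientation = character(),
                      fragment_length = integer(), outside_bases = integer(),
                      sstart = integer(), send = integer(), pident = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  L <- nchar(contigs)[hits$sseqid]
  slo <- pmin(hits$sstart, hits$send)
  shi <- pmax(hits$sstart, hits$send)
  out_left <- slo - 1L
  out_right <- L - shi
  side <- ifelse(out_left <= out_right, "LEFT", "RIGHT")
  outside <- pmin(out_left, out_right)
  frag <- shi - slo + 1L
  keep <- outside <= end_slack & frag >= min_hit
  if (!any(keep)) return(empty)
  data.frame(contig_id = hits$sseqid[keep],
             terminus = ifelse(hits$qseqid[keep] == "vstart", "START", "END"),
             side = side[keep],
             orientation = ifelse(hits$sstart[keep] <= hits$send[keep],
                                  "forward", "reverse"),
             fragment_length = frag[keep], outside_bases = outside[keep],
             sstart = hits$sstart[keep], send = hits$send[keep],
             pident = hits$pident[keep], stringsAsFactors = FALSE)
}

# extents (bases from each contig end covered by vector hits incl. the
# outside slack) for one contig's accepted hits
vector_extents <- function(hits, contig_length) {
  slo <- pmin(hits$sstart, hits$send)
  shi <- pmax(hits$sstart, hits$send)
  left <- hits$side == "LEFT"
  list(left = if (any(left)) max(shi[left]) else 0L,
       right = if (any(!left)) max(contig_length - slo[!left] + 1L) else 0L)
}

classify_one <- function(contig_length, hits, length_range) {
  n <- nrow(hits)
  ext <- if (n > 0) vector_extents(hits, contig_length) else list(left = 0L, right = 0L)
  insert_len <- contig_length - ext$left - ext$right
  proper <- FALSE
  if (n >= 2) {
    left <- hits[hits$side == "LEFT", , drop = FALSE]
    right <- hits[hits$side == "RIGHT", , drop = FALSE]
    for (i in seq_len(nrow(left))) {
      for (j in seq_len(nrow(right))) {
        same_strand <- left$orientation[i] == right$orientation[j]
        diff_term <- left$terminus[i] != right$terminus[j]
        outward <- (left$orientation[i] == "forward" && left$terminus[i] == "END") ||
                   (left$orientation[i] == "reverse" && left$terminus[i] == "START")
        if (same_strand && diff_term && outward) proper <- TRUE
      }
    }
  }
  cls <- if (proper) "proper" else if (n >= 1) "partial" else "none"
  list(class = cls,
       in_expected_range = insert_len >= length_range[1] &&
                           insert_len <= length_range[2],
       n_hits = n, insert_length_estimate = insert_len)
}

#' Classify one contig from its vector-end hits
#'
#' A contig is `proper` when vector START and END fragments sit on opposite
#' contig sides, on the same strand, facing outward as on the original
#' circular clone; `partial` with at least one hit otherwise; `none` with no
#' hits. The expected-length flag compares the vector-trimmed (insert
#' equivalent) length, contig length minus the vector-hit extents, against
#' `length_range`.
#'
#' @param contig_length Contig length in bases.
#' @param hits Accepted hits for this contig from [find_vector_end_hits()].
#' @param length_range Expected insert length range (default `c(27000, 47000)`).
#' @return A one-row `data.frame`: `class`, `in_expected_range`, `n_hits`,
#'   `insert_length_estimate`.
#' @export
classify_contig <- function(contig_length, hits,
                            length_range = c(27000, 47000)) {
  res <- classify_one(contig_length, hits, length_range)
  data.frame(class = res$class, in_expected_range = res$in_expected_range,
             n_hits = res$n_hits,
             insert_length_estimate = res$insert_length_estimate,
             stringsAsFactors = FALSE)
}

#' Classify a set of contigs
#'
#' Vectorised [classify_contig()] over all contigs named in
#' `contig_lengths`; contigs without hits classify `none`.
#'
#' @param hits Hits from [find_vector_end_hits()].
#' @param contig_lengths Named integer vector of contig lengths (or named
#'   character sequences, from which lengths are taken).
#' @param length_range Expected insert length range.
#' @return A `data.frame` with one row per contig: `contig_id`, `class`,
#'   `in_expected_range`, `n_hits`, `insert_length_estimate`.
#' @export
classify_contigs <- function(hits, contig_lengths,
                             length_range = c(27000, 47000)) {
  if (is.character(contig_lengths)) {
    contig_lengths <- setNames(nchar(contig_lengths), names(contig_lengths))
  }
  out <- lapply(names(contig_lengths), function(id) {
    h <- hits[hits$contig_id == id, , drop = FALSE]
    cbind(data.frame(contig_id = id, stringsAsFactors = FALSE),
          classify_contig(contig_lengths[[id]], h, length_range))
  })
  do.call(rbind, out)
}

#' Trim vector fragments from contig ends
#'
#' For each contig side carrying an accepted vector-end hit, removes the
#' larger of the hit extent (including the outside slack bases) and
#' `min_trim` bases. Trimming is idempotent: re-running
#' [find_vector_end_hits()] on the trimmed sequence finds nothing.
#'
#' @param contig Contig sequence (single character string).
#' @param hits Accepted hits for this contig.
#' @param min_trim Minimum bases removed from a hit-bearing side (default 30).
#' @return A list: `seq` (trimmed sequence), `trimmed_left`,
#'   `trimmed_right`, `collapsed` (TRUE when trimming consumed the contig).
#' @export
trim_vector_ends <- function(contig, hits, min_trim = 30) {
  contig <- as.character(contig)
  L <- nchar(contig)
  ext <- if (nrow(hits) > 0) vector_extents(hits, L) else list(left = 0L, right = 0L)
  lt <- if (ext$left > 0) max(ext$left, min_trim) else 0L
  rt <- if (ext$right > 0) max(ext$right, min_trim) else 0L
  if (lt + rt >= L) {
    return(list(seq = "", trimmed_left = min(lt, L), trimmed_right = min(rt, L),
                collapsed = TRUE))
  }
  list(seq = substr(contig, lt + 1, L - rt), trimmed_left = lt,
       trimmed_right = rt, collapsed = FALSE)
}

#' Detect vector/insert junction reads
#'
#' A read is a junction read when a read-terminal vector segment of at
#' least `m` bases ends exactly at a vector terminus inside the read (a read
#' crossing the START junction runs insert-then-vector to its edge; one
#' crossing the END junction starts with vector), adjacent to `f` bases of
#' insert-side flank that are not vector sequence. Both read orientations
#' are scanned; up to `max_mismatch` mismatches are tolerated over the
#' vector-side segment. Flanks are reported
#' orientation-normalised: for the START terminus the `f` insert bases that
#' precede the vector start, for the END terminus the `f` insert bases that
#' follow the vector end, both read along the vector's strand.
#'
#' @param reads A `read_set` (both mates are scanned) or a character vector
#'   of read sequences.
#' @param vector Vector sequence.
#' @param m Minimum vector-side bases (default 15).
#' @param f Insert-side flank length in bases (default 20).
#' @param max_mismatch Mismatches tolerated in the vector segment (default 1).
#' @return A `data.frame`: `read_id`, `mate`, `terminus`, `flank`.
#' @export
detect_junction_reads <- function(reads, vector, m = 15, f = 20,
                                  max_mismatch = 1) {
  vector <- as.character(vector)
  if (nchar(vector) < m) stop("vector shorter than `m`", call. = FALSE)
  if (!max_mismatch %in% 0:1) {
    stop("`max_mismatch` must be 0 or 1 (seed prefilter assumption)",
         call. = FALSE)
  }
  if (inherits(reads, "read_set") || is.data.frame(reads)) {
    seqs <- c(reads$read1, reads$read2)
    ids <- c(reads$id, reads$id)
    mate <- rep(1:2, each = nrow(reads))
  } else {
    seqs <- as_seq_vector(reads, "read")
    ids <- names(seqs)
    mate <- rep(1L, length(seqs))
  }
  if (any(nchar(seqs) < m + f)) {
    stop("all reads must be at least m + f bases long", call. = FALSE)
  }
  j <- junction_scan_cpp(seqs, vector, as.integer(m), as.integer(f),
                         as.integer(max_mismatch))
  data.frame(read_id = ids[j$read], mate = mate[j$read], terminus = j$terminus,
             flank = j$flank, stringsAsFactors = FALSE)
}

cluster_flank_count <- function(flanks, collapse_distance) {
  u <- sort(unique(flanks))
  n <- length(u)
  if (n <= 1) return(n)
  # single-linkage components at <= collapse_distance edits: transitive, so
  # two error variants of one true flank merge even when they differ from
  # each other by more than the threshold
  D <- adist(u)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  close_pairs <- which(D <= collapse_distance & upper.tri(D), arr.ind = TRUE)
  for (r in seq_len(nrow(close_pairs))) {
    a <- find_root(close_pairs[r, 1])
    b <- find_root(close_pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find_root, 1L)))
}

#' Estimate the clone count of a pool from junction reads
#'
#' Each clone contributes exactly one distinct insert-side flank per vector
#' terminus, so the number of distinct flank sequences per terminus counts
#' clones. Flanks are deduplicated and clustered into single-linkage
#' components at up to `collapse_distance` edits (sequencing-error variants
#' collapse onto the true flank, including variants that differ from each
#' other by more than the threshold but share it); the estimate is the mean
#' of the two per-terminus component counts, rounded. Deduplication plus
#' component clustering makes the estimate invariant to read order and
#' duplication.
#'
#' @param records Junction records from [detect_junction_reads()] for one
#'   pool.
#' @param collapse_distance Maximum edit distance merged into one flank
#'   cluster (default 2).
#' @param target Intended clone count, for the recovery ratio (optional).
#' @return A `clone_count_estimate`: list with `estimate`, `per_terminus`
#'   (named counts), `target`, `ratio_percent`.
#' @export
estimate_clone_count <- function(records, collapse_distance = 2,
                                 target = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    warning("no junction records; clone-count estimate is 0")
    counts <- c(START = 0L, END = 0L)
  } else {
    counts <- vapply(c("START", "END"), function(t) {
      cluster_flank_count(records$flank[records$terminus == t],
                          collapse_distance)
    }, 0L)
  }
  est <- as.integer(round(mean(counts)))
  structure(list(estimate = est, per_terminus = counts, target = target,
                 ratio_percent = if (!is.null(target)) percent(est, target)
                                 else NA_real_),
            class = "clone_count_estimate")
}

#' @export
print.clone_count_estimate <- function(x, ...) {
  cat(sprintf("clone-count estimate: %d (START %d, END %d)%s\n",
              x$estimate, x$per_terminus[["START"]], x$per_terminus[["END"]],
              if (!is.null(x$target))
                sprintf("; target %d, recovery %.1f%%", x$target, x$ratio_percent)
              else ""))
  invisible(x)
}

#' Vector-end summary percentages
#'
#' Report-level arithmetic on supplied counts: fraction of contigs carrying
#' at least one vector end and fraction of two-fragment contigs that are
#' proper, both as percentages with one decimal.
#'
#' @param n_contigs Total contigs searched.
#' @param n_with_end Contigs with at least one vector-end fragment.
#' @param n_two_fragment Contigs with two vector fragments.
#' @param n_proper Two-fragment contigs with both termini in correct
#'   orientation.
#' @return A `data.frame` with counts and `pct_with_end`, `pct_proper`.
#' @export
#' @examples
#' vector_end_summary(1071614, 83855, 1694, 1516)
vector_end_summary <- function(n_contigs, n_with_end, n_two_fragment,
                               n_proper) {
  data.frame(n_contigs = n_contigs, n_with_end = n_with_end,
             n_two_fragment = n_two_fragment, n_proper = n_proper,
             pct_with_end = percent(n_with_end, n_contigs),
             pct_proper = percent(n_proper, n_two_fragment))
}
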