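# Local alignment surface: seed-and-extend aligner, exact Smith-Waterman
# oracle, alignment-free k-mer containment and the 12-column tabular dialect.

default_align_scores <- function() {
  list(match = 1L, mismatch = -2L, gap_open = 3L, gap_ext = 1L)
}

# Karlin-Altschul-style surrogate statistics for the raw score; informational
# only (not calibrated to a database size).
score_to_bits <- function(score, lambda = 1.28, K = 0.46) {
  (lambda * score - log(K)) / log(2)
}

#' Seed-and-extend local alignment
#'
#' Aligns every query against every subject on both strands: exact k-mer
#' seeds, seeds grouped into diagonal bands and chained along the query, each
#' cluster extended by banded affine-gap dynamic programming in a window
#' reaching `margin` bases beyond the outermost seeds. Hits passing
#' `min_identity` (percent, gap columns counted) and `min_length` (alignment
#' columns) are reported in BLAST-style 12-column form plus raw `score` and
#' `matches` columns. Coordinates are 1-based inclusive; minus-strand hits
#' have `sstart > send`. Output is deterministic, ordered by
#' (query, subject, subject start, query start).
#'
#' @param queries,subjects Named character vectors or `DNAStringSet`s.
#' @param k Seed length (>= 8, <= 31; default 11).
#' @param min_identity Minimum percent identity (default 70).
#' @param min_length Minimum alignment length in columns (default 30,
#'   must be >= `k`).
#' @param scores List with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   (defaults +1/-2/3/1; a gap of length g costs `gap_open + g * gap_ext`).
#' @param band_pad Extra diagonals kept around the seed diagonals (default 32).
#' @param band_merge Max diagonal gap merged into one seed band (default 15).
#' @param chain_gap Max query gap chained into one cluster (default 200).
#' @param margin Extension window past the outermost seeds (default 250).
#' @param max_kmer_hits Seeds occurring more often than this in the subject
#'   index are skipped (default 50000).
#' @return A `data.frame` with columns `qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, `score`, `matches`.
#' @export
#' @examples
#' s <- random_dna(2000, seed = 1)
#' q <- substr(s, 501, 1100)
#' local_align(c(q = q), c(s = s))
local_align <- function(queries, subjects, k = 11, min_identity = 70,
                        min_length = 30, scores = default_align_scores(),
                        band_pad = 32, band_merge = 15, chain_gap = 200,
                        margin = 250, max_kmer_hits = 50000) {
  queries <- as_seq_vector(queries, "query")
  subjects <- as_seq_vector(subjects, "subject")
  if (k < 8 || k > 31) stop("`k` must be between 8 and 31", call. = FALSE)
  if (min_length < k) stop("`min_length` must be >= `k`", call. = FALSE)
  sc <- utils::modifyList(default_align_scores(), as.list(scores))
  empty <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      score = integer(), matches = integer(),
                      stringsAsFactors = FALSE)
  if (length(queries) == 0 || length(subjects) == 0) return(empty)
  if (max(nchar(subjects)) < k || max(nchar(queries)) < k) {
    warning("`k` exceeds every sequence length; no seeds possible")
    return(empty)
  }
  h <- local_align_cpp(unname(queries), unname(subjects),
                       as.integer(k), min_identity, as.integer(min_length),
                       as.integer(sc$match), as.integer(sc$mismatch),
                       as.integer(sc$gap_open), as.integer(sc$gap_ext),
                       as.integer(band_pad), as.integer(band_merge),
                       as.integer(chain_gap), as.integer(margin),
                       as.integer(max_kmer_hits))
  if (nrow(h) == 0) return(empty)
  bits <- score_to_bits(h$score)
  ev <- nchar(queries)[h$qidx] * sum(as.numeric(nchar(subjects))) * 2^(-bits)
  data.frame(qseqid = names(queries)[h$qidx], sseqid = names(subjects)[h$sidx],
             pident = h$pident, length = h$length, mismatch = h$mismatch,
             gapopen = h$gapopen, qstart = h$qstart, qend = h$qend,
             sstart = h$sstart, send = h$send, evalue = ev, bitscore = bits,
             score = h$score, matches = h$matches, stringsAsFactors = FALSE)
}

#' Exact Smith-Waterman local alignment (test oracle)
#'
#' Full affine-gap local dynamic programming over the complete alignment
#' matrix, plus strand only. Quadratic in sequence length; both sequences are
#' limited to 20 kb.
#'
#' @param query,subject Single DNA sequences (character or `DNAString`).
#' @param scores Scoring scheme as in [local_align()].
#' @return A list with `score`, `qstart`, `qend`, `sstart`, `send`,
#'   `matches`, `mismatches`, `gap_openings`, `columns` and `identity`
#'   (percent); coordinates are 1-based, 0 when no positive-scoring
#'   alignment exists.
#' @export
#' @examples
#' smith_waterman_oracle("ACGT", "TTTT")$score  # 1
smith_waterman_oracle <- function(query, subject, scores = default_align_scores()) {
  query <- as.character(query); subject <- as.character(subject)
  stopifnot(length(query) == 1, length(subject) == 1)
  if (nchar(query) == 0 || nchar(subject) == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (nchar(query) > 20000 || nchar(subject) > 20000) {
    stop("sequences longer than 20 kb are rejected (quadratic cost guard)",
         call. = FALSE)
  }
  sc <- utils::modifyList(default_align_scores(), as.list(scores))
  sw_align_cpp(query, subject, as.integer(sc$match), as.integer(sc$mismatch),
               as.integer(sc$gap_open), as.integer(sc$gap_ext))
}

#' Build a canonical k-mer index
#'
#' Collects the canonical (strand-symmetric, lexicographic minimum of k-mer
#' and reverse complement) k-mers of a set of reference sequences into a
#' sorted set usable by [kmer_containment()]. Windows containing ambiguous
#' bases are skipped.
#'
#' @param seqs Character vector or `DNAStringSet` of reference sequences.
#' @param k K-mer length (4..26; default 21).
#' @return Numeric vector of canonical k-mer codes with attributes `k`.
#' @export
kmer_index <- function(seqs, k = 21) {
  if (k < 4 || k > 26) stop("`k` must be between 4 and 26", call. = FALSE)
  idx <- kmer_index_cpp(unname(as_seq_vector(seqs)), as.integer(k))
  attr(idx, "k") <- as.integer(k)
  idx
}

#' Fraction of a sequence's k-mers present in an index
#'
#' Canonical-form containment: for each sequence, the fraction of its valid
#' k-mer windows whose canonical code is present in `index`. Invariant under
#' reverse complement of the sequence.
#'
#' @param seqs Character vector or `DNAStringSet`.
#' @param index Index from [kmer_index()].
#' @param k K-mer length; defaults to the index's `k`.
#' @return Numeric vector of fractions in `[0, 1]` (`NA` when a sequence has
#'   no valid window).
#' @export
kmer_containment <- function(seqs, index, k = attr(index, "k")) {
  seqs <- as_seq_vector(seqs)
  if (is.null(k)) stop("`k` missing and not recorded on the index", call. = FALSE)
  if (any(nchar(seqs) < k)) {
    stop("all sequences must be at least `k` bases long", call. = FALSE)
  }
  out <- kmer_containment_cpp(unname(seqs), as.numeric(index), as.integer(k))
  names(out) <- names(seqs)
  out
}

blast_tab_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")

#' Write alignment hits in 12-column tabular form
#'
#' Tab-separated BLAST-style dialect: identity printed with two decimals,
#' e-value in scientific notation, no header. Extra columns (e.g. `score`)
#' are dropped.
#'
#' @param hits Data frame from [local_align()] or [read_blast_tab()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(blast_tab_columns %in% names(hits)))
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.3g",
                   hits$qseqid, hits$sseqid, hits$pident,
                   as.integer(hits$length), as.integer(hits$mismatch),
                   as.integer(hits$gapopen), as.integer(hits$qstart),
                   as.integer(hits$qend), as.integer(hits$sstart),
                   as.integer(hits$send), hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Read 12-column tabular alignments
#'
#' Parses the tab-separated dialect written by [write_blast_tab()] (and by
#' external aligners with `-outfmt 6`); downstream stages accept these hits
#' in place of [local_align()] output. Malformed rows raise an error naming
#' the line.
#'
#' @param path Input file path.
#' @return A `data.frame` with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad) > 0) {
    stop(sprintf("malformed tabular alignment row at line %d: expected 12 columns, found %d",
                 bad[1], lengths(parts)[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$pident) || anyNA(out$qstart) || anyNA(out$sstart)) {
    stop("non-numeric fields in tabular alignment file", call. = FALSE)
  }
  out
}
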