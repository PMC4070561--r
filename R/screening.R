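# Two-round contamination screening: alignment-free k-mer screening of read
# pairs, alignment-based screening of assembled contigs, short-contig
# filtering and composition reporting.

canonical_label_order <- c("vector", "ecoli_mobile", "ecoli", "chloroplast",
                           "mitochondrion")

order_labels <- function(labels) {
  c(intersect(canonical_label_order, labels),
    setdiff(labels, canonical_label_order))
}

#' Build a contaminant k-mer index
#'
#' One canonical k-mer set per contaminant label. Label precedence for
#' tie-breaking is fixed: vector, ecoli_mobile, ecoli, chloroplast,
#' mitochondrion, then custom labels in input order.
#'
#' @param refs Named list (or named character vector) of reference
#'   sequences per label; a label may hold several sequences.
#' @param k K-mer length (default 21).
#' @return A `contaminant_index`: list with `k`, `labels` (in precedence
#'   order) and `sets` (named list of k-mer indexes).
#' @export
build_contaminant_index <- function(refs, k = 21) {
  if (is.null(names(refs)) || any(names(refs) == "")) {
    stop("`refs` must be named by contaminant label", call. = FALSE)
  }
  if (anyDuplicated(names(refs))) stop("labels must be unique", call. = FALSE)
  labels <- order_labels(names(refs))
  sets <- lapply(labels, function(l) kmer_index(refs[[l]], k))
  names(sets) <- labels
  structure(list(k = as.integer(k), labels = labels, sets = sets),
            class = "contaminant_index")
}

#' Screen read pairs against contaminants
#'
#' A pair is assigned contaminant label L when the maximum over its mates of
#' the canonical k-mer containment against L's index reaches `theta`; among
#' qualifying labels the highest containment wins, ties broken by the fixed
#' precedence order. Labelled pairs are removed from the retained set. Mates
#' shorter than `k` are skipped (counted, never labelled from that mate).
#'
#' @param reads A `read_set`.
#' @param index A `contaminant_index`.
#' @param theta Containment threshold in `(0, 1]` (default 0.5).
#' @return A list: `labels` (per input pair; `NA` = retained),
#'   `retained` (`read_set`), `containment` (pair x label matrix),
#'   `skipped_short` (count of mates shorter than `k`).
#' @export
screen_reads <- function(reads, index, theta = 0.5) {
  stopifnot(inherits(index, "contaminant_index"))
  if (theta <= 0 || theta > 1) stop("`theta` must lie in (0, 1]", call. = FALSE)
  n <- nrow(reads)
  k <- index$k
  ok1 <- nchar(reads$read1) >= k
  ok2 <- nchar(reads$read2) >= k
  skipped <- sum(!ok1) + sum(!ok2)
  cont <- matrix(NA_real_, n, length(index$labels),
                 dimnames = list(NULL, index$labels))
  for (lab in index$labels) {
    c1 <- c2 <- rep(NA_real_, n)
    if (any(ok1)) c1[ok1] <- kmer_containment_cpp(reads$read1[ok1],
                                                  index$sets[[lab]], k)
    if (any(ok2)) c2[ok2] <- kmer_containment_cpp(reads$read2[ok2],
                                                  index$sets[[lab]], k)
    cont[, lab] <- pmax(c1, c2, na.rm = TRUE)
  }
  bestval <- rep(-Inf, n)
  bestlab <- rep(NA_character_, n)
  for (lab in index$labels) {
    v <- cont[, lab]
    sel <- !is.na(v) & v > bestval
    bestval[sel] <- v[sel]
    bestlab[sel] <- lab
  }
  labels <- ifelse(!is.na(bestlab) & bestval >= theta, bestlab, NA_character_)
  retained <- reads[is.na(labels), , drop = FALSE]
  rownames(retained) <- NULL
  class(retained) <- class(reads)
  for (a in c("read_length", "fragment_mean", "fragment_sd", "depth",
              "quality_char")) {
    attr(retained, a) <- attr(reads, a)
  }
  list(labels = labels, retained = retained, containment = cont,
       skipped_short = skipped)
}

#' Screen assembled contigs against contaminant references
#'
#' Second-round screening for contaminant sequence that escaped read-level
#' filtering: a contig is assigned label L when local alignments against
#' L's references at or above `min_identity` percent cover (as an interval
#' union on the contig) at least `min_cov` of its length. The best-covered
#' qualifying label wins, ties broken by precedence.
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param refs Named list of labelled reference sequences.
#' @param min_identity Minimum percent identity (default 95).
#' @param min_cov Minimum covered fraction of the contig (default 0.5).
#' @return Named character vector of labels per contig (`NA` = clean).
#' @export
screen_contigs <- function(contigs, refs, min_identity = 95, min_cov = 0.5) {
  if (min_identity <= 0 || min_identity > 100) {
    stop("`min_identity` must lie in (0, 100]", call. = FALSE)
  }
  contigs <- as_seq_vector(contigs, "contig")
  labels <- order_labels(names(refs))
  lens <- nchar(contigs)
  cov <- matrix(0, length(contigs), length(labels),
                dimnames = list(names(contigs), labels))
  for (lab in labels) {
    hits <- local_align(contigs, refs[[lab]], k = 11,
                        min_identity = min_identity, min_length = 50)
    if (nrow(hits) == 0) next
    for (id in unique(hits$qseqid)) {
      h <- hits[hits$qseqid == id, , drop = FALSE]
      cov[id, lab] <- interval_union_length(h$qstart, h$qend) / lens[[id]]
    }
  }
  bestval <- rep(-Inf, length(contigs))
  bestlab <- rep(NA_character_, length(contigs))
  for (lab in labels) {
    sel <- cov[, lab] > bestval
    bestval[sel] <- cov[sel, lab]
    bestlab[sel] <- lab
  }
  out <- ifelse(bestval >= min_cov, bestlab, NA_character_)
  names(out) <- names(contigs)
  out
}

#' Remove short contigs
#'
#' Retains contigs of at least `min_length` bases; shorter contigs usually
#' betray mis-assembly (orphan reads, aberrant pair orientation) and are
#' logged with a reason.
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param min_length Minimum retained length in bases (default 500).
#' @return A list: `retained` (named character) and `removed` (data.frame
#'   `contig_id`, `length`, `reason`).
#' @export
#' @examples
#' filter_contigs(c(a = strrep("A", 499), b = strrep("A", 500)))$removed
filter_contigs <- function(contigs, min_length = 500) {
  if (min_length < 0) stop("`min_length` must be >= 0", call. = FALSE)
  contigs <- as_seq_vector(contigs, "contig")
  lens <- nchar(contigs)
  keep <- lens >= min_length
  list(retained = contigs[keep],
       removed = data.frame(contig_id = names(contigs)[!keep],
                            length = unname(lens[!keep]),
                            reason = rep("short_contig", sum(!keep)),
                            stringsAsFactors = FALSE))
}

#' Pool composition report
#'
#' Per-label fractions of read pairs and of contig bases, with the residual
#' (unlabelled) fraction; label fractions and residual sum to 1 exactly on
#' each axis.
#'
#' @param read_labels Per-pair labels from [screen_reads()] (`NA` = clean).
#' @param contig_labels Per-contig labels from [screen_contigs()] (optional).
#' @param contig_lengths Named contig lengths (or sequences), required with
#'   `contig_labels`.
#' @return A `data.frame` with one row per label plus a `residual` row:
#'   `label`, `read_pairs`, `read_fraction`, `contig_bases`,
#'   `contig_fraction`.
#' @export
composition_report <- function(read_labels = NULL, contig_labels = NULL,
                               contig_lengths = NULL) {
  labs <- order_labels(unique(c(
    read_labels[!is.na(read_labels)],
    if (!is.null(contig_labels)) contig_labels[!is.na(contig_labels)])))
  read_pairs <- read_frac <- contig_bases <- contig_frac <- NULL
  n_pairs <- length(read_labels)
  read_pairs <- vapply(labs, function(l) sum(read_labels == l, na.rm = TRUE), 0L)
  read_frac <- if (n_pairs > 0) read_pairs / n_pairs else rep(0, length(labs))
  if (!is.null(contig_labels)) {
    if (is.character(contig_lengths) && any(nchar(contig_lengths) > 20)) {
      contig_lengths <- setNames(nchar(contig_lengths), names(contig_lengths))
    }
    total_bases <- sum(as.numeric(contig_lengths))
    contig_bases <- vapply(labs, function(l) {
      sum(as.numeric(contig_lengths[which(contig_labels == l)]))
    }, 0)
    contig_frac <- if (total_bases > 0) contig_bases / total_bases
                   else rep(0, length(labs))
  } else {
    contig_bases <- rep(NA_real_, length(labs))
    contig_frac <- rep(NA_real_, length(labs))
    total_bases <- NA_real_
  }
  out <- data.frame(label = c(labs, "residual"),
                    read_pairs = c(read_pairs, n_pairs - sum(read_pairs)),
                    read_fraction = c(read_frac, 1 - sum(read_frac)),
                    contig_bases = c(contig_bases,
                                     if (is.null(contig_labels)) NA_real_
                                     else total_bases - sum(contig_bases)),
                    contig_fraction = c(contig_frac,
                                        if (is.null(contig_labels)) NA_real_
                                        else 1 - sum(contig_frac)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
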