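# Repeat mapping and resolution statistics, genome-saturation analysis and
# assembly-efficiency / coverage metrics.

#' Map a repeat library onto contigs
#'
#' Aligns the repeat consensus library against the contigs on both strands
#' and keeps hits with percent identity strictly greater than
#' `min_identity` (default 78, the conventional cutoff below which
#' repeat-family assignment is unreliable).
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param library Repeat library (named character vector of consensus
#'   sequences).
#' @param min_identity Strict lower bound on percent identity (default 78).
#' @param min_length Minimum alignment length in columns (default 30; short
#'   enough for the fragmentary hits repeat annotation produces, long enough
#'   to keep chance seed extensions out without an e-value model).
#' @return Alignment hits as from [local_align()] (queries are repeat
#'   families, subjects are contigs).
#' @export
map_repeats <- function(contigs, library, min_identity = 78,
                        min_length = 30) {
  if (length(library) == 0) stop("`library` must be non-empty", call. = FALSE)
  hits <- local_align(library, contigs, k = 11, min_identity = min_identity,
                      min_length = max(11, min_length))
  hits[hits$pident > min_identity, , drop = FALSE]
}

#' Repeat-hit statistics over a contig set
#'
#' Mean hits per contig, fraction of contigs without any hit, and the
#' resolved fraction: a repeat hit counts as resolved when it lies in the
#' contig interior, at least `end_margin` bases from both contig ends
#' (the assembler traversed the repeat rather than breaking at it).
#'
#' @param hits Hits from [map_repeats()].
#' @param contigs Named character vector, `DNAStringSet`, or named integer
#'   lengths.
#' @param end_margin Interior margin in bases (default 10).
#' @return A `repeat_hit_stats`: list with `total_hits`, `n_contigs`,
#'   `mean_hits_per_contig`, `zero_hit_fraction`, `resolved_fraction` and
#'   `per_hit` (data.frame `contig_id`, `repeat_id`, `identity`, `length`,
#'   `start`, `end`, `resolved`).
#' @export
repeat_statistics <- function(hits, contigs, end_margin = 10) {
  if (length(contigs) == 0) stop("empty contig set", call. = FALSE)
  lens <- if (is.numeric(contigs)) contigs
          else setNames(nchar(as_seq_vector(contigs)), names(as_seq_vector(contigs)))
  n_contigs <- length(lens)
  slo <- pmin(hits$sstart, hits$send)
  shi <- pmax(hits$sstart, hits$send)
  L <- unname(lens[hits$sseqid])
  resolved <- (slo - 1) >= end_margin & (L - shi) >= end_margin
  per_hit <- data.frame(contig_id = hits$sseqid, repeat_id = hits$qseqid,
                        identity = hits$pident, length = hits$length,
                        start = slo, end = shi, resolved = resolved,
                        stringsAsFactors = FALSE)
  structure(list(
    total_hits = nrow(hits),
    n_contigs = n_contigs,
    mean_hits_per_contig = nrow(hits) / n_contigs,
    zero_hit_fraction = 1 - length(unique(hits$sseqid)) / n_contigs,
    resolved_fraction = if (nrow(hits) > 0) mean(resolved) else NA_real_,
    per_hit = per_hit), class = "repeat_hit_stats")
}

#' @export
print.repeat_hit_stats <- function(x, ...) {
  cat(sprintf(paste0("repeat hits: %d over %d contigs (%.1f per contig); ",
                     "%.1f%% contigs without hits; resolved %.1f%%\n"),
              x$total_hits, x$n_contigs, x$mean_hits_per_contig,
              100 * x$zero_hit_fraction, 100 * x$resolved_fraction))
  invisible(x)
}

#' Repeat-load arithmetic on supplied counts
#'
#' Report code path for aggregate counts (as published summary tables give
#' them): mean identified repeat regions per contig at one decimal, and
#' contigs per pool (floor).
#'
#' @param n_hits Total repeat hits.
#' @param n_contigs Total contigs.
#' @param n_pools Number of pools (optional).
#' @return A list with `mean_hits_per_contig` and `contigs_per_pool`.
#' @export
#' @examples
#' repeat_load_summary(40559402, 13090107, 457)
repeat_load_summary <- function(n_hits, n_contigs, n_pools = NULL) {
  check_positive(n_contigs = n_contigs)
  list(mean_hits_per_contig = round(n_hits / n_contigs, 1),
       contigs_per_pool = if (!is.null(n_pools)) n_contigs %/% n_pools
                          else NA_integer_)
}

#' Genome-saturation curve over successive pools
#'
#' Presents pool contig sets in random order against a reference assembly
#' and measures how much reference sequence each pool claims for the first
#' time. Contigs longer than `min_contig` are aligned to the reference;
#' alignments of at least `min_alignment` columns with identity strictly
#' above `min_identity` claim every yet-unclaimed reference marker strictly
#' inside their reference interval, where markers sit at discrete points
#' every `grid` bases along each reference sequence. A pool's novel length
#' is its newly claimed markers times `grid`; its novel fraction divides by
#' the pool's passing contig length.
#'
#' @param fp_contig_sets List of contig sets (named character vectors,
#'   `DNAStringSet`s or `fp_contigs`), one per pool.
#' @param reference Named character vector or `DNAStringSet`.
#' @param min_contig Strict minimum contig length (default 1000).
#' @param min_alignment Minimum alignment length (default 500).
#' @param min_identity Strict minimum percent identity (default 99).
#' @param grid Marker spacing in bases (default 500).
#' @param seed Seed for the random pool order.
#' @param k Seed length passed to the aligner (default 15; long seeds keep
#'   random k-mer collisions negligible against megabase references).
#' @return A `data.frame`, one row per pool in presentation order:
#'   `ordinal`, `pool`, `n_contigs_passing`, `pool_contig_length`,
#'   `cumulative_contig_length`, `new_markers`, `novel_length`,
#'   `cumulative_matched_length`, `novel_fraction`. The attribute
#'   `per_contig` holds a data.frame (`ordinal`, `pool`, `contig_id`,
#'   `length`, `new_markers`) of per-contig gains; contigs are the sampling
#'   units for any uncertainty estimate on the novel fraction, since one
#'   insert claims a whole block of markers.
#' @export
saturation_curve <- function(fp_contig_sets, reference, min_contig = 1000,
                             min_alignment = 500, min_identity = 99,
                             grid = 500, seed = NULL, k = 15) {
  if (length(fp_contig_sets) == 0) stop("need at least one pool", call. = FALSE)
  check_positive(grid = grid)
  reference <- as_seq_vector(reference, "ref")
  if (sum(nchar(reference)) == 0) stop("empty reference", call. = FALSE)
  sets <- lapply(fp_contig_sets, function(s) {
    if (inherits(s, "fp_contigs")) s$seq else as_seq_vector(s, "contig")
  })
  pool_names <- names(sets)
  if (is.null(pool_names)) pool_names <- sprintf("pool%d", seq_along(sets))
  ord <- local_seed(seed, sample(length(sets)))
  claimed <- lapply(reference, function(s) {
    logical(floor((nchar(s) - 1) / grid) + 1)  # markers at 0, grid, 2*grid, ...
  })
  rows <- vector("list", length(sets))
  detail <- vector("list", length(sets))
  cum_len <- 0; cum_match <- 0
  for (step in seq_along(ord)) {
    pool_i <- ord[step]
    contigs <- sets[[pool_i]]
    contigs <- contigs[nchar(contigs) > min_contig]
    new_markers <- 0L
    per_ctg <- setNames(rep(0L, length(contigs)), names(contigs))
    plen <- sum(as.numeric(nchar(contigs)))
    if (length(contigs) > 0) {
      hits <- local_align(contigs, reference, k = k,
                          min_identity = min_identity,
                          min_length = min_alignment)
      hits <- hits[hits$pident > min_identity, , drop = FALSE]
      if (nrow(hits) > 0) {
        slo <- pmin(hits$sstart, hits$send)
        shi <- pmax(hits$sstart, hits$send)
        for (h in seq_len(nrow(hits))) {
          ref_id <- hits$sseqid[h]
          kmin <- ceiling(slo[h] / grid)
          kmax <- floor((shi[h] - 2) / grid)
          if (kmax < kmin) next
          idx <- (kmin:kmax) + 1L
          idx <- idx[idx <= length(claimed[[ref_id]])]
          fresh <- idx[!claimed[[ref_id]][idx]]
          claimed[[ref_id]][fresh] <- TRUE
          new_markers <- new_markers + length(fresh)
          per_ctg[[hits$qseqid[h]]] <- per_ctg[[hits$qseqid[h]]] + length(fresh)
        }
      }
    }
    cum_len <- cum_len + plen
    cum_match <- cum_match + new_markers * grid
    rows[[step]] <- data.frame(
      ordinal = step, pool = pool_names[pool_i],
      n_contigs_passing = length(contigs), pool_contig_length = plen,
      cumulative_contig_length = cum_len, new_markers = new_markers,
      novel_length = new_markers * grid,
      cumulative_matched_length = cum_match,
      novel_fraction = if (plen > 0) new_markers * grid / plen else 0,
      stringsAsFactors = FALSE)
    detail[[step]] <- data.frame(
      ordinal = step, pool = pool_names[pool_i],
      contig_id = names(per_ctg),
      length = unname(nchar(contigs)),
      new_markers = unname(per_ctg),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "per_contig") <- do.call(rbind, detail)
  out
}

#' Assembly efficiency at length thresholds
#'
#' For each threshold T, the total length of contigs longer than T divided
#' by the pool's expected genomic content, `n * mean_insert`.
#'
#' @param contigs Named character vector, `DNAStringSet`, or numeric
#'   lengths.
#' @param thresholds Ascending length thresholds in bases
#'   (default `c(5000, 10000, 20000)`).
#' @param n Clones in the pool.
#' @param mean_insert Mean insert length in bases (default 40000).
#' @return A `data.frame`: `threshold`, `total_length`, `efficiency`.
#' @export
#' @examples
#' assembly_efficiency(c(6000, 4000, 12000), 5000, n = 1, mean_insert = 40000)
assembly_efficiency <- function(contigs, thresholds = c(5000, 10000, 20000),
                                n, mean_insert = 40000) {
  check_positive(n = n, mean_insert = mean_insert)
  if (is.unsorted(thresholds)) {
    stop("`thresholds` must be sorted ascending", call. = FALSE)
  }
  lens <- if (is.numeric(contigs)) contigs else nchar(as_seq_vector(contigs))
  expected <- n * mean_insert
  data.frame(threshold = thresholds,
             total_length = vapply(thresholds,
                                   function(t) sum(as.numeric(lens[lens > t])), 0),
             efficiency = vapply(thresholds,
                                 function(t) sum(as.numeric(lens[lens > t])), 0) / expected)
}

#' Per-contig mean read depth from alignment hits
#'
#' Mean depth along each contig: aligned bases (sum of subject spans of all
#' read hits to the contig) divided by contig length.
#'
#' @param hits Read-to-contig hits from [local_align()] (contigs as
#'   subjects).
#' @param contig_lengths Named lengths or sequences.
#' @return Named numeric vector of mean depths (0 for contigs without hits).
#' @export
contig_mean_depth <- function(hits, contig_lengths) {
  if (is.character(contig_lengths)) {
    contig_lengths <- setNames(nchar(contig_lengths), names(contig_lengths))
  }
  spans <- pmax(hits$sstart, hits$send) - pmin(hits$sstart, hits$send) + 1
  agg <- tapply(as.numeric(spans), hits$sseqid, sum)
  out <- setNames(rep(0, length(contig_lengths)), names(contig_lengths))
  out[names(agg)] <- agg
  out / contig_lengths
}

#' Fraction of contigs at or above depth thresholds
#'
#' @param per_contig_mean_depth Numeric vector of mean depths.
#' @param depth_thresholds Fold-coverage thresholds (default `c(5, 10, 20)`).
#' @return A `data.frame`: `threshold`, `fraction`.
#' @export
#' @examples
#' coverage_distribution(c(5, 15), 10)
coverage_distribution <- function(per_contig_mean_depth,
                                  depth_thresholds = c(5, 10, 20)) {
  if (length(per_contig_mean_depth) == 0) stop("empty input", call. = FALSE)
  if (any(per_contig_mean_depth < 0)) stop("depths must be >= 0", call. = FALSE)
  data.frame(threshold = depth_thresholds,
             fraction = vapply(depth_thresholds,
                               function(c) mean(per_contig_mean_depth >= c), 0))
}
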