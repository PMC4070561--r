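# Closed-form pool-design models: within-pool overlap probabilities, pool
# sequencing depth and Lander-Waterman novelty expectations.

#' Probability that two fosmid inserts from one pool overlap
#'
#' Two fragments of length `L` placed independently and uniformly on a linear
#' genome of length `G` share at least one base with probability
#' `(2L - 1) / G` (edge effects ignored, valid for `G >> L`); the value is
#' capped at 1.
#'
#' @param L Insert length in bases (`0 < L < G`).
#' @param G Genome size in bases.
#' @return Overlap probability in `[0, 1]`.
#' @export
#' @examples
#' pairwise_overlap_probability(40000, 2e10)
pairwise_overlap_probability <- function(L, G) {
  check_positive(L = L, G = G)
  if (L >= G) stop("`L` must be smaller than `G`", call. = FALSE)
  min(1, (2 * L - 1) / G)
}

#' Probability of at least one insert overlap within a pool
#'
#' Under independent uniform placement of `n` inserts, `per_fosmid` mode
#' returns the probability that one given fosmid overlaps any of the other
#' `n - 1`, `1 - (1 - p)^(n - 1)`; `any_pair` mode returns the probability
#' that any of the `n (n - 1) / 2` pairs overlap, `1 - (1 - p)^(n (n - 1) / 2)`,
#' with `p = pairwise_overlap_probability(L, G)`. At production-scale
#' parameters (1000 fosmids of 40 kb on a 20 Gb genome) the per-fosmid
#' probability is of order 1e-3.
#'
#' @param n Number of fosmids in the pool (>= 1).
#' @param L Insert length in bases.
#' @param G Genome size in bases.
#' @param mode `"per_fosmid"` (default) or `"any_pair"`.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' pool_overlap_probability(1000, 40000, 2e10)
#' order_of_magnitude(pool_overlap_probability(1000, 40000, 2e10))  # -3
pool_overlap_probability <- function(n, L, G, mode = c("per_fosmid", "any_pair")) {
  mode <- match.arg(mode)
  check_positive(n = n)
  if (n %% 1 != 0) stop("`n` must be an integer count", call. = FALSE)
  p <- pairwise_overlap_probability(L, G)
  k <- if (mode == "per_fosmid") n - 1 else n * (n - 1) / 2
  min(1, 1 - (1 - p)^k)
}

#' Order of magnitude of a probability
#'
#' `floor(log10(p))`, used to state order-of-magnitude claims
#' machine-checkably.
#'
#' @param p Probability, strictly positive.
#' @return Integer exponent.
#' @export
order_of_magnitude <- function(p) {
  check_positive(p = p)
  as.integer(floor(log10(p)))
}

#' Expected sequencing depth of a fosmid pool
#'
#' Sequenced bases divided by the pool's total clone length
#' `n * (insert_length + vector_length)`. The vector is part of every clone
#' circle and is sequenced alongside the insert, so it belongs in the
#' denominator.
#'
#' @param sequenced_bases Total sequenced bases allocated to the pool.
#' @param n Number of fosmids in the pool.
#' @param insert_length Nominal insert length in bases (default 40000).
#' @param vector_length Vector length in bases (default 8000).
#' @return Fold-coverage.
#' @export
#' @examples
#' expected_pool_depth(3e9, 1000, 40000, 8000)  # 62.5
expected_pool_depth <- function(sequenced_bases, n, insert_length = 40000,
                                vector_length = 8000) {
  check_positive(sequenced_bases = sequenced_bases, n = n,
                 insert_length = insert_length)
  if (!is.numeric(vector_length) || length(vector_length) != 1 ||
      is.na(vector_length) || vector_length < 0) {
    stop("`vector_length` must be a single non-negative number", call. = FALSE)
  }
  denom <- n * (insert_length + vector_length)
  if (denom <= 0) stop("zero pool content", call. = FALSE)
  sequenced_bases / denom
}

#' Expected novel fraction of a new fragment under uniform sampling
#'
#' Lander-Waterman expectation: after `total_sampled` bases have been drawn
#' uniformly from a genome of size `G`, the expected fraction of a new
#' fragment that is not already covered is `exp(-total_sampled / G)`.
#'
#' @param total_sampled Cumulative sampled bases (>= 0).
#' @param G Genome size in bases.
#' @return Fraction in `(0, 1]`.
#' @export
#' @examples
#' novel_fraction(4e10, 2e10)  # e^-2
novel_fraction <- function(total_sampled, G) {
  check_positive(G = G)
  if (!is.numeric(total_sampled) || length(total_sampled) != 1 ||
      is.na(total_sampled) || total_sampled < 0) {
    stop("`total_sampled` must be a single non-negative number", call. = FALSE)
  }
  exp(-total_sampled / G)
}

#' Pool design report
#'
#' Evaluates the closed-form design models at one parameter set and returns a
#' long-format table (quantity, value) suitable for TSV export: the pairwise
#' and pool-level overlap probabilities, the order of magnitude of the
#' latter, the pool depth implied by `sequenced_bases` (or, when absent, the
#' bases required to reach `target_depth`), and the expected novel fraction
#' of a new insert after one pool has been sampled.
#'
#' @param genome_size Genome size `G` in bases.
#' @param insert_length Insert length `L` in bases (default 40000).
#' @param pool_size Fosmids per pool `n` (default 1000).
#' @param vector_length Vector length in bases (default 8000).
#' @param target_depth Target fold-coverage (default 75).
#' @param sequenced_bases Optional sequenced bases actually allocated.
#' @return A `data.frame` with columns `quantity` and `value`.
#' @export
#' @examples
#' design_report(2e10)
design_report <- function(genome_size, insert_length = 40000, pool_size = 1000,
                          vector_length = 8000, target_depth = 75,
                          sequenced_bases = NULL) {
  p_pair <- pairwise_overlap_probability(insert_length, genome_size)
  p_pool <- pool_overlap_probability(pool_size, insert_length, genome_size)
  rows <- list(
    c("pairwise_overlap_probability", p_pair),
    c("pool_overlap_probability_per_fosmid", p_pool),
    c("pool_overlap_order_of_magnitude", order_of_magnitude(p_pool))
  )
  if (!is.null(sequenced_bases)) {
    rows <- c(rows, list(c("expected_pool_depth",
      expected_pool_depth(sequenced_bases, pool_size, insert_length,
                          vector_length))))
  } else {
    rows <- c(rows, list(c("required_sequenced_bases",
      target_depth * pool_size * (insert_length + vector_length))))
  }
  rows <- c(rows, list(c("novel_fraction_after_one_pool",
    novel_fraction(pool_size * insert_length, genome_size))))
  data.frame(quantity = vapply(rows, `[`, "", 1),
             value = as.numeric(vapply(rows, `[`, "", 2)),
             stringsAsFactors = FALSE)
}
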