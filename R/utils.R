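# Shared helpers: seed scoping, sequence coercion, interval arithmetic and
# percentage formatting used by the report code paths.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so generators are pure functions of their inputs and
#' seed without clobbering the caller's random stream. A `NULL` seed evaluates
#' `expr` against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases over {A, C, G, T}, drawn from the R random stream.
#'
#' @param n Sequence length in bases.
#' @param seed Optional integer seed; when given, the global RNG state is
#'   left untouched.
#' @return A single character string of length `n`.
#' @export
#' @examples
#' random_dna(20, seed = 1)
random_dna <- function(n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, is.finite(n), n >= 0)
  local_seed(seed, random_dna_cpp(as.integer(n)))
}

#' Reverse complement of character sequences
#'
#' @param seqs Character vector of DNA sequences.
#' @return Character vector of reverse complements (names preserved).
#' @export
reverse_complement <- function(seqs) {
  out <- revcomp_cpp(as.character(seqs))
  names(out) <- names(seqs)
  out
}

# Coerce DNAStringSet / character to a named character vector of sequences.
as_seq_vector <- function(x, prefix = "seq") {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else {
    x <- unlist(x, use.names = TRUE)
    nm <- names(x)
    out <- as.character(x)
    names(out) <- nm
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    names(out) <- sprintf("%s%d", prefix, seq_along(out))
  }
  out
}

# Total length of a union of 1-based inclusive intervals (two column matrix
# or data.frame with start <= end).
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0L
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Percentage formatting used by the QC reports
#'
#' Computes `100 * x / n` rounded to `digits` decimals, the convention used
#' throughout the summary tables (e.g. proper-contig rates, clone-count
#' recovery ratios).
#'
#' @param x Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places to keep (default 1).
#' @return Numeric percentage.
#' @export
#' @examples
#' percent(83855, 1071614)  # 7.8
#' percent(1516, 1694)      # 89.5
percent <- function(x, n, digits = 1) {
  stopifnot(n > 0)
  round(100 * x / n, digits)
}

check_positive <- function(..., .finite = TRUE) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        (.finite && !is.finite(v)) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
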