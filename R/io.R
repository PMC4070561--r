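# File-format boundaries: FASTA/FASTQ via Biostrings, truth annotations as
# BED-style TSV. These are the only places that translate between the
# package's 0-based half-open coordinates and on-disk conventions.

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector (names truncated at the first whitespace).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_seq_vector(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a read set as paired FASTQ files
#'
#' Two files, `<prefix>_1.fastq` and `<prefix>_2.fastq`, with `/1` and `/2`
#' read-id suffixes and constant quality (the set's `quality_char`).
#'
#' @param reads A `read_set`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_reads_fastq <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_set"))
  q <- attr(reads, "quality_char")
  if (is.null(q)) q <- "I"
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("read", m)]])
    names(seqs) <- paste0(reads$id, "/", m)
    quals <- Biostrings::BStringSet(strrep(q, Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, paths[m], format = "fastq",
                                qualities = quals)
  }
  invisible(paths)
}

#' Read paired FASTQ files as a read set
#'
#' @param path1,path2 Mate-1 and mate-2 FASTQ files (matching order).
#' @return A `read_set` data.frame (labels set to `NA`).
#' @export
read_reads_fastq <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2)) stop("mate files differ in length", call. = FALSE)
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  out <- data.frame(id = ids, read1 = as.character(r1),
                    read2 = as.character(r2), label = NA_character_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("read_set", "data.frame"),
            read_length = max(nchar(out$read1)), quality_char = "I")
}

#' Write planted-repeat truth annotations as BED
#'
#' BED6+1: chrom, start, end (0-based half-open), repeat id, score 0,
#' strand, realised percent identity.
#'
#' @param genome A `synthetic_genome`.
#' @param path Output path.
#' @param chrom Chromosome name used in column 1.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(genome, path, chrom = "genome") {
  tr <- genome$truth_repeats
  if (nrow(tr) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(chrom = chrom, start = tr$start, end = tr$end,
                   name = tr$repeat_id, score = 0, strand = tr$strand,
                   identity = sprintf("%.6f", tr$identity))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read repeat truth annotations from BED
#'
#' @param path BED file from [write_repeat_bed()].
#' @return Data frame with `start`, `end`, `repeat_id`, `identity`, `strand`.
#' @export
read_repeat_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop("expected BED6+1 with an identity column", call. = FALSE)
  data.frame(start = as.integer(df[[2]]), end = as.integer(df[[3]]),
             repeat_id = df[[4]], identity = as.numeric(df[[7]]),
             strand = df[[6]], stringsAsFactors = FALSE)
}

#' Write fosmid insert coordinates as BED
#'
#' @param pool A `fosmid_pool`.
#' @param path Output path.
#' @param chrom Chromosome name used in column 1.
#' @return `path`, invisibly.
#' @export
write_insert_bed <- function(pool, path, chrom = "genome") {
  cl <- pool$clones
  df <- data.frame(chrom = chrom, start = cl$start, end = cl$end,
                   name = cl$clone_id, score = 0, strand = cl$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read fosmid insert coordinates from BED
#'
#' @param path BED file from [write_insert_bed()].
#' @return Data frame with `clone_id`, `start`, `end`, `strand`.
#' @export
read_insert_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(clone_id = df[[4]], start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), strand = df[[6]],
             stringsAsFactors = FALSE)
}
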