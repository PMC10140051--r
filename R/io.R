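# Sequence file IO: thin tibble-facing wrappers around Biostrings readers and
# writers. FASTA is written with a 60-column wrap, FASTQ as Phred+33.

#' Read a FASTA file into a tibble
#'
#' @param path File path.
#' @param type `"AA"` for protein, `"DNA"` for nucleotide.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "AA") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  tibble(
    id = sub("\\s.*$", "", names(x)),
    seq = as.character(x)
  )
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param x A tibble with `id` and `seq` columns (extra columns ignored), or a
#'   named character vector.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.data.frame(x)) {
    seqs <- setNames(x$seq, x$id)
  } else {
    seqs <- x
  }
  set <- if (type == "AA") {
    Biostrings::AAStringSet(seqs)
  } else {
    Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path File path.
#' @return A tibble with columns `id`, `seq` and `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A tibble with `id`, `seq`, `qual` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  set <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(
    set, path,
    format = "fastq",
    qualities = Biostrings::PhredQuality(reads$qual)
  )
  invisible(path)
}

#' Mean Phred score of quality strings
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return Numeric vector of per-read mean quality scores.
#' @export
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1), USE.NAMES = FALSE)
}
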