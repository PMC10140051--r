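# Six-frame ORF prediction with single-best-ORF reporting and completeness
# classification: the protein-prediction stage of the pipeline. "Best" means
# longest (with a fully deterministic tie-break); candidate ORFs are the
# maximal open reading frames of each frame and strand.

GENETIC_CODE_TABLE <- NULL

genetic_code <- function() {
  # cached standard-code lookup, codon -> single-letter aa ("*" = stop)
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# Translate the codons of one frame of one strand; returns the full aa vector
# including "*" for stops and "X" for codons containing ambiguous bases.
frame_codons <- function(seq, frame, strand) {
  s <- if (strand == "-") revcomp(seq) else seq
  L <- nchar(s)
  n_codons <- (L - frame) %/% 3
  if (n_codons < 1) return(character(0))
  starts <- frame + 1 + 3 * (0:(n_codons - 1))
  codons <- substring(s, starts, starts + 2)
  aa <- genetic_code()[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Translate a nucleotide sequence in a given frame and strand
#'
#' Standard genetic code; translation stops before the first stop codon;
#' codons containing ambiguous bases translate to `X`.
#'
#' @param nt Nucleotide string over A, C, G, T, N.
#' @param frame Frame offset 0, 1 or 2.
#' @param strand `"+"` or `"-"` (the reverse complement is translated).
#' @return An amino-acid string (possibly empty).
#' @export
translate_frame <- function(nt, frame = 0, strand = "+") {
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  aa <- frame_codons(nt, frame, strand)
  stop_at <- which(aa == "*")[1]
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1)]
  paste(aa, collapse = "")
}

#' Find candidate ORFs across six frames
#'
#' Enumerates the maximal open reading frames of every frame and strand. A
#' maximal ORF runs from the transcript edge (when no upstream in-frame stop
#' exists) or from the first methionine after the previous stop, to the next
#' stop codon or the transcript edge. Completeness: `complete` (starts with
#' M, ends at a stop), `5prime_partial` (edge start without M, stop present),
#' `3prime_partial` (M start, runs off the 3' end), `internal` (neither).
#'
#' Coordinates (`cds_start`, `cds_end`) are 0-based half-open on the
#' *reported strand*; for `-` strand ORFs the forward-strand interval is
#' `(L - cds_end, L - cds_start)` with `L` the transcript length. `cds_end`
#' includes the stop codon when present.
#'
#' @param seq Nucleotide string.
#' @param min_aa Minimum protein length in residues (default 100).
#' @return A tibble with one row per candidate ORF: `aa_seq`, `aa_len`,
#'   `completeness`, `strand`, `frame`, `cds_start`, `cds_end`.
#' @export
find_orfs <- function(seq, min_aa = 100) {
  out <- list()
  for (strand in c("+", "-")) {
    for (frame in 0:2) {
      aa <- frame_codons(seq, frame, strand)
      n_codons <- length(aa)
      if (n_codons < min_aa) next
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)
      seg_end <- c(stops - 1L, n_codons)
      for (k in seq_along(seg_start)) {
        cs <- seg_start[k]
        ce <- seg_end[k]
        if (ce < cs) next
        at_edge <- cs == 1L
        if (at_edge) {
          orf_start <- cs
          has_start <- aa[1] == "M"
        } else {
          m <- which(aa[cs:ce] == "M")[1]
          if (is.na(m)) next
          orf_start <- cs + m - 1L
          has_start <- TRUE
        }
        has_stop <- ce < n_codons
        len <- ce - orf_start + 1L
        if (len < min_aa) next
        completeness <- if (has_start && has_stop) {
          "complete"
        } else if (!has_start && has_stop) {
          "5prime_partial"
        } else if (has_start && !has_stop) {
          "3prime_partial"
        } else {
          "internal"
        }
        out[[length(out) + 1]] <- tibble(
          aa_seq = paste(aa[orf_start:ce], collapse = ""),
          aa_len = len,
          completeness = completeness,
          strand = strand,
          frame = frame,
          cds_start = frame + 3L * (orf_start - 1L),
          cds_end = frame + 3L * ce + if (has_stop) 3L else 0L
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(
      aa_seq = character(), aa_len = integer(), completeness = character(),
      strand = character(), frame = integer(), cds_start = integer(),
      cds_end = integer()
    ))
  }
  list_rbind(out)
}

#' Single best ORF of a transcript
#'
#' The longest candidate ORF; ties broken deterministically by strand (`+`
#' before `-`), then lowest frame, then smallest `cds_start`.
#'
#' @inheritParams find_orfs
#' @return A one-row tibble (columns as [find_orfs()]) or a zero-row tibble
#'   when no ORF reaches `min_aa`.
#' @export
best_orf <- function(seq, min_aa = 100) {
  orfs <- find_orfs(seq, min_aa)
  if (nrow(orfs) == 0) return(orfs)
  orfs |>
    arrange(
      desc(.data$aa_len), factor(.data$strand, c("+", "-")),
      .data$frame, .data$cds_start
    ) |>
    slice(1)
}

#' Predict a proteome from a set of transcripts
#'
#' Applies [best_orf()] to every transcript and summarises the coding and
#' completeness fractions (percentages formatted to one decimal,
#' half-up, matching the usual assembly-report convention).
#'
#' @param transcripts A tibble with `id`, `seq` and optionally `species`
#'   columns.
#' @param min_aa Minimum protein length (default 100).
#' @return A tibble of class `predicted_proteome`: one row per transcript
#'   with an ORF (`id` = transcript id + ".p1", `transcript_id`, `species`,
#'   `aa_seq`, `aa_len`, `completeness`, `strand`, `frame`, `cds_start`,
#'   `cds_end`). The summary is available via [glance()].
#' @export
predict_proteome <- function(transcripts, min_aa = 100) {
  species <- transcripts$species %||% rep(NA_character_, nrow(transcripts))
  rows <- map(seq_len(nrow(transcripts)), function(i) {
    orf <- best_orf(transcripts$seq[i], min_aa)
    if (nrow(orf) == 0) return(NULL)
    mutate(orf,
      id = paste0(transcripts$id[i], ".p1"),
      transcript_id = transcripts$id[i],
      species = species[i],
      .before = 1
    )
  })
  proteins <- list_rbind(compact_null(rows))
  n_tr <- nrow(transcripts)
  n_coding <- nrow(proteins)
  n_complete <- sum(proteins$completeness == "complete")
  summary <- tibble(
    n_transcripts = n_tr,
    n_coding = n_coding,
    pct_coding = if (n_tr > 0) pct_round(n_coding, n_tr) else NA_real_,
    n_complete = n_complete,
    pct_complete = if (n_coding > 0) pct_round(n_complete, n_coding) else NA_real_
  )
  attr(proteins, "summary") <- summary
  class(proteins) <- c("predicted_proteome", class(proteins))
  proteins
}

compact_null <- function(x) x[!vapply(x, is.null, logical(1))]

#' @export
glance.predicted_proteome <- function(x, ...) attr(x, "summary")
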