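# Assembly-level quality statistics: transcript counts, length extremes,
# Nxx values, GC content, and a homology-based core-gene completeness
# summary (a BUSCO-style measure, not BUSCO itself).

#' Nxx assembly statistic
#'
#' The length L such that contigs of length >= L (taken in descending length
#' order) together contain at least `fraction` of the total assembled bases.
#' `nxx(lengths, 0.5)` is the familiar N50. Ties follow the standard Trinity
#' convention: the contig whose inclusion first reaches the threshold
#' supplies the value.
#'
#' @param lengths Positive integer vector of contig lengths.
#' @param fraction Fraction of total bases in (0, 1].
#' @return The Nxx length (same units as `lengths`).
#' @export
nxx <- function(lengths, fraction = 0.5) {
  if (length(lengths) == 0) abort("no sequences")
  stopifnot(all(lengths > 0), fraction > 0, fraction <= 1)
  srt <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(srt))
  srt[which(cum >= fraction * cum[length(cum)])[1]]
}

#' GC content of nucleotide sequences
#'
#' Percent of unambiguous bases (A, C, G, T) that are G or C; ambiguous
#' bases (N etc.) are excluded from the denominator so undefined composition
#' does not dilute the statistic.
#'
#' @param seqs Character vector of nucleotide sequences (or a tibble with a
#'   `seq` column).
#' @return GC percentage in 0 to 100.
#' @export
gc_content <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  set <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::letterFrequency(set, c("A", "C", "G", "T"))
  tot <- colSums(f)
  100 * (tot[["C"]] + tot[["G"]]) / sum(tot)
}

#' Assembly summary statistics
#'
#' @param transcripts A tibble with `id` and `seq` columns (one transcript
#'   per row; duplicates counted separately).
#' @return A one-row tibble of class `assembly_stats`: `n_transcripts`,
#'   `total_bases`, `min_len`, `max_len`, `n25`, `n50`, `n75`, `gc_percent`.
#' @export
assembly_stats <- function(transcripts) {
  if (nrow(transcripts) == 0) abort("no sequences")
  lens <- nchar(transcripts$seq)
  out <- tibble(
    n_transcripts = nrow(transcripts),
    total_bases = sum(lens),
    min_len = min(lens),
    max_len = max(lens),
    n25 = nxx(lens, 0.25),
    n50 = nxx(lens, 0.50),
    n75 = nxx(lens, 0.75),
    gc_percent = gc_content(transcripts$seq)
  )
  class(out) <- c("assembly_stats", class(out))
  out
}

#' Core-gene completeness of a predicted proteome
#'
#' A homology-based stand-in for a BUSCO-style completeness assessment: each
#' core-panel protein is searched against the proteome; it is *complete*
#' when the best hit at E <= `e_max` covers at least `min_coverage` of the
#' core protein length, *fragmented* when a qualifying hit covers less, and
#' *missing* otherwise. Thresholds are a documented convention, not
#' equivalent to BUSCO's internal model.
#'
#' @param proteome A tibble with `id` and `aa_seq` columns (may be empty:
#'   everything is then missing).
#' @param core_panel A non-empty tibble with `id` and `aa_seq` columns.
#' @param params A [scoring_params()] object.
#' @param e_max E-value cutoff for a qualifying hit (default 1e-10).
#' @param min_coverage Fraction of the core protein that must be aligned for
#'   a complete call (default 0.9).
#' @return A one-row tibble of class `core_completeness` with counts and
#'   percents; the per-gene classification is in `attr(, "detail")`.
#' @export
core_completeness <- function(proteome, core_panel, params = scoring_params(),
                              e_max = 1e-10, min_coverage = 0.9) {
  if (nrow(core_panel) == 0) abort("empty core panel")
  detail <- map(seq_len(nrow(core_panel)), function(i) {
    hit <- homology_search(core_panel$aa_seq[i], proteome, params,
      e_max = e_max, query_id = core_panel$id[i]
    )
    if (nrow(hit) == 0) {
      tibble(
        core_id = core_panel$id[i], status = "missing",
        best_hit = NA_character_, coverage = NA_real_
      )
    } else {
      tibble(
        core_id = core_panel$id[i],
        status = if (hit$q_coverage >= min_coverage) "complete" else "fragmented",
        best_hit = hit$subject_id,
        coverage = hit$q_coverage
      )
    }
  }) |> list_rbind()
  n <- nrow(core_panel)
  counts <- table(factor(detail$status, c("complete", "fragmented", "missing")))
  out <- tibble(
    n_core = n,
    complete = as.integer(counts[["complete"]]),
    fragmented = as.integer(counts[["fragmented"]]),
    missing = as.integer(counts[["missing"]]),
    pct_complete = pct_round(counts[["complete"]], n),
    pct_fragmented = pct_round(counts[["fragmented"]], n),
    pct_missing = pct_round(counts[["missing"]], n)
  )
  attr(out, "detail") <- detail
  class(out) <- c("core_completeness", class(out))
  out
}
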