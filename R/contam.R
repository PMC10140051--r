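# Read cleaning and contamination screening: Phred/length read filters, a
# k-mer classifier against a COI "species filter" marker panel, marker-based
# species confirmation, and an rRNA foreign-sequence screen.

#' Clean sequencing reads
#'
#' Trims the first `trim` bases from every read, then drops reads shorter
#' than `min_len` or with mean Phred quality below `min_phred` (trimming
#' first, filters second).
#'
#' @param reads A tibble with `id`, `seq`, `qual` (Phred+33) columns.
#' @param trim Bases removed from the 5' end (default 12).
#' @param min_len Minimum retained length after trimming (default 50).
#' @param min_phred Minimum mean Phred score (default 30).
#' @return The filtered read tibble.
#' @export
clean_reads <- function(reads, trim = 12, min_len = 50, min_phred = 30) {
  out <- reads |>
    mutate(
      seq = substr(.data$seq, trim + 1, nchar(.data$seq)),
      qual = substr(.data$qual, trim + 1, nchar(.data$qual))
    ) |>
    filter(nchar(.data$seq) >= min_len)
  out[mean_phred(out$qual) >= min_phred, ]
}

all_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

#' Assign reads to marker-panel species by k-mer matching
#'
#' Each read is assigned to the panel species sharing the most k-mers with
#' it (either strand of the markers is indexed); assignment requires at
#' least `min_hits` shared k-mers and a unique best species, otherwise the
#' read is unassigned. A deterministic alignment-free stand-in for mapping
#' reads against an artificial COI reference.
#'
#' @param reads A tibble with `id`, `seq` columns.
#' @param panel A tibble with `species`, `seq` marker columns (unique
#'   labels, non-empty sequences).
#' @param k k-mer size (default 21).
#' @param min_hits Minimum shared k-mers for assignment (default 3).
#' @return A `contamination_report` list: `per_species` tibble (`species`,
#'   `n_reads`, `frac_assigned`, `frac_total`), `n_assigned`,
#'   `n_unassigned`, `n_total`.
#' @export
assign_reads <- function(reads, panel, k = 21, min_hits = 3) {
  stopifnot(!anyDuplicated(panel$species), all(nchar(panel$seq) > 0))
  index <- map(seq_len(nrow(panel)), function(i) {
    mk <- unique(c(
      all_kmers(panel$seq[i], k),
      all_kmers(revcomp(panel$seq[i]), k)
    ))
    tibble(kmer = mk, species = panel$species[i])
  }) |> list_rbind()

  n <- nrow(reads)
  assigned <- rep(NA_character_, n)
  if (n > 0) {
    read_kmers <- map(reads$seq, all_kmers, k = k)
    lens <- lengths(read_kmers)
    long <- tibble(
      read = rep(seq_len(n), lens),
      kmer = unlist(read_kmers)
    )
    hits <- inner_join(long, index, by = "kmer",
      relationship = "many-to-many"
    )
    if (nrow(hits) > 0) {
      counts <- hits |>
        count(.data$read, .data$species, name = "n_kmers") |>
        group_by(.data$read) |>
        arrange(desc(.data$n_kmers), .by_group = TRUE) |>
        summarise(
          best = .data$species[1],
          best_n = .data$n_kmers[1],
          tie = n() > 1 && .data$n_kmers[2] == .data$n_kmers[1]
        )
      ok <- counts$best_n >= min_hits & !counts$tie
      assigned[counts$read[ok]] <- counts$best[ok]
    }
  }
  per_species <- tibble(species = panel$species) |>
    mutate(
      n_reads = map_int(.data$species, function(s) sum(assigned %in% s)),
      frac_assigned = if (sum(!is.na(assigned)) > 0) {
        .data$n_reads / sum(!is.na(assigned))
      } else {
        NA_real_
      },
      frac_total = if (n > 0) .data$n_reads / n else NA_real_
    )
  structure(
    list(
      per_species = per_species,
      n_assigned = sum(!is.na(assigned)),
      n_unassigned = sum(is.na(assigned)),
      n_total = n,
      assignments = tibble(id = reads$id, species = assigned)
    ),
    class = "contamination_report"
  )
}

#' Foreign-read fraction of a contamination report
#'
#' @param report A `contamination_report`.
#' @param native_species Label(s) of the expected (native) species.
#' @return Fraction of all reads attracted to non-native markers.
#' @export
contamination_fraction <- function(report, native_species) {
  foreign <- report$per_species |>
    filter(!.data$species %in% native_species)
  sum(foreign$n_reads) / report$n_total
}

#' @export
print.contamination_report <- function(x, ...) {
  cat(sprintf(
    "Contamination report: %d reads, %d assigned, %d unassigned\n",
    x$n_total, x$n_assigned, x$n_unassigned
  ))
  print(x$per_species)
  invisible(x)
}

#' @export
tidy.contamination_report <- function(x, ...) x$per_species

#' @export
glance.contamination_report <- function(x, ...) {
  tibble(
    n_total = x$n_total, n_assigned = x$n_assigned,
    n_unassigned = x$n_unassigned
  )
}

# Nucleotide local alignment identity (match +2 / mismatch -3, gap 5/2).
nt_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
    baseOnly = TRUE
  )
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  list(
    pid = Biostrings::pid(pa),
    aln_len = BiocGenerics::end(Biostrings::pattern(pa)) -
      BiocGenerics::start(Biostrings::pattern(pa)) + 1L,
    score = BiocGenerics::score(pa)
  )
}

#' Confirm species identity from an assembled marker sequence
#'
#' Aligns the assembly's marker (COI-like) sequence against a reference
#' marker set; the check passes when the best-matching reference species is
#' the expected one with identity above `min_identity` percent.
#'
#' @param marker_seq Assembled marker nucleotide sequence.
#' @param expected_species Label the assembly is supposed to be.
#' @param reference_db A non-empty tibble with `species`, `seq` columns.
#' @param min_identity Percent-identity requirement (default 97).
#' @return A one-row tibble: `best_species`, `pct_identity`, `pass`.
#' @export
confirm_species <- function(marker_seq, expected_species, reference_db,
                            min_identity = 97) {
  if (nrow(reference_db) == 0) abort("no references")
  res <- map(seq_len(nrow(reference_db)), function(i) {
    al <- nt_identity(marker_seq, reference_db$seq[i])
    tibble(
      species = reference_db$species[i], pct_identity = al$pid,
      score = al$score
    )
  }) |> list_rbind()
  best <- res |> arrange(desc(.data$score), .data$species) |> slice(1)
  tibble(
    best_species = best$species,
    pct_identity = best$pct_identity,
    pass = best$species == expected_species & best$pct_identity > min_identity
  )
}

#' Screen an assembly for foreign rRNA-like sequences
#'
#' Reports assembly sequences that align to any rRNA reference (native or
#' foreign) over at least `min_len` aligned bases at `min_pid_hit` percent
#' identity or better; among those, sequences whose identity to the
#' *native* reference is at or below `max_native_identity` percent are
#' flagged as candidate foreign rRNA.
#'
#' @param assembly A tibble with `id`, `seq` columns.
#' @param native_rrna_ref Native rRNA reference sequence (string).
#' @param foreign_refs Optional character vector of foreign rRNA references.
#' @param max_native_identity Flagging threshold on identity to the native
#'   reference (default 93, "low 90s or below").
#' @param min_len Minimum aligned length to count as rRNA-like (default 100).
#' @param min_pid_hit Minimum identity to any reference to count as
#'   rRNA-like (default 80).
#' @return A tibble of flagged-or-reported sequences: `id`, `pid_native`,
#'   `flagged_foreign`.
#' @export
rrna_screen <- function(assembly, native_rrna_ref, foreign_refs = character(0),
                        max_native_identity = 93, min_len = 100,
                        min_pid_hit = 80) {
  refs <- c(native_rrna_ref, foreign_refs)
  rows <- map(seq_len(nrow(assembly)), function(i) {
    is_rrna <- FALSE
    for (r in refs) {
      al <- nt_identity(assembly$seq[i], r)
      if (al$aln_len >= min_len && al$pid >= min_pid_hit) {
        is_rrna <- TRUE
        break
      }
    }
    if (!is_rrna) return(NULL)
    nat <- nt_identity(assembly$seq[i], native_rrna_ref)
    pid_native <- if (nat$aln_len >= min_len) nat$pid else 0
    tibble(
      id = assembly$id[i],
      pid_native = pid_native,
      flagged_foreign = pid_native <= max_native_identity
    )
  })
  found <- compact_null(rows)
  if (length(found) == 0) {
    return(tibble(
      id = character(), pid_native = numeric(), flagged_foreign = logical()
    ))
  }
  list_rbind(found)
}
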