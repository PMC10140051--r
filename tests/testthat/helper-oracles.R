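# Independent oracles and fixture builders used across the suite.

# Brute-force Nxx: walk the sorted lengths accumulating until the fraction
# of total bases is reached.
oracle_nxx <- function(lengths, fraction) {
  srt <- sort(lengths, decreasing = TRUE)
  target <- fraction * sum(lengths)
  acc <- 0
  for (l in srt) {
    acc <- acc + l
    if (acc >= target) return(l)
  }
  srt[length(srt)]
}

# Brute-force six-frame ORF enumeration, built on Biostrings translation and
# regex segmentation rather than the package's codon-index arithmetic.
# Returns maximal ORFs (aa_seq, completeness, strand, frame) >= min_aa.
oracle_orfs <- function(seq, min_aa = 100) {
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    } else {
      seq
    }
    for (frame in 0:2) {
      n_codons <- (nchar(s) - frame) %/% 3
      if (n_codons < 1) next
      sub <- substr(s, frame + 1, frame + 3 * n_codons)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub),
        if.fuzzy.codon = "X", no.init.codon = TRUE
      ))
      # segment positions between stops
      stop_pos <- as.integer(gregexpr("\\*", aa)[[1]])
      has_stops <- stop_pos[1] != -1
      bounds <- if (has_stops) stop_pos else integer(0)
      seg_start <- c(1L, bounds + 1L)
      seg_end <- c(bounds - 1L, nchar(aa))
      for (k in seq_along(seg_start)) {
        if (seg_end[k] < seg_start[k]) next
        segment <- substr(aa, seg_start[k], seg_end[k])
        at_edge <- seg_start[k] == 1L
        terminated <- seg_end[k] < nchar(aa)
        if (at_edge) {
          orf <- segment
          has_start <- substr(segment, 1, 1) == "M"
        } else {
          m <- regexpr("M", segment, fixed = TRUE)
          if (m == -1) next
          orf <- substr(segment, m, nchar(segment))
          has_start <- TRUE
        }
        if (nchar(orf) < min_aa) next
        completeness <- if (has_start && terminated) {
          "complete"
        } else if (terminated) {
          "5prime_partial"
        } else if (has_start) {
          "3prime_partial"
        } else {
          "internal"
        }
        out[[length(out) + 1]] <- data.frame(
          aa_seq = orf, completeness = completeness,
          strand = strand, frame = frame
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      aa_seq = character(), completeness = character(),
      strand = character(), frame = integer()
    ))
  }
  do.call(rbind, out)
}

random_transcript <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_protein <- function(len, first_m = FALSE) {
  aas <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  s <- sample(aas, len, replace = TRUE)
  if (first_m) s[1] <- "M"
  paste(s, collapse = "")
}

# A transcript guaranteed to contain one complete ORF coding exactly `aa`.
transcript_for_protein <- function(aa, utr5 = 30, utr3 = 30) {
  codons <- split(names(Biostrings::GENETIC_CODE), unname(Biostrings::GENETIC_CODE))
  cds <- paste(vapply(strsplit(aa, "")[[1]], function(a) codons[[a]][1], ""),
    collapse = ""
  )
  paste0(
    paste0(random_transcript(max(utr5 - 3, 0)), "TAA"),
    cds, "TAA", random_transcript(utr3)
  )
}

# Small per-category proteome databases from a simulated dataset.
category_dbs <- function(dataset) {
  category_databases(dataset$proteomes, dataset$tree)
}

# Truth-based family label per protein id (clustering oracle).
truth_family_labels <- function(dataset) {
  stats::setNames(dataset$proteomes$family_id, dataset$proteomes$id)
}
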