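# Pairwise protein homology: Smith-Waterman local alignment (affine gaps,
# BLOSUM62) scored on the Karlin-Altschul scale. This is the scoring layer
# under functional annotation, ortholog clustering, core-gene completeness
# and the taxonomic similarity scan.

#' Scoring parameters for protein homology searches
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul constants lambda and K used to convert raw
#' Smith-Waterman scores into bit scores and E-values. Defaults are the
#' standard gapped BLOSUM62 parameterisation (gap open 11, extend 1,
#' lambda 0.267, K 0.041).
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` ships) or an
#'   actual numeric matrix with amino-acid dimnames.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,K Karlin-Altschul constants (> 0).
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    stopifnot(matrix == "BLOSUM62")
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  stopifnot(is.matrix(matrix), lambda > 0, K > 0, gap_open > 0, gap_extend > 0)
  structure(
    list(
      matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
      lambda = lambda, K = K
    ),
    class = "scoring_params"
  )
}

#' Bit score from a raw alignment score
#'
#' S' = (lambda * S - ln K) / ln 2.
#'
#' @param raw_score Raw Smith-Waterman score(s).
#' @param params A [scoring_params()] object.
#' @return Numeric bit score(s).
#' @export
bitscore <- function(raw_score, params = scoring_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' E = m * n * 2^(-S') with S' the bit score, m the query length and n the
#' total residue count of the searched database. Floating underflow is
#' clamped at 1e-300 so that -log10(E) stays finite (capped at 300).
#'
#' @param raw_score Raw alignment score(s).
#' @param m Query length (residues).
#' @param n Database size (total residues).
#' @param params A [scoring_params()] object.
#' @return Numeric E-value(s), always > 0.
#' @export
evalue <- function(raw_score, m, n, params = scoring_params()) {
  e <- m * n * 2^(-bitscore(raw_score, params))
  pmax(e, 1e-300)
}

#' Similarity on the -log10(E-value) scale
#'
#' The taxonomic-scan similarity measure: -log10 of the best-hit E-value,
#' clamped to the interval 0 to 300.
#'
#' @param e E-value(s).
#' @return Similarity value(s) in 0 to 300.
#' @export
similarity_from_evalue <- function(e) {
  pmin(300, pmax(0, -log10(e)))
}

#' Local pairwise protein alignment
#'
#' Smith-Waterman local alignment with affine gap penalties. Exact O(mn)
#' dynamic programming with a deterministic traceback (via
#' `Biostrings::pairwiseAlignment`).
#'
#' @param query,subject Amino-acid strings.
#' @param params A [scoring_params()] object.
#' @return A one-row tibble: `raw_score`, `pct_identity` (percent identical
#'   aligned positions), `q_start`, `q_end`, `s_start`, `s_end` (1-based
#'   inclusive spans on query and subject).
#' @export
align_pair <- function(query, subject, params = scoring_params()) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  tibble(
    raw_score = BiocGenerics::score(pa),
    pct_identity = Biostrings::pid(pa),
    q_start = BiocGenerics::start(Biostrings::pattern(pa)),
    q_end = BiocGenerics::end(Biostrings::pattern(pa)),
    s_start = BiocGenerics::start(Biostrings::subject(pa)),
    s_end = BiocGenerics::end(Biostrings::subject(pa))
  )
}

# Vectorised raw local-alignment scores of one query against many subjects.
local_scores <- function(query, subjects, params = scoring_params()) {
  if (length(subjects) == 0) return(numeric(0))
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE
  )
}

#' Best-hit homology search of a protein database
#'
#' Scores the query against every database protein and reports the hit with
#' the lowest E-value (ties: higher raw score, then lexicographically first
#' subject id). The E-value is computed against the whole database size
#' (n = total residues).
#'
#' @param query Amino-acid string.
#' @param database A tibble with `id` and `aa_seq` columns, or a named
#'   character vector of protein sequences.
#' @param params A [scoring_params()] object.
#' @param e_max Report no hit when the best E-value exceeds this cutoff
#'   (default `Inf`: always report the best hit).
#' @param n_best Number of top hits to return (default 1).
#' @param query_id Optional query identifier carried into the result.
#' @return A tibble with up to `n_best` rows (zero rows when the database is
#'   empty or the best hit fails `e_max`): `query_id`, `subject_id`,
#'   `raw_score`, `bitscore`, `evalue`, `pct_identity`, spans, and
#'   `q_coverage` (aligned fraction of the query).
#' @export
homology_search <- function(query, database, params = scoring_params(),
                            e_max = Inf, n_best = 1, query_id = NA_character_) {
  db <- as_protein_db(database)
  empty <- tibble(
    query_id = character(), subject_id = character(), raw_score = numeric(),
    bitscore = numeric(), evalue = numeric(), pct_identity = numeric(),
    q_start = integer(), q_end = integer(), s_start = integer(),
    s_end = integer(), q_coverage = numeric()
  )
  if (nrow(db) == 0) return(empty)
  scores <- local_scores(query, setNames(db$aa_seq, db$id), params)
  ord <- order(-scores, db$id)
  take <- head(ord, n_best)
  m <- nchar(query)
  n_db <- sum(nchar(db$aa_seq))
  hits <- map(take, function(i) {
    aln <- align_pair(query, db$aa_seq[i], params)
    tibble(
      query_id = query_id,
      subject_id = db$id[i],
      raw_score = aln$raw_score,
      bitscore = bitscore(aln$raw_score, params),
      evalue = evalue(aln$raw_score, m, n_db, params),
      pct_identity = aln$pct_identity,
      q_start = aln$q_start, q_end = aln$q_end,
      s_start = aln$s_start, s_end = aln$s_end,
      q_coverage = (aln$q_end - aln$q_start + 1) / m
    )
  }) |> list_rbind()
  hits <- filter(hits, .data$evalue <= e_max)
  if (nrow(hits) == 0) empty else hits
}

# Accept either a tibble (id, aa_seq) or a named character vector.
as_protein_db <- function(database) {
  if (is.data.frame(database)) {
    stopifnot(all(c("id", "aa_seq") %in% names(database)))
    tibble(id = database$id, aa_seq = database$aa_seq)
  } else {
    tibble(id = names(database), aa_seq = unname(database))
  }
}
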