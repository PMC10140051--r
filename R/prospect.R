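# Bioprospecting for novel proteins: intersect non-annotated taxonomically
# homogeneous clusters with differential-expression lists, scan each
# candidate against per-category proteomes to build a -log10(E-value)
# similarity profile, call the phylogenetic point of emergence at the first
# sharp similarity drop, and corroborate it with the stem length of the
# high-similarity clade in a neighbor-joining tree of the top hits.

#' Intersect clusters with differential-expression lists
#'
#' A cluster is eco-responsive for a condition when any focal-species
#' member's transcript id appears in that condition's DEG list.
#'
#' @param clusters An `ortho_clusters` tibble.
#' @param deg_a,deg_b Character vectors of transcript ids.
#' @param focal Focal species label (default `"Nf"`).
#' @return A list: `a`, `b`, `both` (cluster subsets) and `counts` (one-row
#'   tibble `n_a`, `n_b`, `n_both`).
#' @export
eco_responsive_clusters <- function(clusters, deg_a, deg_b, focal = "Nf") {
  hit_list <- function(deg) {
    map_lgl(clusters$members, function(mem) {
      any(mem$species == focal & mem$transcript_id %in% deg)
    })
  }
  in_a <- hit_list(deg_a)
  in_b <- hit_list(deg_b)
  list(
    a = new_ortho_clusters(clusters[in_a, ]),
    b = new_ortho_clusters(clusters[in_b, ]),
    both = new_ortho_clusters(clusters[in_a & in_b, ]),
    counts = tibble(n_a = sum(in_a), n_b = sum(in_b), n_both = sum(in_a & in_b))
  )
}

#' Taxonomic similarity scan of a query protein
#'
#' Searches the query against one proteome per taxonomic category (ordered
#' nearest to farthest from the focal species) with no E-value cutoff and
#' records the best hit per category as similarity = -log10(E), capped at
#' 300 and floored at 0. Categories with no positive-scoring alignment (or
#' an empty database) are marked missing. The two best hits are kept so a
#' partial top hit can be substituted downstream when building the
#' cladogram.
#'
#' @param query Amino-acid string (a cluster representative).
#' @param category_databases Ordered named list: category label -> protein
#'   tibble (`id`, `aa_seq`).
#' @param params A [scoring_params()] object.
#' @param query_id Optional query identifier.
#' @return A tibble of class `similarity_profile`, one row per category in
#'   input order: `category`, `n_db`, `missing`, `best_evalue`,
#'   `similarity`, `top_hit_id`, `top_hit_score`, `top_hit_coverage`,
#'   `top_hit_seq`, `alt_hit_id`, `alt_hit_coverage`, `alt_hit_seq`.
#' @export
taxonomic_scan <- function(query, category_databases, params = scoring_params(),
                           query_id = NA_character_) {
  rows <- imap(category_databases, function(db, cat) {
    hits <- homology_search(query, db, params, e_max = Inf, n_best = 2,
      query_id = query_id
    )
    hits <- filter(hits, .data$raw_score > 0)
    if (nrow(hits) == 0) {
      return(tibble(
        category = cat, n_db = nrow(as_protein_db(db)), missing = TRUE,
        best_evalue = NA_real_, similarity = NA_real_,
        top_hit_id = NA_character_, top_hit_score = NA_real_,
        top_hit_coverage = NA_real_, top_hit_seq = NA_character_,
        alt_hit_id = NA_character_, alt_hit_coverage = NA_real_,
        alt_hit_seq = NA_character_
      ))
    }
    db_tbl <- as_protein_db(db)
    top <- hits[1, ]
    alt <- if (nrow(hits) > 1) hits[2, ] else NULL
    tibble(
      category = cat, n_db = nrow(db_tbl), missing = FALSE,
      best_evalue = top$evalue,
      similarity = similarity_from_evalue(top$evalue),
      top_hit_id = top$subject_id,
      top_hit_score = top$raw_score,
      top_hit_coverage = top$q_coverage,
      top_hit_seq = db_tbl$aa_seq[match(top$subject_id, db_tbl$id)],
      alt_hit_id = if (is.null(alt)) NA_character_ else alt$subject_id,
      alt_hit_coverage = if (is.null(alt)) NA_real_ else alt$q_coverage,
      alt_hit_seq = if (is.null(alt)) NA_character_ else db_tbl$aa_seq[match(alt$subject_id, db_tbl$id)]
    )
  }) |> list_rbind()
  attr(rows, "query_id") <- query_id
  class(rows) <- c("similarity_profile", class(rows))
  rows
}

#' Call the phylogenetic point of emergence from a similarity profile
#'
#' Scans adjacent category boundaries from nearest to farthest. The first
#' boundary where similarity drops by at least `delta_min` log units (a
#' missing next category counts as similarity 0), or beyond which every
#' farther category is missing, marks the emergence point at the nearer
#' side. Broadly conserved profiles with only gradual declines yield no
#' call.
#'
#' @param profile A `similarity_profile` tibble (>= 2 categories).
#' @param delta_min Minimum similarity drop in log10(E) units (default 25,
#'   the scale of adjacent-category differences seen for conserved,
#'   rapidly-evolving reference proteins).
#' @return An `emergence_call` object: `query_id`, `emergence_category`
#'   (label or `NA`), `emergence_index`, `delta`, `missing_beyond`.
#' @export
call_emergence <- function(profile, delta_min = 25) {
  k <- nrow(profile)
  if (k < 2) abort("similarity profile needs at least two categories")
  sims <- profile$similarity
  miss <- profile$missing
  call <- list(
    query_id = attr(profile, "query_id") %||% NA_character_,
    emergence_category = NA_character_, emergence_index = NA_integer_,
    delta = NA_real_, missing_beyond = FALSE
  )
  for (i in seq_len(k - 1)) {
    if (miss[i]) next
    rest_missing <- all(miss[(i + 1):k])
    nxt <- if (miss[i + 1]) 0 else sims[i + 1]
    drop <- sims[i] - nxt
    if (rest_missing || drop >= delta_min) {
      call$emergence_category <- profile$category[i]
      call$emergence_index <- i
      call$delta <- drop
      call$missing_beyond <- rest_missing
      break
    }
  }
  structure(call, class = "emergence_call")
}

#' @export
print.emergence_call <- function(x, ...) {
  cat("Emergence call for", x$query_id %||% "<query>", "\n")
  if (is.na(x$emergence_category)) {
    cat("  no emergence boundary (broadly conserved profile)\n")
  } else {
    cat(
      "  emergence at:", x$emergence_category,
      sprintf("(delta %.1f log units%s)\n", x$delta,
        if (x$missing_beyond) ", no hits beyond" else ""
      )
    )
  }
  invisible(x)
}

#' @export
tidy.emergence_call <- function(x, ...) {
  tibble(
    query_id = x$query_id,
    emergence_category = x$emergence_category,
    emergence_index = x$emergence_index,
    delta = x$delta,
    missing_beyond = x$missing_beyond
  )
}

#' Poisson-corrected protein distance matrix
#'
#' Global pairwise alignment of every sequence pair; p is the proportion of
#' differing aligned positions (gapped columns excluded) and the distance is
#' d = -ln(1 - p). p is clamped below 1 so distances stay finite; saturated
#' pairs get the ceiling distance.
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param params A [scoring_params()] object (matrix and gap penalties are
#'   reused for the global alignment).
#' @param p_max Clamp on p (default 0.999).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
protein_distances <- function(seqs, params = scoring_params(), p_max = 0.999) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
        type = "global", substitutionMatrix = params$matrix,
        gapOpening = params$gap_open, gapExtension = params$gap_extend
      )
      a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      ok <- a != "-" & b != "-"
      p <- if (any(ok)) mean(a[ok] != b[ok]) else 1
      p <- min(p, p_max)
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Neighbor-joining tree with optional outgroup rooting
#'
#' Canonical neighbor-joining on a distance matrix; negative branch lengths
#' are clamped to zero; when an outgroup tip is given the tree is rooted on
#' its edge. A deterministic distance-based stand-in for Bayesian or
#' maximum-likelihood tree inference.
#'
#' @param dm Symmetric distance matrix with tip names, or a `dist`.
#' @param outgroup Optional tip label to root on.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm, outgroup = NULL) {
  tree <- ape::nj(stats::as.dist(dm))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (!is.null(outgroup) && outgroup %in% tree$tip.label) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

#' Stem-length check of a high-similarity clade
#'
#' Verifies that the proposed high-similarity taxa form a clade in the tree
#' and that the stem branch subtending that clade is longer than
#' `min_stem` substitutions per site -- long stems corroborate a
#' taxonomically restricted (novel) protein, short stems a broadly
#' conserved one.
#'
#' @param tree A rooted `ape::phylo` tree.
#' @param high_similarity_taxa Tip labels of the proposed clade.
#' @param min_stem Stem-length support threshold (default 0.5).
#' @return A one-row tibble: `stem_length`, `supported`, `reason`.
#' @export
stem_check <- function(tree, high_similarity_taxa, min_stem = 0.5) {
  taxa <- intersect(high_similarity_taxa, tree$tip.label)
  if (length(taxa) < length(high_similarity_taxa) || length(taxa) == 0) {
    return(tibble(
      stem_length = NA_real_, supported = FALSE, reason = "taxa absent from tree"
    ))
  }
  if (length(taxa) == length(tree$tip.label)) {
    return(tibble(
      stem_length = NA_real_, supported = FALSE, reason = "clade is the whole tree"
    ))
  }
  if (!ape::is.monophyletic(tree, taxa)) {
    return(tibble(
      stem_length = NA_real_, supported = FALSE, reason = "non-monophyletic"
    ))
  }
  node <- if (length(taxa) == 1) {
    match(taxa, tree$tip.label)
  } else {
    ape::getMRCA(tree, taxa)
  }
  edge_row <- which(tree$edge[, 2] == node)
  if (length(edge_row) == 0) {
    return(tibble(
      stem_length = NA_real_, supported = FALSE, reason = "clade at root"
    ))
  }
  stem <- tree$edge.length[edge_row]
  tibble(
    stem_length = stem, supported = stem > min_stem,
    reason = if (stem > min_stem) "stem long" else "stem short"
  )
}

#' Full bioprospecting pipeline over candidate clusters
#'
#' Chains the discovery steps for a set of (typically non-annotated,
#' taxonomically homogeneous) clusters: drop annotated clusters, keep
#' eco-responsive ones, scan the focal-species representative (longest
#' member) across the category databases, call the emergence point, build a
#' neighbor-joining tree from the per-category hits (substituting the
#' next-best hit when the top hit covers under half the query) and check
#' the high-similarity clade's stem length.
#'
#' @param clusters An `ortho_clusters` tibble with annotation flags.
#' @param deg_a,deg_b DEG transcript-id lists.
#' @param category_databases Ordered named list of per-category proteomes.
#' @param params A [scoring_params()] object.
#' @param focal Focal species label (default `"Nf"`).
#' @param delta_min Emergence threshold (default 25).
#' @param min_stem Stem support threshold (default 0.5).
#' @param outgroup_preference Category labels tried in order when rooting
#'   (default crustacean then arthropod outgroup); falls back to the
#'   farthest category with a usable hit.
#' @param min_hit_coverage Top hits covering less than this fraction of the
#'   query are replaced by the next-best hit in the cladogram (default 0.5).
#' @return A tibble of class `prospect_report`, one row per candidate:
#'   cluster id, representative, DEG flags, emergence call fields, stem
#'   check fields. Per-candidate profiles are kept in `attr(, "profiles")`.
#' @export
prospect_pipeline <- function(clusters, deg_a, deg_b, category_databases,
                              params = scoring_params(), focal = "Nf",
                              delta_min = 25, min_stem = 0.5,
                              outgroup_preference = c("Cr", "Ar"),
                              min_hit_coverage = 0.5) {
  candidates <- clusters[!(clusters$annotated %in% TRUE), ]
  eco <- eco_responsive_clusters(candidates, deg_a, deg_b, focal)
  in_a <- candidates$cluster_id %in% eco$a$cluster_id
  in_b <- candidates$cluster_id %in% eco$b$cluster_id
  responsive <- candidates[in_a | in_b, ]
  flags_a <- in_a[in_a | in_b]
  flags_b <- in_b[in_a | in_b]

  profiles <- list()
  rows <- map(seq_len(nrow(responsive)), function(i) {
    mem <- responsive$members[[i]]
    focal_mem <- mem[mem$species == focal, ]
    if (nrow(focal_mem) == 0) return(NULL)
    rep_row <- focal_mem[order(-nchar(focal_mem$aa_seq), focal_mem$protein_id), ][1, ]
    prof <- taxonomic_scan(rep_row$aa_seq, category_databases, params,
      query_id = rep_row$protein_id
    )
    profiles[[responsive$cluster_id[i]]] <<- prof
    call <- call_emergence(prof, delta_min)
    stem <- cluster_stem_check(
      prof, call, min_stem, outgroup_preference, min_hit_coverage, params
    )
    tibble(
      cluster_id = responsive$cluster_id[i],
      representative_id = rep_row$protein_id,
      deg_a = flags_a[i], deg_b = flags_b[i], deg_both = flags_a[i] && flags_b[i],
      emergence_category = call$emergence_category,
      emergence_index = call$emergence_index,
      delta = call$delta,
      missing_beyond = call$missing_beyond,
      stem_length = stem$stem_length,
      stem_supported = stem$supported,
      stem_reason = stem$reason
    )
  })
  report <- list_rbind(compact_null(rows))
  attr(report, "profiles") <- profiles
  class(report) <- c("prospect_report", class(report))
  report
}

# Tree + stem check for one scanned candidate. Tips are category labels,
# sequences the per-category cladogram hits (top hit, or next-best when the
# top hit covers too little of the query).
cluster_stem_check <- function(profile, call, min_stem, outgroup_preference,
                               min_hit_coverage, params) {
  if (is.na(call$emergence_category)) {
    return(tibble(
      stem_length = NA_real_, supported = FALSE, reason = "no emergence"
    ))
  }
  hits <- cladogram_hits(profile, min_hit_coverage)
  if (nrow(hits) < 4) {
    return(tibble(
      stem_length = NA_real_, supported = FALSE, reason = "too few hits for tree"
    ))
  }
  seqs <- setNames(hits$seq, hits$category)
  D <- protein_distances(seqs, params)
  outgroup <- intersect(outgroup_preference, hits$category)
  outgroup <- if (length(outgroup)) {
    outgroup[1]
  } else {
    hits$category[nrow(hits)] # farthest category with a usable hit
  }
  tree <- neighbor_joining(D, outgroup = outgroup)
  high <- profile$category[seq_len(call$emergence_index)]
  stem_check(tree, intersect(high, tree$tip.label), min_stem)
}

#' Per-category proteome databases for the taxonomic scan
#'
#' Splits a multi-species proteome tibble into one database per scan
#' category (tip), ordered nearest to farthest from the focal species.
#'
#' @param proteomes A tibble with `species`, `id`, `aa_seq` columns.
#' @param tree The species tree.
#' @param focal Focal species tip (default `"Nf"`).
#' @return A named ordered list of tibbles (`id`, `aa_seq`).
#' @export
category_databases <- function(proteomes, tree, focal = "Nf") {
  cats <- scan_categories(tree, focal)
  dbs <- lapply(cats, function(sp) {
    pr <- proteomes[proteomes$species == sp, ]
    tibble(id = pr$id, aa_seq = pr$aa_seq)
  })
  setNames(dbs, cats)
}

#' Evaluate emergence-point recovery against generator truth
#'
#' Scans the focal-species member of every family in a synthetic dataset,
#' calls the emergence point and compares it with the category expected
#' from the family's true origin node ([expected_emergence()]).
#'
#' @param dataset A [simulate_dataset()] result.
#' @param params A [scoring_params()] object.
#' @param delta_min Emergence threshold (default 25).
#' @param focal Focal species tip (default `"Nf"`).
#' @return A tibble with one row per focal-species family: `family_id`,
#'   `origin_node`, `expected`, `called`, `correct`.
#' @export
emergence_recovery <- function(dataset, params = scoring_params(),
                               delta_min = 25, focal = "Nf") {
  dbs <- category_databases(dataset$proteomes, dataset$tree, focal)
  members <- dataset$truth$members
  fams <- dataset$truth$families
  focal_members <- members[members$species == focal, ]
  rows <- map(seq_len(nrow(focal_members)), function(i) {
    m <- focal_members[i, ]
    origin <- fams$origin_node[fams$family_id == m$family_id]
    prof <- taxonomic_scan(m$aa_seq, dbs, params, query_id = m$protein_id)
    call <- call_emergence(prof, delta_min)
    expected <- expected_emergence(dataset$tree, origin, focal)
    tibble(
      family_id = m$family_id, origin_node = origin,
      expected = expected, called = call$emergence_category,
      correct = identical(expected, call$emergence_category) ||
        (is.na(expected) && is.na(call$emergence_category))
    )
  })
  list_rbind(rows)
}

#' Per-category hit sequences used for the cladogram
#'
#' The top hit of each non-missing category, substituting the next-best hit
#' when the top hit covers less than `min_hit_coverage` of the query (short
#' partial hits distort distance estimates).
#'
#' @param profile A `similarity_profile` tibble.
#' @param min_hit_coverage Coverage threshold (default 0.5).
#' @return A tibble: `category`, `hit_id`, `seq`.
#' @export
cladogram_hits <- function(profile, min_hit_coverage = 0.5) {
  present <- filter(profile, !.data$missing)
  rows <- map(seq_len(nrow(present)), function(i) {
    r <- present[i, ]
    use_alt <- !is.na(r$alt_hit_id) &&
      !is.na(r$top_hit_coverage) && r$top_hit_coverage < min_hit_coverage
    tibble(
      category = r$category,
      hit_id = if (use_alt) r$alt_hit_id else r$top_hit_id,
      seq = if (use_alt) r$alt_hit_seq else r$top_hit_seq
    )
  })
  list_rbind(rows)
}
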