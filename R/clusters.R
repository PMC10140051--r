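# Ortholog clustering of multi-species proteomes and the cluster set algebra
# used to summarise sharing across species: a homology graph (edges at
# E <= 1e-15, bitscore-weighted) partitioned by Markov clustering (inflation
# 1.5), then annotation flags, sharing orders, shared-by-all selection and
# foreign-member purging.

#' Cluster multi-species proteomes into ortholog groups
#'
#' Builds a graph over proteins with an edge wherever the pairwise local
#' alignment reaches E <= `e_cut` (pairwise E-value: m and n are the two
#' protein lengths), weighted by bit score, and partitions it. The default
#' partitioner is Markov clustering (expansion 2, the given inflation,
#' pruning at 1e-5, convergence when the biggest matrix change is below
#' 1e-8, at most 100 iterations, self-loops at each column's maximum
#' weight); `method = "components"` uses plain connected components as an
#' oracle-friendly fallback. Every protein lands in exactly one cluster;
#' unconnected proteins become singletons. Input order does not matter:
#' proteins are canonicalised by id.
#'
#' @param proteins A tibble with `id`, `species`, `aa_seq` and optionally
#'   `transcript_id` columns (complete predicted proteins).
#' @param params A [scoring_params()] object.
#' @param e_cut Pairwise E-value cutoff for an edge (default 1e-15).
#' @param inflation MCL inflation (default 1.5).
#' @param method `"mcl"` or `"components"`.
#' @return A tibble of class `ortho_clusters`, one row per cluster:
#'   `cluster_id`, `n_members`, `n_species`, `species` (list of tip labels),
#'   `members` (list of member tibbles), `annotated` (NA until
#'   [annotate_clusters()]), `annotation_label`.
#' @export
cluster_proteomes <- function(proteins, params = scoring_params(),
                              e_cut = 1e-15, inflation = 1.5,
                              method = c("mcl", "components")) {
  method <- match.arg(method)
  if (nrow(proteins) == 0) {
    return(new_ortho_clusters(tibble(
      cluster_id = character(), n_members = integer(), n_species = integer(),
      species = list(), members = list(), annotated = logical(),
      annotation_label = character()
    )))
  }
  if (!"transcript_id" %in% names(proteins)) {
    proteins$transcript_id <- NA_character_
  }
  proteins <- arrange(proteins, .data$id)
  n <- nrow(proteins)
  lens <- nchar(proteins$aa_seq)

  # sparse edge list over the upper triangle
  edge_i <- integer(0); edge_j <- integer(0); edge_w <- numeric(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      sc <- local_scores(proteins$aa_seq[i], proteins$aa_seq[js], params)
      ev <- evalue(sc, lens[i], lens[js], params)
      hit <- which(ev <= e_cut)
      if (length(hit)) {
        edge_i <- c(edge_i, rep(i, length(hit)))
        edge_j <- c(edge_j, js[hit])
        edge_w <- c(edge_w, bitscore(sc[hit], params))
      }
    }
  }

  membership <- if (method == "components") {
    components_membership(n, edge_i, edge_j)
  } else {
    mcl_membership(n, edge_i, edge_j, edge_w, inflation)
  }

  build_cluster_table(proteins, membership)
}

components_membership <- function(n, edge_i, edge_j) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edge_i)) {
    g <- igraph::add_edges(g, rbind(edge_i, edge_j))
  }
  igraph::components(g)$membership
}

# Dense Markov clustering on the connected vertices; isolated vertices are
# singletons by construction.
mcl_membership <- function(n, edge_i, edge_j, edge_w, inflation,
                           prune = 1e-5, tol = 1e-8, max_iter = 100) {
  membership <- integer(n)
  connected <- sort(unique(c(edge_i, edge_j)))
  isolated <- setdiff(seq_len(n), connected)
  if (length(connected)) {
    idx <- match(seq_len(n), connected)
    m <- length(connected)
    W <- matrix(0, m, m)
    W[cbind(idx[edge_i], idx[edge_j])] <- edge_w
    W <- W + t(W)
    diag(W) <- apply(W, 2, max)
    M <- sweep(W, 2, colSums(W), "/")
    for (iter in seq_len(max_iter)) {
      M2 <- M %*% M
      M2 <- M2^inflation
      M2[M2 < prune] <- 0
      M2 <- sweep(M2, 2, colSums(M2), "/")
      delta <- max(abs(M2 - M))
      M <- M2
      if (delta < tol) break
    }
    g <- igraph::graph_from_adjacency_matrix(
      (M + t(M)) > 0, mode = "undirected", diag = FALSE
    )
    comp <- igraph::components(g)$membership
    membership[connected] <- comp
  }
  k <- max(membership, 0)
  membership[isolated] <- k + seq_along(isolated)
  membership
}

build_cluster_table <- function(proteins, membership) {
  proteins$.cluster <- membership
  groups <- split(seq_len(nrow(proteins)), membership)
  # canonical order: by smallest member protein id
  first_ids <- vapply(groups, function(ix) min(proteins$id[ix]), character(1))
  groups <- groups[order(first_ids)]
  rows <- imap(groups, function(ix, nm) {
    mem <- proteins[ix, c("id", "transcript_id", "species", "aa_seq")]
    names(mem)[1] <- "protein_id"
    tibble(
      n_members = length(ix),
      n_species = length(unique(mem$species)),
      species = list(sort(unique(mem$species))),
      members = list(mem)
    )
  })
  out <- list_rbind(rows) |>
    mutate(
      cluster_id = sprintf("CL%05d", row_number()),
      annotated = NA,
      annotation_label = NA_character_,
      .before = 1
    )
  new_ortho_clusters(out)
}

new_ortho_clusters <- function(x) {
  class(x) <- c("ortho_clusters", setdiff(class(x), "ortho_clusters"))
  x
}

#' Annotate clusters against a reference protein panel
#'
#' A cluster is annotated when any member's best panel hit reaches
#' E <= `e_max`; the annotation label is the subject id of the lowest-E
#' member hit.
#'
#' @param clusters An `ortho_clusters` tibble.
#' @param panel A tibble with `id`, `aa_seq` (may be empty: nothing is
#'   annotated).
#' @param params A [scoring_params()] object.
#' @param e_max Annotation E-value cutoff (default 1e-5).
#' @return `clusters` with `annotated` and `annotation_label` filled in.
#' @export
annotate_clusters <- function(clusters, panel, params = scoring_params(),
                              e_max = 1e-5) {
  res <- map(clusters$members, function(mem) {
    best_e <- Inf
    best_lab <- NA_character_
    for (i in seq_len(nrow(mem))) {
      hit <- homology_search(mem$aa_seq[i], panel, params, e_max = Inf)
      if (nrow(hit) && hit$evalue < best_e) {
        best_e <- hit$evalue
        best_lab <- hit$subject_id
      }
    }
    tibble(
      annotated = is.finite(best_e) && best_e <= e_max,
      annotation_label = if (is.finite(best_e) && best_e <= e_max) best_lab else NA_character_
    )
  }) |> list_rbind()
  clusters$annotated <- res$annotated
  clusters$annotation_label <- res$annotation_label
  clusters
}

#' Sharing-order summary of a cluster set
#'
#' Counts clusters by sharing order: the number of `selected_species`
#' present in the cluster. Order-1 clusters are species-specific; the
#' shared-by-all count requires every selected species. Percents are
#' formatted one-decimal round-half-up as in printed summary tables.
#'
#' @param clusters An `ortho_clusters` tibble.
#' @param selected_species Character vector of species labels.
#' @return A one-row tibble: `total_clusters`, `n_specific`,
#'   `n_shared_2plus`, `n_shared_all` and the corresponding percents.
#' @export
sharing_summary <- function(clusters, selected_species) {
  order_k <- map_int(clusters$species, function(sp) {
    length(intersect(sp, selected_species))
  })
  if (any(order_k == 0)) {
    warn("clusters with no selected species are excluded from the summary")
  }
  keep <- order_k > 0
  total <- sum(keep)
  n_specific <- sum(order_k == 1)
  n_2plus <- sum(order_k >= 2)
  n_all <- sum(map_lgl(clusters$species, function(sp) {
    all(selected_species %in% sp)
  }) & keep)
  tibble(
    total_clusters = total,
    n_specific = n_specific,
    n_shared_2plus = n_2plus,
    n_shared_all = n_all,
    pct_specific = pct_round(n_specific, total),
    pct_shared_2plus = pct_round(n_2plus, total),
    pct_shared_all = pct_round(n_all, total)
  )
}

#' Clusters shared by all selected species
#'
#' Keeps clusters whose species signature contains every selected species
#' (additional species are allowed; combine with [purge_foreign()] for a
#' taxonomically homogeneous set).
#'
#' @param clusters An `ortho_clusters` tibble.
#' @param selected_species Character vector of species labels; an empty
#'   selection keeps everything (with a warning).
#' @return The filtered `ortho_clusters` tibble.
#' @export
shared_by_all <- function(clusters, selected_species) {
  if (length(selected_species) == 0) {
    warn("empty species selection: every cluster is vacuously shared by all")
    return(clusters)
  }
  keep <- map_lgl(clusters$species, function(sp) all(selected_species %in% sp))
  new_ortho_clusters(clusters[keep, ])
}

#' Purge clusters containing foreign species
#'
#' Keeps only clusters whose species signature is a subset of
#' `allowed_species`, removing clusters with members from outside the
#' taxonomic category of interest.
#'
#' @param clusters An `ortho_clusters` tibble.
#' @param allowed_species Character vector of allowed species labels.
#' @return The taxonomically homogeneous `ortho_clusters` subset.
#' @export
purge_foreign <- function(clusters, allowed_species) {
  keep <- map_lgl(clusters$species, function(sp) all(sp %in% allowed_species))
  new_ortho_clusters(clusters[keep, ])
}

#' Non-annotated cluster summary
#'
#' Reports how many shared-by-all clusters lack annotation and how many of
#' those survive foreign-member purging, with one-decimal round-half-up
#' percents.
#'
#' @param clusters_all Shared-by-all `ortho_clusters` (annotated flags set).
#' @param clusters_homogeneous The purged subset of `clusters_all`.
#' @return A one-row tibble: `n_shared_all`, `n_nonannotated`,
#'   `pct_nonannotated`, `n_homogeneous_nonannotated`,
#'   `pct_homogeneous_of_nonannotated`.
#' @export
nonannotated_summary <- function(clusters_all, clusters_homogeneous) {
  n_all <- nrow(clusters_all)
  n_non <- sum(!clusters_all$annotated)
  n_hom_non <- sum(!clusters_homogeneous$annotated)
  tibble(
    n_shared_all = n_all,
    n_nonannotated = n_non,
    pct_nonannotated = if (n_all > 0) pct_round(n_non, n_all) else NA_real_,
    n_homogeneous_nonannotated = n_hom_non,
    pct_homogeneous_of_nonannotated = if (n_non > 0) pct_round(n_hom_non, n_non) else NA_real_
  )
}

#' Build the truth clustering from a synthetic dataset
#'
#' One cluster per simulated family, with annotation flags taken from the
#' ground truth. Useful as the reference partition for clustering
#' evaluation and for exercising downstream set algebra without re-running
#' the aligner.
#'
#' @param truth Truth list from [simulate_families()].
#' @return An `ortho_clusters` tibble.
#' @export
clusters_from_truth <- function(truth) {
  fams <- arrange(truth$families, .data$family_id)
  rows <- map(seq_len(nrow(fams)), function(i) {
    mem <- truth$members[truth$members$family_id == fams$family_id[i], ]
    tibble(
      cluster_id = fams$family_id[i],
      n_members = nrow(mem),
      n_species = length(unique(mem$species)),
      species = list(sort(unique(mem$species))),
      members = list(tibble(
        protein_id = mem$protein_id, transcript_id = mem$transcript_id,
        species = mem$species, aa_seq = mem$aa_seq
      )),
      annotated = fams$annotated[i],
      annotation_label = NA_character_
    )
  })
  new_ortho_clusters(list_rbind(rows))
}

#' @export
tidy.ortho_clusters <- function(x, ...) {
  x |>
    select("cluster_id", "annotated", "annotation_label", "members") |>
    unnest("members")
}

#' @export
glance.ortho_clusters <- function(x, ...) {
  tibble(
    n_clusters = nrow(x),
    n_proteins = sum(x$n_members),
    n_species = length(unique(unlist(x$species))),
    n_annotated = sum(x$annotated, na.rm = TRUE)
  )
}
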