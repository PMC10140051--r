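hand_profile <- function(sims, missing = rep(FALSE, length(sims)),
                         cats = NULL) {
  k <- length(sims)
  cats <- cats %||% paste0("cat", seq_len(k))
  p <- tibble::tibble(
    category = cats, n_db = 10L, missing = missing,
    best_evalue = ifelse(missing, NA, 10^(-sims)),
    similarity = ifelse(missing, NA, sims),
    top_hit_id = ifelse(missing, NA, paste0("h", seq_len(k))),
    top_hit_score = NA_real_, top_hit_coverage = 1,
    top_hit_seq = NA_character_, alt_hit_id = NA_character_,
    alt_hit_coverage = NA_real_, alt_hit_seq = NA_character_
  )
  class(p) <- c("similarity_profile", class(p))
  p
}

test_that("emergence is called at the first sharp similarity drop", {
  p <- hand_profile(c(300, 280, 270, 255, 30, 25, 20, 15, 10, 5, 0))
  call <- call_emergence(p)
  expect_equal(call$emergence_index, 4)
  expect_equal(call$emergence_category, "cat4")
  expect_equal(call$delta, 225)
  expect_false(call$missing_beyond)
})

test_that("gradual profiles give no emergence call", {
  p <- hand_profile(seq(180, 60, length.out = 11))
  call <- call_emergence(p)
  expect_true(is.na(call$emergence_category))
})

test_that("all-farther-missing marks emergence with missing_beyond", {
  p <- hand_profile(
    c(120, 110, 100, rep(0, 5)),
    missing = c(rep(FALSE, 3), rep(TRUE, 5))
  )
  call <- call_emergence(p)
  expect_equal(call$emergence_index, 3)
  expect_true(call$missing_beyond)

  expect_error(call_emergence(hand_profile(100)), "two categories")
})

test_that("scan profiles self-hit high, descend with distance, miss absent clades", {
  cfg <- sim_config(
    seed = 71, n_families = 8, origin_weights = c(Neocalanus = 0.5, Arthropoda = 0.5),
    deg_sizes = c(3, 2), deg_overlap = 1
  )
  ds <- simulate_dataset(cfg)
  dbs <- category_dbs(ds)
  truth <- ds$truth

  genus_fam <- truth$families$family_id[truth$families$origin_node == "Neocalanus"][1]
  q <- truth$members[truth$members$family_id == genus_fam &
    truth$members$species == "Nf", ]
  prof <- taxonomic_scan(q$aa_seq, dbs, query_id = q$protein_id)
  expect_equal(prof$category, scan_categories(ds$tree))
  # self category: essentially exact self-hit
  expect_gt(prof$similarity[1], 100)
  expect_equal(prof$top_hit_id[1], q$protein_id)
  # congeners similar, non-descendants near zero
  expect_true(all(prof$similarity[2:3] > 50))
  expect_true(all(prof$similarity[4:11] < 25 | is.na(prof$similarity[4:11])))

  # empty database for a category is missing
  dbs0 <- dbs
  dbs0[["Ar"]] <- dbs0[["Ar"]][0, ]
  prof0 <- taxonomic_scan(q$aa_seq, dbs0)
  expect_true(prof0$missing[prof0$category == "Ar"])

  # root-born family: hits in every category
  root_fam <- truth$families$family_id[truth$families$origin_node == "Arthropoda"][1]
  q2 <- truth$members[truth$members$family_id == root_fam &
    truth$members$species == "Nf", ]
  prof2 <- taxonomic_scan(q2$aa_seq, dbs)
  expect_false(any(prof2$missing))
})

test_that("eco-responsive intersection counts match generator truth", {
  cfg <- sim_config(seed = 72, n_families = 15, deg_sizes = c(6, 5), deg_overlap = 2)
  ds <- simulate_dataset(cfg)
  # clusters straight from truth: perfect recovery case
  cl <- cluster_proteomes(
    ds$proteomes[ds$proteomes$species %in% c("Nf", "Np", "Nc", "Cm", "Eb", "Mp"), ]
  )
  eco <- eco_responsive_clusters(cl, ds$deg$deg_a, ds$deg$deg_b)
  expect_equal(eco$counts$n_a, 6)
  expect_equal(eco$counts$n_b, 5)
  expect_equal(eco$counts$n_both, 2)

  # disjoint lists: empty intersection; unknown ids contribute nothing
  eco0 <- eco_responsive_clusters(cl, ds$deg$deg_a[1:2], c("nope1", "nope2"))
  expect_equal(eco0$counts$n_both, 0)
  expect_equal(eco0$counts$n_b, 0)
})

test_that("neighbor joining is exact on additive quartets and permutation-stable", {
  # additive quartet: ((A:1,B:2):1,(C:3,D:4):1) pairwise path lengths
  D <- matrix(
    c(
      0, 3, 5, 6,
      3, 0, 6, 7,
      5, 6, 0, 7,
      6, 7, 7, 0
    ),
    4, 4,
    dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  )
  tr <- neighbor_joining(D)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), rownames(D)]),
    unname(D),
    tolerance = 1e-10
  )
  perm <- c("C", "A", "D", "B")
  tr2 <- neighbor_joining(D[perm, perm])
  d2 <- as.matrix(ape::cophenetic.phylo(tr2))[rownames(D), rownames(D)]
  expect_equal(unname(d2), unname(D), tolerance = 1e-10)

  # three identical sequences plus one distant taxon
  seqs <- c(a = random_protein(80), b = NA, c = NA, d = random_protein(80))
  seqs["b"] <- seqs["a"]
  seqs["c"] <- seqs["a"]
  Dm <- protein_distances(seqs)
  expect_true(all(Dm[c("a", "b", "c"), c("a", "b", "c")] == 0))
  tr3 <- neighbor_joining(Dm, outgroup = "d")
  expect_true(ape::is.monophyletic(tr3, c("a", "b", "c")))
})

test_that("stem check reports long and short stems and degenerate cases", {
  tr <- ape::read.tree(text = "(((A:0.1,B:0.1):0.8,C:0.9):0.1,D:1.0);")
  long <- stem_check(tr, c("A", "B"))
  expect_true(long$supported)
  expect_equal(long$stem_length, 0.8)
  short <- stem_check(tr, c("A", "B"), min_stem = 0.85)
  expect_false(short$supported)
  expect_false(stem_check(tr, c("A", "Z"))$supported)
  expect_equal(stem_check(tr, c("A", "Z"))$reason, "taxa absent from tree")
  expect_false(stem_check(tr, c("A", "C"))$supported) # non-monophyletic
  expect_equal(stem_check(tr, c("A", "C"))$reason, "non-monophyletic")
  expect_equal(
    stem_check(tr, c("A", "B", "C", "D"))$reason,
    "clade is the whole tree"
  )
})

test_that("pipeline recovers genus-born DEG families and is deterministic", {
  cfg <- sim_config(
    seed = 73, n_families = 16, truncation_prob = 0,
    origin_weights = c(Neocalanus = 0.5, Arthropoda = 0.5),
    deg_sizes = c(6, 5), deg_overlap = 2
  )
  ds <- simulate_dataset(cfg)
  focal6 <- c("Nf", "Np", "Nc", "Cm", "Eb", "Mp")
  cl <- annotate_clusters(
    cluster_proteomes(ds$proteomes[ds$proteomes$species %in% focal6, ]),
    ds$panel
  )
  dbs <- category_dbs(ds)
  rep1 <- prospect_pipeline(cl, ds$deg$deg_a, ds$deg$deg_b, dbs)
  # annotated clusters are excluded up front
  ann_ids <- cl$cluster_id[cl$annotated]
  expect_false(any(rep1$cluster_id %in% ann_ids))
  # reported candidates: non-annotated eco-responsive; genus-born ones
  # must be called at the genus category
  fam_of <- truth_family_labels(ds)
  truth <- ds$truth
  for (i in seq_len(nrow(rep1))) {
    fam <- unname(fam_of[rep1$representative_id[i]])
    org <- truth$families$origin_node[truth$families$family_id == fam]
    if (org == "Neocalanus") {
      expect_equal(rep1$emergence_category[i], "Nc")
    }
  }
  rep2 <- prospect_pipeline(cl, ds$deg$deg_a, ds$deg$deg_b, dbs)
  expect_identical(
    as.data.frame(rep1[names(rep1) != "profiles"]),
    as.data.frame(rep2[names(rep2) != "profiles"])
  )
})

test_that("cladogram hits substitute next-best when the top hit is too partial", {
  p <- hand_profile(c(100, 50))
  p$top_hit_coverage <- c(1, 0.3)
  p$top_hit_seq <- c("AAAA", "BBBB")
  p$alt_hit_id <- c(NA, "alt2")
  p$alt_hit_seq <- c(NA, "CCCC")
  hits <- cladogram_hits(p)
  expect_equal(hits$hit_id, c("h1", "alt2"))
  expect_equal(hits$seq, c("AAAA", "CCCC"))
})
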