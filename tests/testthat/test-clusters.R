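make_family <- function(seed, n, len = 120, divergence = 0.03) {
  set.seed(seed)
  aas <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  anc <- random_protein(len, first_m = TRUE)
  vapply(seq_len(n), function(i) {
    chars <- strsplit(anc, "")[[1]]
    hit <- which(stats::runif(len) < divergence)
    hit <- setdiff(hit, 1)
    for (j in hit) chars[j] <- sample(setdiff(aas, chars[j]), 1)
    paste(chars, collapse = "")
  }, character(1))
}

test_that("two disjoint triplet families form two clusters of three", {
  f1 <- make_family(61, 3)
  f2 <- make_family(62, 3)
  prot <- tibble::tibble(
    id = sprintf("p%d", 1:6),
    species = rep(c("A", "B", "C"), 2),
    aa_seq = c(f1, f2)
  )
  for (method in c("components", "mcl")) {
    cl <- cluster_proteomes(prot, method = method)
    expect_equal(nrow(cl), 2)
    expect_equal(sort(cl$n_members), c(3, 3))
    expect_equal(sum(cl$n_members), 6)
  }
})

test_that("mutually unrelated proteins become singletons", {
  set.seed(63)
  prot <- tibble::tibble(
    id = sprintf("p%d", 1:8),
    species = rep(c("A", "B"), 4),
    aa_seq = vapply(rep(150, 8), random_protein, "")
  )
  cl <- cluster_proteomes(prot)
  expect_equal(nrow(cl), 8)
  expect_true(all(cl$n_members == 1))
})

test_that("clustering partitions the input and is input-order invariant", {
  cfg <- sim_config(seed = 64, n_families = 10, deg_sizes = c(3, 2), deg_overlap = 1)
  ds <- simulate_dataset(cfg)
  prot <- ds$proteomes[ds$proteomes$species %in% c("Nf", "Np", "Nc", "Cm", "Eb", "Mp"), ]
  cl <- cluster_proteomes(prot)
  members <- tidy(cl)
  expect_setequal(members$protein_id, prot$id)
  expect_equal(anyDuplicated(members$protein_id), 0)

  shuffled <- prot[sample(nrow(prot)), ]
  cl2 <- cluster_proteomes(shuffled)
  expect_identical(
    lapply(cl$members, function(m) sort(m$protein_id)),
    lapply(cl2$members, function(m) sort(m$protein_id))
  )
})

test_that("clustering recovers synthetic families (ARI vs truth)", {
  cfg <- sim_config(seed = 65, n_families = 20, deg_sizes = c(5, 4), deg_overlap = 2)
  ds <- simulate_dataset(cfg)
  prot <- ds$proteomes[ds$proteomes$species %in% c("Nf", "Np", "Nc", "Cm", "Eb", "Mp"), ]
  cl <- cluster_proteomes(prot)
  members <- tidy(cl)
  truth <- truth_family_labels(ds)
  ari <- mclust::adjustedRandIndex(members$cluster_id, truth[members$protein_id])
  expect_gte(ari, 0.95)
})

test_that("cluster annotation follows synthetic truth at E <= 1e-5", {
  cfg <- sim_config(seed = 66, n_families = 12, deg_sizes = c(4, 3), deg_overlap = 2)
  ds <- simulate_dataset(cfg)
  prot <- ds$proteomes[ds$proteomes$species %in% c("Nf", "Np", "Nc", "Cm", "Eb", "Mp"), ]
  cl <- annotate_clusters(cluster_proteomes(prot), ds$panel)
  truth <- ds$truth$families
  fam_of <- truth_family_labels(ds)
  for (i in seq_len(nrow(cl))) {
    fams <- unique(fam_of[cl$members[[i]]$protein_id])
    expect_equal(length(fams), 1)
    expect_equal(
      cl$annotated[i],
      truth$annotated[truth$family_id == fams]
    )
  }
  # empty panel annotates nothing
  cl0 <- annotate_clusters(cl, ds$panel[0, ])
  expect_equal(sum(cl0$annotated), 0)
})

test_that("sharing summary reproduces printed-table ratio arithmetic", {
  expect_equal(pct_round(7174, 10453), 68.6)
  expect_equal(pct_round(1387, 19231), 7.2)

  # constructed clusters with known sharing orders
  mk <- function(id, species) {
    tibble::tibble(
      cluster_id = id, n_members = length(species),
      n_species = length(unique(species)),
      species = list(sort(unique(species))),
      members = list(tibble::tibble(
        protein_id = paste0(id, "_", seq_along(species)),
        transcript_id = NA_character_, species = species,
        aa_seq = NA_character_
      )),
      annotated = NA, annotation_label = NA_character_
    )
  }
  cl <- dplyr::bind_rows(
    mk("c1", c("A")), mk("c2", c("B")),
    mk("c3", c("A", "B")), mk("c4", c("A", "B", "C")),
    mk("c5", c("A", "B", "C"))
  )
  s <- sharing_summary(cl, c("A", "B", "C"))
  expect_equal(s$total_clusters, 5)
  expect_equal(s$n_specific, 2)
  expect_equal(s$n_shared_2plus, 3)
  expect_equal(s$n_shared_all, 2)
  expect_equal(s$n_specific + s$n_shared_2plus, s$total_clusters)

  # single selected species: every cluster containing it is specific
  expect_warning(s1 <- sharing_summary(cl, "A"), "excluded")
  expect_equal(s1$n_specific, s1$total_clusters)

  sel <- shared_by_all(cl, c("A", "B", "C"))
  expect_setequal(sel$cluster_id, c("c4", "c5"))
  sel2 <- shared_by_all(cl, c("A", "B"))
  expect_setequal(sel2$cluster_id, c("c3", "c4", "c5"))
  expect_warning(shared_by_all(cl, character(0)), "vacuous")

  pur <- purge_foreign(cl, c("A", "B"))
  expect_setequal(pur$cluster_id, c("c1", "c2", "c3"))
  # purge after shared_by_all leaves signatures exactly within the set
  hom <- purge_foreign(shared_by_all(cl, c("A", "B")), c("A", "B"))
  expect_true(all(vapply(hom$species, function(sp) all(sp %in% c("A", "B")), TRUE)))
})

test_that("foreign-member purging matches family truth for genus clusters", {
  cfg <- sim_config(seed = 67, n_families = 15, deg_sizes = c(4, 3), deg_overlap = 2)
  ds <- simulate_dataset(cfg)
  focal6 <- c("Nf", "Np", "Nc", "Cm", "Eb", "Mp")
  prot <- ds$proteomes[ds$proteomes$species %in% focal6, ]
  cl <- cluster_proteomes(prot)
  genus <- c("Nf", "Np", "Nc")
  hom <- purge_foreign(shared_by_all(cl, genus), genus)
  fam_of <- truth_family_labels(ds)
  got <- sort(unique(fam_of[tidy(hom)$protein_id]))
  truth <- ds$truth
  want <- sort(truth$families$family_id[truth$families$origin_node == "Neocalanus"])
  expect_identical(got, want)
})

test_that("non-annotated summary matches printed-table arithmetic", {
  expect_equal(pct_round(2857, 7174), 39.8)
  expect_equal(pct_round(240, 643), 37.3)

  all_cl <- tibble::tibble(
    cluster_id = paste0("c", 1:10),
    annotated = rep(c(TRUE, FALSE), 5)
  )
  hom_cl <- all_cl[c(2, 4), ]
  s <- nonannotated_summary(all_cl, hom_cl)
  expect_equal(s$n_shared_all, 10)
  expect_equal(s$n_nonannotated, 5)
  expect_equal(s$pct_nonannotated, 50)
  expect_equal(s$n_homogeneous_nonannotated, 2)
  expect_equal(s$pct_homogeneous_of_nonannotated, 40)

  none <- all_cl[all_cl$annotated, ]
  s0 <- nonannotated_summary(none, none[0, ])
  expect_equal(s0$n_nonannotated, 0)
  expect_equal(s0$pct_nonannotated, 0)
})
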