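test_that("taxonomy has the nested focal clades and outgroup categories", {
  tree <- simulate_taxonomy(sim_config())
  expect_setequal(descendant_tips(tree, "Neocalanus"), c("Nf", "Np", "Nc"))
  expect_setequal(descendant_tips(tree, "Calanidae"), c("Nf", "Np", "Nc", "Cm"))
  expect_setequal(descendant_tips(tree, "Myelinata"), c("Nf", "Np", "Nc", "Cm", "Eb"))
  expect_true(all(c("Ha", "Cy", "Cr", "Ar") %in% tree$tip.label))
  expect_true(all(tree$edge.length >= 0))
  expect_false(any(duplicated(tree$tip.label)))

  focal <- simulate_taxonomy(sim_config(include_outgroups = FALSE))
  expect_equal(length(focal$tip.label), 6)

  # deterministic
  expect_identical(
    ape::write.tree(simulate_taxonomy(sim_config(seed = 5))),
    ape::write.tree(simulate_taxonomy(sim_config(seed = 5)))
  )
})

test_that("families respect the descent constraint exhaustively", {
  cfg <- sim_config(seed = 41, n_families = 25, deg_sizes = c(5, 4), deg_overlap = 2)
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  origin <- stats::setNames(
    fam$truth$families$origin_node,
    fam$truth$families$family_id
  )
  for (i in seq_len(nrow(fam$truth$members))) {
    m <- fam$truth$members[i, ]
    expect_true(m$species %in% descendant_tips(tree, origin[[m$family_id]]))
  }
  # genus-born families have members in exactly the three congeners
  genus <- fam$truth$families$family_id[fam$truth$families$origin_node == "Neocalanus"]
  for (f in genus) {
    sp <- fam$truth$members$species[fam$truth$members$family_id == f]
    expect_setequal(sp, c("Nf", "Np", "Nc"))
  }
})

test_that("substitution rate zero leaves family members identical", {
  cfg <- sim_config(
    seed = 42, n_families = 6, substitution_rate = 0,
    deg_sizes = c(2, 2), deg_overlap = 1
  )
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  per_fam <- split(fam$truth$members$aa_seq, fam$truth$members$family_id)
  for (seqs in per_fam) {
    expect_equal(length(unique(seqs)), 1)
  }
})

test_that("sister-species identity matches the binomial substitution expectation", {
  # rate chosen so sister species expect ~90% identity: sister path is
  # 2 * 0.0275 * rate, so rate 1.9 gives 1 - exp(-0.1045) ~ 0.099 expected
  # differing fraction before back-substitutions
  cfg <- sim_config(
    seed = 43, n_families = 20, substitution_rate = 1.9,
    origin_weights = c(Neocalanus = 1), deg_sizes = c(5, 4), deg_overlap = 2
  )
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  idents <- vapply(
    split(fam$truth$members, fam$truth$members$family_id),
    function(mem) {
      pairs <- utils::combn(nrow(mem), 2)
      mean(apply(pairs, 2, function(ix) {
        a <- strsplit(mem$aa_seq[ix[1]], "")[[1]]
        b <- strsplit(mem$aa_seq[ix[2]], "")[[1]]
        mean(a == b)
      }))
    },
    numeric(1)
  )
  expect_gte(mean(idents), 0.85)
  expect_lte(mean(idents), 0.95)
})

test_that("within-family identity decreases with tree path length", {
  cfg <- sim_config(
    seed = 44, n_families = 25, origin_weights = c(Arthropoda = 1),
    deg_sizes = c(5, 4), deg_overlap = 2
  )
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  paths <- ape::cophenetic.phylo(tree)
  rows <- do.call(rbind, lapply(
    split(fam$truth$members, fam$truth$members$family_id),
    function(mem) {
      pairs <- utils::combn(nrow(mem), 2)
      t(apply(pairs, 2, function(ix) {
        a <- strsplit(mem$aa_seq[ix[1]], "")[[1]]
        b <- strsplit(mem$aa_seq[ix[2]], "")[[1]]
        c(paths[mem$species[ix[1]], mem$species[ix[2]]], mean(a == b))
      }))
    }
  ))
  rho <- stats::cor(rows[, 1], rows[, 2], method = "spearman")
  expect_lt(rho, 0)
})

test_that("emitted transcripts code the proteins and respect length rules", {
  cfg <- sim_config(
    seed = 45, n_families = 10, truncation_prob = 0,
    deg_sizes = c(3, 3), deg_overlap = 1
  )
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  tx <- emit_transcripts(fam$proteomes, cfg)
  expect_true(all(nchar(tx$seq) >= cfg$min_len))
  expect_true(all(tx$truncated == "none"))

  # 100-aa protein gives a 303-nt CDS including the stop
  one <- tibble::tibble(
    id = "P1", transcript_id = "T1", species = "Nf",
    aa_seq = random_protein(100, first_m = TRUE), family_id = "FAM0001"
  )
  tx1 <- emit_transcripts(one, cfg)
  orf <- best_orf(tx1$seq)
  expect_equal(orf$cds_end - orf$cds_start, 303)
  expect_equal(orf$aa_seq, one$aa_seq)
})

test_that("forced 5'-truncation removes all complete ORFs", {
  cfg <- sim_config(
    seed = 46, n_families = 8, truncation_prob = 1,
    truncation_side = "5prime", deg_sizes = c(3, 2), deg_overlap = 1
  )
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  tx <- emit_transcripts(fam$proteomes, cfg)
  expect_true(all(tx$truncated == "5prime"))
  prot <- predict_proteome(tx)
  expect_true(all(prot$completeness != "complete"))
})

test_that("annotation panel covers old families and misses novel ones", {
  cfg <- sim_config(seed = 47, n_families = 14, deg_sizes = c(4, 3), deg_overlap = 2)
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  panel <- emit_annotation_panel(fam$truth, cfg)
  expect_equal(
    sum(grepl("^PANEL_", panel$id)),
    sum(fam$truth$families$annotated)
  )
  ann <- fam$truth$families$family_id[fam$truth$families$annotated][1:2]
  nov <- fam$truth$families$family_id[!fam$truth$families$annotated][1:2]
  for (f in ann) {
    q <- fam$truth$members$aa_seq[fam$truth$members$family_id == f][1]
    expect_lte(homology_search(q, panel)$evalue, 1e-5)
  }
  for (f in nov) {
    q <- fam$truth$members$aa_seq[fam$truth$members$family_id == f][1]
    hit <- homology_search(q, panel)
    expect_gt(hit$evalue, 1e-5)
  }
  # empty panel: no hits at all
  empty <- panel[0, ]
  q <- fam$truth$members$aa_seq[1]
  expect_equal(nrow(homology_search(q, empty)), 0)
})

test_that("DEG lists have the configured sizes and overlap", {
  cfg <- sim_config(seed = 48, n_families = 160)
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  deg <- emit_deg_lists(fam$truth, cfg)
  expect_equal(length(deg$deg_a), 101)
  expect_equal(length(deg$deg_b), 83)
  expect_equal(deg$overlap, 30)

  cfg0 <- sim_config(seed = 48, n_families = 30, deg_sizes = c(6, 5), deg_overlap = 0)
  fam0 <- simulate_families(tree, cfg0)
  deg0 <- emit_deg_lists(fam0$truth, cfg0)
  expect_equal(deg0$overlap, 0)

  cfgN <- sim_config(seed = 48, n_families = 30, deg_sizes = c(6, 5), deg_overlap = 5)
  famN <- simulate_families(tree, cfgN)
  degN <- emit_deg_lists(famN$truth, cfgN)
  expect_true(all(degN$deg_b %in% degN$deg_a))
})

test_that("reads carry the spiked contamination fraction and are reproducible", {
  cfg <- sim_config(
    seed = 49, n_families = 6, n_reads = 20000,
    contamination_fraction = 0.05, deg_sizes = c(2, 2), deg_overlap = 1
  )
  tree <- simulate_taxonomy(cfg)
  fam <- simulate_families(tree, cfg)
  tx <- emit_transcripts(fam$proteomes, cfg)
  markers <- simulate_marker_panel(tree, cfg)
  rd <- emit_reads(tx[tx$species == "Nf", ], markers, cfg)
  n_contam <- sum(rd$truth$source == "contaminant")
  se3 <- 3 * sqrt(20000 * 0.05 * 0.95)
  expect_lt(abs(n_contam - 1000), se3)

  rd2 <- emit_reads(tx[tx$species == "Nf", ], markers, cfg)
  expect_identical(rd$reads, rd2$reads)

  cfg0 <- sim_config(
    seed = 49, n_families = 6, n_reads = 2000,
    contamination_fraction = 0, deg_sizes = c(2, 2), deg_overlap = 1
  )
  rd0 <- emit_reads(tx[tx$species == "Nf", ], markers, cfg0)
  expect_equal(sum(rd0$truth$source == "contaminant"), 0)
})

test_that("the whole generator is seed-deterministic", {
  cfg <- sim_config(seed = 50, n_families = 8, deg_sizes = c(3, 2), deg_overlap = 1)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$proteomes, d2$proteomes)
  expect_identical(d1$transcripts, d2$transcripts)
  expect_identical(d1$panel, d2$panel)
  expect_identical(d1$deg, d2$deg)
  expect_identical(d1$markers, d2$markers)
})

test_that("a dataset round-trips through plain-text files", {
  cfg <- sim_config(seed = 51, n_families = 5, deg_sizes = c(2, 2), deg_overlap = 1)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  tx <- read_fasta(file.path(dir, "Nf_transcripts.fasta"), "DNA")
  expect_setequal(tx$id, ds$transcripts$id[ds$transcripts$species == "Nf"])
  expect_setequal(tx$seq, ds$transcripts$seq[ds$transcripts$species == "Nf"])
  deg_a <- readLines(file.path(dir, "deg_condition_a.txt"))
  expect_identical(deg_a, ds$deg$deg_a)
})
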