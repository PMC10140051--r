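# Synthetic multi-species data with known ground truth. Protein families are
# born at chosen tree nodes and evolve by i.i.d. per-site substitution along
# branch lengths (no indels), keeping identity arithmetic analytic; families
# are absent from species outside their origin clade by construction, so
# taxonomically restricted proteins exist and are known. Transcripts,
# annotation panels, DEG lists and reads are emitted from the same truth.

#' Simulate protein families along the species tree
#'
#' Each family is assigned an origin node (sampled from
#' `config$origin_weights`), given a random ancestral protein (uniform
#' residues, initiator methionine fixed) and evolved down the tree: on a
#' branch of length b each site substitutes with probability 1 - exp(-b * r)
#' to a uniformly drawn different residue. Families born at or above
#' `config$old_node` are "old": they are flagged annotated and evolve at
#' `config$conserved_rate_scale` times the base rate. Differential-expression
#' labels for two conditions (sizes and overlap from the config) are drawn
#' over families with a focal-species member.
#'
#' @param tree Tree from [simulate_taxonomy()].
#' @param config A [sim_config()] object.
#' @param focal Focal species tip (default `"Nf"`), used for DEG labelling.
#' @return A list: `proteomes` (tibble `id`, `transcript_id`, `species`,
#'   `aa_seq`, `family_id`) and `truth` (list of `families` and `members`
#'   tibbles recording origin nodes, annotation and DEG flags, and member
#'   ids).
#' @export
simulate_families <- function(tree, config = sim_config(), focal = "Nf") {
  set.seed(config$seed)
  w <- config$origin_weights
  known <- c(tree$node.label, tree$tip.label)
  w <- w[names(w) %in% known]
  if (length(w) == 0) abort("no origin_weights node is present in the tree")
  old_nodes <- if (config$old_node %in% known) {
    ancestor_labels(tree, config$old_node)
  } else {
    character(0)
  }

  origins <- sample(names(w), config$n_families, replace = TRUE, prob = w)
  fam_ids <- sprintf("FAM%04d", seq_len(config$n_families))

  members <- vector("list", config$n_families)
  families <- vector("list", config$n_families)
  for (i in seq_len(config$n_families)) {
    len <- sample(seq(config$protein_length[1], config$protein_length[2]), 1)
    anc <- random_aa(len, first_m = TRUE)
    old <- origins[i] %in% old_nodes
    rate <- if (old) config$conserved_rate_scale else 1
    tips <- evolve_family(tree, origins[i], anc, rate)
    mem <- tibble(
      family_id = fam_ids[i],
      species = names(tips),
      protein_id = paste(names(tips), fam_ids[i], "p", sep = "_"),
      transcript_id = paste(names(tips), fam_ids[i], "t", sep = "_"),
      aa_seq = unname(tips)
    )
    members[[i]] <- mem
    families[[i]] <- tibble(
      family_id = fam_ids[i], origin_node = origins[i], annotated = old,
      rate_scale = rate, ancestral_seq = anc
    )
  }
  members <- list_rbind(members)
  families <- list_rbind(families)

  families <- assign_deg_labels(families, members, config, focal)

  proteomes <- members |>
    transmute(
      id = .data$protein_id, transcript_id = .data$transcript_id,
      species = .data$species, aa_seq = .data$aa_seq,
      family_id = .data$family_id
    )
  list(proteomes = proteomes, truth = list(families = families, members = members))
}

# Evolve one ancestral protein from `origin` down to every descendant tip.
evolve_family <- function(tree, origin, ancestral, rate) {
  start <- node_number(tree, origin)
  ntip <- ape::Ntip(tree)
  out <- character(0)
  recurse <- function(node, seq) {
    if (node <= ntip) {
      out[[tree$tip.label[node]]] <<- seq
      return(invisible())
    }
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (kid in kids) {
      b <- tree$edge.length[which(tree$edge[, 1] == node & tree$edge[, 2] == kid)]
      p <- 1 - exp(-b * rate)
      recurse(kid, mutate_seq(seq, p, fix_first = TRUE))
    }
  }
  if (start <= ntip) {
    out[[tree$tip.label[start]]] <- ancestral
  } else {
    recurse(start, ancestral)
  }
  out
}

# Two-condition DEG labels with exact sizes and overlap, drawn over families
# that have a focal-species member.
assign_deg_labels <- function(families, members, config, focal) {
  eligible <- members |>
    filter(.data$species == focal) |>
    pull("family_id") |>
    unique()
  n_a <- config$deg_sizes[1]
  n_b <- config$deg_sizes[2]
  ov <- config$deg_overlap
  need <- n_a + n_b - ov
  if (length(eligible) < need) {
    abort(sprintf(
      "DEG configuration needs %d focal-species families but only %d exist",
      need, length(eligible)
    ))
  }
  picked <- sample(eligible, need)
  a_set <- picked[seq_len(n_a)]
  b_set <- c(
    picked[seq_len(ov)],
    if (n_b > ov) picked[n_a + seq_len(n_b - ov)] else character(0)
  )
  families |>
    mutate(
      deg_a = .data$family_id %in% a_set,
      deg_b = .data$family_id %in% b_set
    )
}

#' Emit transcripts for simulated proteomes
#'
#' Each protein is back-translated with uniform synonymous codons (the
#' initiator M becomes ATG), a random stop codon is appended and random UTRs
#' are added; the last 5'-UTR codon position is forced to an in-frame stop
#' so the coding ORF is exactly the emitted protein. A configured fraction
#' of transcripts is truncated into the CDS at the 5' or 3' side to create
#' partial ORFs. All transcripts respect `config$min_len` (short ones are
#' 3'-padded).
#'
#' @param proteomes Proteome tibble from [simulate_families()].
#' @param config A [sim_config()] object.
#' @return A tibble: `id` (transcript id), `species`, `seq`, `truncated`
#'   (`"none"`, `"5prime"` or `"3prime"`).
#' @export
emit_transcripts <- function(proteomes, config = sim_config()) {
  set.seed(config$seed + 1L)
  codons <- codon_table()
  n <- nrow(proteomes)
  seqs <- character(n)
  truncated <- character(n)
  for (i in seq_len(n)) {
    cds <- back_translate(proteomes$aa_seq[i], codons)
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
    u5_len <- sample(seq(config$utr_length[1], config$utr_length[2]), 1)
    u3_len <- sample(seq(config$utr_length[1], config$utr_length[2]), 1)
    u5 <- random_nt(u5_len)
    # force an in-frame stop immediately upstream of the ATG
    if (u5_len >= 3) substr(u5, u5_len - 2, u5_len) <- "TAA"
    u3 <- random_nt(u3_len)
    tr <- paste0(u5, cds, stop_codon, u3)
    side <- "none"
    if (runif(1) < config$truncation_prob) {
      side <- switch(config$truncation_side,
        both = sample(c("5prime", "3prime"), 1),
        config$truncation_side
      )
      tr2 <- truncate_transcript(tr, side, u5_len, u3_len, config$min_len)
      if (is.null(tr2)) side <- "none" else tr <- tr2
    }
    if (nchar(tr) < config$min_len) {
      tr <- paste0(tr, random_nt(config$min_len - nchar(tr)))
    }
    seqs[i] <- tr
    truncated[i] <- side
  }
  tibble(
    id = proteomes$transcript_id, species = proteomes$species,
    seq = seqs, truncated = truncated
  )
}

codon_table <- function() {
  gc <- genetic_code()
  split(names(gc), unname(gc))
}

back_translate <- function(aa, codons = codon_table()) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  picked <- vapply(chars, function(a) {
    cs <- codons[[a]]
    if (length(cs) == 1) cs else sample(cs, 1)
  }, character(1), USE.NAMES = FALSE)
  paste(picked, collapse = "")
}

# Remove the UTR plus a few codons from one end, cutting into the CDS, while
# keeping at least `min_len` nt. NULL when no valid cut exists.
truncate_transcript <- function(tr, side, u5_len, u3_len, min_len) {
  L <- nchar(tr)
  extra <- 3L * sample(1:5, 1) + sample(0:2, 1)
  cut <- if (side == "5prime") u5_len + 3L + extra else u3_len + 3L + extra
  min_cut <- if (side == "5prime") u5_len + 6L else u3_len + 6L
  cut <- min(cut, L - min_len)
  if (cut < min_cut) return(NULL)
  if (side == "5prime") {
    # the first complete in-frame codon after the cut must not be ATG, or
    # the downstream ORF would still be predicted complete
    repeat {
      off <- cut - u5_len
      p <- u5_len + 3L * as.integer(ceiling(off / 3)) + 1L
      if (p + 2L > L || substr(tr, p, p + 2L) != "ATG") break
      cut <- cut + 3L
      if (cut > L - min_len) return(NULL)
    }
    substr(tr, cut + 1L, L)
  } else {
    substr(tr, 1L, L - cut)
  }
}

#' Emit the annotation panel
#'
#' One diverged homolog per annotated family (the ancestral protein evolved
#' by `config$panel_divergence` expected substitutions per site), no entry
#' for novel families, plus unrelated decoy proteins. Emulates a curated
#' reference protein database that covers only anciently-established
#' families.
#'
#' @param truth Truth list from [simulate_families()].
#' @param config A [sim_config()] object.
#' @return A tibble with `id` and `aa_seq`.
#' @export
emit_annotation_panel <- function(truth, config = sim_config()) {
  set.seed(config$seed + 2L)
  ann <- filter(truth$families, .data$annotated)
  p <- 1 - exp(-config$panel_divergence)
  hom <- map(seq_len(nrow(ann)), function(i) {
    tibble(
      id = paste0("PANEL_", ann$family_id[i]),
      aa_seq = mutate_seq(ann$ancestral_seq[i], p, fix_first = TRUE)
    )
  }) |> list_rbind()
  decoys <- tibble(
    id = sprintf("DECOY%03d", seq_len(config$n_decoys)),
    aa_seq = vapply(
      seq_len(config$n_decoys),
      function(i) {
        random_aa(sample(seq(config$protein_length[1], config$protein_length[2]), 1))
      },
      character(1)
    )
  )
  bind_rows(hom, decoys)
}

#' Emit the two differential-expression transcript lists
#'
#' Extracts the focal-species transcript ids of the families flagged
#' differentially expressed under each condition; sizes and overlap are
#' exactly the configured values.
#'
#' @param truth Truth list from [simulate_families()].
#' @param config A [sim_config()] object.
#' @param focal Focal species tip (default `"Nf"`).
#' @return A list: `deg_a`, `deg_b` (character vectors of transcript ids)
#'   and `overlap` (their intersection size).
#' @export
emit_deg_lists <- function(truth, config = sim_config(), focal = "Nf") {
  focal_tr <- truth$members |>
    filter(.data$species == focal) |>
    select("family_id", "transcript_id")
  a <- focal_tr$transcript_id[
    focal_tr$family_id %in% truth$families$family_id[truth$families$deg_a]
  ]
  b <- focal_tr$transcript_id[
    focal_tr$family_id %in% truth$families$family_id[truth$families$deg_b]
  ]
  list(deg_a = a, deg_b = b, overlap = length(intersect(a, b)))
}

#' Simulate a COI-like marker panel
#'
#' One mitochondrial-marker sequence per tree tip, evolved along the tree
#' from a random ancestral sequence at an accelerated nucleotide rate, so
#' markers are related but species-distinct -- the "species filter" used for
#' read-level contamination screening.
#'
#' @param tree Tree from [simulate_taxonomy()].
#' @param config A [sim_config()] object.
#' @param rate_nt Nucleotide rate multiplier (default 2, mitochondrial-fast).
#' @return A tibble with `species` and `seq`.
#' @export
simulate_marker_panel <- function(tree, config = sim_config(), rate_nt = 2) {
  set.seed(config$seed + 5L)
  anc <- random_nt(config$marker_length)
  root_label <- node_label(tree, ape::Ntip(tree) + 1L)
  ntip <- ape::Ntip(tree)
  out <- character(0)
  recurse <- function(node, seq) {
    if (node <= ntip) {
      out[[tree$tip.label[node]]] <<- seq
      return(invisible())
    }
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (kid in kids) {
      b <- tree$edge.length[which(tree$edge[, 1] == node & tree$edge[, 2] == kid)]
      p <- 1 - exp(-b * rate_nt)
      recurse(kid, mutate_seq(seq, p, alphabet = NT_ALPHABET))
    }
  }
  recurse(node_number(tree, root_label), anc)
  tibble(species = names(out), seq = unname(out))
}

#' Emit sequencing reads with spiked contamination
#'
#' Fixed-length reads with Phred+33 qualities: each read is drawn (i) with
#' probability `contamination_fraction` from the contaminant species' COI
#' marker, (ii) with probability `native_coi_fraction` from the focal
#' species' own marker, (iii) otherwise uniformly from the transcript set.
#' Start position and strand are uniform; a configured fraction of reads
#' receives low (mean < 30) qualities.
#'
#' @param transcripts Transcript tibble (focal species) with `id`, `seq`.
#' @param marker_panel Marker tibble from [simulate_marker_panel()].
#' @param config A [sim_config()] object.
#' @param focal Focal species tip (default `"Nf"`).
#' @return A list: `reads` (tibble `id`, `seq`, `qual`) and `truth` (tibble
#'   `id`, `source` in transcript/native_coi/contaminant) plus
#'   `contamination_fraction` realised.
#' @export
emit_reads <- function(transcripts, marker_panel, config = sim_config(),
                       focal = "Nf") {
  set.seed(config$seed + 4L)
  n <- config$n_reads
  L <- config$read_length
  pool <- transcripts$seq[nchar(transcripts$seq) >= L]
  if (length(pool) == 0) abort("no transcript is as long as read_length")
  contam_seq <- marker_panel$seq[marker_panel$species == config$contaminant_species]
  native_seq <- marker_panel$seq[marker_panel$species == focal]
  if (length(contam_seq) != 1 || length(native_seq) != 1) {
    abort("marker panel must contain the focal and contaminant species")
  }
  u <- runif(n)
  source <- ifelse(
    u < config$contamination_fraction, "contaminant",
    ifelse(u < config$contamination_fraction + config$native_coi_fraction,
      "native_coi", "transcript"
    )
  )
  seqs <- character(n)
  quals <- character(n)
  low <- runif(n) < config$low_quality_fraction
  for (i in seq_len(n)) {
    src <- switch(source[i],
      contaminant = contam_seq,
      native_coi = native_seq,
      transcript = pool[sample.int(length(pool), 1)]
    )
    start <- sample.int(nchar(src) - L + 1L, 1)
    r <- substr(src, start, start + L - 1L)
    if (runif(1) < 0.5) r <- revcomp(r)
    seqs[i] <- r
    q <- if (low[i]) sample(20:29, L, TRUE) else sample(32:40, L, TRUE)
    quals[i] <- intToUtf8(q + 33L)
  }
  reads <- tibble(
    id = sprintf("read%06d", seq_len(n)),
    seq = seqs, qual = quals
  )
  truth <- tibble(id = reads$id, source = source)
  list(
    reads = reads, truth = truth,
    contamination_fraction = mean(source == "contaminant")
  )
}

#' Run the whole synthetic-data generator
#'
#' Convenience wrapper chaining taxonomy, family simulation, transcript,
#' panel, DEG-list, marker and read emission under one configuration.
#'
#' @param config A [sim_config()] object.
#' @param focal Focal species tip (default `"Nf"`).
#' @param reads Also emit reads (default FALSE; read emission is the slow
#'   part and many analyses only need sequences).
#' @return A list: `tree`, `proteomes`, `truth`, `transcripts`, `panel`,
#'   `deg`, `markers`, and (when requested) `reads`.
#' @export
simulate_dataset <- function(config = sim_config(), focal = "Nf", reads = FALSE) {
  tree <- simulate_taxonomy(config)
  fam <- simulate_families(tree, config, focal)
  transcripts <- emit_transcripts(fam$proteomes, config)
  panel <- emit_annotation_panel(fam$truth, config)
  deg <- emit_deg_lists(fam$truth, config, focal)
  markers <- simulate_marker_panel(tree, config)
  out <- list(
    tree = tree, proteomes = fam$proteomes, truth = fam$truth,
    transcripts = transcripts, panel = panel, deg = deg, markers = markers
  )
  if (reads) {
    focal_tr <- filter(transcripts, .data$species == focal)
    out$reads <- emit_reads(focal_tr, markers, config, focal)
  }
  out
}

#' Expected emergence category for a family origin
#'
#' The taxonomic-scan category (tip label) at which a family born at
#' `origin_node` should be called: the farthest scan category whose species
#' descends from the origin. Families born at the tree root span every
#' category and should yield no emergence call.
#'
#' @param tree A `phylo` tree.
#' @param origin_node Node (or tip) label where the family was born.
#' @param focal Focal species tip (default `"Nf"`).
#' @return A tip label, or `NA_character_` for root-born families.
#' @export
expected_emergence <- function(tree, origin_node, focal = "Nf") {
  cats <- scan_categories(tree, focal)
  desc <- descendant_tips(tree, origin_node)
  if (all(cats %in% desc)) return(NA_character_)
  inside <- cats %in% desc
  cats[max(which(inside))]
}

#' Write a simulated dataset to plain-text files
#'
#' FASTA (60-column) per-species transcriptomes and proteomes, the
#' annotation panel, marker panel, DEG lists, truth tables (TSV) and reads
#' (FASTQ) when present.
#'
#' @param dataset List from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sp in unique(dataset$transcripts$species)) {
    write_fasta(
      filter(dataset$transcripts, .data$species == sp),
      file.path(dir, paste0(sp, "_transcripts.fasta")), "DNA"
    )
    pr <- filter(dataset$proteomes, .data$species == sp)
    write_fasta(
      tibble(id = pr$id, seq = pr$aa_seq),
      file.path(dir, paste0(sp, "_proteome.fasta")), "AA"
    )
  }
  write_fasta(
    tibble(id = dataset$panel$id, seq = dataset$panel$aa_seq),
    file.path(dir, "annotation_panel.fasta"), "AA"
  )
  write_fasta(
    tibble(id = dataset$markers$species, seq = dataset$markers$seq),
    file.path(dir, "marker_panel.fasta"), "DNA"
  )
  writeLines(dataset$deg$deg_a, file.path(dir, "deg_condition_a.txt"))
  writeLines(dataset$deg$deg_b, file.path(dir, "deg_condition_b.txt"))
  fam <- dataset$truth$families
  utils::write.table(
    fam[, c("family_id", "origin_node", "annotated", "deg_a", "deg_b")],
    file.path(dir, "truth_families.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    dataset$truth$members[, c("family_id", "species", "protein_id", "transcript_id")],
    file.path(dir, "truth_members.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  ape::write.tree(dataset$tree, file.path(dir, "taxonomy.nwk"))
  if (!is.null(dataset$reads)) {
    write_fastq(dataset$reads$reads, file.path(dir, "reads.fastq"))
  }
  invisible(dir)
}
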