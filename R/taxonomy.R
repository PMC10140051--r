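# Study taxonomy: a fixed, named, ultrametric species tree mirroring the
# taxonomic categories of a calanoid copepod survey. Six focal species
# (three congeners nested in genus < family < myelinate group < order) plus
# outgroup tips representing progressively more distant categories
# (a second in-order superfamily, harpacticoid and cyclopoid copepods, a
# non-copepod crustacean, a non-crustacean arthropod).

#' Simulation configuration
#'
#' One object carrying every tunable of the synthetic-data generator; the
#' single integer `seed` fully determines all outputs (individual emitters
#' draw from fixed small offsets of it).
#'
#' @param seed Integer seed.
#' @param n_families Number of protein families to simulate.
#' @param origin_weights Named weights over internal node labels: the
#'   probability that a family is born at that node.
#' @param protein_length Length range (aa) of ancestral proteins.
#' @param substitution_rate Global multiplier on branch lengths (expected
#'   substitutions per site).
#' @param conserved_rate_scale Rate multiplier applied to families born at or
#'   above `old_node` (anciently-born families evolve under stronger
#'   purifying selection).
#' @param old_node Node at or above which families count as "old": they are
#'   the annotated, conserved ones.
#' @param include_outgroups Keep the five non-focal tips (FALSE gives the
#'   6-tip focal tree).
#' @param utr_length UTR length range (nt) for emitted transcripts.
#' @param truncation_prob Probability a transcript is truncated into its CDS.
#' @param truncation_side `"both"`, `"5prime"` or `"3prime"`.
#' @param min_len Minimum emitted transcript length (nt), default 301.
#' @param deg_sizes Sizes of the two differential-expression lists.
#' @param deg_overlap Number of transcripts present in both lists.
#' @param n_decoys Unrelated decoy proteins in the annotation panel.
#' @param panel_divergence Divergence (expected substitutions per site)
#'   between a family's ancestral protein and its panel homolog.
#' @param contamination_fraction Fraction of reads drawn from a foreign
#'   species' COI marker.
#' @param native_coi_fraction Fraction of reads drawn from the focal
#'   species' own COI marker.
#' @param low_quality_fraction Fraction of reads given low Phred qualities.
#' @param read_length Read length (nt).
#' @param n_reads Number of reads emitted.
#' @param contaminant_species Tip label whose marker contaminating reads are
#'   drawn from.
#' @param marker_length COI-like marker length (nt), default the 658-nt
#'   barcode region.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_families = 160,
                       origin_weights = c(
                         Arthropoda = 0.12, Crustacea = 0.08, Copepoda = 0.12,
                         Calanoida = 0.18, Myelinata = 0.12, Calanidae = 0.18,
                         Neocalanus = 0.20
                       ),
                       protein_length = c(100, 500),
                       substitution_rate = 1,
                       conserved_rate_scale = 0.25,
                       old_node = "Copepoda",
                       include_outgroups = TRUE,
                       utr_length = c(30, 120),
                       truncation_prob = 0.1,
                       truncation_side = c("both", "5prime", "3prime"),
                       min_len = 301,
                       deg_sizes = c(101, 83),
                       deg_overlap = 30,
                       n_decoys = 50,
                       panel_divergence = 0.3,
                       contamination_fraction = 0.05,
                       native_coi_fraction = 0.02,
                       low_quality_fraction = 0.05,
                       read_length = 75,
                       n_reads = 20000,
                       contaminant_species = "Ha",
                       marker_length = 658) {
  truncation_side <- match.arg(truncation_side)
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    n_families >= 1,
    all(origin_weights >= 0), sum(origin_weights) > 0,
    length(protein_length) == 2, protein_length[1] >= 2,
    protein_length[1] <= protein_length[2],
    substitution_rate >= 0, conserved_rate_scale >= 0,
    truncation_prob >= 0, truncation_prob <= 1,
    min_len >= 1,
    length(deg_sizes) == 2, all(deg_sizes >= 0),
    deg_overlap >= 0, deg_overlap <= min(deg_sizes),
    contamination_fraction >= 0, contamination_fraction <= 1,
    native_coi_fraction >= 0, native_coi_fraction + contamination_fraction <= 1,
    low_quality_fraction >= 0, low_quality_fraction <= 1,
    read_length >= 21, n_reads >= 0, marker_length >= read_length
  )
  structure(
    list(
      seed = as.integer(seed), n_families = n_families,
      origin_weights = origin_weights, protein_length = protein_length,
      substitution_rate = substitution_rate,
      conserved_rate_scale = conserved_rate_scale, old_node = old_node,
      include_outgroups = include_outgroups, utr_length = utr_length,
      truncation_prob = truncation_prob, truncation_side = truncation_side,
      min_len = min_len, deg_sizes = deg_sizes, deg_overlap = deg_overlap,
      n_decoys = n_decoys, panel_divergence = panel_divergence,
      contamination_fraction = contamination_fraction,
      native_coi_fraction = native_coi_fraction,
      low_quality_fraction = low_quality_fraction,
      read_length = read_length, n_reads = n_reads,
      contaminant_species = contaminant_species, marker_length = marker_length
    ),
    class = "sim_config"
  )
}

# Ultrametric node heights (expected substitutions per site, tip to node).
# Heights are calibrated so that, for proteins up to 500 aa, the similarity
# difference between adjacent scan categories of a family present in both
# stays safely below the 25 log-unit emergence threshold. Each substituted
# residue costs about 0.73 log units of -log10(E) similarity, and the drop
# between adjacent categories fluctuates with the binomial substitution
# counts of the unshared branches (sd ~5-7 log units for 500-aa proteins),
# so the requirement is mean + ~2.5 sd < 25 per boundary: adjacent
# within-order increments are kept at 0.02 expected substitutions per site.
# Between-clade absences still produce drops of 100+ log units. Sister
# congeners split at height 0.0275 (about 95% expected amino-acid identity
# for young families).
TAXONOMY_NEWICK_FULL <- paste0(
  "(((((((Nf:0.0275,Np:0.0275,Nc:0.0275)Neocalanus:0.02,Cm:0.0475)",
  "Calanidae:0.02,Eb:0.0675)Myelinata:0.02,Cn:0.0875,Mp:0.0875)",
  "Calanoida:0.0625,Ha:0.15,Cy:0.15)Copepoda:0.05,Cr:0.2)Crustacea:0.06,",
  "Ar:0.26)Arthropoda;"
)

TAXONOMY_NEWICK_FOCAL <- paste0(
  "((((Nf:0.0275,Np:0.0275,Nc:0.0275)Neocalanus:0.02,Cm:0.0475)",
  "Calanidae:0.02,Eb:0.0675)Myelinata:0.02,Mp:0.0875)Calanoida;"
)

#' Simulate the study taxonomy
#'
#' Returns the fixed species tree the generator evolves families along: tips
#' are species abbreviations (Nf, Np, Nc congeners; Cm completing the
#' family; Eb completing the myelinate group; Mp completing the order; Cn,
#' Ha, Cy, Cr, Ar outgroup categories), internal nodes are named clades.
#' Deterministic: the same configuration always returns the same tree.
#'
#' @param config A [sim_config()] object.
#' @return An `ape::phylo` tree with named internal nodes and branch lengths
#'   in expected substitutions per site.
#' @export
simulate_taxonomy <- function(config = sim_config()) {
  txt <- if (config$include_outgroups) TAXONOMY_NEWICK_FULL else TAXONOMY_NEWICK_FOCAL
  tree <- ape::read.tree(text = txt)
  tree$edge.length <- tree$edge.length * config$substitution_rate
  tree
}

# --- small phylo helpers (labelled-node access) ------------------------------

node_number <- function(tree, label) {
  if (label %in% tree$tip.label) {
    return(match(label, tree$tip.label))
  }
  idx <- match(label, tree$node.label)
  if (is.na(idx)) abort(paste0("unknown node label: ", label))
  ape::Ntip(tree) + idx
}

node_label <- function(tree, number) {
  if (number <= ape::Ntip(tree)) {
    tree$tip.label[number]
  } else {
    tree$node.label[number - ape::Ntip(tree)]
  }
}

#' Tips descending from a named node
#'
#' @param tree A `phylo` tree with named internal nodes.
#' @param label A tip or internal node label.
#' @return Character vector of descendant tip labels (the tip itself when
#'   `label` names a tip).
#' @export
descendant_tips <- function(tree, label) {
  n <- node_number(tree, label)
  if (n <= ape::Ntip(tree)) return(tree$tip.label[n])
  ape::extract.clade(tree, n)$tip.label
}

# Labels of `node` and all its ancestors up to the root.
ancestor_labels <- function(tree, label) {
  n <- node_number(tree, label)
  root <- ape::Ntip(tree) + 1L
  out <- node_label(tree, n)
  while (n != root) {
    n <- tree$edge[tree$edge[, 2] == n, 1]
    out <- c(out, node_label(tree, n))
  }
  out
}

#' Order taxonomic categories by distance from a focal species
#'
#' The taxonomic-scan category order: every tip, nearest first, starting
#' with the focal species itself. Ties (equidistant tips) keep the tree's
#' tip order, which matches the conventional category ordering.
#'
#' @param tree A `phylo` tree.
#' @param focal Focal tip label (default `"Nf"`).
#' @return Character vector of tip labels, focal first.
#' @export
scan_categories <- function(tree, focal = "Nf") {
  d <- ape::cophenetic.phylo(tree)[focal, ]
  names(sort(d[tree$tip.label], method = "radix"))
}
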