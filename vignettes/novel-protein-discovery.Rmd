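---
title: "Discovering taxonomically restricted proteins from multi-species transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering taxonomically restricted proteins from multi-species transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoprospect)
library(dplyr)
```

## The problem and the approach

De novo transcriptomes of non-model animals routinely contain predicted
proteins that no reference database annotates. Some of these are assembly
artifacts; others are genuine lineage-restricted ("taxonomically
restricted") genes, and the most interesting among them respond to
environmental conditions. `orthoprospect` implements a desk-scale pipeline
for finding such candidates across the transcriptomes of several related
species — here modelled on a set of calanoid copepods spanning a genus, a
family, a myelinate-lineage group and an order — and for locating the
taxonomic point at which each candidate family emerged.

The chain is:

1. **Assembly QC** (`assembly_stats()`, `core_completeness()`): transcript
   counts, length extremes, N25/N50/N75, GC content and a homology-based
   core-gene completeness measure.
2. **Read screening** (`clean_reads()`, `assign_reads()`,
   `confirm_species()`, `rrna_screen()`): quality filtering and
   contamination quantification against a COI marker "species filter".
3. **Protein prediction** (`predict_proteome()`): the single best
   (longest) ORF of at least 100 aa per transcript across six frames, with
   completeness classification; downstream analysis keeps only complete
   proteins.
4. **Ortholog clustering** (`cluster_proteomes()`,
   `annotate_clusters()`): a homology graph at E ≤ 1e-15 partitioned by
   Markov clustering (inflation 1.5), then cluster-level annotation
   against a reference panel at E ≤ 1e-5.
5. **Set algebra** (`shared_by_all()`, `purge_foreign()`,
   `sharing_summary()`, `nonannotated_summary()`): sharing orders,
   shared-by-all selection for a taxonomic category, and purging of
   clusters containing foreign species.
6. **Bioprospecting** (`prospect_pipeline()`): intersect the non-annotated
   homogeneous clusters with differential-expression lists, scan each
   candidate across per-category proteomes, call the emergence point from
   the similarity profile and corroborate it with a neighbor-joining
   stem-length check.

## Homology scoring

All protein comparisons use exact Smith–Waterman local alignment (affine
gaps, BLOSUM62, gap open 11, extend 1) scored on the Karlin–Altschul
scale:

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'}$$

with the standard gapped constants $\lambda = 0.267$, $K = 0.041$, query
length $m$ and database size $n$ (total residues). Similarity is
$-\log_{10} E$, floored at 0 and capped at 300 (E-values are clamped at
1e-300 so the similarity scale stays finite rather than degenerating to a
printed "0.0"). These constants are the conventional gapped-BLOSUM62
parameterisation; absolute E-values therefore differ from any particular
BLAST build, which is why every decision rule downstream depends only on
the *shape* of the similarity profile, never on absolute values.

## Emergence calling

For a query protein, `taxonomic_scan()` records the best-hit similarity in
one proteome per taxonomic category, ordered from the focal species
outward. `call_emergence()` walks adjacent category boundaries nearest to
farthest and calls the emergence point at the first boundary where
similarity falls by at least `delta_min` log units (a missing next
category counts as similarity 0), or beyond which every farther category
has no positive-scoring hit. Profiles that only decline gradually — the
behaviour of broadly conserved families such as the glutathione
S-transferases — produce no call.

`delta_min = 25` is a calibration taken from the observation that
adjacent-category differences for a conserved, rapidly evolving reference
family stay within about 25 log units; it is exposed as an argument
because no published numeric rule exists.

The call is corroborated by `stem_check()`: a neighbor-joining tree
(`ape::nj`, negative branches clamped to zero, rooted on the most distant
available outgroup category, preferring the non-copepod crustacean then
the non-crustacean arthropod) is built from Poisson-corrected pairwise
distances ($d = -\ln(1-p)$, $p$ the fraction of differing aligned
positions in a global alignment, clamped at 0.999) between the
per-category hits. When the top hit covers less than half the query, the
next-best hit substitutes for it, since short partial hits distort
distance estimates. The call is supported when the high-similarity
categories are monophyletic and their stem branch exceeds 0.5
substitutions per site; conserved families show stems well under that.
This distance tree is a deterministic stand-in for Bayesian or
maximum-likelihood inference — adequate for a stem-length screen, not a
substitute for a publishable phylogeny.

## The synthetic-data generator

Real multi-species discovery runs involve tens of millions of reads and
external databases; the package instead validates every stage against a
generator with known ground truth (`simulate_dataset()`).

**Species tree.** A fixed, named, ultrametric tree: three congeners
(`Nf`, `Np`, `Nc`), a fourth in-family species (`Cm`), a fifth completing
the myelinate group (`Eb`), a sixth completing the order (`Mp`), plus
outgroup categories (`Cn` within the order, harpacticoid `Ha`, cyclopoid
`Cy`, non-copepod crustacean `Cr`, non-crustacean arthropod `Ar`).

**Families.** Each family is born at a node drawn from
`origin_weights`, receives a random ancestral protein of 100–500 aa
(initiator M fixed) and evolves down the tree by i.i.d. per-site
substitution: on a branch of length $b$ a site substitutes with
probability $1 - e^{-b r}$ to a uniformly drawn different residue. No
indels are introduced, keeping identity arithmetic analytic for the test
oracles. Families are present only in species descending from their
origin, so taxonomically restricted proteins exist by construction.

**Age, annotation and conservation.** Families born at or above the
configured `old_node` (default the whole-copepod clade) are "old": they
are the ones the annotation panel covers, and they evolve at
`conserved_rate_scale` (default 0.25) times the base rate. Coupling age,
annotation and conservation reproduces the empirical contrast the caller
relies on — anciently established families decline gradually across the
whole scan range, while young families are highly similar within their
clade and absent outside it.

**Calibration of tree heights.** Similarity is proportional to alignment
length times identity: each substituted residue costs about
$6.3 \cdot \lambda / \ln 10 \approx 0.73$ log units (6.3 being the mean
BLOSUM62 score difference between a conserved and a substituted
position). The drop between adjacent categories also fluctuates with the
binomial substitution counts on the unshared branch segments — roughly
5–7 log units (sd) for 500-aa proteins at these divergences. For the
no-call guarantee on families present in both categories the requirement
is therefore mean + ~2.5 sd < 25 log units per boundary, which bounds
adjacent divergence increments at about 0.02 expected substitutions per
site for full-rate families. The default heights (congeners at 0.0275,
then 0.0475 / 0.0675 / 0.0875 for the successively larger clades) follow
that rule; deeper nodes are wider apart, which is safe because families
spanning them are conserved-rate. Sister congeners of a young family
expect ~95% amino-acid identity under these defaults; between-family
identity is that of unrelated random sequences (~6%).

**Transcripts.** Proteins are back-translated with uniform synonymous
codons, given a random stop codon and random UTRs (the last 5'-UTR codon
slot is forced to an in-frame stop so the predicted ORF is exactly the
simulated protein), and padded to the 301-nt minimum transcript length
used by the emulated assemblies. A configured fraction is truncated into
the CDS at the 5' or 3' side to create partial ORFs; 5' cuts skip
positions that would leave an in-frame ATG at the first complete codon,
since the downstream ORF would then still be complete.

**Annotation panel, DEG lists, markers, reads.** The panel holds one
diverged homolog (0.3 expected substitutions per site) per old family
plus unrelated decoys. Differential-expression lists for two conditions
are drawn over focal-species families with exact sizes and overlap
(defaults 101, 83 and 30, the structure of the emulated study). COI-like
markers evolve along the tree at an accelerated nucleotide rate; reads
are fixed-length with Phred+33 qualities, a configured fraction drawn
from a foreign species' marker (spiked contamination) and a small
fraction from the native marker.

**What the generator does not emulate.** Indels and alignment ambiguity,
sequencing-error substitutions in reads, expression levels (DEG status is
label-level), isoforms, assembly chimerism and fragmentation beyond the
simple truncation model, and database-scale search statistics. Passing
tests therefore demonstrate correctness of the pipeline's logic and
statistics under a clean evolutionary model, not performance on raw field
data.

## Numerical and design choices

- **"Best" ORF = longest**, with a fully deterministic tie-break
  (+ strand, then lowest frame, then smallest start); the coding-potential
  Markov model used by production ORF predictors is out of scope. The
  length threshold is ≥ 100 aa.
- **Maximal ORFs only**: per stop-free segment, the ORF runs from the
  transcript edge (no upstream in-frame stop) or the first methionine;
  shorter contained ORFs are not reported.
- **Nxx ties** follow the standard convention: the contig whose inclusion
  first reaches the threshold supplies the value.
- **GC content** excludes ambiguous bases from the denominator.
- **Core completeness**: complete when the best hit at E ≤ 1e-10 covers
  ≥ 90% of the core protein; fragmented when a qualifying hit covers
  less; missing otherwise. A convention, documented as non-equivalent to
  BUSCO scores.
- **MCL details**: column-normalised bitscore matrix with self-loops at
  each column's maximum weight, expansion 2, inflation 1.5, pruning below
  1e-5, convergence when the largest entry change is below 1e-8, at most
  100 iterations; clusters are the connected components of the converged
  matrix. A connected-components fallback (`method = "components"`)
  serves as the oracle in tests. Canonicalisation by protein id makes the
  result independent of input order.
- **Cluster annotation** is any-member-best-hit at E ≤ 1e-5.
- **Percent formatting** in summary tables is one decimal, round half
  up, matching the printed-report convention the worked examples
  reproduce.
- **k-mer read classifier**: k = 21, at least 3 shared k-mers and a
  unique best species; ties and sub-threshold reads stay unassigned. A
  deterministic, alignment-free stand-in for short-read mapping that is
  adequate for divergent mitochondrial markers.
- **rRNA screen**: sequences aligning to any reference over ≥ 100 nt at
  ≥ 80% identity are reported; those at ≤ 93% identity to the native
  reference ("low 90s or below") are flagged foreign.
- **Read cleaning** trims the first 12 bases, then drops reads under
  50 nt or mean Phred below 30 — trim first, filters second.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script runs use desk-scale problem sizes
chosen to exercise every code path while completing quickly: 1000 random
transcripts for the ORF oracle; 1000 random length sets for Nxx; 20
families × 6 species × 5 seeds for clustering recovery (adjusted Rand
index vs truth); 50 target families per origin condition (plus root-born
background families so distant categories are non-empty) for emergence
recovery; 20,000 reads with 5% spiked contamination for the species
filter; 20 random additive quartets for the neighbor-joining check; the
study-default 160 families for the 101/83/30 DEG structure.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(
  seed = 1, n_families = 16, truncation_prob = 0,
  origin_weights = c(Neocalanus = 0.5, Arthropoda = 0.5),
  deg_sizes = c(6, 5), deg_overlap = 2
)
ds <- simulate_dataset(cfg)

focal6 <- c("Nf", "Np", "Nc", "Cm", "Eb", "Mp")
clusters <- ds$proteomes |>
  filter(species %in% focal6) |>
  cluster_proteomes() |>
  annotate_clusters(ds$panel)

report <- prospect_pipeline(
  clusters, ds$deg$deg_a, ds$deg$deg_b,
  category_databases(ds$proteomes, ds$tree)
)
report
```

## Known limitations

- E-values are parametric approximations under standard constants;
  absolute values differ from BLAST services, so only profile shapes are
  interpreted.
- The emergence rule is a single-threshold heuristic; borderline families
  whose within-clade similarity steps approach `delta_min` can be called
  one category early (the calibration above bounds, but cannot
  eliminate, this).
- The distance cladogram is a screening tree; stem support says nothing
  about topological support within the high-similarity clade.
- Cluster-level DEG intersection assumes transcript ids propagate from
  the focal species' predicted proteins; transcript-level and
  cluster-level counts can differ when clustering merges families.
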