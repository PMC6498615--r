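# End-to-end orchestration: simulate (or load) genomes, compute ANI and the
# hybrid distance tree, cluster families, build the pangenome matrix and the
# core-SNP tree, and profile clades.

#' Map truth families to discovered family labels
#'
#' For ground-truth comparisons: each truth family is mapped to the
#' discovered family that contains the plurality of its member genes.
#'
#' @param families a `family_table` from [build_families()].
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @return named character vector: truth family id -> discovered family id.
#' @export
match_truth_families <- function(families, truth) {
  fog <- truth$family_of_gene
  common <- intersect(names(fog), names(families$family_of))
  tab <- table(fog[common], families$family_of[common])
  found <- colnames(tab)[apply(tab, 1, which.max)]
  setNames(found, rownames(tab))
}

#' Run the full comparative-genomics pipeline
#'
#' Executes every stage on a genome set: ANIb + ANIm matrices and the hybrid
#' distance matrix with its rooted NJ tree; protein families, the ternary
#' pangenome matrix and its core/variable/singleton partition; the
#' unfragmented-core SNP supermatrix and its K2P NJ bootstrap tree; and the
#' complete-linkage dendrogram of the pangenome matrix. The outgroup (any
#' genome whose species label differs from the majority label) is excluded
#' from the pangenome and core-SNP stages and used to root the ANI tree.
#'
#' @param genomes named list of [genome_assembly()] objects.
#' @param annotations annotation data.frame for all genomes.
#' @param proteins named `AAStringSet` of protein translations.
#' @param ani_par [ani_params()].
#' @param id_threshold,cov_threshold family clustering thresholds.
#' @param n_boot bootstrap replicates for the core-SNP tree (default 100).
#' @param seed seed for the bootstrap resampling stream.
#' @return a list with `anib`, `anim`, `hybrid_dist`, `ani_tree` (rooted if
#'   an outgroup is present), `families`, `ternary`, `partition`,
#'   `core_families`, `supermatrix`, `core_tree` (with supports),
#'   `dendrogram`, and `ingroup` (genome ids analysed in the pangenome).
#' @export
run_pipeline <- function(genomes, annotations, proteins,
                         ani_par = ani_params(), id_threshold = 0.80,
                         cov_threshold = 0.80, n_boot = 100L, seed = 1L) {
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  species <- vapply(genomes, `[[`, character(1), "species_label")
  names(species) <- ids
  major <- names(sort(table(species), decreasing = TRUE))[1]
  ingroup <- ids[species == major]
  outgroup <- setdiff(ids, ingroup)

  message("panclade: ANIb matrix over ", length(ids), " genomes")
  anib <- ani_matrix(genomes, "anib", ani_par)
  message("panclade: ANIm matrix")
  anim <- ani_matrix(genomes, "anim", ani_par)
  hybrid <- hybrid_distance_matrix(anim, anib, species)
  ani_tree <- nj_tree(hybrid)
  if (length(outgroup) == 1L) ani_tree <- root_tree(ani_tree, outgroup)

  message("panclade: clustering ", length(proteins), " proteins")
  ing_ann <- annotations[annotations$genome_id %in% ingroup, ]
  fams <- build_families(proteins[names(proteins) %in% ing_ann$gene_id],
                         id_threshold, cov_threshold)
  ternary <- ternary_presence(fams, ing_ann, genomes = sort(ingroup))
  part <- partition_pangenome(ternary, lengths(fams$members))

  message("panclade: core-SNP supermatrix")
  core <- select_core_unfragmented(fams, ternary, ing_ann)
  sm <- core_snp_supermatrix(genomes[match(sort(ingroup), ids)], ing_ann,
                             fams, ternary)
  message("panclade: bootstrap NJ tree (", n_boot, " replicates)")
  core_tree <- bootstrap_support(sm, n_reps = n_boot, seed = seed)

  dend <- complete_linkage_dendrogram(ternary)

  list(anib = anib, anim = anim, hybrid_dist = hybrid, ani_tree = ani_tree,
       families = fams, ternary = ternary, partition = part,
       core_families = core, supermatrix = sm, core_tree = core_tree,
       dendrogram = dend, ingroup = sort(ingroup), outgroup = outgroup,
       species = species)
}

#' Robinson-Foulds distance to the clade skeleton
#'
#' Collapses each clade of the comparison tree to its set of tips and counts
#' how many clade bipartitions are missing from the tree, plus how many
#' non-trivial tree bipartitions conflict with clade monophyly. A value of 0
#' means every clade is monophyletic.
#'
#' @param tree an `ape::phylo` tree.
#' @param clade_of named vector genome id -> clade label (tips absent from
#'   the mapping are ignored).
#' @return number of clade labels that are not monophyletic in the tree.
#' @export
clades_not_monophyletic <- function(tree, clade_of) {
  tips <- intersect(tree$tip.label, names(clade_of))
  cl <- clade_of[tips]
  clades <- unique(cl)
  ntip <- length(tree$tip.label)
  keys <- tree_bipartitions(tree)
  all_sorted <- sort(tree$tip.label, method = "radix")
  ref <- all_sorted[1]
  bad <- 0L
  for (cd in clades) {
    side <- sort(tips[cl == cd], method = "radix")
    if (length(side) < 2L || length(side) > ntip - 2L) next # trivially mono
    if (ref %in% side) side <- setdiff(all_sorted, side)
    if (!(paste(side, collapse = "\r") %in% keys)) bad <- bad + 1L
  }
  bad
}
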