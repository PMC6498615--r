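#' Configuration for the synthetic genome generator
#'
#' The generator emulates a structured bacterial population: a star-like
#' clade tree with a fixed number of clades, per-branch nucleotide divergence
#' under a Kimura 2-parameter substitution process, per-strain gene loss and
#' pseudogenization, one planted clade-specific operon block per clade, and
#' an optional divergent outgroup genome.
#'
#' @param n_clades number of clades (default 4).
#' @param strains_per_clade integer vector of strains per clade (recycled to
#'   `n_clades`; default 5 each).
#' @param n_ancestral_families number of ancestral gene families shared by the
#'   whole ingroup (default 300).
#' @param gene_length_range ancestral gene length range in bp, inclusive of
#'   the terminal stop codon; lengths are drawn uniformly on codon counts
#'   (default 300--1500).
#' @param intergenic_length fixed intergenic spacer length in bp (default 50).
#' @param inter_clade_divergence substitutions/site on each clade stem branch
#'   (default 0.02).
#' @param intra_clade_divergence substitutions/site on each strain tip branch
#'   (default 0.002).
#' @param transition_bias ratio of transition to transversion rates
#'   (default 4).
#' @param gene_loss_prob per-family per-strain loss probability (default 0.03).
#' @param pseudogenization_prob per-family per-strain pseudogenization
#'   probability (default 0.02).
#' @param blocks_per_clade planted clade-specific insert blocks per clade
#'   (default 1).
#' @param block_cds CDS count of each planted block (default 10).
#' @param outgroup emit one divergent outgroup genome (default TRUE).
#' @param outgroup_divergence substitutions/site on the outgroup stem branch
#'   (default 0.15).
#' @param split_contigs number of random gene-boundary contig breakpoints per
#'   genome (default 0 = single contig).
#' @param seed integer seed; every randomized stage derives its stream from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_clades = 4L,
                       strains_per_clade = 5L,
                       n_ancestral_families = 300L,
                       gene_length_range = c(300L, 1500L),
                       intergenic_length = 50L,
                       inter_clade_divergence = 0.02,
                       intra_clade_divergence = 0.002,
                       transition_bias = 4.0,
                       gene_loss_prob = 0.03,
                       pseudogenization_prob = 0.02,
                       blocks_per_clade = 1L,
                       block_cds = 10L,
                       outgroup = TRUE,
                       outgroup_divergence = 0.15,
                       split_contigs = 0L,
                       seed = 1L) {
  strains_per_clade <- rep_len(as.integer(strains_per_clade), n_clades)
  if (n_clades < 1L) stopf("'n_clades' must be >= 1")
  if (any(strains_per_clade < 1L))
    stopf("'strains_per_clade' entries must be >= 1")
  if (n_ancestral_families < 1L) stopf("need at least one ancestral family")
  assert_prob(gene_loss_prob, "gene_loss_prob")
  assert_prob(pseudogenization_prob, "pseudogenization_prob")
  assert_nonneg(inter_clade_divergence, "inter_clade_divergence")
  assert_nonneg(intra_clade_divergence, "intra_clade_divergence")
  assert_nonneg(outgroup_divergence, "outgroup_divergence")
  if (transition_bias <= 0) stopf("'transition_bias' must be positive")
  if (length(gene_length_range) != 2L ||
      gene_length_range[1] < 9L || diff(gene_length_range) < 0)
    stopf("'gene_length_range' must be an increasing bp interval >= 9")
  structure(list(n_clades = as.integer(n_clades),
                 strains_per_clade = strains_per_clade,
                 n_ancestral_families = as.integer(n_ancestral_families),
                 gene_length_range = as.integer(gene_length_range),
                 intergenic_length = as.integer(intergenic_length),
                 inter_clade_divergence = inter_clade_divergence,
                 intra_clade_divergence = intra_clade_divergence,
                 transition_bias = transition_bias,
                 gene_loss_prob = gene_loss_prob,
                 pseudogenization_prob = pseudogenization_prob,
                 blocks_per_clade = as.integer(blocks_per_clade),
                 block_cds = as.integer(block_cds),
                 outgroup = isTRUE(outgroup),
                 outgroup_divergence = outgroup_divergence,
                 split_contigs = as.integer(split_contigs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Mutate a nucleotide sequence under a Kimura 2-parameter process
#'
#' Each site substitutes independently with probability `subst_per_site`
#' (expected substitution count = rate x length). A substitution is a
#' transition (A<->G, C<->T) with probability
#' `transition_bias / (transition_bias + 2)`, otherwise one of the two
#' transversions with equal probability. `N` sites are left untouched; length
#' is always preserved. Uses the current RNG stream.
#'
#' @param residues nucleotide string over A/C/G/T/N.
#' @param subst_per_site substitution probability per site (>= 0).
#' @param transition_bias transition/transversion rate ratio (default 4).
#' @return the mutated string.
#' @export
mutate_sequence <- function(residues, subst_per_site, transition_bias = 4.0) {
  if (!is.numeric(subst_per_site) || subst_per_site < 0)
    stopf("'subst_per_site' must be non-negative")
  if (subst_per_site == 0) return(residues)
  v <- utf8ToInt(residues)
  n <- length(v)
  hit <- which(runif(n) < subst_per_site)
  hit <- hit[v[hit] != utf8ToInt("N")]
  if (length(hit) == 0L) return(residues)
  is_ts <- runif(length(hit)) < transition_bias / (transition_bias + 2)
  tv_first <- runif(length(hit)) < 0.5
  A <- utf8ToInt("A"); C <- utf8ToInt("C"); G <- utf8ToInt("G")
  Tn <- utf8ToInt("T")
  cur <- v[hit]
  new <- integer(length(hit))
  # transitions
  new[is_ts & cur == A] <- G; new[is_ts & cur == G] <- A
  new[is_ts & cur == C] <- Tn; new[is_ts & cur == Tn] <- C
  # transversions: A/G -> C or T ; C/T -> A or G
  purine <- cur == A | cur == G
  new[!is_ts & purine & tv_first] <- C
  new[!is_ts & purine & !tv_first] <- Tn
  new[!is_ts & !purine & tv_first] <- A
  new[!is_ts & !purine & !tv_first] <- G
  v[hit] <- new
  intToUtf8(v)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# replace internal stop codons created by random substitution with a sense
# codon (middle base -> C), emulating purifying selection against nonsense
# mutations; the terminal stop codon is preserved
repair_internal_stops <- function(seq) {
  n <- nchar(seq)
  ncod <- n %/% 3L
  if (ncod < 2L) return(seq)
  starts <- seq.int(1L, by = 3L, length.out = ncod - 1L)
  codons <- substring(seq, starts, starts + 2L)
  bad <- which(codons %in% STOP_CODONS)
  if (length(bad) == 0L) return(seq)
  v <- chars(seq)
  v[starts[bad] + 1L] <- "C"
  collapse0(v)
}

random_gene <- function(len_bp) {
  ncod <- len_bp %/% 3L
  sense <- setdiff(names(which(Biostrings::GENETIC_CODE != "*")),
                   STOP_CODONS)
  body <- sample(sense, ncod - 1L, replace = TRUE)
  collapse0(c("ATG", body[-1], sample(STOP_CODONS, 1L)))
}

random_spacer <- function(len_bp) {
  collapse0(sample(c("A", "C", "G", "T"), len_bp, replace = TRUE))
}

#' Pseudogenize a gene sequence
#'
#' Introduces a premature stop codon at a random codon position at least 30%
#' into the gene, and either truncates the annotation to the 5' portion (one
#' fragment) or splits it into two fragments around the new stop. The genomic
#' sequence keeps its full length; only the annotation fragments change.
#' Genes shorter than 150 bp are returned unchanged with a warning.
#'
#' @param seq gene nucleotide sequence (length a multiple of 3, terminal stop).
#' @param gene_id id used for messages.
#' @return a list with `seq` (possibly modified), `fragments` (data.frame of
#'   `start`,`end` offsets within the gene, or NULL if unchanged) and `mode`
#'   (`"truncation"`, `"split"` or `"unchanged"`).
#' @export
pseudogenize_gene <- function(seq, gene_id = "gene") {
  n <- nchar(seq)
  if (n < 150L) {
    warnf("gene '%s' is shorter than 150 bp; left intact", gene_id)
    return(list(seq = seq, fragments = NULL, mode = "unchanged"))
  }
  ncod <- n %/% 3L
  # premature stop at codon j; 5' fragment [1, 3j] must cover >= 30% of length
  jmin <- max(2L, ceiling(0.3 * ncod))
  j <- if (jmin >= ncod - 1L) jmin else sample(jmin:(ncod - 1L), 1L)
  v <- chars(seq)
  v[(3L * j - 2L):(3L * j)] <- chars(sample(STOP_CODONS, 1L))
  split_mode <- runif(1L) < 0.5
  fragments <- if (split_mode && 3L * j + 3L <= n - 2L) {
    data.frame(start = c(1L, 3L * j + 1L), end = c(3L * j, n))
  } else {
    data.frame(start = 1L, end = 3L * j)
  }
  list(seq = collapse0(v), fragments = fragments,
       mode = if (nrow(fragments) == 2L) "split" else "truncation")
}

#' Insert a clade-specific gene block into an assembled genome
#'
#' Inserts a contiguous run of CDS (with fixed spacers between them) at a
#' gene boundary, shifting all downstream annotations.
#'
#' @param genome a list with `seq` (contig string) and `annotations`
#'   (data.frame with at least `gene_id`, `start`, `end`).
#' @param block a list with `genes` (named character vector of gene
#'   sequences), `families` (character vector of family ids) and `spacers`
#'   (character vector of `length(genes) - 1` spacer sequences).
#' @param at 0-based insertion offset: the block is inserted between positions
#'   `at` and `at + 1`. Must not fall inside an annotated gene.
#' @return the genome list with updated `seq` and `annotations`, plus a
#'   `region` entry (`start`, `end`, `n_cds`) describing the insert; the
#'   genome is returned unchanged (with `region = NULL`) for an empty block.
#' @export
plant_insert_region <- function(genome, block, at) {
  a <- genome$annotations
  n <- nchar(genome$seq)
  if (length(block$genes) == 0L) { genome$region <- NULL; return(genome) }
  if (at < 0L || at > n) stopf("insertion offset %d outside genome", at)
  if (nrow(a) > 0L && any(a$start <= at & at < a$end))
    stopf("insertion at offset %d overlaps gene '%s'", at,
          a$gene_id[a$start <= at & at < a$end][1])
  ng <- length(block$genes)
  if (length(block$spacers) != max(ng - 1L, 0L))
    stopf("block must have exactly %d spacers", ng - 1L)
  pieces <- character(2L * ng - 1L)
  pieces[seq(1L, 2L * ng - 1L, by = 2L)] <- unname(block$genes)
  if (ng > 1L) pieces[seq(2L, 2L * ng - 2L, by = 2L)] <- block$spacers
  insert <- collapse0(pieces)
  ins_len <- nchar(insert)
  glens <- nchar(block$genes)
  slens <- c(0L, cumsum(nchar(block$spacers) + glens[-ng]))
  gstart <- at + 1L + slens
  gend <- gstart + glens - 1L
  gid <- if (!is.null(a$genome_id)) a$genome_id[1] else
    genome$genome_id %||% NA_character_
  cid <- if (!is.null(a$contig_id)) a$contig_id[1] else
    genome$contig_id %||% NA_character_
  new_rows <- data.frame(gene_id = names(block$genes),
                         genome_id = gid,
                         contig_id = cid,
                         start = as.integer(gstart), end = as.integer(gend),
                         strand = "+", status = "intact",
                         product = sprintf("clade-specific block protein %s",
                                           block$families),
                         stringsAsFactors = FALSE)
  shift <- a$start > at
  a$start[shift] <- a$start[shift] + ins_len
  a$end[shift] <- a$end[shift] + ins_len
  for (nm in setdiff(names(a), names(new_rows))) new_rows[[nm]] <- NA
  new_rows <- new_rows[, names(a), drop = FALSE]
  a <- rbind(a, new_rows)
  a <- a[order(a$start), , drop = FALSE]
  rownames(a) <- NULL
  genome$seq <- paste0(substr(genome$seq, 1L, at), insert,
                       substr(genome$seq, at + 1L, n))
  genome$annotations <- a
  genome$region <- list(start = at + 1L, end = at + ins_len, n_cds = ng)
  genome
}

#' Simulate a structured genome dataset with known truth
#'
#' Generates an ancestral genome of `n_ancestral_families` genes separated by
#' fixed spacers, evolves it along a clade tree (K2P substitutions), inserts
#' one or more clade-specific gene blocks per clade, applies per-strain gene
#' loss and pseudogenization, and assembles each strain into a single contig
#' (optionally split for I/O tests). All randomness derives from
#' `config$seed`; repeated runs are identical.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_dataset` with elements `genomes` (named list
#'   of [genome_assembly()]), `annotations` (one data.frame for all genomes),
#'   `proteins` (named `AAStringSet`, all genomes), and `truth` (clade map,
#'   gene-to-family map, family content matrix, clade-specific families,
#'   planted regions, generating tree, config).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  cl_labels <- make.unique(rep(LETTERS, length.out = config$n_clades),
                           sep = "")
  n_fam <- config$n_ancestral_families
  codon_range <- config$gene_length_range %/% 3L
  fam_ids <- sprintf("F%04d", seq_len(n_fam))

  # ancestral gene + spacer per family
  gene_cod <- sample(codon_range[1]:codon_range[2], n_fam, replace = TRUE)
  anc_genes <- vapply(gene_cod * 3L, random_gene, character(1))
  anc_spacers <- vapply(rep(config$intergenic_length, n_fam), random_spacer,
                        character(1))

  # planted clade-specific blocks (new families beyond the ancestral set)
  n_block_genes <- config$n_clades * config$blocks_per_clade * config$block_cds
  blocks <- list()
  next_fam <- n_fam
  for (cl in cl_labels) {
    blocks[[cl]] <- lapply(seq_len(config$blocks_per_clade), function(b) {
      cods <- sample(codon_range[1]:codon_range[2], config$block_cds,
                     replace = TRUE)
      fams <- sprintf("F%04d", next_fam + seq_len(config$block_cds))
      next_fam <<- next_fam + config$block_cds
      list(genes = vapply(cods * 3L, random_gene, character(1)),
           families = fams,
           spacers = vapply(rep(config$intergenic_length,
                                max(config$block_cds - 1L, 0L)),
                            random_spacer, character(1)),
           anchor = sample.int(n_fam - 1L, 1L)) # insert after this family slot
    })
  }
  if (n_fam * length(anc_genes) == 0L) stopf("configuration yields no genes")

  # clade ancestors: mutate ancestral elements down each stem branch
  mut_elems <- function(genes, spacers, rate) {
    if (rate == 0) return(list(genes = genes, spacers = spacers))
    g <- vapply(genes, function(s)
      repair_internal_stops(mutate_sequence(s, rate, config$transition_bias)),
      character(1), USE.NAMES = FALSE)
    sp <- vapply(spacers, function(s)
      mutate_sequence(s, rate, config$transition_bias),
      character(1), USE.NAMES = FALSE)
    list(genes = g, spacers = sp)
  }

  clade_anc <- lapply(cl_labels, function(cl)
    mut_elems(anc_genes, anc_spacers, config$inter_clade_divergence))
  names(clade_anc) <- cl_labels
  # block sequences live in the clade ancestor (planted once, then inherited)
  clade_blocks <- blocks

  genome_ids <- unlist(lapply(seq_along(cl_labels), function(i)
    sprintf("%s%02d", cl_labels[i], seq_len(config$strains_per_clade[i]))))
  clade_of <- setNames(rep(cl_labels, config$strains_per_clade), genome_ids)

  out_id <- "OUT01"
  if (config$outgroup) {
    outg <- mut_elems(anc_genes, anc_spacers, config$outgroup_divergence)
  }

  all_fam_ids <- sprintf("F%04d", seq_len(next_fam))
  content <- matrix("absent",
                    nrow = length(genome_ids) + config$outgroup,
                    ncol = next_fam,
                    dimnames = list(c(genome_ids, if (config$outgroup) out_id),
                                    all_fam_ids))

  genomes <- list()
  annotations <- list()
  proteins <- list()
  family_of_gene <- character(0)
  planted <- list()

  build_strain <- function(gid, elems, blocks_here, lose, pseudo, rate) {
    genes <- elems$genes; spacers <- elems$spacers
    if (rate > 0) {
      e <- mut_elems(genes, spacers, rate)
      genes <- e$genes; spacers <- e$spacers
    }
    keep <- runif(n_fam) >= lose
    frag <- keep & (runif(n_fam) < pseudo)
    content[gid, fam_ids[keep & !frag]] <<- "intact"

    # lay out surviving elements; record coordinates
    rows <- list(); prots <- list()
    seq_parts <- character(0)
    pos <- 0L
    gcount <- 0L
    fam_slot_end <- integer(n_fam) # genome offset after family slot's spacer
    for (f in seq_len(n_fam)) {
      if (keep[f]) {
        g <- genes[f]
        gcount <- gcount + 1L
        base_id <- sprintf("%s_g%04d", gid, gcount)
        if (frag[f]) {
          ps <- pseudogenize_gene(g, base_id)
          if (is.null(ps$fragments)) { # too short to pseudogenize
            frag[f] <- FALSE
            rows[[length(rows) + 1L]] <- data.frame(
              gene_id = base_id, start = pos + 1L, end = pos + nchar(g),
              status = "intact", family = fam_ids[f],
              stringsAsFactors = FALSE)
            prots[[base_id]] <- g
            content[gid, fam_ids[f]] <<- "intact"
          } else {
            g <- ps$seq
            content[gid, fam_ids[f]] <<- "fragment"
            for (k in seq_len(nrow(ps$fragments))) {
              fid <- sprintf("%s_f%d", base_id, k)
              fs <- ps$fragments$start[k]; fe <- ps$fragments$end[k]
              rows[[length(rows) + 1L]] <- data.frame(
                gene_id = fid, start = pos + fs, end = pos + fe,
                status = "fragment", family = fam_ids[f],
                stringsAsFactors = FALSE)
              prots[[fid]] <- substr(g, fs, fe)
            }
          }
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = base_id, start = pos + 1L, end = pos + nchar(g),
            status = "intact", family = fam_ids[f],
            stringsAsFactors = FALSE)
          prots[[base_id]] <- g
        }
        seq_parts <- c(seq_parts, g)
        pos <- pos + nchar(g)
      }
      seq_parts <- c(seq_parts, spacers[f])
      pos <- pos + nchar(spacers[f])
      fam_slot_end[f] <- pos
    }
    ann <- do.call(rbind, rows)
    ann$genome_id <- gid
    ann$contig_id <- paste0(gid, "_c1")
    ann$strand <- "+"
    ann$product <- sprintf("protein of family %s", ann$family)
    g <- list(genome_id = gid, contig_id = paste0(gid, "_c1"),
              seq = collapse0(seq_parts),
              annotations = ann[, c("gene_id", "genome_id", "contig_id",
                                    "start", "end", "strand", "status",
                                    "product", "family")])

    # insert evolved copies of the clade blocks at their anchor boundaries
    regions <- list()
    for (bl in blocks_here) {
      bgenes <- vapply(bl$genes, function(s)
        repair_internal_stops(mutate_sequence(s, rate,
                                              config$transition_bias)),
        character(1), USE.NAMES = FALSE)
      ids <- sprintf("%s_b%s", gid, bl$families)
      names(bgenes) <- ids
      at <- fam_slot_end[bl$anchor]
      # account for previously inserted blocks shifting this anchor
      for (r in regions) if (r$start <= at) at <- at + (r$end - r$start + 1L)
      g <- plant_insert_region(g, list(genes = bgenes,
                                       families = bl$families,
                                       spacers = bl$spacers), at)
      regions[[length(regions) + 1L]] <- g$region
      content[gid, bl$families] <<- "intact"
      for (k in seq_along(ids)) prots[[ids[k]]] <- bgenes[[k]]
      fam <- setNames(bl$families, ids)
      g$annotations$family[match(ids, g$annotations$gene_id)] <- bl$families
    }
    list(genome = g, proteins = prots, regions = regions)
  }

  for (gid in genome_ids) {
    cl <- clade_of[gid]
    res <- build_strain(gid, clade_anc[[cl]], clade_blocks[[cl]],
                        config$gene_loss_prob, config$pseudogenization_prob,
                        config$intra_clade_divergence)
    genomes[[gid]] <- res$genome
    proteins[[gid]] <- res$proteins
    if (length(res$regions) > 0L)
      planted[[gid]] <- data.frame(
        genome_id = gid, contig = res$genome$contig_id,
        start = vapply(res$regions, `[[`, integer(1) + 0, "start"),
        end = vapply(res$regions, `[[`, integer(1) + 0, "end"),
        n_cds = vapply(res$regions, `[[`, integer(1) + 0, "n_cds"))
  }
  if (config$outgroup) {
    res <- build_strain(out_id, outg, list(), config$gene_loss_prob,
                        config$pseudogenization_prob, 0)
    genomes[[out_id]] <- res$genome
    proteins[[out_id]] <- res$proteins
    clade_of[out_id] <- "outgroup"
  }

  # contig splitting for I/O exercises (one draw per genome, shared between
  # the assembly and its annotations)
  splits <- lapply(genomes, split_genome_contigs, config$split_contigs)
  assemblies <- lapply(genomes, function(g) {
    species <- if (g$genome_id == out_id && config$outgroup) "outgroup_sp"
               else "ingroup_sp"
    genome_assembly(g$genome_id, splits[[g$genome_id]]$contigs,
                    species_label = species,
                    clade_label = unname(clade_of[g$genome_id]))
  })
  annotations <- do.call(rbind, lapply(splits, `[[`, "annotations"))
  rownames(annotations) <- NULL
  family_of_gene <- setNames(annotations$family, annotations$gene_id)
  cds_all <- unlist(proteins, use.names = FALSE)
  prot_set <- Biostrings::AAStringSet(translate_cds_batch(unlist(cds_all)))
  names(prot_set) <- unlist(lapply(proteins, names), use.names = FALSE)

  truth <- list(
    clade_of = clade_of,
    family_of_gene = family_of_gene,
    family_content = content,
    clade_specific_families = setNames(lapply(cl_labels, function(cl)
      unlist(lapply(clade_blocks[[cl]], `[[`, "families"))), cl_labels),
    planted_regions = if (length(planted)) do.call(rbind, planted) else NULL,
    generating_tree = generating_tree(config, genome_ids, clade_of, out_id),
    config = config)
  if (!is.null(truth$planted_regions)) rownames(truth$planted_regions) <- NULL

  n_genes_total <- nrow(annotations)
  if (n_genes_total == 0L) stopf("configuration yields zero genes")

  structure(list(genomes = assemblies,
                 annotations = annotations[, c("gene_id", "genome_id",
                                               "contig_id", "start", "end",
                                               "strand", "status", "product")],
                 proteins = prot_set,
                 truth = truth),
            class = "sim_dataset")
}

# translate CDS sequences in one batched call, dropping terminal stops
translate_cds_batch <- function(seqs) {
  seqs <- vapply(seqs, function(s) substr(s, 1L, nchar(s) - nchar(s) %% 3L),
                 character(1), USE.NAMES = FALSE)
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                           if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

generating_tree <- function(config, genome_ids, clade_of, out_id) {
  cl_labels <- unique(clade_of[genome_ids])
  tips <- character(0); txt <- character(0)
  clade_parts <- vapply(cl_labels, function(cl) {
    members <- genome_ids[clade_of[genome_ids] == cl]
    paste0("(", paste(sprintf("%s:%s", members,
                              format(config$intra_clade_divergence,
                                     scientific = FALSE)),
                      collapse = ","), "):",
           format(config$inter_clade_divergence, scientific = FALSE))
  }, character(1))
  ing <- paste0("(", paste(clade_parts, collapse = ","), ")")
  nwk <- if (config$outgroup)
    sprintf("(%s:0,%s:%s);", ing, out_id,
            format(config$outgroup_divergence, scientific = FALSE))
  else paste0(ing, ";")
  ape::read.tree(text = nwk)
}

split_genome_contigs <- function(g, n_breaks) {
  if (n_breaks <= 0L) {
    contigs <- Biostrings::DNAStringSet(setNames(g$seq, g$contig_id))
    return(list(contigs = contigs, annotations = g$annotations))
  }
  a <- g$annotations
  # candidate breakpoints: positions not inside any gene
  len <- nchar(g$seq)
  cand <- setdiff(unique(pmin(a$end, len)), len)
  cand <- cand[vapply(cand, function(p) !any(a$start <= p & p < a$end),
                      logical(1))]
  brk <- sort(sample(cand, min(n_breaks, length(cand))))
  bounds <- cbind(c(1L, brk + 1L), c(brk, len))
  contigs <- Biostrings::DNAStringSet(substring(g$seq, bounds[, 1],
                                                bounds[, 2]))
  names(contigs) <- sprintf("%s_c%d", g$genome_id, seq_len(nrow(bounds)))
  idx <- findInterval(a$start, bounds[, 1])
  a$contig_id <- names(contigs)[idx]
  a$start <- a$start - bounds[idx, 1] + 1L
  a$end <- a$end - bounds[idx, 1] + 1L
  list(contigs = contigs, annotations = a)
}

#' Write a simulated dataset to disk
#'
#' Emits per-genome FASTA (genome and proteins), GFF3 with `status`
#' attributes, the truth tables as TSV, and the generating tree as Newick.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) {
    write_fasta(g$contigs, file.path(dir, paste0(g$genome_id, ".fasta")))
    a <- sim$annotations[sim$annotations$genome_id == g$genome_id, ]
    write_gff3(a, file.path(dir, paste0(g$genome_id, ".gff3")))
    write_fasta(sim$proteins[names(sim$proteins) %in% a$gene_id],
                file.path(dir, paste0(g$genome_id, ".faa")))
  }
  tr <- sim$truth
  write.table(data.frame(genome_id = names(tr$clade_of),
                         clade = unname(tr$clade_of)),
              file.path(dir, "clades.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = names(tr$family_of_gene),
                         family = unname(tr$family_of_gene)),
              file.path(dir, "gene_families_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(tr$generating_tree, file.path(dir, "generating_tree.nwk"))
  invisible(dir)
}
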