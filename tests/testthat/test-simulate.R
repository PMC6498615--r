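# synthetic genome generator: substitution process, pseudogenization,
# planted regions, determinism, truth bookkeeping

test_that("mutate_sequence matches its K2P process statistics", {
  set.seed(5)
  s <- rand_dna(100000)
  expect_identical(mutate_sequence(s, 0), s)
  m <- mutate_sequence(s, 0.05, transition_bias = 4)
  v0 <- strsplit(s, "")[[1]]; v1 <- strsplit(m, "")[[1]]
  diff <- v0 != v1
  frac <- mean(diff)
  # binomial 4-sigma bounds at n = 1e5, p = 0.05
  expect_gt(frac, 0.045)
  expect_lt(frac, 0.055)
  is_ts <- (v0 %in% c("A", "G") & v1 %in% c("A", "G")) |
    (v0 %in% c("C", "T") & v1 %in% c("C", "T"))
  ts_frac <- mean(is_ts[diff])
  expect_gt(ts_frac, 0.62)
  expect_lt(ts_frac, 0.71)
  expect_equal(nchar(m), nchar(s))
  expect_error(mutate_sequence(s, -0.1), "non-negative")
})

test_that("mutate_sequence is reproducible under a fixed RNG state", {
  s <- rand_dna(5000)
  set.seed(99); a <- mutate_sequence(s, 0.02)
  set.seed(99); b <- mutate_sequence(s, 0.02)
  expect_identical(a, b)
  # N sites are never touched
  sN <- paste0(substr(s, 1, 100), strrep("N", 50))
  set.seed(1)
  mN <- mutate_sequence(sN, 0.5)
  expect_equal(substr(mN, 101, 150), strrep("N", 50))
})

test_that("pseudogenize_gene produces in-bound fragments and guards", {
  set.seed(7)
  gene <- paste0("ATG", paste(rep("GCT", 98), collapse = ""), "TAA") # 300 bp
  for (i in 1:20) {
    ps <- pseudogenize_gene(gene, "g")
    expect_true(ps$mode %in% c("truncation", "split"))
    expect_gte(ps$fragments$end[1] - ps$fragments$start[1] + 1, 90)
    expect_lte(max(ps$fragments$end), 300)
    expect_equal(nchar(ps$seq), 300)
    # a premature stop was planted at the 5' fragment boundary
    stop_cod <- substr(ps$seq, ps$fragments$end[1] - 2, ps$fragments$end[1])
    expect_true(stop_cod %in% c("TAA", "TAG", "TGA"))
  }
  short <- paste0("ATG", paste(rep("GCT", 38), collapse = ""), "TAA") # 120 bp
  expect_warning(ps <- pseudogenize_gene(short, "tiny"), "shorter than 150")
  expect_identical(ps$seq, short)
  expect_null(ps$fragments)
})

test_that("plant_insert_region shifts coordinates and records the span", {
  set.seed(3)
  genes <- setNames(vapply(rep(600, 10), rand_dna, character(1)),
                    paste0("b", 1:10))
  spacers <- vapply(rep(50, 9), rand_dna, character(1))
  genome <- list(genome_id = "G", contig_id = "c1", seq = rand_dna(5000),
                 annotations = data.frame(gene_id = c("g1", "g2"),
                                          genome_id = "G", contig_id = "c1",
                                          start = c(101L, 2001L),
                                          end = c(700L, 2600L),
                                          strand = "+", status = "intact",
                                          product = NA))
  out <- plant_insert_region(genome,
                             list(genes = genes, families = names(genes),
                                  spacers = spacers), at = 1000L)
  expect_equal(out$region$end - out$region$start + 1L, 10 * 600 + 9 * 50)
  expect_equal(out$region$n_cds, 10L)
  expect_equal(nchar(out$seq), 5000 + 6450)
  a <- out$annotations
  expect_equal(a$start[a$gene_id == "g1"], 101L) # upstream untouched
  expect_equal(a$start[a$gene_id == "g2"], 2001L + 6450L) # downstream shifted
  expect_equal(substr(out$seq, a$start[a$gene_id == "b1"],
                      a$end[a$gene_id == "b1"]), unname(genes["b1"]))

  # empty block is a no-op
  same <- plant_insert_region(genome, list(genes = character(0),
                                           families = character(0),
                                           spacers = character(0)), 1000L)
  expect_identical(same$seq, genome$seq)
  expect_null(same$region)

  # insertion inside a gene is refused
  expect_error(plant_insert_region(genome,
                                   list(genes = genes,
                                        families = names(genes),
                                        spacers = spacers), at = 150L),
               "overlaps gene 'g1'")
})

test_that("null model: zero rates give identical genomes, all intact", {
  cfg <- sim_config(n_clades = 2, strains_per_clade = 2,
                    n_ancestral_families = 20,
                    gene_length_range = c(300, 600),
                    inter_clade_divergence = 0, intra_clade_divergence = 0,
                    gene_loss_prob = 0, pseudogenization_prob = 0,
                    blocks_per_clade = 0, outgroup = FALSE, seed = 9L)
  sim <- simulate_dataset(cfg)
  seqs <- vapply(sim$genomes, function(g) as.character(g$contigs)[1],
                 character(1))
  expect_equal(length(unique(seqs)), 1L)
  expect_true(all(sim$annotations$status == "intact"))
  expect_true(all(sim$truth$family_content == "intact"))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_clades = 2, strains_per_clade = 2,
                    n_ancestral_families = 30, seed = 17L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("planted blocks are clade-exclusive and truth maps every gene", {
  sim <- acceptance_dataset()
  truth <- sim$truth
  for (cl in names(truth$clade_specific_families)) {
    fams <- truth$clade_specific_families[[cl]]
    members <- names(truth$clade_of)[truth$clade_of == cl]
    others <- setdiff(rownames(truth$family_content), members)
    expect_true(all(truth$family_content[members, fams] == "intact"))
    expect_true(all(truth$family_content[others, fams] == "absent"))
  }
  # conservation of annotation: every emitted gene has exactly one family
  expect_true(all(sim$annotations$gene_id %in% names(truth$family_of_gene)))
  expect_false(any(is.na(truth$family_of_gene)))
  # fragment bookkeeping agrees between annotations and truth content
  frag_ann <- unique(paste(sim$annotations$genome_id[
    sim$annotations$status == "fragment"],
    truth$family_of_gene[sim$annotations$gene_id[
      sim$annotations$status == "fragment"]]))
  frag_truth <- which(truth$family_content == "fragment", arr.ind = TRUE)
  expect_equal(length(frag_ann), nrow(frag_truth))
})

test_that("realised pairwise divergence tracks the generating tree", {
  sim <- acceptance_dataset()
  tree <- sim$truth$generating_tree
  pd <- ape::cophenetic.phylo(tree)
  pick <- list(c("A01", "A02"), c("A01", "B01"), c("C01", "D01"))
  for (pr in pick) {
    g1 <- as.character(sim$genomes[[pr[1]]]$contigs)[1]
    g2 <- as.character(sim$genomes[[pr[2]]]$contigs)[1]
    # compare over the shared prefix of ungapped genomes: use common genes
    a1 <- sim$annotations[sim$annotations$genome_id == pr[1], ]
    a2 <- sim$annotations[sim$annotations$genome_id == pr[2], ]
    f1 <- sim$truth$family_of_gene[a1$gene_id]
    f2 <- sim$truth$family_of_gene[a2$gene_id]
    shared <- intersect(f1[a1$status == "intact"], f2[a2$status == "intact"])
    obs <- vapply(shared, function(f) {
      r1 <- a1[f1 == f & a1$status == "intact", ][1, ]
      r2 <- a2[f2 == f & a2$status == "intact", ][1, ]
      s1 <- substr(g1, r1$start, r1$end)
      s2 <- substr(g2, r2$start, r2$end)
      if (nchar(s1) != nchar(s2)) return(NA_real_)
      v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]
      mean(v1 != v2)
    }, numeric(1))
    obs <- mean(obs, na.rm = TRUE)
    expected <- pd[pr[1], pr[2]]
    expect_lt(abs(obs - expected) / expected, 0.15)
  }
})

test_that("contig splitting keeps annotations consistent", {
  cfg <- sim_config(n_clades = 2, strains_per_clade = 2,
                    n_ancestral_families = 30, split_contigs = 3,
                    outgroup = FALSE, seed = 23L)
  sim <- simulate_dataset(cfg)
  g <- sim$genomes[[1]]
  expect_equal(length(g$contigs), 4L)
  a <- sim$annotations[sim$annotations$genome_id == g$genome_id, ]
  cs <- as.character(g$contigs)
  prot <- sim$proteins
  # every annotated CDS translates to its recorded protein
  for (i in seq_len(nrow(a))) {
    cds <- substr(cs[[a$contig_id[i]]], a$start[i], a$end[i])
    aa <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1, nchar(cds) - nchar(cds) %% 3)))))
    expect_identical(aa, unname(as.character(prot[a$gene_id[i]])),
                     label = a$gene_id[i])
  }
})
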