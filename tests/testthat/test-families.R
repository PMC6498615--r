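# gene-family clustering, ternary matrix, partition, rarefaction, bootstrap

test_that("pairwise metrics follow their definitions", {
  set.seed(2)
  p <- rand_protein(100)
  m <- pairwise_protein_metrics(p, p)
  expect_equal(m$identity, 1)
  expect_equal(m$coverage_a, 1)
  expect_equal(m$coverage_b, 1)

  half <- substr(p, 1, 50)
  m <- pairwise_protein_metrics(half, p)
  expect_equal(m$identity, 1) # terminal gaps excluded
  expect_equal(m$coverage_a, 1)
  expect_equal(m$coverage_b, 0.5)

  p2 <- substitute_positions(p, 15, AA20)
  m <- pairwise_protein_metrics(p, p2)
  expect_equal(m$identity, 0.85)
  expect_error(pairwise_protein_metrics("", p), "non-empty")
})

test_that("clustering applies strict identity and coverage thresholds", {
  set.seed(12)
  base <- rand_protein(100)
  sim85 <- substitute_positions(base, 15, AA20) # identity 0.85
  id80 <- substitute_positions(base, 20, AA20)  # identity exactly 0.80
  short <- substr(base, 1, 70)                  # coverage_b = 0.70

  fams <- brute_force_families(c(a = base, b = sim85))
  expect_equal(unname(fams$family_of["a"]), unname(fams$family_of["b"]))

  fams <- brute_force_families(c(a = base, b = id80))
  expect_false(fams$family_of[["a"]] == fams$family_of[["b"]])

  fams <- brute_force_families(c(a = base, b = short))
  expect_false(fams$family_of[["a"]] == fams$family_of[["b"]])
})

test_that("seeded clustering equals brute force on random fixtures", {
  for (seed in 1:20) {
    set.seed(seed)
    # 10 base proteins, each with a handful of diverged copies (some below
    # threshold), 50 proteins total
    lens <- sample(80:300, 10, replace = TRUE)
    bases <- vapply(lens, rand_protein, character(1))
    prot <- character(0)
    k <- 0L
    for (b in bases) {
      n_copies <- sample(3:6, 1)
      for (cc in seq_len(n_copies)) {
        k <- k + 1L
        rate <- sample(c(0.02, 0.1, 0.17, 0.3, 0.5), 1)
        prot[sprintf("p%03d", k)] <-
          substitute_positions(b, round(rate * nchar(b)), AA20)
        if (k >= 50) break
      }
      if (k >= 50) break
    }
    fast <- build_families(prot)
    slow <- brute_force_families(prot)
    expect_identical(fast$members, slow$members, label = paste("seed", seed))
  }
})

test_that("family ids and the partition are input-order invariant", {
  set.seed(31)
  base <- rand_protein(120)
  prot <- c(a = base,
            b = substitute_positions(base, 10, AA20),
            c = substitute_positions(base, 60, AA20),
            d = rand_protein(90))
  f1 <- build_families(prot)
  f2 <- build_families(rev(prot))
  expect_identical(f1$members, f2$members)
  expect_identical(sort(names(f1$family_of)), sort(names(f2$family_of)))
})

test_that("ternary matrix encodes intact dominance over fragments", {
  fams <- structure(list(
    family_of = c(g1 = "famA", g2 = "famA", g3 = "famA", g4 = "famB"),
    members = list(famA = c("g1", "g2", "g3"), famB = "g4")),
    class = "family_table")
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    genome_id = c("G1", "G2", "G2", "G1"),
                    status = c("intact", "fragment", "fragment", "fragment"))
  m <- ternary_presence(fams, ann)
  expect_equal(m["G1", "famA"], 2L)
  expect_equal(m["G2", "famA"], 1L) # two fragments collapse to state 1
  expect_equal(m["G1", "famB"], 1L)
  expect_equal(m["G2", "famB"], 0L)

  ann2 <- rbind(ann, data.frame(gene_id = "g9", genome_id = "G1",
                                status = "intact"))
  expect_error(ternary_presence(fams, ann2), "no family")
})

test_that("pangenome partition is disjoint and exhaustive", {
  m <- matrix(c(2L, 2L, 2L,   # F1 in all
                2L, 2L, 0L,   # F2 in two
                0L, 0L, 2L),  # F3 one member, one genome
              nrow = 3, dimnames = list(c("G1", "G2", "G3"),
                                        c("F1", "F2", "F3")))
  counts <- c(F1 = 3L, F2 = 2L, F3 = 1L)
  p <- partition_pangenome(m, counts)
  expect_equal(p$core, "F1")
  expect_equal(p$variable, "F2")
  expect_equal(p$singleton, "F3")

  # single-genome set: everything core or singleton
  m1 <- m[1, , drop = FALSE]
  p1 <- partition_pangenome(m1, counts)
  expect_length(p1$variable, 0L)

  # partition property on the full synthetic matrix
  pipe <- acceptance_pipeline()
  pt <- pipe$partition
  expect_equal(sort(c(pt$core, pt$variable, pt$singleton)),
               sort(colnames(pipe$ternary)))
  expect_length(intersect(pt$core, pt$variable), 0L)
  expect_length(intersect(pt$core, pt$singleton), 0L)
})

test_that("rarefaction endpoints and flat-curve behavior are exact", {
  m <- matrix(2L, nrow = 4, ncol = 6,
              dimnames = list(paste0("G", 1:4), paste0("F", 1:6)))
  rc <- rarefaction_curve(m, reps = 5, seed = 1)
  expect_true(all(rc$pan == 6L))
  expect_true(all(rc$core == 6L))

  pipe <- acceptance_pipeline()
  rc <- rarefaction_curve(pipe$ternary, reps = 3, seed = 2)
  full <- rc[rc$n_strains == nrow(pipe$ternary), ]
  expect_true(all(full$pan == ncol(pipe$ternary)))
  expect_true(all(full$core == length(pipe$partition$core)))
})

test_that("group resampling: exhaustive group gives sd 0, reruns identical", {
  set.seed(10)
  m <- matrix(sample(0:2, 10 * 30, replace = TRUE), nrow = 10,
              dimnames = list(paste0("G", 1:10), paste0("F", 1:30)))
  part <- list(variable = paste0("F", 1:20), singleton = paste0("F", 21:30))
  grp <- setNames(rep(c("x", "y"), each = 5), rownames(m))
  st <- group_bootstrap_stats(m, grp, part, sample_n = 5, reps = 50, seed = 3)
  expect_equal(st$unique_micfams_sd, c(0, 0))
  expect_equal(st$singletons_sd, c(0, 0))

  s1 <- group_bootstrap_stats(m, grp, part, sample_n = 3, reps = 1, seed = 11)
  s2 <- group_bootstrap_stats(m, grp, part, sample_n = 3, reps = 1, seed = 11)
  expect_identical(s1, s2)

  grp_small <- setNames(c(rep("x", 3), rep("y", 7)), rownames(m))
  expect_error(group_bootstrap_stats(m, grp_small, part, sample_n = 5,
                                     reps = 10, seed = 1),
               "group 'x'")
})

test_that("group resampling matches exhaustive enumeration for 6 strains", {
  set.seed(40)
  m <- matrix(sample(0:2, 6 * 40, replace = TRUE, prob = c(0.4, 0.1, 0.5)),
              nrow = 6, dimnames = list(paste0("G", 1:6), paste0("F", 1:40)))
  part <- list(variable = paste0("F", 1:30), singleton = paste0("F", 31:40))
  grp <- setNames(rep("g", 6), rownames(m))
  st <- group_bootstrap_stats(m, grp, part, sample_n = 5, reps = 10000,
                              seed = 5)
  subsets <- combn(6, 5)
  exact <- mean(apply(subsets, 2, function(rows)
    sum(colSums(m[rows, part$variable, drop = FALSE] >= 1L) > 0L)))
  tol <- 2 * st$unique_micfams_sd / sqrt(10000)
  expect_lt(abs(st$unique_micfams_mean - exact), max(tol, 1e-8))
})
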