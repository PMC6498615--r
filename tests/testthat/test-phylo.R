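# K2P distances, neighbor joining, rooting, bootstrap, Fitch, dendrograms

test_that("K2P distance matches the closed form and raises on saturation", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)

  # 100 sites, 10 transitions, 0 transversions
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(a, b), -0.5 * log(0.8), tolerance = 1e-12)

  # saturation boundary: P = 0.25, Q = 0.5 -> 1 - 2P - Q = 0
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 25), strrep("C", 50), strrep("A", 25))
  expect_error(k2p_distance(a, b, label = "x/y"), "saturated for x/y")

  # gaps and Ns are excluded pairwise; all-excluded errors
  expect_equal(k2p_distance("ACG-N", "ACGTA"), 0)
  expect_error(k2p_distance("----", "ACGT"), "no usable sites")
})

test_that("K2P equals the analytic formula on 1000 random site profiles", {
  set.seed(19)
  for (i in 1:1000) {
    n <- sample(50:400, 1)
    nts <- sample(0:floor(n * 0.2), 1)
    ntv <- sample(0:floor(n * 0.2), 1)
    P <- nts / n; Q <- ntv / n
    a <- strrep("A", n)
    b <- paste0(strrep("G", nts), strrep("C", ntv), strrep("A", n - nts - ntv))
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
      expect_error(k2p_distance(a, b))
    } else {
      expect_equal(k2p_distance(a, b),
                   -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
                   tolerance = 1e-12)
    }
  }
})

test_that("NJ solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(d), colnames(d)], d, tolerance = 1e-12)
  # branch lengths are the three-point solutions
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(el["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(el["c"]), (9 + 10 - 5) / 2)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(29)
  for (i in 1:200) {
    n <- sample(4:6, 1)
    gen <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(gen)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tr <- nj_tree(d)
    expect_equal(phangorn::RF.dist(tr, gen), 0)
    pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(pd - d)), 1e-9)
  }
})

test_that("4-leaf NJ agrees with least-squares over enumerated topologies", {
  lsq_best_topology <- function(d) {
    labs <- rownames(d)
    tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    fits <- vapply(tops, function(tp) {
      # ((a,b),(c,d)) with 5 branch lengths fit by least squares
      a <- labs[tp[1]]; b <- labs[tp[2]]; cc <- labs[tp[3]]; dd <- labs[tp[4]]
      X <- rbind(c(1, 1, 0, 0, 0),   # d(a,b)
                 c(1, 0, 1, 0, 1),   # d(a,c)
                 c(1, 0, 0, 1, 1),   # d(a,d)
                 c(0, 1, 1, 0, 1),   # d(b,c)
                 c(0, 1, 0, 1, 1),   # d(b,d)
                 c(0, 0, 1, 1, 0))   # d(c,d)
      y <- c(d[a, b], d[a, cc], d[a, dd], d[b, cc], d[b, dd], d[cc, dd])
      fit <- stats::lm.fit(X, y)
      sum(fit$residuals^2)
    }, numeric(1))
    tops[[which.min(fits)]]
  }
  set.seed(37)
  for (i in 1:50) {
    gen <- ape::rtree(4, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(gen)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tp <- lsq_best_topology(d)
    labs <- rownames(d)
    oracle <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                            labs[tp[1]], labs[tp[2]],
                                            labs[tp[3]], labs[tp[4]]))
    expect_equal(phangorn::RF.dist(nj_tree(d), oracle), 0)
  }
})

test_that("NJ is invariant to label order and validates its input", {
  set.seed(41)
  gen <- ape::rtree(6, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(gen)
  perm <- sample(rownames(d))
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(phangorn::RF.dist(t1, t2), 0)
  expect_equal(ape::cophenetic.phylo(t1)[perm, perm],
               ape::cophenetic.phylo(t2)[perm, perm], tolerance = 1e-12)

  dna <- d; dna[1, 3] <- NA; dna[3, 1] <- NA
  expect_error(nj_tree(dna), "missing distance")
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("outgroup rooting places the root mid-pendant and is stable", {
  d <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 4,
                6, 6, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  rt <- root_tree(tr, "d")
  expect_true(ape::is.rooted(rt))
  kids <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1L, 2]
  dtip <- which(rt$tip.label == "d")
  expect_true(dtip %in% kids)
  # the two root edges split the original pendant edge evenly
  pend <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "d")]
  e_out <- rt$edge.length[rt$edge[, 1] == length(rt$tip.label) + 1L &
                            rt$edge[, 2] == dtip]
  expect_equal(e_out, pend / 2)
  # unrooted reduction preserves path lengths
  expect_equal(ape::cophenetic.phylo(rt)[letters[1:4], letters[1:4]],
               ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]],
               tolerance = 1e-12)
  # re-rooting is topologically idempotent
  rt2 <- root_tree(ape::unroot(rt), "d")
  expect_equal(phangorn::RF.dist(rt, rt2), 0)
  expect_error(root_tree(tr, "zz"), "not a tip")
})

test_that("bootstrap gives full support to a unanimous split and is seeded", {
  # every variant column separates {A1,A2} from {B1,B2}
  arow <- strsplit(strrep("A", 10), "")[[1]]
  brow <- arow; brow[1:2] <- "G"
  m <- rbind(A1 = arow, A2 = arow, B1 = brow, B2 = brow)
  tr <- suppressWarnings(bootstrap_support(m, n_reps = 50, seed = 13))
  lab <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(lab == 100, na.rm = TRUE))

  t1 <- suppressWarnings(bootstrap_support(m, n_reps = 20, seed = 99))
  t2 <- suppressWarnings(bootstrap_support(m, n_reps = 20, seed = 99))
  expect_identical(t1$node.label, t2$node.label)
})

test_that("bootstrap supports are invariant to column order", {
  pipe <- acceptance_pipeline()
  sm <- pipe$supermatrix$matrix[, 1:400]
  t1 <- bootstrap_support(sm, n_reps = 30, seed = 7)
  t2 <- bootstrap_support(sm[, rev(seq_len(ncol(sm)))], n_reps = 30, seed = 7)
  s1 <- clade_supports(t1, acceptance_dataset()$truth$clade_of)
  s2 <- clade_supports(t2, acceptance_dataset()$truth$clade_of)
  expect_identical(s1, s2)
})

test_that("Fitch score matches exhaustive minimization on 6-leaf trees", {
  brute_fitch_column <- function(tree, states) {
    tree <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    syms <- unique(states)
    internal <- ntip + seq_len(nnode)
    grid <- as.matrix(expand.grid(rep(list(syms), nnode),
                                  stringsAsFactors = FALSE))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      assign_state <- c(states[tree$tip.label], setNames(grid[r, ],
                                                         internal))
      chg <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        sp <- assign_state[[as.character(p)]]
        sc <- if (ch <= ntip) states[[tree$tip.label[ch]]] else
          assign_state[[as.character(ch)]]
        if (sp != sc) chg <- chg + 1L
      }
      best <- min(best, chg)
    }
    best
  }
  set.seed(53)
  for (i in 1:100) {
    tr <- ape::rtree(6)
    col <- setNames(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                    tr$tip.label)
    m <- matrix(col, ncol = 1, dimnames = list(names(col), NULL))
    expect_equal(fitch_score(tr, m), brute_fitch_column(tr, col),
                 label = paste("instance", i))
  }
  # multi-column additivity and the all-constant case
  tr <- ape::rtree(6)
  m0 <- matrix("A", 6, 4, dimnames = list(tr$tip.label, NULL))
  expect_equal(fitch_score(tr, m0), 0L)
  tr2 <- ape::read.tree(text = "((A1,A2),(G1,G2));")
  m1 <- matrix(c("A", "A", "G", "G"), 4, 1,
               dimnames = list(c("A1", "A2", "G1", "G2"), NULL))
  expect_equal(fitch_score(tr2, m1), 1L)
})

test_that("complete linkage merges by maximum distance with fixed order", {
  rows <- rbind(a = c(0, 0), b = c(0, 1), c = c(10, 10))
  dd <- complete_linkage_dendrogram(rows)
  expect_equal(dd$heights, c(1, sqrt(200)))
  # identical rows merge first at height 0
  rows2 <- rbind(a = c(1, 1), b = c(5, 5), c = c(1, 1))
  dd2 <- complete_linkage_dendrogram(rows2)
  expect_equal(dd2$heights[1], 0)
  m1 <- dd2$hclust$merge[1, ]
  expect_true(all(sort(dd2$hclust$labels[-m1]) == c("a", "c")))

  # row order does not change the result
  pipe <- acceptance_pipeline()
  tm <- pipe$ternary
  d1 <- complete_linkage_dendrogram(tm)
  d2 <- complete_linkage_dendrogram(tm[rev(seq_len(nrow(tm))), ])
  expect_identical(d1$order, d2$order)
  expect_equal(d1$heights, d2$heights)
})

test_that("K2P correction never underestimates the raw mismatch fraction", {
  set.seed(61)
  for (i in 1:25) {
    n <- 500
    a <- rand_dna(n)
    b <- substitute_positions(a, sample(10:80, 1))
    sc <- site_counts(a, b)
    expect_gte(k2p_distance(a, b), sc$P + sc$Q)
  }
})
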