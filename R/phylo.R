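# Distances (Kimura 2-parameter), neighbor joining with bootstrap, outgroup
# rooting, Fitch parsimony and complete-linkage dendrograms.

#' Transition/transversion site counts for two aligned rows
#'
#' Sites where either row holds a gap or `N` are excluded pairwise; the rest
#' are classified as identical, transition (A<->G, C<->T) or transversion.
#'
#' @param a,b equal-length aligned sequences (strings or character vectors).
#' @return list with `n_sites`, `P` (transition proportion) and `Q`
#'   (transversion proportion).
#' @export
site_counts <- function(a, b) {
  va <- if (length(a) == 1L) chars(a) else a
  vb <- if (length(b) == 1L) chars(b) else b
  if (length(va) != length(vb)) stopf("rows must have equal length")
  code <- function(v) {
    out <- integer(length(v))
    out[v == "A"] <- 1L; out[v == "C"] <- 2L
    out[v == "G"] <- 3L; out[v == "T"] <- 4L
    out
  }
  ca <- code(va); cb <- code(vb)
  ok <- ca > 0L & cb > 0L
  n <- sum(ok)
  if (n == 0L) stopf("no usable sites (all gaps or Ns)")
  ca <- ca[ok]; cb <- cb[ok]
  diffs <- ca != cb
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  ts <- diffs & (purine[ca] == purine[cb])
  list(n_sites = n, P = sum(ts) / n, Q = sum(diffs & !ts) / n)
}

k2p_from_pq <- function(P, Q, label = "pair") {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stopf("K2P distance saturated for %s (1-2P-Q = %.4g, 1-2Q = %.4g)",
          label, w1, w2)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura 2-parameter distance between two aligned rows
#'
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with transition proportion P
#' and transversion proportion Q over pairwise-complete sites.
#'
#' @inheritParams site_counts
#' @param label pair label used in error messages.
#' @return the K2P distance (non-negative scalar).
#' @export
k2p_distance <- function(a, b, label = "pair") {
  sc <- site_counts(a, b)
  k2p_from_pq(sc$P, sc$Q, label)
}

#' Pairwise K2P distance matrix from a character supermatrix
#'
#' @param chars a `character_matrix` from [build_supermatrix()] or a plain
#'   character matrix with genome row names.
#' @return symmetric distance matrix with zero diagonal.
#' @export
k2p_matrix <- function(chars) {
  m <- if (inherits(chars, "character_matrix")) chars$matrix else chars
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- k2p_distance(m[i, ], m[j, ],
                                       label = paste(ids[i], ids[j], sep = "/"))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ with the Q-criterion: ties are broken by the
#' lexicographically smallest label pair (a cluster is labeled by its
#' smallest descendant tip), negative branch lengths are clamped to zero.
#' The returned tree is unrooted (trifurcating root node).
#'
#' @param dist symmetric numeric matrix with zero diagonal, complete
#'   off-diagonal values, and at least 3 labeled rows.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stopf("'dist' must be a square matrix")
  n <- nrow(dist)
  if (n < 3L) stopf("need at least 3 taxa")
  ids <- rownames(dist)
  if (is.null(ids) || anyDuplicated(ids)) stopf("'dist' needs unique labels")
  if (any(is.na(dist))) {
    bad <- which(is.na(dist), arr.ind = TRUE)[1, ]
    stopf("missing distance for pair %s / %s", ids[bad[1]], ids[bad[2]])
  }
  if (max(abs(dist - t(dist))) > 1e-12) stopf("'dist' must be symmetric")

  fmt <- function(x) sprintf("%.17g", max(x, 0))
  node_str <- ids        # newick fragment per active cluster
  node_key <- ids        # smallest descendant label per cluster
  D <- dist
  active <- seq_len(n)
  while (length(active) > 3L) {
    Dm <- D[active, active, drop = FALSE]
    N <- length(active)
    r <- rowSums(Dm)
    Q <- (N - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(rc) {
      kk <- sort(c(node_key[active[rc[1]]], node_key[active[rc[2]]]))
      paste(kk, collapse = "\r")
    })
    pick <- cand[order(keys, method = "radix")[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (N - 2))
    vj <- dij - vi
    ai <- active[i]; aj <- active[j]
    new_str <- sprintf("(%s:%s,%s:%s)", node_str[ai], fmt(vi),
                       node_str[aj], fmt(vj))
    dnew <- 0.5 * (D[ai, active] + D[aj, active] - dij)
    D <- rbind(cbind(D, 0), 0)
    idx_new <- nrow(D)
    D[idx_new, active] <- dnew
    D[active, idx_new] <- dnew
    D[idx_new, idx_new] <- 0
    node_str[idx_new] <- new_str
    node_key[idx_new] <- min(node_key[ai], node_key[aj])
    active <- c(setdiff(active, c(ai, aj)), idx_new)
  }
  a <- active
  Dm <- D[a, a]
  v1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  v2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  v3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node_str[a[1]], fmt(v1), node_str[a[2]], fmt(v2),
                 node_str[a[3]], fmt(v3))
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree an unrooted `ape::phylo` tree.
#' @param outgroup_label tip label of the outgroup.
#' @return a rooted `ape::phylo` tree.
#' @export
root_tree <- function(tree, outgroup_label) {
  if (!outgroup_label %in% tree$tip.label)
    stopf("outgroup '%s' is not a tip of the tree", outgroup_label)
  tip <- which(tree$tip.label == outgroup_label)
  pend <- which(tree$edge[, 2] == tip)
  L <- tree$edge.length[pend]
  rooted <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  rt <- length(rooted$tip.label) + 1L
  tip2 <- which(rooted$tip.label == outgroup_label)
  e_out <- which(rooted$edge[, 1] == rt & rooted$edge[, 2] == tip2)
  e_in <- which(rooted$edge[, 1] == rt & rooted$edge[, 2] != tip2)
  if (length(e_out) != 1L || length(e_in) != 1L)
    stopf("unexpected root structure after rooting on '%s'", outgroup_label)
  # ape::root leaves the outgroup pendant edge at L and the opposite root
  # edge at 0; move the root to the middle of the pendant edge
  half <- L / 2
  rooted$edge.length[e_out] <- half
  rooted$edge.length[e_in] <- rooted$edge.length[e_in] + (L - half)
  rooted
}

# canonical bipartition keys of all non-trivial splits of an unrooted tree
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  all_sorted <- sort(tree$tip.label, method = "radix")
  ref <- all_sorted[1]
  keys <- vapply(parts, function(p) {
    side <- sort(tree$tip.label[p], method = "radix")
    if (ref %in% side) side <- setdiff(all_sorted, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(side, collapse = "\r")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Builds the point-estimate tree (K2P + NJ) from the full supermatrix, then
#' resamples columns with replacement `n_reps` times, rebuilds the tree each
#' time, and attaches to each internal edge of the point tree the percentage
#' of replicates containing that bipartition. Replicates that saturate the
#' K2P correction are skipped with a warning; more than 20% skipped is an
#' error.
#'
#' @param chars a `character_matrix` or plain character matrix.
#' @param n_reps bootstrap replicates (default 100).
#' @param seed optional seed for the resampling stream.
#' @return an `ape::phylo` tree with integer `node.label` supports (the root
#'   label is empty).
#' @export
bootstrap_support <- function(chars, n_reps = 100L, seed = NULL) {
  m <- if (inherits(chars, "character_matrix")) chars$matrix else chars
  if (nrow(m) < 4L) stopf("need at least 4 genomes for bootstrap support")
  if (ncol(m) < 1L) stopf("supermatrix has no columns")
  ids <- rownames(m)
  n <- nrow(m)
  code <- matrix(0L, n, ncol(m))
  code[m == "A"] <- 1L; code[m == "C"] <- 2L
  code[m == "G"] <- 3L; code[m == "T"] <- 4L
  purine <- c(FALSE, TRUE, FALSE, TRUE, FALSE) # index = code + 1

  pairs <- t(utils::combn(n, 2L))
  np <- nrow(pairs)
  # per pair/column classification as 0/1 matrices for fast weighted counts
  cls_same <- matrix(0, np, ncol(m))
  cls_ts <- matrix(0, np, ncol(m))
  cls_tv <- matrix(0, np, ncol(m))
  for (p in seq_len(np)) {
    ca <- code[pairs[p, 1], ]; cb <- code[pairs[p, 2], ]
    ok <- ca > 0L & cb > 0L
    same <- ok & ca == cb
    ts <- ok & ca != cb & purine[ca + 1L] == purine[cb + 1L]
    cls_same[p, same] <- 1
    cls_ts[p, ts] <- 1
    cls_tv[p, ok & ca != cb & !(purine[ca + 1L] == purine[cb + 1L])] <- 1
  }
  dist_from_weights <- function(w) {
    ns <- as.vector(cls_same %*% w + cls_ts %*% w + cls_tv %*% w)
    if (any(ns == 0)) return(NULL)
    P <- as.vector(cls_ts %*% w) / ns
    Q <- as.vector(cls_tv %*% w) / ns
    if (any(1 - 2 * P - Q <= 0 | 1 - 2 * Q <= 0)) return(NULL)
    dv <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    d[pairs] <- dv
    d[pairs[, c(2, 1)]] <- dv
    d
  }
  d0 <- dist_from_weights(rep(1, ncol(m)))
  if (is.null(d0))
    stopf("K2P saturation on the full supermatrix; cannot build point tree")
  point <- nj_tree(d0)

  run <- function() {
    point_keys <- tree_bipartitions(point)
    hits <- setNames(numeric(length(point_keys)), point_keys)
    skipped <- 0L
    for (r in seq_len(n_reps)) {
      w <- tabulate(sample.int(ncol(m), ncol(m), replace = TRUE), ncol(m))
      d <- dist_from_weights(w)
      if (is.null(d)) {
        skipped <- skipped + 1L
        warnf("bootstrap replicate %d skipped (K2P saturation)", r)
        next
      }
      bt <- nj_tree(d)
      bk <- tree_bipartitions(bt)
      inb <- point_keys %in% bk
      hits[inb] <- hits[inb] + 1
    }
    if (skipped >= 0.2 * n_reps)
      stopf("%d of %d bootstrap replicates saturated; supports unreliable",
            skipped, n_reps)
    support <- round(100 * hits / (n_reps - skipped))
    attach_supports(point, support)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# put split supports (named by bipartition key) onto node labels
attach_supports <- function(tree, support) {
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  all_sorted <- sort(tree$tip.label, method = "radix")
  ref <- all_sorted[1]
  labels <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]], method = "radix")
    if (ref %in% side) side <- setdiff(all_sorted, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    key <- paste(side, collapse = "\r")
    if (key %in% names(support)) labels[k] <- as.character(support[[key]])
  }
  tree$node.label <- labels
  tree
}

#' Bootstrap support of the clade bipartitions
#'
#' Convenience accessor: for each clade label, returns the attached support
#' of the bipartition separating that clade from everything else (NA if the
#' clade is not monophyletic in the tree).
#'
#' @param tree a tree with supports from [bootstrap_support()].
#' @param clade_of named character vector genome id -> clade label.
#' @param clades clade labels to look up (default: all in `clade_of` present
#'   in the tree).
#' @return named numeric vector of supports.
#' @export
clade_supports <- function(tree, clade_of, clades = NULL) {
  tips <- tree$tip.label
  cl <- clade_of[tips]
  clades <- clades %||% sort(unique(cl[!is.na(cl)]))
  all_sorted <- sort(tips, method = "radix")
  ref <- all_sorted[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(p) {
    side <- sort(tips[p], method = "radix")
    if (ref %in% side) side <- setdiff(all_sorted, side)
    paste(side, collapse = "\r")
  }, character(1))
  out <- setNames(rep(NA_real_, length(clades)), clades)
  ntip <- length(tips)
  for (cd in clades) {
    side <- sort(tips[!is.na(cl) & cl == cd], method = "radix")
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (ref %in% side) side <- setdiff(all_sorted, side)
    key <- paste(side, collapse = "\r")
    hit <- which(keys == key)
    if (length(hit) == 1L && !is.null(tree$node.label)) {
      lab <- tree$node.label[hit]
      out[cd] <- suppressWarnings(as.numeric(lab))
    }
  }
  out
}

#' Fitch parsimony score of a character matrix on a tree
#'
#' Sum over columns of the minimum number of state changes under Fitch
#' set operations. Polytomies are resolved arbitrarily first (zero-length
#' edges), which does not change the score for binary-compatible data; the
#' score is invariant to rooting.
#'
#' @param tree an `ape::phylo` tree whose tips match the matrix rows.
#' @param chars a `character_matrix` or plain character matrix.
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, chars) {
  m <- if (inherits(chars, "character_matrix")) chars$matrix else chars
  if (!setequal(tree$tip.label, rownames(m)))
    stopf("tree tips and matrix rows do not match")
  if (ncol(m) == 0L) return(0L)
  tree <- ape::multi2di(tree)
  m <- m[tree$tip.label, , drop = FALSE]
  syms <- sort(unique(as.vector(m)))
  bit <- setNames(bitwShiftL(1L, seq_along(syms) - 1L), syms)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- matrix(0L, ntip + nnode, ncol(m))
  sets[seq_len(ntip), ] <- matrix(bit[m], ntip, ncol(m))
  counts <- integer(ncol(m))
  tr <- ape::reorder.phylo(tree, "postorder")
  seen <- logical(ntip + nnode)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (!seen[par]) { sets[par, ] <- sets[ch, ]; seen[par] <- TRUE; next }
    inter <- bitwAnd(sets[par, ], sets[ch, ])
    empty <- inter == 0L
    counts[empty] <- counts[empty] + 1L
    inter[empty] <- bitwOr(sets[par, empty], sets[ch, empty])
    sets[par, ] <- inter
  }
  sum(counts)
}

#' Complete-linkage dendrogram of matrix rows
#'
#' Rows are sorted by label first, so the merge order is independent of the
#' input row order; distances are Euclidean on the numeric row vectors
#' (ternary states count as 0/1/2).
#'
#' @param rows a numeric matrix with row names (e.g. a `ternary_matrix`).
#' @param metric distance metric (only `"euclidean"`).
#' @return a list with `hclust` (the [stats::hclust] object), `order` (leaf
#'   labels in dendrogram order) and `heights` (merge heights).
#' @export
complete_linkage_dendrogram <- function(rows, metric = c("euclidean")) {
  metric <- match.arg(metric)
  if (nrow(rows) < 2L) stopf("need at least 2 rows")
  rows <- rows[order(rownames(rows), method = "radix"), , drop = FALSE]
  storage.mode(rows) <- "double"
  hc <- stats::hclust(stats::dist(rows, method = metric), method = "complete")
  list(hclust = hc, order = rownames(rows)[hc$order], heights = hc$height)
}
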