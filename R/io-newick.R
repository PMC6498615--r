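#' Write a phylogenetic tree to Newick with deterministic layout
#'
#' Serialises an [ape::phylo] tree with branch lengths at 6 significant
#' digits and integer bootstrap supports (if present in `node.label`) as
#' internal-node labels. Children are ordered lexicographically by their
#' smallest descendant tip label, so the same tree always produces a
#' byte-identical file.
#'
#' @param tree an `ape::phylo` object; every tip must be labeled.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stopf("'tree' must be an ape phylo object")
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stopf("tree has an unlabeled leaf")
  writeLines(newick_string(tree), path)
  invisible(path)
}

# deterministic Newick serialisation (canonical child order)
newick_string <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(tree$edge)) else
    tree$edge.length
  edge_of <- setNames(seq_len(nrow(tree$edge)), tree$edge[, 2])
  nlabel <- tree$node.label
  fmt_len <- function(x) if (is.na(x)) "" else sprintf(":%s",
    sub("\\.$", "", sprintf("%#.6g", x)))

  build <- function(node) {
    ch <- kids[[as.character(node)]]
    if (is.null(ch)) { # tip
      key <- tree$tip.label[node]
      list(str = tree$tip.label[node], key = key)
    } else {
      sub <- lapply(ch, build)
      keys <- vapply(sub, `[[`, character(1), "key")
      o <- order(keys, method = "radix")
      parts <- vapply(seq_along(ch)[o], function(i) {
        child <- ch[i]
        br <- fmt_len(elen[edge_of[as.character(child)]])
        paste0(sub[[i]]$str, br)
      }, character(1))
      lab <- ""
      if (!is.null(nlabel)) {
        l <- nlabel[node - ntip]
        if (!is.na(l) && l != "") lab <- as.character(l)
      }
      list(str = paste0("(", paste(parts, collapse = ","), ")", lab),
           key = min(keys))
    }
  }
  paste0(build(root)$str, ";")
}

#' Read a Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]; internal node labels are
#' interpreted as bootstrap supports where numeric.
#'
#' @param path path to a Newick file.
#' @return an `ape::phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("Newick file not found: %s", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stopf("could not parse Newick in %s", path)
  tree
}
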