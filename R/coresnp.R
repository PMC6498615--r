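# Core-genome SNP/indel supermatrix: select unfragmented single-copy core
# families, align each family (center-star MSA), extract variant columns
# excluding Ns, and concatenate.

#' Select unfragmented single-copy core families
#'
#' Keeps families that are intact in every genome, have no fragment member
#' anywhere, and have exactly one intact member per genome (so the one-row-
#' per-genome family alignment is well defined).
#'
#' @param families a `family_table` from [build_families()].
#' @param matrix a `ternary_matrix` over the genomes of interest.
#' @param annotations annotation data.frame (columns `gene_id`, `genome_id`,
#'   `status`) covering the clustered genes.
#' @return character vector of family ids.
#' @export
select_core_unfragmented <- function(families, matrix, annotations) {
  stopifnot(inherits(families, "family_table"))
  intact_everywhere <- colnames(matrix)[colSums(matrix == 2L) == nrow(matrix)]
  ann <- annotations[annotations$genome_id %in% rownames(matrix), ]
  fam <- families$family_of[ann$gene_id]
  has_frag <- unique(fam[ann$status == "fragment"])
  cand <- setdiff(intact_everywhere, has_frag)
  # single intact copy per genome
  tab <- table(fam[ann$status == "intact"], ann$genome_id[ann$status == "intact"])
  multi <- rownames(tab)[apply(tab, 1, function(x) any(x > 1L))]
  out <- setdiff(cand, multi)
  if (length(out) == 0L)
    stopf(paste0("no unfragmented single-copy core families; ",
                 "review clustering thresholds or genome set"))
  sort(out)
}

#' Center-star multiple alignment of one gene family
#'
#' The center is the sequence minimizing the total pairwise edit distance
#' (ties broken by smallest genome label). All other sequences are aligned
#' to the center globally (match 1, mismatch -1, gap open -4, extend -1) and
#' merged under the once-a-gap-always-a-gap rule.
#'
#' @param sequences named character vector (or `DNAStringSet`), one gene per
#'   genome; names are genome ids.
#' @return a list (`alignment_block`) with `rows` (named character vector of
#'   equal-length aligned strings) and `center` (the center genome id).
#' @export
align_family <- function(sequences) {
  nm <- names(sequences)
  seqs <- setNames(as.character(sequences), nm)
  if (length(seqs) < 2L) stopf("need at least 2 sequences to align")
  if (any(nchar(seqs) == 0L)) stopf("empty sequence in family alignment")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("sequences must carry unique genome labels")
  seqs <- seqs[order(names(seqs), method = "radix")]
  n <- length(seqs)

  # fast path: equal-length sequences with scattered substitutions (every
  # pairwise Hamming fraction <= 0.15) align gaplessly; indel-bearing or
  # highly diverged families take the full center-star route
  if (length(unique(nchar(seqs))) == 1L) {
    vm <- do.call(rbind, lapply(seqs, utf8ToInt))
    maxh <- 0
    for (i in seq_len(n - 1L)) {
      h <- max(colSums(t(vm[(i + 1L):n, , drop = FALSE]) != vm[i, ]))
      maxh <- max(maxh, h)
      if (maxh > 0.15 * ncol(vm)) break
    }
    if (maxh <= 0.15 * ncol(vm)) {
      return(structure(list(rows = seqs, center = names(seqs)[1]),
                       class = "alignment_block"))
    }
  }

  sm <- dna_score_matrix()
  # edit-distance center: score with unit costs (match 0, mismatch/gap -1)
  ed <- matrix(0, n, n)
  unit <- matrix(-1, 5, 5, dimnames = dimnames(sm)); diag(unit) <- 0
  pr <- t(utils::combn(n, 2L))
  s <- cpp_align_stats_batch(seqs[pr[, 1]], seqs[pr[, 2]], "ACGTN", unit,
                             0, 1, 0L, NA_integer_, NA_integer_)
  for (e in seq_len(nrow(pr))) {
    ed[pr[e, 1], pr[e, 2]] <- ed[pr[e, 2], pr[e, 1]] <- -s[e, "score"]
  }
  center <- which.min(rowSums(ed)) # first minimum = smallest label (sorted)
  cseq <- seqs[center]

  # align every other sequence to the center, then merge gap maps
  others <- setdiff(seq_len(n), center)
  aln <- lapply(others, function(i)
    cpp_align_global_strings(cseq, seqs[i], "ACGTN", sm, 4, 1))
  # merged center coordinates: number of inserted columns after each center
  # position (position 0 = before the first)
  clen <- nchar(cseq)
  ins_after <- integer(clen + 1L)
  parsed <- lapply(aln, function(p) {
    gc <- chars(p[1]); go <- chars(p[2])
    cpos <- cumsum(gc != "-") # center position per column (0 while leading gap)
    list(gc = gc, go = go, cpos = cpos)
  })
  for (p in parsed) {
    runs <- tabulate(p$cpos[p$gc == "-"] + 1L, nbins = clen + 1L)
    ins_after <- pmax(ins_after, runs)
  }
  width <- clen + sum(ins_after)
  out <- matrix("-", nrow = n, ncol = width,
                dimnames = list(names(seqs), NULL))
  # column index of center position i in the merged alignment
  col_of <- cumsum(ins_after[seq_len(clen)]) + seq_len(clen)
  out[center, col_of] <- chars(cseq)
  for (kk in seq_along(others)) {
    p <- parsed[[kk]]
    # place each pairwise column: center-consuming columns go to col_of;
    # insertion columns stack left-to-right in their reserved slots
    ins_seen <- 0L; last_c <- 0L
    row <- rep("-", width)
    for (ci in seq_along(p$gc)) {
      if (p$gc[ci] != "-") {
        last_c <- p$cpos[ci]; ins_seen <- 0L
        row[col_of[last_c]] <- p$go[ci]
      } else {
        ins_seen <- ins_seen + 1L
        base <- if (last_c == 0L) 0L else col_of[last_c]
        row[base + ins_seen] <- p$go[ci]
      }
    }
    out[others[kk], ] <- row
  }
  rows <- setNames(apply(out, 1, collapse0), names(seqs))
  structure(list(rows = rows, center = names(seqs)[center]),
            class = "alignment_block")
}

#' Extract variant (SNP and indel) columns from an alignment block
#'
#' A column is emitted when it holds at least two distinct symbols from
#' `{A,C,G,T,-}` and no `N` in any row; a gap counts as a character state.
#'
#' @param block an `alignment_block` from [align_family()].
#' @return a character matrix (rows = genomes, one column per variant site)
#'   with an integer vector attribute `positions` (column index in the
#'   source alignment).
#' @export
variant_columns <- function(block) {
  rows <- block$rows
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- names(rows)
  has_n <- colSums(mat == "N") > 0L
  n_states <- apply(mat, 2, function(col) length(unique(col)))
  keep <- which(!has_n & n_states >= 2L)
  out <- mat[, keep, drop = FALSE]
  attr(out, "positions") <- keep
  out
}

#' Concatenate family variant columns into a supermatrix
#'
#' @param blocks named list of `alignment_block`s (names = family ids); each
#'   must cover every genome in `genome_order`.
#' @param genome_order character vector fixing the row order.
#' @return a list (`character_matrix`) with `matrix` (genomes x variant
#'   columns, symbols in `{A,C,G,T,-}`) and `provenance` (data.frame of
#'   `family` and `column` giving each supermatrix column's origin).
#' @export
build_supermatrix <- function(blocks, genome_order) {
  if (length(blocks) == 0L) stopf("no alignment blocks supplied")
  if (is.null(names(blocks))) stopf("blocks must be named by family id")
  ord <- order(names(blocks), method = "radix")
  blocks <- blocks[ord]
  pieces <- list(); prov <- list()
  for (fam in names(blocks)) {
    b <- blocks[[fam]]
    missing <- setdiff(genome_order, names(b$rows))
    if (length(missing) > 0L)
      stopf("family '%s' is missing genome '%s'", fam, missing[1])
    vc <- variant_columns(b)
    if (ncol(vc) == 0L) next
    pieces[[fam]] <- vc[genome_order, , drop = FALSE]
    prov[[fam]] <- data.frame(family = fam, column = attr(vc, "positions"))
  }
  if (length(pieces) == 0L) {
    warnf("no variant columns across %d families; supermatrix is empty",
          length(blocks))
    return(structure(list(matrix = matrix(character(0),
                                          nrow = length(genome_order),
                                          ncol = 0L,
                                          dimnames = list(genome_order, NULL)),
                          provenance = data.frame(family = character(0),
                                                  column = integer(0))),
                     class = "character_matrix"))
  }
  structure(list(matrix = do.call(cbind, pieces),
                 provenance = do.call(rbind, c(prov, make.row.names = FALSE))),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix> %d genomes x %d variant columns (%d families)\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$provenance$family))))
  invisible(x)
}

#' Core-SNP supermatrix straight from annotations
#'
#' Convenience wrapper: selects unfragmented single-copy core families,
#' extracts each family's gene sequences from the genomes, aligns them and
#' concatenates the variant columns.
#'
#' @param genomes named list of [genome_assembly()] objects.
#' @param annotations annotation data.frame for those genomes.
#' @param families `family_table` over the annotated genes.
#' @param matrix `ternary_matrix` over the same genomes.
#' @return a `character_matrix` (see [build_supermatrix()]).
#' @export
core_snp_supermatrix <- function(genomes, annotations, families, matrix) {
  core <- select_core_unfragmented(families, matrix, annotations)
  genome_order <- rownames(matrix)
  ann <- annotations[annotations$genome_id %in% genome_order &
                       annotations$status == "intact", ]
  fam <- families$family_of[ann$gene_id]
  contig_seq <- lapply(genomes, function(g) as.character(g$contigs))
  blocks <- lapply(core, function(f) {
    rows <- ann[fam == f, ]
    seqs <- setNames(vapply(seq_len(nrow(rows)), function(i) {
      cs <- contig_seq[[rows$genome_id[i]]][[rows$contig_id[i]]]
      substr(cs, rows$start[i], rows$end[i])
    }, character(1)), rows$genome_id)
    align_family(seqs)
  })
  names(blocks) <- core
  build_supermatrix(blocks, genome_order)
}
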