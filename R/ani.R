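# Average nucleotide identity: fragment-based ANIb, maximal-match ANIm,
# symmetric ANI matrices, and the hybrid intra/inter-species distance matrix.

#' ANI computation parameters
#'
#' @param fragment_length ANIb query fragment length in bp (default 1020).
#' @param min_fragment_identity minimum alignment identity to retain a
#'   fragment (default 0.30).
#' @param min_fragment_coverage minimum aligned fraction of a fragment to
#'   retain it (default 0.70).
#' @param seed_kmer k-mer size used to seed fragment placement (default 15).
#' @param min_exact_match minimum maximal exact match length for ANIm
#'   anchoring (default 20).
#' @param max_gap largest inter-anchor gap (bp) closed by global alignment in
#'   ANIm; larger gaps are left unaligned (default 5000).
#' @param min_chain_bp minimum total exact-match bp in an ANIm chain; smaller
#'   chains are chance k-mer hits between unrelated genomes (expected at rate
#'   about L^2/4^k) and are reported as missing, not as an ANI (default 100).
#' @param window_pad bp of subject context added around a seeded fragment
#'   placement before local alignment (default 48).
#' @param band_extra extra half-width of the alignment band beyond the
#'   seeded diagonal range (default 16).
#' @return a validated `ani_params` list.
#' @export
ani_params <- function(fragment_length = 1020L, min_fragment_identity = 0.30,
                       min_fragment_coverage = 0.70, seed_kmer = 15L,
                       min_exact_match = 20L, max_gap = 5000L,
                       min_chain_bp = 100L, window_pad = 48L,
                       band_extra = 16L) {
  if (fragment_length < 100L) stopf("'fragment_length' must be >= 100 bp")
  assert_prob(min_fragment_identity, "min_fragment_identity")
  assert_prob(min_fragment_coverage, "min_fragment_coverage")
  if (min_fragment_identity <= 0 || min_fragment_coverage <= 0)
    stopf("fragment retention thresholds must be > 0")
  if (seed_kmer < 8L || seed_kmer > 26L)
    stopf("'seed_kmer' must be in [8, 26]")
  if (min_exact_match < 12L || min_exact_match > 26L)
    stopf("'min_exact_match' must be in [12, 26]")
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_coverage = min_fragment_coverage,
                 seed_kmer = as.integer(seed_kmer),
                 min_exact_match = as.integer(min_exact_match),
                 max_gap = as.integer(max_gap),
                 min_chain_bp = as.integer(min_chain_bp),
                 window_pad = as.integer(window_pad),
                 band_extra = as.integer(band_extra)),
            class = "ani_params")
}

#' Cut a sequence into consecutive ANIb fragments
#'
#' Non-overlapping windows of `fragment_length`; a final remainder is kept if
#' it is at least half a fragment long, otherwise dropped.
#'
#' @param residues nucleotide string.
#' @param fragment_length window size in bp.
#' @return character vector of fragments.
#' @export
fragment_sequence <- function(residues, fragment_length = 1020L) {
  n <- nchar(residues)
  if (n == 0L) stopf("cannot fragment an empty sequence")
  n_full <- n %/% fragment_length
  starts <- seq.int(1L, by = fragment_length, length.out = n_full)
  ends <- starts + fragment_length - 1L
  rem <- n - n_full * fragment_length
  if (rem >= ceiling(fragment_length / 2)) {
    starts <- c(starts, n_full * fragment_length + 1L)
    ends <- c(ends, n)
  }
  if (length(starts) == 0L) return(character(0))
  substring(residues, starts, ends)
}

dna_score_matrix <- function(match = 1, mismatch = -1) {
  K <- 5L
  m <- matrix(mismatch, K, K,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0 # N never counts for or against
  m
}

#' Fragment-based average nucleotide identity (ANIb style)
#'
#' Cuts the query into fragments, places each fragment on the subject by
#' shared-k-mer seeding (modal diagonal of matched subject-unique k-mers),
#' aligns it locally to the seeded window with affine gaps, discards
#' fragments below the identity or coverage thresholds, and averages the
#' identity of the retained fragments.
#'
#' @param query,subject [genome_assembly()] objects.
#' @param params an [ani_params()] object.
#' @return a list (`ani_pair`) with `query_id`, `subject_id`, `ani`
#'   (NA if no fragment is retained), `aligned_fraction` (retained fragment bp
#'   over total fragment bp) and `n_fragments`.
#' @export
anib_pair <- function(query, subject, params = ani_params()) {
  sseq <- genome_sequence(subject)
  sidx <- unique_kmer_index(sseq, params$seed_kmer)
  anib_pair_impl(query, subject, sseq, sidx, params)
}

anib_pair_impl <- function(query, subject, sseq, sidx, params) {
  L <- params$fragment_length
  k <- params$seed_kmer
  contigs <- as.character(query$contigs)
  frags <- character(0); anchor_diag <- list()
  # seed every fragment with one k-mer match pass per contig
  for (cs in contigs) {
    cf <- fragment_sequence(cs, L)
    if (length(cf) == 0L) next
    ck <- kmer_codes(cs, k)
    m <- match(ck, sidx$codes)
    hit <- which(!is.na(m))
    dg <- sidx$pos[m[hit]] - hit # subject offset of contig position 1 - 1
    f0 <- seq.int(1L, by = L, length.out = length(cf))
    fi <- findInterval(hit, f0)
    # k-mers belong to the fragment containing their start; k-mers whose
    # start lies past the last fragment (dropped remainder) are discarded
    fend <- f0 + nchar(cf) - 1L
    ok <- hit <= fend[fi]
    ad <- split(dg[ok] + (f0[fi] - 1L)[ok], fi[ok])
    # diagonal now expressed as subject offset of the fragment start - 1
    lst <- setNames(vector("list", length(cf)), as.character(seq_along(cf)))
    lst[names(ad)] <- lapply(ad, function(d) d)
    anchor_diag <- c(anchor_diag, lst)
    frags <- c(frags, cf)
  }
  if (length(frags) == 0L)
    stopf("genome '%s' is shorter than half a fragment", query$genome_id)
  flen <- nchar(frags)
  sm <- dna_score_matrix()
  pad <- params$window_pad
  ns <- nchar(sseq)

  ids <- numeric(length(frags)); cov <- numeric(length(frags))
  seeded <- logical(length(frags))
  windows <- character(length(frags)); qs <- character(length(frags))
  band_lo <- integer(length(frags)); band_hi <- integer(length(frags))
  for (i in seq_along(frags)) {
    dgs <- anchor_diag[[i]]
    if (is.null(dgs) || length(dgs) == 0L) next
    # diagonal relative to fragment start; modal value places the fragment
    r <- rle(sort(dgs))
    dmode <- as.integer(r$values[which.max(r$lengths)])
    w0 <- max(1L, dmode + 1L - pad)
    w1 <- min(ns, dmode + flen[i] + pad)
    if (w1 - w0 + 1L < 2L) next
    seeded[i] <- TRUE
    windows[i] <- substr(sseq, w0, w1)
    qs[i] <- frags[i]
    off <- (dmode + 1L) - w0 # expected fragment start offset inside window
    band_lo[i] <- off - (pad + params$band_extra)
    band_hi[i] <- off + pad + params$band_extra
  }
  if (any(seeded)) {
    sel <- which(seeded)
    # band limits are per-fragment but identical by construction except at
    # genome edges; align in groups sharing the same band
    grp <- split(sel, paste(band_lo[sel], band_hi[sel]))
    for (g in grp) {
      s <- cpp_align_stats_batch(qs[g], windows[g], "ACGTN", sm, 4, 1, 1L,
                                 band_lo[g[1]], band_hi[g[1]])
      cols <- s[, "n_match"] + s[, "n_mismatch"] + s[, "n_gap_internal"]
      ids[g] <- ifelse(cols > 0, s[, "n_match"] / cols, 0)
      cov[g] <- (s[, "a_last"] - s[, "a_first"] + 1) / flen[g]
    }
  }
  retained <- seeded & ids >= params$min_fragment_identity &
    cov >= params$min_fragment_coverage
  if (!any(retained)) {
    warnf("no aligned fragments between '%s' and '%s'; ANI recorded missing",
          query$genome_id, subject$genome_id)
    return(structure(list(query_id = query$genome_id,
                          subject_id = subject$genome_id, ani = NA_real_,
                          aligned_fraction = 0,
                          n_fragments = length(frags)), class = "ani_pair"))
  }
  structure(list(query_id = query$genome_id, subject_id = subject$genome_id,
                 ani = mean(ids[retained]),
                 aligned_fraction = sum(flen[retained]) / sum(flen),
                 n_fragments = length(frags)),
            class = "ani_pair")
}

#' Maximal-exact-match average nucleotide identity (ANIm style)
#'
#' Finds maximal exact matches of at least `min_exact_match` bp that are
#' unique in both genomes, chains them collinearly, closes inter-match gaps
#' up to `max_gap` bp by global alignment, and reports identity over the
#' matched (non-gap) columns of the chained alignment.
#'
#' @inheritParams anib_pair
#' @return an `ani_pair` list as in [anib_pair()]; `aligned_fraction` is the
#'   chained query bp over query length.
#' @export
anim_pair <- function(query, subject, params = ani_params()) {
  qseq <- genome_sequence(query)
  sseq <- genome_sequence(subject)
  anim_pair_impl(query, subject, qseq, sseq,
                 unique_kmer_index(qseq, params$min_exact_match),
                 unique_kmer_index(sseq, params$min_exact_match), params)
}

# k-mer codes unique within the genome, with their positions
unique_kmer_index <- function(seq, k) {
  codes <- kmer_codes(seq, k)
  u <- !(duplicated(codes, incomparables = NA) |
           duplicated(codes, fromLast = TRUE, incomparables = NA)) &
    !is.na(codes)
  list(codes = codes[u], pos = which(u))
}

anim_pair_impl <- function(query, subject, qseq, sseq, qidx, sidx, params) {
  k <- params$min_exact_match
  m <- match(qidx$codes, sidx$codes)
  hit <- !is.na(m)
  anchors_q <- qidx$pos[hit]
  anchors_s <- sidx$pos[m[hit]]
  miss <- function() {
    warnf("no exact-match chain between '%s' and '%s'; ANI recorded missing",
          query$genome_id, subject$genome_id)
    structure(list(query_id = query$genome_id,
                   subject_id = subject$genome_id,
                   ani = NA_real_, aligned_fraction = 0, n_fragments = 0L),
              class = "ani_pair")
  }
  if (length(anchors_q) == 0L) return(miss())
  o <- order(anchors_q)
  aq <- anchors_q[o]; as_ <- anchors_s[o]
  # merge runs of consecutive anchor positions on the same diagonal into
  # maximal exact-match segments of length run + k - 1
  brk <- c(TRUE, !(diff(aq) == 1L & diff(as_) == 1L))
  seg_id <- cumsum(brk)
  seg_q0 <- aq[brk]
  seg_s0 <- as_[brk]
  seg_len <- as.integer(tabulate(seg_id) + k - 1L)

  # greedy collinear chaining in query order, trimming overlaps
  nseg <- length(seg_q0)
  cq0 <- integer(nseg); cs0 <- integer(nseg); clen <- integer(nseg)
  nc <- 0L
  last_q <- 0L; last_s <- 0L
  for (i in seq_len(nseg)) {
    q0 <- seg_q0[i]; s0 <- seg_s0[i]; len <- seg_len[i]
    trim <- max(last_q - q0 + 1L, last_s - s0 + 1L, 0L)
    q0 <- q0 + trim; s0 <- s0 + trim; len <- len - trim
    if (len < k) next
    nc <- nc + 1L
    cq0[nc] <- q0; cs0[nc] <- s0; clen[nc] <- len
    last_q <- q0 + len - 1L; last_s <- s0 + len - 1L
  }
  if (nc == 0L) return(miss())
  cq0 <- cq0[seq_len(nc)]; cs0 <- cs0[seq_len(nc)]; clen <- clen[seq_len(nc)]
  # a chain this small is a chance k-mer hit, not evidence of homology
  if (sum(clen) < (params$min_chain_bp %||% 100L)) return(miss())

  n_match <- sum(clen)
  n_mm <- 0
  q_aligned <- sum(clen)
  # close gaps between consecutive chained matches
  if (length(cq0) > 1L) {
    gq0 <- cq0[-length(cq0)] + clen[-length(clen)]
    gq1 <- cq0[-1] - 1L
    gs0 <- cs0[-length(cs0)] + clen[-length(clen)]
    gs1 <- cs0[-1] - 1L
    glq <- gq1 - gq0 + 1L
    gls <- gs1 - gs0 + 1L
    both <- glq > 0L & gls > 0L & glq <= params$max_gap & gls <= params$max_gap
    indel_only <- xor(glq > 0L, gls > 0L) & pmax(glq, gls) <= params$max_gap
    if (any(both)) {
      sm <- dna_score_matrix()
      s <- cpp_align_stats_batch(substring(qseq, gq0[both], gq1[both]),
                                 substring(sseq, gs0[both], gs1[both]),
                                 "ACGTN", sm, 4, 1, 0L,
                                 NA_integer_, NA_integer_)
      n_match <- n_match + sum(s[, "n_match"])
      n_mm <- n_mm + sum(s[, "n_mismatch"])
      q_aligned <- q_aligned + sum(glq[both])
    }
    q_aligned <- q_aligned + sum(glq[indel_only & glq > 0L])
  }
  structure(list(query_id = query$genome_id, subject_id = subject$genome_id,
                 ani = n_match / (n_match + n_mm),
                 aligned_fraction = q_aligned / nchar(qseq),
                 n_fragments = length(cq0)),
            class = "ani_pair")
}

#' Symmetric ANI matrix over a genome set
#'
#' Computes both directed ANI values for every genome pair and averages them;
#' the diagonal is 1. A pair with either directed value missing is flagged
#' `NA` (with a warning), never coerced to 0.
#'
#' @param genomes named list of [genome_assembly()] objects.
#' @param method `"anib"` or `"anim"`.
#' @param params an [ani_params()] object.
#' @return a symmetric numeric matrix of ANI fractions with unit diagonal.
#' @export
ani_matrix <- function(genomes, method = c("anib", "anim"),
                       params = ani_params()) {
  method <- match.arg(method)
  if (length(genomes) < 2L) stopf("need at least 2 genomes")
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  names(genomes) <- ids
  n <- length(ids)
  seqs <- lapply(genomes, genome_sequence)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  if (method == "anib") {
    idx <- lapply(seqs, unique_kmer_index, k = params$seed_kmer)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d1 <- anib_pair_impl(genomes[[i]], genomes[[j]], seqs[[j]], idx[[j]],
                           params)
      d2 <- anib_pair_impl(genomes[[j]], genomes[[i]], seqs[[i]], idx[[i]],
                           params)
      m[i, j] <- m[j, i] <- mean(c(d1$ani, d2$ani)) # NA if either missing
    }
  } else {
    kms <- lapply(seqs, unique_kmer_index, k = params$min_exact_match)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d1 <- anim_pair_impl(genomes[[i]], genomes[[j]], seqs[[i]], seqs[[j]],
                           kms[[i]], kms[[j]], params)
      d2 <- anim_pair_impl(genomes[[j]], genomes[[i]], seqs[[j]], seqs[[i]],
                           kms[[j]], kms[[i]], params)
      m[i, j] <- m[j, i] <- mean(c(d1$ani, d2$ani))
    }
  }
  m
}

#' Hybrid intra/inter-species ANI distance matrix
#'
#' Distance between two genomes is `1 - ANIm` when they share a species
#' label (ANIm resolves close relatives best) and `1 - ANIb` otherwise
#' (fragment-based ANI is robust across species); the diagonal is 0.
#'
#' @param anim,anib symmetric ANI matrices over the same genomes in the same
#'   order, from [ani_matrix()].
#' @param species_of named character vector mapping genome id to species
#'   label.
#' @return a symmetric distance matrix with zero diagonal.
#' @export
hybrid_distance_matrix <- function(anim, anib, species_of) {
  if (!identical(dimnames(anim), dimnames(anib)))
    stopf("ANIm and ANIb matrices must have identical labels and order")
  ids <- rownames(anim)
  if (!all(ids %in% names(species_of)))
    stopf("species label missing for genome '%s'",
          setdiff(ids, names(species_of))[1])
  sp <- species_of[ids]
  same <- outer(sp, sp, `==`)
  src <- ifelse(same, anim, anib)
  bad <- which(is.na(src) & row(src) != col(src), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("missing ANI for pair %s / %s; hybrid distances need a complete matrix",
          ids[bad[1, 1]], ids[bad[1, 2]])
  d <- 1 - src
  diag(d) <- 0
  dimnames(d) <- dimnames(anim)
  d
}
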