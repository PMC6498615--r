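# Protein clustering into gene families at identity/coverage thresholds,
# the ternary presence/fragmentation/absence matrix, pangenome partition,
# rarefaction and group resampling statistics.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# global affine alignment stats for protein pairs (BLOSUM62, open 11, ext 1)
protein_align_stats <- function(a, b, gap_open = 11, gap_ext = 1) {
  sm <- blosum62_matrix()
  cpp_align_stats_batch(a, b, collapse0(rownames(sm)), sm, gap_open, gap_ext,
                        0L, NA_integer_, NA_integer_)
}

#' Identity and coverage of a protein pair
#'
#' Globally aligns two proteins with affine gaps (BLOSUM62, gap open 11,
#' extension 1). Identity is the fraction of identical residues over aligned
#' columns excluding terminal gaps (internal gap columns count against
#' identity); coverage of each protein is its aligned span divided by its
#' length.
#'
#' @param a,b protein sequences (single strings).
#' @return a list with `identity`, `coverage_a`, `coverage_b`.
#' @export
pairwise_protein_metrics <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stopf("proteins must be non-empty")
  s <- protein_align_stats(a, b)
  cols <- s[1, "n_match"] + s[1, "n_mismatch"] + s[1, "n_gap_internal"]
  list(identity = if (cols > 0) unname(s[1, "n_match"] / cols) else 0,
       coverage_a = unname((s[1, "a_last"] - s[1, "a_first"] + 1) / nchar(a)),
       coverage_b = unname((s[1, "b_last"] - s[1, "b_first"] + 1) / nchar(b)))
}

# candidate pairs sharing >= min_shared distinct amino-acid k-mers and
# passing the provable length-ratio bound min(len)/max(len) > id_thr*cov_thr
candidate_pairs <- function(proteins, id_threshold, cov_threshold,
                            seed_k = 5L, min_shared = 2L) {
  n <- length(proteins)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  lens <- nchar(proteins)
  kms <- lapply(proteins, function(p) {
    np <- nchar(p)
    if (np < seed_k) return(p) # whole short protein as its own seed
    unique(substring(p, 1:(np - seed_k + 1L), seed_k:np))
  })
  all_k <- unique(unlist(kms, use.names = FALSE))
  ii <- rep.int(seq_len(n), lengths(kms))
  jj <- match(unlist(kms, use.names = FALSE), all_k)
  inc <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(n, length(all_k)))
  shared <- Matrix::tcrossprod(inc)
  sh <- methods::as(methods::as(shared, "generalMatrix"), "TsparseMatrix")
  keep <- sh@i < sh@j & sh@x >= min_shared
  pr <- cbind(sh@i[keep] + 1L, sh@j[keep] + 1L)
  cnt <- sh@x[keep]
  la <- lens[pr[, 1]]; lb <- lens[pr[, 2]]
  # provable necessity: both coverages > c and identity > t force
  # min(len)/max(len) > t*c
  ok <- pmin(la, lb) / pmax(la, lb) > id_threshold * cov_threshold
  # expected-count prescreen: a pair at the identity/coverage thresholds
  # shares about t^k * (c * min_len - k) seeds; requiring a quarter of that
  # leaves a 4x margin while pruning chance collisions
  expect <- id_threshold^seed_k *
    pmax(cov_threshold * pmin(la, lb) - seed_k, 0)
  ok <- ok & cnt >= pmax(min_shared, ceiling(0.25 * expect))
  pr[ok, , drop = FALSE]
}

#' Cluster proteins into gene families
#'
#' Places an edge between two proteins when global-alignment identity and
#' both-sided coverage strictly exceed the thresholds, and takes connected
#' components as families (single linkage). Candidate pairs are pre-filtered
#' by shared amino-acid k-mers and a provable length-ratio bound; the filter's
#' completeness at the default thresholds is validated against brute-force
#' all-pairs clustering in the test-suite.
#'
#' @param proteins a named `AAStringSet` or named character vector.
#' @param id_threshold identity threshold (strict `>`; default 0.80).
#' @param cov_threshold coverage threshold on both sequences (strict `>`;
#'   default 0.80).
#' @param seed_k k-mer size of the candidate filter (default 5).
#' @param min_shared minimum shared distinct k-mers for a candidate pair
#'   (default 2).
#' @param brute_force align every pair, bypassing the candidate filter.
#' @return a `family_table`: list with `family_of` (gene id -> family id) and
#'   `members` (family id -> character vector of gene ids). Family ids are
#'   `fam_<smallest member id>`, so the partition is order-invariant.
#' @export
build_families <- function(proteins, id_threshold = 0.80,
                           cov_threshold = 0.80, seed_k = 5L,
                           min_shared = 2L, brute_force = FALSE) {
  if (length(proteins) == 0L) stopf("no proteins to cluster")
  nm <- names(proteins)
  px <- setNames(as.character(proteins), nm)
  if (is.null(names(px)) || anyDuplicated(names(px)))
    stopf("proteins must have unique names")
  assert_prob(id_threshold, "id_threshold")
  assert_prob(cov_threshold, "cov_threshold")
  ids <- names(px)
  n <- length(px)
  ord <- order(ids, method = "radix") # order-invariant processing
  px <- px[ord]; ids <- ids[ord]
  pairs <- if (brute_force || n <= 2L) {
    if (n < 2L) matrix(integer(0), ncol = 2L) else t(utils::combn(n, 2L))
  } else candidate_pairs(px, id_threshold, cov_threshold, seed_k, min_shared)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0L) {
    lens <- nchar(px)
    chunk <- 20000L
    for (off in seq(1L, nrow(pairs), by = chunk)) {
      idx <- off:min(off + chunk - 1L, nrow(pairs))
      s <- protein_align_stats(px[pairs[idx, 1]], px[pairs[idx, 2]])
      cols <- s[, "n_match"] + s[, "n_mismatch"] + s[, "n_gap_internal"]
      identity <- ifelse(cols > 0, s[, "n_match"] / cols, 0)
      cov_a <- (s[, "a_last"] - s[, "a_first"] + 1) / lens[pairs[idx, 1]]
      cov_b <- (s[, "b_last"] - s[, "b_first"] + 1) / lens[pairs[idx, 2]]
      hit <- identity > id_threshold & pmin(cov_a, cov_b) > cov_threshold
      for (e in which(hit)) {
        ra <- find(pairs[idx[e], 1]); rb <- find(pairs[idx[e], 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  members <- split(ids, root)
  fam_ids <- vapply(members, function(m) paste0("fam_", min(m)), character(1))
  names(members) <- fam_ids
  members <- members[order(names(members), method = "radix")]
  family_of <- setNames(rep(names(members), lengths(members)),
                        unlist(members, use.names = FALSE))
  structure(list(family_of = family_of, members = members),
            class = "family_table")
}

#' @export
print.family_table <- function(x, ...) {
  cat(sprintf("<family_table> %d genes in %d families (largest: %d members)\n",
              length(x$family_of), length(x$members),
              max(lengths(x$members))))
  invisible(x)
}

#' Ternary presence/fragmentation/absence matrix
#'
#' For every genome and family: 2 if the genome has at least one intact
#' member of the family, 1 if it has only fragment members, 0 if absent.
#'
#' @param families a `family_table` from [build_families()].
#' @param annotations annotation data.frame covering every clustered gene
#'   (columns `gene_id`, `genome_id`, `status`).
#' @param genomes optional genome order for the rows (default: sorted unique
#'   genome ids in `annotations`).
#' @return an integer matrix (genomes x families) of class `ternary_matrix`
#'   with values in `{0, 1, 2}`.
#' @export
ternary_presence <- function(families, annotations, genomes = NULL) {
  stopifnot(inherits(families, "family_table"))
  miss <- setdiff(annotations$gene_id, names(families$family_of))
  if (length(miss) > 0L)
    stopf("gene '%s' has no family assignment", miss[1])
  genomes <- genomes %||% sort(unique(annotations$genome_id))
  fams <- names(families$members)
  fam_of <- families$family_of[annotations$gene_id]
  score <- ifelse(annotations$status == "intact", 2L, 1L)
  m <- matrix(0L, nrow = length(genomes), ncol = length(fams),
              dimnames = list(genomes, fams))
  gi <- match(annotations$genome_id, genomes)
  fi <- match(fam_of, fams)
  keep <- !is.na(gi)
  for (k in which(keep)) {
    if (score[k] > m[gi[k], fi[k]]) m[gi[k], fi[k]] <- score[k]
  }
  structure(m, class = c("ternary_matrix", class(m)))
}

#' Partition the pangenome into core, variable and singleton families
#'
#' Core families are present (state >= 1, i.e. fragment counts as presence)
#' in every genome; singleton families have exactly one member gene in the
#' whole dataset; everything else is variable.
#'
#' @param matrix a `ternary_matrix`.
#' @param member_counts optional named vector of total member-gene counts per
#'   family (from `lengths(families$members)`); without it a singleton is
#'   approximated as a family seen in exactly one genome.
#' @return list with `core`, `variable`, `singleton` (character vectors) that
#'   partition the column names of `matrix`.
#' @export
partition_pangenome <- function(matrix, member_counts = NULL) {
  if (nrow(matrix) < 1L) stopf("need at least one genome")
  present <- matrix >= 1L
  core <- colnames(matrix)[colSums(present) == nrow(matrix)]
  singleton <- if (!is.null(member_counts)) {
    colnames(matrix)[member_counts[colnames(matrix)] == 1L]
  } else {
    colnames(matrix)[colSums(present) == 1L]
  }
  singleton <- setdiff(singleton, core)
  variable <- setdiff(colnames(matrix), c(core, singleton))
  list(core = core, variable = variable, singleton = singleton)
}

#' Pangenome and coregenome rarefaction curves
#'
#' For every subset size n = 1..N, draws `reps` random strain subsets without
#' replacement and records the pangenome size (families present in at least
#' one sampled strain) and coregenome size (families present in all sampled
#' strains).
#'
#' @param matrix a `ternary_matrix`.
#' @param reps random subsets per size (default 10).
#' @param seed optional seed for reproducibility.
#' @return a data.frame with columns `n_strains`, `rep`, `pan`, `core`.
#' @export
rarefaction_curve <- function(matrix, reps = 10L, seed = NULL) {
  if (reps < 1L) stopf("'reps' must be >= 1")
  present <- matrix >= 1L
  N <- nrow(present)
  run <- function() {
    out <- vector("list", N * reps)
    k <- 0L
    for (n in seq_len(N)) {
      for (r in seq_len(reps)) {
        k <- k + 1L
        rows <- sample.int(N, n)
        sub <- present[rows, , drop = FALSE]
        cs <- colSums(sub)
        out[[k]] <- c(n_strains = n, rep = r, pan = sum(cs > 0L),
                      core = sum(cs == n))
      }
    }
    as.data.frame(do.call(rbind, out))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Group resampling statistics of the variable genome
#'
#' For each group, repeatedly samples `sample_n` strains (without replacement
#' by default) and reports mean and standard deviation over replicates of:
#' distinct variable families present in the sample (`unique_micfams`), the
#' sum over sampled strains of per-strain variable-family counts (`micfams`),
#' and the analogous singleton statistics.
#'
#' @param matrix a `ternary_matrix`.
#' @param group_of named character vector: genome id -> group label.
#' @param partition output of [partition_pangenome()] identifying variable
#'   and singleton families.
#' @param sample_n strains sampled per replicate (default 5).
#' @param reps replicates (default 10000).
#' @param replace sample with replacement (default FALSE).
#' @param seed optional seed.
#' @return a data.frame with one row per group and columns
#'   `unique_micfams_mean/sd`, `unique_singletons_mean/sd`,
#'   `micfams_mean/sd`, `singletons_mean/sd`.
#' @export
group_bootstrap_stats <- function(matrix, group_of, partition,
                                  sample_n = 5L, reps = 10000L,
                                  replace = FALSE, seed = NULL) {
  groups <- sort(unique(group_of[rownames(matrix)]))
  run <- function() {
    res <- lapply(groups, function(gr) {
      rows <- rownames(matrix)[group_of[rownames(matrix)] == gr]
      if (!replace && length(rows) < sample_n)
        stopf("group '%s' has %d strains, fewer than sample_n = %d", gr,
              length(rows), sample_n)
      vm <- matrix[rows, partition$variable, drop = FALSE] >= 1L
      sm <- matrix[rows, partition$singleton, drop = FALSE] >= 1L
      per_strain_var <- rowSums(vm)
      per_strain_sing <- rowSums(sm)
      stats <- matrix(0, nrow = reps, ncol = 4L)
      for (r in seq_len(reps)) {
        pick <- sample(length(rows), sample_n, replace = replace)
        stats[r, 1] <- sum(colSums(vm[pick, , drop = FALSE]) > 0L)
        stats[r, 2] <- sum(colSums(sm[pick, , drop = FALSE]) > 0L)
        stats[r, 3] <- sum(per_strain_var[pick])
        stats[r, 4] <- sum(per_strain_sing[pick])
      }
      data.frame(group = gr,
                 unique_micfams_mean = mean(stats[, 1]),
                 unique_micfams_sd = sd_pop0(stats[, 1]),
                 unique_singletons_mean = mean(stats[, 2]),
                 unique_singletons_sd = sd_pop0(stats[, 2]),
                 micfams_mean = mean(stats[, 3]),
                 micfams_sd = sd_pop0(stats[, 3]),
                 singletons_mean = mean(stats[, 4]),
                 singletons_sd = sd_pop0(stats[, 4]))
    })
    do.call(rbind, res)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# sample sd, 0 for constant input (instead of NA for a single replicate)
sd_pop0 <- function(x) {
  if (length(x) < 2L || all(x == x[1])) return(0)
  stats::sd(x)
}
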