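# Clade-level profiling: clade-specific families, variable regions, pathway
# completion, PTS component counts and gene-status slices.

presence_of <- function(matrix, presence = c("any", "intact_only")) {
  presence <- match.arg(presence)
  if (presence == "any") matrix >= 1L else matrix == 2L
}

#' Detect clade-specific gene families
#'
#' A family is specific to clade `c` when it is present in at least `min_in`
#' of the clade's genomes and at most `max_out` of all other genomes.
#'
#' @param matrix a `ternary_matrix`.
#' @param clade_of named character vector genome id -> clade label.
#' @param min_in minimum presence fraction inside the clade (default 0.90).
#' @param max_out maximum presence fraction outside the clade (default 0.05).
#' @param presence `"any"` (state >= 1) or `"intact_only"` (state == 2).
#' @return named list: clade label -> character vector of family ids.
#' @export
clade_specific_families <- function(matrix, clade_of, min_in = 0.90,
                                    max_out = 0.05,
                                    presence = c("any", "intact_only")) {
  assert_prob(min_in, "min_in")
  assert_prob(max_out, "max_out")
  miss <- setdiff(rownames(matrix), names(clade_of))
  if (length(miss) > 0L) stopf("genome '%s' has no clade label", miss[1])
  pres <- presence_of(matrix, presence)
  cl <- clade_of[rownames(matrix)]
  clades <- sort(unique(cl))
  setNames(lapply(clades, function(cd) {
    inside <- pres[cl == cd, , drop = FALSE]
    outside <- pres[cl != cd, , drop = FALSE]
    f_in <- colMeans(inside)
    f_out <- if (nrow(outside) > 0L) colMeans(outside) else
      rep(0, ncol(pres))
    colnames(matrix)[f_in >= min_in & f_out <= max_out]
  }), clades)
}

#' Detect variable regions of one genome against a comparison group
#'
#' Marks CDS whose family is absent from every genome of the comparison
#' group, and reports maximal runs of at least `min_run` marked CDS
#' (tolerating up to `gap_tolerance` unmarked CDS between marked ones)
#' as regions. Region length is last CDS end minus first CDS start + 1.
#'
#' @param annotations annotations of the target genome (one genome only),
#'   ordered or orderable by contig and start.
#' @param matrix a `ternary_matrix` covering the comparison group.
#' @param family_of named vector gene id -> family id for the target genes.
#' @param other_group character vector of comparison genome ids.
#' @param min_run minimum marked-CDS run length (default 5).
#' @param gap_tolerance unmarked CDS allowed inside a run (default 0).
#' @return a list (`region_report`) with `genome_id`, `regions` (data.frame
#'   `contig`, `start`, `end`, `n_cds`) and `totals` (list `n_regions`,
#'   `total_bp`, `total_cds`).
#' @export
detect_variable_regions <- function(annotations, matrix, family_of,
                                    other_group, min_run = 5L,
                                    gap_tolerance = 0L) {
  if (length(other_group) == 0L) stopf("comparison group is empty")
  miss <- setdiff(other_group, rownames(matrix))
  if (length(miss) > 0L)
    stopf("comparison genome '%s' not in the matrix", miss[1])
  gid <- unique(annotations$genome_id)
  if (length(gid) != 1L) stopf("annotations must cover exactly one genome")
  a <- annotations[order(annotations$contig_id, annotations$start), ]
  fam <- family_of[a$gene_id]
  if (any(is.na(fam))) stopf("gene '%s' has no family", a$gene_id[is.na(fam)][1])
  pres_other <- matrix[other_group, , drop = FALSE] >= 1L
  absent_out <- colSums(pres_other) == 0L
  marked <- fam %in% colnames(matrix)[absent_out] |
    !(fam %in% colnames(matrix)) # family unseen in matrix = absent outside
  regions <- list()
  for (ct in unique(a$contig_id)) {
    sel <- which(a$contig_id == ct)
    mk <- marked[sel]
    i <- 1L
    while (i <= length(mk)) {
      if (!mk[i]) { i <- i + 1L; next }
      j <- i; gap <- 0L; last_marked <- i
      while (j < length(mk)) {
        if (mk[j + 1L]) { j <- j + 1L; last_marked <- j; gap <- 0L }
        else if (gap < gap_tolerance) { j <- j + 1L; gap <- gap + 1L }
        else break
      }
      run <- sel[i:last_marked]
      if (sum(marked[run]) >= min_run) {
        regions[[length(regions) + 1L]] <- data.frame(
          contig = ct, start = min(a$start[run]), end = max(a$end[run]),
          n_cds = length(run))
      }
      i <- last_marked + 1L
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               n_cds = integer(0))
  structure(list(genome_id = gid, regions = regions,
                 totals = list(n_regions = nrow(regions),
                               total_bp = sum(regions$end - regions$start + 1L),
                               total_cds = sum(regions$n_cds))),
            class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("<region_report> %s: %d region(s), %s bp, %d CDS\n",
              x$genome_id, x$totals$n_regions,
              format(x$totals$total_bp, big.mark = ","), x$totals$total_cds))
  invisible(x)
}

#' Pathway completion per strain
#'
#' Completion of a pathway in a strain is the fraction of its roles whose
#' family is present; by default only intact copies count (function, not
#' mere presence).
#'
#' @param matrix a `ternary_matrix`.
#' @param pathways data.frame with columns `pathway_id` and `role` (one row
#'   per required gene family; `role` holds the family label).
#' @param presence `"intact_only"` (default) or `"any"`.
#' @return numeric matrix strains x pathways with values in `[0, 1]`.
#' @export
pathway_completion <- function(matrix, pathways,
                               presence = c("intact_only", "any")) {
  presence <- match.arg(presence)
  if (!all(c("pathway_id", "role") %in% names(pathways)))
    stopf("'pathways' needs columns pathway_id and role")
  ids <- unique(pathways$pathway_id)
  if (any(tapply(pathways$role, pathways$pathway_id, length) == 0L) ||
      nrow(pathways) == 0L)
    stopf("empty pathway definition")
  pres <- presence_of(matrix, presence)
  out <- matrix(NA_real_, nrow(matrix), length(ids),
                dimnames = list(rownames(matrix), ids))
  for (pw in ids) {
    roles <- pathways$role[pathways$pathway_id == pw]
    known <- roles[roles %in% colnames(pres)]
    if (length(known) < length(roles))
      warnf("pathway '%s': %d of %d roles not in the matrix (counted absent)",
            pw, length(roles) - length(known), length(roles))
    hit <- if (length(known) > 0L)
      rowSums(pres[, known, drop = FALSE]) else rep(0, nrow(pres))
    out[, pw] <- hit / length(roles)
  }
  out
}

#' Phosphotransferase-system component counts per strain
#'
#' Counts how many of a system's EII components (1-4 family labels) are
#' present in each strain.
#'
#' @param matrix a `ternary_matrix`.
#' @param systems data.frame with columns `system_id` and `component` (one
#'   row per component; `component` holds the family label), optionally
#'   `substrate`.
#' @param presence `"intact_only"` (default) or `"any"`.
#' @return integer matrix strains x systems.
#' @export
pts_component_counts <- function(matrix, systems,
                                 presence = c("intact_only", "any")) {
  presence <- match.arg(presence)
  if (!all(c("system_id", "component") %in% names(systems)))
    stopf("'systems' needs columns system_id and component")
  if (nrow(systems) == 0L) stopf("empty PTS definition")
  sizes <- tapply(systems$component, systems$system_id, length)
  if (any(sizes < 1L) || any(sizes > 4L))
    stopf("each PTS must have 1-4 components")
  ids <- unique(systems$system_id)
  pres <- presence_of(matrix, presence)
  out <- matrix(0L, nrow(matrix), length(ids),
                dimnames = list(rownames(matrix), ids))
  for (sy in ids) {
    comp <- systems$component[systems$system_id == sy]
    known <- comp[comp %in% colnames(pres)]
    if (length(known) < length(comp))
      warnf("PTS '%s': %d of %d components not in the matrix (counted absent)",
            sy, length(comp) - length(known), length(comp))
    out[, sy] <- if (length(known) > 0L)
      as.integer(rowSums(pres[, known, drop = FALSE])) else 0L
  }
  out
}

#' Ternary-state slice for a set of families
#'
#' Returns the ternary matrix restricted to the requested families and
#' strains, in the requested order; unresolvable family labels become
#' all-absent columns with a warning.
#'
#' @param matrix a `ternary_matrix`.
#' @param family_labels columns to slice.
#' @param strains rows to slice (default all, matrix order).
#' @return integer matrix strains x families with values in `{0, 1, 2}`.
#' @export
gene_status_report <- function(matrix, family_labels, strains = NULL) {
  strains <- strains %||% rownames(matrix)
  miss <- setdiff(strains, rownames(matrix))
  if (length(miss) > 0L) stopf("unknown strain '%s'", miss[1])
  out <- matrix(0L, length(strains), length(family_labels),
                dimnames = list(strains, family_labels))
  known <- family_labels[family_labels %in% colnames(matrix)]
  if (length(known) < length(family_labels))
    warnf("%d of %d family labels not in the matrix (all-absent columns)",
          length(family_labels) - length(known), length(family_labels))
  out[, known] <- matrix[strains, known]
  out
}
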