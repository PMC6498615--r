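#' Read CDS annotations from a GFF3 file
#'
#' Reads `CDS` features and joins them with their protein translations.
#' Coordinates stay 1-based inclusive, as in GFF3; conversion to 0-based
#' half-open intervals happens only inside region arithmetic. Gene status
#' (intact vs pseudogenized fragment) is carried in a `status=` attribute;
#' records without the attribute are treated as intact.
#'
#' @param path path to a GFF3 file.
#' @param proteins an `AAStringSet` (or named character vector) of protein
#'   translations; names must cover every CDS id.
#' @param genome_id genome identifier recorded for every annotation; defaults
#'   to the file name without extension.
#' @return a `data.frame` with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `status`, `product`.
#' @export
read_gff3 <- function(path, proteins, genome_id = NULL) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stopf("no CDS features in %s", path)
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  if (any(is.na(ids) | ids == "")) stopf("CDS feature without an ID in %s", path)
  if (anyDuplicated(ids))
    stopf("duplicate CDS id '%s' in %s", ids[duplicated(ids)][1], path)
  status <- if ("status" %in% colnames(md)) as.character(md$status) else
    rep(NA_character_, length(gr))
  status[is.na(status)] <- "intact"
  if (!all(status %in% c("intact", "fragment")))
    stopf("invalid status value '%s' (must be intact or fragment)",
          setdiff(status, c("intact", "fragment"))[1])
  product <- if ("product" %in% colnames(md)) as.character(md$product) else
    rep(NA_character_, length(gr))
  st <- BiocGenerics::start(gr)
  en <- BiocGenerics::end(gr)
  if (any(en < st)) stopf("CDS '%s' has end < start", ids[en < st][1])
  missing_prot <- setdiff(ids, names(proteins))
  if (length(missing_prot) > 0L)
    stopf("CDS '%s' has no matching protein translation", missing_prot[1])
  data.frame(gene_id = ids,
             genome_id = genome_id %||% sub("\\.gff3?$", "", basename(path)),
             contig_id = as.character(GenomeInfoDb::seqnames(gr)),
             start = st, end = en,
             strand = as.character(BiocGenerics::strand(gr)),
             status = status, product = product,
             stringsAsFactors = FALSE)
}

#' Write CDS annotations to a GFF3 file
#'
#' @param annotations a `data.frame` as returned by [read_gff3()].
#' @param path output path.
#' @export
write_gff3 <- function(annotations, path) {
  req <- c("gene_id", "contig_id", "start", "end", "strand", "status")
  if (!all(req %in% names(annotations)))
    stopf("annotations must have columns: %s", paste(req, collapse = ", "))
  if (any(annotations$end < annotations$start))
    stopf("annotation with end < start cannot be written")
  a <- annotations
  attrs <- sprintf("ID=%s;status=%s", a$gene_id, a$status)
  if ("product" %in% names(a) && any(!is.na(a$product)))
    attrs <- ifelse(is.na(a$product), attrs,
                    sprintf("%s;product=%s", attrs, a$product))
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\t%s",
                     a$contig_id, "panclade", "CDS",
                     as.integer(a$start), as.integer(a$end),
                     a$strand, attrs))
  writeLines(lines, path)
  invisible(path)
}
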