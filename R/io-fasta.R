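#' Read a FASTA file into a validated string set
#'
#' Reads nucleotide or protein FASTA, normalises residues to upper case,
#' removes line wrapping, and enforces the invariants the rest of the pipeline
#' relies on: unique non-empty ids, non-empty sequences, and a strict alphabet
#' (`A/C/G/T/N` for nucleotide, the 20 amino acids plus `X` and `*` for
#' protein).
#'
#' @param path path to a FASTA file.
#' @param kind `"nucleotide"` or `"protein"`.
#' @return a [Biostrings::DNAStringSet] (nucleotide) or
#'   [Biostrings::AAStringSet] (protein). Names hold the record ids (first
#'   whitespace-delimited token of the header); the remainder of each header is
#'   kept in the `description` metadata column.
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stopf("no records in FASTA file: %s", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stopf("record %d has an empty id", which(ids == "")[1])
  if (anyDuplicated(ids))
    stopf("duplicate sequence id '%s' in %s", ids[duplicated(ids)][1], path)
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    stopf("empty sequence for id '%s'", ids[nchar(seqs) == 0L][1])
  alpha <- if (kind == "nucleotide") DNA_ALPHABET else c(AA_ALPHABET, "*")
  ok <- grepl(paste0("^[", collapse0(alpha), "]*$"), seqs)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    pos <- regexpr(paste0("[^", collapse0(alpha), "]"), seqs[bad])
    stopf("record '%s' has character '%s' outside the %s alphabet at position %d",
          ids[bad], substr(seqs[bad], pos, pos), kind, as.integer(pos))
  }
  out <- if (kind == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param x a named character vector, `DNAStringSet` or `AAStringSet`.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    if (is.null(names(x)) || any(names(x) == ""))
      stopf("all sequences must be named")
    x <- Biostrings::BStringSet(x)
  }
  if (length(x) == 0L) stopf("no sequences to write")
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Bundle contigs into a genome assembly
#'
#' @param genome_id unique genome identifier (no whitespace).
#' @param contigs a `DNAStringSet` (or named character vector) of contigs.
#' @param species_label species tag used by the hybrid ANI distance rule.
#' @param clade_label optional known clade label.
#' @return an object of class `genome_assembly`.
#' @export
genome_assembly <- function(genome_id, contigs, species_label = "ingroup",
                            clade_label = NULL) {
  if (!is.character(genome_id) || length(genome_id) != 1L ||
      grepl("\\s", genome_id) || genome_id == "")
    stopf("'genome_id' must be a single non-empty token")
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (length(contigs) == 0L || sum(Biostrings::width(contigs)) == 0L)
    stopf("genome '%s' has no sequence", genome_id)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stopf("contig ids of genome '%s' must be unique and non-empty", genome_id)
  structure(list(genome_id = genome_id, contigs = contigs,
                 species_label = species_label, clade_label = clade_label),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d contig(s), %s bp, species=%s%s\n",
              x$genome_id, length(x$contigs),
              format(sum(Biostrings::width(x$contigs)), big.mark = ","),
              x$species_label,
              if (is.null(x$clade_label)) "" else
                paste0(", clade=", x$clade_label)))
  invisible(x)
}

# single concatenated sequence of a genome (contigs joined, no separator)
genome_sequence <- function(genome) {
  paste(as.character(genome$contigs), collapse = "")
}
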