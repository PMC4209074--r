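# FASTA / GFF3 / species-map input handling.

#' Read protein sequences from FASTA
#'
#' Reads wrapped or single-line FASTA via Biostrings. The description line is
#' parsed as \code{"id key=value ..."}; a \code{species=XX} field, when
#' present, is stored in \code{mcols(x)$species}. Sequences are validated
#' against the 20-letter amino-acid alphabet plus X.
#'
#' @param file FASTA path.
#' @return an [Biostrings::AAStringSet] named by id, with a \code{species}
#'   metadata column (NA where not declared).
#' @export
readProteinFasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  full <- names(aa)
  ids <- vapply(strsplit(full, "\\s+"), `[`, character(1), 1L)
  species <- vapply(full, function(d) {
    m <- regmatches(d, regexpr("species=\\S+", d))
    if (length(m)) sub("^species=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate protein ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(aa) <- ids
  S4Vectors::mcols(aa)$species <- species
  for (i in seq_along(aa)) .validateSequence(as.character(aa[[i]]), ids[i])
  aa
}

#' Write protein sequences to FASTA
#'
#' Writes \code{id species=XX} description lines so that
#' [readProteinFasta()] round-trips the species assignment.
#'
#' @param proteins an \code{AAStringSet}; a \code{species} metadata column is
#'   emitted when present.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeProteinFasta <- function(proteins, file) {
  out <- proteins
  sp <- S4Vectors::mcols(proteins)$species
  if (!is.null(sp)) {
    nm <- ifelse(is.na(sp), names(proteins),
                 paste0(names(proteins), " species=", sp))
    names(out) <- nm
  }
  Biostrings::writeXStringSet(out, file)
  invisible(file)
}

#' Assign species codes to gene ids by longest-prefix match
#'
#' Follows the field's id convention (e.g. \code{At}, \code{Ppa}): each gene
#' id is matched against the declared species-code table and the longest
#' matching prefix wins, so \code{"Ppa1"} resolves to \code{Ppa} rather than
#' \code{Pp}.
#'
#' @param ids character vector of gene ids.
#' @param codes character vector of valid species codes.
#' @return named character vector mapping id to species code.
#' @export
speciesFromIds <- function(ids, codes) {
  codes <- codes[order(-nchar(codes))]
  out <- vapply(ids, function(id) {
    hit <- codes[startsWith(id, codes)]
    if (!length(hit))  # fall back to case-insensitive matching
      hit <- codes[startsWith(tolower(id), tolower(codes))]
    if (!length(hit))
      stop("gene id '", id, "' matches no declared species code")
    hit[1L]
  }, character(1))
  stats::setNames(out, ids)
}

#' Read per-gene intron counts
#'
#' Either a two-column TSV (\code{gene_id}, \code{intron_count}) or a GFF3
#' file. For GFF3, introns are counted within coding sequence only: the
#' number of CDS segments per mRNA minus one, reported under the mRNA/
#' transcript id (Parent of the CDS features).
#'
#' @param file path to a TSV or GFF3 file.
#' @param format \code{"auto"} (by extension), \code{"tsv"} or \code{"gff3"}.
#' @return named integer vector of intron counts.
#' @export
readIntronCounts <- function(file, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", file, ignore.case = TRUE)) "gff3"
              else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.delim(file, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (!all(c("gene_id", "intron_count") %in% names(df)))
      stop("intron TSV must have columns gene_id and intron_count")
    if (any(df$intron_count < 0)) stop("negative intron_count")
    return(stats::setNames(as.integer(df$intron_count), df$gene_id))
  }
  gr <- rtracklayer::import(file, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) return(stats::setNames(integer(0), character(0)))
  parents <- as.character(unlist(cds$Parent))
  tab <- table(parents)
  stats::setNames(as.integer(tab) - 1L, names(tab))
}
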