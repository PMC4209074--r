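# Rule-based AHL typing from motif evidence.
#
# Domain composition decides the type (N- to C-terminal order matters: the
# AT-hook(s) must lie N-terminal to the PPC domain):
#   Type-I   = one Type-I AT-hook + Type-A PPC          (Clade-A)
#   Type-II  = Type-II + Type-I AT-hooks + Type-B PPC   (Clade-B)
#   Type-III = Type-II AT-hook only + Type-B PPC        (Clade-B)
# A PPC domain with no AT-hook anywhere is PPC_ONLY (the picoeukaryote/
# prokaryote configuration); every other combination — mixed-clade evidence,
# untyped PPC with AT-hooks, AT-hooks C-terminal to the domain — is
# UNCLASSIFIED with the evidence retained.

.CLADE_OF <- c(TYPE_I = "A", TYPE_II = "B", TYPE_III = "B",
               PPC_ONLY = "NONE", UNCLASSIFIED = "NONE")

.classifyOne <- function(id, hits, seqLen = NA_integer_) {
  h <- hits[hits$protein_id == id, , drop = FALSE]
  if (!is.na(seqLen) && nrow(h) &&
      (any(h$start0 < 0L) || any(h$end0 > seqLen)))
    stop("protein '", id, "': hit coordinates outside the sequence")
  ppc <- h[h$motif_class %in% c("PPC_A", "PPC_B", "PPC_UNTYPED"), ,
           drop = FALSE]
  hooks <- h[h$motif_class %in% c("AT_HOOK_I", "AT_HOOK_II"), , drop = FALSE]
  multiPpc <- nrow(ppc) > 1L
  verdict <- "UNCLASSIFIED"
  ppcClass <- NA_character_
  n1 <- 0L
  n2 <- 0L
  if (nrow(ppc)) {
    # the family has a single PPC domain; keep the best-scoring hit and flag
    # records where more than one was found
    ppc <- ppc[order(-ppc$score, ppc$start0), , drop = FALSE][1L, ]
    ppcClass <- ppc$motif_class
    if (nrow(hooks) == 0L) {
      verdict <- "PPC_ONLY"
    } else {
      # composition uses AT-hooks N-terminal to the domain anchor
      nterm <- hooks[hooks$end0 <= ppc$anchor_pos, , drop = FALSE]
      n1 <- sum(nterm$motif_class == "AT_HOOK_I")
      n2 <- sum(nterm$motif_class == "AT_HOOK_II")
      if (nrow(nterm) && ppcClass == "PPC_A" && n1 >= 1L && n2 == 0L)
        verdict <- "TYPE_I"
      else if (nrow(nterm) && ppcClass == "PPC_B" && n1 >= 1L && n2 >= 1L)
        verdict <- "TYPE_II"
      else if (nrow(nterm) && ppcClass == "PPC_B" && n1 == 0L && n2 >= 1L)
        verdict <- "TYPE_III"
      # else: mixed-clade, untyped PPC, or hooks only C-terminal
    }
  }
  data.frame(protein_id = id, ahl_type = verdict,
             clade = .CLADE_OF[[verdict]],
             n_at_hook_i = n1, n_at_hook_ii = n2,
             ppc_class = ppcClass, multi_ppc = multiPpc,
             intron_consistent = "UNKNOWN",
             n_hits = nrow(h), stringsAsFactors = FALSE)
}

#' Classify proteins into AHL types from motif evidence
#'
#' Applies the domain-composition decision table (see the package vignette)
#' to the hits of each protein. Exactly one verdict is produced per protein:
#' \code{TYPE_I}, \code{TYPE_II}, \code{TYPE_III}, \code{PPC_ONLY} or
#' \code{UNCLASSIFIED}. Clade is a pure function of the type (Type-I is
#' Clade-A; Types-II/-III are Clade-B; otherwise none). When several PPC hits
#' exist the highest-scoring one is used and the record is flagged
#' (\code{multi_ppc}).
#'
#' @param x proteins as an \code{AAStringSet} or named character vector (used
#'   for the id universe and coordinate validation), or a plain character
#'   vector of protein ids.
#' @param hits motif hits data.frame from [scanMotifs()] (or
#'   [readHitsTsv()]).
#' @return data.frame with one row per protein: \code{protein_id},
#'   \code{ahl_type}, \code{clade}, AT-hook counts (N-terminal to the PPC
#'   anchor), \code{ppc_class}, \code{multi_ppc}, \code{intron_consistent}
#'   (initially \code{UNKNOWN}).
#' @seealso [checkIntronConsistency()], [summarizeTypes()]
#' @export
classifyProteins <- function(x, hits) {
  if (is.character(x) && is.null(names(x))) {
    # an unnamed character vector is taken as protein ids (no coordinate
    # validation possible); named vectors / AAStringSets carry sequences
    ids <- x
    lens <- rep(NA_integer_, length(ids))
  } else {
    seqs <- .asSequences(x)
    ids <- names(seqs)
    lens <- nchar(seqs)
  }
  unknown <- setdiff(unique(hits$protein_id), ids)
  if (length(unknown))
    stop("hits reference unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  out <- do.call(rbind, lapply(seq_along(ids), function(i) {
    .classifyOne(ids[i], hits, lens[i])
  }))
  rownames(out) <- NULL
  out
}

#' Check the intron rule against a classification
#'
#' Type-I AHL genes lack introns while Type-II/-III genes generally contain
#' them. A classified record is \code{CONSISTENT} when its intron count obeys
#' that rule, \code{DISCORDANT} when it violates it, and \code{UNKNOWN} when
#' the count is missing or the record is not Type-I/-II/-III. The type itself
#' is never changed.
#'
#' @param classifications data.frame from [classifyProteins()].
#' @param intronCounts named integer vector (see [readIntronCounts()]);
#'   proteins absent from it stay \code{UNKNOWN}.
#' @return the classification data.frame with \code{intron_consistent}
#'   updated.
#' @export
checkIntronConsistency <- function(classifications, intronCounts) {
  if (any(intronCounts < 0, na.rm = TRUE))
    stop("negative intron count")
  cls <- classifications
  for (i in seq_len(nrow(cls))) {
    ty <- cls$ahl_type[i]
    if (!ty %in% c("TYPE_I", "TYPE_II", "TYPE_III")) next
    ic <- intronCounts[cls$protein_id[i]]
    if (length(ic) != 1L || is.na(ic)) next
    ok <- (ty == "TYPE_I" && ic == 0L) ||
          (ty %in% c("TYPE_II", "TYPE_III") && ic >= 1L)
    cls$intron_consistent[i] <- if (ok) "CONSISTENT" else "DISCORDANT"
  }
  cls
}

#' Per-species type counts and percentages
#'
#' One summary row per species: total records, counts of Types I/II/III, and
#' percentages of each type over the classified (typed) records. Species
#' whose records are all unclassified or PPC-only report zero counts and
#' blank (NA) percentages.
#'
#' @param classifications data.frame from [classifyProteins()].
#' @param speciesOf named character vector mapping every protein id to a
#'   species code (e.g. from [speciesFromIds()] or FASTA metadata).
#' @return data.frame: \code{species}, \code{n_total}, \code{n_type1},
#'   \code{n_type2}, \code{n_type3}, \code{pct_type1..3}.
#' @export
summarizeTypes <- function(classifications, speciesOf) {
  if (nrow(classifications) == 0L)
    return(data.frame(species = character(0), n_total = integer(0),
                      n_type1 = integer(0), n_type2 = integer(0),
                      n_type3 = integer(0), pct_type1 = numeric(0),
                      pct_type2 = numeric(0), pct_type3 = numeric(0),
                      stringsAsFactors = FALSE))
  unmapped <- setdiff(classifications$protein_id, names(speciesOf))
  if (length(unmapped))
    stop("protein(s) without a species mapping: ",
         paste(unmapped, collapse = ", "))
  sp <- speciesOf[classifications$protein_id]
  out <- do.call(rbind, lapply(sort(unique(sp)), function(s) {
    sub <- classifications[sp == s, , drop = FALSE]
    n1 <- sum(sub$ahl_type == "TYPE_I")
    n2 <- sum(sub$ahl_type == "TYPE_II")
    n3 <- sum(sub$ahl_type == "TYPE_III")
    den <- n1 + n2 + n3
    pct <- function(k) if (den > 0) 100 * k / den else NA_real_
    data.frame(species = s, n_total = nrow(sub),
               n_type1 = n1, n_type2 = n2, n_type3 = n3,
               pct_type1 = pct(n1), pct_type2 = pct(n2), pct_type3 = pct(n3),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
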