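# Signature scanning for AT-hook motifs and PPC (DUF296) domains.
#
# AT-hooks share an exact Arg-Gly-Arg core; the downstream context decides the
# type: Gly-Ser-Lys-Asn-Lys (<=1 mismatch) -> Type-I, Arg-Lys-Tyr (exact) ->
# Type-II. PPC domains anchor on the conserved Gly-Arg-Phe-Glu-Ile-Leu
# hexapeptide (<=1 mismatch); the tripeptide immediately upstream
# (Thr-Lys-His vs Thr-Tyr-Glu) and/or the domain-window prefix
# (Leu-Arg-Ser-His vs Phe-Thr-Pro-His) decide Type-A vs Type-B.

.SIG <- list(
  RGR    = c("R", "G", "R"),
  GSKNK  = c("G", "S", "K", "N", "K"),
  RKY    = c("R", "K", "Y"),
  GRFEIL = c("G", "R", "F", "E", "I", "L"),
  LRSH   = c("L", "R", "S", "H"),
  FTPH   = c("F", "T", "P", "H"),
  TKH    = c("T", "K", "H"),
  TYE    = c("T", "Y", "E")
)

.asSequences <- function(x) {
  if (is(x, "AAStringSet")) {
    seqs <- as.character(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    return(seqs)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("expected an AAStringSet or a named character vector of sequences")
}

.scanAtHooksOne <- function(chars, id, window) {
  n <- length(chars)
  cand <- .emptyHits()
  cores <- .sigMatches(chars, .SIG$RGR, 0L)
  for (i in cores) {
    # downstream search span: context start within `window` residues after
    # the core's last residue (1-based starts i+3 .. i+2+window)
    from <- i + 3L
    to <- i + 2L + window
    g <- .sigMatchesMM(chars, .SIG$GSKNK, 1L, from, to)
    if (nrow(g)) {
      g <- g[order(g$mm, g$start), , drop = FALSE]
      j <- g$start[1L]
      cand <- rbind(cand, data.frame(
        protein_id = id, motif_class = "AT_HOOK_I",
        start0 = i - 1L, end0 = j + 4L, anchor_pos = i - 1L,
        score = 3 + (5 - g$mm[1L]),
        matched = paste(chars[i:(j + 4L)], collapse = ""),
        stringsAsFactors = FALSE))
      next
    }
    r <- .sigMatches(chars, .SIG$RKY, 0L, from, to)
    if (length(r)) {
      j <- r[1L]
      cand <- rbind(cand, data.frame(
        protein_id = id, motif_class = "AT_HOOK_II",
        start0 = i - 1L, end0 = j + 2L, anchor_pos = i - 1L,
        score = 3 + 3,
        matched = paste(chars[i:(j + 2L)], collapse = ""),
        stringsAsFactors = FALSE))
    }
    # an RGR with neither context yields no hit
  }
  .resolveOverlaps(cand)
}

.scanPPCOne <- function(chars, id, span) {
  n <- length(chars)
  cand <- .emptyHits()
  anchors <- .sigMatchesMM(chars, .SIG$GRFEIL, 1L)
  for (k in seq_len(nrow(anchors))) {
    a <- anchors$start[k]              # 1-based anchor start
    start1 <- max(1L, a - span)
    end1 <- min(n, a + 5L + span)      # inclusive
    aFire <- FALSE
    bFire <- FALSE
    if (a >= 4L)
      aFire <- .mismatches(chars[(a - 3L):(a - 1L)], .SIG$TKH) <= 1L
    if (end1 - start1 + 1L >= 4L) {
      pre <- chars[start1:(start1 + 3L)]
      aFire <- aFire || .mismatches(pre, .SIG$LRSH) <= 1L
      bFire <- .mismatches(pre, .SIG$FTPH) <= 1L
    }
    if (a >= 4L)
      bFire <- bFire || .mismatches(chars[(a - 3L):(a - 1L)], .SIG$TYE) <= 1L
    cls <- if (aFire && !bFire) "PPC_A"
           else if (bFire && !aFire) "PPC_B"
           else "PPC_UNTYPED"          # both-or-neither: surfaced, not broken
    cand <- rbind(cand, data.frame(
      protein_id = id, motif_class = cls,
      start0 = start1 - 1L, end0 = end1, anchor_pos = a - 1L,
      score = 6 - anchors$mm[k],
      matched = paste(chars[start1:end1], collapse = ""),
      stringsAsFactors = FALSE))
  }
  .resolveOverlaps(cand)
}

#' Scan protein sequences for AT-hook motifs
#'
#' Locates exact Arg-Gly-Arg cores and types each by its downstream context:
#' \code{AT_HOOK_I} when Gly-Ser-Lys-Asn-Lys occurs (at most one mismatch)
#' with its first residue within \code{window} residues after the core's last
#' arginine; \code{AT_HOOK_II} when Arg-Lys-Tyr occurs exactly in that span
#' and the Type-I test fails. A core with neither context yields no hit.
#' Overlapping candidates are resolved by score, ties by leftmost start, so
#' returned hits never overlap. An X residue never matches a signature
#' position.
#'
#' @param x an [Biostrings::AAStringSet] or named character vector of
#'   amino-acid sequences (20-letter alphabet plus X).
#' @param window search span (residues) downstream of the core for the typing
#'   context; must be >= 5. Default 10.
#' @return data.frame of hits with columns \code{protein_id},
#'   \code{motif_class}, \code{start0}, \code{end0} (0-based half-open),
#'   \code{anchor_pos} (0-based start of the RGR core), \code{score},
#'   \code{matched}; sorted by \code{protein_id} input order then
#'   \code{start0}.
#' @examples
#' scanAtHooks(c(p1 = "MKKRPRGRPAGSKNKPKA"))
#' @export
scanAtHooks <- function(x, window = 10L) {
  stopifnot(length(window) == 1L, window >= 5L)
  seqs <- .asSequences(x)
  out <- lapply(names(seqs), function(id) {
    chars <- .validateSequence(seqs[[id]], id)
    .scanAtHooksOne(chars, id, as.integer(window))
  })
  do.call(rbind, c(list(.emptyHits()), out))
}

#' Scan protein sequences for PPC (DUF296) domains
#'
#' Anchors on the conserved Gly-Arg-Phe-Glu-Ile-Leu hexapeptide (at most one
#' mismatch) and reports a domain window extending \code{span} residues on
#' each side of the anchor (clipped to the sequence), approximately 120
#' residues at the default. Typing: \code{PPC_A} if the tripeptide
#' immediately upstream of the anchor matches Thr-Lys-His (<=1 mismatch) or
#' the window begins with Leu-Arg-Ser-His (<=1 mismatch); \code{PPC_B}
#' likewise via Thr-Tyr-Glu / Phe-Thr-Pro-His. If both or neither rule fires
#' the hit is \code{PPC_UNTYPED}: ambiguity is surfaced, never tie-broken.
#' Overlapping anchor windows are resolved by score then leftmost start.
#'
#' @inheritParams scanAtHooks
#' @param span domain window radius in residues around the anchor; >= 60.
#' @return data.frame of hits in the same shape as [scanAtHooks()];
#'   \code{anchor_pos} is the 0-based start of the hexapeptide anchor.
#' @export
scanPPC <- function(x, span = 60L) {
  stopifnot(length(span) == 1L, span >= 60L)
  seqs <- .asSequences(x)
  out <- lapply(names(seqs), function(id) {
    chars <- .validateSequence(seqs[[id]], id)
    .scanPPCOne(chars, id, as.integer(span))
  })
  do.call(rbind, c(list(.emptyHits()), out))
}

#' Scan for both AT-hook motifs and PPC domains
#'
#' Convenience wrapper combining [scanAtHooks()] and [scanPPC()].
#' @inheritParams scanAtHooks
#' @param span passed to [scanPPC()].
#' @return combined hits data.frame.
#' @export
scanMotifs <- function(x, window = 10L, span = 60L) {
  rbind(scanAtHooks(x, window), scanPPC(x, span))
}

#' Build a position-frequency conservation profile
#'
#' Computes per-column relative residue frequencies and a conservation score,
#' \code{log2(20)} minus the column's Shannon entropy in bits, from a set of
#' equal-length aligned motif instances (the sequence-logo computation).
#'
#' @param instances character vector of aligned motif strings, all the same
#'   length, over the 20-letter amino-acid alphabet.
#' @return a [MotifProfile-class] object.
#' @examples
#' conservation(buildProfile(c("RGR", "RGR", "RGR")))
#' @export
buildProfile <- function(instances) {
  if (length(instances) < 1L) stop("at least one instance required")
  lens <- nchar(instances)
  if (length(unique(lens)) != 1L)
    stop("ragged instance lengths: all instances must be equally long")
  mat <- do.call(rbind, strsplit(instances, "", fixed = TRUE))
  bad <- !mat %in% AA_ALPHABET20
  if (any(bad))
    stop("instances must use only the 20 standard residues")
  L <- ncol(mat)
  freqs <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = AA_ALPHABET20))
    as.numeric(tab) / nrow(mat)
  }, numeric(20))
  freqs <- matrix(freqs, nrow = 20L, dimnames = list(AA_ALPHABET20, NULL))
  cons <- apply(freqs, 2L, function(p) {
    p <- p[p > 0]
    log2(20) - sum(-p * log2(p))
  })
  new("MotifProfile", freqs = freqs, nSequences = length(instances),
      conservation = as.numeric(cons))
}

#' Log-odds score of a window against a profile
#'
#' Returns \code{sum_j log2(f'_j(w_j) / b(w_j))} where \code{f'} are the
#' profile's column frequencies regularized with an additive pseudocount
#' (\code{f' = (f + pc) / (1 + 20 pc)}) and \code{b} is a background
#' distribution over the 20 residues. Higher scores indicate a better match.
#'
#' @param window string of the same length as the profile has columns.
#' @param profile a [MotifProfile-class].
#' @param background named numeric vector of per-residue background
#'   frequencies summing to 1; default uniform 1/20.
#' @param pseudocount additive regularizer per residue; default 0.01.
#' @return scalar log-odds score in bits.
#' @export
scoreWindow <- function(window, profile,
                        background = stats::setNames(rep(1 / 20, 20),
                                                     AA_ALPHABET20),
                        pseudocount = 0.01) {
  stopifnot(is(profile, "MotifProfile"))
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (length(chars) != ncol(profile@freqs))
    stop("window length must equal the number of profile columns")
  if (!all(chars %in% AA_ALPHABET20))
    stop("window must use only the 20 standard residues")
  if (!all(AA_ALPHABET20 %in% names(background)) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must cover the 20 residues and sum to 1")
  f <- (profile@freqs + pseudocount) / (1 + 20 * pseudocount)
  sum(vapply(seq_along(chars), function(j) {
    log2(f[chars[j], j] / background[[chars[j]]])
  }, numeric(1)))
}

#' Write motif hits as TSV
#'
#' Writes the 0-based half-open coordinates plus 1-based inclusive columns
#' for human consumption, with a provenance header comment.
#'
#' @param hits data.frame from [scanAtHooks()]/[scanPPC()]/[scanMotifs()].
#' @param file output path.
#' @param config optional configuration list echoed into the header hash.
#' @return the file path, invisibly.
#' @export
writeHitsTsv <- function(hits, file, config = NULL) {
  out <- data.frame(protein_id = hits$protein_id,
                    motif_class = hits$motif_class,
                    start0 = hits$start0, end0 = hits$end0,
                    start1 = hits$start0 + 1L, end1 = hits$end0,
                    anchor_pos = hits$anchor_pos, score = hits$score,
                    matched = hits$matched, stringsAsFactors = FALSE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(.fileHeader(config), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a motif hits TSV written by [writeHitsTsv()]
#' @param file path to the TSV.
#' @return hits data.frame (0-based columns).
#' @export
readHitsTsv <- function(file) {
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  df[, c("protein_id", "motif_class", "start0", "end0", "anchor_pos",
         "score", "matched")]
}
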