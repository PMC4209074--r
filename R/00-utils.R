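# Internal helpers: alphabet validation, mismatch counting, logging.

# The 20 standard residues; X is tolerated in input sequences but never
# matches a signature position.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.validateSequence <- function(seq, id = "<sequence>") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("empty sequence for protein '", id, "'", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(AA_ALPHABET20, "X"))
  if (length(bad))
    stop("protein '", id, "': unknown character '", chars[bad[1L]],
         "' at position ", bad[1L], " (1-based)", call. = FALSE)
  chars
}

# Mismatch count between a sequence window and a signature, both as character
# vectors of equal length. X in the sequence never matches.
.mismatches <- function(window, signature) {
  sum(window != signature | window == "X")
}

# All start positions (1-based) where `sig` occurs in `chars` with at most
# `maxMismatch` mismatches, restricted to starts in [from, to].
.sigMatches <- function(chars, sig, maxMismatch = 0L,
                        from = 1L, to = length(chars)) {
  L <- length(sig)
  to <- min(to, length(chars) - L + 1L)
  if (from > to) return(integer(0))
  starts <- from:to
  mm <- vapply(starts, function(s) {
    .mismatches(chars[s:(s + L - 1L)], sig)
  }, integer(1))
  starts[mm <= maxMismatch]
}

# As above but also return mismatch counts.
.sigMatchesMM <- function(chars, sig, maxMismatch = 0L,
                          from = 1L, to = length(chars)) {
  L <- length(sig)
  to <- min(to, length(chars) - L + 1L)
  if (from > to) return(data.frame(start = integer(0), mm = integer(0)))
  starts <- from:to
  mm <- vapply(starts, function(s) {
    .mismatches(chars[s:(s + L - 1L)], sig)
  }, integer(1))
  keep <- mm <= maxMismatch
  data.frame(start = starts[keep], mm = mm[keep])
}

.LOG_LEVELS <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

.logMsg <- function(level, ..., logLevel = getOption("ahltools.logLevel", "INFO")) {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[logLevel]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

# Header comment written at the top of every output file: tool version and a
# hash of the effective configuration, for provenance.
.fileHeader <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("ahltools"))
  h <- "none"
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tf)
    h <- unname(tools::md5sum(tf))
  }
  sprintf("# ahltools %s config=%s", ver, h)
}

# Greedy non-overlap resolution: keep hits by decreasing score, ties broken
# by leftmost start, discarding any hit overlapping an already-kept one.
.resolveOverlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$score, hits$start0)
  kept <- logical(nrow(hits))
  for (i in ord) {
    ok <- TRUE
    for (j in which(kept)) {
      if (hits$start0[i] < hits$end0[j] && hits$start0[j] < hits$end0[i]) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  out <- hits[kept, , drop = FALSE]
  out[order(out$start0), , drop = FALSE]
}

.emptyHits <- function() {
  data.frame(protein_id = character(0), motif_class = character(0),
             start0 = integer(0), end0 = integer(0),
             anchor_pos = integer(0), score = numeric(0),
             matched = character(0), stringsAsFactors = FALSE)
}
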