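# Shared fixtures: tiny trees and constructed hit rows.

nwk <- function(text) ape::read.tree(text = text)

# a hit row in the shape scanMotifs() produces
hitRow <- function(id, class, start0, end0, anchor = start0, score = 1) {
  data.frame(protein_id = id, motif_class = class,
             start0 = start0, end0 = end0, anchor_pos = anchor,
             score = score, matched = "", stringsAsFactors = FALSE)
}

# the constructed PPC test sequence: prefix + 40 filler + tripeptide +
# GRFEIL + 77 filler (130 residues)
ppcSeq <- function(prefix, up) {
  paste0(prefix, strrep("A", 40), up, "GRFEIL", strrep("A", 77))
}

# (duplications, losses) from a Reconciliation
eventCounts <- function(rec) {
  c(sum(nodeEvents(rec) == "DUPLICATION"), nrow(lossTable(rec)))
}
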