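#' @import methods
NULL

#' Position-frequency conservation profile for aligned motif instances
#'
#' A \code{MotifProfile} stores per-column relative residue frequencies over
#' the 20-letter amino-acid alphabet together with a per-column conservation
#' score, defined as \code{log2(20)} minus the Shannon entropy of the column
#' (in bits). Conservation is therefore maximal (\code{log2(20)} ~ 4.32 bits)
#' for a single-residue column and 0 for a uniform column.
#'
#' @slot freqs numeric matrix, 20 rows (residues) by one column per aligned
#'   position; every column sums to 1.
#' @slot nSequences number of training instances.
#' @slot conservation numeric vector of per-column conservation in bits,
#'   each within \code{[0, log2(20)]}.
#'
#' @seealso [buildProfile()], [scoreWindow()]
#' @exportClass MotifProfile
setClass("MotifProfile",
         representation(freqs = "matrix",
                        nSequences = "integer",
                        conservation = "numeric"))

setValidity("MotifProfile", function(object) {
  msg <- character(0)
  if (nrow(object@freqs) != 20L ||
      !identical(rownames(object@freqs), AA_ALPHABET20))
    msg <- c(msg, "freqs must have the 20 standard residues as rows")
  cs <- colSums(object@freqs)
  if (length(cs) && any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "column frequencies must sum to 1 (tolerance 1e-9)")
  if (length(object@conservation) != ncol(object@freqs))
    msg <- c(msg, "conservation length must equal number of columns")
  if (any(object@conservation < -1e-9 |
          object@conservation > log2(20) + 1e-9))
    msg <- c(msg, "conservation must lie in [0, log2(20)]")
  if (object@nSequences < 1L)
    msg <- c(msg, "nSequences must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Duplication-loss parsimony reconciliation of a gene tree
#'
#' Produced by [annotateEvents()]. Holds the LCA mapping of every gene-tree
#' node into the species tree, a SPECIATION/DUPLICATION label for every
#' internal gene-tree node, and the list of losses, each attributed to the
#' species-tree node (sibling subtree) in which the gene lineage is absent.
#'
#' @slot geneTree,speciesTree \code{ape::phylo} trees (rooted).
#' @slot mapping integer vector over gene-tree node numbers giving the
#'   species-tree node each maps to.
#' @slot events named character vector over internal gene-tree nodes,
#'   \code{"SPECIATION"} or \code{"DUPLICATION"}.
#' @slot losses data.frame with one row per inferred loss: the gene-tree edge
#'   (\code{gene_parent}, \code{gene_child}) it is charged to and the species
#'   node (\code{species_node}, \code{species_label}) where the lineage is
#'   missing.
#'
#' @seealso [lcaMap()], [summarizeEvents()], [inferOrthologPairs()]
#' @exportClass Reconciliation
setClass("Reconciliation",
         representation(geneTree = "ANY",
                        speciesTree = "ANY",
                        mapping = "integer",
                        events = "character",
                        losses = "data.frame"))

setValidity("Reconciliation", function(object) {
  msg <- character(0)
  gt <- object@geneTree
  if (!inherits(gt, "phylo")) msg <- c(msg, "geneTree must be a phylo")
  if (!inherits(object@speciesTree, "phylo"))
    msg <- c(msg, "speciesTree must be a phylo")
  if (inherits(gt, "phylo") &&
      length(object@mapping) != ape::Ntip(gt) + gt$Nnode)
    msg <- c(msg, "mapping must cover every gene-tree node")
  if (!all(object@events %in% c("SPECIATION", "DUPLICATION")))
    msg <- c(msg, "events must be SPECIATION or DUPLICATION")
  if (length(msg)) msg else TRUE
})

#' Ground-truth event history from the gene-family simulator
#'
#' The simulator logs every duplication and loss event it generates —
#' including events whose descendants all go extinct and are therefore
#' invisible in the output gene tree. Per-species-node tallies are the
#' reference against which reconciliation output is checked.
#'
#' @slot events data.frame: \code{event} (DUPLICATION/LOSS),
#'   \code{species_node} (label of the species-tree node at the lower end of
#'   the branch on which the event occurred), \code{time} (position along the
#'   branch, within \code{[0, branch length]}), \code{lineage} (gene lineage
#'   id).
#' @slot counts data.frame: one row per species-tree node with
#'   \code{n_duplications} and \code{n_losses}; always equal to tallies over
#'   \code{events}.
#'
#' @seealso [simulateFamily()]
#' @exportClass TrueHistory
setClass("TrueHistory",
         representation(events = "data.frame",
                        counts = "data.frame"))

setValidity("TrueHistory", function(object) {
  ev <- object@events
  ct <- object@counts
  need <- c("event", "species_node", "time", "lineage")
  if (!all(need %in% names(ev)))
    return("events must have columns event, species_node, time, lineage")
  for (i in seq_len(nrow(ct))) {
    nd <- sum(ev$event == "DUPLICATION" & ev$species_node == ct$node[i])
    nl <- sum(ev$event == "LOSS" & ev$species_node == ct$node[i])
    if (nd != ct$n_duplications[i] || nl != ct$n_losses[i])
      return("per-node counts do not equal event-log tallies")
  }
  TRUE
})

#' @describeIn MotifProfile-class number of training instances
#' @param x a \code{MotifProfile}
#' @export
nSequences <- function(x) {
  stopifnot(is(x, "MotifProfile"))
  x@nSequences
}

#' @describeIn MotifProfile-class per-column relative frequency matrix
#' @export
profileFreqs <- function(x) {
  stopifnot(is(x, "MotifProfile"))
  x@freqs
}

#' @describeIn MotifProfile-class per-column conservation in bits
#' @export
conservation <- function(x) {
  stopifnot(is(x, "MotifProfile"))
  x@conservation
}

#' @describeIn Reconciliation-class node mapping into the species tree
#' @param x a \code{Reconciliation}
#' @export
nodeMapping <- function(x) {
  stopifnot(is(x, "Reconciliation"))
  x@mapping
}

#' @describeIn Reconciliation-class SPECIATION/DUPLICATION labels for internal
#'   gene-tree nodes
#' @export
nodeEvents <- function(x) {
  stopifnot(is(x, "Reconciliation"))
  x@events
}

#' @describeIn Reconciliation-class inferred losses with species attribution
#' @export
lossTable <- function(x) {
  stopifnot(is(x, "Reconciliation"))
  x@losses
}

#' @describeIn TrueHistory-class full event log
#' @param x a \code{TrueHistory}
#' @export
trueEvents <- function(x) {
  stopifnot(is(x, "TrueHistory"))
  x@events
}

#' @describeIn TrueHistory-class per-species-node true event counts
#' @export
trueCounts <- function(x) {
  stopifnot(is(x, "TrueHistory"))
  x@counts
}

setMethod("show", "MotifProfile", function(object) {
  cat(sprintf("MotifProfile: %d columns, %d instance(s)\n",
              ncol(object@freqs), object@nSequences))
  cat("conservation (bits):",
      paste(sprintf("%.3f", object@conservation), collapse = " "), "\n")
})

setMethod("show", "Reconciliation", function(object) {
  nd <- sum(object@events == "DUPLICATION")
  cat(sprintf("Reconciliation: %d gene leaves onto %d species\n",
              ape::Ntip(object@geneTree), ape::Ntip(object@speciesTree)))
  cat(sprintf("  duplications: %d   losses: %d\n", nd, nrow(object@losses)))
})

setMethod("show", "TrueHistory", function(object) {
  cat(sprintf("TrueHistory: %d duplication(s), %d loss(es)\n",
              sum(object@events$event == "DUPLICATION"),
              sum(object@events$event == "LOSS")))
})
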