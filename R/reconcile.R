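# Duplication-loss parsimony reconciliation via LCA mapping.
#
# Every gene-tree node is mapped to the lowest common ancestor, in the
# species tree, of the species its leaves belong to. An internal gene node is
# a DUPLICATION iff it maps to the same species node as one of its children,
# otherwise a SPECIATION. Losses are read off each gene-tree edge from the
# species path between the endpoint mappings: a speciation charges one loss
# per off-path child at every intermediate node below the parent's image; a
# duplication additionally charges the parent's own off-path children
# (d-1 vs d losses on a path of d edges in a binary species tree).

# ---- internal light-weight tree index ------------------------------------

.tindex <- function(tr) {
  nt <- length(tr$tip.label)
  ntot <- nt + tr$Nnode
  parent <- rep(NA_integer_, ntot)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  children <- vector("list", ntot)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]
    children[[p]] <- c(children[[p]], tr$edge[k, 2])
  }
  root <- nt + 1L
  depth <- rep(NA_integer_, ntot)
  depth[root] <- 0L
  # edges in ape's default (cladewise) order visit parents before children
  for (k in seq_len(nrow(tr$edge)))
    depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + 1L
  labels <- c(tr$tip.label,
              if (!is.null(tr$node.label) && length(tr$node.label))
                tr$node.label
              else paste0("node", (nt + 1L):ntot))
  labels[labels == "" | is.na(labels)] <-
    paste0("node", which(labels == "" | is.na(labels)))
  blen <- rep(NA_real_, ntot)
  if (!is.null(tr$edge.length)) blen[tr$edge[, 2]] <- tr$edge.length
  list(tree = tr, nTip = nt, ntot = ntot, parent = parent,
       children = children, root = root, depth = depth, labels = labels,
       blen = blen)
}

.lcaPair <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] >= idx$depth[b]) a <- idx$parent[a] else b <- idx$parent[b]
  }
  a
}

.isAncestorOrEqual <- function(idx, a, b) {
  # is a an ancestor of b, or equal to it?
  while (!is.na(b) && idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
  identical(a, b)
}

# child of `a` on the path down to `b` (a must be a proper ancestor of b)
.firstStep <- function(idx, a, b) {
  x <- b
  while (idx$parent[x] != a) x <- idx$parent[x]
  x
}

.postorderNodes <- function(idx) {
  ord <- integer(0)
  stack <- idx$root
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(nd, ord)
    stack <- c(stack, idx$children[[nd]])
  }
  ord
}

.checkGeneTree <- function(gt) {
  if (!inherits(gt, "phylo")) stop("gene tree must be an ape phylo object")
  if (!ape::is.rooted(gt))
    stop("gene tree is unrooted (trifurcating root); reconciliation ",
         "requires a rooted tree - reroot on a known outgroup leaf first ",
         "(see rerootOnOutgroup())")
  deg <- table(factor(gt$edge[, 1], levels = unique(gt$edge[, 1])))
  if (any(deg != 2L))
    stop("gene tree contains polytomies; resolve them before reconciling")
  invisible(gt)
}

.speciesAssignment <- function(gidx, sidx, species) {
  tips <- gidx$tree$tip.label
  if (is.null(species)) species <- speciesFromIds(tips, sidx$tree$tip.label)
  sp <- species[tips]
  missing <- tips[is.na(sp)]
  if (length(missing))
    stop("no species assignment for gene leaf: ",
         paste(missing, collapse = ", "))
  bad <- tips[!sp %in% sidx$tree$tip.label]
  if (length(bad))
    stop("gene leaf '", bad[1L],
         "' is assigned species '", sp[match(bad[1L], tips)],
         "' which is absent from the species tree")
  match(sp, sidx$tree$tip.label)
}

.lcaMapIdx <- function(gidx, sidx, tipSpeciesIdx) {
  M <- rep(NA_integer_, gidx$ntot)
  M[seq_len(gidx$nTip)] <- tipSpeciesIdx
  for (nd in .postorderNodes(gidx)) {
    kids <- gidx$children[[nd]]
    if (length(kids)) M[nd] <- Reduce(function(a, b) .lcaPair(sidx, a, b),
                                      M[kids])
  }
  M
}

# losses charged to edge (gParent -> gChild), given the event at gParent;
# returns integer vector of species nodes (one per loss)
.edgeLosses <- function(sidx, mParent, mChild, isDup) {
  if (mParent == mChild && !isDup) return(integer(0))
  # chain of species nodes from mParent (n0) down to mChild (nd)
  chain <- mChild
  x <- mChild
  while (x != mParent) {
    x <- sidx$parent[x]
    chain <- c(x, chain)
  }
  d <- length(chain) - 1L
  ks <- if (isDup) seq_len(d) else if (d >= 2L) 2:d else integer(0)
  out <- integer(0)
  for (k in ks) {           # chain[k] is n_{k-1}; next on path is chain[k+1]
    off <- setdiff(sidx$children[[chain[k]]], chain[k + 1L])
    out <- c(out, off)
  }
  out
}

# ---- exported operations --------------------------------------------------

#' LCA mapping of a gene tree into a species tree
#'
#' Maps every gene-tree node to a species-tree node: leaves to their species,
#' internal nodes (bottom-up) to the lowest common ancestor of their
#' children's images. Pure and deterministic; the first step of
#' duplication-loss parsimony reconciliation.
#'
#' @param geneTree rooted binary \code{phylo}; leaf labels are gene ids.
#' @param speciesTree rooted \code{phylo} with unique tip labels (species
#'   codes); polytomies are permitted.
#' @param species optional named character vector gene id -> species code.
#'   When omitted, species are derived from gene ids by longest-prefix match
#'   against the species-tree tip labels ([speciesFromIds()]).
#' @return integer vector over gene-tree node numbers (ape numbering: tips
#'   first) giving the species-tree node each maps to.
#' @export
lcaMap <- function(geneTree, speciesTree, species = NULL) {
  .checkGeneTree(geneTree)
  gidx <- .tindex(geneTree)
  sidx <- .tindex(speciesTree)
  .lcaMapIdx(gidx, sidx, .speciesAssignment(gidx, sidx, species))
}

#' Annotate duplication/speciation events and losses
#'
#' Given the LCA mapping, labels every internal gene-tree node DUPLICATION
#' (it maps to the same species node as one of its children) or SPECIATION,
#' and attributes losses along each gene-tree edge to the species-tree nodes
#' (sibling subtrees) in which the gene lineage is absent: on a species path
#' of d edges a speciation charges the d-1 intermediate nodes' off-path
#' children and a duplication charges d (including the parent's own image).
#'
#' @inheritParams lcaMap
#' @param mapping optional mapping from [lcaMap()]; recomputed when omitted.
#' @return a [Reconciliation-class] object.
#' @export
annotateEvents <- function(geneTree, speciesTree, mapping = NULL,
                           species = NULL) {
  .checkGeneTree(geneTree)
  gidx <- .tindex(geneTree)
  sidx <- .tindex(speciesTree)
  if (is.null(mapping))
    mapping <- .lcaMapIdx(gidx, sidx,
                          .speciesAssignment(gidx, sidx, species))
  if (length(mapping) != gidx$ntot)
    stop("mapping length does not match the gene tree")
  # consistency: every parent's image must be ancestor-or-equal of its
  # children's images
  for (k in seq_len(nrow(geneTree$edge))) {
    p <- geneTree$edge[k, 1]
    c_ <- geneTree$edge[k, 2]
    if (!.isAncestorOrEqual(sidx, mapping[p], mapping[c_]))
      stop("inconsistent mapping on gene-tree edge ", p, " -> ", c_)
  }
  internal <- (gidx$nTip + 1L):gidx$ntot
  events <- vapply(internal, function(g) {
    kids <- gidx$children[[g]]
    if (any(mapping[kids] == mapping[g])) "DUPLICATION" else "SPECIATION"
  }, character(1))
  names(events) <- as.character(internal)
  losses <- data.frame(gene_parent = integer(0), gene_child = integer(0),
                       species_node = integer(0),
                       species_label = character(0),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(geneTree$edge))) {
    p <- geneTree$edge[k, 1]
    c_ <- geneTree$edge[k, 2]
    ls <- .edgeLosses(sidx, mapping[p], mapping[c_],
                      events[[as.character(p)]] == "DUPLICATION")
    if (length(ls))
      losses <- rbind(losses, data.frame(
        gene_parent = p, gene_child = c_, species_node = ls,
        species_label = sidx$labels[ls], stringsAsFactors = FALSE))
  }
  new("Reconciliation", geneTree = geneTree, speciesTree = speciesTree,
      mapping = as.integer(mapping), events = events, losses = losses)
}

#' Per-species-node duplication and loss counts
#'
#' Bins each duplication at the species node its gene node maps to and each
#' loss at its attributed species node. Leaf rows are the extant-species
#' summary (a duplication is assigned to an extant species only when it maps
#' to that leaf); internal rows summarize ancestral lineages.
#'
#' @param reconciliation a [Reconciliation-class] (or a list of them, whose
#'   counts are accumulated).
#' @param cladeLabel optional label (e.g. \code{"A"}) recorded in the output.
#' @return data.frame with one row per species-tree node: \code{node},
#'   \code{label}, \code{is_leaf}, \code{clade}, \code{n_duplications},
#'   \code{n_losses}.
#' @export
summarizeEvents <- function(reconciliation, cladeLabel = NA_character_) {
  recs <- if (is(reconciliation, "Reconciliation")) list(reconciliation)
          else reconciliation
  stopifnot(length(recs) >= 1L)
  sidx <- .tindex(recs[[1L]]@speciesTree)
  ndup <- integer(sidx$ntot)
  nloss <- integer(sidx$ntot)
  for (rec in recs) {
    stopifnot(is(rec, "Reconciliation"))
    dupNodes <- as.integer(names(rec@events)[rec@events == "DUPLICATION"])
    for (g in dupNodes) ndup[rec@mapping[g]] <- ndup[rec@mapping[g]] + 1L
    for (s in rec@losses$species_node) nloss[s] <- nloss[s] + 1L
  }
  data.frame(node = seq_len(sidx$ntot), label = sidx$labels,
             is_leaf = seq_len(sidx$ntot) <= sidx$nTip,
             clade = cladeLabel, n_duplications = ndup, n_losses = nloss,
             stringsAsFactors = FALSE)
}

#' Ortholog/paralog calls for all gene pairs
#'
#' For every unordered pair of gene-tree leaves, the pair is ORTHOLOG when
#' the event at their gene-tree LCA is a speciation and PARALOG when it is a
#' duplication.
#'
#' @param reconciliation a [Reconciliation-class].
#' @return data.frame with n(n-1)/2 rows: \code{gene1}, \code{gene2},
#'   \code{relation}.
#' @export
inferOrthologPairs <- function(reconciliation) {
  stopifnot(is(reconciliation, "Reconciliation"))
  gidx <- .tindex(reconciliation@geneTree)
  tips <- seq_len(gidx$nTip)
  if (length(tips) < 2L)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  pairs <- utils::combn(tips, 2L)
  relation <- vapply(seq_len(ncol(pairs)), function(k) {
    anc <- .lcaPair(gidx, pairs[1L, k], pairs[2L, k])
    if (reconciliation@events[[as.character(anc)]] == "DUPLICATION")
      "PARALOG" else "ORTHOLOG"
  }, character(1))
  data.frame(gene1 = gidx$labels[pairs[1L, ]],
             gene2 = gidx$labels[pairs[2L, ]],
             relation = relation, stringsAsFactors = FALSE)
}

#' Brute-force minimum duplication-loss reconciliation (test oracle)
#'
#' Exhaustively enumerates every valid mapping of the gene tree into the
#' species tree (leaves fixed to their species; each internal node ranging
#' over the ancestors-or-equal of its LCA image, subject to parent/child
#' ancestry consistency) and returns the minimum duplication count and,
#' among mappings achieving it, the minimum loss count. Intended as an
#' independent oracle for small cases only.
#'
#' @inheritParams lcaMap
#' @return named numeric vector \code{c(duplications = , losses = )}.
#' @export
bruteForceMinReconciliation <- function(geneTree, speciesTree,
                                        species = NULL) {
  .checkGeneTree(geneTree)
  if (ape::Ntip(geneTree) > 8L)
    stop("brute-force oracle limited to gene trees with <= 8 leaves")
  if (ape::Ntip(speciesTree) > 5L)
    stop("brute-force oracle limited to species trees with <= 5 leaves")
  gidx <- .tindex(geneTree)
  sidx <- .tindex(speciesTree)
  M0 <- .lcaMapIdx(gidx, sidx, .speciesAssignment(gidx, sidx, species))
  ancSet <- function(s) {       # s and all its ancestors up to the root
    out <- s
    while (!is.na(sidx$parent[s])) {
      s <- sidx$parent[s]
      out <- c(out, s)
    }
    out
  }
  cand <- vector("list", gidx$ntot)
  for (nd in seq_len(gidx$ntot))
    cand[[nd]] <- if (nd <= gidx$nTip) M0[nd] else ancSet(M0[nd])
  # internal nodes in postorder so children are assigned before parents
  internal <- .postorderNodes(gidx)
  internal <- internal[internal > gidx$nTip]
  nchild <- lengths(sidx$children)
  cost <- function(M) {
    dups <- 0L
    losses <- 0L
    for (g in internal) {
      kids <- gidx$children[[g]]
      isDup <- any(M[kids] == M[g])
      if (!isDup) {
        # a node whose children both descend through the same child of its
        # image must also be a duplication
        steps <- vapply(kids, function(c_) .firstStep(sidx, M[g], M[c_]),
                        integer(1))
        isDup <- anyDuplicated(steps) > 0L
      }
      if (isDup) dups <- dups + 1L
      for (c_ in kids) {
        d <- sidx$depth[M[c_]] - sidx$depth[M[g]]
        if (d == 0L) next
        # one loss per off-path child at each counted path node
        x <- M[c_]
        chain <- x
        while (x != M[g]) {
          x <- sidx$parent[x]
          chain <- c(x, chain)
        }
        ks <- if (isDup) seq_len(d) else if (d >= 2L) 2:d else integer(0)
        for (k in ks)
          losses <- losses + nchild[chain[k]] - 1L
      }
    }
    c(dups, losses)
  }
  best <- c(Inf, Inf)
  M <- M0
  recurse2 <- function(i) {
    if (i > length(internal)) {
      cc <- cost(M)
      if (cc[1] < best[1] || (cc[1] == best[1] && cc[2] < best[2]))
        best <<- cc
      return(invisible(NULL))
    }
    g <- internal[i]
    kids <- gidx$children[[g]]
    for (s in cand[[g]]) {
      if (all(vapply(kids, function(c_) .isAncestorOrEqual(sidx, s, M[c_]),
                     logical(1)))) {
        M[g] <<- s
        recurse2(i + 1L)
      }
    }
    invisible(NULL)
  }
  recurse2(1L)
  c(duplications = best[1], losses = best[2])
}

#' Reroot a gene tree on a named outgroup leaf
#'
#' Reconciliation results depend on the root; no automatic (e.g. midpoint)
#' rooting is ever performed. This helper reroots explicitly on a declared
#' outgroup.
#'
#' @param tree a \code{phylo}.
#' @param outgroup a tip label.
#' @return rooted \code{phylo}.
#' @export
rerootOnOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Read rooted gene trees from a Newick file
#'
#' Branch lengths and support values are tolerated (and preserved on the
#' returned \code{phylo} objects) but not used. Trees must be rooted and
#' binary; a trifurcating root is rejected with rooting guidance.
#'
#' @param file Newick path (one or more trees).
#' @return list of \code{phylo} objects.
#' @export
readGeneTrees <- function(file) {
  trs <- ape::read.tree(file)
  if (inherits(trs, "phylo")) trs <- list(trs)
  lapply(trs, .checkGeneTree)
}

#' Enumerate all rooted binary tree topologies over given leaf labels
#'
#' Recursive leaf insertion: every rooted binary topology on n labeled leaves
#' is produced exactly once ((2n-3)!! trees). Used to drive exhaustive
#' oracle-equivalence checks of the reconciliation.
#'
#' @param labels character vector of leaf labels (2 to 7).
#' @return character vector of Newick strings.
#' @export
enumerateRootedTrees <- function(labels) {
  stopifnot(length(labels) >= 2L, length(labels) <= 7L)
  insertLeaf <- function(tree, leaf) {
    res <- list(.gnode(tree, leaf))
    if (!is.null(tree$kids)) {
      for (i in 1:2) {
        for (sub in insertLeaf(tree$kids[[i]], leaf)) {
          copy <- tree
          copy$kids[[i]] <- sub
          res <- c(res, list(copy))
        }
      }
    }
    res
  }
  trees <- list(.gleaf(labels[[1L]]))
  for (lab in labels[-1L]) {
    trees <- unlist(lapply(trees, insertLeaf, leaf = .gleaf(lab)),
                    recursive = FALSE)
  }
  vapply(trees, function(t) paste0(.toNewick(t), ";"), character(1))
}
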