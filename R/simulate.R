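# Birth-death gene-family simulation on a species tree, with protein
# sequences realizing the AHL motif grammar and a logged true event history.

#' Simulation configuration
#'
#' Collects all tunables of the gene-family simulator. Defaults emulate the
#' scale of sequenced land-plant AHL family sizes: duplication rate 0.05 and
#' loss rate 0.02 per unit branch length on the 19-taxon species tree yield
#' families in the tens of genes.
#'
#' @param duplication_rate birth rate lambda, events per unit branch length.
#' @param loss_rate death rate mu.
#' @param root_copies number of ancestral gene copies at the species root;
#'   these pre-divergence copies are not counted as duplication events.
#' @param seed integer seed; all simulator randomness derives from it.
#' @param type_assignment \code{"ALL_TYPE_I"}, \code{"ALL_TYPE_II"} or
#'   \code{"MIXED"} (root copies drawn uniformly from Type-I/Type-II).
#' @param type2_to_type3_prob per-gene-lineage probability that a Type-II
#'   gene has lost its Type-I AT-hook and become Type-III.
#' @param residue_mutation_rate per-position substitution probability applied
#'   to motif signature residues of emitted sequences.
#' @param scaffold_length length of the N-terminal scaffold leader.
#' @return validated configuration list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(duplication_rate = 0.05, loss_rate = 0.02,
                             root_copies = 1L, seed = 1L,
                             type_assignment = c("MIXED", "ALL_TYPE_I",
                                                 "ALL_TYPE_II"),
                             type2_to_type3_prob = 0.25,
                             residue_mutation_rate = 0,
                             scaffold_length = 25L) {
  type_assignment <- match.arg(type_assignment)
  stopifnot(is.finite(duplication_rate), duplication_rate >= 0,
            is.finite(loss_rate), loss_rate >= 0,
            root_copies >= 1L,
            type2_to_type3_prob >= 0, type2_to_type3_prob <= 1,
            residue_mutation_rate >= 0, residue_mutation_rate <= 1,
            scaffold_length >= 1L)
  structure(list(duplication_rate = duplication_rate, loss_rate = loss_rate,
                 root_copies = as.integer(root_copies),
                 seed = as.integer(seed), type_assignment = type_assignment,
                 type2_to_type3_prob = type2_to_type3_prob,
                 residue_mutation_rate = residue_mutation_rate,
                 scaffold_length = as.integer(scaffold_length)),
            class = "SimulationConfig")
}

#' The 19-taxon land-plant species tree
#'
#' The fixed rooted species tree over the 19 sequenced land-plant genomes
#' used throughout the package, with the moss \emph{Physcomitrella patens}
#' (Pp) as outgroup to all other taxa. Internal nodes carry the standard
#' lineage labels (Em Embryophyta, T Tracheophyta, A Angiosperms, G Grasses,
#' Eu Eudicots, F Fabidae/Eurosids I, NF nitrogen-fixing clade, Mp
#' Malpighiales, Mv Malvidae/Eurosids II, B Brassicaceae) plus descriptive
#' labels for the remaining clades. All branch lengths are 1.
#'
#' @return rooted, binary \code{phylo} with 19 tips and named internal nodes.
#' @export
landPlantSpeciesTree <- function() {
  nk <- paste0(
    "(Pp,(Sm,(((Bd,Os)BEP,(Sb,Zm)PAC)G,",
    "(Vv,((((Mes,Rc)Eup,Pt)Mp,((Mt,Gm)Leg,((Ppa,Mdp)Ros,Cs)CR)NF)F,",
    "(((At,Al)Ath,Bra)B,Cpa)Mv)Ro)Eu)A)T)Em;")
  tr <- ape::read.tree(text = nk)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# nested gene-tree node constructors (internal)
.gleaf <- function(name) list(leaf = name)
.gnode <- function(a, b) list(kids = list(a, b))

.toNewick <- function(x) {
  if (!is.null(x$leaf)) return(x$leaf)
  paste0("(", paste(vapply(x$kids, .toNewick, character(1)),
                    collapse = ","), ")")
}

.countLeaves <- function(x) {
  if (!is.null(x$leaf)) return(1L)
  sum(vapply(x$kids, .countLeaves, integer(1)))
}

#' Simulate a gene family on a species tree
#'
#' Starting from \code{root_copies} gene lineages at the species-tree root,
#' every lineage evolves down each species branch under a continuous-time
#' birth-death process (duplication rate lambda, loss rate mu per unit branch
#' length); at every species-tree internal node each surviving lineage
#' speciates into all child branches. The returned gene tree contains only
#' lineages with surviving descendants; speciation nodes with a single
#' surviving child branch are suppressed. The [TrueHistory-class] log records
#' every event, including those invisible in the output tree. Deterministic
#' given \code{config$seed}.
#'
#' @param speciesTree rooted binary \code{phylo} with positive branch
#'   lengths (e.g. [landPlantSpeciesTree()]).
#' @param config a [simulationConfig()].
#' @return list with \code{tree} (rooted binary \code{phylo}, or \code{NULL}
#'   when fewer than two genes survive), \code{leaves} (data.frame:
#'   \code{gene_id}, \code{species}, \code{root_copy}) and \code{history}
#'   (a [TrueHistory-class]).
#' @export
simulateFamily <- function(speciesTree, config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  sidx <- .tindex(speciesTree)
  if (any(lengths(sidx$children)[(sidx$nTip + 1L):sidx$ntot] != 2L))
    stop("the simulator requires a binary species tree")
  bl <- sidx$blen[-sidx$root]
  if (any(is.na(bl)) || any(bl <= 0))
    stop("species tree must have positive branch lengths")
  set.seed(config$seed)
  lam <- config$duplication_rate
  mu <- config$loss_rate
  rate <- lam + mu
  lineageCounter <- 0L
  spCount <- integer(sidx$nTip)
  events <- list()
  leaves <- list()
  newLineage <- function() {
    lineageCounter <<- lineageCounter + 1L
    lineageCounter
  }
  logEvent <- function(type, snode, time, lin) {
    events[[length(events) + 1L]] <<- data.frame(
      event = type, species_node = sidx$labels[snode], time = time,
      lineage = lin, stringsAsFactors = FALSE)
  }
  atNode <- function(snode, rootCopy) {
    if (snode <= sidx$nTip) {
      spCount[snode] <<- spCount[snode] + 1L
      id <- paste0(sidx$labels[snode], spCount[snode])
      leaves[[length(leaves) + 1L]] <<- data.frame(
        gene_id = id, species = sidx$labels[snode], root_copy = rootCopy,
        stringsAsFactors = FALSE)
      return(.gleaf(id))
    }
    surv <- list()
    for (k in sidx$children[[snode]]) {
      st <- descendBranch(k, 0, newLineage(), rootCopy)
      if (!is.null(st)) surv[[length(surv) + 1L]] <- st
    }
    if (length(surv) == 0L) return(NULL)
    if (length(surv) == 1L) return(surv[[1L]])  # unifurcation suppressed
    .gnode(surv[[1L]], surv[[2L]])
  }
  descendBranch <- function(snode, t0, lin, rootCopy) {
    L <- sidx$blen[snode]
    dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (t0 + dt < L) {
      if (stats::runif(1L) < lam / rate) {
        logEvent("DUPLICATION", snode, t0 + dt, lin)
        a <- descendBranch(snode, t0 + dt, lin, rootCopy)
        b <- descendBranch(snode, t0 + dt, newLineage(), rootCopy)
        if (!is.null(a) && !is.null(b)) return(.gnode(a, b))
        if (!is.null(a)) return(a)
        return(b)
      }
      logEvent("LOSS", snode, t0 + dt, lin)
      return(NULL)
    }
    atNode(snode, rootCopy)
  }
  copies <- list()
  for (rc in seq_len(config$root_copies)) {
    st <- atNode(sidx$root, rc)
    if (!is.null(st)) copies[[length(copies) + 1L]] <- st
  }
  # pre-divergence root copies are joined at the gene root but not logged as
  # duplication events
  geneRoot <- if (length(copies) == 0L) NULL
              else Reduce(.gnode, copies)
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(event = character(0), species_node = character(0),
                        time = numeric(0), lineage = integer(0),
                        stringsAsFactors = FALSE)
  counts <- data.frame(
    node = sidx$labels,
    n_duplications = vapply(sidx$labels, function(l)
      sum(ev$event == "DUPLICATION" & ev$species_node == l), integer(1)),
    n_losses = vapply(sidx$labels, function(l)
      sum(ev$event == "LOSS" & ev$species_node == l), integer(1)),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  leavesDf <- if (length(leaves)) do.call(rbind, leaves)
              else data.frame(gene_id = character(0), species = character(0),
                              root_copy = integer(0), stringsAsFactors = FALSE)
  tree <- NULL
  if (!is.null(geneRoot) && .countLeaves(geneRoot) >= 2L)
    tree <- ape::read.tree(text = paste0(.toNewick(geneRoot), ";"))
  list(tree = tree, leaves = leavesDf,
       history = new("TrueHistory", events = ev, counts = counts))
}

# ---- sequence emission -----------------------------------------------------

# scaffold/filler alphabet: the 20 standard residues minus R, G and K, so
# that no AT-hook core (RGR), downstream context (GSKNK/RKY at their mismatch
# budgets) or PPC anchor (GRFEIL at <=1 mismatch) can arise outside a
# cassette, including across cassette/scaffold junctions
.SAFE_ALPHABET <- setdiff(AA_ALPHABET20, c("R", "G", "K"))

.rndFill <- function(n) sample(.SAFE_ALPHABET, n, replace = TRUE)

# a cassette is a list of segments, each a character vector plus a flag
# saying whether its residues are signature positions (mutable under the
# residue mutation model)
.seg <- function(s, sig) list(chars = strsplit(s, "")[[1L]], sig = sig)
.fillSeg <- function(n) list(chars = .rndFill(n), sig = FALSE)

.cassetteAT1 <- function() list(.seg("RGR", TRUE), .seg("PA", FALSE),
                                .seg("GSKNK", TRUE))
.cassetteAT2 <- function() list(.seg("RGR", TRUE), .seg("PK", FALSE),
                                .seg("RKY", TRUE))
.cassettePPC <- function(type) {
  pre <- if (type == "A") "LRSH" else "FTPH"
  up <- if (type == "A") "TKH" else "TYE"
  list(.seg(pre, TRUE), .fillSeg(53L), .seg(up, TRUE), .seg("GRFEIL", TRUE),
       .fillSeg(57L))
}

.assembleSequence <- function(trueType, config) {
  lead <- list(.fillSeg(config$scaffold_length))
  segs <- switch(trueType,
    TYPE_I = c(lead, .cassetteAT1(), list(.fillSeg(15L)),
               .cassettePPC("A"), list(.fillSeg(20L))),
    TYPE_II = c(lead, .cassetteAT2(), list(.fillSeg(6L)), .cassetteAT1(),
                list(.fillSeg(15L)), .cassettePPC("B"),
                list(.fillSeg(20L))),
    TYPE_III = c(lead, .cassetteAT2(), list(.fillSeg(15L)),
                 .cassettePPC("B"), list(.fillSeg(20L))),
    stop("unknown type ", trueType))
  chars <- unlist(lapply(segs, `[[`, "chars"))
  sig <- unlist(lapply(segs, function(s) rep(s$sig, length(s$chars))))
  m <- config$residue_mutation_rate
  if (m > 0) {
    hit <- which(sig & stats::runif(length(chars)) < m)
    for (i in hit) chars[i] <- sample(setdiff(AA_ALPHABET20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Assign true AHL types and emit protein sequences for a simulated family
#'
#' Each gene inherits a type from its root copy (\code{ALL_TYPE_I},
#' \code{ALL_TYPE_II}, or \code{MIXED}: drawn uniformly from Type-I/Type-II
#' per root copy); every Type-II gene lineage independently converts to
#' Type-III with probability \code{type2_to_type3_prob}, emulating the
#' secondary loss of the Type-I AT-hook. Sequences carry the type-appropriate
#' motif cassettes in N-to-C order (Type-II AT-hook, Type-I AT-hook, PPC
#' domain; subsets per type) on a scaffold that cannot produce spurious
#' signature matches; signature residues are then substituted independently
#' at \code{residue_mutation_rate}. Intron counts are 0 for Type-I and drawn
#' uniformly from 1..4 for Type-II/-III. Deterministic given
#' \code{config$seed}.
#'
#' @param family result of [simulateFamily()] (or any data.frame shaped like
#'   its \code{leaves} element).
#' @param config the same [simulationConfig()].
#' @return list with \code{proteins} (an \code{AAStringSet} named by gene id,
#'   species in \code{mcols}) and \code{truth} (data.frame: \code{gene_id},
#'   \code{species}, \code{true_type}, \code{intron_count}).
#' @export
emitProteins <- function(family, config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  leaves <- if (is.data.frame(family)) family else family$leaves
  stopifnot(all(c("gene_id", "species", "root_copy") %in% names(leaves)))
  # separate stream from the tree simulation, still a pure function of seed
  set.seed((config$seed %% 2000000000L) + 104729L)
  copyIds <- sort(unique(leaves$root_copy))
  copyType <- switch(config$type_assignment,
    ALL_TYPE_I = stats::setNames(rep("TYPE_I", length(copyIds)), copyIds),
    ALL_TYPE_II = stats::setNames(rep("TYPE_II", length(copyIds)), copyIds),
    MIXED = stats::setNames(sample(c("TYPE_I", "TYPE_II"), length(copyIds),
                                   replace = TRUE), copyIds))
  n <- nrow(leaves)
  trueType <- character(n)
  intron <- integer(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    ty <- copyType[[as.character(leaves$root_copy[i])]]
    if (ty == "TYPE_II" &&
        stats::runif(1L) < config$type2_to_type3_prob)
      ty <- "TYPE_III"
    trueType[i] <- ty
    intron[i] <- if (ty == "TYPE_I") 0L else sample(1:4, 1L)
    seqs[i] <- .assembleSequence(ty, config)
  }
  proteins <- Biostrings::AAStringSet(stats::setNames(seqs, leaves$gene_id))
  S4Vectors::mcols(proteins)$species <- leaves$species
  truth <- data.frame(gene_id = leaves$gene_id, species = leaves$species,
                      true_type = trueType, intron_count = intron,
                      stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth)
}
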