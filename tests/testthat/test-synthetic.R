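# Birth-death gene-family simulation and motif-grammar sequence emission.

test_that("the land-plant species tree has the published structure", {
  st <- landPlantSpeciesTree()
  expect_equal(ape::Ntip(st), 19L)
  expect_true(ape::is.rooted(st))
  # the moss is the outgroup to all other 18 taxa
  expect_true(ape::is.monophyletic(st, setdiff(st$tip.label, "Pp")))
  # Tracheophyta contains the lycophyte and all angiosperms but not the moss
  idx <- ahltools:::.tindex(st)
  tnode <- which(idx$labels == "T")
  desc <- st$tip.label[vapply(seq_len(idx$nTip), function(tp)
    ahltools:::.isAncestorOrEqual(idx, tnode, tp), logical(1))]
  expect_setequal(desc, setdiff(st$tip.label, "Pp"))
  expect_true(all(c("Sm", "At", "Os", "Zm") %in% desc))
  expect_equal(st$edge.length, rep(1, nrow(st$edge)))
})

test_that("a rate-free simulation returns a congruent tree and empty log", {
  st <- landPlantSpeciesTree()
  fam <- simulateFamily(st, simulationConfig(duplication_rate = 0,
                                             loss_rate = 0, seed = 3))
  expect_equal(ape::Ntip(fam$tree), 19L)
  expect_equal(nrow(trueEvents(fam$history)), 0L)
  expect_equal(sort(speciesFromIds(fam$tree$tip.label, st$tip.label)),
               sort(stats::setNames(fam$leaves$species, fam$leaves$gene_id)))
  # congruent family reconciles with zero events
  rec <- annotateEvents(fam$tree, st)
  expect_equal(eventCounts(rec), c(0, 0))
  # two root copies give a root join of two congruent copies, still no
  # logged events (ancestral copies are not duplications)
  fam2 <- simulateFamily(st, simulationConfig(duplication_rate = 0,
                                              loss_rate = 0, root_copies = 2,
                                              seed = 3))
  expect_equal(ape::Ntip(fam2$tree), 38L)
  expect_equal(nrow(trueEvents(fam2$history)), 0L)
})

test_that("simulation is deterministic given the seed", {
  st <- landPlantSpeciesTree()
  cfg <- simulationConfig(duplication_rate = 0.08, loss_rate = 0.03,
                          seed = 99)
  a <- simulateFamily(st, cfg)
  b <- simulateFamily(st, cfg)
  expect_equal(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_equal(trueEvents(a$history), trueEvents(b$history))
  expect_equal(a$leaves, b$leaves)
  ea <- emitProteins(a, cfg)
  eb <- emitProteins(b, cfg)
  expect_equal(as.character(ea$proteins), as.character(eb$proteins))
  expect_equal(ea$truth, eb$truth)
})

test_that("true event counts always equal event-log tallies", {
  st <- landPlantSpeciesTree()
  for (seed in 1:5) {
    fam <- simulateFamily(st, simulationConfig(duplication_rate = 0.1,
                                               loss_rate = 0.05,
                                               seed = 500 + seed))
    ev <- trueEvents(fam$history)
    ct <- trueCounts(fam$history)
    for (i in seq_len(nrow(ct))) {
      expect_equal(ct$n_duplications[i],
                   sum(ev$event == "DUPLICATION" &
                       ev$species_node == ct$node[i]))
      expect_equal(ct$n_losses[i],
                   sum(ev$event == "LOSS" & ev$species_node == ct$node[i]))
    }
    expect_true(all(ev$time >= 0 & ev$time <= 1))  # unit branches
  }
})

test_that("pure-birth lineage counts match the closed-form expectation", {
  # a lineage on a branch of length 5 at lambda = 0.2 leaves e^{1} surviving
  # copies in expectation; checked by Monte Carlo within 3 standard errors
  st <- nwk("(A:5,B:5);")
  nrep <- 2000
  counts <- vapply(seq_len(nrep), function(i) {
    fam <- simulateFamily(st, simulationConfig(duplication_rate = 0.2,
                                               loss_rate = 0,
                                               seed = 10000 + i))
    sum(fam$leaves$species == "A")
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - exp(1)), 3 * se)
})

test_that("zero-noise emission round-trips through scan and classify", {
  st <- landPlantSpeciesTree()
  cfg <- simulationConfig(duplication_rate = 0.05, loss_rate = 0, seed = 21)
  fam <- simulateFamily(st, cfg)
  em <- emitProteins(fam, cfg)
  hits <- scanMotifs(em$proteins)
  cls <- classifyProteins(em$proteins, hits)
  got <- cls$ahl_type[match(em$truth$gene_id, cls$protein_id)]
  expect_equal(got, em$truth$true_type)
  # the intron rule holds by construction and is marked consistent
  ic <- stats::setNames(em$truth$intron_count, em$truth$gene_id)
  expect_true(all(ic[em$truth$true_type == "TYPE_I"] == 0))
  expect_true(all(ic[em$truth$true_type != "TYPE_I"] >= 1))
  cls2 <- checkIntronConsistency(cls, ic)
  expect_true(all(cls2$intron_consistent == "CONSISTENT"))
})

test_that("type assignment knobs force the expected compositions", {
  st <- landPlantSpeciesTree()
  cfg1 <- simulationConfig(duplication_rate = 0, loss_rate = 0, seed = 5,
                           type_assignment = "ALL_TYPE_I")
  fam <- simulateFamily(st, cfg1)
  expect_true(all(emitProteins(fam, cfg1)$truth$true_type == "TYPE_I"))
  # forced Type-II -> Type-III conversion
  cfg2 <- simulationConfig(duplication_rate = 0, loss_rate = 0, seed = 5,
                           type_assignment = "ALL_TYPE_II",
                           type2_to_type3_prob = 1)
  expect_true(all(emitProteins(fam, cfg2)$truth$true_type == "TYPE_III"))
  cfg3 <- simulationConfig(duplication_rate = 0, loss_rate = 0, seed = 5,
                           type_assignment = "ALL_TYPE_II",
                           type2_to_type3_prob = 0)
  expect_true(all(emitProteins(fam, cfg3)$truth$true_type == "TYPE_II"))
})

test_that("zero-noise Type-I sequences carry exactly the expected cassettes", {
  st <- landPlantSpeciesTree()
  cfg <- simulationConfig(duplication_rate = 0, loss_rate = 0, seed = 8,
                          type_assignment = "ALL_TYPE_I")
  em <- emitProteins(simulateFamily(st, cfg), cfg)
  s <- as.character(em$proteins[[1]])
  expect_equal(lengths(regmatches(s, gregexpr("RGRPAGSKNK", s))), 1L)
  expect_equal(lengths(regmatches(s, gregexpr("GRFEIL", s))), 1L)
  expect_equal(lengths(regmatches(s, gregexpr("TKHGRFEIL", s))), 1L)
  h <- scanMotifs(stats::setNames(s, "g"))
  expect_setequal(h$motif_class, c("AT_HOOK_I", "PPC_A"))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulationConfig(duplication_rate = -1))
  expect_error(simulationConfig(type2_to_type3_prob = 2))
  expect_error(simulationConfig(root_copies = 0))
  expect_error(simulationConfig(type_assignment = "WHATEVER"))
  expect_error(simulateFamily(nwk("(A,B);") , simulationConfig()),
               "positive branch lengths")
  # polytomous species trees are rejected by the simulator
  expect_error(simulateFamily(ape::compute.brlen(nwk("(A,B,C);"), 1),
                              simulationConfig()), "binary")
})
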