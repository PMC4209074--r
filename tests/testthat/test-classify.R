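# Domain-composition classification, intron rule, per-species summaries.

test_that("the decision table maps compositions to the three types", {
  hits <- rbind(
    # Type-I: one Type-I AT-hook N-terminal to a Type-A PPC
    hitRow("t1", "AT_HOOK_I", 10, 20),
    hitRow("t1", "PPC_A", 0, 160, anchor = 60),
    # Type-II: Type-II hook, then Type-I hook, then Type-B PPC
    hitRow("t2", "AT_HOOK_II", 5, 13),
    hitRow("t2", "AT_HOOK_I", 30, 40),
    hitRow("t2", "PPC_B", 20, 200, anchor = 80),
    # Type-III: Type-II hook only + Type-B PPC
    hitRow("t3", "AT_HOOK_II", 5, 13),
    hitRow("t3", "PPC_B", 0, 180, anchor = 60),
    # PPC domain with no AT-hook anywhere
    hitRow("t4", "PPC_A", 12, 170, anchor = 70))
  cls <- classifyProteins(c("t1", "t2", "t3", "t4", "t5"), hits)
  expect_equal(cls$ahl_type,
               c("TYPE_I", "TYPE_II", "TYPE_III", "PPC_ONLY",
                 "UNCLASSIFIED"))
  expect_equal(cls$clade, c("A", "B", "B", "NONE", "NONE"))
})

test_that("mixed-clade, untyped and misordered evidence is unclassified", {
  hits <- rbind(
    hitRow("m1", "AT_HOOK_I", 5, 15),               # I hook + B domain
    hitRow("m1", "PPC_B", 0, 160, anchor = 60),
    hitRow("m2", "AT_HOOK_II", 5, 13),              # II hook + A domain
    hitRow("m2", "PPC_A", 0, 160, anchor = 60),
    hitRow("m3", "AT_HOOK_I", 5, 15),               # untyped PPC + hooks
    hitRow("m3", "PPC_UNTYPED", 0, 160, anchor = 60),
    hitRow("m4", "AT_HOOK_I", 100, 110),            # hook C-terminal to PPC
    hitRow("m4", "PPC_A", 0, 96, anchor = 36),
    hitRow("m5", "AT_HOOK_I", 5, 15),               # both hook types + A
    hitRow("m5", "AT_HOOK_II", 20, 28),
    hitRow("m5", "PPC_A", 30, 190, anchor = 90),
    hitRow("m6", "AT_HOOK_I", 5, 15))               # hooks but no PPC
  cls <- classifyProteins(paste0("m", 1:6), hits)
  expect_true(all(cls$ahl_type == "UNCLASSIFIED"))
  expect_true(all(cls$clade == "NONE"))
})

test_that("multiple PPC hits use the best-scoring one and are flagged", {
  hits <- rbind(
    hitRow("p", "AT_HOOK_I", 5, 15),
    hitRow("p", "PPC_B", 20, 100, anchor = 60, score = 5),
    hitRow("p", "PPC_A", 120, 260, anchor = 180, score = 6))
  cls <- classifyProteins("p", hits)
  expect_equal(cls$ahl_type, "TYPE_I")   # the score-6 PPC_A wins
  expect_true(cls$multi_ppc)
})

test_that("every randomly generated hit set maps to exactly one verdict", {
  classes <- c("AT_HOOK_I", "AT_HOOK_II", "PPC_A", "PPC_B", "PPC_UNTYPED")
  verdicts <- c("TYPE_I", "TYPE_II", "TYPE_III", "PPC_ONLY", "UNCLASSIFIED")
  cladeOf <- c(TYPE_I = "A", TYPE_II = "B", TYPE_III = "B",
               PPC_ONLY = "NONE", UNCLASSIFIED = "NONE")
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(0:5, 1)
    hits <- if (n == 0) hitRow("x", "AT_HOOK_I", 1, 2)[0, ] else
      do.call(rbind, lapply(seq_len(n), function(i) {
        s <- sample(0:200, 1)
        hitRow("x", sample(classes, 1), s, s + sample(5:120, 1),
               anchor = s + sample(0:4, 1), score = stats::runif(1))
      }))
    cls <- classifyProteins("x", hits)
    expect_equal(nrow(cls), 1L)
    expect_true(cls$ahl_type %in% verdicts)
    expect_equal(cls$clade, unname(cladeOf[cls$ahl_type]))
  }
})

test_that("hit coordinates outside the sequence are an error", {
  hits <- hitRow("s", "AT_HOOK_I", 5, 500)
  expect_error(classifyProteins(c(s = strrep("A", 50)), hits),
               "outside the sequence")
  expect_error(classifyProteins(c("a"), hitRow("zz", "PPC_A", 0, 10)),
               "unknown protein")
})

test_that("the intron rule marks consistency without changing the type", {
  cls <- classifyProteins(c("a", "b", "c", "d"), rbind(
    hitRow("a", "AT_HOOK_I", 5, 15), hitRow("a", "PPC_A", 20, 140, 80),
    hitRow("b", "AT_HOOK_II", 5, 13), hitRow("b", "AT_HOOK_I", 20, 30),
    hitRow("b", "PPC_B", 40, 160, 100),
    hitRow("c", "AT_HOOK_II", 5, 13), hitRow("c", "PPC_B", 20, 140, 80)))
  out <- checkIntronConsistency(cls, c(a = 0L, b = 0L))
  expect_equal(out$intron_consistent,
               c("CONSISTENT",   # TYPE_I with 0 introns
                 "DISCORDANT",   # TYPE_II with 0 introns
                 "UNKNOWN",      # TYPE_III, count absent
                 "UNKNOWN"))     # unclassified record
  expect_equal(out$ahl_type, cls$ahl_type)
  out2 <- checkIntronConsistency(cls, c(c = 3L))
  expect_equal(out2$intron_consistent[3], "CONSISTENT")
  expect_error(checkIntronConsistency(cls, c(a = -1L)), "negative")
})

test_that("per-species summaries count types and percentages", {
  cls <- data.frame(
    protein_id = c("x1", "x2", "x3", "x4", "y1"),
    ahl_type = c("TYPE_I", "TYPE_I", "TYPE_II", "TYPE_III", "PPC_ONLY"),
    stringsAsFactors = FALSE)
  sp <- c(x1 = "Xs", x2 = "Xs", x3 = "Xs", x4 = "Xs", y1 = "Ys")
  s <- summarizeTypes(cls, sp)
  xs <- s[s$species == "Xs", ]
  expect_equal(xs$n_total, 4L)
  expect_equal(c(xs$pct_type1, xs$pct_type2, xs$pct_type3), c(50, 25, 25))
  expect_equal(xs$pct_type1 + xs$pct_type2 + xs$pct_type3, 100,
               tolerance = 0.1)
  # species with only PPC-only records: zero counts, blank percentages
  ys <- s[s$species == "Ys", ]
  expect_equal(ys$n_total, 1L)
  expect_equal(ys$n_type1 + ys$n_type2 + ys$n_type3, 0L)
  expect_true(is.na(ys$pct_type1))
  # empty input -> empty summary
  expect_equal(nrow(summarizeTypes(cls[0, ], sp)), 0L)
  expect_error(summarizeTypes(cls, sp[-1]), "without a species")
})

test_that("intron counts load from TSV and from GFF3 (CDS per mRNA - 1)", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tintron_count", "g1\t0", "g2\t3"), tsv)
  ic <- readIntronCounts(tsv)
  expect_equal(ic, c(g1 = 0L, g2 = 3L))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t2000\t.\t+\t.\tID=geneA",
    "chr1\tsrc\tmRNA\t1\t2000\t.\t+\t.\tID=mA;Parent=geneA",
    "chr1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=cA1;Parent=mA",
    "chr1\tsrc\tCDS\t500\t800\t.\t+\t0\tID=cA2;Parent=mA",
    "chr1\tsrc\tCDS\t900\t1200\t.\t+\t0\tID=cA3;Parent=mA",
    "chr1\tsrc\tgene\t3000\t4000\t.\t+\t.\tID=geneB",
    "chr1\tsrc\tmRNA\t3000\t4000\t.\t+\t.\tID=mB;Parent=geneB",
    "chr1\tsrc\tCDS\t3000\t4000\t.\t+\t0\tID=cB1;Parent=mB"), gff)
  ic2 <- readIntronCounts(gff)
  expect_equal(ic2[["mA"]], 2L)   # 3 CDS segments -> 2 introns
  expect_equal(ic2[["mB"]], 0L)   # single-exon CDS -> intron-less
})
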