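# Similarity-based clade assignment, database mining, chimeric assembly.

clade_db <- function(seed = 19) {
  lib <- buildElementLibrary(nClades = 6, familiesPerClade = 1,
                             cladeDivergence = 0.3, familyDivergence = 0.05,
                             panelRefsPerClade = 5, seed = seed)
  labs <- panelLabels(elementPanel(lib))
  list(lib = lib, db = panelSeqs(elementPanel(lib)),
       clades = stats::setNames(labs$clade, labs$id))
}

test_that("the five-best-hit rule assigns clean queries and rejects mixes", {
  fx <- clade_db()
  info <- elementInfo(fx$lib)
  gy <- info[info$superfamily == "Gypsy", ][1, ]
  set.seed(80)
  q <- LTRcensus:::.mutate_aa(
    as.character(fx$lib@rtAA[[match(gy$family_id, info$family_id)]]), 0.05)
  res <- assignBySimilarity(q, fx$db, fx$clades,
                            cladeAssignParams(gapMode = "log10"))
  expect_equal(res$clade, gy$clade_id)
  expect_equal(unique(res$top_hits$clade), gy$clade_id)
  # equally good references from two clades interleave the top five
  a <- as.character(fx$lib@rtAA[[match(gy$family_id, info$family_id)]])
  dbMix <- Biostrings::AAStringSet(stats::setNames(rep(a, 6),
                                                   paste0("r", 1:6)))
  clMix <- stats::setNames(rep(c("cladeX", "cladeY"), 3), paste0("r", 1:6))
  resMix <- assignBySimilarity(a, dbMix, clMix,
                               cladeAssignParams(gapMode = "log10"))
  expect_equal(resMix$clade, "unassigned")
  expect_equal(resMix$reason, "mixed_top_hits")
  # top five agree but the best other-clade hit is nearly as strong:
  # the E-value gap clause rejects in either mode
  n <- nchar(a)
  xref <- substr(a, 1, n - 2)     # loses two terminal residues of score
  yref <- substr(a, 1, n - 4)     # loses four: close behind every X ref
  dbGap <- Biostrings::AAStringSet(stats::setNames(c(rep(xref, 5), yref),
                                                   paste0("s", 1:6)))
  clGap <- stats::setNames(c(rep("cladeX", 5), "cladeY"), paste0("s", 1:6))
  for (mode in c("arithmetic", "log10")) {
    resGap <- assignBySimilarity(a, dbGap, clGap,
                                 cladeAssignParams(gapMode = mode))
    expect_equal(resGap$clade, "unassigned")
    expect_equal(resGap$reason, "insufficient_evalue_gap")
  }
})

test_that("the arithmetic E-value gap reads the rule exactly as printed", {
  fx <- clade_db()
  info <- elementInfo(fx$lib)
  gy <- info[info$superfamily == "Gypsy", ][1, ]
  set.seed(81)
  q <- LTRcensus:::.mutate_aa(
    as.character(fx$lib@rtAA[[match(gy$family_id, info$family_id)]]), 0.05)
  # strong homology everywhere: both E-values underflow toward zero, their
  # difference cannot exceed 1e-10, so the printed rule rejects
  resA <- assignBySimilarity(q, fx$db, fx$clades,
                             cladeAssignParams(gapMode = "arithmetic"))
  expect_equal(resA$clade, "unassigned")
  expect_equal(resA$reason, "insufficient_evalue_gap")
  # with no other clade in the database, clause (ii) passes vacuously
  own <- names(fx$clades)[fx$clades == gy$clade_id]
  resV <- assignBySimilarity(q, fx$db[own], fx$clades[own],
                             cladeAssignParams(gapMode = "arithmetic"))
  expect_equal(resV$clade, gy$clade_id)
  expect_equal(resV$reason, "assigned_vacuous_gap")
})

test_that("mining applies the strict and relaxed Copia thresholds", {
  lib <- buildElementLibrary(nClades = 3, familiesPerClade = 1, seed = 20)
  info <- elementInfo(lib)
  gypsy <- info$family_id[info$superfamily == "Gypsy"]
  copia <- info$family_id[info$superfamily == "Copia"]
  queries <- lib@rtAA[c(gypsy, copia)]
  qsf <- stats::setNames(info$superfamily[match(names(queries),
                                                info$family_id)],
                         names(queries))
  tx <- simulateTranscripts(lib, families = gypsy, perFamily = 1,
                            subRate = 0.02, seed = 82)
  res <- mineDatabase(queries, qsf, tx)
  expect_gte(nrow(res$candidates), 1)
  expect_true(all(res$candidates$superfamily == "Gypsy"))
  expect_gte(nrow(res$families), 1)
  # a 60%-coverage Copia homolog: excluded by the strict thresholds,
  # admitted by the relaxed ones
  cq <- as.character(lib@rtAA[[match(copia[1], info$family_id)]])
  fragment <- substr(cq, 1, floor(0.6 * nchar(cq)))
  set.seed(83)
  subject <- Biostrings::DNAStringSet(c(
    frag_tx = paste0(rand_dna(90), LTRcensus:::.backtranslate(fragment),
                     rand_dna(90))))
  strict <- mineDatabase(queries[copia[1]], qsf[copia[1]], subject,
                         relaxedForCopia = FALSE)
  relaxed <- mineDatabase(queries[copia[1]], qsf[copia[1]], subject,
                          relaxedForCopia = TRUE)
  expect_equal(nrow(strict$candidates), 0)
  expect_equal(nrow(relaxed$candidates), 1)
  # empty collection
  none <- mineDatabase(queries, qsf, Biostrings::DNAStringSet())
  expect_equal(nrow(none$candidates), 0)
})

test_that("chimeric assembly reconstructs a split domain exactly", {
  set.seed(84)
  full <- paste(sample(names(LTRcensus:::.AA_BG), 300, TRUE), collapse = "")
  two <- c(f1 = substr(full, 1, 170), f2 = substr(full, 141, 300))
  expect_identical(buildChimericElement(two), full)
  three <- c(a = substr(full, 1, 120), b = substr(full, 95, 220),
             c = substr(full, 190, 300))
  expect_identical(buildChimericElement(three), full)
  # fragments that do not overlap are an error
  apart <- c(p = substr(full, 1, 100), q = substr(full, 200, 300))
  expect_error(buildChimericElement(apart), "overlap")
})
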