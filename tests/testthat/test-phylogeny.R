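# Phylogeny: domain extraction, progressive alignment, distances, NJ,
# bootstrap, clade definition.

exact_panel <- function(aaVec) {
  ids <- names(aaVec)
  new("ReferencePanel",
      seqs = stats::setNames(Biostrings::AAStringSet(unname(aaVec)), ids),
      labels = S4Vectors::DataFrame(id = ids,
                                    superfamily = rep("Gypsy", length(ids)),
                                    clade = rep("cladeZ", length(ids))))
}

test_that("domain extraction returns the exact planted translation", {
  lib <- buildElementLibrary(nClades = 1, familiesPerClade = 1, seed = 17)
  rt <- as.character(lib@rtAA[[1]])
  panel <- exact_panel(c(ref1 = rt))
  blue <- paste0(as.character(lib@ltrSeqs[[1]]),
                 as.character(lib@internalSeqs[[1]]),
                 as.character(lib@ltrSeqs[[1]]))
  dom <- extractDomain(blue, panel)
  expect_equal(dom$aa, rt)
  expect_gt(dom$frame, 0)
  # minus-strand element: same domain from a negative frame
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(blue)))
  domRC <- extractDomain(rc, panel)
  expect_equal(domRC$aa, rt)
  expect_lt(domRC$frame, 0)
  # no hit -> NULL
  expect_null(extractDomain(rand_dna(2000, seed = 75), panel))
})

test_that("a mid-domain frameshift is spliced into one chimeric protein", {
  lib <- buildElementLibrary(nClades = 1, familiesPerClade = 1, seed = 18)
  rt <- as.character(lib@rtAA[[1]])
  panel <- exact_panel(c(ref1 = rt))
  info <- elementInfo(lib)
  internal <- as.character(lib@internalSeqs[[1]])
  shiftAt <- info$rt_start[1] + 450L
  shifted <- paste0(substr(internal, 1, shiftAt), "A",
                    substr(internal, shiftAt + 1L, nchar(internal)))
  dom <- extractDomain(shifted, panel)
  expect_false(is.null(dom))
  expect_gte(dom$n_segments, 2L)
  # the chimeric protein is the blueprint translation minus a few residues
  # around the shift point
  expect_gte(nchar(dom$aa), nchar(rt) - 5L)
  expect_true(startsWith(rt, substr(dom$aa, 1, 80)))
  expect_true(endsWith(rt, substr(dom$aa, nchar(dom$aa) - 79, nchar(dom$aa))))
})

test_that("progressive alignment handles identities and single indels", {
  s <- paste(sample(names(LTRcensus:::.AA_BG), 120, TRUE), collapse = "")
  msa1 <- alignDomains(c(a = s, b = s, c = s))
  expect_true(all(nchar(as.character(msa1)) == 120))
  expect_false(any(grepl("-", as.character(msa1), fixed = TRUE)))
  # one sequence with a single internal deletion: exactly one gap column
  del <- paste0(substr(s, 1, 59), substr(s, 61, 120))
  msa2 <- alignDomains(c(a = s, b = s, d = del))
  ch <- as.character(msa2)
  expect_true(all(nchar(ch) == 120))
  expect_equal(sum(strsplit(ch[["d"]], "")[[1]] == "-"), 1L)
  expect_false(any(grepl("-", ch[c("a", "b")], fixed = TRUE)))
  # width is never below the longest input
  expect_gte(unique(nchar(ch)), 120)
  expect_error(alignDomains(c(a = s, b = s)), "at least 3")
})

test_that("distances honour pairwise deletion and the gamma correction", {
  m <- c(a = strrep("A", 100), b = paste0(strrep("A", 90), strrep("C", 10)))
  D <- distanceMatrix(Biostrings::AAStringSet(m),
                      phyloParams(model = "p_distance"))
  expect_equal(D["a", "b"], 0.10)
  expect_equal(diag(D), c(a = 0, b = 0))
  # gamma correction at shape 1: d = p/(1-p)
  Dg <- distanceMatrix(Biostrings::AAStringSet(m), phyloParams())
  expect_equal(Dg["a", "b"], 0.1 / 0.9, tolerance = 1e-9)
  # pairwise vs complete deletion on a constructed 3-row case
  three <- Biostrings::AAStringSet(c(
    x = "AAAAAAAAAA", y = "AAAAACCCCC", z = "AAAAA-----"))
  Dp <- distanceMatrix(three, phyloParams(model = "p_distance",
                                          deletion = "pairwise"))
  Dc <- distanceMatrix(three, phyloParams(model = "p_distance",
                                          deletion = "complete"))
  expect_equal(Dp["x", "y"], 0.5)   # all ten columns shared
  expect_equal(Dc["x", "y"], 0.0)   # z's gaps drop the differing columns
  # a pair with no shared columns is an error naming the pair
  bad <- Biostrings::AAStringSet(c(p = "AA---", q = "---CC", r = "AACCC"))
  expect_error(distanceMatrix(bad, phyloParams()), "p.*q")
})

test_that("NJ recovers additive trees exactly, with the 3-taxon closed form", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(tr)
  my <- neighborJoining(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(my))), 0)
  expect_equal(max(abs(ape::cophenetic.phylo(my)[rownames(D), colnames(D)] -
                         D)), 0, tolerance = 1e-9)
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighborJoining(D3)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))
  # stability under tiny perturbation
  set.seed(76)
  tr2 <- ape::rtree(8, br = function(n) runif(n, 0.2, 1.5))
  D2 <- ape::cophenetic.phylo(tr2)
  eps <- matrix(runif(64, 0, 1e-7), 8); eps <- (eps + t(eps)) / 2
  diag(eps) <- 0
  expect_equal(as.numeric(ape::dist.topo(
    ape::unroot(neighborJoining(D2)),
    ape::unroot(neighborJoining(D2 + eps)))), 0)
  expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("bootstrap saturates on clean signal and is seed-deterministic", {
  set.seed(77)
  alphabet <- names(LTRcensus:::.AA_BG)
  base <- paste(sample(alphabet, 120, TRUE), collapse = "")
  # four groups radiating from one ancestor: many diagnostic columns per
  # group, but distances far from saturation
  anc <- vapply(1:4, function(i) LTRcensus:::.mutate_aa(base, 0.25),
                character(1))
  seqs <- c(g1a = anc[1], g1b = anc[1], g2a = anc[2], g2b = anc[2],
            g3a = anc[3], g3b = anc[3], g4a = anc[4], g4b = anc[4])
  seqs[c(2, 4, 6, 8)] <- vapply(seqs[c(2, 4, 6, 8)], function(s)
    LTRcensus:::.mutate_aa(s, 0.03), character(1))
  msa <- alignDomains(Biostrings::AAStringSet(seqs))
  tree <- bootstrapSupport(msa, phyloParams(bootstrapReps = 50, seed = 9))
  # each two-leaf group's edge carries many diagnostic columns: support 100;
  # the backbone resolution of the star radiation is free to be weak
  sup <- suppressWarnings(as.numeric(tree$node.label))
  pp <- ape::prop.part(tree)
  isPair <- vapply(seq_along(pp), function(i) {
    ids <- tree$tip.label[pp[[i]]]
    length(ids) == 2 && length(unique(substr(ids, 1, 2))) == 1
  }, logical(1))
  expect_true(all(sup[isPair] == 100))
  tree2 <- bootstrapSupport(msa, phyloParams(bootstrapReps = 50, seed = 9))
  expect_identical(tree$node.label, tree2$node.label)
  # degenerate alignment of identical sequences: resolved by the tie-break
  # rule, deterministically under a fixed seed
  same <- Biostrings::AAStringSet(stats::setNames(rep(substr(base, 1, 60), 4),
                                                  paste0("t", 1:4)))
  td1 <- bootstrapSupport(same, phyloParams(bootstrapReps = 20, seed = 3))
  td2 <- bootstrapSupport(same, phyloParams(bootstrapReps = 20, seed = 3))
  expect_identical(ape::write.tree(td1), ape::write.tree(td2))
})

test_that("clade calls demand support above 70 and two species", {
  nwk <- "((fA_1:1,fB_1:1)x:1,(fC_1:1,fD_1:1)y:1,fE_1:1);"
  tree <- ape::read.tree(text = nwk)
  spMap <- c(fA_1 = "spA", fB_1 = "spB", fC_1 = "spC", fD_1 = "spC",
             fE_1 = "spA")
  tree$node.label <- c(NA, "85", "95")
  calls <- defineClades(tree, spMap, phyloParams())
  byFam <- stats::setNames(calls$clade, calls$family_id)
  expect_equal(unname(byFam[c("fA_1", "fB_1")]), rep("clade_1", 2))
  # fC/fD: support 95 but a single species -> not a clade
  expect_equal(unname(byFam[["fC_1"]]), "other")
  expect_equal(unname(byFam[["fE_1"]]), "other")
  # support 66 is rejected unless the manual override names the group
  tree$node.label <- c(NA, "66", "95")
  calls66 <- defineClades(tree, spMap, phyloParams())
  expect_false(any(calls66$clade[calls66$family_id %in%
                                   c("fA_1", "fB_1")] != "other"))
  callsOv <- defineClades(tree, spMap, phyloParams(),
                          overrides = list(c("fA_1", "fB_1")))
  byFamOv <- stats::setNames(callsOv$clade, callsOv$family_id)
  expect_true(all(byFamOv[c("fA_1", "fB_1")] != "other"))
})
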