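# The synthetic generator: element libraries, mutation model, planting.

test_that("zero divergence gives identical RT/RNaseH translations", {
  lib <- buildElementLibrary(nClades = 1, familiesPerClade = 2,
                             cladeDivergence = 0, familyDivergence = 0,
                             seed = 3)
  aa <- as.character(lib@rtAA)
  expect_identical(aa[[1]], aa[[2]])
})

test_that("libraries are byte-identical under a fixed seed", {
  a <- buildElementLibrary(nClades = 3, familiesPerClade = 2, seed = 11)
  b <- buildElementLibrary(nClades = 3, familiesPerClade = 2, seed = 11)
  expect_identical(as.character(a@ltrSeqs), as.character(b@ltrSeqs))
  expect_identical(as.character(a@internalSeqs), as.character(b@internalSeqs))
  expect_identical(as.character(panelSeqs(a)), as.character(panelSeqs(b)))
  c <- buildElementLibrary(nClades = 3, familiesPerClade = 2, seed = 12)
  expect_false(identical(as.character(a@ltrSeqs), as.character(c@ltrSeqs)))
})

test_that("within-clade RT identity exceeds between-clade identity", {
  lib <- buildElementLibrary(nClades = 3, familiesPerClade = 2,
                             cladeDivergence = 0.3, familyDivergence = 0.05,
                             seed = 1)
  aa <- as.character(lib@rtAA)
  clade <- elementInfo(lib)$clade_id
  # exhaustive pairwise identity; sequences are unaligned-equal-length by
  # construction, so column-wise comparison is the exact oracle
  idmat <- function(x, y) {
    mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  }
  within <- c(); between <- c()
  for (i in 1:(length(aa) - 1)) for (j in (i + 1):length(aa)) {
    v <- idmat(aa[[i]], aa[[j]])
    if (clade[i] == clade[j]) within <- c(within, v)
    else between <- c(between, v)
  }
  expect_gt(mean(within), mean(between))
})

test_that("element geometry always satisfies the detection distance window", {
  lib <- buildElementLibrary(nClades = 6, familiesPerClade = 3, seed = 5)
  d <- elementInfo(lib)$ltr_len + elementInfo(lib)$internal_len
  expect_true(all(d >= 2500 & d <= 11000))
  expect_true(all(elementInfo(lib)$ltr_len >= 80 &
                    elementInfo(lib)$ltr_len <= 1500))
  # Copia integrase upstream, others downstream
  info <- elementInfo(lib)
  expect_true(all(info$integrase_position[info$superfamily == "Copia"] ==
                    "upstream_of_RT"))
  expect_true(all(info$integrase_position[info$superfamily != "Copia"] ==
                    "downstream_of_RNaseH"))
})

test_that("mutateSequence records exactly the edits it applies", {
  x <- rand_dna(2000, seed = 2)
  expect_identical(as.character(mutateSequence(x, 0, 0, seed = 1)), x)
  y <- mutateSequence(x, 0.1, 0, seed = 3)
  ed <- attr(y, "edits")
  hamming <- sum(strsplit(x, "")[[1]] != strsplit(as.character(y), "")[[1]])
  expect_equal(sum(ed$type == "sub"), hamming)
  expect_identical(as.character(mutateSequence(x, 0.1, 0.01, seed = 9)),
                   as.character(mutateSequence(x, 0.1, 0.01, seed = 9)))
})

test_that("unmutated plants are exact blueprint substrings with exact truth", {
  fx <- small_planted()
  pg <- fx$pg; lib <- fx$lib
  tr <- truthSet(pg)
  expect_true(all(tr$state == "full"))
  genome <- genomeSeq(pg)
  info <- elementInfo(lib)
  for (i in seq_along(tr)) {
    ctg <- as.character(GenomicRanges::seqnames(tr))[i]
    seq <- substr(as.character(genome[[ctg]]),
                  GenomicRanges::start(tr)[i], GenomicRanges::end(tr)[i])
    k <- match(tr$family_id[i], info$family_id)
    blue <- paste0(as.character(lib@ltrSeqs[[k]]),
                   as.character(lib@internalSeqs[[k]]),
                   as.character(lib@ltrSeqs[[k]]))
    if (as.character(GenomicRanges::strand(tr))[i] == "-")
      blue <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(blue)))
    expect_identical(seq, blue)
  }
  # conservation: contig lengths equal the requested length exactly
  expect_true(all(Biostrings::width(genome) == pg@plantSpec$contigLength))
})

test_that("substitution load matches the binomial expectation", {
  lib <- buildElementLibrary(nClades = 1, familiesPerClade = 1, seed = 4)
  pg <- plantCopies(lib, plantSpec(nContigs = 5, contigLength = 800000,
                                   copiesPerFamily = 50, subRate = 0.05,
                                   revcompProb = 0, seed = 13))
  tr <- truthSet(pg)
  genome <- genomeSeq(pg)
  blue <- paste0(as.character(lib@ltrSeqs[[1]]),
                 as.character(lib@internalSeqs[[1]]),
                 as.character(lib@ltrSeqs[[1]]))
  bl <- strsplit(blue, "")[[1]]
  ids <- vapply(seq_along(tr), function(i) {
    ctg <- as.character(GenomicRanges::seqnames(tr))[i]
    s <- substr(as.character(genome[[ctg]]),
                GenomicRanges::start(tr)[i], GenomicRanges::end(tr)[i])
    mean(strsplit(s, "")[[1]] == bl)
  }, numeric(1))
  # 99% binomial interval around 95% identity for the mean of 50 copies
  n <- length(tr) * nchar(blue)
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_gt(mean(ids), 0.95 - half)
  expect_lt(mean(ids), 0.95 + half)
})

test_that("forced solo-LTR state reduces every copy to one LTR", {
  lib <- buildElementLibrary(nClades = 1, familiesPerClade = 2, seed = 6)
  pg <- plantCopies(lib, plantSpec(nContigs = 1, contigLength = 100000,
                                   copiesPerFamily = 3, soloLtrProb = 1,
                                   seed = 21))
  tr <- truthSet(pg)
  expect_true(all(tr$state == "solo_ltr"))
  lens <- elementInfo(lib)$ltr_len[match(tr$family_id,
                                         elementInfo(lib)$family_id)]
  expect_equal(GenomicRanges::width(tr), lens)
})

test_that("planting is deterministic and truth round-trips through TSV", {
  lib <- buildElementLibrary(nClades = 2, familiesPerClade = 1, seed = 6)
  sp <- plantSpec(nContigs = 1, contigLength = 120000, copiesPerFamily = 2,
                  subRate = 0.03, indelRate = 0.001, seed = 31)
  a <- plantCopies(lib, sp); b <- plantCopies(lib, sp)
  expect_identical(as.character(genomeSeq(a)), as.character(genomeSeq(b)))
  expect_identical(as.data.frame(truthSet(a)), as.data.frame(truthSet(b)))
  tf <- tempfile(fileext = ".tsv")
  writeTruthTSV(truthSet(a), tf)
  rt <- readTruthTSV(tf)
  expect_equal(GenomicRanges::start(rt), GenomicRanges::start(truthSet(a)))
  expect_equal(rt$family_id, truthSet(a)$family_id)
})
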