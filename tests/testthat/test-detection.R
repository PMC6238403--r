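# Structural detection: seeding, chaining, parameter window, overlap rules.

test_that("seed matching is exhaustive within the distance window", {
  set.seed(1)
  S <- rand_dna(200)
  contig <- paste0(rand_dna(500), S, rand_dna(2800), S, rand_dna(500))
  # spacing between the two copies of S is 200 + 2800 = 3000
  k <- 20L
  m <- findSeedMatches(contig, k = k, distMin = 2500, distMax = 11000)
  # every k-mer of S pairs its two occurrences at spacing 3000 exactly once
  want <- cbind(pos1 = 501:(501 + 200 - k), pos2 = 3501:(3501 + 200 - k))
  got <- paste(m[, 1], m[, 2])
  expect_true(all(paste(want[, 1], want[, 2]) %in% got))
  expect_false(any(duplicated(got)))
  # and every reported pair is a genuine exact repeat
  expect_true(all(vapply(seq_len(nrow(m)), function(i)
    substr(contig, m[i, 1], m[i, 1] + k - 1) ==
      substr(contig, m[i, 2], m[i, 2] + k - 1), logical(1))))
  # a spacing below the window yields nothing
  contig2 <- paste0(rand_dna(300), S, rand_dna(1800), S, rand_dna(300))
  m2 <- findSeedMatches(contig2, k = k, distMin = 2500, distMax = 11000)
  expect_equal(nrow(m2), 0)
  # no repeated k-mer at all
  expect_equal(nrow(findSeedMatches(rand_dna(3000, seed = 8), k = 20,
                                    distMin = 100, distMax = 2000)), 0)
})

test_that("a constructed element is called with exact LTR coordinates", {
  set.seed(33)
  ltr <- paste0("AC", rand_dna(296), "GT")
  internal <- paste0("TT", rand_dna(2996), "AA")
  # flanks chosen so the maximal repeat cannot extend by chance:
  # before LTR5 is G, before LTR3 is the internal's trailing A;
  # after LTR5 is the internal's leading T, after LTR3 is C
  left <- paste0(rand_dna(4000), "G")
  right <- paste0("C", rand_dna(4000))
  contig <- paste0(left, ltr, internal, ltr, right)
  s5 <- nchar(left) + 1L
  seeds <- findSeedMatches(contig)
  gr <- extendAndCall(contig, seeds, contigName = "c1")
  expect_equal(length(gr), 1L)
  expect_equal(gr$ltr5_start, s5)
  expect_equal(gr$ltr5_end, s5 + 299L)
  expect_equal(gr$ltr3_start, s5 + 300L + 3000L)
  expect_equal(gr$ltr3_end, s5 + 300L + 3000L + 299L)
  expect_equal(gr$ltr_identity, 100)
  expect_equal(GenomicRanges::start(gr), s5)
})

test_that("candidates violating the parameter window are rejected", {
  set.seed(34)
  internal <- rand_dna(3000)
  # 75% LTR identity: below the 80 percent rule
  ltr <- rand_dna(300)
  ltr2 <- substitute_bases(ltr, 75, seed = 35)
  contig <- paste0(rand_dna(2000), ltr, internal, ltr2, rand_dna(2000))
  gr <- extendAndCall(contig, findSeedMatches(contig))
  expect_equal(length(gr), 0L)
  # 60 bp LTRs: below the length window
  sl <- rand_dna(60)
  contig2 <- paste0(rand_dna(2000), sl, internal, sl, rand_dna(2000))
  gr2 <- extendAndCall(contig2, findSeedMatches(contig2))
  expect_equal(length(gr2), 0L)
})

test_that("full-state plants are recovered with tight boundaries", {
  fx <- small_planted()
  tr <- truthSet(fx$pg)
  gr <- detectLTR(genomeSeq(fx$pg))
  expect_equal(length(gr), length(tr))
  ov <- GenomicRanges::findOverlaps(gr, tr, minoverlap = 1000L,
                                    ignore.strand = TRUE)
  expect_equal(length(ov), length(tr))
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  # chance extension of the maximal exact repeat into the background is
  # geometric with mean 1/3 bp per boundary; 6 bp is a generous bound
  expect_true(all(abs(gr$ltr5_start[q] - tr$ltr5_start[s]) <= 6))
  expect_true(all(abs(gr$ltr3_end[q] - tr$ltr3_end[s]) <= 6))
})

test_that("every candidate satisfies all detection bounds", {
  fx <- small_planted()
  p <- detectionParams()
  gr <- detectLTR(genomeSeq(fx$pg), p)
  l5 <- gr$ltr5_end - gr$ltr5_start + 1
  l3 <- gr$ltr3_end - gr$ltr3_start + 1
  d <- gr$ltr3_start - gr$ltr5_start
  expect_true(all(l5 >= p$ltrMin & l5 <= p$ltrMax))
  expect_true(all(l3 >= p$ltrMin & l3 <= p$ltrMax))
  expect_true(all(d >= p$distMin & d <= p$distMax))
  expect_true(all(gr$ltr_identity >= p$ltrIdentityMin))
})

test_that("identity floor is monotone and detection is deterministic", {
  fx <- small_planted()
  g <- genomeSeq(fx$pg)
  lo <- detectLTR(g, detectionParams(ltrIdentityMin = 80))
  hi <- detectLTR(g, detectionParams(ltrIdentityMin = 95))
  expect_lte(length(hi), length(lo))
  again <- detectLTR(g, detectionParams(ltrIdentityMin = 80))
  expect_identical(as.data.frame(lo), as.data.frame(again))
})
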