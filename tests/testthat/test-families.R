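# Family building: 80-80-80 comparator, clustering, curation, merging,
# orphan promotion.

test_that("the 80-80-80 comparator applies all three clauses", {
  x <- rand_dna(5000, seed = 50)
  same <- passes808080(x, x)
  expect_true(same$pass)
  expect_equal(same$identity, 100)
  expect_equal(same$overlap, 5000)
  expect_equal(same$fracA, 100)
  # 15% substitutions pass, 25% fail (identity clause)
  expect_true(passes808080(x, substitute_bases(x, 750, seed = 51))$pass)
  expect_false(passes808080(x, substitute_bases(x, 1250, seed = 52))$pass)
  # an exact 1 kb fragment fails the length-fraction clause
  frag <- substr(x, 2001, 3000)
  res <- passes808080(x, frag)
  expect_false(res$pass)
  expect_gte(res$identity, 99)
  expect_gte(res$overlap, 990)
  # symmetry
  y <- substitute_bases(x, 750, seed = 53)
  a <- passes808080(x, y); b <- passes808080(y, x)
  expect_equal(a$pass, b$pass)
  expect_equal(a$identity, b$identity, tolerance = 1e-6)
})

test_that("clustering is single linkage over comparator edges", {
  a <- rand_dna(4000, seed = 54)
  b <- substitute_bases(a, 600, seed = 55)   # a~b at 85%
  c <- substitute_bases(b, 600, seed = 56)   # b~c at 85%, a-c ~72%
  expect_false(passes808080(a, c)$pass)
  cl <- clusterCopies(c(a = a, b = b, c = c))
  expect_equal(length(unique(cl)), 1L)
  # mutually dissimilar copies stay apart
  cl2 <- clusterCopies(c(x = rand_dna(3000, seed = 57),
                         y = rand_dna(3000, seed = 58),
                         z = rand_dna(3000, seed = 59)))
  expect_equal(length(unique(cl2)), 3L)
})

test_that("clustering recovers planted families and ignores input order", {
  lib <- buildElementLibrary(nClades = 3, familiesPerClade = 1, seed = 10)
  seqs <- character(); fam <- character()
  set.seed(60)
  for (i in 1:3) {
    blue <- paste0(as.character(lib@ltrSeqs[[i]]),
                   as.character(lib@internalSeqs[[i]]),
                   as.character(lib@ltrSeqs[[i]]))
    for (r in 1:4) {
      seqs <- c(seqs, blue); fam <- c(fam, elementInfo(lib)$family_id[i])
    }
  }
  names(seqs) <- paste0("c", seq_along(seqs))
  cl <- clusterCopies(seqs)
  expect_equal(length(unique(cl)), 3L)
  expect_true(all(tapply(cl, fam, function(v) length(unique(v))) == 1))
  # shuffling the input yields the same partition
  set.seed(61)
  perm <- sample(length(seqs))
  cl2 <- clusterCopies(seqs[perm])
  expect_equal(mclust::adjustedRandIndex(cl[perm], cl2), 1)
})

test_that("curation excises private insertions above the 20 bp rule only", {
  base <- rand_dna(4000, seed = 62)
  insert <- rand_dna(500, seed = 63)
  nested <- paste0(substr(base, 1, 2000), insert, substr(base, 2001, 4000))
  mates <- c(base, substitute_bases(base, 100, seed = 64),
             substitute_bases(base, 100, seed = 65))
  expect_identical(curateCopy(nested, mates), base)
  # a private 15 bp insertion is retained
  small <- paste0(substr(base, 1, 2000), rand_dna(15, seed = 66),
                  substr(base, 2001, 4000))
  expect_identical(curateCopy(small, mates), small)
  # identical members are untouched; singletons returned unchanged
  expect_identical(curateCopy(base, c(base, base)), base)
  expect_identical(curateCopy(base, character()), base)
})

test_that("cluster merging follows representative identity, idempotently", {
  x <- rand_dna(4000, seed = 67)
  near <- substitute_bases(x, 600, seed = 68)    # 85%: merge
  far <- rand_dna(4000, seed = 69)               # unrelated: stay apart
  seqs <- c(a1 = x, a2 = x, b1 = near, b2 = near, c1 = far, c2 = far)
  cl <- c(1L, 1L, 2L, 2L, 3L, 3L)
  fs <- mergeClusters(seqs, cl, "Gypsy", "spT")
  expect_equal(nrow(familyInfo(fs)), 2L)
  mem <- familyMembers(fs)
  famOf <- stats::setNames(mem$family_id, mem$copy_id)
  expect_equal(famOf[["a1"]], famOf[["b2"]])
  expect_false(famOf[["a1"]] == famOf[["c1"]])
  # representative is the longest member; merging again changes nothing
  reps <- representatives(fs)
  fs2 <- mergeClusters(stats::setNames(as.character(reps), names(reps)),
                       seq_along(reps), "Gypsy", "spT")
  expect_equal(nrow(familyInfo(fs2)), 2L)
})

test_that("orphans need a translatable domain to become families", {
  lib <- buildElementLibrary(nClades = 1, familiesPerClade = 1, seed = 12)
  good <- paste0(as.character(lib@ltrSeqs[[1]]),
                 as.character(lib@internalSeqs[[1]]),
                 as.character(lib@ltrSeqs[[1]]))
  # corrupt the domain with in-frame stops across its middle
  info <- elementInfo(lib)
  internal <- as.character(lib@internalSeqs[[1]])
  mid <- info$rt_start[1] + 300L
  stops <- strrep("TAA", 40)
  badInternal <- paste0(substr(internal, 1, mid - 1), stops,
                        substr(internal, mid + nchar(stops),
                               nchar(internal)))
  bad <- paste0(as.character(lib@ltrSeqs[[1]]), badInternal,
                as.character(lib@ltrSeqs[[1]]))
  res <- promoteOrphans(c(good = good, bad = bad), elementPanel(lib),
                        species = "spO", superfamily = "Copia")
  expect_equal(familyInfo(res$families)$n_members, 1L)
  expect_equal(unname(familyMembers(res$families)$copy_id), "good")
  expect_equal(res$discarded$copy_id, "bad")
  expect_equal(res$discarded$reason, "stop_in_domain")
  # empty input
  res0 <- promoteOrphans(character(), elementPanel(lib))
  expect_equal(nrow(familyInfo(res0$families)), 0L)
  expect_equal(nrow(res0$discarded), 0L)
})
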