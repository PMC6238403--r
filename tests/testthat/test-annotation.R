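# Library-based re-annotation: genome scan, defragmentation, family
# assignment, genomic proportions.

make_family_set <- function(lib, species = "lib") {
  ids <- elementInfo(lib)$family_id
  reps <- Biostrings::DNAStringSet(vapply(seq_along(ids), function(i)
    paste0(as.character(lib@ltrSeqs[[i]]), as.character(lib@internalSeqs[[i]]),
           as.character(lib@ltrSeqs[[i]])), character(1)))
  names(reps) <- ids
  new("TEFamilySet", representatives = reps,
      info = S4Vectors::DataFrame(family_id = ids, species = species,
                                  superfamily = elementInfo(lib)$superfamily,
                                  origin = "cluster", n_members = 1L),
      members = S4Vectors::DataFrame(copy_id = ids, family_id = ids))
}

test_that("the scan recovers full, diverged-below-cutoff and solo copies", {
  lib <- buildElementLibrary(nClades = 1, familiesPerClade = 1, seed = 14)
  fs <- make_family_set(lib)
  blue <- as.character(representatives(fs)[[1]])
  ltr <- as.character(lib@ltrSeqs[[1]])
  seqs <- list(
    full = blue,
    diverged30 = as.character(mutateSequence(blue, 0.30, 0, seed = 70)),
    solo = ltr)
  set.seed(71)
  contig <- paste0(rand_dna(15000), seqs$full, rand_dna(15000),
                   seqs$diverged30, rand_dna(15000), seqs$solo,
                   rand_dna(15000))
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  h <- scanGenome(genome, fs)
  fullStart <- 15001L
  fullEnd <- 15000L + nchar(blue)
  covFull <- h[h$start <= fullStart + 100 & h$end >= fullEnd - 100, ]
  expect_gte(nrow(covFull), 1)           # full copy: near-complete span
  # the 30%-diverged copy is invisible at -div 20
  divStart <- fullEnd + 15000L
  divEnd <- divStart + nchar(seqs$diverged30)
  expect_equal(nrow(h[h$start > divStart - 50 & h$end < divEnd + 50, ]), 0)
  # the solo LTR is recovered as an LTR-sized hit
  soloStart <- divEnd + 15000L
  hSolo <- h[h$start > soloStart - 50 & h$start < soloStart + 50, ]
  expect_gte(nrow(hSolo), 1)
  expect_lte(max(hSolo$end - hSolo$start + 1), nchar(ltr) + 50)
})

test_that("defragmentation obeys the strict 500 bp same-type rule", {
  frag <- function(contig, start, end, sf, strand = "+", score = 100)
    data.frame(contig = contig, start = start, end = end, strand = strand,
               superfamily = sf, family_id = paste0(sf, "-1"), score = score)
  # 499 bp gap: merge (one copy spanning both plus the gap)
  h1 <- rbind(frag("c", 1000, 1999, "Gypsy"), frag("c", 2499, 3499, "Gypsy"))
  d1 <- defragmentHits(h1, 500L)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$start, 1000); expect_equal(d1$end, 3499)
  expect_equal(d1$n_fragments, 2L)
  # exactly 500 bp gap: no merge
  h2 <- rbind(frag("c", 1000, 1999, "Gypsy"), frag("c", 2500, 3499, "Gypsy"))
  expect_equal(nrow(defragmentHits(h2, 500L)), 2)
  # different superfamilies never merge, however close
  h3 <- rbind(frag("c", 1000, 1999, "Gypsy"), frag("c", 2100, 3000, "Copia"))
  expect_equal(nrow(defragmentHits(h3, 500L)), 2)
  # idempotent and order-independent
  d1b <- defragmentHits(d1[, c("contig", "start", "end", "strand",
                               "superfamily", "family_id", "score")], 500L)
  expect_equal(d1b$start, d1$start)
  expect_equal(d1b$end, d1$end)
  h1shuf <- h1[2:1, ]
  expect_equal(defragmentHits(h1shuf, 500L)$start, d1$start)
  expect_equal(defragmentHits(h1shuf, 500L)$end, d1$end)
})

test_that("copies are assigned to families, flagged cross-species or dropped", {
  lib <- buildElementLibrary(nClades = 2, familiesPerClade = 1, seed = 15)
  fsA <- make_family_set(lib, species = "spA")
  # pretend family 2 was defined in another species
  info <- familyInfo(fsA)
  info$species[2] <- "spB"
  fsMix <- new("TEFamilySet", representatives = representatives(fsA),
               info = info, members = familyMembers(fsA))
  blue1 <- as.character(representatives(fsA)[[1]])
  blue2 <- as.character(representatives(fsA)[[2]])
  set.seed(72)
  contig <- paste0(rand_dna(13000), blue1, rand_dna(13000), blue2,
                   rand_dna(13000))
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  copies <- data.frame(
    contig = "c1",
    start = c(13001L, 13000L + nchar(blue1) + 13000L + 1L,
              nchar(contig) - 5000L),
    end = c(13000L + nchar(blue1),
            13000L + nchar(blue1) + 13000L + nchar(blue2), nchar(contig)),
    strand = "+", superfamily = "Copia", family_id = NA, score = 0)
  res <- assignFamily(copies, genome, fsMix, species = "spA")
  expect_equal(res$assignment[1], info$family_id[1])
  expect_equal(res$assignment[2], "cross_species_candidate")
  expect_equal(res$assignment[3], "unassigned")
})

test_that("cross-species candidates with a domain found new families", {
  lib <- buildElementLibrary(nClades = 1, familiesPerClade = 1, seed = 16)
  blue <- paste0(as.character(lib@ltrSeqs[[1]]),
                 as.character(lib@internalSeqs[[1]]),
                 as.character(lib@ltrSeqs[[1]]))
  info <- elementInfo(lib)
  # a truncated candidate missing the whole coding region
  headless <- substr(blue, info$ltr_len[1] + info$rt_end[1] + 50L,
                     nchar(blue))
  set.seed(73)
  contig <- paste0(rand_dna(2000), blue, rand_dna(13000), headless,
                   rand_dna(2000))
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  cands <- data.frame(
    contig = "c1", start = c(2001L, 2000L + nchar(blue) + 13001L),
    end = c(2000L + nchar(blue), 2000L + nchar(blue) + 13000L + nchar(headless)),
    strand = "+", superfamily = info$superfamily[1],
    assignment = "cross_species_candidate")
  fams <- promoteAnnotationFamilies(cands, genome, elementPanel(lib),
                                    species = "spN")
  expect_equal(nrow(familyInfo(fams)), 1L)
  expect_equal(familyInfo(fams)$origin, "annotation_derived")
  # no candidates -> no families
  expect_equal(nrow(familyInfo(promoteAnnotationFamilies(
    cands[0, ], genome, elementPanel(lib), species = "spN"))), 0L)
})

test_that("genomic proportions use interval unions", {
  expect_equal(nrow(genomicProportion(data.frame(contig = character(),
                                                 start = integer(),
                                                 end = integer(),
                                                 superfamily = character()),
                                      1e6)), 0)
  one <- data.frame(contig = "c", start = 1, end = 10000,
                    superfamily = "Gypsy")
  expect_equal(genomicProportion(one, 1e6)$percent, 1.0)
  # overlapping copies count once
  two <- data.frame(contig = "c", start = c(1, 5001), end = c(10000, 15000),
                    superfamily = "Gypsy")
  expect_equal(genomicProportion(two, 1e6)$percent, 1.5)
})
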