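# Census summaries and the packaged published-count transcription.

test_that("the packaged transcription is arithmetically consistent", {
  rep <- verifyPublishedCounts()
  expect_true(all(rep$pass))
  by <- stats::setNames(rep$computed, rep$check)
  expect_equal(unname(by["copies_total"]), 1637)
  expect_equal(unname(by["families_total"]), 724)
  expect_equal(unname(by["clade_rows"]), 31)
  expect_equal(unname(by["galea_families"]), 72)
  expect_equal(unname(by["sailor_families"]), 209)
})

test_that("the census table partitions families and keeps totals", {
  fams <- data.frame(
    family_id = sprintf("f%d", 1:8),
    superfamily = c(rep("Gypsy", 5), rep("Copia", 3)),
    source = c("genome", "genome", "database", "genome", "database",
               "genome", "genome", "database"),
    n_copies = c(5, 3, 0, 2, 0, 7, 1, 0))
  calls <- data.frame(family_id = c("f1", "f2", "f3", "f6"),
                      clade = c("cladeX", "cladeX", "cladeX", "cladeY"))
  tab <- cladeFamilyTable(fams, calls)
  x <- tab[tab$clade == "cladeX", ]
  expect_equal(x$families_genome, 2)
  expect_equal(x$copies_genome, 8)
  expect_equal(x$families_database, 1)
  oth <- tab[tab$superfamily == "Gypsy" & tab$clade == "other", ]
  expect_equal(oth$families_genome + oth$families_database, 2)
  tot <- tab[tab$is_total & tab$superfamily == "Gypsy", ]
  body <- tab[!tab$is_total & tab$superfamily == "Gypsy", ]
  expect_equal(tot$families_genome, sum(body$families_genome))
  expect_equal(tot$copies_genome, sum(body$copies_genome))
  # every family in exactly one cell
  expect_equal(sum(tab$families_genome[!tab$is_total]) +
                 sum(tab$families_database[!tab$is_total]), nrow(fams))
  # no calls at all: everything lands in "other"
  tab0 <- cladeFamilyTable(fams, calls[0, ])
  expect_true(all(tab0$clade[!tab0$is_total] == "other"))
})

test_that("species distribution counts each species once per clade", {
  calls <- data.frame(
    clade = c(rep("cladeX", 5), "cladeY", "other"),
    species = c("sp1", "sp1", "sp1", "sp1", "sp1", "sp2", "sp3"))
  map <- c(sp1 = "bivalve", sp2 = "gastropod", sp3 = "bivalve")
  d <- cladeSpeciesDistribution(calls, map, allClades = c("cladeX", "cladeY",
                                                          "cladeZ"))
  expect_equal(d$n_species[d$clade == "cladeX"], 1)
  expect_equal(d$bivalve[d$clade == "cladeX"], 1)
  expect_equal(d$gastropod[d$clade == "cladeY"], 1)
  expect_equal(d$n_species[d$clade == "cladeZ"], 0)
  expect_error(cladeSpeciesDistribution(calls, map[-2]), "class mapping")
})

test_that("relative clade proportions sum to one within a superfamily", {
  ann <- data.frame(
    species = "sp1", superfamily = "Gypsy",
    clade = c("cladeX", "cladeX", "cladeY", NA),
    length = c(3000, 3000, 2000, 1000))
  p <- cladeRelativeProportions(ann)
  expect_equal(sum(p$share), 1)
  expect_equal(p$share[p$clade == "cladeX"], 6 / 9)
  expect_equal(p$share[p$clade == "other"], 1 / 9)
  # single clade -> share 1; all unplaced -> other = 1
  p1 <- cladeRelativeProportions(data.frame(
    species = "s", superfamily = "Copia", clade = "cladeZ", length = 500))
  expect_equal(p1$share, 1)
  p2 <- cladeRelativeProportions(data.frame(
    species = "s", superfamily = "Copia", clade = NA_character_,
    length = c(10, 20)))
  expect_equal(p2$share[p2$clade == "other"], 1)
})

test_that("superfamily composition reports counts, proportions and shares", {
  res <- list(spX = list(
    detections = data.frame(superfamily = c("Gypsy", "Gypsy", "Copia")),
    annotated = data.frame(contig = "c", start = c(1, 20001),
                           end = c(10000, 25000),
                           superfamily = c("Gypsy", "Copia")),
    families = data.frame(superfamily = c("Gypsy", "Copia")),
    genomeLength = 1e6))
  comp <- superfamilyComposition(res)
  gy <- comp[comp$superfamily == "Gypsy", ]
  expect_equal(gy$copies, 2)
  expect_equal(gy$genomic_pct, 1.0)
  expect_equal(gy$copy_share, 100 * 2 / 3)
  # a species with only one superfamily: share 100; empty genome: NA shares
  only <- list(spY = list(
    detections = data.frame(superfamily = "Gypsy"),
    annotated = data.frame(contig = character(), start = integer(),
                           end = integer(), superfamily = character()),
    families = data.frame(superfamily = "Gypsy"), genomeLength = 1e6))
  co <- superfamilyComposition(only)
  expect_equal(co$copy_share[co$superfamily == "Gypsy"], 100)
  none <- list(spZ = list(
    detections = data.frame(superfamily = character()),
    annotated = data.frame(contig = character(), start = integer(),
                           end = integer(), superfamily = character()),
    families = data.frame(superfamily = character()), genomeLength = 1e6))
  cn <- superfamilyComposition(none)
  expect_true(all(is.na(cn$copy_share)))
})
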