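# End-to-end orchestration: detect -> classify -> families -> annotate ->
# phylogeny -> clade assignment -> report, per species, with one shared
# reference panel and pooled scan libraries (the staged-database design:
# the scan library holds curated cluster families of all species, the
# assignment library adds orphans, and the re-assignment library adds the
# annotation-derived families).

#' Run the full census pipeline
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{species}{named list; each element a list with \code{genome}
#'       (a \code{DNAStringSet}) and optionally \code{class} (taxonomic
#'       class label).}
#'     \item{panel}{a \code{\linkS4class{ReferencePanel}}.}
#'     \item{detection, family, scan, phylo, cladeAssign}{optional parameter
#'       blocks (defaults used when missing).}
#'     \item{extraLibrary}{optional \code{\linkS4class{TEFamilySet}} of
#'       externally referenced families added to the scan library.}
#'     \item{seed}{integer seed propagated to all stochastic stages.}
#'   }
#' @return a manifest list: parameter echo, per-species stage counts, the
#'   families (\code{\linkS4class{TEFamilySet}}), clade calls, annotated
#'   copies and report tables. Re-running with the same config reproduces
#'   the manifest.
#' @export
runPipeline <- function(config) {
  if (is.null(config$panel) || !is(config$panel, "ReferencePanel"))
    stop("config$panel must be a ReferencePanel")
  if (is.null(config$species) || !length(config$species))
    stop("config$species must name at least one genome")
  for (sp in names(config$species))
    if (is.null(config$species[[sp]]$genome))
      stop("species ", sp, " has no genome")
  detP <- config$detection %||% detectionParams()
  famP <- config$family %||% familyParams()
  scanP <- config$scan %||% scanParams()
  phyP <- config$phylo %||% phyloParams(seed = config$seed %||% 1L)
  clP <- config$cladeAssign %||% cladeAssignParams()
  aaSch <- aaScoringScheme()
  ntSch <- ntScoringScheme()
  panel <- config$panel

  manifest <- list(params = list(detection = detP, family = famP,
                                 scan = scanP, phylo = phyP,
                                 cladeAssign = clP,
                                 seed = config$seed %||% 1L),
                   counts = list())
  perSpecies <- list()

  # stage 1-3: detection, classification, family building per species
  for (sp in names(config$species)) {
    genome <- config$species[[sp]]$genome
    cands <- detectLTR(genome, detP)
    copySet <- candidateCopySet(cands, genome, species = sp)
    cls <- if (length(copySet@seqs))
      classifySuperfamily(copySeqs(copySet), panel, scheme = aaSch)
    else data.frame(superfamily = character(), strand = character())
    info <- copyInfo(copySet)
    info$superfamily <- cls$superfamily[match(info$copy_id, cls$id)]
    info$strand <- cls$strand[match(info$copy_id, cls$id)]
    # orient to the coding strand, then clean tandem repeats
    oriented <- orientCopies(new("TECopySet", seqs = copySeqs(copySet),
                                 info = info))
    seqs <- copySeqs(oriented)
    keep <- which(!is.na(info$superfamily) & info$superfamily != "unclassified")
    cleaned <- Biostrings::DNAStringSet(vapply(keep, function(i)
      maskTandemRepeats(as.character(seqs[[i]]))$masked, character(1)))
    names(cleaned) <- info$copy_id[keep]
    copies <- new("TECopySet", seqs = cleaned, info = info[keep, , drop = FALSE])
    fb <- buildFamilies(copies, panel, species = sp, params = famP,
                        scheme = aaSch)
    perSpecies[[sp]] <- list(genome = genome, candidates = cands,
                             copies = copies, families = fb$families,
                             discarded = fb$discarded)
    manifest$counts[[sp]] <- list(
      candidates = length(cands),
      classified = length(keep),
      families_structural = nrow(fb$families@info))
  }

  # stage 4: genome re-annotation with pooled libraries
  allFam <- .bind_family_sets(lapply(perSpecies, function(x) x$families))
  clusterFams <- allFam@info$family_id[allFam@info$origin == "cluster"]
  scanLib <- .subset_family_set(allFam, clusterFams)
  if (!is.null(config$extraLibrary))
    scanLib <- .bind_family_sets(list(scanLib, config$extraLibrary))
  assignLib <- allFam                       # clusters + orphans
  if (!is.null(config$extraLibrary))
    assignLib <- .bind_family_sets(list(assignLib, config$extraLibrary))

  annDerived <- list()
  for (sp in names(perSpecies)) {
    genome <- perSpecies[[sp]]$genome
    hits <- scanGenome(genome, scanLib, scanP, scheme = ntSch)
    copies <- defragmentHits(hits, scanP$mergeGapMax)
    copies <- assignFamily(copies, genome, assignLib, species = sp,
                           maxE = scanP$assignMaxE, scheme = ntSch)
    cross <- copies[copies$assignment == "cross_species_candidate", ,
                    drop = FALSE]
    newFams <- promoteAnnotationFamilies(
      cross, genome, panel, species = sp, params = famP, scheme = aaSch,
      startIndex = sum(allFam@info$species == sp) + 1L)
    if (nrow(newFams@info)) annDerived[[sp]] <- newFams
    perSpecies[[sp]]$scanHits <- hits
    perSpecies[[sp]]$annotated <- copies
    manifest$counts[[sp]]$scan_hits <- nrow(hits)
    manifest$counts[[sp]]$annotated_copies <- nrow(copies)
    manifest$counts[[sp]]$families_annotation <- nrow(newFams@info)
  }
  allFam <- .bind_family_sets(c(list(allFam), unname(annDerived)))
  finalLib <- if (!is.null(config$extraLibrary))
    .bind_family_sets(list(allFam, config$extraLibrary)) else allFam

  # stage 5: re-assignment against the augmented library
  for (sp in names(perSpecies)) {
    copies <- perSpecies[[sp]]$annotated
    copies <- assignFamily(copies[, setdiff(names(copies),
                                            c("assignment", "assigned_family",
                                              "assigned_evalue"))],
                           perSpecies[[sp]]$genome, finalLib, species = sp,
                           maxE = scanP$assignMaxE, scheme = ntSch)
    copies$species <- sp
    perSpecies[[sp]]$annotated <- copies
  }

  # stage 6: domains, trees, clades per superfamily
  doms <- extractDomains(allFam, panel, scheme = aaSch)
  speciesMap <- stats::setNames(allFam@info$species, allFam@info$family_id)
  sfOfFam <- stats::setNames(allFam@info$superfamily, allFam@info$family_id)
  labsAll <- panelLabels(panel)
  cladeCalls <- list()
  trees <- list()
  for (sf in unique(sfOfFam)) {
    ids <- names(doms$domains)[sfOfFam[names(doms$domains)] == sf]
    if (length(ids) < 3) next
    # trees include the labelled clade references alongside the new families
    refIds <- labsAll$id[labsAll$superfamily == sf & !is.na(labsAll$clade)]
    refClades <- stats::setNames(labsAll$clade[match(refIds, labsAll$id)],
                                 refIds)
    treeSeqs <- c(doms$domains[ids], panelSeqs(panel)[refIds])
    msa <- alignDomains(treeSeqs, scheme = aaSch)
    tree <- bootstrapSupport(msa, phyP)
    trees[[sf]] <- tree
    calls <- defineClades(tree, speciesMap, phyP, refClades = refClades)
    auto <- grepl("^(clade|lineage)_", calls$clade)
    calls$clade[auto] <- paste0(sf, "_", calls$clade[auto])
    cladeCalls[[sf]] <- cbind(calls, superfamily = sf)
  }
  cladeCalls <- if (length(cladeCalls)) do.call(rbind, cladeCalls)
                else data.frame(clade = character(), family_id = character(),
                                species = character(), support = numeric(),
                                lineage = character(),
                                superfamily = character())
  rownames(cladeCalls) <- NULL

  # stage 7: similarity route for families without a phylogenetic placement
  labs <- panelLabels(panel)
  dbClades <- stats::setNames(labs$clade, labs$id)
  unplaced <- setdiff(allFam@info$family_id,
                      cladeCalls$family_id[cladeCalls$clade != "other"])
  simRows <- list()
  for (f in intersect(unplaced, names(doms$domains))) {
    res <- assignBySimilarity(doms$domains[[f]], panelSeqs(panel), dbClades,
                              clP, scheme = aaSch)
    if (res$clade != "unassigned")
      simRows[[length(simRows) + 1L]] <- data.frame(
        clade = res$clade, family_id = f,
        species = unname(speciesMap[f]), support = NA_real_,
        lineage = NA_character_, superfamily = unname(sfOfFam[f]),
        route = "similarity", stringsAsFactors = FALSE)
  }
  if (nrow(cladeCalls)) cladeCalls$route <- "phylogeny"
  if (length(simRows)) {
    sim <- do.call(rbind, simRows)
    cladeCalls <- rbind(cladeCalls[cladeCalls$clade != "other" |
                                     !cladeCalls$family_id %in% sim$family_id, ],
                        sim)
  }

  # stage 8: reports
  annotatedAll <- do.call(rbind, lapply(names(perSpecies), function(sp) {
    a <- perSpecies[[sp]]$annotated
    if (nrow(a) == 0) return(NULL)
    famOfCopy <- ifelse(a$assignment %in% allFam@info$family_id,
                        a$assignment, NA_character_)
    a$clade <- cladeCalls$clade[match(famOfCopy, cladeCalls$family_id)]
    a
  }))
  speciesResults <- lapply(names(perSpecies), function(sp) {
    p <- perSpecies[[sp]]
    det <- data.frame(superfamily = copyInfo(p$copies)$superfamily)
    list(detections = det, annotated = p$annotated,
         families = as.data.frame(allFam@info[allFam@info$species == sp, ]),
         genomeLength = sum(Biostrings::width(p$genome)))
  })
  names(speciesResults) <- names(perSpecies)
  composition <- superfamilyComposition(speciesResults)
  proportions <- if (!is.null(annotatedAll) && nrow(annotatedAll))
    cladeRelativeProportions(annotatedAll) else NULL

  manifest$families <- allFam
  manifest$cladeCalls <- cladeCalls
  manifest$annotated <- annotatedAll
  manifest$trees <- trees
  manifest$excludedDomains <- doms$excluded
  manifest$composition <- composition
  manifest$proportions <- proportions
  manifest$counts$total_families <- nrow(allFam@info)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset a family set by family ids
.subset_family_set <- function(fs, ids) {
  keep <- fs@info$family_id %in% ids
  new("TEFamilySet",
      representatives = fs@representatives[keep],
      info = fs@info[keep, , drop = FALSE],
      members = fs@members[fs@members$family_id %in% ids, , drop = FALSE])
}
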