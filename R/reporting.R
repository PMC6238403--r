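# Census summaries: superfamily composition per genome, clade-by-source
# family counts, clade occurrence across host classes, relative clade
# proportions, and arithmetic verification of the packaged transcription of
# the published counts.

#' Superfamily composition per species
#'
#' Three panels per species: structurally detected copy counts, genomic
#' proportion from the library scan, and distinct family counts, each by
#' superfamily, with relative shares.
#'
#' @param speciesResults named list (by species); each element is a list with
#'   \code{detections} (data.frame or GRanges-derived data.frame with a
#'   \code{superfamily} column), \code{annotated} (defragmented copies with
#'   \code{superfamily}, \code{start}, \code{end}, \code{contig}),
#'   \code{families} (data.frame with \code{superfamily}) and
#'   \code{genomeLength}.
#' @return data.frame (species, superfamily, copies, genomic_pct, families,
#'   copy_share, family_share); shares are \code{NA} when a species has no
#'   elements.
#' @export
superfamilyComposition <- function(speciesResults) {
  .stopifnot_named(speciesResults, "speciesResults")
  sfs <- c("Copia", "BELPao", "Gypsy")
  out <- list()
  for (sp in names(speciesResults)) {
    r <- speciesResults[[sp]]
    copies <- vapply(sfs, function(sf)
      sum(r$detections$superfamily == sf, na.rm = TRUE), numeric(1))
    fams <- vapply(sfs, function(sf)
      sum(r$families$superfamily == sf, na.rm = TRUE), numeric(1))
    pct <- vapply(sfs, function(sf) {
      m <- r$annotated[r$annotated$superfamily == sf, , drop = FALSE]
      if (nrow(m) == 0) return(0)
      genomicProportion(m, r$genomeLength, "superfamily")$percent[1]
    }, numeric(1))
    shares <- function(x) if (sum(x) > 0) 100 * x / sum(x) else rep(NA_real_, length(x))
    out[[sp]] <- data.frame(species = sp, superfamily = sfs,
                            copies = copies, genomic_pct = pct,
                            families = fams, copy_share = shares(copies),
                            family_share = shares(fams),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Clade-by-source family census table
#'
#' One row per (superfamily, clade): families found in genomes, their summed
#' copy numbers, and families from database mining. Families in no clade are
#' tallied as \code{"other"} per superfamily. Per-superfamily totals are
#' appended and always equal the column sums of their section.
#'
#' @param families data.frame with columns \code{family_id},
#'   \code{superfamily}, \code{source} (\code{"genome"} or
#'   \code{"database"}) and \code{n_copies} (copies in genomes; 0 for
#'   database families).
#' @param cladeCalls data.frame with \code{family_id} and \code{clade}
#'   (\code{"other"} or \code{NA} for unplaced families).
#' @return data.frame (superfamily, clade, families_genome, copies_genome,
#'   families_database, is_total).
#' @export
cladeFamilyTable <- function(families, cladeCalls) {
  stopifnot(all(c("family_id", "superfamily", "source", "n_copies") %in%
                  names(families)))
  cl <- cladeCalls$clade[match(families$family_id, cladeCalls$family_id)]
  cl[is.na(cl)] <- "other"
  families$clade <- cl
  rows <- list()
  for (sf in unique(families$superfamily)) {
    m <- families[families$superfamily == sf, , drop = FALSE]
    for (cld in unique(m$clade)) {
      g <- m[m$clade == cld, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        superfamily = sf, clade = cld,
        families_genome = sum(g$source == "genome"),
        copies_genome = sum(g$n_copies[g$source == "genome"]),
        families_database = sum(g$source == "database"),
        is_total = FALSE, stringsAsFactors = FALSE)
    }
    sec <- do.call(rbind, rows)
    sec <- sec[sec$superfamily == sf & !sec$is_total, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      superfamily = sf, clade = "TOTAL",
      families_genome = sum(sec$families_genome),
      copies_genome = sum(sec$copies_genome),
      families_database = sum(sec$families_database),
      is_total = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # invariant: totals equal column sums
  for (sf in unique(out$superfamily)) {
    sec <- out[out$superfamily == sf, ]
    stopifnot(sec$families_genome[sec$is_total] ==
                sum(sec$families_genome[!sec$is_total]))
  }
  out
}

#' Clade occurrence across species, split by taxonomic class
#'
#' @param cladeCalls data.frame with \code{clade} and \code{species}
#'   (\code{"other"} rows are ignored).
#' @param speciesClassMap named character vector: species -> class.
#' @param allClades optional clade universe so absent clades keep a row of
#'   zeros.
#' @return data.frame (clade, class columns, n_species); a species counts
#'   once per clade regardless of how many of its families belong to it.
#' @export
cladeSpeciesDistribution <- function(cladeCalls, speciesClassMap,
                                     allClades = NULL) {
  calls <- cladeCalls[cladeCalls$clade != "other", , drop = FALSE]
  unmapped <- setdiff(unique(calls$species), names(speciesClassMap))
  if (length(unmapped))
    stop("species without a class mapping: ", paste(unmapped, collapse = ", "))
  classes <- sort(unique(unname(speciesClassMap)))
  clades <- unique(c(allClades, unique(calls$clade)))
  rows <- lapply(clades, function(cl) {
    sp <- unique(calls$species[calls$clade == cl])
    counts <- vapply(classes, function(k)
      sum(speciesClassMap[sp] == k), integer(1))
    cbind(data.frame(clade = cl, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(n_species = length(sp)))
  })
  out <- do.call(rbind, rows)
  names(out)[2:(1 + length(classes))] <- classes
  out
}

#' Relative clade proportions per species and superfamily
#'
#' Shares of each clade (plus \code{"other"}) in the base pairs covered by
#' annotated copies, per species and superfamily; shares sum to 1 wherever a
#' superfamily has any annotated bp.
#'
#' @param annotated data.frame of annotated copies with \code{species},
#'   \code{superfamily}, \code{clade} (\code{NA} means unplaced) and
#'   \code{length} (bp).
#' @return data.frame (species, superfamily, clade, bp, share).
#' @export
cladeRelativeProportions <- function(annotated) {
  stopifnot(all(c("species", "superfamily", "length") %in% names(annotated)))
  if (!"clade" %in% names(annotated)) annotated$clade <- NA_character_
  annotated$clade[is.na(annotated$clade)] <- "other"
  rows <- list()
  for (sp in unique(annotated$species)) {
    for (sf in unique(annotated$superfamily[annotated$species == sp])) {
      m <- annotated[annotated$species == sp & annotated$superfamily == sf, ,
                     drop = FALSE]
      agg <- tapply(m$length, m$clade, sum)
      tot <- sum(agg)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, superfamily = sf, clade = names(agg),
        bp = as.integer(agg),
        share = if (tot > 0) as.numeric(agg) / tot else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged transcription of the published counts
#'
#' Loads the packaged transcription of the published clade-by-source family
#' table and the Results tallies. Bracketed copy-number columns are stored
#' but excluded from verification (their printed form is typographically
#' unreliable; see the notes column).
#'
#' @return list with \code{table1} and \code{tallies} data.frames.
#' @export
publishedCounts <- function() {
  t1 <- utils::read.delim(system.file("extdata", "published_census_table.tsv",
                                      package = "LTRcensus"),
                          stringsAsFactors = FALSE)
  tl <- utils::read.delim(system.file("extdata",
                                      "published_results_tallies.tsv",
                                      package = "LTRcensus"),
                          stringsAsFactors = FALSE)
  list(table1 = t1, tallies = tl)
}

#' Verify the arithmetic consistency of the published counts
#'
#' Recomputes every derived tally (row sums, cross-superfamily sums, clade
#' row counts) from the packaged table cells and compares each with the
#' stated value.
#'
#' @param fixture output of \code{\link{publishedCounts}}.
#' @return data.frame (check, computed, stated, pass).
#' @export
verifyPublishedCounts <- function(fixture = publishedCounts()) {
  t1 <- fixture$table1
  tl <- stats::setNames(fixture$tallies$value, fixture$tallies$key)
  rowTotal <- function(clade) {
    r <- t1[t1$clade == clade, ]
    if (nrow(r) != 1) return(NA_real_)
    r$families_genome + r$families_database
  }
  checks <- list(
    c("copies_total", tl[["copies_copia"]] + tl[["copies_belpao"]] +
        tl[["copies_gypsy"]], tl[["copies_total_stated"]]),
    c("families_total", tl[["families_cluster"]] + tl[["families_orphan"]] +
        tl[["families_repbase"]] + tl[["families_repeatmasker"]],
      tl[["families_total_stated"]]),
    c("clade_rows", nrow(t1), tl[["clades_total_stated"]]),
    c("galea_families", rowTotal("GalEa"), tl[["galea_total_stated"]]),
    c("hydra_families", rowTotal("Hydra"), tl[["hydra_total_stated"]]),
    c("sailor_families", rowTotal("Sparrow") + rowTotal("Sinbad") +
        rowTotal("Surcouf"), tl[["sailor_total_stated"]]),
    c("sinbad_families", rowTotal("Sinbad"), tl[["sinbad_total_stated"]]),
    c("surcouf_families", rowTotal("Surcouf"), tl[["surcouf_total_stated"]]),
    c("tas_families", rowTotal("TAS"), tl[["tas_total_stated"]]),
    c("suzu_families", rowTotal("Suzu"), tl[["suzu_total_stated"]]),
    c("abclade_families", rowTotal("AB-clade"), tl[["abclade_total_stated"]]),
    c("molgy1_families", rowTotal("MolGy1"), tl[["molgy1_total_stated"]]),
    c("molgy2_families", rowTotal("MolGy2"), tl[["molgy2_total_stated"]]))
  out <- data.frame(
    check = vapply(checks, `[`, character(1), 1),
    computed = as.numeric(vapply(checks, `[`, character(1), 2)),
    stated = as.numeric(vapply(checks, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  out$pass <- !is.na(out$computed) & !is.na(out$stated) &
    out$computed == out$stated
  out
}
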