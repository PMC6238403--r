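# Library-based genome re-annotation: seeded nucleotide scan of family
# representatives against the genome, defragmentation of nearby
# same-superfamily hits, family assignment by best nucleotide hit, and
# genomic-proportion summaries.

#' Genome-scan parameters
#'
#' @param maxDivergence maximum percent divergence (100 - percent identity)
#'   of a reported hit, mirroring a \code{-div 20} masking cut.
#' @param minHitScore minimum raw alignment score of a fragment.
#' @param minHitLen minimum fragment length (alignment columns).
#' @param mergeGapMax fragments of the same superfamily and strand closer
#'   than this many intervening bases are concatenated (strict: a gap of
#'   exactly \code{mergeGapMax} does not merge).
#' @param assignMaxE E-value ceiling for family assignment.
#' @param seedK seed k-mer length of the scan.
#' @return a list of class \code{scan_params}.
#' @export
scanParams <- function(maxDivergence = 20, minHitScore = 60,
                       minHitLen = 50L, mergeGapMax = 500L,
                       assignMaxE = 1e-10, seedK = 12L) {
  stopifnot(maxDivergence > 0, maxDivergence < 100, mergeGapMax >= 0)
  p <- list(maxDivergence = maxDivergence, minHitScore = minHitScore,
            minHitLen = as.integer(minHitLen),
            mergeGapMax = as.integer(mergeGapMax), assignMaxE = assignMaxE,
            seedK = as.integer(seedK))
  class(p) <- "scan_params"
  p
}

#' Scan a genome with a family library
#'
#' Seeded local nucleotide search of every family representative (and its
#' reverse complement) against every contig. Hits more divergent than
#' \code{maxDivergence} percent are dropped; overlapping hits from different
#' families are resolved per contig by score.
#'
#' @param genome a \code{DNAStringSet} of contigs.
#' @param library a \code{\linkS4class{TEFamilySet}} (the scan library).
#' @param params a \code{\link{scanParams}} list.
#' @param scheme calibrated nucleotide scheme.
#' @return data.frame of fragments: contig, start, end, strand, family_id,
#'   superfamily, score, identity, length.
#' @export
scanGenome <- function(genome, library, params = scanParams(), scheme = NULL) {
  stopifnot(is(library, "TEFamilySet"))
  if (is.null(scheme)) scheme <- ntScoringScheme()
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      family_id = character(), superfamily = character(),
                      score = numeric(), identity = numeric(),
                      length = integer())
  if (nrow(library@info) == 0) return(empty)
  reps <- as.character(representatives(library))
  info <- familyInfo(library)
  rows <- list()
  for (ctg in names(genome)) {
    sub <- as.character(genome[[ctg]])
    for (fi in seq_along(reps)) {
      for (str in c("+", "-")) {
        q <- if (str == "+") reps[[fi]] else .revcomp(reps[[fi]])
        h <- .seeded_local_hits(q, sub, scheme, k = params$seedK,
                                minLen = params$minHitLen)
        if (nrow(h) == 0) next
        ident <- 100 * h$n_match / h$n_cols
        ok <- ident >= 100 - params$maxDivergence &
          h$score >= params$minHitScore
        h <- h[ok, , drop = FALSE]
        if (nrow(h) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = h$sstart, end = h$send, strand = str,
          family_id = info$family_id[fi], superfamily = info$superfamily[fi],
          score = h$score, identity = ident[ok],
          length = h$send - h$sstart + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else return(empty)
  # per contig, resolve heavy overlaps across families/strands: keep best
  out <- list()
  for (ctg in unique(hits$contig)) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    h <- h[order(-h$score, h$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(h))
    for (i in seq_len(nrow(h))) {
      if (!keep[i]) next
      if (i < nrow(h)) for (j in seq(i + 1L, nrow(h))) {
        if (!keep[j]) next
        ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1L
        if (ov > 0.5 * (h$end[j] - h$start[j] + 1L)) keep[j] <- FALSE
      }
    }
    out[[length(out) + 1L]] <- h[keep, , drop = FALSE]
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Defragment scan hits into annotated copies
#'
#' Concatenates same-superfamily, same-strand fragments on a contig whose
#' intervening gap is strictly smaller than \code{mergeGapMax} bases,
#' integrating the central sequence into one copy. Fragments of different
#' superfamilies never merge. Idempotent and order-independent.
#'
#' @param hits data.frame from \code{\link{scanGenome}}.
#' @param mergeGapMax strict gap bound (bp); fragments 499 bp apart merge
#'   under the default, fragments 500 bp apart do not.
#' @return data.frame of copies: contig, start, end, strand, superfamily,
#'   family_id (of the highest-scoring fragment), n_fragments, score (max),
#'   length.
#' @export
defragmentHits <- function(hits, mergeGapMax = 500L) {
  cols <- c("contig", "start", "end", "strand", "superfamily", "family_id",
            "score")
  stopifnot(all(cols %in% names(hits)))
  if (nrow(hits) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      superfamily = character(), family_id = character(),
                      n_fragments = integer(), score = numeric(),
                      length = integer()))
  out <- list()
  keyOf <- interaction(hits$contig, hits$superfamily, hits$strand, drop = TRUE)
  for (key in levels(keyOf)) {
    h <- hits[keyOf == key, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    grp <- integer(nrow(h)); g <- 1L; grp[1] <- 1L
    curEnd <- h$end[1]
    for (i in seq_len(nrow(h))[-1]) {
      gap <- h$start[i] - curEnd - 1L
      if (gap < mergeGapMax) {
        grp[i] <- g
        curEnd <- max(curEnd, h$end[i])
      } else {
        g <- g + 1L; grp[i] <- g
        curEnd <- h$end[i]
      }
    }
    for (gi in seq_len(g)) {
      m <- h[grp == gi, , drop = FALSE]
      best <- which.max(m$score)
      out[[length(out) + 1L]] <- data.frame(
        contig = m$contig[1], start = min(m$start), end = max(m$end),
        strand = m$strand[best], superfamily = m$superfamily[1],
        family_id = m$family_id[best], n_fragments = nrow(m),
        score = max(m$score),
        length = max(m$end) - min(m$start) + 1L, stringsAsFactors = FALSE)
    }
  }
  ans <- do.call(rbind, out)
  ans <- ans[order(ans$contig, ans$start), , drop = FALSE]
  rownames(ans) <- NULL
  ans
}

#' Assign annotated copies to families by best nucleotide hit
#'
#' Each copy sequence is searched against the family library; the best hit
#' under \code{maxE} determines the family. When that family was defined in
#' another species, the copy is flagged \code{cross_species_candidate} (it
#' may seed a new family in this species); with no qualifying hit the copy
#' is \code{unassigned}.
#'
#' @param copies data.frame from \code{\link{defragmentHits}}.
#' @param genome the scanned \code{DNAStringSet}.
#' @param library a \code{\linkS4class{TEFamilySet}} (assignment database;
#'   typically the scan library plus orphan families).
#' @param species species of the scanned genome.
#' @param maxE E-value ceiling (1e-10 by default).
#' @param scheme calibrated nucleotide scheme.
#' @return \code{copies} with columns \code{assignment} (family id,
#'   \code{"cross_species_candidate"} or \code{"unassigned"}),
#'   \code{assigned_family} and \code{assigned_evalue}.
#' @export
assignFamily <- function(copies, genome, library, species,
                         maxE = 1e-10, scheme = NULL) {
  stopifnot(is(library, "TEFamilySet"))
  if (is.null(scheme)) scheme <- ntScoringScheme()
  info <- familyInfo(library)
  db <- representatives(library)
  assignment <- character(nrow(copies))
  famBest <- character(nrow(copies)); eBest <- numeric(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    seq <- substr(as.character(genome[[copies$contig[i]]]),
                  copies$start[i], copies$end[i])
    hits <- searchHits(seq, db, mode = "nt", scheme = scheme, maxE = maxE,
                       qid = "copy")
    if (nrow(hits) == 0) {
      assignment[i] <- "unassigned"; famBest[i] <- NA_character_
      eBest[i] <- NA_real_
      next
    }
    top <- hits[1, ]
    famBest[i] <- top$subject
    eBest[i] <- top$evalue
    famSpecies <- info$species[match(top$subject, info$family_id)]
    assignment[i] <- if (identical(famSpecies, species)) top$subject
                     else "cross_species_candidate"
  }
  copies$assignment <- assignment
  copies$assigned_family <- famBest
  copies$assigned_evalue <- eBest
  copies
}

#' Promote cross-species candidates to new families
#'
#' Candidates keep only copies with a recognisable, automatically
#' translatable RT/RNaseH domain; survivors are clustered under the
#' 80-80-80 rule into families with origin \code{annotation_derived}.
#'
#' @param candidates data.frame rows of \code{\link{assignFamily}} output
#'   flagged \code{cross_species_candidate}.
#' @param genome the scanned \code{DNAStringSet}.
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param species species label for the new families.
#' @param params a \code{\link{familyParams}} list.
#' @param scheme calibrated amino-acid scheme.
#' @param minDomainAA minimum domain length (aa).
#' @param startIndex first family number per superfamily used in naming.
#' @return a \code{\linkS4class{TEFamilySet}} (possibly empty).
#' @export
promoteAnnotationFamilies <- function(candidates, genome, panel, species,
                                      params = familyParams(), scheme = NULL,
                                      minDomainAA = 100L, startIndex = 1L) {
  if (is.null(scheme)) scheme <- aaScoringScheme()
  if (nrow(candidates) == 0) return(.empty_family_set())
  seqs <- vapply(seq_len(nrow(candidates)), function(i)
    substr(as.character(genome[[candidates$contig[i]]]),
           candidates$start[i], candidates$end[i]), character(1))
  names(seqs) <- sprintf("%s_ann_%03d", species, seq_len(nrow(candidates)))
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    dom <- extractDomain(seqs[[i]], panel, scheme = scheme, maxE = 1e-5)
    keep[i] <- !is.null(dom) && !grepl("*", dom$aa, fixed = TRUE) &&
      nchar(dom$aa) >= minDomainAA
  }
  if (!any(keep)) return(.empty_family_set())
  sets <- list()
  for (sf in unique(candidates$superfamily[keep])) {
    ix <- which(keep & candidates$superfamily == sf)
    cl <- clusterCopies(seqs[ix], params)
    fams <- mergeClusters(seqs[ix], cl, sf, species, params,
                          origin = "annotation_derived")
    # renumber to avoid clashing with existing family ids
    newIds <- sprintf("%s-%d_%s", sf,
                      seq.int(startIndex, length.out = nrow(fams@info)),
                      species)
    old <- fams@info$family_id
    fams@info$family_id <- newIds
    names(fams@representatives) <- newIds
    fams@members$family_id <- newIds[match(fams@members$family_id, old)]
    sets[[length(sets) + 1L]] <- fams
  }
  .bind_family_sets(sets)
}

#' Genomic proportion of annotated copies
#'
#' Per group, the union of copy intervals (overlaps counted once) divided by
#' the genome length, in percent.
#'
#' @param copies data.frame with contig, start, end and the grouping column.
#' @param genomeLength total genome length (bp), > 0.
#' @param groupBy grouping column name (e.g. \code{"superfamily"},
#'   \code{"family_id"} or a clade column).
#' @return data.frame (group, bp, percent).
#' @export
genomicProportion <- function(copies, genomeLength,
                              groupBy = "superfamily") {
  stopifnot(genomeLength > 0)
  if (nrow(copies) == 0)
    return(data.frame(group = character(), bp = integer(),
                      percent = numeric()))
  stopifnot(groupBy %in% names(copies))
  groups <- unique(copies[[groupBy]])
  out <- lapply(groups, function(g) {
    m <- copies[copies[[groupBy]] == g, , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      m$contig, IRanges::IRanges(m$start, m$end)))
    bp <- sum(GenomicRanges::width(gr))
    data.frame(group = g, bp = bp, percent = 100 * bp / genomeLength,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
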