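# De-novo structural detection of paired-LTR elements: exact k-mer seeding
# within the allowed inter-LTR distance window, co-linear chaining into
# maximal repeat pairs, global alignment of the two repeats for identity,
# and parameter-window filtering.

#' Detection parameters
#'
#' The structural search window: LTR length 80-1500 bp, inter-LTR distance
#' 2500-11000 bp and LTR pair identity of at least 80 percent.
#'
#' @param ltrMin,ltrMax allowed LTR length (bp).
#' @param distMin,distMax allowed inter-LTR distance (bp).
#' @param ltrIdentityMin minimum percent identity between the two LTRs.
#' @param seedK exact k-mer seed length.
#' @param maxBand seed-chaining gap tolerance and alignment band pad (bp).
#' @param distanceMode whether the inter-LTR distance is measured
#'   start-to-start (default) or end-to-start; the choice is exposed because
#'   either reading of "distance between LTRs" is defensible.
#' @return a list of class \code{detection_params}.
#' @export
detectionParams <- function(ltrMin = 80L, ltrMax = 1500L, distMin = 2500L,
                            distMax = 11000L, ltrIdentityMin = 80,
                            seedK = 20L, maxBand = 50L,
                            distanceMode = c("start_start", "end_start")) {
  stopifnot(ltrMin > 0, ltrMin <= ltrMax, distMin <= distMax,
            ltrIdentityMin > 0, ltrIdentityMin <= 100, seedK >= 8)
  p <- list(ltrMin = as.integer(ltrMin), ltrMax = as.integer(ltrMax),
            distMin = as.integer(distMin), distMax = as.integer(distMax),
            ltrIdentityMin = ltrIdentityMin, seedK = as.integer(seedK),
            maxBand = as.integer(maxBand),
            distanceMode = match.arg(distanceMode))
  class(p) <- "detection_params"
  p
}

#' Exact k-mer seed pairs at an in-window spacing
#'
#' Reports every pair of identical k-mers in a contig whose start-to-start
#' spacing falls inside the window; direct orientation only. Exhaustive:
#' every in-window repeat pair appears exactly once.
#'
#' @param contig character or \code{DNAString}.
#' @param k k-mer length (>= 8).
#' @param distMin,distMax spacing window (bp).
#' @return integer matrix with columns \code{pos1}, \code{pos2} (1-based
#'   starts, \code{pos1 < pos2}), ordered by (pos1, pos2).
#' @export
findSeedMatches <- function(contig, k = 20L, distMin = 2500L,
                            distMax = 11000L) {
  stopifnot(k >= 8)
  m <- cpp_kmer_pairs_self(toupper(as.character(contig)), as.integer(k),
                           as.integer(distMin), as.integer(distMax))
  colnames(m) <- c("pos1", "pos2")
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Chain seeds and call LTR candidates on one contig
#'
#' Seed pairs are chained along near-constant spacings (diagonal tolerance
#' and positional gap tolerance \code{maxBand}); each chain delimits a
#' repeat pair whose identity is computed by global alignment. Candidates
#' violating any detection bound are discarded, and overlapping candidates
#' are resolved deterministically (higher identity, then longer element,
#' then leftmost start).
#'
#' @param contig character or \code{DNAString}.
#' @param seeds seed matrix from \code{\link{findSeedMatches}} on the same
#'   contig.
#' @param params a \code{\link{detectionParams}} list.
#' @param contigName name used in the output.
#' @return a \code{GRanges} of candidate elements (plus strand; element
#'   strand is resolved later from the best translated hit) with metadata
#'   columns \code{ltr5_start}, \code{ltr5_end}, \code{ltr3_start},
#'   \code{ltr3_end}, \code{ltr_identity}, \code{internal_start},
#'   \code{internal_end}.
#' @export
extendAndCall <- function(contig, seeds, params = detectionParams(),
                          contigName = "contig") {
  x <- toupper(as.character(contig))
  empty <- GenomicRanges::GRanges()
  if (is.null(seeds) || nrow(seeds) == 0) return(empty)
  chains <- .chain_seeds(seeds, params$seedK, diagTol = params$maxBand,
                         gapTol = params$maxBand)
  if (nrow(chains) == 0) return(empty)
  cand <- list()
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i, ]
    len1 <- ch$a_end - ch$a_start + 1L
    len2 <- ch$b_end - ch$b_start + 1L
    if (len1 < params$ltrMin || len1 > params$ltrMax ||
        len2 < params$ltrMin || len2 > params$ltrMax) next
    d <- if (params$distanceMode == "start_start") ch$b_start - ch$a_start
         else ch$b_start - ch$a_end
    if (d < params$distMin || d > params$distMax) next
    if (ch$b_start <= ch$a_end) next   # repeats must not overlap
    id <- ltrPairIdentity(substr(x, ch$a_start, ch$a_end),
                          substr(x, ch$b_start, ch$b_end))
    if (id < params$ltrIdentityMin) next
    cand[[length(cand) + 1L]] <- data.frame(
      start = ch$a_start, end = ch$b_end,
      ltr5_start = ch$a_start, ltr5_end = ch$a_end,
      ltr3_start = ch$b_start, ltr3_end = ch$b_end,
      ltr_identity = id,
      internal_start = ch$a_end + 1L, internal_end = ch$b_start - 1L)
  }
  if (!length(cand)) return(empty)
  df <- do.call(rbind, cand)
  # overlap resolution: identity desc, element length desc, leftmost
  df <- df[order(-df$ltr_identity, -(df$end - df$start), df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) for (j in seq(i + 1L, nrow(df))) {
      if (!keep[j]) next
      if (df$start[j] <= df$end[i] && df$end[j] >= df$start[i]) keep[j] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(contigName,
                               IRanges::IRanges(df$start, df$end),
                               strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, -(1:2)])
  .assert_candidate_bounds(gr, params)
  gr
}

# soundness: every returned candidate satisfies all detection bounds
.assert_candidate_bounds <- function(gr, params) {
  if (!length(gr)) return(invisible(TRUE))
  l5 <- gr$ltr5_end - gr$ltr5_start + 1L
  l3 <- gr$ltr3_end - gr$ltr3_start + 1L
  d <- if (params$distanceMode == "start_start") gr$ltr3_start - gr$ltr5_start
       else gr$ltr3_start - gr$ltr5_end
  stopifnot(all(l5 >= params$ltrMin & l5 <= params$ltrMax),
            all(l3 >= params$ltrMin & l3 <= params$ltrMax),
            all(d >= params$distMin & d <= params$distMax),
            all(gr$ltr_identity >= params$ltrIdentityMin))
  invisible(TRUE)
}

#' Detect candidate LTR retrotransposons in a genome
#'
#' Runs \code{\link{findSeedMatches}} and \code{\link{extendAndCall}} on
#' every contig. Candidates are reported on the plus strand; the element
#' strand is resolved during superfamily classification from the frame of
#' the best translated hit.
#'
#' @param genome a \code{DNAStringSet} of contigs.
#' @param params a \code{\link{detectionParams}} list.
#' @return a \code{GRanges} of candidates across contigs.
#' @examples
#' lib <- buildElementLibrary(seed = 1)
#' pg <- plantCopies(lib, plantSpec(nContigs = 2, contigLength = 120000,
#'                                  copiesPerFamily = 1, seed = 7))
#' detectLTR(genomeSeq(pg))
#' @export
detectLTR <- function(genome, params = detectionParams()) {
  .stopifnot_named(stats::setNames(seq_along(genome), names(genome)), "genome")
  out <- list()
  for (ctg in names(genome)) {
    x <- as.character(genome[[ctg]])
    seeds <- findSeedMatches(x, params$seedK, params$distMin, params$distMax)
    gr <- extendAndCall(x, seeds, params, contigName = ctg)
    if (length(gr)) out[[length(out) + 1L]] <- gr
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, out))
}

#' Orient copies to their coding strand
#'
#' Reverse-complements every copy whose \code{strand} is \code{"-"} (as
#' resolved from the best translated hit), so that family clustering and
#' domain work see all copies in the same orientation.
#'
#' @param copies a \code{\linkS4class{TECopySet}} whose info has a
#'   \code{strand} column.
#' @return the re-oriented \code{\linkS4class{TECopySet}}.
#' @export
orientCopies <- function(copies) {
  stopifnot(is(copies, "TECopySet"))
  info <- copyInfo(copies)
  if (!"strand" %in% colnames(info)) stop("copy info has no strand column")
  seqs <- copySeqs(copies)
  flip <- which(!is.na(info$strand) & info$strand == "-")
  if (length(flip))
    seqs[flip] <- Biostrings::reverseComplement(seqs[flip])
  new("TECopySet", seqs = seqs, info = info)
}

#' Extract candidate element sequences as a copy set
#'
#' @param candidates a \code{GRanges} from \code{\link{detectLTR}}.
#' @param genome the \code{DNAStringSet} the candidates were called on.
#' @param species species label recorded for every copy.
#' @param superfamily optional vector of superfamily labels (recycled).
#' @return a \code{\linkS4class{TECopySet}} with provenance
#'   \code{"structural"}.
#' @export
candidateCopySet <- function(candidates, genome, species = "sp",
                             superfamily = NA_character_) {
  n <- length(candidates)
  ids <- sprintf("%s_cand_%03d", species, seq_len(n))
  seqs <- if (n) Biostrings::DNAStringSet(vapply(seq_len(n), function(i) {
    ctg <- as.character(GenomicRanges::seqnames(candidates))[i]
    substr(as.character(genome[[ctg]]),
           GenomicRanges::start(candidates)[i],
           GenomicRanges::end(candidates)[i])
  }, character(1))) else Biostrings::DNAStringSet()
  names(seqs) <- ids
  info <- S4Vectors::DataFrame(
    copy_id = ids, species = species,
    superfamily = rep(superfamily, length.out = n),
    contig = if (n) as.character(GenomicRanges::seqnames(candidates)) else character(),
    start = GenomicRanges::start(candidates),
    end = GenomicRanges::end(candidates),
    strand = if (n) rep("+", n) else character(),
    provenance = if (n) rep("structural", n) else character())
  new("TECopySet", seqs = seqs, info = info)
}
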