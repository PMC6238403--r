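# Similarity-based clade assignment (five-best-hit rule with an E-value
# gap), database mining with translated search, and chimeric-element
# reconstruction from overlapping fragments.

#' Clade-assignment and mining parameters
#'
#' @param nTopHits the best hits that must agree on one clade (five, after
#'   the published rule).
#' @param evalueGapMin required gap between the best same-clade E-value and
#'   the best other-clade E-value.
#' @param gapMode \code{"arithmetic"} applies the rule exactly as printed
#'   (difference of E-values greater than \code{evalueGapMin});
#'   \code{"log10"} instead requires at least
#'   \code{-log10(evalueGapMin)} orders of magnitude between the two
#'   E-values, which is the reading that stays informative for very strong
#'   hits. The mode used is recorded in the output.
#' @param assignMaxE E-value ceiling for hits considered at all.
#' @param miningMaxE,miningMinCover tBLASTn-style mining thresholds
#'   (E <= 1e-70, query cover > 80 percent).
#' @param copiaMaxE,copiaMinCover relaxed thresholds applied to Copia
#'   queries when mining with \code{relaxedForCopia = TRUE}
#'   (E <= 1e-40, cover > 50 percent).
#' @return a list of class \code{clade_assign_params}.
#' @export
cladeAssignParams <- function(nTopHits = 5L, evalueGapMin = 1e-10,
                              gapMode = c("arithmetic", "log10"),
                              assignMaxE = 1e-5,
                              miningMaxE = 1e-70, miningMinCover = 80,
                              copiaMaxE = 1e-40, copiaMinCover = 50) {
  stopifnot(nTopHits >= 1, evalueGapMin > 0, miningMaxE > 0, copiaMaxE > 0)
  p <- list(nTopHits = as.integer(nTopHits), evalueGapMin = evalueGapMin,
            gapMode = match.arg(gapMode), assignMaxE = assignMaxE,
            miningMaxE = miningMaxE, miningMinCover = miningMinCover,
            copiaMaxE = copiaMaxE, copiaMinCover = copiaMinCover)
  class(p) <- "clade_assign_params"
  p
}

#' Assign a domain to a clade by the five-best-hit rule
#'
#' The query domain is searched against a database of clade-labelled
#' RT/RNaseH sequences. It is assigned to clade X when (i) the
#' \code{nTopHits} best hits are all labelled X, and (ii) the best E-value
#' from any other clade is separated from the best X E-value by more than
#' \code{evalueGapMin} (arithmetic difference by default, or the log10
#' reading; when no other clade has any hit the clause passes vacuously).
#'
#' @param domain an amino-acid sequence (character or \code{AAString}).
#' @param db an \code{AAStringSet} of labelled reference domains.
#' @param dbClades named character vector: db sequence id -> clade.
#' @param params a \code{\link{cladeAssignParams}} list.
#' @param scheme calibrated amino-acid scheme.
#' @return list with \code{clade} (label or \code{"unassigned"}),
#'   \code{reason}, \code{gap_mode}, \code{top_hits} (data.frame) and
#'   \code{e_gap} (the realised gap, arithmetic or log10 according to mode).
#' @export
assignBySimilarity <- function(domain, db, dbClades,
                               params = cladeAssignParams(), scheme = NULL) {
  if (length(db) == 0) stop("classified database must be non-empty")
  if (is.null(scheme)) scheme <- aaScoringScheme()
  hits <- .aa_search(domain, db, scheme, params$assignMaxE)
  if (nrow(hits) == 0)
    return(list(clade = "unassigned", reason = "no_hits",
                gap_mode = params$gapMode, top_hits = hits, e_gap = NA_real_))
  hits$clade <- unname(dbClades[hits$subject])
  top <- utils::head(hits, params$nTopHits)
  if (length(unique(top$clade)) != 1L)
    return(list(clade = "unassigned", reason = "mixed_top_hits",
                gap_mode = params$gapMode, top_hits = top, e_gap = NA_real_))
  cl <- top$clade[1]
  otherIdx <- which(hits$clade != cl)
  if (!length(otherIdx)) {
    return(list(clade = cl, reason = "assigned_vacuous_gap",
                gap_mode = params$gapMode, top_hits = top, e_gap = Inf))
  }
  bestSame <- hits[hits$clade == cl, ][1, ]
  bestOther <- hits[otherIdx[1], ]
  if (params$gapMode == "arithmetic") {
    gap <- bestOther$evalue - bestSame$evalue
    ok <- gap > params$evalueGapMin
  } else {
    gap <- bestOther$log10_evalue - bestSame$log10_evalue
    ok <- gap >= -log10(params$evalueGapMin)
  }
  if (ok)
    list(clade = cl, reason = "assigned", gap_mode = params$gapMode,
         top_hits = top, e_gap = gap)
  else
    list(clade = "unassigned", reason = "insufficient_evalue_gap",
         gap_mode = params$gapMode, top_hits = top, e_gap = gap)
}

# direct amino-acid vs amino-acid search (no translation)
.aa_search <- function(query, db, scheme, maxE) {
  qChar <- as.character(query)
  m <- nchar(qChar)
  n <- sum(nchar(as.character(db)))
  rows <- list()
  for (s in names(db)) {
    h <- .best_local_hit(qChar, as.character(db[[s]]), scheme)
    if (is.null(h)) next
    rows[[length(rows) + 1L]] <-
      .hit_row("query", s, h, 0L, m, m, n, scheme)
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
  out <- out[out$evalue <= maxE, , drop = FALSE]
  out <- out[order(out$evalue, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine a sequence collection for RT/RNaseH-bearing elements
#'
#' Translated (tBLASTn-style) search of clade-representative domain queries
#' against a nucleotide collection (transcripts, ESTs, assemblies). Hits
#' passing the E-value and query-coverage thresholds (relaxed for Copia
#' queries when \code{relaxedForCopia}) contribute their translated subject
#' envelope as a candidate domain; candidates are clustered under the
#' 80-80-80 rule per superfamily and the largest sequence represents each
#' mined family.
#'
#' @param queries an \code{AAStringSet} of domain queries.
#' @param querySuperfamily named character vector: query id -> superfamily.
#' @param collection a \code{DNAStringSet}.
#' @param params a \code{\link{cladeAssignParams}} list.
#' @param scheme calibrated amino-acid scheme.
#' @param relaxedForCopia apply the relaxed Copia thresholds.
#' @param familyParamsList 80-80-80 parameters for candidate clustering.
#' @return list with \code{candidates} (data.frame: id, superfamily,
#'   collection entry, nt coordinates, frame, aa sequence) and
#'   \code{families} (data.frame: family_id, superfamily, representative aa,
#'   n_members).
#' @export
mineDatabase <- function(queries, querySuperfamily, collection,
                         params = cladeAssignParams(), scheme = NULL,
                         relaxedForCopia = TRUE,
                         familyParamsList = familyParams()) {
  if (is.null(scheme)) scheme <- aaScoringScheme()
  empty <- list(candidates = data.frame(), families = data.frame())
  if (length(collection) == 0) {
    empty$candidates <- data.frame(id = character(), superfamily = character(),
                                   subject = character(), nt_start = integer(),
                                   nt_end = integer(), frame = integer(),
                                   aa = character())
    empty$families <- data.frame(family_id = character(),
                                 superfamily = character(), aa = character(),
                                 n_members = integer())
    return(empty)
  }
  cand <- list()
  for (q in names(queries)) {
    sf <- unname(querySuperfamily[q])
    relaxed <- relaxedForCopia && identical(sf, "Copia")
    maxE <- if (relaxed) params$copiaMaxE else params$miningMaxE
    minCov <- if (relaxed) params$copiaMinCover else params$miningMinCover
    hits <- searchHits(queries[[q]], collection, mode = "translated",
                       scheme = scheme, maxE = maxE, minCoverage = minCov,
                       qid = q)
    if (nrow(hits) == 0) next
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      frames <- sixFrameTranslate(collection[[h$subject]])
      fa <- as.character(frames[[sprintf("%+d", h$frame)]])
      # recover the aa envelope on the subject frame
      sw <- smithWaterman(as.character(queries[[q]]), fa, scheme)
      aaseg <- substr(fa, sw$b_start, sw$b_end)
      cand[[length(cand) + 1L]] <- data.frame(
        id = sprintf("%s|%s", h$subject, q), superfamily = sf,
        subject = h$subject, nt_start = h$sstart, nt_end = h$send,
        frame = h$frame, aa = aaseg, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    return(mineDatabase(queries, querySuperfamily,
                        Biostrings::DNAStringSet(), params, scheme))
  }
  cand <- do.call(rbind, cand)
  # one candidate per collection entry and superfamily (best envelope kept)
  cand <- cand[!duplicated(paste(cand$subject, cand$superfamily)), , drop = FALSE]
  fams <- list()
  for (sf in unique(cand$superfamily)) {
    m <- cand[cand$superfamily == sf, , drop = FALSE]
    seqs <- stats::setNames(m$aa, m$id)
    cl <- clusterCopies(seqs, familyParamsList)
    for (g in sort(unique(cl))) {
      mem <- which(cl == g)
      rep <- mem[which.max(nchar(seqs[mem]))]
      fams[[length(fams) + 1L]] <- data.frame(
        family_id = sprintf("%s-mined-%d", sf, g), superfamily = sf,
        aa = unname(seqs[rep]), n_members = length(mem),
        stringsAsFactors = FALSE)
    }
  }
  list(candidates = cand, families = do.call(rbind, fams))
}

#' Reconstruct a chimeric element from overlapping fragments
#'
#' Merges fragments of one family's domain (e.g. from several incomplete
#' copies) into a single sequence. Fragments must chain by overlaps of at
#' least \code{minOverlap} residues at \code{minIdentity} percent or better;
#' disagreements inside overlaps are resolved by majority, ties by the
#' earliest-placed fragment.
#'
#' @param fragments an \code{AAStringSet} or character vector (>= 2).
#' @param minOverlap minimum overlap length (aa).
#' @param minIdentity minimum percent identity inside the overlap.
#' @param scheme calibrated amino-acid scheme.
#' @return the merged sequence (character).
#' @export
buildChimericElement <- function(fragments, minOverlap = 20L,
                                 minIdentity = 90, scheme = NULL) {
  frags <- as.character(fragments)
  names(frags) <- names(fragments)
  if (length(frags) < 2) stop("need at least 2 fragments")
  if (is.null(names(frags))) names(frags) <- paste0("frag", seq_along(frags))
  if (is.null(scheme)) scheme <- aaScoringScheme()
  # seed the layout with the longest fragment
  ord <- order(-nchar(frags))
  placed <- list(list(offset = 0L, seq = frags[[ord[1]]], idx = ord[1]))
  pending <- ord[-1]
  consensus <- function() {
    lo <- min(vapply(placed, function(p) p$offset, integer(1)))
    hi <- max(vapply(placed, function(p) p$offset + nchar(p$seq) - 1L,
                     integer(1)))
    width <- hi - lo + 1L
    votes <- matrix("", length(placed), width)
    for (k in seq_along(placed)) {
      p <- placed[[k]]
      at <- (p$offset - lo + 1L):(p$offset - lo + nchar(p$seq))
      votes[k, at] <- .seq_chars(p$seq)
    }
    cons <- apply(votes, 2, function(col) {
      col <- col[col != ""]
      tb <- table(col)
      mx <- names(tb)[tb == max(tb)]
      if (length(mx) == 1) mx else col[col %in% mx][1]  # earliest fragment wins
    })
    list(seq = paste(cons, collapse = ""), lo = lo)
  }
  while (length(pending)) {
    cns <- consensus()
    best <- NULL; bestScore <- -Inf; bestIdx <- NA_integer_
    for (pi in pending) {
      sw <- smithWaterman(frags[[pi]], cns$seq, scheme)
      if (sw$score > bestScore) { bestScore <- sw$score; best <- sw; bestIdx <- pi }
    }
    ident <- 100 * best$n_match / max(best$n_cols, 1L)
    if (best$n_cols < minOverlap || ident < minIdentity)
      stop("fragment ", names(frags)[bestIdx],
           " does not overlap the assembly by >= ", minOverlap,
           " aa at >= ", minIdentity, "% identity (gap in the tiling)")
    offset <- cns$lo + (best$b_start - 1L) - (best$a_start - 1L)
    placed[[length(placed) + 1L]] <- list(offset = offset,
                                          seq = frags[[bestIdx]],
                                          idx = bestIdx)
    pending <- setdiff(pending, bestIdx)
  }
  consensus()$seq
}
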