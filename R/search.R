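# Local-alignment search engine: seeded nucleotide search, translated
# (six-frame) search, superfamily classification and tandem-repeat masking.

# Chain co-linear seed matches. seeds: 2-col matrix (pos_a, pos_b), 1-based.
# Seeds join a chain when their diagonal (pos_b - pos_a) is within diagTol of
# the chain's last diagonal and their pos_a gap is at most gapTol.
# Returns a data.frame, one row per chain.
.chain_seeds <- function(seeds, k, diagTol, gapTol) {
  if (nrow(seeds) == 0)
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      n_seeds = integer(), diag_lo = integer(),
                      diag_hi = integer()))
  ord <- order(seeds[, 1], seeds[, 2])
  pa <- seeds[ord, 1]; pb <- seeds[ord, 2]
  dg <- pb - pa
  n <- length(pa)
  chain_id <- integer(n)
  # active chains: last pos_a, last diag, id
  act_pa <- integer(0); act_dg <- integer(0); act_id <- integer(0)
  nxt <- 0L
  for (i in seq_len(n)) {
    keep <- act_pa >= pa[i] - gapTol
    act_pa <- act_pa[keep]; act_dg <- act_dg[keep]; act_id <- act_id[keep]
    hit <- which(abs(act_dg - dg[i]) <= diagTol & act_pa <= pa[i])
    if (length(hit)) {
      j <- hit[which.min(abs(act_dg[hit] - dg[i]))]
      chain_id[i] <- act_id[j]
      act_pa[j] <- pa[i]; act_dg[j] <- dg[i]
    } else {
      nxt <- nxt + 1L
      chain_id[i] <- nxt
      act_pa <- c(act_pa, pa[i]); act_dg <- c(act_dg, dg[i])
      act_id <- c(act_id, nxt)
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(n), chain_id), function(ix) {
    data.frame(a_start = min(pa[ix]), a_end = max(pa[ix]) + k - 1L,
               b_start = min(pb[ix]), b_end = max(pb[ix]) + k - 1L,
               n_seeds = length(ix), diag_lo = min(dg[ix]),
               diag_hi = max(dg[ix]))
  }))
  rownames(out) <- NULL
  out
}

# Seed-and-extend local hits of `query` inside `subject` (both nt character).
# Each seed chain is refined by a banded local alignment of the full query
# against a padded subject window. Returns all (deduplicated) hits.
.seeded_local_hits <- function(query, subject, scheme, k = 12L,
                               diagTol = 60L, gapTol = 400L, pad = 200L,
                               minChainSeeds = 2L, minLen = 40L) {
  cq <- .codes(query, scheme); cs <- .codes(subject, scheme)
  nq <- length(cq); ns <- length(cs)
  seeds <- if (scheme@type == "nt") cpp_kmer_matches(query, subject, k)
           else cpp_kmer_matches_gen(query, subject, k)
  empty <- data.frame(qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      score = numeric(), n_match = integer(),
                      n_cols = integer(), n_gapcols = integer(),
                      gapopens = integer())
  if (nrow(seeds) == 0) return(empty)
  chains <- .chain_seeds(seeds, k, diagTol, gapTol)
  chains <- chains[chains$n_seeds >= minChainSeeds |
                     (chains$a_end - chains$a_start + 1L) >= minLen, , drop = FALSE]
  if (nrow(chains) == 0) return(empty)
  hits <- vector("list", nrow(chains))
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i, ]
    ws <- max(1L, ch$b_start - (ch$a_start - 1L) - pad)
    we <- min(ns, ch$b_end + (nq - ch$a_end) + pad)
    win <- cs[ws:we]
    # window the query symmetrically so the DP size tracks the chain
    qws <- max(1L, ch$a_start - (ch$b_start - 1L) - pad)
    qwe <- min(nq, ch$a_end + (ns - ch$b_end) + pad)
    qwin <- cq[qws:qwe]
    dlo <- ch$diag_lo + (qws - ws) - 100L
    dhi <- ch$diag_hi + (qws - ws) + 100L
    res <- cpp_pair_align(qwin, win, scheme@matrix, scheme@gapOpen,
                          scheme@gapExtend, TRUE, dlo, dhi)
    if (res$n_cols < minLen || res$score <= 0) next
    gaps <- res$path_a == 0L | res$path_b == 0L
    hits[[i]] <- data.frame(
      qstart = qws + res$a_start - 1L, qend = qws + res$a_end - 1L,
      sstart = ws + res$b_start - 1L, send = ws + res$b_end - 1L,
      score = res$score, n_match = res$n_match, n_cols = res$n_cols,
      n_gapcols = sum(gaps), gapopens = nrow(.true_runs(gaps)))
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  # deduplicate hits covering the same subject stretch (keep best score)
  hits <- hits[order(-hits$score, hits$sstart), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) for (j in seq(i + 1L, nrow(hits))) {
      if (!keep[j]) next
      ov <- min(hits$send[i], hits$send[j]) - max(hits$sstart[i], hits$sstart[j]) + 1L
      lj <- hits$send[j] - hits$sstart[j] + 1L
      if (ov > 0.5 * lj) keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# best local hit between two sequences given codes; full DP for small
# problems, seeded otherwise
.best_local_hit <- function(query, subject, scheme, fullLimit = NULL) {
  nq <- nchar(query); ns <- nchar(subject)
  if (is.null(fullLimit))
    fullLimit <- if (scheme@type == "aa") 1.2e5 else 4e6
  if (as.numeric(nq) * ns <= fullLimit) {
    res <- smithWaterman(query, subject, scheme)
    if (res$n_cols == 0) return(NULL)
    gaps <- res$path_a == 0L | res$path_b == 0L
    return(data.frame(qstart = res$a_start, qend = res$a_end,
                      sstart = res$b_start, send = res$b_end,
                      score = res$score, n_match = res$n_match,
                      n_cols = res$n_cols, n_gapcols = sum(gaps),
                      gapopens = nrow(.true_runs(gaps))))
  }
  k <- if (scheme@type == "aa") 4L else 12L
  h <- .seeded_local_hits(query, subject, scheme, k = k,
                          minChainSeeds = 1L,
                          minLen = if (scheme@type == "aa") 15L else 40L)
  if (nrow(h) == 0) return(NULL)
  h[which.max(h$score), , drop = FALSE]
}

.hit_row <- function(qid, sid, h, frame, qlen, m, n, scheme, qUnitsNt = FALSE,
                     sUnitsNt = FALSE, qNtLen = NA, sNtLen = NA) {
  qs <- h$qstart; qe <- h$qend; ss <- h$sstart; se <- h$send
  if (qUnitsNt) { co <- .frame_to_nt(frame, h$qstart, h$qend, qNtLen); qs <- co[1]; qe <- co[2] }
  if (sUnitsNt) { co <- .frame_to_nt(frame, h$sstart, h$send, sNtLen); ss <- co[1]; se <- co[2] }
  span <- if (qUnitsNt) abs(qe - qs) + 1L else qe - qs + 1L
  data.frame(query = qid, subject = sid,
             pident = 100 * h$n_match / h$n_cols, length = h$n_cols,
             mismatches = h$n_cols - h$n_gapcols - h$n_match,
             gapopens = h$gapopens,
             qstart = qs, qend = qe, sstart = ss, send = se,
             evalue = evalueOf(h$score, m, n, scheme),
             bitscore = bitScoreOf(h$score, scheme),
             score = h$score, frame = frame,
             coverage = 100 * span / qlen,
             log10_evalue = .log10_evalue(h$score, m, n, scheme),
             stringsAsFactors = FALSE)
}

#' Search a query against a sequence database
#'
#' Local-alignment search with analytic Karlin-Altschul E-values, in
#' nucleotide mode (query and database both DNA) or translated mode (DNA
#' query against a protein database, frames on the query, as in BLASTx; or
#' protein query against a DNA database, frames on the subjects, as in
#' tBLASTn). Translated mode reports the best frame per subject.
#'
#' @param query a single sequence (character or \code{XString}).
#' @param db an \code{XStringSet} (or named character vector) of subjects.
#' @param mode \code{"nt"} or \code{"translated"}.
#' @param scheme calibrated scoring scheme matching the comparison alphabet
#'   (amino acid for translated mode); defaults are built when \code{NULL}.
#' @param maxE report hits with E-value at most this.
#' @param minCoverage minimum aligned query coverage in percent.
#' @param qid query id used in the output.
#' @return a data.frame in tabular-BLAST style (query, subject, pident,
#'   length, mismatches, gapopens, qstart, qend, sstart, send, evalue,
#'   bitscore) plus \code{score}, \code{frame} (0 in nt mode),
#'   \code{coverage} and \code{log10_evalue}, sorted by ascending E-value
#'   then descending score. Empty database yields an empty table.
#' @export
searchHits <- function(query, db, mode = c("nt", "translated"), scheme = NULL,
                       maxE = 10, minCoverage = 0, qid = "query") {
  mode <- match.arg(mode)
  if (length(db) == 0) return(.empty_hits())
  .stopifnot_named(stats::setNames(seq_along(db), names(db)), "db")
  dbChar <- as.character(db)
  n <- sum(nchar(dbChar))
  rows <- list()
  qChar <- as.character(query)
  isDNAq <- .looks_dna(qChar)
  if (mode == "nt") {
    if (is.null(scheme)) scheme <- ntScoringScheme()
    m <- nchar(qChar)
    for (s in names(dbChar)) {
      h <- .best_local_hit(qChar, dbChar[[s]], scheme)
      if (is.null(h)) next
      rows[[length(rows) + 1L]] <-
        .hit_row(qid, s, h, 0L, m, m, n, scheme)
    }
  } else {
    if (is.null(scheme)) scheme <- aaScoringScheme()
    if (isDNAq) {
      # blastx-like: translate the query
      frames <- sixFrameTranslate(qChar)
      qNtLen <- nchar(qChar)
      m <- qNtLen %/% 3L
      for (s in names(dbChar)) {
        best <- NULL; bestFrame <- NA_integer_
        for (fn in names(frames)) {
          fa <- as.character(frames[[fn]])
          if (nchar(fa) == 0) next
          h <- .best_local_hit(fa, dbChar[[s]], scheme)
          if (!is.null(h) && (is.null(best) || h$score > best$score)) {
            best <- h; bestFrame <- as.integer(fn)
          }
        }
        if (is.null(best)) next
        rows[[length(rows) + 1L]] <-
          .hit_row(qid, s, best, bestFrame, qNtLen, m, n, scheme,
                   qUnitsNt = TRUE, qNtLen = qNtLen)
      }
    } else {
      # tblastn-like: translate the subjects
      m <- nchar(qChar)
      for (s in names(dbChar)) {
        sNtLen <- nchar(dbChar[[s]])
        frames <- sixFrameTranslate(dbChar[[s]])
        best <- NULL; bestFrame <- NA_integer_
        for (fn in names(frames)) {
          fa <- as.character(frames[[fn]])
          if (nchar(fa) == 0) next
          h <- .best_local_hit(qChar, fa, scheme)
          if (!is.null(h) && (is.null(best) || h$score > best$score)) {
            best <- h; bestFrame <- as.integer(fn)
          }
        }
        if (is.null(best)) next
        rows[[length(rows) + 1L]] <-
          .hit_row(qid, s, best, bestFrame, m, m, n, scheme,
                   sUnitsNt = TRUE, sNtLen = sNtLen)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
  out <- out[out$evalue <= maxE & out$coverage >= minCoverage, , drop = FALSE]
  out <- out[order(out$evalue, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(query = character(), subject = character(), pident = numeric(),
             length = integer(), mismatches = integer(), gapopens = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             score = numeric(), frame = integer(), coverage = numeric(),
             log10_evalue = numeric(), stringsAsFactors = FALSE)
}

.looks_dna <- function(x) {
  ch <- unique(.seq_chars(substr(x, 1, 200)))
  all(ch %in% c("A", "C", "G", "T", "N", "-"))
}

#' Classify candidate elements into superfamilies
#'
#' Translated search of each candidate sequence against the labelled
#' RT/RNaseH reference panel; the superfamily of the single best hit is the
#' call, and the element strand is the sign of the best frame. Candidates
#' with no hit under \code{maxE} are returned as \code{"unclassified"}.
#'
#' @param x a \code{DNAStringSet} (or named character vector) of candidate
#'   sequences.
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param scheme calibrated amino-acid scheme (default BLOSUM62 11/1).
#' @param maxE E-value ceiling for an informative hit.
#' @return data.frame with columns \code{id}, \code{superfamily},
#'   \code{strand} (\code{+}, \code{-} or \code{NA}), \code{best_ref},
#'   \code{evalue}, \code{frame}.
#' @export
classifySuperfamily <- function(x, panel, scheme = NULL, maxE = 1e-5) {
  stopifnot(is(panel, "ReferencePanel"))
  if (is.null(scheme)) scheme <- aaScoringScheme()
  if (is.null(names(x))) names(x) <- paste0("cand_", seq_along(x))
  labs <- panelLabels(panel)
  res <- lapply(names(x), function(id) {
    hits <- searchHits(x[[id]], panelSeqs(panel), mode = "translated",
                       scheme = scheme, maxE = maxE, qid = id)
    if (nrow(hits) == 0)
      return(data.frame(id = id, superfamily = "unclassified",
                        strand = NA_character_, best_ref = NA_character_,
                        evalue = NA_real_, frame = NA_integer_,
                        stringsAsFactors = FALSE))
    top <- hits[1, ]
    data.frame(id = id,
               superfamily = labs$superfamily[match(top$subject, labs$id)],
               strand = if (top$frame > 0) "+" else "-",
               best_ref = top$subject, evalue = top$evalue,
               frame = top$frame, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Mask tandem repeats
#'
#' Period-scan tandem-array detector: for each period p in
#' [\code{minPeriod}, \code{maxPeriod}], positions where the sequence equals
#' itself shifted by p over a window of (\code{minCopies}-1) * p positions at
#' \code{minIdentity} percent or better are called part of a tandem array.
#' Arrays are masked with \code{N}. This is a deliberately simple stand-in
#' for a dedicated tandem-repeat finder; exact parity with external tools is
#' not a goal.
#'
#' @param seq character or \code{DNAString}.
#' @param minPeriod,maxPeriod period range scanned (bp).
#' @param minCopies minimum number of repeat units.
#' @param minIdentity minimum percent identity between adjacent units.
#' @param minArrayLen minimum masked array span (bp); short-period chance
#'   repeats below this length are left alone.
#' @return list with \code{masked} (character) and \code{intervals}
#'   (data.frame start, end, period).
#' @export
maskTandemRepeats <- function(seq, minPeriod = 1L, maxPeriod = 50L,
                              minCopies = 3L, minIdentity = 80,
                              minArrayLen = 24L) {
  x <- toupper(as.character(seq))
  n <- nchar(x)
  empty <- data.frame(start = integer(), end = integer(), period = integer())
  if (n == 0) return(list(masked = "", intervals = empty))
  v <- .seq_chars(x)
  ivs <- list()
  for (p in seq(minPeriod, maxPeriod)) {
    w <- (minCopies - 1L) * p
    if (n - p < w) next
    eq <- v[seq_len(n - p)] == v[seq(p + 1L, n)]
    cs <- cumsum(c(0L, eq))
    wins <- cs[(w + 1L):(n - p + 1L)] - cs[1:(n - p + 1L - w)]
    ok <- wins >= ceiling(w * minIdentity / 100)
    if (!any(ok)) next
    runs <- .true_runs(ok)
    for (r in seq_len(nrow(runs))) {
      span <- c(runs[r, 1], runs[r, 2] + w + p - 1L)
      if (span[2] - span[1] + 1L >= minArrayLen)
        ivs[[length(ivs) + 1L]] <- c(span, p)
    }
  }
  if (!length(ivs)) return(list(masked = x, intervals = empty))
  m <- do.call(rbind, ivs)
  ir <- IRanges::reduce(IRanges::IRanges(m[, 1], pmin(m[, 2], n)))
  for (i in seq_along(ir))
    v[IRanges::start(ir)[i]:IRanges::end(ir)[i]] <- "N"
  list(masked = paste(v, collapse = ""),
       intervals = data.frame(start = m[, 1], end = pmin(m[, 2], n),
                              period = m[, 3]))
}
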