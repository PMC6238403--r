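# Pairwise alignment wrappers around the C++ kernels.

# low-level: align two code vectors; band given as diagonal range, or NULL
.pair_align_codes <- function(ca, cb, scheme, local, band = NULL) {
  if (is.null(band)) {
    dlo <- 1L; dhi <- 0L        # unbanded sentinel
  } else {
    dlo <- as.integer(band[1]); dhi <- as.integer(band[2])
  }
  cpp_pair_align(ca, cb, scheme@matrix, scheme@gapOpen, scheme@gapExtend,
                 local, dlo, dhi)
}

# proportional band covering all paths between similar-length sequences
.global_band <- function(la, lb, pad = 150L) {
  c(min(0L, lb - la) - pad, max(0L, lb - la) + pad)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Full dynamic-programming local alignment of two sequences under a scoring
#' scheme. Used as the alignment kernel of the search engine; exposed for
#' direct use and for oracle testing.
#'
#' @param a,b character strings or \code{XString}s over the scheme alphabet.
#' @param scheme a \code{\linkS4class{ScoringScheme}} (defaults to the
#'   calibrated amino-acid scheme if both inputs look like protein, else the
#'   nucleotide scheme).
#' @return a list with \code{score}, 1-based spans \code{a_start}, \code{a_end},
#'   \code{b_start}, \code{b_end}, \code{n_match}, \code{n_cols} (alignment
#'   columns including gaps) and the aligned position vectors \code{path_a},
#'   \code{path_b} (0 marks a gap).
#' @examples
#' sw <- smithWaterman("MKLVLL", "MKLVLL", aaScoringScheme())
#' sw$score
#' @export
smithWaterman <- function(a, b, scheme) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  ca <- .codes(a, scheme); cb <- .codes(b, scheme)
  .pair_align_codes(ca, cb, scheme, local = TRUE)
}

# banded global alignment returning identity statistics over the aligned
# region (terminal gap runs trimmed); used by the 80-80-80 comparator
.global_stats <- function(a, b, scheme, pad = 150L) {
  ca <- .codes(a, scheme); cb <- .codes(b, scheme)
  res <- .pair_align_codes(ca, cb, scheme, local = FALSE,
                           band = .global_band(length(ca), length(cb), pad))
  pa <- res$path_a; pb <- res$path_b
  both <- which(pa > 0L & pb > 0L)
  if (!length(both))
    return(list(identity = 0, overlap = 0L, a_span = c(0L, 0L),
                b_span = c(0L, 0L), n_match = 0L))
  rng <- range(both)
  cols <- seq(rng[1], rng[2])
  aligned <- pa[cols] > 0L & pb[cols] > 0L
  nmatch <- sum(aligned & ca[pmax(pa[cols], 1L)] == cb[pmax(pb[cols], 1L)])
  list(identity = 100 * nmatch / length(cols),
       overlap = length(cols),
       a_span = range(pa[cols][pa[cols] > 0L]),
       b_span = range(pb[cols][pb[cols] > 0L]),
       n_match = nmatch)
}

#' Percent identity between two LTR sequences
#'
#' Identity of the optimal global alignment, counting matching columns over
#' all aligned columns (gap columns count as mismatch). Symmetric and in
#' [0, 100].
#'
#' @param ltr5,ltr3 the two repeat sequences (character or \code{DNAString}).
#' @return percent identity.
#' @examples
#' ltrPairIdentity("ACGTACGT", "ACGTACGT")  # 100
#' @export
ltrPairIdentity <- function(ltr5, ltr3) {
  a <- as.character(ltr5); b <- as.character(ltr3)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  scheme <- .identity_scheme()
  ca <- .codes(a, scheme); cb <- .codes(b, scheme)
  res <- .pair_align_codes(ca, cb, scheme, local = FALSE)
  100 * res$n_match / res$n_cols
}

# simple +1/-1 scheme used for identity-centric global alignments
.identity_scheme_cache <- new.env(parent = emptyenv())
.identity_scheme <- function() {
  if (is.null(.identity_scheme_cache$s))
    .identity_scheme_cache$s <- ntScoringScheme(match = 1, mismatch = -1,
                                                gapOpen = 2, gapExtend = 1)
  .identity_scheme_cache$s
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Stop codons are rendered as \code{*}; frames -1 to
#' -3 read the reverse complement. Trailing partial codons are dropped.
#'
#' @param nuc a character string or \code{DNAString}.
#' @return an \code{AAStringSet} of up to six entries named
#'   \code{"+1" ... "-3"}; frames shorter than one codon are omitted.
#' @export
sixFrameTranslate <- function(nuc) {
  x <- Biostrings::DNAString(as.character(nuc))
  rc <- Biostrings::reverseComplement(x)
  out <- list()
  for (f in 1:3) {
    for (strand in c(1, -1)) {
      src <- if (strand > 0) x else rc
      n <- length(src) - f + 1L
      if (n < 3) next
      sub <- Biostrings::subseq(src, start = f, width = (n %/% 3L) * 3L)
      aa <- suppressWarnings(Biostrings::translate(sub, if.fuzzy.codon = "X"))
      out[[sprintf("%+d", strand * f)]] <- aa
    }
  }
  if (!length(out)) return(Biostrings::AAStringSet())
  res <- Biostrings::AAStringSet(unlist(lapply(out, as.character)))
  names(res) <- names(out)
  res[order(match(names(res), c("+1", "+2", "+3", "-1", "-2", "-3")))]
}

# translated query coordinates (aa, within frame) -> nucleotide coordinates
# on the forward strand of the original sequence
.frame_to_nt <- function(frame, aaStart, aaEnd, ntLen) {
  f <- abs(frame)
  if (frame > 0) {
    c(f + 3L * (aaStart - 1L), f + 3L * aaEnd - 1L)
  } else {
    # position p on reverse complement maps to ntLen - p + 1 on forward
    rcs <- f + 3L * (aaStart - 1L)
    rce <- f + 3L * aaEnd - 1L
    c(ntLen - rce + 1L, ntLen - rcs + 1L)
  }
}
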