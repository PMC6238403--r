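#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Scoring scheme with Karlin-Altschul statistics
#'
#' Holds a substitution matrix, affine gap penalties and, once calibrated,
#' the Karlin-Altschul parameters lambda and K used to convert raw local
#' alignment scores into E-values. A gap of length k costs
#' \code{gapOpen + k * gapExtend}.
#'
#' @slot type either \code{"nt"} or \code{"aa"}.
#' @slot matrix named square substitution matrix.
#' @slot gapOpen,gapExtend non-negative gap penalties.
#' @slot lambda,K Karlin-Altschul scale and prefactor (\code{NA} until
#'   \code{\link{calibrateScheme}} is called).
#' @slot bg named background frequencies over (a subset of) the matrix
#'   alphabet; must sum to 1.
#'
#' @seealso \code{\link{ntScoringScheme}}, \code{\link{aaScoringScheme}},
#'   \code{\link{calibrateScheme}}, \code{\link{evalueOf}}
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(type = "character", matrix = "matrix",
                 gapOpen = "numeric", gapExtend = "numeric",
                 lambda = "numeric", K = "numeric", bg = "numeric"),
  prototype(lambda = NA_real_, K = NA_real_))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (!object@type %in% c("nt", "aa"))
    msg <- c(msg, "type must be 'nt' or 'aa'")
  if (is.null(rownames(object@matrix)) ||
      !identical(rownames(object@matrix), colnames(object@matrix)))
    msg <- c(msg, "matrix must be square with identical row/col names")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    msg <- c(msg, "gap penalties must be non-negative")
  if (length(object@bg)) {
    if (is.null(names(object@bg)) || !all(names(object@bg) %in% rownames(object@matrix)))
      msg <- c(msg, "bg names must be matrix alphabet letters")
    if (abs(sum(object@bg) - 1) > 1e-6)
      msg <- c(msg, "bg must sum to 1")
  }
  if (!is.na(object@lambda) && object@lambda <= 0)
    msg <- c(msg, "lambda must be positive")
  if (!is.na(object@K) && object@K <= 0)
    msg <- c(msg, "K must be positive")
  if (length(msg)) msg else TRUE
})

#' Labelled RT/RNaseH reference panel
#'
#' Amino-acid RT/RNaseH sequences, each labelled with its superfamily
#' (Copia, BELPao or Gypsy) and optionally a clade. Used for superfamily
#' classification of candidates, orphan validation, domain extraction and
#' similarity-based clade assignment.
#'
#' @slot seqs an \code{AAStringSet}; names are panel sequence ids.
#' @slot labels a \code{DataFrame} with columns \code{id}, \code{superfamily}
#'   and \code{clade} (clade may be \code{NA}), one row per sequence.
#'
#' @exportClass ReferencePanel
setClass("ReferencePanel",
  representation(seqs = "AAStringSet", labels = "DataFrame"))

setValidity("ReferencePanel", function(object) {
  msg <- character()
  if (length(object@seqs) != nrow(object@labels))
    msg <- c(msg, "one label row per sequence required")
  if (!all(c("id", "superfamily", "clade") %in% colnames(object@labels)))
    msg <- c(msg, "labels must have columns id, superfamily, clade")
  else {
    if (!identical(as.character(object@labels$id), names(object@seqs)))
      msg <- c(msg, "labels$id must match sequence names in order")
    if (any(!object@labels$superfamily %in% c("Copia", "BELPao", "Gypsy")))
      msg <- c(msg, "superfamily labels must be Copia, BELPao or Gypsy")
  }
  if (length(msg)) msg else TRUE
})

#' Library of element blueprints for the synthetic generator
#'
#' One blueprint per family: an LTR sequence, an internal sequence and the
#' coordinates of the RT/RNaseH coding region inside the internal sequence.
#' Copia blueprints place the integrase upstream of RT, Gypsy and BEL/Pao
#' place it downstream of RNaseH.
#'
#' @slot info \code{DataFrame} with one row per family: \code{family_id},
#'   \code{clade_id}, \code{superfamily}, \code{ltr_len}, \code{internal_len},
#'   \code{rt_start}, \code{rt_end} (1-based nucleotide coordinates of the
#'   RT/RNaseH CDS inside the internal sequence), \code{integrase_position}.
#' @slot ltrSeqs,internalSeqs \code{DNAStringSet}s named by family.
#' @slot rtAA \code{AAStringSet} of the RT/RNaseH translations, named by family.
#' @slot panel the \code{\link{ReferencePanel}} generated alongside the
#'   blueprints (the labelled clade references).
#'
#' @exportClass ElementLibrary
setClass("ElementLibrary",
  representation(info = "DataFrame", ltrSeqs = "DNAStringSet",
                 internalSeqs = "DNAStringSet", rtAA = "AAStringSet",
                 panel = "ReferencePanel"))

setValidity("ElementLibrary", function(object) {
  msg <- character()
  n <- nrow(object@info)
  if (length(object@ltrSeqs) != n || length(object@internalSeqs) != n ||
      length(object@rtAA) != n)
    msg <- c(msg, "sequence sets must have one entry per family")
  if (n > 0) {
    d <- object@info$ltr_len + object@info$internal_len
    if (any(object@info$ltr_len < 80 | object@info$ltr_len > 1500))
      msg <- c(msg, "LTR lengths must lie in [80, 1500]")
    if (any(d < 2500 | d > 11000))
      msg <- c(msg, "inter-LTR start-to-start distance must lie in [2500, 11000]")
    ok <- object@info$integrase_position[object@info$superfamily == "Copia"] == "upstream_of_RT"
    if (length(ok) && !all(ok))
      msg <- c(msg, "Copia blueprints must have integrase upstream of RT")
  }
  if (length(msg)) msg else TRUE
})

#' A synthetic genome with its planted truth set
#'
#' @slot genome \code{DNAStringSet} of contigs.
#' @slot truth \code{GRanges} of planted copies with metadata columns
#'   \code{family_id}, \code{clade_id}, \code{superfamily}, \code{state}
#'   (full, truncated, solo_ltr or nested_host) and, where exact, the LTR
#'   spans \code{ltr5_start}, \code{ltr5_end}, \code{ltr3_start},
#'   \code{ltr3_end}.
#' @slot library the \code{\link{ElementLibrary}} the copies were drawn from.
#' @slot plantSpec the planting parameters used (see \code{\link{plantSpec}}).
#'
#' @exportClass PlantedGenome
setClass("PlantedGenome",
  representation(genome = "DNAStringSet", truth = "GRanges",
                 library = "ElementLibrary", plantSpec = "list"))

setValidity("PlantedGenome", function(object) {
  msg <- character()
  if (length(object@truth)) {
    w <- GenomicRanges::width(object@truth)
    if (any(w <= 0)) msg <- c(msg, "truth spans must have positive width")
    lens <- stats::setNames(Biostrings::width(object@genome), names(object@genome))
    ends <- GenomicRanges::end(object@truth)
    ctg <- as.character(GenomicRanges::seqnames(object@truth))
    if (any(ends > lens[ctg])) msg <- c(msg, "truth spans exceed contig bounds")
  }
  if (length(msg)) msg else TRUE
})

#' A set of detected or annotation-derived element copies
#'
#' @slot seqs \code{DNAStringSet} of copy sequences, named by copy id.
#' @slot info \code{DataFrame} with one row per copy: \code{copy_id},
#'   \code{species}, \code{superfamily}, \code{contig}, \code{start},
#'   \code{end}, \code{strand}, \code{provenance} (structural, genome_scan or
#'   database_mining).
#'
#' @exportClass TECopySet
setClass("TECopySet",
  representation(seqs = "DNAStringSet", info = "DataFrame"))

setValidity("TECopySet", function(object) {
  if (length(object@seqs) != nrow(object@info))
    return("one info row per sequence required")
  if (!identical(as.character(object@info$copy_id), names(object@seqs)))
    return("info$copy_id must match sequence names in order")
  TRUE
})

#' A set of element families
#'
#' The unit of the census: each family has a representative sequence (its
#' longest member), a species, a superfamily and an origin describing how it
#' was defined (cluster, orphan, external_reference or annotation_derived).
#'
#' @slot representatives \code{DNAStringSet} named by family id.
#' @slot info \code{DataFrame} with columns \code{family_id}, \code{species},
#'   \code{superfamily}, \code{origin}, \code{n_members}.
#' @slot members \code{DataFrame} mapping \code{copy_id} to \code{family_id}.
#'
#' @exportClass TEFamilySet
setClass("TEFamilySet",
  representation(representatives = "DNAStringSet", info = "DataFrame",
                 members = "DataFrame"))

setValidity("TEFamilySet", function(object) {
  msg <- character()
  if (length(object@representatives) != nrow(object@info))
    msg <- c(msg, "one info row per representative required")
  if (nrow(object@info)) {
    if (!identical(as.character(object@info$family_id), names(object@representatives)))
      msg <- c(msg, "info$family_id must match representative names in order")
    if (any(object@info$n_members < 1)) msg <- c(msg, "families need >= 1 member")
    if (!all(object@members$family_id %in% object@info$family_id))
      msg <- c(msg, "members reference unknown families")
  }
  if (length(msg)) msg else TRUE
})
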