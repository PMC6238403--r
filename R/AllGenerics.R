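# Accessor generics for the package's S4 containers.

#' @rdname ReferencePanel-class
#' @param x a package object.
#' @export
setGeneric("panelSeqs", function(x) standardGeneric("panelSeqs"))

#' @rdname ReferencePanel-class
#' @export
setGeneric("panelLabels", function(x) standardGeneric("panelLabels"))

#' @rdname PlantedGenome-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname PlantedGenome-class
#' @export
setGeneric("truthSet", function(x) standardGeneric("truthSet"))

#' @rdname ElementLibrary-class
#' @export
setGeneric("elementInfo", function(x) standardGeneric("elementInfo"))

#' @rdname ElementLibrary-class
#' @export
setGeneric("elementPanel", function(x) standardGeneric("elementPanel"))

#' @rdname TEFamilySet-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname TEFamilySet-class
#' @export
setGeneric("familyInfo", function(x) standardGeneric("familyInfo"))

#' @rdname TEFamilySet-class
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))

#' @rdname TECopySet-class
#' @export
setGeneric("copySeqs", function(x) standardGeneric("copySeqs"))

#' @rdname TECopySet-class
#' @export
setGeneric("copyInfo", function(x) standardGeneric("copyInfo"))

#' @rdname ReferencePanel-class
setMethod("panelSeqs", "ReferencePanel", function(x) x@seqs)
#' @rdname ReferencePanel-class
setMethod("panelLabels", "ReferencePanel", function(x) x@labels)
#' @rdname ElementLibrary-class
setMethod("panelSeqs", "ElementLibrary", function(x) x@panel@seqs)
#' @rdname ElementLibrary-class
setMethod("panelLabels", "ElementLibrary", function(x) x@panel@labels)
#' @rdname PlantedGenome-class
setMethod("genomeSeq", "PlantedGenome", function(x) x@genome)
#' @rdname PlantedGenome-class
setMethod("truthSet", "PlantedGenome", function(x) x@truth)
#' @rdname ElementLibrary-class
setMethod("elementInfo", "ElementLibrary", function(x) x@info)
#' @rdname ElementLibrary-class
setMethod("elementPanel", "ElementLibrary", function(x) x@panel)
#' @rdname PlantedGenome-class
setMethod("elementInfo", "PlantedGenome", function(x) x@library@info)
#' @rdname PlantedGenome-class
setMethod("elementPanel", "PlantedGenome", function(x) x@library@panel)
#' @rdname TEFamilySet-class
setMethod("representatives", "TEFamilySet", function(x) x@representatives)
#' @rdname TEFamilySet-class
setMethod("familyInfo", "TEFamilySet", function(x) x@info)
#' @rdname TEFamilySet-class
setMethod("familyMembers", "TEFamilySet", function(x) x@members)
#' @rdname TECopySet-class
setMethod("copySeqs", "TECopySet", function(x) x@seqs)
#' @rdname TECopySet-class
setMethod("copyInfo", "TECopySet", function(x) x@info)

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme (", object@type, "): ", nrow(object@matrix), "x",
      ncol(object@matrix), " matrix, gap ", object@gapOpen, "/",
      object@gapExtend, sep = "")
  if (!is.na(object@lambda))
    cat(sprintf(", lambda=%.4f, K=%.4g", object@lambda, object@K))
  else cat(", uncalibrated")
  cat("\n")
})

setMethod("show", "ReferencePanel", function(object) {
  tab <- table(object@labels$superfamily)
  cat("ReferencePanel with", length(object@seqs), "RT/RNaseH sequences (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
})

setMethod("show", "ElementLibrary", function(object) {
  cat("ElementLibrary:", nrow(object@info), "family blueprints,",
      length(unique(object@info$clade_id)), "clades\n")
})

setMethod("show", "PlantedGenome", function(object) {
  cat("PlantedGenome:", length(object@genome), "contigs (",
      sum(Biostrings::width(object@genome)), "bp ),",
      length(object@truth), "planted copies\n")
})

setMethod("show", "TECopySet", function(object) {
  cat("TECopySet with", length(object@seqs), "copies\n")
})

setMethod("show", "TEFamilySet", function(object) {
  tab <- table(object@info$origin)
  cat("TEFamilySet with", nrow(object@info), "families (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
})
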