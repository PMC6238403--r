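# Writers for the standard interchange formats: GFF3 for candidates and
# annotated copies, FASTA for family representatives and panels, TSV tables.

#' Write LTR candidates as GFF3
#'
#' Each candidate becomes an \code{LTR_retrotransposon} feature with two
#' \code{long_terminal_repeat} children (1-based inclusive coordinates, as
#' GFF3 requires).
#'
#' @param candidates \code{GRanges} from \code{\link{detectLTR}}.
#' @param file output path.
#' @export
writeCandidatesGFF3 <- function(candidates, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(candidates) == 0) return(invisible(file))
  for (i in seq_along(candidates)) {
    ctg <- as.character(GenomicRanges::seqnames(candidates))[i]
    id <- sprintf("ltr_rt_%04d", i)
    at <- sprintf("ID=%s;ltr_identity=%.2f", id, candidates$ltr_identity[i])
    writeLines(paste(ctg, "LTRcensus", "LTR_retrotransposon",
                     GenomicRanges::start(candidates)[i],
                     GenomicRanges::end(candidates)[i], ".", "+", ".", at,
                     sep = "\t"), con)
    writeLines(paste(ctg, "LTRcensus", "long_terminal_repeat",
                     candidates$ltr5_start[i], candidates$ltr5_end[i],
                     ".", "+", ".", sprintf("Parent=%s", id), sep = "\t"), con)
    writeLines(paste(ctg, "LTRcensus", "long_terminal_repeat",
                     candidates$ltr3_start[i], candidates$ltr3_end[i],
                     ".", "+", ".", sprintf("Parent=%s", id), sep = "\t"), con)
  }
  invisible(file)
}

#' Write a family set as FASTA plus membership TSV
#'
#' @param families a \code{\linkS4class{TEFamilySet}}.
#' @param fastaFile,membersFile output paths.
#' @export
writeFamilySet <- function(families, fastaFile, membersFile) {
  Biostrings::writeXStringSet(representatives(families), fastaFile)
  utils::write.table(as.data.frame(familyMembers(families)), membersFile,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastaFile)
}

#' Write a reference panel as FASTA plus label TSV
#'
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param fastaFile,labelFile output paths.
#' @export
writePanel <- function(panel, fastaFile, labelFile) {
  Biostrings::writeXStringSet(panelSeqs(panel), fastaFile)
  utils::write.table(as.data.frame(panelLabels(panel)), labelFile,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastaFile)
}

#' Read a reference panel from FASTA plus label TSV
#'
#' @param fastaFile amino-acid FASTA of RT/RNaseH sequences.
#' @param labelFile TSV with columns id, superfamily, clade.
#' @return a \code{\linkS4class{ReferencePanel}}.
#' @export
readPanel <- function(fastaFile, labelFile) {
  seqs <- Biostrings::readAAStringSet(fastaFile)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  labs <- utils::read.delim(labelFile, stringsAsFactors = FALSE)
  labs <- labs[match(names(seqs), labs$id), , drop = FALSE]
  if (!"clade" %in% names(labs)) labs$clade <- NA_character_
  new("ReferencePanel", seqs = seqs,
      labels = S4Vectors::DataFrame(labs[, c("id", "superfamily", "clade")]))
}
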