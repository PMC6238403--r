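# Synthetic genomes with planted LTR-retrotransposon content. The generator
# defines the study conditions for every downstream test: each planted copy
# is recorded in a truth set that serves as the testing oracle.

.SUPERFAMILIES <- c("Copia", "BELPao", "Gypsy")

# mutate an amino-acid sequence: per-site substitution to a different residue
.mutate_aa <- function(aa, rate) {
  if (rate <= 0) return(aa)
  v <- .seq_chars(aa)
  alphabet <- names(.AA_BG)
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(alphabet, v[i]), 1L)
  paste(v, collapse = "")
}

# back-translate an amino-acid sequence with uniformly random synonymous
# codons (no internal stops by construction)
.backtranslate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  byAA <- split(names(gc), gc)
  v <- .seq_chars(aa)
  paste(vapply(v, function(r) sample(byAA[[r]], 1L), character(1)),
        collapse = "")
}

.random_aa <- function(n) {
  paste(sample(names(.AA_BG), n, replace = TRUE, prob = .AA_BG), collapse = "")
}

#' Build a library of element blueprints with a labelled reference panel
#'
#' Generates one ancestral pol-like protein per superfamily, radiates clade
#' ancestors from it at \code{cladeDivergence} substitutions/site (amino
#' acid), then radiates family proteins from each clade ancestor at
#' \code{familyDivergence}. Each family's internal sequence is a random UTR +
#' back-translated CDS + UTR, flanked in planted copies by a family-specific
#' random LTR. Copia blueprints carry the integrase upstream of RT; Gypsy and
#' BEL/Pao downstream of RNaseH. The reference panel holds
#' \code{panelRefsPerClade} labelled RT/RNaseH sequences per clade, drawn
#' around each clade ancestor.
#'
#' @param nClades number of clades (assigned to the three superfamilies
#'   round-robin).
#' @param familiesPerClade families per clade.
#' @param cladeDivergence,familyDivergence amino-acid substitution rates in
#'   [0, 0.6] used for the two radiations.
#' @param seed integer seed; fixed seed gives a byte-identical library.
#' @param ltrLenRange LTR length range (bp) sampled per family.
#' @param rtLen RT/RNaseH domain length (aa).
#' @param panelRefsPerClade labelled reference sequences per clade.
#' @param utr5Len,utr3Len untranslated padding inside the element (bp).
#' @return an \code{\linkS4class{ElementLibrary}}.
#' @examples
#' lib <- buildElementLibrary(nClades = 3, familiesPerClade = 2, seed = 1)
#' elementInfo(lib)
#' @export
buildElementLibrary <- function(nClades = 3L, familiesPerClade = 2L,
                                cladeDivergence = 0.3, familyDivergence = 0.05,
                                seed = 1L, ltrLenRange = c(250L, 400L),
                                rtLen = 300L, panelRefsPerClade = 6L,
                                utr5Len = 600L, utr3Len = 500L) {
  stopifnot(nClades >= 1, familiesPerClade >= 1,
            cladeDivergence >= 0, cladeDivergence <= 0.6,
            familyDivergence >= 0, familyDivergence <= 0.6)
  .with_seed(seed, {
    sfOf <- rep(.SUPERFAMILIES, length.out = nClades)
    # ancestral protein parts per superfamily
    anc <- lapply(stats::setNames(nm = unique(sfOf)), function(sf) {
      list(gag = .random_aa(60L), int = .random_aa(100L),
           rt = .random_aa(rtLen), tail = .random_aa(30L))
    })
    info <- list(); ltrs <- character(); internals <- character()
    rtaa <- character()
    panelSeqsL <- character(); panelSf <- character(); panelClade <- character()
    for (ci in seq_len(nClades)) {
      sf <- sfOf[ci]
      cladeId <- sprintf("%s_clade%d", sf, ci)
      a <- anc[[sf]]
      cl <- lapply(a, .mutate_aa, rate = cladeDivergence)
      for (r in seq_len(panelRefsPerClade)) {
        ref <- .mutate_aa(cl$rt, max(familyDivergence, 0.02))
        panelSeqsL <- c(panelSeqsL, ref)
        panelSf <- c(panelSf, sf); panelClade <- c(panelClade, cladeId)
      }
      for (fi in seq_len(familiesPerClade)) {
        famId <- sprintf("%s_c%d_f%d", sf, ci, fi)
        fam <- lapply(cl, .mutate_aa, rate = familyDivergence)
        prot <- if (sf == "Copia")
          paste0(fam$gag, fam$int, fam$rt, fam$tail)
        else
          paste0(fam$gag, fam$rt, fam$int, fam$tail)
        rtAaStart <- if (sf == "Copia") 60L + 100L + 1L else 60L + 1L
        cds <- .backtranslate(prot)
        internal <- paste0(.random_dna(utr5Len), cds, .random_dna(utr3Len))
        rtStart <- utr5Len + 3L * (rtAaStart - 1L) + 1L
        rtEnd <- rtStart + 3L * rtLen - 1L
        ltrLen <- sample(seq(ltrLenRange[1], ltrLenRange[2]), 1L)
        d <- ltrLen + nchar(internal)
        if (d < 2500 || d > 11000)
          stop("element geometry violates the inter-LTR distance window [2500, 11000]: ",
               famId, " has start-to-start distance ", d)
        info[[length(info) + 1L]] <- data.frame(
          family_id = famId, clade_id = cladeId, superfamily = sf,
          ltr_len = ltrLen, internal_len = nchar(internal),
          rt_start = rtStart, rt_end = rtEnd,
          integrase_position = if (sf == "Copia") "upstream_of_RT"
                               else "downstream_of_RNaseH",
          stringsAsFactors = FALSE)
        ltrs <- c(ltrs, .random_dna(ltrLen))
        internals <- c(internals, internal)
        rtaa <- c(rtaa, fam$rt)
      }
    }
    info <- S4Vectors::DataFrame(do.call(rbind, info))
    ids <- info$family_id
    panelIds <- sprintf("REF_%s_%d", panelClade,
                        unlist(lapply(table(panelClade)[unique(panelClade)], seq_len)))
    panel <- new("ReferencePanel",
                 seqs = stats::setNames(Biostrings::AAStringSet(panelSeqsL), panelIds),
                 labels = S4Vectors::DataFrame(id = panelIds,
                                               superfamily = panelSf,
                                               clade = panelClade))
    new("ElementLibrary", info = info,
        ltrSeqs = stats::setNames(Biostrings::DNAStringSet(ltrs), ids),
        internalSeqs = stats::setNames(Biostrings::DNAStringSet(internals), ids),
        rtAA = stats::setNames(Biostrings::AAStringSet(rtaa), ids),
        panel = panel)
  })
}

#' Mutate a DNA sequence with a recorded edit script
#'
#' Per-site substitutions at \code{subRate} (always to a different base),
#' then indel events at \code{indelRate} per site with geometric lengths of
#' mean \code{meanIndelLen}; insertions and deletions are equiprobable. The
#' applied edits are attached as attribute \code{"edits"}.
#'
#' @param seq character or \code{DNAString}.
#' @param subRate,indelRate per-site event probabilities in [0, 1].
#' @param meanIndelLen mean indel length (bp).
#' @param seed optional integer seed.
#' @return the mutated sequence (character) with attribute \code{edits}, a
#'   data.frame of (type, pos, len). Zero rates return the input unchanged.
#' @export
mutateSequence <- function(seq, subRate, indelRate, meanIndelLen = 5,
                           seed = NULL) {
  stopifnot(subRate >= 0, subRate <= 1, indelRate >= 0, indelRate <= 1)
  x <- toupper(as.character(seq))
  if (nchar(x) == 0) stop("seq must be non-empty")
  .with_seed(seed, {
    v <- .seq_chars(x)
    n <- length(v)
    edits <- list()
    hit <- which(stats::runif(n) < subRate)
    for (i in hit) {
      old <- v[i]
      v[i] <- sample(setdiff(NT_BASES, old), 1L)
      edits[[length(edits) + 1L]] <- data.frame(type = "sub", pos = i, len = 1L)
    }
    if (indelRate > 0) {
      sites <- which(stats::runif(n) < indelRate)
      # apply from the right so earlier positions stay valid
      for (i in rev(sites)) {
        len <- stats::rgeom(1L, 1 / max(meanIndelLen, 1)) + 1L
        if (stats::runif(1) < 0.5) {
          ins <- sample(NT_BASES, len, replace = TRUE)
          v <- append(v, ins, after = i)
          edits[[length(edits) + 1L]] <- data.frame(type = "ins", pos = i, len = len)
        } else {
          drop <- seq(i, min(i + len - 1L, length(v)))
          v <- v[-drop]
          edits[[length(edits) + 1L]] <- data.frame(type = "del", pos = i,
                                                    len = length(drop))
        }
      }
    }
    out <- paste(v, collapse = "")
    attr(out, "edits") <- if (length(edits)) do.call(rbind, rev(edits))
                          else data.frame(type = character(), pos = integer(),
                                          len = integer())
    out
  })
}

#' Planting parameters for the synthetic generator
#'
#' @param nContigs,contigLength genome shape.
#' @param copiesPerFamily copies planted per family (scalar or per-family
#'   vector, recycled).
#' @param subRate,indelRate,meanIndelLen per-copy mutation parameters
#'   (see \code{\link{mutateSequence}}).
#' @param truncationProb probability that a copy is truncated: a uniform
#'   20-80\% fraction is removed from a random end, which destroys one LTR
#'   and makes the copy structurally undetectable.
#' @param soloLtrProb probability that a copy is reduced to a solo LTR.
#' @param nestingProb probability that a full copy hosts a nested full copy
#'   of another family inside its internal region.
#' @param revcompProb probability a copy is planted on the minus strand.
#' @param minGap minimum background gap between planted copies (bp). The
#'   default exceeds the detector's maximum inter-LTR distance so repeats of
#'   neighbouring identical copies cannot pair with each other.
#' @param familyStates optional data.frame (family_id, state, n) that
#'   overrides the stochastic state draws for the named families.
#' @param gc background GC content.
#' @param seed integer seed.
#' @return a list of class \code{plant_spec}.
#' @export
plantSpec <- function(nContigs = 5L, contigLength = 500000L,
                      copiesPerFamily = 3L, subRate = 0, indelRate = 0,
                      meanIndelLen = 5, truncationProb = 0, soloLtrProb = 0,
                      nestingProb = 0, revcompProb = 0.5, minGap = 12000L,
                      familyStates = NULL, gc = 0.5, seed = 1L) {
  p <- list(nContigs = as.integer(nContigs),
            contigLength = as.integer(contigLength),
            copiesPerFamily = copiesPerFamily, subRate = subRate,
            indelRate = indelRate, meanIndelLen = meanIndelLen,
            truncationProb = truncationProb, soloLtrProb = soloLtrProb,
            nestingProb = nestingProb, revcompProb = revcompProb,
            minGap = as.integer(minGap), familyStates = familyStates,
            gc = gc, seed = as.integer(seed))
  rates <- c(p$subRate, p$indelRate, p$truncationProb, p$soloLtrProb,
             p$nestingProb, p$revcompProb)
  stopifnot(all(rates >= 0 & rates <= 1), p$nContigs >= 1,
            p$contigLength >= 1000)
  class(p) <- "plant_spec"
  p
}

# build one mutated copy of a blueprint; returns the sequence, its state and
# exact LTR spans relative to the copy start (NA when not meaningful)
.build_copy <- function(lib, fam, spec, state, nestedDonor = NULL) {
  i <- match(fam, lib@info$family_id)
  ltr <- as.character(lib@ltrSeqs[[i]])
  internal <- as.character(lib@internalSeqs[[i]])
  mut <- function(s) as.character(mutateSequence(s, spec$subRate,
                                                 spec$indelRate,
                                                 spec$meanIndelLen))
  if (state == "solo_ltr") {
    seq <- mut(ltr)
    return(list(seq = seq, ltr = rep(NA_integer_, 4L)))
  }
  l5 <- mut(ltr); int <- mut(internal); l3 <- mut(ltr)
  if (state == "nested_host" && !is.null(nestedDonor)) {
    at <- sample(seq(50L, max(51L, nchar(int) - 50L)), 1L)
    int <- paste0(substr(int, 1L, at), nestedDonor$seq,
                  substr(int, at + 1L, nchar(int)))
  }
  seq <- paste0(l5, int, l3)
  if (state == "truncated") {
    frac <- stats::runif(1, 0.2, 0.8)
    cut <- max(1L, round(frac * nchar(seq)))
    seq <- if (stats::runif(1) < 0.5) substr(seq, cut + 1L, nchar(seq))
           else substr(seq, 1L, nchar(seq) - cut)
    return(list(seq = seq, ltr = rep(NA_integer_, 4L)))
  }
  n5 <- nchar(l5); ni <- nchar(int); n3 <- nchar(l3)
  list(seq = seq, ltr = c(1L, n5, n5 + ni + 1L, n5 + ni + n3),
       nested_at = if (state == "nested_host") NA else NULL)
}

#' Plant element copies into a synthetic genome
#'
#' Draws copies per family, mutates each copy (substitutions, indels,
#' optional truncation, solo-LTR reduction and nesting), reverse-complements
#' a fraction, and places all copies on random background contigs separated
#' by at least \code{minGap} of background. Every planted copy is recorded in
#' the truth set; extracting a truth span from the genome reproduces the
#' mutated copy exactly.
#'
#' @param library an \code{\linkS4class{ElementLibrary}}.
#' @param spec a \code{\link{plantSpec}}.
#' @return a \code{\linkS4class{PlantedGenome}}.
#' @examples
#' lib <- buildElementLibrary(seed = 1)
#' pg <- plantCopies(lib, plantSpec(nContigs = 2, contigLength = 120000,
#'                                  copiesPerFamily = 1, seed = 7))
#' truthSet(pg)
#' @export
plantCopies <- function(library, spec = plantSpec()) {
  stopifnot(is(library, "ElementLibrary"), inherits(spec, "plant_spec"))
  .with_seed(spec$seed, {
    fams <- library@info$family_id
    nPer <- rep(spec$copiesPerFamily, length.out = length(fams))
    roster <- data.frame(family = rep(fams, nPer), stringsAsFactors = FALSE)
    if (nrow(roster) == 0) stop("no copies requested")
    # state per copy
    u <- stats::runif(nrow(roster))
    roster$state <- ifelse(u < spec$soloLtrProb, "solo_ltr",
                    ifelse(u < spec$soloLtrProb + spec$truncationProb, "truncated",
                    ifelse(u < spec$soloLtrProb + spec$truncationProb +
                             spec$nestingProb, "nested_host", "full")))
    if (!is.null(spec$familyStates)) {
      fs <- spec$familyStates
      roster <- roster[!roster$family %in% fs$family_id, , drop = FALSE]
      add <- do.call(rbind, lapply(seq_len(nrow(fs)), function(i)
        data.frame(family = rep(fs$family_id[i], fs$n[i]),
                   state = fs$state[i], stringsAsFactors = FALSE)))
      roster <- rbind(roster, add)
    }
    roster <- roster[sample.int(nrow(roster)), , drop = FALSE]

    built <- vector("list", nrow(roster))
    for (i in seq_len(nrow(roster))) {
      st <- roster$state[i]
      nested <- NULL
      if (st == "nested_host") {
        donorFam <- sample(setdiff(fams, roster$family[i]), 1L)
        donorSpec <- spec; donorSpec$subRate <- spec$subRate
        donor <- .build_copy(library, donorFam, spec, "full")
        nested <- list(seq = donor$seq, family = donorFam)
      }
      cp <- .build_copy(library, roster$family[i], spec, st, nested)
      strand <- if (stats::runif(1) < spec$revcompProb) "-" else "+"
      seq <- cp$seq
      ltr <- cp$ltr
      if (strand == "-") {
        seq <- .revcomp(seq)
        if (!is.na(ltr[1])) {
          n <- nchar(seq)
          ltr <- c(n - ltr[4] + 1L, n - ltr[3] + 1L,
                   n - ltr[2] + 1L, n - ltr[1] + 1L)
        }
      }
      built[[i]] <- list(seq = seq, state = st, strand = strand,
                         family = roster$family[i], ltr = ltr,
                         nested = nested)
    }

    # distribute copies round-robin across contigs, then pack each contig
    contigs <- character(spec$nContigs)
    names(contigs) <- sprintf("contig_%02d", seq_len(spec$nContigs))
    assign <- rep(seq_len(spec$nContigs), length.out = length(built))
    truth <- list()
    for (ci in seq_len(spec$nContigs)) {
      mine <- built[assign == ci]
      copyLens <- vapply(mine, function(b) nchar(b$seq), integer(1))
      bg <- spec$contigLength - sum(copyLens)
      nGaps <- length(mine) + 1L
      if (bg < nGaps * spec$minGap) {
        first <- if (length(mine)) mine[[1]]$family else "(none)"
        stop("placement saturation on contig ", ci,
             ": cannot place copy of family ", first,
             " with minGap = ", spec$minGap)
      }
      extra <- bg - nGaps * spec$minGap
      cuts <- sort(stats::runif(nGaps - 1L, 0, extra))
      gapLens <- spec$minGap + round(diff(c(0, cuts, extra)))
      gapLens[nGaps] <- bg - sum(gapLens[-nGaps])   # exact total
      parts <- character(0)
      pos <- 0L
      for (j in seq_along(mine)) {
        parts <- c(parts, .random_dna(gapLens[j], spec$gc))
        pos <- pos + gapLens[j]
        b <- mine[[j]]
        start <- pos + 1L
        end <- pos + nchar(b$seq)
        parts <- c(parts, b$seq)
        pos <- end
        ltrAbs <- if (!is.na(b$ltr[1])) start - 1L + b$ltr else rep(NA_integer_, 4L)
        truth[[length(truth) + 1L]] <- data.frame(
          contig = names(contigs)[ci], start = start, end = end,
          strand = b$strand, family_id = b$family,
          state = b$state, ltr5_start = ltrAbs[1], ltr5_end = ltrAbs[2],
          ltr3_start = ltrAbs[3], ltr3_end = ltrAbs[4],
          stringsAsFactors = FALSE)
      }
      parts <- c(parts, .random_dna(gapLens[nGaps], spec$gc))
      contigs[ci] <- paste(parts, collapse = "")
    }
    tdf <- do.call(rbind, truth)
    idx <- match(tdf$family_id, library@info$family_id)
    tdf$clade_id <- library@info$clade_id[idx]
    tdf$superfamily <- library@info$superfamily[idx]
    gr <- GenomicRanges::GRanges(
      seqnames = tdf$contig,
      ranges = IRanges::IRanges(tdf$start, tdf$end),
      strand = tdf$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      tdf[, c("family_id", "clade_id", "superfamily", "state",
              "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")])
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    new("PlantedGenome",
        genome = Biostrings::DNAStringSet(contigs),
        truth = gr, library = library, plantSpec = unclass(spec))
  })
}

#' Simulate transcripts from planted families
#'
#' Returns one or more mutated internal-region transcripts per selected
#' family; a stand-in for EST/TSA collections when testing database mining.
#'
#' @param library an \code{\linkS4class{ElementLibrary}}.
#' @param families family ids (default all).
#' @param perFamily transcripts per family.
#' @param subRate substitution rate applied to each transcript.
#' @param seed integer seed.
#' @return a \code{DNAStringSet} named \code{<family>_tx<i>}.
#' @export
simulateTranscripts <- function(library, families = NULL, perFamily = 1L,
                                subRate = 0.02, seed = 1L) {
  stopifnot(is(library, "ElementLibrary"))
  if (is.null(families)) families <- library@info$family_id
  .with_seed(seed, {
    out <- character(); nm <- character()
    for (f in families) {
      i <- match(f, library@info$family_id)
      for (r in seq_len(perFamily)) {
        out <- c(out, as.character(
          mutateSequence(as.character(library@internalSeqs[[i]]), subRate, 0)))
        nm <- c(nm, sprintf("%s_tx%d", f, r))
      }
    }
    stats::setNames(Biostrings::DNAStringSet(out), nm)
  })
}

#' Write / read a truth set as TSV (0-based half-open coordinates)
#'
#' @param truth a \code{GRanges} truth set from \code{\link{plantCopies}}.
#' @param file path.
#' @return \code{readTruthTSV} returns a \code{GRanges} (1-based internally).
#' @export
writeTruthTSV <- function(truth, file) {
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(truth)),
                   start = GenomicRanges::start(truth) - 1L,
                   end = GenomicRanges::end(truth),
                   strand = as.character(GenomicRanges::strand(truth)),
                   family_id = truth$family_id, clade_id = truth$clade_id,
                   superfamily = truth$superfamily, state = truth$state)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTruthTSV
#' @export
readTruthTSV <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    df[, c("family_id", "clade_id", "superfamily", "state")])
  gr
}
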