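# Family building: the 80-80-80 comparator, single-linkage clustering,
# copy curation (purging copy-specific insertions), cluster merging and
# orphan promotion.

#' Family-building parameters
#'
#' @param minIdentity minimum percent identity over the aligned region.
#' @param minOverlap minimum aligned region length (bp).
#' @param minLengthFraction minimum percent of each sequence's length covered
#'   by the aligned region.
#' @param insertionPurgeMin copy-specific insertions strictly longer than
#'   this many bp are excised during curation.
#' @return a list of class \code{family_params}.
#' @export
familyParams <- function(minIdentity = 80, minOverlap = 80L,
                         minLengthFraction = 80, insertionPurgeMin = 20L) {
  stopifnot(minIdentity > 0, minIdentity <= 100, minLengthFraction > 0,
            minLengthFraction <= 100, insertionPurgeMin > 0)
  p <- list(minIdentity = minIdentity, minOverlap = as.integer(minOverlap),
            minLengthFraction = minLengthFraction,
            insertionPurgeMin = as.integer(insertionPurgeMin))
  class(p) <- "family_params"
  p
}

#' The 80-80-80 family comparator
#'
#' Two copies belong to the same family when their alignment shows at least
#' 80 percent identity, over at least 80 bp, covering at least 80 percent of
#' each sequence's length. Identity counts matching columns over all aligned
#' columns of the (terminal-gap-trimmed) global alignment; gap columns count
#' as mismatch.
#'
#' @param a,b DNA sequences (character or \code{XString}).
#' @param params a \code{\link{familyParams}} list.
#' @return list with \code{pass}, \code{identity}, \code{overlap},
#'   \code{fracA}, \code{fracB}.
#' @export
passes808080 <- function(a, b, params = familyParams()) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  la <- nchar(a); lb <- nchar(b)
  st <- .global_stats(a, b, .identity_scheme())
  fracA <- 100 * (st$a_span[2] - st$a_span[1] + 1) / la
  fracB <- 100 * (st$b_span[2] - st$b_span[1] + 1) / lb
  pass <- st$identity >= params$minIdentity &&
    st$overlap >= params$minOverlap &&
    fracA >= params$minLengthFraction && fracB >= params$minLengthFraction
  list(pass = pass, identity = st$identity, overlap = st$overlap,
       fracA = fracA, fracB = fracB)
}

#' Cluster copies by the 80-80-80 rule (single linkage)
#'
#' Clusters are the connected components of the graph whose edges are copy
#' pairs passing \code{\link{passes808080}}. The result is a partition of
#' the input and is independent of input order (up to label renumbering).
#'
#' @param copies a \code{DNAStringSet}, named character vector or
#'   \code{\linkS4class{TECopySet}}.
#' @param params a \code{\link{familyParams}} list.
#' @return integer vector of cluster ids (1-based, in order of first member).
#' @export
clusterCopies <- function(copies, params = familyParams()) {
  seqs <- if (is(copies, "TECopySet")) copySeqs(copies) else copies
  n <- length(seqs)
  if (n == 0) return(integer())
  ch <- as.character(seqs)
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    li <- nchar(ch[i]); lj <- nchar(ch[j])
    if (min(li, lj) < params$minLengthFraction / 100 * max(li, lj)) next
    if (passes808080(ch[i], ch[j], params)$pass)
      edges[[length(edges) + 1L]] <- c(i, j)
  }
  if (n == 1) return(1L)
  .components(n, edges)
}

#' Purge copy-specific insertions from one copy
#'
#' Aligns the copy against every cluster mate; positions of the copy that
#' fall in an internal insertion run longer than
#' \code{params$insertionPurgeMin} against \emph{every} mate are excised
#' (they are private to this copy, e.g. a nested element). Runs of at most
#' \code{insertionPurgeMin} bp are retained. A copy without mates is
#' returned unchanged.
#'
#' @param copy DNA sequence (character or \code{XString}).
#' @param mates DNA sequences of the other cluster members.
#' @param params a \code{\link{familyParams}} list.
#' @return the curated copy (character).
#' @export
curateCopy <- function(copy, mates, params = familyParams()) {
  x <- toupper(as.character(copy))
  mates <- as.character(mates)
  if (!length(mates)) return(x)
  n <- nchar(x)
  private <- rep(TRUE, n)
  scheme <- .identity_scheme()
  ca <- .codes(x, scheme)
  for (m in mates) {
    cb <- .codes(m, scheme)
    res <- .pair_align_codes(ca, cb, scheme, local = FALSE,
                             band = .global_band(length(ca), length(cb),
                                                 pad = 200L))
    pa <- res$path_a; pb <- res$path_b
    ins <- rep(FALSE, n)
    both <- which(pa > 0L & pb > 0L)
    if (length(both) >= 2) {
      inner <- seq(min(both), max(both))
      gapcols <- inner[pb[inner] == 0L & pa[inner] > 0L]
      if (length(gapcols)) {
        runs <- .true_runs(seq_len(res$n_cols) %in% gapcols)
        for (r in seq_len(nrow(runs))) {
          len <- runs[r, 2] - runs[r, 1] + 1L
          if (len > params$insertionPurgeMin)
            ins[pa[runs[r, 1]:runs[r, 2]]] <- TRUE
        }
      }
    }
    private <- private & ins
    if (!any(private)) break
  }
  if (!any(private)) return(x)
  runs <- .true_runs(private)
  drop <- logical(n)
  for (r in seq_len(nrow(runs)))
    if (runs[r, 2] - runs[r, 1] + 1L > params$insertionPurgeMin)
      drop[runs[r, 1]:runs[r, 2]] <- TRUE
  if (!any(drop)) return(x)
  paste(.seq_chars(x)[!drop], collapse = "")
}

#' Curate every member of a cluster
#'
#' @param seqs \code{DNAStringSet} or character vector of cluster members.
#' @param params a \code{\link{familyParams}} list.
#' @return character vector of curated sequences (same names/order).
#' @export
curateCluster <- function(seqs, params = familyParams()) {
  ch <- as.character(seqs)
  names(ch) <- names(seqs)
  if (length(ch) < 2) return(ch)
  out <- vapply(seq_along(ch), function(i)
    curateCopy(ch[i], ch[-i], params), character(1))
  names(out) <- names(ch)
  out
}

#' Merge clusters sharing 80 percent identity and emit families
#'
#' Cluster-to-cluster identity is computed between cluster representatives
#' (longest members); clusters passing the comparator are merged under
#' transitive closure. Each final cluster becomes a family whose
#' representative is its longest member, named
#' \code{<Superfamily>-<n>_<speciesCode>}.
#'
#' @param seqs named character vector or \code{DNAStringSet} of (curated)
#'   copies.
#' @param clusters integer cluster ids from \code{\link{clusterCopies}}.
#' @param superfamily superfamily label of these copies.
#' @param species species label; \code{speciesCode} defaults to it.
#' @param params a \code{\link{familyParams}} list.
#' @param origin origin recorded on the families.
#' @return a \code{\linkS4class{TEFamilySet}}.
#' @export
mergeClusters <- function(seqs, clusters, superfamily, species,
                          params = familyParams(), origin = "cluster") {
  ch <- as.character(seqs)
  names(ch) <- names(seqs)
  if (is.null(names(ch))) names(ch) <- paste0("copy_", seq_along(ch))
  stopifnot(length(clusters) == length(ch))
  ids <- sort(unique(clusters))
  reps <- vapply(ids, function(cl) {
    members <- which(clusters == cl)
    members[which.max(nchar(ch[members]))]
  }, integer(1))
  k <- length(ids)
  edges <- list()
  if (k >= 2) for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (passes808080(ch[reps[i]], ch[reps[j]], params)$pass)
      edges[[length(edges) + 1L]] <- c(i, j)
  }
  comp <- .components(k, edges)
  fams <- sort(unique(comp))
  famIdx <- lapply(fams, function(f) which(clusters %in% ids[comp == f]))
  # deterministic numbering by first member position
  ord <- order(vapply(famIdx, min, integer(1)))
  famIdx <- famIdx[ord]
  famIds <- sprintf("%s-%d_%s", superfamily, seq_along(famIdx), species)
  repSeq <- vapply(famIdx, function(ix) ch[ix][which.max(nchar(ch[ix]))],
                   character(1))
  members <- do.call(rbind, lapply(seq_along(famIdx), function(i)
    data.frame(copy_id = names(ch)[famIdx[[i]]], family_id = famIds[i],
               stringsAsFactors = FALSE)))
  new("TEFamilySet",
      representatives = stats::setNames(Biostrings::DNAStringSet(repSeq), famIds),
      info = S4Vectors::DataFrame(
        family_id = famIds, species = species, superfamily = superfamily,
        origin = origin,
        n_members = vapply(famIdx, length, integer(1))),
      members = S4Vectors::DataFrame(members))
}

#' Promote orphan copies to one-member families
#'
#' A copy that joined no cluster becomes a family of its own only if it has
#' a translatable RT/RNaseH domain: a translated hit against the reference
#' panel whose aligned query segment contains no internal stop codon and
#' spans at least \code{minDomainAA} residues. Others are discarded with a
#' reason.
#'
#' @param orphans a \code{\linkS4class{TECopySet}} (or named DNA vector) of
#'   singleton copies.
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param species,superfamily labels for the resulting families (recycled
#'   from the copy info when \code{orphans} is a \code{TECopySet}).
#' @param scheme calibrated amino-acid scheme.
#' @param maxE E-value ceiling for the panel hit.
#' @param minDomainAA minimum domain length (aa).
#' @param startIndex first family number to use in naming.
#' @return list with \code{families} (a \code{\linkS4class{TEFamilySet}},
#'   possibly empty) and \code{discarded} (data.frame copy_id, reason).
#' @export
promoteOrphans <- function(orphans, panel, species = "sp",
                           superfamily = NA_character_, scheme = NULL,
                           maxE = 1e-5, minDomainAA = 100L,
                           startIndex = 1L) {
  if (is.null(scheme)) scheme <- aaScoringScheme()
  seqs <- if (is(orphans, "TECopySet")) copySeqs(orphans) else
    Biostrings::DNAStringSet(orphans)
  infoSf <- if (is(orphans, "TECopySet")) copyInfo(orphans)$superfamily
            else rep(superfamily, length(seqs))
  keep <- character(); keepSf <- character(); disc <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    dom <- extractDomain(seqs[[i]], panel, scheme = scheme, maxE = maxE)
    if (is.null(dom)) {
      disc[[length(disc) + 1L]] <- data.frame(copy_id = id,
                                              reason = "no_panel_hit")
    } else if (grepl("*", dom$aa, fixed = TRUE)) {
      disc[[length(disc) + 1L]] <- data.frame(copy_id = id,
                                              reason = "stop_in_domain")
    } else if (nchar(dom$aa) < minDomainAA) {
      disc[[length(disc) + 1L]] <- data.frame(copy_id = id,
                                              reason = "short_domain")
    } else {
      keep <- c(keep, id); keepSf <- c(keepSf, infoSf[i])
    }
  }
  if (length(keep)) {
    famIds <- sprintf("%s-%d_%s", keepSf,
                      seq.int(startIndex, length.out = length(keep)), species)
    fams <- new("TEFamilySet",
                representatives = stats::setNames(
                  Biostrings::DNAStringSet(as.character(seqs[keep])), famIds),
                info = S4Vectors::DataFrame(
                  family_id = famIds, species = species, superfamily = keepSf,
                  origin = "orphan", n_members = 1L),
                members = S4Vectors::DataFrame(
                  copy_id = keep, family_id = famIds))
  } else {
    fams <- .empty_family_set()
  }
  list(families = fams,
       discarded = if (length(disc)) do.call(rbind, disc)
                   else data.frame(copy_id = character(), reason = character()))
}

.empty_family_set <- function() {
  new("TEFamilySet", representatives = Biostrings::DNAStringSet(),
      info = S4Vectors::DataFrame(family_id = character(),
                                  species = character(),
                                  superfamily = character(),
                                  origin = character(),
                                  n_members = integer()),
      members = S4Vectors::DataFrame(copy_id = character(),
                                     family_id = character()))
}

# concatenate family sets
.bind_family_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s@info) > 0, unname(sets))
  if (!length(sets)) return(.empty_family_set())
  new("TEFamilySet",
      representatives = do.call(c, lapply(sets, function(s) s@representatives)),
      info = do.call(rbind, lapply(sets, function(s) s@info)),
      members = do.call(rbind, lapply(sets, function(s) s@members)))
}

#' Build families from classified copies of one species
#'
#' Per superfamily: cluster copies under the 80-80-80 rule, curate members
#' of multi-copy clusters (purging copy-specific insertions), merge clusters
#' whose representatives still pass the comparator, and promote orphans with
#' a translatable RT/RNaseH domain to one-member families.
#'
#' @param copies a \code{\linkS4class{TECopySet}} with superfamily labels.
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param species species label.
#' @param params a \code{\link{familyParams}} list.
#' @param scheme calibrated amino-acid scheme (for orphan validation).
#' @return list with \code{families} (\code{\linkS4class{TEFamilySet}}),
#'   \code{discarded} (data.frame) and \code{clusters} (named integer vector
#'   of cluster ids per copy).
#' @export
buildFamilies <- function(copies, panel, species = "sp",
                          params = familyParams(), scheme = NULL) {
  stopifnot(is(copies, "TECopySet"))
  if (is.null(scheme)) scheme <- aaScoringScheme()
  info <- copyInfo(copies)
  seqs <- copySeqs(copies)
  sets <- list(); disc <- list(); clustersOut <- integer(); clNames <- character()
  for (sf in unique(info$superfamily)) {
    if (is.na(sf) || sf == "unclassified") next
    ix <- which(info$superfamily == sf)
    ch <- stats::setNames(as.character(seqs[ix]), info$copy_id[ix])
    cl <- clusterCopies(ch, params)
    clustersOut <- c(clustersOut, cl)
    clNames <- c(clNames, names(ch))
    sizes <- table(cl)
    multi <- names(sizes)[sizes >= 2]
    single <- names(sizes)[sizes == 1]
    curated <- ch
    for (g in multi) {
      mem <- which(cl == as.integer(g))
      curated[mem] <- curateCluster(ch[mem], params)
    }
    if (length(multi)) {
      mi <- which(cl %in% as.integer(multi))
      fams <- mergeClusters(curated[mi], cl[mi], sf, species, params)
      sets[[length(sets) + 1L]] <- fams
      nFams <- nrow(fams@info)
    } else nFams <- 0L
    if (length(single)) {
      si <- which(cl %in% as.integer(single))
      orph <- promoteOrphans(stats::setNames(curated[si], names(ch)[si]),
                             panel, species = species,
                             superfamily = sf, scheme = scheme,
                             startIndex = nFams + 1L)
      sets[[length(sets) + 1L]] <- orph$families
      if (nrow(orph$discarded)) disc[[length(disc) + 1L]] <- orph$discarded
    }
  }
  list(families = .bind_family_sets(sets),
       discarded = if (length(disc)) do.call(rbind, disc)
                   else data.frame(copy_id = character(), reason = character()),
       clusters = stats::setNames(clustersOut, clNames))
}
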