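# RT/RNaseH phylogeny: domain extraction from family representatives,
# progressive multiple alignment, pairwise-deletion distances (p-distance or
# gamma-corrected), neighbor joining, non-parametric bootstrap support and
# clade definition under the two-criterion rule (>= 2 species, support > 70).

#' Phylogeny parameters
#'
#' @param model \code{"jtt_gamma"} (gamma-corrected model distance, shape
#'   \code{gammaShape}) or \code{"p_distance"}.
#' @param gammaShape gamma shape parameter (default 1).
#' @param deletion \code{"pairwise"} (default) or \code{"complete"} gap
#'   handling.
#' @param bootstrapReps bootstrap replicates (default 100).
#' @param supportMin clades require bootstrap support strictly above this.
#' @param minSpecies clades require families from at least this many species.
#' @param seed RNG seed for the bootstrap.
#' @return a list of class \code{phylo_params}.
#' @export
phyloParams <- function(model = c("jtt_gamma", "p_distance"), gammaShape = 1,
                        deletion = c("pairwise", "complete"),
                        bootstrapReps = 100L, supportMin = 70,
                        minSpecies = 2L, seed = 1L) {
  stopifnot(bootstrapReps >= 1, supportMin > 0, supportMin <= 100,
            gammaShape > 0)
  p <- list(model = match.arg(model), gammaShape = gammaShape,
            deletion = match.arg(deletion),
            bootstrapReps = as.integer(bootstrapReps),
            supportMin = supportMin, minSpecies = as.integer(minSpecies),
            seed = as.integer(seed))
  class(p) <- "phylo_params"
  p
}

#' Extract the RT/RNaseH domain of a sequence
#'
#' Translated search against the reference panel; the domain is the
#' translated query envelope of the best hit, frame-corrected. When the
#' domain is interrupted by a frameshift, qualifying hits to the best
#' subject in different frames of the same strand are spliced in query order
#' into one chimeric protein.
#'
#' @param seq a nucleotide sequence (character or \code{DNAString}).
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param scheme calibrated amino-acid scheme.
#' @param maxE E-value ceiling for qualifying hits.
#' @return \code{NULL} when no hit qualifies, else a list with \code{aa}
#'   (the domain), \code{frame}, \code{ref} (best panel sequence),
#'   \code{evalue} and \code{n_segments} (> 1 when spliced across a
#'   frameshift).
#' @export
extractDomain <- function(seq, panel, scheme = NULL, maxE = 1e-5) {
  stopifnot(is(panel, "ReferencePanel"))
  if (is.null(scheme)) scheme <- aaScoringScheme()
  qChar <- as.character(seq)
  frames <- sixFrameTranslate(qChar)
  if (!length(frames)) return(NULL)
  n <- sum(nchar(as.character(panelSeqs(panel))))
  qNtLen <- nchar(qChar)
  m <- max(qNtLen %/% 3L, 1L)
  hits <- list()
  for (fn in names(frames)) {
    fa <- as.character(frames[[fn]])
    if (nchar(fa) < 10) next
    for (s in names(panelSeqs(panel))) {
      h <- .best_local_hit(fa, as.character(panelSeqs(panel)[[s]]), scheme)
      if (is.null(h)) next
      e <- evalueOf(h$score, m, n, scheme)
      if (e > maxE) next
      hits[[length(hits) + 1L]] <- cbind(
        data.frame(frame = as.integer(fn), subject = s, evalue = e,
                   stringsAsFactors = FALSE), h,
        data.frame(aaseg = substr(fa, h$qstart, h$qend)))
    }
  }
  if (!length(hits)) return(NULL)
  hits <- do.call(rbind, hits)
  best <- hits[which.min(hits$evalue), ]
  same <- hits[hits$subject == best$subject &
                 sign(hits$frame) == sign(best$frame), , drop = FALSE]
  # query-order nt coordinates of each segment (forward strand)
  nt <- t(vapply(seq_len(nrow(same)), function(i)
    .frame_to_nt(same$frame[i], same$qstart[i], same$qend[i], qNtLen),
    integer(2)))
  same$nt_start <- nt[, 1]; same$nt_end <- nt[, 2]
  # order along the element (5'->3' of the coding strand)
  ord <- if (best$frame > 0) order(same$nt_start) else order(-same$nt_start)
  same <- same[ord, , drop = FALSE]
  segs <- character(); lastEnd <- -Inf
  used <- 0L
  for (i in seq_len(nrow(same))) {
    s <- if (best$frame > 0) same$nt_start[i] else -same$nt_start[i]
    e <- if (best$frame > 0) same$nt_end[i] else -same$nt_end[i]
    if (e <= lastEnd) next              # fully contained in previous segment
    aaseg <- as.character(same$aaseg[i])
    if (s <= lastEnd) {                 # trim the overlapping prefix
      trim <- ceiling((lastEnd - s + 1) / 3)
      aaseg <- substr(aaseg, trim + 1L, nchar(aaseg))
      if (!nchar(aaseg)) next
    }
    segs <- c(segs, aaseg)
    lastEnd <- max(lastEnd, e)
    used <- used + 1L
  }
  list(aa = paste(segs, collapse = ""), frame = best$frame,
       ref = best$subject, evalue = best$evalue, n_segments = used)
}

#' Extract domains for every family of a set
#'
#' @param families a \code{\linkS4class{TEFamilySet}}.
#' @param panel a \code{\linkS4class{ReferencePanel}}.
#' @param scheme calibrated amino-acid scheme.
#' @param maxE E-value ceiling.
#' @param minAA families whose domain is shorter are excluded.
#' @return list with \code{domains} (an \code{AAStringSet} named by family)
#'   and \code{excluded} (data.frame family_id, reason).
#' @export
extractDomains <- function(families, panel, scheme = NULL, maxE = 1e-5,
                           minAA = 100L) {
  if (is.null(scheme)) scheme <- aaScoringScheme()
  reps <- representatives(families)
  out <- character(); nm <- character(); excl <- list()
  for (f in names(reps)) {
    dom <- extractDomain(reps[[f]], panel, scheme = scheme, maxE = maxE)
    if (is.null(dom)) {
      excl[[length(excl) + 1L]] <- data.frame(family_id = f,
                                              reason = "no_panel_hit")
    } else if (nchar(dom$aa) < minAA) {
      excl[[length(excl) + 1L]] <- data.frame(family_id = f,
                                              reason = "short_domain")
    } else {
      aa <- gsub("*", "X", dom$aa, fixed = TRUE)
      out <- c(out, aa); nm <- c(nm, f)
    }
  }
  list(domains = stats::setNames(Biostrings::AAStringSet(out), nm),
       excluded = if (length(excl)) do.call(rbind, excl)
                  else data.frame(family_id = character(),
                                  reason = character()))
}

# k-mer (3-mer) Jaccard distance between amino-acid sequences
.kmer_dist <- function(chs, k = 3L) {
  sets <- lapply(chs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(chs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    u <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0) 1 else
      1 - length(intersect(sets[[i]], sets[[j]])) / u
  }
  d
}

#' Progressive multiple alignment of domain sequences
#'
#' Pairwise 3-mer distances feed a UPGMA guide tree; profiles are merged
#' along the tree by profile-profile global alignment under BLOSUM62 with
#' affine gaps. Every input residue appears in the output.
#'
#' @param domains an \code{AAStringSet} (or named character vector) of at
#'   least 3 sequences.
#' @param scheme amino-acid scheme used for profile scoring.
#' @return an \code{AAStringSet} of equal-width aligned sequences, in input
#'   order.
#' @export
alignDomains <- function(domains, scheme = NULL) {
  chs <- as.character(domains)
  names(chs) <- names(domains)
  if (length(chs) < 3) stop("alignment needs at least 3 sequences")
  if (is.null(names(chs))) names(chs) <- paste0("seq", seq_along(chs))
  if (is.null(scheme)) scheme <- aaScoringScheme()
  alphabet <- rownames(scheme@matrix)
  K <- length(alphabet)
  d <- .kmer_dist(chs)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # alignment state per active node: character matrix (rows = seqs)
  states <- lapply(chs, function(s) matrix(.seq_chars(s), nrow = 1))
  rowsOf <- as.list(seq_along(chs))
  profOf <- function(mat) {
    L <- ncol(mat)
    p <- matrix(0, K, L)
    for (j in seq_len(L)) {
      tab <- table(factor(mat[, j][mat[, j] != "-"], levels = alphabet))
      p[, j] <- as.numeric(tab) / nrow(mat)
    }
    p
  }
  merged <- vector("list", nrow(hc$merge))
  mergedRows <- vector("list", nrow(hc$merge))
  getState <- function(id) if (id < 0) states[[-id]] else merged[[id]]
  getRows <- function(id) if (id < 0) rowsOf[[-id]] else mergedRows[[id]]
  for (s in seq_len(nrow(hc$merge))) {
    a <- getState(hc$merge[s, 1]); b <- getState(hc$merge[s, 2])
    pr <- cpp_profile_align(profOf(a), profOf(b), scheme@matrix,
                            scheme@gapOpen, scheme@gapExtend)
    pa <- pr$path_a; pb <- pr$path_b
    L <- length(pa)
    out <- matrix("-", nrow(a) + nrow(b), L)
    out[seq_len(nrow(a)), pa > 0] <- a[, pa[pa > 0], drop = FALSE]
    out[nrow(a) + seq_len(nrow(b)), pb > 0] <- b[, pb[pb > 0], drop = FALSE]
    merged[[s]] <- out
    mergedRows[[s]] <- c(getRows(hc$merge[s, 1]), getRows(hc$merge[s, 2]))
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- order(mergedRows[[nrow(hc$merge)]])
  final <- final[ord, , drop = FALSE]
  res <- Biostrings::AAStringSet(apply(final, 1, paste, collapse = ""))
  names(res) <- names(chs)
  res
}

#' Pairwise-deletion distance matrix from an alignment
#'
#' Under pairwise deletion, each pair uses only the columns where both rows
#' are ungapped; under complete deletion, columns with any gap are dropped
#' for all pairs. The p-distance is optionally gamma-corrected,
#' \eqn{d = \alpha((1-p)^{-1/\alpha} - 1)} (shape \code{gammaShape}), the
#' rate-heterogeneous model distance used for the trees.
#'
#' @param msa an \code{AAStringSet} of aligned sequences (equal width).
#' @param params a \code{\link{phyloParams}} list.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distanceMatrix <- function(msa, params = phyloParams()) {
  chs <- as.character(msa)
  names(chs) <- names(msa)
  n <- length(chs)
  if (n < 2) stop("need at least 2 sequences")
  w <- unique(nchar(chs))
  if (length(w) != 1) stop("sequences must be aligned (equal width)")
  mat <- do.call(rbind, lapply(chs, .seq_chars))
  if (params$deletion == "complete") {
    keep <- colSums(mat == "-") == 0
    mat <- mat[, keep, drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(names(chs), names(chs)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(shared))
      stop("no shared columns between ", names(chs)[i], " and ", names(chs)[j])
    p <- mean(mat[i, shared] != mat[j, shared])
    d <- if (params$model == "p_distance") p else {
      a <- params$gammaShape
      pc <- min(p, 0.95)
      a * ((1 - pc)^(-1 / a) - 1)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Q-criterion agglomeration. On an additive distance matrix the
#' generating topology and branch lengths are recovered exactly. Ties in Q
#' are broken by lexicographic pair order (node creation order); negative
#' branch lengths are clamped to zero with the length transferred to the
#' sibling branch.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal and
#'   at least 3 rows; dimnames give the tip labels.
#' @return an \pkg{ape} \code{phylo} (unrooted; trifurcation at the root
#'   node).
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(D < -1e-12) || any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be non-negative with zero diagonal")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  # newick fragment per active node
  frag <- labs
  act <- seq_len(n)      # creation order ids for tie-breaking
  Dm <- D
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(act) > 3) {
    r <- length(act)
    rs <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(pmin(act[cand[, 1]], act[cand[, 2]]),
                 pmax(act[cand[, 1]], act[cand[, 2]]))
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    li <- Dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dk <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newFrag)
    act <- c(act[keep], max(act) + 1L)
  }
  # final three-way join (closed form)
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(l1), frag[2], fmt(l2),
                 frag[3], fmt(l3))
  ape::read.tree(text = nwk)
}

#' Bootstrap support for the full-data NJ tree
#'
#' Resamples alignment columns with replacement \code{bootstrapReps} times,
#' rebuilds the NJ tree per replicate and scores each internal edge of the
#' full-data tree by the percentage of replicates containing the same
#' bipartition. Supports are stored as internal node labels.
#'
#' @param msa aligned \code{AAStringSet}.
#' @param params a \code{\link{phyloParams}} list; \code{params$seed} drives
#'   the resampling.
#' @return the full-data \code{phylo} with \code{node.label} holding
#'   supports in percent (root label \code{NA}).
#' @export
bootstrapSupport <- function(msa, params = phyloParams()) {
  tree <- neighborJoining(distanceMatrix(msa, params))
  chs <- as.character(msa)
  names(chs) <- names(msa)
  mat <- do.call(rbind, lapply(chs, .seq_chars))
  rownames(mat) <- names(chs)
  btrees <- .with_seed(params$seed, {
    out <- list()
    for (b in seq_len(params$bootstrapReps)) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      sub <- Biostrings::AAStringSet(apply(mat[, cols, drop = FALSE], 1,
                                           paste, collapse = ""))
      names(sub) <- rownames(mat)
      bt <- tryCatch(neighborJoining(distanceMatrix(sub, params)),
                     error = function(e) NULL)
      if (!is.null(bt)) out[[length(out) + 1L]] <- bt
    }
    out
  })
  if (!length(btrees)) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(tree, btrees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(btrees)
  support[1] <- NA_real_                      # root of the unrooted display
  tree$node.label <- as.character(round(support, 1))
  attr(tree, "bootstrapReps") <- length(btrees)
  tree
}

# descendant tips per internal node
.node_tips <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  lapply(seq_along(pp), function(i) tree$tip.label[pp[[i]]])
}

#' Define clades on a supported tree
#'
#' Works on the unrooted bipartitions of the tree: each internal edge offers
#' its two leaf sides as candidate groups, scored by the edge's bootstrap
#' support. A candidate qualifies when its support strictly exceeds
#' \code{supportMin}, its families span at least \code{minSpecies} distinct
#' species, and it does not mix references of two or more known clades (a
#' composite group). Clades are the maximal qualifying candidates under set
#' containment; they are named after the references they contain (or
#' systematically when anchorless). Qualifying composite groups that are
#' unions of accepted clades are reported as lineages through the
#' \code{lineage} column. Families in no accepted group are labelled
#' \code{"other"}. An override list of family-id sets forces acceptance of a
#' group regardless of its support (the analyst's manual exception).
#'
#' @param tree a \code{phylo} with node labels from
#'   \code{\link{bootstrapSupport}}.
#' @param speciesMap named character vector: family id -> species.
#' @param params a \code{\link{phyloParams}} list.
#' @param overrides list of character vectors of family ids; a candidate
#'   whose family set equals one of them is accepted regardless of support.
#' @param refClades optional named character vector (leaf id -> known clade)
#'   for reference sequences included in the tree; references anchor clade
#'   names and veto composite groups, and are excluded from the output.
#' @return data.frame with columns \code{clade}, \code{family_id},
#'   \code{species}, \code{support}, \code{lineage} (\code{NA} or the name
#'   of a qualifying union of clades); unplaced families have
#'   \code{clade == "other"}.
#' @export
defineClades <- function(tree, speciesMap, params = phyloParams(),
                         overrides = list(), refClades = NULL) {
  tips <- tree$tip.label
  missing <- setdiff(setdiff(tips, names(refClades)), names(speciesMap))
  if (length(missing))
    stop("no species mapping for: ", paste(missing, collapse = ", "))
  n <- length(tips)
  nodeTips <- .node_tips(tree)        # indexed by internal node - n
  support <- suppressWarnings(as.numeric(tree$node.label))
  if (length(support) != length(nodeTips))
    support <- rep(NA_real_, length(nodeTips))
  refIds <- names(refClades)
  spOf <- function(ids) unique(stats::na.omit(speciesMap[ids]))

  # Candidate groups. With references in the tree, both sides of every
  # internal edge are candidates and reference mixing vetoes composite sides
  # (root placement then cannot hide a clade). Without references there is no
  # anchor to tell a clade from the union on the far side of its edge, so
  # only the rooted descendant sides are considered — the literal maximal
  # reading; include labelled references for root-independent calls.
  useComplements <- length(refIds) > 0
  cand <- list()
  for (i in seq_along(nodeTips)) {
    if (i == 1L) next
    side <- nodeTips[[i]]
    grps <- if (useComplements) list(side, setdiff(tips, side)) else list(side)
    for (grp in grps) {
      if (length(grp) < 2 || length(grp) >= n) next
      cand[[length(cand) + 1L]] <- list(ids = grp, support = support[i])
    }
  }
  if (!length(cand)) cand <- list()
  qualifies <- vapply(cand, function(cc) {
    fams <- setdiff(cc$ids, refIds)
    if (!length(fams)) return(FALSE)
    if (any(vapply(overrides, function(o) setequal(o, fams), logical(1))))
      return(TRUE)
    refs <- unique(refClades[intersect(cc$ids, refIds)])
    if (length(refs) >= 2) return(FALSE)      # composite: spans known clades
    !is.na(cc$support) && cc$support > params$supportMin &&
      length(spOf(fams)) >= params$minSpecies
  }, logical(1))
  q <- which(qualifies)
  # maximal qualifying candidates under strict set containment
  isSubset <- function(a, b) length(a) < length(b) && all(a %in% b)
  maximal <- q[vapply(q, function(i)
    !any(vapply(setdiff(q, i), function(j)
      isSubset(cand[[i]]$ids, cand[[j]]$ids), logical(1))), logical(1))]
  # drop duplicated leaf sets (an edge can be seen from both ends)
  sig <- vapply(maximal, function(i)
    paste(sort(cand[[i]]$ids), collapse = "\r"), character(1))
  maximal <- maximal[!duplicated(sig)]
  # greedy disjointness: larger, better-supported groups first
  if (length(maximal) > 1) {
    ord <- order(-vapply(maximal, function(i) length(cand[[i]]$ids), numeric(1)),
                 -vapply(maximal, function(i)
                   ifelse(is.na(cand[[i]]$support), 101, cand[[i]]$support),
                   numeric(1)))
    maximal <- maximal[ord]
    taken <- character()
    keep <- logical(length(maximal))
    for (k in seq_along(maximal)) {
      ids <- cand[[maximal[k]]]$ids
      if (!any(ids %in% taken)) {
        keep[k] <- TRUE
        taken <- c(taken, ids)
      }
    }
    maximal <- maximal[keep]
  }

  rows <- list()
  cladeCount <- 0L
  for (i in maximal) {
    ids <- setdiff(cand[[i]]$ids, refIds)
    refs <- refClades[intersect(cand[[i]]$ids, refIds)]
    nm <- if (length(refs)) names(sort(table(refs), decreasing = TRUE))[1]
          else { cladeCount <- cladeCount + 1L; sprintf("clade_%d", cladeCount) }
    rows[[length(rows) + 1L]] <- data.frame(
      clade = nm, family_id = ids, species = unname(speciesMap[ids]),
      support = cand[[i]]$support, lineage = NA_character_,
      stringsAsFactors = FALSE)
  }
  # same-name groups are fragments of one clade around the display root
  if (length(rows) >= 2) {
    nms <- vapply(rows, function(r) r$clade[1], character(1))
    rows <- lapply(unique(nms), function(nm) {
      m <- do.call(rbind, rows[nms == nm])
      m$support <- min(m$support)
      m
    })
  }
  # lineages: well-supported multi-species unions of >= 2 accepted clades
  if (length(rows) >= 2) {
    cladeSets <- lapply(rows, function(r) r$family_id)
    lineageCount <- 0L
    for (cc in cand) {
      fams <- setdiff(cc$ids, refIds)
      if (is.na(cc$support) || cc$support <= params$supportMin) next
      if (length(spOf(fams)) < params$minSpecies) next
      inside <- vapply(cladeSets, function(s) all(s %in% fams), logical(1))
      covered <- all(fams %in% unlist(cladeSets[inside]))
      if (sum(inside) >= 2 && covered) {
        lineageCount <- lineageCount + 1L
        ln <- sprintf("lineage_%d", lineageCount)
        for (r in which(inside))
          rows[[r]]$lineage <- ifelse(is.na(rows[[r]]$lineage), ln,
                                      rows[[r]]$lineage)
      }
    }
  }
  placed <- unlist(lapply(rows, function(r) r$family_id))
  others <- setdiff(setdiff(tips, refIds), placed)
  if (length(others))
    rows[[length(rows) + 1L]] <- data.frame(
      clade = "other", family_id = others,
      species = unname(speciesMap[others]), support = NA_real_,
      lineage = NA_character_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
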