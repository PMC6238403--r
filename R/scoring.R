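# Scoring schemes and Karlin-Altschul calibration.

# Robinson & Robinson amino-acid background frequencies (the standard BLAST
# ungapped background).
.AA_BG <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
            Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
            L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
            S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Nucleotide scoring scheme
#'
#' Builds a match/mismatch nucleotide scheme over the alphabet ACGTN. N
#' scores 0 against everything, so masked stretches neither help nor hurt a
#' local alignment. Defaults follow the common BLASTn-style parameters
#' (match +2, mismatch -3, gap 5/2).
#'
#' @param match,mismatch match reward and mismatch penalty.
#' @param gapOpen,gapExtend affine gap penalties; a gap of length k costs
#'   \code{gapOpen + k * gapExtend}.
#' @param bg background base frequencies (named, over ACGT).
#' @param calibrate if \code{TRUE} (default) the Karlin-Altschul parameters
#'   are solved immediately.
#' @return a \code{\linkS4class{ScoringScheme}}.
#' @export
ntScoringScheme <- function(match = 2, mismatch = -3, gapOpen = 5,
                            gapExtend = 2, bg = c(A = .25, C = .25, G = .25, T = .25),
                            calibrate = TRUE) {
  ab <- c(NT_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  s <- new("ScoringScheme", type = "nt", matrix = m, gapOpen = gapOpen,
           gapExtend = gapExtend, bg = bg[NT_BASES])
  if (calibrate) calibrateScheme(s) else s
}

#' Amino-acid scoring scheme
#'
#' BLOSUM62 with gap penalties 11/1 by default, calibrated against the
#' Robinson-Robinson background frequencies.
#'
#' @param matrix a named substitution matrix (default BLOSUM62 from
#'   \pkg{Biostrings}).
#' @inheritParams ntScoringScheme
#' @return a \code{\linkS4class{ScoringScheme}}.
#' @export
aaScoringScheme <- function(matrix = NULL, gapOpen = 11, gapExtend = 1,
                            bg = .AA_BG, calibrate = TRUE) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  s <- new("ScoringScheme", type = "aa", matrix = matrix, gapOpen = gapOpen,
           gapExtend = gapExtend, bg = bg)
  if (calibrate) calibrateScheme(s) else s
}

#' Solve the Karlin-Altschul parameters of a scheme
#'
#' lambda is the unique positive root of
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}, solved to a residual below
#' 1e-9. K is computed by the standard ungapped lattice approximation: with
#' step distribution q over the integer scores, span delta (the gcd of score
#' differences) and relative entropy
#' \eqn{H = \lambda \sum_j j\, q(j) e^{\lambda j}},
#' \deqn{K = \frac{\delta\, \lambda\, e^{-2\sigma}}{H\,(1 - e^{-\lambda\delta})},
#'   \quad \sigma = \sum_{k \ge 1} \frac1k \Big(\Pr(S_k \ge 0) +
#'   \mathrm{E}\big[e^{\lambda S_k}; S_k < 0\big]\Big).}
#'
#' @param scheme an uncalibrated \code{\linkS4class{ScoringScheme}}.
#' @param kIter number of terms of the sigma series (25 is ample for the
#'   matrices used here).
#' @return the scheme with \code{lambda} and \code{K} filled in.
#' @export
calibrateScheme <- function(scheme, kIter = 25L) {
  stopifnot(is(scheme, "ScoringScheme"))
  p <- scheme@bg / sum(scheme@bg)
  S <- scheme@matrix[names(p), names(p)]
  pp <- outer(p, p)
  es <- sum(pp * S)
  if (es >= 0)
    stop("expected score under the background must be negative")
  if (max(S) <= 0)
    stop("no positive score achievable: cannot calibrate")
  f <- function(l) sum(pp * exp(l * S)) - 1
  hi <- 0.5
  while (f(hi) < 0) hi <- hi * 2
  lambda <- stats::uniroot(f, c(1e-8, hi), tol = 1e-14)$root
  # Newton polish to push the defining identity below 1e-9
  for (i in 1:8) {
    fv <- f(lambda)
    if (abs(fv) < 1e-12) break
    fp <- sum(pp * S * exp(lambda * S))
    lambda <- lambda - fv / fp
  }
  if (abs(f(lambda)) > 1e-9)
    stop("lambda did not converge")

  # integer step-score distribution
  sv <- round(as.vector(S))
  if (max(abs(as.vector(S) - sv)) > 1e-9)
    stop("K approximation requires integer scores")
  q <- tapply(as.vector(pp), sv, sum)
  sval <- as.integer(names(q))
  q <- as.numeric(q)
  delta <- Reduce(function(a, b) {
    while (b) { t <- b; b <- a %% b; a <- t }
    a
  }, abs(sval[sval != 0L]))
  if (length(delta) == 0 || delta == 0) delta <- 1L

  # sigma by repeated convolution of the lattice distribution
  lo <- min(sval) * kIter
  conv <- numeric(max(sval) * kIter - lo + 1)     # S_k distribution on lattice
  step <- numeric(length(conv))
  step[sval - lo + 1] <- q                         # offset so index 1 == lo
  sigma <- 0
  cur <- NULL
  for (k in seq_len(kIter)) {
    if (k == 1) {
      cur <- numeric(length(conv))
      cur[sval - lo + 1] <- q
    } else {
      nxt <- numeric(length(conv))
      nz <- which(cur > 0)
      for (j in seq_along(sval)) {
        idx <- nz + sval[j]
        ok <- idx >= 1 & idx <= length(nxt)
        nxt[idx[ok]] <- nxt[idx[ok]] + cur[nz[ok]] * q[j]
      }
      cur <- nxt
    }
    vals <- (seq_along(cur) + lo - 1L)
    nz <- which(cur > 0)
    term <- sum(cur[nz] * ifelse(vals[nz] >= 0, 1, exp(lambda * vals[nz])))
    sigma <- sigma + term / k
  }
  H <- lambda * sum(q * sval * exp(lambda * sval))
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  scheme@lambda <- lambda
  scheme@K <- max(K, 1e-6)
  validObject(scheme)
  scheme
}

#' E-value of a raw local-alignment score
#'
#' \eqn{E = K m n e^{-\lambda S}}: the expected number of chance local
#' alignments scoring at least S between a query of length m and a database
#' of total length n.
#'
#' @param score raw alignment score (vectorised).
#' @param m query length.
#' @param n total database length (sum of subject lengths).
#' @param scheme a calibrated \code{\linkS4class{ScoringScheme}}.
#' @return numeric E-value(s).
#' @export
evalueOf <- function(score, m, n, scheme) {
  if (is.na(scheme@lambda)) stop("scheme is not calibrated")
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  scheme@K * m * n * exp(-scheme@lambda * score)
}

# log10 E-value, safe against underflow of exp(-lambda*S)
.log10_evalue <- function(score, m, n, scheme) {
  log10(scheme@K) + log10(m) + log10(n) - scheme@lambda * score / log(10)
}

#' @rdname evalueOf
#' @export
bitScoreOf <- function(score, scheme) {
  (scheme@lambda * score - log(scheme@K)) / log(2)
}
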