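# Shared fixtures: built once per test run, in code.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_bases <- function(seq, n, seed = 1) {
  set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  idx <- sample(length(v), n)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# naive full-DP affine local alignment, independent of the package kernel:
# plain R loops over the three-state recurrence
naive_sw <- function(a, b, mat, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1); X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0; M[, 1] <- 0   # local: fresh starts allowed anywhere
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge,
                     Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge,
                     Y[i, j - 1] - ge)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  max(best, 0)
}

# one small planted genome reused by several files (cached per session)
.fixture_env <- new.env()
small_planted <- function() {
  if (is.null(.fixture_env$pg)) {
    lib <- buildElementLibrary(nClades = 3, familiesPerClade = 2, seed = 1)
    .fixture_env$lib <- lib
    .fixture_env$pg <- plantCopies(lib, plantSpec(
      nContigs = 2, contigLength = 200000, copiesPerFamily = 1, seed = 7))
  }
  list(lib = .fixture_env$lib, pg = .fixture_env$pg)
}

aa_scheme <- function() {
  if (is.null(.fixture_env$aa)) .fixture_env$aa <- aaScoringScheme()
  .fixture_env$aa
}

nt_scheme <- function() {
  if (is.null(.fixture_env$nt)) .fixture_env$nt <- ntScoringScheme()
  .fixture_env$nt
}
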