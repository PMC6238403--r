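# Internal helpers shared across modules.

NT_BASES <- c("A", "C", "G", "T")

.seq_chars <- function(x) {
  strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1]]
}

# integer codes into a scheme's matrix alphabet; unknown letters map to the
# scheme's wildcard (N for nt, X for aa)
.codes <- function(x, scheme) {
  alphabet <- rownames(scheme@matrix)
  codes <- match(.seq_chars(x), alphabet)
  wild <- match(if (scheme@type == "nt") "N" else "X", alphabet)
  codes[is.na(codes)] <- wild
  codes
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(abs(seed) %% (.Machine$integer.max - 1L)))
  force(expr)
}

# derive a reproducible sub-seed (keeps values well below 2^31)
.subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

.random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(NT_BASES, n, replace = TRUE, prob = p), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# union-find with path compression; returns component id per element
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in edges) {
      ra <- find(e[1]); rb <- find(e[2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

# maximal runs of TRUE as a 2-col matrix (start, end)
.true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

.stopifnot_named <- function(x, what) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop(what, " must be named", call. = FALSE)
}
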