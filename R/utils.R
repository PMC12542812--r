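#' @importFrom stats setNames
NULL

# Aligned sequences as a character matrix (rows = sequences).
alnMatrix <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  stopifnot(length(unique(nchar(seqs))) <= 1L)
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# Collapse a character matrix back into named strings.
matrixAln <- function(m) {
  setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}

# Maximal runs of TRUE in a logical vector, as an integer matrix with
# columns start0/end0 (0-based half-open).
logicalRuns <- function(x) {
  if (!length(x) || !any(x)) {
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start0", "end0"))))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start0 = starts[keep], end0 = ends[keep])
}

# Deterministic 31-bit seed derived from a base seed and a string key, so
# per-locus random draws are independent of processing order.
substreamSeed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(as.character(key))) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Reverse complement that tolerates the mask and gap symbols.
revCompMasked <- function(s) {
  rev <- paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  chartr("ACGTacgtNn", "TGCAtgcaNn", rev)
}

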