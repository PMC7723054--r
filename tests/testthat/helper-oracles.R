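# Independent brute-force oracles and random-structure generators used by the
# property tests. Everything here works directly on pair tables with plain
# scans — none of it shares code with the tree-walk implementation.

# random balanced dot-bracket string of length n (non-crossing, hairpin
# loops >= 3); recursive construction
randomDotBracket <- function(n, pPair = 0.6) {
  if (n <= 0) return("")
  if (n < 7 || runif(1) > pPair) {
    k <- sample.int(min(3L, n), 1L)
    return(paste0(strrep(".", k), randomDotBracket(n - k, pPair)))
  }
  m <- sample(7:n, 1L)  # enclosed substructure incl. its closing pair
  paste0("(", randomDotBracket(m - 2L, pPair), ")",
         randomDotBracket(n - m, pPair))
}

randomSequence <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

randomStructure <- function(n = sample(30:90, 1L), id = "rnd") {
  db <- randomDotBracket(n)
  parseDotBracket(id, randomSequence(nchar(db)), db, warnDNA = FALSE)
}

# pair table scans ------------------------------------------------------------

.oracleTopLevelHelices <- function(pt, a, b) {
  out <- list()
  p <- a
  while (p <= b) {
    if (pt[p] == 0L) {
      p <- p + 1L
    } else {
      out[[length(out) + 1L]] <- c(p, pt[p])
      p <- pt[p] + 1L
    }
  }
  out
}

.oracleHairpinCount <- function(pt, i, j) {
  sum(vapply(i:j, function(a) {
    if (pt[a] <= a) return(FALSE)
    b <- pt[a]
    if (b > j) return(FALSE)
    a + 1L > b - 1L || all(pt[(a + 1L):(b - 1L)] == 0L)
  }, logical(1)))
}

# the pair directly enclosing (i, j), or NULL (external)
.oracleEnclosingPair <- function(pt, i, j) {
  cand <- which(seq_along(pt) < i & pt > j)
  if (!length(cand)) return(NULL)
  p <- max(cand)
  c(p, pt[p])
}

# is the element directly enclosing pair (i, j) branched (>= 2 helices) or
# the external loop?
.oracleEnclosureBranchedOrExternal <- function(pt, i, j) {
  enc <- .oracleEnclosingPair(pt, i, j)
  if (is.null(enc)) return(TRUE)
  length(.oracleTopLevelHelices(pt, enc[1L] + 1L, enc[2L] - 1L)) >= 2L
}

# brute-force single-terminal motif intervals: pairs enclosing exactly one
# hairpin whose enclosing element is branched or external
oracleSingleTerminalSet <- function(s) {
  pt <- pairTable(s)
  op <- which(pt > seq_along(pt))
  keep <- vapply(op, function(i) {
    j <- pt[i]
    .oracleHairpinCount(pt, i, j) == 1L &&
      .oracleEnclosureBranchedOrExternal(pt, i, j)
  }, logical(1))
  ivs <- lapply(op[keep], function(i) c(i, pt[i]))
  ivs[order(vapply(ivs, `[`, integer(1), 1L))]
}

# brute-force multi-terminal motifs: one per junction-closing pair (a pair
# whose direct interior holds >= 2 helices), spanned by the outward walk
# through unbranched enclosures
oracleMultiTerminalSet <- function(s) {
  pt <- pairTable(s)
  op <- which(pt > seq_along(pt))
  closers <- op[vapply(op, function(i) {
    length(.oracleTopLevelHelices(pt, i + 1L, pt[i] - 1L)) >= 2L
  }, logical(1))]
  ivs <- lapply(closers, function(i) {
    cur <- c(i, pt[i])
    repeat {
      # outermost pair of the current helix
      while (cur[1L] > 1L && cur[2L] < length(pt) &&
             pt[cur[1L] - 1L] == cur[2L] + 1L) {
        cur <- c(cur[1L] - 1L, cur[2L] + 1L)
      }
      enc <- .oracleEnclosingPair(pt, cur[1L], cur[2L])
      if (is.null(enc)) break
      if (length(.oracleTopLevelHelices(pt, enc[1L] + 1L,
                                        enc[2L] - 1L)) != 1L) break
      cur <- enc
    }
    cur
  })
  ivs <- unique(ivs)
  ivs[order(vapply(ivs, `[`, integer(1), 1L))]
}

asIntervalKey <- function(ivs) {
  vapply(ivs, function(x) paste(x, collapse = "-"), character(1))
}

# regex oracle for the canonical G-quadruplex pattern
oracleG4Regex <- function(seq, gMin = 2L, nTracts = 4L, loopMax = 7L) {
  pattern <- sprintf("G{%d,}([ACGUN]{1,%d}G{%d,}){%d}",
                     gMin, loopMax, gMin, nTracts - 1L)
  grepl(pattern, seq, perl = TRUE)
}
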