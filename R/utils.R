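## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats median sd rlnorm runif setNames aggregate wilcox.test
#' @importFrom utils read.table write.table head
NULL

## Classed conditions so callers can distinguish validation failures.
.stop2 <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "stemlooplib_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

## Evaluate `code` with a temporary RNG state seeded from `seed`; the caller's
## RNG stream is untouched.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a per-item sub-seed below 2^31 from a master seed.
.subSeed <- function(seed, i) {
  (abs(as.integer(seed)) + 7919L * as.integer(i)) %% 2147483629L + 1L
}

.toRNA <- function(x) chartr("Tt", "Uu", toupper(x))
.toDNA <- function(x) chartr("Uu", "Tt", toupper(x))

## scalar reverse complements; vectorised callers go through Biostrings
.revString <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.revCompDNA <- function(x) chartr("ACGTN", "TGCAN", .revString(x))

.revCompRNA <- function(x) chartr("ACGUN", "UGCAN", .revString(x))

## Hamming distance between equal-length strings.
.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

.gcFraction <- function(x) {
  ch <- strsplit(toupper(x), "")[[1]]
  mean(ch %in% c("G", "C"))
}
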