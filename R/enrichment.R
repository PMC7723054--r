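## Sequence/structure interpretation of binding profiles: k-mer
## relative-frequency enrichment, PFM building, structural-context motif
## analysis and G-quadruplex G-tract scanning.

.allKmers <- function(k) {
  bases <- c("A", "C", "G", "U")
  out <- bases
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      out <- as.vector(outer(out, bases, paste0))
    }
  }
  sort(out)
}

## overlapping forward-strand k-mer occurrence counts over all 4^k k-mers
.countKmers <- function(seqs, k, kmers = .allKmers(k)) {
  counts <- setNames(numeric(length(kmers)), kmers)
  short <- 0L
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) {
      short <- short + 1L
      next
    }
    wins <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    tb <- table(wins)
    hit <- intersect(names(tb), kmers)
    counts[hit] <- counts[hit] + as.numeric(tb[hit])
  }
  if (short > 0L) {
    warning(sprintf("%d sequence%s shorter than k = %d contributed no counts",
                    short, if (short == 1L) "" else "s", k), call. = FALSE)
  }
  counts
}

#' K-mer relative-frequency enrichment
#'
#' Counts overlapping forward-strand k-mers (occurrence counting, step 1) in
#' an enriched set (e.g. the top 5% of a binding profile) and in the whole
#' population, normalizes each count by its set's total, and forms the
#' relative frequency \code{RF(k) = normCount_enriched / normCount_all}.
#' K-mers whose Z-score over all 4^k relative frequencies exceeds
#' \code{zThreshold} are selected, sorted by RF descending. When any
#' population count is zero, a pseudocount is added to both raw count vectors
#' before normalization so RF stays finite.
#'
#' @param enrichedSeqs,allSeqs character vectors of RNA sequences (T
#'   normalized to U).
#' @param k k-mer length (default 4).
#' @param zThreshold selection threshold on the RF Z-score (default 2.58).
#' @param pseudocount added to raw counts when needed (default 0.5).
#' @return list with \code{$table} (kmer, count_enriched, count_all,
#'   norm_enriched, norm_all, relative_frequency, z_score; one row per 4^k
#'   k-mer) and \code{$selected} (selected k-mers, RF-descending).
#' @export
kmerEnrichment <- function(enrichedSeqs, allSeqs, k = 4L, zThreshold = 2.58,
                           pseudocount = 0.5) {
  stopifnot(k >= 1L)
  if (!length(enrichedSeqs)) {
    .stop2("enrichError", "enriched sequence set is empty")
  }
  enrichedSeqs <- .toRNA(enrichedSeqs)
  allSeqs <- .toRNA(allSeqs)
  kmers <- .allKmers(k)
  ce <- .countKmers(enrichedSeqs, k, kmers)
  ca <- .countKmers(allSeqs, k, kmers)
  if (any(ca == 0)) {
    ce <- ce + pseudocount
    ca <- ca + pseudocount
  }
  ne <- ce / sum(ce)
  na <- ca / sum(ca)
  rf <- ne / na
  sdrf <- sd(rf)
  z <- if (sdrf > 0) (rf - mean(rf)) / sdrf else rep(0, length(rf))
  tab <- data.frame(
    kmer = kmers, count_enriched = unname(ce), count_all = unname(ca),
    norm_enriched = unname(ne), norm_all = unname(na),
    relative_frequency = unname(rf), z_score = unname(z),
    stringsAsFactors = FALSE
  )
  sel <- tab[!is.na(tab$z_score) & tab$z_score > zThreshold, , drop = FALSE]
  sel <- sel[order(-sel$relative_frequency, sel$kmer), , drop = FALSE]
  list(table = tab, selected = sel$kmer)
}

#' Build a position frequency matrix from selected k-mers
#'
#' A greedy ungapped alignment: the first k-mer (pass them RF-descending) is
#' the anchor at offset 0; each further k-mer is placed at the offset
#' (|shift| <= k - 1) maximizing matches to the current majority consensus,
#' ties resolved toward smaller |shift| and then the leftmost shift. Returns
#' column-wise base frequencies and the majority consensus (ties alphabetic).
#'
#' @param kmers character vector of equal-length k-mers, highest priority
#'   first.
#' @param weights optional per-k-mer weights (default 1).
#' @return list with \code{$pfm} (4 x width frequency matrix, rows A/C/G/U),
#'   \code{$consensus} (string) and \code{$offsets} (named integer vector).
#' @examples
#' buildPFM(c("GCAC", "CACG"))$consensus  # "GCACG"
#' @export
buildPFM <- function(kmers, weights = NULL) {
  stopifnot(length(kmers) >= 1L)
  kmers <- .toRNA(kmers)
  k <- nchar(kmers[1L])
  stopifnot(all(nchar(kmers) == k))
  if (is.null(weights)) weights <- rep(1, length(kmers))
  bases <- c("A", "C", "G", "U")
  lo <- -(k - 1L); hi <- (k - 1L) + k - 1L  # column index range, 0-based
  width <- hi - lo + 1L
  counts <- matrix(0, 4L, width, dimnames = list(bases, NULL))
  addKmer <- function(counts, km, shift, w) {
    ch <- strsplit(km, "")[[1]]
    for (p in seq_len(k)) {
      col <- shift + p - 1L - lo + 1L
      counts[ch[p], col] <- counts[ch[p], col] + w
    }
    counts
  }
  consensusOf <- function(counts) {
    apply(counts, 2L, function(col) {
      if (all(col == 0)) NA_character_ else bases[which.max(col)]
    })
  }
  offsets <- integer(length(kmers))
  counts <- addKmer(counts, kmers[1L], 0L, weights[1L])
  if (length(kmers) > 1L) {
    for (i in 2L:length(kmers)) {
      cons <- consensusOf(counts)
      ch <- strsplit(kmers[i], "")[[1]]
      shifts <- (-(k - 1L)):(k - 1L)
      score <- vapply(shifts, function(sh) {
        cols <- sh + seq_len(k) - 1L - lo + 1L
        sum(!is.na(cons[cols]) & cons[cols] == ch, na.rm = TRUE)
      }, numeric(1))
      best <- order(-score, abs(shifts), shifts)[1L]
      offsets[i] <- shifts[best]
      counts <- addKmer(counts, kmers[i], shifts[best], weights[i])
    }
  }
  used <- which(colSums(counts) > 0)
  counts <- counts[, used, drop = FALSE]
  pfm <- sweep(counts, 2L, colSums(counts), "/")
  colnames(pfm) <- seq_len(ncol(pfm))
  consensus <- paste(apply(counts, 2L, function(col) {
    bases[which.max(col)]
  }), collapse = "")
  names(offsets) <- kmers
  list(pfm = pfm, consensus = consensus, offsets = offsets)
}

#' Structural-context analysis of a sequence motif
#'
#' Finds every (possibly overlapping) occurrence of a motif in each
#' structure's sequence and labels its context from the pairing status of the
#' matched positions: \code{loop} (all unpaired), \code{stem} (all paired),
#' else \code{mixed}. When a binding profile is supplied, occurrences are
#' linked to intensities, contexts are summarized (n, mean, median), and loop
#' vs stem intensities are compared with a Wilcoxon rank-sum test (delegated
#' to \code{stats::wilcox.test}).
#'
#' @param motif motif string (e.g. "GCAC").
#' @param structures list of [SecondaryStructure-class].
#' @param profile optional binding-profile data.frame keyed by the structure
#'   ids.
#' @return list with \code{$occurrences} (structure_id, start, end, context,
#'   intensity), \code{$summary} (per context: n, mean, median intensity) and
#'   \code{$test} (htest or NULL).
#' @export
motifContextAnalysis <- function(motif, structures, profile = NULL) {
  stopifnot(nzchar(motif))
  motif <- .toRNA(motif)
  L <- nchar(motif)
  if (is(structures, "SecondaryStructure")) structures <- list(structures)
  rows <- list()
  for (s in structures) {
    hits <- gregexpr(paste0("(?=", motif, ")"), s@sequence, perl = TRUE)[[1]]
    if (hits[1L] == -1L) next
    for (p in as.integer(hits)) {
      paired <- s@pairTable[p:(p + L - 1L)] > 0L
      context <- if (all(!paired)) "loop" else if (all(paired)) "stem"
                 else "mixed"
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = s@id, start = p, end = p + L - 1L, context = context,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(list(occurrences = data.frame(structure_id = character(0),
                                         start = integer(0), end = integer(0),
                                         context = character(0),
                                         intensity = numeric(0)),
                summary = NULL, test = NULL))
  }
  occ <- do.call(rbind, rows)
  occ$intensity <- if (!is.null(profile)) {
    profile$intensity[match(occ$structure_id, profile$structure_ref)]
  } else {
    NA_real_
  }
  summary <- do.call(rbind, lapply(split(occ, occ$context), function(g) {
    data.frame(context = g$context[1L], n = nrow(g),
               mean_intensity = mean(g$intensity),
               median_intensity = median(g$intensity),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  test <- NULL
  loopI <- occ$intensity[occ$context == "loop"]
  stemI <- occ$intensity[occ$context == "stem"]
  if (!is.null(profile) && length(loopI) >= 2L && length(stemI) >= 2L &&
      all(is.finite(c(loopI, stemI)))) {
    test <- wilcox.test(loopI, stemI, exact = FALSE)
  }
  list(occurrences = occ, summary = summary, test = test)
}

#' Scan a sequence for G-tracts and canonical G-quadruplex patterns
#'
#' Reports the G number (literal count of guanines), the maximal runs of at
#' least \code{gMin} consecutive G, and whether a canonical G-quadruplex
#' pattern exists: \code{nTracts} tracts of >= \code{gMin} G separated by
#' loops of 1..\code{loopMax} nt (loops may themselves contain G). The search
#' is a memoised tract/loop decomposition, so tract boundaries inside longer
#' G runs are considered.
#'
#' @param seq RNA string.
#' @param gMin minimum tract length (default 2, covering two-tier
#'   quadruplexes).
#' @param nTracts tracts required (default 4).
#' @param loopMax maximum loop length (default 7).
#' @return list with \code{$g_number}, \code{$g_tracts} (data.frame start,
#'   length of maximal runs >= gMin) and \code{$canonical_g4} (logical).
#' @examples
#' scanG4("GGGAGGGAGGGAGGG")$canonical_g4  # TRUE
#' scanG4(strrep("GAA", 16))$canonical_g4  # FALSE (no tract of >= 2 G)
#' @export
scanG4 <- function(seq, gMin = 2L, nTracts = 4L, loopMax = 7L) {
  seq <- .toRNA(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  isG <- ch == "G"
  gNumber <- sum(isG)
  ## length of the G run starting at each position
  runG <- integer(n)
  if (n >= 1L && isG[n]) runG[n] <- 1L
  if (n >= 2L) {
    for (i in (n - 1L):1L) if (isG[i]) runG[i] <- runG[i + 1L] + 1L
  }
  starts <- which(runG >= gMin & c(TRUE, !isG[-n])[seq_len(n)])
  tracts <- data.frame(start = starts, length = runG[starts])
  ## memoised search: can `t` tracts be laid down with the first starting at i?
  memo <- matrix(NA, nrow = n + 1L, ncol = nTracts)
  fits <- function(i, t) {
    if (i > n - gMin + 1L) return(FALSE)
    if (!is.na(memo[i, t])) return(memo[i, t])
    res <- FALSE
    if (runG[i] >= gMin) {
      if (t == 1L) {
        res <- TRUE
      } else {
        for (len in gMin:runG[i]) {
          for (lp in 1L:loopMax) {
            nxt <- i + len + lp
            if (nxt <= n && fits(nxt, t - 1L)) {
              res <- TRUE
              break
            }
          }
          if (res) break
        }
      }
    }
    memo[i, t] <<- res
    res
  }
  canonical <- FALSE
  if (n >= nTracts * gMin + (nTracts - 1L)) {
    for (i in which(isG)) {
      if (fits(i, nTracts)) {
        canonical <- TRUE
        break
      }
    }
  }
  list(g_number = gNumber, g_tracts = tracts, canonical_g4 = canonical)
}
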