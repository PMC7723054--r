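## Pre-miRNA terminal-loop extraction from miRBase-style hairpin records.

#' Construct a MiRBaseHairpin record
#'
#' @param geneId gene name (e.g. "hsa-mir-21").
#' @param sequence,dotbracket the precursor hairpin sequence and structure.
#' @param matures data.frame with columns name, start, end (1-based inclusive
#'   hairpin coordinates), 1 or 2 rows.
#' @return a [MiRBaseHairpin-class].
#' @export
miRBaseHairpin <- function(geneId, sequence, dotbracket, matures) {
  s <- parseDotBracket(geneId, sequence, dotbracket, warnDNA = FALSE)
  matures$start <- as.integer(matures$start)
  matures$end <- as.integer(matures$end)
  new("MiRBaseHairpin", geneId = geneId, structure = s,
      matures = matures[, c("name", "start", "end"), drop = FALSE])
}

.loopRejection <- function(geneId, reason) {
  list(status = "rejected", gene_id = geneId, reason = reason)
}

## Choose the terminal hairpin loop used for the extraction. Single-hairpin
## precursors use their only hairpin; multi-hairpin precursors use the hairpin
## enclosed by both mature arms (rejected when undeterminable).
.chooseTerminalLoop <- function(h, tree) {
  hp <- enumerateHairpins(tree)
  if (!nrow(hp)) return(NULL)
  if (nrow(hp) == 1L) return(hp[1L, , drop = FALSE])
  m <- h@matures
  if (nrow(m) == 2L) {
    lo <- min(m$end); hi <- max(m$start)
    cand <- hp[hp$loop_start > lo & hp$loop_end < hi, , drop = FALSE]
    if (nrow(cand) == 1L) return(cand)
  }
  NULL
}

#' Extract the pre-miRNA terminal loop of a hairpin record
#'
#' The loop region is bounded near the Dicer cleavage site: (a) the defining
#' mature is the single mature, or of two matures the one whose loop-side end
#' lies farther from the terminal loop (i.e. closer to the basal end), ties
#' broken toward the 5' arm; (b) the mature's loop-side end is its 3' end on
#' the 5' arm and its 5' end on the 3' arm; (c) the loop boundary starts at
#' the \code{matureOffset + 1}-th nucleotide counting from that end toward the
#' basal side (the loop-side terminal nucleotide counts as 1; the default
#' offset 3 makes the boundary the 4th nucleotide); (d) the other boundary is
#' the pairing partner of that position ("same column"); when the position is
#' unpaired the nearest paired position toward the basal end is used and the
#' record is flagged as a fallback; (e) loops longer than \code{limit} are
#' rejected.
#'
#' @param h a [MiRBaseHairpin-class].
#' @param limit maximum loop length in nt (default 86).
#' @param matureOffset nucleotides retreated from the loop-side end (3 =
#'   boundary at the 4th nucleotide, the default; 4 is the alternative
#'   off-by-one reading).
#' @param tieBreak arm preferred when two matures are equidistant from the
#'   loop (\code{"5prime"} default, or \code{"3prime"}).
#' @return list with \code{$status}; on \code{"ok"} a one-row \code{$loop}
#'   data.frame (loop_id, gene_ids, start, end, sequence, dotbracket,
#'   chosen_mature, fallback, notes); on \code{"rejected"} a \code{$reason}.
#' @export
extractPreMiRNALoop <- function(h, limit = 86L, matureOffset = 3L,
                                tieBreak = c("5prime", "3prime")) {
  stopifnot(is(h, "MiRBaseHairpin"))
  tieBreak <- match.arg(tieBreak)
  validObject(h)
  s <- h@structure
  pt <- s@pairTable
  tree <- buildStructureTree(s)
  hp <- .chooseTerminalLoop(h, tree)
  if (is.null(hp)) {
    return(.loopRejection(h@geneId,
      "terminal hairpin loop undeterminable for this precursor"))
  }
  loopStart <- hp$loop_start; loopEnd <- hp$loop_end
  m <- h@matures

  ## arm and loop-side end per mature; reject matures overlapping the loop
  arms <- character(nrow(m)); loopSide <- integer(nrow(m))
  for (r in seq_len(nrow(m))) {
    if (m$end[r] < loopStart) {
      arms[r] <- "5prime"; loopSide[r] <- m$end[r]
    } else if (m$start[r] > loopEnd) {
      arms[r] <- "3prime"; loopSide[r] <- m$start[r]
    } else {
      return(.loopRejection(h@geneId, sprintf(
        "mature '%s' overlaps the terminal loop", m$name[r])))
    }
  }
  if (nrow(m) == 2L && arms[1L] == arms[2L]) {
    return(.loopRejection(h@geneId, "both matures lie on the same arm"))
  }

  ## distance from the loop-side end to the terminal loop
  dist <- ifelse(arms == "5prime", loopStart - loopSide, loopSide - loopEnd)
  chosen <- if (nrow(m) == 1L) 1L else {
    if (dist[1L] > dist[2L]) 1L
    else if (dist[2L] > dist[1L]) 2L
    else which(arms == tieBreak)[1L]
  }

  n <- nchar(s@sequence)
  anchor <- if (arms[chosen] == "5prime") loopSide[chosen] - matureOffset
            else loopSide[chosen] + matureOffset
  if (anchor < 1L || anchor > n) {
    return(.loopRejection(h@geneId,
      "loop boundary falls outside the hairpin"))
  }
  fallback <- FALSE
  step <- if (arms[chosen] == "5prime") -1L else 1L
  while (anchor >= 1L && anchor <= n && pt[anchor] == 0L) {
    anchor <- anchor + step   # toward the basal end
    fallback <- TRUE
  }
  if (anchor < 1L || anchor > n || pt[anchor] == 0L) {
    return(.loopRejection(h@geneId,
      "no paired position toward the basal end of the loop boundary"))
  }
  start <- min(anchor, pt[anchor]); end <- max(anchor, pt[anchor])
  if (end - start + 1L > limit) {
    return(.loopRejection(h@geneId, sprintf(
      "exceeds length limit (%d nt > %d)", end - start + 1L, limit)))
  }
  loop <- data.frame(
    loop_id = h@geneId, gene_ids = h@geneId,
    start = start, end = end,
    sequence = substr(s@sequence, start, end),
    dotbracket = substr(s@dotbracket, start, end),
    chosen_mature = m$name[chosen], fallback = fallback,
    notes = if (fallback) "boundary moved to nearest paired position" else "",
    stringsAsFactors = FALSE
  )
  list(status = "ok", loop = loop)
}

#' Extract pre-miRNA loops from many records and deduplicate
#'
#' @param hairpins list of [MiRBaseHairpin-class].
#' @param ... passed to [extractPreMiRNALoop()].
#' @return list with \code{$loops} (deduplicated loop data.frame) and
#'   \code{$rejected} (data.frame of gene_id, reason).
#' @export
extractPreMiRNALoops <- function(hairpins, ...) {
  res <- lapply(hairpins, extractPreMiRNALoop, ...)
  ok <- Filter(function(x) x$status == "ok", res)
  rej <- Filter(function(x) x$status == "rejected", res)
  loops <- if (length(ok)) {
    do.call(rbind, lapply(ok, `[[`, "loop"))
  } else {
    data.frame(loop_id = character(0), gene_ids = character(0),
               start = integer(0), end = integer(0), sequence = character(0),
               dotbracket = character(0), chosen_mature = character(0),
               fallback = logical(0), notes = character(0),
               stringsAsFactors = FALSE)
  }
  rejected <- data.frame(
    gene_id = vapply(rej, `[[`, character(1), "gene_id"),
    reason = vapply(rej, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  list(loops = deduplicateLoops(loops), rejected = rejected)
}

## gene-name suffix used when merging duplicate loops:
## "hsa-mir-3648-1" -> "3648-1"
.geneSuffix <- function(g) sub("^[A-Za-z0-9]+-[A-Za-z]+-", "", g)

#' Merge identical pre-miRNA loops
#'
#' Loops identical in (sequence, dotbracket) merge into one record annotated
#' with all source genes; the merged loop_id joins the first full gene name
#' with the suffixes of the others using "_" (miRBase style, e.g.
#' "hsa-mir-3648-1_3648-2").
#'
#' @param loops loop data.frame as returned by [extractPreMiRNALoop()] rows.
#' @return deduplicated loop data.frame.
#' @export
deduplicateLoops <- function(loops) {
  if (!nrow(loops)) return(loops)
  key <- paste(loops$sequence, loops$dotbracket, sep = "\r")
  first <- !duplicated(key)
  groups <- split(seq_len(nrow(loops)), factor(key, levels = key[first]))
  out <- loops[first, , drop = FALSE]
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (length(idx) > 1L) {
      genes <- loops$gene_ids[idx]
      out$gene_ids[g] <- paste(genes, collapse = ",")
      out$loop_id[g] <- paste(c(genes[1L], .geneSuffix(genes[-1L])),
                              collapse = "_")
    }
  }
  rownames(out) <- NULL
  out
}

#' Read and write miRBase-like hairpin records as TSV
#'
#' Columns: gene_id, sequence, dotbracket, matures — the latter a comma-joined
#' list of \code{name:start-end} entries in hairpin coordinates.
#'
#' @param path input/output file.
#' @return \code{readMiRBaseRecords}: list of [MiRBaseHairpin-class].
#' @export
readMiRBaseRecords <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tb)), function(r) {
    parts <- strsplit(tb$matures[r], ",", fixed = TRUE)[[1]]
    mm <- do.call(rbind, lapply(parts, function(p) {
      f <- regmatches(p, regexec("^(.*):(\\d+)-(\\d+)$", p))[[1]]
      if (length(f) != 4L) {
        .stop2("mirbaseFormatError", sprintf(
          "row %d: bad mature entry '%s'", r, p))
      }
      data.frame(name = f[2L], start = as.integer(f[3L]),
                 end = as.integer(f[4L]), stringsAsFactors = FALSE)
    }))
    miRBaseHairpin(tb$gene_id[r], tb$sequence[r], tb$dotbracket[r], mm)
  })
}

#' @rdname readMiRBaseRecords
#' @param hairpins list of [MiRBaseHairpin-class].
#' @export
writeMiRBaseRecords <- function(hairpins, path) {
  tb <- do.call(rbind, lapply(hairpins, function(h) {
    data.frame(
      gene_id = h@geneId, sequence = h@structure@sequence,
      dotbracket = h@structure@dotbracket,
      matures = paste(sprintf("%s:%d-%d", h@matures$name, h@matures$start,
                              h@matures$end), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
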