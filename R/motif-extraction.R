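## Extraction of single- and multi-terminal stem-loop motifs from structure
## trees, with length-limit trimming and deduplication.

.emptyMotifTable <- function() {
  data.frame(
    motif_id = character(0), parent_id = character(0),
    start = integer(0), end = integer(0),
    kind = character(0), n_hairpins = integer(0), trimmed = logical(0),
    sequence = character(0), dotbracket = character(0),
    provenance = character(0), stringsAsFactors = FALSE
  )
}

.motifRow <- function(parent_id, start, end, kind, n_hairpins, s,
                      trimmed = FALSE, provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- sprintf("%s:%d-%d", parent_id, start, end)
  }
  data.frame(
    motif_id = sprintf("%s|%d-%d", parent_id, start, end),
    parent_id = parent_id, start = as.integer(start), end = as.integer(end),
    kind = kind, n_hairpins = as.integer(n_hairpins), trimmed = trimmed,
    sequence = substr(s@sequence, start, end),
    dotbracket = substr(s@dotbracket, start, end),
    provenance = provenance, stringsAsFactors = FALSE
  )
}

#' Enumerate hairpin loops of a structure tree
#'
#' One row per HAIRPIN node, left to right: the hairpin's closing base pair
#' (the innermost pair of its stem) and its loop interval (empty loops give
#' \code{loop_start > loop_end}).
#'
#' @param tree a [StructureTree-class].
#' @return data.frame with columns node_id, closing_i, closing_j, loop_start,
#'   loop_end.
#' @examples
#' t <- buildStructureTree(parseDotBracket("x", "GGGAAACCC", "(((...)))"))
#' enumerateHairpins(t)  # closing pair (3, 7)
#' @export
enumerateHairpins <- function(tree) {
  stopifnot(is(tree, "StructureTree"))
  hp <- Filter(function(nd) nd$kind == "HAIRPIN", tree@nodes)
  out <- data.frame(
    node_id = vapply(hp, `[[`, integer(1), "id"),
    closing_i = vapply(hp, `[[`, integer(1), "closing_i"),
    closing_j = vapply(hp, `[[`, integer(1), "closing_j"),
    stringsAsFactors = FALSE
  )
  out$loop_start <- out$closing_i + 1L
  out$loop_end <- out$closing_j - 1L
  out[order(out$closing_i), , drop = FALSE]
}

## Walk outward from a stem through unbranched enclosing elements (internal
## loops / bulges); stop before a multiloop junction or the external loop.
## Returns the outermost stem node reached.
.walkOutward <- function(tree, stemId) {
  nodes <- tree@nodes
  cur <- stemId
  repeat {
    above <- nodes[[cur]]$parent   # loop element containing this stem
    if (is.na(above)) break
    kind <- nodes[[above]]$kind
    if (kind == "INTERNAL") {
      cur <- nodes[[above]]$parent # the stem closing that internal loop
    } else {
      break                        # MULTILOOP or EXTERNAL: stop
    }
  }
  cur
}

.countHairpinsWithin <- function(tree, start, end) {
  sum(vapply(tree@nodes, function(nd) {
    nd$kind == "HAIRPIN" && nd$closing_i >= start && nd$closing_j <= end
  }, logical(1)))
}

#' Extract the single-terminal motif anchored at a hairpin
#'
#' From the hairpin's closing pair, the stem is extended outward through
#' enclosing elements with exactly one helix branch (internal loops and bulges
#' are part of the stem); the walk stops before a multiloop junction or the
#' external loop. The motif spans the outermost pair reached, so its first and
#' last positions are base-paired to each other (blunt end).
#'
#' @param tree a [StructureTree-class].
#' @param hairpin a row of [enumerateHairpins()] output (or its node_id).
#' @return one-row motif data.frame (see [extractTerminalMotifs()]).
#' @export
extractSingleTerminal <- function(tree, hairpin) {
  stopifnot(is(tree, "StructureTree"))
  nodeId <- if (is.data.frame(hairpin)) hairpin$node_id[1L] else hairpin
  nd <- tree@nodes[[nodeId]]
  if (is.null(nd) || nd$kind != "HAIRPIN") {
    .stop2("motifError", "hairpin must reference a HAIRPIN node of the tree")
  }
  top <- .walkOutward(tree, nd$parent)
  i <- tree@nodes[[top]]$outer_i
  j <- tree@nodes[[top]]$outer_j
  .motifRow(tree@structure@id, i, j, "single_terminal", 1L, tree@structure)
}

#' Extract all multi-terminal motifs of a structure tree
#'
#' One motif per MULTILOOP node: the outward walk from the junction's closing
#' stem (as in [extractSingleTerminal()]) defines the outermost pair, and the
#' motif encloses all hairpins of the junction's subtree (>= 2). Nested
#' junctions each yield their own motif.
#'
#' @param tree a [StructureTree-class].
#' @return motif data.frame, one row per junction (possibly empty).
#' @export
extractMultiTerminal <- function(tree) {
  stopifnot(is(tree, "StructureTree"))
  ml <- Filter(function(nd) nd$kind == "MULTILOOP", tree@nodes)
  if (!length(ml)) return(.emptyMotifTable())
  rows <- lapply(ml, function(nd) {
    top <- .walkOutward(tree, nd$parent)
    i <- tree@nodes[[top]]$outer_i
    j <- tree@nodes[[top]]$outer_j
    .motifRow(tree@structure@id, i, j, "multi_terminal",
              .countHairpinsWithin(tree, i, j), tree@structure)
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Shorten a motif to a synthesis length limit
#'
#' While the motif is longer than \code{limit}, the outermost base pair is
#' removed together with any terminal unpaired nucleotides thereby exposed, so
#' the intermediate always has blunt paired ends. The first state with length
#' \code{<= limit} is returned flagged \code{trimmed = TRUE}. If the closing
#' helix is exhausted before reaching the limit (a junction or no base pair
#' remains), the motif is rejected.
#'
#' @param motif one-row motif data.frame (columns sequence, dotbracket, start,
#'   end at least).
#' @param limit maximum length in nt (>= 1).
#' @return list with \code{$status} (\code{"ok"} or \code{"rejected"}),
#'   \code{$motif} (updated row, when ok) and \code{$reason} (when rejected).
#' @examples
#' m <- extractTerminalMotifs(
#'   list(parseDotBracket("x", "GGGGGGGGACGUCCCCCCCC",
#'                        "((((((((....))))))))")), limit = 100)
#' shortenToLimit(m, 12)$motif$dotbracket  # "((((....))))"
#' @export
shortenToLimit <- function(motif, limit) {
  stopifnot(is.data.frame(motif), nrow(motif) == 1L, limit >= 1L)
  seq <- motif$sequence; db <- motif$dotbracket
  offL <- 0L
  trimmed <- FALSE
  repeat {
    n <- nchar(db)
    pt <- parseDotBracket("trim", seq, db, warnDNA = FALSE)@pairTable
    if (!any(pt > 0L)) {
      return(list(status = "rejected", reason = sprintf(
        "no base pair remains above the length limit (%d nt left, limit %d)",
        n, limit)))
    }
    ## every retained state must have blunt paired ends
    if (pt[1L] != n) {
      return(list(status = "rejected", reason =
        "junction exposed before reaching the length limit (no blunt end)"))
    }
    if (n <= limit) break
    ## drop the outermost pair, then exposed terminal unpaired nucleotides
    a <- 2L; b <- n - 1L
    while (a <= b && pt[a] == 0L) a <- a + 1L
    while (b >= a && pt[b] == 0L) b <- b - 1L
    if (a > b) {
      return(list(status = "rejected", reason = sprintf(
        "no base pair remains above the length limit (limit %d)", limit)))
    }
    seq <- substr(seq, a, b); db <- substr(db, a, b)
    offL <- offL + a - 1L
    trimmed <- TRUE
  }
  out <- motif
  out$start <- motif$start + offL
  out$end <- out$start + nchar(db) - 1L
  out$sequence <- seq
  out$dotbracket <- db
  out$trimmed <- trimmed
  out$motif_id <- sprintf("%s|%d-%d", out$parent_id, out$start, out$end)
  list(status = "ok", motif = out)
}

#' Extract, trim and deduplicate all terminal motifs of a structure set
#'
#' Orchestrates hairpin enumeration, single- and multi-terminal extraction,
#' length-limit trimming and deduplication over a list of structures. Motifs
#' shorter than \code{minLen} are dropped; motifs identical in (sequence,
#' dotbracket) are merged with their provenance concatenated. Output order is
#' deterministic: input structure order, then position.
#'
#' @param structures list of [SecondaryStructure-class].
#' @param limit synthesis length limit in nt (default 86, the v1 library
#'   limit; use 116 for v2 rules).
#' @param minLen minimum motif length (default 6).
#' @param kinds \code{"both"} (default), \code{"singles"} or \code{"multis"}.
#' @return motif data.frame with columns motif_id, parent_id, start, end,
#'   kind, n_hairpins, trimmed, sequence, dotbracket, provenance.
#' @export
extractTerminalMotifs <- function(structures, limit = 86L, minLen = 6L,
                                  kinds = c("both", "singles", "multis")) {
  kinds <- match.arg(kinds)
  if (is(structures, "SecondaryStructure")) structures <- list(structures)
  rows <- list()
  for (s in structures) {
    tree <- buildStructureTree(s)
    cand <- .emptyMotifTable()
    if (kinds != "multis") {
      hp <- enumerateHairpins(tree)
      if (nrow(hp)) {
        singles <- do.call(rbind, lapply(seq_len(nrow(hp)), function(r) {
          extractSingleTerminal(tree, hp[r, , drop = FALSE])
        }))
        cand <- rbind(cand, singles)
      }
    }
    if (kinds != "singles") cand <- rbind(cand, extractMultiTerminal(tree))
    if (!nrow(cand)) next
    cand <- cand[order(cand$start, cand$end), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      sh <- shortenToLimit(cand[r, , drop = FALSE], limit)
      if (sh$status != "ok") next
      m <- sh$motif
      if (nchar(m$sequence) < minLen) next
      rows[[length(rows) + 1L]] <- m
    }
  }
  if (!length(rows)) return(.emptyMotifTable())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .deduplicateMotifs(out)
}

## merge motifs identical in (sequence, dotbracket); keep first occurrence,
## concatenate provenance with ";"
.deduplicateMotifs <- function(motifs) {
  key <- paste(motifs$sequence, motifs$dotbracket, sep = "\r")
  first <- !duplicated(key)
  prov <- vapply(split(motifs$provenance, factor(key, levels = key[first])),
                 paste, character(1), collapse = ";")
  out <- motifs[first, , drop = FALSE]
  out$provenance <- unname(prov)
  rownames(out) <- NULL
  out
}

#' Write a motif table as TSV or as a .dbn file of the motifs
#'
#' @param motifs a motif data.frame from [extractTerminalMotifs()].
#' @param path output file.
#' @param format \code{"tsv"} (default) or \code{"dbn"}.
#' @export
writeMotifTable <- function(motifs, path, format = c("tsv", "dbn")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeDBN(lapply(seq_len(nrow(motifs)), function(r) {
      parseDotBracket(motifs$motif_id[r], motifs$sequence[r],
                      motifs$dotbracket[r], warnDNA = FALSE)
    }), path)
  }
  invisible(path)
}
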