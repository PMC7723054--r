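## Parsing, validation and tree decomposition of RNA secondary structures.

#' Parse a dot-bracket secondary structure
#'
#' Builds a validated [SecondaryStructure-class] by bracket matching. The
#' sequence is upper-cased and DNA input (T) is normalized to U with a warning.
#' Extra bracket layers (\code{[] \{\} <>}, typically pseudoknots) are rejected
#' by default or, with \code{pseudoknots = "strip"}, converted to unpaired
#' positions so that only the nested \code{()} layer is retained.
#'
#' @param id record identifier.
#' @param sequence RNA (or DNA) string.
#' @param dotbracket structure string over \code{"()."} (plus optional
#'   pseudoknot layers).
#' @param pseudoknots \code{"error"} (default) or \code{"strip"}.
#' @param warnDNA warn when T is normalized to U (default TRUE).
#' @return a [SecondaryStructure-class].
#'
#' @details Distinct validation failures raise distinct condition classes:
#'   \code{dbLengthError} (length mismatch), \code{dbAlphabetError} (illegal
#'   characters), \code{dbUnbalancedError} (unbalanced brackets),
#'   \code{dbPseudoknotError} (extra bracket layers when rejecting).
#'
#' @examples
#' s <- parseDotBracket("x", "GGGAAACCC", "(((...)))")
#' pairTable(s)  # 9 8 7 0 0 0 3 2 1
#' @export
parseDotBracket <- function(id, sequence, dotbracket,
                            pseudoknots = c("error", "strip"),
                            warnDNA = TRUE) {
  pseudoknots <- match.arg(pseudoknots)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    .stop2("dbLengthError", "sequence must be a non-empty string")
  }
  if (!is.character(dotbracket) || length(dotbracket) != 1L ||
      !nzchar(dotbracket)) {
    .stop2("dbLengthError", "dotbracket must be a non-empty string")
  }
  if (nchar(sequence) != nchar(dotbracket)) {
    .stop2("dbLengthError", sprintf(
      "record '%s': sequence length %d != structure length %d",
      id, nchar(sequence), nchar(dotbracket)))
  }
  if (warnDNA && grepl("[Tt]", sequence)) {
    warning(sprintf("record '%s': DNA input (T) normalized to U", id),
            call. = FALSE)
  }
  sequence <- .toRNA(sequence)
  if (grepl("[^ACGUN]", sequence)) {
    .stop2("dbAlphabetError", sprintf(
      "record '%s': illegal sequence characters: %s", id,
      paste(unique(strsplit(gsub("[ACGUN]", "", sequence), "")[[1]]),
            collapse = " ")))
  }
  db <- strsplit(dotbracket, "")[[1]]
  pkChars <- c("[", "]", "{", "}", "<", ">")
  bad <- setdiff(unique(db), c("(", ")", ".", pkChars))
  if (length(bad)) {
    .stop2("dbAlphabetError", sprintf(
      "record '%s': illegal structure characters: %s", id,
      paste(bad, collapse = " ")))
  }
  if (any(db %in% pkChars)) {
    if (pseudoknots == "error") {
      .stop2("dbPseudoknotError", sprintf(
        "record '%s': extra bracket layers present; use pseudoknots = \"strip\" to drop them",
        id))
    }
    db[db %in% pkChars] <- "."
  }
  n <- length(db)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (db[i] == "(") {
      stack <- c(stack, i)
    } else if (db[i] == ")") {
      if (!length(stack)) {
        .stop2("dbUnbalancedError", sprintf(
          "record '%s': unmatched ')' at position %d", id, i))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) {
    .stop2("dbUnbalancedError", sprintf(
      "record '%s': unmatched '(' at position %d", id, stack[length(stack)]))
  }
  new("SecondaryStructure", id = as.character(id), sequence = sequence,
      dotbracket = paste(db, collapse = ""), pairTable = pt)
}

#' Decompose a secondary structure into its loop/helix tree
#'
#' Produces the canonical loop decomposition: an EXTERNAL root, STEM nodes for
#' maximal helices (no unpaired gaps; lone pairs count as stems), and one loop
#' node per stem interior (HAIRPIN, INTERNAL for internal/bulge loops, or
#' MULTILOOP for junctions with >= 2 helix children).
#'
#' @param s a [SecondaryStructure-class].
#' @return a [StructureTree-class].
#' @examples
#' t <- buildStructureTree(parseDotBracket("x", "GGGAAACCC", "(((...)))"))
#' t
#' @export
buildStructureTree <- function(s) {
  stopifnot(is(s, "SecondaryStructure"))
  validObject(s)
  pt <- s@pairTable
  n <- length(pt)
  nodes <- vector("list", 0L)

  newNode <- function(kind, parent, extra) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- c(list(id = id, kind = kind, parent = parent,
                           children = integer(0)), extra)
    if (!is.na(parent)) {
      nodes[[parent]]$children <<- c(nodes[[parent]]$children, id)
    }
    id
  }

  ## top-level helices and unpaired positions of a region
  scanRegion <- function(a, b) {
    helices <- list(); unp <- integer(0)
    p <- a
    while (p <= b) {
      if (pt[p] == 0L) {
        unp <- c(unp, p); p <- p + 1L
      } else {
        helices <- c(helices, list(c(p, pt[p]))); p <- pt[p] + 1L
      }
    }
    list(helices = helices, unpaired = unp)
  }

  processHelix <- function(i, j, parent) {
    nbp <- 1L
    while (i + nbp < j - nbp && pt[i + nbp] == j - nbp) nbp <- nbp + 1L
    ii <- i + nbp - 1L; jj <- j - nbp + 1L
    sid <- newNode("STEM", parent, list(outer_i = i, outer_j = j,
                                        inner_i = ii, inner_j = jj, nbp = nbp))
    sc <- scanRegion(ii + 1L, jj - 1L)
    kind <- if (!length(sc$helices)) "HAIRPIN"
            else if (length(sc$helices) == 1L) "INTERNAL"
            else "MULTILOOP"
    lid <- newNode(kind, sid, list(closing_i = ii, closing_j = jj,
                                   unpaired = sc$unpaired))
    for (h in sc$helices) processHelix(h[1L], h[2L], lid)
    sid
  }

  root <- newNode("EXTERNAL", NA_integer_, list(unpaired = integer(0)))
  sc <- scanRegion(1L, n)
  nodes[[root]]$unpaired <- sc$unpaired
  for (h in sc$helices) processHelix(h[1L], h[2L], root)
  new("StructureTree", structure = s, nodes = nodes)
}

#' Read structures from a dot-bracket (.dbn) or CT file
#'
#' \code{dbn} files are (header, sequence, structure) triplets with headers
#' starting with \code{>}; \code{ct} files are standard 6-column CT, possibly
#' with several concatenated records. Writers producing byte-identical dbn
#' round trips are provided.
#'
#' @param path input file.
#' @param format \code{"dbn"} (default) or \code{"ct"}.
#' @param pseudoknots passed to [parseDotBracket()].
#' @return list of [SecondaryStructure-class] in file order.
#' @examples
#' f <- tempfile(fileext = ".dbn")
#' writeDBN(list(parseDotBracket("a", "GGGAAACCC", "(((...)))")), f)
#' loadStructures(f)
#' @export
loadStructures <- function(path, format = c("dbn", "ct"),
                           pseudoknots = c("error", "strip")) {
  format <- match.arg(format)
  pseudoknots <- match.arg(pseudoknots)
  if (!file.exists(path)) .stop2("fileError", sprintf("no such file: %s", path))
  if (format == "dbn") {
    .readDBN(path, pseudoknots)
  } else {
    .readCT(path)
  }
}

.readDBN <- function(path, pseudoknots) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L; rec <- 0L
  sawT <- FALSE
  while (i <= length(lines)) {
    rec <- rec + 1L
    if (!startsWith(lines[i], ">")) {
      .stop2("dbnFormatError", sprintf(
        "record %d: expected '>' header, got '%s'", rec,
        substr(lines[i], 1L, 30L)))
    }
    if (i + 2L > length(lines)) {
      .stop2("dbnFormatError", sprintf(
        "record %d: truncated record (need sequence and structure lines)", rec))
    }
    id <- sub("^>\\s*", "", lines[i])
    seq <- trimws(lines[i + 1L]); db <- trimws(lines[i + 2L])
    if (grepl("[Tt]", seq)) sawT <- TRUE
    s <- tryCatch(
      parseDotBracket(id, seq, db, pseudoknots = pseudoknots, warnDNA = FALSE),
      stemlooplib_error = function(e) {
        .stop2(class(e)[1L], sprintf("record %d: %s", rec, conditionMessage(e)))
      })
    out[[length(out) + 1L]] <- s
    i <- i + 3L
  }
  if (sawT) {
    warning(sprintf("%s: DNA input (T) normalized to U", path), call. = FALSE)
  }
  out
}

#' @rdname loadStructures
#' @param structures list of [SecondaryStructure-class] (or a single one).
#' @export
writeDBN <- function(structures, path) {
  if (is(structures, "SecondaryStructure")) structures <- list(structures)
  lines <- unlist(lapply(structures, function(s) {
    c(paste0(">", s@id), s@sequence, s@dotbracket)
  }))
  writeLines(lines, path)
  invisible(path)
}

.readCT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L; rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    n <- suppressWarnings(as.integer(hdr[1L]))
    if (is.na(n) || n < 1L) {
      .stop2("ctFormatError", sprintf(
        "record %d: header must start with the sequence length", rec))
    }
    id <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ")
          else sprintf("ct_record_%d", rec)
    if (i + n > length(lines)) {
      .stop2("ctFormatError", sprintf("record %d: truncated (%d rows needed)",
                                      rec, n))
    }
    body <- lines[(i + 1L):(i + n)]
    fields <- strsplit(trimws(body), "\\s+")
    if (any(lengths(fields) < 6L)) {
      .stop2("ctFormatError", sprintf(
        "record %d: CT rows need 6 columns", rec))
    }
    base <- vapply(fields, `[[`, character(1), 2L)
    pair <- as.integer(vapply(fields, `[[`, character(1), 5L))
    if (anyNA(pair) || any(pair < 0L) || any(pair > n)) {
      .stop2("ctFormatError", sprintf("record %d: bad pairing column", rec))
    }
    db <- rep(".", n)
    db[pair > seq_len(n)] <- "("
    db[pair > 0L & pair < seq_len(n)] <- ")"
    s <- parseDotBracket(id, paste(base, collapse = ""),
                         paste(db, collapse = ""), warnDNA = FALSE)
    ## cross-check the CT pairing survived the nested-bracket reconstruction
    if (!identical(s@pairTable, pair)) {
      .stop2("ctFormatError", sprintf(
        "record %d: pairing is not nested (pseudoknot?) or inconsistent", rec))
    }
    out[[length(out) + 1L]] <- s
    i <- i + n + 1L
  }
  out
}

#' @rdname loadStructures
#' @export
writeCT <- function(structures, path) {
  if (is(structures, "SecondaryStructure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    n <- nchar(s@sequence)
    base <- strsplit(s@sequence, "")[[1]]
    writeLines(sprintf("%d %s", n, s@id), con)
    writeLines(sprintf("%d %s %d %d %d %d", seq_len(n), base,
                       seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                       s@pairTable, seq_len(n)), con)
  }
  invisible(path)
}
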