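## Barcoded probe/oligo library design: barcode pools and assignment, probe
## assembly with stabilizing stems and T7 promoter templates, and export.

## Built-in 18-bp stabilizing stem (forward strand, RNA): GC ~ 55%, no
## homopolymer > 3, no 6-mer shared with either promoter. Overridable via
## designRules(stemForward = ...).
.DEFAULT_STEM_FORWARD <- "GAUCGGAUCCGUAGUCAC"

.PROMOTER_V1 <- "GCGCTAATACGACTCACTATAGGG"
.PROMOTER_V2 <- "CCGCGCTAATACGACTCACTATAG"

#' Design rules for the barcoded probe library
#'
#' Returns the synthesis/assembly constants of a library version. Version
#' \code{"v1"} uses a 170-nt oligo limit, promoter
#' \code{GCGCTAATACGACTCACTATAGGG} and transcript leader \code{GGG}; version
#' \code{"v2"} a 200-nt limit, promoter \code{CCGCGCTAATACGACTCACTATAG} and
#' leader \code{G}. Both use 25-nt barcodes, 18-nt stabilizing stems and a
#' total attachment overhead of 84 nt, so the maximum structure length is
#' 86 (v1), 116 (v2), or 266 nt for an extended 350-nt oligo limit.
#'
#' The per-component sum (promoter + CC + barcode + two stems) does not
#' reconcile exactly with the 84-nt overhead; the overhead is treated as the
#' authoritative constant (it reproduces all printed structure-length limits)
#' and the anti-promoter region of the template is its remainder,
#' \code{84 - 61 = 23} nt. A mismatch triggers a one-off warning, not an error.
#'
#' @param version \code{"v1"} (default) or \code{"v2"}.
#' @param oligoLimit override the oligo length limit (e.g. 350).
#' @param nBarcodes barcodes per structure, 3..5 (default 5 for v1, 3
#'   otherwise).
#' @param stemForward override the forward stabilizing stem (RNA, 18 nt);
#'   the reverse stem is always its reverse complement.
#' @param promoter,leader,attachmentOverhead,barcodeLen,stemLen overrides.
#' @return a [DesignRules-class].
#' @examples
#' maxStructureLength(designRules("v2"))  # 116
#' @export
designRules <- function(version = c("v1", "v2"), oligoLimit = NULL,
                        nBarcodes = NULL, stemForward = .DEFAULT_STEM_FORWARD,
                        promoter = NULL, leader = NULL,
                        attachmentOverhead = 84L, barcodeLen = 25L,
                        stemLen = 18L) {
  version <- match.arg(version)
  if (is.null(oligoLimit)) oligoLimit <- if (version == "v1") 170L else 200L
  if (is.null(promoter)) {
    promoter <- if (version == "v1") .PROMOTER_V1 else .PROMOTER_V2
  }
  if (is.null(leader)) leader <- if (version == "v1") "GGG" else "G"
  if (is.null(nBarcodes)) nBarcodes <- if (version == "v1") 5L else 3L
  stemForward <- .toRNA(stemForward)
  rules <- new("DesignRules",
    version = version, oligoLimit = as.integer(oligoLimit),
    attachmentOverhead = as.integer(attachmentOverhead),
    barcodeLen = as.integer(barcodeLen), stemLen = as.integer(stemLen),
    nBarcodes = as.integer(nBarcodes), promoter = toupper(promoter),
    leader = .toRNA(leader), stemForward = stemForward,
    stemReverse = .revCompRNA(stemForward))
  compSum <- nchar(rules@promoter) + 2L + rules@barcodeLen + 2L * rules@stemLen
  if (compSum != rules@attachmentOverhead) {
    warning(sprintf(
      "component sum (promoter %d + CC + barcode %d + 2 x stem %d = %d nt) differs from attachment overhead %d nt; the overhead is authoritative",
      nchar(rules@promoter), rules@barcodeLen, rules@stemLen, compSum,
      rules@attachmentOverhead), call. = FALSE)
  }
  rules
}

#' Maximum structure length permitted by a set of design rules
#'
#' @param rules a [DesignRules-class].
#' @return \code{oligoLimit - attachmentOverhead}, in nt.
#' @examples
#' maxStructureLength(designRules("v1", oligoLimit = 350))  # 266
#' @export
maxStructureLength <- function(rules) {
  stopifnot(is(rules, "DesignRules"))
  len <- rules@oligoLimit - rules@attachmentOverhead
  if (len < 1L) {
    .stop2("designError", sprintf(
      "oligo limit %d nt leaves no room for a structure (overhead %d nt)",
      rules@oligoLimit, rules@attachmentOverhead))
  }
  len
}

#' Construct and validate a barcode pool
#'
#' @param barcodes character vector of barcodes (RNA or DNA; T normalized
#'   to U).
#' @param minHamming minimum pairwise Hamming distance to enforce (0 = skip
#'   the O(n^2) check).
#' @param gcRange length-2 GC-content bounds to enforce (NULL = skip).
#' @param barcodeLen required barcode length (default 25).
#' @return a [BarcodePool-class].
#' @export
barcodePool <- function(barcodes, minHamming = 0L, gcRange = NULL,
                        barcodeLen = 25L) {
  barcodes <- .toRNA(barcodes)
  bad <- which(nchar(barcodes) != barcodeLen)
  if (length(bad)) {
    .stop2("barcodeError", sprintf(
      "barcode length != %d at entr%s %s", barcodeLen,
      if (length(bad) == 1L) "y" else "ies",
      paste(head(bad, 5L), collapse = ", ")))
  }
  dup <- which(duplicated(barcodes))
  if (length(dup)) {
    .stop2("barcodeError", sprintf(
      "duplicate barcode at entr%s %s",
      if (length(dup) == 1L) "y" else "ies",
      paste(head(dup, 5L), collapse = ", ")))
  }
  if (!is.null(gcRange)) {
    gc <- vapply(barcodes, .gcFraction, numeric(1), USE.NAMES = FALSE)
    bad <- which(gc < gcRange[1L] | gc > gcRange[2L])
    if (length(bad)) {
      .stop2("barcodeError", sprintf(
        "GC content outside [%.2f, %.2f] at entr%s %s", gcRange[1L],
        gcRange[2L], if (length(bad) == 1L) "y" else "ies",
        paste(head(bad, 5L), collapse = ", ")))
    }
  } else {
    gcRange <- c(0, 1)
  }
  if (minHamming > 0L && length(barcodes) > 1L) {
    mat <- do.call(rbind, strsplit(barcodes, ""))
    for (i in seq_len(nrow(mat) - 1L)) {
      d <- rowSums(mat[(i + 1L):nrow(mat), , drop = FALSE] !=
                     matrix(mat[i, ], nrow(mat) - i, barcodeLen, byrow = TRUE))
      if (any(d < minHamming)) {
        j <- i + which(d < minHamming)[1L]
        .stop2("barcodeError", sprintf(
          "barcodes %d and %d are only Hamming distance %d apart (< %d)",
          i, j, d[j - i], minHamming))
      }
    }
  }
  new("BarcodePool", barcodes = barcodes,
      minPairwiseHamming = as.integer(minHamming), gcRange = gcRange)
}

#' Load a barcode pool from a plain-text file (one barcode per line)
#'
#' Constraint violations are reported with their line numbers.
#'
#' @param path input file.
#' @inheritParams barcodePool
#' @return a [BarcodePool-class].
#' @export
loadBarcodePool <- function(path, minHamming = 0L, gcRange = NULL,
                            barcodeLen = 25L) {
  if (!file.exists(path)) .stop2("fileError", sprintf("no such file: %s", path))
  lines <- trimws(readLines(path))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  bc <- .toRNA(lines[keep])
  bad <- which(nchar(bc) != barcodeLen)
  if (length(bad)) {
    .stop2("barcodeError", sprintf(
      "%s line %d: barcode length %d != %d", path, lineno[bad[1L]],
      nchar(bc[bad[1L]]), barcodeLen))
  }
  dup <- which(duplicated(bc))
  if (length(dup)) {
    .stop2("barcodeError", sprintf(
      "%s line %d: duplicate barcode (first seen line %d)", path,
      lineno[dup[1L]], lineno[match(bc[dup[1L]], bc)]))
  }
  barcodePool(bc, minHamming = minHamming, gcRange = gcRange,
              barcodeLen = barcodeLen)
}

#' Assign barcodes to structures
#'
#' Each structure receives \code{n} distinct barcodes; no barcode is reused
#' across structures (so the spot-to-structure mapping stays unambiguous).
#' The draw is deterministic under \code{seed} and order-stable in the input
#' structure order.
#'
#' @param structureIds character vector of structure/motif ids.
#' @param pool a [BarcodePool-class].
#' @param n barcodes per structure (3..5 typically).
#' @param seed integer seed.
#' @return data.frame with columns structure_ref, barcode_id, barcode.
#' @export
assignBarcodes <- function(structureIds, pool, n, seed = 1L) {
  stopifnot(is(pool, "BarcodePool"))
  need <- n * length(structureIds)
  avail <- length(pool@barcodes)
  if (need > avail) {
    .stop2("barcodeError", sprintf(
      "barcode pool exhausted: %d needed (%d structures x %d) but only %d available",
      need, length(structureIds), n, avail))
  }
  idx <- withSeed(seed, sample.int(avail, need))
  data.frame(
    structure_ref = rep(structureIds, each = n),
    barcode_id = sprintf("bc%04d", idx),
    barcode = pool@barcodes[idx],
    stringsAsFactors = FALSE
  )
}

#' Assemble one probe and its synthesis template
#'
#' The probe RNA carries, 5' to 3': transcript leader, 25-nt barcode, forward
#' stabilizing stem, the extracted structure, reverse stabilizing stem. The
#' ssDNA synthesis template is the reverse complement of (anti-promoter region
#' + probe body), so its 3' end hybridizes to the T7 promoter strand and its
#' total length is structure length + attachment overhead. A
#' cross-hybridization flag is raised when the barcode contains the exact
#' reverse complement of any \code{crossHybMin}-nt window of the stems or
#' structure.
#'
#' @param structureSeq the motif's RNA sequence (or a one-row motif
#'   data.frame with a \code{sequence} column).
#' @param barcode a 25-nt RNA barcode.
#' @param rules a [DesignRules-class].
#' @param crossHybMin shortest screened duplex (default 8 nt).
#' @return list with \code{probe_rna}, \code{template_dna},
#'   \code{cross_hyb} (logical).
#' @export
assembleProbe <- function(structureSeq, barcode, rules,
                          crossHybMin = 8L) {
  stopifnot(is(rules, "DesignRules"))
  if (is.data.frame(structureSeq)) structureSeq <- structureSeq$sequence[1L]
  structureSeq <- .toRNA(structureSeq)
  barcode <- .toRNA(barcode)
  if (nchar(barcode) != rules@barcodeLen) {
    .stop2("designError", sprintf("barcode length %d != %d", nchar(barcode),
                                  rules@barcodeLen))
  }
  maxLen <- maxStructureLength(rules)
  if (nchar(structureSeq) > maxLen) {
    .stop2("designError", sprintf(
      "structure length %d nt exceeds the %d-nt limit (oligo limit %d, overhead %d)",
      nchar(structureSeq), maxLen, rules@oligoLimit,
      rules@attachmentOverhead))
  }
  if (.revCompRNA(rules@stemForward) != rules@stemReverse) {
    .stop2("designError", "stabilizing stem pair is not complementary")
  }
  body <- paste0(barcode, rules@stemForward, structureSeq, rules@stemReverse)
  probe_rna <- paste0(rules@leader, body)
  antiLen <- rules@attachmentOverhead -
    (rules@barcodeLen + 2L * rules@stemLen)
  promoterTail <- substr(rules@promoter,
                         nchar(rules@promoter) - antiLen + 1L,
                         nchar(rules@promoter))
  template_dna <- .revCompDNA(paste0(promoterTail, .toDNA(body)))
  ## cross-hybridization screen: barcode vs stems + structure
  target <- paste0(rules@stemForward, structureSeq, rules@stemReverse)
  cross <- FALSE
  if (nchar(barcode) >= crossHybMin) {
    ## windows of the barcode's reverse complement are the reverse
    ## complements of the barcode's windows
    rcb <- .revCompRNA(barcode)
    nw <- nchar(rcb) - crossHybMin + 1L
    wins <- substring(rcb, seq_len(nw), seq_len(nw) + crossHybMin - 1L)
    cross <- any(vapply(wins, grepl, logical(1), x = target, fixed = TRUE))
  }
  list(probe_rna = probe_rna, template_dna = template_dna, cross_hyb = cross)
}

#' In-silico transcription of a synthesis template
#'
#' Reverse-complements the template, strips the non-transcribed part of the
#' anti-promoter region and converts T to U; with a correctly assembled
#' template this reproduces the probe RNA exactly.
#'
#' @param templateDNA ssDNA template from [assembleProbe()].
#' @param rules the [DesignRules-class] used for assembly.
#' @return the transcript RNA string.
#' @export
transcribeTemplate <- function(templateDNA, rules) {
  stopifnot(is(rules, "DesignRules"))
  coding <- .revCompDNA(templateDNA)
  antiLen <- rules@attachmentOverhead -
    (rules@barcodeLen + 2L * rules@stemLen)
  .toRNA(substr(coding, antiLen - nchar(rules@leader) + 1L, nchar(coding)))
}

#' Design the full probe library for a motif table
#'
#' Assigns barcodes and assembles every probe.
#'
#' @param motifs motif data.frame ([extractTerminalMotifs()]) or any
#'   data.frame with motif_id/loop_id and sequence columns.
#' @param pool a [BarcodePool-class].
#' @param rules a [DesignRules-class].
#' @param seed integer seed for barcode assignment.
#' @param n barcodes per structure (default \code{rules@nBarcodes}).
#' @return probe data.frame: probe_id, structure_ref, barcode_id, barcode,
#'   probe_rna, template_dna, cross_hyb.
#' @export
designLibrary <- function(motifs, pool, rules, seed = 1L, n = NULL) {
  if (is.null(n)) n <- rules@nBarcodes
  idcol <- intersect(c("motif_id", "loop_id", "structure_ref", "id"),
                     names(motifs))[1L]
  if (is.na(idcol)) .stop2("designError", "motifs need an id column")
  ids <- motifs[[idcol]]
  asg <- assignBarcodes(ids, pool, n, seed)
  seqs <- setNames(motifs$sequence, ids)
  rows <- lapply(seq_len(nrow(asg)), function(r) {
    pr <- assembleProbe(seqs[[asg$structure_ref[r]]], asg$barcode[r], rules)
    data.frame(
      probe_id = paste0(asg$structure_ref[r], ".", asg$barcode_id[r]),
      structure_ref = asg$structure_ref[r],
      barcode_id = asg$barcode_id[r], barcode = asg$barcode[r],
      probe_rna = pr$probe_rna, template_dna = pr$template_dna,
      cross_hyb = pr$cross_hyb, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a designed probe library
#'
#' \code{oligo_tsv} lists one synthesis template per probe; \code{oligo_fasta}
#' writes the templates as FASTA; \code{array_tsv} writes the microarray
#' design — one row per spot, i.e. each probe's anti-barcode DNA repeated
#' \code{replicationFactor} times with stable spot ids.
#'
#' @param probes probe data.frame from [designLibrary()].
#' @param path output file.
#' @param format \code{"oligo_tsv"}, \code{"oligo_fasta"} or
#'   \code{"array_tsv"}.
#' @param replicationFactor spots per barcode for the array export (>= 1;
#'   5 for v1-style arrays, 2 for v2).
#' @return the path, invisibly.
#' @export
exportDesigns <- function(probes, path,
                          format = c("oligo_tsv", "oligo_fasta", "array_tsv"),
                          replicationFactor = 1L) {
  format <- match.arg(format)
  if (format == "array_tsv" && replicationFactor < 1L) {
    .stop2("designError", "replicationFactor must be >= 1")
  }
  if (format == "oligo_tsv") {
    write.table(probes[, c("probe_id", "template_dna")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (format == "oligo_fasta") {
    xs <- Biostrings::DNAStringSet(setNames(probes$template_dna,
                                            probes$probe_id))
    Biostrings::writeXStringSet(xs, path)
  } else {
    spots <- do.call(rbind, lapply(seq_len(nrow(probes)), function(r) {
      data.frame(
        spot_id = sprintf("%s_r%d", probes$barcode_id[r],
                          seq_len(replicationFactor)),
        barcode_id = probes$barcode_id[r],
        structure_ref = probes$structure_ref[r],
        anti_barcode = .revCompDNA(.toDNA(probes$barcode[r])),
        stringsAsFactors = FALSE
      )
    }))
    write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
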