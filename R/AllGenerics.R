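## Accessor generics and show methods.

#' Accessors for SecondaryStructure and friends
#'
#' @param x an object.
#' @return \code{structureId}: the record id; \code{rnaSequence}: the RNA
#'   string; \code{dotBracket}: the dot-bracket string; \code{pairTable}: the
#'   integer partner vector (0 = unpaired); \code{structureLength}: the number
#'   of nucleotides; \code{barcodes}: the barcode character vector of a pool;
#'   \code{treeNodes}: the node list of a [StructureTree-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setGeneric("rnaSequence", function(x) standardGeneric("rnaSequence"))
#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))
#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setGeneric("structureLength", function(x) standardGeneric("structureLength"))
#' @rdname accessors
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))
#' @rdname accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname accessors
#' @export
setMethod("structureId", "SecondaryStructure", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("rnaSequence", "SecondaryStructure", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotbracket)
#' @rdname accessors
#' @export
setMethod("pairTable", "SecondaryStructure", function(x) x@pairTable)
#' @rdname accessors
#' @export
setMethod("structureLength", "SecondaryStructure",
          function(x) nchar(x@sequence))

#' @rdname accessors
#' @export
setMethod("rnaSequence", "MiRBaseHairpin", function(x) x@structure@sequence)
#' @rdname accessors
#' @export
setMethod("structureId", "MiRBaseHairpin", function(x) x@geneId)

#' @rdname accessors
#' @export
setMethod("barcodes", "BarcodePool", function(x) x@barcodes)
#' @rdname accessors
#' @export
setMethod("treeNodes", "StructureTree", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("structureId", "StructureTree", function(x) x@structure@id)

setMethod("show", "SecondaryStructure", function(object) {
  n <- nchar(object@sequence)
  cat(sprintf("SecondaryStructure '%s' (%d nt, %d base pairs)\n",
              object@id, n, sum(object@pairTable > 0L) %/% 2L))
  if (n <= 70L) {
    cat(" ", object@sequence, "\n ", object@dotbracket, "\n", sep = "")
  } else {
    cat(" ", substr(object@sequence, 1L, 67L), "...\n ",
        substr(object@dotbracket, 1L, 67L), "...\n", sep = "")
  }
})

setMethod("show", "StructureTree", function(object) {
  kinds <- vapply(object@nodes, `[[`, character(1), "kind")
  cat(sprintf(
    "StructureTree of '%s': %d stems, %d hairpins, %d internal loops, %d multiloops\n",
    object@structure@id, sum(kinds == "STEM"), sum(kinds == "HAIRPIN"),
    sum(kinds == "INTERNAL"), sum(kinds == "MULTILOOP")))
})

setMethod("show", "DesignRules", function(object) {
  cat(sprintf(
    "DesignRules '%s': oligo limit %d nt, overhead %d nt (max structure %d nt)\n",
    object@version, object@oligoLimit, object@attachmentOverhead,
    object@oligoLimit - object@attachmentOverhead))
  cat(sprintf("  promoter %s | leader %s | %d barcodes of %d nt | stems %d nt\n",
              object@promoter, object@leader, object@nBarcodes,
              object@barcodeLen, object@stemLen))
})

setMethod("show", "BarcodePool", function(object) {
  cat(sprintf("BarcodePool: %d barcodes of %d nt (min pairwise Hamming >= %d)\n",
              length(object@barcodes), nchar(object@barcodes[1L]),
              object@minPairwiseHamming))
})

setMethod("show", "MiRBaseHairpin", function(object) {
  cat(sprintf("MiRBaseHairpin '%s' (%d nt, %d mature%s)\n", object@geneId,
              nchar(object@structure@sequence), nrow(object@matures),
              if (nrow(object@matures) == 1L) "" else "s"))
})
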