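## Core S4 containers. Flat result tables (motifs, probes, fluorescence,
## binding profiles, k-mer tables) are returned as plain data.frames.

#' SecondaryStructure: an RNA sequence with its secondary structure
#'
#' Holds an RNA sequence, its dot-bracket string and the derived pair table
#' (a 1-based partial involution: \code{pairTable(x)[i]} is the partner of
#' position \code{i}, or \code{0L} if unpaired). The retained bracket layer is
#' pseudoknot-free: brackets are balanced and non-crossing.
#'
#' @slot id character(1) record identifier.
#' @slot sequence uppercase RNA string (A/C/G/U, N tolerated).
#' @slot dotbracket string over "()." of the same length as the sequence.
#' @slot pairTable integer vector of partner positions (0 = unpaired).
#'
#' @seealso [parseDotBracket()], [buildStructureTree()]
#' @export
setClass("SecondaryStructure",
  representation(
    id = "character",
    sequence = "character",
    dotbracket = "character",
    pairTable = "integer"
  )
)

setValidity("SecondaryStructure", function(object) {
  msgs <- character(0)
  n <- nchar(object@sequence)
  if (length(object@id) != 1L || !nzchar(object@id)) {
    msgs <- c(msgs, "id must be a non-empty single string")
  }
  if (nchar(object@dotbracket) != n) {
    msgs <- c(msgs, "sequence and dotbracket lengths differ")
  }
  if (length(object@pairTable) != n) {
    msgs <- c(msgs, "pair table length differs from sequence length")
  }
  pt <- object@pairTable
  paired <- which(pt > 0L)
  if (length(paired)) {
    if (any(pt[pt[paired]] != paired)) {
      msgs <- c(msgs, "pair table is not an involution")
    }
    if (any(pt[paired] == paired)) {
      msgs <- c(msgs, "a position cannot pair with itself")
    }
    ## non-crossing: for pairs (i,j), (k,l) with i<k, require nested or disjoint
    op <- paired[pt[paired] > paired]
    if (length(op) > 1L) {
      i <- rep(op, each = length(op)); k <- rep(op, times = length(op))
      keep <- i < k
      i <- i[keep]; k <- k[keep]
      j <- pt[i]; l <- pt[k]
      if (any(k < j & l > j)) msgs <- c(msgs, "crossing base pairs (pseudoknot)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' StructureTree: canonical loop decomposition of a secondary structure
#'
#' A rooted ordered tree over structural elements. The root is the EXTERNAL
#' loop; STEM nodes are maximal helices (stacked pairs, no unpaired gaps; lone
#' pairs allowed); each stem encloses exactly one loop element, classified as
#' HAIRPIN (no child helix), INTERNAL (one child helix; covers bulges), or
#' MULTILOOP (>= 2 child helices). Every sequence position belongs to exactly
#' one element: stems own their paired positions, loop elements their unpaired
#' positions.
#'
#' @slot structure the decomposed [SecondaryStructure-class].
#' @slot nodes list of node records (id, kind, parent, children, and
#'   kind-specific coordinates, all 1-based).
#'
#' @export
setClass("StructureTree",
  representation(structure = "SecondaryStructure", nodes = "list")
)

#' DesignRules: constants of the probe/oligo library design
#'
#' Synthesis and assembly constants: the oligo length limit, the fixed 84-nt
#' attachment overhead (barcode 25 + two 18-nt stabilizing stems + 23-nt
#' anti-promoter region), the T7 promoter, the transcript leader it encodes,
#' and the stabilizing stem duplex. The maximum structure length is
#' \code{oligoLimit - attachmentOverhead}.
#'
#' @seealso [designRules()], [maxStructureLength()]
#' @export
setClass("DesignRules",
  representation(
    version = "character",
    oligoLimit = "integer",
    attachmentOverhead = "integer",
    barcodeLen = "integer",
    stemLen = "integer",
    nBarcodes = "integer",
    promoter = "character",
    leader = "character",
    stemForward = "character",
    stemReverse = "character"
  )
)

setValidity("DesignRules", function(object) {
  msgs <- character(0)
  if (object@oligoLimit < 1L) msgs <- c(msgs, "oligoLimit must be positive")
  if (object@attachmentOverhead < 1L) {
    msgs <- c(msgs, "attachmentOverhead must be positive")
  }
  if (object@nBarcodes < 1L) msgs <- c(msgs, "nBarcodes must be positive")
  if (nchar(object@stemForward) != object@stemLen ||
      nchar(object@stemReverse) != object@stemLen) {
    msgs <- c(msgs, "stabilizing stem sequences must have length stemLen")
  }
  if (.revCompRNA(object@stemForward) != object@stemReverse) {
    msgs <- c(msgs, "stemReverse is not the reverse complement of stemForward")
  }
  if (length(msgs)) msgs else TRUE
})

#' BarcodePool: an orthogonal pool of 25-mer barcodes
#'
#' Unique fixed-length RNA barcodes with a guaranteed minimum pairwise Hamming
#' distance, used as molecular identifiers hybridizing to complementary DNA
#' spots on the quantification microarray.
#'
#' @slot barcodes character vector of RNA barcodes, all the same length.
#' @slot minPairwiseHamming asserted minimum pairwise Hamming distance
#'   (0 = unchecked).
#' @slot gcRange length-2 numeric GC-content bounds (may be c(0, 1)).
#'
#' @seealso [barcodePool()], [loadBarcodePool()], [genBarcodePool()]
#' @export
setClass("BarcodePool",
  representation(
    barcodes = "character",
    minPairwiseHamming = "integer",
    gcRange = "numeric"
  )
)

setValidity("BarcodePool", function(object) {
  msgs <- character(0)
  bc <- object@barcodes
  if (!length(bc)) msgs <- c(msgs, "empty barcode pool")
  if (length(unique(nchar(bc))) > 1L) {
    msgs <- c(msgs, "barcodes differ in length")
  }
  if (anyDuplicated(bc)) msgs <- c(msgs, "duplicate barcodes")
  if (length(msgs)) msgs else TRUE
})

#' MiRBaseHairpin: a miRNA precursor hairpin with mature coordinates
#'
#' A hairpin record in the style of miRBase: the precursor's sequence and
#' secondary structure plus one or two mature-miRNA intervals (1-based,
#' inclusive, in hairpin coordinates), each lying on one arm of the hairpin.
#'
#' @slot geneId character(1) gene name (e.g. "hsa-mir-21").
#' @slot structure the precursor [SecondaryStructure-class].
#' @slot matures data.frame with columns name, start, end.
#'
#' @seealso [extractPreMiRNALoop()], [genMiRBaseRecords()]
#' @export
setClass("MiRBaseHairpin",
  representation(
    geneId = "character",
    structure = "SecondaryStructure",
    matures = "data.frame"
  )
)

setValidity("MiRBaseHairpin", function(object) {
  msgs <- character(0)
  m <- object@matures
  if (!all(c("name", "start", "end") %in% names(m))) {
    msgs <- c(msgs, "matures needs columns name, start, end")
  } else {
    if (nrow(m) < 1L || nrow(m) > 2L) {
      msgs <- c(msgs, "a hairpin carries 1 or 2 mature miRNAs")
    }
    n <- nchar(object@structure@sequence)
    if (nrow(m) && (any(m$start < 1L) || any(m$end > n) ||
                    any(m$start > m$end))) {
      msgs <- c(msgs, "mature intervals must lie within the hairpin")
    }
  }
  if (length(msgs)) msgs else TRUE
})
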