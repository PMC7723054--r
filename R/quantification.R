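## Spot-level fluorescence -> per-structure binding intensities, Z-scores,
## ranks, top-fraction selection and between-condition comparison.

.FLUO_COLS <- c("spot_id", "barcode_id", "structure_ref", "sample_id",
                "intensity")

#' Read / write spot-level fluorescence tables
#'
#' TSV with columns spot_id, barcode_id, structure_ref, sample_id, intensity.
#'
#' @param path input/output file.
#' @return \code{readFluorescenceTable}: the table as a data.frame.
#' @export
readFluorescenceTable <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(.FLUO_COLS, names(tb))
  if (length(missing)) {
    .stop2("fluoFormatError", sprintf(
      "%s: missing column%s %s", path, if (length(missing) == 1L) "" else "s",
      paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(tb$intensity))) {
    .stop2("fluoFormatError", sprintf("%s: non-finite intensities", path))
  }
  tb
}

#' @rdname readFluorescenceTable
#' @param table a fluorescence data.frame.
#' @export
writeFluorescenceTable <- function(table, path) {
  write.table(table[, .FLUO_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Aggregate replicate spots to per-barcode intensities
#'
#' Per (barcode, sample), the median across replicate spots — robust to a
#' single bad spot. The number of spots aggregated is recorded.
#'
#' @param table fluorescence data.frame (spot level).
#' @return data.frame with barcode_id, structure_ref, sample_id, intensity
#'   (median), n_spots.
#' @export
aggregateSpots <- function(table) {
  key <- interaction(table$barcode_id, table$sample_id, drop = TRUE,
                     lex.order = TRUE)
  idx <- split(seq_len(nrow(table)), key)
  rows <- lapply(idx, function(ii) {
    data.frame(
      barcode_id = table$barcode_id[ii[1L]],
      structure_ref = table$structure_ref[ii[1L]],
      sample_id = table$sample_id[ii[1L]],
      intensity = median(table$intensity[ii]),
      n_spots = length(ii),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$barcode_id), , drop = FALSE]
}

## trimmed barcode mean: n >= 4 drops one max and one min, n <= 3 plain mean
.trimmedBarcodeMean <- function(d) {
  if (length(d) >= 4L) {
    s <- sort(d)
    mean(s[2:(length(s) - 1L)])
  } else {
    mean(d)
  }
}

#' Compute per-structure binding intensities
#'
#' Per barcode, the no-protein control intensity is subtracted from the sample
#' intensity. Per structure, barcode differences are combined as: with five
#' barcodes, the maximum and minimum are excluded and the middle three
#' averaged; with three, a plain mean. The general rule is n >= 4: drop one
#' max and one min, then mean; n <= 3: mean. Negative intensities are retained
#' (not clipped) so downstream Z-scores stay unbiased.
#'
#' @param sample,control fluorescence data.frames — spot level (aggregated
#'   internally via [aggregateSpots()]) or already per-barcode.
#' @param barcodeMap optional data.frame (barcode_id, structure_ref)
#'   overriding the mapping carried by the tables.
#' @return binding-profile data.frame: structure_ref, intensity, n_barcodes,
#'   flag ("" or a note; structures with no usable barcode are flagged
#'   "no_usable_barcode" with NA intensity).
#' @examples
#' # five barcode differences 1,5,6,7,100 -> trimmed mean of {5,6,7} = 6
#' @export
computeBindingIntensity <- function(sample, control, barcodeMap = NULL) {
  agg <- function(tb) if ("spot_id" %in% names(tb)) aggregateSpots(tb) else tb
  sample <- agg(sample); control <- agg(control)
  if (is.null(barcodeMap)) {
    barcodeMap <- unique(rbind(sample[, c("barcode_id", "structure_ref")],
                               control[, c("barcode_id", "structure_ref")]))
  }
  if (anyDuplicated(barcodeMap$barcode_id)) {
    .stop2("quantError", "a barcode maps to more than one structure")
  }
  si <- setNames(sample$intensity, sample$barcode_id)
  ci <- setNames(control$intensity, control$barcode_id)
  rows <- lapply(split(barcodeMap, barcodeMap$structure_ref), function(bm) {
    d <- si[bm$barcode_id] - ci[bm$barcode_id]
    usable <- is.finite(d)
    flag <- ""
    if (!all(usable)) flag <- "missing_barcode"
    d <- d[usable]
    if (!length(d)) {
      return(data.frame(structure_ref = bm$structure_ref[1L],
                        intensity = NA_real_, n_barcodes = 0L,
                        flag = "no_usable_barcode", stringsAsFactors = FALSE))
    }
    data.frame(structure_ref = bm$structure_ref[1L],
               intensity = .trimmedBarcodeMean(unname(d)),
               n_barcodes = length(d), flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$structure_ref), , drop = FALSE]
}

#' Average binding profiles from replicate experiments
#'
#' Replicate experiments are averaged on the post-subtraction intensity scale,
#' per structure.
#'
#' @param profiles list of binding-profile data.frames over the same
#'   structures.
#' @return one binding-profile data.frame.
#' @export
averageProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  out <- profiles[[1L]]
  if (length(profiles) == 1L) return(out)
  ids <- out$structure_ref
  mat <- vapply(profiles, function(p) {
    p$intensity[match(ids, p$structure_ref)]
  }, numeric(length(ids)))
  out$intensity <- rowMeans(mat)
  out
}

#' Z-scores and ranks of a binding profile
#'
#' \code{z = (I - mean) / sd} with the sample standard deviation (n - 1),
#' computed over the chosen population (the whole profile or a named
#' sublibrary); ranks are by intensity, 1 = highest, ties broken by structure
#' id. Structures outside the population keep their intensity but get their z
#' relative to the population.
#'
#' @param profile binding-profile data.frame ([computeBindingIntensity()]).
#' @param population optional character vector of structure_refs defining the
#'   Z-score population (default: all structures with finite intensity).
#' @return the profile with z_score and rank columns added.
#' @export
computeZScores <- function(profile, population = NULL) {
  ok <- is.finite(profile$intensity)
  pop <- if (is.null(population)) profile$structure_ref[ok] else population
  ii <- profile$intensity[ok & profile$structure_ref %in% pop]
  if (length(ii) < 2L) {
    .stop2("quantError", sprintf(
      "Z-score population '%s' has fewer than 2 usable structures",
      if (is.null(population)) "all" else "selection"))
  }
  m <- mean(ii); s <- sd(ii)
  if (s == 0) {
    .stop2("quantError", sprintf(
      "Z-score population '%s' (%d structures) has zero standard deviation",
      if (is.null(population)) "all" else "selection", length(ii)))
  }
  profile$z_score <- (profile$intensity - m) / s
  ord <- order(-profile$intensity, profile$structure_ref, na.last = TRUE)
  profile$rank <- NA_integer_
  profile$rank[ord] <- seq_along(ord)
  profile
}

#' Select the top fraction of a binding profile
#'
#' Structures ranked by intensity descending; the top
#' \code{ceiling(fraction * N)} are returned, boundary ties broken by stable
#' structure id order.
#'
#' @param profile binding-profile data.frame.
#' @param fraction in (0, 1]; default 0.05 (top 5%).
#' @return character vector of selected structure_refs.
#' @export
selectTopFraction <- function(profile, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  ok <- profile[is.finite(profile$intensity), , drop = FALSE]
  if (!nrow(ok)) .stop2("quantError", "empty binding profile")
  k <- ceiling(fraction * nrow(ok))
  ord <- order(-ok$intensity, ok$structure_ref)
  ok$structure_ref[ord[seq_len(k)]]
}

#' Compare binding profiles from two conditions
#'
#' Per structure: the intensity difference and both Z-scores, plus a label —
#' "A_specific" (\code{z_a >= t, z_b < t}), "B_specific", "shared" (both
#' above), "neither". Structures missing in one profile are flagged.
#'
#' @param profileA,profileB binding-profile data.frames (Z-scores are
#'   computed if absent).
#' @param threshold Z-score threshold t (default 2.0).
#' @return data.frame: structure_ref, intensity_a, intensity_b,
#'   delta_intensity, z_a, z_b, class, flag.
#' @export
compareConditions <- function(profileA, profileB, threshold = 2.0) {
  if (!"z_score" %in% names(profileA)) profileA <- computeZScores(profileA)
  if (!"z_score" %in% names(profileB)) profileB <- computeZScores(profileB)
  ids <- union(profileA$structure_ref, profileB$structure_ref)
  ia <- match(ids, profileA$structure_ref)
  ib <- match(ids, profileB$structure_ref)
  out <- data.frame(
    structure_ref = ids,
    intensity_a = profileA$intensity[ia],
    intensity_b = profileB$intensity[ib],
    z_a = profileA$z_score[ia],
    z_b = profileB$z_score[ib],
    stringsAsFactors = FALSE
  )
  out$delta_intensity <- out$intensity_a - out$intensity_b
  za <- !is.na(out$z_a) & out$z_a >= threshold
  zb <- !is.na(out$z_b) & out$z_b >= threshold
  out$class <- ifelse(za & zb, "shared",
               ifelse(za, "A_specific",
               ifelse(zb, "B_specific", "neither")))
  out$flag <- ifelse(is.na(ia), "missing_in_A",
              ifelse(is.na(ib), "missing_in_B", ""))
  out[order(out$structure_ref), , drop = FALSE]
}
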