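## Generators for every input class the pipeline consumes: random hairpin and
## multibranch structures, miRBase-like hairpin records, orthogonal barcode
## pools, and simulated two-channel fluorescence experiments with planted
## binders. All generators are bit-reproducible given (config, seed).

#' Simulation configuration
#'
#' Defaults describe the study conditions the simulated experiments emulate:
#' 200 structures with hairpin stems of 5-12 bp and loops of 4-8 nt, 30%
#' internal-loop and 20% multibranch probability, GC content 0.5 with 10%
#' wobble (G-U) pairs in stems; 5% of structures carry the planted motif
#' "GCAC" in a hairpin loop. Fluorescence: baseline 1000 AU with lognormal
#' spot noise (sdlog 0.1, i.e. spot SD about 100 AU) and per-barcode
#' multiplicative bias (sdlog 0.05); planted loop-context binders add 500 AU
#' (5x the spot noise SD), paired-context occurrences 250 AU. Three barcodes
#' per structure, five spots per barcode.
#'
#' @param ... overrides of any default listed above (see
#'   \code{formals(simulationConfig)}).
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_structures = 200L,
                             stem_len_range = c(5L, 12L),
                             loop_len_range = c(4L, 8L),
                             p_internal_loop = 0.3,
                             p_multiloop = 0.2,
                             gc_content = 0.5,
                             wobble_prob = 0.1,
                             planted_motif = "GCAC",
                             planted_fraction = 0.05,
                             affinity_high = 500,
                             affinity_mid = 250,
                             affinity_zero = 0,
                             noise_sd_log = 0.1,
                             barcode_bias_sd_log = 0.05,
                             baseline_fluorescence = 1000,
                             replication_factor = 5L,
                             n_barcodes = 3L,
                             condition_affinity = list()) {
  cfg <- list(
    n_structures = as.integer(n_structures),
    stem_len_range = as.integer(stem_len_range),
    loop_len_range = as.integer(loop_len_range),
    p_internal_loop = p_internal_loop, p_multiloop = p_multiloop,
    gc_content = gc_content, wobble_prob = wobble_prob,
    planted_motif = .toRNA(planted_motif),
    planted_fraction = planted_fraction,
    affinity_high = affinity_high, affinity_mid = affinity_mid,
    affinity_zero = affinity_zero,
    noise_sd_log = noise_sd_log, barcode_bias_sd_log = barcode_bias_sd_log,
    baseline_fluorescence = baseline_fluorescence,
    replication_factor = as.integer(replication_factor),
    n_barcodes = as.integer(n_barcodes),
    condition_affinity = condition_affinity
  )
  probs <- c(cfg$p_internal_loop, cfg$p_multiloop, cfg$gc_content,
             cfg$wobble_prob, cfg$planted_fraction)
  if (any(probs < 0 | probs > 1)) {
    .stop2("cfgError", "probabilities must lie in [0, 1]")
  }
  if (cfg$stem_len_range[1L] > cfg$stem_len_range[2L] ||
      cfg$loop_len_range[1L] > cfg$loop_len_range[2L] ||
      cfg$stem_len_range[1L] < 1L || cfg$loop_len_range[1L] < 0L) {
    .stop2("cfgError", "invalid stem/loop length ranges")
  }
  if (cfg$loop_len_range[1L] < nchar(cfg$planted_motif)) {
    .stop2("cfgError",
           "minimum loop length must fit the planted motif")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

.sampleRange <- function(r) if (r[1L] == r[2L]) r[1L] else
  sample(r[1L]:r[2L], 1L)

.sampleBases <- function(n, gc) {
  if (n == 0L) return(character(0))
  sample(c("A", "C", "G", "U"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## Fill a dot-bracket shape with a sequence: paired positions get Watson-Crick
## (or, with wobble_prob, G-U) complements; unpaired positions are sampled at
## the configured GC content.
.fillSequence <- function(db, cfg) {
  pt <- parseDotBracket("shape", strrep("A", nchar(db)), db,
                        warnDNA = FALSE)@pairTable
  n <- length(pt)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  wob <- c(G = "U", U = "G")
  ch <- character(n)
  for (i in seq_len(n)) {
    if (pt[i] == 0L) {
      ch[i] <- .sampleBases(1L, cfg$gc_content)
    } else if (pt[i] > i) {
      b <- .sampleBases(1L, cfg$gc_content)
      ch[i] <- b
      ch[pt[i]] <- if (b %in% names(wob) && runif(1L) < cfg$wobble_prob) {
        wob[[b]]
      } else {
        comp[[b]]
      }
    }
  }
  paste(ch, collapse = "")
}

## Dot-bracket of one hairpin arm: a stem of `stem` bp, optionally split by an
## internal loop, around a terminal loop of `loop` nt.
.hairpinShape <- function(stem, loop, cfg) {
  if (runif(1L) < cfg$p_internal_loop && stem >= 4L) {
    a <- sample(2L:(stem - 2L), 1L)
    b <- stem - a
    l5 <- sample(0L:3L, 1L)
    l3 <- sample(0L:3L, 1L)
    if (l5 + l3 == 0L) l5 <- 1L
    paste0(strrep("(", a), strrep(".", l5), strrep("(", b),
           strrep(".", loop), strrep(")", b), strrep(".", l3),
           strrep(")", a))
  } else {
    paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
  }
}

#' Generate a random single-hairpin structure
#'
#' Stem/loop geometry is sampled from the configured ranges; with probability
#' \code{p_internal_loop} the stem is split by an internal loop or bulge.
#' Paired positions carry Watson-Crick (or wobble) complements. Deterministic
#' under \code{seed}.
#'
#' @param cfg a [simulationConfig()].
#' @param seed integer seed.
#' @param id record id (default derived from the seed).
#' @return a [SecondaryStructure-class].
#' @export
genHairpinStructure <- function(cfg = simulationConfig(), seed = 1L,
                                id = sprintf("synth_hp_%d", seed)) {
  withSeed(seed, {
    db <- .hairpinShape(.sampleRange(cfg$stem_len_range),
                        .sampleRange(cfg$loop_len_range), cfg)
    parseDotBracket(id, .fillSequence(db, cfg), db, warnDNA = FALSE)
  })
}

#' Generate a random multibranch structure
#'
#' Two or three hairpin arms inside a closing stem, separated by short
#' unpaired junction segments: the tree has exactly one MULTILOOP and at
#' least two hairpins.
#'
#' @inheritParams genHairpinStructure
#' @return a [SecondaryStructure-class].
#' @export
genMultibranchStructure <- function(cfg = simulationConfig(), seed = 1L,
                                    id = sprintf("synth_mb_%d", seed)) {
  withSeed(seed, {
    nArms <- sample(2:3, 1L)
    arms <- vapply(seq_len(nArms), function(a) {
      .hairpinShape(.sampleRange(cfg$stem_len_range),
                    .sampleRange(cfg$loop_len_range), cfg)
    }, character(1))
    spacers <- vapply(seq_len(nArms + 1L), function(a) {
      strrep(".", sample(1:3, 1L))
    }, character(1))
    close <- max(2L, .sampleRange(cfg$stem_len_range) %/% 2L)
    inner <- paste0(spacers[1L],
                    paste0(arms, spacers[-1L], collapse = ""))
    db <- paste0(strrep("(", close), inner, strrep(")", close))
    parseDotBracket(id, .fillSequence(db, cfg), db, warnDNA = FALSE)
  })
}

## Replace the characters of a loop interval with the motif (all positions
## unpaired, so no partner bookkeeping is needed).
.plantMotifInLoop <- function(s, motif) {
  tree <- buildStructureTree(s)
  hp <- enumerateHairpins(tree)
  L <- nchar(motif)
  ok <- hp[hp$loop_end - hp$loop_start + 1L >= L, , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  row <- ok[sample.int(nrow(ok), 1L), , drop = FALSE]
  at <- row$loop_start +
    sample.int(row$loop_end - row$loop_start + 2L - L, 1L) - 1L
  seq <- s@sequence
  substr(seq, at, at + L - 1L) <- motif
  parseDotBracket(s@id, seq, s@dotbracket, warnDNA = FALSE)
}

## Remove motif occurrences outside `keep` (a protected interval or NULL) by
## point mutations that respect pairing.
.scrubMotif <- function(s, motif, keep = NULL) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  L <- nchar(motif)
  for (iter in seq_len(50L)) {
    hits <- gregexpr(paste0("(?=", motif, ")"), s@sequence, perl = TRUE)[[1]]
    hits <- as.integer(hits[hits > 0L])
    if (!is.null(keep)) {
      hits <- hits[!(hits >= keep[1L] & hits + L - 1L <= keep[2L])]
    }
    if (!length(hits)) return(s)
    p <- hits[1L] + sample.int(L, 1L) - 1L
    old <- substr(s@sequence, p, p)
    b <- sample(setdiff(c("A", "C", "G", "U"), old), 1L)
    seq <- s@sequence
    substr(seq, p, p) <- b
    if (s@pairTable[p] > 0L) {
      q <- s@pairTable[p]
      substr(seq, q, q) <- comp[[b]]
    }
    s <- parseDotBracket(s@id, seq, s@dotbracket, warnDNA = FALSE)
  }
  s
}

#' Generate a structure library with planted binders
#'
#' Draws \code{n_structures} structures (multibranch with probability
#' \code{p_multiloop}, single hairpins otherwise) and plants the configured
#' motif into a hairpin loop of a \code{planted_fraction} subset. Accidental
#' occurrences of the planted motif elsewhere are scrubbed by
#' pairing-respecting point mutations, so the planted set is exactly the
#' truth set.
#'
#' @param cfg a [simulationConfig()].
#' @param seed integer seed.
#' @return list with \code{$structures} (list of
#'   [SecondaryStructure-class]) and \code{$truth} (data.frame structure_id,
#'   planted).
#' @export
genStructureLibrary <- function(cfg = simulationConfig(), seed = 1L) {
  n <- cfg$n_structures
  nPlanted <- round(cfg$planted_fraction * n)
  plan <- withSeed(seed, {
    list(planted = sort(sample.int(n, nPlanted)),
         multibranch = runif(n) < cfg$p_multiloop,
         subseeds = sample.int(2147483600L, n))
  })
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    si <- plan$subseeds[i]
    id <- sprintf("synth_%04d", i)
    s <- if (plan$multibranch[i]) {
      genMultibranchStructure(cfg, si, id = id)
    } else {
      genHairpinStructure(cfg, si, id = id)
    }
    structures[[i]] <- withSeed(.subSeed(si, 1L), {
      if (i %in% plan$planted) {
        planted <- .plantMotifInLoop(s, cfg$planted_motif)
        if (is.null(planted)) {
          ## no loop wide enough; drops out of the planted set
          .scrubMotif(s, cfg$planted_motif)
        } else {
          hit <- regexpr(cfg$planted_motif, planted@sequence, fixed = TRUE)
          .scrubMotif(planted, cfg$planted_motif,
                      keep = c(hit, hit + nchar(cfg$planted_motif) - 1L))
        }
      } else {
        .scrubMotif(s, cfg$planted_motif)
      }
    })
  }
  plantedNow <- vapply(structures, function(s) {
    grepl(cfg$planted_motif, s@sequence, fixed = TRUE)
  }, logical(1))
  list(
    structures = structures,
    truth = data.frame(
      structure_id = vapply(structures, structureId, character(1)),
      planted = plantedNow, stringsAsFactors = FALSE
    )
  )
}

#' Generate miRBase-like hairpin records
#'
#' Perfect-stem precursors with one or two matures placed on the arms; the
#' 3' mature follows a 2-nt overhang convention relative to the 5' mature's
#' pairing partners and never spans the terminal loop.
#'
#' @param cfg a [simulationConfig()] (GC content is used).
#' @param n number of records.
#' @param seed integer seed.
#' @return list of [MiRBaseHairpin-class].
#' @export
genMiRBaseRecords <- function(cfg = simulationConfig(), n = 10L, seed = 1L) {
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      mlen <- sample(18:22, 1L)
      stem <- mlen + sample(2:5, 1L)
      loop <- sample(4:10, 1L)
      db <- paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
      seq <- .fillSequence(db, cfg)
      total <- 2L * stem + loop
      m5 <- c(1L, mlen)
      ## partner of position k is total + 1 - k; 2-nt 3' overhang
      m3 <- c(total + 1L - mlen - 2L, total - 2L)
      two <- runif(1L) < 0.5
      mm <- if (two) {
        data.frame(name = sprintf("syn-miR-%d-%s", i, c("5p", "3p")),
                   start = c(m5[1L], m3[1L]), end = c(m5[2L], m3[2L]),
                   stringsAsFactors = FALSE)
      } else if (runif(1L) < 0.5) {
        data.frame(name = sprintf("syn-miR-%d-5p", i),
                   start = m5[1L], end = m5[2L], stringsAsFactors = FALSE)
      } else {
        data.frame(name = sprintf("syn-miR-%d-3p", i),
                   start = m3[1L], end = m3[2L], stringsAsFactors = FALSE)
      }
      miRBaseHairpin(sprintf("syn-mir-%d", i), seq, db, mm)
    })
  })
}

#' Generate an orthogonal barcode pool
#'
#' Rejection sampling of unique fixed-length barcodes meeting pairwise
#' Hamming-distance and GC-content constraints; deterministic under
#' \code{seed}.
#'
#' @param n pool size.
#' @param length barcode length (default 25).
#' @param minHamming minimum pairwise Hamming distance (default 8).
#' @param gcRange GC-content bounds (default c(0.3, 0.7)).
#' @param seed integer seed.
#' @param maxAttempts rejection-sampling cap (default 1000 * n).
#' @return a [BarcodePool-class].
#' @export
genBarcodePool <- function(n, length = 25L, minHamming = 8L,
                           gcRange = c(0.3, 0.7), seed = 1L,
                           maxAttempts = 1000L * n) {
  withSeed(seed, {
    accepted <- character(0)
    mat <- matrix(character(0), 0L, length)
    attempts <- 0L
    while (base::length(accepted) < n) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts) {
        .stop2("barcodeError", sprintf(
          "barcode sampling cap (%d attempts) exceeded with %d/%d accepted; relax minHamming or gcRange",
          maxAttempts, base::length(accepted), n))
      }
      ch <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
      gc <- mean(ch %in% c("G", "C"))
      if (gc < gcRange[1L] || gc > gcRange[2L]) next
      if (nrow(mat)) {
        d <- rowSums(mat != matrix(ch, nrow(mat), length, byrow = TRUE))
        if (any(d < minHamming)) next
      }
      accepted <- c(accepted, paste(ch, collapse = ""))
      mat <- rbind(mat, ch)
    }
    barcodePool(accepted, minHamming = minHamming, gcRange = gcRange,
                barcodeLen = length)
  })
}

## Affinity of a structure to the (simulated) ligand: high when the planted
## motif occurs fully unpaired (loop context), mid when it occurs but not
## fully unpaired, zero otherwise.
.structureAffinity <- function(s, cfg, condition = NULL) {
  aff <- list(high = cfg$affinity_high, mid = cfg$affinity_mid,
              zero = cfg$affinity_zero)
  if (!is.null(condition) && condition %in% names(cfg$condition_affinity)) {
    ov <- cfg$condition_affinity[[condition]]
    aff[names(ov)] <- ov
  }
  L <- nchar(cfg$planted_motif)
  hits <- gregexpr(paste0("(?=", cfg$planted_motif, ")"), s@sequence,
                   perl = TRUE)[[1]]
  hits <- as.integer(hits[hits > 0L])
  if (!length(hits)) return(aff$zero)
  anyLoop <- any(vapply(hits, function(p) {
    all(s@pairTable[p:(p + L - 1L)] == 0L)
  }, logical(1)))
  if (anyLoop) aff$high else aff$mid
}

#' Simulate a two-channel fluorescence experiment
#'
#' Spot intensity = baseline x per-barcode bias x lognormal spot noise, plus
#' a per-structure affinity term in the protein sample (the no-protein
#' control omits it). The affinity is \code{affinity_high} when the planted
#' motif occurs in loop context in the structure, \code{affinity_mid} when it
#' occurs paired/mixed, else \code{affinity_zero}; per-condition overrides
#' come from \code{cfg$condition_affinity} (a named list of named affinity
#' overrides). Every probe barcode is replicated over
#' \code{replication_factor} spots. All draws are seeded.
#'
#' @param probes probe data.frame from [designLibrary()].
#' @param structures list of [SecondaryStructure-class] referenced by
#'   \code{probes$structure_ref}.
#' @param cfg a [simulationConfig()].
#' @param conditions character vector of sample conditions (default
#'   \code{"sample"}).
#' @param seed integer seed.
#' @return named list of spot-level fluorescence data.frames: one per
#'   condition plus \code{$control}.
#' @export
simulateExperiment <- function(probes, structures,
                               cfg = simulationConfig(),
                               conditions = "sample", seed = 1L) {
  ids <- vapply(structures, structureId, character(1))
  if (!all(probes$structure_ref %in% ids)) {
    .stop2("simError", "probes reference structures not in `structures`")
  }
  withSeed(seed, {
    bcs <- unique(probes$barcode_id)
    bias <- setNames(rlnorm(length(bcs), 0, cfg$barcode_bias_sd_log), bcs)
    affinity <- vapply(conditions, function(cond) {
      vapply(structures, .structureAffinity, numeric(1), cfg = cfg,
             condition = cond)
    }, numeric(length(structures)))
    dim(affinity) <- c(length(structures), length(conditions))
    rownames(affinity) <- ids
    nSpots <- nrow(probes) * cfg$replication_factor
    spotTemplate <- data.frame(
      spot_id = sprintf("%s_s%d",
                        rep(probes$barcode_id, each = cfg$replication_factor),
                        rep(seq_len(cfg$replication_factor), nrow(probes))),
      barcode_id = rep(probes$barcode_id, each = cfg$replication_factor),
      structure_ref = rep(probes$structure_ref,
                          each = cfg$replication_factor),
      stringsAsFactors = FALSE
    )
    base <- cfg$baseline_fluorescence * bias[spotTemplate$barcode_id]
    tables <- list()
    for (ci in seq_along(conditions)) {
      tb <- spotTemplate
      tb$sample_id <- conditions[ci]
      tb$intensity <- unname(base) *
        rlnorm(nSpots, 0, cfg$noise_sd_log) +
        affinity[tb$structure_ref, ci]
      tables[[conditions[ci]]] <- tb[, .FLUO_COLS]
    }
    ctl <- spotTemplate
    ctl$sample_id <- "control"
    ctl$intensity <- unname(base) * rlnorm(nSpots, 0, cfg$noise_sd_log)
    tables$control <- ctl[, .FLUO_COLS]
    tables
  })
}
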