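test_that("configuration validation rejects impossible settings", {
  expect_error(simulationConfig(p_multiloop = 1.5), class = "cfgError")
  expect_error(simulationConfig(stem_len_range = c(5, 2)), class = "cfgError")
  expect_error(simulationConfig(loop_len_range = c(2, 8)), class = "cfgError")
})

test_that("hairpin generation is shape-exact and seed-deterministic", {
  cfg <- simulationConfig(stem_len_range = c(8, 8), loop_len_range = c(4, 4),
                          p_internal_loop = 0)
  s <- genHairpinStructure(cfg, 1)
  expect_identical(dotBracket(s), "((((((((....))))))))")
  expect_identical(rnaSequence(genHairpinStructure(cfg, 1)), rnaSequence(s))
  expect_false(identical(rnaSequence(genHairpinStructure(cfg, 2)),
                         rnaSequence(s)))
})

test_that("generated stems carry complementary (or wobble) pairs", {
  cfg <- simulationConfig()
  ok <- c("AU", "UA", "CG", "GC", "GU", "UG")
  allOK <- vapply(seq_len(1000L), function(seed) {
    s <- if (seed %% 3 == 0) genMultibranchStructure(cfg, seed) else
      genHairpinStructure(cfg, seed)
    pt <- pairTable(s)
    ch <- strsplit(rnaSequence(s), "")[[1]]
    op <- which(pt > seq_along(pt))
    all(paste0(ch[op], ch[pt[op]]) %in% ok)
  }, logical(1))
  expect_true(all(allOK))
})

test_that("multibranch structures have one junction and >= 2 hairpins", {
  cfg <- simulationConfig(p_multiloop = 1)
  for (seed in 1:50) {
    s <- genMultibranchStructure(cfg, seed)
    tree <- buildStructureTree(s)
    kinds <- vapply(treeNodes(tree), `[[`, character(1), "kind")
    expect_equal(sum(kinds == "MULTILOOP"), 1L)
    expect_gte(sum(kinds == "HAIRPIN"), 2L)
    # extraction on it yields singles for each hairpin and >= 1 multi
    motifs <- extractTerminalMotifs(list(s), limit = 500, minLen = 1)
    expect_gte(sum(motifs$kind == "single_terminal"), 2L)
    expect_gte(sum(motifs$kind == "multi_terminal"), 1L)
  }
})

test_that("generated structures always pass validation", {
  cfg <- simulationConfig()
  lib <- genStructureLibrary(simulationConfig(n_structures = 50), seed = 50)
  for (s in lib$structures) validObject(s)
  expect_identical(lib$truth$planted,
                   genStructureLibrary(simulationConfig(n_structures = 50),
                                       seed = 50)$truth$planted)
})

test_that("planted motifs sit in loops and only in planted structures", {
  cfg <- simulationConfig(n_structures = 60)
  lib <- genStructureLibrary(cfg, seed = 51)
  for (i in seq_along(lib$structures)) {
    s <- lib$structures[[i]]
    hits <- gregexpr("(?=GCAC)", rnaSequence(s), perl = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (lib$truth$planted[i]) {
      expect_gte(length(hits), 1L)
      loopHit <- any(vapply(hits, function(p) {
        all(pairTable(s)[p:(p + 3)] == 0L)
      }, logical(1)))
      expect_true(loopHit)
    } else {
      expect_length(hits, 0L)
    }
  }
  expect_equal(sum(lib$truth$planted), round(0.05 * 60))
})

test_that("miRBase-like records satisfy the hairpin invariants", {
  recs <- genMiRBaseRecords(simulationConfig(), n = 25, seed = 52)
  for (h in recs) {
    validObject(h)
    res <- extractPreMiRNALoop(h)
    expect_identical(res$status, "ok")
  }
  r2 <- genMiRBaseRecords(simulationConfig(), n = 25, seed = 52)
  expect_identical(vapply(recs, rnaSequence, character(1)),
                   vapply(r2, rnaSequence, character(1)))
})

test_that("barcode pools meet Hamming and GC constraints", {
  pool <- genBarcodePool(100, minHamming = 8, seed = 53)
  bc <- barcodes(pool)
  expect_equal(length(bc), 100L)
  mat <- do.call(rbind, strsplit(bc, ""))
  for (i in seq_len(99)) {
    d <- rowSums(mat[(i + 1):100, , drop = FALSE] !=
                   matrix(mat[i, ], 100 - i, 25, byrow = TRUE))
    expect_true(all(d >= 8))
  }
  gc <- vapply(bc, function(b) {
    mean(strsplit(b, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  expect_true(all(gc >= 0.3 & gc <= 0.7))
  expect_identical(barcodes(genBarcodePool(100, minHamming = 8, seed = 53)),
                   bc)
  # infeasible constraints hit the sampling cap with a clear error
  expect_error(genBarcodePool(3, length = 4, minHamming = 5, seed = 54,
                              maxAttempts = 50), class = "barcodeError")
})

test_that("a noise-free experiment reproduces affinities exactly", {
  cfg <- simulationConfig(n_structures = 20, noise_sd_log = 0,
                          barcode_bias_sd_log = 0)
  lib <- genStructureLibrary(cfg, seed = 55)
  motifs <- data.frame(
    motif_id = lib$truth$structure_id,
    sequence = vapply(lib$structures, rnaSequence, character(1)))
  pool <- genBarcodePool(70, seed = 56)
  rules <- suppressWarnings(designRules("v2", nBarcodes = 3))
  probes <- designLibrary(motifs, pool, rules, seed = 57)
  tabs <- simulateExperiment(probes, lib$structures, cfg, seed = 58)

  # null case: control and sample identical for non-binders
  nonb <- lib$truth$structure_id[!lib$truth$planted]
  smp <- tabs$sample[tabs$sample$structure_ref %in% nonb, ]
  ctl <- tabs$control[tabs$control$structure_ref %in% nonb, ]
  expect_equal(smp$intensity, ctl$intensity)

  # planted binders: intensity exactly affinity_high after quantification
  prof <- computeBindingIntensity(tabs$sample, tabs$control)
  planted <- lib$truth$structure_id[lib$truth$planted]
  expect_true(all(abs(prof$intensity[prof$structure_ref %in% planted] -
                        cfg$affinity_high) < 1e-9))
  expect_true(all(abs(prof$intensity[!prof$structure_ref %in% planted]) <
                    1e-9))
})

test_that("condition-dependent binders are classified as condition-specific", {
  cfg <- simulationConfig(
    n_structures = 40,
    condition_affinity = list(lithium = list(high = 0, mid = 0)))
  lib <- genStructureLibrary(cfg, seed = 60)
  motifs <- data.frame(
    motif_id = lib$truth$structure_id,
    sequence = vapply(lib$structures, rnaSequence, character(1)))
  pool <- genBarcodePool(130, seed = 61)
  rules <- suppressWarnings(designRules("v2", nBarcodes = 3))
  probes <- designLibrary(motifs, pool, rules, seed = 62)
  tabs <- simulateExperiment(probes, lib$structures, cfg,
                             conditions = c("potassium", "lithium"),
                             seed = 63)
  pK <- computeZScores(computeBindingIntensity(tabs$potassium, tabs$control))
  pLi <- computeZScores(computeBindingIntensity(tabs$lithium, tabs$control))
  cmp <- compareConditions(pK, pLi, threshold = 2)
  planted <- lib$truth$structure_id[lib$truth$planted]
  expect_true(all(cmp$class[cmp$structure_ref %in% planted] == "A_specific"))
})
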