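test_that("relative frequency is 1 when enriched equals all", {
  set.seed(30)
  seqs <- replicate(20, randomSequence(40))
  res <- kmerEnrichment(seqs, seqs)
  expect_true(all(res$table$relative_frequency == 1))
  expect_length(res$selected, 0L)
})

test_that("RF is invariant to duplicating every enriched sequence", {
  set.seed(31)
  enr <- replicate(10, randomSequence(30))
  # include every 4-mer once so no pseudocount path triggers
  allKmers <- apply(expand.grid(rep(list(c("A", "C", "G", "U")), 4)), 1,
                    paste, collapse = "")
  all <- c(replicate(50, randomSequence(30)), allKmers)
  r1 <- kmerEnrichment(enr, all)
  r2 <- kmerEnrichment(c(enr, enr), all)
  expect_equal(r1$table$relative_frequency, r2$table$relative_frequency,
               tolerance = 1e-12)
})

test_that("normalized counts sum to one without pseudocounts", {
  # cover all 256 4-mers so no pseudocount path triggers
  allK <- apply(expand.grid(rep(list(c("A", "C", "G", "U")), 4)), 1, paste,
                collapse = "")
  res <- kmerEnrichment(allK[1:10], allK)
  expect_lt(abs(sum(res$table$norm_enriched) - 1), 1e-12)
  expect_lt(abs(sum(res$table$norm_all) - 1), 1e-12)
  expect_true(all(res$table$relative_frequency >= 0))
})

test_that("a planted 4-mer dominates the relative frequencies", {
  planted <- "GCAC"
  nFound <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    background <- replicate(1000, randomSequence(40))
    enriched <- vapply(seq_len(50), function(i) {
      s <- randomSequence(40)
      at <- sample.int(37, 1)
      substr(s, at, at + 3) <- planted
      s
    }, character(1))
    res <- kmerEnrichment(enriched, background)
    top <- res$table$kmer[which.max(res$table$relative_frequency)]
    # brute-force recount of the planted k-mer in the enriched set
    countIn <- function(seqs) {
      sum(vapply(seqs, function(s) {
        hits <- gregexpr(paste0("(?=", planted, ")"), s, perl = TRUE)[[1]]
        sum(hits > 0)
      }, numeric(1)))
    }
    row <- res$table[res$table$kmer == planted, ]
    pseudo <- if (row$count_enriched %% 1 != 0) 0.5 else 0
    expect_equal(row$count_enriched - pseudo, countIn(enriched))
    if (top == planted && planted %in% res$selected) nFound <- nFound + 1L
  }
  expect_gte(nFound, 4L)
})

test_that("sequences shorter than k warn and contribute nothing", {
  # both the enriched and the population pass warn once each
  expect_warning(expect_warning(
    res <- kmerEnrichment(c("GCAC", "AU"), c("GCAC", "AU")),
    "shorter than k"), "shorter than k")
  expect_error(kmerEnrichment(character(0), "GCAC"), class = "enrichError")
})

test_that("the greedy PFM aligns overlapping k-mers", {
  one <- buildPFM("GCAC")
  expect_identical(one$consensus, "GCAC")
  expect_true(all(one$pfm[cbind(c("G", "C", "A", "C"), 1:4)] == 1))

  two <- buildPFM(c("GCAC", "CACG"))
  expect_identical(two$consensus, "GCACG")
  expect_equal(unname(two$offsets["CACG"]), 1L)

  none <- buildPFM(c("AAAA", "UUUU"))
  expect_equal(unname(none$offsets), c(0L, 0L))
  expect_true(all(none$pfm["A", ] == 0.5 & none$pfm["U", ] == 0.5))
})

test_that("motif context is labelled from pairing status", {
  # GCAC wholly inside the hairpin loop
  loopS <- parseDotBracket("loop", "GGGGGCACGCCCC", "((((.....))))")
  # GCAC across paired stem positions
  stemS <- parseDotBracket("stem", "GCACAAAAGUGC", "((((....))))")
  # half paired, half unpaired
  mixS <- parseDotBracket("mix", "GGGCACAAAGUCCC", "(((((....)))))")
  prof <- data.frame(structure_ref = c("loop", "stem", "mix"),
                     intensity = c(100, 10, 50), n_barcodes = 3L, flag = "")
  res <- motifContextAnalysis("GCAC", list(loopS, stemS, mixS), prof)
  ctx <- setNames(res$occurrences$context, res$occurrences$structure_id)
  expect_identical(unname(ctx["loop"]), "loop")
  expect_identical(unname(ctx["stem"]), "stem")
  expect_identical(unname(ctx["mix"]), "mixed")
  expect_equal(res$occurrences$intensity[res$occurrences$structure_id ==
                                           "loop"], 100)
  expect_equal(sort(res$summary$context), c("loop", "mixed", "stem"))

  empty <- motifContextAnalysis("GCAC", list(parseDotBracket(
    "none", "AAAA", "....")))
  expect_equal(nrow(empty$occurrences), 0L)
})

test_that("G4 scanning counts guanines and finds canonical patterns", {
  gaa <- scanG4(strrep("GAA", 16))
  expect_equal(gaa$g_number, 16L)
  expect_false(gaa$canonical_g4)
  expect_equal(nrow(gaa$g_tracts), 0L)

  g4 <- scanG4("GGGAGGGAGGGAGGG")
  expect_true(g4$canonical_g4)
  expect_equal(nrow(g4$g_tracts), 4L)
  expect_equal(g4$g_number, 12L)

  none <- scanG4("AAAA")
  expect_equal(none$g_number, 0L)
  expect_false(none$canonical_g4)

  # loops longer than loop_max break the pattern
  expect_false(scanG4("GGAAAAAAAAGGAGGAGG")$canonical_g4)
  # tract boundaries may fall inside longer G runs (loops can contain G)
  expect_true(scanG4("GGGGGGGGGGGGGG", gMin = 2, nTracts = 4)$canonical_g4)
})

test_that("the scanner agrees with the regex oracle on random sequences", {
  set.seed(33)
  for (rep in seq_len(10000L)) {
    n <- sample(10:40, 1L)
    # G-rich alphabet so canonical patterns actually occur
    s <- paste(sample(c("G", "G", "A", "C", "U"), n, replace = TRUE),
               collapse = "")
    expect_identical(scanG4(s)$canonical_g4, oracleG4Regex(s))
  }
})
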