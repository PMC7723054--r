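mkStruct <- function(db, id = "p") {
  parseDotBracket(id, randomSequence(nchar(db)), db, warnDNA = FALSE)
}

test_that("single-terminal extraction walks through internal loops only", {
  set.seed(1)
  # stem with internal loop: whole paired span is one motif
  s <- mkStruct("..(((..((...))..)))..")
  t <- buildStructureTree(s)
  m <- extractSingleTerminal(t, enumerateHairpins(t)[1, , drop = FALSE])
  expect_equal(c(m$start, m$end), c(3L, 19L))
  expect_identical(m$dotbracket, "(((..((...))..)))")
  expect_identical(m$kind, "single_terminal")

  # extension stops at a multiloop
  s2 <- mkStruct("((.((...))((...)).))")
  t2 <- buildStructureTree(s2)
  hp2 <- enumerateHairpins(t2)
  m2 <- extractSingleTerminal(t2, hp2[1, , drop = FALSE])
  expect_equal(c(m2$start, m2$end), c(4L, 10L))
  expect_identical(m2$dotbracket, "((...))")

  # a pure hairpin is its own motif
  s3 <- mkStruct("(((...)))")
  t3 <- buildStructureTree(s3)
  m3 <- extractSingleTerminal(t3, enumerateHairpins(t3)[1, , drop = FALSE])
  expect_equal(c(m3$start, m3$end), c(1L, 9L))
})

test_that("multi-terminal extraction emits one motif per junction", {
  set.seed(2)
  s <- mkStruct("((.((...))((...)).))")
  mm <- extractMultiTerminal(buildStructureTree(s))
  expect_equal(nrow(mm), 1L)
  expect_equal(c(mm$start, mm$end, mm$n_hairpins), c(1L, 20L, 2L))

  expect_equal(nrow(extractMultiTerminal(
    buildStructureTree(mkStruct("(((...)))")))), 0L)

  # nested junctions: inner and outer each produce a motif
  s2 <- mkStruct("((((...))((...)))((...)))")
  mm2 <- extractMultiTerminal(buildStructureTree(s2))
  expect_equal(nrow(mm2), 2L)
  expect_equal(sort(mm2$n_hairpins), c(2L, 3L))
})

test_that("trimming removes outer pairs down to blunt ends", {
  set.seed(3)
  m <- extractTerminalMotifs(list(mkStruct("((((((((....))))))))")),
                             limit = 100)
  sh <- shortenToLimit(m, 12)
  expect_identical(sh$status, "ok")
  expect_identical(sh$motif$dotbracket, "((((....))))")
  expect_true(sh$motif$trimmed)
  expect_equal(c(sh$motif$start, sh$motif$end), c(5L, 16L))

  m2 <- extractTerminalMotifs(list(mkStruct("((..((....))..))")), limit = 100)
  sh2 <- shortenToLimit(m2, 14)
  expect_identical(sh2$motif$dotbracket, "(..((....))..)")

  # length <= limit is untouched
  sh3 <- shortenToLimit(m2, 50)
  expect_false(sh3$motif$trimmed)
  expect_identical(sh3$motif$dotbracket, m2$dotbracket)

  # helix exhausted before reaching the limit: typed rejection, no error
  m3 <- extractTerminalMotifs(list(mkStruct("((((....))))")), limit = 100)
  rej <- shortenToLimit(m3, 3)
  expect_identical(rej$status, "rejected")
  expect_match(rej$reason, "limit")
})

test_that("orchestrated extraction deduplicates and keeps stable order", {
  set.seed(4)
  hp <- mkStruct("(((...)))", id = "a")
  out <- extractTerminalMotifs(list(hp), limit = 100, minLen = 6)
  expect_equal(nrow(out), 1L)
  expect_identical(out$kind, "single_terminal")

  # duplicate input structures merge with combined provenance
  hp2 <- parseDotBracket("b", rnaSequence(hp), dotBracket(hp))
  out2 <- extractTerminalMotifs(list(hp, hp2), limit = 100)
  expect_equal(nrow(out2), 1L)
  expect_equal(length(strsplit(out2$provenance, ";")[[1]]), 2L)

  # min-length filter drops short motifs
  short <- mkStruct("((...))")  # 7 nt motif
  expect_equal(nrow(extractTerminalMotifs(list(short), minLen = 8)), 0L)
  expect_equal(nrow(extractTerminalMotifs(list(short), minLen = 6)), 1L)

  # determinism
  set.seed(99); strs <- replicate(10, randomStructure(), simplify = FALSE)
  o1 <- extractTerminalMotifs(strs)
  o2 <- extractTerminalMotifs(strs)
  expect_identical(o1, o2)
})

test_that("tree-walk extraction matches the brute-force oracle", {
  set.seed(5)
  nChecked <- 0L
  for (rep in seq_len(500L)) {
    s <- randomStructure()
    tree <- buildStructureTree(s)
    hp <- enumerateHairpins(tree)
    singles <- if (nrow(hp)) {
      do.call(rbind, lapply(seq_len(nrow(hp)), function(r) {
        extractSingleTerminal(tree, hp[r, , drop = FALSE])
      }))
    } else {
      NULL
    }
    got <- if (is.null(singles)) character(0) else {
      unique(sprintf("%d-%d", singles$start, singles$end))
    }
    want <- asIntervalKey(oracleSingleTerminalSet(s))
    expect_setequal(got, want)

    multis <- extractMultiTerminal(tree)
    gotM <- sprintf("%d-%d", multis$start, multis$end)
    wantM <- asIntervalKey(oracleMultiTerminalSet(s))
    expect_setequal(gotM, wantM)
    if (nrow(multis)) expect_true(all(multis$n_hairpins >= 2L))
    nChecked <- nChecked + 1L
  }
  expect_gte(nChecked, 500L)
})

test_that("trimmed motifs are blunt-ended, within limit and centered", {
  set.seed(6)
  for (rep in seq_len(200L)) {
    s <- randomStructure(n = sample(40:120, 1))
    out <- extractTerminalMotifs(list(s), limit = 30, minLen = 1)
    for (r in seq_len(nrow(out))) {
      db <- out$dotbracket[r]
      n <- nchar(db)
      expect_lte(n, 30L)
      pt <- pairTable(parseDotBracket("m", out$sequence[r], db))
      expect_identical(pt[1L], n)  # blunt paired end
      # contiguous sub-interval of the parent
      expect_identical(substr(dotBracket(s), out$start[r], out$end[r]), db)
    }
  }
})
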