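mkTable <- function(barcode_id, structure_ref, sample_id, intensity,
                    spot_id = paste0(barcode_id, "_s", seq_along(intensity))) {
  data.frame(spot_id = spot_id, barcode_id = barcode_id,
             structure_ref = structure_ref, sample_id = sample_id,
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("spot aggregation takes the per-barcode median", {
  tb <- mkTable(rep("b1", 3), "s1", "x", c(10, 12, 11))
  agg <- aggregateSpots(tb)
  expect_equal(agg$intensity, 11)
  expect_equal(agg$n_spots, 3L)

  one <- aggregateSpots(mkTable("b1", "s1", "x", 7))
  expect_equal(one$intensity, 7)
  expect_equal(one$n_spots, 1L)
})

test_that("binding intensity follows the 3-mean / 5-trimmed rules", {
  # 3 barcodes: plain mean of the differences
  smp <- mkTable(paste0("b", 1:3), "s1", "smp", c(10, 20, 30))
  ctl <- mkTable(paste0("b", 1:3), "s1", "ctl", c(1, 2, 3))
  expect_equal(computeBindingIntensity(smp, ctl)$intensity, 18)

  # 5 barcodes: drop max and min, mean the middle three
  smp5 <- mkTable(paste0("b", 1:5), "s1", "smp", c(1, 5, 6, 7, 100))
  ctl5 <- mkTable(paste0("b", 1:5), "s1", "ctl", rep(0, 5))
  prof5 <- computeBindingIntensity(smp5, ctl5)
  expect_equal(prof5$intensity, 6)
  expect_equal(prof5$n_barcodes, 5L)

  # 4 barcodes: generalized rule, drop one max and one min
  smp4 <- mkTable(paste0("b", 1:4), "s1", "smp", c(0, 4, 6, 100))
  ctl4 <- mkTable(paste0("b", 1:4), "s1", "ctl", rep(0, 4))
  expect_equal(computeBindingIntensity(smp4, ctl4)$intensity, 5)

  # control above sample: negative intensity retained
  neg <- computeBindingIntensity(
    mkTable(paste0("b", 1:3), "s1", "smp", c(1, 2, 3)),
    mkTable(paste0("b", 1:3), "s1", "ctl", c(10, 20, 30)))
  expect_equal(neg$intensity, -18)
})

test_that("trimmed aggregation equals the plain mean on equal differences", {
  smp <- mkTable(paste0("b", 1:5), "s1", "smp", rep(42, 5))
  ctl <- mkTable(paste0("b", 1:5), "s1", "ctl", rep(2, 5))
  expect_equal(computeBindingIntensity(smp, ctl)$intensity, 40)
})

test_that("binding intensity ignores row order and replication count", {
  set.seed(20)
  smp <- rbind(
    mkTable(rep("b1", 3), "s1", "smp", c(8, 10, 12)),
    mkTable(rep("b2", 5), "s1", "smp", c(18, 20, 22, 19, 21)),
    mkTable(rep("b3", 1), "s1", "smp", 30)
  )
  ctl <- mkTable(paste0("b", 1:3), "s1", "ctl", c(0, 0, 0),
                 spot_id = paste0("c", 1:3))
  base <- computeBindingIntensity(smp, ctl)
  shuffled <- smp[sample.int(nrow(smp)), ]
  expect_equal(computeBindingIntensity(shuffled, ctl), base)
  expect_equal(base$intensity, mean(c(10, 20, 30)))
})

test_that("missing barcodes are flagged, empty structures excluded", {
  smp <- mkTable(paste0("b", 1:2), c("s1", "s2"), "smp", c(10, 20))
  ctl <- mkTable(paste0("b", 1:2), c("s1", "s2"), "ctl", c(0, 0))
  bmap <- data.frame(barcode_id = paste0("b", 1:3),
                     structure_ref = c("s1", "s2", "s3"))
  prof <- computeBindingIntensity(smp, ctl, barcodeMap = bmap)
  expect_identical(prof$flag[prof$structure_ref == "s3"],
                   "no_usable_barcode")
  expect_true(is.na(prof$intensity[prof$structure_ref == "s3"]))
})

test_that("Z-scores standardize the profiled population", {
  p <- data.frame(structure_ref = c("a", "b"), intensity = c(0, 10),
                  n_barcodes = 3L, flag = "", stringsAsFactors = FALSE)
  z <- computeZScores(p)
  expect_equal(z$z_score, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(z$rank, c(2L, 1L))

  # zero SD is a named error
  flat <- data.frame(structure_ref = letters[1:3], intensity = 5,
                     n_barcodes = 3L, flag = "")
  expect_error(computeZScores(flat), class = "quantError")

  # population mean 0, sample SD 1 to 1e-9
  set.seed(21)
  big <- data.frame(structure_ref = sprintf("s%03d", 1:200),
                    intensity = rnorm(200, 50, 12), n_barcodes = 5L,
                    flag = "")
  zb <- computeZScores(big)
  expect_lt(abs(mean(zb$z_score)), 1e-9)
  expect_lt(abs(sd(zb$z_score) - 1), 1e-9)
  expect_setequal(zb$rank, 1:200)

  # sublibrary population: z computed against the named subset
  zs <- computeZScores(big, population = big$structure_ref[1:50])
  sub <- big$intensity[1:50]
  expect_equal(zs$z_score[1], (big$intensity[1] - mean(sub)) / sd(sub))
})

test_that("top-fraction selection uses the ceiling and stable ties", {
  p <- data.frame(structure_ref = sprintf("s%03d", 1:100),
                  intensity = c(rep(100, 3), seq(96, 0)), n_barcodes = 3L,
                  flag = "")
  expect_equal(length(selectTopFraction(p, 0.05)), 5L)
  p10 <- p[1:10, ]
  expect_equal(length(selectTopFraction(p10, 0.05)), 1L)
  # tie at the top broken by structure id order
  expect_identical(selectTopFraction(p10, 0.05), "s001")
  expect_equal(length(selectTopFraction(p, 1.0)), 100L)
  expect_error(selectTopFraction(p[0, ]), class = "quantError")
})

test_that("condition comparison classifies shared and specific binders", {
  mkprof <- function(i) {
    data.frame(structure_ref = sprintf("s%02d", seq_along(i)), intensity = i,
               n_barcodes = 3L, flag = "", stringsAsFactors = FALSE)
  }
  set.seed(22)
  base <- rnorm(50, 0, 1)
  a <- mkprof(c(base, 30, 40))   # s51 high in A only, s52 high in both
  b <- mkprof(c(base, 0, 40))
  cmp <- compareConditions(a, b, threshold = 2)
  expect_identical(cmp$class[cmp$structure_ref == "s51"], "A_specific")
  expect_identical(cmp$class[cmp$structure_ref == "s52"], "shared")
  expect_true(all(cmp$class[1:50] %in% c("neither", "shared")))

  # identical profiles: all deltas zero
  same <- compareConditions(a, a)
  expect_true(all(same$delta_intensity == 0))

  # structures missing on one side are flagged
  cmp2 <- compareConditions(mkprof(c(1, 2)), mkprof(c(1, 2, 50))[c(1, 3), ])
  expect_true("missing_in_B" %in% cmp2$flag || "missing_in_A" %in% cmp2$flag)
})
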