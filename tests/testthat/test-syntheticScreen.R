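test_that("generator layout: plates per bait/level/day/array, 670 TFs fit", {
  cfg <- simConfig()  # defaults: 670 TFs on two arrays, 26 baits, days 7+10
  maps <- y1hscreen:::buildArrayMaps(cfg@nTfs, cfg@nControlsEmpty,
                                     cfg@nControlsAd)
  expect_length(maps, 2L)
  occ <- unlist(lapply(maps, function(m) m$occupant[m$kind == "tf"]))
  expect_length(occ, 670L)
  expect_false(anyDuplicated(occ) > 0)
  kinds <- table(maps[[1]]$kind)
  expect_equal(unname(kinds[c("empty_no_tf", "ad_only", "tf")]),
               c(25L, 24L, 335L), ignore_attr = TRUE)

  scr <- generateScreen(smallConfig(), seed = 5)
  # 1 tested bait x 3 levels x 1 day x 1 array
  expect_length(plates(scr), 3L)
  pl <- plates(scr)[[1]]
  expect_equal(nrow(colonies(pl)), 1536L)
})

test_that("the same seed reproduces an identical screen", {
  cfg <- smallConfig()
  s1 <- generateScreen(cfg, seed = 17)
  s2 <- generateScreen(cfg, seed = 17)
  expect_identical(lapply(plates(s1), colonies),
                   lapply(plates(s2), colonies))
  s3 <- generateScreen(cfg, seed = 18)
  expect_false(identical(lapply(plates(s1), colonies),
                         lapply(plates(s3), colonies)))
})

test_that("with vanishing noise every quartet mean sits at mu0", {
  cfg <- simConfig(nTfs = 335, baits = defaultBaitTable()[1, , drop = FALSE],
                   days = 7L, sigma0 = 1e-9, quartetCorRatio = 0,
                   noncircularRate = 0, missingRate = 0)
  scr <- generateScreen(cfg, seed = 1)
  q <- assembleQuartets(plates(scr)[[1]], arrayMaps(scr)[[1]])
  vals <- rowMeans(as.matrix(q[, paste0("ln_area_", 1:4)]))
  # pixel areas are rounded to integers, so agreement is to rounding error
  expect_equal(vals, rep(log(round(exp(6.5))), 384), tolerance = 1e-6)
  expect_equal(unique(vals), 6.5, tolerance = 1e-3)
})

test_that("planted artifacts and controls appear at the configured places", {
  cfg <- smallConfig(noncircularRate = 0.05, missingRate = 0.05)
  scr <- generateScreen(cfg, seed = 9)
  tr <- groundTruth(scr)
  cc <- colonies(plates(scr)[[1]])
  art <- tr$artifacts[tr$artifacts$plate_id == plateId(plates(scr)[[1]]), ]
  nc <- art[art$type == "noncircular", ]
  expect_gt(nrow(nc), 0)
  key <- paste(cc$well_row, cc$well_col)
  expect_true(all(!cc$circular[key %in% paste(nc$well_row, nc$well_col)]))
  ms <- art[art$type == "missing", ]
  expect_true(all(!cc$present[key %in% paste(ms$well_row, ms$well_col)]))
  # rates are in the right ballpark (binomial over 1536 wells)
  expect_equal(nrow(ms) / 1536, 0.05, tolerance = 0.5)
})

test_that("a strongly planted interaction is recovered by the full pipeline", {
  # one pair, delta = 5 sigma0 at two 3AT levels: exactly that pair called
  plants <- plantTable("TF0042", levels = c(10L, 20L), delta = 5 * 0.4)
  scr <- generateScreen(smallConfig(interactions = plants), seed = 21)
  pp <- screenPipeline(scr)
  called <- pp$calls[pp$calls$called, ]
  expect_equal(nrow(called), 1L)
  expect_equal(called$tf_id, "TF0042")
  expect_equal(called$bait_id, "mel_A1")
  tm <- truthMetrics(pp$calls, groundTruth(scr))
  expect_equal(tm$recall, 1)
  expect_equal(tm$n_false_positive, 0L)
})

test_that("planting a TF absent from the array is a config error", {
  plants <- plantTable("TF9999")
  expect_error(generateScreen(smallConfig(interactions = plants), seed = 1),
               "not present in the array")
})

test_that("recall is non-decreasing in the planted effect size", {
  tfs <- sprintf("TF%04d", seq(10, 100, by = 10))
  recalls <- vapply(c(0, 1, 2, 3, 5), function(k) {
    plants <- plantTable(tfs, levels = c(10L, 20L), delta = k * 0.4)
    got <- numeric(3)
    for (s in 1:3) {
      scr <- generateScreen(smallConfig(interactions = plants),
                            seed = 400 + s)
      pp <- screenPipeline(scr)
      got[s] <- truthMetrics(pp$calls, groundTruth(scr))$recall
    }
    mean(got)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_lt(recalls[1], 0.1)   # delta = 0: essentially never called
  expect_gt(recalls[5], 0.95)  # delta = 5 sigma: essentially always
})

test_that("background quartet values look normal on edge-free plates", {
  scr <- generateScreen(smallConfig(), seed = 33)
  q <- qcQuartets(assembleQuartets(plates(scr)[[1]], arrayMaps(scr)[[1]]))
  v <- q$value[q$status == "ok"]
  expect_gt(length(v), 350)
  expect_lt(abs(sampleSkewness(v)), 0.5)
})

test_that("truth metrics handle the degenerate call sets", {
  truth <- list(interactions = data.frame(
    bait_id = "mel_A1", tf_id = c("TF0001", "TF0002"),
    level = 10L, delta = 2
  ))
  allCalled <- data.frame(bait_id = "mel_A1",
                          tf_id = c("TF0001", "TF0002"),
                          called = TRUE)
  tm <- truthMetrics(allCalled, truth)
  expect_equal(tm$recall, 1)
  expect_equal(tm$n_false_positive, 0L)
  none <- transform(allCalled, called = FALSE)
  expect_equal(truthMetrics(none, truth)$recall, 0)
  # a called pair never planted is a false positive
  extra <- rbind(allCalled,
                 data.frame(bait_id = "mel_A1", tf_id = "TF0099",
                            called = TRUE))
  expect_equal(truthMetrics(extra, truth)$n_false_positive, 1L)
})
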