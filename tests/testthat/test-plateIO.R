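test_that("Gitter tables parse sizes, flags and empty positions", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# plate p1, day 7",
    "row\tcol\tsize\tcircularity\tflags",
    "1\t1\t100\t0.95\t",
    "1\t2\t0\t0.00\t",
    "2\t1\t250\t0.40\tC"
  ), tf)
  rec <- readGitterTable(tf)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$pixel_area, c(100L, 0L, 250L))
  expect_equal(rec$present, c(TRUE, FALSE, TRUE))
  # noncircular flag screens the colony; size is retained
  expect_equal(rec$circular, c(TRUE, TRUE, FALSE))
})

test_that("dialect is configurable, including a circularity cutoff", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "r\tc\tarea\tcirc\tnote",
    "3\t4\t500\t0.30\t",
    "3\t5\t500\t0.90\t"
  ), tf)
  d <- gitterDialect(row = "r", col = "c", size = "area",
                     circularity = "circ", flags = "note",
                     circularityCutoff = 0.5)
  rec <- readGitterTable(tf, dialect = d)
  expect_equal(rec$circular, c(FALSE, TRUE))
  # unknown dialect column is a config error
  expect_error(readGitterTable(tf, gitterDialect(row = "nope")),
               "not found in header")
})

test_that("parse errors carry line numbers; duplicates and off-grid rejected", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("row\tcol\tsize\tcircularity\tflags",
               "1\t1\t100\t1.0\t",
               "1\tx\t100\t1.0\t"), tf)
  expect_error(readGitterTable(tf), "line 3")

  writeLines(c("row\tcol\tsize\tcircularity\tflags",
               "1\t1\t100\t1.0\t",
               "1\t1\t90\t1.0\t"), tf)
  expect_error(readGitterTable(tf), "duplicate position")

  writeLines(c("row\tcol\tsize\tcircularity\tflags",
               "33\t1\t100\t1.0\t"), tf)
  expect_error(readGitterTable(tf), "outside")
})

test_that("write/read round-trips record lists, including the empty one", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  rec <- uniformColonies(148L)
  rec$circular[5] <- FALSE
  rec$pixel_area[10] <- 0L
  rec$present[10] <- FALSE
  writeGitterTable(rec, tf)
  back <- readGitterTable(tf)
  ord <- order(rec$well_row, rec$well_col)
  expect_equal(back, `rownames<-`(rec[ord, ], NULL))

  writeGitterTable(rec[0, ], tf)
  expect_equal(nrow(readGitterTable(tf)), 0L)
  expect_equal(length(readLines(tf)), 1L)  # header only
})

test_that("quartet assembly collects ln-areas of present circular colonies", {
  rec <- uniformColonies(148L)
  pl <- y1hPlate(rec, "p1", "mel_A1", "mel", 10, 7, "arr1")
  q <- assembleQuartets(pl, tfArray384())
  expect_equal(nrow(q), 384L)
  expect_true(all(q$n_present_circular == 4L))
  expect_equal(unname(as.matrix(q[, paste0("ln_area_", 1:4)])[1, ]),
               rep(log(148), 4))

  # one absent well: (148, 148, 148, 0) -> three ln values of 4.997
  rec2 <- rec
  i <- which(rec2$well_row == 1 & rec2$well_col == 2)
  rec2$pixel_area[i] <- 0L
  rec2$present[i] <- FALSE
  # and one noncircular well in quartet (1, 2)
  j <- which(rec2$well_row == 1 & rec2$well_col == 3)
  rec2$circular[j] <- FALSE
  q2 <- assembleQuartets(y1hPlate(rec2, "p1", "mel_A1", "mel", 10, 7, "a"),
                         tfArray384())
  q11 <- q2[q2$qrow == 1 & q2$qcol == 1, ]
  expect_equal(q11$n_present_circular, 3L)
  expect_equal(unlist(q11[paste0("ln_area_", 1:3)], use.names = FALSE),
               rep(log(148), 3), tolerance = 1e-12)
  expect_equal(round(q11$ln_area_1, 3), 4.997)
  expect_true(is.na(q11$ln_area_4))
  q12 <- q2[q2$qrow == 1 & q2$qcol == 2, ]
  expect_equal(q12$n_present_circular, 3L)
})

test_that("missing wells are treated as no colony detected", {
  rec <- uniformColonies(100L)
  rec <- rec[-(1:4), ]  # drop some wells entirely
  pl <- y1hPlate(rec, "p1", "mel_A1", "mel", 10, 7, "a")
  q <- assembleQuartets(pl, tfArray384())
  expect_equal(nrow(q), 384L)
  expect_equal(sum(q$n_present_circular), 1536L - 4L)
})

test_that("quartet ownership partitions the 32x48 well grid", {
  # each well maps to exactly one quartet under the ceil-halving rule
  wr <- rep(1:32, times = 48)
  wc <- rep(1:48, each = 32)
  qkey <- paste(ceiling(wr / 2), ceiling(wc / 2))
  expect_equal(length(unique(qkey)), 384L)
  expect_true(all(table(qkey) == 4L))

  # and assembleQuartets sees each colony exactly once: total detected count
  rec <- uniformColonies(100L)
  q <- assembleQuartets(y1hPlate(rec, "p", "mel_A1", "mel", 0, 3, "a"),
                        tfArray384())
  expect_equal(sum(q$n_present_circular), 1536L)
})

test_that("well masks force positions to absent", {
  rec <- uniformColonies(100L)
  masked <- applyWellMask(rec, data.frame(well_row = 1:2, well_col = c(1L, 1L)))
  hit <- masked$well_row <= 2 & masked$well_col == 1
  expect_true(all(!masked$present[hit]))
  expect_true(all(masked$pixel_area[hit] == 0L))
  expect_equal(sum(masked$present), 1536L - 2L)
})

test_that("plate validity catches bad metadata and colony frames", {
  rec <- uniformColonies(10L)
  expect_error(y1hPlate(rec, "p", "b", "mel", 15, 7, "a"), "selection3AT")
  expect_error(y1hPlate(rec, "p", "b", "hsap", 10, 7, "a"), "species")
  expect_error(y1hPlate(rec, "p", "b", "mel", 10, 3, "a"), "day-3")
  bad <- rec
  bad$present[1] <- FALSE  # present = FALSE with nonzero area
  expect_error(y1hPlate(bad, "p", "b", "mel", 10, 7, "a"), "pixel_area 0")
})
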