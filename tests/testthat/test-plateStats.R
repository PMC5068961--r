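test_that("Grubbs screen removes a clear outlier at the published critical value", {
  x <- c(rep(1, 9), 5)
  n <- 10
  tq <- qt(1 - 0.05 / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  G <- max(abs(x - mean(x))) / sd(x)
  expect_equal(G, 2.846, tolerance = 5e-4)
  expect_equal(crit, 2.290, tolerance = 5e-4)
  res <- grubbsScreen(x, alpha = 0.05)
  expect_equal(res$outliers, 10L)
  expect_equal(res$kept, rep(1, 9))
})

test_that("Grubbs screen leaves constant and unremarkable data alone", {
  expect_equal(grubbsScreen(c(3, 3, 3, 3, 3))$outliers, integer(0))
  # bounded symmetric draws never reach the critical value at n = 100
  for (s in 1:40) {
    set.seed(s)
    u <- runif(100, pnorm(-1.9), pnorm(1.9))
    expect_equal(grubbsScreen(qnorm(u))$outliers, integer(0))
  }
  expect_error(grubbsScreen(c(1, 2)), "at least 3")
})

test_that("Grubbs screen agrees with the brute-force oracle on random vectors", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(3:20, 1)
    x <- rnorm(n, sd = sample(c(0.1, 1, 10), 1))
    if (runif(1) < 0.3) x[sample(n, 1)] <- x[1] + sample(c(-1, 1), 1) * runif(1, 3, 20)
    res <- grubbsScreen(x)
    ora <- grubbsOracle(x)
    expect_identical(res$outliers, ora$outliers)
    expect_identical(res$keptIdx, ora$keptIdx)
  }
})

test_that("edge correction detects and removes a constructed edge shift", {
  set.seed(1)
  vals <- rnorm(384, 3, 0.01)
  q <- qcGrid(vals)
  isEdge <- q$qrow %in% c(1, 2, 15, 16) | q$qcol %in% c(1, 2, 23, 24)
  expect_equal(sum(isEdge), 144L)     # 144 edge vs 240 interior quartets
  q$value[isEdge] <- q$value[isEdge] + 1
  ec <- edgeCorrection(q)
  expect_true(ec$detected)
  expect_equal(ec$shift, mean(q$value[isEdge]) - mean(q$value[!isEdge]))
  expect_equal(mean(ec$values[isEdge]), 3, tolerance = 0.01)
  # re-test after correction: stratum means equalized, t = 0
  reT <- t.test(ec$values[isEdge], ec$values[!isEdge])
  expect_gt(reT$p.value, 0.95)
})

test_that("edge correction holds its nominal type-I error on null plates", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    ec <- edgeCorrection(qcGrid(rnorm(384, 6.5, 0.3)))
    hits <- hits + ec$detected
  }
  # nominal 5%; allow 3 binomial SDs
  expect_lte(hits, 5 + 3 * sqrt(100 * 0.05 * 0.95))
  # and an undetected plate is left untouched
  set.seed(1001)
  q <- qcGrid(rnorm(384, 6.5, 0.3))
  ec <- edgeCorrection(q)
  if (!ec$detected) expect_equal(ec$values, q$value)
})

test_that("edge correction is skipped with a warning on starved strata", {
  q <- qcGrid(rnorm(384, 5, 0.1))
  q$status[q$qrow %in% c(1, 2, 15, 16) | q$qcol %in% c(1, 2, 23, 24)] <-
    "excluded_low_area"
  q$status[which(q$status == "ok")[-1]] <- "excluded_low_area"
  expect_warning(ec <- edgeCorrection(q), "skipped")
  expect_false(ec$detected)
})

test_that("plate scoring yields calibrated Z-scores and one-sided p-values", {
  set.seed(3)
  q <- qcGrid(rnorm(384, 3, 0.1))
  res <- scorePlate(q)
  expect_true(res$stats$scorable)
  surv <- res$scored$status == "ok" & !res$scored$is_outlier
  expect_equal(mean(res$scored$z[surv]), 0, tolerance = 1e-9)
  expect_equal(sd(res$scored$z[surv]), 1, tolerance = 1e-9)
  # z -> p is the standard normal upper tail: z = 3 gives p = 0.00135
  z3 <- (res$stats$background_mean + 3 * res$stats$background_sd -
           res$stats$background_mean) / res$stats$background_sd
  expect_equal(pnorm(z3, lower.tail = FALSE), 0.00135, tolerance = 1e-3)
  # p is strictly decreasing in z and p(0) = 0.5
  ordz <- order(res$scored$z[surv])
  expect_true(all(diff(res$scored$p[surv][ordz]) < 0))
  iMid <- which.min(abs(res$scored$z))
  expect_equal(res$scored$p[iMid], pnorm(res$scored$z[iMid], lower.tail = FALSE))
})

test_that("Grubbs-removed quartets still receive scores from survivor stats", {
  set.seed(4)
  vals <- rnorm(384, 3, 0.1)
  vals[50] <- 3 + 10 * 0.1  # a strong hit: removed as outlier, scored anyway
  res <- scorePlate(qcGrid(vals))
  expect_gte(res$stats$n_outliers_removed, 1L)
  expect_true(res$scored$is_outlier[50])
  expect_equal(res$scored$z[50],
               (vals[50] - res$stats$background_mean) /
                 res$stats$background_sd)
  expect_lt(res$scored$p[50], 0.005)
  # excluded quartets carry no score
  q <- qcGrid(vals)
  q$status[1] <- "excluded_dispersion"
  res2 <- scorePlate(q)
  expect_true(is.na(res2$scored$z[1]))
  expect_true(is.na(res2$scored$p[1]))
})

test_that("degenerate plates are marked unscorable", {
  q <- qcGrid(rep(3, 384))
  expect_warning(res <- scorePlate(q), "unscorable")
  expect_false(res$stats$scorable)
  expect_true(all(is.na(res$scored$z)))

  few <- qcGrid(rnorm(384, 3, 0.1), status = "excluded_low_area")
  few$status[1:2] <- "ok"
  expect_warning(res2 <- scorePlate(few), "unscorable")
  expect_false(res2$stats$scorable)
})
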