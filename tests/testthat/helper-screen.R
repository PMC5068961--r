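# Shared fixtures and independent oracles, built in code.

# Full-grid colony record frame with constant area.
uniformColonies <- function(area = 148L) {
  rec <- expand.grid(well_row = 1:32, well_col = 1:48,
                     KEEP.OUT.ATTRS = FALSE)
  rec$pixel_area <- as.integer(area)
  rec$circular <- TRUE
  rec$present <- area > 0L
  rec
}

tfArray384 <- function() {
  arrayMap(sprintf("TF%03d", 1:384), rep("tf", 384))
}

# A QC-level quartet frame over the 16x24 grid with given values.
qcGrid <- function(values, plate_id = "p1", status = "ok") {
  data.frame(
    plate_id = plate_id, bait_id = "mel_A1",
    occupant = sprintf("TF%03d", 1:384),
    kind = "tf",
    qrow = rep(1:16, each = 24), qcol = rep(1:24, times = 16),
    value = values, status = status
  )
}

# Independent iterative Grubbs oracle: explicit sums, recompute after each
# removal, first-index tie break.
grubbsOracle <- function(x, alpha = 0.05) {
  idx <- seq_along(x)
  removed <- integer(0)
  repeat {
    v <- x[idx]
    n <- length(v)
    if (n < 3L) break
    mu <- sum(v) / n
    s <- sqrt(sum((v - mu)^2) / (n - 1))
    if (s == 0) break
    dev <- abs(v - mu)
    G <- max(dev) / s
    tq <- qt(1 - alpha / (2 * n), df = n - 2)
    crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G <= crit) break
    drop <- which(dev == max(dev))[1]
    removed <- c(removed, idx[drop])
    idx <- idx[-drop]
  }
  list(keptIdx = idx, outliers = sort(removed))
}

sampleSkewness <- function(x) {
  m <- mean(x)
  s <- sd(x)
  mean(((x - m) / s)^3)
}

# Small synthetic-screen config: one 335-TF array, one mel bait (3 levels),
# day 7, generator defaults otherwise.
smallConfig <- function(nBaits = 1, interactions = NULL, ...) {
  args <- list(nTfs = 335L, baits = defaultBaitTable()[seq_len(nBaits), ,
                                                       drop = FALSE],
               days = 7L, ...)
  if (!is.null(interactions)) args$interactions <- interactions
  do.call(simConfig, args)
}

plantTable <- function(tfs, bait = "mel_A1", levels = c(10L, 20L),
                       delta = 2) {
  expand.grid(tf_id = tfs, level = levels, stringsAsFactors = FALSE) |>
    transform(bait_id = bait, delta = delta)
}
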