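#' @include AllClasses.R
NULL

#' Iterative two-sided Grubbs outlier screen
#'
#' Repeatedly removes the single most extreme value while the Grubbs
#' statistic G = max |x_i - mean| / sd exceeds the two-sided critical value
#' ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)), where t is the upper
#' alpha / (2n) quantile of Student's t on n - 2 degrees of freedom. The
#' screen stops when no value exceeds the critical value, when fewer than 3
#' values remain, or when the remaining values have zero spread.
#'
#' @param values numeric vector, length >= 3, no NAs.
#' @param alpha numeric(1) significance level of each removal step
#'   (default 0.05).
#' @return list with \code{kept} (surviving values), \code{keptIdx}
#'   (their indices in \code{values}) and \code{outliers} (sorted indices of
#'   removed values).
#' @examples
#' grubbsScreen(c(rep(1, 9), 5))$outliers  # the value 5 is removed
#' @export
grubbsScreen <- function(values, alpha = 0.05) {
  if (length(values) < 3L) {
    stop("Grubbs screening needs at least 3 values")
  }
  if (anyNA(values)) stop("'values' must not contain NAs")
  stopifnot(alpha > 0, alpha < 1)
  keep <- seq_along(values)
  removed <- integer(0)
  repeat {
    x <- values[keep]
    n <- length(x)
    if (n < 3L) break
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    tq <- stats::qt(1 - alpha / (2 * n), df = n - 2L)
    crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2L + tq^2))
    if (G > crit) {
      removed <- c(removed, keep[i])
      keep <- keep[-i]
    } else {
      break
    }
  }
  list(kept = values[keep], keptIdx = keep, outliers = sort(removed))
}

edgeQuartetMask <- function(qrow, qcol,
                            edgeRows = c(1L, 2L, QUARTET_ROWS - 1L, QUARTET_ROWS),
                            edgeCols = c(1L, 2L, QUARTET_COLS - 1L, QUARTET_COLS)) {
  qrow %in% edgeRows | qcol %in% edgeCols
}

#' Detect and remove a plate edge effect
#'
#' Colonies near the plate border often grow systematically differently
#' (more medium, less competition). The outermost two quartet rows and
#' columns (144 of the 384 quartet positions) are compared against the
#' interior 240 with a two-sample t-test on the QC-passing quartet values.
#' If the difference is significant at \code{alpha}, every edge quartet's
#' value is shifted by -(mean(edge) - mean(interior)), equalising the
#' stratum means; the shift is applied whichever direction the difference
#' runs (the typical, and the motivating, case is edge growth above
#' interior).
#'
#' @param quartets data.frame from [qcQuartets()] (needs \code{qrow},
#'   \code{qcol}, \code{value}, \code{status}).
#' @param alpha numeric(1) t-test significance level (default 0.05).
#' @param welch logical(1); Welch unequal-variance t-test (default) or
#'   pooled-variance.
#' @return list with \code{values} (corrected value per input row; NA for
#'   non-ok quartets), \code{detected}, \code{shift} (mean(edge) -
#'   mean(interior) when detected, else 0), \code{p} (t-test p-value) and
#'   \code{is_edge} (logical per input row).
#' @export
edgeCorrection <- function(quartets, alpha = 0.05, welch = TRUE) {
  isEdge <- edgeQuartetMask(quartets$qrow, quartets$qcol)
  ok <- quartets$status == "ok"
  vals <- ifelse(ok, quartets$value, NA_real_)
  e <- vals[ok & isEdge]
  i <- vals[ok & !isEdge]
  if (length(e) < 2L || length(i) < 2L) {
    warning("fewer than 2 QC-passing quartets in an edge stratum; ",
            "edge correction skipped")
    return(list(values = vals, detected = FALSE, shift = 0,
                p = NA_real_, is_edge = isEdge))
  }
  pEdge <- tryCatch(
    stats::t.test(e, i, var.equal = !welch)$p.value,
    error = function(err) NA_real_   # e.g. both strata essentially constant
  )
  tt <- list(p.value = pEdge)
  detected <- is.finite(tt$p.value) && tt$p.value < alpha
  shift <- if (detected) mean(e) - mean(i) else 0
  if (detected) vals[isEdge] <- vals[isEdge] - shift
  list(values = vals, detected = detected, shift = shift,
       p = tt$p.value, is_edge = isEdge)
}

#' Score one plate: background distribution and per-quartet Z-scores
#'
#' Builds the plate's background distribution and assigns a Z-score and
#' one-sided p-value to every QC-passing quartet. The pipeline order is:
#' edge correction of the QC-passing quartet values, then iterative Grubbs
#' outlier screening of the corrected values, then background mean and
#' sample SD from the Grubbs survivors. Z-scores are computed for every
#' QC-passing quartet — including the Grubbs-removed outliers, which is how
#' strong interactions surface — as z = (corrected value - background mean)
#' / background SD, and p = P(Z >= z) under the standard normal.
#' QC-excluded quartets carry NA scores. Control quartets (empty wells,
#' AD-only) contribute to the background but are flagged by their
#' \code{kind} so interaction calling can skip them.
#'
#' A plate with fewer than 3 QC-passing quartets, or with zero background
#' spread, is marked unscorable.
#'
#' @param quartets data.frame from [qcQuartets()] for a single plate.
#' @param alphaOutlier Grubbs removal level (default 0.05).
#' @param alphaEdge edge t-test level (default 0.05).
#' @param welch passed to [edgeCorrection()].
#' @return list with \code{stats} (one-row data.frame: plate_id, scorable,
#'   edge_effect_detected, edge_shift, edge_p, background_mean,
#'   background_sd, n_ok, n_outliers_removed, outlier_alpha, edge_alpha)
#'   and \code{scored} (the input data.frame with \code{corrected_value},
#'   \code{z}, \code{p}, \code{is_outlier}, \code{is_edge} columns).
#' @examples
#' set.seed(1)
#' q <- data.frame(qrow = rep(1:16, each = 24), qcol = rep(1:24, 16),
#'                 plate_id = "p", value = rnorm(384, 6.5, 0.3),
#'                 status = "ok")
#' sp <- scorePlate(q)
#' sp$stats$background_sd
#' @export
scorePlate <- function(quartets, alphaOutlier = 0.05, alphaEdge = 0.05,
                       welch = TRUE) {
  pid <- if ("plate_id" %in% names(quartets)) quartets$plate_id[1] else NA
  scored <- quartets
  scored$corrected_value <- NA_real_
  scored$z <- NA_real_
  scored$p <- NA_real_
  scored$is_outlier <- FALSE
  scored$is_edge <- edgeQuartetMask(quartets$qrow, quartets$qcol)
  unscorable <- function(edge = NULL) {
    list(
      stats = data.frame(
        plate_id = pid, scorable = FALSE,
        edge_effect_detected = if (is.null(edge)) FALSE else edge$detected,
        edge_shift = if (is.null(edge)) 0 else edge$shift,
        edge_p = if (is.null(edge)) NA_real_ else edge$p,
        background_mean = NA_real_, background_sd = NA_real_,
        n_ok = sum(quartets$status == "ok"), n_outliers_removed = NA_integer_,
        outlier_alpha = alphaOutlier, edge_alpha = alphaEdge
      ),
      scored = scored
    )
  }
  ok <- quartets$status == "ok"
  if (sum(ok) < 3L) {
    warning(sprintf("plate %s: fewer than 3 QC-passing quartets; unscorable", pid))
    return(unscorable())
  }
  edge <- edgeCorrection(quartets, alpha = alphaEdge, welch = welch)
  corrected <- edge$values
  g <- grubbsScreen(corrected[ok], alpha = alphaOutlier)
  bgMean <- mean(g$kept)
  bgSd <- stats::sd(g$kept)
  if (!is.finite(bgSd) || bgSd == 0) {
    warning(sprintf("plate %s: degenerate background spread; unscorable", pid))
    return(unscorable(edge))
  }
  scored$corrected_value <- corrected
  scored$z[ok] <- (corrected[ok] - bgMean) / bgSd
  scored$p[ok] <- stats::pnorm(scored$z[ok], lower.tail = FALSE)
  outRows <- which(ok)[g$outliers]
  scored$is_outlier[outRows] <- TRUE
  list(
    stats = data.frame(
      plate_id = pid, scorable = TRUE,
      edge_effect_detected = edge$detected, edge_shift = edge$shift,
      edge_p = edge$p, background_mean = bgMean, background_sd = bgSd,
      n_ok = sum(ok), n_outliers_removed = length(g$outliers),
      outlier_alpha = alphaOutlier, edge_alpha = alphaEdge
    ),
    scored = scored
  )
}

#' Score every plate of a screen
#'
#' Runs quartet assembly, QC and [scorePlate()] over all plates of a
#' [Y1HScreen-class]. Plates flagged excluded are carried through with NA
#' scores so downstream calling can report their pairs as untested rather
#' than negative.
#'
#' @param screen a [Y1HScreen-class].
#' @param meanCutoff,dispersionCutoff passed to [qcQuartets()].
#' @param alphaOutlier,alphaEdge,welch passed to [scorePlate()].
#' @return list with \code{scored} (row-bound scored-quartet data.frame
#'   across plates, with plate metadata columns \code{selection_3at_mM},
#'   \code{day}, \code{plate_excluded}) and \code{plateStats} (one row per
#'   scorable-attempted plate).
#' @export
scoreScreen <- function(screen, meanCutoff = 2, dispersionCutoff = 0.2,
                        alphaOutlier = 0.05, alphaEdge = 0.05, welch = TRUE) {
  maps <- arrayMaps(screen)
  scoredList <- vector("list", length(plates(screen)))
  statsList <- vector("list", length(plates(screen)))
  for (k in seq_along(plates(screen))) {
    pl <- plates(screen)[[k]]
    q <- assembleQuartets(pl, maps[[tfArrayId(pl)]])
    q <- qcQuartets(q, meanCutoff = meanCutoff,
                    dispersionCutoff = dispersionCutoff)
    if (isExcluded(pl)) {
      sc <- q
      sc$corrected_value <- NA_real_
      sc$z <- NA_real_
      sc$p <- NA_real_
      sc$is_outlier <- FALSE
      sc$is_edge <- edgeQuartetMask(q$qrow, q$qcol)
      st <- data.frame(
        plate_id = plateId(pl), scorable = FALSE,
        edge_effect_detected = FALSE, edge_shift = 0, edge_p = NA_real_,
        background_mean = NA_real_, background_sd = NA_real_,
        n_ok = sum(q$status == "ok"), n_outliers_removed = NA_integer_,
        outlier_alpha = alphaOutlier, edge_alpha = alphaEdge
      )
    } else {
      res <- scorePlate(q, alphaOutlier = alphaOutlier,
                        alphaEdge = alphaEdge, welch = welch)
      sc <- res$scored
      st <- res$stats
    }
    sc$selection_3at_mM <- selection3AT(pl)
    sc$day <- imagingDay(pl)
    sc$plate_excluded <- isExcluded(pl)
    sc$plate_scorable <- st$scorable
    scoredList[[k]] <- sc
    statsList[[k]] <- st
  }
  list(
    scored = do.call(rbind, scoredList),
    plateStats = do.call(rbind, statsList)
  )
}
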