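#' @include AllClasses.R
NULL

#' Collect per-(bait, TF, 3AT level, day) interaction records
#'
#' Converts scored quartets into one interaction record per TF quartet per
#' plate. Control occupants (empty wells, AD-only) never produce records:
#' they are a QC channel, not candidate interactions. A record is
#' \code{tested} when its plate was scorable and not excluded and the
#' quartet passed QC; \code{significant} requires \code{tested} and a
#' one-sided p-value strictly below \code{threshold}.
#'
#' @param scored scored-quartet data.frame from [scoreScreen()] (or a
#'   row-bound set of [scorePlate()] outputs carrying
#'   \code{selection_3at_mM}, \code{day}, \code{plate_excluded},
#'   \code{plate_scorable} columns).
#' @param threshold numeric(1) p-value significance threshold
#'   (default 0.005).
#' @return data.frame with columns \code{bait_id}, \code{tf_id},
#'   \code{selection_3at_mM}, \code{day}, \code{z}, \code{p},
#'   \code{tested}, \code{significant}.
#' @export
collectRecords <- function(scored, threshold = 0.005) {
  stopifnot(threshold > 0, threshold < 1)
  need <- c("bait_id", "occupant", "kind", "status", "p", "z",
            "selection_3at_mM", "day", "plate_excluded", "plate_scorable")
  miss <- setdiff(need, names(scored))
  if (length(miss)) {
    stop("scored table lacks columns: ", paste(miss, collapse = ", "))
  }
  tf <- scored[scored$kind == "tf", , drop = FALSE]
  tested <- !tf$plate_excluded & tf$plate_scorable & tf$status == "ok"
  data.frame(
    bait_id = tf$bait_id,
    tf_id = tf$occupant,
    selection_3at_mM = tf$selection_3at_mM,
    day = tf$day,
    z = ifelse(tested, tf$z, NA_real_),
    p = ifelse(tested, tf$p, NA_real_),
    tested = tested,
    significant = tested & !is.na(tf$p) & tf$p < threshold,
    row.names = NULL
  )
}

#' Consensus interaction calls across 3AT levels
#'
#' A bait-TF interaction is called when the pair is significant at
#' \code{minLevels} or more distinct 3AT concentrations on the calling day.
#' Growth at multiple selection stringencies is a semi-independent
#' confirmation: the same transformant must re-activate the reporter in a
#' more demanding medium, which suppresses one-off technical false
#' positives.
#'
#' @param records data.frame from [collectRecords()].
#' @param day integer(1) calling day (default 7).
#' @param minLevels integer(1) minimum number of significant 3AT levels
#'   (default 2).
#' @return data.frame with one row per tested (bait, TF) pair:
#'   \code{bait_id}, \code{tf_id}, \code{n_levels_tested},
#'   \code{n_levels_significant}, \code{levels} (comma-separated significant
#'   mM values), \code{called}.
#' @export
consensusCall <- function(records, day = 7, minLevels = 2) {
  rec <- records[records$day == day, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("no records at day %d", day))
  idx <- split(seq_len(nrow(rec)),
               paste(rec$bait_id, rec$tf_id, sep = "\r"))
  nTested <- vapply(idx, function(i) {
    length(unique(rec$selection_3at_mM[i][rec$tested[i]]))
  }, integer(1))
  sigLv <- lapply(idx, function(i) {
    sort(unique(rec$selection_3at_mM[i][rec$significant[i]]))
  })
  ids <- strsplit(names(idx), "\r", fixed = TRUE)
  out <- data.frame(
    bait_id = vapply(ids, `[`, character(1), 1L),
    tf_id = vapply(ids, `[`, character(1), 2L),
    n_levels_tested = nTested,
    n_levels_significant = lengths(sigLv),
    levels = vapply(sigLv, paste, character(1), collapse = ","),
    row.names = NULL
  )
  out$called <- out$n_levels_significant >= minLevels
  out[order(out$bait_id, out$tf_id), , drop = FALSE]
}

#' Threshold-sensitivity curves of the hit count
#'
#' Recomputes, over a grid of p-value thresholds, the number of distinct TFs
#' with a qualifying interaction on at least one bait fragment — the
#' screen-level hit count — for each imaging day and each minimum number of
#' significant 3AT levels (the pooled condition), and additionally per
#' single 3AT level (significance at that level alone). These curves show
#' how the hit count decays with statistical stringency and how much the
#' multi-level consensus requirement tightens the screen.
#'
#' @param records data.frame from [collectRecords()]; its \code{p} column is
#'   re-thresholded, so pass records built with any threshold.
#' @param pGrid numeric vector of p-value thresholds.
#' @param days integer vector of days to evaluate (default the days
#'   present).
#' @param minLevels integer vector of consensus requirements for the pooled
#'   condition (default 1:3).
#' @param perLevel logical(1); also emit per-3AT-level curves (default
#'   TRUE).
#' @return data.frame with columns \code{neg_log10_p}, \code{p_threshold},
#'   \code{condition} (\code{"pooled"} or \code{"<mM> mM"}), \code{day},
#'   \code{min_levels}, \code{n_tfs_with_hit}.
#' @export
sensitivityCurve <- function(records, pGrid, days = NULL, minLevels = 1:3,
                             perLevel = TRUE) {
  if (!length(pGrid)) stop("empty threshold grid")
  stopifnot(all(pGrid > 0), all(pGrid < 1))
  if (is.null(days)) days <- sort(unique(records$day))
  pGrid <- sort(unique(pGrid), decreasing = TRUE)
  out <- list()
  for (d in days) {
    rec <- records[records$day == d & records$tested, , drop = FALSE]
    if (!nrow(rec)) stop(sprintf("no tested records at day %d", d))
    pairKey <- paste(rec$bait_id, rec$tf_id)
    for (thr in pGrid) {
      sig <- !is.na(rec$p) & rec$p < thr
      ## distinct significant levels per (bait, tf) pair
      if (any(sig)) {
        nlev <- vapply(split(rec$selection_3at_mM[sig], pairKey[sig]),
                       function(v) length(unique(v)), integer(1))
      } else {
        nlev <- stats::setNames(integer(0), character(0))
      }
      tfOfPair <- rec$tf_id[match(names(nlev), pairKey)]
      for (ml in minLevels) {
        out[[length(out) + 1L]] <- data.frame(
          neg_log10_p = -log10(thr), p_threshold = thr,
          condition = "pooled", day = d, min_levels = ml,
          n_tfs_with_hit = length(unique(tfOfPair[nlev >= ml]))
        )
      }
      if (perLevel) {
        for (lv in sort(unique(rec$selection_3at_mM))) {
          atLv <- sig & rec$selection_3at_mM == lv
          out[[length(out) + 1L]] <- data.frame(
            neg_log10_p = -log10(thr), p_threshold = thr,
            condition = sprintf("%d mM", lv), day = d, min_levels = 1L,
            n_tfs_with_hit = length(unique(rec$tf_id[atLv]))
          )
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Plot threshold-sensitivity curves
#'
#' Hit count versus -log10(p) threshold, coloured by condition, faceted by
#' day, with line type distinguishing the consensus requirement. Requires
#' ggplot2.
#'
#' @param curve data.frame from [sensitivityCurve()].
#' @return a ggplot object.
#' @export
plotSensitivity <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotSensitivity requires the ggplot2 package")
  }
  curve$min_levels <- factor(curve$min_levels)
  ggplot2::ggplot(
    curve,
    ggplot2::aes(x = neg_log10_p, y = n_tfs_with_hit,
                 colour = condition, linetype = min_levels)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~day, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(-log[10](italic(p))~threshold),
                  y = "TFs with ≥ 1 significant fragment",
                  colour = "3AT condition", linetype = "min levels") +
    ggplot2::theme_bw()
}
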