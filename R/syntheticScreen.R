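#' @include AllClasses.R
NULL

#' Default bait metadata table
#'
#' The screen design tests 26 enhancer-fragment baits: 8 from
#' *D. melanogaster*, 9 from *D. pseudoobscura* and 9 from *D. willistoni*,
#' each selected at three 3AT concentrations chosen per bait by a wet-lab
#' self-activation pre-screen (an input here, not a computation). Three
#' further fragments that could not be integrated into the yeast genome are
#' carried as excluded rows with a reason, so that reports can distinguish
#' "never screened" from "screened, no hit". Bait identifiers other than the
#' four the design names explicitly (pse_B8, pse_B9, will_C8, will_C11) are
#' synthetic placeholders.
#'
#' @return data.frame with columns \code{bait_id}, \code{species},
#'   \code{levels} (comma-separated 3AT mM), \code{excluded}, \code{reason}.
#' @export
defaultBaitTable <- function() {
  mk <- function(ids, sp) {
    data.frame(bait_id = ids, species = sp, levels = "10,20,40",
               excluded = FALSE, reason = "")
  }
  b <- rbind(
    mk(sprintf("mel_A%d", 1:8), "mel"),
    mk(sprintf("pse_B%d", 1:10), "pse"),
    mk(sprintf("will_C%d", 1:11), "will")
  )
  never <- b$bait_id %in% c("pse_B8", "will_C8", "will_C11")
  b$excluded[never] <- TRUE
  b$reason[never] <- "bait could not be integrated into the yeast genome"
  b
}

parseLevels <- function(levels) {
  lapply(strsplit(as.character(levels), ","), function(v) as.integer(trimws(v)))
}

#' Build the synthetic-screen configuration
#'
#' Defaults reproduce the screen architecture the pipeline is designed for:
#' a 670-TF arrayed collection spread over two 384-position source arrays
#' (with fixed empty-well and AD-only control positions), 26 tested baits
#' with three 3AT selection levels each, and imaging at days 7 and 10.
#' Colony growth is modelled on the natural-log scale: a well's ln-area is
#' normal with mean mu0, plus the planted interaction shift where one
#' applies, plus the edge shift on edge-affected plates, with a shared
#' quartet-level offset (fraction \code{quartetCorRatio} of the total SD)
#' making replicate spots of one transformant correlate.
#'
#' @param nTfs number of TFs in the collection (default 670).
#' @param baits bait table as from [defaultBaitTable()].
#' @param days imaging days, subset of c(7, 10).
#' @param mu0,sigma0 background ln-area mean and total SD (defaults 6.5 and
#'   0.4: a typical colony of ~660 pixels with ~40\% multiplicative spread).
#' @param quartetCorRatio fraction of sigma0 assigned to the shared
#'   quartet-level offset (default 0.5).
#' @param edgeDelta additive ln-area shift on edge quartets of edge-affected
#'   plates (default 0).
#' @param edgePlateFraction fraction of plates receiving the edge shift
#'   (default 0).
#' @param interactions planted-interaction data.frame (\code{bait_id},
#'   \code{tf_id}, \code{level}, \code{delta}); empty by default.
#' @param noncircularRate,missingRate per-well artifact probabilities
#'   (default 0.01 each).
#' @param nControlsEmpty,nControlsAd control positions per array (default
#'   25 and 24, leaving 335 TF positions per array so two arrays carry 670
#'   TFs).
#' @return a [SimConfig-class] object.
#' @seealso [generateScreen()]
#' @export
simConfig <- function(nTfs = 670L, baits = defaultBaitTable(),
                      days = c(7L, 10L), mu0 = 6.5, sigma0 = 0.4,
                      quartetCorRatio = 0.5, edgeDelta = 0,
                      edgePlateFraction = 0,
                      interactions = data.frame(
                        bait_id = character(0), tf_id = character(0),
                        level = integer(0), delta = numeric(0)
                      ),
                      noncircularRate = 0.01, missingRate = 0.01,
                      nControlsEmpty = 25L, nControlsAd = 24L) {
  new("SimConfig",
      nTfs = as.integer(nTfs), baits = baits, days = as.integer(days),
      mu0 = mu0, sigma0 = sigma0, quartetCorRatio = quartetCorRatio,
      edgeDelta = edgeDelta, edgePlateFraction = edgePlateFraction,
      interactions = interactions,
      noncircularRate = noncircularRate, missingRate = missingRate,
      nControlsEmpty = as.integer(nControlsEmpty),
      nControlsAd = as.integer(nControlsAd))
}

## Deterministic control-position layout: controls are spread evenly over the
## 384 quartet positions, alternating empty-well and AD-only, mimicking the
## fixed scattered control positions of an arrayed collection.
buildArrayMaps <- function(nTfs, nEmpty, nAd) {
  nq <- QUARTET_ROWS * QUARTET_COLS
  perArray <- nq - nEmpty - nAd
  nArrays <- max(1L, as.integer(ceiling(nTfs / perArray)))
  tfIds <- sprintf("TF%04d", seq_len(nTfs))
  maps <- vector("list", nArrays)
  names(maps) <- sprintf("array%d", seq_len(nArrays))
  nCtrl <- nEmpty + nAd
  ctrlPos <- if (nCtrl > 0) {
    unique(round(seq(1, nq, length.out = nCtrl)))
  } else integer(0)
  ## rounding collisions would silently drop controls; nudge onto free slots
  while (length(ctrlPos) < nCtrl) {
    free <- setdiff(seq_len(nq), ctrlPos)
    ctrlPos <- sort(c(ctrlPos, free[1]))
  }
  ctrlKind <- c(rep("empty_no_tf", nEmpty), rep("ad_only", nAd))
  for (k in seq_len(nArrays)) {
    occ <- rep(NA_character_, nq)
    kind <- rep(NA_character_, nq)
    occ[ctrlPos] <- ifelse(ctrlKind == "empty_no_tf", "empty", "AD_only")
    kind[ctrlPos] <- ctrlKind
    lo <- (k - 1L) * perArray + 1L
    hi <- min(k * perArray, nTfs)
    slot <- setdiff(seq_len(nq), ctrlPos)
    ids <- if (lo <= hi) tfIds[lo:hi] else character(0)
    occ[slot[seq_along(ids)]] <- ids
    kind[slot[seq_along(ids)]] <- "tf"
    ## unused TF positions on a short final array become empty controls
    spare <- is.na(occ)
    occ[spare] <- "empty"
    kind[spare] <- "empty_no_tf"
    maps[[k]] <- arrayMap(occ, kind)
  }
  maps
}

#' Generate a seeded synthetic Y1H screen
#'
#' Emits, for each tested bait, each of its 3AT levels, each imaging day and
#' each TF source array, one 1536-position plate of colony records, plus the
#' ground truth needed to score recovery. Pixel areas are
#' \code{round(exp(x))} with x normal around \code{mu0}, shifted by the
#' planted interaction delta where (bait, TF, level) matches, and by
#' \code{edgeDelta} on the outermost two quartet rows/columns of
#' edge-affected plates. Control quartets receive background-only growth.
#' Noncircular and missing-colony artifacts are injected per well at the
#' configured rates. The same seed always produces an identical screen.
#'
#' @param config a [simConfig()] object.
#' @param seed integer(1) RNG seed.
#' @return a [Y1HScreen-class]; its \code{groundTruth()} list has elements
#'   \code{interactions} (the planted table), \code{artifacts} (plate_id,
#'   well_row, well_col, type) and \code{edge_plates} (plate ids).
#' @examples
#' cfg <- simConfig(nTfs = 40, baits = defaultBaitTable()[1:2, ],
#'                  days = 7, nControlsEmpty = 4L, nControlsAd = 4L)
#' scr <- generateScreen(cfg, seed = 1)
#' length(plates(scr))  # 1 bait x 3 levels x 1 day x 1 array
#' @export
generateScreen <- function(config, seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(as.integer(seed))
  maps <- buildArrayMaps(config@nTfs, config@nControlsEmpty, config@nControlsAd)
  allTfs <- unlist(lapply(maps, function(m) m$occupant[m$kind == "tf"]))
  it <- config@interactions
  baits <- config@baits
  tested <- baits[!baits$excluded, , drop = FALSE]
  if (nrow(it)) {
    if (!all(it$tf_id %in% allTfs)) {
      stop("planted TF(s) not present in the array: ",
           paste(setdiff(it$tf_id, allTfs), collapse = ", "))
    }
    if (!all(it$bait_id %in% tested$bait_id)) {
      stop("planted bait(s) not among the tested baits: ",
           paste(setdiff(it$bait_id, tested$bait_id), collapse = ", "))
    }
  }
  levelsByBait <- parseLevels(tested$levels)
  sigmaQ <- config@sigma0 * config@quartetCorRatio
  sigmaW <- config@sigma0 * sqrt(1 - config@quartetCorRatio^2)
  nq <- QUARTET_ROWS * QUARTET_COLS
  ## well -> quartet geometry, fixed for all plates
  wr <- rep(seq_len(PLATE_ROWS), times = PLATE_COLS)
  wc <- rep(seq_len(PLATE_COLS), each = PLATE_ROWS)
  qr <- ceiling(wr / 2)
  qc <- ceiling(wc / 2)
  qidxOfWell <- (qc - 1L) * QUARTET_ROWS + qr
  qrowOfQ <- rep(seq_len(QUARTET_ROWS), times = QUARTET_COLS)
  qcolOfQ <- rep(seq_len(QUARTET_COLS), each = QUARTET_ROWS)
  edgeQ <- edgeQuartetMask(qrowOfQ, qcolOfQ)
  occByArray <- lapply(maps, function(m) {
    ord <- (m$qcol - 1L) * QUARTET_ROWS + m$qrow
    occ <- character(nq)
    occ[ord] <- m$occupant
    occ
  })
  plateList <- list()
  artifacts <- list()
  edgePlates <- character(0)
  for (b in seq_len(nrow(tested))) {
    bait <- tested$bait_id[b]
    sp <- tested$species[b]
    for (lv in levelsByBait[[b]]) {
      deltaByTf <- it[it$bait_id == bait & it$level == lv, , drop = FALSE]
      for (d in config@days) {
        for (a in seq_along(maps)) {
          pid <- sprintf("%s_%03dmM_d%02d_%s", bait, lv, d, names(maps)[a])
          occ <- occByArray[[a]]
          delta <- numeric(nq)
          if (nrow(deltaByTf)) {
            mIdx <- match(occ, deltaByTf$tf_id)
            delta[!is.na(mIdx)] <- deltaByTf$delta[mIdx[!is.na(mIdx)]]
          }
          isEdgePlate <- config@edgePlateFraction > 0 &&
            stats::runif(1) < config@edgePlateFraction
          if (isEdgePlate) edgePlates <- c(edgePlates, pid)
          qMean <- config@mu0 + delta +
            (if (isEdgePlate) config@edgeDelta * edgeQ else 0) +
            stats::rnorm(nq, 0, sigmaQ)
          x <- qMean[qidxOfWell] + stats::rnorm(length(wr), 0, sigmaW)
          px <- as.integer(round(exp(x)))
          noncirc <- stats::runif(length(wr)) < config@noncircularRate
          missing <- stats::runif(length(wr)) < config@missingRate
          px[missing] <- 0L
          present <- px > 0L
          noncirc <- noncirc & present
          rec <- data.frame(
            well_row = wr, well_col = wc, pixel_area = px,
            circular = !noncirc, present = present
          )
          plateList[[pid]] <- y1hPlate(
            rec, plateId = pid, baitId = bait, species = sp,
            selection3AT = lv, day = d, tfArrayId = names(maps)[a]
          )
          nArt <- sum(noncirc) + sum(missing)
          if (nArt) {
            artifacts[[pid]] <- data.frame(
              plate_id = pid,
              well_row = c(wr[noncirc], wr[missing]),
              well_col = c(wc[noncirc], wc[missing]),
              type = rep(c("noncircular", "missing"),
                         c(sum(noncirc), sum(missing)))
            )
          }
        }
      }
    }
  }
  truth <- list(
    interactions = it,
    artifacts = if (length(artifacts)) {
      do.call(rbind, c(artifacts, list(make.row.names = FALSE)))
    } else {
      data.frame(plate_id = character(0), well_row = integer(0),
                 well_col = integer(0), type = character(0))
    },
    edge_plates = edgePlates
  )
  new("Y1HScreen", plates = plateList, arrays = maps, baits = baits,
      truth = truth)
}

#' Run the full scoring and calling pipeline on a screen
#'
#' Convenience wrapper: [scoreScreen()], then [collectRecords()], then
#' [consensusCall()].
#'
#' @param screen a [Y1HScreen-class].
#' @param threshold p-value significance threshold (default 0.005).
#' @param day calling day (default 7).
#' @param minLevels consensus requirement (default 2).
#' @param ... passed to [scoreScreen()].
#' @return list with \code{scored}, \code{plateStats}, \code{records},
#'   \code{calls}.
#' @export
screenPipeline <- function(screen, threshold = 0.005, day = 7, minLevels = 2,
                           ...) {
  sc <- scoreScreen(screen, ...)
  records <- collectRecords(sc$scored, threshold = threshold)
  calls <- consensusCall(records, day = day, minLevels = minLevels)
  list(scored = sc$scored, plateStats = sc$plateStats,
       records = records, calls = calls)
}

#' Compare pipeline calls against synthetic ground truth
#'
#' @param calls data.frame from [consensusCall()].
#' @param truth ground-truth list from a generated screen
#'   ([groundTruth()]).
#' @return list with \code{recall} (fraction of planted (bait, TF) pairs
#'   called), \code{n_false_positive} (called pairs never planted),
#'   \code{fp_rate} (false positives over tested non-planted pairs) and
#'   \code{per_delta} (per planted pair: max delta, number of planted
#'   levels, detected flag).
#' @export
truthMetrics <- function(calls, truth) {
  it <- truth$interactions
  plantedKey <- unique(paste(it$bait_id, it$tf_id))
  callKey <- paste(calls$bait_id, calls$tf_id)
  calledKey <- callKey[calls$called]
  nPlanted <- length(plantedKey)
  recall <- if (nPlanted) {
    sum(plantedKey %in% calledKey) / nPlanted
  } else {
    NA_real_
  }
  fp <- setdiff(calledKey, plantedKey)
  nNonPlantedTested <- sum(!callKey %in% plantedKey)
  perDelta <- if (nPlanted) {
    idx <- split(seq_len(nrow(it)), paste(it$bait_id, it$tf_id))
    data.frame(
      bait_id = vapply(idx, function(i) it$bait_id[i[1]], character(1)),
      tf_id = vapply(idx, function(i) it$tf_id[i[1]], character(1)),
      max_delta = vapply(idx, function(i) max(it$delta[i]), numeric(1)),
      n_levels_planted = lengths(idx),
      detected = names(idx) %in% calledKey,
      row.names = NULL
    )
  } else {
    data.frame(bait_id = character(0), tf_id = character(0),
               max_delta = numeric(0), n_levels_planted = integer(0),
               detected = logical(0))
  }
  list(
    recall = recall,
    n_false_positive = length(fp),
    fp_rate = if (nNonPlantedTested) length(fp) / nNonPlantedTested else NA_real_,
    per_delta = perDelta
  )
}
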