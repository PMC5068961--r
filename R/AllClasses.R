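#' @import methods
NULL

## Plate geometry for the quadruplicated 384 -> 1536 format. A 1536-position
## selection plate is 32 rows x 48 columns of wells; each 2x2 block of wells
## ("quartet") replicates one bait-TF (or control) transformant, giving a
## 16 x 24 quartet grid.
PLATE_ROWS <- 32L
PLATE_COLS <- 48L
QUARTET_ROWS <- 16L
QUARTET_COLS <- 24L

#' Y1HPlate: one quantified 1536-position selection plate
#'
#' Container for the Gitter-style colony quantification of a single selection
#' plate together with its metadata: which enhancer-fragment bait the yeast
#' strain carries, the 3AT concentration of the medium (selection stringency),
#' the incubation day at imaging, and which 384-position TF source array was
#' spotted onto it.
#'
#' The \code{colonies} slot is a data.frame with one row per well position and
#' columns \code{well_row} (1..32), \code{well_col} (1..48), \code{pixel_area}
#' (non-negative integer; 0 means no colony detected), \code{circular}
#' (logical; \code{FALSE} when the quantifier flagged the colony as
#' noncircular) and \code{present} (logical; \code{FALSE} when no colony was
#' detected, which forces \code{pixel_area = 0}).
#'
#' @slot plateId character(1) unique plate identifier.
#' @slot baitId character(1) enhancer-fragment bait carried by the strain.
#' @slot species character(1), one of \code{"mel"}, \code{"pse"},
#'   \code{"will"}.
#' @slot selection3AT integer(1) 3AT concentration in mM (0 for the
#'   permissive reference plate). One of 0, 10, 20, 40, 60, 80, 100.
#' @slot day integer(1) incubation day at imaging (3, 7 or 10; day 3 is only
#'   valid for the permissive 0 mM plate).
#' @slot tfArrayId character(1) identifier of the 384-position TF source
#'   array spotted on this plate.
#' @slot excluded logical(1) whether the plate is excluded from analysis
#'   (e.g. contamination).
#' @slot colonies data.frame of colony records as described above.
#'
#' @seealso [readGitterTable()], [assembleQuartets()]
#' @export
setClass("Y1HPlate",
  representation(
    plateId = "character",
    baitId = "character",
    species = "character",
    selection3AT = "integer",
    day = "integer",
    tfArrayId = "character",
    excluded = "logical",
    colonies = "data.frame"
  ),
  prototype(
    plateId = NA_character_, baitId = NA_character_, species = NA_character_,
    selection3AT = 0L, day = 7L, tfArrayId = NA_character_, excluded = FALSE,
    colonies = data.frame(
      well_row = integer(0), well_col = integer(0),
      pixel_area = integer(0), circular = logical(0), present = logical(0)
    )
  )
)

setValidity("Y1HPlate", function(object) {
  msgs <- character(0)
  for (slotnm in c("plateId", "baitId", "species", "tfArrayId")) {
    if (length(slot(object, slotnm)) != 1L) {
      msgs <- c(msgs, sprintf("'%s' must have length 1", slotnm))
    }
  }
  if (!is.na(object@species) && !object@species %in% c("mel", "pse", "will")) {
    msgs <- c(msgs, "'species' must be one of 'mel', 'pse', 'will'")
  }
  if (!object@selection3AT %in% c(0L, 10L, 20L, 40L, 60L, 80L, 100L)) {
    msgs <- c(msgs, "'selection3AT' must be one of 0, 10, 20, 40, 60, 80, 100 mM")
  }
  if (!object@day %in% c(3L, 7L, 10L)) {
    msgs <- c(msgs, "'day' must be 3, 7 or 10")
  }
  if (object@day == 3L && object@selection3AT != 0L) {
    msgs <- c(msgs, "day-3 imaging is only valid for the permissive (0 mM 3AT) plate")
  }
  cc <- object@colonies
  need <- c("well_row", "well_col", "pixel_area", "circular", "present")
  if (!all(need %in% names(cc))) {
    msgs <- c(msgs, sprintf(
      "'colonies' must have columns %s", paste(need, collapse = ", ")
    ))
  } else if (nrow(cc) > 0L) {
    if (any(cc$well_row < 1L | cc$well_row > PLATE_ROWS) ||
        any(cc$well_col < 1L | cc$well_col > PLATE_COLS)) {
      msgs <- c(msgs, sprintf(
        "well positions must lie on the %d x %d grid", PLATE_ROWS, PLATE_COLS
      ))
    }
    if (any(cc$pixel_area < 0L)) {
      msgs <- c(msgs, "'pixel_area' must be non-negative")
    }
    if (any(!cc$present & cc$pixel_area != 0L)) {
      msgs <- c(msgs, "absent colonies (present = FALSE) must have pixel_area 0")
    }
    if (anyDuplicated(cc[, c("well_row", "well_col")])) {
      msgs <- c(msgs, "duplicate well positions in 'colonies'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Y1HScreen: a collection of selection plates plus layout metadata
#'
#' Bundles the plates of one screen with the TF array maps (which quartet
#' position holds which TF or control), the bait table (species and tested
#' 3AT levels per enhancer fragment) and, for synthetic screens, the ground
#' truth of planted interactions and injected artifacts.
#'
#' @slot plates list of [Y1HPlate-class] objects, named by plate id.
#' @slot arrays named list of array-map data.frames (one per TF source
#'   array), each with columns \code{qrow}, \code{qcol}, \code{occupant},
#'   \code{kind} (\code{"tf"}, \code{"empty_no_tf"} or \code{"ad_only"}).
#' @slot baits data.frame with columns \code{bait_id}, \code{species},
#'   \code{levels} (comma-separated tested 3AT levels in mM),
#'   \code{excluded}, \code{reason}.
#' @slot truth list with elements \code{interactions}, \code{artifacts},
#'   \code{edge_plates} for synthetic screens; empty list otherwise.
#'
#' @seealso [generateScreen()], [scoreScreen()]
#' @export
setClass("Y1HScreen",
  representation(
    plates = "list",
    arrays = "list",
    baits = "data.frame",
    truth = "list"
  ),
  prototype(plates = list(), arrays = list(),
            baits = data.frame(), truth = list())
)

setValidity("Y1HScreen", function(object) {
  msgs <- character(0)
  if (length(object@plates) &&
      !all(vapply(object@plates, is, logical(1), "Y1HPlate"))) {
    msgs <- c(msgs, "'plates' must be a list of Y1HPlate objects")
  }
  if (length(object@arrays)) {
    if (is.null(names(object@arrays)) || any(names(object@arrays) == "")) {
      msgs <- c(msgs, "'arrays' must be a named list")
    }
    okmap <- vapply(object@arrays, function(a) {
      is.data.frame(a) &&
        all(c("qrow", "qcol", "occupant", "kind") %in% names(a))
    }, logical(1))
    if (!all(okmap)) {
      msgs <- c(msgs, "each array map needs columns qrow, qcol, occupant, kind")
    }
  }
  for (pl in object@plates) {
    if (length(object@arrays) && !pl@tfArrayId %in% names(object@arrays)) {
      msgs <- c(msgs, sprintf(
        "plate '%s' references unknown TF array '%s'", pl@plateId, pl@tfArrayId
      ))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: parameters of the synthetic-screen generator
#'
#' Describes a synthetic Y1H screen: the arrayed TF collection, the baits and
#' their per-bait 3AT level series, the log-scale growth model (colony
#' ln-areas are normal around a plate background mean, with a shared
#' quartet-level offset inducing within-quartet correlation), planted
#' bait-TF interactions with per-level ln-area shifts, an optional additive
#' edge effect on the outermost two quartet rows/columns, and artifact rates
#' (noncircular and missing colonies).
#'
#' @slot nTfs integer(1) number of TFs in the arrayed collection.
#' @slot baits data.frame as in [Y1HScreen-class] (tested baits drive plate
#'   generation).
#' @slot days integer vector of imaging days for selective plates (subset of
#'   7, 10).
#' @slot mu0,sigma0 numeric(1) background mean and total SD of well ln-areas.
#' @slot quartetCorRatio numeric(1) in [0, 1): fraction of \code{sigma0}
#'   attributed to a shared quartet-level offset (within-quartet correlation).
#' @slot edgeDelta numeric(1) additive ln-area shift applied to quartets in
#'   the outermost two quartet rows/columns of edge-affected plates.
#' @slot edgePlateFraction numeric(1) in [0, 1] fraction of plates receiving
#'   the edge shift.
#' @slot interactions data.frame of planted interactions with columns
#'   \code{bait_id}, \code{tf_id}, \code{level} (3AT mM), \code{delta}
#'   (ln-area shift, >= 0).
#' @slot noncircularRate,missingRate numeric(1) per-well artifact
#'   probabilities.
#' @slot nControlsEmpty,nControlsAd integer(1) number of empty-well and
#'   AD-only control positions per 384-position array.
#'
#' @seealso [simConfig()], [generateScreen()]
#' @export
setClass("SimConfig",
  representation(
    nTfs = "integer",
    baits = "data.frame",
    days = "integer",
    mu0 = "numeric",
    sigma0 = "numeric",
    quartetCorRatio = "numeric",
    edgeDelta = "numeric",
    edgePlateFraction = "numeric",
    interactions = "data.frame",
    noncircularRate = "numeric",
    missingRate = "numeric",
    nControlsEmpty = "integer",
    nControlsAd = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nTfs < 1L) msgs <- c(msgs, "'nTfs' must be >= 1")
  if (object@sigma0 <= 0) msgs <- c(msgs, "'sigma0' must be > 0")
  if (object@quartetCorRatio < 0 || object@quartetCorRatio >= 1) {
    msgs <- c(msgs, "'quartetCorRatio' must be in [0, 1)")
  }
  for (r in c("noncircularRate", "missingRate", "edgePlateFraction")) {
    v <- slot(object, r)
    if (v < 0 || v > 1) msgs <- c(msgs, sprintf("'%s' must be in [0, 1]", r))
  }
  if (!all(object@days %in% c(7L, 10L))) {
    msgs <- c(msgs, "'days' must be a subset of {7, 10}")
  }
  it <- object@interactions
  if (nrow(it)) {
    if (!all(c("bait_id", "tf_id", "level", "delta") %in% names(it))) {
      msgs <- c(msgs, "'interactions' needs columns bait_id, tf_id, level, delta")
    } else if (any(it$delta < 0)) {
      msgs <- c(msgs, "planted 'delta' shifts must be >= 0")
    }
  }
  perArray <- 384L - object@nControlsEmpty - object@nControlsAd
  if (perArray < 1L) {
    msgs <- c(msgs, "control positions leave no room for TFs on a 384 array")
  }
  if (length(msgs)) msgs else TRUE
})
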