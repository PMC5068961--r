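#' @include AllClasses.R
NULL

#' Accessors for Y1HPlate and Y1HScreen objects
#'
#' Standard read accessors for the plate and screen containers: plate
#' identity, bait, species, 3AT selection level, imaging day, TF array id,
#' exclusion flag and the colony record table.
#'
#' @param object a [Y1HPlate-class] or [Y1HScreen-class] object.
#' @return The corresponding slot value; for `plates()` a named list of
#'   plates, for `arrayMaps()` a named list of array-map data.frames, for
#'   `baitTable()` the bait metadata data.frame, for `groundTruth()` the
#'   synthetic ground-truth list.
#' @examples
#' pl <- new("Y1HPlate", plateId = "p1", baitId = "mel_A1", species = "mel",
#'           selection3AT = 10L, day = 7L, tfArrayId = "arr1")
#' plateId(pl)
#' selection3AT(pl)
#' @name y1h-accessors
NULL

#' @rdname y1h-accessors
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))
#' @rdname y1h-accessors
#' @export
setGeneric("baitId", function(object) standardGeneric("baitId"))
#' @rdname y1h-accessors
#' @export
setGeneric("species", function(object) standardGeneric("species"))
#' @rdname y1h-accessors
#' @export
setGeneric("selection3AT", function(object) standardGeneric("selection3AT"))
#' @rdname y1h-accessors
#' @export
setGeneric("imagingDay", function(object) standardGeneric("imagingDay"))
#' @rdname y1h-accessors
#' @export
setGeneric("tfArrayId", function(object) standardGeneric("tfArrayId"))
#' @rdname y1h-accessors
#' @export
setGeneric("isExcluded", function(object) standardGeneric("isExcluded"))
#' @rdname y1h-accessors
#' @export
setGeneric("colonies", function(object) standardGeneric("colonies"))
#' @rdname y1h-accessors
#' @export
setGeneric("plates", function(object) standardGeneric("plates"))
#' @rdname y1h-accessors
#' @export
setGeneric("arrayMaps", function(object) standardGeneric("arrayMaps"))
#' @rdname y1h-accessors
#' @export
setGeneric("baitTable", function(object) standardGeneric("baitTable"))
#' @rdname y1h-accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname y1h-accessors
#' @export
setMethod("plateId", "Y1HPlate", function(object) object@plateId)
#' @rdname y1h-accessors
#' @export
setMethod("baitId", "Y1HPlate", function(object) object@baitId)
#' @rdname y1h-accessors
#' @export
setMethod("species", "Y1HPlate", function(object) object@species)
#' @rdname y1h-accessors
#' @export
setMethod("selection3AT", "Y1HPlate", function(object) object@selection3AT)
#' @rdname y1h-accessors
#' @export
setMethod("imagingDay", "Y1HPlate", function(object) object@day)
#' @rdname y1h-accessors
#' @export
setMethod("tfArrayId", "Y1HPlate", function(object) object@tfArrayId)
#' @rdname y1h-accessors
#' @export
setMethod("isExcluded", "Y1HPlate", function(object) object@excluded)
#' @rdname y1h-accessors
#' @export
setMethod("colonies", "Y1HPlate", function(object) object@colonies)

#' @rdname y1h-accessors
#' @export
setMethod("plates", "Y1HScreen", function(object) object@plates)
#' @rdname y1h-accessors
#' @export
setMethod("arrayMaps", "Y1HScreen", function(object) object@arrays)
#' @rdname y1h-accessors
#' @export
setMethod("baitTable", "Y1HScreen", function(object) object@baits)
#' @rdname y1h-accessors
#' @export
setMethod("groundTruth", "Y1HScreen", function(object) object@truth)

setMethod("show", "Y1HPlate", function(object) {
  cc <- object@colonies
  cat(sprintf(
    "Y1HPlate '%s': bait %s (%s), %d mM 3AT, day %d, array %s%s\n",
    object@plateId, object@baitId, object@species, object@selection3AT,
    object@day, object@tfArrayId, if (object@excluded) " [excluded]" else ""
  ))
  cat(sprintf(
    "  %d colony records (%d present, %d noncircular)\n",
    nrow(cc), sum(cc$present), sum(cc$present & !cc$circular)
  ))
})

setMethod("show", "Y1HScreen", function(object) {
  nb <- if (nrow(object@baits)) sum(!object@baits$excluded) else 0L
  cat(sprintf(
    "Y1HScreen: %d plates, %d TF arrays, %d tested baits%s\n",
    length(object@plates), length(object@arrays), nb,
    if (length(object@truth)) " (synthetic, with ground truth)" else ""
  ))
  if (length(object@plates)) {
    lv <- sort(unique(vapply(object@plates, selection3AT, integer(1))))
    dy <- sort(unique(vapply(object@plates, imagingDay, integer(1))))
    cat(sprintf("  3AT levels (mM): %s; days: %s\n",
                paste(lv, collapse = ", "), paste(dy, collapse = ", ")))
  }
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d TFs, %d tested baits, days %s\n",
    object@nTfs, sum(!object@baits$excluded),
    paste(object@days, collapse = ",")
  ))
  cat(sprintf(
    "  ln-area background N(%.2f, %.2f^2), quartet cor ratio %.2f\n",
    object@mu0, object@sigma0, object@quartetCorRatio
  ))
  cat(sprintf(
    "  %d planted interaction level(s); edge delta %.2f on %.0f%% of plates\n",
    nrow(object@interactions), object@edgeDelta, 100 * object@edgePlateFraction
  ))
})
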