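#' @include AllClasses.R
NULL

#' Write a screen to disk as plate tables plus a manifest
#'
#' Each plate becomes one Gitter-style TSV under \code{dir/plates/}; plate
#' metadata, array maps and the bait table go into \code{manifest.yaml};
#' for synthetic screens the ground truth is written as
#' \code{truth_interactions.tsv}, \code{truth_artifacts.tsv} and an
#' \code{edge_plates} manifest entry.
#'
#' @param screen a [Y1HScreen-class].
#' @param dir output directory (created if needed).
#' @param dialect a [gitterDialect()] used for the plate tables.
#' @return invisibly, \code{dir}.
#' @seealso [readScreen()]
#' @export
writeScreen <- function(screen, dir, dialect = gitterDialect()) {
  plateDir <- file.path(dir, "plates")
  dir.create(plateDir, recursive = TRUE, showWarnings = FALSE)
  plateMeta <- lapply(plates(screen), function(pl) {
    fn <- paste0(plateId(pl), ".tsv")
    writeGitterTable(colonies(pl), file.path(plateDir, fn),
                     dialect = dialect)
    list(plate_id = plateId(pl), file = file.path("plates", fn),
         bait_id = baitId(pl), species = species(pl),
         selection_3at_mM = selection3AT(pl), day = imagingDay(pl),
         tf_array_id = tfArrayId(pl), excluded = isExcluded(pl))
  })
  arrays <- lapply(arrayMaps(screen), function(m) {
    m <- m[order(m$qrow, m$qcol), ]
    list(occupant = as.list(m$occupant), kind = as.list(m$kind))
  })
  baits <- baitTable(screen)
  manifest <- list(
    plates = unname(plateMeta),
    arrays = arrays,
    baits = lapply(seq_len(nrow(baits)), function(i) as.list(baits[i, ])),
    edge_plates = as.list(groundTruth(screen)$edge_plates)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  tr <- groundTruth(screen)
  if (length(tr)) {
    utils::write.table(tr$interactions,
                       file.path(dir, "truth_interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tr$artifacts, file.path(dir, "truth_artifacts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a screen written by [writeScreen()]
#'
#' @param dir directory containing \code{manifest.yaml} and the plate
#'   tables.
#' @param dialect a [gitterDialect()] for the plate tables.
#' @return a [Y1HScreen-class].
#' @export
readScreen <- function(dir, dialect = gitterDialect()) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  arrays <- lapply(manifest$arrays, function(a) {
    arrayMap(unlist(a$occupant), unlist(a$kind))
  })
  plateList <- lapply(manifest$plates, function(pm) {
    rec <- readGitterTable(file.path(dir, pm$file), dialect = dialect)
    y1hPlate(rec, plateId = pm$plate_id, baitId = pm$bait_id,
             species = pm$species, selection3AT = pm$selection_3at_mM,
             day = pm$day, tfArrayId = pm$tf_array_id,
             excluded = isTRUE(pm$excluded))
  })
  names(plateList) <- vapply(manifest$plates, `[[`, character(1), "plate_id")
  baits <- do.call(rbind, lapply(manifest$baits, function(b) {
    data.frame(bait_id = b$bait_id, species = b$species,
               levels = as.character(b$levels),
               excluded = isTRUE(b$excluded),
               reason = if (is.null(b$reason)) "" else as.character(b$reason))
  }))
  truth <- list()
  fi <- file.path(dir, "truth_interactions.tsv")
  if (file.exists(fi)) {
    truth$interactions <- utils::read.delim(fi, stringsAsFactors = FALSE)
    fa <- file.path(dir, "truth_artifacts.tsv")
    truth$artifacts <- if (file.exists(fa)) {
      utils::read.delim(fa, stringsAsFactors = FALSE)
    } else {
      data.frame()
    }
    truth$edge_plates <- as.character(unlist(manifest$edge_plates))
  }
  new("Y1HScreen", plates = plateList, arrays = arrays,
      baits = baits, truth = truth)
}
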