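#' @include AllClasses.R
NULL

#' Describe the column layout of a Gitter-style colony table
#'
#' Colony quantifiers in the Gitter family emit one tab-separated row per
#' grid position with at least a row index, a column index, a colony size in
#' pixels, a circularity measure and a flag field. Column names and the flag
#' vocabulary differ between versions, so the mapping is configurable. A
#' colony is treated as noncircular when its flag field contains
#' \code{noncircularCode}, or (optionally) when its circularity value falls
#' below \code{circularityCutoff}; the default is flag-only.
#'
#' @param row,col,size,circularity,flags column names in the input table.
#' @param noncircularCode character(1) substring of the flag field marking a
#'   noncircular colony.
#' @param circularityCutoff numeric(1) or NA; when not NA, colonies with
#'   circularity below this value are also treated as noncircular.
#' @return A named list of class \code{gitter_dialect}.
#' @examples
#' gitterDialect()
#' gitterDialect(size = "area", noncircularCode = "NC")
#' @export
gitterDialect <- function(row = "row", col = "col", size = "size",
                          circularity = "circularity", flags = "flags",
                          noncircularCode = "C", circularityCutoff = NA_real_) {
  structure(
    list(row = row, col = col, size = size, circularity = circularity,
         flags = flags, noncircularCode = noncircularCode,
         circularityCutoff = circularityCutoff),
    class = "gitter_dialect"
  )
}

emptyColonyFrame <- function() {
  data.frame(
    well_row = integer(0), well_col = integer(0), pixel_area = integer(0),
    circular = logical(0), present = logical(0)
  )
}

#' Read a Gitter-style colony quantification table
#'
#' Parses one tab-separated plate table (lines starting with \code{#} are
#' comments) into a colony record data.frame with columns \code{well_row},
#' \code{well_col}, \code{pixel_area}, \code{circular} and \code{present}.
#' A size of 0 pixels is recorded as \code{present = FALSE}: no colony was
#' detected at that position. Noncircular colonies keep their area but are
#' flagged \code{circular = FALSE} so downstream quartet assembly screens
#' them out.
#'
#' @param file path to (or connection for) the table.
#' @param dialect a [gitterDialect()] column mapping.
#' @param plateRows,plateCols grid dimensions; positions outside the grid
#'   are rejected with an error.
#' @return data.frame of colony records, ordered by row then column.
#' @seealso [writeGitterTable()], [assembleQuartets()]
#' @export
readGitterTable <- function(file, dialect = gitterDialect(),
                            plateRows = PLATE_ROWS, plateCols = PLATE_COLS) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty Gitter table: no header found")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  for (colkey in c("row", "col", "size", "circularity", "flags")) {
    if (!dialect[[colkey]] %in% header) {
      stop(sprintf("dialect column '%s' (mapped to '%s') not found in header",
                   dialect[[colkey]], colkey))
    }
  }
  body <- lines[-1]
  if (!length(body)) return(emptyColonyFrame())
  ## sentinel keeps a trailing empty field (e.g. a blank flags column)
  fields <- strsplit(paste0(body, "\t"), "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop(sprintf("malformed line %d: expected %d fields, found %d",
                 lineNo[-1][bad], length(header), nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  toInt <- function(key) {
    v <- suppressWarnings(as.integer(m[, dialect[[key]]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("malformed line %d: non-integer value '%s' in column '%s'",
                   lineNo[-1][bad], m[bad, dialect[[key]]], dialect[[key]]))
    }
    v
  }
  wr <- toInt("row")
  wc <- toInt("col")
  sz <- toInt("size")
  if (any(wr < 1L | wr > plateRows | wc < 1L | wc > plateCols)) {
    bad <- which(wr < 1L | wr > plateRows | wc < 1L | wc > plateCols)[1]
    stop(sprintf("line %d: position (%d, %d) outside the %d x %d grid",
                 lineNo[-1][bad], wr[bad], wc[bad], plateRows, plateCols))
  }
  if (any(sz < 0L)) {
    stop(sprintf("line %d: negative pixel area",
                 lineNo[-1][which(sz < 0L)[1]]))
  }
  dupIdx <- anyDuplicated(cbind(wr, wc))
  if (dupIdx) {
    stop(sprintf("duplicate position (%d, %d) at line %d",
                 wr[dupIdx], wc[dupIdx], lineNo[-1][dupIdx]))
  }
  flagged <- grepl(dialect$noncircularCode, m[, dialect$flags], fixed = TRUE)
  if (!is.na(dialect$circularityCutoff)) {
    circ <- suppressWarnings(as.numeric(m[, dialect$circularity]))
    flagged <- flagged | (!is.na(circ) & circ < dialect$circularityCutoff)
  }
  rec <- data.frame(
    well_row = wr, well_col = wc, pixel_area = sz,
    circular = !flagged, present = sz > 0L
  )
  rec <- rec[order(rec$well_row, rec$well_col), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write colony records as a Gitter-style table
#'
#' Emits a tab-separated table readable by [readGitterTable()] with the
#' default dialect. Noncircular colonies are encoded through the dialect's
#' flag code; absent colonies get size 0.
#'
#' @param records colony record data.frame (see [readGitterTable()]).
#' @param file output path or connection.
#' @param dialect a [gitterDialect()]; its column names and noncircular code
#'   are used for the output.
#' @param comment optional character vector written as \code{#} comment
#'   lines before the header.
#' @return invisibly, \code{file}.
#' @export
writeGitterTable <- function(records, file, dialect = gitterDialect(),
                             comment = NULL) {
  stopifnot(is.data.frame(records))
  header <- paste(dialect$row, dialect$col, dialect$size,
                  dialect$circularity, dialect$flags, sep = "\t")
  if (nrow(records)) {
    body <- paste(
      records$well_row, records$well_col, records$pixel_area,
      ifelse(records$circular, "1.0", "0.0"),
      ifelse(records$circular, "", dialect$noncircularCode),
      sep = "\t"
    )
  } else {
    body <- character(0)
  }
  lines <- c(if (!is.null(comment)) paste0("# ", comment), header, body)
  writeLines(lines, file)
  invisible(file)
}

#' Force masked wells to "no colony detected"
#'
#' Manual contaminant masking is an upstream, image-level step; its result
#' enters the pipeline as a per-plate list of wells to drop. Masked wells are
#' set to \code{present = FALSE}, \code{pixel_area = 0}.
#'
#' @param records colony record data.frame.
#' @param mask data.frame with columns \code{well_row}, \code{well_col}
#'   (a \code{plate_id} column, if present, is ignored here; filter before
#'   calling).
#' @return the updated record data.frame.
#' @export
applyWellMask <- function(records, mask) {
  if (!nrow(mask)) return(records)
  key <- paste(records$well_row, records$well_col)
  hit <- key %in% paste(mask$well_row, mask$well_col)
  records$present[hit] <- FALSE
  records$pixel_area[hit] <- 0L
  records$circular[hit] <- TRUE
  records
}

#' Construct a Y1HPlate
#'
#' @param colonies colony record data.frame from [readGitterTable()].
#' @param plateId,baitId,species,tfArrayId character(1) identifiers.
#' @param selection3AT 3AT level in mM.
#' @param day imaging day.
#' @param excluded logical(1) plate-level exclusion flag.
#' @return a [Y1HPlate-class] object.
#' @export
y1hPlate <- function(colonies, plateId, baitId, species, selection3AT, day,
                     tfArrayId, excluded = FALSE) {
  new("Y1HPlate",
      plateId = as.character(plateId), baitId = as.character(baitId),
      species = as.character(species),
      selection3AT = as.integer(selection3AT), day = as.integer(day),
      tfArrayId = as.character(tfArrayId), excluded = isTRUE(excluded),
      colonies = colonies)
}

#' Build a TF array map
#'
#' An array map records, for each of the 384 quartet positions (16 rows by
#' 24 columns), the occupant spotted there: a TF identifier or one of the
#' two negative-control kinds (\code{empty_no_tf}: untransformed cells;
#' \code{ad_only}: activation domain without a TF).
#'
#' @param occupants character(384) occupant ids in row-major quartet order.
#' @param kinds character(384) matching \code{occupants}; each one of
#'   \code{"tf"}, \code{"empty_no_tf"}, \code{"ad_only"}.
#' @return data.frame with columns \code{qrow}, \code{qcol},
#'   \code{occupant}, \code{kind}.
#' @export
arrayMap <- function(occupants, kinds) {
  nq <- QUARTET_ROWS * QUARTET_COLS
  stopifnot(length(occupants) == nq, length(kinds) == nq)
  if (!all(kinds %in% c("tf", "empty_no_tf", "ad_only"))) {
    stop("'kinds' must be 'tf', 'empty_no_tf' or 'ad_only'")
  }
  data.frame(
    qrow = rep(seq_len(QUARTET_ROWS), each = QUARTET_COLS),
    qcol = rep(seq_len(QUARTET_COLS), times = QUARTET_ROWS),
    occupant = as.character(occupants),
    kind = as.character(kinds)
  )
}

#' Group a plate's colonies into replicate quartets
#'
#' Each transformant genotype is spotted four times in a 2x2 quartet of
#' neighbouring wells, so quartet (qrow, qcol) on the 16 x 24 quartet grid
#' owns wells (2 qrow - 1, 2 qrow) x (2 qcol - 1, 2 qcol). For every quartet
#' the natural-log areas of its present, circular colonies are collected;
#' noncircular colonies are screened out at this step and detected-colony
#' counts recorded. Missing well positions are treated as "no colony
#' detected".
#'
#' @param plate a [Y1HPlate-class] object (or a colony record data.frame).
#' @param map an [arrayMap()] data.frame for the plate's TF array.
#' @return data.frame with one row per quartet: \code{plate_id},
#'   \code{bait_id}, \code{occupant}, \code{kind}, \code{qrow}, \code{qcol},
#'   \code{ln_area_1..4} (NA beyond the detected count) and
#'   \code{n_present_circular}.
#' @examples
#' rec <- expand.grid(well_row = 1:32, well_col = 1:48)
#' rec$pixel_area <- 148L; rec$circular <- TRUE; rec$present <- TRUE
#' pl <- y1hPlate(rec, "p1", "mel_A1", "mel", 10, 7, "arr1")
#' am <- arrayMap(sprintf("TF%03d", 1:384), rep("tf", 384))
#' q <- assembleQuartets(pl, am)
#' stopifnot(nrow(q) == 384, all(q$n_present_circular == 4))
#' @export
assembleQuartets <- function(plate, map) {
  if (is(plate, "Y1HPlate")) {
    rec <- plate@colonies
    pid <- plate@plateId
    bait <- plate@baitId
  } else {
    rec <- plate
    pid <- NA_character_
    bait <- NA_character_
  }
  if (any(rec$well_row > PLATE_ROWS | rec$well_col > PLATE_COLS |
          rec$well_row < 1L | rec$well_col < 1L)) {
    stop("colony positions outside the 32 x 48 grid")
  }
  ## ln-area matrix over the full grid; NA = absent / noncircular / unseen
  V <- matrix(NA_real_, nrow = PLATE_ROWS, ncol = PLATE_COLS)
  use <- rec$present & rec$circular & rec$pixel_area > 0L
  V[cbind(rec$well_row[use], rec$well_col[use])] <- log(rec$pixel_area[use])
  ## reshape into (2, 16, 2, 24) and collect the 4 wells of each quartet
  dim(V) <- c(2L, QUARTET_ROWS, 2L, QUARTET_COLS)
  W <- aperm(V, c(2L, 4L, 1L, 3L))          # qrow x qcol x 4 replicate slots
  dim(W) <- c(QUARTET_ROWS * QUARTET_COLS, 4L)
  ## left-compact the non-NA values into ln_area_1..4
  lnm <- t(apply(W, 1L, function(v) {
    v <- v[!is.na(v)]
    c(v, rep(NA_real_, 4L - length(v)))
  }))
  qrow <- rep(seq_len(QUARTET_ROWS), times = QUARTET_COLS)
  qcol <- rep(seq_len(QUARTET_COLS), each = QUARTET_ROWS)
  out <- data.frame(
    plate_id = pid, bait_id = bait,
    qrow = qrow, qcol = qcol,
    ln_area_1 = lnm[, 1], ln_area_2 = lnm[, 2],
    ln_area_3 = lnm[, 3], ln_area_4 = lnm[, 4],
    n_present_circular = rowSums(!is.na(lnm))
  )
  key <- paste(map$qrow, map$qcol)
  idx <- match(paste(out$qrow, out$qcol), key)
  if (anyNA(idx)) stop("array map does not cover the 16 x 24 quartet grid")
  out$occupant <- map$occupant[idx]
  out$kind <- map$kind[idx]
  out <- out[order(out$qrow, out$qcol),
             c("plate_id", "bait_id", "occupant", "kind", "qrow", "qcol",
               paste0("ln_area_", 1:4), "n_present_circular")]
  rownames(out) <- NULL
  out
}
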