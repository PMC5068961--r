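#' @include AllClasses.R
NULL

#' Natural-log colony area
#'
#' Colony areas enter all downstream statistics as the natural log of the
#' number of pixels in the colony.
#'
#' @param pixel_area positive integer vector of pixel counts.
#' @return numeric vector of ln-areas.
#' @examples
#' lnArea(c(1L, 148L, 1000L))
#' @export
lnArea <- function(pixel_area) {
  if (any(pixel_area < 1L)) {
    stop("ln-area is defined for pixel areas >= 1 (use present = FALSE for 0)")
  }
  log(pixel_area)
}

#' Index of dispersion of quartet ln-areas
#'
#' Sample variance (n - 1 denominator) divided by the mean. Quartets whose
#' four replicate spots disagree — dispersion above the cutoff — are treated
#' as unreliable and excluded by [qcQuartets()].
#'
#' @param values numeric vector of at least 2 ln-areas with nonzero mean.
#' @return numeric(1) dispersion index.
#' @examples
#' indexOfDispersion(c(2, 3, 4, 3))   # 0.2222
#' @export
indexOfDispersion <- function(values) {
  if (length(values) < 2L) {
    stop("index of dispersion needs at least 2 values")
  }
  m <- mean(values)
  if (m == 0) stop("index of dispersion is undefined for mean 0")
  stats::var(values) / m
}

#' Quartet-level quality control
#'
#' Applies the three quartet exclusion rules, in order, to each quartet's
#' ln-areas (only present, circular colonies contribute):
#' \enumerate{
#'   \item fewer than two detectable circular colonies
#'     (\code{excluded_single_colony}; a zero-colony quartet is excluded for
#'     the same reason),
#'   \item mean ln-area below \code{meanCutoff} (\code{excluded_low_area}),
#'   \item index of dispersion above \code{dispersionCutoff}
#'     (\code{excluded_dispersion}).
#' }
#' Exclusion is by strict inequality: a quartet with mean exactly at the
#' cutoff, or dispersion exactly at the cutoff, survives. Surviving quartets
#' get status \code{ok} and their value — the mean of the quartet's
#' ln-areas — which every later stage consumes.
#'
#' @param quartets data.frame from [assembleQuartets()].
#' @param meanCutoff numeric(1); quartets with mean ln-area strictly below
#'   this are excluded (default 2, i.e. a geometric-mean colony under
#'   ~7.4 pixels).
#' @param dispersionCutoff numeric(1); quartets with dispersion strictly
#'   above this are excluded (default 0.2).
#' @return the input data.frame with added columns \code{value} (mean
#'   ln-area; NA when fewer than one colony) and \code{status}.
#' @examples
#' q <- data.frame(ln_area_1 = c(3, 1.0, 2), ln_area_2 = c(3.1, 1.1, 3),
#'                 ln_area_3 = c(2.9, 0.9, 4), ln_area_4 = c(3, 1.0, 3),
#'                 n_present_circular = 4)
#' qcQuartets(q)$status
#' @export
qcQuartets <- function(quartets, meanCutoff = 2, dispersionCutoff = 0.2) {
  lnm <- as.matrix(quartets[, paste0("ln_area_", 1:4)])
  n <- rowSums(!is.na(lnm))
  value <- rowMeans(lnm, na.rm = TRUE)
  value[n == 0L] <- NA_real_
  ## row-wise sample variance over the available replicates
  ss <- rowSums((lnm - value)^2, na.rm = TRUE)
  disp <- ifelse(n >= 2L & value != 0, ss / (n - 1L) / value, NA_real_)
  status <- rep("ok", nrow(quartets))
  status[!is.na(disp) & disp > dispersionCutoff] <- "excluded_dispersion"
  status[!is.na(value) & value < meanCutoff] <- "excluded_low_area"
  status[n < 2L] <- "excluded_single_colony"
  out <- quartets
  out$value <- value
  out$status <- status
  out
}
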