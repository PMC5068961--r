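#' @include AllClasses.R
NULL

#' Count the unique bait-TF tests of a screen
#'
#' The nominal test count is simply TFs times baits; partial exclusions
#' (such as one contaminated array half, removing about half the TFs for
#' one bait) are reported alongside as an adjusted count.
#'
#' @param nTfs,nBaits non-negative integers.
#' @param exclusions optional data.frame with columns \code{bait_id} and
#'   \code{n_tfs_untested}.
#' @return list with \code{total} (nTfs * nBaits) and \code{adjusted}
#'   (total minus the excluded pair counts).
#' @examples
#' countTests(670, 26)$total  # 17420
#' countTests(670, 26, data.frame(bait_id = "pse_B9",
#'                                n_tfs_untested = 335))$adjusted
#' @export
countTests <- function(nTfs, nBaits, exclusions = NULL) {
  stopifnot(nTfs >= 0, nBaits >= 0)
  total <- as.integer(nTfs) * as.integer(nBaits)
  adj <- total
  if (!is.null(exclusions) && nrow(exclusions)) {
    adj <- total - sum(as.integer(exclusions$n_tfs_untested))
  }
  list(total = total, adjusted = adj)
}

#' Summarize interaction calls into per-TF hit profiles
#'
#' Builds the screen's headline summary: for every TF with at least one
#' called bait fragment, the number of fragments hit per species and in
#' total; the distinct-TF count per species; the multi-fragment TF list;
#' and the TF(s) hitting the most fragments (ties all reported, sorted by
#' identifier).
#'
#' @param calls data.frame with columns \code{bait_id}, \code{tf_id},
#'   \code{called} (as from [consensusCall()]).
#' @param baitSpecies named character vector mapping bait_id to species
#'   (\code{"mel"}, \code{"pse"}, \code{"will"}), or a data.frame with
#'   columns \code{bait_id}, \code{species}.
#' @param nrAnnotation optional data.frame (\code{tf_id},
#'   \code{is_nuclear_receptor}); TFs absent from it are taken as not
#'   nuclear receptors.
#' @return list with \code{profiles} (tf_id, mel, pse, will,
#'   total_fragments_hit, is_nuclear_receptor) and \code{summary} (list:
#'   n_tfs_hit, n_tfs_mel, n_tfs_pse, n_tfs_will, n_tfs_multi_fragment,
#'   max_tf, max_fragments, n_nuclear_receptors_hit).
#' @export
summarizeHits <- function(calls, baitSpecies, nrAnnotation = NULL) {
  if (is.data.frame(baitSpecies)) {
    baitSpecies <- stats::setNames(baitSpecies$species, baitSpecies$bait_id)
  }
  hit <- calls[calls$called, , drop = FALSE]
  sp <- unname(baitSpecies[hit$bait_id])
  if (anyNA(sp)) {
    stop("bait(s) without a species mapping: ",
         paste(unique(hit$bait_id[is.na(sp)]), collapse = ", "))
  }
  tfs <- sort(unique(hit$tf_id))
  cnt <- function(spp) {
    v <- table(hit$tf_id[sp == spp])
    out <- stats::setNames(integer(length(tfs)), tfs)
    out[names(v)] <- as.integer(v)
    out
  }
  profiles <- data.frame(
    tf_id = tfs,
    mel = cnt("mel"), pse = cnt("pse"), will = cnt("will"),
    row.names = NULL
  )
  profiles$total_fragments_hit <-
    profiles$mel + profiles$pse + profiles$will
  isNR <- rep(FALSE, nrow(profiles))
  if (!is.null(nrAnnotation) && nrow(nrAnnotation)) {
    m <- match(profiles$tf_id, nrAnnotation$tf_id)
    isNR <- !is.na(m) & as.logical(nrAnnotation$is_nuclear_receptor[m])
  }
  profiles$is_nuclear_receptor <- isNR
  maxFrag <- if (nrow(profiles)) max(profiles$total_fragments_hit) else 0L
  maxTf <- sort(profiles$tf_id[profiles$total_fragments_hit == maxFrag])
  summary <- list(
    n_tfs_hit = nrow(profiles),
    n_tfs_mel = sum(profiles$mel > 0),
    n_tfs_pse = sum(profiles$pse > 0),
    n_tfs_will = sum(profiles$will > 0),
    n_tfs_multi_fragment = sum(profiles$total_fragments_hit > 1),
    max_tf = if (nrow(profiles)) maxTf else character(0),
    max_fragments = maxFrag,
    n_nuclear_receptors_hit = sum(profiles$is_nuclear_receptor)
  )
  list(profiles = profiles, summary = summary)
}

#' Join Y1H hit profiles with RNAi phenotype results
#'
#' The dual-evidence set — TFs that both bound a bait fragment in yeast and
#' altered the phenotype when knocked down in vivo — is the screen's
#' strongest candidate list. TFs absent from the RNAi table are reported as
#' not tested by RNAi, never as negative.
#'
#' @param profiles data.frame from [summarizeHits()].
#' @param rnaiTable data.frame with columns \code{tf_id}, \code{affected}
#'   (logical) and optionally \code{categories} (comma-separated phenotype
#'   category codes).
#' @return list with \code{overlap} (sorted tf_ids with a Y1H hit and
#'   affected = TRUE), \code{n_overlap}, and \code{table} (profiles with
#'   \code{rnai_tested}, \code{rnai_affected}, \code{rnai_categories}
#'   columns).
#' @export
integrateRnai <- function(profiles, rnaiTable) {
  if (anyDuplicated(rnaiTable$tf_id)) {
    stop("duplicate tf_id rows in the RNAi table")
  }
  m <- match(profiles$tf_id, rnaiTable$tf_id)
  tested <- !is.na(m)
  affected <- tested & as.logical(rnaiTable$affected[m])
  affected[is.na(affected)] <- FALSE
  cats <- if ("categories" %in% names(rnaiTable)) {
    as.character(rnaiTable$categories[m])
  } else {
    rep(NA_character_, nrow(profiles))
  }
  cats[!tested] <- NA_character_
  out <- profiles
  out$rnai_tested <- tested
  out$rnai_affected <- ifelse(tested, affected, NA)
  out$rnai_categories <- cats
  overlap <- sort(profiles$tf_id[affected & profiles$total_fragments_hit > 0])
  list(overlap = overlap, n_overlap = length(overlap), table = out)
}

#' Expand a TF-by-species fragment-count matrix into call rows
#'
#' The hit matrix gives, per TF and species, how many bait fragments the TF
#' interacted with, but not which fragments. For summary statistics only
#' the counts matter, so the expansion assigns placeholder bait identifiers
#' (\code{mel_1}, \code{mel_2}, ... per species); these are synthetic
#' labels, not the screen's real fragment names.
#'
#' @param hitMatrix data.frame with columns \code{tf_id}, \code{mel},
#'   \code{pse}, \code{will} (fragment counts).
#' @return list with \code{calls} (bait_id, tf_id, called) and
#'   \code{baitSpecies} (data.frame bait_id, species covering the
#'   placeholder baits).
#' @export
expandHitMatrix <- function(hitMatrix) {
  rows <- list()
  for (spp in c("mel", "pse", "will")) {
    k <- hitMatrix[[spp]]
    has <- which(k > 0)
    if (!length(has)) next
    rows[[spp]] <- data.frame(
      bait_id = sprintf("%s_%d", spp, unlist(lapply(k[has], seq_len))),
      tf_id = rep(hitMatrix$tf_id[has], k[has]),
      called = TRUE
    )
  }
  calls <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  nb <- vapply(c("mel", "pse", "will"),
               function(spp) max(0L, hitMatrix[[spp]]), integer(1))
  baitSpecies <- do.call(rbind, lapply(c("mel", "pse", "will"), function(spp) {
    if (nb[[spp]] == 0L) return(NULL)
    data.frame(bait_id = sprintf("%s_%d", spp, seq_len(nb[[spp]])),
               species = spp)
  }))
  list(calls = calls, baitSpecies = baitSpecies)
}

#' Read the bundled screen-hit matrix and annotation fixtures
#'
#' The package ships, under \code{inst/extdata}, a transcription of the
#' published screen outcome: the TF-by-species fragment-count matrix of the
#' 45 hit TFs (\code{table1_hits.tsv}), the RNAi phenotype table of the 32
#' TFs whose knockdown altered abdominal pigmentation
#' (\code{rnai_phenotypes.tsv}, with Fig-7-style category codes), and the
#' nuclear-receptor annotation (\code{nuclear_receptors.tsv}). These are
#' data inputs, shipped so the headline summary counts are reproducible
#' offline.
#'
#' @param which one of \code{"hits"}, \code{"rnai"},
#'   \code{"nuclear_receptors"}.
#' @return the fixture as a data.frame.
#' @examples
#' head(readScreenFixture("hits"))
#' @export
readScreenFixture <- function(which = c("hits", "rnai", "nuclear_receptors")) {
  which <- match.arg(which)
  fname <- switch(which,
    hits = "table1_hits.tsv",
    rnai = "rnai_phenotypes.tsv",
    nuclear_receptors = "nuclear_receptors.tsv"
  )
  path <- system.file("extdata", fname, package = "y1hscreen",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Headline screen report from a hit matrix and annotations
#'
#' One-call wrapper reproducing the screen's summary numbers: expands the
#' hit matrix, summarizes per-TF and per-species counts, and integrates the
#' RNAi phenotype table.
#'
#' @param hitMatrix TF-by-species fragment-count data.frame (default: the
#'   bundled fixture).
#' @param rnaiTable RNAi phenotype data.frame (default: bundled fixture).
#' @param nrAnnotation nuclear-receptor annotation (default: bundled
#'   fixture).
#' @return list with \code{profiles}, \code{summary} (including
#'   \code{n_overlap_rnai}), \code{overlap} and the annotated \code{table}.
#' @examples
#' rep <- screenReport()
#' rep$summary$n_tfs_hit          # 45
#' rep$summary$n_overlap_rnai     # 9
#' @export
screenReport <- function(hitMatrix = readScreenFixture("hits"),
                         rnaiTable = readScreenFixture("rnai"),
                         nrAnnotation = readScreenFixture("nuclear_receptors")) {
  ex <- expandHitMatrix(hitMatrix)
  sh <- summarizeHits(ex$calls, ex$baitSpecies, nrAnnotation = nrAnnotation)
  ri <- integrateRnai(sh$profiles, rnaiTable)
  summary <- sh$summary
  summary$n_overlap_rnai <- ri$n_overlap
  list(profiles = sh$profiles, summary = summary,
       overlap = ri$overlap, table = ri$table)
}
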