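## Three-stage apoptosis classification, the Casp3 intensity threshold for
## late events, debris filtering, and population attribution.

#' Stage an apoptotic event from morphology flags and Casp3 pattern
#'
#' Deterministic decision table over nuclear morphology and the Casp3
#' staining pattern:
#' \itemize{
#'   \item early: intact nucleus surrounded by cytoplasmic Casp3;
#'   \item mid: nuclear membrane disintegration, Casp3 overlapping the
#'     nucleus, chromatin granules;
#'   \item late: reduced nuclear size with fully compacted chromatin.
#' }
#' Flag combinations matching no stage, or more than one, are
#' unclassifiable (`NA`, for curation).
#'
#' @param flags data frame with logical columns `nucleus_intact`,
#'   `membrane_disintegrated`, `chromatin_granules`, `chromatin_compacted`,
#'   `reduced_size` and character `casp3_pattern`
#'   (`"cytoplasmic"`/`"nuclear"`).
#' @return character vector of stages (`"early"`, `"mid"`, `"late"`, or
#'   `NA` for unclassifiable).
#' @export
stage_from_features <- function(flags) {
  f <- as.data.frame(flags)
  need <- c("nucleus_intact", "membrane_disintegrated", "chromatin_granules",
            "chromatin_compacted", "reduced_size", "casp3_pattern")
  check_that(all(need %in% names(f)), "incomplete morphology flags")
  early <- f$nucleus_intact & f$casp3_pattern == "cytoplasmic" &
    !f$membrane_disintegrated & !f$chromatin_compacted & !f$reduced_size
  mid <- f$membrane_disintegrated & f$chromatin_granules &
    f$casp3_pattern == "nuclear" & !f$nucleus_intact & !f$reduced_size
  late <- f$reduced_size & f$chromatin_compacted & !f$nucleus_intact &
    !f$membrane_disintegrated
  nmatch <- early + mid + late
  out <- rep(NA_character_, nrow(f))
  out[early & nmatch == 1] <- "early"
  out[mid & nmatch == 1] <- "mid"
  out[late & nmatch == 1] <- "late"
  out
}

#' Casp3 intensity threshold for late-event validation
#'
#' The 90th percentile (type-7 interpolation) of the mean Casp3 signal
#' measured in early apoptotic events.
#'
#' @param early_casp3 Casp3 means of early events (>= 10 values).
#' @param probs percentile (default 0.9).
#' @return intensity threshold.
#' @export
casp3_threshold <- function(early_casp3, probs = 0.9) {
  check_that(length(early_casp3) >= 10,
             "need at least 10 early events for the Casp3 threshold")
  stats::quantile(early_casp3, probs, type = 7, names = FALSE)
}

#' Separate validated late apoptotic events from debris
#'
#' Candidates are kept when their Casp3 mean strictly exceeds the threshold
#' from [casp3_threshold()] AND their area lies above a debris size cut
#' obtained by the same KDE bandwidth-scan rule used for cell validation
#' ([estimate_min_area_threshold()]); everything else is labelled debris.
#'
#' @param candidates data frame with `casp3_mean` and `area` columns.
#' @param casp3_thr intensity threshold.
#' @param area_cut debris size cut, µm²; if `NULL`, estimated from the
#'   candidate areas by KDE (falling back to `fallback_area` when the
#'   distribution is not separably bimodal).
#' @param fallback_area constant debris cut used if the KDE rule finds no
#'   threshold; `NULL` propagates the error.
#' @return list: `kept`, `debris` (row subsets of `candidates`),
#'   `area_cut`, `casp3_thr`.
#' @export
filter_late_candidates <- function(candidates, casp3_thr, area_cut = NULL,
                                   fallback_area = NULL) {
  if (is.null(area_cut)) {
    area_cut <- tryCatch(
      estimate_min_area_threshold(candidates$area)$min_area,
      gastrucomp_no_threshold = function(e) {
        if (is.null(fallback_area)) stop(e)
        fallback_area
      })
  }
  keep <- candidates$casp3_mean > casp3_thr & candidates$area > area_cut
  list(kept = candidates[keep, , drop = FALSE],
       debris = candidates[!keep, , drop = FALSE],
       area_cut = area_cut, casp3_thr = casp3_thr)
}

#' Attribute apoptotic events to a population by normalised fluorescence
#'
#' Each event's nuclear mean in the mCherry and emiRFP channels is divided
#' by that channel's robust scale -- the median of the channel over viable
#' cells of the owning population -- and the event is assigned to the
#' channel with the larger normalised value. Ties are left unassigned and
#' flagged.
#'
#' @param events data frame with `mcherry_mean` and `emirfp_mean`.
#' @param viable_cells viable cell table with `population` and per-channel
#'   levels/means (columns containing `mcherry` and `emirfp`).
#' @return list: `population` (character, `NA` on tie), `tied` (logical),
#'   `scales` (the two normalisation medians).
#' @export
assign_event_population <- function(events, viable_cells) {
  mc_col <- grep("mcherry", names(viable_cells), value = TRUE)[1]
  em_col <- grep("emirfp", names(viable_cells), value = TRUE)[1]
  check_that(!is.na(mc_col) && !is.na(em_col),
             "viable_cells must carry mCherry and emiRFP intensities")
  s_mch <- stats::median(
    viable_cells[[mc_col]][viable_cells$population == "mCherry"])
  s_emi <- stats::median(
    viable_cells[[em_col]][viable_cells$population == "emiRFP"])
  check_that(is.finite(s_mch) && is.finite(s_emi) && s_mch > 0 && s_emi > 0,
             "cannot form normalisation scales from viable cells")
  nm <- events$mcherry_mean / s_mch
  ne <- events$emirfp_mean / s_emi
  tied <- nm == ne
  pop <- ifelse(nm > ne, "mCherry", "emiRFP")
  pop[tied] <- NA_character_
  list(population = pop, tied = tied, scales = c(mCherry = s_mch,
                                                 emiRFP = s_emi))
}
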