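#' Regional per-hemisphere spindle power
#'
#' Mean of the per-event mean powers over one derivation's events in one
#' frequency band. Returns `NA` (with a reason attribute) when the
#' derivation has no events in that band or was excluded.
#'
#' @param events a `spindle_events` data frame for one subject.
#' @param region region name (`FC`, `FT`, `CT`, `CO`, `TO`).
#' @param band `"full"`, `"slow"` or `"fast"`.
#' @param side `"left"` or `"right"`.
#' @param regions region map, see [region_map()].
#' @param excluded derivations excluded as bad.
#' @return mean power in microvolts squared, or `NA`.
#' @export
regional_band_power <- function(events, region, band, side,
                                regions = region_map(),
                                excluded = character(0)) {
  assert_that(region %in% names(regions), "parameter",
              sprintf("unknown region '%s'", region))
  assert_that(band %in% c("full", "slow", "fast"), "parameter",
              sprintf("unknown band '%s'", band))
  assert_that(side %in% c("left", "right"), "parameter",
              sprintf("side must be 'left' or 'right'"))
  deriv <- regions[[region]][if (side == "left") 1L else 2L]
  if (deriv %in% excluded) {
    return(structure(NA_real_, reason = "excluded channel"))
  }
  sel <- events$derivation == deriv
  if (band != "full") sel <- sel & events$band == band
  if (!any(sel)) return(structure(NA_real_, reason = "no events"))
  mean(events$mean_power_uv2[sel])
}

#' Spindle power asymmetry ratio
#'
#' SPA = P_lesioned / P_non-lesioned. A value of 1 means interhemispheric
#' symmetry; values below 1 mean weaker spindles over the lesioned
#' hemisphere.
#'
#' @param power_lesioned,power_nonlesioned mean spindle powers in microvolts
#'   squared; `NA` propagates.
#' @return dimensionless ratio, or `NA`.
#' @export
compute_spa <- function(power_lesioned, power_nonlesioned) {
  if (is.na(power_lesioned) || is.na(power_nonlesioned)) return(NA_real_)
  assert_that(power_lesioned > 0 && power_nonlesioned > 0, "domain",
              "spindle powers must be positive")
  power_lesioned / power_nonlesioned
}

#' The 15 SPA indexes for one subject
#'
#' Computes the lesioned/non-lesioned power ratio for each of the five
#' regions and three bands. The lesioned hemisphere is taken from metadata:
#' for a left-sided lesion the numerator comes from left-hemisphere
#' derivations, for a right-sided lesion from right-hemisphere derivations.
#'
#' @param events a `spindle_events` data frame for one subject.
#' @param lesion_side `"left"` or `"right"`.
#' @param subject_id subject identifier.
#' @param regions region map.
#' @param excluded derivations excluded as bad.
#' @return object of class `spa_index_set`: list with `subject_id`,
#'   `lesion_side`, `spa` (named numeric vector of 15 `<region>_<band>_SPA`
#'   values, `NA` where missing) and `reasons` (named character vector for
#'   the missing entries).
#' @export
spa_indexes <- function(events, lesion_side, subject_id = NULL,
                        regions = region_map(), excluded = character(0)) {
  assert_that(lesion_side %in% c("left", "right"), "parameter",
              "lesion_side must be 'left' or 'right'")
  if (is.null(subject_id)) {
    subject_id <- if (nrow(events)) events$subject_id[1] else "unknown"
  }
  les <- lesion_side
  non <- if (les == "left") "right" else "left"
  bands <- c("full", "slow", "fast")
  spa <- numeric(0)
  reasons <- character(0)
  for (r in names(regions)) {
    for (b in bands) {
      p_les <- regional_band_power(events, r, b, les, regions, excluded)
      p_non <- regional_band_power(events, r, b, non, regions, excluded)
      v <- compute_spa(p_les, p_non)
      key <- paste(r, b, "SPA", sep = "_")
      spa[key] <- v
      if (is.na(v)) {
        reasons[key] <- paste(c(attr(p_les, "reason"), attr(p_non, "reason")),
                              collapse = "; ")
      }
    }
  }
  structure(list(subject_id = subject_id, lesion_side = lesion_side,
                 spa = spa, reasons = reasons),
            class = "spa_index_set")
}

#' @export
print.spa_index_set <- function(x, ...) {
  cat(sprintf("<spa_index_set> %s (lesion: %s)\n", x$subject_id, x$lesion_side))
  print(round(x$spa, 3))
  invisible(x)
}

#' Cohort SPA table
#'
#' One row per subject: the 15 SPA columns plus lesion side and outcome.
#'
#' @param index_sets list of [spa_indexes()] results.
#' @param outcomes named character vector mapping subject id to outcome
#'   (`"UCP"` or `"typical"`), or `NA` to omit.
#' @return data frame with columns `subject_id`, `lesion_side`, `outcome`
#'   and the 15 `<region>_<band>_SPA` columns.
#' @export
spa_table <- function(index_sets, outcomes = NULL) {
  assert_that(length(index_sets) >= 1, "parameter", "need at least 1 subject")
  ids <- vapply(index_sets, function(s) s$subject_id, character(1))
  assert_that(!anyDuplicated(ids), "validation",
              sprintf("duplicate subject_id: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  spa <- do.call(rbind, lapply(index_sets, function(s) s$spa))
  out <- data.frame(subject_id = ids,
                    lesion_side = vapply(index_sets, function(s) s$lesion_side,
                                         character(1)),
                    outcome = if (is.null(outcomes)) NA_character_
                              else unname(outcomes[ids]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(spa))
}

#' Names of the 15 SPA index columns
#' @return character vector in region-major order.
#' @export
spa_index_names <- function() {
  as.vector(t(outer(names(region_map()), c("full", "slow", "fast"),
                    function(r, b) paste(r, b, "SPA", sep = "_"))))
}
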