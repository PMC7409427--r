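.artefact_flags <- c("banding", "blink", "vessel_doubling", "stretching",
                     "out_of_window", "crisscross")

#' Apply image-quality and artefact exclusions to a cohort roster
#'
#' An eye is excluded iff its image score is below 50, or any of the six
#' named artefacts (banding, blink, vessel doubling, stretching, out of
#' window, crisscross) is flagged, or it has two or more motion artefacts
#' wider than the primary branch vein diameter. Exactly one reason is logged
#' per eye, prioritised in that order; roster order is preserved.
#'
#' @param roster Data.frame with columns `eye_id`, `image_score`,
#'   `flag_banding` ... `flag_crisscross` (logical) and
#'   `wide_motion_artefact_count`.
#' @return A list with `included` and `excluded` (row subsets of the
#'   roster) and `log` (data.frame `eye_id`, `included`, `reason`).
#' @export
apply_exclusions <- function(roster) {
  if (!is.data.frame(roster) || nrow(roster) == 0) {
    stop("`roster` must be a non-empty data.frame", call. = FALSE)
  }
  needed <- c("eye_id", "image_score", paste0("flag_", .artefact_flags),
              "wide_motion_artefact_count")
  missing_cols <- setdiff(needed, names(roster))
  if (length(missing_cols)) {
    stop("roster is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(roster))
  low <- roster$image_score < 50
  reason[low] <- "image_score_below_50"
  for (fl in .artefact_flags) {
    hit <- is.na(reason) & roster[[paste0("flag_", fl)]]
    reason[hit] <- paste0("artefact_", fl)
  }
  hit <- is.na(reason) & roster$wide_motion_artefact_count >= 2
  reason[hit] <- "wide_motion_artefacts_ge_2"

  included <- is.na(reason)
  list(
    included = roster[included, , drop = FALSE],
    excluded = roster[!included, , drop = FALSE],
    log = data.frame(eye_id = roster$eye_id, included = included,
                     reason = ifelse(included, "included", reason),
                     stringsAsFactors = FALSE)
  )
}
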