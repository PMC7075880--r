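# Composite 0-9 memory scoring -----------------------------------------------
#
# The memory test has three parts, each worth 0-3 points:
#   * item recognition: 6-point confidence scale, 1 = "very sure seen" ...
#     6 = "very sure not seen"; correct (old) responses earn 3/2/1 points for
#     confidence 1/2/3, "new" responses (4-6) and timeouts earn 0;
#   * associative recall: two raters score the written description 0 / 0.5 / 1;
#     the rater mean is multiplied by 3 so the part carries equal weight;
#   * associative recognition: 2AFC with a 6-point left/right confidence
#     scale; a correct side earns 3/2/1 points for the high/medium/low
#     confidence band, the wrong side or a timeout earns 0.
# Item recognition gates everything: without a correct "old" response the
# later phases never ran, so the trial scores 0 overall.

#' Score the item-recognition phase
#'
#' Converts 6-point recognition confidence into item points. For studied
#' (non-lure) objects, "old" responses earn confidence-weighted points
#' (confidence 1 -> 3, 2 -> 2, 3 -> 1); "new" responses (4-6) and timeouts
#' earn 0. For lures, an "old" response (confidence 1-3) is a false alarm:
#' it earns 0 memory points but carries pseudo-points 3/2/1 recording the
#' points it *would* have earned, which feed the guessing chance level.
#'
#' @param item_confidence Integer vector in 1..6, `NA` = timeout.
#' @param is_lure Logical vector, `TRUE` for lure objects.
#' @return A tibble with one row per input: `points` (0-3),
#'   `is_false_alarm`, and `fa_pseudo_points` (NA unless a false alarm).
#' @examples
#' score_item_recognition(c(1, 6, 2), is_lure = c(FALSE, FALSE, TRUE))
#' @export
score_item_recognition <- function(item_confidence, is_lure = FALSE) {
  n <- length(item_confidence)
  is_lure <- vctrs_recycle_flag(is_lure, n, "is_lure")
  check_confidence(item_confidence, "item_confidence")

  old_response <- !is.na(item_confidence) & item_confidence <= 3L
  conf_points <- ifelse(old_response, 4L - as.integer(item_confidence), 0L)

  tibble(
    points = ifelse(is_lure, 0L, conf_points),
    is_false_alarm = is_lure & old_response,
    fa_pseudo_points = ifelse(is_lure & old_response, conf_points, NA_integer_)
  )
}

#' Score the associative-recall phase
#'
#' Two independent raters score the written scene description as incorrect
#' (0), partly correct (0.5) or correct (1). The rater mean is multiplied by
#' 3 so recall carries the same weight as the recognition parts, giving
#' points in \{0, 0.75, 1.5, 2.25, 3\}. A missing rating (phase never
#' reached, or empty answer) scores 0.
#'
#' @param rater1,rater2 Numeric vectors with values in \{0, 0.5, 1\} or `NA`.
#' @return Numeric vector of recall points.
#' @examples
#' score_associative_recall(c(1, 0.5, 0), c(1, 1, 0))
#' @export
score_associative_recall <- function(rater1, rater2 = rater1) {
  check_rater(rater1, "rater1")
  check_rater(rater2, "rater2")
  r1 <- ifelse(is.na(rater1), 0, rater1)
  r2 <- ifelse(is.na(rater2), 0, rater2)
  3 * (r1 + r2) / 2
}

#' Score the associative-recognition phase
#'
#' The participant saw two scenes and rated which was indirectly associated
#' with the object on a 6-point scale: 1-3 express (high to low) confidence
#' in the *left* scene, 4-6 (low to high) confidence in the *right* scene.
#' A response on the correct side earns points by confidence band —
#' \{1,6\} -> 3, \{2,5\} -> 2, \{3,4\} -> 1 — and the wrong side or a
#' timeout earns 0.
#'
#' @param assoc_confidence Integer vector in 1..6, `NA` = timeout.
#' @param correct_side Character vector, `"left"` or `"right"`.
#' @return Integer vector of associative-recognition points (0-3).
#' @examples
#' score_associative_recognition(c(1, 4, 5), c("left", "left", "right"))
#' @export
score_associative_recognition <- function(assoc_confidence, correct_side) {
  n <- length(assoc_confidence)
  if (length(correct_side) == 1L) correct_side <- rep(correct_side, n)
  if (length(correct_side) != n) {
    abort_bad_arg("`correct_side` must have length 1 or %d.", n)
  }
  check_confidence(assoc_confidence, "assoc_confidence")
  bad_side <- !is.na(correct_side) & !correct_side %in% c("left", "right")
  if (any(bad_side)) {
    abort_bad_arg(
      "`correct_side` must be \"left\" or \"right\" (row %d).",
      which(bad_side)[1]
    )
  }

  chosen <- ifelse(is.na(assoc_confidence), NA_character_,
    ifelse(assoc_confidence <= 3L, "left", "right")
  )
  # distance from the scale ends: 1 and 6 are the confident extremes
  band_points <- ifelse(assoc_confidence <= 3L,
    4L - as.integer(assoc_confidence), # 1,2,3 -> 3,2,1
    as.integer(assoc_confidence) - 3L  # 4,5,6 -> 1,2,3
  )
  out <- ifelse(!is.na(chosen) & chosen == correct_side, band_points, 0L)
  as.integer(out)
}

#' Score memory-test trials into the 0-9 composite memory score
#'
#' Applies the three phase-scoring rules to a table of studied (non-lure)
#' test trials and sums them into the composite memory score. Item
#' recognition gates the total: if item points are 0 (miss, "new" response,
#' or timeout) the later phases never took place, so recall and
#' associative-recognition points are forced to 0 and the trial scores 0.
#'
#' @param test_trials A data frame of memory-test trials with columns
#'   `participant_id`, `triad_id`, `item_confidence`, `recall_rater1`,
#'   `recall_rater2`, `assoc_confidence`, `assoc_correct_side`, and
#'   optionally `is_lure` (lure rows are rejected: lures carry no memory
#'   points and are scored by [score_item_recognition()] alone).
#' @return A tibble of scored trials: `participant_id`, `triad_id`,
#'   `item_points`, `recall_points`, `assoc_points`, `memory_score`.
#' @seealso [score_item_recognition()], [score_associative_recall()],
#'   [score_associative_recognition()], [attach_conditions()]
#' @examples
#' trials <- tibble::tibble(
#'   participant_id = "p1", triad_id = 1:2,
#'   item_confidence = c(1L, 2L),
#'   recall_rater1 = c(0, 1), recall_rater2 = c(0, 1),
#'   assoc_confidence = c(3L, 2L), assoc_correct_side = "left"
#' )
#' score_trials(trials)
#' @export
score_trials <- function(test_trials) {
  check_columns(test_trials, c(
    "participant_id", "triad_id", "item_confidence",
    "recall_rater1", "recall_rater2", "assoc_confidence",
    "assoc_correct_side"
  ), "test_trials")
  if ("is_lure" %in% names(test_trials) && any(test_trials$is_lure)) {
    abort_bad_arg(
      "`test_trials` contains %d lure row(s); lures earn no memory points. Score them with score_item_recognition() and drop them here.",
      sum(test_trials$is_lure)
    )
  }

  item <- score_item_recognition(test_trials$item_confidence, is_lure = FALSE)
  recall <- score_associative_recall(
    test_trials$recall_rater1, test_trials$recall_rater2
  )
  assoc <- score_associative_recognition(
    test_trials$assoc_confidence, test_trials$assoc_correct_side
  )

  gate <- item$points > 0L
  tibble(
    participant_id = test_trials$participant_id,
    triad_id = test_trials$triad_id,
    item_points = item$points,
    recall_points = ifelse(gate, recall, 0),
    assoc_points = ifelse(gate, assoc, 0L),
  ) |>
    mutate(memory_score = .data$item_points + .data$recall_points +
      .data$assoc_points)
}

#' Score lure trials for false alarms
#'
#' @param test_trials A data frame with `participant_id`, `item_confidence`
#'   and `is_lure`; only lure rows are used.
#' @return A tibble with one row per lure: `participant_id`,
#'   `is_false_alarm`, `fa_pseudo_points`.
#' @export
score_lures <- function(test_trials) {
  check_columns(
    test_trials, c("participant_id", "item_confidence", "is_lure"),
    "test_trials"
  )
  lures <- dplyr::filter(test_trials, .data$is_lure)
  scored <- score_item_recognition(lures$item_confidence, is_lure = TRUE)
  tibble(
    participant_id = lures$participant_id,
    is_false_alarm = scored$is_false_alarm,
    fa_pseudo_points = scored$fa_pseudo_points
  )
}

#' Attach congruency bins and reactivation levels to scored trials
#'
#' Joins post-hoc congruency ratings (binned with [bin_congruency()]) and
#' the encoding-phase reactivation report onto scored trials, keyed by
#' participant and triad. Trials without a rating or without a reactivation
#' button press keep `NA` in the respective column; condition analyses drop
#' them downstream.
#'
#' @param scored Output of [score_trials()].
#' @param ratings Data frame with `participant_id`, `triad_id`, `rating`
#'   (1-5).
#' @param encoding Data frame with `participant_id`, `triad_id`,
#'   `reactivation_response` (1 = none, 2 = a bit, 3 = strong, `NA` =
#'   timeout). Optional.
#' @return `scored` with `congruency_bin` and (if `encoding` is given)
#'   `reactivation_level` columns added.
#' @export
attach_conditions <- function(scored, ratings = NULL, encoding = NULL) {
  out <- as_tibble(scored)
  if (!is.null(ratings)) {
    check_columns(ratings, c("participant_id", "triad_id", "rating"), "ratings")
    out <- left_join(
      out,
      ratings |>
        mutate(congruency_bin = bin_congruency(.data$rating)) |>
        select("participant_id", "triad_id", "congruency_bin"),
      by = c("participant_id", "triad_id")
    )
  }
  if (!is.null(encoding)) {
    check_columns(
      encoding, c("participant_id", "triad_id", "reactivation_response"),
      "encoding"
    )
    out <- left_join(
      out,
      encoding |>
        select("participant_id", "triad_id",
          reactivation_level = "reactivation_response"
        ),
      by = c("participant_id", "triad_id")
    )
  }
  out
}

# validation helpers ----------------------------------------------------------

check_confidence <- function(x, what) {
  bad <- !is.na(x) & (x < 1 | x > 6 | x != round(x))
  if (any(bad)) {
    abort_bad_arg(
      "`%s` must be an integer in 1..6 or NA; found %s at position %d.",
      what, format(x[bad][1]), which(bad)[1]
    )
  }
  invisible(x)
}

check_rater <- function(x, what) {
  bad <- !is.na(x) & !x %in% c(0, 0.5, 1)
  if (any(bad)) {
    abort_bad_arg(
      "`%s` must be 0, 0.5 or 1 (or NA); found %s at position %d.",
      what, format(x[bad][1]), which(bad)[1]
    )
  }
  invisible(x)
}

vctrs_recycle_flag <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) abort_bad_arg("`%s` must have length 1 or %d.", what, n)
  x
}
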