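# ggplot2 result figures -------------------------------------------------------

#' Plot condition cell means with between-participant error bars
#'
#' The behavioral-results figure: mean of the per-participant cell means
#' per congruency bin x reactivation level, error bars = SEM across
#' participants, individual participants as jittered dots.
#'
#' @param cond_table Output of [condition_summary()].
#' @param ylab Axis label, default "Memory score".
#' @return A ggplot object.
#' @export
plot_condition_means <- function(cond_table, ylab = "Memory score") {
  check_columns(
    cond_table,
    c("participant_id", "congruency_bin", "reactivation_level", "mean"),
    "cond_table"
  )
  cells <- cond_table |>
    dplyr::filter(!is.na(.data$mean)) |>
    mutate(reactivation = factor(.data$reactivation_level,
      levels = 1:3, labels = c("none", "a bit", "strong")))
  summary <- cells |>
    group_by(.data$congruency_bin, .data$reactivation) |>
    summarise(
      m = mean(.data$mean),
      sem = sd(.data$mean) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$reactivation, y = .data$m,
    fill = .data$congruency_bin, group = .data$congruency_bin
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$sem, ymax = .data$m + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::geom_point(
      data = cells,
      ggplot2::aes(y = .data$mean, group = .data$congruency_bin),
      position = ggplot2::position_jitterdodge(
        jitter.width = 0.15, dodge.width = 0.8
      ),
      alpha = 0.4, size = 0.8, show.legend = FALSE
    ) +
    ggplot2::labs(
      x = "Reactivation", y = ylab, fill = "Congruency"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null distribution of decoding accuracy
#'
#' Histogram of null cross-validation accuracies with the observed
#' accuracy marked.
#'
#' @param decoder A `scene_decoder` from [train_reinstatement_decoder()],
#'   or the list returned by [permutation_test()].
#' @return A ggplot object.
#' @export
plot_permutation_null <- function(decoder) {
  null_acc <- decoder$null_accuracies
  observed <- decoder$observed %||% decoder$cv_accuracy
  if (length(null_acc) == 0) {
    abort_bad_arg("No null accuracies; run the permutation test first.")
  }
  ggplot2::ggplot(tibble(accuracy = null_acc), ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = observed, color = "red",
      linetype = "dashed") +
    ggplot2::labs(
      x = "Null CV accuracy", y = "Permutations",
      title = sprintf("Observed accuracy %.3f", observed)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot rm_anova
#' @export
autoplot.rm_anova <- function(object, ...) {
  plot_condition_means(object$cells |>
    rename(congruency_bin = "congruency",
      reactivation_level = "reactivation") |>
    mutate(reactivation_level = as.integer(as.character(
      .data$reactivation_level))), ...)
}

#' @method autoplot scene_decoder
#' @export
autoplot.scene_decoder <- function(object, ...) {
  plot_permutation_null(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
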