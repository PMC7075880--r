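# broom-style tidiers ----------------------------------------------------------

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object from [rm_anova_2x3()].
#' @param ... Unused.
#' @return A tibble with one row per effect: `term`, `statistic` (F),
#'   `df1`, `df2`, `p.value`, `pes` (partial eta squared).
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  x$effects |>
    rename(statistic = "F", p.value = "p_value")
}

#' @rdname tidy.rm_anova
#' @return For `glance()`: a one-row tibble with `n`, `n_dropped`,
#'   `correction`.
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n = x$n, n_dropped = length(x$dropped), correction = x$correction)
}

#' Tidy a trained reinstatement decoder
#'
#' @param x A `scene_decoder` object from [train_reinstatement_decoder()].
#' @param ... Unused.
#' @return A tibble with one row per cross-validation fold: `fold`,
#'   `accuracy`.
#' @method tidy scene_decoder
#' @export
tidy.scene_decoder <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracies), accuracy = x$fold_accuracies)
}

#' @rdname tidy.scene_decoder
#' @return For `glance()`: one row with `cv_accuracy`, `permutation_p`,
#'   `n_permutations`, `n_scans`, `k_features`.
#' @method glance scene_decoder
#' @export
glance.scene_decoder <- function(x, ...) {
  tibble(
    cv_accuracy = x$cv_accuracy,
    permutation_p = x$permutation_p,
    n_permutations = length(x$null_accuracies),
    n_scans = nrow(x$selection),
    k_features = length(x$features)
  )
}

#' Tidy a guessing profile
#'
#' @param x A [guessing_profile()].
#' @param ... Unused.
#' @return A tibble of the conditional point distributions: `x` (item
#'   points), `y` (associative points), `p` (probability of the pair given
#'   a false alarm).
#' @method tidy guessing_profile
#' @export
tidy.guessing_profile <- function(x, ...) {
  grid <- tidyr::expand_grid(x_points = 1:3, y_points = 0:3)
  grid |>
    mutate(p = purrr::map2_dbl(.data$x_points, .data$y_points, function(i, j) {
      if (x$degenerate) 0 else x$p_x_given_fa[i] * x$p_y_given_fa_x[i, j + 1]
    }))
}

#' @rdname tidy.guessing_profile
#' @return For `glance()`: one row with `p_fa`, `chance_level`,
#'   `degenerate`.
#' @method glance guessing_profile
#' @export
glance.guessing_profile <- function(x, ...) {
  tibble(
    p_fa = x$p_fa,
    chance_level = chance_level_eq1(x),
    degenerate = x$degenerate
  )
}
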