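# Condition binning, exclusions, one-sample tests, 2x3 RM-ANOVA --------------

#' Bin post-hoc congruency ratings
#'
#' Ratings of how well scene and object fit together (1 = very incongruent
#' ... 5 = very congruent) are collapsed into analysis bins: 1-2 ->
#' incongruent, 4-5 -> congruent. A rating of 3 expresses indifference and
#' is excluded from condition analyses.
#'
#' @param rating Integer vector in 1..5.
#' @return A factor with levels `incongruent`, `excluded`, `congruent`.
#' @examples
#' bin_congruency(1:5)
#' @export
bin_congruency <- function(rating) {
  bad <- !is.na(rating) & (rating < 1 | rating > 5 | rating != round(rating))
  if (any(bad)) {
    abort_bad_arg(
      "`rating` must be an integer in 1..5; found %s at position %d.",
      format(rating[bad][1]), which(bad)[1]
    )
  }
  cut(as.numeric(rating),
    breaks = c(0.5, 2.5, 3.5, 5.5),
    labels = c("incongruent", "excluded", "congruent")
  )
}

#' Per-participant condition cell summary
#'
#' Builds the participant x (congruency bin x reactivation level) table of
#' cell means and trial counts that the one-sample tests and the
#' repeated-measures ANOVA consume. Trials with an excluded congruency
#' rating (a "3"), no rating, or a missing reactivation report are dropped.
#' The grid is completed: cells a participant never filled appear with
#' `n = 0` and `NA` mean, so downstream listwise deletion can see them.
#'
#' @param scored Scored trials carrying `congruency_bin` and
#'   `reactivation_level` (see [attach_conditions()]).
#' @param value Column to average, default `"memory_score"`. Use
#'   `"recall_points"` for a cued-recall-only analysis, or a decoded
#'   probability column.
#' @return A tibble with `participant_id`, `congruency_bin` (factor:
#'   incongruent/congruent), `reactivation_level` (1/2/3), `mean`, `n`.
#' @export
condition_summary <- function(scored, value = "memory_score") {
  check_columns(
    scored,
    c("participant_id", "congruency_bin", "reactivation_level", value),
    "scored"
  )
  kept <- scored |>
    dplyr::filter(
      !is.na(.data$congruency_bin),
      .data$congruency_bin != "excluded",
      .data$reactivation_level %in% 1:3
    )
  cells <- kept |>
    mutate(
      congruency_bin = factor(.data$congruency_bin,
        levels = c("incongruent", "congruent")
      ),
      reactivation_level = as.integer(.data$reactivation_level)
    ) |>
    group_by(.data$participant_id, .data$congruency_bin,
      .data$reactivation_level) |>
    summarise(
      mean = mean(.data[[value]]),
      n = dplyr::n(),
      .groups = "drop"
    )
  # complete the 2 x 3 grid per participant
  grid <- tidyr::expand_grid(
    participant_id = unique(scored$participant_id),
    congruency_bin = factor(c("incongruent", "congruent"),
      levels = c("incongruent", "congruent")
    ),
    reactivation_level = 1:3
  )
  left_join(grid, cells,
    by = c("participant_id", "congruency_bin", "reactivation_level")
  ) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Apply the low-trial-count participant exclusion rule
#'
#' A participant is excluded when any analyzed condition cell (congruency
#' bin x reactivation level) holds fewer than `min_trials` trials.
#'
#' @param cond_table Output of [condition_summary()].
#' @param min_trials Minimum trials per cell; the default 10 excludes
#'   participants with any cell below 10.
#' @return A list with `included` (character vector of participant ids),
#'   `excluded` (ditto) and `report` (tibble of offending cells:
#'   `participant_id`, `congruency_bin`, `reactivation_level`, `n`).
#' @export
apply_exclusions <- function(cond_table, min_trials = 10) {
  check_columns(
    cond_table,
    c("participant_id", "congruency_bin", "reactivation_level", "n"),
    "cond_table"
  )
  report <- cond_table |>
    dplyr::filter(.data$n < min_trials) |>
    select("participant_id", "congruency_bin", "reactivation_level", "n") |>
    arrange(.data$participant_id)
  excluded <- unique(report$participant_id)
  included <- setdiff(unique(cond_table$participant_id), excluded)
  list(included = included, excluded = excluded, report = report)
}

#' One-sample t-test against a fixed chance level
#'
#' Two-tailed one-sample t-test of per-participant means against a null
#' value (typically the analytic guessing chance level). Two effect sizes
#' are reported: `cohens_d = (mean - null) / sd`, the standard one-sample
#' definition, and `d_vs_zero = mean / sd`, the mean in standard-deviation
#' units ignoring the null.
#'
#' @param values Numeric vector of per-participant means (length >= 2).
#' @param null The chance level to test against (default 0).
#' @return A one-row tibble: `n`, `mean`, `sd`, `t`, `df`, `p_value`,
#'   `cohens_d`, `d_vs_zero`.
#' @examples
#' one_sample_test(c(3.2, 4.1, 3.8, 4.4), null = 0.68)
#' @export
one_sample_test <- function(values, null = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort_bad_arg("`values` must contain at least 2 non-NA values.")
  s <- sd(values)
  if (s == 0) abort_bad_arg("`values` has zero variance; t is undefined.")
  m <- mean(values)
  t_stat <- (m - null) / (s / sqrt(n))
  df <- n - 1L
  tibble(
    n = n, mean = m, sd = s,
    t = t_stat, df = df,
    p_value = 2 * pt(abs(t_stat), df, lower.tail = FALSE),
    cohens_d = (m - null) / s,
    d_vs_zero = m / s
  )
}

#' Two-by-three repeated-measures ANOVA
#'
#' Within-subject ANOVA of cell means with factors congruency (2 levels)
#' and reactivation (3 levels), their interaction, and per-effect error
#' strata (subject x factor). Participants missing any of the six cells
#' are dropped listwise. Effect size is partial eta squared,
#' SS_effect / (SS_effect + SS_error).
#'
#' No sphericity correction is applied by default;
#' `correction = "greenhouse-geisser"` adjusts the reactivation and
#' interaction tests by the Greenhouse-Geisser epsilon.
#'
#' @param cond_table Output of [condition_summary()] (column `mean` is the
#'   dependent variable).
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return An object of class `rm_anova`; see [tidy.rm_anova()]. Components:
#'   `effects` (tibble with term, F, dfs, p, partial eta squared), `n`
#'   (complete cases used), `dropped` (participants removed listwise),
#'   `cells` (the complete-case cell data).
#' @export
rm_anova_2x3 <- function(cond_table, correction = c("none", "greenhouse-geisser")) {
  correction <- match.arg(correction)
  check_columns(
    cond_table,
    c("participant_id", "congruency_bin", "reactivation_level", "mean"),
    "cond_table"
  )
  cells <- cond_table |>
    dplyr::filter(.data$congruency_bin != "excluded") |>
    mutate(
      congruency = droplevels(factor(.data$congruency_bin)),
      reactivation = factor(.data$reactivation_level),
      subject = factor(.data$participant_id)
    )
  complete <- cells |>
    group_by(.data$subject) |>
    dplyr::filter(sum(!is.na(.data$mean)) == 6L) |>
    ungroup()
  dropped <- setdiff(levels(cells$subject), unique(as.character(complete$subject)))
  n_complete <- length(unique(complete$subject))
  if (n_complete < 3) {
    abort_bad_arg(
      "Need >= 3 participants with all 6 cells; have %d.", n_complete
    )
  }
  complete$subject <- droplevels(complete$subject)

  fit <- aov(
    mean ~ congruency * reactivation +
      Error(subject / (congruency * reactivation)),
    data = complete
  )
  strata <- summary(fit)
  ss_scale <- max(sum((complete$mean - mean(complete$mean))^2), 1)
  effects <- purrr::map(
    c(
      congruency = "Error: subject:congruency",
      reactivation = "Error: subject:reactivation",
      interaction = "Error: subject:congruency:reactivation"
    ),
    function(nm) {
      tab <- strata[[nm]][[1]]
      ss <- tab[["Sum Sq"]]
      f_val <- tab[["F value"]][1]
      p_val <- tab[["Pr(>F)"]][1]
      pes <- ss[1] / (ss[1] + ss[2])
      # degenerate data (zero effect SS up to rounding): report a null effect
      if (!is.finite(f_val) || ss[1] <= 1e-12 * ss_scale) {
        f_val <- 0
        p_val <- 1
        pes <- 0
      }
      tibble(
        F = f_val,
        df1 = tab[["Df"]][1],
        df2 = tab[["Df"]][2],
        p_value = p_val,
        pes = pes
      )
    }
  ) |>
    list_rbind(names_to = "term")

  if (correction == "greenhouse-geisser") {
    effects <- gg_correct(effects, complete)
  }

  structure(
    list(
      effects = effects, n = n_complete, dropped = dropped,
      cells = complete, correction = correction
    ),
    class = "rm_anova"
  )
}

# Greenhouse-Geisser epsilon from the double-centered covariance of the
# within-factor cell matrix; applied to the factors with > 1 df.
gg_correct <- function(effects, complete) {
  eps_for <- function(wide) {
    S <- stats::cov(wide)
    k <- ncol(S)
    H <- diag(k) - matrix(1 / k, k, k)
    S <- H %*% S %*% H
    sum(diag(S))^2 / ((k - 1) * sum(S^2))
  }
  react_wide <- complete |>
    group_by(.data$subject, .data$reactivation) |>
    summarise(mean = mean(.data$mean), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "reactivation", values_from = "mean")
  eps_r <- eps_for(as.matrix(react_wide[-1]))
  inter_wide <- complete |>
    mutate(cell = interaction(.data$congruency, .data$reactivation)) |>
    select("subject", "cell", "mean") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "mean")
  eps_i <- eps_for(as.matrix(inter_wide[-1]))

  adjust <- function(row, eps) {
    row$p_value <- pf(row$F, eps * row$df1, eps * row$df2, lower.tail = FALSE)
    row
  }
  effects[effects$term == "reactivation", ] <-
    adjust(effects[effects$term == "reactivation", ], eps_r)
  effects[effects$term == "interaction", ] <-
    adjust(effects[effects$term == "interaction", ], min(eps_r, eps_i))
  effects
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "2x3 repeated-measures ANOVA (%d complete cases%s)\n", x$n,
    if (length(x$dropped)) {
      sprintf(", %d dropped listwise", length(x$dropped))
    } else {
      ""
    }
  ))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf(
      "  %-12s F(%d, %d) = %6.2f, p = %.4g, partial eta^2 = %.2f\n",
      e$term[i], e$df1[i], e$df2[i], e$F[i], e$p_value[i], e$pes[i]
    ))
  }
  invisible(x)
}
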