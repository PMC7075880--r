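# Analytic guessing chance level of the composite memory score ---------------
#
# A memory-free responder can only earn points through a false alarm at item
# recognition (endorsing a lure-like "old" response), followed by a lucky
# 2AFC guess at associative recognition; associative recall is assumed to
# contribute nothing. The expected score of such a responder is
#
#   C = p(FA) * sum_x p(x | FA) * ( x + 0.5 * sum_y p(y | FA & x) * y )
#
# where x in {1,2,3} are the item points implied by the false-alarm
# confidence, y in {0,..,3} the associative-recognition points given a
# chance response, and 0.5 the chance of guessing the correct side.

#' Construct a guessing profile
#'
#' Bundles the three ingredients of the analytic chance level: the
#' false-alarm rate on lures, the distribution of item pseudo-points given a
#' false alarm, and for each item-point level the distribution of
#' associative-recognition points given a chance response.
#'
#' @param p_fa False-alarm probability in \[0, 1\].
#' @param p_x_given_fa Numeric length-3 vector, probabilities of item points
#'   x = 1, 2, 3 given a false alarm. Must sum to 1 (unless `p_fa` = 0, in
#'   which case it may be all-`NA` to flag undefined conditionals).
#' @param p_y_given_fa_x 3 x 4 numeric matrix; row i is the distribution of
#'   associative points y = 0..3 given item points x = i. Rows must sum
#'   to 1 (again, may be `NA` when `p_fa` = 0).
#' @return An object of class `guessing_profile`.
#' @examples
#' guessing_profile(
#'   p_fa = 0.2,
#'   p_x_given_fa = c(0, 0, 1),
#'   p_y_given_fa_x = matrix(rep(c(0, 0, 0, 1), each = 3), nrow = 3)
#' )
#' @export
guessing_profile <- function(p_fa, p_x_given_fa, p_y_given_fa_x) {
  if (!is.numeric(p_fa) || length(p_fa) != 1L || is.na(p_fa) ||
    p_fa < 0 || p_fa > 1) {
    abort_bad_arg("`p_fa` must be a single probability in [0, 1].")
  }
  p_x_given_fa <- as.numeric(p_x_given_fa)
  if (length(p_x_given_fa) != 3L) {
    abort_bad_arg("`p_x_given_fa` must have length 3 (x = 1, 2, 3).")
  }
  p_y_given_fa_x <- as.matrix(p_y_given_fa_x)
  if (!all(dim(p_y_given_fa_x) == c(3L, 4L))) {
    abort_bad_arg("`p_y_given_fa_x` must be a 3 x 4 matrix (x = 1..3, y = 0..3).")
  }
  dimnames(p_y_given_fa_x) <- list(x = 1:3, y = 0:3)
  names(p_x_given_fa) <- 1:3

  degenerate <- p_fa == 0 && all(is.na(p_x_given_fa))
  if (!degenerate) {
    check_distribution(p_x_given_fa, "p_x_given_fa")
    for (i in 1:3) {
      check_distribution(p_y_given_fa_x[i, ], sprintf("p_y_given_fa_x[%d, ]", i))
    }
  }

  structure(
    list(
      p_fa = p_fa,
      p_x_given_fa = p_x_given_fa,
      p_y_given_fa_x = p_y_given_fa_x,
      degenerate = degenerate
    ),
    class = "guessing_profile"
  )
}

#' @export
print.guessing_profile <- function(x, ...) {
  cat("<guessing_profile>\n")
  cat(sprintf("  p(FA) = %.4f%s\n", x$p_fa,
    if (x$degenerate) " (no false alarms; conditionals undefined)" else ""
  ))
  if (!x$degenerate) {
    cat("  p(x | FA):", sprintf("%.3f", x$p_x_given_fa), "\n")
    cat("  E[y | FA & x]:",
      sprintf("%.3f", as.numeric(x$p_y_given_fa_x %*% (0:3))), "\n")
  }
  invisible(x)
}

#' Analytic chance level of the composite memory score
#'
#' Expected memory score of a responder with no memory, whose only route to
#' points is a false alarm at item recognition followed by a 50:50 guess at
#' the two-alternative associative recognition; associative recall is
#' assumed to contribute 0.
#'
#' @param profile A [guessing_profile()].
#' @return A single number, the expected guessing score in \[0, 9\]
#'   (in practice at most `p_fa * 4.5`).
#' @examples
#' p <- guessing_profile(0.2, c(0, 0, 1),
#'   matrix(rep(c(0, 0, 0, 1), each = 3), nrow = 3))
#' chance_level_eq1(p) # 0.2 * (3 + 0.5 * 3) = 0.9
#' @export
chance_level_eq1 <- function(profile) {
  stopifnot(inherits(profile, "guessing_profile"))
  if (profile$p_fa == 0) {
    return(0)
  }
  x <- 1:3
  y <- 0:3
  e_y_given_x <- as.numeric(profile$p_y_given_fa_x %*% y)
  profile$p_fa * sum(profile$p_x_given_fa * (x + 0.5 * e_y_given_x))
}

#' Monte-Carlo oracle for the guessing chance level
#'
#' Simulates a memory-free responder trial by trial: with probability
#' `p_fa` a false alarm occurs and item points x are drawn from
#' `p_x_given_fa`; with probability 0.5 the associative-recognition guess
#' lands on the correct side and y is drawn from `p_y_given_fa_x[x, ]`,
#' otherwise y = 0. The trial score is x + y. Serves as an independent
#' check of [chance_level_eq1()].
#'
#' @param profile A [guessing_profile()].
#' @param n_trials Number of simulated trials.
#' @param seed Optional integer seed for reproducibility.
#' @return The empirical mean guessing score.
#' @export
monte_carlo_guessing_chance <- function(profile, n_trials, seed = NULL) {
  stopifnot(inherits(profile, "guessing_profile"))
  if (!is.numeric(n_trials) || n_trials < 1) {
    abort_bad_arg("`n_trials` must be >= 1.")
  }
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)

  fa <- runif(n_trials) < profile$p_fa
  scores <- numeric(n_trials)
  n_fa <- sum(fa)
  if (n_fa > 0) {
    x <- sample.int(3L, n_fa, replace = TRUE, prob = profile$p_x_given_fa)
    correct_side <- runif(n_fa) < 0.5
    y <- integer(n_fa)
    for (xi in 1:3) {
      idx <- which(x == xi & correct_side)
      if (length(idx) > 0) {
        y[idx] <- sample(0:3, length(idx),
          replace = TRUE, prob = profile$p_y_given_fa_x[xi, ]
        )
      }
    }
    scores[fa] <- x + y
  }
  mean(scores)
}

#' Estimate a guessing profile from one participant's test data
#'
#' The false-alarm rate comes from lure trials (confidence 1-3 on a lure =
#' false alarm); the item-point distribution given a false alarm comes from
#' the pseudo-points implied by the false-alarm confidences; and the
#' conditional associative-point distributions come from the participant's
#' studied trials, as the empirical contingency of associative points (y)
#' against item points (x), row-normalized. False alarms have no
#' associative phase of their own, so the studied-trial contingency is the
#' available stand-in for "points given a chance response". Item-point
#' levels the participant never produced fall back to their marginal
#' associative-point distribution, keeping the chance level defined.
#'
#' @param test_trials One participant's memory-test table, including lure
#'   rows (`is_lure`, `item_confidence`).
#' @param scored The participant's scored studied trials from
#'   [score_trials()].
#' @return A [guessing_profile()]. With zero false alarms the profile is
#'   degenerate (`p_fa` = 0, conditionals `NA`) and the chance level is 0.
#' @export
estimate_guessing_profile <- function(test_trials, scored) {
  check_columns(test_trials, c("is_lure", "item_confidence"), "test_trials")
  check_columns(scored, c("item_points", "assoc_points"), "scored")
  lure_scores <- score_lures(
    mutate(test_trials,
      participant_id = if ("participant_id" %in% names(test_trials)) {
        .data$participant_id
      } else {
        "p"
      }
    )
  )
  n_lures <- nrow(lure_scores)
  if (n_lures == 0) {
    abort_bad_arg("`test_trials` contains no lures; p(FA) is inestimable.")
  }
  n_fa <- sum(lure_scores$is_false_alarm)
  p_fa <- n_fa / n_lures

  if (n_fa == 0) {
    return(guessing_profile(
      p_fa = 0,
      p_x_given_fa = rep(NA_real_, 3),
      p_y_given_fa_x = matrix(NA_real_, 3, 4)
    ))
  }

  pseudo <- lure_scores$fa_pseudo_points[lure_scores$is_false_alarm]
  p_x <- tabulate(pseudo, nbins = 3L) / n_fa

  # contingency of associative points given item points, from studied trials
  # that passed the item gate (x >= 1); y is rounded to the 0..3 grid only
  # for binning (recall points are not involved here, assoc points are ints)
  hits <- dplyr::filter(scored, .data$item_points >= 1L)
  marg_y <- if (nrow(hits) > 0) {
    tabulate(hits$assoc_points + 1L, nbins = 4L) / nrow(hits)
  } else {
    c(1, 0, 0, 0) # no hit trials at all: assume y = 0 under guessing
  }
  p_y <- matrix(NA_real_, 3, 4)
  for (xi in 1:3) {
    rows <- hits$assoc_points[hits$item_points == xi]
    p_y[xi, ] <- if (length(rows) > 0) {
      tabulate(rows + 1L, nbins = 4L) / length(rows)
    } else {
      marg_y
    }
  }
  guessing_profile(p_fa = p_fa, p_x_given_fa = p_x, p_y_given_fa_x = p_y)
}

#' Per-participant guessing profiles and chance levels
#'
#' Maps [estimate_guessing_profile()] over participants and evaluates the
#' analytic chance level for each.
#'
#' @param test_trials Memory-test table for all participants (studied and
#'   lure rows, `participant_id` column).
#' @param scored Scored studied trials from [score_trials()].
#' @return A tibble with `participant_id`, `profile` (list column of
#'   [guessing_profile()] objects), `p_fa`, and `chance_level`.
#' @export
estimate_guessing_profiles <- function(test_trials, scored) {
  check_columns(test_trials, "participant_id", "test_trials")
  ids <- unique(test_trials$participant_id)
  profiles <- map(ids, function(id) {
    estimate_guessing_profile(
      dplyr::filter(test_trials, .data$participant_id == id),
      dplyr::filter(scored, .data$participant_id == id)
    )
  })
  tibble(
    participant_id = ids,
    profile = profiles,
    p_fa = map_dbl(profiles, "p_fa"),
    chance_level = map_dbl(profiles, chance_level_eq1)
  )
}

#' Group-level chance level
#'
#' Aggregates per-participant chance levels. The default is the unweighted
#' arithmetic mean of the per-participant values; `method = "pooled"`
#' instead evaluates the formula once on pooled ingredients (mean
#' false-alarm rate, FA-weighted conditional distributions).
#'
#' @param profiles A list of [guessing_profile()] objects, or the tibble
#'   returned by [estimate_guessing_profiles()].
#' @param method `"mean"` (default) or `"pooled"`.
#' @return A single number, the group chance level.
#' @export
group_chance_level <- function(profiles, method = c("mean", "pooled")) {
  method <- match.arg(method)
  if (is.data.frame(profiles) && "profile" %in% names(profiles)) {
    profiles <- profiles$profile
  }
  if (length(profiles) == 0) {
    abort_bad_arg("`profiles` is empty; need at least one participant.")
  }
  stopifnot(all(map_lgl(profiles, inherits, "guessing_profile")))

  if (method == "mean") {
    return(mean(map_dbl(profiles, chance_level_eq1)))
  }

  p_fa <- map_dbl(profiles, "p_fa")
  w <- p_fa / sum(p_fa)
  if (all(p_fa == 0)) {
    return(0)
  }
  p_x <- Reduce(`+`, imap(profiles, function(p, i) {
    if (p$degenerate) matrix(0, 1, 3) else w[i] * rbind(p$p_x_given_fa)
  }))
  p_y <- Reduce(`+`, imap(profiles, function(p, i) {
    if (p$degenerate) matrix(0, 3, 4) else w[i] * p$p_y_given_fa_x
  }))
  # renormalize rows in case degenerate participants contributed zeros
  p_x <- as.numeric(p_x / sum(p_x))
  p_y <- p_y / rowSums(p_y)
  chance_level_eq1(
    guessing_profile(mean(p_fa), p_x, p_y)
  )
}

check_distribution <- function(p, what) {
  if (anyNA(p)) abort_bad_arg("`%s` contains NA.", what)
  if (any(p < 0 | p > 1)) {
    abort_bad_arg("`%s` has probabilities outside [0, 1].", what)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort_bad_arg("`%s` must sum to 1 (got %.12f).", what, sum(p))
  }
  invisible(p)
}
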