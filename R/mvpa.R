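# Scene-vs-face reinstatement decoding ---------------------------------------
#
# Pipeline: per-run temporal preprocessing (discrete-cosine high-pass +
# voxelwise z-scoring), selection of localizer training volumes at fixed TR
# offsets after block onset, top-K ANOVA-F feature selection, L2-regularized
# linear logistic classification under leave-one-chunk-out cross-validation,
# chunk-level permutation inference, and per-trial scene-probability
# decoding of encoding events.

#' Decoder configuration
#'
#' @param k_features Number of voxels kept by ANOVA-F feature selection
#'   (default 250).
#' @param n_chunks Number of cross-validation chunks (default 20).
#' @param chunk_size Scans per chunk (default 2: one scan of each class).
#' @param tr_offset Volumes between stimulus onset and the scan read out
#'   (default 3, i.e. 6 s at TR = 2 s). Localizer training also uses the
#'   scan at `2 * tr_offset` (the block's second half).
#' @param n_permutations Label permutations for the null distribution
#'   (default 1000).
#' @param lambda L2 penalty of the logistic fit, on the glmnet scale
#'   (objective: mean log-loss + lambda/2 * ||w||^2). `NULL` (default) uses
#'   `1 / n_train`, the unit-strength convention of common MVPA toolboxes.
#' @param seed Integer seed governing chunk assignment and permutations.
#' @return An object of class `decoder_spec`.
#' @export
decoder_spec <- function(k_features = 250, n_chunks = 20, chunk_size = 2,
                         tr_offset = 3, n_permutations = 1000,
                         lambda = NULL, seed = 1L) {
  for (nm in c("k_features", "n_chunks", "chunk_size", "tr_offset")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      abort_bad_arg("`%s` must be a positive integer.", nm)
    }
  }
  if (!is.null(lambda) && (!is.numeric(lambda) || lambda <= 0)) {
    abort_bad_arg("`lambda` must be a positive number or NULL.")
  }
  structure(
    list(
      k_features = as.integer(k_features), n_chunks = as.integer(n_chunks),
      chunk_size = as.integer(chunk_size), tr_offset = as.integer(tr_offset),
      n_permutations = as.integer(n_permutations), lambda = lambda,
      seed = as.integer(seed)
    ),
    class = "decoder_spec"
  )
}

#' Select localizer training volumes at fixed TR offsets
#'
#' For every block of the two training classes, picks the volume
#' `tr_offset` TRs after block onset and the volume `2 * tr_offset` TRs
#' after onset (for a 12 s block at TR = 2 s and offset 3: the 4th and 7th
#' scans of the block, both riding the hemodynamic plateau). Blocks of
#' other conditions (e.g. objects) are ignored.
#'
#' @param ds A [pattern_dataset()] of the localizer.
#' @param classes Length-2 character vector of training conditions
#'   (default `c("scene", "face")`).
#' @param tr_offset Volumes after onset (default 3).
#' @return A tibble with one row per selected scan: `row` (index into
#'   `ds$data`), `label`, `event_id`, `run`, `offset`.
#' @export
select_training_scans <- function(ds, classes = c("scene", "face"),
                                  tr_offset = 3) {
  stopifnot(inherits(ds, "pattern_dataset"))
  blocks <- dplyr::filter(ds$events, .data$condition %in% classes)
  run_len <- ds$scans |> dplyr::count(.data$run, name = "n_vols")
  out <- blocks |>
    tidyr::expand_grid(offset = c(tr_offset, 2L * tr_offset)) |>
    mutate(t = .data$onset_vol + .data$offset) |>
    left_join(run_len, by = "run")
  beyond <- out$t >= out$n_vols
  if (any(beyond)) {
    abort_bad_arg(
      "Block %s (run %s): selected volume %d is beyond the run's %d volumes.",
      out$event_id[beyond][1], out$run[beyond][1],
      out$t[beyond][1], out$n_vols[beyond][1]
    )
  }
  tibble(
    row = purrr::map2_int(out$run, out$t, function(r, t) volume_row(ds, r, t)),
    label = out$condition,
    event_id = out$event_id,
    run = out$run,
    offset = out$offset
  )
}

#' Temporal preprocessing: high-pass filter and voxelwise standardization
#'
#' Per run, regresses out a discrete-cosine low-frequency basis (periods
#' longer than `highpass_cutoff` seconds — scanner drift), then z-scores
#' every voxel (subtract the run mean, divide by the run standard
#' deviation). Voxels that are constant or all-zero within a run are set to
#' zero there and flagged in the `"flagged_voxels"` attribute.
#'
#' @param ds A [pattern_dataset()].
#' @param highpass_cutoff High-pass cutoff period in seconds (default 128).
#' @return A [pattern_dataset()] with filtered, standardized data.
#' @export
temporal_preprocess <- function(ds, highpass_cutoff = 128) {
  stopifnot(inherits(ds, "pattern_dataset"))
  out <- ds$data
  flagged <- rep(FALSE, ncol(out))
  for (r in unique(ds$scans$run)) {
    rows <- run_rows(ds, r)
    n <- length(rows)
    if (n < 3) {
      abort_bad_arg("Run %s has only %d volumes; need at least 3.", format(r), n)
    }
    x <- ds$data[rows, , drop = FALSE]
    const <- matrixStats_sd(x) == 0
    basis <- dct_basis(n, ds$tr, highpass_cutoff)
    # residualize on the drift basis (includes the constant term)
    x <- stats::lsfit(basis, x, intercept = FALSE)$residuals
    s <- matrixStats_sd(x)
    dead <- const | s < 1e-12
    s[dead] <- 1
    x <- sweep(x, 2, colMeans(x), "-")
    x <- sweep(x, 2, s * sqrt((n - 1) / n), "/") # population sd: mean 0, sd 1
    x[, dead] <- 0
    out[rows, ] <- x
    flagged <- flagged | dead
  }
  res <- pattern_dataset(out, ds$scans, ds$events, ds$tr, ds$voxel_index)
  attr(res, "flagged_voxels") <- flagged
  res
}

# column standard deviations without extra deps
matrixStats_sd <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  sqrt(pmax(colMeans(x^2) - m^2, 0) * n / (n - 1))
}

# Discrete-cosine drift basis (constant + cosines with period > cutoff),
# the conventional high-pass regressor set for fMRI time series.
dct_basis <- function(n, tr, cutoff) {
  order <- floor(2 * n * tr / cutoff)
  t_idx <- seq_len(n) - 0.5
  basis <- matrix(1 / sqrt(n), n, 1)
  if (order >= 1) {
    k <- seq_len(order)
    basis <- cbind(basis, sqrt(2 / n) * cos(pi * outer(t_idx, k) / n))
  }
  basis
}

#' Two-class ANOVA F scores per voxel
#'
#' Between-class one-way ANOVA F statistic computed independently for each
#' voxel column — the ranking statistic of top-K univariate feature
#' selection.
#'
#' @param x Scans x voxels matrix.
#' @param labels Two-class label vector, one per row.
#' @return Numeric vector of F values, one per voxel (0 where the voxel is
#'   constant).
#' @export
anova_f_scores <- function(x, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L) {
    abort_bad_arg("`labels` must contain exactly 2 classes; got %d.", length(cls))
  }
  n <- nrow(x)
  g1 <- labels == cls[1]
  n1 <- sum(g1)
  n2 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ss_between <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ss_total <- colSums(sweep(x, 2, gm, "-")^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  ms_between <- ss_between / 1
  ms_within <- ss_within / (n - 2)
  f <- ifelse(ms_within > 0, ms_between / ms_within, 0)
  ifelse(is.finite(f), f, 0)
}

#' Top-K voxel selection by ANOVA F
#'
#' Returns the indices of the `k` voxels with the largest between-class
#' ANOVA F statistic on the supplied (training) scans. Ties are broken
#' deterministically by ascending voxel index.
#'
#' @param x Training scans x voxels matrix.
#' @param labels Class labels, one per row.
#' @param k Number of voxels to keep.
#' @return Integer vector of `k` voxel column indices.
#' @export
select_features <- function(x, labels, k) {
  if (k > ncol(x)) {
    abort_bad_arg("`k` = %d exceeds the %d available voxels.", k, ncol(x))
  }
  f <- anova_f_scores(x, labels)
  order(-f, seq_along(f))[seq_len(k)]
}

# L2-regularized linear logistic fit (deterministic convex solver). glmnet's
# advisory note about small per-class counts is muffled: the design is a
# fixed, balanced 2-class problem and small folds are intentional.
fit_ridge_logit <- function(x, y01, lambda) {
  withCallingHandlers(
    glmnet::glmnet(
      x, y01,
      family = "binomial", alpha = 0, lambda = lambda,
      standardize = FALSE, thresh = 1e-6
    ),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

predict_prob <- function(fit, x) {
  as.numeric(predict(fit, x, type = "response"))
}

#' Pair training scans into cross-validation chunks
#'
#' Builds `n_chunks` chunks of `chunk_size` scans each; by construction
#' every chunk pairs one scan of each class, drawn from different localizer
#' blocks, so each held-out fold is class-balanced and never shares a block
#' with itself. Assignment is deterministic given the seed.
#'
#' @param selection Output of [select_training_scans()].
#' @param spec A [decoder_spec()].
#' @return `selection` with a `chunk` column added.
#' @export
make_chunks <- function(selection, spec) {
  n <- nrow(selection)
  if (n != spec$n_chunks * spec$chunk_size) {
    abort_bad_arg(
      "%d training scans cannot fill %d chunks of %d.",
      n, spec$n_chunks, spec$chunk_size
    )
  }
  cls <- sort(unique(selection$label))
  if (length(cls) != 2L) {
    abort_bad_arg("Training scans must span exactly 2 classes.")
  }
  per_class <- n / 2L
  set.seed(spec$seed)
  idx1 <- sample(which(selection$label == cls[1]))
  idx2 <- sample(which(selection$label == cls[2]))
  if (length(idx1) != per_class || length(idx2) != per_class) {
    abort_bad_arg(
      "Training scans are class-imbalanced (%d vs %d).",
      length(idx1), length(idx2)
    )
  }
  chunk <- integer(n)
  chunk[idx1] <- seq_len(per_class)
  chunk[idx2] <- seq_len(per_class)
  mutate(selection, chunk = chunk)
}

#' Leave-one-chunk-out cross-validation of the decoder
#'
#' For each fold, feature selection and the logistic fit use the training
#' chunks only; accuracy is the proportion of held-out scans classified
#' correctly, averaged over folds.
#'
#' @param x Training scans x voxels matrix (already preprocessed).
#' @param labels Class labels, one per row.
#' @param chunks Integer chunk assignment, one per row.
#' @param spec A [decoder_spec()].
#' @return A list: `cv_accuracy`, `fold_accuracies`.
#' @export
crossvalidate <- function(x, labels, chunks, spec) {
  positive <- sort(unique(as.character(labels)))[2]
  y <- as.integer(labels == positive)
  lambda <- spec$lambda %||% (1 / (nrow(x) - spec$chunk_size))
  fold_ids <- sort(unique(chunks))
  fold_acc <- map_dbl(fold_ids, function(ch) {
    tr <- chunks != ch
    if (length(unique(y[tr])) < 2L) {
      abort_bad_arg("Fold %d leaves a single-class training set.", ch)
    }
    feats <- select_features(x[tr, , drop = FALSE], labels[tr], spec$k_features)
    fit <- fit_ridge_logit(x[tr, feats, drop = FALSE], y[tr], lambda)
    p <- predict_prob(fit, x[!tr, feats, drop = FALSE])
    mean((p > 0.5) == (y[!tr] == 1L))
  })
  list(cv_accuracy = mean(fold_acc), fold_accuracies = fold_acc)
}

#' Chunk-level permutation test of decoding accuracy
#'
#' Builds the null distribution by shuffling stimulus-class labels at the
#' chunk level (each chunk holds one scan per class; a shuffle reassigns
#' which member carries which label) and re-running the full
#' cross-validation — feature selection included — for every permutation.
#' The p-value is the proportion of null accuracies greater than or equal
#' to the observed accuracy; `plus_one = TRUE` applies the (B+1)
#' finite-sample correction instead.
#'
#' @param x,labels,chunks,spec As in [crossvalidate()].
#' @param observed Observed cross-validated accuracy (computed if `NULL`).
#' @param plus_one Use the (sum + 1) / (B + 1) estimator (default FALSE:
#'   the plain proportion).
#' @return A list: `p_value`, `null_accuracies`, `observed`.
#' @export
permutation_test <- function(x, labels, chunks, spec, observed = NULL,
                             plus_one = FALSE) {
  if (spec$n_permutations < 1) {
    abort_bad_arg("`n_permutations` must be >= 1.")
  }
  if (is.null(observed)) {
    observed <- crossvalidate(x, labels, chunks, spec)$cv_accuracy
  }
  fold_ids <- sort(unique(chunks))
  set.seed(spec$seed + 1L)
  null_acc <- map_dbl(seq_len(spec$n_permutations), function(b) {
    perm <- labels
    flip <- runif(length(fold_ids)) < 0.5
    for (i in seq_along(fold_ids)) {
      if (flip[i]) {
        rows <- which(chunks == fold_ids[i])
        perm[rows] <- rev(perm[rows])
      }
    }
    crossvalidate(x, perm, chunks, spec)$cv_accuracy
  })
  p <- if (plus_one) {
    (sum(null_acc >= observed) + 1) / (spec$n_permutations + 1)
  } else {
    mean(null_acc >= observed)
  }
  list(p_value = p, null_accuracies = null_acc, observed = observed)
}

#' Train the scene-vs-face reinstatement decoder
#'
#' Full training stage on a (preprocessed) localizer dataset: select
#' training volumes at the configured TR offsets, chunk them, estimate
#' cross-validated accuracy, optionally run the chunk-level permutation
#' test, and refit the final model — feature selection and logistic fit —
#' on all training scans for event decoding.
#'
#' @param ds A preprocessed localizer [pattern_dataset()] (see
#'   [temporal_preprocess()]).
#' @param spec A [decoder_spec()].
#' @param classes Training conditions, default `c("scene", "face")`; the
#'   second (alphabetically last) is the positive class whose probability
#'   [decode_events()] reports — "scene" for the default pair.
#' @param permute Run the permutation test (default TRUE when
#'   `spec$n_permutations` > 0).
#' @return An object of class `scene_decoder`: training selection, chunk
#'   table, `cv_accuracy`, `fold_accuracies`, `permutation_p`,
#'   `null_accuracies`, selected `features`, and the fitted model.
#' @export
train_reinstatement_decoder <- function(ds, spec = decoder_spec(),
                                        classes = c("scene", "face"),
                                        permute = spec$n_permutations > 0) {
  selection <- select_training_scans(ds, classes, spec$tr_offset)
  selection <- make_chunks(selection, spec)
  x <- ds$data[selection$row, , drop = FALSE]
  labels <- selection$label
  cv <- crossvalidate(x, labels, selection$chunk, spec)
  perm <- if (permute) {
    permutation_test(x, labels, selection$chunk, spec,
      observed = cv$cv_accuracy)
  } else {
    list(p_value = NA_real_, null_accuracies = numeric(0))
  }
  positive <- sort(unique(as.character(labels)))[2]
  features <- select_features(x, labels, spec$k_features)
  lambda <- spec$lambda %||% (1 / nrow(x))
  fit <- fit_ridge_logit(
    x[, features, drop = FALSE],
    as.integer(labels == positive), lambda
  )
  structure(
    list(
      spec = spec, classes = classes, positive = positive,
      selection = selection,
      cv_accuracy = cv$cv_accuracy, fold_accuracies = cv$fold_accuracies,
      permutation_p = perm$p_value, null_accuracies = perm$null_accuracies,
      features = features, fit = fit
    ),
    class = "scene_decoder"
  )
}

#' @export
print.scene_decoder <- function(x, ...) {
  cat(sprintf(
    "<scene_decoder> %s vs %s, %d scans, %d features\n",
    x$classes[1], x$classes[2], nrow(x$selection), length(x$features)
  ))
  cat(sprintf("  CV accuracy: %.3f", x$cv_accuracy))
  if (!is.na(x$permutation_p)) {
    cat(sprintf(
      " (permutation p = %.4g, %d permutations)",
      x$permutation_p, length(x$null_accuracies)
    ))
  }
  cat("\n")
  invisible(x)
}

#' Decode scene probability for encoding events
#'
#' Applies the trained decoder to the volume `tr_offset` TRs after each
#' event onset and returns the model's probability of the positive
#' (scene) class, per trial. Events whose read-out volume falls beyond the
#' run are skipped with a warning.
#'
#' @param decoder A [train_reinstatement_decoder()] fit.
#' @param ds A preprocessed [pattern_dataset()] of the encoding session.
#' @param conditions Event conditions to decode (default `"ac"`).
#' @param tr_offset Volumes after onset (default: the decoder's).
#' @return A tibble with the event metadata plus `scene_prob`.
#' @export
decode_events <- function(decoder, ds, conditions = "ac",
                          tr_offset = decoder$spec$tr_offset) {
  stopifnot(inherits(decoder, "scene_decoder"), inherits(ds, "pattern_dataset"))
  ev <- dplyr::filter(ds$events, .data$condition %in% conditions)
  run_len <- ds$scans |> dplyr::count(.data$run, name = "n_vols")
  ev <- left_join(ev, run_len, by = "run") |>
    mutate(t = .data$onset_vol + tr_offset)
  beyond <- ev$t >= ev$n_vols
  if (any(beyond)) {
    warn(sprintf(
      "Skipping %d event(s) whose read-out volume falls beyond the run.",
      sum(beyond)
    ))
    ev <- ev[!beyond, , drop = FALSE]
  }
  rows <- purrr::map2_int(ev$run, ev$t, function(r, t) volume_row(ds, r, t))
  xs <- ds$data[rows, decoder$features, drop = FALSE]
  ev |>
    select(-"n_vols", -"t") |>
    mutate(scene_prob = predict_prob(decoder$fit, xs))
}

#' Relate decoded scene probabilities to behavioral conditions
#'
#' Joins per-trial scene probabilities to the scored behavioral trials
#' (congruency bin, reactivation level), aggregates to per-participant 2x3
#' cell means, and runs the repeated-measures ANOVA — the same machinery
#' used for memory scores.
#'
#' @param probabilities Tibble with `participant_id`, `triad_id`,
#'   `scene_prob` (from [decode_events()], joined to trial identity).
#' @param conditions Scored trials carrying `congruency_bin` and
#'   `reactivation_level` (see [attach_conditions()]).
#' @return A list: `cells` (the 2x3 condition table of probabilities) and
#'   `anova` (an `rm_anova` object).
#' @export
relate_probabilities_to_conditions <- function(probabilities, conditions) {
  check_columns(probabilities, c("participant_id", "triad_id", "scene_prob"),
    "probabilities")
  check_columns(conditions,
    c("participant_id", "triad_id", "congruency_bin", "reactivation_level"),
    "conditions")
  joined <- inner_join(
    probabilities,
    conditions |>
      select("participant_id", "triad_id", "congruency_bin",
        "reactivation_level"),
    by = c("participant_id", "triad_id")
  )
  cells <- condition_summary(joined, value = "scene_prob")
  list(cells = cells, anova = rm_anova_2x3(cells))
}
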