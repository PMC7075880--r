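# A deterministic toy localizer: known onsets, optional injected patterns.
toy_localizer <- function(n_blocks_per_class = 4, n_vox = 30, snr = 0,
                          seed = 1, n_signal = 10) {
  cfg <- synthetic_config(
    n_voxels = n_vox, n_signal_voxels = n_signal,
    blocks_per_class = n_blocks_per_class, n_runs = 2,
    snr = snr, seed = seed
  )
  simulate_localizer(cfg)
}

test_that("training-scan selection picks the 4th and 7th volumes per block", {
  loc <- toy_localizer()
  sel <- select_training_scans(loc$dataset)
  expect_equal(nrow(sel), 16L) # 4 + 4 blocks x 2 scans
  expect_equal(as.integer(table(sel$label)), c(8L, 8L))
  # a block with onset volume o contributes volumes o + 3 and o + 6
  first <- dplyr::filter(loc$dataset$events, condition %in% c("scene", "face"))[1, ]
  rows <- dplyr::filter(sel, event_id == first$event_id)
  ts <- loc$dataset$scans$t[rows$row]
  expect_setequal(ts, first$onset_vol + c(3L, 6L))
  # object blocks are ignored entirely
  expect_false(any(sel$label == "object"))
  obj_only <- select_training_scans(loc$dataset, classes = c("zzz", "yyy"))
  expect_equal(nrow(obj_only), 0L)
})

test_that("the study-shaped localizer yields 40 scans, 20 per class", {
  loc <- simulate_localizer(synthetic_config(seed = 10))
  sel <- select_training_scans(loc$dataset)
  expect_equal(nrow(sel), 40L)
  expect_equal(as.integer(table(sel$label)), c(20L, 20L))
})

test_that("selection errors when the read-out volume leaves the run", {
  ds <- pattern_dataset(
    matrix(rnorm(8 * 4), 8, 4),
    scans = tibble::tibble(run = 1L, t = 0:7),
    events = tibble::tibble(run = 1L, event_id = "b1", condition = "scene",
      onset = 6, duration = 12),
    tr = 2
  )
  expect_error(select_training_scans(ds), "beyond")
})

test_that("temporal preprocessing standardizes and removes drift", {
  loc <- toy_localizer(snr = 1, seed = 5)
  ds <- loc$dataset
  # plant a constant voxel, and give voxel 3 the same time course as voxel 2
  # plus a strong linear drift
  n <- nrow(ds$data)
  ds$data[, 1] <- 7
  run1 <- which(ds$scans$run == 1)
  drift <- seq(-1, 1, length.out = length(run1))
  set.seed(5)
  ds$data[, 2] <- rnorm(n)
  ds$data[, 3] <- ds$data[, 2]
  ds$data[run1, 3] <- ds$data[run1, 3] + 5 * drift
  ds$data[-run1, 3] <- ds$data[-run1, 3] +
    5 * seq(-1, 1, length.out = n - length(run1))

  pre <- temporal_preprocess(ds)
  flagged <- attr(pre, "flagged_voxels")
  expect_true(flagged[1])
  expect_true(all(pre$data[, 1] == 0))
  # every non-flagged voxel: mean 0, sd 1 within each run
  for (r in 1:2) {
    rows <- which(pre$scans$run == r)
    mats <- pre$data[rows, !flagged]
    expect_lt(max(abs(colMeans(mats))), 1e-9)
    n_r <- length(rows)
    sds <- sqrt(colMeans(mats^2)) # population sd after demeaning
    expect_lt(max(abs(sds - 1)), 1e-9)
  }
  # the drift-contaminated copy must match its clean twin after filtering:
  # the added linear trend is absorbed by the drift basis
  expect_gt(stats::cor(pre$data[run1, 2], pre$data[run1, 3]), 0.9)

  expect_error(
    temporal_preprocess(pattern_dataset(
      matrix(rnorm(8), 2, 4),
      scans = tibble::tibble(run = 1L, t = 0:1),
      events = tibble::tibble(run = 1L, event_id = "e", condition = "x",
        onset = 0, duration = 1),
      tr = 2
    )),
    "at least 3"
  )
})

test_that("voxelwise ANOVA F matches stats::anova and selection is deterministic", {
  set.seed(77)
  x <- matrix(rnorm(20 * 6), 20, 6)
  labels <- rep(c("scene", "face"), each = 10)
  f_fast <- anova_f_scores(x, labels)
  f_ref <- apply(x, 2, function(v) {
    stats::anova(stats::lm(v ~ labels))[["F value"]][1]
  })
  expect_equal(f_fast, unname(f_ref), tolerance = 1e-10)

  top <- select_features(x, labels, 3)
  expect_equal(top, order(-f_fast, seq_along(f_fast))[1:3])
  expect_equal(length(unique(top)), 3L)
  expect_error(select_features(x, labels, 7), "exceeds")

  # exact ties break by ascending voxel index
  x_tie <- cbind(x[, 1], x[, 1], x[, 1])
  expect_equal(select_features(x_tie, labels, 2), c(1L, 2L))
})

test_that("injected signal voxels are recovered by top-K selection", {
  cfg <- synthetic_config(
    n_voxels = 500, n_signal_voxels = 50, snr = 2, seed = 21
  )
  loc <- simulate_localizer(cfg)
  pre <- temporal_preprocess(loc$dataset)
  sel <- select_training_scans(pre)
  feats <- select_features(pre$data[sel$row, ], sel$label, 250)
  # recoverability is bounded by the injected scene-vs-face contrast: voxels
  # whose class patterns happen to coincide carry no signal by construction
  contrast <- cfg$snr * abs(loc$truth$patterns["scene", ] -
    loc$truth$patterns["face", ])[loc$truth$signal_voxels]
  strong <- loc$truth$signal_voxels[contrast > 0.5]
  expect_true(all(strong %in% feats))
  expect_gt(mean(loc$truth$signal_voxels %in% feats), 0.8)
})

test_that("label-shuffled data yields null-like selected F values", {
  set.seed(31)
  loc <- toy_localizer(snr = 2, seed = 31)
  pre <- temporal_preprocess(loc$dataset)
  sel <- select_training_scans(pre)
  x <- pre$data[sel$row, ]
  shuffled <- sample(sel$label)
  f <- anova_f_scores(x, shuffled)
  # under the null, F(1, 14) has median ~ 1; the observed median must sit in
  # a generous neighborhood rather than the signal regime (>> 1)
  expect_lt(median(f), 3)
})

test_that("cross-validation is deterministic, separable at high SNR, chance on noise", {
  spec <- small_spec(seed = 4)
  hi <- toy_localizer(snr = 5, seed = 4)
  pre <- temporal_preprocess(hi$dataset)
  dec1 <- train_reinstatement_decoder(pre, spec)
  dec2 <- train_reinstatement_decoder(pre, spec)
  expect_identical(dec1$cv_accuracy, dec2$cv_accuracy)
  expect_identical(dec1$fold_accuracies, dec2$fold_accuracies)
  expect_identical(dec1$selection$chunk, dec2$selection$chunk)
  expect_equal(dec1$cv_accuracy, 1.0)

  # chunks pair one scan of each class from different blocks
  per_chunk <- split(dec1$selection, dec1$selection$chunk)
  for (ch in per_chunk) {
    expect_equal(nrow(ch), 2L)
    expect_setequal(ch$label, c("scene", "face"))
    expect_equal(length(unique(ch$event_id)), 2L)
  }

  accs <- purrr::map_dbl(1:30, function(i) {
    noise <- toy_localizer(snr = 0, seed = 100 + i)
    p <- temporal_preprocess(noise$dataset)
    train_reinstatement_decoder(p, small_spec(seed = i))$cv_accuracy
  })
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("fold-internal feature selection does not leak test information", {
  # leaky variant: features chosen once on ALL scans (test folds included)
  leaky_cv <- function(x, labels, chunks, spec) {
    feats <- select_features(x, labels, spec$k_features)
    xk <- x[, feats, drop = FALSE]
    y <- as.integer(labels == sort(unique(labels))[2])
    lam <- 1 / (nrow(x) - spec$chunk_size)
    acc <- purrr::map_dbl(sort(unique(chunks)), function(ch) {
      tr <- chunks != ch
      fit <- suppressWarnings(glmnet::glmnet(xk[tr, ], y[tr],
        family = "binomial", alpha = 0, lambda = lam, standardize = FALSE))
      p <- as.numeric(predict(fit, xk[!tr, , drop = FALSE], type = "response"))
      mean((p > 0.5) == (y[!tr] == 1L))
    })
    mean(acc)
  }
  spec <- small_spec(k_features = 5)
  diffs <- purrr::map_dbl(1:15, function(i) {
    noise <- toy_localizer(snr = 0, seed = 300 + i, n_vox = 120)
    pre <- temporal_preprocess(noise$dataset)
    sel <- make_chunks(select_training_scans(pre), small_spec(seed = i,
      k_features = 5))
    x <- pre$data[sel$row, ]
    leaky_cv(x, sel$label, sel$chunk, spec) -
      crossvalidate(x, sel$label, sel$chunk, spec)$cv_accuracy
  })
  # on pure noise the leaky route inflates accuracy; the honest route must
  # sit clearly below it on average
  expect_gt(mean(diffs), 0.1)
})

test_that("label flip complements decoded probabilities", {
  loc <- toy_localizer(snr = 2, seed = 9)
  pre <- temporal_preprocess(loc$dataset)
  sel <- select_training_scans(pre)
  x <- pre$data[sel$row, ]
  y <- as.integer(sel$label == "scene")
  feats <- select_features(x, sel$label, 20)
  fit_pos <- suppressWarnings(glmnet::glmnet(x[, feats], y,
    family = "binomial", alpha = 0, lambda = 1 / nrow(x),
    standardize = FALSE, thresh = 1e-10))
  fit_neg <- suppressWarnings(glmnet::glmnet(x[, feats], 1 - y,
    family = "binomial", alpha = 0, lambda = 1 / nrow(x),
    standardize = FALSE, thresh = 1e-10))
  p_pos <- as.numeric(predict(fit_pos, x[, feats], type = "response"))
  p_neg <- as.numeric(predict(fit_neg, x[, feats], type = "response"))
  expect_equal(p_pos, 1 - p_neg, tolerance = 1e-5)
})

test_that("permutation test: determinism, edge p-value, plus-one variant", {
  hi <- toy_localizer(snr = 5, seed = 12)
  pre <- temporal_preprocess(hi$dataset)
  spec <- small_spec(seed = 12, n_permutations = 30)
  sel <- make_chunks(select_training_scans(pre), spec)
  x <- pre$data[sel$row, ]

  pt1 <- permutation_test(x, sel$label, sel$chunk, spec)
  pt2 <- permutation_test(x, sel$label, sel$chunk, spec)
  expect_identical(pt1$null_accuracies, pt2$null_accuracies)
  # separable data: observed accuracy 1.0 beats every noise-null permutation
  # except permutations equal to the original labeling, which the chunk
  # scheme can reproduce; p is near 0 either way
  expect_equal(pt1$observed, 1.0)
  expect_lt(pt1$p_value, 0.1)
  p_plus <- permutation_test(x, sel$label, sel$chunk, spec, plus_one = TRUE)
  expect_equal(
    p_plus$p_value,
    (sum(p_plus$null_accuracies >= p_plus$observed) + 1) / (30 + 1)
  )
  expect_error(
    permutation_test(x, sel$label, sel$chunk,
      small_spec(seed = 1, n_permutations = 0)),
    "n_permutations"
  )
})

test_that("event decoding tracks the training patterns and amplitude", {
  loc <- toy_localizer(snr = 3, seed = 15, n_vox = 60, n_signal = 30)
  pre <- temporal_preprocess(loc$dataset)
  dec <- train_reinstatement_decoder(pre, small_spec(seed = 15))

  sel <- dec$selection
  x <- pre$data[sel$row, ]
  scene_mean <- colMeans(x[sel$label == "scene", ])
  face_mean <- colMeans(x[sel$label == "face", ])
  p_scene <- as.numeric(predict(dec$fit,
    rbind(scene_mean[dec$features]), type = "response"))
  p_face <- as.numeric(predict(dec$fit,
    rbind(face_mean[dec$features]), type = "response"))
  expect_gt(p_scene, 0.5)
  expect_lt(p_face, 0.5)

  # graded reinstatement: probability increases with injected amplitude
  cfg <- synthetic_config(
    n_voxels = 60, n_signal_voxels = 30, blocks_per_class = 4,
    n_runs = 2, snr = 3, seed = 15, n_triads = 24
  )
  probs_by_a <- purrr::map_dbl(c(0, 0.5, 1.0), function(a) {
    truth <- tibble::tibble(triad_id = 1:24, r = rep(2, 24))
    cfg_a <- synthetic_config(
      n_voxels = 60, n_signal_voxels = 30, blocks_per_class = 4,
      n_runs = 2, snr = 3, seed = 15, n_triads = 24,
      gamma = 2 * a, a_sd = 0.05
    )
    ac <- simulate_ac_encoding(cfg_a, truth, loc$truth)
    mean(decode_events(dec, temporal_preprocess(ac))$scene_prob)
  })
  expect_true(all(diff(probs_by_a) > 0))
})

test_that("decoding skips events whose read-out volume leaves the run", {
  loc <- toy_localizer(snr = 3, seed = 16)
  pre <- temporal_preprocess(loc$dataset)
  dec <- train_reinstatement_decoder(pre, small_spec(seed = 16))
  ds <- pattern_dataset(
    matrix(rnorm(10 * 60), 10, 60),
    scans = tibble::tibble(run = 1L, t = 0:9),
    events = tibble::tibble(run = 1L, event_id = c("a1", "a2"),
      condition = "ac", onset = c(0, 16), duration = 3),
    tr = 2
  )
  expect_warning(out <- decode_events(dec, ds), "Skipping 1")
  expect_equal(nrow(out), 1L)
  expect_equal(out$event_id, "a1")
})

test_that("constant probabilities produce null condition effects", {
  probs <- tidyr::expand_grid(
    participant_id = sprintf("s%d", 1:5), triad_id = 1:24
  )
  probs$scene_prob <- 0.6
  conditions <- tidyr::expand_grid(
    participant_id = sprintf("s%d", 1:5), triad_id = 1:24
  ) |>
    dplyr::mutate(
      congruency_bin = bin_congruency(rep(c(1L, 5L), 60)),
      reactivation_level = rep(1:3, 40)
    )
  res <- relate_probabilities_to_conditions(probs, conditions)
  expect_equal(res$anova$effects$F, rep(0, 3))
})
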