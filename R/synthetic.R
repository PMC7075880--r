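# Synthetic study generator ---------------------------------------------------
#
# Emulates the study design end to end: 120 ABC triads per participant
# (half congruent by stimulus-set assignment), 60 lures, a 3-level
# reactivation report during AC encoding, the three-part memory test with
# 6-point confidence scales and two recall raters, post-hoc 1-5 congruency
# ratings, and block-design localizer plus event-related AC-encoding voxel
# patterns with class-specific signals and reinstatement amplitude tied to
# the latent reactivation level.
#
# The behavioral model is an ordered-threshold (cumulative) response model
# on a latent association-strength scale:
#   s = mu + u_p + beta_c * [congruent] + e_s          (association strength)
#   r = 3-level threshold readout of s + noise          (reactivation report)
#   m = s + beta_r * r + beta_cr * r * [congruent] + e_m   (memory strength)
# and every observed response (confidence levels, rater scores, 2AFC side)
# is a thresholded or logistic readout of m.

#' Synthetic study configuration
#'
#' All generative parameters of [simulate_behavior()],
#' [simulate_localizer()] and [simulate_ac_encoding()]. Defaults encode the
#' study-shaped design (120 triads half congruent, 60 lures, a 17.1%
#' lure false-alarm rate, 10 localizer blocks per class over 2 runs at
#' TR = 2 s) with behavioral effect sizes calibrated once so that the 6-bin
#' cell means reproduce the qualitative congruency-by-reactivation ordering
#' of the study.
#'
#' @param n_participants Number of participants (default 25).
#' @param n_triads ABC triads per participant (default 120, half congruent).
#' @param n_lures Lure objects at test (default 60).
#' @param mu Baseline latent association strength.
#' @param tau SD of the participant random intercept.
#' @param beta_c Congruency effect on latent strength.
#' @param sigma_s Trial noise SD of latent strength.
#' @param beta_r Reactivation coupling: memory strength gained per
#'   reactivation level.
#' @param beta_cr Congruency x reactivation interaction on memory strength.
#' @param sigma_m Trial noise SD of memory strength.
#' @param react_thresholds Length-2 increasing cutpoints turning latent
#'   strength into the 1/2/3 reactivation report.
#' @param sigma_react SD of the report noise added before thresholding.
#' @param item_thresholds Length-5 increasing cutpoints turning memory
#'   strength into 6-point recognition confidence (low strength -> 6,
#'   high -> 1).
#' @param recall_thresholds Length-2 cutpoints for the rater score
#'   (0 / 0.5 / 1); `sigma_rater` is each rater's private noise SD.
#' @param sigma_rater Rater noise SD.
#' @param assoc_slope Logistic slope linking memory strength to the
#'   probability of choosing the correct 2AFC side.
#' @param assoc_thresholds Length-2 cutpoints for the 2AFC confidence band
#'   (low/medium/high) as a readout of memory strength.
#' @param p_fa Lure false-alarm probability (default 0.171, the study's
#'   group rate).
#' @param fa_conf_probs Probabilities of false-alarm confidence 1, 2, 3
#'   (default proportional to 3.5% / 4.8% / 8.8%, the study's split of
#'   pseudo-points 3 / 2 / 1).
#' @param cr_conf_probs Probabilities of correct-rejection confidence
#'   4, 5, 6.
#' @param p_react_timeout,p_item_timeout,p_assoc_timeout Probabilities of a
#'   missing (timed-out) response at each phase.
#' @param rating_shift Distance of the designed-congruency rating means
#'   from the scale midpoint 3 (congruent ~ 3 + shift, incongruent ~ 3 -
#'   shift before noise and rounding).
#' @param sigma_rating Congruency-rating noise SD.
#' @param n_voxels In-mask voxels of the simulated patterns (default 500).
#' @param n_signal_voxels Voxels carrying class-specific signal (default
#'   250).
#' @param blocks_per_class Localizer blocks per category (default 10,
#'   split over `n_runs`).
#' @param block_duration Localizer block length in seconds (default 12).
#' @param iti Inter-block interval in seconds (default 8, keeping block
#'   onsets TR-aligned).
#' @param tr Repetition time in seconds (default 2).
#' @param n_runs Localizer / AC-encoding runs (default 2).
#' @param snr Signal amplitude of the class patterns in units of the
#'   white-noise SD (default 2).
#' @param hrf_shift Hemodynamic delay modeled as a fixed boxcar shift, in
#'   volumes (default 2).
#' @param drift_amplitude Amplitude of the low-frequency scanner drift.
#' @param gamma Reinstatement gain: an AC trial with latent reactivation r
#'   carries the scene pattern at amplitude `gamma * (r - 1) / 2` (so r = 1
#'   contributes nothing and r = 3 the full gain; default 1.5).
#' @param a_sd Trial-to-trial SD of the reinstatement amplitude.
#' @param ac_spacing Seconds between AC-encoding trial onsets (default 12).
#' @param seed Master seed; per-component seeds are derived from it unless
#'   given explicitly.
#' @param seed_behavior,seed_localizer,seed_ac Component seeds (defaults:
#'   `seed + 101`, `seed + 202`, `seed + 303`), keeping the behavioral and
#'   pattern random streams independent.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 25,
                             n_triads = 120,
                             n_lures = 60,
                             mu = -0.3,
                             tau = 0.4,
                             beta_c = 0.5,
                             sigma_s = 0.7,
                             beta_r = 0.15,
                             beta_cr = 0.4,
                             sigma_m = 0.8,
                             react_thresholds = c(-1.1, 0.65),
                             sigma_react = 2.0,
                             item_thresholds = c(-1.2, -0.6, 0.0, 0.9, 1.8),
                             recall_thresholds = c(1.0, 2.0),
                             sigma_rater = 0.45,
                             assoc_slope = 0.9,
                             assoc_thresholds = c(0.6, 1.8),
                             p_fa = 0.171,
                             fa_conf_probs = c(0.035, 0.048, 0.088) / 0.171,
                             cr_conf_probs = c(0.15, 0.25, 0.60),
                             p_react_timeout = 0.02,
                             p_item_timeout = 0.01,
                             p_assoc_timeout = 0.02,
                             rating_shift = 1.3,
                             sigma_rating = 0.65,
                             n_voxels = 500,
                             n_signal_voxels = 250,
                             blocks_per_class = 10,
                             block_duration = 12,
                             iti = 8,
                             tr = 2,
                             n_runs = 2,
                             snr = 2,
                             hrf_shift = 2,
                             drift_amplitude = 2,
                             gamma = 1.5,
                             a_sd = 0.2,
                             ac_spacing = 12,
                             seed = 42L,
                             seed_behavior = NULL,
                             seed_localizer = NULL,
                             seed_ac = NULL) {
  cfg <- as.list(environment())
  cfg$seed_behavior <- seed_behavior %||% (seed + 101L)
  cfg$seed_localizer <- seed_localizer %||% (seed + 202L)
  cfg$seed_ac <- seed_ac %||% (seed + 303L)

  counts <- c(
    "n_participants", "n_triads", "n_lures", "n_voxels", "n_signal_voxels",
    "blocks_per_class", "n_runs"
  )
  for (nm in counts) {
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]])) {
      abort_bad_arg("`%s` must be a positive integer.", nm)
    }
  }
  for (nm in c("sigma_s", "sigma_m", "sigma_react", "sigma_rater",
    "sigma_rating", "tr", "block_duration", "ac_spacing")) {
    if (cfg[[nm]] <= 0) abort_bad_arg("`%s` must be > 0.", nm)
  }
  if (cfg$snr < 0) abort_bad_arg("`snr` must be >= 0.")
  if (cfg$n_signal_voxels > cfg$n_voxels) {
    abort_bad_arg("`n_signal_voxels` cannot exceed `n_voxels`.")
  }
  for (nm in c("p_fa", "p_react_timeout", "p_item_timeout", "p_assoc_timeout")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort_bad_arg("`%s` must be a probability.", nm)
    }
  }
  cfg$fa_conf_probs <- cfg$fa_conf_probs / sum(cfg$fa_conf_probs)
  cfg$cr_conf_probs <- cfg$cr_conf_probs / sum(cfg$cr_conf_probs)
  for (nm in c("react_thresholds", "item_thresholds", "recall_thresholds",
    "assoc_thresholds")) {
    if (is.unsorted(cfg[[nm]], strictly = TRUE)) {
      abort_bad_arg("`%s` must be strictly increasing.", nm)
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d participants, %d triads + %d lures; %d voxels (%d signal), SNR %g, gamma %g, seed %d\n",
    x$n_participants, x$n_triads, x$n_lures, x$n_voxels, x$n_signal_voxels,
    x$snr, x$gamma, x$seed
  ))
  invisible(x)
}

threshold_readout <- function(x, cutpoints) {
  findInterval(x, cutpoints) + 1L
}

#' Simulate behavioral tables with known latent truth
#'
#' Generates encoding trials (with 3-level reactivation reports), the
#' memory-test table (studied + lure rows with 6-point confidences, rater
#' scores, and a 2AFC side), and post-hoc congruency ratings, for all
#' participants, from the latent ordered-threshold model described in
#' [synthetic_config()]. The returned `truth` table carries the latent
#' association strength `s`, memory strength `m` and latent reactivation
#' level `r` per trial for parameter-recovery checks.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of tibbles: `encoding`, `test`, `ratings`, `truth`.
#' @export
simulate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed_behavior)

  ids <- sprintf("p%02d", seq_len(cfg$n_participants))
  n_cong <- floor(cfg$n_triads / 2)

  per_participant <- map(ids, function(id) {
    u <- rnorm(1, 0, cfg$tau)
    congruent <- sample(rep(c(TRUE, FALSE),
      c(n_cong, cfg$n_triads - n_cong)))
    s <- cfg$mu + u + cfg$beta_c * congruent + rnorm(cfg$n_triads, 0, cfg$sigma_s)
    r <- threshold_readout(
      s + rnorm(cfg$n_triads, 0, cfg$sigma_react), cfg$react_thresholds
    )
    m <- s + cfg$beta_r * r + cfg$beta_cr * r * congruent +
      rnorm(cfg$n_triads, 0, cfg$sigma_m)

    react_report <- ifelse(
      runif(cfg$n_triads) < cfg$p_react_timeout, NA_integer_, r
    )
    rt <- ifelse(is.na(react_report), NA_real_,
      round(pmin(pmax(rnorm(cfg$n_triads, 1.4, 0.4), 0.2), 3), 3))

    encoding <- tibble(
      participant_id = id,
      triad_id = seq_len(cfg$n_triads),
      designed_congruency = ifelse(congruent, "congruent", "incongruent"),
      reactivation_response = react_report,
      reaction_time = rt
    )

    # memory test: studied rows --------------------------------------------
    conf_level <- threshold_readout(m, cfg$item_thresholds) # 1..6, high = strong
    item_conf <- 7L - conf_level
    item_conf[runif(cfg$n_triads) < cfg$p_item_timeout] <- NA_integer_

    rate <- function() {
      g <- threshold_readout(m + rnorm(cfg$n_triads, 0, cfg$sigma_rater),
        cfg$recall_thresholds)
      c(0, 0.5, 1)[g]
    }
    rater1 <- rate()
    rater2 <- rate()

    correct_side <- sample(c("left", "right"), cfg$n_triads, replace = TRUE)
    side_correct <- runif(cfg$n_triads) < plogis(cfg$assoc_slope * m)
    band <- threshold_readout(m + rnorm(cfg$n_triads, 0, cfg$sigma_rater),
      cfg$assoc_thresholds) # 1..3 = low..high confidence
    chosen <- ifelse(side_correct, correct_side,
      ifelse(correct_side == "left", "right", "left"))
    assoc_conf <- ifelse(chosen == "left", 4L - band, 3L + band)
    assoc_conf[runif(cfg$n_triads) < cfg$p_assoc_timeout] <- NA_integer_

    # item gate: later phases only happened after a correct "old" response
    gated <- is.na(item_conf) | item_conf > 3L
    rater1[gated] <- NA_real_
    rater2[gated] <- NA_real_
    assoc_conf[gated] <- NA_integer_
    correct_side_rec <- ifelse(gated, NA_character_, correct_side)

    studied <- tibble(
      participant_id = id,
      object_id = sprintf("obj%03d", seq_len(cfg$n_triads)),
      is_lure = FALSE,
      triad_id = seq_len(cfg$n_triads),
      item_confidence = item_conf,
      recall_rater1 = rater1,
      recall_rater2 = rater2,
      assoc_confidence = assoc_conf,
      assoc_correct_side = correct_side_rec
    )

    # lure rows --------------------------------------------------------------
    fa <- runif(cfg$n_lures) < cfg$p_fa
    lure_conf <- integer(cfg$n_lures)
    lure_conf[fa] <- sample.int(3L, sum(fa), replace = TRUE,
      prob = cfg$fa_conf_probs)
    lure_conf[!fa] <- 3L + sample.int(3L, sum(!fa), replace = TRUE,
      prob = cfg$cr_conf_probs)
    lures <- tibble(
      participant_id = id,
      object_id = sprintf("lure%03d", seq_len(cfg$n_lures)),
      is_lure = TRUE,
      triad_id = NA_integer_,
      item_confidence = lure_conf,
      recall_rater1 = NA_real_,
      recall_rater2 = NA_real_,
      assoc_confidence = NA_integer_,
      assoc_correct_side = NA_character_
    )

    # congruency ratings -----------------------------------------------------
    raw <- 3 + ifelse(congruent, cfg$rating_shift, -cfg$rating_shift) +
      rnorm(cfg$n_triads, 0, cfg$sigma_rating)
    ratings <- tibble(
      participant_id = id,
      triad_id = seq_len(cfg$n_triads),
      rating = pmin(pmax(round(raw), 1L), 5L)
    )

    truth <- tibble(
      participant_id = id,
      triad_id = seq_len(cfg$n_triads),
      congruent = congruent,
      s = s, m = m, r = r
    )

    list(encoding = encoding, test = bind_rows(studied, lures),
      ratings = ratings, truth = truth)
  })

  list(
    encoding = list_rbind(map(per_participant, "encoding")),
    test = list_rbind(map(per_participant, "test")),
    ratings = list_rbind(map(per_participant, "ratings")),
    truth = list_rbind(map(per_participant, "truth"))
  )
}

# shared voxel-pattern machinery ----------------------------------------------

# class-specific spatial patterns: N(0,1) on the signal voxels, 0 elsewhere
make_class_patterns <- function(cfg, classes = c("scene", "face", "object")) {
  signal_voxels <- sort(sample.int(cfg$n_voxels, cfg$n_signal_voxels))
  patterns <- matrix(0, length(classes), cfg$n_voxels,
    dimnames = list(classes, NULL))
  for (cl in classes) {
    patterns[cl, signal_voxels] <- rnorm(cfg$n_signal_voxels)
  }
  list(signal_voxels = signal_voxels, patterns = patterns)
}

# low-frequency scanner drift: per-voxel random linear trend + slow cosine
make_drift <- function(cfg, n_vol) {
  t_sec <- (seq_len(n_vol) - 1) * cfg$tr
  slope <- rnorm(cfg$n_voxels, 0, 0.5)
  amp <- rnorm(cfg$n_voxels, 0, 0.5)
  phase <- runif(cfg$n_voxels, 0, 2 * pi)
  lin <- scale(t_sec, center = TRUE, scale = FALSE)[, 1] / max(t_sec)
  cfg$drift_amplitude *
    (outer(lin, slope) + cos(outer(2 * pi * t_sec / 240, rep(1, cfg$n_voxels)) +
      matrix(phase, n_vol, cfg$n_voxels, byrow = TRUE)) *
      matrix(amp, n_vol, cfg$n_voxels, byrow = TRUE))
}

#' Simulate a block-design localizer run set
#'
#' Builds a scene/face/object block-design pattern dataset: per class a
#' fixed random spatial pattern over the signal voxels; each block
#' contributes that pattern, at amplitude `snr`, to the volumes covered by
#' its boxcar shifted `hrf_shift` volumes (the modeled hemodynamic delay);
#' plus low-frequency drift and unit white noise. Blocks alternate
#' pseudorandomly (no immediate category repeats), `block_duration` s on /
#' `iti` s off, split over `n_runs` runs.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `dataset` (a [pattern_dataset()]) and `truth`
#'   (`signal_voxels`, `patterns`).
#' @export
simulate_localizer <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed_localizer)
  classes <- c("scene", "face", "object")
  truth <- make_class_patterns(cfg, classes)

  blocks_per_run <- cfg$blocks_per_class * length(classes) / cfg$n_runs
  if (blocks_per_run != round(blocks_per_run)) {
    abort_bad_arg("blocks_per_class * 3 must be divisible by n_runs.")
  }
  cycle <- cfg$block_duration + cfg$iti
  block_vols <- cfg$block_duration / cfg$tr
  n_vol <- blocks_per_run * cycle / cfg$tr
  if (n_vol != round(n_vol) || block_vols != round(block_vols)) {
    abort_bad_arg("block_duration and iti must be multiples of tr.")
  }

  data <- list()
  events <- list()
  block_counter <- 0L
  for (run in seq_len(cfg$n_runs)) {
    # pseudorandom order: shuffled triples, no same category twice in a row
    order <- character(0)
    for (i in seq_len(blocks_per_run / length(classes))) {
      repeat {
        tri <- sample(classes)
        if (length(order) == 0 || tri[1] != order[length(order)]) break
      }
      order <- c(order, tri)
    }
    onsets <- (seq_along(order) - 1) * cycle
    mat <- matrix(rnorm(n_vol * cfg$n_voxels), n_vol, cfg$n_voxels) +
      make_drift(cfg, n_vol)
    for (b in seq_along(order)) {
      vols <- onsets[b] / cfg$tr + cfg$hrf_shift + seq_len(block_vols)
      vols <- vols[vols <= n_vol]
      mat[vols, ] <- mat[vols, ] +
        matrix(cfg$snr * truth$patterns[order[b], ],
          length(vols), cfg$n_voxels, byrow = TRUE)
    }
    block_counter <- block_counter + length(order)
    data[[run]] <- mat
    events[[run]] <- tibble(
      run = run,
      event_id = sprintf("run%d_block%02d", run, seq_along(order)),
      condition = order,
      onset = onsets,
      duration = cfg$block_duration
    )
  }
  ds <- pattern_dataset(
    do.call(rbind, data),
    scans = tibble(
      run = rep(seq_len(cfg$n_runs), each = n_vol),
      t = rep(seq_len(n_vol) - 1L, cfg$n_runs)
    ),
    events = list_rbind(events),
    tr = cfg$tr
  )
  list(dataset = ds, truth = truth)
}

#' Simulate event-related AC-encoding patterns with graded reinstatement
#'
#' For one participant's AC-encoding session: each trial contributes, at
#' `hrf_shift + 1` volumes after onset (covering the read-out volume
#' `tr_offset = 3` TRs after onset), the scene class pattern scaled by the
#' reinstatement amplitude `a = gamma * (r - 1) / 2 + noise`, where `r` is
#' the trial's latent reactivation level from the behavioral truth table.
#' `gamma = 0` yields pure noise + drift. Trials are evenly spaced
#' (`ac_spacing` s) and split over `n_runs` runs.
#'
#' @param cfg A [synthetic_config()].
#' @param truth One participant's rows of the `truth` table from
#'   [simulate_behavior()] (columns `triad_id`, `r`).
#' @param localizer_truth The `truth` component of [simulate_localizer()]
#'   (the same class patterns must be reinstated).
#' @return A [pattern_dataset()] whose events carry `triad_id` and the
#'   true amplitude `a_true`.
#' @export
simulate_ac_encoding <- function(cfg, truth, localizer_truth) {
  stopifnot(inherits(cfg, "synthetic_config"))
  check_columns(truth, c("triad_id", "r"), "truth")
  if (length(unique(truth[["participant_id"]] %||% "p")) > 1) {
    abort_bad_arg("`truth` must contain a single participant's trials.")
  }
  if (nrow(truth) != cfg$n_triads) {
    abort_bad_arg(
      "`truth` has %d trials but the config expects %d.",
      nrow(truth), cfg$n_triads
    )
  }
  set.seed(cfg$seed_ac)
  scene_pattern <- localizer_truth$patterns["scene", ]

  trials_per_run <- cfg$n_triads / cfg$n_runs
  if (trials_per_run != round(trials_per_run)) {
    abort_bad_arg("n_triads must be divisible by n_runs.")
  }
  spacing_vols <- cfg$ac_spacing / cfg$tr
  if (spacing_vols != round(spacing_vols)) {
    abort_bad_arg("ac_spacing must be a multiple of tr.")
  }
  n_vol <- trials_per_run * spacing_vols + cfg$hrf_shift + 4L

  a_all <- cfg$gamma * (truth$r - 1) / 2 + rnorm(nrow(truth), 0, cfg$a_sd)

  data <- list()
  events <- list()
  for (run in seq_len(cfg$n_runs)) {
    idx <- (run - 1L) * trials_per_run + seq_len(trials_per_run)
    onsets <- (seq_len(trials_per_run) - 1) * cfg$ac_spacing
    mat <- matrix(rnorm(n_vol * cfg$n_voxels), n_vol, cfg$n_voxels) +
      make_drift(cfg, n_vol)
    for (j in seq_len(trials_per_run)) {
      # the reinstated pattern spans the volumes a 3-TR read-out samples
      vols <- onsets[j] / cfg$tr + cfg$hrf_shift + (1:2)
      vols <- vols[vols <= n_vol]
      mat[vols, ] <- mat[vols, ] +
        matrix(a_all[idx[j]] * scene_pattern, length(vols), cfg$n_voxels,
          byrow = TRUE)
    }
    data[[run]] <- mat
    events[[run]] <- tibble(
      run = run,
      event_id = sprintf("run%d_ac%03d", run, seq_len(trials_per_run)),
      condition = "ac",
      onset = onsets,
      duration = 3,
      triad_id = truth$triad_id[idx],
      a_true = a_all[idx]
    )
  }
  pattern_dataset(
    do.call(rbind, data),
    scans = tibble(
      run = rep(seq_len(cfg$n_runs), each = n_vol),
      t = rep(seq_len(n_vol) - 1L, cfg$n_runs)
    ),
    events = list_rbind(events),
    tr = cfg$tr
  )
}
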