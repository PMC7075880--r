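# Shared fixtures: everything is built in code at test time.

withr_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# A small study configuration: full trial structure, reduced pattern sizes
# so decoder tests stay fast.
small_cfg <- function(seed = 1, ...) {
  synthetic_config(
    n_participants = 6,
    n_triads = 24,
    n_lures = 12,
    n_voxels = 60,
    n_signal_voxels = 30,
    blocks_per_class = 4,
    n_runs = 2,
    seed = seed,
    ...
  )
}

# Matching decoder spec: 4 blocks/class x 2 scans = 16 training scans.
small_spec <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    k_features = 20, n_chunks = 8, chunk_size = 2,
    n_permutations = 0, seed = seed
  )
  do.call(decoder_spec, utils::modifyList(defaults, args))
}

# A hand-written memory-test table: 4 studied rows + 2 lures.
tiny_test_trials <- function() {
  tibble::tibble(
    participant_id = "p1",
    object_id = sprintf("o%d", 1:6),
    is_lure = c(rep(FALSE, 4), TRUE, TRUE),
    triad_id = c(1:4, NA, NA),
    item_confidence = c(1L, 2L, 6L, NA, 2L, 6L),
    recall_rater1 = c(1, 0.5, NA, NA, NA, NA),
    recall_rater2 = c(1, 1, NA, NA, NA, NA),
    assoc_confidence = c(1L, 5L, NA, NA, NA, NA),
    assoc_correct_side = c("left", "right", NA, NA, NA, NA)
  )
}

# Independent scalar re-implementation of the scoring rules, written as
# plain lookup logic straight from the test-procedure description. Used as
# the brute-force oracle; deliberately shares no code with the package.
oracle_score <- function(item_conf, r1, r2, assoc_conf, correct_side) {
  item_pts <- if (is.na(item_conf)) {
    0
  } else {
    c(3, 2, 1, 0, 0, 0)[item_conf]
  }
  if (item_pts == 0) {
    return(list(item = 0, recall = 0, assoc = 0, total = 0))
  }
  v1 <- if (is.na(r1)) 0 else r1
  v2 <- if (is.na(r2)) 0 else r2
  recall_pts <- 3 * (v1 + v2) / 2
  assoc_pts <- 0
  if (!is.na(assoc_conf)) {
    side <- if (assoc_conf <= 3) "left" else "right"
    if (side == correct_side) {
      assoc_pts <- c(3, 2, 1, 1, 2, 3)[assoc_conf]
    }
  }
  list(
    item = item_pts, recall = recall_pts, assoc = assoc_pts,
    total = item_pts + recall_pts + assoc_pts
  )
}

# Random valid guessing profile for property sweeps.
random_profile <- function() {
  p_x <- runif(3)
  p_y <- matrix(runif(12), 3, 4)
  guessing_profile(
    p_fa = runif(1),
    p_x_given_fa = p_x / sum(p_x),
    p_y_given_fa_x = p_y / rowSums(p_y)
  )
}

# Independent sums-of-squares decomposition of the balanced 2x3
# within-subject design, written from the textbook formulas: per-effect
# error term = subject x effect interaction.
oracle_rm_anova <- function(df) {
  # df: subject, a (2 levels), b (3 levels), y; fully balanced
  gm <- mean(df$y)
  n_s <- length(unique(df$subject))
  mean_by <- function(...) aggregate(y ~ ..., data = df, FUN = mean)
  ma <- tapply(df$y, df$a, mean)
  mb <- tapply(df$y, df$b, mean)
  mab <- tapply(df$y, list(df$a, df$b), mean)
  ms <- tapply(df$y, df$subject, mean)
  msa <- tapply(df$y, list(df$subject, df$a), mean)
  msb <- tapply(df$y, list(df$subject, df$b), mean)

  ss_a <- n_s * 3 * sum((ma - gm)^2)
  ss_b <- n_s * 2 * sum((mb - gm)^2)
  ss_ab <- n_s * sum((mab - outer(ma - gm, mb - gm, "+") - gm)^2)
  ss_sa <- 3 * sum((msa - outer(ms - gm, ma - gm, "+") - gm)^2)
  ss_sb <- 2 * sum((msb - outer(ms - gm, mb - gm, "+") - gm)^2)
  # residual = total within-subject SS minus all modeled terms
  ss_total <- sum((df$y - gm)^2)
  ss_s <- 6 * sum((ms - gm)^2)
  ss_sab <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb

  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    list(
      F = (ss_eff / df_eff) / (ss_err / df_err),
      df1 = df_eff, df2 = df_err,
      p = pf((ss_eff / df_eff) / (ss_err / df_err), df_eff, df_err,
        lower.tail = FALSE),
      pes = ss_eff / (ss_eff + ss_err)
    )
  }
  list(
    congruency = f_of(ss_a, 1, ss_sa, n_s - 1),
    reactivation = f_of(ss_b, 2, ss_sb, 2 * (n_s - 1)),
    interaction = f_of(ss_ab, 2, ss_sab, 2 * (n_s - 1))
  )
}
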