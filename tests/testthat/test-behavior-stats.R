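test_that("congruency binning partitions the rating scale", {
  bins <- bin_congruency(1:5)
  expect_equal(
    as.character(bins),
    c("incongruent", "incongruent", "excluded", "congruent", "congruent")
  )
  expect_error(bin_congruency(6), "rating")
  expect_error(bin_congruency(0), "rating")
  # every rating lands in exactly one bin
  counts <- table(bin_congruency(rep(1:5, 10)))
  expect_equal(sum(counts), 50)
})

test_that("condition summary aggregates per participant and completes the grid", {
  scored <- tibble::tibble(
    participant_id = "p1",
    triad_id = 1:6,
    memory_score = c(2, 4, 6, 8, 5, 3),
    congruency_bin = bin_congruency(c(5L, 5L, 1L, 1L, 3L, 4L)),
    reactivation_level = c(1L, 1L, 2L, 2L, 3L, NA)
  )
  tab <- condition_summary(scored)
  expect_equal(nrow(tab), 6L) # full 2 x 3 grid
  cong1 <- dplyr::filter(tab, congruency_bin == "congruent",
    reactivation_level == 1)
  expect_equal(cong1$mean, 3)
  expect_equal(cong1$n, 2L)
  incong2 <- dplyr::filter(tab, congruency_bin == "incongruent",
    reactivation_level == 2)
  expect_equal(incong2$mean, 7)
  # rated-3 and missing-reactivation trials contribute nowhere
  expect_equal(sum(tab$n), 4L)
  empty <- dplyr::filter(tab, n == 0)
  expect_true(all(is.na(empty$mean)))

  # all trials rated 3: a fully missing table
  all3 <- dplyr::mutate(scored,
    congruency_bin = bin_congruency(rep(3L, 6)))
  tab3 <- condition_summary(all3)
  expect_true(all(tab3$n == 0))
  expect_true(all(is.na(tab3$mean)))
})

test_that("the low-trial exclusion rule uses the < 10 boundary", {
  tab <- tidyr::expand_grid(
    participant_id = c("a", "b", "c"),
    congruency_bin = factor(c("incongruent", "congruent")),
    reactivation_level = 1:3
  )
  tab$mean <- 1
  tab$n <- 12L
  tab$n[tab$participant_id == "a" & tab$reactivation_level == 3 &
    tab$congruency_bin == "congruent"] <- 9L   # below threshold
  tab$n[tab$participant_id == "b"] <- 10L      # exactly at threshold
  res <- apply_exclusions(tab)
  expect_equal(res$excluded, "a")
  expect_setequal(res$included, c("b", "c"))
  expect_equal(nrow(res$report), 1L)
  expect_equal(res$report$n, 9L)

  none <- apply_exclusions(dplyr::mutate(tab, n = 15L))
  expect_setequal(none$included, c("a", "b", "c"))
  expect_equal(length(none$excluded), 0L)
})

test_that("one-sample test matches the textbook formula and stats::t.test", {
  set.seed(99)
  for (i in 1:5) {
    v <- rnorm(8 + i, mean = 2, sd = 1.5)
    null <- 0.5
    out <- one_sample_test(v, null)
    ref <- stats::t.test(v, mu = null)
    expect_equal(out$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(out$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(out$t, (mean(v) - null) / (sd(v) / sqrt(length(v))),
      tolerance = 1e-12)
    expect_equal(out$cohens_d, (mean(v) - null) / sd(v), tolerance = 1e-12)
    expect_equal(out$d_vs_zero, mean(v) / sd(v), tolerance = 1e-12)
  }
  expect_equal(one_sample_test(c(1, 2, 3), null = 2)$t, 0)
  expect_error(one_sample_test(rep(1, 5), 0), "zero variance")
  expect_error(one_sample_test(1), "at least 2")
})

test_that("the repeated-measures ANOVA matches an independent SS oracle", {
  set.seed(123)
  df <- tidyr::expand_grid(
    subject = sprintf("s%d", 1:4),
    a = c("incongruent", "congruent"),
    b = 1:3
  )
  df$y <- round(rnorm(nrow(df), mean = 3, sd = 1.5), 2)

  tab <- tibble::tibble(
    participant_id = df$subject,
    congruency_bin = factor(df$a, levels = c("incongruent", "congruent")),
    reactivation_level = df$b,
    mean = df$y
  )
  fit <- rm_anova_2x3(tab)
  oracle <- oracle_rm_anova(
    data.frame(subject = df$subject, a = df$a, b = factor(df$b), y = df$y)
  )
  for (term in c("congruency", "reactivation", "interaction")) {
    row <- dplyr::filter(fit$effects, term == !!term)
    expect_equal(row$F, oracle[[term]]$F, tolerance = 1e-10)
    expect_equal(row$df1, oracle[[term]]$df1)
    expect_equal(row$df2, oracle[[term]]$df2)
    expect_equal(row$p_value, oracle[[term]]$p, tolerance = 1e-10)
    expect_equal(row$pes, oracle[[term]]$pes, tolerance = 1e-10)
  }
})

test_that("degenerate and incomplete inputs are handled", {
  base <- tidyr::expand_grid(
    participant_id = sprintf("s%d", 1:5),
    congruency_bin = factor(c("incongruent", "congruent")),
    reactivation_level = 1:3
  )
  # within-participant constant cells: every effect F = 0
  const <- dplyr::mutate(base,
    mean = as.numeric(factor(participant_id)))
  fit <- rm_anova_2x3(const)
  expect_equal(fit$effects$F, rep(0, 3))

  # a participant missing one cell is dropped listwise
  holes <- dplyr::mutate(base, mean = rnorm(dplyr::n()))
  holes$mean[holes$participant_id == "s1" & holes$reactivation_level == 2 &
    holes$congruency_bin == "congruent"] <- NA
  fit2 <- rm_anova_2x3(holes)
  expect_equal(fit2$n, 4L)
  expect_equal(fit2$dropped, "s1")
  expect_equal(dplyr::filter(fit2$effects, term == "congruency")$df2, 3)

  # fewer than 3 complete cases is an error
  tiny <- dplyr::filter(base, participant_id %in% c("s1", "s2"))
  tiny$mean <- rnorm(nrow(tiny))
  expect_error(rm_anova_2x3(tiny), ">= 3 participants")
})

test_that("ANOVA p-values are uniform under the global null", {
  set.seed(2025)
  n_rep <- 300
  p_mat <- matrix(NA_real_, n_rep, 3)
  grid <- tidyr::expand_grid(
    participant_id = sprintf("s%d", 1:8),
    congruency_bin = factor(c("incongruent", "congruent")),
    reactivation_level = 1:3
  )
  for (i in seq_len(n_rep)) {
    tab <- dplyr::mutate(grid, mean = rnorm(dplyr::n()))
    p_mat[i, ] <- rm_anova_2x3(tab)$effects$p_value
  }
  for (j in 1:3) {
    ks <- stats::ks.test(p_mat[, j], "punif")
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("Greenhouse-Geisser correction only deflates multi-df effects", {
  set.seed(8)
  grid <- tidyr::expand_grid(
    participant_id = sprintf("s%d", 1:10),
    congruency_bin = factor(c("incongruent", "congruent")),
    reactivation_level = 1:3
  )
  tab <- dplyr::mutate(grid,
    mean = rnorm(dplyr::n()) + 0.8 * reactivation_level)
  plain <- rm_anova_2x3(tab)
  gg <- rm_anova_2x3(tab, correction = "greenhouse-geisser")
  expect_equal(plain$effects$F, gg$effects$F) # F unchanged, p adjusted
  expect_equal(
    dplyr::filter(plain$effects, term == "congruency")$p_value,
    dplyr::filter(gg$effects, term == "congruency")$p_value
  )
  expect_gte(
    dplyr::filter(gg$effects, term == "reactivation")$p_value,
    dplyr::filter(plain$effects, term == "reactivation")$p_value
  )
})
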