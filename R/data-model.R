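# Domain tables and pattern-dataset I/O ---------------------------------------
#
# Behavioral tables are plain TSV with fixed schemas (one row per trial;
# lures flagged by a boolean column). Pattern data travel as NIfTI-1 4D
# volumes plus a binary NIfTI mask, a BIDS-events-like TSV, and a small
# JSON sidecar carrying the TR and per-run volume counts.

ENCODING_COLS <- c(
  "participant_id", "triad_id", "designed_congruency",
  "reactivation_response", "reaction_time"
)
TEST_COLS <- c(
  "participant_id", "object_id", "is_lure", "triad_id", "item_confidence",
  "recall_rater1", "recall_rater2", "assoc_confidence", "assoc_correct_side"
)
RATING_COLS <- c("participant_id", "triad_id", "rating")

#' Read and validate the behavioral trial tables
#'
#' Reads the three delimited-text tables of an experiment session —
#' encoding trials (with the 3-level reactivation report), memory-test
#' trials (studied + lure rows), and post-hoc congruency ratings — and
#' validates every schema invariant. Missing responses (timeouts) must be
#' encoded as empty fields / `NA`; they are preserved as `NA`, never
#' coerced to 0.
#'
#' @param encoding,test,ratings Paths to TSV files (any subset may be
#'   `NULL` to skip that table).
#' @return A list with tibbles `encoding`, `test`, `ratings` (NULL where
#'   not requested).
#' @export
read_behavior_tables <- function(encoding = NULL, test = NULL, ratings = NULL) {
  out <- list(encoding = NULL, test = NULL, ratings = NULL)
  if (!is.null(encoding)) {
    out$encoding <- validate_encoding_trials(read_tsv_strict(encoding))
  }
  if (!is.null(test)) {
    out$test <- validate_test_trials(read_tsv_strict(test))
  }
  if (!is.null(ratings)) {
    out$ratings <- validate_congruency_ratings(read_tsv_strict(ratings))
  }
  out
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort_bad_arg("File not found: %s", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Validate an encoding-trial table
#'
#' @param x Data frame of encoding trials.
#' @return `x` as a validated tibble (reactivation as integer 1/2/3 or NA).
#' @export
validate_encoding_trials <- function(x) {
  check_columns(x, ENCODING_COLS, "encoding")
  x <- as_tibble(x)
  bad_cong <- !x$designed_congruency %in% c("congruent", "incongruent")
  if (any(bad_cong)) {
    abort_bad_arg(
      "encoding: `designed_congruency` must be congruent/incongruent (row %d).",
      which(bad_cong)[1]
    )
  }
  bad_r <- !is.na(x$reactivation_response) & !x$reactivation_response %in% 1:3
  if (any(bad_r)) {
    abort_bad_arg(
      "encoding: `reactivation_response` must be 1, 2, 3 or NA (row %d).",
      which(bad_r)[1]
    )
  }
  bad_rt <- !is.na(x$reaction_time) & x$reaction_time < 0
  if (any(bad_rt)) {
    abort_bad_arg("encoding: negative `reaction_time` (row %d).", which(bad_rt)[1])
  }
  dup <- x |>
    dplyr::count(.data$participant_id, .data$triad_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_bad_arg(
      "encoding: duplicated triad_id %s for participant %s.",
      dup$triad_id[1], dup$participant_id[1]
    )
  }
  mutate(x, reactivation_response = as.integer(.data$reactivation_response))
}

#' Validate a memory-test trial table
#'
#' @param x Data frame of test trials (studied and lure rows).
#' @return `x` as a validated tibble.
#' @export
validate_test_trials <- function(x) {
  check_columns(x, TEST_COLS, "test")
  x <- as_tibble(x)
  if (!is.logical(x$is_lure)) {
    abort_bad_arg("test: `is_lure` must be logical.")
  }
  check_confidence(x$item_confidence, "item_confidence")
  check_confidence(x$assoc_confidence, "assoc_confidence")
  check_rater(x$recall_rater1, "recall_rater1")
  check_rater(x$recall_rater2, "recall_rater2")
  bad_side <- !is.na(x$assoc_correct_side) &
    !x$assoc_correct_side %in% c("left", "right")
  if (any(bad_side)) {
    abort_bad_arg(
      "test: `assoc_correct_side` must be left/right (row %d).",
      which(bad_side)[1]
    )
  }
  # lures carry no associative fields and no triad
  lure <- x$is_lure
  leaky <- lure & (!is.na(x$triad_id) | !is.na(x$recall_rater1) |
    !is.na(x$recall_rater2) | !is.na(x$assoc_confidence) |
    !is.na(x$assoc_correct_side))
  if (any(leaky)) {
    abort_bad_arg(
      "test: lure row %d carries recall/associative fields or a triad_id.",
      which(leaky)[1]
    )
  }
  if (any(!lure & is.na(x$triad_id))) {
    abort_bad_arg(
      "test: studied row %d has no triad_id.", which(!lure & is.na(x$triad_id))[1]
    )
  }
  x
}

#' Validate a congruency-rating table
#'
#' @param x Data frame of ratings.
#' @return `x` as a validated tibble.
#' @export
validate_congruency_ratings <- function(x) {
  check_columns(x, RATING_COLS, "ratings")
  x <- as_tibble(x)
  bin_congruency(x$rating) # range check
  dup <- x |>
    dplyr::count(.data$participant_id, .data$triad_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_bad_arg(
      "ratings: duplicated rating for participant %s, triad %s.",
      dup$participant_id[1], dup$triad_id[1]
    )
  }
  x
}

# pattern_dataset --------------------------------------------------------------

#' Construct a pattern dataset
#'
#' A scan x voxel matrix with per-scan and per-event metadata — the
#' in-memory form of a masked 4D acquisition. Rows of `data` are volumes
#' (all runs concatenated in run order); columns are in-mask voxels.
#'
#' @param data Numeric matrix, volumes x voxels.
#' @param scans Tibble with one row per volume: `run` (integer), `t`
#'   (0-based volume index within run).
#' @param events Tibble with one row per block/event: `run`, `event_id`,
#'   `condition` (e.g. scene/face/object/ac), `onset` (seconds), `duration`
#'   (seconds), plus any extra columns (e.g. `triad_id`). A 0-based
#'   `onset_vol` = floor(onset / tr) column is derived.
#' @param tr Repetition time in seconds (> 0).
#' @param voxel_index Optional integer matrix (voxels x 3) of mask
#'   coordinates for each column of `data`.
#' @return An object of class `pattern_dataset`.
#' @export
pattern_dataset <- function(data, scans, events, tr, voxel_index = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    abort_bad_arg("`tr` must be a single positive number of seconds.")
  }
  check_columns(scans, c("run", "t"), "scans")
  scans <- as_tibble(scans)
  if (nrow(scans) != nrow(data)) {
    abort_bad_arg(
      "`scans` has %d rows but `data` has %d volumes; they must align 1:1.",
      nrow(scans), nrow(data)
    )
  }
  check_columns(events, c("run", "event_id", "condition", "onset", "duration"),
    "events")
  events <- as_tibble(events) |>
    mutate(onset_vol = as.integer(floor(.data$onset / tr)))

  run_len <- scans |> dplyr::count(.data$run, name = "n_vols")
  ev_check <- left_join(events, run_len, by = "run")
  if (anyNA(ev_check$n_vols)) {
    abort_bad_arg(
      "events reference run %s which has no volumes.",
      ev_check$run[which(is.na(ev_check$n_vols))[1]]
    )
  }
  beyond <- ev_check$onset_vol >= ev_check$n_vols
  if (any(beyond)) {
    abort_bad_arg(
      "event %s (run %s) has onset volume %d beyond the run's %d volumes.",
      ev_check$event_id[beyond][1], ev_check$run[beyond][1],
      ev_check$onset_vol[beyond][1], ev_check$n_vols[beyond][1]
    )
  }
  if (!is.null(voxel_index)) {
    voxel_index <- as.matrix(voxel_index)
    if (nrow(voxel_index) != ncol(data)) {
      abort_bad_arg("`voxel_index` must have one row per voxel column.")
    }
  }
  structure(
    list(data = data, scans = scans, events = events, tr = tr,
      voxel_index = voxel_index),
    class = "pattern_dataset"
  )
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf(
    "<pattern_dataset> %d volumes x %d voxels, %d run(s), TR = %gs\n",
    nrow(x$data), ncol(x$data), length(unique(x$scans$run)), x$tr
  ))
  cond <- table(x$events$condition)
  cat("  events:", paste(sprintf("%s=%d", names(cond), cond), collapse = ", "),
    "\n")
  invisible(x)
}

#' @export
dim.pattern_dataset <- function(x) dim(x$data)

# row indices of a dataset's volumes for a given run
run_rows <- function(ds, run) which(ds$scans$run == run)

# global row index of volume `t` (0-based within run) of `run`
volume_row <- function(ds, run, t) {
  rows <- run_rows(ds, run)
  hit <- rows[ds$scans$t[rows] == t]
  if (length(hit) != 1L) {
    abort_bad_arg("volume t = %d not found in run %s.", t, format(run))
  }
  hit
}

#' Read a masked 4D NIfTI acquisition into a pattern dataset
#'
#' Loads a 4D NIfTI volume series, restricts it to the voxels of a binary
#' 3D mask (column order = mask voxel order, x fastest), and attaches event
#' metadata. Onsets are converted to 0-based volume indices by
#' `floor(onset / tr)` — i.e. the 1-based "4th scan" of a block starting at
#' volume 0 is index 3.
#'
#' @param nifti_4d Path to the 4D NIfTI file (one or more runs
#'   concatenated).
#' @param mask Path to a binary 3D NIfTI mask on the same grid.
#' @param events Path to a TSV with columns `run`, `event_id`, `condition`,
#'   `onset`, `duration` (+ extras).
#' @param tr Repetition time in seconds; if `NULL`, read from the JSON
#'   sidecar next to `nifti_4d` (same name, `.json` extension, fields `tr`
#'   and `run_lengths`).
#' @param run_lengths Integer vector of volumes per run; if `NULL`, read
#'   from the sidecar, else a single run spanning all volumes is assumed.
#' @return A [pattern_dataset()].
#' @export
read_pattern_dataset <- function(nifti_4d, mask, events, tr = NULL,
                                 run_lengths = NULL) {
  img <- RNifti::readNifti(nifti_4d)
  msk <- RNifti::readNifti(mask)
  di <- dim(img)
  dm <- dim(msk)
  if (length(di) != 4L) {
    abort_bad_arg("`nifti_4d` must be 4-dimensional; got %d dims.", length(di))
  }
  if (!all(di[1:3] == dm[1:3])) {
    abort_bad_arg(
      "Grid mismatch: image %s vs mask %s.",
      paste(di[1:3], collapse = "x"), paste(dm[1:3], collapse = "x")
    )
  }
  keep <- which(msk != 0)
  if (length(keep) == 0) abort_bad_arg("Mask selects no voxels.")

  n_vol <- di[4]
  mat <- t(matrix(img, prod(di[1:3]), n_vol)[keep, , drop = FALSE])
  voxel_index <- arrayInd(keep, dm[1:3])

  sidecar_path <- sub("\\.nii(\\.gz)?$", ".json", nifti_4d)
  if ((is.null(tr) || is.null(run_lengths)) && file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    tr <- tr %||% sc$tr
    run_lengths <- run_lengths %||% sc$run_lengths
  }
  if (is.null(tr)) {
    abort_bad_arg("`tr` not given and no JSON sidecar found at %s.", sidecar_path)
  }
  run_lengths <- run_lengths %||% n_vol
  if (sum(run_lengths) != n_vol) {
    abort_bad_arg(
      "`run_lengths` sum to %d but the image has %d volumes.",
      sum(run_lengths), n_vol
    )
  }
  scans <- tibble(
    run = rep(seq_along(run_lengths), run_lengths),
    t = unlist(lapply(run_lengths, function(k) seq_len(k) - 1L))
  )
  ev <- read_tsv_strict(events)
  pattern_dataset(mat, scans, ev, tr = tr, voxel_index = voxel_index)
}

#' Write a pattern dataset as NIfTI + events TSV + JSON sidecar
#'
#' Inverse of [read_pattern_dataset()]: materializes the dataset as a 4D
#' NIfTI image (voxels placed on a compact 3D grid, or at `voxel_index`
#' coordinates), a matching binary mask, a BIDS-events-like TSV and a JSON
#' sidecar with `tr` and `run_lengths`.
#'
#' @param ds A [pattern_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>_mask.nii.gz`, `<prefix>_events.tsv`, `<prefix>.json`.
#' @param grid_dim Optional 3D grid dimensions when `ds$voxel_index` is
#'   NULL; defaults to a near-cubic grid holding all voxels.
#' @return Invisibly, a named list of the four file paths.
#' @export
write_pattern_dataset <- function(ds, prefix, grid_dim = NULL) {
  stopifnot(inherits(ds, "pattern_dataset"))
  n_vox <- ncol(ds$data)
  n_vol <- nrow(ds$data)
  if (is.null(ds$voxel_index)) {
    if (is.null(grid_dim)) {
      side <- ceiling(n_vox^(1 / 3))
      grid_dim <- c(side, side, ceiling(n_vox / side^2))
    }
    voxel_index <- arrayInd(seq_len(n_vox), grid_dim)
  } else {
    voxel_index <- ds$voxel_index
    grid_dim <- apply(voxel_index, 2, max)
  }
  lin <- voxel_index[, 1] +
    (voxel_index[, 2] - 1L) * grid_dim[1] +
    (voxel_index[, 3] - 1L) * grid_dim[1] * grid_dim[2]

  vol4d <- array(0, c(grid_dim, n_vol))
  plane <- prod(grid_dim)
  for (v in seq_len(n_vol)) {
    vol4d[lin + (v - 1L) * plane] <- ds$data[v, ]
  }
  msk <- array(0L, grid_dim)
  msk[lin] <- 1L

  paths <- list(
    image = paste0(prefix, ".nii.gz"),
    mask = paste0(prefix, "_mask.nii.gz"),
    events = paste0(prefix, "_events.tsv"),
    sidecar = paste0(prefix, ".json")
  )
  RNifti::writeNifti(RNifti::asNifti(vol4d, datatype = "double"), paths$image)
  RNifti::writeNifti(RNifti::asNifti(msk, datatype = "int16"), paths$mask)
  readr::write_tsv(ds$events, paths$events, progress = FALSE)
  run_lengths <- as.integer(table(factor(ds$scans$run,
    levels = unique(ds$scans$run))))
  jsonlite::write_json(
    list(tr = ds$tr, run_lengths = run_lengths),
    paths$sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Write an analysis result to disk
#'
#' Flat tables go to TSV (losslessly re-readable); structured summaries
#' (ANOVA fits, decoding results, lists) go to JSON.
#'
#' @param x A data frame, `rm_anova`, `scene_decoder` result, or list.
#' @param path Output file path (`.tsv` for tables, `.json` otherwise).
#' @return Invisibly, `path`.
#' @export
write_results <- function(x, path) {
  if (is.data.frame(x)) {
    readr::write_tsv(as_tibble(x), path, progress = FALSE)
  } else if (inherits(x, "rm_anova")) {
    jsonlite::write_json(
      list(
        effects = x$effects, n = x$n, dropped = x$dropped,
        correction = x$correction
      ),
      path,
      auto_unbox = TRUE, digits = NA
    )
  } else if (is.list(x)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  } else {
    abort_bad_arg("Don't know how to serialize a %s.", class(x)[1])
  }
  invisible(path)
}

#' Write the behavioral tables of a simulated (or real) session
#'
#' @param tables A list with tibbles `encoding`, `test`, `ratings` (as
#'   produced by [simulate_behavior()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_behavior_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    encoding = file.path(dir, "encoding.tsv"),
    test = file.path(dir, "test.tsv"),
    ratings = file.path(dir, "ratings.tsv")
  )
  readr::write_tsv(tables$encoding, paths$encoding, progress = FALSE)
  readr::write_tsv(tables$test, paths$test, progress = FALSE)
  readr::write_tsv(tables$ratings, paths$ratings, progress = FALSE)
  invisible(paths)
}
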