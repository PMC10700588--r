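#' Convert an attributed percent speed to a true speed
#'
#' The dial reports speed as a percentage of the recorded stimulus speed;
#' the true attributed speed in pixels/frame is `(percent / 100) *
#' base_speed`. Attributing 200% to a face moving at 2.5 pixels/frame gives
#' 5 pixels/frame.
#'
#' @param percent Attributed percent speed(s), within the 25-300 dial.
#' @param base_speed Recorded facial-movement speed(s), pixels/frame, > 0.
#' @return True attributed speed(s) in pixels/frame.
#' @export
#' @examples
#' true_speed(200, 2.5) # 5
true_speed <- function(percent, base_speed) {
  if (any(!is.finite(percent)) || any(percent < 25 | percent > 300)) {
    abort("`percent` must lie within the 25-300 dial bounds",
      class = "affectmap_bad_input"
    )
  }
  if (any(!is.finite(base_speed)) || any(base_speed <= 0)) {
    abort("`base_speed` must be positive", class = "affectmap_bad_input")
  }
  (percent / 100) * base_speed
}

#' Representational consistency and mean attributed speeds
#'
#' For each participant, actor and emotion the four repetitions' attributed
#' speeds are reduced to a consistency score: -1 times their standard
#' deviation (sample SD, n-1), so 0 is perfect consistency and more negative
#' is less consistent. Consistency is averaged across actors within each
#' emotion and then across emotions. Mean attributed speeds per emotion are
#' retained for distance scoring. By default the SD is taken on true speeds
#' (pixels/frame) after percent-to-speed conversion; `scale = "percent"`
#' scores the raw percent scale instead.
#'
#' @param expressionmap Tibble with columns `participant_id`, `actor`,
#'   `emotion`, `repetition`, `attributed_pct` (4 repetitions per
#'   participant x actor x emotion in the standard design; any uniform
#'   repetition count >= 2 is accepted).
#' @param base_speeds Recorded speeds per actor x emotion, see
#'   [default_base_speeds()].
#' @param scale `"speed"` (default) or `"percent"`.
#' @return A tibble, one row per participant: `rep_consistency_<emotion>`,
#'   `mean_rep_consistency`, `mean_speed_<emotion>`.
#' @export
representational_consistency <- function(expressionmap,
                                         base_speeds = default_base_speeds(),
                                         scale = c("speed", "percent")) {
  scale <- match.arg(scale)
  df <- dplyr::left_join(
    expressionmap, base_speeds,
    by = c("actor", "emotion")
  )
  df$value <- if (scale == "speed") {
    true_speed(df$attributed_pct, df$base_speed)
  } else {
    df$attributed_pct
  }
  per_cell <- df |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      consistency = -sd(.data$value),
      mean_speed = mean(true_speed(.data$attributed_pct, .data$base_speed)),
      .by = c("participant_id", "actor", "emotion")
    )
  if (length(unique(per_cell$n_rep)) != 1L || any(per_cell$n_rep < 2L)) {
    abort(
      "every participant x actor x emotion cell needs the same number of repetitions (>= 2; 4 in the standard design)",
      class = "affectmap_bad_input"
    )
  }
  per_emotion <- per_cell |>
    dplyr::summarise(
      consistency = mean(.data$consistency),
      mean_speed = mean(.data$mean_speed),
      .by = c("participant_id", "emotion")
    )
  wide <- per_emotion |>
    tidyr::pivot_wider(
      id_cols = "participant_id", names_from = "emotion",
      values_from = c("consistency", "mean_speed"), names_sort = TRUE
    ) |>
    dplyr::rename_with(
      ~ sub("^consistency_", "rep_consistency_", .x),
      dplyr::starts_with("consistency_")
    )
  wide$mean_rep_consistency <- rowMeans(
    wide[, paste0("rep_consistency_", am_emotions)]
  )
  wide
}

#' Distances between represented emotion speeds
#'
#' Absolute differences between the mean speeds attributed to each pair of
#' emotions, plus their mean: a participant-level index of how
#' differentiated the visual representations are.
#'
#' @param rep_scores Output of [representational_consistency()] (uses the
#'   `mean_speed_<emotion>` columns).
#' @return `rep_scores` with added `rep_distance_<pair>` columns (3) and
#'   `mean_rep_distance`.
#' @export
representation_distances <- function(rep_scores) {
  pairs <- utils::combn(am_emotions, 2, simplify = FALSE)
  for (p in pairs) {
    col <- paste0("rep_distance_", p[1], "_", p[2])
    rep_scores[[col]] <- abs(
      rep_scores[[paste0("mean_speed_", p[1])]] -
        rep_scores[[paste0("mean_speed_", p[2])]]
    )
  }
  rep_scores$mean_rep_distance <- rowMeans(
    rep_scores[, paste0(
      "rep_distance_",
      vapply(pairs, function(p) paste(p, collapse = "_"), character(1))
    )]
  )
  rep_scores
}

#' Visual-matching deviation scores and the median-split grouping
#'
#' Per trial the deviation is the absolute percent-point gap between the
#' attributed and displayed speeds; deviations are averaged per emotion and
#' overall (matching difficulty — higher means worse matching). Participants
#' are split at the cohort median of the overall deviation into a
#' `high_matching` (at or below the median) and `low_matching` group.
#'
#' @param matching Tibble with columns `participant_id`, `emotion`,
#'   `target_pct`, `attributed_pct` (48 trials per participant).
#' @return A tibble, one row per participant: `matching_<emotion>` (3),
#'   `matching_difficulty` (overall mean deviation, percent points),
#'   `matching_group`.
#' @export
matching_scores <- function(matching) {
  n_per <- dplyr::count(matching, .data$participant_id)
  if (any(n_per$n != 48L)) {
    abort("each participant needs exactly 48 matching trials",
      class = "affectmap_bad_input"
    )
  }
  matching$deviation <- abs(matching$attributed_pct - matching$target_pct)
  per_emotion <- matching |>
    dplyr::summarise(
      deviation = mean(.data$deviation),
      .by = c("participant_id", "emotion")
    ) |>
    tidyr::pivot_wider(
      names_from = "emotion", values_from = "deviation",
      names_prefix = "matching_", names_sort = TRUE
    )
  overall <- matching |>
    dplyr::summarise(
      matching_difficulty = mean(.data$deviation), .by = "participant_id"
    )
  out <- dplyr::left_join(per_emotion, overall, by = "participant_id")
  med <- median(out$matching_difficulty)
  out$matching_group <- ifelse(
    out$matching_difficulty <= med, "high_matching", "low_matching"
  )
  out
}

#' Emotion recognition accuracy
#'
#' Per trial, accuracy is the rating on the displayed emotion's scale minus
#' the mean of the two incorrect scales, in \[-10, 10\]; averaged per
#' emotion and over all trials.
#'
#' @param recognition Tibble with columns `participant_id`, `emotion` (the
#'   displayed emotion) and `rating_anger`, `rating_happiness`,
#'   `rating_sadness` in \[0, 10\].
#' @return A tibble, one row per participant: `accuracy_<emotion>` (3) and
#'   `accuracy` (mean over all trials).
#' @export
recognition_accuracy <- function(recognition) {
  rating_cols <- paste0("rating_", am_emotions)
  if (!all(rating_cols %in% names(recognition))) {
    abort(paste(
      "`recognition` needs columns", paste(rating_cols, collapse = ", ")
    ), class = "affectmap_bad_input")
  }
  r <- as.matrix(recognition[, rating_cols])
  if (any(!is.finite(r)) || any(r < 0 | r > 10)) {
    abort("ratings must lie in [0, 10]", class = "affectmap_bad_input")
  }
  correct_idx <- match(paste0("rating_", recognition$emotion), rating_cols)
  correct <- r[cbind(seq_len(nrow(r)), correct_idx)]
  recognition$trial_accuracy <- correct - (rowSums(r) - correct) / 2
  per_emotion <- recognition |>
    dplyr::summarise(
      accuracy = mean(.data$trial_accuracy),
      .by = c("participant_id", "emotion")
    ) |>
    tidyr::pivot_wider(
      names_from = "emotion", values_from = "accuracy",
      names_prefix = "accuracy_", names_sort = TRUE
    )
  overall <- recognition |>
    dplyr::summarise(
      accuracy = mean(.data$trial_accuracy), .by = "participant_id"
    )
  dplyr::left_join(per_emotion, overall, by = "participant_id")
}

#' Representation-matching composite
#'
#' Per emotion, the product of representational consistency (<= 0) and
#' matching difficulty (>= 0), plus the mean composite. Zero when
#' consistency is perfect; otherwise negative, with higher (less negative)
#' values indexing superior consistency, matching ability, or both.
#'
#' @param rep_scores Output of [representational_consistency()].
#' @param match_scores Output of [matching_scores()].
#' @param standardize If `TRUE`, z-score the per-emotion factors across
#'   participants before multiplying (off by default: the composite is
#'   defined on the raw scales).
#' @return A tibble keyed by `participant_id` with
#'   `representation_matching_<emotion>` (3) and `representation_matching`
#'   (the mean composite).
#' @export
representation_matching <- function(rep_scores, match_scores,
                                    standardize = FALSE) {
  df <- dplyr::left_join(rep_scores, match_scores, by = "participant_id")
  out <- tibble::tibble(participant_id = df$participant_id)
  for (e in am_emotions) {
    cons <- df[[paste0("rep_consistency_", e)]]
    diff <- df[[paste0("matching_", e)]]
    if (standardize) {
      cons <- as.numeric(scale(cons))
      diff <- as.numeric(scale(diff))
    }
    out[[paste0("representation_matching_", e)]] <- cons * diff
  }
  out$representation_matching <- rowMeans(
    out[, paste0("representation_matching_", am_emotions)]
  )
  out
}

#' Assemble the participant-level wide score table
#'
#' Scores every task of a cohort (simulated via [simulate_cohort()] or read
#' from response CSVs) and joins the results with the trait covariates into
#' the one-row-per-participant table consumed by the model-search stage.
#'
#' @param cohort An `affectmap_cohort` list, or any list with elements
#'   `choices`, `expressionmap`, `matching`, `recognition` and optionally
#'   `similarity` and `profiles` (for traits `aq`, `tas`, `nvr`).
#' @param embed Whether to embed similarity ratings (slowest step); when
#'   `FALSE` or `similarity` is absent, the landscape distance columns are
#'   omitted.
#' @param scale SD scale for [representational_consistency()].
#' @param seed,n_restarts,max_iter,tol Embedding controls, see
#'   [embed_landscape()].
#' @return A wide tibble, one row per participant.
#' @export
score_cohort <- function(cohort, embed = TRUE,
                         scale = c("speed", "percent"),
                         seed = 1L, n_restarts = 8L, max_iter = 300L,
                         tol = 1e-6) {
  scale <- match.arg(scale)
  base <- if (!is.null(cohort$config)) {
    cohort$config$base_speeds
  } else {
    default_base_speeds()
  }
  emo <- emomap_participant_scores(
    cohort$choices,
    similarity = if (embed) cohort$similarity else NULL,
    seed = seed, n_restarts = n_restarts, max_iter = max_iter, tol = tol
  )
  rep <- representational_consistency(
    cohort$expressionmap,
    base_speeds = base, scale = scale
  ) |>
    representation_distances()
  mat <- matching_scores(cohort$matching)
  acc <- recognition_accuracy(cohort$recognition)
  comp <- representation_matching(rep, mat)
  out <- emo |>
    dplyr::left_join(rep, by = "participant_id") |>
    dplyr::left_join(mat, by = "participant_id") |>
    dplyr::left_join(comp, by = "participant_id") |>
    dplyr::left_join(acc, by = "participant_id")
  if (!is.null(cohort$profiles)) {
    traits <- dplyr::select(
      cohort$profiles, "participant_id",
      dplyr::any_of(c("aq", "tas", "nvr"))
    )
    out <- dplyr::left_join(out, traits, by = "participant_id")
  }
  out
}
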