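test_that("percent-to-speed conversion follows the dial formula", {
  expect_equal(true_speed(200, 2.5), 5)
  expect_equal(true_speed(100, 1.7), 1.7)
  expect_equal(true_speed(50, 3.0), 1.5)
  expect_error(true_speed(20, 2), class = "affectmap_bad_input")
  expect_error(true_speed(310, 2), class = "affectmap_bad_input")
  expect_error(true_speed(100, 0), class = "affectmap_bad_input")
})

make_expr_table <- function(values_by_emotion, actors = 1L) {
  # one participant, given attributed percents per emotion, same per actor
  purrr::imap_dfr(values_by_emotion, function(vals, emo) {
    tidyr::crossing(actor = actors, repetition = seq_along(vals)) |>
      dplyr::mutate(
        participant_id = "p1", emotion = emo,
        attributed_pct = rep(vals, length(actors))
      )
  })
}

unit_base <- function() {
  tidyr::crossing(
    actor = 1:4, emotion = c("anger", "happiness", "sadness")
  ) |>
    dplyr::mutate(base_speed = 1)
}

test_that("representational consistency is -1 x sample SD of attributed speeds", {
  # the worked trio 119/120/121% at 1 px/frame has SD exactly 1
  tbl <- make_expr_table(list(
    anger = c(119, 120, 121),
    happiness = c(100, 100, 100),
    sadness = c(80, 90, 100)
  ))
  rs <- representational_consistency(tbl, base_speeds = unit_base())
  expect_equal(rs$rep_consistency_anger, -1 / 100)
  expect_equal(true_speed(c(119, 120, 121), 100), c(119, 120, 121))
  rs_pct <- representational_consistency(
    tbl,
    base_speeds = unit_base(), scale = "percent"
  )
  expect_equal(rs_pct$rep_consistency_anger, -1)
  expect_equal(rs_pct$rep_consistency_happiness, 0)
  expect_equal(
    rs_pct$rep_consistency_sadness, -oracle_sd(c(80, 90, 100))
  )
  expect_equal(
    rs_pct$mean_rep_consistency,
    mean(c(-1, 0, -oracle_sd(c(80, 90, 100))))
  )
})

test_that("consistency matches an independent SD oracle on random speeds", {
  set.seed(6)
  vals <- list(
    anger = runif(4, 50, 250),
    happiness = runif(4, 50, 250),
    sadness = runif(4, 50, 250)
  )
  tbl <- make_expr_table(vals)
  rs <- representational_consistency(
    tbl,
    base_speeds = unit_base(), scale = "percent"
  )
  for (e in names(vals)) {
    expect_equal(
      rs[[paste0("rep_consistency_", e)]], -oracle_sd(vals[[e]])
    )
  }
  # shift and permutation invariance of the SD
  shifted <- lapply(vals, function(v) sample(v + 37.5))
  rs2 <- representational_consistency(
    make_expr_table(shifted),
    base_speeds = unit_base(), scale = "percent"
  )
  expect_equal(rs2$mean_rep_consistency, rs$mean_rep_consistency)
  # zero iff all repetitions identical
  expect_equal(
    representational_consistency(
      make_expr_table(list(
        anger = rep(120, 4), happiness = rep(80, 4), sadness = rep(60, 4)
      )),
      base_speeds = unit_base()
    )$mean_rep_consistency, 0
  )
  expect_lt(rs$mean_rep_consistency, 0)
})

test_that("representation distances are symmetric absolute speed gaps", {
  rs <- tibble::tibble(
    participant_id = "p1",
    mean_speed_anger = 3.85,
    mean_speed_happiness = 2.80,
    mean_speed_sadness = 1.63
  )
  out <- representation_distances(rs)
  expect_equal(out$rep_distance_anger_happiness, 1.05)
  expect_equal(out$rep_distance_anger_sadness, 2.22)
  expect_equal(out$rep_distance_happiness_sadness, 1.17)
  expect_equal(out$mean_rep_distance, mean(c(1.05, 2.22, 1.17)))
  # swapping two emotions leaves the pairwise distance unchanged
  rs_swapped <- rs
  rs_swapped$mean_speed_anger <- rs$mean_speed_happiness
  rs_swapped$mean_speed_happiness <- rs$mean_speed_anger
  expect_equal(
    representation_distances(rs_swapped)$rep_distance_anger_happiness,
    out$rep_distance_anger_happiness
  )
  # equal means collapse every distance to zero
  rs_eq <- rs
  rs_eq$mean_speed_happiness <- 3.85
  rs_eq$mean_speed_sadness <- 3.85
  expect_equal(representation_distances(rs_eq)$mean_rep_distance, 0)
})

test_that("matching deviations and the median split behave as specified", {
  design <- build_speed_design("matching", seed = 1L)
  perfect <- design |>
    dplyr::mutate(
      participant_id = "p1",
      target_pct = start_speed_pct,
      attributed_pct = start_speed_pct
    )
  off <- perfect |>
    dplyr::mutate(participant_id = "p2", attributed_pct = target_pct + 20)
  ms <- matching_scores(dplyr::bind_rows(perfect, off))
  expect_equal(ms$matching_difficulty[ms$participant_id == "p1"], 0)
  expect_equal(ms$matching_group[ms$participant_id == "p1"], "high_matching")
  expect_equal(ms$matching_difficulty[ms$participant_id == "p2"], 20)
  expect_equal(ms$matching_group[ms$participant_id == "p2"], "low_matching")
  expect_error(matching_scores(perfect[1:40, ]), class = "affectmap_bad_input")

  # distinct deviations split ceiling(n/2) high vs floor(n/2) low
  for (n in c(4L, 5L, 7L)) {
    cohort <- purrr::map_dfr(seq_len(n), function(i) {
      dplyr::mutate(
        perfect,
        participant_id = sprintf("p%02d", i),
        attributed_pct = pmin(300, target_pct + i * 3)
      )
    })
    grp <- table(matching_scores(cohort)$matching_group)
    expect_equal(unname(grp["high_matching"]), ceiling(n / 2))
    expect_equal(unname(grp["low_matching"]), floor(n / 2))
  }
})

test_that("recognition accuracy is correct minus mean incorrect, bounded", {
  base <- tibble::tibble(
    participant_id = "p1", emotion = "happiness",
    rating_anger = 2, rating_happiness = 8, rating_sadness = 4
  )
  expect_equal(recognition_accuracy(base)$accuracy, 5) # 8 - (2 + 4) / 2
  extreme <- dplyr::mutate(
    base,
    rating_anger = 0, rating_happiness = 10, rating_sadness = 0
  )
  expect_equal(recognition_accuracy(extreme)$accuracy, 10)
  flat <- dplyr::mutate(
    base,
    rating_anger = 6.2, rating_happiness = 6.2, rating_sadness = 6.2
  )
  expect_equal(recognition_accuracy(flat)$accuracy, 0)
  expect_error(
    recognition_accuracy(dplyr::mutate(base, rating_anger = 11)),
    class = "affectmap_bad_input"
  )
  # trial order never changes the aggregates
  fix <- fixture_cohort()
  acc1 <- recognition_accuracy(fix$recognition)
  shuffled <- fix$recognition[sample(nrow(fix$recognition)), ]
  acc2 <- recognition_accuracy(shuffled)
  expect_equal(
    dplyr::arrange(acc1, participant_id),
    dplyr::arrange(acc2, participant_id)
  )
  expect_true(all(acc1$accuracy >= -10 & acc1$accuracy <= 10))
})

test_that("the representation-matching composite multiplies the raw scales", {
  rep_scores <- tibble::tibble(
    participant_id = c("p1", "p2", "p3"),
    rep_consistency_anger = c(0, -2, -3),
    rep_consistency_happiness = c(0, -2, -3),
    rep_consistency_sadness = c(0, -2, -3)
  )
  match_scores <- tibble::tibble(
    participant_id = c("p1", "p2", "p3"),
    matching_anger = c(15, 10, 10),
    matching_happiness = c(20, 10, 10),
    matching_sadness = c(25, 10, 10)
  )
  comp <- representation_matching(rep_scores, match_scores)
  expect_equal(comp$representation_matching[1], 0)
  expect_equal(comp$representation_matching_anger[2], -20)
  expect_equal(comp$representation_matching[2], -20)
  # holding difficulty fixed, the composite rises with consistency
  expect_gt(
    comp$representation_matching[2], comp$representation_matching[3]
  )
})

test_that("scored noise measures rank-order the generative noise scales", {
  fix <- fixture_cohort()
  rep <- representational_consistency(fix$expressionmap)
  mat <- matching_scores(fix$matching)
  prof <- fix$profiles
  expect_equal(
    rep$mean_rep_consistency[rep$participant_id == "p0002"], 0
  )
  joined <- prof |>
    dplyr::left_join(rep, by = "participant_id") |>
    dplyr::left_join(mat, by = "participant_id")
  expect_lt(
    cor(joined$sigma_rep, joined$mean_rep_consistency, method = "spearman"),
    -0.7
  )
  expect_gt(
    cor(joined$sigma_match, joined$matching_difficulty, method = "spearman"),
    0.7
  )
})
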