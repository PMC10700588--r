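test_that("shadow screening confirms a perfect predictor and real signal", {
  set.seed(1)
  n <- 500
  x1 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  dat <- tibble::tibble(
    y = y, y_copy = y, x1 = x1,
    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n)
  )
  rep_copy <- screen_importance(
    dat, "y", c("y_copy", "n1"),
    n_iter = 15, num_trees = 100, seed = 2
  )
  expect_equal(
    rep_copy$decision[rep_copy$variable == "y_copy"], "confirmed"
  )
  rep_sig <- screen_importance(
    dat, "y", c("x1", "n1", "n2", "n3", "n4"),
    n_iter = 30, num_trees = 150, seed = 3
  )
  expect_equal(rep_sig$decision[rep_sig$variable == "x1"], "confirmed")
  expect_true(all(
    rep_sig$decision[rep_sig$variable != "x1"] %in%
      c("rejected", "tentative")
  ))
  # ranked by mean importance, signal first
  expect_equal(rep_sig$variable[1], "x1")
})

test_that("pure-noise candidates are almost never confirmed", {
  # Type-I control is at the dataset level: a chance in-sample association
  # survives shadowing (only the permuted copy loses it), so the check
  # needs enough rows for spurious correlations to sit below the forest's
  # noise floor. 50 variable-decisions across 10 cohorts.
  confirmed <- 0L
  for (r in 1:10) {
    set.seed(100 + r)
    dat <- tibble::as_tibble(
      setNames(
        as.data.frame(matrix(rnorm(600 * 6), 600)),
        c("y", paste0("x", 1:5))
      )
    )
    rep <- screen_importance(
      dat, "y", paste0("x", 1:5),
      n_iter = 25, num_trees = 100, seed = r
    )
    confirmed <- confirmed + sum(rep$decision == "confirmed")
  }
  expect_lte(confirmed, 1L)
})

test_that("screening rejects unusable tables", {
  dat <- tibble::tibble(y = rnorm(100), x = rnorm(100), k = 1)
  expect_error(
    screen_importance(dat, "y", c("x", "k"), n_iter = 5),
    class = "affectmap_bad_input"
  )
  expect_error(
    screen_importance(dat[1:10, ], "y", "x", n_iter = 5),
    class = "affectmap_bad_input"
  )
})

test_that("sequential building admits signal and stops at noise", {
  set.seed(7)
  n <- 800
  sig <- rnorm(n)
  noise <- rnorm(n)
  out <- 0.6 * sig + rnorm(n, 0, 0.8)
  dat <- tibble::tibble(outcome = out, sig = sig, noise = noise)
  build <- sequential_build(
    dat, "outcome", c("sig", "noise"),
    n_restarts = 2
  )
  expect_equal(build$entered, "sig")
  expect_equal(nrow(build$spec$paths), 1L)
  expect_true(build$log$entered[1])
  expect_false(build$log$entered[2])
  # entry order equals the provided importance ranking
  expect_equal(build$log$variable, c("sig", "noise"))
})

test_that("an empty confirmed set returns the measurement-only base model", {
  set.seed(8)
  n <- 300
  f <- rnorm(n)
  dat <- tibble::tibble(
    o1 = f + rnorm(n, 0, 0.6),
    o2 = f + rnorm(n, 0, 0.6),
    o3 = f + rnorm(n, 0, 0.6)
  )
  build <- sequential_build(
    dat, "acc", character(),
    latent_map = list(acc = c("o1", "o2", "o3")), n_restarts = 2
  )
  expect_equal(build$entered, character())
  expect_equal(nrow(build$spec$paths), 0L)
  expect_s3_class(build$fit, "affectmap_sem")
})

test_that("covariance-equivalent reversals tie and colliders resist reversal", {
  set.seed(9)
  n <- 1200
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)
  d2 <- tibble::tibble(x = x, y = y)
  f2 <- fit_path_model(
    d2, model_spec(paths = data.frame(from = "x", to = "y"))
  )
  rv2 <- reverse_path_search(f2, d2)
  expect_equal(nrow(rv2$report), 1L)
  expect_lt(abs(rv2$report$delta_bic), 0.1)
  expect_equal(rv2$report$evidence, "tie")
  expect_equal(rv2$report$retained, "original")

  n <- 2000
  xa <- rnorm(n)
  xb <- rnorm(n)
  m <- 0.6 * xa + 0.6 * xb + rnorm(n)
  dc <- tibble::tibble(x = xa, y = xb, m = m)
  fc <- fit_path_model(dc, model_spec(paths = data.frame(
    from = c("x", "y"), to = c("m", "m")
  )))
  rvc <- reverse_path_search(fc, dc)
  # each structural edge appears exactly once in the report
  expect_equal(nrow(rvc$report), 2L)
  expect_equal(
    anyDuplicated(paste(rvc$report$from, rvc$report$to)), 0L
  )
  expect_true(all(rvc$report$delta_bic > 6))
  expect_true(all(rvc$report$evidence == "strong_original"))
  expect_true(all(!rvc$final_check$loses_strongly))
})

test_that("reversal repairs a wrongly oriented edge", {
  set.seed(10)
  n <- 2000
  xa <- rnorm(n)
  xb <- rnorm(n)
  m <- 0.7 * xa + 0.7 * xb + rnorm(n)
  dc <- tibble::tibble(x = xa, y = xb, m = m)
  # y -> m deliberately mis-specified as m -> y
  wrong <- fit_path_model(dc, model_spec(paths = data.frame(
    from = c("x", "m"), to = c("m", "y")
  )))
  rv <- reverse_path_search(wrong, dc)
  flipped <- rv$report[rv$report$from == "m" & rv$report$to == "y", ]
  expect_equal(flipped$retained, "reversed")
  expect_true(
    any(rv$final_spec$paths$from == "y" & rv$final_spec$paths$to == "m")
  )
  expect_lt(rv$final_fit$bic, wrong$bic)
})

test_that("the association screen recovers the generative coupling", {
  run_screen <- function(rho, seed) {
    cfg <- cohort_config(n_participants = 400, seed = seed, rho_cons = rho)
    co <- simulate_cohort(cfg, tasks = c("emomap", "expression_matching"))
    scores <- emomap_participant_scores(co$choices) |>
      dplyr::left_join(
        representational_consistency(
          co$expressionmap,
          base_speeds = cfg$base_speeds
        ),
        by = "participant_id"
      ) |>
      dplyr::left_join(
        co$profiles[, c("participant_id", "aq", "tas", "nvr")],
        by = "participant_id"
      )
    association_screen(scores)
  }
  coupled <- run_screen(0.6, seed = 41)
  row <- coupled[coupled$model == "rep_consistency" &
    coupled$term == "emotional_consistency", ]
  expect_gt(row$estimate, 0)
  expect_lt(row$p.value, 0.05)
  # the independently generated control consistency carries no signal
  ctl <- coupled[coupled$model == "rep_consistency" &
    coupled$term == "consistency_control", ]
  expect_gt(ctl$p.value, 0.05)

  uncoupled <- run_screen(0, seed = 42)
  row0 <- uncoupled[uncoupled$model == "rep_consistency" &
    uncoupled$term == "emotional_consistency", ]
  expect_lt(abs(row0$statistic), 3)
})
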