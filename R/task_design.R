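#' Enumerate the affect-similarity pair design
#'
#' Fifteen affect-inducing images (five per emotion: anger, happiness,
#' sadness) are rated pairwise for the similarity of the feelings they evoke.
#' Every unordered pair appears exactly once, giving 105 trials: 30 within a
#' single emotion category (10 per emotion) and 75 between categories (25 per
#' category pair).
#'
#' @return A tibble with one row per unordered image pair and columns
#'   `trial`, `image_a`, `image_b`, `category_a`, `category_b`, `pair_type`
#'   (`"within"` or `"between"`) and `pair_label` (e.g. `"anger-sadness"`;
#'   the single category for within pairs).
#' @export
#' @examples
#' d <- build_emopair_design()
#' nrow(d) # 105
#' table(d$pair_type) # 30 within, 75 between
build_emopair_design <- function() {
  images <- tibble::tibble(
    image = sprintf("%s_%02d", rep(am_emotions, each = 5L), rep(1:5, 3L)),
    category = rep(am_emotions, each = 5L)
  )
  idx <- utils::combn(nrow(images), 2L)
  tibble::tibble(
    trial = seq_len(ncol(idx)),
    image_a = images$image[idx[1L, ]],
    image_b = images$image[idx[2L, ]],
    category_a = images$category[idx[1L, ]],
    category_b = images$category[idx[2L, ]]
  ) |>
    dplyr::mutate(
      pair_type = ifelse(.data$category_a == .data$category_b,
        "within", "between"
      ),
      pair_label = purrr::map2_chr(
        .data$category_a, .data$category_b,
        function(a, b) paste(sort(unique(c(a, b))), collapse = "-")
      )
    )
}

#' Enumerate one forced-choice intensity triplet condition
#'
#' In each condition (anger, happiness, sadness, or a colourfulness control)
#' the 11 target images are presented in all 55 unordered pairs; a third
#' "trap" image — a strong inducer of a different emotion, or a grayscale
#' image in the control condition — is shown alongside each pair as an
#' attention check. Trap images for each trial are drawn at random (seeded)
#' from the opposing-category pool; traps may repeat across trials.
#'
#' @param condition One of `"anger"`, `"happiness"`, `"sadness"`,
#'   `"color_control"`.
#' @param seed Integer seed governing trap assignment.
#' @return A 55-row tibble with columns `condition`, `trial`, `target_a`,
#'   `target_b`, `trap_image`, `trap_category`.
#' @export
build_triplet_design <- function(condition, seed = 1L) {
  valid <- c(am_emotions, "color_control")
  if (!is.character(condition) || length(condition) != 1L ||
    !condition %in% valid) {
    abort(paste0(
      "`condition` must be one of ",
      paste(sprintf("\"%s\"", valid), collapse = ", ")
    ), class = "affectmap_bad_condition")
  }
  if (condition == "color_control") {
    targets <- sprintf("neutral_t%02d", 1:11)
    trap_pool <- tibble::tibble(
      image = sprintf("grayscale_%02d", 1:5),
      category = "grayscale"
    )
  } else {
    targets <- sprintf("%s_t%02d", condition, 1:11)
    others <- setdiff(am_emotions, condition)
    trap_pool <- tibble::tibble(
      image = sprintf("%s_i%02d", rep(others, each = 5L), rep(1:5, 2L)),
      category = rep(others, each = 5L)
    )
  }
  idx <- utils::combn(11L, 2L)
  withr::with_seed(seed, {
    trap_i <- sample.int(nrow(trap_pool), ncol(idx), replace = TRUE)
    tibble::tibble(
      condition = condition,
      trial = seq_len(ncol(idx)),
      target_a = targets[idx[1L, ]],
      target_b = targets[idx[2L, ]],
      trap_image = trap_pool$image[trap_i],
      trap_category = trap_pool$category[trap_i]
    )
  })
}

#' Enumerate the speed-dial trial design
#'
#' Both speed tasks present point-light faces from 4 actors x 3 emotions x 4
#' repetitions (48 trials). The response dial is bounded at 25% and 300% of
#' the recorded speed. For the expression task (attributing the speed of a
#' typical angry/happy/sad expression) the starting speed of each video is
#' random within the dial range. For the visual matching task the displayed
#' speeds of the 16 videos per emotion are exactly 50%, 60%, ..., 200% of
#' the recorded speed, assigned to actor x repetition cells in a seeded
#' random order.
#'
#' @param task `"expressionmap"` or `"matching"`.
#' @param seed Integer seed for the start-speed assignment.
#' @return A 48-row tibble with columns `task`, `actor`, `emotion`,
#'   `repetition`, `start_speed_pct`, `dial_min_pct`, `dial_max_pct`.
#' @export
build_speed_design <- function(task = c("expressionmap", "matching"),
                               seed = 1L) {
  task <- match.arg(task)
  grid <- tidyr::crossing(
    emotion = am_emotions, actor = 1:4, repetition = 1:4
  )
  withr::with_seed(seed, {
    if (task == "matching") {
      start <- unlist(lapply(am_emotions, function(e) {
        sample(seq(50, 200, by = 10))
      }))
    } else {
      start <- runif(nrow(grid), 25, 300)
    }
    grid |>
      dplyr::mutate(
        task = task,
        start_speed_pct = start,
        dial_min_pct = 25,
        dial_max_pct = 300
      ) |>
      dplyr::select(
        "task", "actor", "emotion", "repetition",
        "start_speed_pct", "dial_min_pct", "dial_max_pct"
      )
  })
}

#' Enumerate the point-light emotion recognition design
#'
#' The full crossing of 4 actors x 3 emotions x 3 spatial-exaggeration
#' levels x 3 kinematic (speed) levels, one trial per cell: 108 trials,
#' 12 per spatial x kinematic condition.
#'
#' @return A 108-row tibble with columns `actor`, `emotion`,
#'   `spatial_level`, `kinematic_level` (levels in percent of the recorded
#'   stimulus).
#' @export
build_recognition_design <- function() {
  tidyr::crossing(
    actor = 1:4,
    emotion = am_emotions,
    spatial_level = c(50, 100, 150),
    kinematic_level = c(50, 100, 150)
  )
}

#' Build all task designs at once
#'
#' @param seed Integer seed passed to the seeded designs.
#' @return A named list with elements `emopair`, `triplet` (all four
#'   conditions row-bound), `expressionmap`, `matching`, `recognition`.
#' @export
build_designs <- function(seed = 1L) {
  list(
    emopair = build_emopair_design(),
    triplet = dplyr::bind_rows(lapply(
      c(am_emotions, "color_control"),
      function(cond) build_triplet_design(cond, seed = seed)
    )),
    expressionmap = build_speed_design("expressionmap", seed = seed),
    matching = build_speed_design("matching", seed = seed),
    recognition = build_recognition_design()
  )
}

#' Write the design tables to CSV
#'
#' One file per design, plain numbers throughout (percentages carry no sign).
#'
#' @param designs A list as returned by [build_designs()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_designs <- function(designs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(designs, function(tbl, name) {
    path <- file.path(dir, paste0("design_", name, ".csv"))
    readr::write_csv(tbl, path)
    path
  })
  invisible(paths)
}
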