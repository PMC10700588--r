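#' Run the simulate -> score -> model -> report pipeline
#'
#' Orchestrates the full analysis on a synthetic cohort: simulate responses
#' for every task, score them into the wide participant table, run the
#' model search (importance screening, sequential building, path-reversal
#' comparison), and write a human-readable report. Each stage writes its
#' outputs under `out_dir` and later stages re-read them, so stages can be
#' re-run individually; a manifest records the seed and a config hash so
#' identical runs are byte-identical.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param seed Master seed (defaults to the config's).
#' @param stages Subset of `c("simulate", "score", "model", "report")`.
#' @param embed Whether scoring embeds the similarity ratings (the slowest
#'   step).
#' @param outcome,candidates,latent_map Model-search options; sensible
#'   defaults cover the standard score table.
#' @param screen_iter Shadow iterations for [screen_importance()].
#' @param alpha LRT level for [sequential_build()].
#' @return Invisibly, a list with the stage artifacts that were produced.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         seed = config$seed,
                         stages = c("simulate", "score", "model", "report"),
                         embed = TRUE,
                         outcome = "accuracy",
                         candidates = NULL,
                         latent_map = NULL,
                         screen_iter = 100L,
                         alpha = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "seed")])
  artifacts <- list()
  response_files <- c(
    similarity = "responses_similarity.csv",
    choices = "responses_choices.csv",
    expressionmap = "responses_expressionmap.csv",
    matching = "responses_matching.csv",
    recognition = "responses_recognition.csv"
  )

  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(config, seed = seed)
    write_designs(cohort$designs, out_dir)
    for (nm in names(response_files)) {
      readr::write_csv(cohort[[nm]], file.path(out_dir, response_files[nm]))
    }
    traits <- dplyr::select(
      cohort$profiles, "participant_id", "aq", "tas", "nvr"
    )
    readr::write_csv(traits, file.path(out_dir, "participants.csv"))
    artifacts$cohort <- cohort
  }

  if ("score" %in% stages) {
    # always score from the on-disk responses so a score-only rerun is
    # byte-identical to a combined simulate + score run
    paths <- file.path(out_dir, response_files)
    if (!all(file.exists(paths))) {
      abort(
        paste0(
          "score stage: missing response files: ",
          paste(response_files[!file.exists(paths)], collapse = ", ")
        ),
        class = "affectmap_stage_score"
      )
    }
    score_input <- lapply(response_files, function(f) {
      readr::read_csv(file.path(out_dir, f), show_col_types = FALSE)
    })
    score_input$profiles <- readr::read_csv(
      file.path(out_dir, "participants.csv"),
      show_col_types = FALSE
    )
    score_input$config <- config
    if (is.null(artifacts$cohort)) artifacts$cohort <- score_input
    scores <- score_cohort(score_input, embed = embed, seed = seed)
    readr::write_csv(scores, file.path(out_dir, "scores.csv"))
    artifacts$scores <- scores
  }

  if ("model" %in% stages) {
    if (is.null(artifacts$scores)) {
      sp <- file.path(out_dir, "scores.csv")
      if (!file.exists(sp)) {
        abort("model stage: scores.csv not found; run the score stage",
          class = "affectmap_stage_model"
        )
      }
      artifacts$scores <- readr::read_csv(sp, show_col_types = FALSE)
    }
    scores <- artifacts$scores
    if (is.null(candidates)) {
      candidates <- intersect(
        c(
          "emotional_consistency", "mean_rep_consistency",
          "matching_difficulty", "representation_matching",
          "mean_rep_distance", "mean_between", "mean_within",
          "consistency_control", "aq", "tas", "nvr"
        ),
        names(scores)
      )
    }
    if (is.null(latent_map)) {
      latent_map <- default_latent_map(scores)
    }
    screen <- screen_importance(
      scores, outcome, candidates,
      n_iter = screen_iter, seed = seed
    )
    build <- sequential_build(
      scores, outcome, screen,
      latent_map = latent_map, alpha = alpha, seed = seed
    )
    model_out <- list(
      seed = seed, config_hash = cfg_hash,
      importance = as.data.frame(screen),
      build_log = as.data.frame(build$log),
      entered = build$entered
    )
    if (!is.null(build$fit) && nrow(build$spec$paths)) {
      rev <- reverse_path_search(build$fit, scores, seed = seed)
      model_out$reversal <- as.data.frame(rev$report)
      model_out$final <- list(
        paths = as.data.frame(rev$final_spec$paths),
        latent = rev$final_spec$latent,
        estimates = as.data.frame(tidy(rev$final_fit)),
        fit = as.data.frame(glance(rev$final_fit))
      )
      artifacts$final_fit <- rev$final_fit
      artifacts$reversal <- rev
    }
    artifacts$screen <- screen
    artifacts$build <- build
    jsonlite::write_json(
      model_out, file.path(out_dir, "model.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  if ("report" %in% stages) {
    lines <- c(
      "affectmap pipeline report",
      sprintf("seed: %d  config_hash: %s", seed, cfg_hash),
      ""
    )
    if (!is.null(artifacts$cohort$choices)) {
      counts <- c(
        similarity = nrow(artifacts$cohort$similarity),
        choices = nrow(artifacts$cohort$choices),
        expressionmap = nrow(artifacts$cohort$expressionmap),
        matching = nrow(artifacts$cohort$matching),
        recognition = nrow(artifacts$cohort$recognition)
      )
      n_p <- length(unique(artifacts$cohort$choices$participant_id))
      expected <- n_p * c(105L, 220L, 48L, 48L, 108L)
      lines <- c(lines, "response row counts (observed / expected):",
        sprintf(
          "  %-14s %7d / %7d", names(counts), counts, expected
        ), ""
      )
    }
    if (!is.null(artifacts$final_fit)) {
      eff <- effects_table(artifacts$final_fit)
      lines <- c(
        lines, "final model direct effects:",
        utils::capture.output(print(as.data.frame(eff), digits = 3))
      )
    }
    writeLines(lines, file.path(out_dir, "report.txt"))
  }

  jsonlite::write_json(
    list(
      seed = seed, config_hash = cfg_hash,
      stages = stages, files = sort(list.files(out_dir))
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(artifacts)
}

#' Build the small bundled test cohort
#'
#' A deterministic 12-participant cohort spanning extreme latent profiles,
#' used throughout the test suite: a noiseless experiencer (zero experience
#' noise and lapse probability, so all consistency scores hit the maximum),
#' a perfectly consistent representer (zero representation noise), a
#' perfect matcher (zero matching noise), a high-noise participant and a
#' lapse-prone participant, plus unremarkable cohort members.
#'
#' @param seed Integer seed.
#' @return An `affectmap_cohort` list (profiles, designs, response tables).
#' @export
make_fixtures <- function(seed = 42L) {
  config <- cohort_config(n_participants = 12L, seed = seed)
  designs <- build_designs(seed = seed)
  profiles <- generate_profiles(config)
  profiles$sigma_exp[1] <- 0
  profiles$sigma_control[1] <- 0
  profiles$lapse_prob[1] <- 0
  profiles$sigma_rep[2] <- 0
  profiles$sigma_match[3] <- 0
  profiles$sigma_exp[4] <- 5
  profiles$sigma_rep[4] <- 3
  profiles$lapse_prob[5] <- 0.5
  em <- simulate_emomap(profiles, designs, seed = seed + 101L)
  sm <- simulate_expression_matching(
    profiles, designs,
    seed = seed + 202L, base_speeds = config$base_speeds
  )
  rec <- simulate_recognition(
    profiles, designs,
    seed = seed + 303L, base_speeds = config$base_speeds
  )
  structure(
    list(
      profiles = profiles, designs = designs,
      similarity = em$similarity, choices = em$choices,
      expressionmap = sm$expressionmap, matching = sm$matching,
      recognition = rec, config = config, seed = as.integer(seed)
    ),
    class = "affectmap_cohort"
  )
}
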