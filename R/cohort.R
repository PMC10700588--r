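#' Default recorded facial-movement speeds per actor and emotion
#'
#' Latent stimulus property used both by the simulator and by the scorers
#' when converting attributed percent speeds to pixels/frame. Emotion-level
#' speeds follow the characteristic ordering of expression kinematics
#' (anger fastest, sadness slowest: 3.85, 2.80, 1.63 pixels/frame), scaled
#' by a fixed per-actor factor.
#'
#' @return A tibble with columns `actor`, `emotion`, `base_speed`
#'   (pixels/frame).
#' @export
default_base_speeds <- function() {
  emo_speed <- c(anger = 3.85, happiness = 2.80, sadness = 1.63)
  actor_factor <- c(0.90, 1.00, 1.05, 1.15)
  tidyr::crossing(actor = 1:4, emotion = am_emotions) |>
    dplyr::mutate(
      base_speed = unname(
        emo_speed[.data$emotion] * actor_factor[.data$actor]
      )
    )
}

#' Configuration for a synthetic cohort
#'
#' Collects every distributional choice behind the generative model in one
#' place. The generator assumes a 2-D latent affect plane (axes interpretable
#' as valence/arousal) on which each participant's emotion clusters sit at a
#' distance governed by their modularity; experienced affect is the latent
#' position plus isotropic noise of scale `sigma_exp`. Visual representation
#' speeds per emotion are latent set-points sampled around the default
#' stimulus speeds with per-trial noise `sigma_rep`. The precision of
#' experience (1/sigma_exp) and of representation (1/sigma_rep) are coupled
#' across participants through a Gaussian copula with correlation
#' `rho_cons` — the generative experience-to-representation link the
#' recovery analyses target.
#'
#' @param n_participants Cohort size (>= 1).
#' @param seed Integer seed recorded in the config.
#' @param rho_cons Copula correlation between experiential and
#'   representational precision, in \[-1, 1\].
#' @param modularity_meanlog,modularity_sdlog Lognormal parameters of the
#'   cluster-separation radius (affect-plane units).
#' @param image_spread SD of image positions around their cluster centre.
#' @param lambda Length scale of the similarity kernel mapping affect-plane
#'   distance to the 0-10 similarity scale.
#' @param intensity_mean,intensity_sd Normal parameters of latent per-image
#'   evoked intensity in the triplet conditions (the stimulus set is
#'   calibrated so conditions share mean ~3.5 and SD ~0.8).
#' @param prec_exp_meanlog,prec_exp_sdlog Lognormal parameters of
#'   experiential precision 1/sigma_exp.
#' @param prec_control_meanlog,prec_control_sdlog Lognormal parameters of
#'   the perceptual (colourfulness-control) precision 1/sigma_control,
#'   drawn independently of the emotional noise scales.
#' @param prec_rep_meanlog,prec_rep_sdlog Lognormal parameters of
#'   representational precision 1/sigma_rep (pixels/frame scale).
#' @param sigma_match_meanlog,sigma_match_sdlog Lognormal parameters of the
#'   matching noise SD (percent points).
#' @param lapse_shape1,lapse_shape2 Beta parameters of the trap-selection
#'   lapse probability.
#' @param rep_speed_sd SD of a participant's latent representation speed
#'   around the emotion's recorded speed (pixels/frame).
#' @param tau Width of the recognition rating kernel (pixels/frame).
#' @param rating_noise SD of additive rating noise on the 0-10 scales.
#' @param deploy_via_matching If `TRUE` (default), the per-trial deployment
#'   noise of a representation during recognition is
#'   `sigma_rep * sigma_match / match_ref`: consistent representations help
#'   most when matching ability is poor, the moderation the
#'   representation-matching composite is designed to capture. If `FALSE`
#'   deployment noise is `sigma_rep` alone.
#' @param match_ref Reference matching noise (percent points) at which
#'   deployment noise equals `sigma_rep`.
#' @param aq_mean,aq_sd,tas_mean,tas_sd,nvr_mean,nvr_sd Trait covariate
#'   distributions (autistic traits 0-50, alexithymia 20-100, non-verbal
#'   reasoning percent), defaults matching a typical online adult sample.
#' @param base_speeds Recorded stimulus speeds, see [default_base_speeds()].
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_participants = 100L,
                          seed = 1L,
                          rho_cons = 0.6,
                          modularity_meanlog = log(3),
                          modularity_sdlog = 0.25,
                          image_spread = 1,
                          lambda = 4,
                          intensity_mean = 3.5,
                          intensity_sd = 0.8,
                          prec_exp_meanlog = log(1 / 0.8),
                          prec_exp_sdlog = 0.5,
                          prec_control_meanlog = log(1 / 0.8),
                          prec_control_sdlog = 0.5,
                          prec_rep_meanlog = log(1 / 0.5),
                          prec_rep_sdlog = 0.5,
                          sigma_match_meanlog = log(30),
                          sigma_match_sdlog = 0.4,
                          lapse_shape1 = 1,
                          lapse_shape2 = 40,
                          rep_speed_sd = 0.45,
                          tau = 1.0,
                          rating_noise = 0.4,
                          deploy_via_matching = TRUE,
                          match_ref = 30,
                          aq_mean = 18.9, aq_sd = 6.8,
                          tas_mean = 48.1, tas_sd = 11.6,
                          nvr_mean = 61.2, nvr_sd = 14.8,
                          base_speeds = default_base_speeds()) {
  cfg <- as.list(environment())
  if (!is.numeric(n_participants) || n_participants < 1) {
    abort("`n_participants` must be >= 1", class = "affectmap_bad_config")
  }
  if (abs(rho_cons) > 1) {
    abort("`rho_cons` must lie in [-1, 1]", class = "affectmap_bad_config")
  }
  if (any(base_speeds$base_speed <= 0)) {
    abort("base speeds must be positive", class = "affectmap_bad_config")
  }
  cfg$n_participants <- as.integer(n_participants)
  structure(cfg, class = "cohort_config")
}

# Cluster centres on the affect plane at radius m. Anger and sadness sit
# 60 degrees apart, both far from happiness, so the anger-sadness clusters
# overlap most — the asymmetry typical of valence/arousal geometry.
cluster_centres <- function(m) {
  angle <- c(anger = 240, happiness = 90, sadness = 300) * pi / 180
  tibble::tibble(
    category = names(angle),
    cx = m * cos(angle),
    cy = m * sin(angle)
  )
}

#' Draw latent participant profiles
#'
#' Samples one [cohort_config()] realisation: per-participant modularity,
#' noise scales (via the precision copula), lapse probability, trait
#' covariates, per-image affect-plane positions, per-condition latent image
#' intensities, and per-emotion representation speeds.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant; scalar parameters as
#'   columns plus nested list-columns `affect_pos` (image, x, y),
#'   `target_intensity` (condition, image, intensity) and `rep_speed`
#'   (emotion, speed).
#' @export
generate_profiles <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  withr::with_seed(config$seed, {
    z1 <- rnorm(n)
    z2 <- config$rho_cons * z1 + sqrt(1 - config$rho_cons^2) * rnorm(n)
    prec_exp <- exp(config$prec_exp_meanlog + config$prec_exp_sdlog * z1)
    prec_rep <- exp(config$prec_rep_meanlog + config$prec_rep_sdlog * z2)
    prec_ctl <- stats::rlnorm(
      n, config$prec_control_meanlog, config$prec_control_sdlog
    )
    profiles <- tibble::tibble(
      participant_id = sprintf("p%04d", seq_len(n)),
      modularity = stats::rlnorm(
        n, config$modularity_meanlog, config$modularity_sdlog
      ),
      sigma_exp = 1 / prec_exp,
      sigma_rep = 1 / prec_rep,
      sigma_control = 1 / prec_ctl,
      sigma_match = stats::rlnorm(
        n, config$sigma_match_meanlog, config$sigma_match_sdlog
      ),
      lapse_prob = stats::rbeta(n, config$lapse_shape1, config$lapse_shape2),
      aq = clip(round(rnorm(n, config$aq_mean, config$aq_sd)), 0, 50),
      tas = clip(round(rnorm(n, config$tas_mean, config$tas_sd)), 20, 100),
      nvr = clip(rnorm(n, config$nvr_mean, config$nvr_sd), 0, 100),
      lambda = config$lambda,
      tau = config$tau,
      rating_noise = config$rating_noise
    )
    pair_images <- build_emopair_design()
    image_tbl <- tibble::tibble(
      image = unique(c(pair_images$image_a, pair_images$image_b))
    ) |>
      dplyr::mutate(category = sub("_[0-9]+$", "", .data$image))
    emo_speed <- dplyr::summarise(
      config$base_speeds,
      base = mean(.data$base_speed), .by = "emotion"
    )
    nest_by_participant <- function(df, col) {
      df |>
        tidyr::nest(.by = "participant_id", .key = col) |>
        dplyr::arrange(match(.data$participant_id, profiles$participant_id))
    }
    pos_all <- tidyr::crossing(
      participant_id = profiles$participant_id, image_tbl
    ) |>
      dplyr::left_join(
        dplyr::select(profiles, "participant_id", "modularity"),
        by = "participant_id"
      )
    ang <- c(anger = 240, happiness = 90, sadness = 300) * pi / 180
    pos_all <- pos_all |>
      dplyr::mutate(
        x = .data$modularity * cos(ang[.data$category]) +
          rnorm(dplyr::n(), 0, config$image_spread),
        y = .data$modularity * sin(ang[.data$category]) +
          rnorm(dplyr::n(), 0, config$image_spread)
      ) |>
      dplyr::select("participant_id", "image", "x", "y")
    conds <- c(am_emotions, "color_control")
    int_all <- tidyr::crossing(
      participant_id = profiles$participant_id,
      tibble::tibble(
        condition = rep(conds, each = 11L),
        image = unlist(lapply(conds, function(cond) {
          prefix <- if (cond == "color_control") "neutral" else cond
          sprintf("%s_t%02d", prefix, 1:11)
        }))
      )
    ) |>
      dplyr::mutate(
        intensity = rnorm(
          dplyr::n(), config$intensity_mean, config$intensity_sd
        )
      )
    speed_all <- tidyr::crossing(
      participant_id = profiles$participant_id,
      tibble::tibble(emotion = emo_speed$emotion, base = emo_speed$base)
    ) |>
      dplyr::mutate(
        speed = pmax(
          rnorm(dplyr::n(), .data$base, config$rep_speed_sd), 0.05
        )
      ) |>
      dplyr::select("participant_id", "emotion", "speed")
    profiles$affect_pos <- nest_by_participant(pos_all, "affect_pos")$affect_pos
    profiles$target_intensity <-
      nest_by_participant(int_all, "target_intensity")$target_intensity
    profiles$rep_speed <- nest_by_participant(speed_all, "rep_speed")$rep_speed
    profiles
  })
}

unnest_profile_col <- function(profiles, col) {
  profiles |>
    dplyr::select("participant_id", dplyr::all_of(col)) |>
    tidyr::unnest(dplyr::all_of(col))
}

#' Simulate the affect-similarity and triplet-choice tasks
#'
#' Pair similarity is a monotone kernel of the distance between the two
#' images' noisy affect-plane positions, `10 * exp(-d / lambda)`, reported
#' at the task's 4-decimal resolution. Triplet choices are the argmax of
#' noisy evoked intensity over the two targets; with probability
#' `lapse_prob` the trap is selected first (an attention lapse), the trial
#' is retried once with fresh noise, and only the final target choice plus
#' a lapse flag are recorded, mirroring the task's forced retry.
#'
#' @param profiles Output of [generate_profiles()].
#' @param designs Output of [build_designs()].
#' @param seed Integer seed.
#' @return A list with tibbles `similarity` (participant_id, trial, image_a,
#'   image_b, similarity) and `choices` (participant_id, condition, trial,
#'   target_a, target_b, trap_image, chosen, unchosen, lapsed).
#' @export
simulate_emomap <- function(profiles, designs = build_designs(), seed = 1L) {
  pos <- unnest_profile_col(profiles, "affect_pos")
  intensity <- unnest_profile_col(profiles, "target_intensity")
  withr::with_seed(seed, {
    sim <- profiles |>
      dplyr::select("participant_id", "sigma_exp", "lambda") |>
      dplyr::cross_join(designs$emopair) |>
      dplyr::left_join(
        dplyr::rename(pos, image_a = "image", xa = "x", ya = "y"),
        by = c("participant_id", "image_a")
      ) |>
      dplyr::left_join(
        dplyr::rename(pos, image_b = "image", xb = "x", yb = "y"),
        by = c("participant_id", "image_b")
      )
    nr <- nrow(sim)
    dx <- (sim$xa + rnorm(nr) * sim$sigma_exp) -
      (sim$xb + rnorm(nr) * sim$sigma_exp)
    dy <- (sim$ya + rnorm(nr) * sim$sigma_exp) -
      (sim$yb + rnorm(nr) * sim$sigma_exp)
    sim$similarity <- round(10 * exp(-sqrt(dx^2 + dy^2) / sim$lambda), 4)

    cho <- profiles |>
      dplyr::select(
        "participant_id", "sigma_exp", "sigma_control", "lapse_prob"
      ) |>
      dplyr::cross_join(designs$triplet) |>
      dplyr::mutate(noise_sd = ifelse(
        .data$condition == "color_control",
        .data$sigma_control, .data$sigma_exp
      )) |>
      dplyr::left_join(
        dplyr::rename(intensity, target_a = "image", mu_a = "intensity"),
        by = c("participant_id", "condition", "target_a")
      ) |>
      dplyr::left_join(
        dplyr::rename(intensity, target_b = "image", mu_b = "intensity"),
        by = c("participant_id", "condition", "target_b")
      )
    nc <- nrow(cho)
    ia1 <- cho$mu_a + rnorm(nc) * cho$noise_sd
    ib1 <- cho$mu_b + rnorm(nc) * cho$noise_sd
    lapsed <- runif(nc) < cho$lapse_prob
    # retry draw, used only on lapsed trials
    ia2 <- cho$mu_a + rnorm(nc) * cho$noise_sd
    ib2 <- cho$mu_b + rnorm(nc) * cho$noise_sd
    pick_a <- ifelse(lapsed, ia2 >= ib2, ia1 >= ib1)
    cho$chosen <- ifelse(pick_a, cho$target_a, cho$target_b)
    cho$unchosen <- ifelse(pick_a, cho$target_b, cho$target_a)
    cho$lapsed <- lapsed
    list(
      similarity = dplyr::select(
        sim, "participant_id", "trial", "image_a", "image_b", "similarity"
      ),
      choices = dplyr::select(
        cho, "participant_id", "condition", "trial", "target_a", "target_b",
        "trap_image", "chosen", "unchosen", "lapsed"
      )
    )
  })
}

#' Simulate the speed-attribution and visual-matching tasks
#'
#' Expression task: the attributed true speed on each trial is
#' `Normal(s_e, sigma_rep)` around the participant's latent representation
#' speed for that emotion, converted to percent of the actor's recorded
#' speed and clipped to the 25-300% dial. Matching task: the attributed
#' percent is `Normal(target, sigma_match)` around the displayed video's
#' percent speed (independent of the dial's random starting position),
#' clipped to the dial.
#'
#' @inheritParams simulate_emomap
#' @param base_speeds Recorded speeds, see [default_base_speeds()].
#' @return A list with tibbles `expressionmap` and `matching`, both keyed by
#'   participant_id, actor, emotion, repetition, with `attributed_pct` (and
#'   `target_pct` for matching).
#' @export
simulate_expression_matching <- function(profiles,
                                         designs = build_designs(),
                                         seed = 1L,
                                         base_speeds = default_base_speeds()) {
  speeds <- unnest_profile_col(profiles, "rep_speed")
  withr::with_seed(seed, {
    expr <- profiles |>
      dplyr::select("participant_id", "sigma_rep") |>
      dplyr::cross_join(designs$expressionmap) |>
      dplyr::left_join(speeds, by = c("participant_id", "emotion")) |>
      dplyr::left_join(base_speeds, by = c("actor", "emotion"))
    attributed_speed <- rnorm(nrow(expr), expr$speed, expr$sigma_rep)
    expr$attributed_pct <- clip(
      100 * attributed_speed / expr$base_speed,
      expr$dial_min_pct, expr$dial_max_pct
    )
    mat <- profiles |>
      dplyr::select("participant_id", "sigma_match") |>
      dplyr::cross_join(designs$matching)
    mat$target_pct <- mat$start_speed_pct
    mat$attributed_pct <- clip(
      rnorm(nrow(mat), mat$target_pct, mat$sigma_match),
      mat$dial_min_pct, mat$dial_max_pct
    )
    list(
      expressionmap = dplyr::select(
        expr, "participant_id", "actor", "emotion", "repetition",
        "start_speed_pct", "attributed_pct"
      ),
      matching = dplyr::select(
        mat, "participant_id", "actor", "emotion", "repetition",
        "target_pct", "attributed_pct"
      )
    )
  })
}

#' Simulate the point-light emotion recognition task
#'
#' The stimulus plays at `base_speed * kinematic_level / 100` pixels/frame.
#' For each of the three rating scales the participant deploys their stored
#' representation of that emotion, sampling
#' `shat ~ Normal(s_e, sigma_deploy)`, and rates
#' `10 * exp(-(v_stim - shat)^2 / (2 tau^2))` plus rating noise, bounded to
#' \[0, 10\] at the task's 3-decimal resolution: stimuli moving at the
#' speed of their representation of an emotion are rated high on that
#' emotion's scale. By default the deployment noise is
#' `sigma_rep * sigma_match / match_ref` — an inconsistent representation
#' is most costly when visual matching ability is also poor, which is the
#' moderation the representation-matching composite indexes; with
#' `deploy_via_matching = FALSE` it is `sigma_rep` alone.
#'
#' @inheritParams simulate_expression_matching
#' @param deploy_via_matching,match_ref See [cohort_config()].
#' @return A tibble keyed by participant_id, actor, emotion, spatial_level,
#'   kinematic_level with columns `rating_anger`, `rating_happiness`,
#'   `rating_sadness`.
#' @export
simulate_recognition <- function(profiles,
                                 designs = build_designs(),
                                 seed = 1L,
                                 base_speeds = default_base_speeds(),
                                 deploy_via_matching = TRUE,
                                 match_ref = 30) {
  speeds_wide <- unnest_profile_col(profiles, "rep_speed") |>
    tidyr::pivot_wider(
      names_from = "emotion", values_from = "speed", names_prefix = "s_"
    )
  withr::with_seed(seed, {
    rec <- profiles |>
      dplyr::select(
        "participant_id", "sigma_rep", "sigma_match", "tau", "rating_noise"
      ) |>
      dplyr::cross_join(designs$recognition) |>
      dplyr::left_join(speeds_wide, by = "participant_id") |>
      dplyr::left_join(base_speeds, by = c("actor", "emotion"))
    rec$sigma_deploy <- if (deploy_via_matching) {
      rec$sigma_rep * rec$sigma_match / match_ref
    } else {
      rec$sigma_rep
    }
    v_stim <- rec$base_speed * rec$kinematic_level / 100
    nr <- nrow(rec)
    for (e in am_emotions) {
      shat <- rnorm(nr, rec[[paste0("s_", e)]], rec$sigma_deploy)
      raw <- 10 * exp(-(v_stim - shat)^2 / (2 * rec$tau^2)) +
        rnorm(nr, 0, rec$rating_noise)
      rec[[paste0("rating_", e)]] <- round(clip(raw, 0, 10), 3)
    }
    dplyr::select(
      rec, "participant_id", "actor", "emotion", "spatial_level",
      "kinematic_level", dplyr::starts_with("rating_")
    )
  })
}

#' Simulate a full cohort across all tasks
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; task-level seeds are derived from it. Defaults
#'   to the config's seed.
#' @param tasks Character subset of
#'   `c("emomap", "expression_matching", "recognition")`.
#' @return A list of class `affectmap_cohort` with elements `profiles`,
#'   `designs`, the response tibbles (`similarity`, `choices`,
#'   `expressionmap`, `matching`, `recognition`), `config` and `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            seed = config$seed,
                            tasks = c(
                              "emomap", "expression_matching", "recognition"
                            )) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  config$seed <- as.integer(seed)
  designs <- build_designs(seed = config$seed)
  profiles <- generate_profiles(config)
  out <- list(
    profiles = profiles, designs = designs,
    config = config, seed = config$seed
  )
  if ("emomap" %in% tasks) {
    em <- simulate_emomap(profiles, designs, seed = config$seed + 101L)
    out$similarity <- em$similarity
    out$choices <- em$choices
  }
  if ("expression_matching" %in% tasks) {
    sm <- simulate_expression_matching(
      profiles, designs,
      seed = config$seed + 202L, base_speeds = config$base_speeds
    )
    out$expressionmap <- sm$expressionmap
    out$matching <- sm$matching
  }
  if ("recognition" %in% tasks) {
    out$recognition <- simulate_recognition(
      profiles, designs,
      seed = config$seed + 303L, base_speeds = config$base_speeds,
      deploy_via_matching = config$deploy_via_matching,
      match_ref = config$match_ref
    )
  }
  structure(out, class = "affectmap_cohort")
}

#' Read and write cohort configurations as YAML
#'
#' The full set of generator parameters round-trips through a plain YAML
#' file, so a simulation is reproducible from its config and seed alone.
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  out$base_speeds <- lapply(
    seq_len(nrow(config$base_speeds)),
    function(i) as.list(config$base_speeds[i, ])
  )
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$base_speeds <- dplyr::bind_rows(
    lapply(raw$base_speeds, tibble::as_tibble)
  )
  do.call(cohort_config, raw)
}
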