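#' Shadow-feature importance screening
#'
#' Classifies candidate predictors of an outcome as confirmed, rejected or
#' tentative by comparing random-forest permutation importance against
#' "shadow" copies of the candidates (each column independently permuted,
#' destroying any real association while preserving its marginal
#' distribution). On each iteration fresh shadows are appended, a forest is
#' grown, and a candidate scores a hit when its importance exceeds the
#' maximum shadow importance. Hit counts over iterations are assessed with
#' a two-sided binomial test against chance (p = 0.5).
#'
#' @param data Wide score table, one row per participant.
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param n_iter Number of shadow iterations.
#' @param alpha Two-sided binomial significance level for the
#'   confirmed/rejected decision.
#' @param num_trees Trees per forest.
#' @param seed Integer seed.
#' @return A tibble of class `affectmap_importance`, ordered by mean
#'   importance: `variable`, `decision`, `hits`, `n_iter`, `p_value`,
#'   `mean_importance`, `mean_shadow_max`; the per-iteration importance
#'   history is kept in the `"history"` attribute.
#' @export
screen_importance <- function(data, outcome, candidates,
                              n_iter = 100L, alpha = 0.01,
                              num_trees = 200L, seed = 1L) {
  cols <- c(outcome, candidates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "missing columns: ", paste(missing_cols, collapse = ", ")
    ), class = "affectmap_bad_input")
  }
  df <- as.data.frame(data[, cols])
  if (any(!complete.cases(df))) {
    abort("rows with missing values are not supported",
      class = "affectmap_bad_input"
    )
  }
  sds <- vapply(df, sd, numeric(1))
  if (any(sds == 0)) {
    abort(paste0(
      "constant columns: ", paste(cols[sds == 0], collapse = ", ")
    ), class = "affectmap_bad_input")
  }
  if (nrow(df) < 25L) {
    abort("too few rows for a stable ensemble (need >= 25)",
      class = "affectmap_bad_input"
    )
  }
  shadow_names <- paste0("shadow_", candidates)
  history <- matrix(
    NA_real_, n_iter, length(candidates),
    dimnames = list(NULL, candidates)
  )
  shadow_max <- numeric(n_iter)
  hits <- setNames(integer(length(candidates)), candidates)
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      aug <- df
      for (k in seq_along(candidates)) {
        aug[[shadow_names[k]]] <- sample(df[[candidates[k]]])
      }
      rf <- ranger::ranger(
        dependent.variable.name = outcome, data = aug,
        num.trees = num_trees, importance = "permutation",
        seed = sample.int(.Machine$integer.max, 1L),
        num.threads = 1L
      )
      imp <- rf$variable.importance
      history[it, ] <- imp[candidates]
      shadow_max[it] <- max(imp[shadow_names])
      hits <- hits + as.integer(imp[candidates] > shadow_max[it])
    }
  })
  p_two <- vapply(hits, function(h) {
    lo <- pbinom(h, n_iter, 0.5)
    hi <- pbinom(h - 1L, n_iter, 0.5, lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  out <- tibble::tibble(
    variable = candidates,
    hits = as.integer(hits),
    n_iter = as.integer(n_iter),
    p_value = p_two,
    mean_importance = colMeans(history),
    mean_shadow_max = mean(shadow_max),
    decision = dplyr::case_when(
      p_two < alpha & hits > n_iter / 2 ~ "confirmed",
      p_two < alpha & hits < n_iter / 2 ~ "rejected",
      .default = "tentative"
    )
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_importance))
  attr(out, "history") <- history
  class(out) <- c("affectmap_importance", class(out))
  out
}

#' Default latent measurement map for the standard score table
#'
#' The constructs scored per emotion — recognition accuracy, emotional
#' consistency, the representation-matching composite, and (when the
#' landscape was embedded) between-cluster distance — are modelled as
#' latent variables with their three per-emotion scores as indicators;
#' every other measure stays manifest. Construct names deliberately match
#' the participant-level mean columns used at the screening step, so a
#' screened variable can enter the structural model as its latent
#' counterpart.
#'
#' @param scores Wide score table (used to drop constructs whose indicator
#'   columns are absent).
#' @return Named list mapping construct names to indicator columns.
#' @export
default_latent_map <- function(scores) {
  map <- list(
    accuracy = paste0("accuracy_", am_emotions),
    emotional_consistency = paste0("consistency_", am_emotions),
    representation_matching = paste0(
      "representation_matching_", am_emotions
    ),
    mean_between = c(
      "between_anger_happiness", "between_anger_sadness",
      "between_happiness_sadness"
    )
  )
  keep <- vapply(
    map, function(ind) all(ind %in% names(scores)), logical(1)
  )
  map[keep]
}

# Internal: spec covering `vars` (outcome + entered predictors), all
# predictors pointing at the outcome, latents expanded per `latent_map`.
build_outcome_spec <- function(outcome, predictors, latent_map,
                               zero_covariances = list()) {
  vars <- c(outcome, predictors)
  model_spec(
    paths = tibble::tibble(
      from = predictors, to = rep(outcome, length(predictors))
    ),
    latent = latent_map[intersect(names(latent_map), vars)],
    zero_covariances = zero_covariances
  )
}

#' Sequential structural-model building
#'
#' Starting from the outcome alone, candidate predictors enter the model in
#' descending order of screened importance. Each addition (a direct path
#' from the candidate to the outcome) is kept only if it improves fit
#' significantly — a likelihood-ratio test against the same variable set
#' with that path constrained to zero, at level `alpha` — and building
#' stops at the first rejected addition.
#'
#' @param data Wide score table.
#' @param outcome Outcome variable (manifest column or latent name).
#' @param importance An `affectmap_importance` report (its confirmed
#'   variables are used, most important first) or a character vector already
#'   in entry order.
#' @param latent_map Named list mapping latent construct names (usable as
#'   outcome or candidates) to indicator columns.
#' @param alpha LRT significance level for keeping an addition.
#' @param ... Passed to [fit_path_model()].
#' @return A list: `fit` (final `affectmap_sem`), `spec`, `entered`
#'   (character), `log` (tibble: variable, statistic, df, p.value,
#'   entered).
#' @export
sequential_build <- function(data, outcome, importance,
                             latent_map = list(), alpha = 0.05, ...) {
  candidates <- if (inherits(importance, "affectmap_importance")) {
    importance$variable[importance$decision == "confirmed"]
  } else {
    as.character(importance)
  }
  entered <- character()
  log_rows <- list()
  current_fit <- NULL
  for (v in candidates) {
    alt_spec <- build_outcome_spec(outcome, c(entered, v), latent_map)
    null_spec <- build_outcome_spec(
      outcome, c(entered, v), latent_map,
      zero_covariances = list(c(v, outcome))
    )
    null_spec$paths <- dplyr::filter(
      null_spec$paths, !(.data$from == v & .data$to == outcome)
    )
    # keep v (and a path-less outcome) in the null model's variable set
    null_spec$manifest <- union(
      null_spec$manifest,
      setdiff(c(v, outcome), names(latent_map))
    )
    alt_fit <- fit_path_model(data, alt_spec, ...)
    null_fit <- fit_path_model(data, null_spec, ...)
    test <- lrt_sem(null_fit, alt_fit)
    keep <- is.finite(test$p.value) && test$p.value < alpha
    log_rows[[length(log_rows) + 1L]] <- dplyr::mutate(
      test,
      variable = v, entered = keep, .before = 1L
    )
    if (!keep) break
    entered <- c(entered, v)
    current_fit <- alt_fit
  }
  if (is.null(current_fit)) {
    base_spec <- if (outcome %in% names(latent_map)) {
      model_spec(latent = latent_map[outcome])
    } else {
      NULL
    }
    current_fit <- if (is.null(base_spec)) NULL else {
      fit_path_model(data, base_spec, ...)
    }
    spec <- base_spec
  } else {
    spec <- current_fit$spec
  }
  list(
    fit = current_fit, spec = spec, entered = entered,
    log = dplyr::bind_rows(log_rows)
  )
}

#' Systematic path-reversal comparison by BIC
#'
#' Each structural path of a fitted model is reversed one at a time, the
#' model refit, and the BIC difference recorded. Evidence follows the
#' conventional BIC rule: an absolute difference below 2 is a tie (the
#' original direction is retained — covariance-equivalent reversals such as
#' a lone two-variable path land here with a difference of 0), 2-6 is
#' positive and above 6 strong evidence for the lower-BIC direction. A
#' final model assembling every retained direction is refit and checked
#' against each of its own single-reversal variants.
#'
#' @param fit A fitted `affectmap_sem`.
#' @param data The score table the model was fitted to.
#' @param ... Passed to [fit_path_model()] for the refits.
#' @return A list: `report` (tibble: from, to, bic_original, bic_reversed,
#'   delta_bic, evidence, retained), `final_fit`, `final_spec`, and
#'   `final_check` (tibble comparing the final model with its
#'   single-reversal variants).
#' @export
reverse_path_search <- function(fit, data, ...) {
  spec <- fit$spec
  paths <- spec$paths
  if (!nrow(paths)) {
    abort("model has no structural paths to reverse",
      class = "affectmap_bad_input"
    )
  }
  refit_with <- function(new_paths) {
    sp <- spec
    sp$paths <- new_paths
    tryCatch(
      fit_path_model(data, sp, ...),
      error = function(e) NULL
    )
  }
  rows <- lapply(seq_len(nrow(paths)), function(r) {
    rev_paths <- paths
    rev_paths$from[r] <- paths$to[r]
    rev_paths$to[r] <- paths$from[r]
    if (anyDuplicated(paste(rev_paths$from, rev_paths$to))) {
      rev_fit <- NULL # reversal duplicates an existing path
    } else {
      rev_fit <- refit_with(rev_paths)
    }
    delta <- if (is.null(rev_fit) || !rev_fit$converged) {
      NA_real_
    } else {
      rev_fit$bic - fit$bic
    }
    evidence <- dplyr::case_when(
      is.na(delta) ~ "not_comparable",
      abs(delta) < 2 ~ "tie",
      delta >= 2 & delta <= 6 ~ "positive_original",
      delta > 6 ~ "strong_original",
      delta <= -2 & delta >= -6 ~ "positive_reversed",
      .default = "strong_reversed"
    )
    tibble::tibble(
      from = paths$from[r], to = paths$to[r],
      bic_original = fit$bic,
      bic_reversed = if (is.null(rev_fit)) NA_real_ else rev_fit$bic,
      delta_bic = delta,
      evidence = evidence,
      retained = ifelse(
        !is.na(delta) & delta < -2, "reversed", "original"
      )
    )
  })
  report <- dplyr::bind_rows(rows)
  final_paths <- paths
  flip <- which(report$retained == "reversed")
  if (length(flip)) {
    tmp <- final_paths$from[flip]
    final_paths$from[flip] <- final_paths$to[flip]
    final_paths$to[flip] <- tmp
  }
  final_fit <- if (length(flip)) refit_with(final_paths) else fit
  final_spec <- final_fit$spec
  # the retained model must not lose to any of its single-reversal variants
  check <- lapply(seq_len(nrow(final_paths)), function(r) {
    if (!length(flip)) {
      delta <- report$delta_bic[r]
    } else {
      rp <- final_paths
      rp$from[r] <- final_paths$to[r]
      rp$to[r] <- final_paths$from[r]
      vf <- if (anyDuplicated(paste(rp$from, rp$to))) NULL else {
        refit_with(rp)
      }
      delta <- if (is.null(vf)) NA_real_ else vf$bic - final_fit$bic
    }
    tibble::tibble(
      from = final_paths$from[r], to = final_paths$to[r],
      delta_bic_vs_reversal = delta,
      loses_strongly = !is.na(delta) & delta < -6
    )
  })
  list(
    report = report, final_fit = final_fit, final_spec = final_spec,
    final_check = dplyr::bind_rows(check)
  )
}

#' Least-squares association screen
#'
#' Participant-level ordinary least-squares fits of the score-table
#' associations (by default: does emotional consistency predict
#' representational consistency controlling for trait covariates and the
#' colourfulness-control consistency; do representational consistency and
#' the representation-matching composite predict recognition accuracy).
#' Plumbing for quick checks, not a substitute for the structural model.
#'
#' @param data Wide score table.
#' @param formulas Named list of model formulas; defaults cover the core
#'   associations when the columns are present.
#' @return A tibble: `model`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
association_screen <- function(data, formulas = NULL) {
  if (is.null(formulas)) {
    formulas <- list()
    has <- function(...) all(c(...) %in% names(data))
    if (has(
      "mean_rep_consistency", "emotional_consistency", "aq", "tas",
      "nvr", "consistency_control"
    )) {
      formulas$rep_consistency <- mean_rep_consistency ~
        emotional_consistency + aq + tas + nvr + consistency_control
    }
    if (has("accuracy", "mean_rep_consistency", "aq", "tas", "nvr")) {
      formulas$accuracy_rep <- accuracy ~ mean_rep_consistency +
        aq + tas + nvr
    }
    if (has("accuracy", "representation_matching", "aq", "tas", "nvr")) {
      formulas$accuracy_matching <- accuracy ~ representation_matching +
        aq + tas + nvr
    }
  }
  if (!length(formulas)) {
    abort("no applicable formulas for this table",
      class = "affectmap_bad_input"
    )
  }
  purrr::imap_dfr(formulas, function(f, nm) {
    fit <- lm(f, data = data)
    if (any(is.na(coef(fit)))) {
      abort(sprintf("rank-deficient fit in model \"%s\"", nm),
        class = "affectmap_rank_deficient"
      )
    }
    cf <- summary(fit)$coefficients
    tibble::tibble(
      model = nm,
      term = rownames(cf),
      estimate = cf[, 1L], std.error = cf[, 2L],
      statistic = cf[, 3L], p.value = cf[, 4L]
    )
  })
}
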