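#' Embed similarity judgments into a spatial affect landscape
#'
#' Similarity ratings on the 0-10 scale are converted to dissimilarities
#' `delta = 10 - similarity` and embedded by metric multidimensional scaling:
#' least-squares SMACOF stress majorization, initialised from classical
#' scaling with additional seeded random restarts, keeping the lowest-stress
#' solution. Stress is reported as Kruskal's stress-1,
#' `sqrt(sum((delta - d)^2) / sum(delta^2))`.
#'
#' @param similarity A tibble with columns `image_a`, `image_b`,
#'   `similarity` (one rating in \[0, 10\] per unordered pair of images).
#' @param n_dimensions Embedding dimensionality (2 by default: affect
#'   landscapes are conventionally read on a valence/arousal plane).
#' @param seed Seed for the random restarts.
#' @param n_restarts Number of starts (the first is classical scaling).
#' @param max_iter,tol Majorization iteration cap and relative stress
#'   convergence tolerance.
#' @return An object of class `landscape_embedding`: list with
#'   `coordinates` (tibble image, dim1, ...), `stress`, `n_dimensions`,
#'   `n_iter`.
#' @export
embed_landscape <- function(similarity, n_dimensions = 2L, seed = 1L,
                            n_restarts = 8L, max_iter = 300L, tol = 1e-6) {
  req <- c("image_a", "image_b", "similarity")
  if (!all(req %in% names(similarity))) {
    abort("`similarity` needs columns image_a, image_b, similarity",
      class = "affectmap_bad_input"
    )
  }
  if (any(!is.finite(similarity$similarity)) ||
    any(similarity$similarity < 0 | similarity$similarity > 10)) {
    abort("similarity ratings must lie in [0, 10]",
      class = "affectmap_bad_input"
    )
  }
  images <- sort(unique(c(similarity$image_a, similarity$image_b)))
  n <- length(images)
  expected <- choose(n, 2)
  if (nrow(similarity) != expected) {
    abort(sprintf(
      "expected one rating per unordered pair (%d), got %d rows",
      expected, nrow(similarity)
    ), class = "affectmap_bad_input")
  }
  delta <- matrix(0, n, n, dimnames = list(images, images))
  ia <- match(similarity$image_a, images)
  ib <- match(similarity$image_b, images)
  if (any(ia == ib)) {
    abort("self-pairs are not allowed", class = "affectmap_bad_input")
  }
  d <- 10 - similarity$similarity
  delta[cbind(ia, ib)] <- d
  delta[cbind(ib, ia)] <- d

  fit <- smacof_fit(delta, n_dimensions, seed, n_restarts, max_iter, tol)
  coords <- tibble::as_tibble(fit$conf, .name_repair = "minimal")
  names(coords) <- paste0("dim", seq_len(n_dimensions))
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble::tibble(image = images), coords),
      stress = fit$stress,
      n_dimensions = as.integer(n_dimensions),
      n_iter = fit$n_iter
    ),
    class = "landscape_embedding"
  )
}

# SMACOF majorization on a full dissimilarity matrix with unit weights.
# Guttman transform: X <- B(X) X / n, with b_ij = -delta_ij / d_ij(X).
smacof_fit <- function(delta, k, seed, n_restarts, max_iter, tol) {
  n <- nrow(delta)
  denom <- sum(delta^2)
  stress1 <- function(X) {
    d <- as.matrix(dist(X))
    if (denom == 0) return(0)
    sqrt(sum((delta - d)^2) / 2 / (denom / 2))
  }
  run <- function(X) {
    s_old <- stress1(X)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d <- as.matrix(dist(X))
      B <- ifelse(d > 0, -delta / pmax(d, .Machine$double.eps), 0)
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
      s_new <- stress1(X)
      if (iter >= max_iter ||
        (s_old - s_new) < tol * max(s_old, .Machine$double.eps)) {
        break
      }
      s_old <- s_new
    }
    list(conf = X, stress = s_new, n_iter = iter)
  }
  # classical-scaling start; fall back to random when degenerate
  starts <- list()
  cs <- suppressWarnings(try(
    cmdscale(stats::as.dist(delta), k = k), silent = TRUE
  ))
  if (!inherits(cs, "try-error") && is.matrix(cs) && ncol(cs) == k) {
    starts[[1L]] <- cs
  }
  withr::with_seed(seed, {
    while (length(starts) < n_restarts) {
      starts[[length(starts) + 1L]] <-
        matrix(rnorm(n * k), n, k) * max(mean(delta) / 2, 1e-3)
    }
  })
  fits <- lapply(starts, run)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
}

#' @export
print.landscape_embedding <- function(x, ...) {
  cat(sprintf(
    "<landscape_embedding> %d images in %d dimensions, stress-1 = %.4g\n",
    nrow(x$coordinates), x$n_dimensions, x$stress
  ))
  invisible(x)
}

#' Within- and between-cluster distances of an embedded landscape
#'
#' Mean embedded Euclidean distance over each emotion's 10 within-category
#' image pairs and each category pair's 25 cross-category pairs, plus the
#' unweighted means across emotions and across category pairs. Larger
#' distances index greater emotion differentiation.
#'
#' @param embedding A [embed_landscape()] result (or any object with a
#'   `coordinates` tibble).
#' @param design The pair design from [build_emopair_design()].
#' @return A one-row tibble: `within_<emotion>` (3), `between_<pair>` (3),
#'   `mean_within`, `mean_between`.
#' @export
cluster_distances <- function(embedding, design = build_emopair_design()) {
  coords <- embedding$coordinates
  missing <- setdiff(
    unique(c(design$image_a, design$image_b)), coords$image
  )
  if (length(missing)) {
    abort(paste0(
      "design images missing from embedding: ",
      paste(missing, collapse = ", ")
    ), class = "affectmap_bad_input")
  }
  dims <- grep("^dim", names(coords), value = TRUE)
  xa <- as.matrix(coords[match(design$image_a, coords$image), dims])
  xb <- as.matrix(coords[match(design$image_b, coords$image), dims])
  design$distance <- sqrt(rowSums((xa - xb)^2))
  per <- design |>
    dplyr::summarise(
      distance = mean(.data$distance),
      .by = c("pair_type", "pair_label")
    )
  wide <- per |>
    dplyr::mutate(name = paste0(
      ifelse(.data$pair_type == "within", "within_", "between_"),
      gsub("-", "_", .data$pair_label)
    )) |>
    dplyr::select("name", "distance") |>
    tidyr::pivot_wider(names_from = "name", values_from = "distance")
  wide$mean_within <- mean(per$distance[per$pair_type == "within"])
  wide$mean_between <- mean(per$distance[per$pair_type == "between"])
  wide
}

#' Transitivity-based consistency score for a triplet-choice condition
#'
#' Each image's rank score is the number of trials on which it was chosen.
#' Per trial the unchosen target's rank is subtracted from the chosen
#' target's rank (the item difference); the consistency score is the sum of
#' item differences. A participant whose choices obey a strict preference
#' order attains the maximum — 220 on the standard 11-target design, where
#' the sorted rank scores are exactly 10, 9, ..., 0 — while inconsistent
#' (intransitive) choices contribute item differences <= 0 and lower the
#' score. Trap selections were retried in-task, so the table is expected to
#' contain only final target choices; `lapsed` flags are counted for QC.
#'
#' @param choices A tibble with columns `target_a`, `target_b`, `chosen`
#'   (and optionally `unchosen`, `condition`, `lapsed`) holding one final
#'   choice for every unordered pair of a complete pairwise design.
#' @param condition Optional condition label to filter on.
#' @return A one-row tibble: `condition`, `score`, `max_score`, `n_trials`,
#'   `n_lapses`, and a `rank_scores` list-column (tibble image, rank_score).
#' @export
consistency_score <- function(choices, condition = NULL) {
  if (!is.null(condition)) {
    cond <- condition
    choices <- dplyr::filter(choices, .data$condition == cond)
  }
  cond_label <- if (!is.null(condition)) {
    condition
  } else if ("condition" %in% names(choices)) {
    paste(unique(choices$condition), collapse = "+")
  } else {
    NA_character_
  }
  targets <- sort(unique(c(choices$target_a, choices$target_b)))
  k <- length(targets)
  if (nrow(choices) != choose(k, 2)) {
    abort(sprintf(
      "expected %d trials for %d targets, got %d",
      choose(k, 2), k, nrow(choices)
    ), class = "affectmap_bad_input")
  }
  pair_key <- paste(
    pmin(choices$target_a, choices$target_b),
    pmax(choices$target_a, choices$target_b)
  )
  if (anyDuplicated(pair_key)) {
    abort("each unordered target pair must appear exactly once",
      class = "affectmap_bad_input"
    )
  }
  if (!all(choices$chosen == choices$target_a |
    choices$chosen == choices$target_b)) {
    abort("`chosen` must be one of the trial's two targets",
      class = "affectmap_bad_input"
    )
  }
  rank <- setNames(integer(k), targets)
  counts <- table(choices$chosen)
  rank[names(counts)] <- as.integer(counts)
  unchosen <- ifelse(
    choices$chosen == choices$target_a, choices$target_b, choices$target_a
  )
  score <- sum(rank[choices$chosen] - rank[unchosen])
  # maximum: sum over pairs of |i - j| for ranks 0..k-1, i.e. k(k^2-1)/6
  tibble::tibble(
    condition = cond_label,
    score = as.integer(score),
    max_score = as.integer(k * (k^2 - 1) / 6),
    n_trials = nrow(choices),
    n_lapses = if ("lapsed" %in% names(choices)) {
      sum(choices$lapsed)
    } else {
      NA_integer_
    },
    rank_scores = list(tibble::tibble(
      image = targets, rank_score = as.integer(rank)
    ))
  )
}

# Vectorized transitivity scoring across participants x conditions.
# Same contract as consistency_score(), without the per-group toy checks:
# validates the choice-in-pair invariant and the standard trial count.
consistency_scores_all <- function(choices) {
  if (!all(choices$chosen == choices$target_a |
    choices$chosen == choices$target_b)) {
    abort("`chosen` must be one of the trial's two targets",
      class = "affectmap_bad_input"
    )
  }
  if (!"unchosen" %in% names(choices)) {
    choices$unchosen <- ifelse(
      choices$chosen == choices$target_a,
      choices$target_b, choices$target_a
    )
  }
  if (!"lapsed" %in% names(choices)) choices$lapsed <- NA
  n_tr <- dplyr::count(choices, .data$participant_id, .data$condition)
  if (any(n_tr$n != 55L)) {
    abort("each participant x condition needs the full 55-trial design",
      class = "affectmap_bad_input"
    )
  }
  ranks <- dplyr::count(
    choices, .data$participant_id, .data$condition, .data$chosen,
    name = "rank_chosen"
  )
  choices |>
    dplyr::left_join(
      ranks,
      by = c("participant_id", "condition", "chosen")
    ) |>
    dplyr::left_join(
      dplyr::rename(ranks, unchosen = "chosen", rank_unchosen = "rank_chosen"),
      by = c("participant_id", "condition", "unchosen")
    ) |>
    dplyr::summarise(
      score = sum(
        .data$rank_chosen - dplyr::coalesce(.data$rank_unchosen, 0L)
      ),
      n_trials = dplyr::n(),
      n_lapses = sum(.data$lapsed),
      .by = c("participant_id", "condition")
    )
}

#' Per-participant EmoMap scores
#'
#' Assembles, for every participant, the three emotional consistency scores
#' and the colourfulness-control consistency from the triplet task, and
#' (when similarity ratings are supplied) the embedded landscape's within-
#' and between-cluster distances.
#'
#' @param choices Triplet-choice responses for one or more participants
#'   (columns `participant_id`, `condition`, `target_a`, `target_b`,
#'   `chosen`, optionally `lapsed`).
#' @param similarity Optional pairwise similarity responses
#'   (`participant_id`, `image_a`, `image_b`, `similarity`). When `NULL`
#'   the distance columns are omitted.
#' @param design Pair design for [cluster_distances()].
#' @param seed,n_restarts,max_iter,tol Passed to [embed_landscape()].
#' @return A tibble with one row per participant: `consistency_<emotion>`,
#'   `consistency_control`, `emotional_consistency` (mean of the three
#'   emotion scores), `n_lapses`, `incomplete`, and when similarity data are
#'   present the [cluster_distances()] columns plus `stress`.
#' @export
emomap_participant_scores <- function(choices, similarity = NULL,
                                      design = build_emopair_design(),
                                      seed = 1L, n_restarts = 8L,
                                      max_iter = 300L, tol = 1e-6) {
  cons <- consistency_scores_all(choices)
  wide <- cons |>
    dplyr::mutate(condition = ifelse(
      .data$condition == "color_control", "control", .data$condition
    )) |>
    tidyr::pivot_wider(
      id_cols = "participant_id", names_from = "condition",
      values_from = "score", names_prefix = "consistency_",
      names_sort = TRUE
    )
  lapses <- cons |>
    dplyr::summarise(
      n_lapses = sum(.data$n_lapses), .by = "participant_id"
    )
  need <- paste0(
    "consistency_",
    c(am_emotions, "control")
  )
  for (col in setdiff(need, names(wide))) wide[[col]] <- NA_integer_
  out <- wide |>
    dplyr::left_join(lapses, by = "participant_id") |>
    dplyr::mutate(
      emotional_consistency = (.data$consistency_anger +
        .data$consistency_happiness + .data$consistency_sadness) / 3,
      incomplete = !complete.cases(
        dplyr::pick(dplyr::all_of(need))
      )
    )
  if (!is.null(similarity)) {
    dists <- similarity |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::group_modify(function(df, key) {
        emb <- embed_landscape(df,
          seed = seed, n_restarts = n_restarts,
          max_iter = max_iter, tol = tol
        )
        dplyr::mutate(
          cluster_distances(emb, design = design),
          stress = emb$stress
        )
      }) |>
      dplyr::ungroup()
    out <- dplyr::left_join(out, dists, by = "participant_id")
    out$incomplete <- out$incomplete | !complete.cases(
      out[, c("mean_within", "mean_between")]
    )
  }
  out
}
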