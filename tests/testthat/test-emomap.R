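test_that("exactly realizable configurations embed with vanishing stress", {
  # equilateral triangle, side 1 (similarity 9 <-> dissimilarity 1)
  tri <- tibble::tibble(
    image_a = c("a", "a", "b"), image_b = c("b", "c", "c"),
    similarity = 9
  )
  emb <- embed_landscape(tri)
  expect_lt(emb$stress, 1e-8)
  d <- as.matrix(dist(emb$coordinates[, c("dim1", "dim2")]))
  expect_equal(d[upper.tri(d)], rep(1, 3), tolerance = 1e-6)

  # a random planar configuration is recovered exactly too
  set.seed(4)
  coords <- tibble::tibble(
    image = sprintf("im%02d", 1:7),
    x = runif(7, -2, 2), y = runif(7, -2, 2)
  )
  emb2 <- embed_landscape(similarity_from_coords(coords))
  expect_lt(emb2$stress, 1e-8)
})

test_that("majorization never ends above the classical-scaling start", {
  set.seed(11)
  sim <- tibble::tibble(
    image_a = toy_design(6)$target_a,
    image_b = toy_design(6)$target_b,
    similarity = round(runif(15, 1, 9), 4)
  )
  emb <- embed_landscape(sim)
  delta <- matrix(0, 6, 6)
  images <- sort(unique(c(sim$image_a, sim$image_b)))
  ia <- match(sim$image_a, images)
  ib <- match(sim$image_b, images)
  delta[cbind(ia, ib)] <- 10 - sim$similarity
  delta <- delta + t(delta)
  classical <- cmdscale(as.dist(delta), k = 2)
  stress_classical <- sqrt(
    sum((as.dist(delta) - dist(classical))^2) / sum(as.dist(delta)^2)
  )
  expect_lte(emb$stress, stress_classical + 1e-12)
})

test_that("embedding validates its input", {
  bad <- tibble::tibble(
    image_a = c("a", "a"), image_b = c("b", "c"), similarity = c(5, 5)
  )
  expect_error(embed_landscape(bad), class = "affectmap_bad_input")
  bad2 <- tibble::tibble(
    image_a = c("a", "a", "b"), image_b = c("b", "c", "c"),
    similarity = c(5, 5, 12)
  )
  expect_error(embed_landscape(bad2), class = "affectmap_bad_input")
})

test_that("cluster distances match a brute-force pair loop", {
  design <- build_emopair_design()
  set.seed(2)
  coords <- tibble::tibble(
    image = unique(c(design$image_a, design$image_b)),
    dim1 = rnorm(15), dim2 = rnorm(15)
  )
  emb <- structure(
    list(coordinates = coords),
    class = "landscape_embedding"
  )
  got <- cluster_distances(emb, design)
  oracle <- oracle_pair_distance_means(coords, design)
  expect_equal(got$within_anger, unname(oracle["within anger"]))
  expect_equal(
    got$between_anger_sadness, unname(oracle["between anger-sadness"])
  )
  expect_equal(
    got$mean_within,
    mean(oracle[startsWith(names(oracle), "within")])
  )
  expect_equal(
    got$mean_between,
    mean(oracle[startsWith(names(oracle), "between")])
  )
  # geometry limit: three tight clusters 10 apart
  tight <- coords
  cat3 <- sub("_[0-9]+$", "", tight$image)
  tight$dim1 <- c(anger = 0, happiness = 10, sadness = 5)[cat3]
  tight$dim2 <- c(anger = 0, happiness = 0, sadness = 10 * sqrt(3) / 2)[cat3]
  got2 <- cluster_distances(
    structure(list(coordinates = tight), class = "landscape_embedding"),
    design
  )
  expect_equal(got2$mean_within, 0)
  expect_equal(got2$mean_between, 10)
})

test_that("consistency scoring follows the rank-difference rules", {
  # fully transitive choices over the standard 11-target design hit 220
  design <- build_triplet_design("happiness", seed = 1L)
  order <- sample(sprintf("happiness_t%02d", 1:11))
  full <- transitive_choices(design, order)
  sc <- consistency_score(full)
  expect_equal(sc$score, 220L)
  expect_equal(sc$max_score, 220L)
  expect_equal(
    sort(sc$rank_scores[[1]]$rank_score), 0:10
  )
  expect_equal(sum(sc$rank_scores[[1]]$rank_score), 55L)

  # 3-item toys: forced arithmetic and the circular zero
  toy <- toy_design(3)
  lin <- toy
  lin$chosen <- c("A", "A", "B") # A>B, A>C, B>C
  expect_equal(consistency_score(lin)$score, 4L)
  circ <- toy
  circ$chosen <- c("A", "C", "B") # A>B, C>A, B>C
  expect_equal(consistency_score(circ)$score, 0L)
  expect_true(all(consistency_score(circ)$rank_scores[[1]]$rank_score == 1L))
})

test_that("the scorer agrees with exhaustive enumeration on 4-item designs", {
  design <- toy_design(4)
  for (ch in all_choice_patterns(design)) {
    d <- design
    d$chosen <- ch
    expect_equal(
      consistency_score(d)$score,
      oracle_consistency_score(design$target_a, design$target_b, ch)
    )
  }
})

test_that("single choice swaps never raise a perfect score and lower it unless rank-adjacent", {
  # Swapping the choice between two adjacently ranked items relabels the
  # preference order (still transitive, still 220); every other swap
  # strictly lowers the score. Verified here over all 55 possible swaps.
  design <- build_triplet_design("anger", seed = 2L)
  order <- sprintf("anger_t%02d", 1:11)
  pos <- setNames(seq_along(order), order)
  full <- transitive_choices(design, order)
  for (r in seq_len(nrow(full))) {
    swapped <- full
    swapped$chosen[r] <- ifelse(
      full$chosen[r] == full$target_a[r],
      full$target_b[r], full$target_a[r]
    )
    sc <- consistency_score(swapped)$score
    adjacent <- abs(pos[full$target_a[r]] - pos[full$target_b[r]]) == 1L
    if (adjacent) {
      expect_identical(sc, 220L)
    } else {
      expect_lt(sc, 220L)
    }
  }
})

test_that("scoring rejects malformed choice tables", {
  design <- toy_design(3)
  design$chosen <- c("A", "A", "B")
  expect_error(
    consistency_score(design[1:2, ]),
    class = "affectmap_bad_input"
  )
  bad <- design
  bad$chosen[1] <- "C" # not in the {A, B} pair
  expect_error(consistency_score(bad), class = "affectmap_bad_input")
})

test_that("participant-level EmoMap scores recover the generative noise ordering", {
  fix <- fixture_cohort()
  scores <- emomap_participant_scores(fix$choices)
  p1 <- scores[scores$participant_id == "p0001", ]
  expect_equal(p1$consistency_anger, 220L)
  expect_equal(p1$consistency_happiness, 220L)
  expect_equal(p1$consistency_sadness, 220L)
  expect_equal(p1$emotional_consistency, 220)
  expect_false(p1$incomplete)

  joined <- dplyr::left_join(
    scores, fix$profiles[, c("participant_id", "sigma_exp")],
    by = "participant_id"
  )
  expect_lt(
    cor(joined$sigma_exp, joined$emotional_consistency,
      method = "spearman"
    ), 0
  )
})

test_that("embedded landscape distances rise with generative modularity", {
  # wide modularity spread so the recovery signal dominates sampling noise
  cfg <- cohort_config(
    n_participants = 24, seed = 17, modularity_sdlog = 0.8
  )
  profiles <- generate_profiles(cfg)
  designs <- build_designs(seed = 17)
  em <- simulate_emomap(profiles, designs, seed = 18)
  scores <- emomap_participant_scores(
    em$choices, em$similarity,
    n_restarts = 2, max_iter = 100
  )
  joined <- dplyr::left_join(
    scores, profiles[, c("participant_id", "modularity")],
    by = "participant_id"
  )
  expect_gt(
    cor(joined$modularity, joined$mean_between, method = "spearman"), 0.7
  )
  # embedded distances are Euclidean: spot-check the triangle inequality
  emb <- embed_landscape(
    dplyr::filter(em$similarity, participant_id == "p0001"),
    n_restarts = 2
  )
  cm <- as.matrix(dist(emb$coordinates[, c("dim1", "dim2")]))
  for (k in 2:14) {
    expect_lte(cm[1, 15], cm[1, k] + cm[k, 15] + 1e-12)
  }
})
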