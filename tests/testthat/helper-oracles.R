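# Independent oracles used across the suite. Deliberately written as plain
# loops, separate from the package's vectorized implementations.

# Brute-force transitivity scorer: tally ranks trial by trial, then sum
# item differences with an explicit loop.
oracle_consistency_score <- function(pairs_a, pairs_b, chosen) {
  targets <- sort(unique(c(pairs_a, pairs_b)))
  rank <- setNames(rep(0L, length(targets)), targets)
  for (t in seq_along(chosen)) {
    rank[chosen[t]] <- rank[chosen[t]] + 1L
  }
  score <- 0L
  for (t in seq_along(chosen)) {
    other <- if (chosen[t] == pairs_a[t]) pairs_b[t] else pairs_a[t]
    score <- score + rank[chosen[t]] - rank[other]
  }
  as.integer(score)
}

# All-pairs design over k toy items and every one of the 2^C(k,2) choice
# patterns (chooser bit 1 = first item of the pair).
toy_design <- function(k) {
  items <- LETTERS[seq_len(k)]
  idx <- utils::combn(k, 2L)
  tibble::tibble(
    condition = "toy",
    target_a = items[idx[1L, ]],
    target_b = items[idx[2L, ]]
  )
}

all_choice_patterns <- function(design) {
  n <- nrow(design)
  lapply(seq_len(2^n) - 1L, function(bits) {
    pick_a <- bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0
    ifelse(pick_a, design$target_a, design$target_b)
  })
}

# Choices implied by a strict preference order (earlier = preferred).
transitive_choices <- function(design, order) {
  pos <- setNames(seq_along(order), order)
  design$chosen <- ifelse(
    pos[design$target_a] < pos[design$target_b],
    design$target_a, design$target_b
  )
  design
}

# Plain-loop mean pairwise distances per pair type, as an oracle for
# cluster_distances().
oracle_pair_distance_means <- function(coords, design) {
  get_xy <- function(img) {
    row <- which(coords$image == img)
    c(coords$dim1[row], coords$dim2[row])
  }
  d <- numeric(nrow(design))
  for (r in seq_len(nrow(design))) {
    d[r] <- sqrt(sum((get_xy(design$image_a[r]) -
      get_xy(design$image_b[r]))^2))
  }
  tapply(d, paste(design$pair_type, design$pair_label), mean)
}

# Two-pass standard deviation (n - 1), written out longhand.
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Similarity table whose dissimilarities (10 - similarity) are realized
# exactly by the given planar coordinates.
similarity_from_coords <- function(coords) {
  idx <- utils::combn(nrow(coords), 2L)
  tibble::tibble(
    image_a = coords$image[idx[1L, ]],
    image_b = coords$image[idx[2L, ]],
    similarity = 10 - sqrt(
      (coords$x[idx[1L, ]] - coords$x[idx[2L, ]])^2 +
        (coords$y[idx[1L, ]] - coords$y[idx[2L, ]])^2
    )
  )
}

# Shared small fixture cohort (built once per test run).
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- affectmap::make_fixtures(seed = 42L)
    cache
  }
})
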