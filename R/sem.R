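#' Specify a structural model
#'
#' Defines a directed structural model over manifest variables and latent
#' constructs with reflective indicators, in the RAM formulation: a matrix
#' `A` of directed effects (structural paths and factor loadings, the first
#' loading of each latent fixed to 1 for scale) and a matrix `S` of
#' variances (free for every variable; residual variances for endogenous
#' ones) and covariances (free between exogenous variables unless
#' suppressed). Nonrecursive loops (both `a -> b` and `b -> a`) are allowed
#' provided the structural matrix stays invertible.
#'
#' @param paths A data frame with columns `from`, `to`: one directed
#'   structural edge per row.
#' @param latent Named list mapping each latent variable to its character
#'   vector of indicator columns.
#' @param zero_covariances Optional list of length-2 character vectors:
#'   exogenous covariances to fix at zero.
#' @param manifest Additional manifest variables to include without any
#'   structural path (e.g. for a saturated covariance model).
#' @return An object of class `affectmap_sem_spec`.
#' @export
model_spec <- function(paths = NULL, latent = list(),
                       zero_covariances = list(), manifest = character()) {
  if (is.null(paths)) {
    paths <- tibble::tibble(from = character(), to = character())
  }
  paths <- tibble::as_tibble(paths)[, c("from", "to")]
  if (any(paths$from == paths$to)) {
    abort("self-loops are not allowed", class = "affectmap_bad_spec")
  }
  if (anyDuplicated(paste(paths$from, paths$to))) {
    abort("duplicate paths", class = "affectmap_bad_spec")
  }
  latents <- names(latent)
  indicators <- unlist(latent, use.names = FALSE)
  if (anyDuplicated(indicators)) {
    abort("an indicator may load on only one latent",
      class = "affectmap_bad_spec"
    )
  }
  structural <- unique(c(paths$from, paths$to))
  if (length(intersect(structural, indicators))) {
    abort("indicators cannot also appear as structural variables",
      class = "affectmap_bad_spec"
    )
  }
  structure(
    list(
      paths = paths, latent = latent,
      zero_covariances = zero_covariances,
      manifest = as.character(manifest)
    ),
    class = "affectmap_sem_spec"
  )
}

#' @export
print.affectmap_sem_spec <- function(x, ...) {
  cat("<affectmap_sem_spec>\n")
  if (length(x$latent)) {
    for (l in names(x$latent)) {
      cat(sprintf("  %s =~ %s\n", l, paste(x$latent[[l]], collapse = " + ")))
    }
  }
  if (nrow(x$paths)) {
    cat(sprintf("  %s -> %s\n", x$paths$from, x$paths$to), sep = "")
  } else {
    cat("  (no structural paths)\n")
  }
  invisible(x)
}

# Internal: expand a spec into index bookkeeping for the RAM matrices.
sem_layout <- function(spec) {
  latents <- names(spec$latent)
  indicators <- unlist(spec$latent, use.names = FALSE)
  structural <- unique(c(spec$paths$from, spec$paths$to, spec$manifest))
  manifest <- setdiff(structural, latents)
  observed <- unique(c(indicators, manifest))
  all_vars <- c(observed, latents)
  t_n <- length(all_vars)
  idx <- function(v) match(v, all_vars)

  par <- list() # rows: matrix, i, j, type, label, fixed_value
  add <- function(mat, i, j, type, label, fixed = NA_real_) {
    par[[length(par) + 1L]] <<- tibble::tibble(
      matrix = mat, i = i, j = j, type = type, label = label,
      fixed_value = fixed
    )
  }
  for (l in latents) {
    inds <- spec$latent[[l]]
    add("A", idx(inds[1L]), idx(l), "loading",
      paste0(l, " =~ ", inds[1L]),
      fixed = 1
    )
    for (ind in inds[-1L]) {
      add("A", idx(ind), idx(l), "loading", paste0(l, " =~ ", ind))
    }
  }
  if (nrow(spec$paths)) {
    for (r in seq_len(nrow(spec$paths))) {
      add(
        "A", idx(spec$paths$to[r]), idx(spec$paths$from[r]),
        "path", paste0(spec$paths$from[r], " -> ", spec$paths$to[r])
      )
    }
  }
  partab <- if (length(par)) {
    dplyr::bind_rows(par)
  } else {
    tibble::tibble(
      matrix = character(), i = integer(), j = integer(),
      type = character(), label = character(), fixed_value = double()
    )
  }
  has_incoming <- all_vars %in% all_vars[
    partab$i[partab$matrix == "A"]
  ]
  exogenous <- all_vars[!has_incoming]
  for (v in all_vars) {
    lab <- if (v %in% exogenous) paste0("var(", v, ")") else {
      paste0("resid(", v, ")")
    }
    partab <- dplyr::bind_rows(partab, tibble::tibble(
      matrix = "S", i = idx(v), j = idx(v), type = "variance",
      label = lab, fixed_value = NA_real_
    ))
  }
  zero_keys <- vapply(
    spec$zero_covariances,
    function(p) paste(sort(p), collapse = "\r"), character(1)
  )
  if (length(exogenous) > 1L) {
    combos <- utils::combn(sort(exogenous), 2L)
    for (c_i in seq_len(ncol(combos))) {
      a <- combos[1L, c_i]
      b <- combos[2L, c_i]
      if (paste(sort(c(a, b)), collapse = "\r") %in% zero_keys) next
      partab <- dplyr::bind_rows(partab, tibble::tibble(
        matrix = "S", i = idx(a), j = idx(b), type = "covariance",
        label = paste0("cov(", a, ", ", b, ")"), fixed_value = NA_real_
      ))
    }
  }
  partab$free <- is.na(partab$fixed_value)
  partab$par_idx <- NA_integer_
  partab$par_idx[partab$free] <- seq_len(sum(partab$free))
  list(
    all_vars = all_vars, observed = observed, latents = latents,
    manifest = manifest, exogenous = exogenous,
    t_n = t_n, p = length(observed), partab = partab
  )
}

# Internal: RAM matrices from the working parameter vector (variances are
# log-parameterized to keep them positive).
sem_matrices <- function(theta, layout) {
  t_n <- layout$t_n
  A <- matrix(0, t_n, t_n)
  S <- matrix(0, t_n, t_n)
  pt <- layout$partab
  vals <- ifelse(pt$free, theta[pt$par_idx], pt$fixed_value)
  vals[pt$type == "variance"] <- exp(vals[pt$type == "variance"])
  a <- pt$matrix == "A"
  A[cbind(pt$i[a], pt$j[a])] <- vals[a]
  S[cbind(pt$i[!a], pt$j[!a])] <- vals[!a]
  S[cbind(pt$j[!a], pt$i[!a])] <- vals[!a]
  list(A = A, S = S)
}

sem_implied <- function(theta, layout) {
  m <- sem_matrices(theta, layout)
  IA <- diag(layout$t_n) - m$A
  IAinv <- tryCatch(solve(IA), error = function(e) NULL)
  if (is.null(IAinv)) {
    return(NULL)
  }
  V <- IAinv %*% m$S %*% t(IAinv)
  obs <- match(layout$observed, layout$all_vars)
  list(V = V, sigma = V[obs, obs, drop = FALSE], A = m$A, S = m$S)
}

#' Fit a structural model by maximum likelihood
#'
#' Minimizes the multivariate-normal ML discrepancy between the sample
#' covariance of the (z-standardized) observed variables and the RAM-implied
#' covariance, by quasi-Newton optimization with seeded restarts. Returns
#' log-likelihood, `BIC = -2 logL + k log N` with `N` the number of
#' participants, parameter estimates with delta-method standard errors from
#' the numerical Hessian, and standardized coefficients from the
#' model-implied variances.
#'
#' @param data A data frame containing every observed variable (one row per
#'   participant); variables are z-scored internally.
#' @param spec A [model_spec()].
#' @param n_restarts Optimizer restarts with jittered starts.
#' @param seed Seed for the restarts.
#' @param standardize Whether to z-score the observed columns (default).
#' @param reltol Convergence tolerance of the quasi-Newton optimizer.
#' @return An object of class `affectmap_sem`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods.
#' @export
fit_path_model <- function(data, spec, n_restarts = 5L, seed = 1L,
                           standardize = TRUE, reltol = 1e-10) {
  layout <- sem_layout(spec)
  missing_cols <- setdiff(layout$observed, names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "data lacks observed variables: ",
      paste(missing_cols, collapse = ", ")
    ), class = "affectmap_bad_input")
  }
  X <- as.matrix(data[, layout$observed, drop = FALSE])
  if (any(!is.finite(X))) {
    abort("observed variables contain missing or non-finite values",
      class = "affectmap_bad_input"
    )
  }
  if (standardize) X <- scale(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1L) {
    abort("need more participants than observed variables",
      class = "affectmap_bad_input"
    )
  }
  Sm <- cov(X) * (n - 1) / n
  logdet_sm <- determinant(Sm, logarithm = TRUE)$modulus[1]
  npar <- sum(layout$partab$free)

  discrepancy <- function(theta) {
    imp <- sem_implied(theta, layout)
    if (is.null(imp)) {
      return(1e8 + sum(theta^2))
    }
    ch <- tryCatch(chol(imp$sigma), error = function(e) NULL)
    if (is.null(ch)) {
      return(1e8 + sum(theta^2))
    }
    logdet <- 2 * sum(log(diag(ch)))
    sinv <- chol2inv(ch)
    val <- logdet + sum(Sm * sinv)
    if (!is.finite(val)) {
      return(1e8 + sum(theta^2))
    }
    val
  }

  # analytic gradient of the ML discrepancy in the RAM parameterization:
  # with B = (I - A)^-1, W = B S B', Sigma = [W]_obs and
  # C = Sigma^-1 - Sigma^-1 Sm Sigma^-1, the derivative wrt A[i, j] is
  # 2 (W Ct B)[j, i] and wrt S[k, l] is (2 - [k == l]) (B' Ct B)[k, l],
  # where Ct embeds C at the observed block (chain rule adds a factor
  # exp(theta) for the log-parameterized variances).
  obs_idx <- match(layout$observed, layout$all_vars)
  ptf <- layout$partab[layout$partab$free, ]
  gradient <- function(theta) {
    m <- sem_matrices(theta, layout)
    IA <- diag(layout$t_n) - m$A
    B <- tryCatch(solve(IA), error = function(e) NULL)
    if (is.null(B)) {
      return(2 * theta)
    }
    W <- B %*% m$S %*% t(B)
    sigma <- W[obs_idx, obs_idx, drop = FALSE]
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      return(2 * theta)
    }
    sinv <- chol2inv(ch)
    C <- sinv - sinv %*% Sm %*% sinv
    Ct <- matrix(0, layout$t_n, layout$t_n)
    Ct[obs_idx, obs_idx] <- C
    QA <- W %*% Ct %*% B
    QS <- t(B) %*% Ct %*% B
    g <- numeric(npar)
    a <- ptf$matrix == "A"
    g[ptf$par_idx[a]] <- 2 * QA[cbind(ptf$j[a], ptf$i[a])]
    sv <- !a & ptf$type == "variance"
    g[ptf$par_idx[sv]] <- QS[cbind(ptf$i[sv], ptf$i[sv])] *
      exp(theta[ptf$par_idx[sv]])
    sc <- !a & ptf$type == "covariance"
    g[ptf$par_idx[sc]] <- 2 * QS[cbind(ptf$i[sc], ptf$j[sc])]
    g
  }

  pt <- layout$partab
  start0 <- numeric(npar)
  start0[pt$par_idx[pt$free & pt$type == "path"]] <- 0
  start0[pt$par_idx[pt$free & pt$type == "loading"]] <- 1
  start0[pt$par_idx[pt$free & pt$type == "variance"]] <- log(0.5)
  start0[pt$par_idx[pt$free & pt$type == "covariance"]] <- 0

  fits <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      st <- if (r == 1L) start0 else start0 + rnorm(npar, 0, 0.3)
      tryCatch(
        optim(st, discrepancy,
          gr = gradient, method = "BFGS",
          control = list(maxit = 1000L, reltol = reltol)
        ),
        error = function(e) NULL
      )
    })
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits)) {
    abort("optimization failed from every start",
      class = "affectmap_no_convergence"
    )
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- best$par
  imp <- sem_implied(theta, layout)
  # best$value is logdet(Sigma) + tr(Sm Sigma^-1); the ML fit function
  # subtracts its saturated minimum so a saturated model scores 0
  fml <- best$value - logdet_sm - p
  loglik <- -(n / 2) * (p * log(2 * pi) + best$value)
  bic <- -2 * loglik + npar * log(n)
  aic <- -2 * loglik + 2 * npar

  negll <- function(th) (n / 2) * discrepancy(th)
  H <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
  vcov_theta <- if (!is.null(H)) {
    tryCatch(solve(H), error = function(e) NULL)
  } else {
    NULL
  }
  se_theta <- if (!is.null(vcov_theta)) {
    sq <- diag(vcov_theta)
    sqrt(ifelse(sq > 0, sq, NA_real_))
  } else {
    rep(NA_real_, npar)
  }

  Vd <- diag(imp$V)
  est <- pt |>
    dplyr::filter(.data$free) |>
    dplyr::mutate(
      raw = theta[.data$par_idx],
      estimate = ifelse(.data$type == "variance", exp(.data$raw), .data$raw),
      std.error = ifelse(
        .data$type == "variance",
        exp(.data$raw) * se_theta[.data$par_idx],
        se_theta[.data$par_idx]
      ),
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * pnorm(-abs(.data$statistic)),
      std_beta = ifelse(
        .data$type %in% c("path", "loading"),
        .data$estimate * sqrt(Vd[.data$j] / Vd[.data$i]),
        NA_real_
      )
    ) |>
    dplyr::select(
      term = "label", type = "type", "estimate", "std.error",
      "statistic", "p.value", "std_beta"
    )

  structure(
    list(
      spec = spec, layout = layout, estimates = est,
      theta = theta, vcov_theta = vcov_theta,
      loglik = loglik, npar = npar, bic = bic, aic = aic,
      n = n, p = p, discrepancy = fml,
      sample_cov = Sm, implied_cov = imp$sigma, implied_V = imp$V,
      converged = best$convergence == 0
    ),
    class = "affectmap_sem"
  )
}

#' @export
print.affectmap_sem <- function(x, ...) {
  cat(sprintf(
    "<affectmap_sem> N = %d, %d observed vars, k = %d, logLik = %.2f, BIC = %.2f%s\n",
    x$n, x$p, x$npar, x$loglik, x$bic,
    if (x$converged) "" else " (NOT converged)"
  ))
  paths <- dplyr::filter(x$estimates, .data$type == "path")
  if (nrow(paths)) {
    print(as.data.frame(paths[, c(
      "term", "estimate", "statistic", "p.value", "std_beta"
    )]), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted structural model
#'
#' @param x An `affectmap_sem` fit.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `type`,
#'   `estimate`, `std.error`, `statistic`, `p.value`, `std_beta`.
#' @method tidy affectmap_sem
#' @export
tidy.affectmap_sem <- function(x, ...) x$estimates

#' One-row fit summary of a structural model
#'
#' @param x An `affectmap_sem` fit.
#' @param ... Unused.
#' @return A one-row tibble: `nobs`, `npar`, `logLik`, `AIC`, `BIC`,
#'   `discrepancy`, `converged`.
#' @method glance affectmap_sem
#' @export
glance.affectmap_sem <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, npar = x$npar, logLik = x$loglik,
    AIC = x$aic, BIC = x$bic, discrepancy = x$discrepancy,
    converged = x$converged
  )
}

#' Likelihood-ratio test between nested fits
#'
#' @param null_fit,alt_fit Nested `affectmap_sem` fits on the same observed
#'   variables (the null has fewer free parameters).
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @export
lrt_sem <- function(null_fit, alt_fit) {
  if (alt_fit$p != null_fit$p) {
    abort("LRT requires the same observed variables in both fits",
      class = "affectmap_bad_input"
    )
  }
  df <- alt_fit$npar - null_fit$npar
  if (df <= 0) {
    abort("`alt_fit` must have more free parameters than `null_fit`",
      class = "affectmap_bad_input"
    )
  }
  stat <- max(0, -2 * (null_fit$loglik - alt_fit$loglik))
  tibble::tibble(
    statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Indirect effect along a directed chain
#'
#' The indirect effect of `chain[1]` on the final variable through the
#' intermediate ones: the product of the component path coefficients, with
#' a multivariate-delta (Sobel) standard error from the fitted parameter
#' covariance. The standardized indirect effect is the product of the
#' component standardized paths.
#'
#' @param fit An `affectmap_sem` fit.
#' @param chain Character vector of >= 3 variable names, e.g.
#'   `c("a", "b", "c")` for `a -> b -> c`.
#' @return One-row tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `std_beta`.
#' @export
indirect_effect <- function(fit, chain) {
  if (length(chain) < 3L) {
    abort("`chain` must name at least three variables",
      class = "affectmap_bad_input"
    )
  }
  terms <- paste0(head(chain, -1L), " -> ", chain[-1L])
  est <- fit$estimates
  rows <- match(terms, est$term)
  if (any(is.na(rows))) {
    abort(paste0(
      "chain edges not in the model: ",
      paste(terms[is.na(rows)], collapse = ", ")
    ), class = "affectmap_bad_input")
  }
  b <- est$estimate[rows]
  point <- prod(b)
  # delta method: gradient wrt each component is the product of the others
  grad <- vapply(seq_along(b), function(i) prod(b[-i]), numeric(1))
  par_rows <- fit$layout$partab |>
    dplyr::filter(.data$free, .data$label %in% terms)
  par_idx <- par_rows$par_idx[match(terms, par_rows$label)]
  se <- if (!is.null(fit$vcov_theta)) {
    Vsub <- fit$vcov_theta[par_idx, par_idx, drop = FALSE]
    sqrt(max(0, as.numeric(t(grad) %*% Vsub %*% grad)))
  } else {
    NA_real_
  }
  z <- point / se
  tibble::tibble(
    term = paste(chain, collapse = " -> "),
    estimate = point, std.error = se, statistic = z,
    p.value = 2 * pnorm(-abs(z)),
    std_beta = prod(est$std_beta[rows])
  )
}

#' Direct and indirect effects table
#'
#' All structural paths of a fitted model plus any requested indirect
#' chains, in one table (estimate, z, p, standardized beta).
#'
#' @param fit An `affectmap_sem` fit.
#' @param indirect Optional list of chains for [indirect_effect()].
#' @return A tibble with columns `term`, `effect` (`"direct"` or
#'   `"indirect"`), `estimate`, `std.error`, `statistic`, `p.value`,
#'   `std_beta`.
#' @export
effects_table <- function(fit, indirect = list()) {
  direct <- fit$estimates |>
    dplyr::filter(.data$type == "path") |>
    dplyr::mutate(effect = "direct") |>
    dplyr::select(
      "term", "effect", "estimate", "std.error", "statistic",
      "p.value", "std_beta"
    )
  ind <- purrr::map_dfr(indirect, function(ch) {
    dplyr::mutate(indirect_effect(fit, ch), effect = "indirect")
  })
  dplyr::bind_rows(direct, ind) |>
    dplyr::relocate("effect", .after = "term")
}
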