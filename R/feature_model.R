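#' Build a PCA feature model from a cohort
#'
#' Fits the gender-stratified feature model: the cohort's eight numeric gait
#' features (see [gait_feature_names]) are z-scored (the features mix years,
#' kg, m, degrees and Hz, so unstandardised PCA would be dominated by the
#' degree-scaled flexions), and principal components of the standardised
#' matrix are retained in decreasing eigenvalue order until the cumulative
#' explained variance reaches `variance_threshold` (at least one component).
#' Eigenvalues come from the sample covariance with an `n - 1` denominator.
#'
#' @param cohort Tibble of feature rows, e.g. from [assemble_features()] or
#'   [generate_cohort()]; all rows must share one `gender` stratum (a missing
#'   `gender` column yields stratum `"unstratified"`).
#' @param variance_threshold Fraction in (0, 1\] of variance to retain.
#' @return Object of class `feature_model` with fields `mean`, `scale`,
#'   `loadings` (d2 x d1, rows orthonormal), `eigenvalues`,
#'   `explained_variance`, `n_samples`, `stratum`, `feature_names`,
#'   `feature_version`.
#' @export
build_feature_model <- function(cohort, variance_threshold = 0.90) {
  missing_feats <- setdiff(gait_feature_names, names(cohort))
  if (length(missing_feats)) {
    rlang::abort(paste0("cohort lacks feature(s): ",
                        paste(missing_feats, collapse = ", ")),
                 class = "posegait_validation_error")
  }
  if (nrow(cohort) < 3L) {
    rlang::abort("cohort must contain at least 3 samples",
                 class = "posegait_validation_error")
  }
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1) {
    rlang::abort("`variance_threshold` must lie in (0, 1]",
                 class = "posegait_validation_error")
  }
  stratum <- if ("gender" %in% names(cohort)) unique(cohort$gender) else "unstratified"
  if (length(stratum) != 1L) {
    rlang::abort("cohort mixes gender strata; build one model per stratum",
                 class = "posegait_validation_error")
  }
  X <- as.matrix(cohort[gait_feature_names])
  if (anyNA(X) || !all(is.finite(X))) {
    rlang::abort("cohort features must be finite", class = "posegait_validation_error")
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  flat <- sds <= .Machine$double.eps
  if (any(flat)) {
    rlang::abort(paste0("zero-variance feature(s): ",
                        paste(gait_feature_names[flat], collapse = ", ")),
                 class = "posegait_validation_error")
  }
  Z <- scale(X, center = mu, scale = sds)
  eg <- eigen(stats::cov(Z), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  frac <- ev / total
  d2 <- which(cumsum(frac) >= variance_threshold - 1e-12)[1]
  if (is.na(d2)) d2 <- length(ev)
  d2 <- max(1L, d2)
  load <- t(eg$vectors[, seq_len(d2), drop = FALSE])
  # deterministic sign: largest-|entry| coordinate of each PC made positive
  for (i in seq_len(d2)) {
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) load[i, ] <- -load[i, ]
  }
  structure(
    list(mean = mu,
         scale = sds,
         loadings = load,
         eigenvalues = ev[seq_len(d2)],
         explained_variance = frac[seq_len(d2)],
         n_samples = nrow(cohort),
         stratum = stratum,
         feature_names = gait_feature_names,
         feature_version = gait_feature_version,
         variance_threshold = variance_threshold),
    class = "feature_model"
  )
}

#' Hotelling T-squared scores against a feature model
#'
#' Standardises each subject's features with the model's mean and scale,
#' projects onto the retained principal components and returns
#' `sum(t_i^2 / lambda_i)` - the squared PCA-subspace Mahalanobis distance
#' from the cohort. Higher scores mean a gait more atypical of the cohort;
#' a subject exactly at the cohort mean scores 0. With full component
#' retention the score equals the classical squared Mahalanobis distance.
#'
#' @param data Data frame with the [gait_feature_names] columns (one or more
#'   rows), or a named numeric vector for a single subject.
#' @param model A [build_feature_model()] result.
#' @param normalisation `"none"` or `"per_pc"` (divide by the number of
#'   retained components).
#' @return Numeric vector of nonnegative scores, one per row.
#' @export
t2_score <- function(data, model, normalisation = c("none", "per_pc")) {
  normalisation <- match.arg(normalisation)
  if (is.numeric(data) && !is.null(names(data))) {
    data <- tibble::as_tibble(as.list(data))
  }
  missing_feats <- setdiff(model$feature_names, names(data))
  if (length(missing_feats)) {
    rlang::abort(paste0("data lacks feature(s): ",
                        paste(missing_feats, collapse = ", ")),
                 class = "posegait_validation_error")
  }
  X <- as.matrix(data[model$feature_names])
  if (anyNA(X) || !all(is.finite(X))) {
    rlang::abort("features must be finite", class = "posegait_validation_error")
  }
  Z <- scale(X, center = model$mean, scale = model$scale)
  scores <- Z %*% t(model$loadings)
  t2 <- drop(scores^2 %*% (1 / model$eigenvalues))
  if (normalisation == "per_pc") t2 <- t2 / length(model$eigenvalues)
  unname(t2)
}

#' Leave-one-out T-squared scores over a cohort
#'
#' The cross-validation used to compare feature models: each sample in turn is
#' held out, a feature model is built on the remainder, and the held-out
#' sample's T-squared score against that model is reported.
#'
#' @param cohort Feature tibble with at least 4 rows.
#' @param variance_threshold Passed to [build_feature_model()].
#' @param normalisation Passed to [t2_score()].
#' @return Tibble with columns `row` and `t2`.
#' @export
loo_t2 <- function(cohort, variance_threshold = 0.90,
                   normalisation = c("none", "per_pc")) {
  normalisation <- match.arg(normalisation)
  n <- nrow(cohort)
  if (n < 4L) {
    rlang::abort("leave-one-out needs a cohort of at least 4",
                 class = "posegait_validation_error")
  }
  t2 <- purrr::map_dbl(seq_len(n), function(i) {
    m <- build_feature_model(cohort[-i, , drop = FALSE], variance_threshold)
    t2_score(cohort[i, , drop = FALSE], m, normalisation)
  })
  tibble::tibble(row = seq_len(n), t2 = t2)
}

#' Cosine similarity of principal components between two feature models
#'
#' Absolute cosine of the angle between the i-th loading vectors of two
#' models, i = 1..k; the absolute value absorbs the sign ambiguity of
#' principal components. 1 means identical directions, 0 orthogonal.
#'
#' @param a,b Feature models over the same features.
#' @param k Number of leading components to compare (defaults to the smaller
#'   retained dimension).
#' @return Tibble with columns `pc` and `cosine_similarity` (values in
#'   \[0, 1\]).
#' @export
pc_cosine_similarity <- function(a, b, k = NULL) {
  if (!identical(a$feature_names, b$feature_names)) {
    rlang::abort("feature models use different feature orders",
                 class = "posegait_validation_error")
  }
  kmax <- min(nrow(a$loadings), nrow(b$loadings))
  if (is.null(k)) k <- kmax
  if (k > kmax) {
    rlang::abort(sprintf("k = %d exceeds the retained components (%d)", k, kmax),
                 class = "posegait_validation_error")
  }
  cs <- vapply(seq_len(k), function(i) {
    u <- a$loadings[i, ]
    v <- b$loadings[i, ]
    abs(sum(u * v)) / (vec_norm(u) * vec_norm(v))
  }, numeric(1))
  tibble::tibble(pc = seq_len(k), cosine_similarity = cs)
}

#' Serialise / load a feature model as JSON
#'
#' The on-disk format records mean, scale, loadings, eigenvalues, explained
#' variance, sample count, stratum, the feature order and a format version,
#' so that stored models stay compatible across sessions.
#'
#' @param model A `feature_model`.
#' @param path Output / input path.
#' @return `write_feature_model()` returns `path` invisibly;
#'   `read_feature_model()` returns the `feature_model`.
#' @export
write_feature_model <- function(model, path) {
  payload <- list(
    format_version = "1",
    feature_version = model$feature_version,
    feature_names = model$feature_names,
    stratum = model$stratum,
    n_samples = model$n_samples,
    variance_threshold = model$variance_threshold,
    mean = unname(model$mean),
    scale = unname(model$scale),
    loadings = unname(apply(model$loadings, 1, identity, simplify = FALSE)),
    eigenvalues = model$eigenvalues,
    explained_variance = model$explained_variance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_model
#' @export
read_feature_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- if (is.list(p$loadings)) {
    do.call(rbind, p$loadings)
  } else if (is.matrix(p$loadings)) {
    p$loadings
  } else {
    matrix(p$loadings, nrow = 1)
  }
  structure(
    list(mean = stats::setNames(p$mean, p$feature_names),
         scale = stats::setNames(p$scale, p$feature_names),
         loadings = load,
         eigenvalues = p$eigenvalues,
         explained_variance = p$explained_variance,
         n_samples = p$n_samples,
         stratum = p$stratum,
         feature_names = p$feature_names,
         feature_version = p$feature_version,
         variance_threshold = p$variance_threshold),
    class = "feature_model"
  )
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf("<feature_model> stratum=%s n=%d d1=%d d2=%d (%.1f%% variance)\n",
              x$stratum, x$n_samples, length(x$feature_names),
              nrow(x$loadings), 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Tidy a feature model
#'
#' One row per retained principal component: eigenvalue, explained-variance
#' fraction and cumulative fraction.
#'
#' @param x A `feature_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy feature_model
#' @export
tidy.feature_model <- function(x, ...) {
  tibble::tibble(
    pc = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    explained_variance = x$explained_variance,
    cumulative_variance = cumsum(x$explained_variance)
  )
}

#' Glance at a feature model
#'
#' @param x A `feature_model`.
#' @param ... Unused.
#' @return One-row tibble with stratum, sample count, input and retained
#'   dimensions and total retained variance.
#' @method glance feature_model
#' @export
glance.feature_model <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum,
    n_samples = x$n_samples,
    d1 = length(x$feature_names),
    d2 = nrow(x$loadings),
    retained_variance = sum(x$explained_variance)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
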