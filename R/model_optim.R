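#' Mean squared error between reference and candidate feature maps
#'
#' Compares a compact backend's mean feature maps against the reference
#' model's over an evaluation set (no annotations needed): squared
#' differences averaged per image, then over the set.
#'
#' @param reference,candidate lists of same-shape numeric matrices.
#' @return Non-negative scalar.
#' @export
feature_map_mse <- function(reference, candidate) {
  if (length(reference) != length(candidate))
    stop_config("reference and candidate sets differ in length")
  per_image <- vapply(seq_along(reference), function(i) {
    if (!identical(dim(reference[[i]]), dim(candidate[[i]])))
      stop_config("feature-map shape mismatch")
    mean((reference[[i]] - candidate[[i]])^2)
  }, numeric(1))
  mean(per_image)
}

#' Min-max normalization with direction adjustment
#'
#' Maps raw metric values to `[0, 1]` by `(x - min) / (max - min)`; when a
#' lower raw value indicates better performance the result is flipped to
#' `1 - value`, so that after adjustment higher is always better. All-equal
#' inputs map to the neutral 0.5.
#'
#' @param values numeric vector.
#' @param lower_is_better flip direction after normalization.
#' @return Vector in `[0, 1]`.
#' @export
minmax_direction_normalize <- function(values, lower_is_better = FALSE) {
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(values)))
  x <- (values - rng[1L]) / (rng[2L] - rng[1L])
  if (lower_is_better) 1 - x else x
}

#' Composite trade-off score over candidate models
#'
#' `alpha * execution_time + beta * memory + gamma * feature_quality`, each
#' metric min-max normalized with direction adjustment (time, memory and MSE
#' all improve downwards, so each is flipped). Weights must sum to 1; higher
#' composite score means a better trade-off.
#'
#' @param metrics data frame with columns `model`, `time_s`, `memory_bytes`,
#'   `mse`, and optionally `n_parameters` (used to break ties: fewer wins).
#' @param alpha,beta,gamma weights in `[0, 1]` summing to 1 (defaults 0.5,
#'   0, 0.5: the speed/quality trade-off).
#' @return `metrics` with normalized columns and `score`, sorted best-first;
#'   attribute `best` holds the flagged best model id.
#' @export
composite_score <- function(metrics, alpha = 0.5, beta = 0, gamma = 0.5) {
  w <- c(alpha, beta, gamma)
  if (any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-9)
    stop_config("weights must lie in [0,1] and sum to 1")
  out <- metrics
  out$time_norm <- minmax_direction_normalize(metrics$time_s, TRUE)
  out$memory_norm <- minmax_direction_normalize(metrics$memory_bytes, TRUE)
  out$quality_norm <- minmax_direction_normalize(metrics$mse, TRUE)
  out$score <- alpha * out$time_norm + beta * out$memory_norm +
    gamma * out$quality_norm
  tie <- if ("n_parameters" %in% names(out)) out$n_parameters else
    seq_len(nrow(out))
  ord <- order(-out$score, tie)
  out <- out[ord, , drop = FALSE]
  attr(out, "best") <- out$model[1L]
  out
}

#' Ranked model-selection report
#'
#' Sorts candidate models by composite score, flags the best trade-off, and
#' keeps both raw and normalized metrics for traceability.
#'
#' @inheritParams composite_score
#' @return Data frame sorted by score with a logical `best` column.
#' @export
sweep_report <- function(metrics, alpha = 0.5, beta = 0, gamma = 0.5) {
  if (nrow(metrics) < 2) stop_config("need at least two models to rank")
  out <- composite_score(metrics, alpha, beta, gamma)
  out$best <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}
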