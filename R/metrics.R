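#' Symmetric fold error
#'
#' `FE = max(pred/obs, obs/pred)`: 1 for a perfect prediction, identical for
#' k-fold over- and under-prediction.
#'
#' @param pred,obs positive numeric vectors of equal length.
#' @return Fold errors, all >= 1.
#' @examples
#' fold_error(c(1, 2, 0.1), c(1, 1, 1))  # 1, 2, 10
#' @export
fold_error <- function(pred, obs) {
  check_pred_obs(pred, obs)
  pmax(pred / obs, obs / pred)
}

#' Percentage of predictions within k-fold of observed
#'
#' `100 * mean(FE <= k)`, boundary inclusive (a prediction exactly k-fold
#' off counts as within).
#'
#' @param pred,obs positive numeric vectors of equal length, non-empty.
#' @param k fold threshold, > 1.
#' @return Percentage in [0, 100].
#' @export
pct_within <- function(pred, obs, k) {
  check_pred_obs(pred, obs)
  if (length(pred) == 0) stop("empty prediction vector")
  if (k <= 1) stop("fold threshold k must be > 1")
  100 * mean(fold_error(pred, obs) <= k)
}

#' Absolute average fold error
#'
#' `AAFE = 10^(mean(|log10(pred/obs)|))`: the geometric-mean fold
#' discrepancy regardless of direction; 1.0 means every prediction exact.
#'
#' @param pred,obs positive numeric vectors of equal length, non-empty.
#' @return AAFE, >= 1.
#' @examples
#' aafe(c(10, 0.1), c(1, 1))  # 10
#' @export
aafe <- function(pred, obs) {
  check_pred_obs(pred, obs)
  if (length(pred) == 0) stop("empty prediction vector")
  10^mean(abs(log10(pred / obs)))
}

#' Squared Pearson correlation of predictions and observations
#'
#' Computed on log10-transformed values by default, since Vd,ss spans
#' orders of magnitude and method comparisons are made on log-log scatter;
#' `log_scale = FALSE` gives the linear-scale alternative. Returns `NA`
#' with a warning when either vector has zero variance.
#'
#' @param pred,obs positive numeric vectors, length >= 3.
#' @param log_scale correlate log10 values (default TRUE).
#' @return Squared Pearson r, or `NA` if undefined.
#' @export
log_r2 <- function(pred, obs, log_scale = TRUE) {
  check_pred_obs(pred, obs)
  if (length(pred) < 3) stop("r2 requires at least 3 observations")
  x <- if (log_scale) log10(pred) else pred
  y <- if (log_scale) log10(obs) else obs
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in predictions or observations; r2 undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

check_pred_obs <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("prediction and observation vectors must have equal length")
  }
  if (any(pred <= 0, na.rm = TRUE) || any(obs <= 0, na.rm = TRUE)) {
    stop("fold-based metrics require strictly positive values")
  }
  invisible(TRUE)
}

#' Method-comparison evaluation report
#'
#' Summarizes predictive performance per method: n, percentage of compounds
#' within 2-, 3- and 10-fold of observed, squared log-scale Pearson
#' correlation, and AAFE — the layout of a method-comparison table.
#' Compounds lacking a prediction or an observation are excluded per
#' method, so n varies across methods; exclusion counts are attached as the
#' `"n_excluded"` attribute.
#'
#' @param predictions data frame with `compound_id, method_label,
#'   vdss_L_per_kg` (rows from any mix of methods).
#' @param observed data frame with `compound_id, vdss_obs`, or a numeric
#'   vector named by compound id.
#' @param log_scale passed to [log_r2()].
#' @return Data frame with one row per method: `method_label, n,
#'   pct_within_2fold, pct_within_3fold, pct_within_10fold, r2, aafe`.
#' @export
evaluate_methods <- function(predictions, observed, log_scale = TRUE) {
  if (is.data.frame(observed)) {
    obs_map <- stats::setNames(observed$vdss_obs,
                               as.character(observed$compound_id))
  } else {
    obs_map <- observed
  }
  methods <- unique(predictions$method_label)
  n_excluded <- integer(0)
  rows <- lapply(methods, function(m) {
    sub <- predictions[predictions$method_label == m, , drop = FALSE]
    obs <- unname(obs_map[as.character(sub$compound_id)])
    keep <- !is.na(obs) & !is.na(sub$vdss_L_per_kg) & obs > 0 &
      sub$vdss_L_per_kg > 0
    n_excluded[m] <<- sum(!keep)
    pred <- sub$vdss_L_per_kg[keep]
    o <- obs[keep]
    if (length(pred) == 0) {
      stop("method '", m, "' has no compounds with observed values")
    }
    r2 <- if (length(pred) >= 3) {
      suppressWarnings(log_r2(pred, o, log_scale))
    } else {
      NA_real_
    }
    data.frame(method_label = m, n = length(pred),
               pct_within_2fold = pct_within(pred, o, 2),
               pct_within_3fold = pct_within(pred, o, 3),
               pct_within_10fold = pct_within(pred, o, 10),
               r2 = r2, aafe = aafe(pred, o), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excluded
  out
}
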