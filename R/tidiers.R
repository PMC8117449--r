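# broom-style tidy()/glance() methods for the fitted result objects.

#' Tidy an ROC result into its curve points
#'
#' @param x A `fetdki_roc`.
#' @param ... Unused.
#' @return Tibble with `cutoff`, `sensitivity`, `specificity`.
#' @method tidy fetdki_roc
#' @export
tidy.fetdki_roc <- function(x, ...) x$curve

#' One-row summary of an ROC result
#'
#' @param x A `fetdki_roc`.
#' @param ... Unused.
#' @method glance fetdki_roc
#' @export
glance.fetdki_roc <- function(x, ...) {
  tibble(
    auc = x$auc, ci_lo = x$auc_ci[1], ci_hi = x$auc_ci[2],
    optimal_cutoff = x$optimal_cutoff, direction = x$direction,
    sensitivity = x$sensitivity, specificity = x$specificity,
    accuracy = x$accuracy, p_value = x$p_value,
    n_positive = x$n_positive, n_negative = x$n_negative
  )
}

#' Tidy a logistic model's coefficient table
#'
#' @param x A `fetdki_logistic`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value` (log-odds scale).
#' @method tidy fetdki_logistic
#' @export
tidy.fetdki_logistic <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' One-row summary of a logistic model
#'
#' @param x A `fetdki_logistic`.
#' @param ... Unused.
#' @method glance fetdki_logistic
#' @export
glance.fetdki_logistic <- function(x, ...) {
  tibble(
    model = paste(x$predictors, collapse = " + "),
    accuracy = x$accuracy, converged = x$converged,
    separation = x$separation,
    deviance = x$fit$deviance, null_deviance = x$fit$null.deviance,
    aic = x$fit$aic, n = length(x$fitted_prob)
  )
}

#' Tidy the per-feature comparison table of a group analysis
#'
#' @param x A `fetdki_group_analysis`.
#' @param ... Unused.
#' @method tidy fetdki_group_analysis
#' @export
tidy.fetdki_group_analysis <- function(x, ...) x$comparisons

#' One-row summary of a group analysis
#'
#' @param x A `fetdki_group_analysis`.
#' @param ... Unused.
#' @method glance fetdki_group_analysis
#' @export
glance.fetdki_group_analysis <- function(x, ...) {
  idx_acc <- if (nrow(x$index_calls) && "group" %in% names(x$index_calls)) {
    100 * mean(x$index_calls$class == x$index_calls$group, na.rm = TRUE)
  } else NA_real_
  tibble(
    n_positive = unname(x$n["positive"]),
    n_negative = unname(x$n["negative"]),
    n_features = nrow(x$comparisons),
    n_significant = sum(x$comparisons$category == "significant"),
    n_suggestive = sum(x$comparisons$category ==
                         "significant prior to correction"),
    best_auc = if (nrow(x$roc)) max(x$roc$auc) else NA_real_,
    best_auc_feature = if (nrow(x$roc)) {
      x$roc$feature[which.max(x$roc$auc)]
    } else NA_character_,
    index_accuracy = idx_acc
  )
}

#' Tidy a relative-frequency histogram
#'
#' @param x A `fetdki_histogram`.
#' @param ... Unused.
#' @return Tibble with `mid`, `rel_freq`, `smoothed`.
#' @method tidy fetdki_histogram
#' @export
tidy.fetdki_histogram <- function(x, ...) {
  tibble(mid = x$mid, rel_freq = x$rel_freq, smoothed = x$smoothed)
}
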