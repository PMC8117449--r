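# Group statistics: Mann-Whitney screening with Bonferroni control, ROC
# characterization with optimal cutoffs and DeLong AUC comparison,
# logistic biomarker combination, and the composite FET-DKI index.

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midrank ties. For small samples
#' (`n1 + n2 <= 12`) the two-sided p-value comes from exact enumeration of
#' all group assignments (valid with ties); otherwise from the normal
#' approximation with tie and continuity correction (via
#' [stats::wilcox.test()]).
#'
#' @param x,y Numeric observations for the two groups (each nonempty).
#' @return List with `U` (for the first group), `p` (two-sided), and
#'   `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) abort_fetdki("both groups need observations")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 12L) {
    # exact null distribution by enumeration of group assignments
    comb <- utils::combn(n1 + n2, n1)
    u_all <- apply(comb, 2L, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)
    )
    p <- wt$p.value
    method <- "normal approximation"
  }
  list(U = unname(U), p = min(1, p), method = method)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni(0.05, 18) # 0.002777...
bonferroni <- function(alpha = 0.05, m) {
  if (!is_scalar_number(m) || m < 1) abort_fetdki("m must be >= 1")
  alpha / m
}

# classify a p-value against corrected and uncorrected thresholds
significance_category <- function(p, alpha, m) {
  thr <- bonferroni(alpha, m)
  dplyr::case_when(
    p <= thr ~ "significant",
    p <= alpha ~ "significant prior to correction",
    TRUE ~ "ns"
  )
}

# DeLong placement machinery --------------------------------------------

# placement values and AUC for one marker; pos/neg value vectors,
# orientation: higher value = positive class
delong_placements <- function(pos, neg) {
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(pos, function(a) mean(psi(a, neg)), numeric(1))
  V01 <- vapply(neg, function(b) mean(psi(pos, b)), numeric(1))
  list(auc = mean(V10), V10 = V10, V01 = V01)
}

delong_var <- function(pl, n1, n0) {
  s10 <- if (n1 > 1) var(pl$V10) else 0
  s01 <- if (n0 > 1) var(pl$V01) else 0
  s10 / n1 + s01 / n0
}

#' ROC analysis with optimal cutoff
#'
#' Empirical ROC with ties counted one half. The optimal cutoff maximizes
#' the Youden index J = sensitivity + specificity - 1 over criteria of the
#' form `value > c`; ties in J resolve toward higher specificity. The
#' p-value tests AUC = 0.5 with the DeLong variance; the 95% CI uses exact
#' (Clopper-Pearson) binomial bounds on the placement proportion. Markers
#' where higher values indicate the negative class are auto-oriented
#' (`direction = "<"`) before analysis.
#'
#' @param values Marker values.
#' @param labels Class labels.
#' @param positive Label of the positive class (default `"TPR"`).
#' @return Object of class `fetdki_roc`: list with `auc`, `auc_ci`,
#'   `optimal_cutoff`, `sensitivity`, `specificity`, `accuracy` (all in %),
#'   `direction` (`">"` when higher values indicate the positive class),
#'   `p_value`, counts, and the ROC curve tibble.
#' @export
roc_analysis <- function(values, labels, positive = "TPR") {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) {
    abort_fetdki("both classes must be present (got %d positive, %d negative)",
                 n1, n0)
  }
  pl <- delong_placements(values[is_pos], values[!is_pos])
  direction <- ">"
  v <- values
  if (pl$auc < 0.5) {
    direction <- "<"
    v <- -values
    pl <- delong_placements(v[is_pos], v[!is_pos])
  }
  auc <- pl$auc
  # candidate cutoffs: every observed value (criterion v > c), plus -Inf
  cand <- sort(unique(c(-Inf, v)))
  sens <- vapply(cand, function(cc) mean(v[is_pos] > cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(v[!is_pos] <= cc), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[which.max(spec[best])] # tie -> higher specificity
  cutoff <- cand[best]
  se <- sqrt(delong_var(pl, n1, n0))
  z <- if (se > 0) (auc - 0.5) / se else Inf
  p <- if (is.finite(z)) 2 * pnorm(-abs(z)) else 0
  # exact binomial bounds on the placement proportion
  npair <- n1 * n0
  xs <- auc * npair
  ci <- c(
    if (xs <= 0) 0 else qbeta(0.025, xs, npair - xs + 1),
    if (xs >= npair) 1 else qbeta(0.975, xs + 1, npair - xs)
  )
  tp <- sum(v[is_pos] > cutoff); tn <- sum(v[!is_pos] <= cutoff)
  structure(
    list(
      auc = auc, auc_ci = ci,
      optimal_cutoff = if (direction == ">") cutoff else -cutoff,
      direction = direction,
      sensitivity = 100 * sens[best], specificity = 100 * spec[best],
      accuracy = 100 * (tp + tn) / (n1 + n0),
      p_value = p, n_positive = n1, n_negative = n0,
      curve = tibble(
        cutoff = if (direction == ">") cand else rev(-cand),
        sensitivity = if (direction == ">") sens else rev(sens),
        specificity = if (direction == ">") spec else rev(spec)
      ),
      positive = positive
    ),
    class = "fetdki_roc"
  )
}

#' @export
print.fetdki_roc <- function(x, ...) {
  cat(sprintf(
    "<fetdki_roc> AUC %.3f (95%% CI %.3f-%.3f), cutoff %s %.4g: sens %.0f%%, spec %.0f%%, acc %.0f%% (p = %.2g)\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$direction, x$optimal_cutoff,
    x$sensitivity, x$specificity, x$accuracy, x$p_value))
  invisible(x)
}

#' Compare two correlated AUCs (DeLong)
#'
#' Both markers must be measured on the same subjects (paired design). The
#' covariance of the two AUCs is estimated from the placement values; the
#' difference is tested with a z statistic.
#'
#' @param values1,values2 Paired marker values.
#' @param labels Class labels (shared).
#' @param positive Positive class label.
#' @param orient Auto-orient each marker so AUC >= 0.5 before comparison
#'   (default TRUE, matching [roc_analysis()]).
#' @return List with `auc1`, `auc2`, `z`, `p`.
#' @export
delong_compare <- function(values1, values2, labels, positive = "TPR",
                           orient = TRUE) {
  if (length(values1) != length(values2) ||
      length(values1) != length(labels)) {
    abort_fetdki("markers must be paired: equal lengths required")
  }
  keep <- is.finite(values1) & is.finite(values2) & !is.na(labels)
  values1 <- values1[keep]; values2 <- values2[keep]
  labels <- labels[keep]
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) abort_fetdki("both classes must be present")
  orient1 <- orient && mean(rank(values1)[is_pos]) < mean(rank(values1)[!is_pos])
  orient2 <- orient && mean(rank(values2)[is_pos]) < mean(rank(values2)[!is_pos])
  if (orient1) values1 <- -values1
  if (orient2) values2 <- -values2
  p1 <- delong_placements(values1[is_pos], values1[!is_pos])
  p2 <- delong_placements(values2[is_pos], values2[!is_pos])
  cov10 <- if (n1 > 1) stats::cov(p1$V10, p2$V10) else 0
  cov01 <- if (n0 > 1) stats::cov(p1$V01, p2$V01) else 0
  vd <- delong_var(p1, n1, n0) + delong_var(p2, n1, n0) -
    2 * (cov10 / n1 + cov01 / n0)
  d <- p1$auc - p2$auc
  if (abs(d) < 1e-15) {
    z <- 0; p <- 1
  } else if (vd <= 0) {
    z <- sign(d) * Inf; p <- 0
  } else {
    z <- d / sqrt(vd); p <- 2 * pnorm(-abs(z))
  }
  list(auc1 = p1$auc, auc2 = p2$auc, z = z, p = p)
}

#' Logistic regression with separation diagnostics
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()], tolerance
#' 1e-8, up to 100 iterations) of the binary diagnosis on the chosen
#' predictors. Complete or quasi-separation is detected (fitted
#' probabilities numerically 0/1 or diverging coefficients) and flagged
#' rather than silently reported. Classification accuracy is evaluated at
#' predicted probability 0.5.
#'
#' @param cohort Data frame with a `group` column and the predictors.
#' @param predictors Character vector of predictor column names.
#' @param positive Positive class label (coded 1).
#' @return Object of class `fetdki_logistic`: the `glm` fit plus
#'   `separation`, `converged`, `accuracy` (%), and the confusion counts.
#' @export
logistic_fit <- function(cohort, predictors, positive = "TPR") {
  stopifnot(length(predictors) >= 1L)
  missing_cols <- setdiff(c("group", predictors), names(cohort))
  if (length(missing_cols)) {
    abort_fetdki("cohort lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  dat <- cohort[, c("group", predictors)]
  if (anyNA(dat)) abort_fetdki("missing values among selected columns")
  dat$.y <- as.integer(dat$group == positive)
  X <- as.matrix(dat[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(predictors) + 1L) {
    abort_fetdki("rank-deficient design: collinear predictors")
  }
  form <- stats::as.formula(
    paste(".y ~", paste(sprintf("`%s`", predictors), collapse = " + "))
  )
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat,
        control = list(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  separation <- sep_warn || max(abs(coef(fit)[-1])) > 1e3
  prob <- fitted(fit)
  pred <- as.integer(prob > 0.5)
  tp <- sum(pred == 1 & dat$.y == 1); tn <- sum(pred == 0 & dat$.y == 0)
  structure(
    list(
      fit = fit, predictors = predictors,
      coefficients = coef(fit), converged = fit$converged,
      separation = separation,
      accuracy = 100 * (tp + tn) / nrow(dat),
      confusion = c(tp = tp, fp = sum(pred == 1) - tp,
                    fn = sum(dat$.y == 1) - tp, tn = tn),
      fitted_prob = prob, positive = positive
    ),
    class = "fetdki_logistic"
  )
}

#' @export
print.fetdki_logistic <- function(x, ...) {
  cat(sprintf(
    "<fetdki_logistic> %s; accuracy %.0f%% at p = 0.5%s%s\n",
    paste(x$predictors, collapse = " + "), x$accuracy,
    if (x$separation) "; SEPARATION flagged" else "",
    if (!x$converged) "; NOT converged" else ""))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' The composite FET-DKI index
#'
#' `index = 4.7 * TBRmax + 39.2 * MK_C90`; values strictly above the
#' decision threshold (41) classify as tumor progression (TPR), otherwise
#' as treatment-related change (TRC).
#'
#' @param tbr_max Maximum tumor-to-brain ratio.
#' @param mk_c90 90th centile of the mean-kurtosis lesion histogram.
#' @param w_tbr,w_mk Index weights.
#' @param cutoff Decision threshold.
#' @return Tibble with `index` and `class` (`NA` class where an input is
#'   missing).
#' @export
#' @examples
#' fet_dki_index(3.30, 0.78) # 46.086 -> TPR
#' fet_dki_index(2.50, 0.61) # 35.662 -> TRC
fet_dki_index <- function(tbr_max, mk_c90, w_tbr = 4.7, w_mk = 39.2,
                          cutoff = 41) {
  idx <- w_tbr * tbr_max + w_mk * mk_c90
  cls <- ifelse(is.na(idx), NA_character_,
                ifelse(idx > cutoff, "TPR", "TRC"))
  tibble(index = idx, class = cls)
}

#' Full group analysis of a patient cohort
#'
#' Runs the complete statistical stage on a feature table: per-feature
#' Mann-Whitney comparisons with family-specific Bonferroni thresholds
#' (m = 18 for the DT/KT histogram variables, m = 4 for the PET
#' parameters), ROC analysis for every feature significant before
#' correction, univariate logistic fits for the Bonferroni-significant
#' DT/KT features, the preset multivariate combination (MK C90 + TBRmax),
#' and the per-patient FET-DKI index classification.
#'
#' @param cohort Tibble with `group` (two levels) and the 22-feature schema
#'   (see [calibration_targets()]); extra columns are ignored, missing feature
#'   columns are skipped.
#' @param alpha Uncorrected significance level.
#' @param positive Positive class label.
#' @return Object of class `fetdki_group_analysis`: list with tibbles
#'   `comparisons` (medians/quartiles/U/p/category per feature), `roc`
#'   (one row per analyzed feature), `logistic` (one row per model),
#'   `index_calls` (per patient), and the fitted objects in
#'   `roc_objects` / `logistic_objects`.
#' @export
run_group_analysis <- function(cohort, alpha = 0.05, positive = "TPR") {
  stopifnot("group" %in% names(cohort))
  groups <- unique(cohort$group)
  if (length(groups) != 2L || !positive %in% groups) {
    abort_fetdki("cohort must contain exactly two groups incl. '%s' (got: %s)",
                 positive, paste(groups, collapse = ", "))
  }
  negative <- setdiff(groups, positive)
  features <- intersect(FEATURE_SCHEMA, names(cohort))
  if (!length(features)) abort_fetdki("no schema features found in cohort")

  comparisons <- purrr::map_dfr(features, function(f) {
    xs <- cohort[[f]][cohort$group == positive]
    ys <- cohort[[f]][cohort$group == negative]
    xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
    mw <- mann_whitney(xs, ys)
    panel <- if (f %in% PET_FEATURES) "pet" else "dtkt"
    m <- if (panel == "pet") 4L else 18L
    tibble(
      feature = f, panel = panel,
      median_pos = median(xs), q1_pos = quantile(xs, 0.25, names = FALSE),
      q3_pos = quantile(xs, 0.75, names = FALSE),
      median_neg = median(ys), q1_neg = quantile(ys, 0.25, names = FALSE),
      q3_neg = quantile(ys, 0.75, names = FALSE),
      U = mw$U, p = mw$p, m = m,
      threshold = bonferroni(alpha, m),
      category = significance_category(mw$p, alpha, m)
    )
  })

  roc_feats <- comparisons$feature[comparisons$category != "ns"]
  roc_objects <- purrr::map(
    setNames(roc_feats, roc_feats),
    function(f) roc_analysis(cohort[[f]], cohort$group, positive)
  )
  roc_tbl <- purrr::imap_dfr(roc_objects, function(r, f) {
    tibble(
      feature = f, auc = r$auc, ci_lo = r$auc_ci[1], ci_hi = r$auc_ci[2],
      cutoff = r$optimal_cutoff, direction = r$direction,
      sensitivity = r$sensitivity, specificity = r$specificity,
      accuracy = r$accuracy, p = r$p_value
    )
  })

  # univariate logistic for Bonferroni-significant DT/KT features, plus the
  # preset multivariate combination
  uni_feats <- comparisons$feature[comparisons$category == "significant" &
                                     comparisons$panel == "dtkt"]
  model_sets <- c(
    purrr::map(uni_feats, identity),
    if (all(c("MK_C90", "TBR_max") %in% features)) {
      list(c("MK_C90", "TBR_max"))
    }
  )
  logistic_objects <- purrr::map(model_sets, function(pr) {
    tryCatch(logistic_fit(cohort, pr, positive), error = function(e) NULL)
  })
  keep <- !purrr::map_lgl(logistic_objects, is.null)
  logistic_objects <- logistic_objects[keep]
  logistic_tbl <- purrr::map_dfr(logistic_objects, function(lf) {
    tibble(
      model = paste(lf$predictors, collapse = " + "),
      n_predictors = length(lf$predictors),
      accuracy = lf$accuracy, separation = lf$separation,
      converged = lf$converged
    )
  })

  index_calls <- if (all(c("MK_C90", "TBR_max") %in% features)) {
    dplyr::bind_cols(
      cohort[, c("patient_id", "group")[c("patient_id", "group") %in%
                                          names(cohort)]],
      fet_dki_index(cohort$TBR_max, cohort$MK_C90)
    )
  } else {
    tibble()
  }

  structure(
    list(
      comparisons = comparisons, roc = roc_tbl, logistic = logistic_tbl,
      index_calls = index_calls,
      roc_objects = roc_objects, logistic_objects = logistic_objects,
      alpha = alpha, positive = positive, negative = negative,
      n = c(positive = sum(cohort$group == positive),
            negative = sum(cohort$group == negative))
    ),
    class = "fetdki_group_analysis"
  )
}

#' @export
print.fetdki_group_analysis <- function(x, ...) {
  cat(sprintf(
    "<fetdki_group_analysis> %d %s vs %d %s; %d features compared, %d significant after Bonferroni\n",
    x$n[1], x$positive, x$n[2], x$negative, nrow(x$comparisons),
    sum(x$comparisons$category == "significant")))
  if (nrow(x$roc)) {
    cat(sprintf("  best AUC: %s (%.3f)\n",
                x$roc$feature[which.max(x$roc$auc)], max(x$roc$auc)))
  }
  if (nrow(x$index_calls) && "group" %in% names(x$index_calls)) {
    acc <- mean(x$index_calls$class == x$index_calls$group, na.rm = TRUE)
    cat(sprintf("  FET-DKI index accuracy: %.0f%%\n", 100 * acc))
  }
  invisible(x)
}
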