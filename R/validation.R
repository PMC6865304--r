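#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties counted one half);
#' the CI is DeLong's asymptotic interval.
#'
#' @param scores numeric risk scores (higher = more likely event).
#' @param labels 0/1 event indicators.
#' @param level confidence level, default 0.95.
#' @return list `auc`, `lower`, `upper`.
#' @export
roc_auc <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = labels, predictor = scores,
                 direction = "<", levels = c(0, 1), quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = level, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), lower = ci[1], upper = ci[3])
}

# exact binomial (Clopper-Pearson) interval; NA-safe for empty denominators
.cp_ci <- function(x, n, level = 0.95) {
  if (is.na(n) || n == 0) return(c(NA_real_, NA_real_))
  ci <- stats::binom.test(x, n, conf.level = level)$conf.int
  c(ci[1], ci[2])
}

#' Classification metrics at a risk cutoff
#'
#' Scores at or above the cutoff are called positive.  Sensitivity,
#' specificity, PPV and NPV are reported with exact Clopper-Pearson
#' confidence intervals; a metric whose denominator is empty is reported
#' as `NA`, never as 0.
#'
#' @inheritParams roc_auc
#' @param cutoff finite classification threshold.
#' @return data frame with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `lower`, `upper`.
#' @examples
#' # 2x2 arithmetic: sensitivity 95/96, specificity 658/1346
#' s <- c(rep(1, 95), 0, rep(1, 688), rep(0, 658))
#' l <- c(rep(1, 96), rep(0, 1346))
#' confusion_metrics(s, l, cutoff = 0.5)
#' @export
confusion_metrics <- function(scores, labels, cutoff, level = 0.95) {
  if (is.na(cutoff)) stop("cutoff must not be missing", call. = FALSE)
  labels <- as.integer(labels)
  pos <- scores >= cutoff
  tp <- sum(pos & labels == 1L); fn <- sum(!pos & labels == 1L)
  fp <- sum(pos & labels == 0L); tn <- sum(!pos & labels == 0L)
  num <- c(tp, tn, tp, tn)
  den <- c(tp + fn, tn + fp, tp + fp, tn + fn)
  est <- ifelse(den > 0, num / den, NA_real_)
  cis <- t(mapply(function(x, n) if (n > 0) .cp_ci(x, n, level)
                  else c(NA_real_, NA_real_), num, den))
  data.frame(metric = c("sensitivity", "specificity", "ppv", "npv"),
             numerator = num, denominator = den, estimate = est,
             lower = cis[, 1], upper = cis[, 2])
}

#' Calibration bins: predicted versus observed event rates
#'
#' Quantile-based binning of predicted risks; per bin, the mean predicted
#' risk is compared with the observed event rate (exact binomial CI).
#'
#' @param predicted predicted probabilities in `[0, 1]`.
#' @param observed 0/1 outcomes, same length.
#' @param n_bins number of bins, default 10; must not exceed `n / 5`.
#' @param level confidence level for the per-bin binomial CI.
#' @return data frame: `bin`, `n`, `mean_predicted`, `observed_rate`,
#'   `lower`, `upper`.
#' @export
calibration_bins <- function(predicted, observed, n_bins = 10, level = 0.95) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length", call. = FALSE)
  if (any(predicted < 0 | predicted > 1))
    stop("predicted must lie in [0, 1]", call. = FALSE)
  n <- length(predicted)
  if (n_bins > n / 5)
    stop("n_bins exceeds n/5; too few observations per bin", call. = FALSE)
  qs <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  bin <- if (length(qs) < 2L) rep(1L, n) else
    cut(predicted, breaks = qs, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    x <- sum(observed[i]); m <- sum(i)
    ci <- .cp_ci(x, m, level)
    data.frame(bin = b, n = m, mean_predicted = mean(predicted[i]),
               observed_rate = x / m, lower = ci[1], upper = ci[2])
  }))
  rownames(out) <- NULL
  out
}

#' Stratified k-fold cross-validated discrimination
#'
#' Folds are stratified by event status with seeded shuffling; the model is
#' refitted on each training set, held-out infants are scored by their
#' predicted cumulative risk at the horizon, and the pooled held-out scores
#' yield one AUC.
#'
#' @param cohort cohort data frame (see [expand_person_time()] schema).
#' @param encoding a [digirop_encoding()].
#' @param k number of folds, default 10; must satisfy `2 <= k < n`.
#' @param seed integer seed for fold assignment.
#' @param horizon scoring horizon in weeks, default 20.
#' @param interval_width person-time interval width passed to the fit.
#' @return list: `cv_auc` (with CI), `apparent_auc`, `k`, `scores`
#'   (pooled held-out risks), `fold` assignment.
#' @export
cross_validate <- function(cohort, encoding = digirop_encoding(), k = 10,
                           seed, horizon = 20, interval_width = 1) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n", call. = FALSE)
  n_events <- sum(cohort$event)
  if (k > n_events) {
    warning("more folds than events; reducing k to ", n_events)
    k <- n_events
  }
  set.seed(seed)
  fold <- integer(n)
  for (cls in c(0L, 1L)) {
    i <- which(cohort$event == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  scores <- numeric(n)
  for (f in seq_len(k)) {
    train <- cohort[fold != f, , drop = FALSE]
    test <- cohort[fold == f, , drop = FALSE]
    m <- digirop_fit(train, encoding, interval_width = interval_width)
    scores[fold == f] <- cumulative_risk(
      test[, c("ga_weeks", "sex", "bwsds")], horizon, m, horizon = horizon)
  }
  m_all <- digirop_fit(cohort, encoding, interval_width = interval_width)
  apparent <- cumulative_risk(cohort[, c("ga_weeks", "sex", "bwsds")],
                              horizon, m_all, horizon = horizon)
  list(cv_auc = roc_auc(scores, cohort$event),
       apparent_auc = roc_auc(apparent, cohort$event),
       k = k, scores = scores, fold = fold)
}
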