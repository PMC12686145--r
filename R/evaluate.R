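#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (predicted positive
#' iff score >= threshold), recording (FPR, TPR) from (0,0) to (1,1); tied
#' scores move the curve in a single simultaneous step. The AUC is the
#' trapezoidal area, which equals the Mann-Whitney concordance probability
#' with half-credit for ties.
#'
#' @param scores numeric scores, higher = more positive (non-responder).
#' @param labels 0/1 or R/NR labels (1/NR = positive).
#' @return list of class \code{"roc_curve"}: \code{fpr}, \code{tpr},
#'   \code{thresholds}, \code{auc}.
#' @examples
#' roc_auc(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else response01(labels)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  # one step per unique score (ties collapse into a simultaneous step)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x a \code{\link{roc_auc}} result.
#' @param ... passed to \code{plot.default}.
#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Confusion matrix at a threshold
#'
#' Predicted positive iff score >= threshold (inclusive rule). Returns the
#' four counts plus accuracy, sensitivity and specificity derived from them.
#'
#' @inheritParams roc_auc
#' @param threshold finite decision threshold.
#' @return list of class \code{"confusion_matrix"}: \code{tp, fp, tn, fn,
#'   accuracy, sensitivity, specificity, threshold}.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  y <- if (is.numeric(labels)) as.integer(labels) else response01(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y == 1)
  fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0)
  fn <- sum(!pred & y == 1)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(y),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 threshold = threshold),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix at threshold %.4g\n", x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Youden-optimal threshold
#'
#' The unique score maximizing sensitivity + specificity - 1 under the
#' inclusive (>=) prediction rule; ties resolved toward the smaller
#' threshold.
#'
#' @inheritParams roc_auc
#' @return scalar threshold.
#' @export
youden_threshold <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else response01(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    cm <- confusion_at_threshold(scores, y, th)
    cm$sensitivity + cm$specificity - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Calibration table
#'
#' Bins predicted probabilities into equal-width bins over [0, 1] and
#' reports, per bin, the mean predicted probability and the observed event
#' fraction. Empty bins are kept with n = 0 and missing observed fraction.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels 0/1 or R/NR event labels.
#' @param n_bins number of equal-width bins (default 10).
#' @return data.frame: \code{bin, lower, upper, n, mean_predicted,
#'   observed}.
#' @export
calibration_table <- function(probs, labels, n_bins = 10) {
  if (any(probs < 0 | probs > 1)) {
    stop("`probs` must lie in [0, 1]", call. = FALSE)
  }
  y <- if (is.numeric(labels)) as.integer(labels) else response01(labels)
  n_bins <- check_count(n_bins, "n_bins")
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(probs, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin = seq_len(n_bins), lower = br[-length(br)],
                    upper = br[-1])
  out$n <- vapply(out$bin, function(b) sum(bin == b), integer(1))
  out$mean_predicted <- vapply(out$bin, function(b) {
    if (sum(bin == b) == 0) NA_real_ else mean(probs[bin == b])
  }, numeric(1))
  out$observed <- vapply(out$bin, function(b) {
    if (sum(bin == b) == 0) NA_real_ else mean(y[bin == b])
  }, numeric(1))
  out
}

#' Decision curve analysis (net benefit)
#'
#' Net benefit of calling positives at probability threshold pt:
#' NB(pt) = TP/N - (FP/N) * pt/(1 - pt), with predictions positive iff
#' predicted probability >= pt. Reported alongside the treat-all policy
#' (everyone positive) and treat-none (identically zero). Thresholds must
#' lie strictly inside (0, 1); pt = 1 is undefined and excluded.
#'
#' @param probs predicted probabilities of the event.
#' @param labels 0/1 or R/NR event labels.
#' @param thresholds probability thresholds (default 0.01 to 0.99 by 0.01).
#' @return data.frame: \code{threshold, nb_model, nb_all, nb_none}.
#' @export
net_benefit_curve <- function(probs, labels,
                              thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- if (is.numeric(labels)) as.integer(labels) else response01(labels)
  drop <- thresholds <= 0 | thresholds >= 1
  if (any(drop)) {
    warning("excluding ", sum(drop), " threshold(s) outside (0, 1)")
    thresholds <- thresholds[!drop]
  }
  n <- length(y)
  prev <- mean(y)
  out <- data.frame(threshold = thresholds)
  out$nb_model <- vapply(thresholds, function(pt) {
    pred <- probs >= pt
    sum(pred & y == 1) / n - sum(pred & y == 0) / n * pt / (1 - pt)
  }, numeric(1))
  out$nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out$nb_none <- 0
  out
}

#' Univariate and multivariate logistic model comparison
#'
#' Maximum-likelihood logistic fits of the outcome on the covariates, either
#' one model per covariate (univariate) or a single joint model
#' (multivariate). Reports coefficients, SEs, odds ratios with Wald 95\%
#' CIs and p-values; covariates showing perfect separation are flagged and
#' their Wald inference withheld.
#'
#' @param data data.frame holding outcome and covariates.
#' @param outcome name of the 0/1 (or R/NR) outcome column.
#' @param covariates character vector of covariate column names.
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @return data.frame: \code{model, term, estimate, se, or, ci_low, ci_high,
#'   p, separation}.
#' @export
logistic_compare <- function(data, outcome, covariates,
                             mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  y <- data[[outcome]]
  y <- if (is.numeric(y)) as.integer(y) else response01(y)
  if (length(unique(y)) < 2) stop("both outcome classes required", call. = FALSE)
  if (nrow(data) <= length(covariates) + 1) {
    stop("need n > number of covariates + 1", call. = FALSE)
  }
  fit_one <- function(covs, label) {
    df <- data.frame(.y = y, data[covs], check.names = FALSE)
    fit <- suppressWarnings(
      glm(as.formula(paste(".y ~", paste(sprintf("`%s`", covs), collapse = "+"))),
          data = df, family = binomial()))
    sm <- summary(fit)$coefficients
    sep <- !fit$converged | any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
    rows <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    data.frame(model = label, term = rownames(rows),
               estimate = rows[, 1], se = rows[, 2],
               or = exp(rows[, 1]),
               ci_low = if (sep) NA_real_ else exp(rows[, 1] - 1.96 * rows[, 2]),
               ci_high = if (sep) NA_real_ else exp(rows[, 1] + 1.96 * rows[, 2]),
               p = if (sep) NA_real_ else rows[, 4],
               separation = sep, stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (mode == "univariate") {
    do.call(rbind, lapply(covariates, function(cv) fit_one(cv, cv)))
  } else {
    fit_one(covariates, "multivariate")
  }
  rownames(out) <- NULL
  out
}
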