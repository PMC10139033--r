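#' Paired observed/predicted activities with training-set provenance
#'
#' Container for a set of observed and predicted activities (pIC50 units)
#' together with the training-set summaries needed by the external-validation
#' statistics (the training mean for QF1 and the training variance for QF3).
#'
#' @param observed numeric vector of experimental activities.
#' @param predicted numeric vector of model predictions, same length.
#' @param kind provenance of the predictions: cross-validated (`"cv"`),
#'   leave-one-out (`"loo"`), external test set (`"external"`) or training-set
#'   fit (`"train"`).
#' @param train_observed optional numeric vector of training-set activities;
#'   when given, `train_mean`, `train_ss` and `n_train` are derived from it.
#' @param train_mean mean training-set activity (Y-bar over TR).
#' @param train_ss total sum of squares of the training activities about
#'   `train_mean`.
#' @param n_train training-set size.
#' @param ids optional compound identifiers.
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(observed, predicted,
                           kind = c("cv", "loo", "external", "train"),
                           train_observed = NULL,
                           train_mean = NULL, train_ss = NULL, n_train = NULL,
                           ids = NULL) {
  kind <- match.arg(kind)
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted)) {
    .err("observed and predicted must have equal length")
  }
  if (length(observed) < 2L) .err("need at least 2 paired values")
  if (anyNA(observed) || anyNA(predicted) ||
      any(!is.finite(observed)) || any(!is.finite(predicted))) {
    .err("observed and predicted must be finite")
  }
  if (!is.null(train_observed)) {
    train_mean <- mean(train_observed)
    train_ss <- .ss(train_observed - train_mean)
    n_train <- length(train_observed)
  }
  # without external provenance, fall back to the evaluation set itself
  if (is.null(train_mean)) train_mean <- mean(observed)
  if (is.null(train_ss)) train_ss <- .ss(observed - mean(observed))
  if (is.null(n_train)) n_train <- length(observed)
  structure(list(
    observed = observed, predicted = predicted, kind = kind,
    train_mean = train_mean, train_ss = train_ss,
    n_train = as.integer(n_train), n = length(observed), ids = ids
  ), class = "prediction_set")
}

#' External-validation statistics for a prediction set
#'
#' Computes the full battery of regression validation statistics used for
#' QSAR model acceptance: the determination coefficient Q2/R2, the
#' regression-through-origin (RTO) slopes k and k', the RTO determination
#' coefficients R0^2 and R'0^2, the concordance correlation coefficient
#' (CCC), the external functions QF1^2, QF2^2 and QF3^2, the rm^2 metrics
#' and the mean absolute error.
#'
#' Formulas (Y observed, Yh predicted, n pairs):
#' \deqn{R^2 = 1 - \sum(Y - \hat Y)^2 / \sum(Y - \bar Y)^2}
#' \deqn{k = \sum Y\hat Y / \sum \hat Y^2, \quad k' = \sum Y\hat Y / \sum Y^2}
#' \deqn{R_0^2 = 1 - \sum(Y - k\hat Y)^2 / \sum(Y - \bar Y)^2}
#' \deqn{R'^2_0 = 1 - \sum(\hat Y - k'Y)^2 / \sum(\hat Y - \bar{\hat Y})^2}
#' \deqn{CCC = 2\sum(Y-\bar Y)(\hat Y-\bar{\hat Y}) /
#'   [\sum(Y-\bar Y)^2 + \sum(\hat Y-\bar{\hat Y})^2 + n(\bar Y-\bar{\hat Y})^2]}
#' QF1 uses the training mean in the denominator, QF2 the evaluation-set
#' mean, and QF3 compares the mean squared prediction error against the
#' training-set variance. `rm2 = R2 (1 - sqrt(|R2 - R0^2|))` and its primed
#' analogue use the absolute difference under the root; near-perfect fits can
#' make the difference numerically negative, in which case `rm2_abs_flag` is
#' set on the report.
#'
#' @param ps a [prediction_set()].
#' @return An object of class `validation_report`: a list of named numeric
#'   statistics plus bookkeeping fields (`n`, `kind`, `rm2_abs_flag`).
#' @export
regression_metrics <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  y <- ps$observed
  yh <- ps$predicted
  n <- ps$n
  if (n < 3L) .err("at least 3 pairs required for validation statistics")
  ybar <- mean(y)
  yhbar <- mean(yh)
  ss_tot <- .ss(y - ybar)
  if (ss_tot <= 0) .err("observed values have zero variance; metrics undefined")
  ss_res <- .ss(y - yh)
  ss_pred <- .ss(yh - yhbar)

  r2 <- 1 - ss_res / ss_tot
  k <- sum(y * yh) / .ss(yh)
  kp <- sum(y * yh) / .ss(y)
  r2_0 <- 1 - .ss(y - k * yh) / ss_tot
  r2_0p <- if (ss_pred > 0) 1 - .ss(yh - kp * y) / ss_pred else NA_real_
  ccc <- 2 * sum((y - ybar) * (yh - yhbar)) /
    (ss_tot + ss_pred + n * (ybar - yhbar)^2)
  qf1 <- 1 - ss_res / .ss(y - ps$train_mean)
  qf2 <- 1 - ss_res / ss_tot
  qf3 <- 1 - (ss_res / n) / (ps$train_ss / ps$n_train)
  mae <- mean(abs(y - yh))

  d <- r2 - r2_0
  dp <- r2 - r2_0p
  flag <- isTRUE(d < 0) || isTRUE(dp < 0)
  rm2 <- r2 * (1 - sqrt(abs(d)))
  rm2p <- if (is.na(r2_0p)) NA_real_ else r2 * (1 - sqrt(abs(dp)))
  validation_report(
    r2 = r2, mae = mae, k_slope = k, k_prime = kp,
    r2_0 = r2_0, r2_0_prime = r2_0p, ccc = ccc,
    qf1 = qf1, qf2 = qf2, qf3 = qf3,
    rm2 = rm2, rm2_prime = rm2p,
    n = n, kind = ps$kind, rm2_abs_flag = flag
  )
}

#' Assemble a validation report
#'
#' Builds a `validation_report` from named statistics, recomputing
#' `rm2_bar` as the exact mean of `rm2` and `rm2_prime`. Useful both as the
#' return container of [regression_metrics()] and for feeding externally
#' reported statistics into the decision rules.
#'
#' @param r2 determination coefficient of the evaluation set (Q2 for
#'   cross-validated predictions, R2 for an external set).
#' @param mae mean absolute error.
#' @param k_slope,k_prime regression-through-origin slopes.
#' @param r2_0,r2_0_prime RTO determination coefficients.
#' @param ccc concordance correlation coefficient.
#' @param qf1,qf2,qf3 external QFn^2 functions.
#' @param rm2,rm2_prime rm^2 metrics; `rm2_bar` is always their mean.
#' @param auc optional threshold-classification AUC.
#' @param q2_cv optional cross-validated Q2 carried alongside external
#'   statistics.
#' @param n number of evaluation pairs.
#' @param kind provenance tag.
#' @param rm2_abs_flag whether `|R2 - R0^2|` clamping was triggered.
#' @return A list with class `validation_report`.
#' @export
validation_report <- function(r2 = NA_real_, mae = NA_real_,
                              k_slope = NA_real_, k_prime = NA_real_,
                              r2_0 = NA_real_, r2_0_prime = NA_real_,
                              ccc = NA_real_,
                              qf1 = NA_real_, qf2 = NA_real_, qf3 = NA_real_,
                              rm2 = NA_real_, rm2_prime = NA_real_,
                              auc = NA_real_, q2_cv = NA_real_,
                              n = NA_integer_, kind = "external",
                              rm2_abs_flag = FALSE) {
  rep <- list(
    r2 = r2, mae = mae, k_slope = k_slope, k_prime = k_prime,
    r2_0 = r2_0, r2_0_prime = r2_0_prime, ccc = ccc,
    qf1 = qf1, qf2 = qf2, qf3 = qf3,
    rm2 = rm2, rm2_prime = rm2_prime,
    rm2_bar = (rm2 + rm2_prime) / 2,
    auc = auc, q2_cv = q2_cv,
    n = n, kind = kind, rm2_abs_flag = isTRUE(rm2_abs_flag)
  )
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 4, ...) {
  cat("Validation report (", x$kind, ", n = ", x$n, ")\n", sep = "")
  nm <- c("r2", "mae", "k_slope", "k_prime", "r2_0", "r2_0_prime",
          "ccc", "qf1", "qf2", "qf3", "rm2", "rm2_prime", "rm2_bar",
          "auc", "q2_cv")
  for (f in nm) {
    v <- x[[f]]
    if (!is.null(v) && !is.na(v)) {
      cat(sprintf("  %-11s %s\n", f, format(round(v, digits), nsmall = digits)))
    }
  }
  if (x$rm2_abs_flag) cat("  note: |R2 - R0^2| clamped under the square root\n")
  invisible(x)
}

.decision_outcome <- function(name, value, threshold, pass) {
  criteria <- data.frame(
    name = name, value = value, threshold = threshold,
    pass = pass, stringsAsFactors = FALSE
  )
  structure(list(criteria = criteria, overall = all(criteria$pass)),
            class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  df <- x$criteria
  df$value <- signif(df$value, 4)
  print(df, row.names = FALSE)
  cat("overall:", if (x$overall) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Golbraikh-Tropsha model acceptance decision
#'
#' Applies the regression-through-origin decision rule for external
#' predictivity: Q2 (cross-validated) above 0.5, external R2 above 0.6, at
#' least one of the relative RTO gaps `(R2 - R0^2)/R2` and
#' `(R2 - R'0^2)/R2` below 0.1, at least one RTO slope within
#' \[0.85, 1.15\], and `|R0^2 - R'0^2|` below 0.3.
#'
#' @param report a [validation_report()] carrying the external statistics.
#' @param q2_cv cross-validated Q2; defaults to the report's `q2_cv` field.
#' @return A `decision_outcome`: a criteria table (name, value, threshold,
#'   pass) and the overall conjunction.
#' @export
gtr_decision <- function(report, q2_cv = report$q2_cv) {
  stopifnot(inherits(report, "validation_report"))
  r2 <- report$r2
  if (is.na(q2_cv)) .err("q2_cv is required for the Golbraikh-Tropsha rule")
  if (!is.finite(r2)) .err("report lacks an external R2")
  if (r2 > 0) {
    gap <- (r2 - report$r2_0) / r2
    gap_p <- (r2 - report$r2_0_prime) / r2
    gap_pass <- isTRUE(gap < 0.1) || isTRUE(gap_p < 0.1)
    gap_val <- suppressWarnings(min(gap, gap_p, na.rm = TRUE))
  } else {
    # R2 <= 0: relative gaps are meaningless, criterion fails outright
    gap_pass <- FALSE
    gap_val <- NA_real_
  }
  k_ok <- function(k) isTRUE(k >= 0.85) && isTRUE(k <= 1.15)
  slope_pass <- k_ok(report$k_slope) || k_ok(report$k_prime)
  r0_diff <- abs(report$r2_0 - report$r2_0_prime)
  .decision_outcome(
    name = c("Q2_cv", "R2_external", "RTO_gap_ratio", "RTO_slope", "R0_diff"),
    value = c(q2_cv, r2, gap_val,
              if (k_ok(report$k_slope)) report$k_slope else report$k_prime,
              r0_diff),
    threshold = c("> 0.5", "> 0.6", "min < 0.1", "0.85..1.15 (k or k')",
                  "< 0.3"),
    pass = c(isTRUE(q2_cv > 0.5), isTRUE(r2 > 0.6), gap_pass, slope_pass,
             isTRUE(r0_diff < 0.3))
  )
}

#' Chirico-Gramatica model acceptance decision
#'
#' Concordance-based acceptance thresholds for external validation:
#' CCC at least 0.85, each of QF1^2, QF2^2 and QF3^2 at least 0.70, and the
#' averaged rm^2 at least 0.65.
#'
#' @param report a [validation_report()].
#' @return A `decision_outcome`, as for [gtr_decision()].
#' @export
cg_decision <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  vals <- c(report$ccc, report$qf1, report$qf2, report$qf3, report$rm2_bar)
  if (anyNA(vals)) .err("report is incomplete for the Chirico-Gramatica rule")
  .decision_outcome(
    name = c("CCC", "QF1_2", "QF2_2", "QF3_2", "rm2_bar"),
    value = vals,
    threshold = c(">= 0.85", ">= 0.70", ">= 0.70", ">= 0.70", ">= 0.65"),
    pass = c(vals[1] >= 0.85, vals[2] >= 0.70, vals[3] >= 0.70,
             vals[4] >= 0.70, vals[5] >= 0.65)
  )
}

#' Threshold-classification AUC of a regression model
#'
#' Dichotomises the observed activities at `activity_threshold` (active when
#' observed pIC50 is at or above the threshold) and scores the ROC AUC of the
#' predicted values as a ranking statistic for that class, using the
#' Mann-Whitney midrank formulation (exact under ties).
#'
#' @param ps a [prediction_set()].
#' @param activity_threshold pIC50 cut separating actives from inactives.
#' @return AUC in \[0, 1\].
#' @export
classification_auc <- function(ps, activity_threshold = 6.0) {
  stopifnot(inherits(ps, "prediction_set"))
  label <- ps$observed >= activity_threshold
  if (all(label) || !any(label)) {
    .err("AUC undefined: only one class present at threshold %g",
         activity_threshold)
  }
  auc_midrank(ps$predicted, label)
}
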