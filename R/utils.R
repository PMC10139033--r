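# Internal helpers shared across modules.

#' Mann-Whitney (midrank) area under the ROC curve
#'
#' AUC of `score` as a ranking statistic for the binary `label`, computed via
#' midranks so ties contribute 1/2 per tied pair. Larger scores are assumed
#' better; negate the score for a lower-is-better convention.
#'
#' @param score numeric vector of ranking scores.
#' @param label logical (or 0/1) vector; `TRUE` marks the positive class.
#' @return AUC in \[0, 1\].
#' @keywords internal
#' @noRd
auc_midrank <- function(score, label) {
  label <- as.logical(label)
  if (anyNA(score) || anyNA(label)) stop("scores and labels must not contain NA")
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# sum(x^2) guarding against length-0
.ss <- function(x) sum(x * x)

# stop() with sprintf formatting, call suppressed
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# validate a count argument
.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    .err("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}
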