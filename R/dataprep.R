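# Dataset curation, pIC50 conversion, train/test splitting, fold assignment
# and correlation-based feature selection (CFS with best-first search).

#' Binary fingerprint dataset
#'
#' The modelling substrate: a compounds x bits binary matrix paired with a
#' pIC50 activity vector.
#'
#' @param ids character compound identifiers.
#' @param bits numeric matrix over \{0, 1\}, one row per compound.
#' @param activity numeric pIC50 vector.
#' @param fingerprint_name label for the fingerprint type.
#' @param metadata free-form list (e.g. planted-bit provenance).
#' @return An object of class `fingerprint_dataset`.
#' @export
fingerprint_dataset <- function(ids, bits, activity,
                                fingerprint_name = "fingerprint",
                                metadata = list()) {
  bits <- as.matrix(bits)
  if (nrow(bits) != length(ids) || nrow(bits) != length(activity)) {
    .err("ids, bits rows and activity must agree in length")
  }
  if (!all(bits %in% c(0, 1))) .err("bits must be a 0/1 matrix")
  if (is.null(colnames(bits))) {
    colnames(bits) <- sprintf("bit_%04d", seq_len(ncol(bits)))
  }
  structure(list(
    ids = as.character(ids), bits = bits, activity = as.numeric(activity),
    fingerprint_name = fingerprint_name, metadata = metadata
  ), class = "fingerprint_dataset")
}

#' @export
print.fingerprint_dataset <- function(x, ...) {
  cat(sprintf("fingerprint_dataset: %d compounds x %d bits (%s)\n",
              nrow(x$bits), ncol(x$bits), x$fingerprint_name))
  cat(sprintf("  pIC50 range: %.3f .. %.3f\n",
              min(x$activity), max(x$activity)))
  invisible(x)
}

#' Subset a fingerprint dataset by row
#'
#' @param ds a [fingerprint_dataset()].
#' @param rows integer row indices to keep.
#' @param cols optional column indices to keep.
#' @return A `fingerprint_dataset` on the selected rows/columns.
#' @export
subset_dataset <- function(ds, rows, cols = NULL) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  if (is.null(cols)) cols <- seq_len(ncol(ds$bits))
  fingerprint_dataset(ds$ids[rows], ds$bits[rows, cols, drop = FALSE],
                      ds$activity[rows], ds$fingerprint_name, ds$metadata)
}

#' Convert IC50 to pIC50
#'
#' `pIC50 = -log10(IC50 in mol/L)`; for nanomolar input this is
#' `9 - log10(value)`.
#'
#' @param ic50 positive IC50 value(s).
#' @param unit unit of `ic50`: `"nM"`, `"uM"` or `"M"`.
#' @return pIC50 value(s).
#' @examples
#' to_pic50(1000, "nM")   # 6
#' to_pic50(40000, "nM")  # 4.398 at 3 d.p.
#' @export
to_pic50 <- function(ic50, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    .err("IC50 must be finite and positive")
  }
  offset <- c(nM = 9, uM = 6, M = 0)[[unit]]
  offset - log10(ic50)
}

#' Curate raw activity records into a per-compound table
#'
#' Collapses exact (`eq`) duplicate measurements per compound to their
#' median (even counts: mean of the two central values). Qualified records
#' (`gt`/`lt`) are retained only when the inequality unambiguously places
#' the compound on one side of the 1000 nM activity-class boundary — `gt`
#' with a bound of at least 1000 nM, or `lt` with a bound of at most
#' 1000 nM — and then contribute their bound as the working IC50; otherwise
#' they are dropped. Records with non-positive or non-finite values are
#' rejected with a logged reason.
#'
#' @param records data frame with columns `compound_id`, `ic50_value`
#'   (nM), `qualifier` (one of `"eq"`, `"gt"`, `"lt"`); a `source` column is
#'   carried through if present.
#' @param class_boundary_nM activity-class boundary, default 1000 nM.
#' @return A data frame with one row per surviving compound: `compound_id`,
#'   `ic50_nM`, `pic50`, `n_records`, `activity_class` (`"lt_boundary"` /
#'   `"ge_boundary"`) and `class_consistent`. Rejected and dropped records
#'   are attached as attributes `"rejected"` and `"dropped"`.
#' @export
curate_activities <- function(records, class_boundary_nM = 1000) {
  records <- as.data.frame(records)
  need <- c("compound_id", "ic50_value", "qualifier")
  if (!all(need %in% names(records))) {
    .err("records need columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(records) == 0L) .err("records must be non-empty")
  if (!all(records$qualifier %in% c("eq", "gt", "lt"))) {
    .err("qualifier must be one of eq, gt, lt")
  }

  bad <- !is.finite(records$ic50_value) | records$ic50_value <= 0
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "non-positive or non-finite IC50"
  records <- records[!bad, , drop = FALSE]

  keep_qualified <- records$qualifier == "eq" |
    (records$qualifier == "gt" & records$ic50_value >= class_boundary_nM) |
    (records$qualifier == "lt" & records$ic50_value <= class_boundary_nM)
  dropped <- records[!keep_qualified, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "qualifier does not pin activity class"
  records <- records[keep_qualified, , drop = FALSE]

  out <- lapply(split(records, records$compound_id), function(g) {
    eqv <- g$ic50_value[g$qualifier == "eq"]
    working <- if (length(eqv)) stats::median(eqv) else stats::median(g$ic50_value)
    # class implied by each surviving record
    cls <- ifelse(g$qualifier == "gt", "ge_boundary",
           ifelse(g$qualifier == "lt", "lt_boundary",
           ifelse(g$ic50_value < class_boundary_nM, "lt_boundary",
                  "ge_boundary")))
    data.frame(
      compound_id = g$compound_id[1],
      ic50_nM = working,
      pic50 = to_pic50(working, "nM"),
      n_records = nrow(g),
      activity_class = if (working < class_boundary_nM) "lt_boundary" else "ge_boundary",
      class_consistent = length(unique(cls)) == 1L,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rejected") <- rejected
  attr(res, "dropped") <- dropped
  res
}

#' Train/test split indices
#'
#' Uniform random split without replacement. The test size is
#' `ceiling(n * test_fraction)` (minimum 1): at n = 103 with a 10 percent
#' test fraction this yields the conventional 92/11 partition.
#'
#' @param ds a [fingerprint_dataset()] or a row count.
#' @param test_fraction fraction of rows assigned to the test set.
#' @param seed integer RNG seed.
#' @return A list of class `split_indices` with sorted integer vectors
#'   `train` and `test` plus the `seed`.
#' @export
split_dataset <- function(ds, test_fraction = 0.1, seed = 1L) {
  n <- if (inherits(ds, "fingerprint_dataset")) nrow(ds$bits) else
    .check_count(ds, "n", 1L)
  if (n < 2L) .err("need at least 2 rows to split")
  if (test_fraction <= 0 || test_fraction >= 1) {
    .err("test_fraction must lie strictly between 0 and 1")
  }
  n_test <- max(1L, as.integer(ceiling(n * test_fraction)))
  if (n_test >= n) .err("test fraction leaves no training rows")
  set.seed(seed)
  test <- sort(sample.int(n, n_test))
  structure(list(train = setdiff(seq_len(n), test), test = test,
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' Cross-validation fold assignment
#'
#' Assigns rows 1..n to k folds whose sizes differ by at most one, using a
#' seeded shuffle. `k = n` gives leave-one-out.
#'
#' @param n number of rows.
#' @param k number of folds (between 2 and n).
#' @param seed integer RNG seed.
#' @return Integer vector of length `n` with values in 1..k.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  n <- .check_count(n, "n", 2L)
  k <- .check_count(k, "k", 2L)
  if (k > n) .err("k must not exceed n")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# CFS merit M(S) = k * mean|r_cf| / sqrt(k + k (k-1) mean|r_ff|), from the
# incremental sums: s_cf = sum of |feature-activity r|, s_ff = sum over
# member pairs of |feature-feature r|.
.cfs_merit <- function(k, s_cf, s_ff) {
  if (k == 0L) return(-Inf)
  rcf <- s_cf / k
  rff <- if (k > 1L) s_ff / (k * (k - 1L) / 2) else 0
  unname(k * rcf / sqrt(k + k * (k - 1L) * rff))
}

#' Correlation-based feature selection with best-first search
#'
#' Scores feature subsets by the CFS merit
#' \deqn{M(S) = k \bar r_{cf} / \sqrt{k + k(k-1) \bar r_{ff}}}
#' where `k = |S|`, `r_cf` is the mean absolute Pearson correlation between
#' member bits and the activity (point-biserial for binary bits) and
#' `r_ff` the mean absolute pairwise correlation among member bits, and
#' searches subsets by best-first expansion from the empty set. Expansion
#' pops the best unexpanded subset and evaluates all single-feature
#' additions; the search terminates after `max_stale` consecutive
#' expansions that fail to improve the best merit found. Zero-variance
#' columns are excluded before the search.
#'
#' @param ds a [fingerprint_dataset()], or a list with elements `bits` and
#'   `activity`.
#' @param max_stale consecutive non-improving expansions tolerated before
#'   termination (default 5).
#' @param max_expansions hard cap on expansions (safety valve).
#' @return A list of class `feature_selection`: `selected_bits` (original
#'   column indices, sorted), `merit`, and `search_trace` (list of
#'   `list(subset, merit)` for each new incumbent).
#' @export
cfs_select <- function(ds, max_stale = 5L, max_expansions = 10000L) {
  x <- ds$bits
  y <- ds$activity
  if (ncol(x) < 2L) .err("need at least 2 columns for feature selection")
  if (stats::var(y) == 0) .err("activity has zero variance")
  variances <- apply(x, 2, stats::var)
  usable <- which(variances > 0)
  if (length(usable) == 0L) {
    warning("all columns have zero variance; empty selection")
    return(structure(list(selected_bits = integer(0), merit = NA_real_,
                          search_trace = list()),
                     class = "feature_selection"))
  }
  xs <- x[, usable, drop = FALSE]
  m <- ncol(xs)
  r_cf <- abs(as.numeric(stats::cor(xs, y)))

  # best-first over subsets; states keyed by sorted member string
  state_key <- function(S) {
    if (length(S) == 0L) "<empty>" else paste(S, collapse = ",")
  }
  open <- list(list(S = integer(0), merit = -Inf, s_cf = 0, s_ff = 0))
  open_merit <- -Inf
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(state_key(integer(0)), TRUE, envir = seen)
  best <- open[[1]]
  trace <- list()
  stale <- 0L
  expansions <- 0L

  while (length(open) > 0L && stale < max_stale &&
         expansions < max_expansions) {
    idx <- which.max(vapply(open, function(s) s$merit, numeric(1)))
    cur <- open[[idx]]
    open[[idx]] <- NULL
    expansions <- expansions + 1L

    cand <- setdiff(seq_len(m), cur$S)
    if (length(cand) == 0L) { stale <- stale + 1L; next }
    # correlations of current members with every column, for the pair sums
    add_ff <- if (length(cur$S) > 0L) {
      cc <- abs(stats::cor(xs[, cur$S, drop = FALSE], xs))
      colSums(cc)[cand]
    } else {
      rep(0, length(cand))
    }
    improved <- FALSE
    for (j in seq_along(cand)) {
      f <- cand[j]
      S2 <- sort(c(cur$S, f))
      key <- state_key(S2)
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      s_cf2 <- cur$s_cf + r_cf[f]
      s_ff2 <- cur$s_ff + add_ff[j]
      mer <- .cfs_merit(length(S2), s_cf2, s_ff2)
      st <- list(S = S2, merit = mer, s_cf = s_cf2, s_ff = s_ff2)
      open[[length(open) + 1L]] <- st
      if (mer > best$merit + 1e-12) {
        best <- st
        improved <- TRUE
        trace[[length(trace) + 1L]] <- list(subset = usable[S2], merit = mer)
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }

  structure(list(selected_bits = unname(usable[best$S]), merit = best$merit,
                 search_trace = trace),
            class = "feature_selection")
}

#' Exhaustive CFS optimum (oracle-scale inputs only)
#'
#' Enumerates all non-empty subsets of at most `max_features` columns and
#' returns the merit-maximising one. Exponential: intended as an
#' independent check of [cfs_select()] on small inputs.
#'
#' @inheritParams cfs_select
#' @param max_features refuse inputs wider than this (default 15).
#' @return A `feature_selection` as for [cfs_select()].
#' @export
cfs_exhaustive <- function(ds, max_features = 15L) {
  x <- ds$bits
  y <- ds$activity
  variances <- apply(x, 2, stats::var)
  usable <- which(variances > 0)
  xs <- x[, usable, drop = FALSE]
  m <- ncol(xs)
  if (m > max_features) .err("exhaustive search capped at %d features", max_features)
  r_cf <- abs(as.numeric(stats::cor(xs, y)))
  r_ff <- abs(stats::cor(xs))
  best_m <- -Inf
  best_S <- integer(0)
  for (mask in seq_len(2^m - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    k <- length(S)
    s_cf <- sum(r_cf[S])
    s_ff <- if (k > 1L) sum(r_ff[S, S][upper.tri(diag(k))]) else 0
    mer <- .cfs_merit(k, s_cf, s_ff)
    if (mer > best_m) { best_m <- mer; best_S <- S }
  }
  structure(list(selected_bits = unname(usable[best_S]), merit = best_m,
                 search_trace = list()),
            class = "feature_selection")
}

#' Write a fingerprint dataset to CSV (+ JSON metadata sidecar)
#'
#' @param ds a [fingerprint_dataset()].
#' @param path output CSV path (columns: id, bit_0001.., pIC50).
#' @param meta_path optional JSON path for the metadata list.
#' @return `path`, invisibly.
#' @export
write_fingerprint_csv <- function(ds, path, meta_path = NULL) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  df <- data.frame(id = ds$ids, ds$bits, pIC50 = ds$activity,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(ds$metadata, meta_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a fingerprint dataset from CSV
#'
#' @param path CSV written by [write_fingerprint_csv()].
#' @param fingerprint_name label for the loaded fingerprint.
#' @return A [fingerprint_dataset()].
#' @export
read_fingerprint_csv <- function(path, fingerprint_name = "fingerprint") {
  df <- utils::read.csv(path, check.names = FALSE)
  bit_cols <- setdiff(names(df), c("id", "pIC50"))
  fingerprint_dataset(df$id, as.matrix(df[, bit_cols, drop = FALSE]),
                      df$pIC50, fingerprint_name)
}
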