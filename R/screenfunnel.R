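# Screening-funnel analytics: ROC/enrichment validation of scoring
# protocols, Z-normalised consensus ranking, benchmark thresholding, hit
# intersection, and cognate-pose RMSD.

#' Per-compound score table across scoring protocols
#'
#' @param compound_ids character identifiers, one per row.
#' @param scores numeric matrix, one column per protocol; column names are
#'   the protocol names.
#' @param directions named character vector over the protocols, each
#'   `"lower_better"` (docking-energy convention) or `"higher_better"`.
#' @param labels optional logical active flags.
#' @return An object of class `score_table`.
#' @export
score_table <- function(compound_ids, scores, directions, labels = NULL) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) .err("scores must have protocol column names")
  if (length(compound_ids) != nrow(scores)) {
    .err("compound_ids must match score rows")
  }
  prot <- colnames(scores)
  if (!all(prot %in% names(directions))) {
    .err("directions must cover every protocol")
  }
  if (!all(directions %in% c("lower_better", "higher_better"))) {
    .err("directions must be lower_better or higher_better")
  }
  if (!is.null(labels) && length(labels) != nrow(scores)) {
    .err("labels must match score rows")
  }
  structure(list(
    compound_ids = as.character(compound_ids), scores = scores,
    protocol_names = prot, directions = directions[prot],
    labels = if (is.null(labels)) NULL else as.logical(labels)
  ), class = "score_table")
}

# oriented scores: larger = better, regardless of protocol convention
.oriented <- function(table, protocol) {
  if (!protocol %in% table$protocol_names) {
    .err("unknown protocol '%s'", protocol)
  }
  s <- table$scores[, protocol]
  if (table$directions[[protocol]] == "lower_better") -s else s
}

#' ROC AUC of a scoring protocol against activity labels
#'
#' Midrank (Mann-Whitney) AUC of the protocol's scores for the active
#' class, with lower-is-better protocols negated before ranking.
#'
#' @param table a [score_table()] with labels.
#' @param protocol protocol name.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(table, protocol) {
  stopifnot(inherits(table, "score_table"))
  if (is.null(table$labels)) .err("score table has no activity labels")
  auc_midrank(.oriented(table, protocol), table$labels)
}

#' Enrichment factor at a ranked-list fraction
#'
#' `EF = (actives among top ceiling(fraction * N)) / ceiling(fraction * N)`
#' divided by the overall active rate. Ranking honours the protocol's
#' direction; ties are broken lexicographically by compound id for
#' determinism.
#'
#' @param table a [score_table()] with labels.
#' @param protocol protocol name.
#' @param fraction top fraction of the ranked list (default 0.05).
#' @return The enrichment factor.
#' @export
enrichment_factor <- function(table, protocol, fraction = 0.05) {
  stopifnot(inherits(table, "score_table"))
  if (is.null(table$labels)) .err("score table has no activity labels")
  if (fraction <= 0 || fraction > 1) .err("fraction must be in (0, 1]")
  n <- nrow(table$scores)
  n_act <- sum(table$labels)
  if (n_act == 0L) .err("enrichment undefined: no actives")
  n_top <- as.integer(ceiling(fraction * n))
  ord <- order(-.oriented(table, protocol), table$compound_ids)
  hits <- sum(table$labels[ord[seq_len(n_top)]])
  (hits / n_top) / (n_act / n)
}

#' Z-normalised consensus ranking over several protocols
#'
#' Each protocol's scores are standardised over the screened set; z-scores
#' of lower-is-better protocols are negated so larger always means better;
#' the consensus score is the sum of oriented z-scores and compounds are
#' ranked descending (ties broken by compound id).
#'
#' @param table a [score_table()].
#' @param protocols character vector of at least two protocol names.
#' @return An object of class `ranked_list`: `compound_ids` in rank order,
#'   `ranking_score` (consensus, descending), and `protocols` provenance.
#' @export
znorm_consensus <- function(table, protocols = table$protocol_names) {
  stopifnot(inherits(table, "score_table"))
  if (length(protocols) < 2L) .err("consensus needs at least 2 protocols")
  z <- sapply(protocols, function(p) {
    s <- .oriented(table, p)
    sdv <- stats::sd(s)
    if (!is.finite(sdv) || sdv == 0) {
      .err("protocol '%s' has zero score variance", p)
    }
    (s - mean(s)) / sdv
  })
  consensus <- rowSums(z)
  ord <- order(-consensus, table$compound_ids)
  structure(list(
    compound_ids = table$compound_ids[ord],
    ranking_score = consensus[ord],
    protocols = protocols
  ), class = "ranked_list")
}

#' Rank a single protocol into a ranked list
#'
#' @param table a [score_table()].
#' @param protocol protocol name.
#' @return A `ranked_list` ordered best-first under the protocol's
#'   direction (ties broken by compound id).
#' @export
rank_protocol <- function(table, protocol) {
  s <- .oriented(table, protocol)
  ord <- order(-s, table$compound_ids)
  structure(list(compound_ids = table$compound_ids[ord],
                 ranking_score = s[ord], protocols = protocol),
            class = "ranked_list")
}

#' Keep the top n compounds of a ranked list
#'
#' @param ranked a `ranked_list`.
#' @param n number of compounds to keep (e.g. the conventional top 500).
#' @return A `ranked_list` truncated to the first `n` entries.
#' @export
top_n_hits <- function(ranked, n = 500L) {
  stopifnot(inherits(ranked, "ranked_list"))
  n <- min(.check_count(n, "n"), length(ranked$compound_ids))
  structure(list(compound_ids = ranked$compound_ids[seq_len(n)],
                 ranking_score = ranked$ranking_score[seq_len(n)],
                 protocols = ranked$protocols),
            class = "ranked_list")
}

#' Benchmark-threshold selection
#'
#' Keeps compounds whose score is equal to or better than `benchmark` under
#' the protocol's direction: for a lower-is-better protocol (docking
#' energies) this keeps scores at or below the benchmark, e.g. at or more
#' negative than a reference inhibitor's -9.0 kcal/mol.
#'
#' @param table a [score_table()].
#' @param protocol protocol name.
#' @param benchmark threshold score in the protocol's units.
#' @return Character vector of surviving compound ids.
#' @export
apply_score_threshold <- function(table, protocol, benchmark) {
  stopifnot(inherits(table, "score_table"))
  s <- table$scores[, protocol]
  keep <- if (table$directions[[protocol]] == "lower_better") {
    s <= benchmark
  } else {
    s >= benchmark
  }
  table$compound_ids[keep]
}

#' Intersect hit lists
#'
#' Set intersection of the member ids of two or more ranked lists (or plain
#' id vectors), with all pairwise intersection sizes for Venn-style
#' reporting.
#'
#' @param lists list (length >= 2) of `ranked_list`s or character vectors.
#' @return A list: `ids` (the total intersection, sorted), `sizes` (per
#'   input), `pairwise` (data frame of pairwise intersection sizes) and
#'   `n_total` (total intersection size).
#' @export
intersect_hits <- function(lists) {
  if (length(lists) < 2L) .err("need at least 2 hit lists")
  idsets <- lapply(lists, function(l) {
    if (inherits(l, "ranked_list")) unique(l$compound_ids) else
      unique(as.character(l))
  })
  nm <- names(idsets)
  if (is.null(nm)) nm <- paste0("list", seq_along(idsets))
  total <- Reduce(intersect, idsets)
  pairs <- utils::combn(seq_along(idsets), 2)
  pairwise <- data.frame(
    a = nm[pairs[1, ]], b = nm[pairs[2, ]],
    n = apply(pairs, 2, function(p) {
      length(intersect(idsets[[p[1]]], idsets[[p[2]]]))
    }),
    stringsAsFactors = FALSE
  )
  list(ids = sort(total),
       sizes = stats::setNames(lengths(idsets), nm),
       pairwise = pairwise,
       n_total = length(total))
}

#' Cognate-pose RMSD (no superposition)
#'
#' Root-mean-square deviation over corresponding atoms of two poses sharing
#' the receptor frame, the cognate-docking convention: no fitting is
#' applied, so a rigid displacement contributes in full. A pass flag at a
#' configurable threshold (default 2 A) scores pose-reproduction quality.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom).
#' @param correspondence optional two-column index matrix mapping rows of
#'   `coords_a` to rows of `coords_b`; default is row-by-row identity.
#' @param threshold pass threshold in Angstrom.
#' @return A list: `rmsd` (A) and `pass` (logical).
#' @export
pose_rmsd <- function(coords_a, coords_b, correspondence = NULL,
                      threshold = 2.0) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (is.null(correspondence)) {
    if (nrow(coords_a) != nrow(coords_b)) {
      .err("poses differ in atom count; provide a correspondence")
    }
    correspondence <- cbind(seq_len(nrow(coords_a)), seq_len(nrow(coords_a)))
  }
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) == 0L) .err("empty atom correspondence")
  if (anyDuplicated(correspondence[, 1]) || anyDuplicated(correspondence[, 2])) {
    .err("correspondence must be a bijection over compared atoms")
  }
  d <- coords_a[correspondence[, 1], , drop = FALSE] -
       coords_b[correspondence[, 2], , drop = FALSE]
  rmsd <- sqrt(mean(rowSums(d * d)))
  list(rmsd = rmsd, pass = rmsd < threshold)
}
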