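# Rule-based negative design: substructure alerts, physicochemical
# property windows, and annotation-driven exclusions (promiscuity scores,
# aggregator flags). Verdicts are per-compound and order-invariant.

#' Construct a negative-design filter rule
#'
#' Four rule kinds are supported:
#' * `substructure_alert` — fail when the compound's structure matches a
#'   SMARTS pattern (`payload = list(smarts=)`); requires a parsable
#'   structure, otherwise the rule is not evaluable for that compound.
#' * `property_window` — fail when a numeric annotation falls outside
#'   `[min, max]` (`payload = list(property=, min=, max=)`).
#' * `annotation_threshold` — fail when a numeric annotation satisfies the
#'   comparator against a threshold (`payload = list(key=, threshold=,
#'   comparator=)`), e.g. a promiscuity score of at least 300.
#' * `annotation_flag` — fail when a logical annotation is `TRUE`
#'   (`payload = list(key=)`), e.g. a predicted-aggregator flag.
#'
#' @param name rule name (used in verdict columns).
#' @param kind one of the four kinds above.
#' @param ... payload fields for the kind.
#' @return An object of class `filter_rule`.
#' @export
filter_rule <- function(name, kind = c("substructure_alert",
                                       "property_window",
                                       "annotation_threshold",
                                       "annotation_flag"), ...) {
  kind <- match.arg(kind)
  payload <- list(...)
  ok <- switch(kind,
    substructure_alert = !is.null(payload$smarts),
    property_window = all(c("property", "min", "max") %in% names(payload)),
    annotation_threshold = all(c("key", "threshold", "comparator") %in%
                                 names(payload)),
    annotation_flag = !is.null(payload$key)
  )
  if (!ok) .err("malformed payload for %s rule '%s'", kind, name)
  if (kind == "annotation_threshold" &&
      !payload$comparator %in% c(">=", ">", "<=", "<", "==")) {
    .err("comparator must be one of >=, >, <=, <, ==")
  }
  structure(list(name = name, kind = kind, payload = payload),
            class = "filter_rule")
}

# SMARTS matcher backed by OpenBabel (optional dependency); returns a
# logical per SMILES, NA where the structure cannot be handled
.match_smarts_ob <- function(smiles, smarts) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    return(rep(NA, length(smiles)))
  }
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA)
    res <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      ChemmineOB::smartsSearch_OB(mol, smarts, uniqueMatches = TRUE) > 0
    }, error = function(e) NA)
    if (length(res) != 1L) NA else res
  }, logical(1), USE.NAMES = FALSE)
}

# evaluate one rule over the compound table -> "pass"/"fail"/"not_evaluable"
.eval_rule <- function(rule, compounds, smarts_matcher) {
  n <- nrow(compounds)
  p <- rule$payload
  out <- switch(rule$kind,
    substructure_alert = {
      if (!"smiles" %in% names(compounds)) {
        rep(NA, n)
      } else {
        smarts_matcher(compounds$smiles, p$smarts)
      }
    },
    property_window = {
      v <- compounds[[p$property]]
      if (is.null(v)) rep(NA, n) else (v < p$min | v > p$max)
    },
    annotation_threshold = {
      v <- compounds[[p$key]]
      if (is.null(v)) rep(NA, n) else switch(p$comparator,
        ">=" = v >= p$threshold, ">" = v > p$threshold,
        "<=" = v <= p$threshold, "<" = v < p$threshold,
        "==" = v == p$threshold)
    },
    annotation_flag = {
      v <- compounds[[p$key]]
      if (is.null(v)) rep(NA, n) else as.logical(v)
    }
  )
  ifelse(is.na(out), "not_evaluable", ifelse(out, "fail", "pass"))
}

#' Apply negative-design filter rules to a compound panel
#'
#' Every compound receives a verdict for every rule; the overall verdict is
#' a pass exactly when no rule fails. Rules that cannot be evaluated for a
#' compound (missing annotation, unparsable or absent structure) are marked
#' `not_evaluable` and do not fail the compound unless `strict = TRUE`.
#' Compounds are never silently dropped.
#'
#' @param compounds data frame keyed by `compound_id`, optionally with a
#'   `smiles` column and any annotation columns the rules reference.
#' @param rules list of [filter_rule()]s; default [default_ruleset()].
#' @param strict when `TRUE`, `not_evaluable` counts as a failure.
#' @param smarts_matcher function `(smiles, smarts) -> logical` used for
#'   substructure rules; the default uses OpenBabel via ChemmineOB when
#'   installed and reports `not_evaluable` otherwise.
#' @return A list of class `filter_result`:
#'   `verdicts` (data frame: `compound_id`, one outcome column per rule,
#'   `overall`, `reasons`), `rule_counts` (failures per rule, for
#'   Venn-style reporting), and `survivors` (ids with overall pass).
#' @export
apply_filters <- function(compounds, rules = default_ruleset(),
                          strict = FALSE,
                          smarts_matcher = .match_smarts_ob) {
  compounds <- as.data.frame(compounds)
  if (!"compound_id" %in% names(compounds)) {
    .err("compounds need a compound_id column")
  }
  if (length(rules) == 0L) .err("no rules supplied")
  nm <- vapply(rules, function(r) r$name, character(1))
  if (anyDuplicated(nm)) .err("rule names must be unique")

  outcomes <- sapply(rules, .eval_rule, compounds = compounds,
                     smarts_matcher = smarts_matcher)
  outcomes <- matrix(outcomes, nrow = nrow(compounds),
                     dimnames = list(NULL, nm))
  failed <- outcomes == "fail" |
    (strict & outcomes == "not_evaluable")
  overall <- rowSums(failed) == 0L
  reasons <- apply(failed, 1, function(f) paste(nm[f], collapse = ";"))

  verdicts <- data.frame(compound_id = compounds$compound_id,
                         outcomes, overall = overall,
                         reasons = reasons,
                         stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(
    verdicts = verdicts,
    rule_counts = colSums(outcomes == "fail"),
    survivors = compounds$compound_id[overall]
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result: %d compounds, %d survive\n",
              nrow(x$verdicts), length(x$survivors)))
  cat("failures per rule:\n")
  print(x$rule_counts)
  invisible(x)
}

#' Default negative-design ruleset
#'
#' Substructure alerts from a compact curated subset of the published
#' pan-assay interference (PAINS) families A/B/C shipped with the package
#' (see `system.file("extdata", "pains_subset.tsv", package =
#' "funnelscreen")`; a full catalogue can be loaded the same way), a
#' standard drug-likeness property window set (molecular weight, cLogP,
#' hydrogen-bond donors/acceptors, rotatable bonds, read from annotation
#' columns `MW`, `cLogP`, `HBD`, `HBA`, `RotB`), a promiscuity-score
#' threshold (`pScore >= 300` fails) and a predicted-aggregator flag.
#'
#' @param pains whether to include the substructure alerts.
#' @param property_windows whether to include the drug-likeness windows.
#' @return A list of [filter_rule()]s.
#' @export
default_ruleset <- function(pains = TRUE, property_windows = TRUE) {
  rules <- list()
  if (pains) rules <- c(rules, pains_rules())
  if (property_windows) {
    rules <- c(rules, list(
      filter_rule("mw_window", "property_window",
                  property = "MW", min = 100, max = 600),
      filter_rule("clogp_window", "property_window",
                  property = "cLogP", min = -3, max = 6),
      filter_rule("hbd_window", "property_window",
                  property = "HBD", min = 0, max = 5),
      filter_rule("hba_window", "property_window",
                  property = "HBA", min = 0, max = 10),
      filter_rule("rotb_window", "property_window",
                  property = "RotB", min = 0, max = 10)
    ))
  }
  c(rules, list(
    filter_rule("promiscuity", "annotation_threshold",
                key = "pScore", threshold = 300, comparator = ">="),
    filter_rule("aggregator", "annotation_flag", key = "aggregator")
  ))
}

#' PAINS-family substructure alert rules
#'
#' Reads the shipped alert table (tab-separated: `name`, `smarts`,
#' `family`) and wraps each pattern as a `substructure_alert` rule.
#'
#' @param path alert table; defaults to the packaged subset.
#' @return A list of [filter_rule()]s.
#' @export
pains_rules <- function(path = system.file("extdata", "pains_subset.tsv",
                                           package = "funnelscreen")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    filter_rule(paste0("pains_", tab$name[i]), "substructure_alert",
                smarts = tab$smarts[i], family = tab$family[i])
  })
}

#' Read a filter ruleset from YAML
#'
#' The YAML file is a list of entries with fields `name`, `kind` and the
#' payload fields of [filter_rule()].
#'
#' @param path YAML file.
#' @return A list of [filter_rule()]s.
#' @export
read_ruleset <- function(path) {
  spec <- yaml::read_yaml(path)
  lapply(spec, function(e) {
    do.call(filter_rule, c(list(name = e$name, kind = e$kind),
                           e[setdiff(names(e), c("name", "kind"))]))
  })
}
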