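#!/usr/bin/env Rscript
# Stage 4 — negative design on the shared-hit panel.
#
# Annotates a 70-compound hit panel with planted exclusion classes (2
# interference-motif hits, 11 predicted aggregators, 44 promiscuous
# scaffolds at pScore >= 300, overlaps allowed) and applies the rule
# engine; survivors and per-rule failure counts are reported for
# Venn-style accounting.

suppressMessages(library(funnelscreen))
seed <- 20260101L

set.seed(seed + 7L)
ids <- sprintf("HIT%02d", 1:70)
panel <- data.frame(
  compound_id = ids,
  pains_flag = ids %in% sample(ids, 2),
  aggregator = ids %in% sample(ids, 11),
  pScore = ifelse(ids %in% sample(ids, 44), 400, 50))

rules <- list(
  filter_rule("pains", "annotation_flag", key = "pains_flag"),
  filter_rule("aggregator", "annotation_flag", key = "aggregator"),
  filter_rule("promiscuity", "annotation_threshold",
              key = "pScore", threshold = 300, comparator = ">="))
res <- apply_filters(panel, rules = rules)
print(res)
cat(sprintf("%d of %d compounds survive negative design\n",
            length(res$survivors), nrow(panel)))

write.csv(res$verdicts, "results/filter_verdicts.csv", row.names = FALSE)
jsonlite::write_json(list(n_in = nrow(panel),
                          n_survive = length(res$survivors),
                          rule_counts = as.list(res$rule_counts),
                          survivors = res$survivors),
                     "results/negative_design.json", auto_unbox = TRUE)
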