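mk_table <- function(scores, directions, labels = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("C%04d", seq_len(nrow(as.matrix(scores))))
  score_table(ids, scores, directions, labels)
}

test_that("ROC AUC honours separation, direction and chance level", {
  # perfectly separated classes
  tab <- mk_table(cbind(dock = c(-10, -9.5, -9, -5, -4, -3)),
                  c(dock = "lower_better"),
                  labels = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(roc_auc(tab, "dock"), 1)

  # flipping the direction complements the AUC (no ties)
  tab2 <- mk_table(tab$scores, c(dock = "higher_better"), tab$labels)
  expect_equal(roc_auc(tab, "dock") + roc_auc(tab2, "dock"), 1)

  # labels independent of scores: chance level at large n
  set.seed(4)
  tab3 <- mk_table(cbind(s = rnorm(2000)), c(s = "higher_better"),
                   labels = sample(c(TRUE, FALSE), 2000, replace = TRUE))
  a <- roc_auc(tab3, "s")
  expect_gt(a, 0.47); expect_lt(a, 0.53)

  expect_error(roc_auc(mk_table(cbind(s = 1:3), c(s = "higher_better")), "s"),
               "labels")
})

test_that("AUC matches the two-Gaussian closed form", {
  st <- gen_score_set(score_sim_spec(2000, 2000, mean_active = -9,
                                     mean_inactive = -7.8,
                                     sd_active = 1.2, sd_inactive = 0.8,
                                     seed = 12))
  expected <- pnorm(1.2 / sqrt(1.2^2 + 0.8^2))
  expect_lt(abs(roc_auc(st, "sim") - expected), 0.02)
})

test_that("enrichment factor reproduces hand-computable rankings", {
  # 10 actives ranked first out of 100, top 5%: EF = 1 / 0.1 = 10
  lab <- c(rep(TRUE, 10), rep(FALSE, 90))
  tab <- mk_table(cbind(s = seq(100, 1)), c(s = "higher_better"), lab)
  expect_equal(enrichment_factor(tab, "s", 0.05), 10)
  # whole list: EF = 1 exactly, any ranking
  expect_equal(enrichment_factor(tab, "s", 1), 1)
  set.seed(1)
  tab2 <- mk_table(cbind(s = rnorm(100)), c(s = "higher_better"),
                   sample(lab))
  expect_equal(enrichment_factor(tab2, "s", 1), 1)
  # EF is bounded by 1/fraction and N/n_actives
  for (fr in c(0.05, 0.2, 0.5)) {
    ef <- enrichment_factor(tab2, "s", fr)
    expect_lte(ef, min(1 / fr, 100 / 10) + 1e-12)
  }
  expect_error(enrichment_factor(mk_table(cbind(s = 1:4),
                                          c(s = "higher_better"),
                                          rep(FALSE, 4)), "s"),
               "no actives")
})

test_that("random rankings average to EF near one", {
  lab <- c(rep(TRUE, 10), rep(FALSE, 90))
  efs <- vapply(1:300, function(i) {
    set.seed(i)
    tab <- mk_table(cbind(s = rnorm(100)), c(s = "higher_better"), lab)
    enrichment_factor(tab, "s", 0.05)
  }, numeric(1))
  expect_gt(mean(efs), 0.85)
  expect_lt(mean(efs), 1.15)
})

test_that("consensus of identical protocols equals the single ranking", {
  set.seed(2)
  s <- rnorm(40)
  tab <- mk_table(cbind(a = s, b = s), c(a = "higher_better",
                                         b = "higher_better"))
  cons <- znorm_consensus(tab)
  single <- rank_protocol(tab, "a")
  expect_equal(cons$compound_ids, single$compound_ids)
})

test_that("consensus ranking matches a hand-computed 6x3 example", {
  ids <- c("m1", "m2", "m3", "m4", "m5", "m6")
  sc <- cbind(asp = c(50, 60, 55, 40, 70, 45),
              chemplp = c(80, 75, 90, 60, 85, 65),
              goldscore = c(30, 45, 40, 25, 50, 35))
  tab <- score_table(ids, sc, c(asp = "higher_better",
                                chemplp = "higher_better",
                                goldscore = "higher_better"))
  # independent longhand z-scores
  z <- apply(sc, 2, function(v) (v - mean(v)) / sd(v))
  expected_order <- ids[order(-rowSums(z), ids)]
  cons <- znorm_consensus(tab)
  expect_equal(cons$compound_ids, expected_order)
  expect_equal(sort(cons$ranking_score, decreasing = TRUE),
               sort(rowSums(z), decreasing = TRUE), tolerance = 1e-12)
})

test_that("consensus is invariant to positive affine rescaling of one protocol", {
  set.seed(3)
  sc <- cbind(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  dirs <- c(a = "higher_better", b = "lower_better", c = "higher_better")
  tab <- mk_table(sc, dirs)
  base <- znorm_consensus(tab)
  for (i in 1:20) {
    slope <- runif(1, 0.1, 5)
    shift <- rnorm(1, 0, 10)
    sc2 <- sc
    sc2[, "b"] <- slope * sc[, "b"] + shift
    tab2 <- mk_table(sc2, dirs)
    expect_equal(znorm_consensus(tab2)$compound_ids, base$compound_ids)
  }
})

test_that("consensus refuses zero-variance protocols and tiny subsets", {
  tab <- mk_table(cbind(a = rep(1, 5), b = rnorm(5)),
                  c(a = "higher_better", b = "higher_better"))
  expect_error(znorm_consensus(tab), "'a'")
  expect_error(znorm_consensus(tab, "b"), "at least 2")
})

test_that("benchmark thresholding keeps equal-or-better scores", {
  tab <- mk_table(cbind(dock = c(-9.5, -9.0, -8.2)),
                  c(dock = "lower_better"), ids = c("x", "y", "z"))
  expect_equal(apply_score_threshold(tab, "dock", -9.0), c("x", "y"))
  expect_length(apply_score_threshold(tab, "dock", -Inf), 0)
  expect_equal(apply_score_threshold(tab, "dock", Inf), c("x", "y", "z"))
  # higher-is-better flips the comparison
  tab2 <- mk_table(cbind(s = c(1, 2, 3)), c(s = "higher_better"),
                   ids = c("x", "y", "z"))
  expect_equal(apply_score_threshold(tab2, "s", 2), c("y", "z"))
})

test_that("hit intersection obeys set semantics and reports sizes", {
  out <- intersect_hits(list(d = c("A", "B", "C", "D"), l = c("C", "D", "E")))
  expect_equal(out$ids, c("C", "D"))
  expect_equal(out$n_total, 2)
  expect_equal(unname(out$sizes), c(4, 3))
  expect_equal(out$pairwise$n, 2)
  # identical and disjoint lists
  expect_equal(intersect_hits(list(1:3, 1:3))$n_total, 3)
  expect_equal(intersect_hits(list(c("a"), c("b")))$n_total, 0)
  # ranked lists are accepted directly
  tab <- mk_table(cbind(s = c(3, 2, 1)), c(s = "higher_better"),
                  ids = c("x", "y", "z"))
  r <- top_n_hits(rank_protocol(tab, "s"), 2)
  expect_equal(r$compound_ids, c("x", "y"))
  expect_equal(intersect_hits(list(r, c("y", "z")))$ids, "y")
})

test_that("cognate-pose RMSD follows the no-superposition convention", {
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(pose_rmsd(a, a)$rmsd, 0)
  # rigid translation contributes in full
  b <- sweep(a, 2, c(3, 0, 0), "+")
  out <- pose_rmsd(a, b)
  expect_equal(out$rmsd, 3)
  expect_false(out$pass)
  # hand arithmetic: displacements of 1 and 2 Angstrom
  p <- matrix(0, 2, 3)
  q <- rbind(c(1, 0, 0), c(0, 2, 0))
  expect_equal(pose_rmsd(p, q)$rmsd, sqrt((1 + 4) / 2))
  # symmetry
  expect_equal(pose_rmsd(p, q)$rmsd, pose_rmsd(q, p)$rmsd)
  expect_error(pose_rmsd(a, b, correspondence = matrix(nrow = 0, ncol = 2)),
               "empty")
})
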