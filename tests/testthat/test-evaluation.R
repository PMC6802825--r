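test_that("ranking is by descending score with lexicographic ties", {
  expect_equal(rank_and_select(c(0.2, 0.9, 0.5), c("a", "b", "c"), 1), "b")
  expect_equal(rank_and_select(rep(0.5, 4), c("d", "b", "a", "c"), 2),
               c("a", "b"))
  expect_equal(rank_and_select(c(0.3, 0.8, 0.8, 0.1),
                               c("z", "y", "x", "w"), 3),
               c("x", "y", "z"))
})

test_that("rank-statistic AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3)),
               1.0)
  # 6-point toy set, hand-checkable
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  l <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  pairs <- expand.grid(p = which(l), n = which(!l))
  brute <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                       ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(s, l), brute)
  # property: random instances with <= 50 models, including ties
  set.seed(19)
  for (k in 1:20) {
    n <- sample(6:50, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) next
    pairs <- expand.grid(p = which(l), n = which(!l))
    brute <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                         ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
    expect_equal(roc_auc(s, l), brute, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(23)
  s <- rnorm(60)
  l <- runif(60) < 0.5
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("tier reports tally targets by their top-ranked model", {
  counts <- data.frame(tier = c("high", "medium", "low", "failed"),
                       total = c(4, 3, 2, 2), top1 = c(3, 1, 0, 0),
                       top5 = c(4, 2, 1, 0), max_correct = c(4, 2, 1, 1))
  fx <- tier_fixture(counts)
  rep <- tier_report(fx$predictions, fx$labels)
  expect_equal(rep$table$total, counts$total)
  expect_equal(rep$table$top1, counts$top1)
  expect_equal(rep$table$top5, counts$top5)
  expect_equal(rep$table$max, counts$max_correct)
  expect_equal(rep$table$top1_precision[1], round(100 * 3 / 4, 1))
  expect_equal(rep$combined$top1, 4)
  expect_equal(rep$combined$total, 7)
  # count identities asserted internally
  expect_true(all(rep$table$top1 <= rep$table$top5))
  expect_true(all(rep$table$top5 <= rep$table$max))
  expect_true(all(rep$table$max <= rep$table$total))
  expect_equal(sum(rep$table$total), nrow(rep$targets))
})

test_that("an all-correct fixture reports 100 percent everywhere", {
  preds <- data.frame(target_id = rep(c("a", "b"), each = 2),
                      model_id = rep(c("m1", "m2"), 2),
                      score = c(0.9, 0.8, 0.7, 0.6))
  labs <- data.frame(target_id = preds$target_id,
                     model_id = preds$model_id, tm = 0.8)
  rep <- tier_report(preds, labs)
  expect_equal(rep$table$top1_precision[1], 100)
  expect_equal(rep$table$top5_precision[1], 100)
  expect_equal(rep$table$total, c(2, 0, 0, 0))
})

test_that("the per-target TP-FPR curve counts detections at each score", {
  tops <- tier_fixture(data.frame(tier = c("high", "failed"),
                                  total = c(3, 3), top1 = c(2, 0),
                                  top5 = c(2, 0), max_correct = c(3, 1)))
  curve <- tp_vs_fpr_curve(tops$predictions, tops$labels)
  expect_true(all(diff(curve$tp) >= 0))
  expect_true(all(diff(curve$fpr) >= 0))
  expect_equal(max(curve$tp), 2)
  expect_equal(max(curve$fpr), 1)
})

test_that("FPR thresholding picks the most permissive in-budget cutoff", {
  # perfectly separated scores admit FPR 0 with full recall
  s <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  l <- rep(c(FALSE, TRUE), each = 3)
  res <- fpr_threshold_baseline(s, l, 0.01)
  expect_equal(res$fpr, 0)
  expect_equal(res$tpr, 1)
  # overlapping classes at target 0: threshold sits above all negatives
  s2 <- c(0.1, 0.5, 0.4, 0.9)
  l2 <- c(FALSE, FALSE, TRUE, TRUE)
  res2 <- fpr_threshold_baseline(s2, l2, 0)
  expect_equal(res2$threshold, 0.5)
  expect_equal(res2$classification, c(FALSE, FALSE, FALSE, TRUE))
  # exhaustive scan oracle on a toy set
  set.seed(29)
  s3 <- round(runif(10), 2)
  l3 <- runif(10) < 0.5
  if (any(l3) && !all(l3)) {
    for (tgt in c(0.01, 0.1, 0.3)) {
      res3 <- fpr_threshold_baseline(s3, l3, tgt)
      cand <- sort(unique(s3))
      ok <- cand[vapply(cand, function(t) mean(s3[!l3] > t) <= tgt,
                        logical(1))]
      expect_equal(res3$threshold, min(ok))
    }
  }
})

test_that("the convergence baseline applies the strict 0.65 cutoff", {
  nat <- synth_native(30, seed = 44)
  copies <- lapply(1:10, function(i)
    structure_model(sprintf("c%02d", i), "t", nat$res_index,
                    nat$res_name, nat$xyz))
  out <- convergence_baseline(list(t1 = copies),
                              list(t1 = rep(1, 10)))
  expect_true(out$predicted_correct)
  expect_equal(out$mean_pairwise_tm, 1)
  # exactly at the cutoff is not "above"
  with_mocked_bindings(
    mean_pairwise_topk = function(...) 0.65,
    expect_false(convergence_baseline(list(t1 = copies),
                                      list(t1 = rep(1, 10)))$predicted_correct)
  )
})
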