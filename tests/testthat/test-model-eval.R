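test_that("balanced sampling keeps all positives and is deterministic", {
  labels <- c(rep("binding", 10), rep("nonbinding", 100))
  sel <- balanced_sample(labels, seed = 3)
  expect_length(sel, 20)
  expect_true(all(1:10 %in% sel))
  expect_equal(sum(labels[sel] == "nonbinding"), 10)
  expect_identical(sel, balanced_sample(labels, seed = 3))
  expect_false(identical(sel, balanced_sample(labels, seed = 4)))
  # degenerate: fewer negatives than positives
  few <- c(rep("binding", 10), rep("nonbinding", 6))
  expect_warning(sel2 <- balanced_sample(few, seed = 1), "using all")
  expect_length(sel2, 16)
  expect_error(balanced_sample(rep("nonbinding", 5)), "no binding")
})

test_that("SVM separates separable blobs and is deterministic", {
  set.seed(10)
  x <- rbind(matrix(rnorm(200, 3), ncol = 2),
             matrix(rnorm(200, -3), ncol = 2))
  y <- c(rep("binding", 100), rep("nonbinding", 100))
  m <- train_svm(x, y)
  pr <- predict_svm(m, x)
  expect_equal(pr$predicted, y)
  expect_true(all(pr$score[y == "binding"] > pr$score[y == "nonbinding"]))
  m2 <- train_svm(x, y)
  expect_equal(predict_svm(m2, x)$score, pr$score)
  expect_error(train_svm(x, rep("binding", 200)), "single class")
})

test_that("label-permuted data gives chance-level discrimination", {
  set.seed(11)
  x <- rbind(matrix(rnorm(400, 2), ncol = 2),
             matrix(rnorm(400, -2), ncol = 2))
  y <- sample(c(rep("binding", 200), rep("nonbinding", 200)))
  m <- train_svm(x, y)
  acc <- mean(predict_svm(m, x)$predicted == y)
  # in-sample fit can overfit above 0.5, but held-out AUC is near chance
  set.seed(12)
  xt <- rbind(matrix(rnorm(400, 2), ncol = 2),
              matrix(rnorm(400, -2), ncol = 2))
  yt <- sample(c(rep("binding", 200), rep("nonbinding", 200)))
  ra <- roc_auc(predict_svm(m, xt)$score, yt)
  expect_lt(abs(ra$auc - 0.5), 0.08)
})

test_that("prediction rejects a mismatched feature layout", {
  set.seed(13)
  x <- matrix(rnorm(80), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("binding", "nonbinding"), each = 10)
  m <- train_svm(x, y)
  x2 <- x
  colnames(x2) <- paste0("g", 1:4)
  expect_error(predict_svm(m, x2), "layout")
})

test_that("chain-level folds partition chains evenly and reproducibly", {
  ids <- paste0("c", 1:10)
  folds <- chain_kfold(ids, k = 5, seed = 2)
  expect_length(folds, 5)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 2))
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_union, sort(ids))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_identical(chain_kfold(ids, k = 5, seed = 2), folds)
  expect_error(chain_kfold(ids[1:3], k = 5), "cannot form")
})

test_that("confusion metrics match hand arithmetic and conventions", {
  m <- confusion_metrics(3, 1, 5, 1)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, (3 * 5 - 1 * 1) / sqrt(4 * 4 * 6 * 6))
  p <- confusion_metrics(10, 0, 10, 0)
  expect_equal(unlist(p[c("recall", "precision", "accuracy", "f1", "mcc")]),
               c(recall = 1, precision = 1, accuracy = 1, f1 = 1, mcc = 1),
               tolerance = 1e-12)
  z <- confusion_metrics(0, 0, 5, 5)
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
})

test_that("MCC equals the point correlation of indicator vectors", {
  set.seed(14)
  for (i in 1:200) {
    counts <- rmultinom(1, 60, prob = runif(4, 0.05, 1))[, 1]
    truth <- rep(c(1, 1, 0, 0), counts)
    pred <- rep(c(1, 0, 1, 0), counts)
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    m <- confusion_metrics(tp = counts[1], fn = counts[2],
                           fp = counts[3], tn = counts[4])
    expect_equal(m$mcc, suppressWarnings(cor(truth, pred)),
                 tolerance = 1e-12)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    expect_true(m$f1 >= 0 && m$f1 <= 1)
  }
})

test_that("ROC/AUC: perfect, chance, ties, invariance, U-statistic oracle", {
  lab <- c(rep("binding", 5), rep("nonbinding", 5))
  perfect <- roc_auc(c(9, 8, 7, 6, 5, 4, 3, 2, 1, 0), lab)
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[nrow(perfect$roc)], 1)

  set.seed(15)
  y <- sample(c("binding", "nonbinding"), 2000, replace = TRUE)
  s <- rnorm(2000)
  ra <- roc_auc(s, y)
  expect_lt(abs(ra$auc - 0.5), 0.05)
  # monotone transform invariance
  expect_equal(roc_auc(exp(s / 3), y)$auc, ra$auc, tolerance = 1e-12)
  # Mann-Whitney U equivalence
  u <- wilcox.test(s[y == "binding"], s[y == "nonbinding"])$statistic
  expect_equal(ra$auc, unname(u) / (sum(y == "binding") *
                                      sum(y == "nonbinding")),
               tolerance = 1e-9)
  # tied scores are grouped
  tied <- roc_auc(rep(1, 10), lab)
  expect_equal(tied$auc, 0.5)
  expect_error(roc_auc(1:5, rep("binding", 5)), "both classes")
})

test_that("F-score separates group means by their pooled spreads", {
  expect_equal(feature_fscore(c(1, 2, 3), c(1, 2, 3)), 0)
  # two-point groups realize any (mean, population SD) pair exactly
  f <- feature_fscore(c(0.27 - 0.92, 0.27 + 0.92),
                      c(-0.17 - 0.96, -0.17 + 0.96))
  expect_equal(f, abs(0.27 - (-0.17)) / (0.92 + 0.96))
  expect_equal(fscore_from_stats(0.5, 0, 0.5, 0), 0)
  expect_warning(inf <- fscore_from_stats(1, 0, 0, 0), "infinite")
  expect_equal(inf, Inf)
})

test_that("Welch t-test wrapper: null, power and symmetry", {
  a <- c(1, 2, 3, 4)
  t0 <- two_sample_ttest(a, a)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  set.seed(16)
  x <- rnorm(200)
  y <- rnorm(200, mean = 1)
  expect_lt(two_sample_ttest(x, y)$p_value, 1e-6)
  ab <- two_sample_ttest(x, y)
  ba <- two_sample_ttest(y, x)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$statistic, -ba$statistic)
})

test_that("signed-rank test: degenerate pairs, power, order invariance", {
  a <- rnorm(30)
  expect_error(wilcoxon_signed_rank(a, a), "zero")
  b <- a + 1
  expect_lt(wilcoxon_signed_rank(a, b)$p_value, 0.001)
  set.seed(17)
  perm <- sample(30)
  r1 <- wilcoxon_signed_rank(a, b)
  r2 <- wilcoxon_signed_rank(a[perm], b[perm])
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
})

test_that("characterization recovers the generated group structure", {
  ds <- make_labeled_dataset(n_chains = 10, effect_size = 1, seed = 21)
  feats <- as.data.frame(do.call(rbind, lapply(ds, `[[`, "features")))
  labels <- unlist(lapply(ds, `[[`, "labels"))
  types <- rep(rep(c("HIS", "CYS", "MET", "TYR"), length.out = 240), 10)
  ch <- characterize(feats, labels, res_types = types)
  # unit shift at unit SDs gives F close to 0.5 on every topology feature
  expect_equal(ch$stats$fscore, rep(0.5, 4), tolerance = 0.1)
  expect_true(all(ch$stats$p_value < 1e-10))
  # clustering shift is negative, others positive
  d <- ch$stats$mean_binding - ch$stats$mean_nonbinding
  expect_true(all(d[1:3] > 0) && d[4] < 0)
  # section fractions sum to one per feature and class
  sums <- ch$sections$high + ch$sections$medium + ch$sections$low
  expect_equal(sums, rep(1, nrow(ch$sections)))
  # per-type means exist for every present type
  expect_false(any(is.na(ch$type_means$z_degree)))
})

test_that("characterization flags residue types absent from a class as NA", {
  feats <- data.frame(z_degree = rnorm(40))
  labels <- rep(c("binding", "nonbinding"), each = 20)
  types <- c(rep("HIS", 20), rep("CYS", 20))  # HIS never non-binding
  ch <- characterize(feats, labels, res_types = types,
                     section_features = "z_degree")
  his_nb <- ch$type_means[ch$type_means$res_type == "HIS" &
                            ch$type_means$group == "nonbinding", ]
  expect_true(is.na(his_nb$z_degree))
  expect_equal(his_nb$n, 0)
})

test_that("characterize with a null effect yields near-zero F-scores", {
  ds <- make_labeled_dataset(n_chains = 10, effect_size = 0, seed = 22)
  feats <- as.data.frame(do.call(rbind, lapply(ds, `[[`, "features")))
  labels <- unlist(lapply(ds, `[[`, "labels"))
  ch <- characterize(feats, labels)
  expect_true(all(ch$stats$fscore < 0.08))
})

test_that("holo-apo comparison: identical inputs give zero differences", {
  ds <- make_labeled_dataset(n_chains = 1, effect_size = 1.5, seed = 23)
  topo <- as.data.frame(ds[[1]]$features)
  sm <- topology_group_summary(topo, ds[[1]]$labels, id = "toy")
  cmp <- holo_apo_compare(sm, sm)
  expect_equal(cmp$differences$z_degree[1], cmp$differences$z_degree[2])
  expect_equal(nrow(cmp$table), 4)
  # difference column is exactly binding mean minus non-binding mean
  b <- sm[sm$group == "binding", ]
  nb <- sm[sm$group == "nonbinding", ]
  expect_equal(cmp$differences$z_betweenness[1],
               b$z_betweenness - nb$z_betweenness)
})
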