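# RBF-SVM training, chain-level cross-validation, evaluation metrics and
# feature-characterization statistics.

#' SVM model specification
#'
#' RBF kernel `K(x, y) = exp(-gamma * |x - y|^2)` with penalty `C = 2` and
#' `gamma = 0.03125` by default.
#'
#' @param cost Penalty parameter C (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param seed Seed for balanced sampling.
#' @return List of class `hemenet_model_spec`.
#' @export
model_spec <- function(cost = 2.0, gamma = 0.03125, seed = 1L) {
  stopifnot(cost > 0, gamma > 0)
  structure(list(cost = cost, gamma = gamma, seed = as.integer(seed)),
            class = "hemenet_model_spec")
}

#' Class-balanced training sample
#'
#' Keeps every binding index and draws, without replacement, an equal number
#' of non-binding indices; deterministic for a given seed. When fewer
#' non-binding than binding residues exist, all non-binding indices are used
#' with a warning.
#'
#' @param labels Character vector of `binding` / `nonbinding` (any
#'   `excluded` entries are never sampled).
#' @param seed Integer seed.
#' @return Sorted integer vector of selected indices.
#' @export
balanced_sample <- function(labels, seed = 1L) {
  pos <- which(labels == "binding")
  neg <- which(labels == "nonbinding")
  if (length(pos) == 0L) stop("no binding residues to sample", call. = FALSE)
  if (length(neg) < length(pos)) {
    warning(sprintf("only %d non-binding vs %d binding residues: using all",
                    length(neg), length(pos)))
    sel_neg <- neg
  } else {
    sel_neg <- with_seed(seed, sample(neg, length(pos)))
  }
  sort(c(pos, sel_neg))
}

#' Train the RBF-SVM classifier
#'
#' Trains a C-classification support vector machine (libsvm via e1071) with
#' the configured radial kernel on an assembled feature matrix. Features are
#' expected already scaled (see [assemble_matrix()]); no further scaling is
#' applied.
#'
#' @param x Numeric feature matrix.
#' @param y Labels (`binding` / `nonbinding`).
#' @param spec A [model_spec()].
#' @return List of class `hemenet_svm` with the fitted model, feature names
#'   and a layout hash checked at prediction time.
#' @export
train_svm <- function(x, y, spec = model_spec()) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("binding", "nonbinding"))
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = spec$cost, gamma = spec$gamma, scale = FALSE)
  structure(list(fit = fit, spec = spec,
                 feature_names = colnames(x),
                 layout_hash = layout_hash(colnames(x) %||% as.character(ncol(x)))),
            class = "hemenet_svm")
}

#' Predict binding scores and classes
#'
#' Continuous decision values are oriented so that larger means more likely
#' binding; the class call applies `score > threshold`.
#'
#' @param model A `hemenet_svm`.
#' @param x Feature matrix with the same column layout as at training.
#' @param threshold Decision threshold (default 0).
#' @return Data frame with `score` and `predicted`.
#' @export
predict_svm <- function(model, x, threshold = 0) {
  x <- as.matrix(x)
  h <- layout_hash(colnames(x) %||% as.character(ncol(x)))
  if (!identical(h, model$layout_hash)) {
    stop("feature layout of new data does not match the trained model",
         call. = FALSE)
  }
  pr <- stats::predict(model$fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm labels the decision column "lev1/lev2": positive favors lev1
  lev1 <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  score <- if (identical(lev1, "binding")) dv[, 1] else -dv[, 1]
  data.frame(score = as.numeric(score),
             predicted = ifelse(score > threshold, "binding", "nonbinding"),
             stringsAsFactors = FALSE)
}

#' Chain-level k-fold partition
#'
#' Chains are shuffled once (deterministically per seed) and dealt into `k`
#' near-equal folds, so no residue of one chain ever appears in two folds.
#'
#' @param chain_ids Character/integer vector of chain identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` lists with `train` and `test` chain ids.
#' @export
chain_kfold <- function(chain_ids, k = 5L, seed = 1L) {
  n <- length(chain_ids)
  if (n < k) stop(sprintf("%d chains cannot form %d folds", n, k),
                  call. = FALSE)
  shuffled <- with_seed(seed, sample(chain_ids))
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    list(train = shuffled[fold_of != f], test = shuffled[fold_of == f])
  })
}

#' Confusion-matrix metrics
#'
#' Recall, precision, accuracy, F1 and the Matthews correlation coefficient
#' from raw counts; any 0/0 is defined as 0.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Named list with the counts and the five metrics.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  sdiv <- function(num, den) if (den == 0) 0 else num / den
  recall <- sdiv(tp, tp + fn)
  precision <- sdiv(tp, tp + fp)
  accuracy <- (tp + tn) / (tp + fp + tn + fn)
  f1 <- sdiv(2 * precision * recall, precision + recall)
  mcc_den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       recall = recall, precision = precision, accuracy = accuracy,
       f1 = f1, mcc = mcc)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique continuous scores (ties
#' grouped), tracing false positive rate against true positive rate from
#' (0, 0) to (1, 1); AUC by the trapezoidal rule.
#'
#' @param scores Continuous scores, larger = more binding-like.
#' @param labels Logical or `binding`/`nonbinding` vector.
#' @return List with `roc` (data frame fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "binding"
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0L || N == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(y)[grp_end] / P, 1)
  fpr <- c(0, cumsum(!y)[grp_end] / N, 1)
  keep <- !duplicated(cbind(fpr, tpr))
  roc <- data.frame(fpr = fpr[keep], tpr = tpr[keep])
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Discriminatory F-score of a feature
#'
#' `F = |mean_pos - mean_neg| / (sd_pos + sd_neg)` with population standard
#' deviations: the separation of two group means relative to their spreads.
#'
#' @param group_pos,group_neg Numeric values of the binding and non-binding
#'   groups.
#' @return Single non-negative number (`Inf`, with a warning, when both
#'   groups are constant at different means).
#' @export
feature_fscore <- function(group_pos, group_neg) {
  stopifnot(length(group_pos) >= 1, length(group_neg) >= 1)
  fscore_from_stats(mean(group_pos), pop_sd(group_pos),
                    mean(group_neg), pop_sd(group_neg))
}

#' F-score from group summary statistics
#'
#' Same statistic as [feature_fscore()] computed directly from group means
#' and standard deviations, e.g. when only published summaries are
#' available.
#'
#' @param mean_pos,sd_pos Binding-group mean and SD.
#' @param mean_neg,sd_neg Non-binding-group mean and SD.
#' @return Non-negative number (vectorized over its arguments).
#' @export
fscore_from_stats <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  den <- sd_pos + sd_neg
  num <- abs(mean_pos - mean_neg)
  out <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  if (any(is.infinite(out))) {
    warning("both groups constant with different means: F-score infinite")
  }
  out
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test for a feature difference between
#' groups; switch `var_equal = TRUE` for the pooled variant.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param var_equal Use pooled variance.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
two_sample_ttest <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1, df = NA))
    stop("both groups have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided paired signed-rank test; zero differences are dropped first and
#' the normal approximation is used for more than 25 informative pairs.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return List with `statistic`, `p_value`, `n` (informative pairs).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  keep <- d != 0
  n <- sum(keep)
  if (n == 0L) stop("all paired differences are zero", call. = FALSE)
  if (n < 6L) stop("fewer than 6 non-zero differences", call. = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(a[keep], b[keep], paired = TRUE,
                       exact = n <= 25, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n)
}

#' Characterize features across binding and non-binding residues
#'
#' Per feature: group means and population SDs, discriminatory F-score and
#' Welch t-test p-value; for the standardized topology features, the
#' fraction of each class in the high / medium / low z-score sections; and
#' per-residue-type class means of the topology features (cells with no
#' residues of a type in a class are `NA`, not 0).
#'
#' @param features Data frame of numeric per-residue feature columns.
#' @param labels Character vector (`binding`/`nonbinding`/`excluded`)
#'   aligned with rows; excluded rows are dropped.
#' @param res_types Optional residue-type vector aligned with rows.
#' @param section_features Columns to compute z-score sections for.
#' @return List of class `hemenet_characterization` with data frames
#'   `stats`, `sections`, `type_means`.
#' @export
characterize <- function(features, labels, res_types = NULL,
                         section_features = intersect(TOPOLOGY_FEATURES,
                                                      names(features))) {
  keep <- labels != "excluded"
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  if (!is.null(res_types)) res_types <- res_types[keep]
  if (length(unique(labels)) < 2L) {
    stop("characterization needs both binding and non-binding residues",
         call. = FALSE)
  }
  pos <- labels == "binding"
  stats_df <- do.call(rbind, lapply(names(features), function(f) {
    vp <- features[[f]][pos]
    vn <- features[[f]][!pos]
    p <- if (length(vp) >= 2 && length(vn) >= 2) {
      two_sample_ttest(vp, vn)$p_value
    } else {
      NA_real_  # too few residues in a group for a t-test
    }
    data.frame(feature = f,
               mean_binding = mean(vp), sd_binding = pop_sd(vp),
               mean_nonbinding = mean(vn), sd_nonbinding = pop_sd(vn),
               fscore = feature_fscore(vp, vn),
               p_value = p,
               stringsAsFactors = FALSE)
  }))
  sections <- NULL
  if (length(section_features)) {
    sections <- do.call(rbind, lapply(section_features, function(f) {
      do.call(rbind, lapply(c("binding", "nonbinding"), function(g) {
        sec <- zscore_section(features[[f]][labels == g])
        data.frame(feature = f, group = g,
                   high = mean(sec == "high"),
                   medium = mean(sec == "medium"),
                   low = mean(sec == "low"),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  type_means <- NULL
  if (!is.null(res_types)) {
    feats <- section_features
    combos <- expand.grid(res_type = sort(unique(res_types)),
                          group = c("binding", "nonbinding"),
                          stringsAsFactors = FALSE)
    type_means <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      sel <- res_types == combos$res_type[i] & labels == combos$group[i]
      row <- combos[i, , drop = FALSE]
      row$n <- sum(sel)
      for (f in feats) {
        row[[f]] <- if (any(sel)) mean(features[[f]][sel]) else NA_real_
      }
      row
    }))
    rownames(type_means) <- NULL
  }
  structure(list(stats = stats_df, sections = sections,
                 type_means = type_means),
            class = "hemenet_characterization")
}

#' Per-structure topology summary by label group
#'
#' Binding and non-binding residue counts and group means of the four
#' topology z-scores for one structure.
#'
#' @param topo Data frame from [topology_features()].
#' @param labels Label vector aligned with `topo` rows.
#' @param id Structure/chain identifier for the output.
#' @return Data frame with rows `binding` and `nonbinding`.
#' @export
topology_group_summary <- function(topo, labels, id = "structure") {
  do.call(rbind, lapply(c("binding", "nonbinding"), function(g) {
    sel <- labels == g
    out <- data.frame(id = id, group = g, n = sum(sel),
                      stringsAsFactors = FALSE)
    for (f in TOPOLOGY_FEATURES) {
      out[[f]] <- if (any(sel)) mean(topo[[f]][sel]) else NA_real_
    }
    out
  }))
}

#' Compare a holo-apo structure pair
#'
#' Combines the per-group topology summaries of a ligand-bound (holo) and
#' ligand-free (apo) form computed under identical configuration, and
#' reports per form the binding-minus-non-binding difference of each mean
#' topology z-score.
#'
#' @param holo,apo Data frames from [topology_group_summary()].
#' @return List of class `hemenet_holoapo` with `table` (both forms'
#'   group rows) and `differences` (one row per form: binding minus
#'   non-binding mean per feature).
#' @export
holo_apo_compare <- function(holo, apo) {
  holo$form <- "holo"
  apo$form <- "apo"
  tab <- rbind(holo, apo)
  differences <- do.call(rbind, lapply(list(holo, apo), function(x) {
    b <- x[x$group == "binding", ]
    nb <- x[x$group == "nonbinding", ]
    out <- data.frame(form = x$form[1], id = x$id[1],
                      stringsAsFactors = FALSE)
    for (f in TOPOLOGY_FEATURES) out[[f]] <- b[[f]] - nb[[f]]
    out
  }))
  structure(list(table = tab, differences = differences),
            class = "hemenet_holoapo")
}
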