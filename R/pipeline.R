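# High-level pipeline entry points: the operations the command-line
# wrapper (inst/cli/hemenet.R) exposes as subcommands.

#' Compute every per-residue feature for one chain
#'
#' Builds the residue interaction network, the four standardized topology
#' features, the surface profile, binding labels against any heme groups in
#' the structure, the spatial windows and the assembled feature matrix for
#' the surface (non-excluded) residues.
#'
#' @param s A `hemenet_structure`.
#' @param chain Chain identifier.
#' @param pssm Optional `hemenet_pssm` (required when "C" is in the mask).
#' @param config A [hemenet_config()].
#' @return List of class `hemenet_features`: residues, network, topology
#'   table, surface profile, labels, windows, `matrix` (surface rows only)
#'   and `surface_index` (residue indices of the matrix rows).
#' @export
chain_features <- function(s, chain, pssm = NULL,
                           config = hemenet_config()) {
  residues <- protein_residues(s, chain)
  if (!is.null(pssm)) {
    if (nchar(pssm$sequence) != length(residues)) {
      stop(sprintf("PSSM length %d does not match chain length %d",
                   nchar(pssm$sequence), length(residues)), call. = FALSE)
    }
  } else if ("C" %in% config$mask) {
    stop("feature mask includes conservation (C) but no PSSM was given",
         call. = FALSE)
  }
  net <- build_network(residues, cutoff = config$contact_cutoff)
  topo <- topology_features(net)
  surf <- surface_profile(residues, config)
  hemes <- extract_heme_groups(s, config$heme_codes)
  labels <- label_residues(residues, surf$asa, hemes,
                           cutoff = config$ligand_cutoff,
                           asa_epsilon = config$asa_epsilon)
  anchors <- t(vapply(residues, residue_anchor, numeric(3)))
  windows <- lapply(seq_along(residues), function(i) {
    spatial_window(residues, i, k = config$window_neighbors,
                   anchors = anchors)
  })
  surface_index <- which(labels != "excluded")
  mat <- assemble_matrix(windows[surface_index], topo = topo,
                         surface = surf, pssm = pssm, mask = config$mask,
                         window_size = config$window_neighbors + 1L)
  rownames(mat) <- topo$id[surface_index]
  structure(list(id = paste0(s$id, ":", chain), residues = residues,
                 network = net, topology = topo, surface = surf,
                 labels = labels, windows = windows, matrix = mat,
                 surface_index = surface_index, config = config),
            class = "hemenet_features")
}

#' @export
print.hemenet_features <- function(x, ...) {
  cat(sprintf(paste0("<hemenet_features %s: %d residues, %d surface",
                     " (%d binding), matrix %d x %d>\n"),
              x$id, length(x$residues), length(x$surface_index),
              sum(x$labels == "binding"), nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Run feature extraction for a PDB file and write TSV outputs
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier.
#' @param pssm_path Optional PSI-BLAST ASCII PSSM path.
#' @param config A [hemenet_config()].
#' @param out_dir Optional directory; when given, writes `residues.tsv`
#'   (per-residue features and labels), `network_edges.tsv` and
#'   `features.tsv` (the windowed matrix).
#' @return The `hemenet_features` object, invisibly when writing.
#' @export
run_features <- function(pdb_path, chain, pssm_path = NULL,
                         config = hemenet_config(), out_dir = NULL) {
  s <- read_structure(pdb_path)
  pssm <- if (!is.null(pssm_path)) parse_pssm_ascii(pssm_path) else NULL
  fx <- chain_features(s, chain, pssm = pssm, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    res_tbl <- cbind(fx$topology,
                     fx$surface[, setdiff(names(fx$surface), c("id", "res_type")),
                                drop = FALSE],
                     label = as.character(fx$labels))
    utils::write.table(res_tbl, file.path(out_dir, "residues.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(network_edges(fx$network),
                       file.path(out_dir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mat <- data.frame(id = rownames(fx$matrix), fx$matrix,
                      check.names = FALSE)
    utils::write.table(mat, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(fx))
  }
  fx
}

#' Train a predictor on one or more feature sets
#'
#' Pools the surface-residue feature rows of the supplied
#' `hemenet_features` objects, draws a class-balanced training sample and
#' fits the RBF-SVM.
#'
#' @param feature_sets List of `hemenet_features` (or a single one).
#' @param config A [hemenet_config()] (SVM cost/gamma/seed are used).
#' @return A `hemenet_svm`.
#' @export
run_train <- function(feature_sets, config = hemenet_config()) {
  if (inherits(feature_sets, "hemenet_features")) {
    feature_sets <- list(feature_sets)
  }
  x <- do.call(rbind, lapply(feature_sets, `[[`, "matrix"))
  y <- unlist(lapply(feature_sets, function(f) {
    as.character(f$labels[f$surface_index])
  }))
  sel <- balanced_sample(y, seed = config$seed)
  train_svm(x[sel, , drop = FALSE], y[sel],
            spec = model_spec(cost = config$svm_cost,
                              gamma = config$svm_gamma,
                              seed = config$seed))
}

#' Predict binding residues for a feature set
#'
#' @param model A `hemenet_svm`.
#' @param features A `hemenet_features`.
#' @param threshold Decision threshold.
#' @return Data frame: id, label (true), score, predicted.
#' @export
run_predict <- function(model, features, threshold = 0) {
  pr <- predict_svm(model, features$matrix, threshold = threshold)
  data.frame(id = rownames(features$matrix),
             label = as.character(features$labels[features$surface_index]),
             score = pr$score, predicted = pr$predicted,
             stringsAsFactors = FALSE)
}

#' Chain-level k-fold cross-validation
#'
#' Partitions chains (never residues) into folds; in each fold, trains the
#' RBF-SVM on a class-balanced sample of the training chains' surface
#' residues and scores the held-out chains. Predictions are pooled into one
#' confusion matrix and ROC curve.
#'
#' @param chains List of chains: either `hemenet_features` objects or lists
#'   with `features` (matrix) and `labels` as produced by
#'   [make_labeled_dataset()].
#' @param k Number of folds.
#' @param config A [hemenet_config()].
#' @param scale Logistic-scale raw feature matrices (for matrices not built
#'   by [assemble_matrix()], which already scales).
#' @param threshold Decision threshold for class calls.
#' @return List of class `hemenet_eval`: counts + metrics (see
#'   [confusion_metrics()]), `roc`, `auc`, `folds`, and pooled
#'   `predictions`.
#' @export
run_crossval <- function(chains, k = 5L, config = hemenet_config(),
                         scale = FALSE, threshold = 0) {
  std <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    if (inherits(ch, "hemenet_features")) {
      list(id = ch$id, x = ch$matrix,
           y = as.character(ch$labels[ch$surface_index]))
    } else {
      x <- as.matrix(ch$features)
      if (scale) x <- logistic_scale(x)
      list(id = ch$id %||% paste0("chain", i), x = x,
           y = as.character(ch$labels))
    }
  })
  ids <- vapply(std, `[[`, "", "id")
  folds <- chain_kfold(ids, k = k, seed = config$seed)
  spec <- model_spec(cost = config$svm_cost, gamma = config$svm_gamma,
                     seed = config$seed)
  preds <- list()
  for (f in seq_along(folds)) {
    tr <- std[ids %in% folds[[f]]$train]
    te <- std[ids %in% folds[[f]]$test]
    xtr <- do.call(rbind, lapply(tr, `[[`, "x"))
    ytr <- unlist(lapply(tr, `[[`, "y"))
    sel <- balanced_sample(ytr, seed = config$seed + f)
    model <- train_svm(xtr[sel, , drop = FALSE], ytr[sel], spec = spec)
    for (ch in te) {
      pr <- predict_svm(model, ch$x, threshold = threshold)
      preds[[length(preds) + 1L]] <-
        data.frame(chain = ch$id, fold = f, label = ch$y,
                   score = pr$score, predicted = pr$predicted,
                   stringsAsFactors = FALSE)
    }
  }
  preds <- do.call(rbind, preds)
  tp <- sum(preds$predicted == "binding" & preds$label == "binding")
  fp <- sum(preds$predicted == "binding" & preds$label == "nonbinding")
  tn <- sum(preds$predicted == "nonbinding" & preds$label == "nonbinding")
  fn <- sum(preds$predicted == "nonbinding" & preds$label == "binding")
  metrics <- confusion_metrics(tp, fp, tn, fn)
  ra <- roc_auc(preds$score, preds$label)
  structure(c(metrics, list(roc = ra$roc, auc = ra$auc, folds = folds,
                            predictions = preds)),
            class = "hemenet_eval")
}

#' @export
print.hemenet_eval <- function(x, ...) {
  cat(sprintf(paste0("<hemenet_eval: recall %.3f, precision %.3f, accuracy",
                     " %.3f, F1 %.3f, MCC %.3f, AUC %.3f>\n"),
              x$recall, x$precision, x$accuracy, x$f1, x$mcc, x$auc))
  invisible(x)
}

#' Characterize a feature set's residues
#'
#' Runs [characterize()] on the per-residue topology z-scores (plus RASA,
#' depth and protrusion means when available) of one or more feature sets.
#'
#' @param feature_sets List of `hemenet_features` (or one).
#' @return A `hemenet_characterization`.
#' @export
run_characterize <- function(feature_sets) {
  if (inherits(feature_sets, "hemenet_features")) {
    feature_sets <- list(feature_sets)
  }
  df <- do.call(rbind, lapply(feature_sets, function(f) {
    cbind(f$topology[, c("res_type", TOPOLOGY_FEATURES)],
          rasa = f$surface$rasa,
          dpx_mean_all = f$surface$dpx_mean_all,
          cx_mean_all = f$surface$cx_mean_all,
          label = as.character(f$labels))
  }))
  characterize(df[, setdiff(names(df), c("res_type", "label"))],
               df$label, res_types = df$res_type)
}

#' Holo-apo topology comparison for a structure pair
#'
#' Computes the per-group topology summaries of a holo and an apo feature
#' set (optionally importing the holo binding labels into the apo chain via
#' a label table) and tabulates the binding/non-binding differences.
#'
#' @param holo,apo `hemenet_features` objects computed under the same
#'   configuration.
#' @param apo_labels Optional data frame (chain_id, seq_num, icode, label)
#'   overriding the apo labels, e.g. binding sites mapped from the holo
#'   form.
#' @return A `hemenet_holoapo`.
#' @export
run_compare <- function(holo, apo, apo_labels = NULL) {
  apo_lab <- apo$labels
  if (!is.null(apo_labels)) {
    apo_lab <- import_labels(apo_lab, apo$residues, apo_labels)
  }
  hs <- topology_group_summary(holo$topology, holo$labels, id = holo$id)
  as_ <- topology_group_summary(apo$topology, apo_lab, id = apo$id)
  holo_apo_compare(hs, as_)
}

#' Save / load a trained model archive
#'
#' The archive stores the fitted SVM, its parameters and the feature-layout
#' hash; loading a model checks the package version it was written with.
#'
#' @param model A `hemenet_svm`.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  obj <- list(version = as.character(utils::packageVersion("hemenet")),
              model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `hemenet_svm`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj$model, "hemenet_svm")) {
    stop("not a hemenet model archive: ", path, call. = FALSE)
  }
  obj$model
}

#' Published benchmark summary statistics for heme-binding characterization
#'
#' Reference group statistics reported in the literature for per-structure
#' standardized topology features over a benchmark of 141 heme protein
#' chains (5035 binding and 29234 non-binding surface residues): group
#' means and standard deviations of the binding and non-binding classes for
#' degree, closeness, betweenness and clustering coefficient.
#'
#' @return Data frame: feature, mean_binding, sd_binding, mean_nonbinding,
#'   sd_nonbinding, plus attributes `n_binding`, `n_nonbinding`, `n_chains`.
#' @export
reference_feature_stats <- function() {
  out <- data.frame(
    feature = c("degree", "closeness", "betweenness", "clustering"),
    mean_binding = c(0.27, 0.59, 0.67, -0.41),
    sd_binding = c(0.92, 1.01, 1.30, 0.81),
    mean_nonbinding = c(-0.17, -0.18, -0.16, 0.14),
    sd_nonbinding = c(0.96, 0.95, 0.88, 1.03),
    stringsAsFactors = FALSE
  )
  attr(out, "n_binding") <- 5035L
  attr(out, "n_nonbinding") <- 29234L
  attr(out, "n_chains") <- 141L
  out
}
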