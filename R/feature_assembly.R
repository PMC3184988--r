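# PSSM parsing, binding/non-binding labeling, spatial windows and the
# assembled, logistic-scaled feature matrix.

#' Amino-acid column order of PSI-BLAST PSSM files
#' @keywords internal
PSSM_COLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Names of the per-residue feature blocks, in assembly order.
TOPOLOGY_FEATURES <- c("z_degree", "z_closeness", "z_betweenness",
                       "z_clustering")
GEOMETRY_FEATURES <- c("rasa",
                       paste0("dpx_", c("mean_all", "sd_all", "mean_sc",
                                        "sd_sc", "min_all", "max_all")),
                       paste0("cx_", c("mean_all", "sd_all", "mean_sc",
                                       "sd_sc", "min_all", "max_all")))
CONSERVATION_FEATURES <- paste0("pssm_", PSSM_COLS)

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the checkpoint matrix written by PSI-BLAST's `-Q` option: one row
#' per sequence position with the residue letter followed by 20 integer
#' log-odds scores (the trailing 20 weighted-percentage columns and summary
#' columns are ignored). The diagonal conservation score of a position is
#' the log-odds of its own residue type.
#'
#' @param text File content as a single string or character vector of lines,
#'   or a path to an existing file.
#' @return List of class `hemenet_pssm`: `sequence` (1-letter string),
#'   `scores` (L x 20 integer matrix, columns in PSI-BLAST order),
#'   `diagonal` (per-position conservation score).
#' @export
parse_pssm_ascii <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(text)
  }
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_row <- vapply(toks, function(t) {
    length(t) >= 2 && grepl("^[0-9]+$", t[1]) && grepl("^[A-Za-z]$", t[2])
  }, logical(1))
  rows <- which(is_row)
  if (!length(rows)) stop("no PSSM data rows found", call. = FALSE)
  seq_chars <- character(length(rows))
  scores <- matrix(NA_integer_, length(rows), 20,
                   dimnames = list(NULL, PSSM_COLS))
  for (k in seq_along(rows)) {
    t <- toks[[rows[k]]]
    if (length(t) < 22) {
      stop(sprintf("truncated PSSM row at line %d: %d columns, expected >= 22",
                   rows[k], length(t)), call. = FALSE)
    }
    v <- suppressWarnings(as.integer(t[3:22]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric log-odds value in PSSM row at line %d",
                   rows[k]), call. = FALSE)
    }
    seq_chars[k] <- toupper(t[2])
    scores[k, ] <- v
  }
  diag_idx <- match(seq_chars, PSSM_COLS)
  diagonal <- ifelse(is.na(diag_idx), NA_integer_,
                     scores[cbind(seq_len(nrow(scores)), diag_idx)])
  structure(list(sequence = paste(seq_chars, collapse = ""),
                 scores = scores, diagonal = diagonal),
            class = "hemenet_pssm")
}

#' Label residues as binding / non-binding / excluded
#'
#' Residues with zero accessible surface area are excluded (buried residues
#' rarely contact the ligand and would bias the non-binding group). The
#' remaining surface residues are binding when any of their heavy atoms lies
#' within `cutoff` of any heavy atom of any heme group, non-binding
#' otherwise. Apo structures (no heme groups) get all surface residues
#' non-binding; import true labels with [import_labels()] when a holo
#' partner defines them.
#'
#' @param residues Residue list.
#' @param res_asa Per-residue ASA values aligned with `residues`.
#' @param hemes Heme group list from [extract_heme_groups()] (may be empty).
#' @param cutoff Ligand contact cutoff in Angstrom (default 4.5).
#' @param asa_epsilon Buried threshold: excluded when `ASA <= asa_epsilon`.
#' @return Character vector in `{binding, nonbinding, excluded}` aligned
#'   with `residues`, with attribute `ligand_cutoff`.
#' @export
label_residues <- function(residues, res_asa, hemes, cutoff = 4.5,
                           asa_epsilon = 0) {
  stopifnot(cutoff > 0, length(res_asa) == length(residues))
  heme_coords <- if (length(hemes)) {
    do.call(rbind, lapply(hemes, function(h) {
      cbind(h$atoms$x, h$atoms$y, h$atoms$z)
    }))
  } else {
    NULL
  }
  labels <- vapply(seq_along(residues), function(i) {
    if (res_asa[i] <= asa_epsilon) return("excluded")
    if (is.null(heme_coords)) return("nonbinding")
    rc <- residue_heavy_coords(residues[[i]])
    if (min_cross_dist(rc, heme_coords) <= cutoff) "binding" else "nonbinding"
  }, character(1))
  names(labels) <- vapply(residues, residue_id, "")
  attr(labels, "ligand_cutoff") <- cutoff
  labels
}

#' Override labels from an external table
#'
#' Applies labels from a table keyed by (chain_id, seq_num, icode), e.g. apo
#' chains labeled from their holo partner. Keys that match no residue are
#' reported; more than 10 percent unmatched keys is an error.
#'
#' @param labels Label vector from [label_residues()].
#' @param residues Residue list the labels refer to.
#' @param table Data frame with columns chain_id, seq_num, icode, label.
#' @return Updated label vector; unmatched keys in attribute `unmatched`.
#' @export
import_labels <- function(labels, residues, table) {
  if (nrow(table) == 0L) {
    attr(labels, "unmatched") <- table[0, , drop = FALSE]
    return(labels)
  }
  stopifnot(all(c("chain_id", "seq_num", "icode", "label") %in% names(table)))
  res_key <- vapply(residues, function(r) {
    paste(r$chain_id, r$seq_num, r$icode, sep = "\r")
  }, "")
  tab_key <- paste(table$chain_id, table$seq_num,
                   ifelse(is.na(table$icode), "", table$icode), sep = "\r")
  pos <- match(tab_key, res_key)
  unmatched <- table[is.na(pos), , drop = FALSE]
  if (nrow(unmatched) / nrow(table) > 0.1) {
    stop(sprintf("%d of %d label keys match no residue",
                 nrow(unmatched), nrow(table)), call. = FALSE)
  }
  ok <- !is.na(pos)
  labels[pos[ok]] <- table$label[ok]
  attr(labels, "unmatched") <- unmatched
  labels
}

residue_anchor <- function(res) {
  at <- res$atoms[res$atoms$is_heavy, , drop = FALSE]
  ca <- at[at$name == "CA", , drop = FALSE]
  if (nrow(ca) >= 1L) {
    c(ca$x[1], ca$y[1], ca$z[1])
  } else {
    warning(sprintf("residue %s lacks CA; using heavy-atom centroid",
                    residue_id(res)))
    c(mean(at$x), mean(at$y), mean(at$z))
  }
}

#' Spatial window around a target residue
#'
#' The window holds the target residue first, followed by its `k` spatially
#' nearest residues by C-alpha distance (heavy-atom centroid for residues
#' without a C-alpha), in increasing distance, ties broken by sequence
#' order. All residues of the chain are eligible as context, buried ones
#' included. Chains shorter than `k + 1` give a short window with the
#' shortfall recorded as `padding`.
#'
#' @param residues Residue list of the chain.
#' @param target Index of the target residue in `residues`.
#' @param k Number of neighbors (default 14).
#' @param anchors Optional precomputed anchor matrix (n x 3) to avoid
#'   recomputation across targets.
#' @return List with `indices` (target first), `target`, `padding`.
#' @export
spatial_window <- function(residues, target, k = 14L, anchors = NULL) {
  stopifnot(k >= 0, target >= 1, target <= length(residues))
  if (is.null(anchors)) {
    anchors <- t(vapply(residues, residue_anchor, numeric(3)))
  }
  d <- dist_to_point(anchors, anchors[target, ])
  ord <- order(d, seq_along(residues))
  ord <- ord[ord != target]
  nb <- ord[seq_len(min(k, length(ord)))]
  list(indices = c(target, nb), target = target,
       padding = max(0L, k - length(nb)))
}

#' Standard logistic squashing
#'
#' `1 / (1 + exp(-x))`, the scaling applied to every assembled feature
#' except RASA (already a fraction in `[0, 1]`).
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
logistic_scale <- function(x) 1 / (1 + exp(-x))

#' Inverse logistic
#' @param p Values in (0, 1).
#' @return Real values.
#' @export
inv_logistic <- function(p) log(p / (1 - p))

block_features <- function(mask) {
  f <- character(0)
  if ("N" %in% mask) f <- c(f, TOPOLOGY_FEATURES)
  if ("G" %in% mask) f <- c(f, GEOMETRY_FEATURES)
  if ("C" %in% mask) f <- c(f, CONSERVATION_FEATURES)
  f
}

#' Assemble the windowed feature matrix
#'
#' One row per requested window; per window residue, the enabled feature
#' blocks are concatenated in the fixed order topology z-scores (4), RASA
#' (1), DPX statistics (6), CX statistics (6), PSSM row (20). Every feature
#' is squashed to (0, 1) with the logistic function except RASA, which is
#' used as-is. Padded window slots are filled with exact zeros (out of range
#' for logistic-scaled features, so padding stays distinguishable).
#'
#' @param windows List of windows from [spatial_window()].
#' @param topo Data frame with the four topology z-score columns, one row
#'   per chain residue (needed when "N" is in `mask`).
#' @param surface Data frame from [surface_profile()] (needed for "G").
#' @param pssm A `hemenet_pssm` aligned with the chain (needed for "C").
#' @param mask Character subset of c("N", "G", "C").
#' @param window_size Total window slots (target + neighbors).
#' @return Numeric matrix with named columns `w<slot>_<feature>`; attribute
#'   `layout_hash` identifies the column layout.
#' @export
assemble_matrix <- function(windows, topo = NULL, surface = NULL,
                            pssm = NULL, mask = c("N", "G", "C"),
                            window_size = 15L) {
  mask <- match.arg(mask, c("N", "G", "C"), several.ok = TRUE)
  n_res <- max(vapply(windows, function(w) max(w$indices), integer(1)))
  per_res <- NULL
  if ("N" %in% mask) {
    if (is.null(topo)) stop("mask includes N but no topology table given",
                            call. = FALSE)
    stopifnot(all(TOPOLOGY_FEATURES %in% names(topo)))
    per_res <- cbind(per_res,
                     logistic_scale(as.matrix(topo[, TOPOLOGY_FEATURES])))
  }
  if ("G" %in% mask) {
    if (is.null(surface)) stop("mask includes G but no surface profile given",
                               call. = FALSE)
    stopifnot(all(GEOMETRY_FEATURES[-1] %in% names(surface)))
    g <- cbind(surface$rasa,
               logistic_scale(as.matrix(surface[, GEOMETRY_FEATURES[-1]])))
    colnames(g) <- GEOMETRY_FEATURES
    per_res <- cbind(per_res, g)
  }
  if ("C" %in% mask) {
    if (is.null(pssm)) {
      stop("mask includes C but no PSSM given", call. = FALSE)
    }
    if (nrow(pssm$scores) != n_res) {
      stop(sprintf("PSSM has %d positions but chain has %d residues",
                   nrow(pssm$scores), n_res), call. = FALSE)
    }
    p <- logistic_scale(pssm$scores)
    colnames(p) <- CONSERVATION_FEATURES
    per_res <- cbind(per_res, p)
  }
  feats <- block_features(mask)
  width <- length(feats)
  out <- matrix(0, length(windows), width * window_size)
  colnames(out) <- paste0("w", sprintf("%02d", rep(seq_len(window_size),
                                                   each = width)),
                          "_", rep(feats, window_size))
  for (r in seq_along(windows)) {
    idx <- windows[[r]]$indices
    for (slot in seq_along(idx)) {
      if (slot > window_size) break
      cols <- (slot - 1) * width + seq_len(width)
      out[r, cols] <- per_res[idx[slot], ]
    }
  }
  attr(out, "layout_hash") <- layout_hash(colnames(out))
  attr(out, "mask") <- mask
  out
}
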