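# Residue interaction network construction and node centralities.
#
# Nodes are the amino-acid residues of one chain; an edge joins residues i
# and j when any heavy-atom pair lies strictly below the contact cutoff
# (default 5 A, the approximate upper limit of attractive London-van der
# Waals forces). Degree, closeness, betweenness and clustering coefficient
# are computed on unit-length edges; closeness/betweenness shortest paths
# use breadth-first search (equivalent to Dijkstra on unit weights).

#' Build a residue interaction network
#'
#' Adjacency `a_ij = 1` iff the minimum Euclidean distance between any heavy
#' atom of residue i and any heavy atom of residue j is strictly less than
#' `cutoff`. Built over all residues supplied (buried residues included);
#' surface filtering belongs to labeling, not network construction.
#'
#' @param residues Ordered residue list (e.g. from [protein_residues()]).
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @return Object of class `hemenet_rin`: list with `nodes` (data frame: id,
#'   chain_id, seq_num, icode, res_name, res_type) and `adjacency` (symmetric
#'   0/1 integer matrix with zero diagonal).
#' @export
build_network <- function(residues, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  n_heavy <- vapply(residues, function(r) sum(r$atoms$is_heavy), integer(1))
  if (any(n_heavy == 0L)) {
    warning(sprintf("%d residue(s) with no heavy atoms excluded from network",
                    sum(n_heavy == 0L)))
    residues <- residues[n_heavy > 0L]
  }
  N <- length(residues)
  if (N < 1L) stop("network needs at least one residue with heavy atoms",
                   call. = FALSE)
  coords <- lapply(residues, residue_heavy_coords)
  cent <- t(vapply(coords, colMeans, numeric(3)))
  rad <- vapply(seq_len(N), function(i) {
    max(dist_to_point(coords[[i]], cent[i, ]))
  }, numeric(1))

  A <- matrix(0L, N, N)
  if (N >= 2L) {
    cd2 <- outer(rowSums(cent^2), rowSums(cent^2), "+") - 2 * tcrossprod(cent)
    cd <- sqrt(pmax(cd2, 0))
    # candidate pairs by bounding spheres
    lim <- outer(rad, rad, "+") + cutoff
    cand <- which(upper.tri(cd) & cd < lim, arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (min_cross_dist(coords[[i]], coords[[j]]) < cutoff) {
        A[i, j] <- 1L
        A[j, i] <- 1L
      }
    }
  }
  nodes <- data.frame(
    id = vapply(residues, residue_id, ""),
    chain_id = vapply(residues, `[[`, "", "chain_id"),
    seq_num = vapply(residues, `[[`, 0L, "seq_num"),
    icode = vapply(residues, `[[`, "", "icode"),
    res_name = vapply(residues, `[[`, "", "res_name"),
    res_type = vapply(residues, function(r) r$res_type %||% NA_character_, ""),
    stringsAsFactors = FALSE
  )
  dimnames(A) <- list(nodes$id, nodes$id)
  structure(list(nodes = nodes, adjacency = A), class = "hemenet_rin")
}

#' @export
print.hemenet_rin <- function(x, ...) {
  cat(sprintf("<hemenet_rin: %d nodes, %d edges>\n",
              nrow(x$nodes), sum(x$adjacency) / 2))
  invisible(x)
}

adjacency_list <- function(A) {
  lapply(seq_len(nrow(A)), function(i) which(A[i, ] != 0L))
}

bfs_distances <- function(nbrs, s, N) {
  d <- rep(-1L, N)
  d[s] <- 0L
  queue <- integer(N)
  queue[1] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in nbrs[[v]]) {
      if (d[w] < 0L) {
        d[w] <- d[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  d
}

#' Node degrees
#'
#' `k_i = sum_j a_ij`, the number of direct contacts of residue i.
#'
#' @param net A `hemenet_rin`.
#' @return Integer vector named by node id.
#' @export
degree_vector <- function(net) {
  k <- as.integer(rowSums(net$adjacency))
  names(k) <- net$nodes$id
  k
}

#' Closeness centrality
#'
#' Inverse of the average geodesic (shortest-path) distance from a node to
#' all others, on unit-length edges: `C_i = (N-1) / sum_j d_ij` for connected
#' graphs. Disconnected graphs use the Wasserman-Faust component correction
#' `C_i = ((n_c-1)/sum d) * ((n_c-1)/(N-1))` with `n_c` the size of i's
#' component, which reduces to the plain definition when the graph is
#' connected. Isolated nodes get 0.
#'
#' @param net A `hemenet_rin`.
#' @return Numeric vector named by node id.
#' @export
closeness_vector <- function(net) {
  A <- net$adjacency
  N <- nrow(A)
  out <- numeric(N)
  names(out) <- net$nodes$id
  if (N < 2L) {
    warning("closeness undefined for a single-node network; returning 0")
    return(out)
  }
  nbrs <- adjacency_list(A)
  for (i in seq_len(N)) {
    d <- bfs_distances(nbrs, i, N)
    reach <- d > 0L
    nc <- sum(reach) + 1L
    if (nc > 1L) {
      out[i] <- ((nc - 1) / sum(d[reach])) * ((nc - 1) / (N - 1))
    }
  }
  out
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between all residue pairs that pass through a
#' node, normalized by the number of pairs excluding that node,
#' `(N-1)(N-2)/2`. Computed with Brandes' dependency accumulation on
#' unit-length edges; pairs in different components contribute nothing.
#'
#' @param net A `hemenet_rin`.
#' @return Numeric vector in `[0, 1]`, named by node id.
#' @export
betweenness_vector <- function(net) {
  A <- net$adjacency
  N <- nrow(A)
  B <- numeric(N)
  names(B) <- net$nodes$id
  if (N < 3L) return(B)
  nbrs <- adjacency_list(A)
  for (s in seq_len(N)) {
    sigma <- numeric(N); sigma[s] <- 1
    d <- rep(-1L, N); d[s] <- 0L
    preds <- vector("list", N)
    queue <- integer(N); queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in nbrs[[v]]) {
        if (d[w] < 0L) {
          d[w] <- d[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (d[w] == d[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(N)
    for (idx in rev(seq_len(tail))) {
      w <- queue[idx]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) B[w] <- B[w] + delta[w]
    }
  }
  # Brandes counts ordered pairs: halve, then normalize.
  B / 2 / ((N - 1) * (N - 2) / 2)
}

#' Clustering coefficient
#'
#' Edges among a node's neighbors divided by the maximum possible,
#' `CC_i = e_i / (k_i (k_i - 1) / 2)`; defined 0 when `k_i < 2`.
#'
#' @param net A `hemenet_rin`.
#' @return Numeric vector in `[0, 1]`, named by node id.
#' @export
clustering_vector <- function(net) {
  A <- net$adjacency
  N <- nrow(A)
  cc <- numeric(N)
  names(cc) <- net$nodes$id
  for (i in seq_len(N)) {
    nb <- which(A[i, ] != 0L)
    k <- length(nb)
    if (k >= 2L) {
      e <- sum(A[nb, nb]) / 2
      cc[i] <- e / (k * (k - 1) / 2)
    }
  }
  cc
}

#' Per-structure z-score standardization
#'
#' `z_i = (V_i - mean(V)) / sd(V)` with the population standard deviation
#' taken over all residues of the structure (buried residues included), so
#' topological features are comparable across proteins. A constant vector
#' (sd 0) maps to all zeros.
#'
#' @param values Numeric vector of raw per-residue feature values.
#' @return List with `values` (input), `mean`, `sd` (population), `z`.
#' @export
standardize <- function(values) {
  stopifnot(length(values) >= 1L)
  m <- mean(values)
  s <- pop_sd(values)
  z <- if (s > 0) (values - m) / s else rep(0, length(values))
  names(z) <- names(values)
  list(values = values, mean = m, sd = s, z = z)
}

#' Z-score section label
#'
#' Classifies standardized feature values into high (`z >= 1`), medium
#' (`-1 <= z < 1`) and low (`z < -1`) sections.
#'
#' @param z Numeric vector of z-scores.
#' @return Character vector of labels in `{high, medium, low}`.
#' @export
zscore_section <- function(z) {
  ifelse(z >= 1, "high", ifelse(z >= -1, "medium", "low"))
}

#' All four topology features with z-scores for a network
#'
#' @param net A `hemenet_rin`.
#' @return Data frame: node columns plus degree, closeness, betweenness,
#'   clustering and their per-structure z-scores (z_degree, z_closeness,
#'   z_betweenness, z_clustering).
#' @export
topology_features <- function(net) {
  df <- net$nodes
  df$degree <- degree_vector(net)
  df$closeness <- closeness_vector(net)
  df$betweenness <- betweenness_vector(net)
  df$clustering <- clustering_vector(net)
  for (f in c("degree", "closeness", "betweenness", "clustering")) {
    df[[paste0("z_", f)]] <- standardize(df[[f]])$z
  }
  rownames(df) <- NULL
  df
}

#' Export a network as an edge-list table
#'
#' @param net A `hemenet_rin`.
#' @return Data frame with columns node_i, node_j (one row per edge).
#' @export
network_edges <- function(net) {
  A <- net$adjacency
  e <- which(upper.tri(A) & A != 0L, arr.ind = TRUE)
  data.frame(node_i = net$nodes$id[e[, 1]],
             node_j = net$nodes$id[e[, 2]],
             stringsAsFactors = FALSE)
}
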