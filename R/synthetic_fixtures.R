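# Synthetic structures, complexes, graphs, profiles and labeled datasets.
#
# Toy "residues" are single- or few-atom pseudo-glycines so contact
# geometry is fully controlled; the generators are deterministic per seed
# and serve as ground-truth substrates for every pipeline stage. The
# oracle implementations here deliberately share no code with the main
# graph routines.

toy_atom <- function(x, y, z, name = "CA", element = "C",
                     res_name = "GLY", chain = "A", seq_num = 1L,
                     record = "ATOM") {
  data.frame(record = record, serial = NA_integer_, name = name,
             altloc = "", res_name = res_name, chain_id = chain,
             seq_num = as.integer(seq_num), icode = "",
             x = x, y = y, z = z, occupancy = 1.0, element = element,
             is_heavy = !(element %in% c("H", "D")),
             stringsAsFactors = FALSE)
}

icosahedron_vertices <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, g), c(0, -1, g), c(0, 1, -g), c(0, -1, -g),
    c(1, g, 0), c(-1, g, 0), c(1, -g, 0), c(-1, -g, 0),
    c(g, 0, 1), c(-g, 0, 1), c(g, 0, -1), c(-g, 0, -1)
  )
  v / sqrt(1 + g^2)
}

#' Generate a toy single-chain structure
#'
#' Placement rules:
#' * `line`: one C-alpha per residue, `spacing` Angstrom apart along x, so a
#'   cutoff between `spacing` and `2 * spacing` yields a path contact graph.
#' * `helix`: ideal alpha-helical trace (2.3 A radius, 1.5 A rise, 100
#'   degrees per residue), optionally with N/C/O/CB pseudo-atoms for surface
#'   realism.
#' * `cage`: residue 1 at the origin enclosed by 12 single-atom residues on
#'   icosahedron vertices at `radius`, burying the central atom.
#' * `cloud`: uniformly random single-atom residues in a cube with a minimum
#'   separation constraint.
#'
#' @param n Residue count.
#' @param rule One of "line", "helix", "cage", "cloud".
#' @param spacing Line spacing in Angstrom.
#' @param radius Cage radius / cloud half-width in Angstrom.
#' @param min_sep Minimum inter-atom separation for "cloud".
#' @param jitter Gaussian coordinate noise SD in Angstrom.
#' @param full_backbone Add N, C, O, CB pseudo-atoms (helix rule).
#' @param seed Integer seed (same spec + seed gives identical coordinates).
#' @param chain_id Chain identifier.
#' @param res_name Residue name for the pseudo-residues.
#' @param id Structure id.
#' @return A `hemenet_structure`.
#' @export
make_chain <- function(n, rule = c("line", "helix", "cage", "cloud"),
                       spacing = 4.0, radius = 3.0, min_sep = 3.0,
                       jitter = 0.0, full_backbone = FALSE, seed = 1L,
                       chain_id = "A", res_name = "GLY", id = NULL) {
  rule <- match.arg(rule)
  stopifnot(n >= 1)
  rows <- switch(rule,
    line = lapply(seq_len(n), function(i) {
      toy_atom((i - 1) * spacing, 0, 0, chain = chain_id,
               res_name = res_name, seq_num = i)
    }),
    helix = lapply(seq_len(n), function(i) {
      a <- (i - 1) * 100 * pi / 180
      z <- (i - 1) * 1.5
      ca <- toy_atom(2.3 * cos(a), 2.3 * sin(a), z, chain = chain_id,
                     res_name = res_name, seq_num = i)
      if (!full_backbone) return(ca)
      rbind(
        toy_atom(1.6 * cos(a - 0.6), 1.6 * sin(a - 0.6), z - 0.6,
                 name = "N", element = "N", chain = chain_id,
                 res_name = res_name, seq_num = i),
        ca,
        toy_atom(1.8 * cos(a + 0.5), 1.8 * sin(a + 0.5), z + 0.7,
                 name = "C", element = "C", chain = chain_id,
                 res_name = res_name, seq_num = i),
        toy_atom(2.6 * cos(a + 0.8), 2.6 * sin(a + 0.8), z + 1.0,
                 name = "O", element = "O", chain = chain_id,
                 res_name = res_name, seq_num = i),
        toy_atom(3.8 * cos(a), 3.8 * sin(a), z,
                 name = "CB", element = "C", chain = chain_id,
                 res_name = res_name, seq_num = i)
      )
    }),
    cage = {
      if (n > 13) stop("cage rule supports at most 13 residues",
                       call. = FALSE)
      v <- icosahedron_vertices() * radius
      c(list(toy_atom(0, 0, 0, chain = chain_id, res_name = res_name,
                      seq_num = 1L)),
        lapply(seq_len(n - 1), function(i) {
          toy_atom(v[i, 1], v[i, 2], v[i, 3], chain = chain_id,
                   res_name = res_name, seq_num = i + 1L)
        }))
    },
    cloud = with_seed(seed, {
      pts <- matrix(NA_real_, n, 3)
      placed <- 0L
      tries <- 0L
      while (placed < n) {
        cand <- stats::runif(3, -radius, radius)
        ok <- placed == 0L ||
          min(dist_to_point(pts[seq_len(placed), , drop = FALSE], cand)) >= min_sep
        if (ok) {
          placed <- placed + 1L
          pts[placed, ] <- cand
        }
        tries <- tries + 1L
        if (tries > 2000L * n) {
          stop("cannot satisfy minimum separation in cloud placement",
               call. = FALSE)
        }
      }
      lapply(seq_len(n), function(i) {
        toy_atom(pts[i, 1], pts[i, 2], pts[i, 3], chain = chain_id,
                 res_name = res_name, seq_num = i)
      })
    })
  )
  atoms <- do.call(rbind, rows)
  if (jitter > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(seed + 1L, {
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(atoms), sd = jitter), ncol = 3)
    })
  }
  atoms[, c("x", "y", "z")] <- round(atoms[, c("x", "y", "z")], 3)
  rownames(atoms) <- NULL
  structure(list(id = id %||% paste0("toy_", rule, "_", n), atoms = atoms),
            class = "hemenet_structure")
}

#' Add ligand groups to a toy structure
#'
#' Appends one hetero residue per element of `ligands`; each ligand is a
#' data frame of atoms (columns x, y, z and optionally name, element,
#' res_name). Because the caller states the coordinates, ground-truth
#' binding labels are known by construction.
#'
#' @param s A `hemenet_structure`.
#' @param ligands List of ligand atom data frames.
#' @param res_name Default ligand residue name (default "HEM").
#' @return A `hemenet_structure` containing the protein plus ligands.
#' @export
make_complex <- function(s, ligands, res_name = "HEM") {
  start <- max(s$atoms$seq_num) + 1L
  lig_rows <- lapply(seq_along(ligands), function(k) {
    lg <- ligands[[k]]
    nm <- lg$name %||% paste0("L", seq_len(nrow(lg)))
    el <- lg$element %||% rep("FE", nrow(lg))
    rn <- lg$res_name %||% rep(res_name, nrow(lg))
    do.call(rbind, lapply(seq_len(nrow(lg)), function(i) {
      toy_atom(lg$x[i], lg$y[i], lg$z[i], name = nm[i], element = el[i],
               res_name = rn[i], chain = s$atoms$chain_id[1],
               seq_num = start + k - 1L, record = "HETATM")
    }))
  })
  atoms <- rbind(s$atoms, do.call(rbind, lig_rows))
  rownames(atoms) <- NULL
  structure(list(id = paste0(s$id, "_complex"), atoms = atoms),
            class = "hemenet_structure")
}

#' Random Erdos-Renyi network over pseudo-residues
#'
#' @param n Node count.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return A `hemenet_rin` with synthetic node ids R1..Rn.
#' @export
make_random_graph <- function(n, p, seed = 1L) {
  A <- matrix(0L, n, n)
  if (n >= 2) {
    up <- which(upper.tri(A))
    edges <- with_seed(seed, stats::runif(length(up)) < p)
    A[up[edges]] <- 1L
    A <- A + t(A)
  }
  ids <- paste0("R", seq_len(n))
  dimnames(A) <- list(ids, ids)
  nodes <- data.frame(id = ids, chain_id = "A", seq_num = seq_len(n),
                      icode = "", res_name = "GLY", res_type = "GLY",
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, adjacency = A), class = "hemenet_rin")
}

# ---- independent oracles (no shared code with the rin module) -------------

floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# Count all shortest j->k paths and how many pass through each interior
# node, by depth-first enumeration over the distance matrix.
enumerate_shortest_paths <- function(A, D, j, k) {
  n <- nrow(A)
  through <- numeric(n)
  total <- 0
  walk <- function(v, interior) {
    if (v == k) {
      total <<- total + 1
      through[interior] <<- through[interior] + 1
      return(invisible())
    }
    for (w in which(A[v, ] != 0)) {
      if (is.finite(D[w, k]) && D[w, k] == D[v, k] - 1) {
        walk(w, if (w == k) interior else c(interior, w))
      }
    }
  }
  if (is.finite(D[j, k]) && j != k) walk(j, integer(0))
  list(total = total, through = through)
}

#' Brute-force topology oracle
#'
#' Independent recomputation of the four node measures: degree by row sums,
#' closeness from Floyd-Warshall all-pairs distances (with the same
#' component correction as the main path), betweenness by exhaustive
#' shortest-path enumeration (feasible for small graphs), clustering from
#' the diagonal of A^3. Shares no code with the network module.
#'
#' @param net A `hemenet_rin`.
#' @param betweenness Also compute the (exponential-cost) betweenness
#'   enumeration; requires at most 10 nodes.
#' @return List with degree, closeness, clustering and (optionally)
#'   betweenness vectors.
#' @export
oracle_metrics <- function(net, betweenness = nrow(net$adjacency) <= 10) {
  A <- net$adjacency
  n <- nrow(A)
  if (n > 50) stop("oracle limited to 50 nodes", call. = FALSE)
  deg <- as.integer(rowSums(A != 0))
  D <- floyd_warshall(A)
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, ]
    reach <- is.finite(d) & d > 0
    nc <- sum(reach) + 1
    if (nc <= 1 || n < 2) return(0)
    ((nc - 1) / sum(d[reach])) * ((nc - 1) / (n - 1))
  }, numeric(1))
  A3 <- A %*% A %*% A
  cc <- vapply(seq_len(n), function(i) {
    k <- deg[i]
    if (k < 2) return(0)
    (diag(A3)[i] / 2) / (k * (k - 1) / 2)
  }, numeric(1))
  out <- list(degree = deg, closeness = clo, clustering = cc)
  if (betweenness) {
    if (n > 10) stop("exhaustive betweenness oracle limited to 10 nodes",
                     call. = FALSE)
    B <- numeric(n)
    if (n >= 3) {
      for (j in seq_len(n - 1)) {
        for (k in (j + 1):n) {
          pe <- enumerate_shortest_paths(A, D, j, k)
          if (pe$total > 0) B <- B + pe$through / pe$total
        }
      }
      B <- B / ((n - 1) * (n - 2) / 2)
    }
    out$betweenness <- B
  }
  out
}

#' Synthetic labeled per-chain feature sets
#'
#' Emulates the statistical structure of heme-binding characterization:
#' binding residues draw their standardized topology features from unit-SD
#' normals shifted by `+effect_size` (degree, closeness, betweenness) and
#' `-effect_size` (clustering coefficient); non-binding residues draw from
#' standard normals. Defaults mirror a realistic benchmark geometry: 240
#' surface residues per chain with a 14.7 percent binding rate.
#'
#' @param n_chains Number of synthetic chains.
#' @param effect_size Mean shift delta of the binding class.
#' @param seed Integer seed.
#' @param n_residues Residues per chain.
#' @param binding_rate Fraction of binding residues per chain.
#' @return List of chains; each has `id`, `features` (matrix with the four
#'   z-score columns) and `labels`.
#' @export
make_labeled_dataset <- function(n_chains = 10L, effect_size = 1.0,
                                 seed = 1L, n_residues = 240L,
                                 binding_rate = 0.147) {
  shifts <- c(z_degree = 1, z_closeness = 1, z_betweenness = 1,
              z_clustering = -1) * effect_size
  with_seed(seed, {
    lapply(seq_len(n_chains), function(ci) {
      n_bind <- max(1L, round(binding_rate * n_residues))
      labels <- c(rep("binding", n_bind),
                  rep("nonbinding", n_residues - n_bind))
      feats <- vapply(names(shifts), function(f) {
        mu <- ifelse(labels == "binding", shifts[[f]], 0)
        stats::rnorm(n_residues, mean = mu, sd = 1)
      }, numeric(n_residues))
      colnames(feats) <- names(shifts)
      list(id = paste0("chain", ci), features = feats, labels = labels)
    })
  })
}

#' Write a synthetic PSI-BLAST-style ASCII PSSM
#'
#' Generates an integer log-odds matrix for a sequence (elevated scores on
#' the diagonal of each position's own residue type) and renders it in the
#' PSI-BLAST `-Q` ASCII layout, including the 20 weighted-percentage
#' columns, so the parser sees the real row shape.
#'
#' @param sequence 1-letter amino-acid string.
#' @param seed Integer seed.
#' @param path Optional output file.
#' @return Character vector of file lines (invisibly when `path` given);
#'   attribute `scores` holds the generated matrix.
#' @export
make_pssm_fixture <- function(sequence, seed = 1L, path = NULL) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  scores <- with_seed(seed, {
    m <- matrix(sample(-5:4, L * 20, replace = TRUE), L, 20)
    for (i in seq_len(L)) {
      j <- match(chars[i], PSSM_COLS)
      if (!is.na(j)) m[i, j] <- sample(4:9, 1)
    }
    m
  })
  colnames(scores) <- PSSM_COLS
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", PSSM_COLS), collapse = ""),
           "  ", paste(sprintf("%3s", PSSM_COLS), collapse = ""))
  )
  body <- vapply(seq_len(L), function(i) {
    pct <- round(100 * exp(scores[i, ]) / sum(exp(scores[i, ])))
    paste0(sprintf("%5d %s ", i, chars[i]),
           paste(sprintf("%3d", scores[i, ]), collapse = ""), "  ",
           paste(sprintf("%3d", pct), collapse = ""),
           sprintf("  %4.2f %8.2f", 0.5, 1.0))
  }, character(1))
  lines <- c(header, body, "")
  attr(lines, "scores") <- scores
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
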